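#' Default continuous variable specifications for the simulated cohort
#'
#' One row per continuous variable: group-specific arithmetic mean and SD,
#' the sampling family, and the assay limit of detection where one applies.
#' The defaults describe a two-group cardiovascular screening cohort
#' (healthy controls vs post-myocardial-infarction cases): conjunctival
#' microvascular parameters, cardiac and inflammatory biomarkers, and age.
#' Right-skewed markers whose SD rivals or exceeds their mean (NT-proBNP,
#' C-reactive protein, H-FABP, interleukin-6) are sampled lognormally,
#' parameterised so the *arithmetic* mean and SD match the specification;
#' adiponectin is also lognormal so that it stays strictly positive for
#' log-transformation. All other variables are Gaussian.
#'
#' @return A tibble with columns `name`, `control_mean`, `control_sd`,
#'   `case_mean`, `case_sd`, `family` ("normal" or "lognormal"), `lod`
#'   (NA when no limit of detection applies) and `units`.
#' @export
default_variable_specs <- function() {
  tibble::tribble(
    ~name,          ~control_mean, ~control_sd, ~case_mean, ~case_sd, ~family,     ~lod,  ~units,
    "age",          52.50,         9.73,        56.73,      11.41,    "normal",    NA,    "years",
    "d_um",         21.45,         3.03,        22.79,      3.07,     "normal",    NA,    "um",
    "va_mm_s",      0.54,          0.05,        0.50,       0.06,     "normal",    NA,    "mm/s",
    "vs_mm_s",      0.38,          0.04,        0.35,       0.04,     "normal",    NA,    "mm/s",
    "q_pl_s",       159.66,        47.27,       161.00,     48.12,    "normal",    NA,    "pl/s",
    "wsr_per_s",    167.78,        34.37,       143.59,     28.56,    "normal",    NA,    "1/s",
    "nt_probnp",    74.70,         186.68,      1049.11,    1663.65,  "lognormal", NA,    "ng/l",
    "adiponectin",  11.15,         6.20,        8.58,       5.92,     "lognormal", 0.18,  "ug/ml",
    "hfabp",        3.62,          2.04,        13.75,      29.73,    "lognormal", 2.94,  "ng/ml",
    "crp",          3.24,          6.39,        20.96,      42.49,    "lognormal", NA,    "mg/l",
    "il6",          1.92,          2.36,        8.17,       16.77,    "lognormal", 0.12,  "pg/ml"
  )
}

#' Default binary variable specifications for the simulated cohort
#'
#' Per-group prevalences of the demographic / history traits the screening
#' analysis tabulates (male sex, smoking, hypertension, diabetes).
#'
#' @return A tibble with columns `name`, `control_proportion`,
#'   `case_proportion`.
#' @export
default_binary_specs <- function() {
  tibble::tribble(
    ~name,          ~control_proportion, ~case_proportion,
    "male",         45 / 66,             52 / 66,
    "smoking",      29 / 66,             43 / 66,
    "hypertension", 8 / 66,              31 / 66,
    "diabetes",     2 / 66,              15 / 66
  )
}

#' Configuration for the two-group cohort simulator
#'
#' @param n_control,n_case group sizes (>= 2). Defaults 66/66, the design
#'   the screening statistics are calibrated for.
#' @param variable_specs continuous variable table as returned by
#'   [default_variable_specs()].
#' @param binary_specs binary trait table as returned by
#'   [default_binary_specs()].
#' @param correlation single latent (Gaussian-copula) correlation applied
#'   exchangeably between all variables, in [-1, 1]. Default 0: no
#'   dependence structure is asserted between biomarkers and ocular
#'   parameters; the parameter is exposed so sensitivity to dependence can
#'   be explored.
#' @param seed integer seed.
#'
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_control = 66, n_case = 66,
                              variable_specs = default_variable_specs(),
                              binary_specs = default_binary_specs(),
                              correlation = 0,
                              seed = 1L) {
  variable_specs <- tibble::as_tibble(variable_specs)
  binary_specs <- tibble::as_tibble(binary_specs)
  if (n_control < 2 || n_case < 2) stop("need >= 2 subjects per group", call. = FALSE)
  if (nrow(variable_specs) > 0) {
    if (any(variable_specs$control_sd <= 0) || any(variable_specs$case_sd <= 0)) {
      stop("all SDs must be > 0", call. = FALSE)
    }
    bad <- setdiff(unique(variable_specs$family), c("normal", "lognormal"))
    if (length(bad)) stop("unknown family: ", paste(bad, collapse = ", "), call. = FALSE)
    if (any(variable_specs$family == "lognormal" &
            (variable_specs$control_mean <= 0 | variable_specs$case_mean <= 0))) {
      stop("lognormal variables need positive means", call. = FALSE)
    }
  }
  if (nrow(binary_specs) > 0 &&
      (any(binary_specs$control_proportion < 0 | binary_specs$control_proportion > 1) ||
       any(binary_specs$case_proportion < 0 | binary_specs$case_proportion > 1))) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  k <- nrow(variable_specs) + nrow(binary_specs)
  if (k >= 2) {
    R <- matrix(correlation, k, k); diag(R) <- 1
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop(sprintf(
        "correlation %.3f gives a non-positive-semi-definite latent matrix for %d variables",
        correlation, k
      ), call. = FALSE)
    }
  }
  structure(
    list(
      n_control = as.integer(n_control), n_case = as.integer(n_case),
      variable_specs = variable_specs, binary_specs = binary_specs,
      correlation = correlation, seed = as.integer(seed)
    ),
    class = "cohort_sim_config"
  )
}

# arithmetic mean m, sd s -> lognormal (meanlog, sdlog)
lognormal_params <- function(m, s) {
  sdlog2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Simulate a two-group screening cohort
#'
#' Draws one latent multivariate-normal vector per subject (exchangeable
#' correlation on the latent scale — a Gaussian copula) and maps each
#' coordinate through its variable's marginal: Gaussian, lognormal with
#' matching arithmetic moments, or a Bernoulli threshold for binary traits.
#' Values below a variable's limit of detection are flagged in a
#' `<name>_below_lod` column; the raw value is retained so that censoring
#' behaviour can be checked against truth (imputation is a separate,
#' explicit step — see [impute_below_lod()]).
#'
#' @param config a [cohort_sim_config()].
#' @return A tibble with one row per subject: `subject_id`, `group`
#'   (factor, levels `control`, `post_mi`), one column per variable, and a
#'   logical `<name>_below_lod` column for each variable with an LOD.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  vs <- config$variable_specs; bs <- config$binary_specs
  k <- nrow(vs) + nrow(bs)
  n <- config$n_control + config$n_case
  group <- factor(
    rep(c("control", "post_mi"), c(config$n_control, config$n_case)),
    levels = c("control", "post_mi")
  )
  is_case <- group == "post_mi"

  Z <- with_seed(config$seed, {
    if (k == 0) matrix(numeric(0), n, 0)
    else if (k == 1) matrix(stats::rnorm(n), n, 1)
    else {
      R <- matrix(config$correlation, k, k); diag(R) <- 1
      MASS::mvrnorm(n, mu = rep(0, k), Sigma = R)
    }
  })

  out <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = group
  )
  if (nrow(vs) > 0) {
    for (i in seq_len(nrow(vs))) {
      z <- Z[, i]
      m <- ifelse(is_case, vs$case_mean[i], vs$control_mean[i])
      s <- ifelse(is_case, vs$case_sd[i], vs$control_sd[i])
      val <- if (vs$family[i] == "normal") {
        m + s * z
      } else {
        lp_ctl <- lognormal_params(vs$control_mean[i], vs$control_sd[i])
        lp_cas <- lognormal_params(vs$case_mean[i], vs$case_sd[i])
        exp(ifelse(is_case, lp_cas$meanlog, lp_ctl$meanlog) +
              ifelse(is_case, lp_cas$sdlog, lp_ctl$sdlog) * z)
      }
      out[[vs$name[i]]] <- val
      if (!is.na(vs$lod[i])) {
        out[[paste0(vs$name[i], "_below_lod")]] <- val < vs$lod[i]
      }
    }
  }
  if (nrow(bs) > 0) {
    for (j in seq_len(nrow(bs))) {
      z <- Z[, nrow(vs) + j]
      p <- ifelse(is_case, bs$case_proportion[j], bs$control_proportion[j])
      # latent threshold keeps the copula correlation with the other variables
      out[[bs$name[j]]] <- as.integer(z > stats::qnorm(1 - p))
    }
  }
  attr(out, "variable_specs") <- vs
  attr(out, "binary_specs") <- bs
  out
}
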