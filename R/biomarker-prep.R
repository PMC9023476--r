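#' Assay limit-of-detection table
#'
#' The twenty assay detection limits used by the biomarker panel, one row
#' per assay: cytokine-array analytes in pg/ml, plus H-FABP, adiponectin,
#' folate, homocysteine, vitamin B12, HDL-3, ADMA and LRG-1 in their
#' native units. Below-LOD results are imputed as 90% of the LOD (see
#' [impute_below_lod()]).
#'
#' @return A tibble: `name`, `lod`, `units`.
#' @export
assay_lods <- function() {
  tibble::tribble(
    ~name,          ~lod,    ~units,
    "il1a",         0.19,    "pg/ml",
    "il1b",         0.26,    "pg/ml",
    "il2",          2.97,    "pg/ml",
    "il4",          2.12,    "pg/ml",
    "il6",          0.12,    "pg/ml",
    "il8",          0.36,    "pg/ml",
    "il10",         0.37,    "pg/ml",
    "vegf",         3.24,    "pg/ml",
    "egf",          1.04,    "pg/ml",
    "tnfa",         0.59,    "pg/ml",
    "ifng",         0.44,    "pg/ml",
    "mcp1",         3.53,    "pg/ml",
    "hfabp",        2.94,    "ng/ml",
    "adiponectin",  0.18,    "ug/ml",
    "folate",       2.72,    "nmol/l",
    "homocysteine", 1.74,    "umol/l",
    "vitamin_b12",  73.8,    "pmol/l",
    "hdl3",         4,       "mg/dl",
    "adma",         0.938,   "umol/l",
    "lrg1",         0.0047,  "ug/ml"
  )
}

#' Impute below-LOD biomarker values as 90% of the detection limit
#'
#' Values flagged below the assay's limit of detection are replaced by
#' 0.9 x LOD; detectable values pass through unchanged. The operation is
#' idempotent (an already-imputed value is below no new LOD and its flag
#' already records the substitution).
#'
#' @param data cohort tibble with one column per biomarker and, for any
#'   censored assay, a logical `<name>_below_lod` column (as emitted by
#'   [simulate_cohort()]).
#' @param assays LOD table (`name`, `lod`); defaults to [assay_lods()].
#'   A flagged assay missing from the table (or with a non-positive LOD)
#'   is an error naming the assay.
#' @return `data` with censored entries replaced by 0.9 x LOD and an
#'   `imputed_below_lod` attribute counting substitutions per assay.
#' @export
impute_below_lod <- function(data, assays = assay_lods()) {
  stopifnot(is.data.frame(data))
  flag_cols <- grep("_below_lod$", names(data), value = TRUE)
  counts <- integer(0)
  for (fc in flag_cols) {
    var <- sub("_below_lod$", "", fc)
    if (!var %in% names(data)) next
    flags <- data[[fc]] %in% TRUE
    if (!any(flags)) { counts[var] <- 0L; next }
    lod <- assays$lod[match(var, assays$name)]
    if (length(lod) == 0 || is.na(lod)) {
      stop(sprintf("assay '%s' has below-LOD entries but no LOD on record", var),
           call. = FALSE)
    }
    if (lod <= 0) {
      stop(sprintf("assay '%s' has a non-positive LOD (%g)", var, lod),
           call. = FALSE)
    }
    data[[var]][flags] <- 0.9 * lod
    counts[var] <- sum(flags)
  }
  attr(data, "imputed_below_lod") <- counts
  data
}

#' Apply a base-10 log transform to named variables
#'
#' Used for right-skewed biomarkers that fail the normality gate
#' (NT-proBNP, adiponectin, H-FABP, wall shear rate by default in the
#' screening models). Values must be strictly positive — run
#' [impute_below_lod()] first so censored zeros cannot reach the log.
#'
#' @param data cohort tibble.
#' @param variables character vector of column names to transform.
#' @return `data` with the named columns replaced by log10(values) and a
#'   `log10_transformed` attribute listing them.
#' @export
apply_log10 <- function(data, variables) {
  stopifnot(is.data.frame(data))
  missing_vars <- setdiff(variables, names(data))
  if (length(missing_vars)) {
    stop("unknown variable(s): ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  for (v in variables) {
    bad <- which(!is.na(data[[v]]) & data[[v]] <= 0)
    if (length(bad)) {
      id <- if ("subject_id" %in% names(data)) data$subject_id[bad[1]] else bad[1]
      stop(sprintf(
        "variable '%s' has a non-positive value for subject %s; cannot log10",
        v, id
      ), call. = FALSE)
    }
    data[[v]] <- log10(data[[v]])
  }
  attr(data, "log10_transformed") <-
    union(attr(data, "log10_transformed"), variables)
  data
}

#' Aggregate per-segment haemodynamics to per-patient means
#'
#' Combines measurements from all included vessel segments of both eyes
#' (up to four videos per patient) into one unweighted mean per parameter
#' — every segment counts once, regardless of which video it came from.
#'
#' @param segments tibble with one row per vessel segment: `subject_id`,
#'   optionally `eye` / `video` identifiers, the haemodynamic columns
#'   (`d_um`, `va_mm_s`, `vs_mm_s`, `q_pl_s`, `wsr_per_s` — any subset),
#'   and optionally a logical `included` column (only `TRUE` rows pool).
#' @return A tibble with one row per subject and the per-parameter means.
#'   A subject all of whose segments are excluded is reported with
#'   `ocular_missing = TRUE` and NA means.
#' @export
aggregate_patient <- function(segments) {
  stopifnot(is.data.frame(segments), "subject_id" %in% names(segments))
  params <- intersect(
    c("d_um", "va_mm_s", "vs_mm_s", "q_pl_s", "wsr_per_s"),
    names(segments)
  )
  if (length(params) == 0) stop("no haemodynamic columns found", call. = FALSE)
  if (!"included" %in% names(segments)) segments$included <- TRUE
  all_subjects <- unique(segments$subject_id)
  pooled <- segments |>
    dplyr::filter(.data$included) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n_segments = dplyr::n(),
      dplyr::across(dplyr::all_of(params), mean),
      .groups = "drop"
    )
  out <- tibble::tibble(subject_id = all_subjects) |>
    dplyr::left_join(pooled, by = "subject_id") |>
    dplyr::mutate(
      n_segments = dplyr::coalesce(.data$n_segments, 0L),
      ocular_missing = .data$n_segments == 0L
    )
  out
}

#' Shapiro-Wilk normality gate
#'
#' Standard Shapiro-Wilk test with the decision rule used throughout the
#' analysis: a sample is treated as normal when p > 0.05.
#'
#' @param values numeric sample, 3 <= n <= 5000 after NA removal.
#' @return A one-row tibble: `w`, `p_value`, `is_normal`.
#' @export
shapiro_wilk_gate <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3) stop("Shapiro-Wilk needs at least 3 values", call. = FALSE)
  if (n > 5000) stop("Shapiro-Wilk supports at most 5000 values", call. = FALSE)
  if (stats::sd(values) == 0) {
    stop("sample is constant (zero variance); normality undefined", call. = FALSE)
  }
  sw <- stats::shapiro.test(values)
  tibble::tibble(
    w = unname(sw$statistic),
    p_value = sw$p.value,
    is_normal = sw$p.value > 0.05
  )
}
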