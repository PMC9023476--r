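#' Pearson chi-square test on a 2x2 table
#'
#' Pearson chi-square without continuity correction, df = 1 (the
#' uncorrected statistic is the convention this analysis follows for
#' trait-by-group tables).
#'
#' @param a,b,c,d cell counts: rows are groups, columns trait present /
#'   absent, so the table is rbind(c(a, b), c(c, d)).
#' @return A one-row tibble: `test_name`, `statistic`, `df`, `p_value`,
#'   plus the per-group `n/N (%)` summaries.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  n <- sum(counts)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    stop("chi-square undefined: a table margin is zero", call. = FALSE)
  }
  stat <- n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
  tibble::tibble(
    test_name = "chi-square",
    statistic = stat,
    df = 1,
    p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    group1_summary = sprintf("%d/%d (%.1f%%)", a, r1, 100 * a / r1),
    group2_summary = sprintf("%d/%d (%.1f%%)", c, r2, 100 * c / r2)
  )
}

#' Compare one variable between the two cohort groups
#'
#' Continuous variables: independent t-test when both groups pass the
#' Shapiro-Wilk gate (p > 0.05), otherwise the Mann-Whitney U test
#' (rank-sum p; both the medians and the mean-rank summaries are
#' reported, leaving the distribution-shape interpretation to the
#' caller). Binary (0/1) variables delegate to [chi_square_2x2()].
#'
#' @param data cohort tibble with a two-level `group` column.
#' @param variable column name to compare.
#' @param group column name of the group factor (default "group").
#' @return A one-row tibble: `variable`, `test_name`, `statistic`, `df`
#'   (NA where undefined), `p_value`, per-group summaries (mean +/- SD
#'   for continuous, n/N (%) for binary, plus medians for the rank test).
#' @export
compare_groups <- function(data, variable, group = "group") {
  stopifnot(is.data.frame(data), variable %in% names(data),
            group %in% names(data))
  g <- factor(data[[group]])
  if (nlevels(g) != 2) stop("group must have exactly 2 levels", call. = FALSE)
  x <- data[[variable]]
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(g[ok])
  x1 <- x[g == levels(g)[1]]; x2 <- x[g == levels(g)[2]]
  if (length(x1) < 3 || length(x2) < 3) {
    stop("need >= 3 non-missing values per group", call. = FALSE)
  }
  is_binary <- all(x %in% c(0, 1))
  if (is_binary) {
    res <- chi_square_2x2(sum(x1 == 1), sum(x1 == 0), sum(x2 == 1), sum(x2 == 0))
    return(tibble::tibble(variable = variable, res))
  }
  normal1 <- stats::sd(x1) > 0 && shapiro_wilk_gate(x1)$is_normal
  normal2 <- stats::sd(x2) > 0 && shapiro_wilk_gate(x2)$is_normal
  mean_sd <- function(v) sprintf("%.2f ± %.2f", mean(v), stats::sd(v))
  if (normal1 && normal2) {
    tt <- stats::t.test(x1, x2, var.equal = TRUE)
    tibble::tibble(
      variable = variable, test_name = "t-test",
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value,
      group1_summary = mean_sd(x1), group2_summary = mean_sd(x2)
    )
  } else {
    wt <- stats::wilcox.test(x1, x2, exact = FALSE, correct = FALSE)
    r <- rank(c(x1, x2))
    tibble::tibble(
      variable = variable, test_name = "Mann-Whitney",
      statistic = unname(wt$statistic), df = NA_real_,
      p_value = wt$p.value,
      group1_summary = sprintf("%s; median %.2f; mean rank %.1f",
                               mean_sd(x1), stats::median(x1),
                               mean(r[seq_along(x1)])),
      group2_summary = sprintf("%s; median %.2f; mean rank %.1f",
                               mean_sd(x2), stats::median(x2),
                               mean(r[-seq_along(x1)]))
    )
  }
}

# ---- logistic regression by IRLS ------------------------------------------

#' Fit a binary logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with Newton-Raphson/IRLS, converged when
#' the log-likelihood changes by less than `tol` (default 1e-8) or after
#' `max_iter` iterations. Standard errors come from the inverse
#' observed-information matrix (for the logit link this equals the expected
#' information X'WX). Wald statistics are (beta/SE)^2 with chi-square(1)
#' p-values. Complete or quasi-complete separation is detected (diverging
#' coefficients with fitted probabilities collapsing to 0/1) and flagged
#' rather than silently reported.
#'
#' @param y binary 0/1 outcome vector.
#' @param X numeric predictor matrix (no intercept column; one is added),
#'   or a data frame of numeric columns.
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter maximum IRLS iterations (default 50).
#' @return An object of class `screen_logit`: coefficients (intercept
#'   first), `se`, `wald`, `p_values`, `log_likelihood`,
#'   `null_log_likelihood`, `model_chi2`, `model_df`, `model_p`,
#'   `nagelkerke_r2`, `fitted`, `converged`, `separation`, `n`, plus the
#'   design internals needed by the stepwise driver.
#' @export
fit_logistic <- function(y, X, tol = 1e-8, max_iter = 50L) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.null(X)) X <- matrix(numeric(0), length(y), 0)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1)
  if (is.null(colnames(X)) && ncol(X) > 0) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  n <- length(y)
  if (nrow(X) != n) stop("nrow(X) must match length(y)", call. = FALSE)
  if (n < ncol(X) + 2) stop("need n >= number of parameters + 1", call. = FALSE)
  if (ncol(X) > 0) {
    const <- apply(X, 2, function(col) stats::sd(col) == 0)
    if (any(const)) {
      stop("constant predictor column(s): ",
           paste(colnames(X)[const], collapse = ", "), call. = FALSE)
    }
    qrX <- qr(cbind(1, X))
    if (qrX$rank < ncol(X) + 1) {
      drop_idx <- qrX$pivot[(qrX$rank + 1):(ncol(X) + 1)] - 1
      stop("rank-deficient design; collinear column(s): ",
           paste(colnames(X)[drop_idx], collapse = ", "), call. = FALSE)
    }
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  beta <- numeric(p)
  beta[1] <- stats::qlogis(max(min(mean(y), 1 - 1e-8), 1e-8))
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    fit <- stats::lm.wfit(Xd, z, w)
    beta <- fit$coefficients
  }
  eta <- drop(Xd %*% beta)
  mu <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  w <- mu * (1 - mu)
  info <- crossprod(Xd * sqrt(w))
  cov_beta <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, p, p)
  })
  se <- sqrt(diag(cov_beta))
  separation <- max(abs(beta)) > 15 &&
    (min(mu[y == 1]) > 0.999 || max(mu[y == 0]) < 0.001 ||
       mean(abs(y - mu) < 1e-4) > 0.99)
  wald <- (beta / se)^2
  p0 <- mean(y)
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  k <- as.integer(p - 1)
  model_chi2 <- 2 * (ll - ll0)
  cs <- 1 - exp(2 * (ll0 - ll) / n)
  cs_max <- 1 - exp(2 * ll0 / n)
  structure(
    list(
      variables = colnames(X),
      coefficients = beta, se = se, wald = wald,
      p_values = stats::pchisq(wald, df = 1, lower.tail = FALSE),
      vcov = cov_beta,
      log_likelihood = ll, null_log_likelihood = ll0,
      model_chi2 = model_chi2, model_df = k,
      model_p = if (k > 0) stats::pchisq(model_chi2, k, lower.tail = FALSE) else NA_real_,
      nagelkerke_r2 = if (cs_max > 0) cs / cs_max else 0,
      fitted = drop(stats::plogis(drop(Xd %*% beta))),
      y = y, design = Xd,
      converged = converged, separation = separation, n = n
    ),
    class = "screen_logit"
  )
}

#' @export
print.screen_logit <- function(x, ...) {
  cat(sprintf(
    "<screen_logit> n = %d, %d predictor(s), LL = %.3f, chi2(%d) = %.2f, Nagelkerke R2 = %.3f%s\n",
    x$n, x$model_df, x$log_likelihood, x$model_df, x$model_chi2,
    x$nagelkerke_r2, if (x$separation) " [SEPARATION FLAGGED]" else ""
  ))
  print(tidy.screen_logit(x))
  invisible(x)
}

# Rao score test for adding column xnew to a fitted model (entry criterion)
score_test_add <- function(fit, xnew) {
  mu <- fit$fitted
  w <- mu * (1 - mu)
  X <- fit$design
  U <- sum(xnew * (fit$y - mu))
  XtWx <- crossprod(X, w * xnew)
  V <- sum(w * xnew^2) - drop(crossprod(XtWx, solve(crossprod(X * sqrt(w)), XtWx)))
  if (V <= 0) return(list(statistic = 0, p_value = 1))
  stat <- U^2 / V
  list(statistic = stat, p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Stepwise logistic regression with score-test entry and Wald removal
#'
#' Forward steps add the candidate with the smallest score-test p-value,
#' provided it stays below `p_enter` after Bonferroni adjustment for the
#' number of candidates scanned at that step (family-wise entry control,
#' so a screen over many null biomarkers stays at the intercept-only
#' model with probability at least 1 - `p_enter`); after each addition,
#' backward steps remove any included variable whose Wald p-value exceeds
#' `p_remove`, until a fixed point. The full trace (step, action,
#' variable, statistic, raw p) is returned so the selection can be
#' replayed.
#'
#' @param data cohort tibble.
#' @param outcome name of the binary outcome column (0/1, or a two-level
#'   factor whose second level is the event).
#' @param candidates character vector of candidate predictor columns.
#' @param p_enter forward entry threshold (default 0.05).
#' @param p_remove backward removal threshold (default 0.10).
#' @return A list of class `stepwise_result`: `model` (a `screen_logit`;
#'   intercept-only when nothing enters), `trace` (tibble), `selected`
#'   (character vector).
#' @export
stepwise_wald <- function(data, outcome, candidates,
                          p_enter = 0.05, p_remove = 0.10) {
  stopifnot(is.data.frame(data), outcome %in% names(data))
  if (length(candidates) > 0) {
    missing_vars <- setdiff(candidates, names(data))
    if (length(missing_vars)) {
      stop("unknown candidate(s): ", paste(missing_vars, collapse = ", "),
           call. = FALSE)
    }
  }
  cols <- c(outcome, candidates)
  cc <- stats::complete.cases(data[cols])
  d <- data[cc, cols, drop = FALSE]
  y <- d[[outcome]]
  if (is.factor(y)) y <- as.numeric(y == levels(y)[2])
  y <- as.numeric(y)
  if (length(candidates) > 0 && nrow(d) < 10 * length(candidates)) {
    stop(sprintf(
      "only %d complete-case rows for %d candidates (need >= 10 per candidate)",
      nrow(d), length(candidates)
    ), call. = FALSE)
  }
  included <- character(0)
  trace <- list()
  step <- 0L
  fit_current <- function() {
    X <- if (length(included)) as.matrix(d[included]) else NULL
    fit_logistic(y, X)
  }
  fit <- fit_current()
  repeat {
    remaining <- setdiff(candidates, included)
    if (length(remaining) == 0) break
    scores <- purrr::map(remaining, ~ score_test_add(fit, d[[.x]]))
    pvals <- purrr::map_dbl(scores, "p_value")
    if (min(pvals) * length(remaining) >= p_enter) break
    j <- which.min(pvals)
    step <- step + 1L
    trace[[length(trace) + 1L]] <- tibble::tibble(
      step = step, action = "enter", variable = remaining[j],
      statistic = scores[[j]]$statistic, p_value = pvals[j]
    )
    included <- c(included, remaining[j])
    fit <- fit_current()
    # backward sweep at the Wald criterion
    repeat {
      wp <- fit$p_values[-1] # drop intercept
      if (length(wp) == 0 || max(wp) <= p_remove) break
      k <- which.max(wp)
      step <- step + 1L
      trace[[length(trace) + 1L]] <- tibble::tibble(
        step = step, action = "remove", variable = included[k],
        statistic = fit$wald[-1][k], p_value = wp[k]
      )
      included <- included[-k]
      fit <- fit_current()
    }
  }
  structure(
    list(
      model = fit,
      trace = if (length(trace)) dplyr::bind_rows(trace) else tibble::tibble(
        step = integer(), action = character(), variable = character(),
        statistic = numeric(), p_value = numeric()
      ),
      selected = included,
      outcome = outcome, data = d
    ),
    class = "stepwise_result"
  )
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat(sprintf("<stepwise_result> selected: %s\n",
              if (length(x$selected)) paste(x$selected, collapse = ", ")
              else "(intercept only)"))
  if (nrow(x$trace)) print(x$trace)
  invisible(x)
}

#' Replay a stepwise trace
#'
#' Re-applies the recorded enter/remove actions to the same data and
#' refits; the final model must reproduce the original bit-for-bit.
#'
#' @param result a `stepwise_result`.
#' @return A `screen_logit` fit from the replayed variable set.
#' @export
replay_stepwise <- function(result) {
  stopifnot(inherits(result, "stepwise_result"))
  included <- character(0)
  if (nrow(result$trace)) {
    for (i in seq_len(nrow(result$trace))) {
      v <- result$trace$variable[i]
      if (result$trace$action[i] == "enter") included <- c(included, v)
      else included <- setdiff(included, v)
    }
  }
  y <- result$model$y
  X <- if (length(included)) as.matrix(result$data[included]) else NULL
  fit_logistic(y, X)
}

#' Nagelkerke pseudo-R-squared
#'
#' Cox-Snell R2 = 1 - exp(2(LL0 - LL1)/n), rescaled by its maximum
#' 1 - exp(2 LL0 / n) so the statistic can reach 1.
#'
#' @param ll_model fitted-model log-likelihood (or a `screen_logit`, in
#'   which case the remaining arguments are taken from it).
#' @param ll_null intercept-only log-likelihood on the same rows.
#' @param n number of observations.
#' @return Nagelkerke R2 in [0, 1].
#' @export
nagelkerke_r2 <- function(ll_model, ll_null = NULL, n = NULL) {
  if (inherits(ll_model, "screen_logit")) {
    fit <- ll_model
    ll_null <- fit$null_log_likelihood
    n <- fit$n
    ll_model <- fit$log_likelihood
  }
  if (ll_model < ll_null - 1e-8) {
    stop("model log-likelihood below the null: impossible for nested MLE",
         call. = FALSE)
  }
  cs <- 1 - exp(2 * (ll_null - ll_model) / n)
  cs_max <- 1 - exp(2 * ll_null / n)
  if (cs_max <= 0) return(0)
  min(cs / cs_max, 1)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Subjects are grouped into g = 10 deciles of fitted risk (tied fitted
#' probabilities stay in the same group), and the calibration chi-square
#' sum (observed - expected)^2 / (expected (1 - mean p)) is referred to
#' chi-square with g - 2 degrees of freedom. Groups whose expected event
#' count is zero are merged with their neighbour and the merge recorded.
#'
#' @param fit a `screen_logit`, or a list with `fitted` and `y`.
#' @param g number of risk groups (default 10; g >= 3 required so df >= 1).
#' @return A one-row tibble: `chi2`, `df`, `p_value`, `g_used`, `merged`.
#' @export
hosmer_lemeshow <- function(fit, g = 10) {
  p <- fit$fitted; y <- fit$y
  n <- length(y)
  if (g < 3) stop("need g >= 3 so that df = g - 2 >= 1", call. = FALSE)
  if (n < 2 * g) stop("need n >= 2g observations", call. = FALSE)
  br <- stats::quantile(p, probs = seq(0, 1, length.out = g + 1))
  br <- unique(br)
  grp <- cut(p, breaks = br, include.lowest = TRUE)
  tab <- tibble::tibble(grp = grp, y = y, p = p) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(n = dplyr::n(), obs = sum(.data$y),
                     exp = sum(.data$p), pbar = mean(.data$p),
                     .groups = "drop")
  merged <- nlevels(grp) < g
  # merge groups with zero expected events into the neighbour above
  while (nrow(tab) > 3 && any(tab$exp < 1e-9 | (tab$n - tab$exp) < 1e-9)) {
    i <- which(tab$exp < 1e-9 | (tab$n - tab$exp) < 1e-9)[1]
    j <- if (i == nrow(tab)) i - 1 else i + 1
    tab$n[j] <- tab$n[j] + tab$n[i]
    tab$obs[j] <- tab$obs[j] + tab$obs[i]
    tab$exp[j] <- tab$exp[j] + tab$exp[i]
    tab$pbar[j] <- tab$exp[j] / tab$n[j]
    tab <- tab[-i, ]
    merged <- TRUE
  }
  g_used <- nrow(tab)
  if (g_used < 3) stop("too few distinct risk groups for the test", call. = FALSE)
  chi2 <- sum((tab$obs - tab$exp)^2 / (tab$exp * (1 - tab$pbar)))
  df <- g_used - 2
  tibble::tibble(
    chi2 = chi2, df = df,
    p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
    g_used = g_used, merged = merged
  )
}

#' ROC curve with AUROC and operating-point metrics
#'
#' Thresholds are placed at every distinct score; the AUROC is the
#' trapezoidal area, equal to the Mann-Whitney concordance probability
#' with midrank tie handling. The operating point (sensitivity,
#' specificity, PPV, NPV at the sample prevalence) is reported at the
#' classification cut, alongside the Youden-optimal point.
#'
#' @param scores numeric scores (higher = more case-like; typically fitted
#'   probabilities).
#' @param labels binary 0/1 (or two-level factor, second level = case).
#' @param classification_cut score threshold for the reported operating
#'   point (default 0.5, matching fitted-probability classification).
#' @return An object of class `screen_roc`: `curve` (tibble threshold,
#'   sensitivity, specificity), `auroc`, `operating_point` (one-row
#'   tibble), `youden_point`, `n_case`, `n_control`.
#' @export
roc_curve <- function(scores, labels, classification_cut = 0.5) {
  if (is.factor(labels)) labels <- as.numeric(labels == levels(labels)[2])
  labels <- as.numeric(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  # Mann-Whitney concordance with midranks == trapezoidal AUROC
  r <- rank(scores)
  auroc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(-Inf, sort(unique(scores)), Inf)
  curve <- purrr::map_dfr(thr, function(th) {
    pred <- scores >= th
    tibble::tibble(
      threshold = th,
      sensitivity = sum(pred & labels == 1) / n1,
      specificity = sum(!pred & labels == 0) / n0
    )
  })
  op <- function(th) {
    pred <- scores >= th
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    fn <- n1 - tp; tn <- n0 - fp
    tibble::tibble(
      threshold = th,
      sensitivity = tp / n1, specificity = tn / n0,
      ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
      accuracy = (tp + tn) / (n1 + n0)
    )
  }
  youden <- curve$sensitivity + curve$specificity - 1
  best <- curve$threshold[which.max(youden)]
  structure(
    list(
      curve = curve, auroc = auroc,
      operating_point = op(classification_cut),
      youden_point = op(best),
      n_case = n1, n_control = n0
    ),
    class = "screen_roc"
  )
}

#' @export
print.screen_roc <- function(x, ...) {
  o <- x$operating_point
  cat(sprintf(
    "<screen_roc> AUROC %.3f (%d cases / %d controls); at cut %.3g: sens %.1f%%, spec %.1f%%, PPV %.1f%%, NPV %.1f%%\n",
    x$auroc, x$n_case, x$n_control, o$threshold,
    100 * o$sensitivity, 100 * o$specificity, 100 * o$ppv, 100 * o$npv
  ))
  invisible(x)
}

#' Diagnostic-accuracy comparison of candidate screening models
#'
#' Fits a logistic model for each candidate variable set on its
#' complete-case rows and reports AUROC, sensitivity, specificity, PPV
#' and NPV at the classification cut, sorted by AUROC descending —
#' the standard model-comparison table for screening scores.
#'
#' @param data cohort tibble.
#' @param outcome binary outcome column name.
#' @param model_specs named (or unnamed) list of character vectors of
#'   predictor columns.
#' @param classification_cut fitted-probability threshold (default 0.5).
#' @return A tibble: `model`, `n`, `auroc`, `sensitivity_pct`,
#'   `specificity_pct`, `ppv_pct`, `npv_pct`, sorted by AUROC descending.
#' @export
model_comparison_report <- function(data, outcome, model_specs,
                                    classification_cut = 0.5) {
  stopifnot(is.data.frame(data), outcome %in% names(data))
  if (length(model_specs) == 0) {
    return(tibble::tibble(
      model = character(), n = integer(), auroc = numeric(),
      sensitivity_pct = numeric(), specificity_pct = numeric(),
      ppv_pct = numeric(), npv_pct = numeric()
    ))
  }
  rows <- purrr::map_dfr(seq_along(model_specs), function(i) {
    vars <- model_specs[[i]]
    unknown <- setdiff(vars, names(data))
    if (length(unknown)) {
      stop("unknown variable(s) in model spec: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    nm <- names(model_specs)[i]
    if (is.null(nm) || nm == "") nm <- paste(vars, collapse = " + ")
    cc <- stats::complete.cases(data[c(outcome, vars)])
    d <- data[cc, , drop = FALSE]
    y <- d[[outcome]]
    if (is.factor(y)) y <- as.numeric(y == levels(y)[2])
    fit <- fit_logistic(y, as.matrix(d[vars]))
    roc <- roc_curve(fit$fitted, y, classification_cut = classification_cut)
    o <- roc$operating_point
    tibble::tibble(
      model = nm, n = nrow(d), auroc = roc$auroc,
      sensitivity_pct = 100 * o$sensitivity,
      specificity_pct = 100 * o$specificity,
      ppv_pct = 100 * o$ppv, npv_pct = 100 * o$npv
    )
  })
  dplyr::arrange(rows, dplyr::desc(.data$auroc))
}

#' Render a model-comparison report as aligned text
#' @param report tibble from [model_comparison_report()].
#' @return A character vector of lines, invisibly printed.
#' @export
format_report <- function(report) {
  hdr <- sprintf("%-45s %6s %6s %6s %6s %6s %6s",
                 "Model", "n", "AUROC", "Sens%", "Spec%", "PPV%", "NPV%")
  lines <- c(hdr, strrep("-", nchar(hdr)))
  for (i in seq_len(nrow(report))) {
    lines <- c(lines, sprintf(
      "%-45s %6d %6.3f %6.1f %6.1f %6.1f %6.1f",
      substr(report$model[i], 1, 45), report$n[i], report$auroc[i],
      report$sensitivity_pct[i], report$specificity_pct[i],
      report$ppv_pct[i], report$npv_pct[i]
    ))
  }
  lines
}
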