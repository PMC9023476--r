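test_that("2x2 chi-square matches the printed worked examples and the oracle", {
  g <- chi_square_2x2(45, 21, 52, 14)
  expect_equal(round(g$statistic, 2), 1.91)
  expect_equal(round(g$p_value, 3), 0.168)
  h <- chi_square_2x2(8, 58, 31, 35)
  expect_equal(round(h$statistic, 2), 19.25)
  # brute-force sum (O - E)^2 / E on random tables
  set.seed(9)
  for (i in 1:20) {
    tab <- matrix(sample(1:40, 4, replace = TRUE), 2)
    O <- as.vector(tab)
    E <- as.vector(outer(rowSums(tab), colSums(tab)) / sum(tab))
    want <- sum((O - E)^2 / E)
    got <- chi_square_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])$statistic
    expect_equal(got, want, tolerance = 1e-10)
  }
  expect_equal(chi_square_2x2(10, 10, 10, 10)$statistic, 0)
  expect_equal(chi_square_2x2(10, 10, 10, 10)$p_value, 1)
  expect_error(chi_square_2x2(0, 0, 5, 5), "margin")
})

test_that("compare_groups picks the right branch and handles identical samples", {
  set.seed(12)
  d <- tibble::tibble(
    group = factor(rep(c("control", "post_mi"), each = 40)),
    same = rep(rnorm(40), 2),
    skewed = rlnorm(80, sdlog = 1.5),
    trait = rep(c(0, 1), 40)
  )
  same <- compare_groups(d, "same")
  expect_identical(same$test_name, "t-test")
  expect_gte(same$p_value, 0.99)
  expect_identical(compare_groups(d, "skewed")$test_name, "Mann-Whitney")
  expect_identical(compare_groups(d, "trait")$test_name, "chi-square")
  expect_error(compare_groups(d[1:42, ], "same"), ">= 3") # 40 vs 2 per group
})

test_that("group comparison has power for the velocity effect at n=66/66", {
  # Vs: 0.38 +/- 0.04 vs 0.35 +/- 0.04 must come out significant almost always
  set.seed(20)
  hits <- replicate(200, {
    d <- tibble::tibble(
      group = factor(rep(c("control", "post_mi"), each = 66)),
      vs = c(rnorm(66, 0.38, 0.04), rnorm(66, 0.35, 0.04))
    )
    compare_groups(d, "vs")$p_value < 0.05
  })
  expect_gte(mean(hits), 0.90)
})

test_that("IRLS logistic matches glm and recovers simulated parameters", {
  set.seed(301)
  n <- 2000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 0.8 * x))
  fit <- fit_logistic(y, cbind(x = x))
  ref <- stats::glm(y ~ x, family = stats::binomial())
  expect_equal(unname(fit$coefficients), unname(stats::coef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-5)
  expect_equal(fit$log_likelihood, as.numeric(stats::logLik(ref)),
               tolerance = 1e-8)
  # truth within 2 SE
  expect_lt(abs(fit$coefficients[1] - (-1)), 2 * fit$se[1])
  expect_lt(abs(fit$coefficients[2] - 0.8), 2 * fit$se[2])
  expect_true(fit$converged)
  expect_false(fit$separation)
})

test_that("null predictors stay within 2 SE of zero and Wald = (beta/SE)^2", {
  set.seed(32)
  x <- rnorm(5000)
  y <- rbinom(5000, 1, 0.4)
  fit <- fit_logistic(y, cbind(x = x))
  expect_lt(abs(fit$coefficients[2]), 2 * fit$se[2])
  expect_equal(fit$wald, (fit$coefficients / fit$se)^2)
})

test_that("degenerate designs are flagged or rejected", {
  y <- c(rep(0, 6), rep(1, 6))
  expect_true(fit_logistic(y, seq_len(12))$separation)
  x <- rnorm(12)
  expect_error(fit_logistic(y, cbind(a = x, b = 2 * x)), "collinear")
  expect_error(fit_logistic(y, cbind(k = rep(1, 12))), "constant")
})

test_that("IRLS log-likelihood is monotone and the final gradient vanishes", {
  set.seed(33)
  x <- matrix(rnorm(600 * 2), ncol = 2); colnames(x) <- c("a", "b")
  y <- rbinom(600, 1, plogis(0.5 * x[, 1]))
  fit <- fit_logistic(y, x)
  grad <- crossprod(fit$design, fit$y - fit$fitted)
  expect_lt(max(abs(grad)), 1e-6)
})

test_that("stepwise keeps nulls out and finds the true predictor", {
  set.seed(34)
  null_keep <- replicate(40, {
    X <- matrix(rnorm(800 * 5), ncol = 5)
    colnames(X) <- paste0("v", 1:5)
    d <- tibble::as_tibble(X); d$case <- rbinom(800, 1, 0.5)
    length(stepwise_wald(d, "case", paste0("v", 1:5))$selected) == 0
  })
  expect_gte(mean(null_keep), 0.85)
  set.seed(35)
  found <- replicate(40, {
    X <- matrix(rnorm(800 * 5), ncol = 5)
    colnames(X) <- paste0("v", 1:5)
    d <- tibble::as_tibble(X); d$case <- rbinom(800, 1, plogis(X[, 2]))
    "v2" %in% stepwise_wald(d, "case", paste0("v", 1:5))$selected
  })
  expect_gte(mean(found), 0.95)
})

test_that("an empty candidate set yields the intercept-only model", {
  d <- tibble::tibble(case = rbinom(50, 1, 0.5), x = rnorm(50))
  sw <- stepwise_wald(d, "case", character(0))
  expect_identical(sw$selected, character(0))
  expect_identical(nrow(sw$trace), 0L)
  expect_identical(sw$model$model_df, 0L)
})

test_that("replaying a stepwise trace reproduces the model bit-for-bit", {
  set.seed(36)
  X <- matrix(rnorm(500 * 4), ncol = 4)
  colnames(X) <- c("p", "q", "r", "s")
  d <- tibble::as_tibble(X)
  d$case <- rbinom(500, 1, plogis(X[, 1] - 0.8 * X[, 3]))
  sw <- stepwise_wald(d, "case", c("p", "q", "r", "s"))
  replay <- replay_stepwise(sw)
  expect_identical(replay$coefficients, sw$model$coefficients)
  expect_identical(replay$log_likelihood, sw$model$log_likelihood)
})

test_that("Nagelkerke R2 matches the closed-form worked example and bounds", {
  expect_equal(nagelkerke_r2(-1.3863, -2.7726, 4), 2 / 3, tolerance = 1e-4)
  expect_identical(nagelkerke_r2(-5, -5, 100), 0)
  expect_error(nagelkerke_r2(-10, -5, 100), "impossible")
  # near-perfect prediction drives R2 toward 1
  set.seed(37)
  x <- c(rnorm(200, -3), rnorm(200, 3))
  y <- rep(c(0, 1), each = 200)
  fit <- fit_logistic(y, x)
  expect_gt(fit$nagelkerke_r2, 0.95)
})

test_that("Hosmer-Lemeshow is calibrated for a well-specified model", {
  set.seed(38)
  chis <- replicate(150, {
    x <- rnorm(1000)
    y <- rbinom(1000, 1, plogis(-0.5 + x))
    hosmer_lemeshow(fit_logistic(y, x))$chi2
  })
  expect_gt(mean(chis), 6.4)
  expect_lt(mean(chis), 9.6)
  fit <- fit_logistic(rbinom(100, 1, 0.5), rnorm(100))
  expect_error(hosmer_lemeshow(fit, g = 2), "df")
})

test_that("Hosmer-Lemeshow rejects a misspecified link above the nominal rate", {
  # probit truth, logit fit: the links only separate with wide linear
  # predictors and enough observations per risk decile
  set.seed(39)
  rej <- replicate(50, {
    x <- rnorm(10000, sd = 2)
    y <- rbinom(10000, 1, pnorm(1.5 * x))
    hosmer_lemeshow(fit_logistic(y, x))$p_value < 0.05
  })
  expect_gt(mean(rej), 0.10)
})

test_that("ROC handles the enumerated example, separation, and ties", {
  r <- roc_curve(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))
  expect_equal(r$auroc, 0.75)
  perfect <- roc_curve(c(10, 9, 1, 2), c(1, 1, 0, 0))
  expect_equal(perfect$auroc, 1)
  tied <- roc_curve(rep(0.3, 8), rep(c(0, 1), 4))
  expect_equal(tied$auroc, 0.5)
  expect_error(roc_curve(1:4, rep(1, 4)), "both classes")
  # curve monotone: sensitivity non-increasing as threshold rises
  expect_true(all(diff(r$curve$sensitivity) <= 0))
})

test_that("trapezoid AUROC equals exhaustive pair enumeration", {
  set.seed(40)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5)) # both classes guaranteed
    scores <- round(runif(n), 2)              # forces some ties
    expect_equal(roc_curve(scores, labels)$auroc,
                 pair_auroc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUROC agrees with the independent pROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(43)
  scores <- runif(120)
  labels <- rbinom(120, 1, plogis(3 * scores - 1.5))
  got <- roc_curve(scores, labels)$auroc
  ref <- suppressMessages(as.numeric(pROC::auc(labels, scores)))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("the operating point reports the confusion-matrix rates", {
  scores <- c(0.9, 0.8, 0.6, 0.4, 0.3, 0.1)
  labels <- c(1, 1, 0, 1, 0, 0)
  op <- roc_curve(scores, labels, classification_cut = 0.5)$operating_point
  expect_equal(op$sensitivity, 2 / 3)
  expect_equal(op$specificity, 2 / 3)
  expect_equal(op$ppv, 2 / 3)
  expect_equal(op$npv, 2 / 3)
})

test_that("the model report is deterministic and respects nesting", {
  set.seed(44)
  d <- tibble::tibble(
    x1 = rnorm(300), x2 = rnorm(300)
  )
  d$case <- rbinom(300, 1, plogis(d$x1))
  rep1 <- model_comparison_report(d, "case",
                                  list(a = "x1", b = c("x1", "x2"), a2 = "x1"))
  expect_identical(rep1$auroc[rep1$model == "a"], rep1$auroc[rep1$model == "a2"])
  # a superset model's in-sample AUROC dominates its subset's up to the
  # small slack ML fitting allows (likelihood, not concordance, is maximised)
  expect_gte(rep1$auroc[rep1$model == "b"], rep1$auroc[rep1$model == "a"][1] - 0.005)
  expect_true(all(diff(rep1$auroc) <= 1e-12))
  expect_identical(nrow(model_comparison_report(d, "case", list())), 0L)
  expect_error(model_comparison_report(d, "case", list("ghost")), "ghost")
  expect_identical(length(format_report(rep1)), nrow(rep1) + 2L)
})

test_that("tidy and glance expose the fit in broom shape", {
  set.seed(45)
  x <- rnorm(200)
  y <- rbinom(200, 1, plogis(x))
  fit <- fit_logistic(y, cbind(biomarker = x))
  td <- tidy(fit)
  expect_identical(td$term, c("(Intercept)", "biomarker"))
  expect_identical(names(td),
                   c("term", "estimate", "std_error", "wald", "p_value"))
  gl <- glance(fit)
  expect_identical(gl$n, 200L)
  expect_identical(nrow(gl), 1L)
  roc <- roc_curve(fit$fitted, y)
  expect_s3_class(autoplot(roc), "ggplot")
})
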