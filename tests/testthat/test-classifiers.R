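test_that("DLDA discriminant scores equal the brute-force log-density oracle", {
  set.seed(31)
  x <- matrix(rnorm(30 * 4), 30)
  y <- factor(rep(c("g-", "g+"), c(14, 16)), levels = c("g-", "g+"))
  fit <- dlda(x, y)
  newx <- matrix(rnorm(12 * 4), 12)
  pred <- predict(fit, newx)
  oracle <- dlda_oracle_scores(newx, fit$class_means, fit$pooled_vars,
                               fit$priors)
  expect_lt(max(abs(pred$scores - oracle)), 1e-10)
  expect_identical(as.character(pred$label),
                   fit$class_labels[max.col(oracle)])
})

test_that("DLDA centroid and midpoint queries resolve as documented", {
  fit <- structure(
    list(feature_ids = 1:2,
         class_means = matrix(c(0, 0, 1, 1), 2, byrow = TRUE,
                              dimnames = list(c("g-", "g+"), NULL)),
         pooled_vars = c(1, 1), priors = c("g-" = .5, "g+" = .5),
         class_labels = c("g-", "g+"), n_floored = 0L),
    class = "dlda")
  p <- predict(fit, rbind(c(0, 0), c(1, 1), c(0.5, 0.5)))
  expect_equal(as.character(p$label), c("g-", "g+", "g-"))  # tie -> g-
  expect_equal(unname(p$scores[3, 1]), unname(p$scores[3, 2]))
})

test_that("DLDA is invariant to per-feature shift and rescale on refit", {
  set.seed(32)
  x <- matrix(rnorm(60 * 5), 60)
  y <- factor(rep(c("g-", "g+"), each = 30))
  newx <- matrix(rnorm(20 * 5), 20)
  base <- predict(dlda(x, y), newx)$label
  shift <- matrix(rep(c(3, -2, 0, 1, 10), each = 60), 60)
  expect_identical(predict(dlda(x + shift, y), newx + shift[1:20, ])$label,
                   base)
  expect_identical(predict(dlda(x * 4, y), newx * 4)$label, base)
})

test_that("DLDA agrees with full-covariance LDA when the truth is diagonal", {
  set.seed(33)
  n <- 5000
  mu <- c(0.6, -0.4, 0.8)
  cls <- rbinom(n, 1, 0.4)
  x <- matrix(rnorm(n * 3), n) + outer(cls, mu)
  y <- factor(ifelse(cls == 1, "g+", "g-"), levels = c("g-", "g+"))
  ours <- predict(dlda(x, y), x)$label
  full <- MASS::lda(x, grouping = y)
  theirs <- predict(full, x)$class
  expect_gt(mean(ours == theirs), 0.99)
})

test_that("DLDA handles many features, floors degenerate variances, and validates", {
  set.seed(34)
  x <- matrix(rnorm(30 * 10000), 30)
  y <- factor(rep(c("g-", "g+"), each = 15))
  expect_silent(fit <- dlda(x, y))
  expect_equal(ncol(fit$class_means), 10000L)

  xz <- cbind(x[, 1:3], rep(1, 30))  # zero-variance feature
  fitz <- dlda(xz, y)
  expect_equal(fitz$n_floored, 1L)
  expect_true(all(fitz$pooled_vars > 0))

  expect_error(dlda(x, rep("g+", 30)), "two classes")
  expect_error(predict(fit, x[, 1:5]), "features")
})

test_that("ASD voting reproduces hand-enumerated labels and strict thresholds", {
  mk <- data.frame(probe_id = 1L, beta2 = 1, beta3 = 2)
  # score = 1 + 2*0.5 = 2.0: strictly above ln_R = 1, not above ln_R = 2
  r1 <- asd_rule(mk, ln_R = 1, G = 1)
  r2 <- asd_rule(mk, ln_R = 2, G = 1)
  x <- matrix(0.5, 1, 1)
  expect_equal(as.character(predict(r1, x)$label), "g+")
  expect_equal(as.character(predict(r2, x)$label), "g-")

  mk3 <- data.frame(probe_id = 1:3, beta2 = c(0, 0, 0), beta3 = c(1, 1, 1))
  xs <- rbind(c(2, 2, -5), c(2, -5, -5), c(-5, -5, -5))
  # votes at ln_R = 1: 2, 1, 0
  for (g in 1:3) {
    lab <- predict(asd_rule(mk3, 1, g), xs)$label
    expect_equal(as.character(lab),
                 ifelse(c(2, 1, 0) >= g, "g+", "g-"))
  }
  # more votes required than markers exist: always g-
  lab <- predict(asd_rule(mk3, ln_R = -100, G = 4), xs)$label
  expect_true(all(lab == "g-"))
  expect_warning(
    lab0 <- predict(asd_rule(mk3[0, ], 1, 1), xs)$label, "empty")
  expect_true(all(lab0 == "g-"))
})

test_that("ASD labelling is monotone in ln_R and G", {
  set.seed(35)
  mk <- data.frame(probe_id = 1:6, beta2 = rnorm(6), beta3 = rnorm(6))
  x <- matrix(rnorm(50 * 6), 50)
  for (r in 1:20) {
    ln_r <- sort(rnorm(2))
    g <- sort(sample(1:6, 2))
    hi <- predict(asd_rule(mk, ln_r[1], g[1]), x)$label == "g+"
    lo1 <- predict(asd_rule(mk, ln_r[2], g[1]), x)$label == "g+"
    lo2 <- predict(asd_rule(mk, ln_r[1], g[2]), x)$label == "g+"
    expect_true(all(lo1 <= hi))  # raising ln_R never adds g+ patients
    expect_true(all(lo2 <= hi))  # raising G never adds g+ patients
  }
})

test_that("Cox risk-score baseline matches the closed-form Breslow oracle", {
  co <- list(time = c(1, 2, 3, 4), event = c(1L, 1L, 0L, 1L),
             arm = c(0L, 1L, 0L, 1L),
             expression = matrix(c(0.5, -0.5, 1, -1), 4, 1))
  ms <- adaptsig:::marker_set(
    data.frame(probe_id = 1L, beta0 = NA, beta2 = 0, beta3 = 0,
               se3 = NA, p_value = 0.5, converged = TRUE))
  fit <- suppressWarnings(cox_score(co, ms, horizon = 2.5))
  lp <- drop(co$expression %*% fit$weights)
  oracle <- breslow_oracle(co$time, co$event, lp)
  idx <- match(oracle$time, fit$baseline$time)
  expect_false(anyNA(idx))
  expect_equal(-log(fit$baseline$surv[idx]), oracle$hazard,
               tolerance = 1e-6)
})

test_that("a zero-weight risk score predicts the baseline for everyone", {
  co <- simulate_survival_cohort(30, n_probes = 6, n_predictive = 2,
                                 seed = 41)
  ms <- cox_screen_markers(co, top_k = 2)
  fit <- cox_score(co, ms, horizon = 3)
  fit$weights <- rep(0, length(fit$weights))
  pr <- predict(fit, co$expression)
  s0 <- adaptsig:::baseline_surv_at(fit, 3)
  expect_true(all(abs(pr$surv_prob - s0) < 1e-12))
})

test_that("Cox risk-score recovers a known log-hazard coefficient", {
  set.seed(42)
  n <- 2000
  x <- matrix(rnorm(n), n, 1)
  co <- list(time = rexp(n, 0.2 * exp(1.0 * x[, 1])),
             event = rep(1L, n), arm = rep(0:1, n / 2), expression = x)
  ms <- adaptsig:::marker_set(
    data.frame(probe_id = 1L, beta0 = NA, beta2 = 0, beta3 = 0,
               se3 = NA, p_value = 0.5, converged = TRUE))
  fit <- suppressWarnings(cox_score(co, ms))
  expect_equal(fit$weights, 1.0, tolerance = 0.1)
})

test_that("survival-probability cutoff classifies with ties to g+", {
  fit <- structure(
    list(feature_ids = 1L, weights = 1,
         baseline = data.frame(time = c(1, 2), surv = c(0.9, 0.5)),
         horizon = 2, cutoff = 0.5),
    class = "cox_score")
  # lp = x; S(2|x) = 0.5^exp(x): x=0 -> exactly 0.5 -> g+ (tie rule);
  # x<0 -> S>0.5 -> g+; x>0 -> S<0.5 -> g-
  pr <- predict(fit, matrix(c(-1, 0, 1), 3, 1))
  expect_equal(as.character(pr$label), c("g+", "g+", "g-"))
  expect_equal(pr$surv_prob[2], 0.5)
  # monotone: sorting by the linear predictor never flips g- back to g+
  set.seed(43)
  xs <- matrix(sort(rnorm(50)), 50, 1)
  lab <- predict(fit, xs)$label
  expect_true(all(diff(lab == "g-") >= 0))
  # horizon beyond the last baseline time falls back with a warning
  fit$horizon <- 10
  expect_warning(pr2 <- predict(fit, matrix(0, 1, 1)), "baseline")
  expect_equal(pr2$surv_prob, 0.5)
})

test_that("classifier models survive a JSON round trip", {
  set.seed(44)
  x <- matrix(rnorm(40 * 3), 40)
  y <- factor(rep(c("g-", "g+"), each = 20))
  newx <- matrix(rnorm(10 * 3), 10)
  tmp <- withr::local_tempfile(fileext = ".json")

  fit <- dlda(x, y)
  write_model_json(fit, tmp)
  back <- read_model_json(tmp)
  expect_equal(predict(back, newx)$scores, predict(fit, newx)$scores,
               tolerance = 1e-12)

  rule <- asd_rule(data.frame(probe_id = 1:3, beta2 = rnorm(3),
                              beta3 = rnorm(3)), ln_R = 1, G = 2)
  write_model_json(rule, tmp)
  expect_equal(predict(read_model_json(tmp), newx)$votes,
               predict(rule, newx)$votes)

  co <- simulate_survival_cohort(30, n_probes = 6, seed = 45)
  cs <- cox_score(co, cox_screen_markers(co, top_k = 2))
  write_model_json(cs, tmp)
  expect_equal(predict(read_model_json(tmp), co$expression)$surv_prob,
               predict(cs, co$expression)$surv_prob, tolerance = 1e-12)
})
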