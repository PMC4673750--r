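test_that("confusion metrics match hand-computed 2x2 values", {
  pred <- rep(c("g+", "g-", "g-", "g+"), c(3, 2, 90, 5))
  true <- rep(c("g+", "g+", "g-", "g-"), c(3, 2, 90, 5))
  cm <- confusion_metrics(pred, true)
  expect_equal(c(cm$tp, cm$fn, cm$tn, cm$fp), c(3, 2, 90, 5))
  expect_equal(cm$sensitivity, 0.6)
  expect_equal(cm$specificity, 90 / 95, tolerance = 1e-12)
  expect_equal(cm$ppv, 0.375)
  expect_equal(cm$npv, 90 / 92, tolerance = 1e-12)
  expect_equal(cm$accuracy, 0.93)

  perfect <- confusion_metrics(true, true)
  expect_true(all(unlist(perfect[c("sensitivity", "specificity", "ppv",
                                   "npv", "accuracy")]) == 1))
  # zero denominators are NA, not NaN; counts still present
  none <- confusion_metrics(rep("g-", 4), rep("g-", 4))
  expect_true(is.na(none$ppv) && is.na(none$sensitivity))
  expect_equal(none$specificity, 1)
  expect_error(confusion_metrics(c("yes", "no"), c("g+", "g-")), "labels")
})

test_that("Fisher p-values equal the hypergeometric enumeration oracle", {
  # exhaustive over all tables with row sums <= 12, plus random larger
  # tables up to n = 60
  tabs <- list()
  for (a in 0:12) for (b in 0:(12 - a))
    for (c in 0:12) for (d in 0:(12 - c))
      if (a + b > 0 && c + d > 0)
        tabs[[length(tabs) + 1L]] <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  set.seed(71)
  for (r in 1:150) {
    n <- sample(4:60, 1)
    cuts <- sort(sample(0:n, 3, replace = TRUE))
    tabs[[length(tabs) + 1L]] <- matrix(c(cuts[1], cuts[2] - cuts[1],
                                          cuts[3] - cuts[2], n - cuts[3]),
                                        2, byrow = TRUE)
  }
  worst <- 0
  for (tab in tabs) {
    for (alt in c("greater", "two.sided")) {
      p_pkg <- fisher.test(tab, alternative = alt)$p.value
      p_orc <- fisher_oracle(tab, alt)
      worst <- max(worst, abs(p_pkg - p_orc))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("the five comparisons dispatch, orient, and flag as specified", {
  # orientation: one-sided in favor of treatment
  co <- list(response = rep(c(1L, 0L, 1L, 0L), c(40, 10, 10, 40)),
             arm = rep(c(1L, 0L), each = 50))
  lab <- factor(rep(c("g+", "g-"), 50), levels = c("g-", "g+"))
  cr <- run_comparisons(co, lab)
  expect_lt(cr$p[["p1"]], 0.001)  # treatment clearly better
  co_flip <- co
  co_flip$arm <- 1L - co$arm
  expect_gt(run_comparisons(co_flip, lab)$p[["p1"]], 0.999)

  # no responders anywhere: one-sided p = 1
  co0 <- list(response = rep(0L, 40), arm = rep(0:1, 20))
  cr0 <- run_comparisons(co0, factor(rep(c("g-", "g+"), 20),
                                     levels = c("g-", "g+")))
  expect_equal(cr0$p[["p1"]], 1)

  # empty g+ stratum: comparisons 2, 4, 5 not evaluable
  cr_empty <- run_comparisons(co, factor(rep("g-", 100),
                                         levels = c("g-", "g+")))
  expect_false(cr_empty$evaluable[["p2"]])
  expect_false(cr_empty$evaluable[["p4"]])
  expect_true(is.na(cr_empty$p[["p2"]]))
  expect_true(cr_empty$evaluable[["p1"]])

  # p-values agree with direct fisher.test calls of the stated sidedness
  set.seed(72)
  co2 <- list(response = rbinom(80, 1, 0.4), arm = rep(0:1, 40))
  lab2 <- factor(sample(c("g-", "g+"), 80, TRUE), levels = c("g-", "g+"))
  cr2 <- run_comparisons(co2, lab2)
  gp <- lab2 == "g+"
  expect_equal(cr2$p[["p2"]],
               fisher.test(table(factor(co2$arm[gp], levels = 0:1),
                                 factor(co2$response[gp], levels = 0:1)),
                           alternative = "greater")$p.value)
  expect_equal(cr2$p[["p4"]],
               fisher.test(table(factor(gp[co2$arm == 1]),
                                 factor(co2$response[co2$arm == 1],
                                        levels = 0:1)))$p.value)
})

test_that("survival comparisons use the logrank test per stratum", {
  co <- simulate_survival_cohort(40, n_probes = 2,
                                 hazards = c(h00 = .5, h01 = .5,
                                             h10 = .5, h11 = .08),
                                 seed = 73)
  cr <- run_comparisons(co, co$subgroup, endpoint = "survival")
  gp <- co$subgroup == "g+"
  sd2 <- survival::survdiff(
    survival::Surv(co$time[gp], co$event[gp]) ~ co$arm[gp])
  expect_equal(cr$p[["p2"]], pchisq(sd2$chisq, 1, lower.tail = FALSE))
  expect_lt(cr$p[["p2"]], 0.01)  # g+ patients benefit
  expect_true(all(c("n", "median_survival") %in% names(cr$cells)))
})

test_that("power accounting satisfies the overall + rescue identity", {
  plan <- test_plan(alpha = 0.05, alpha1 = 0.02)
  pt <- summarize_power(list(p1 = c(0.01, 0.5, 0.5), p2 = c(0.9, 0.01, 0.5)),
                        plan)
  expect_equal(c(pt$count_overall_sig, pt$count_subgroup_rescue,
                 pt$overall_power_count), c(1, 1, 2))
  expect_equal(summarize_power(list(p1 = rep(1, 5), p2 = rep(1, 5)),
                               plan)$overall_power_count, 0)
  # identity holds for arbitrary p-value lists, including NAs
  set.seed(74)
  for (r in 1:25) {
    p1 <- runif(50)
    p2 <- ifelse(runif(50) < 0.1, NA, runif(50))
    pt <- summarize_power(list(p1 = p1, p2 = p2), plan)
    expect_equal(pt$overall_power_count,
                 sum(p1 <= 0.02) +
                   sum(p1 > 0.02 & !is.na(p2) & p2 <= 0.03))
    expect_lte(pt$overall_power_count, pt$n_replicates)
  }
  expect_error(test_plan(alpha = 0.05, alpha1 = 0.06), "alpha")
})

test_that("comparison results feed power accounting coherently", {
  sc <- small_binary_scenario(n_per_arm = 40, n_probes = 4,
                              n_predictive = 0)
  plan <- test_plan()
  results <- lapply(1:10, function(r) {
    co <- simulate_trial(sc, seed = 750 + r)
    run_comparisons(co, co$subgroup, plan = plan)
  })
  pt <- summarize_power(results, plan)
  p1 <- vapply(results, function(x) x$p[["p1"]], numeric(1))
  expect_equal(pt$count_overall_sig, sum(p1 <= plan$alpha1))
  rescue_flags <- vapply(results, `[[`, TRUE, "subgroup_rescue")
  expect_equal(pt$count_subgroup_rescue, sum(rescue_flags))
})

test_that("expected misclassification arithmetic reproduces the attenuation", {
  e <- builtin_scenario("E")
  ec <- expected_confusion_or(e, 0.991, 0.644)
  expect_equal(ec$false_positives_per_arm, 64)
  expect_equal(ec$table$responders, c(17, 29))
  expect_equal(ec$table$non_responders, c(67, 55))
  expect_equal(round(ec$attenuated_or, 2), 2.08)
  expect_equal(ec$true_or, 16)
  # a perfect classifier recovers the true odds ratio exactly
  expect_equal(expected_confusion_or(e, 1, 1)$attenuated_or, 16)
  # degenerate response probabilities are refused
  bad <- suppressWarnings(
    scenario(pi = .1, u00 = .2, u01 = .2, u10 = .2, u11 = 1))
  expect_error(expected_confusion_or(bad, .9, .9), "degenerate")
})

test_that("attenuation is monotone in the operating characteristics", {
  e <- builtin_scenario("E")
  grid <- seq(0.3, 1, by = 0.05)
  for (sens in c(0.5, 0.8, 1)) {
    ors <- vapply(grid, function(sp)
      expected_confusion_or(e, sens, sp, round_counts = FALSE)$attenuated_or,
      numeric(1))
    expect_true(all(diff(ors) >= -1e-9))
  }
  for (sp in c(0.5, 0.8, 1)) {
    ors <- vapply(grid, function(sens)
      expected_confusion_or(e, sens, sp, round_counts = FALSE)$attenuated_or,
      numeric(1))
    expect_true(all(diff(ors) >= -1e-9))
  }
  expect_equal(
    expected_confusion_or(e, 1, 1, round_counts = FALSE)$attenuated_or, 16)
})

test_that("a misclassification channel reproduces the analytic odds ratio", {
  # simulate scenario E at large n with a label-flipping classifier of
  # fixed sensitivity/specificity and compare the empirical odds ratio
  # among predicted g+ with the analytic expectation
  e <- builtin_scenario("E")
  e$n_per_arm <- 10000L
  e$n_probes <- 2L
  e$n_predictive <- 2L
  set.seed(76)
  co <- simulate_trial(e, seed = 76)
  sens <- 0.991; spec <- 0.644
  gp <- co$subgroup == "g+"
  pred <- ifelse(gp, rbinom(20000, 1, sens), rbinom(20000, 1, 1 - spec))
  sel <- pred == 1
  tab <- table(arm = co$arm[sel], resp = co$response[sel])
  emp_or <- (tab["1", "1"] * tab["0", "0"]) /
    (tab["1", "0"] * tab["0", "1"])
  ana <- expected_confusion_or(e, sens, spec, round_counts = FALSE)
  expect_equal(log(emp_or), log(ana$attenuated_or), tolerance = 0.15)
})
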