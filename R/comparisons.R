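#' Study-wise alpha allocation between the overall and subgroup tests
#'
#' The two primary hypotheses are treatment effect in all patients
#' (Comparison 1) and in the identified `g+` subgroup (Comparison 2). The
#' study-wise type-I error `alpha` is split as `alpha1` for the overall
#' test and `alpha2 = alpha - alpha1` for the subgroup test. The defaults
#' are 2% (one-sided) overall and 3% for the subgroup, i.e. a 5%
#' study-wise budget.
#'
#' @param alpha Study-wise error rate in (0, 1).
#' @param alpha1 Level of the all-patients test, in (0, alpha).
#' @return An object of class `"test_plan"` with `alpha`, `alpha1`,
#'   `alpha2`.
#' @export
test_plan <- function(alpha = 0.05, alpha1 = 0.02) {
  if (alpha <= 0 || alpha >= 1 || alpha1 <= 0 || alpha1 >= alpha)
    stop("need 0 < alpha1 < alpha < 1", call. = FALSE)
  structure(list(alpha = alpha, alpha1 = alpha1, alpha2 = alpha - alpha1),
            class = "test_plan")
}

#' @export
print.test_plan <- function(x, ...) {
  cat(sprintf("Alpha allocation: overall %g + subgroup %g = study-wise %g\n",
              x$alpha1, x$alpha2, x$alpha))
  invisible(x)
}

#' Classifier operating characteristics against the true subgroup
#'
#' Cross-tabulates predicted against true `g+`/`g-` labels (`g+` is the
#' positive class) and reports sensitivity, specificity, positive and
#' negative predictive values, and accuracy. A proportion whose
#' denominator is zero (e.g. PPV with no predicted positives) is reported
#' as `NA` with the counts left to tell the story, never silently
#' propagated.
#'
#' @param predicted,truth Label vectors with values in `{"g+", "g-"}`
#'   (factors or characters), equal length.
#' @return An object of class `"confusion_metrics"`: counts `tp`, `fp`,
#'   `tn`, `fn` and proportions `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `accuracy`.
#' @export
#' @examples
#' confusion_metrics(c("g+", "g+", "g-"), c("g+", "g-", "g-"))
confusion_metrics <- function(predicted, truth) {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (length(predicted) != length(truth))
    stop("'predicted' and 'truth' must have equal length", call. = FALSE)
  ok <- c("g+", "g-")
  if (!all(predicted %in% ok) || !all(truth %in% ok))
    stop("labels must be 'g+' or 'g-'", call. = FALSE)
  tp <- sum(predicted == "g+" & truth == "g+")
  fp <- sum(predicted == "g+" & truth == "g-")
  tn <- sum(predicted == "g-" & truth == "g-")
  fn <- sum(predicted == "g-" & truth == "g+")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = safe_div(tp, tp + fn),
         specificity = safe_div(tn, tn + fp),
         ppv = safe_div(tp, tp + fp),
         npv = safe_div(tn, tn + fn),
         accuracy = safe_div(tp + tn, tp + fp + tn + fn)),
    class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("Confusion (g+ positive): tp=%d fp=%d tn=%d fn=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  v <- unlist(x[c("sensitivity", "specificity", "ppv", "npv", "accuracy")])
  cat(" ", paste(sprintf("%s=%.3f", names(v), v), collapse = "  "), "\n")
  invisible(x)
}

# Fisher's exact test on groups/outcome 0-1 vectors; alternative refers to
# the odds of outcome in group 1 vs group 0.
fisher_p <- function(group, outcome, alternative) {
  tab <- table(factor(group, levels = c(0, 1)),
               factor(outcome, levels = c(0, 1)))
  stats::fisher.test(tab, alternative = alternative)$p.value
}

logrank_p <- function(time, event, group) {
  if (length(unique(group)) < 2L) return(NA_real_)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
}

#' The five subgroup comparisons
#'
#' Given outcomes and a cross-validated subgroup assignment, computes the
#' p-values of the five comparisons of the testing strategy:
#' 1. control vs treatment in all patients;
#' 2. control vs treatment in the predicted `g+` patients;
#' 3. control vs treatment in the predicted `g-` patients;
#' 4. `g+` vs `g-` within the treatment arm;
#' 5. `g+` vs `g-` within the control arm.
#'
#' Binary endpoints use Fisher's exact test — one-sided in favor of
#' treatment for Comparisons 1-2 (matching the one-sided alpha
#' allocation), two-sided for 3-5; survival endpoints use the logrank
#' test. Comparison 2 is always computed (the strategy tests all patients
#' *and* the `g+` subgroup with split alpha, unlike the legacy sequencing
#' that only tested the subgroup after an overall failure; the legacy
#' accounting is available in [summarize_power()]). A comparison with an
#' empty stratum is flagged not-evaluable (`NA`), never fabricated.
#'
#' @param cohort A `"patient_cohort"`, `"survival_cohort"`, or a list with
#'   `arm` plus `response` (binary) or `time` + `event` (survival).
#' @param assignment A `"subgroup_assignment"`, or a `g+`/`g-` label
#'   vector.
#' @param plan A [test_plan()].
#' @param endpoint `"auto"` (detect from the cohort fields), `"binary"`,
#'   or `"survival"`.
#' @return An object of class `"comparison_results"`: `p` (named vector
#'   `p1`..`p5`), `evaluable`, `cells` (per (label, arm) cell: n plus
#'   response rate or median survival), `overall_significant`
#'   (`p1 <= alpha1`), `subgroup_significant` (`p2 <= alpha2`),
#'   `subgroup_rescue` (`p1 > alpha1` and `p2 <= alpha2`), `plan`,
#'   `endpoint`.
#' @export
run_comparisons <- function(cohort, assignment, plan = test_plan(),
                            endpoint = c("auto", "binary", "survival")) {
  endpoint <- match.arg(endpoint)
  label <- if (inherits(assignment, "subgroup_assignment"))
    assignment$label else factor(as.character(assignment),
                                 levels = c("g-", "g+"))
  arm <- cohort$arm
  if (length(label) != length(arm))
    stop("assignment does not cover the cohort", call. = FALSE)
  if (endpoint == "auto")
    endpoint <- if (!is.null(cohort$response)) "binary" else "survival"
  gpos <- label == "g+"
  # a comparison is evaluable only when both compared groups are non-empty
  eval5 <- c(p1 = length(unique(arm)) == 2L,
             p2 = length(unique(arm[gpos])) == 2L,
             p3 = length(unique(arm[!gpos])) == 2L,
             p4 = length(unique(label[arm == 1L])) == 2L,
             p5 = length(unique(label[arm == 0L])) == 2L)
  p <- c(p1 = NA_real_, p2 = NA_real_, p3 = NA_real_, p4 = NA_real_,
         p5 = NA_real_)
  if (endpoint == "binary") {
    y <- cohort$response
    if (eval5["p1"]) p["p1"] <- fisher_p(arm, y, "greater")
    if (eval5["p2"]) p["p2"] <- fisher_p(arm[gpos], y[gpos], "greater")
    if (eval5["p3"]) p["p3"] <- fisher_p(arm[!gpos], y[!gpos], "two.sided")
    if (eval5["p4"]) p["p4"] <- fisher_p(as.integer(gpos[arm == 1L]),
                                         y[arm == 1L], "two.sided")
    if (eval5["p5"]) p["p5"] <- fisher_p(as.integer(gpos[arm == 0L]),
                                         y[arm == 0L], "two.sided")
    cells <- stats::aggregate(
      y, by = list(label = label, arm = arm),
      FUN = function(v) c(n = length(v), rate = mean(v)))
    cells <- data.frame(label = cells$label, arm = cells$arm,
                        n = cells$x[, "n"], response_rate = cells$x[, "rate"])
  } else {
    tm <- cohort$time; ev <- cohort$event
    if (eval5["p1"]) p["p1"] <- logrank_p(tm, ev, arm)
    if (eval5["p2"]) p["p2"] <- logrank_p(tm[gpos], ev[gpos], arm[gpos])
    if (eval5["p3"]) p["p3"] <- logrank_p(tm[!gpos], ev[!gpos], arm[!gpos])
    if (eval5["p4"]) p["p4"] <- logrank_p(tm[arm == 1L], ev[arm == 1L],
                                          label[arm == 1L])
    if (eval5["p5"]) p["p5"] <- logrank_p(tm[arm == 0L], ev[arm == 0L],
                                          label[arm == 0L])
    cells <- do.call(rbind, lapply(split(
      seq_along(arm), list(label = label, arm = arm)), function(ix) {
        if (!length(ix)) return(NULL)
        med <- if (sum(ev[ix]) > 0) {
          sf <- survival::survfit(survival::Surv(tm[ix], ev[ix]) ~ 1)
          unname(stats::quantile(sf, probs = 0.5)$quantile)
        } else NA_real_
        data.frame(label = as.character(label[ix[1L]]), arm = arm[ix[1L]],
                   n = length(ix), median_survival = med)
      }))
    rownames(cells) <- NULL
  }
  structure(
    list(p = p, evaluable = eval5, cells = cells,
         overall_significant = isTRUE(p[["p1"]] <= plan$alpha1),
         subgroup_significant = isTRUE(p[["p2"]] <= plan$alpha2),
         subgroup_rescue = isTRUE(p[["p1"]] > plan$alpha1) &&
           isTRUE(p[["p2"]] <= plan$alpha2),
         plan = plan, endpoint = endpoint),
    class = "comparison_results")
}

#' @export
print.comparison_results <- function(x, ...) {
  lab <- c("1 ctrl vs trt, all patients",
           "2 ctrl vs trt, g+",
           "3 ctrl vs trt, g-",
           "4 g+ vs g-, treatment arm",
           "5 g+ vs g-, control arm")
  cat(sprintf("Subgroup comparisons (%s endpoint)\n", x$endpoint))
  for (i in 1:5) {
    pv <- if (x$evaluable[i]) sprintf("%.4g", x$p[i]) else "not evaluable"
    cat(sprintf("  Comparison %-28s p = %s\n", lab[i], pv))
  }
  cat(sprintf("  overall test at %g: %s; g+ subgroup at %g: %s\n",
              x$plan$alpha1,
              if (x$overall_significant) "significant" else "not significant",
              x$plan$alpha2,
              if (x$subgroup_significant) "significant" else "not significant"))
  invisible(x)
}

#' Replicate-level power accounting
#'
#' Aggregates the overall/subgroup test outcomes of simulated replicates
#' with the legacy adaptive-signature accounting: overall power is the
#' number of replicates in which the all-patients test rejects at
#' `alpha1`, plus the number in which it fails but the `g+` subgroup test
#' rejects at `alpha2`.
#'
#' @param results A list of `"comparison_results"`, or a data.frame/list
#'   with numeric `p1` and `p2` per replicate.
#' @param plan A [test_plan()].
#' @return An object of class `"power_table"`: `count_overall_sig`
#'   (`p1 <= alpha1`), `count_subgroup_rescue` (`p1 > alpha1` and
#'   `p2 <= alpha2`), `overall_power_count` (their sum), `n_replicates`,
#'   and the corresponding proportions. A non-evaluable `p2` never
#'   rescues.
#' @export
summarize_power <- function(results, plan = test_plan()) {
  if (is.list(results) && length(results) &&
      inherits(results[[1L]], "comparison_results")) {
    p1 <- vapply(results, function(r) r$p[["p1"]], numeric(1))
    p2 <- vapply(results, function(r) r$p[["p2"]], numeric(1))
  } else {
    p1 <- results$p1
    p2 <- results$p2
  }
  if (!length(p1)) stop("no replicate results supplied", call. = FALSE)
  overall <- sum(p1 <= plan$alpha1, na.rm = TRUE)
  rescue <- sum(p1 > plan$alpha1 & p2 <= plan$alpha2, na.rm = TRUE)
  structure(
    list(count_overall_sig = overall,
         count_subgroup_rescue = rescue,
         overall_power_count = overall + rescue,
         n_replicates = length(p1),
         prop_overall_sig = overall / length(p1),
         overall_power = (overall + rescue) / length(p1),
         plan = plan),
    class = "power_table")
}

#' @export
print.power_table <- function(x, ...) {
  cat(sprintf("Power over %d replicates (alpha1 = %g, alpha2 = %g)\n",
              x$n_replicates, x$plan$alpha1, x$plan$alpha2))
  cat(sprintf("  overall test significant: %d\n", x$count_overall_sig))
  cat(sprintf("  subgroup rescue (overall failed, g+ significant): %d\n",
              x$count_subgroup_rescue))
  cat(sprintf("  overall power: %d (%.3f)\n", x$overall_power_count,
              x$overall_power))
  invisible(x)
}

# round-half-up, replicating printed-table arithmetic (R's round() is
# round-half-even)
round_half_up <- function(x) floor(x + 0.5)

#' Expected odds-ratio attenuation from classifier misclassification
#'
#' A deterministic calculator for the cost of an imperfect subgroup
#' classifier: given a scenario and the classifier's sensitivity and
#' specificity, it forms the *expected* per-arm 2x2 responder table among
#' the patients predicted `g+` — `sens * pi * n` true `g+` plus
#' `(1 - spec) * (1 - pi) * n` false `g-` per arm, each contributing
#' responders at their cell probability `u` — and reports the odds ratio
#' of treatment response computed from those tables, alongside the true
#' subgroup odds ratio `[u11 / (1 - u11)] / [u10 / (1 - u10)]`. Expected
#' cell counts are rounded half-up to integers before the ratio
#' (`round_counts = FALSE` keeps them continuous, which makes the
#' attenuation exactly monotone in sensitivity and specificity).
#'
#' @param scenario An `"asd_scenario"`.
#' @param sensitivity,specificity Classifier operating characteristics in
#'   `[0, 1]`.
#' @param round_counts Round expected cell counts to integers (default
#'   `TRUE`).
#' @return An object of class `"expected_confusion"`: `table` (per-arm
#'   expected responders / non-responders among predicted `g+`),
#'   `false_positives_per_arm`, `attenuated_or`, `true_or`.
#' @export
#' @examples
#' expected_confusion_or(builtin_scenario("E"), 0.991, 0.644)
expected_confusion_or <- function(scenario, sensitivity, specificity,
                                  round_counts = TRUE) {
  stopifnot(inherits(scenario, "asd_scenario"))
  if (sensitivity < 0 || sensitivity > 1 ||
      specificity < 0 || specificity > 1)
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  us <- c(scenario$u00, scenario$u01, scenario$u10, scenario$u11)
  if (any(us <= 0 | us >= 1))
    stop("degenerate response probabilities (0 or 1): the odds ratio is ",
         "undefined", call. = FALSE)
  n <- scenario$n_per_arm
  n_true_pos <- sensitivity * scenario$pi * n            # per arm
  n_false_pos <- (1 - specificity) * (1 - scenario$pi) * n
  rnd <- if (round_counts) round_half_up else identity
  # expected responders among predicted g+, by arm
  resp <- c(control = n_true_pos * scenario$u10 + n_false_pos * scenario$u00,
            treatment = n_true_pos * scenario$u11 + n_false_pos * scenario$u01)
  total <- n_true_pos + n_false_pos
  nonresp <- total - resp
  resp <- rnd(resp); nonresp <- rnd(nonresp)
  or <- (resp[["treatment"]] / nonresp[["treatment"]]) /
    (resp[["control"]] / nonresp[["control"]])
  true_or <- (scenario$u11 * (1 - scenario$u10)) /
    ((1 - scenario$u11) * scenario$u10)
  structure(
    list(table = data.frame(arm = c("control", "treatment"),
                            responders = unname(resp),
                            non_responders = unname(nonresp)),
         false_positives_per_arm = rnd(n_false_pos),
         attenuated_or = unname(or), true_or = true_or,
         sensitivity = sensitivity, specificity = specificity),
    class = "expected_confusion")
}

#' @export
print.expected_confusion <- function(x, ...) {
  cat(sprintf(
    "Expected predicted-g+ stratum (sens %.3f, spec %.3f):\n",
    x$sensitivity, x$specificity))
  print(x$table, row.names = FALSE)
  cat(sprintf("  expected false-positive g- patients per arm: %g\n",
              x$false_positives_per_arm))
  cat(sprintf("  odds ratio attenuated to %.2f from the true %.2f\n",
              x$attenuated_or, x$true_or))
  invisible(x)
}
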