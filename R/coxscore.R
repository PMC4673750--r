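#' Cox risk-score model with a survival-probability cutoff
#'
#' The two-step subgroup rule for survival endpoints: (1) fit a
#' multivariable Cox proportional hazards model over the screened markers
#' (genes only — no treatment term), giving each patient the univariate
#' predictive score `l(x) = sum_l b_l x_l`; (2) convert the score to a
#' predicted survival probability at a horizon `tau` through the Breslow
#' baseline, `S(tau | x) = S0(tau)^exp(l(x))`, and label a patient `g+`
#' when that probability meets the cutoff.
#'
#' @param cohort A `"survival_cohort"` (or list with `time`, `event`,
#'   `expression`).
#' @param markers A `"marker_set"` naming the predictor columns.
#' @param horizon Prediction time `tau` in the cohort's time units
#'   (years; default 5).
#' @param cutoff Survival-probability threshold in (0, 1) (default 0.5).
#'   `S(tau|x) >= cutoff` labels `g+` (ties to `g+`).
#' @return An object of class `"cox_score"`: `feature_ids`, `weights`
#'   (the `b_l`), `baseline` (data.frame `time`, `surv` of the Breslow
#'   baseline survival, uncentered), `horizon`, `cutoff`.
#' @export
cox_score <- function(cohort, markers, horizon = 5, cutoff = 0.5) {
  stopifnot(inherits(markers, "marker_set"))
  if (horizon <= 0) stop("'horizon' must be > 0", call. = FALSE)
  if (cutoff <= 0 || cutoff >= 1)
    stop("'cutoff' must lie in (0, 1)", call. = FALSE)
  ids <- markers$probe_ids
  if (length(ids) == 0L) stop("empty marker set", call. = FALSE)
  if (sum(cohort$event) == 0L)
    stop("no events in the training data", call. = FALSE)
  x <- cohort$expression[, ids, drop = FALSE]
  if (length(ids) >= nrow(x) / 2)
    warning("marker count is large relative to the sample size; ",
            "the Cox fit may be unstable", call. = FALSE)
  surv <- survival::Surv(cohort$time, cohort$event)
  fit <- tryCatch(
    survival::coxph(surv ~ x),
    error = function(e)
      stop("Cox risk-score fit failed (", conditionMessage(e),
           "); try fewer markers", call. = FALSE))
  b <- stats::coef(fit)
  if (anyNA(b))
    stop("Cox risk-score fit is rank deficient; try fewer markers",
         call. = FALSE)
  bh <- survival::basehaz(fit, centered = FALSE)
  structure(
    list(feature_ids = ids, weights = unname(b),
         baseline = data.frame(time = bh$time,
                               surv = exp(-bh$hazard)),
         horizon = horizon, cutoff = cutoff),
    class = "cox_score")
}

# baseline survival at time tau (right-continuous step function)
baseline_surv_at <- function(model, tau) {
  bt <- model$baseline$time
  if (tau > max(bt)) {
    warning("horizon ", tau, " lies beyond the last baseline event time ",
            max(bt), "; using the last baseline value", call. = FALSE)
    tau <- max(bt)
  }
  idx <- findInterval(tau, bt)
  if (idx == 0L) 1.0 else model$baseline$surv[idx]
}

#' Classify patients with a fitted Cox risk-score rule
#'
#' @param object A `"cox_score"` model.
#' @param newdata Full expression matrix (marker columns selected by id)
#'   or a patients x L marker matrix with
#'   `expression_is_markers = TRUE`.
#' @param expression_is_markers See [predict.asd_rule()].
#' @param ... Unused.
#' @return A list with `label` (factor `g-`/`g+`; `g+` iff the predicted
#'   survival probability at the horizon is `>= cutoff`), `surv_prob`,
#'   and `score` (the linear predictor `l(x)`).
#' @export
predict.cox_score <- function(object, newdata,
                              expression_is_markers = FALSE, ...) {
  newdata <- as.matrix(newdata)
  xm <- if (expression_is_markers) {
    if (ncol(newdata) != length(object$feature_ids))
      stop("'newdata' must supply one column per model marker",
           call. = FALSE)
    newdata
  } else {
    if (max(object$feature_ids) > ncol(newdata))
      stop("'newdata' does not cover all model markers", call. = FALSE)
    newdata[, object$feature_ids, drop = FALSE]
  }
  lp <- drop(xm %*% object$weights)
  s0 <- baseline_surv_at(object, object$horizon)
  sp <- s0^exp(lp)
  list(label = factor(ifelse(sp >= object$cutoff, "g+", "g-"),
                      levels = c("g-", "g+")),
       surv_prob = sp, score = lp)
}

#' @export
print.cox_score <- function(x, ...) {
  cat(sprintf("Cox risk-score rule: %d markers, horizon %g, cutoff %g\n",
              length(x$feature_ids), x$horizon, x$cutoff))
  cat("  weights:", paste(sprintf("%.3g", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.cox_score <- function(object, ...) {
  stats::setNames(object$weights, paste0("probe_", object$feature_ids))
}
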