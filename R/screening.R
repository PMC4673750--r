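#' Fit a single treatment-by-marker interaction model
#'
#' Fits the per-probe generalized linear model
#' `h(y) = beta0 + beta2 * t + beta3 * (z * t)` used to screen for
#' predictive markers: a significant interaction coefficient `beta3`
#' indicates that the treatment effect depends on the marker `z`. Note the
#' model deliberately carries no main effect of `z`. The link `h` is the
#' logit for binary endpoints, the identity for continuous endpoints, or
#' the Cox partial likelihood for survival endpoints (then `response` must
#' be a [survival::Surv] object and the model is
#' `arm + z:arm` on the log-hazard scale).
#'
#' The reported p-value is the two-sided Wald test of `beta3 = 0`
#' (`test = "LRT"` requests the likelihood-ratio test instead).
#' Non-identifiable inputs (constant probe, single-arm data, all-equal
#' response, separation) yield `converged = FALSE` and `p_value = 1`
#' rather than an error, so a genome-wide scan never aborts on one
#' pathological probe.
#'
#' @param response Binary 0/1 vector, numeric vector (identity link), or
#'   a `Surv` object (cox link).
#' @param arm Binary 0/1 treatment indicator.
#' @param probe Numeric marker values, one per patient.
#' @param link `"logit"`, `"identity"`, or `"cox"`.
#' @param test `"Wald"` (default) or `"LRT"` for the `beta3` p-value.
#' @return An object of class `"interaction_fit"`: list with `beta0`,
#'   `beta2`, `beta3`, `se3`, `p_value`, `converged`, `link`.
#'   (`beta0` is `NA` for the Cox link, which has no intercept.)
#' @export
fit_interaction_model <- function(response, arm,  probe,
                                  link = c("logit", "identity", "cox"),
                                  test = c("Wald", "LRT")) {
  link <- match.arg(link)
  test <- match.arg(test)
  n <- length(arm)
  if (length(probe) != n)
    stop("'arm' and 'probe' must have equal length", call. = FALSE)
  bad_fit <- function() {
    structure(list(beta0 = NA_real_, beta2 = NA_real_, beta3 = NA_real_,
                   se3 = NA_real_, p_value = 1, converged = FALSE,
                   link = link),
              class = "interaction_fit")
  }
  if (length(unique(arm)) < 2L) return(bad_fit())
  zt <- probe * arm

  if (link == "cox") {
    if (!survival::is.Surv(response))
      stop("a 'cox' link requires 'response' to be a survival::Surv object",
           call. = FALSE)
    fit <- tryCatch(
      survival::coxph(response ~ arm + zt),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) || anyNA(stats::coef(fit)) ||
        anyNA(sqrt(diag(stats::vcov(fit)))))
      return(bad_fit())
    b <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    p <- if (test == "Wald") {
      2 * stats::pnorm(-abs(b["zt"] / se["zt"]))
    } else {
      fit0 <- survival::coxph(response ~ arm)
      stats::pchisq(2 * (fit$loglik[2] - fit0$loglik[2]), df = 1,
                    lower.tail = FALSE)
    }
    return(structure(list(beta0 = NA_real_, beta2 = unname(b["arm"]),
                          beta3 = unname(b["zt"]),
                          se3 = unname(se["zt"]),
                          p_value = unname(p), converged = TRUE,
                          link = link),
                     class = "interaction_fit"))
  }

  if (stats::var(zt) == 0 || length(unique(response)) < 2L)
    return(bad_fit())
  fam <- if (link == "logit") stats::binomial() else stats::gaussian()
  fit <- tryCatch(
    suppressWarnings(stats::glm(response ~ arm + zt, family = fam)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || anyNA(stats::coef(fit)))
    return(bad_fit())
  b <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  # flag quasi-separation: absurd coefficients mean the Wald test is
  # meaningless for this probe
  if (link == "logit" && any(abs(b) > 30)) return(bad_fit())
  p <- if (test == "Wald") {
    if (link == "logit") 2 * stats::pnorm(-abs(b["zt"] / se["zt"]))
    else summary(fit)$coefficients["zt", 4]
  } else {
    fit0 <- suppressWarnings(stats::glm(response ~ arm, family = fam))
    stats::pchisq(fit0$deviance - fit$deviance, df = 1, lower.tail = FALSE)
  }
  structure(list(beta0 = unname(b["(Intercept)"]),
                 beta2 = unname(b["arm"]), beta3 = unname(b["zt"]),
                 se3 = unname(se["zt"]), p_value = unname(p),
                 converged = TRUE, link = link),
            class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf("Treatment x marker interaction fit (%s link)\n", x$link))
  if (!x$converged) {
    cat("  did not converge (probe dropped from screening: p = 1)\n")
  } else {
    cat(sprintf("  beta0 = %.4g  beta2 = %.4g  beta3 = %.4g (se %.4g)\n",
                x$beta0, x$beta2, x$beta3, x$se3))
    cat(sprintf("  two-sided p[beta3 = 0] = %.4g\n", x$p_value))
  }
  invisible(x)
}

#' @export
coef.interaction_fit <- function(object, ...) {
  c(beta0 = object$beta0, beta2 = object$beta2, beta3 = object$beta3)
}

# Genome-wide scan over all probes of a binary cohort; returns a data.frame
# with one row per probe.  C++ path: exact ML of the printed model via the
# arm-factorized Newton fit.  `rows` restricts the fit to a patient subset
# (cross-validation training folds) without copying the matrix.
interaction_scan <- function(response, arm, expression, rows = NULL) {
  res <- .logit_interaction_scan(as.numeric(response), as.integer(arm),
                                 expression,
                                 if (!is.null(rows)) as.integer(rows))
  conv <- res[, "converged"] == 1
  p <- rep(1, nrow(res))
  p[conv] <- 2 * stats::pnorm(-abs(res[conv, "beta3"] / res[conv, "se3"]))
  data.frame(probe_id = seq_len(nrow(res)),
             beta0 = res[, "beta0"], beta2 = res[, "beta2"],
             beta3 = res[, "beta3"], se3 = res[, "se3"],
             p_value = p, converged = conv)
}

marker_set <- function(fits, alpha_screen = NA_real_, top_k = NA_integer_) {
  structure(
    list(probe_ids = fits$probe_id, fits = fits,
         L = nrow(fits), alpha_screen = alpha_screen, top_k = top_k),
    class = "marker_set")
}

#' Screen probes for treatment-predictive markers
#'
#' Runs the interaction model of [fit_interaction_model()] (logit link)
#' over every probe of a binary-endpoint cohort and retains the set `U` of
#' probes whose two-sided Wald p-value for the interaction coefficient is
#' `<= alpha_screen`. An empty `U` is a legal result. No multiplicity
#' correction is applied: the level is a fixed per-probe threshold.
#'
#' @param cohort A `"patient_cohort"` (or any list with `response`, `arm`,
#'   `expression`).
#' @param alpha_screen Per-probe significance level; defaults to the
#'   cohort's `alpha_screen` (0.001 for the built-in scenarios).
#' @return An object of class `"marker_set"`: `probe_ids` (the set `U`),
#'   `fits` (a data.frame of per-member `beta0`, `beta2`, `beta3`, `se3`,
#'   `p_value`), `L = |U|`, and `alpha_screen`.
#' @export
screen_markers <- function(cohort, alpha_screen = cohort$alpha_screen) {
  if (is.null(alpha_screen)) alpha_screen <- 0.001
  if (length(unique(cohort$arm)) < 2L)
    stop("screening requires patients in both arms", call. = FALSE)
  scan <- interaction_scan(cohort$response, cohort$arm, cohort$expression)
  sel <- scan[scan$p_value <= alpha_screen & scan$converged, , drop = FALSE]
  sel <- sel[order(sel$p_value), , drop = FALSE]
  rownames(sel) <- NULL
  marker_set(sel, alpha_screen = alpha_screen)
}

#' Rank probes by Cox treatment-interaction and keep the top K
#'
#' For a survival cohort, fits the per-gene Cox model
#' `arm + gene:arm` (no gene main effect, matching the binary screen), and
#' retains the `top_k` genes with the smallest two-sided Wald p-values for
#' the interaction term. A gene whose Cox fit fails to converge is
#' assigned p = 1. Top-K selection (rather than a p threshold) suits the
#' small cohorts typical of survival reanalyses.
#'
#' @param cohort A `"survival_cohort"` (or list with `time`, `event`,
#'   `arm`, `expression`).
#' @param top_k Number of genes to retain (default 5).
#' @return A `"marker_set"` with `beta2` (arm log-hazard ratio), `beta3`
#'   (interaction), `se3`, `p_value` per retained gene (`beta0` is `NA`:
#'   the Cox model has no intercept).
#' @export
cox_screen_markers <- function(cohort, top_k = 5L) {
  top_k <- as.integer(top_k)
  if (top_k < 1L) stop("'top_k' must be >= 1", call. = FALSE)
  m <- ncol(cohort$expression)
  if (top_k > m) {
    warning("'top_k' exceeds the probe count; returning all probes",
            call. = FALSE)
    top_k <- m
  }
  surv <- survival::Surv(cohort$time, cohort$event)
  arm <- cohort$arm
  res <- matrix(NA_real_, m, 4,
                dimnames = list(NULL, c("beta2", "beta3", "se3", "p_value")))
  for (j in seq_len(m)) {
    f <- fit_interaction_model(surv, arm, cohort$expression[, j],
                               link = "cox")
    res[j, ] <- c(f$beta2, f$beta3, f$se3, f$p_value)
  }
  ord <- order(res[, "p_value"])[seq_len(top_k)]
  fits <- data.frame(probe_id = ord,
                     beta0 = NA_real_,
                     beta2 = res[ord, "beta2"],
                     beta3 = res[ord, "beta3"],
                     se3 = res[ord, "se3"],
                     p_value = res[ord, "p_value"],
                     converged = res[ord, "p_value"] < 1)
  marker_set(fits, top_k = top_k)
}

#' @export
print.marker_set <- function(x, ...) {
  how <- if (!is.na(x$alpha_screen))
    sprintf("interaction p <= %g", x$alpha_screen)
  else
    sprintf("top %d by Cox interaction p", x$top_k)
  cat(sprintf("Predictive marker set U: %d probes (%s)\n", x$L, how))
  if (x$L > 0L) {
    show <- utils::head(x$fits[, c("probe_id", "beta2", "beta3", "p_value")],
                        10L)
    print(show, row.names = FALSE, digits = 4)
    if (x$L > 10L) cat("  ...", x$L - 10L, "more\n")
  }
  invisible(x)
}

#' Write a marker set to a tab-separated file
#'
#' @param x A `"marker_set"`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_marker_set_tsv <- function(x, file) {
  stopifnot(inherits(x, "marker_set"))
  utils::write.table(
    x$fits[, c("probe_id", "beta0", "beta2", "beta3", "p_value")],
    file = file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
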