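#' Adaptive-signature voting rule
#'
#' The original adaptive-signature classifier: each screened marker
#' `i` in `U` casts a vote for a patient when the fitted per-marker
#' log odds ratio of treatment benefit exceeds a threshold,
#' `beta2_i + beta3_i * x_i > ln(R)` (strict inequality — the odds ratio
#' must *exceed* R), and the patient is labelled `g+` when at least `G`
#' markers vote. `ln_R` may be negative for survival endpoints, where the
#' per-marker quantity is a log hazard ratio and negative thresholds
#' reflect reduced risk under treatment.
#'
#' @param markers A `"marker_set"` (from [screen_markers()] or
#'   [cox_screen_markers()]), or a data.frame with columns `probe_id`,
#'   `beta2`, `beta3`.
#' @param ln_R Log odds-ratio threshold.
#' @param G Minimum number of voting markers (>= 1).
#' @return An object of class `"asd_rule"`.
#' @seealso [predict.asd_rule()]
#' @export
asd_rule <- function(markers, ln_R, G) {
  if (inherits(markers, "marker_set")) markers <- markers$fits
  G <- as.integer(G)
  if (G < 1L) stop("'G' must be >= 1", call. = FALSE)
  stopifnot(all(c("probe_id", "beta2", "beta3") %in% names(markers)))
  structure(
    list(markers = markers[, c("probe_id", "beta2", "beta3")],
         ln_R = ln_R, G = G),
    class = "asd_rule")
}

#' Classify patients with an adaptive-signature voting rule
#'
#' @param object An `"asd_rule"`.
#' @param newdata Full expression matrix (patients x probes; the rule
#'   picks out its marker columns by `probe_id`) or a patients x L matrix
#'   of the marker values themselves when `expression_is_markers = TRUE`.
#' @param expression_is_markers Set to `TRUE` when `newdata` columns are
#'   already the rule's markers, in order.
#' @param ... Unused.
#' @return A list with `label` (factor `g-`/`g+`) and `votes` (integer
#'   votes per patient). An empty marker set labels everyone `g-` with a
#'   warning.
#' @export
predict.asd_rule <- function(object, newdata, expression_is_markers = FALSE,
                             ...) {
  newdata <- as.matrix(newdata)
  n <- nrow(newdata)
  if (nrow(object$markers) == 0L) {
    warning("empty marker set: all patients labelled g-", call. = FALSE)
    return(list(label = factor(rep("g-", n), levels = c("g-", "g+")),
                votes = integer(n)))
  }
  xm <- if (expression_is_markers) {
    if (ncol(newdata) != nrow(object$markers))
      stop("'newdata' must supply one column per rule marker",
           call. = FALSE)
    newdata
  } else {
    if (max(object$markers$probe_id) > ncol(newdata))
      stop("'newdata' does not cover all rule markers", call. = FALSE)
    newdata[, object$markers$probe_id, drop = FALSE]
  }
  # per-marker log odds ratio beta2 + beta3 * x; non-finite marker fits
  # (e.g. undefined beta2) never vote
  lor <- sweep(sweep(xm, 2L, object$markers$beta3, `*`),
               2L, object$markers$beta2, `+`)
  votes <- rowSums(lor > object$ln_R, na.rm = TRUE)
  list(label = factor(ifelse(votes >= object$G, "g+", "g-"),
                      levels = c("g-", "g+")),
       votes = as.integer(votes))
}

#' @export
print.asd_rule <- function(x, ...) {
  cat(sprintf("ASD voting rule (ln R = %g, G = %d) over %d markers\n",
              x$ln_R, x$G, nrow(x$markers)))
  invisible(x)
}
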