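#' Diagonal linear discriminant analysis
#'
#' Gaussian maximum-likelihood classification under a shared diagonal
#' covariance matrix: each class is modelled as Normal with its own
#' per-feature means and a per-feature variance pooled across the two
#' classes. Because the covariance is diagonal and common, the
#' discriminant is linear, requires no matrix inversion, and the decision
#' boundary depends only on the sample means and variances — which makes
#' the rule applicable when features outnumber samples and robust to
#' imbalanced class sizes.
#'
#' The discriminant score of class `c` for a feature vector `x` is
#' `sum_k [ -(x_k - mu_ck)^2 / (2 s_k^2) ] + log(prior_c)`.
#'
#' @param x Numeric matrix, samples x features.
#' @param labels Class labels, coercible to a two-level factor. The
#'   *first* level is the reference ("negative") class: prediction ties
#'   are resolved in its favor.
#' @param prior `"empirical"` (class frequencies; the likelihood-rule
#'   default) or `"equal"`.
#' @return An object of class `"dlda"`: `feature_ids`, `class_means`
#'   (2 x features), `pooled_vars`, `priors`, `class_labels`, `n_floored`
#'   (features whose degenerate variance was floored at
#'   `1e-8 * mean(pooled_vars)`).
#' @seealso [predict.dlda()]
#' @export
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 2), 20))
#' y <- rep(c("g-", "g+"), each = 20)
#' fit <- dlda(x, y)
#' table(predict(fit, x)$label, y)
dlda <- function(x, labels, prior = c("empirical", "equal")) {
  prior <- match.arg(prior)
  x <- as.matrix(x)
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) != 2L)
    stop("'labels' must contain exactly two classes", call. = FALSE)
  if (nrow(x) != length(labels))
    stop("nrow(x) must equal length(labels)", call. = FALSE)
  cnt <- table(labels)
  if (any(cnt < 2L))
    stop("each class needs at least 2 samples to estimate variances",
         call. = FALSE)
  lev <- levels(labels)
  mu <- rbind(colMeans(x[labels == lev[1L], , drop = FALSE]),
              colMeans(x[labels == lev[2L], , drop = FALSE]))
  rownames(mu) <- lev
  # per-feature variance pooled across the two classes
  ss <- function(cls) {
    xc <- x[labels == cls, , drop = FALSE]
    colSums(sweep(xc, 2L, colMeans(xc))^2)
  }
  s2 <- (ss(lev[1L]) + ss(lev[2L])) / (nrow(x) - 2L)
  floor_at <- 1e-8 * max(mean(s2), .Machine$double.eps)
  n_floored <- sum(s2 < floor_at)
  s2 <- pmax(s2, floor_at)
  pr <- if (prior == "empirical") as.numeric(cnt) / nrow(x) else c(0.5, 0.5)
  names(pr) <- lev
  structure(
    list(feature_ids = colnames(x) %||% seq_len(ncol(x)),
         class_means = mu, pooled_vars = s2, priors = pr,
         class_labels = lev, n_floored = n_floored),
    class = "dlda")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify samples with a fitted DLDA rule
#'
#' @param object A `"dlda"` fit.
#' @param newdata Samples x features matrix with the same feature count as
#'   the fit.
#' @param ... Unused.
#' @return A list with `label` (factor with the fit's class levels;
#'   exact score ties go to the first — negative — class) and `scores`
#'   (samples x 2 matrix of per-class discriminant scores).
#' @export
predict.dlda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$class_means))
    stop("'newdata' has ", ncol(newdata), " features but the model was ",
         "fitted with ", ncol(object$class_means), call. = FALSE)
  scores <- vapply(1:2, function(c) {
    d <- sweep(newdata, 2L, object$class_means[c, ])
    unname(-colSums(t(d^2) / (2 * object$pooled_vars)) +
             log(object$priors[[c]]))
  }, numeric(nrow(newdata)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  colnames(scores) <- object$class_labels
  lab <- factor(ifelse(scores[, 2L] > scores[, 1L],
                       object$class_labels[2L], object$class_labels[1L]),
                levels = object$class_labels)
  list(label = lab, scores = scores)
}

#' @export
print.dlda <- function(x, ...) {
  cat(sprintf("DLDA classifier: %d features, classes %s (priors %.3f/%.3f)\n",
              ncol(x$class_means), paste(x$class_labels, collapse = " vs "),
              x$priors[1L], x$priors[2L]))
  if (x$n_floored > 0L)
    cat(sprintf("  %d degenerate feature variance(s) floored\n", x$n_floored))
  invisible(x)
}

#' @export
coef.dlda <- function(object, ...) {
  # linear discriminant weights for the second class vs the first
  w <- (object$class_means[2L, ] - object$class_means[1L, ]) /
    object$pooled_vars
  b <- sum((object$class_means[1L, ]^2 - object$class_means[2L, ]^2) /
             (2 * object$pooled_vars)) +
    log(object$priors[2L] / object$priors[1L])
  c(intercept = unname(b), stats::setNames(w, object$feature_ids))
}
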