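#' Classifier method specifications
#'
#' Lightweight descriptors of the subgroup classifier to be used inside
#' the cross-validation pipeline: `dlda_method()` (binary endpoints;
#' trained on treatment-arm observed response by default),
#' `asd_method(ln_R, G)` (the voting rule, using each fold's screened
#' interaction coefficients; needs no training labels), and
#' `coxcut_method()` (survival endpoints; Cox risk score with a
#' survival-probability cutoff).
#'
#' @param prior Prior for DLDA: `"empirical"` or `"equal"`.
#' @param train_arms `"treatment"` (default: classifier training labels
#'   are the observed responses of treatment-arm patients, the only
#'   observable correlate of treatment benefit) or `"both"` (both arms'
#'   responses; available for sensitivity analysis).
#' @param ln_R,G Voting-rule parameters, see [asd_rule()].
#' @param horizon,cutoff See [cox_score()].
#' @return An object of class `"asd_method"`.
#' @name classifier_methods
NULL

#' @rdname classifier_methods
#' @export
dlda_method <- function(prior = c("empirical", "equal"),
                        train_arms = c("treatment", "both")) {
  structure(list(type = "dlda", prior = match.arg(prior),
                 train_arms = match.arg(train_arms), label = "dlda"),
            class = "asd_method")
}

#' @rdname classifier_methods
#' @export
asd_method <- function(ln_R = 1, G = 1) {
  structure(list(type = "asd", ln_R = ln_R, G = as.integer(G),
                 label = sprintf("asd(%g,%d)", ln_R, as.integer(G))),
            class = "asd_method")
}

#' @rdname classifier_methods
#' @export
coxcut_method <- function(horizon = 5, cutoff = 0.5) {
  structure(list(type = "coxcut", horizon = horizon, cutoff = cutoff,
                 label = sprintf("coxcut(%g,%g)", horizon, cutoff)),
            class = "asd_method")
}

#' @export
print.asd_method <- function(x, ...) {
  cat("Classifier method:", x$label, "\n")
  invisible(x)
}

#' Training labels for a binary-endpoint subgroup classifier
#'
#' For a binary response the treatment-benefit subgroup is learned from
#' the observed outcomes: treatment-arm responders stand in for `g+` and
#' treatment-arm non-responders for `g-`. Control-arm patients are
#' excluded (their response carries no benefit signal when the control
#' response rates of the two subgroups coincide), unless
#' `train_arms = "both"` is requested for sensitivity analysis.
#'
#' @param cohort A `"patient_cohort"` or any list with `response`, `arm`.
#' @param subset Integer indices of the training patients (default all).
#' @param train_arms `"treatment"` or `"both"`.
#' @return A list with `index` (positions within `subset` order of the
#'   patients used for training), `label` (factor `g-`/`g+`), and
#'   `usable` (`FALSE` when the labels are single-class, in which case the
#'   caller should fall back to an all-`g-` assignment).
#' @export
derive_training_labels <- function(cohort, subset = seq_along(cohort$arm),
                                   train_arms = c("treatment", "both")) {
  train_arms <- match.arg(train_arms)
  arm <- cohort$arm[subset]
  resp <- cohort$response[subset]
  idx <- if (train_arms == "treatment") which(arm == 1L) else seq_along(arm)
  lab <- factor(ifelse(resp[idx] == 1L, "g+", "g-"), levels = c("g-", "g+"))
  usable <- length(idx) >= 4L && all(table(lab) >= 2L)
  list(index = idx, label = lab, usable = usable)
}

# Stratified fold assignment: folds drawn once per cohort from the seed,
# stratified by arm so every training set contains both arms.
make_folds <- function(arm, n_folds, seed) {
  n <- length(arm)
  if (identical(n_folds, "loo")) n_folds <- n
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L || n_folds > n)
    stop("'n_folds' must lie between 2 and the number of patients",
         call. = FALSE)
  set.seed(as.integer(seed))
  # cyclic assignment over the arm-blocked shuffled order: spreads both
  # arms as evenly as possible over the folds, leaves no fold empty, and
  # reduces to one patient per fold when n_folds = n (leave-one-out)
  ord <- unlist(lapply(sort(unique(arm)),
                       function(a) sample(which(arm == a))))
  fold <- integer(n)
  fold[ord] <- rep_len(seq_len(n_folds), n)
  fold
}

# Shared cross-validation engine: screening is run once per fold and all
# requested methods classify the held-out patients from that fold's
# screen.  Returns one "subgroup_assignment" per method.
cv_engine <- function(cohort, methods, n_folds, seed,
                      alpha_screen = NULL, top_k = 5L) {
  survival_endpoint <- inherits(cohort, "survival_cohort") ||
    (!is.null(cohort$time) && is.null(cohort$response))
  n <- length(cohort$arm)
  if (length(unique(cohort$arm)) < 2L)
    stop("the cohort must contain both arms", call. = FALSE)
  if (is.null(alpha_screen))
    alpha_screen <- cohort$alpha_screen %||% 0.001
  fold <- make_folds(cohort$arm, n_folds, seed)
  n_folds_eff <- max(fold)

  labels <- lapply(methods, function(m)
    factor(rep("g-", n), levels = c("g-", "g+")))
  audit <- vector("list", n_folds_eff)

  for (f in seq_len(n_folds_eff)) {
    test <- which(fold == f)
    train <- which(fold != f)
    if (length(unique(cohort$arm[train])) < 2L)
      stop("training data for fold ", f, " contains a single arm; ",
           "use fewer folds", call. = FALSE)
    notes <- character(0)

    if (survival_endpoint) {
      sub <- list(arm = cohort$arm[train],
                  time = cohort$time[train],
                  event = cohort$event[train],
                  expression = cohort$expression[train, , drop = FALSE])
      ms <- cox_screen_markers(sub, top_k = top_k)
    } else {
      scan <- interaction_scan(cohort$response, cohort$arm,
                               cohort$expression, rows = train)
      sel <- scan[scan$p_value <= alpha_screen & scan$converged, ,
                  drop = FALSE]
      sel <- sel[order(sel$p_value), , drop = FALSE]
      rownames(sel) <- NULL
      ms <- marker_set(sel, alpha_screen = alpha_screen)
    }
    audit[[f]] <- list(fold = f, train = train, test = test,
                       markers = ms$probe_ids)

    if (ms$L == 0L) {
      audit[[f]]$notes <- "empty marker set: held-out patients labelled g-"
      next
    }
    test_x <- cohort$expression[test, ms$probe_ids, drop = FALSE]

    for (k in seq_along(methods)) {
      m <- methods[[k]]
      pred <- switch(
        m$type,
        dlda = {
          tl <- derive_training_labels(cohort, subset = train,
                                       train_arms = m$train_arms)
          if (!tl$usable) {
            notes <- c(notes, sprintf(
              "%s: degenerate training labels; fold %d labelled g-",
              m$label, f))
            NULL
          } else {
            fit <- dlda(cohort$expression[train[tl$index], ms$probe_ids,
                                          drop = FALSE],
                        tl$label, prior = m$prior)
            predict(fit, test_x)$label
          }
        },
        asd = {
          rule <- asd_rule(ms, ln_R = m$ln_R, G = m$G)
          predict(rule, test_x, expression_is_markers = TRUE)$label
        },
        coxcut = {
          fit <- tryCatch(
            suppressWarnings(cox_score(sub, ms, horizon = m$horizon,
                                       cutoff = m$cutoff)),
            error = function(e) NULL)
          if (is.null(fit)) {
            notes <- c(notes, sprintf(
              "%s: Cox fit failed; fold %d labelled g-", m$label, f))
            NULL
          } else {
            suppressWarnings(
              predict(fit, test_x, expression_is_markers = TRUE)$label)
          }
        },
        stop("unknown method type: ", m$type))
      if (!is.null(pred)) labels[[k]][test] <- pred
    }
    if (length(notes)) audit[[f]]$notes <- notes
  }

  lapply(seq_along(methods), function(k) {
    structure(
      list(label = labels[[k]], fold_id = fold,
           method = methods[[k]]$label, n_folds = n_folds_eff,
           seed = as.integer(seed), folds = audit),
      class = "subgroup_assignment")
  })
}

#' Cross-validated subgroup assignment
#'
#' Assigns every patient a `g+`/`g-` label from a classifier that never
#' saw them: folds are drawn once from the seed, stratified by arm; within
#' each training fold the markers are screened anew (interaction test at
#' `alpha_screen` for binary endpoints, top-`top_k` Cox interaction
#' ranking for survival endpoints) and the chosen classifier is fitted on
#' training patients only, then applied to the held-out patients. A fold
#' whose training screen selects no markers labels its held-out patients
#' `g-` (recorded in the fold audit).
#'
#' @param cohort A `"patient_cohort"` or `"survival_cohort"`.
#' @param method An `"asd_method"` ([dlda_method()], [asd_method()], or
#'   [coxcut_method()]).
#' @param n_folds Number of folds (default 10), or `"loo"` for
#'   leave-one-out.
#' @param seed Integer seed for the fold draw.
#' @param alpha_screen Binary-endpoint screening level (default: the
#'   cohort's, else 0.001).
#' @param top_k Survival-endpoint screening size (default 5).
#' @return An object of class `"subgroup_assignment"`: `label` (factor
#'   per patient), `fold_id`, `method`, `n_folds`, `seed`, and `folds`
#'   (per-fold audit: training/test indices, selected markers, notes).
#' @export
#' @examples
#' sc <- scenario(pi = 0.3, u00 = 0.2, u01 = 0.2, u10 = 0.2, u11 = 0.8,
#'                n_per_arm = 60, n_probes = 50, n_predictive = 5)
#' co <- simulate_trial(sc, seed = 7)
#' a <- cross_validated_assignment(co, dlda_method(), n_folds = 5, seed = 7)
#' table(predicted = a$label, truth = co$subgroup)
cross_validated_assignment <- function(cohort, method, n_folds = 10L,
                                       seed, alpha_screen = NULL,
                                       top_k = 5L) {
  stopifnot(inherits(method, "asd_method"))
  if (missing(seed)) stop("'seed' is required for reproducibility",
                          call. = FALSE)
  cv_engine(cohort, list(method), n_folds, seed,
            alpha_screen = alpha_screen, top_k = top_k)[[1L]]
}

#' @export
print.subgroup_assignment <- function(x, ...) {
  cat(sprintf("Cross-validated subgroup assignment (%s, %d folds, seed %d)\n",
              x$method, x$n_folds, x$seed))
  print(table(x$label))
  notes <- unlist(lapply(x$folds, `[[`, "notes"))
  if (length(notes)) cat("  notes:\n", paste("   ", notes, collapse = "\n"),
                         "\n")
  invisible(x)
}

#' @export
summary.subgroup_assignment <- function(object, truth = NULL, ...) {
  out <- list(method = object$method,
              counts = table(object$label),
              marker_counts = vapply(object$folds,
                                     function(f) length(f$markers),
                                     integer(1)))
  if (!is.null(truth)) out$confusion <- confusion_metrics(object$label, truth)
  class(out) <- "summary.subgroup_assignment"
  out
}

#' @export
print.summary.subgroup_assignment <- function(x, ...) {
  cat("Method:", x$method, "\n")
  print(x$counts)
  cat("Markers selected per fold:",
      paste(x$marker_counts, collapse = " "), "\n")
  if (!is.null(x$confusion)) print(x$confusion)
  invisible(x)
}

#' Write a subgroup assignment to a tab-separated file
#'
#' @param x A `"subgroup_assignment"`.
#' @param file Output path.
#' @param sample_ids Optional sample identifiers (defaults to row order).
#' @return `file`, invisibly.
#' @export
write_assignment_tsv <- function(x, file, sample_ids = NULL) {
  stopifnot(inherits(x, "subgroup_assignment"))
  if (is.null(sample_ids)) sample_ids <- paste0("pt_", seq_along(x$label))
  utils::write.table(
    data.frame(sample_id = sample_ids, fold = x$fold_id,
               predicted_label = as.character(x$label)),
    file = file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
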