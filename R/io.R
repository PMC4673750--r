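#' Write a cohort to the TSV interchange format
#'
#' Writes `expression.tsv` (a `sample_id` column plus one column per
#' probe) and `clinical.tsv` (`sample_id`, `arm`, then `response` for
#' binary cohorts or `time` + `event` for survival cohorts) into a
#' directory.
#'
#' @param cohort A `"patient_cohort"` or `"survival_cohort"`.
#' @param dir Output directory (created if needed).
#' @return The two file paths, invisibly.
#' @export
write_cohort_tsv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- rownames(cohort$expression) %||%
    paste0("pt_", seq_along(cohort$arm))
  ef <- file.path(dir, "expression.tsv")
  cf <- file.path(dir, "clinical.tsv")
  utils::write.table(
    data.frame(sample_id = ids, cohort$expression, check.names = FALSE),
    ef, sep = "\t", quote = FALSE, row.names = FALSE)
  clin <- if (!is.null(cohort$response))
    data.frame(sample_id = ids, arm = cohort$arm,
               response = cohort$response)
  else
    data.frame(sample_id = ids, arm = cohort$arm,
               time = cohort$time, event = cohort$event)
  utils::write.table(clin, cf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expression = ef, clinical = cf))
}

#' Read a cohort from the TSV interchange format
#'
#' Parses and validates the file pair written by [write_cohort_tsv()] (or
#' prepared by the user to the same layout), detecting the endpoint from
#' the clinical columns.
#'
#' @param expression_file,clinical_file Paths.
#' @return A list with `cohort` (a `"patient_cohort"` or
#'   `"survival_cohort"`), `endpoint`, and `sample_ids`.
#' @export
read_cohort_tsv <- function(expression_file, clinical_file) {
  expr <- utils::read.delim(expression_file, check.names = FALSE)
  clin <- utils::read.delim(clinical_file)
  for (d in list(expr, clin))
    if (!"sample_id" %in% names(d))
      stop("both files need a 'sample_id' column", call. = FALSE)
  missing_clin <- setdiff(expr$sample_id, clin$sample_id)
  if (length(missing_clin))
    stop("sample(s) in the expression file but not the clinical file: ",
         paste(utils::head(missing_clin, 5L), collapse = ", "),
         call. = FALSE)
  missing_expr <- setdiff(clin$sample_id, expr$sample_id)
  if (length(missing_expr))
    stop("sample(s) in the clinical file but not the expression file: ",
         paste(utils::head(missing_expr, 5L), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(expr$sample_id) || anyDuplicated(clin$sample_id))
    stop("duplicate sample ids", call. = FALSE)
  clin <- clin[match(expr$sample_id, clin$sample_id), ]
  if (!"arm" %in% names(clin))
    stop("the clinical file needs an 'arm' column", call. = FALSE)
  if (!all(clin$arm %in% c(0L, 1L))) {
    bad <- which(!(clin$arm %in% c(0L, 1L)))[1L]
    stop("non-binary 'arm' value for sample ", clin$sample_id[bad],
         call. = FALSE)
  }
  x <- as.matrix(expr[, setdiff(names(expr), "sample_id"), drop = FALSE])
  if (!is.numeric(x)) stop("non-numeric expression values", call. = FALSE)
  rownames(x) <- expr$sample_id
  ids <- expr$sample_id
  if ("response" %in% names(clin)) {
    if (!all(clin$response %in% c(0L, 1L))) {
      bad <- which(!(clin$response %in% c(0L, 1L)))[1L]
      stop("non-binary 'response' for sample ", clin$sample_id[bad],
           call. = FALSE)
    }
    cohort <- structure(
      list(subgroup = NULL, arm = as.integer(clin$arm),
           response = as.integer(clin$response), expression = x,
           predictive_ids = integer(0), alpha_screen = NULL,
           scenario = NULL, seed = NA_integer_),
      class = "patient_cohort")
    endpoint <- "binary"
  } else if (all(c("time", "event") %in% names(clin))) {
    if (any(!is.finite(clin$time) | clin$time <= 0)) {
      bad <- which(!is.finite(clin$time) | clin$time <= 0)[1L]
      stop("non-positive 'time' for sample ", clin$sample_id[bad],
           call. = FALSE)
    }
    if (!all(clin$event %in% c(0L, 1L))) {
      bad <- which(!(clin$event %in% c(0L, 1L)))[1L]
      stop("non-binary 'event' for sample ", clin$sample_id[bad],
           call. = FALSE)
    }
    cohort <- structure(
      list(time = clin$time, event = as.integer(clin$event),
           arm = as.integer(clin$arm), expression = x,
           subgroup = NULL, predictive_ids = integer(0),
           seed = NA_integer_),
      class = "survival_cohort")
    endpoint <- "survival"
  } else {
    stop("the clinical file needs either a 'response' column or ",
         "'time' + 'event' columns", call. = FALSE)
  }
  list(cohort = cohort, endpoint = endpoint, sample_ids = ids)
}

#' Serialize a fitted classifier to JSON
#'
#' Dumps the parameters of a fitted [dlda()], [asd_rule()], or
#' [cox_score()] model to JSON for audit or reuse; [read_model_json()]
#' restores the object.
#'
#' @param model A fitted classifier.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_model_json <- function(model, file) {
  type <- intersect(class(model), c("dlda", "asd_rule", "cox_score"))
  if (!length(type))
    stop("'model' must be a dlda, asd_rule or cox_score fit",
         call. = FALSE)
  payload <- unclass(model)
  if (type == "dlda")
    payload$class_means <- apply(payload$class_means, 1L, identity,
                                 simplify = FALSE)
  jsonlite::write_json(c(list(model_type = type), payload), file,
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(file)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  type <- obj$model_type
  obj$model_type <- NULL
  if (type == "dlda") {
    obj$class_means <- do.call(rbind, obj$class_means)
    obj$pooled_vars <- as.numeric(obj$pooled_vars)
    obj$priors <- stats::setNames(as.numeric(obj$priors),
                                  obj$class_labels)
  }
  if (type == "asd_rule") obj$markers <- as.data.frame(obj$markers)
  if (type == "cox_score") obj$baseline <- as.data.frame(obj$baseline)
  structure(obj, class = type)
}
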