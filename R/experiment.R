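#' Scenario sweep: operating characteristics and power
#'
#' Runs the full simulation experiment: for each scenario and replicate,
#' simulate a trial, produce a cross-validated subgroup assignment for
#' every requested method (the per-fold screens are shared across
#' methods), score the assignment against the true subgroup, and run the
#' five comparisons. The reported `significances` and `true_positives`
#' are the mean selected-marker counts over the cross-validation training
#' folds — the level at which the procedure actually screens. Replicate `r` of scenario `s` uses a child
#' seed derived deterministically from `master_seed`, so any replicate is
#' reproducible in isolation and the whole sweep is reproducible from the
#' master seed.
#'
#' @param scenarios A character vector of built-in scenario names and/or a
#'   list of `"asd_scenario"` objects.
#' @param methods A list of [classifier_methods] (default: DLDA and the
#'   four reference voting rules).
#' @param n_replicates Replicates per scenario.
#' @param n_folds Cross-validation folds (default 10).
#' @param master_seed Integer master seed.
#' @param plan A [test_plan()].
#' @param out_dir Optional directory; when given, writes
#'   `metrics.csv` (per scenario x method means of sensitivity,
#'   specificity, PPV, NPV, accuracy, plus mean selected and
#'   true-positive marker counts) and `power.csv` (the three power
#'   counts), plus `seeds.csv` logging every per-replicate seed.
#' @param verbose Print one progress line per scenario.
#' @return An object of class `"asd_experiment"`: `metrics` and `power`
#'   data.frames as above, `replicates` (per-replicate metric rows), and
#'   the configuration.
#' @export
run_scenario_experiment <- function(scenarios = "A",
                                    methods = list(
                                      dlda_method(),
                                      asd_method(1, 1), asd_method(1, 2),
                                      asd_method(2, 1), asd_method(2, 2)),
                                    n_replicates = 10L, n_folds = 10L,
                                    master_seed = 1L, plan = test_plan(),
                                    out_dir = NULL, verbose = FALSE) {
  if (inherits(methods, "asd_method")) methods <- list(methods)
  stopifnot(n_replicates >= 1L,
            all(vapply(methods, inherits, TRUE, "asd_method")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir))
      stop("cannot create output directory ", out_dir, call. = FALSE)
  }
  scen_list <- lapply(scenarios, function(s)
    if (inherits(s, "asd_scenario")) s else builtin_scenario(s))
  scen_names <- vapply(seq_along(scen_list), function(i)
    scen_list[[i]]$name %||% paste0("scenario", i), character(1))

  rep_rows <- list()
  seed_log <- list()
  for (si in seq_along(scen_list)) {
    sc <- scen_list[[si]]
    for (r in seq_len(n_replicates)) {
      seed_r <- child_seed(master_seed, r, stream = si)
      cohort <- simulate_trial(sc, seed = seed_r)
      assigns <- cv_engine(cohort, methods, n_folds,
                           seed = child_seed(seed_r, 0L, stream = 1L))
      # marker accounting at the level the procedure screens: the mean
      # candidate-set size (and true-positive content) over the
      # cross-validation training folds
      fold_markers <- lapply(assigns[[1L]]$folds, `[[`, "markers")
      n_sel <- mean(lengths(fold_markers))
      n_tp <- mean(vapply(fold_markers, function(mk)
        sum(mk %in% cohort$predictive_ids), numeric(1)))
      for (k in seq_along(methods)) {
        cm <- confusion_metrics(assigns[[k]]$label, cohort$subgroup)
        cr <- run_comparisons(cohort, assigns[[k]], plan = plan)
        rep_rows[[length(rep_rows) + 1L]] <- data.frame(
          scenario = scen_names[si], method = methods[[k]]$label,
          replicate = r, seed = seed_r,
          n_selected = n_sel,
          n_true_positive = n_tp,
          sensitivity = cm$sensitivity, specificity = cm$specificity,
          ppv = cm$ppv, npv = cm$npv, accuracy = cm$accuracy,
          p1 = cr$p[["p1"]], p2 = cr$p[["p2"]], p3 = cr$p[["p3"]],
          p4 = cr$p[["p4"]], p5 = cr$p[["p5"]])
      }
      seed_log[[length(seed_log) + 1L]] <- data.frame(
        scenario = scen_names[si], replicate = r, seed = seed_r)
    }
    if (verbose)
      message("scenario ", scen_names[si], ": ", n_replicates,
              " replicates done")
  }
  reps <- do.call(rbind, rep_rows)

  mean_na <- function(v) mean(v, na.rm = TRUE)
  metrics <- do.call(rbind, lapply(
    split(reps, list(reps$scenario, reps$method), drop = TRUE),
    function(d) data.frame(
      scenario = d$scenario[1L], method = d$method[1L],
      n_replicates = nrow(d),
      significances = mean_na(d$n_selected),
      true_positives = mean_na(d$n_true_positive),
      sensitivity = mean_na(d$sensitivity),
      specificity = mean_na(d$specificity),
      ppv = mean_na(d$ppv), npv = mean_na(d$npv),
      accuracy = mean_na(d$accuracy))))
  rownames(metrics) <- NULL

  power <- do.call(rbind, lapply(
    split(reps, list(reps$scenario, reps$method), drop = TRUE),
    function(d) {
      pt <- summarize_power(d, plan)
      data.frame(scenario = d$scenario[1L], method = d$method[1L],
                 n_replicates = pt$n_replicates,
                 count_overall_sig = pt$count_overall_sig,
                 count_subgroup_rescue = pt$count_subgroup_rescue,
                 overall_power_count = pt$overall_power_count,
                 overall_power = pt$overall_power)
    }))
  rownames(power) <- NULL

  if (!is.null(out_dir)) {
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(power, file.path(out_dir, "power.csv"),
                     row.names = FALSE)
    utils::write.csv(cbind(master_seed = master_seed,
                           do.call(rbind, seed_log)),
                     file.path(out_dir, "seeds.csv"), row.names = FALSE)
  }
  structure(
    list(metrics = metrics, power = power, replicates = reps,
         scenarios = scen_names, n_replicates = n_replicates,
         n_folds = n_folds, master_seed = master_seed, plan = plan),
    class = "asd_experiment")
}

#' @export
print.asd_experiment <- function(x, ...) {
  cat(sprintf("Scenario experiment: %s; %d replicates, %d folds, seed %d\n",
              paste(x$scenarios, collapse = ", "), x$n_replicates,
              x$n_folds, x$master_seed))
  cat("\nOperating characteristics (means over replicates):\n")
  print(x$metrics, digits = 3, row.names = FALSE)
  cat("\nPower accounting:\n")
  print(x$power, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Cross-validated subgroup analysis of user-supplied trial data
#'
#' Reads an expression matrix and a clinical table from tab-separated
#' files, auto-detects the endpoint (a `response` column means binary; a
#' `time` + `event` pair means survival), runs the cross-validated
#' subgroup assignment with the requested classifier, and reports the
#' five comparisons.
#'
#' File formats (header rows required): `expression.tsv` has a
#' `sample_id` column and one numeric column per probe; `clinical.tsv`
#' has `sample_id`, `arm` (0 = control, 1 = treatment), and either
#' `response` (0/1) or `time` (positive, years) + `event` (1 = event,
#' 0 = censored). Sample ids must match one-to-one.
#'
#' @param expression_file,clinical_file Paths to the TSV files.
#' @param method A classifier spec; default [dlda_method()] for binary
#'   endpoints — pass [coxcut_method()] or [asd_method()] as appropriate.
#' @param n_folds Folds, or `"loo"`.
#' @param seed Integer seed for the fold draw.
#' @param alpha_screen,top_k Screening controls (binary / survival).
#' @param plan A [test_plan()].
#' @param out_dir Optional directory for `assignment.tsv`.
#' @return A list with `assignment` (a `"subgroup_assignment"`),
#'   `comparisons` (a `"comparison_results"`), `endpoint`, and
#'   `sample_ids`.
#' @export
classify_user_data <- function(expression_file, clinical_file,
                               method = dlda_method(), n_folds = 10L,
                               seed = 1L, alpha_screen = 0.001,
                               top_k = 5L, plan = test_plan(),
                               out_dir = NULL) {
  dat <- read_cohort_tsv(expression_file, clinical_file)
  assignment <- cross_validated_assignment(
    dat$cohort, method, n_folds = n_folds, seed = seed,
    alpha_screen = alpha_screen, top_k = top_k)
  comparisons <- run_comparisons(dat$cohort, assignment, plan = plan)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_assignment_tsv(assignment,
                         file.path(out_dir, "assignment.tsv"),
                         sample_ids = dat$sample_ids)
  }
  list(assignment = assignment, comparisons = comparisons,
       endpoint = dat$endpoint, sample_ids = dat$sample_ids)
}
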