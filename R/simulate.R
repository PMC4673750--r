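# Deterministic per-replicate seeds: hash the replicate (and optionally a
# stream) index into the master seed so replicate r is reproducible in
# isolation.  Lehmer steps keep every product below 2^53, so the
# arithmetic is exact in doubles; the scrambling avoids the correlated
# streams that plain arithmetic-progression seeds can produce.  Result is
# in [1, 2^31 - 2].
child_seed <- function(master_seed, replicate, stream = 0L) {
  m <- 2147483647
  x <- (as.double(master_seed) %% m) + 1
  for (k in c(as.double(stream) + 1, as.double(replicate) + 1)) {
    x <- (x * 48271) %% m
    x <- (x + k * 69621) %% m
    x <- (x * 48271) %% m
  }
  floor(x %% (m - 1)) + 1
}

#' Simulate a two-arm trial with a predictive-biomarker subgroup
#'
#' Generates one randomized trial under an `"asd_scenario"`: exactly
#' `n_per_arm` patients per arm; subgroup membership drawn i.i.d.
#' Bernoulli(`pi`); binary response drawn Bernoulli(`u[it]`) according to
#' the patient's (subgroup, arm) cell; and an expression matrix in which
#' the first `n_predictive` probes have mean
#' `probe_mean_from_rate(u11)` for `g+` patients and
#' `probe_mean_from_rate(u01)` for `g-` patients in both arms (expression
#' is measured before treatment, so treatment cannot shift it), all other
#' probes have mean 0 for every patient, and every probe is Normal with
#' standard deviation `scenario$sd`.
#'
#' @param scenario An `"asd_scenario"` object.
#' @param seed Integer seed; the cohort is bit-reproducible given the seed.
#' @return An object of class `"patient_cohort"`: a list with elements
#'   `subgroup` (factor, levels `c("g-", "g+")`), `arm` (integer 0/1),
#'   `response` (integer 0/1), `expression` (patients x probes matrix),
#'   `predictive_ids` (columns of the truly predictive probes),
#'   `alpha_screen`, `scenario`, and `seed`.
#' @export
#' @examples
#' sc <- builtin_scenario("A")
#' sc$n_probes <- 100L; sc$n_predictive <- 5L  # small for the example
#' co <- simulate_trial(sc, seed = 1)
#' co
simulate_trial <- function(scenario, seed) {
  stopifnot(inherits(scenario, "asd_scenario"))
  if (missing(seed)) stop("'seed' is required for reproducibility",
                          call. = FALSE)
  set.seed(as.integer(seed))
  n <- 2L * scenario$n_per_arm
  m <- scenario$n_probes
  arm <- rep(c(0L, 1L), each = scenario$n_per_arm)
  gpos <- stats::rbinom(n, 1L, scenario$pi)
  # response probability by (subgroup, arm) cell
  u <- matrix(c(scenario$u00, scenario$u01,
                scenario$u10, scenario$u11),
              nrow = 2L, byrow = TRUE)      # rows: g-, g+; cols: control, trt
  pr <- u[cbind(gpos + 1L, arm + 1L)]
  response <- stats::rbinom(n, 1L, pr)
  expr <- matrix(stats::rnorm(n * m, mean = 0, sd = scenario$sd),
                 nrow = n, ncol = m)
  npred <- scenario$n_predictive
  if (npred > 0L) {
    mu <- ifelse(gpos == 1L,
                 probe_mean_from_rate(scenario$u11),
                 probe_mean_from_rate(scenario$u01))
    expr[, seq_len(npred)] <- expr[, seq_len(npred)] + mu
  }
  colnames(expr) <- paste0("probe_", seq_len(m))
  rownames(expr) <- paste0("pt_", seq_len(n))
  structure(
    list(subgroup = factor(ifelse(gpos == 1L, "g+", "g-"),
                           levels = c("g-", "g+")),
         arm = arm,
         response = response,
         expression = expr,
         predictive_ids = seq_len(npred),
         alpha_screen = scenario$alpha_screen,
         scenario = scenario,
         seed = as.integer(seed)),
    class = "patient_cohort")
}

#' @export
print.patient_cohort <- function(x, ...) {
  n <- length(x$arm)
  cat(sprintf("Simulated trial cohort: %d patients (%d/arm), %d probes\n",
              n, sum(x$arm == 1L), ncol(x$expression)))
  cat(sprintf("  true g+: %d (%.1f%%); responders: %d\n",
              sum(x$subgroup == "g+"), 100 * mean(x$subgroup == "g+"),
              sum(x$response)))
  cat(sprintf("  predictive probes: %d; seed %d\n",
              length(x$predictive_ids), x$seed))
  invisible(x)
}

#' @export
summary.patient_cohort <- function(object, ...) {
  tab <- table(subgroup = object$subgroup, arm = object$arm)
  rate <- tapply(object$response,
                 list(subgroup = object$subgroup, arm = object$arm), mean)
  out <- list(counts = tab, response_rate = rate)
  class(out) <- "summary.patient_cohort"
  out
}

#' @export
print.summary.patient_cohort <- function(x, ...) {
  cat("Patients by (subgroup, arm):\n")
  print(x$counts)
  cat("Observed response rate by (subgroup, arm):\n")
  print(round(x$response_rate, 3))
  invisible(x)
}

#' Simulate a survival cohort with a treatment-benefiting subgroup
#'
#' Generates a two-arm cohort with exponential event times whose rate
#' depends on the (subgroup, arm) cell, independent exponential censoring,
#' and an expression matrix built as in [simulate_trial()]: the first
#' `n_predictive` probes have subgroup-specific means (identical in both
#' arms), the rest mean 0. This is a synthetic fixture emulating the
#' structure of a small adjuvant-chemotherapy trial with a survival
#' endpoint; it exists so the survival branch of the pipeline (Cox
#' interaction screening, risk-score cutoff classification, logrank
#' comparisons) can be exercised against a known subgroup truth.
#'
#' @param n_per_arm Patients per arm.
#' @param n_probes Total probes.
#' @param n_predictive Number of subgroup-informative probes.
#' @param hazards Named numeric vector of positive exponential event rates
#'   `c(h00=, h01=, h10=, h11=)` for the (subgroup, arm) cells, first index
#'   0 = `g-` / 1 = `g+`, second 0 = control / 1 = treatment.
#' @param censor_rate Rate of the independent exponential censoring time;
#'   `0` disables censoring.
#' @param pi Prevalence of the `g+` subgroup.
#' @param mean_pos,mean_neg Predictive-probe means for `g+` / `g-`
#'   patients.
#' @param sd Probe standard deviation.
#' @param seed Integer seed.
#' @return An object of class `"survival_cohort"`: a list with `time`
#'   (years), `event` (1 = event, 0 = censored), `arm`, `expression`,
#'   `subgroup` (true labels), `predictive_ids`, and `seed`.
#' @export
simulate_survival_cohort <- function(n_per_arm, n_probes = 100L,
                                     n_predictive = 1L,
                                     hazards = c(h00 = 0.5, h01 = 0.5,
                                                 h10 = 0.5, h11 = 0.1),
                                     censor_rate = 0, pi = 0.5,
                                     mean_pos = 1, mean_neg = -1,
                                     sd = 0.3, seed) {
  if (missing(seed)) stop("'seed' is required for reproducibility",
                          call. = FALSE)
  hz <- hazards[c("h00", "h01", "h10", "h11")]
  if (anyNA(hz) || any(hz <= 0))
    stop("'hazards' must supply positive rates h00, h01, h10, h11",
         call. = FALSE)
  if (censor_rate < 0) stop("'censor_rate' must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  n <- 2L * as.integer(n_per_arm)
  arm <- rep(c(0L, 1L), each = as.integer(n_per_arm))
  gpos <- stats::rbinom(n, 1L, pi)
  hmat <- matrix(hz, nrow = 2L, byrow = TRUE)  # rows: g-, g+
  rate <- hmat[cbind(gpos + 1L, arm + 1L)]
  t_event <- stats::rexp(n, rate)
  if (censor_rate > 0) {
    t_cens <- stats::rexp(n, censor_rate)
    event <- as.integer(t_event <= t_cens)
    time <- pmin(t_event, t_cens)
  } else {
    event <- rep(1L, n)
    time <- t_event
  }
  expr <- matrix(stats::rnorm(n * n_probes, 0, sd), n, n_probes)
  if (n_predictive > 0L) {
    mu <- ifelse(gpos == 1L, mean_pos, mean_neg)
    expr[, seq_len(n_predictive)] <- expr[, seq_len(n_predictive)] + mu
  }
  colnames(expr) <- paste0("probe_", seq_len(n_probes))
  rownames(expr) <- paste0("pt_", seq_len(n))
  structure(
    list(time = time, event = event, arm = arm, expression = expr,
         subgroup = factor(ifelse(gpos == 1L, "g+", "g-"),
                           levels = c("g-", "g+")),
         predictive_ids = seq_len(as.integer(n_predictive)),
         seed = as.integer(seed)),
    class = "survival_cohort")
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat(sprintf("Survival cohort: %d patients (%d/arm), %d probes, %d events\n",
              length(x$arm), sum(x$arm == 1L), ncol(x$expression),
              sum(x$event)))
  invisible(x)
}
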