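#' Simulation scenario for a two-arm biomarker trial
#'
#' A scenario bundles the parameters of the trial simulator: the prevalence
#' `pi` of the marker-positive (`g+`) subgroup, the four response
#' probabilities `u00`, `u01`, `u10`, `u11` for the (subgroup, arm) cells
#' (first index: 0 = `g-`, 1 = `g+`; second index: 0 = control,
#' 1 = treatment), the per-arm sample size, the dimension of the expression
#' matrix, the number of truly predictive probes, the per-probe noise
#' standard deviation, and the significance level used for interaction
#' screening.
#'
#' @param pi Prevalence of the `g+` subgroup in the sampled population,
#'   in `[0, 1]`.
#' @param u00,u01,u10,u11 Response probabilities for the four
#'   (subgroup, arm) cells, each in `[0, 1]`. The usual ordering
#'   `u00, u01, u10 <= u11` is checked and violations produce a warning,
#'   not an error, so that null configurations can be simulated.
#' @param n_per_arm Number of patients randomized to each arm (>= 2).
#' @param n_probes Total number of probes in the expression matrix.
#' @param n_predictive Number of truly predictive probes
#'   (`<= n_probes`); these occupy the first `n_predictive` columns.
#' @param sd Standard deviation of every probe (> 0).
#' @param alpha_screen Per-probe significance level for the interaction
#'   test during marker screening.
#' @param name Optional label for the scenario.
#'
#' @return An object of class `"asd_scenario"`: a list with the above
#'   fields.
#' @seealso [builtin_scenario()] for the eight reference scenarios A-H,
#'   [simulate_trial()].
#' @export
#' @examples
#' sc <- scenario(pi = 0.1, u00 = 0.2, u01 = 0.2, u10 = 0.2, u11 = 0.6,
#'                n_predictive = 10)
#' sc
scenario <- function(pi, u00, u01, u10, u11,
                     n_per_arm = 200L, n_probes = 5000L,
                     n_predictive = 10L, sd = 0.3,
                     alpha_screen = 0.001, name = NULL) {
  stopifnot(is.numeric(pi), length(pi) == 1L)
  us <- c(u00 = u00, u01 = u01, u10 = u10, u11 = u11)
  if (pi < 0 || pi > 1)
    stop("'pi' must lie in [0, 1]", call. = FALSE)
  if (any(us < 0 | us > 1))
    stop("all response probabilities must lie in [0, 1]", call. = FALSE)
  if (any(us[c("u00", "u01", "u10")] > us["u11"]))
    warning("response probabilities violate the ordering ",
            "u00, u01, u10 <= u11; proceeding anyway", call. = FALSE)
  n_per_arm <- as.integer(n_per_arm)
  n_probes <- as.integer(n_probes)
  n_predictive <- as.integer(n_predictive)
  if (n_per_arm < 2L) stop("'n_per_arm' must be >= 2", call. = FALSE)
  if (n_predictive > n_probes)
    stop("'n_predictive' cannot exceed 'n_probes'", call. = FALSE)
  if (n_predictive < 0L) stop("'n_predictive' must be >= 0", call. = FALSE)
  if (!is.numeric(sd) || sd <= 0) stop("'sd' must be > 0", call. = FALSE)
  if (alpha_screen < 0 || alpha_screen > 1)
    stop("'alpha_screen' must lie in [0, 1]", call. = FALSE)
  structure(
    list(name = name, pi = pi,
         u00 = unname(u00), u01 = unname(u01),
         u10 = unname(u10), u11 = unname(u11),
         n_per_arm = n_per_arm, n_probes = n_probes,
         n_predictive = n_predictive, sd = sd,
         alpha_screen = alpha_screen),
    class = "asd_scenario")
}

# Reference scenario tuples (pi, u00, u01 = u10, u11, n_predictive); the
# remaining parameters are shared: 200/arm, 5000 probes, sd 0.3, screening
# at 0.001.
.builtin_scenarios <- list(
  A = c(0.1, 0.2, 0.2, 0.6, 10),
  B = c(0.1, 0.2, 0.2, 0.6, 15),
  C = c(0.1, 0.2, 0.2, 0.6, 20),
  D = c(0.1, 0.1, 0.2, 0.6, 10),
  E = c(0.1, 0.2, 0.2, 0.8, 10),
  F = c(0.1, 0.2, 0.4, 0.8, 10),
  G = c(0.3, 0.4, 0.4, 0.8, 10),
  H = c(0.3, 0.4, 0.4, 0.8, 15)
)

#' Built-in reference scenarios A-H
#'
#' Returns one of the eight reference simulation scenarios. Each is a tuple
#' (pi, u00, u01 = u10, u11, number of predictive probes) with 200 patients
#' per arm, 5,000 probes, probe standard deviation 0.3, and interaction
#' screening at 0.001:
#'
#' | name | pi  | u00 | u01 = u10 | u11 | predictive |
#' |------|-----|-----|-----------|-----|------------|
#' | A    | 0.1 | 0.2 | 0.2       | 0.6 | 10 |
#' | B    | 0.1 | 0.2 | 0.2       | 0.6 | 15 |
#' | C    | 0.1 | 0.2 | 0.2       | 0.6 | 20 |
#' | D    | 0.1 | 0.1 | 0.2       | 0.6 | 10 |
#' | E    | 0.1 | 0.2 | 0.2       | 0.8 | 10 |
#' | F    | 0.1 | 0.2 | 0.4       | 0.8 | 10 |
#' | G    | 0.3 | 0.4 | 0.4       | 0.8 | 10 |
#' | H    | 0.3 | 0.4 | 0.4       | 0.8 | 15 |
#'
#' @param name One of `"A"` to `"H"`.
#' @return An `"asd_scenario"` object.
#' @export
#' @examples
#' builtin_scenario("A")
builtin_scenario <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !(name %in% names(.builtin_scenarios)))
    stop("unknown scenario; valid names are ",
         paste(names(.builtin_scenarios), collapse = ", "), call. = FALSE)
  p <- .builtin_scenarios[[name]]
  scenario(pi = p[1], u00 = p[2], u01 = p[3], u10 = p[3], u11 = p[4],
           n_predictive = as.integer(p[5]), name = name)
}

#' Probe mean implied by a response rate
#'
#' The simulator places the mean of a predictive probe at the value `x`
#' solving `exp(x) / (1 + exp(x)) = u`, i.e. the log-odds
#' `log(u / (1 - u))` of the corresponding response probability. This is
#' the inverse of the logistic function.
#'
#' @param u A response probability strictly inside (0, 1).
#' @return `log(u / (1 - u))`.
#' @export
#' @examples
#' probe_mean_from_rate(0.5)  # 0
#' probe_mean_from_rate(0.8)  # +1.386...
probe_mean_from_rate <- function(u) {
  if (!is.numeric(u) || any(u <= 0) || any(u >= 1))
    stop("'u' must lie strictly inside (0, 1): the implied mean is ",
         "infinite at 0 or 1", call. = FALSE)
  stats::qlogis(u)
}

#' @export
print.asd_scenario <- function(x, ...) {
  nm <- if (is.null(x$name)) "(custom)" else x$name
  cat("Trial simulation scenario", nm, "\n")
  cat(sprintf("  g+ prevalence pi = %g\n", x$pi))
  cat(sprintf("  response probabilities (subgroup, arm): u00=%g u01=%g u10=%g u11=%g\n",
              x$u00, x$u01, x$u10, x$u11))
  cat(sprintf("  %d patients/arm; %d probes (%d predictive), probe sd %g\n",
              x$n_per_arm, x$n_probes, x$n_predictive, x$sd))
  cat(sprintf("  interaction screening at alpha = %g\n", x$alpha_screen))
  invisible(x)
}
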