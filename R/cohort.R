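#' Synthetic patient cohorts
#'
#' Per-patient data in the source setting are not publicly deposited, so
#' the cohort module generates synthetic patients whose covariates follow
#' truncated-normal distributions plausible for splenomegalic portal
#' hypertension, together with binary thrombosis labels drawn from a known
#' logistic model on the true (pipeline-computed) ALWSS. This gives every
#' downstream statistic a testable ground truth. The packaged fixture
#' record carries the published cohort summary (n = 15, 6 thrombosis
#' positives, 5 males / 10 females, age 54 +- 11).
#'
#' @name synthetic_cohort
NULL

truncnorm_spec <- function(mean, sd, lower, upper) {
  stopifnot(lower > 0, upper > lower, sd > 0)
  list(mean = mean, sd = sd, lower = lower, upper = upper)
}

r_truncnorm <- function(n, spec) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(2 * (n - length(out)) + 10, spec$mean, spec$sd)
    out <- c(out, draw[draw >= spec$lower & draw <= spec$upper])
  }
  out[seq_len(n)]
}

#' Cohort generation configuration
#'
#' Distribution defaults (truncated normals, SI units): PV velocity
#' 0.15 +- 0.04 m/s on \[0.06, 0.30\]; PV diameter 13 +- 2 mm on \[9, 18\];
#' SV diameter 12 +- 3 mm on \[7, 20\]; SV length 100 +- 25 mm on
#' \[50, 180\]; SV tortuosity 1.3 +- 0.2 on \[1, 2\]; spleen maximum
#' diameter 16 +- 3 cm on \[11, 25\] (descriptive, splenomegalic); anatomy
#' type probabilities (0.5, 0.3, 0.2). The label model draws thrombosis
#' status from `Bernoulli(plogis(beta0 + beta1 * ALWSS_cm2))`; the default
#' slope `beta1 = log(3)/30` triples the odds per 30 cm^2 of ALWSS and the
#' default intercept yields roughly 40% prevalence on the default cohort.
#'
#' @param n number of patients.
#' @param seed integer RNG seed.
#' @param anatomy_probs probabilities of anatomy types 1-3 (sum to 1).
#' @param beta0,beta1 logistic label-model intercept and slope
#'   (per cm^2 ALWSS).
#' @param distributions optional named list overriding entries of the
#'   default distribution specs (each a list with `mean`, `sd`, `lower`,
#'   `upper`).
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n = 15, seed = 1,
                          anatomy_probs = c(0.5, 0.3, 0.2),
                          beta0 = -1.848, beta1 = log(3) / 30,
                          distributions = list()) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (length(anatomy_probs) != 3 || any(anatomy_probs < 0) ||
      abs(sum(anatomy_probs) - 1) > 1e-9)
    stop("anatomy_probs must be 3 non-negative values summing to 1",
         call. = FALSE)
  dists <- list(
    pv_velocity = truncnorm_spec(0.15, 0.04, 0.06, 0.30),
    pv_diameter = truncnorm_spec(0.013, 0.002, 0.009, 0.018),
    sv_diameter = truncnorm_spec(0.012, 0.003, 0.007, 0.020),
    sv_length = truncnorm_spec(0.100, 0.025, 0.050, 0.180),
    sv_tortuosity = truncnorm_spec(1.3, 0.2, 1.0, 2.0),
    spleen_max_diameter = truncnorm_spec(0.16, 0.03, 0.11, 0.25)
  )
  for (nm in names(distributions)) {
    if (!nm %in% names(dists))
      stop("unknown distribution '", nm, "'", call. = FALSE)
    d <- modifyList(dists[[nm]], distributions[[nm]])
    if (d$lower <= 0 || d$upper <= d$lower)
      stop("distribution '", nm, "': truncation bounds must be positive ",
           "and ordered", call. = FALSE)
    dists[[nm]] <- d
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 anatomy_probs = anatomy_probs,
                 beta0 = beta0, beta1 = beta1, distributions = dists),
            class = "cohort_config")
}

#' Sample a synthetic patient cohort
#'
#' Deterministic given the config seed. Columns carry SI unit suffixes.
#'
#' @param config a [cohort_config()].
#' @return data.frame with one row per patient: `id`, `pv_velocity_m_s`,
#'   `pv_diameter_m`, `sv_diameter_m`, `sv_length_m`, `sv_tortuosity`,
#'   `anatomy_type`, `spleen_max_diameter_m`.
#' @export
sample_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n
  d <- config$distributions
  data.frame(
    id = sprintf("P%04d", seq_len(n)),
    pv_velocity_m_s = r_truncnorm(n, d$pv_velocity),
    pv_diameter_m = r_truncnorm(n, d$pv_diameter),
    sv_diameter_m = r_truncnorm(n, d$sv_diameter),
    sv_length_m = r_truncnorm(n, d$sv_length),
    sv_tortuosity = r_truncnorm(n, d$sv_tortuosity),
    anatomy_type = sample(1:3, n, replace = TRUE, prob = config$anatomy_probs),
    spleen_max_diameter_m = r_truncnorm(n, d$spleen_max_diameter),
    stringsAsFactors = FALSE
  )
}

#' Draw thrombosis labels from the logistic risk model
#'
#' `label_i ~ Bernoulli(plogis(beta0 + beta1 * alwss_i))`, deterministic
#' given the seed.
#'
#' @param alwss_values ALWSS scores in cm^2.
#' @param beta0,beta1 logistic coefficients (slope per cm^2).
#' @param seed integer RNG seed.
#' @return integer vector of 0/1 labels.
#' @export
generate_labels <- function(alwss_values, beta0 = -1.848,
                            beta1 = log(3) / 30, seed = 1) {
  stopifnot(is.finite(beta0), is.finite(beta1))
  set.seed(seed)
  rbinom(length(alwss_values), 1L, plogis(beta0 + beta1 * alwss_values))
}

#' Published cohort summary fixture
#'
#' The in-study cohort: 15 portal hypertensive patients treated with
#' splenectomy (5 males, 10 females, age 54 +- 11), of whom 6 developed
#' post-splenectomy thrombosis at the three-month follow-up.
#'
#' @return list with `n`, `positives`, `negatives`, `males`, `females`,
#'   `age_mean`, `age_sd`, `positive_fraction`.
#' @export
fixture_cohort <- function() {
  list(n = 15L, positives = 6L, negatives = 9L,
       males = 5L, females = 10L,
       age_mean = 54, age_sd = 11,
       positive_fraction = 6 / 15)
}
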