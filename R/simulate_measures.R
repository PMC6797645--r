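#' Simulate a trial-level measures table with planted standardized effects
#'
#' Generates outcome measures directly at the trial level, bypassing cursor
#' dynamics, so that standardized ambiguity effects can be planted exactly —
#' the generator for calibration studies (type-I error, parameter recovery)
#' where the estimand must be known in closed form. Continuous outcomes are
#' built as `effect * ambiguous + u_subject + e_trial` with
#' `Var(u) + Var(e) = 1`, so within each ambiguity group the outcome has
#' unit standard deviation and the planted effect is on the standardized
#' scale; trials within a subject share `u`, giving an exchangeable
#' within-subject correlation `icc`. The count outcome `xflips` is Poisson
#' with a log link: planted effects act on the log mean, shared log-normal
#' subject frailty induces the clustering.
#'
#' Subjects also receive `weird_scaling` and `wts` indicators (no effect on
#' outcomes) at realistic rates so the full nuisance-adjusted model matrix
#' is exercised.
#'
#' @param n_subjects Number of subjects (clusters).
#' @param n_trials Trials per subject (default 10).
#' @param ambiguous_fraction Fraction of each subject's trials that are
#'   ambiguous (default 0.5).
#' @param effects Named numeric vector of planted ambiguity effects; names
#'   among `xflips`, `xdev`, `area`, `maxspeed`, `rt`. Continuous effects
#'   are in standardized units; the `xflips` effect is on the log mean.
#'   Unnamed outcomes get effect 0 (the null).
#' @param icc Within-subject exchangeable correlation of the continuous
#'   outcomes (default 0.3).
#' @param base_xflips Baseline mean x-flip count on unambiguous trials
#'   (default 2).
#' @param p_weird_scaling,p_wts Per-subject rates of the two nuisance
#'   indicators (defaults 0.4 and 0.1).
#' @param seed Optional integer seed.
#' @return Data frame shaped like [measures_long_table()] output:
#'   `subject_id`, `stimulus_id`, `ambiguous`, the five outcomes,
#'   `weird_scaling`, `wts`, and two-level `browser` / `operating_system`
#'   columns for moderation models.
#' @export
simulate_measures <- function(n_subjects, n_trials = 10,
                              ambiguous_fraction = 0.5,
                              effects = numeric(0),
                              icc = 0.3,
                              base_xflips = 2,
                              p_weird_scaling = 0.4, p_wts = 0.1,
                              seed = NULL) {
  stopifnot(n_subjects >= 2, n_trials >= 1, icc >= 0, icc < 1)
  if (!is.null(seed)) set.seed(seed)
  eff <- c(xflips = 0, xdev = 0, area = 0, maxspeed = 0, rt = 0)
  if (length(effects)) {
    stopifnot(!is.null(names(effects)),
              all(names(effects) %in% names(eff)))
    eff[names(effects)] <- effects
  }

  n_amb <- round(ambiguous_fraction * n_trials)
  amb <- rep(c(0L, 1L), c(n_trials - n_amb, n_amb))
  n <- n_subjects * n_trials
  sid <- rep(sprintf("P%04d", seq_len(n_subjects)), each = n_trials)
  ambiguous <- rep(amb, n_subjects)

  su <- sqrt(icc)
  se <- sqrt(1 - icc)
  cont <- function(effect) {
    u <- rep(stats::rnorm(n_subjects, 0, su), each = n_trials)
    effect * ambiguous + u + stats::rnorm(n, 0, se)
  }
  frailty <- rep(stats::rnorm(n_subjects, 0, 0.3), each = n_trials)
  lambda <- exp(log(base_xflips) + eff["xflips"] * ambiguous + frailty)

  data.frame(
    subject_id = sid,
    stimulus_id = rep(sprintf("S%02d", seq_len(n_trials)), n_subjects),
    ambiguous = ambiguous,
    xflips = stats::rpois(n, lambda),
    xdev = cont(eff["xdev"]),
    area = cont(eff["area"]),
    maxspeed = cont(eff["maxspeed"]),
    rt = cont(eff["rt"]),
    weird_scaling = rep(as.integer(stats::runif(n_subjects) < p_weird_scaling),
                        each = n_trials),
    wts = rep(as.integer(stats::runif(n_subjects) < p_wts), each = n_trials),
    browser = rep(sample(c("Chrome", "Firefox"), n_subjects, replace = TRUE,
                         prob = c(0.8, 0.2)), each = n_trials),
    operating_system = rep(sample(c("Windows", "Macintosh"), n_subjects,
                                  replace = TRUE, prob = c(0.85, 0.15)),
                           each = n_trials),
    stringsAsFactors = FALSE
  )
}
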