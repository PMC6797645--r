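#' Standardize a trial-level outcome
#'
#' Z-scores across all analyzed trials (both ambiguity groups pooled), so a
#' model coefficient reads as the number of pooled standard deviations by
#' which the outcome differs between ambiguous and unambiguous trials.
#' Missing values are ignored for the moments and propagate in the output.
#'
#' @param values Numeric vector.
#' @return Z-scored vector with attributes `center` and `scale`.
#' @export
standardize <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2L) {
    stop("standardize needs at least 2 non-missing values", call. = FALSE)
  }
  s <- stats::sd(values[ok])
  if (s == 0) {
    stop("cannot standardize an outcome with zero dispersion", call. = FALSE)
  }
  m <- mean(values[ok])
  structure((values - m) / s, center = m, scale = s)
}

.outcomes <- c("xflips", "xdev", "area", "maxspeed", "rt")

# nuisance covariates and their full factorial expansion with ambiguity
.ambiguity_rhs <- "ambiguous * weird_scaling * wts"

#' Fit the stimulus-ambiguity GEE model for one outcome
#'
#' Regresses a trial-level outcome on the stimulus-ambiguity indicator with
#' the two display-idiosyncrasy covariates (`weird_scaling`, `wts`) as main
#' effects plus all their interactions with ambiguity and each other (full
#' factorial). Clusters are subjects; working correlation exchangeable;
#' inference robust. Continuous outcomes (`xdev`, `area`, `maxspeed`, `rt`)
#' are standardized across all analyzed trials and use the identity link;
#' `xflips` is a count and uses the Poisson log link, unstandardized.
#'
#' The ambiguity main effect (`ambiguous`) is the headline estimand: for
#' continuous outcomes, the mean difference in pooled standard deviations
#' between ambiguous and unambiguous trials.
#'
#' @param table Long-format measures table from [measures_long_table()] or
#'   [simulate_measures()]; needs the outcome plus `ambiguous`,
#'   `weird_scaling`, `wts`, and the cluster column.
#' @param outcome One of `"xflips"`, `"xdev"`, `"area"`, `"maxspeed"`,
#'   `"rt"`.
#' @param id Cluster column name (default `"subject_id"`).
#' @return An `mt_gee` fit with extra fields `outcome`, `standardized`,
#'   and `scale_sd` (the SD used, for mapping back to raw units).
#' @export
fit_ambiguity_model <- function(table, outcome, id = "subject_id") {
  outcome <- match.arg(outcome, .outcomes)
  needed <- c(outcome, "ambiguous", "weird_scaling", "wts", id)
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols)) {
    stop("measures table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  is_count <- outcome == "xflips"
  d <- table
  if (is_count) {
    d$.y <- d[[outcome]]
    scale_sd <- 1
  } else {
    z <- standardize(d[[outcome]])
    d$.y <- as.numeric(z)
    scale_sd <- attr(z, "scale")
  }
  f <- stats::as.formula(paste(".y ~", .ambiguity_rhs))
  fit <- gee_fit(f, d, id = id,
                 family = if (is_count) "poisson" else "gaussian")
  fit$outcome <- outcome
  fit$standardized <- !is_count
  fit$scale_sd <- scale_sd
  fit
}

#' Fit all five ambiguity models
#'
#' @inheritParams fit_ambiguity_model
#' @param outcomes Outcomes to fit (default all five).
#' @return Named list of `mt_gee` fits.
#' @export
fit_all_ambiguity_models <- function(table, outcomes = .outcomes,
                                     id = "subject_id") {
  fits <- lapply(outcomes, function(o) fit_ambiguity_model(table, o, id = id))
  names(fits) <- outcomes
  fits
}

#' Fit a browser / operating-system moderation model
#'
#' Refits the ambiguity model adding a two-level moderator's main effect and
#' its interaction with stimulus ambiguity; the interaction estimates how
#' much the ambiguity effect differs between the two levels (e.g. Firefox
#' vs. Chrome). Rows from other moderator levels are excluded first.
#'
#' @inheritParams fit_ambiguity_model
#' @param moderator `"browser"` or `"operating_system"` (any column of
#'   `table` is accepted).
#' @param levels The two levels to retain; defaults to the two most frequent
#'   in the data.
#' @return An `mt_gee` fit with extra fields `moderator`, `levels`, and
#'   `interaction_term` naming the moderation coefficient.
#' @export
fit_moderation_model <- function(table, outcome,
                                 moderator = c("browser", "operating_system"),
                                 levels = NULL, id = "subject_id") {
  outcome <- match.arg(outcome, .outcomes)
  if (length(moderator) > 1L) moderator <- match.arg(moderator)
  if (!moderator %in% names(table)) {
    stop("no column ", dQuote(moderator), " in the measures table",
         call. = FALSE)
  }
  obs <- table[[moderator]][!is.na(table[[moderator]])]
  if (is.null(levels)) {
    tab <- sort(table(obs), decreasing = TRUE)
    if (length(tab) < 2L) {
      stop("moderator ", dQuote(moderator),
           " has fewer than 2 levels in the data", call. = FALSE)
    }
    levels <- names(tab)[1:2]
  }
  if (length(levels) != 2L || !all(levels %in% obs)) {
    stop("moderation needs exactly 2 retained levels present in the data",
         call. = FALSE)
  }
  d <- table[table[[moderator]] %in% levels & !is.na(table[[moderator]]), ,
             drop = FALSE]
  d$.mod <- as.integer(d[[moderator]] == levels[2L])

  is_count <- outcome == "xflips"
  if (is_count) {
    d$.y <- d[[outcome]]
  } else {
    d$.y <- as.numeric(standardize(d[[outcome]]))
  }
  f <- stats::as.formula(paste(".y ~", .ambiguity_rhs, "+ .mod + .mod:ambiguous"))
  fit <- gee_fit(f, d, id = id,
                 family = if (is_count) "poisson" else "gaussian")
  fit$outcome <- outcome
  fit$standardized <- !is_count
  fit$moderator <- moderator
  fit$levels <- levels
  fit$interaction_term <- "ambiguous:.mod"
  fit
}

#' Collect tidy results across fits
#'
#' @param fits Named list of `mt_gee` fits (e.g. from
#'   [fit_all_ambiguity_models()]).
#' @return One data frame with columns `outcome`, `link`, `term`,
#'   `estimate`, `robust_se`, `p_value`.
#' @export
tidy_all <- function(fits) {
  out <- do.call(rbind, lapply(fits, tidy_gee))
  rownames(out) <- NULL
  out[, c("outcome", "link", "term", "estimate", "robust_se", "p_value")]
}
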