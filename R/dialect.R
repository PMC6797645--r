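#' Describe the wide-format raw export dialect
#'
#' A dialect records everything needed to interpret a raw wide-format export
#' from an online mouse-tracking survey: the single character used to separate
#' recordings within a cell, the mapping from codebook roles to CSV header
#' names, and the expected trial counts.
#'
#' In this export format, each subject occupies one CSV row. Continuous
#' recordings (cursor x, cursor y, timestamp) and per-trial quantities (trial
#' onset time, button-click time, alerts, latency, window size, stimulus
#' order) are stored as strings of values joined by `separator`. The default
#' separator is `"a"`, which can never occur inside a decimal number.
#'
#' @param separator Single character separating recordings within a cell.
#'   Must not be a digit, sign, or decimal point.
#' @param columns Named character vector mapping codebook roles to CSV header
#'   names. Roles missing from this map fall back to the defaults (see
#'   [default_column_map()]). Survey platforms rename columns freely, so any
#'   role can be remapped.
#' @param n_trials Expected number of recorded experimental trials per
#'   subject (default 10).
#' @param n_practice Expected number of practice trials, for which no
#'   trajectories are recorded (default 6).
#' @param skip_rows Number of decorative header rows after the column-name
#'   row to skip when reading (some platforms emit 1-2 of these; default 0).
#' @return An object of class `mt_dialect`.
#' @examples
#' d <- export_dialect()
#' d$separator
#' @export
export_dialect <- function(separator = "a",
                           columns = character(),
                           n_trials = 10,
                           n_practice = 6,
                           skip_rows = 0) {
  if (!is.character(separator) || length(separator) != 1L ||
      nchar(separator) != 1L) {
    stop("`separator` must be a single character", call. = FALSE)
  }
  if (grepl("[0-9+.eE-]", separator)) {
    stop("`separator` must not be a digit, sign, decimal point, or exponent letter",
         call. = FALSE)
  }
  if (!is.numeric(n_trials) || n_trials < 1) {
    stop("`n_trials` must be >= 1", call. = FALSE)
  }
  map <- default_column_map()
  if (length(columns)) {
    if (is.null(names(columns)) || any(!nzchar(names(columns)))) {
      stop("`columns` must be a named character vector (role = header)",
           call. = FALSE)
    }
    unknown <- setdiff(names(columns), names(map))
    if (length(unknown)) {
      stop("unknown codebook roles in `columns`: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    map[names(columns)] <- columns
  }
  structure(
    list(separator = separator, columns = map,
         n_trials = as.integer(n_trials),
         n_practice = as.integer(n_practice),
         skip_rows = as.integer(skip_rows)),
    class = "mt_dialect"
  )
}

#' Default mapping from codebook roles to raw export header names
#'
#' Header names follow the survey platform's codebook: coordinate streams
#' `xPos`/`yPos`/`time`, per-trial timing fields, window dimensions, alerts,
#' latency, and stimulus order, plus browser metadata columns.
#'
#' @return Named character vector, names are roles used throughout the
#'   package, values are CSV header names.
#' @export
default_column_map <- function() {
  c(subject_id         = "subject",
    x_stream           = "xPos",
    y_stream           = "yPos",
    t_stream           = "time",
    on_load_times      = "onLoadTime",
    on_ready_times     = "onReadyTime",
    button_click_times = "buttonClickTime",
    page_submit_times  = "pageSubmitTime",
    window_widths      = "windowWidth",
    window_heights     = "windowHeight",
    alerts_stream      = "alerts",
    latency_stream     = "latency",
    stimulus_order     = "stimulusOrder",
    chosen_categories  = "chosenCategory",
    browser            = "browser_Browser",
    browser_version    = "browser_Version",
    operating_system   = "browser_Operating.System",
    resolution         = "browser_Resolution")
}

#' @export
print.mt_dialect <- function(x, ...) {
  cat("<mt_dialect>\n")
  cat("  separator: ", dQuote(x$separator), "\n", sep = "")
  cat("  trials expected: ", x$n_trials,
      " (+", x$n_practice, " practice)\n", sep = "")
  remapped <- x$columns[x$columns != default_column_map()]
  if (length(remapped)) {
    cat("  remapped columns:",
        paste(names(remapped), "=", remapped, collapse = ", "), "\n")
  }
  invisible(x)
}

# token must be a plain decimal: optional sign, digits, optional fraction.
# Scientific notation is rejected; raw streams are pixel/millisecond values.
.numeric_token_re <- "^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)$"

#' Parse a character-separated numeric stream
#'
#' Splits a raw cell on the dialect separator and parses each token as a
#' plain decimal number (optional sign and fraction; scientific notation and
#' locale-specific grouping are rejected). The empty string yields an empty
#' numeric vector; `NA` input (an absent cell) yields `NULL`, which
#' downstream quality control treats as a missing stream rather than an
#' empty one.
#'
#' @param raw A single string (possibly empty or `NA`).
#' @param dialect An [export_dialect()].
#' @param context Optional label (e.g. "subject S01, column xPos") used in
#'   parse-error messages.
#' @return Numeric vector of parsed values in original order, or `NULL` for
#'   an absent cell.
#' @examples
#' parse_separated_stream("312a315a309", export_dialect())
#' parse_separated_stream("", export_dialect())
#' @export
parse_separated_stream <- function(raw, dialect = export_dialect(),
                                   context = "") {
  stopifnot(inherits(dialect, "mt_dialect"))
  if (length(raw) != 1L) stop("`raw` must be a single string", call. = FALSE)
  if (is.na(raw)) return(NULL)
  if (!nzchar(raw)) return(numeric(0))
  tokens <- strsplit(raw, dialect$separator, fixed = TRUE)[[1L]]
  bad <- which(!grepl(.numeric_token_re, tokens))
  if (length(bad)) {
    where <- if (nzchar(context)) paste0(" in ", context) else ""
    stop(sprintf("non-numeric token %s at position %d%s",
                 dQuote(tokens[bad[1L]]), bad[1L], where),
         call. = FALSE)
  }
  as.numeric(tokens)
}

#' Split a character-separated stream without numeric coercion
#'
#' Used for identifier-valued streams (stimulus order, chosen categories)
#' where tokens are not numbers.
#'
#' @inheritParams parse_separated_stream
#' @return Character vector of tokens; `NULL` for an absent cell,
#'   `character(0)` for an empty one.
#' @export
split_stream <- function(raw, dialect = export_dialect()) {
  stopifnot(inherits(dialect, "mt_dialect"))
  if (is.na(raw)) return(NULL)
  if (!nzchar(raw)) return(character(0))
  strsplit(raw, dialect$separator, fixed = TRUE)[[1L]]
}

#' Join values into a character-separated stream
#'
#' Inverse of [parse_separated_stream()] / [split_stream()]: numbers are
#' formatted as plain decimals (never scientific notation), then joined with
#' the dialect separator.
#'
#' @param values Numeric or character vector; `NULL` encodes an absent cell
#'   and yields `NA`.
#' @param dialect An [export_dialect()].
#' @return A single string (`NA_character_` for `NULL` input).
#' @export
join_stream <- function(values, dialect = export_dialect()) {
  stopifnot(inherits(dialect, "mt_dialect"))
  if (is.null(values)) return(NA_character_)
  if (length(values) == 0L) return("")
  if (is.numeric(values)) {
    values <- format_plain_numbers(values)
  }
  paste(values, collapse = dialect$separator)
}

# plain-decimal formatting with enough digits to round-trip px/ms values;
# trailing zeros trimmed so integers serialize as integers. Integer-valued
# vectors (the common case: pixels and milliseconds) take a fast sprintf
# path; %.0f is exact below 2^53.
format_plain_numbers <- function(x) {
  if (anyNA(x)) stop("cannot serialize NA inside a stream", call. = FALSE)
  if (all(x == round(x))) return(sprintf("%.0f", x))
  vapply(x, function(v) {
    format(v, scientific = FALSE, trim = TRUE, digits = 15,
           nsmall = 0, drop0trailing = TRUE)
  }, character(1))
}
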