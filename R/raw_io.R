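#' @name raw_io
#' @title Reading and writing wide-format raw exports
#'
#' @description
#' One subject per CSV row; coordinate and timing recordings are stored as
#' character-separated strings (see [export_dialect()]). On read, header
#' names are translated to stable codebook roles; columns outside the
#' codebook (demographics, platform bookkeeping) are passed through
#' untouched. Streams are kept as raw strings at this stage — parsing is
#' deferred so that malformed cells can be flagged per subject instead of
#' aborting the whole read.
NULL

# roles that must be present in any usable export
.mandatory_roles <- c("subject_id", "x_stream", "y_stream", "t_stream",
                      "on_ready_times", "button_click_times")

#' Read a wide-format raw export
#'
#' @param path Path to a CSV file with a header row.
#' @param dialect An [export_dialect()] describing separator and column names.
#' @return A data frame of class `mt_raw` with one row per subject. Codebook
#'   columns are renamed to their roles (`subject_id`, `x_stream`, ...);
#'   unknown columns keep their original names. All cells are character;
#'   empty cells become `NA` (an absent stream). The dialect is attached as
#'   attribute `"dialect"`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_subjects = 2, seed = 1))
#' f <- tempfile(fileext = ".csv")
#' write_raw_export(sim$records, f)
#' raw <- read_raw_export(f)
#' nrow(raw)
#' @export
read_raw_export <- function(path, dialect = export_dialect()) {
  stopifnot(inherits(dialect, "mt_dialect"))
  if (!file.exists(path)) {
    stop("cannot read raw export: no such file: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        skip = dialect$skip_rows, na.strings = character(0))
  map <- dialect$columns
  missing_cols <- setdiff(map[.mandatory_roles], names(df))
  if (length(missing_cols)) {
    stop("raw export is missing mandatory columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  present <- map[map %in% names(df)]
  # rename codebook headers to roles, preserve original column order
  names(df)[match(present, names(df))] <- names(present)
  # absent roles become all-NA columns so downstream code can rely on them
  for (role in setdiff(names(map), names(df))) df[[role]] <- NA_character_
  df[df == ""] <- NA_character_
  structure(df, class = c("mt_raw", "data.frame"), dialect = dialect)
}

#' Write subject records as a wide-format raw export
#'
#' Inverse of [read_raw_export()]: role-named columns are renamed back to the
#' dialect's header names and absent streams are written as empty cells, so
#' that writing then reading returns field-identical records.
#'
#' @param records An `mt_raw` data frame (or plain data frame with role-named
#'   columns).
#' @param path Output CSV path.
#' @param dialect An [export_dialect()].
#' @return `path`, invisibly.
#' @export
write_raw_export <- function(records, path, dialect = export_dialect()) {
  stopifnot(inherits(dialect, "mt_dialect"), is.data.frame(records))
  df <- as.data.frame(records)
  map <- dialect$columns
  roles <- intersect(names(map), names(df))
  names(df)[match(roles, names(df))] <- map[roles]
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("cannot write raw export to ", path, ": ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(path)
}

#' @export
print.mt_raw <- function(x, ...) {
  cat("<mt_raw> ", nrow(x), " subject(s), ", ncol(x), " columns\n", sep = "")
  if (nrow(x)) {
    n_absent <- sum(is.na(x$x_stream))
    cat("  subjects with absent coordinate streams: ", n_absent, "\n", sep = "")
  }
  invisible(x)
}
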