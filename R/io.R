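## Internal schema validator for long-format trial tables.
check_trials <- function(trials, need_reproduced = TRUE) {
  required <- c("participant_id", "condition", "set_id", "position", "sample_ms")
  if (need_reproduced) required <- c(required, "reproduced_ms")
  if (!is.data.frame(trials)) stop("trials must be a data frame", call. = FALSE)
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"trial" %in% names(trials)) {
    stop("missing required column(s): trial", call. = FALSE)
  }
  bad_cond <- setdiff(unique(as.character(trials$condition)), CONDITIONS)
  if (length(bad_cond)) {
    stop("unknown condition code(s): ", paste(bad_cond, collapse = ", "),
         call. = FALSE)
  }
  invisible(trials)
}

#' Read a long-format trial table
#'
#' Reads and validates trial-level reproduction data: one row per
#' (trial, position) with columns `participant_id`, `block` (optional),
#' `trial`, `condition` (`AS`/`DS`/`RS`), `set_id`, `position` (1-4),
#' `sample_ms` and, unless `require_reproduced = FALSE`, `reproduced_ms`.
#' Durations recorded in seconds are auto-detected by magnitude and converted
#' to ms (with a message on stderr). Files whose columns are named differently
#' can be adapted with `map`.
#'
#' @param path CSV file (UTF-8, header, '.' decimal).
#' @param map Optional named character vector renaming file columns to schema
#'   columns, e.g. `c(condition = "cond", sample_ms = "duration")` (names are
#'   schema names, values the file's names).
#' @param require_reproduced Require a `reproduced_ms` column?
#' @return Validated data frame in ms.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_trials(generate_session("s1", 1), f)
#' head(read_trials(f, require_reproduced = FALSE))
#' @export
read_trials <- function(path, map = NULL, require_reproduced = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!is.null(map)) {
    for (schema_name in names(map)) {
      file_name <- map[[schema_name]]
      if (!file_name %in% names(x)) {
        stop("column mapping refers to absent column: ", file_name, call. = FALSE)
      }
      names(x)[names(x) == file_name] <- schema_name
    }
  }
  check_trials(x, need_reproduced = require_reproduced)
  # unit auto-detection: a median presented interval below 10 can only be
  # seconds in this paradigm (intervals are 0.4-1.1 s)
  if (stats::median(x$sample_ms, na.rm = TRUE) < 10) {
    message("sample_ms appears to be in seconds; converting to ms")
    x$sample_ms <- x$sample_ms * 1000
    if ("reproduced_ms" %in% names(x)) x$reproduced_ms <- x$reproduced_ms * 1000
  }
  # every trial must carry positions 1..4 exactly once
  key <- paste(x$participant_id, x$trial, sep = "/")
  ok <- tapply(x$position, key, function(p) identical(sort(as.integer(p)), 1:4))
  if (any(!ok)) {
    bad <- names(ok)[!ok]
    stop("incomplete trial(s) (positions 1-4 required): ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "", call. = FALSE)
  }
  x
}

#' @rdname read_trials
#' @param trials Trial table to write.
#' @param path Output CSV path.
#' @export
write_trials <- function(trials, path) {
  check_trials(trials, need_reproduced = "reproduced_ms" %in% names(trials))
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

## JSON run manifest: everything needed to reproduce a run.
write_manifest <- function(path, command, seed, inputs = NULL, outputs = NULL,
                           config = NULL) {
  manifest <- list(
    command = command,
    seed = seed,
    inputs = inputs,
    outputs = outputs,
    config = config,
    package_version = as.character(utils::packageVersion("rhythmrep")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
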