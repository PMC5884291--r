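# Readers and writers for the package's plain-text interchange formats.
#
# Skeleton CSV (exact header, exact order): frame,t,joint,x,y,z
#   frame 0-based integer; t seconds; joint lower-snake-case registry label;
#   x,y,z metres.  One row per joint per frame, UTF-8, '.' decimal mark.
# Paired-measurement CSV: subject,a,b (agreement) or
#   subject,session1,session2 (repeatability).
# Reports: JSON via jsonlite.

.SKEL_HEADER <- c("frame", "t", "joint", "x", "y", "z")

.check_header <- function(path, expected) {
  hdr <- readLines(path, n = 1L, warn = FALSE)
  got <- strsplit(hdr, ",", fixed = TRUE)[[1]]
  if (!identical(trimws(got), expected)) {
    abort(sprintf("invalid header in '%s': expected '%s', got '%s'",
                  path, paste(expected, collapse = ","), hdr),
          class = "kinagree_data_error")
  }
}

# Parse a character column to double, reporting the first bad file line.
# Data rows start at file line 2 (line 1 is the header).
.num_col <- function(raw, col, path) {
  v <- suppressWarnings(as.numeric(raw[[col]]))
  bad <- which(is.na(v) & !is.na(raw[[col]]))
  nas <- which(is.na(raw[[col]]))
  first <- min(c(bad, nas, Inf))
  if (is.finite(first)) {
    abort(sprintf("non-numeric '%s' in '%s' at line %d",
                  col, path, first + 1L),
          class = "kinagree_data_error")
  }
  v
}

#' Read and write skeleton CSV files
#'
#' The column order is part of the schema; files with reordered or renamed
#' columns are rejected.  Malformed values are reported with their file line
#' number.  Writing then reading a sequence reproduces it exactly.
#'
#' @param path File path.
#' @param nominal_rate Nominal frame rate recorded on the returned sequence.
#' @return `read_skeleton_csv()` returns a `skeleton_sequence`;
#'   `write_skeleton_csv()` returns `path` invisibly.
#' @export
read_skeleton_csv <- function(path, nominal_rate = 30) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "kinagree_data_error")
  }
  .check_header(path, .SKEL_HEADER)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0L) {
    abort(paste0("empty skeleton file: ", path),
          class = "kinagree_data_error")
  }
  frame <- .num_col(raw, "frame", path)
  tt <- .num_col(raw, "t", path)
  x <- .num_col(raw, "x", path)
  y <- .num_col(raw, "y", path)
  z <- .num_col(raw, "z", path)
  dat <- tibble(frame = as.integer(frame), t = tt, joint = raw$joint,
                x = x, y = y, z = z)
  # strictly increasing t across frames, reported with the offending line
  ord <- order(dat$frame)
  ft <- dat[ord, c("frame", "t")]
  dup <- ft[!duplicated(ft$frame), ]
  if (nrow(dup) > 1L) {
    bad <- which(diff(dup$t) <= 0)
    if (length(bad) > 0L) {
      row <- which(dat$frame == dup$frame[bad[1] + 1L])[1]
      abort(sprintf("non-increasing t in '%s' at line %d", path, row + 1L),
            class = "kinagree_data_error")
    }
  }
  skeleton_sequence(dat, nominal_rate = nominal_rate)
}

#' @param seq A `skeleton_sequence` (or conforming data frame).
#' @rdname read_skeleton_csv
#' @export
write_skeleton_csv <- function(seq, path) {
  cols <- as_tibble(seq)[.SKEL_HEADER]
  readr::write_csv(cols, path, progress = FALSE)
  invisible(path)
}

#' Read and write paired-measurement CSV files
#'
#' Two schemas are recognised by their exact headers: `subject,a,b` for
#' method-agreement pairs and `subject,session1,session2` for two-session
#' repeatability pairs.
#'
#' @param path File path.
#' @return `read_pairs_csv()` returns a tibble whose columns follow the
#'   file's schema, with a `kind` attribute (`"agreement"` or
#'   `"repeatability"`); `write_pairs_csv()` returns `path` invisibly.
#' @export
read_pairs_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "kinagree_data_error")
  }
  hdr <- strsplit(readLines(path, n = 1L, warn = FALSE), ",",
                  fixed = TRUE)[[1]]
  hdr <- trimws(hdr)
  if (identical(hdr, c("subject", "a", "b"))) {
    kind <- "agreement"
    value_cols <- c("a", "b")
  } else if (identical(hdr, c("subject", "session1", "session2"))) {
    kind <- "repeatability"
    value_cols <- c("session1", "session2")
  } else {
    abort(sprintf(
      "invalid header in '%s': expected 'subject,a,b' or 'subject,session1,session2'",
      path
    ), class = "kinagree_data_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  out <- tibble(subject = raw$subject)
  for (cc in value_cols) out[[cc]] <- .num_col(raw, cc, path)
  attr(out, "kind") <- kind
  out
}

#' @param pairs A data frame with columns `subject,a,b` or
#'   `subject,session1,session2`.
#' @rdname read_pairs_csv
#' @export
write_pairs_csv <- function(pairs, path) {
  if (all(c("subject", "a", "b") %in% names(pairs))) {
    cols <- c("subject", "a", "b")
  } else if (all(c("subject", "session1", "session2") %in% names(pairs))) {
    cols <- c("subject", "session1", "session2")
  } else {
    abort("`pairs` must have columns subject,a,b or subject,session1,session2")
  }
  readr::write_csv(as_tibble(pairs)[cols], path, progress = FALSE)
  invisible(path)
}

#' Read and write report JSON
#'
#' Reports are plain named lists (see [agreement_report()]); scalars are
#' written unboxed at full precision, so parse -> serialise -> parse is a
#' fixed point.
#'
#' @param report A named list.
#' @param path File path.
#' @return `write_report_json()` returns `path` invisibly;
#'   `read_report_json()` returns the parsed list.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Write the per-stage cleaning intermediates
#'
#' Writes the `raw`, `deoutliered`, `interpolated` and `smoothed` stages of
#' a preprocessed sequence as skeleton CSVs with the matching suffixes
#' (`<prefix>.raw.csv`, ...).
#'
#' @param pre A sequence from [preprocess_sequence()] with kept stages.
#' @param prefix Output path prefix.
#' @return The written paths, invisibly.
#' @export
write_stage_csvs <- function(pre, prefix) {
  stages <- attr(pre, "stages")
  if (is.null(stages)) {
    abort("sequence has no kept stages; rerun preprocess_sequence() with keep_stages = TRUE")
  }
  paths <- character(0)
  for (nm in names(stages)) {
    p <- paste0(prefix, ".", nm, ".csv")
    write_skeleton_csv(stages[[nm]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
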