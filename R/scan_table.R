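# Scan-table schema and I/O.
#
# A scan table is a plain data.frame with one row per scan. All volumes are
# carried in mm^3 end-to-end; no unit conversion happens anywhere in the
# package. Sex is carried as the strings "female"/"male" in files and mapped
# to a 0/1 indicator (female = 1) only inside model design matrices, because
# the analyses report female effects.

.protocol_levels <- c("HARP", "CRHD", "SRPB_iso", "SRPB_aniso")
.sex_levels <- c("female", "male")
.cohort_roles <- c("main", "traveling", "adolescent_long", "adult_long")

.required_cols <- c("participant_id", "procedure_id", "protocol",
                    "age_at_scan", "sex", "scan_order")
.optional_cols <- c("site", "machine", "vendor", "cohort_role",
                    "etiv_mm3", "sbtiv_mm3", "body_height_cm",
                    "body_weight_kg")

#' Validate a scan table
#'
#' Checks the scan-table schema and row-level invariants: positive volumes,
#' at least one of `etiv_mm3`/`sbtiv_mm3` per row, known protocol and sex
#' levels, unique `participant_id` x `scan_order`, and a single protocol per
#' `procedure_id`. Violations are reported with the offending row numbers.
#'
#' @param x a data.frame of scans.
#' @return `x`, with class `"scan_table"` prepended, invisibly usable as a
#'   plain data.frame.
#' @export
validate_scan_table <- function(x) {
  if (!is.data.frame(x)) stop("scan table must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(.required_cols, names(x))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!any(c("etiv_mm3", "sbtiv_mm3") %in% names(x))) {
    stop("schema error: need at least one of etiv_mm3 / sbtiv_mm3",
         call. = FALSE)
  }
  for (col in setdiff(.optional_cols, names(x))) {
    x[[col]] <- if (col == "cohort_role") "main" else NA
  }

  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) > 0L) {
      stop("row error (", length(rows), " row(s)): ", what,
           " at row(s) ", paste(head(rows, 10L), collapse = ", "),
           if (length(rows) > 10L) ", ..." else "", call. = FALSE)
    }
  }

  num_or_na <- function(v) is.na(v) | (is.finite(suppressWarnings(as.numeric(v))))
  bad(!num_or_na(x$etiv_mm3) | !num_or_na(x$sbtiv_mm3),
      "unparseable numeric volume")
  x$etiv_mm3 <- as.numeric(x$etiv_mm3)
  x$sbtiv_mm3 <- as.numeric(x$sbtiv_mm3)

  bad(is.na(x$etiv_mm3) & is.na(x$sbtiv_mm3),
      "neither etiv_mm3 nor sbtiv_mm3 present")
  bad(!is.na(x$etiv_mm3) & x$etiv_mm3 <= 0, "non-positive etiv_mm3")
  bad(!is.na(x$sbtiv_mm3) & x$sbtiv_mm3 <= 0, "non-positive sbtiv_mm3")
  bad(!(x$protocol %in% .protocol_levels),
      paste0("protocol not one of {", paste(.protocol_levels, collapse = ", "), "}"))
  bad(!(x$sex %in% .sex_levels), "sex not one of {female, male}")
  bad(!is.na(x$age_at_scan) & x$age_at_scan < 0, "negative age_at_scan")
  bad(is.na(x$scan_order) | x$scan_order < 1 |
        x$scan_order != as.integer(x$scan_order), "scan_order not integer >= 1")
  bad(!(x$cohort_role %in% .cohort_roles), "unknown cohort_role")

  key <- paste(x$participant_id, x$scan_order, sep = "\r")
  bad(duplicated(key), "duplicate participant_id + scan_order")

  proto_per_proc <- tapply(x$protocol, x$procedure_id,
                           function(p) length(unique(p)))
  if (any(proto_per_proc > 1L)) {
    stop("row error: procedure(s) with inconsistent protocol: ",
         paste(names(proto_per_proc)[proto_per_proc > 1L], collapse = ", "),
         call. = FALSE)
  }

  class(x) <- unique(c("scan_table", class(x)))
  x
}

#' Read a scan table from CSV or TSV
#'
#' Reads a tidy one-row-per-scan table (UTF-8, header row, empty fields for
#' missing values) and validates it against the scan-table schema.
#'
#' @param path file to read.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return a validated `scan_table` data.frame.
#' @seealso [write_scan_table()], [validate_scan_table()]
#' @export
read_scan_table <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (dialect == "csv") "," else "\t"
  x <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                na.strings = c("NA", ""), fileEncoding = "UTF-8")
  validate_scan_table(x)
}

#' Write a scan table to CSV or TSV
#'
#' Inverse of [read_scan_table()]: UTF-8, header row, missing values written
#' as empty fields. Round-tripping through write/read is the identity on all
#' fields.
#'
#' @param x a scan table (validated or plain data.frame).
#' @param path output file.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(x, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  x <- as.data.frame(x)
  # 17 significant digits so doubles survive the text round-trip exactly
  for (col in names(x)) {
    if (is.double(x[[col]])) {
      v <- sprintf("%.17g", x[[col]])
      v[is.na(x[[col]])] <- NA
      x[[col]] <- v
    }
  }
  write.table(x, path, sep = sep, row.names = FALSE,
              quote = TRUE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Parse a "# Measure" value from a FreeSurfer-style stats file
#'
#' FreeSurfer's `aseg.stats` and SAMSEG's stats output both carry volume
#' summaries on header lines of the form
#' `# Measure <key>, <short>, <description>, <value>, <units>`
#' (SAMSEG writes `# Measure Intra-Cranial, 1620781.818430, mm^3` with fewer
#' fields). Both dialects are accepted, with either `", "` or bare-`","`
#' separators.
#'
#' @param path stats file to read.
#' @param measure_key key to look up, e.g. `"EstimatedTotalIntraCranialVol"`
#'   (aseg/eTIV) or `"Intra-Cranial"` (SAMSEG/sbTIV).
#' @return a list of class `"stats_measure"` with elements `measure_key`,
#'   `value` (numeric) and `units`.
#' @export
parse_measure_stats <- function(path, measure_key) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  idx <- grep("^# Measure ", lines)
  if (length(idx) == 0L) {
    stop("no '# Measure' lines found in ", path, call. = FALSE)
  }
  keys <- character(length(idx))
  parsed <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    body <- sub("^# Measure ", "", lines[idx[i]])
    fields <- trimws(strsplit(body, ",")[[1]])
    if (length(fields) < 3L) {
      stop("malformed measure line at line ", idx[i], ": ", lines[idx[i]],
           call. = FALSE)
    }
    value <- suppressWarnings(as.numeric(fields[length(fields) - 1L]))
    if (!is.finite(value)) {
      stop("malformed measure line at line ", idx[i],
           ": non-numeric value field", call. = FALSE)
    }
    keys[i] <- fields[1L]
    parsed[[i]] <- structure(
      list(measure_key = fields[1L], value = value,
           units = fields[length(fields)]),
      class = "stats_measure")
  }
  hit <- which(keys == measure_key)
  if (length(hit) == 0L) {
    stop("measure key '", measure_key, "' not found; available: ",
         paste(unique(keys), collapse = ", "), call. = FALSE)
  }
  parsed[[hit[1L]]]
}

#' Write a stats-file fixture carrying "# Measure" lines
#'
#' Emits a minimal FreeSurfer-style (`style = "aseg"`) or SAMSEG-style
#' (`style = "samseg"`) stats file from one or more measures, so that
#' parse/write round-trips can be tested without any imaging tool.
#'
#' @param measures a `stats_measure` or list of them.
#' @param path output file.
#' @param style `"aseg"` (5-field lines with short name and description) or
#'   `"samseg"` (3-field lines).
#' @return `path`, invisibly.
#' @export
write_measure_stats <- function(measures, path, style = c("aseg", "samseg")) {
  style <- match.arg(style)
  if (inherits(measures, "stats_measure")) measures <- list(measures)
  hdr <- c("# Title tivagree synthetic stats fixture",
           "# generating_program tivagree")
  body <- vapply(measures, function(m) {
    stopifnot(inherits(m, "stats_measure"))
    if (!identical(m$units, "mm^3")) {
      stop("TIV measures must carry units mm^3, got: ", m$units, call. = FALSE)
    }
    val <- format(m$value, scientific = FALSE, trim = TRUE, digits = 15)
    if (style == "aseg") {
      paste0("# Measure ", m$measure_key, ", ", m$measure_key,
             ", synthetic measure, ", val, ", ", m$units)
    } else {
      paste0("# Measure ", m$measure_key, ", ", val, ", ", m$units)
    }
  }, character(1L))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Published multi-site per-procedure agreement summary
#'
#' Returns the bundled per-procedure summary table of the published
#' multi-site TIV comparison (SRPBS DecNef / BMB-HBM projects): per-procedure
#' and overall n, ICC(2,1) for the full sample and the non-small-eTIV
#' subgroup, and means/SDs of eTIV, sbTIV, deviation and absolute error (all
#' volumes mm^3). These printed values anchor the synthetic generator's
#' defaults and support arithmetic consistency checks.
#'
#' @param include_overall keep the `"Overall"` row (default `TRUE`).
#' @return a data.frame, one row per procedure (plus `Overall`).
#' @export
reference_summary_table <- function(include_overall = TRUE) {
  path <- system.file("extdata", "multisite_tiv_summary.csv",
                      package = "tivagree", mustWork = TRUE)
  x <- read.csv(path, stringsAsFactors = FALSE)
  if (!include_overall) x <- x[x$procedure_id != "Overall", , drop = FALSE]
  x
}

#' Published cohort scan/participant counts
#'
#' Printed design counts of the published multi-site study: total, main and
#' traveling-subject (TS) scan counts, participant counts, TS scans-per
#' -participant range, and body-size subsample descriptives.
#'
#' @return a named numeric vector.
#' @export
reference_cohort_counts <- function() {
  path <- system.file("extdata", "cohort_counts.csv",
                      package = "tivagree", mustWork = TRUE)
  x <- read.csv(path, stringsAsFactors = FALSE)
  setNames(x$value, x$quantity)
}
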