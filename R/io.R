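# CSV readers and writers for the canonical long-format dialect, with
# line-numbered validation errors.

.read_checked <- function(path, required, numeric_cols = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0L) stop("empty file: ", path)
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop("missing column(s) in ", basename(path), ": ",
         paste(miss, collapse = ", "))
  for (col in intersect(numeric_cols, names(d))) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]) & d[[col]] != "")
    if (length(bad))
      stop(sprintf("non-numeric value in column `%s` of %s (line %d: \"%s\")",
                   col, basename(path), bad[1L] + 1L, d[[col]][bad[1L]]))
    d[[col]] <- v
  }
  d
}

#' Read a long-format amplification table
#'
#' Canonical dialect: columns `well, sample_id, target, cycle,
#' fluorescence`, one row per cycle reading. Duplicate
#' sample x target x well x cycle rows are rejected with the offending
#' line number.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_amplification_csv <- function(path) {
  d <- .read_checked(path, c("well", "sample_id", "target", "cycle",
                             "fluorescence"),
                     numeric_cols = c("cycle", "fluorescence"))
  key <- paste(d$sample_id, d$target, d$well, d$cycle)
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("duplicate sample_id x target x well x cycle in %s (line %d)",
                 basename(path), dup[1L] + 1L))
  d
}

#' Read a long-format melt table
#'
#' Canonical dialect: columns `well, sample_id, target, temperature,
#' fluorescence`.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_melt_csv <- function(path) {
  .read_checked(path, c("well", "sample_id", "target", "temperature",
                        "fluorescence"),
                numeric_cols = c("temperature", "fluorescence"))
}

# Parse "05 0.40 N. 26 1.59 W"-style degrees decimal-minutes pairs to
# signed decimal degrees (lat, lon).
.parse_ddm <- function(s) {
  m <- regmatches(s, gregexpr("([0-9]+)\\s+([0-9.]+)\\s*([NSEW])", s))[[1L]]
  if (length(m) != 2L) return(c(NA_real_, NA_real_))
  one <- function(txt) {
    p <- regmatches(txt, regexec("([0-9]+)\\s+([0-9.]+)\\s*([NSEW])", txt))[[1L]]
    val <- as.numeric(p[2L]) + as.numeric(p[3L]) / 60
    if (p[4L] %in% c("S", "W")) val <- -val
    val
  }
  c(one(m[1L]), one(m[2L]))
}

#' Read sample metadata
#'
#' Accepts either survey metadata (columns `sample_id, station,
#' location, date, depth_class` and optionally `depth_m`) or
#' experiment metadata (columns `sample_id, strain, treatment, time,
#' replicate`), plus an optional `material` column (`cDNA`/`gDNA`).
#' Survey `location` strings in degrees decimal-minutes form (e.g.
#' `"05 0.40 N. 26 1.59 W"`) are parsed into signed decimal-degree
#' `latitude`/`longitude` columns.
#'
#' @param path CSV file path.
#' @return Validated data frame with an added `kind` attribute
#'   (`"survey"` or `"experiment"`).
#' @export
read_metadata_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(d)) stop("missing column(s): sample_id")
  survey <- all(c("station", "depth_class") %in% names(d))
  expt <- all(c("strain", "treatment", "time") %in% names(d))
  if (survey == expt)
    stop("metadata must contain either survey columns (station, depth_class) ",
         "or experiment columns (strain, treatment, time), not both or neither")
  if (survey && "location" %in% names(d)) {
    ll <- t(vapply(d$location, .parse_ddm, numeric(2)))
    d$latitude <- ll[, 1L]; d$longitude <- ll[, 2L]
  }
  attr(d, "kind") <- if (survey) "survey" else "experiment"
  d
}

#' Read a Cp summary table
#'
#' Summary-statistics layout: one row per target x depth class with
#' columns `target, depth_class, mean_cp, sd_cp, n`.
#'
#' @param path CSV file path. The packaged example
#'   (`system.file("extdata", "survey_cp_summary.csv", package =
#'   "cladeqpcr")`) holds the six-primer-set, three-depth summary of a
#'   62-station ocean survey.
#' @return Validated data frame.
#' @export
read_cp_summary <- function(path) {
  .read_checked(path, c("target", "depth_class", "mean_cp", "sd_cp"),
                numeric_cols = c("mean_cp", "sd_cp", "n"))
}

#' Write a pipeline table with provenance header
#'
#' Writes a CSV preceded by comment lines recording the package
#' version, a hash of the run configuration and the seed, so every
#' emitted table documents how it was produced. [read_pipeline_csv()]
#' reads these files back, skipping the header.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param config Optional list of run parameters; hashed into the
#'   header.
#' @param seed Optional integer seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_pipeline_csv <- function(x, path, config = NULL, seed = NULL) {
  cfg_hash <- if (is.null(config)) "none" else {
    s <- paste(deparse(config), collapse = "")
    sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% .Machine$integer.max)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# cladeqpcr %s",
                       as.character(utils::packageVersion("cladeqpcr"))),
               sprintf("# config_hash: %s", cfg_hash),
               sprintf("# seed: %s", if (is.null(seed)) "NA" else seed)), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Read back a pipeline table written by [write_pipeline_csv()]
#'
#' @param path CSV file path.
#' @return Data frame (provenance comment lines skipped).
#' @export
read_pipeline_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
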