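## Tabular readers/writers for the toolkit's plain-text dialects.
## Beta/expression/reference matrices: header row = sample (or cell-type)
## IDs, first column = probe/gene IDs. Sample sheets: CSV. Clock
## definitions: one probe ID per line with '#key: value' metadata.

.missingTokens <- c("na", "nan", "")

.err <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "epitocError")))
}

.readDelim <- function(path, sep) {
  if (!file.exists(path)) .err("epitoc_io_error", "file not found: %s", path)
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    row.names = NULL, check.names = FALSE,
                    colClasses = "character", comment.char = "",
                    stringsAsFactors = FALSE)
}

.parseNumericCells <- function(df) {
  ids <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  m[tolower(trimws(m)) %in% .missingTokens] <- NA
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Read a beta-value matrix
#'
#' Reads a TSV/CSV with probe identifiers in the first column and sample
#' identifiers in the header row. The tokens \code{NA}, \code{NaN} and the
#' empty string (case-insensitive) become missing values.
#'
#' @param path path to the file.
#' @param dialect \code{"tsv"} (default) or \code{"csv"}.
#' @param clipOutOfRange if TRUE, values outside \eqn{[0,1]} are clipped to
#'   the nearest bound and the count of clipped cells is reported as the
#'   attribute \code{"clipped"} and via a message; if FALSE (default) such
#'   values are an error naming the offending probe, sample and value.
#' @return a \linkS4class{BetaMatrix}; attribute \code{"clipped"} carries
#'   the number of clipped cells (0 when clipping was off or unneeded).
#' @seealso [writeBetaMatrix()]
#' @export
readBetaMatrix <- function(path, dialect = c("tsv", "csv"),
                           clipOutOfRange = FALSE) {
  dialect <- match.arg(dialect)
  df <- .readDelim(path, if (dialect == "tsv") "\t" else ",")
  m <- .parseNumericCells(df)
  if (anyDuplicated(rownames(m)))
    .err("epitoc_format_error", "duplicate probe IDs in %s (e.g. %s)", path,
         rownames(m)[anyDuplicated(rownames(m))])
  if (anyDuplicated(colnames(m)))
    .err("epitoc_format_error", "duplicate sample IDs in %s (e.g. %s)", path,
         colnames(m)[anyDuplicated(colnames(m))])
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  nClipped <- 0L
  if (nrow(bad) > 0L) {
    if (!clipOutOfRange)
      .err("epitoc_range_error",
           "beta value %g outside [0,1] at probe '%s', sample '%s'",
           m[bad[1L, 1L], bad[1L, 2L]], rownames(m)[bad[1L, 1L]],
           colnames(m)[bad[1L, 2L]])
    m[m < 0 & !is.na(m)] <- 0
    m[m > 1 & !is.na(m)] <- 1
    nClipped <- nrow(bad)
    message(nClipped, " beta value(s) clipped to [0,1]")
  }
  out <- BetaMatrix(m)
  attr(out, "clipped") <- nClipped
  out
}

#' Write a beta-value matrix
#'
#' @param beta a \linkS4class{BetaMatrix}.
#' @param path output path.
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
writeBetaMatrix <- function(beta, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  .writeMatrix(betaValues(beta), path, dialect, idColumn = "probe_id")
}

.writeMatrix <- function(m, path, dialect = "tsv", idColumn = "probe_id") {
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- idColumn
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' CSV with a header; columns \code{sample_id} and \code{age} are
#' mandatory, the optional columns \code{sex}, \code{plate},
#' \code{tissue}, \code{group}, \code{pair_id} and \code{exposure} are
#' carried through when present.
#'
#' @param path path to the CSV.
#' @return data.frame keyed by \code{sample_id} with \code{age} in years.
#' @export
readSampleSheet <- function(path) {
  df <- .readDelim(path, ",")
  need <- c("sample_id", "age")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    .err("epitoc_schema_error", "sample sheet %s lacks column(s): %s", path,
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    .err("epitoc_schema_error", "duplicated sample_id '%s' in %s",
         df$sample_id[anyDuplicated(df$sample_id)], path)
  age <- suppressWarnings(as.numeric(df$age))
  age[tolower(trimws(df$age)) %in% .missingTokens] <- NA
  badRow <- which(!is.na(age) & age < 0)
  if (length(badRow) > 0L)
    .err("epitoc_validation_error",
         "negative age %s at row %d (sample '%s') in %s",
         df$age[badRow[1L]], badRow[1L], df$sample_id[badRow[1L]], path)
  df$age <- age
  if ("exposure" %in% names(df)) {
    ex <- suppressWarnings(as.numeric(df$exposure))
    ex[tolower(trimws(df$exposure)) %in% .missingTokens] <- NA
    if (any(!is.na(ex) & ex < 0))
      .err("epitoc_validation_error", "negative exposure in %s", path)
    df$exposure <- ex
  }
  df
}

#' Read a probe annotation table
#'
#' TSV with columns \code{probe_id}, \code{gene}, \code{tss200} (0/1,
#' probe within 200 bp of a transcription start site) and \code{prc2}
#' (0/1, promoter marked by Polycomb repressive complex 2 in embryonic
#' stem cells). A TSS200 probe must carry a gene symbol.
#'
#' @param path path to the TSV.
#' @return data.frame with logical \code{tss200} and \code{prc2}.
#' @export
readProbeAnnotation <- function(path) {
  df <- .readDelim(path, "\t")
  need <- c("probe_id", "gene", "tss200", "prc2")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    .err("epitoc_schema_error", "annotation %s lacks column(s): %s", path,
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$probe_id))
    .err("epitoc_schema_error", "duplicated probe_id in %s", path)
  df$tss200 <- as.integer(df$tss200) != 0L
  df$prc2 <- as.integer(df$prc2) != 0L
  if (any(df$tss200 & (is.na(df$gene) | trimws(df$gene) == "")))
    .err("epitoc_validation_error",
         "tss200 probes without a gene symbol in %s", path)
  df
}

#' Read a cell-type reference matrix
#'
#' @param path TSV with probe IDs in column 1 and cell-type labels in the
#'   header.
#' @return a \linkS4class{CellTypeReference}.
#' @export
readCellTypeReference <- function(path) {
  df <- .readDelim(path, "\t")
  m <- .parseNumericCells(df)
  if (anyNA(m))
    .err("epitoc_validation_error", "reference %s contains missing values",
         path)
  CellTypeReference(m)
}

#' Read a gene-expression matrix
#'
#' TSV with gene symbols in column 1 and sample IDs in the header.
#' Expression is taken on whatever scale the file supplies; missing values
#' are allowed.
#'
#' @param path path to the TSV.
#' @return numeric matrix, genes in rows.
#' @export
readExpressionMatrix <- function(path) {
  df <- .readDelim(path, "\t")
  m <- .parseNumericCells(df)
  if (anyDuplicated(rownames(m)))
    .err("epitoc_format_error", "duplicate gene IDs in %s", path)
  if (anyDuplicated(colnames(m)))
    .err("epitoc_format_error", "duplicate sample IDs in %s", path)
  m
}

#' Read / write a clock definition
#'
#' Plain text, one probe identifier per line; header lines of the form
#' \code{#key: value} carry \code{name}, \code{direction} (hyper/hypo) and
#' \code{ground_state_bound} metadata. Probe order is not significant;
#' duplicate identifiers are rejected. \code{readClockDefinition} and
#' \code{writeClockDefinition} are mutually inverse up to probe order.
#'
#' @param path path to the clock file.
#' @return a \linkS4class{ClockDefinition}.
#' @export
readClockDefinition <- function(path) {
  if (!file.exists(path)) .err("epitoc_io_error", "file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  meta <- lines[startsWith(lines, "#")]
  ids <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(ids) == 0L)
    .err("epitoc_format_error", "clock file %s contains no probe IDs", path)
  if (anyDuplicated(ids))
    .err("epitoc_format_error", "duplicate probe ID '%s' in %s",
         ids[anyDuplicated(ids)], path)
  kv <- list()
  for (m in meta) {
    m <- sub("^#\\s*", "", m)
    if (grepl(":", m, fixed = TRUE)) {
      key <- trimws(sub(":.*$", "", m))
      kv[[key]] <- trimws(sub("^[^:]*:", "", m))
    }
  }
  direction <- if (!is.null(kv$direction)) kv$direction else "hyper"
  bound <- if (!is.null(kv$ground_state_bound))
    as.numeric(kv$ground_state_bound) else NULL
  name <- if (!is.null(kv$name)) kv$name else
    sub("\\.[^.]*$", "", basename(path))
  ClockDefinition(name = name, direction = direction, probes = ids,
                  groundStateBound = bound)
}

#' @rdname readClockDefinition
#' @param clock a \linkS4class{ClockDefinition}.
#' @return \code{writeClockDefinition}: \code{path}, invisibly.
#' @export
writeClockDefinition <- function(clock, path) {
  stopifnot(is(clock, "ClockDefinition"))
  writeLines(c(paste0("#name: ", clock@name),
               paste0("#direction: ", clock@direction),
               paste0("#ground_state_bound: ", clock@groundStateBound),
               clock@probes), path)
  invisible(path)
}

#' Read / write a calibration as flat JSON
#'
#' @param path path to the JSON document with keys \code{tissue},
#'   \code{alpha_prime}, \code{gamma_prime}, \code{ir}, \code{n_fit},
#'   \code{r_squared}.
#' @return a \linkS4class{Calibration}.
#' @export
readCalibration <- function(path) {
  if (!file.exists(path)) .err("epitoc_io_error", "file not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  Calibration(tissue = x$tissue, alphaPrime = x$alpha_prime,
              gammaPrime = x$gamma_prime,
              ir = if (is.null(x$ir) || is.na(x$ir)) NA_real_ else x$ir,
              nFit = if (is.null(x$n_fit)) NA_real_ else x$n_fit,
              rSquared = if (is.null(x$r_squared)) NA_real_ else x$r_squared)
}

#' @rdname readCalibration
#' @param calib a \linkS4class{Calibration}.
#' @export
writeCalibration <- function(calib, path) {
  jsonlite::write_json(list(tissue = calib@tissue,
                            alpha_prime = calib@alphaPrime,
                            gamma_prime = calib@gammaPrime,
                            ir = calib@ir, n_fit = calib@nFit,
                            r_squared = calib@rSquared),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
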