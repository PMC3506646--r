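## Plate CSV input/output and flat key=value configuration files.

#' Write a plate to CSV
#'
#' Thermocycler-export style: comma-delimited, header
#' \code{Cycle,W001,W002,...}, one row per cycle, 1-based cycle numbers.
#' Per-well metadata (realised draws) goes to a sidecar CSV keyed by well
#' ID.  The round trip through [readPlate()] is lossless to full double
#' precision.
#'
#' @param plate a plate from [simulatePlate()].
#' @param path output CSV path.
#' @param metaPath sidecar metadata path; default replaces ".csv" with
#'   "_meta.csv".
#' @param assay which assay to write (default "fluor", the observed
#'   fluorescence).
#' @return Invisibly, \code{path}.
#' @export
writePlate <- function(plate, path,
                       metaPath = sub("\\.csv$", "_meta.csv", path),
                       assay = "fluor") {
  m <- SummarizedExperiment::assay(plate, assay)
  df <- data.frame(Cycle = seq_len(nrow(m)), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(plate))
  utils::write.csv(cd, metaPath, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plate from CSV
#'
#' Parses the format written by [writePlate()].  Ragged rows and
#' duplicated well IDs raise explicit errors naming the offender.
#'
#' @param path plate CSV path.
#' @param metaPath sidecar metadata path; read when the file exists.
#' @return A \code{SummarizedExperiment} with assay \code{fluor} and any
#'   sidecar metadata as \code{colData}.
#' @export
readPlate <- function(path,
                      metaPath = sub("\\.csv$", "_meta.csv", path)) {
  nf <- utils::count.fields(path, sep = ",")
  if (length(unique(nf)) != 1L)
    stop(sprintf("ragged plate file '%s': row %d has %d fields, expected %d",
                 path, which(nf != nf[1L])[1L],
                 nf[nf != nf[1L]][1L], nf[1L]))
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "Cycle")
    stop("plate file must start with a 'Cycle' column")
  wells <- names(df)[-1L]
  if (anyDuplicated(wells))
    stop(sprintf("duplicate well ID '%s' in '%s'",
                 wells[duplicated(wells)][1L], path))
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- NULL
  cd <- S4Vectors::DataFrame(well = wells, row.names = wells)
  if (file.exists(metaPath)) {
    meta <- utils::read.csv(metaPath)
    if (!"well" %in% names(meta))
      stop("metadata sidecar must have a 'well' column")
    if (anyDuplicated(meta$well))
      stop("duplicate well ID in metadata sidecar")
    cd <- S4Vectors::DataFrame(meta[match(wells, meta$well), , drop = FALSE],
                               row.names = wells)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(fluor = m),
    rowData = S4Vectors::DataFrame(cycle = df$Cycle),
    colData = cd)
}

#' Read a flat key=value configuration file
#'
#' One \code{key = value} pair per line; blank lines and lines starting
#' with \code{#} are ignored.  Keys matching [reactionConditions()] and
#' [variationConfig()] arguments configure the respective object;
#' \code{sources} is a comma-separated list of variation codes.
#'
#' @param path configuration file path.
#' @return A list with elements \code{cond} and \code{var}.
#' @export
readSimConfig <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop(sprintf("malformed config line: '%s'", lines[bad][1L]))
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  named <- as.list(vals)
  names(named) <- keys
  condArgs <- names(formals(reactionConditions))
  varArgs <- names(formals(variationConfig))
  parse1 <- function(key, v) {
    if (key == "sources") {
      s <- trimws(strsplit(v, ",", fixed = TRUE)[[1L]])
      return(s[nzchar(s)])
    }
    if (v %in% c("TRUE", "FALSE", "true", "false"))
      return(toupper(v) == "TRUE")
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) stop(sprintf("cannot parse config value '%s' for '%s'",
                                 v, key))
    num
  }
  unknown <- setdiff(keys, c(condArgs, varArgs))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s",
                 paste(unknown, collapse = ", ")))
  condList <- lapply(setNames(nm = intersect(keys, condArgs)),
                     function(k) parse1(k, named[[k]]))
  varList <- lapply(setNames(nm = intersect(keys, varArgs)),
                    function(k) parse1(k, named[[k]]))
  if (!"n0Mean" %in% names(condList))
    stop("config must set at least 'n0Mean'")
  list(cond = do.call(reactionConditions, condList),
       var = do.call(variationConfig, varList))
}
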