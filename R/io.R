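## Readers/writers: delimited-text timeseries, JSON model and landscape
## serialization, network-label tables.

#' Read a parcel timeseries from delimited text
#'
#' Reads a T-by-N table (TSV by default; a header row of parcel ids is
#' auto-detected). Malformed entries are reported with their row and column.
#'
#' @param path File path.
#' @param tr Sampling interval in seconds.
#' @param runs 1-based run start indices (default: one run).
#' @param sep Field separator (default tab).
#' @return A \linkS4class{ParcelTimeseries}.
#' @export
readTimeseries <- function(path, tr = 0.72, runs = 1L, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
  header <- any(is.na(suppressWarnings(as.numeric(first))))
  raw <- utils::read.table(path, sep = sep, header = header,
                           colClasses = "character",
                           check.names = FALSE)
  m <- matrix(NA_real_, nrow(raw), ncol(raw))
  for (j in seq_len(ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    if (any(is.na(v))) {
      i <- which(is.na(v))[1]
      stop("malformed entry at row ", i + header, ", column ", j,
           ": '", raw[i, j], "'")
    }
    m[, j] <- v
  }
  parcelTimeseries(m, tr = tr, runBoundaries = runs,
                   parcelIds = if (header) colnames(raw) else NULL)
}

#' Write a parcel timeseries as delimited text
#'
#' @param ts A \linkS4class{ParcelTimeseries}.
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @return \code{path}, invisibly.
#' @export
writeTimeseries <- function(ts, path, sep = "\t") {
  utils::write.table(format(ts@data, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = ts@parcelIds)
  invisible(path)
}

#' Read a parcel-to-network label table
#'
#' Two-column TSV (parcel id, network name), no header required.
#'
#' @param path File path.
#' @return Named character vector: parcel id to network.
#' @export
readNetworkLabels <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2) stop("expected two columns: parcel id, network")
  stats::setNames(tab[[2]], tab[[1]])
}

#' Serialize a model to JSON
#'
#' Writes all parameter tensors (matrices as row-major nested lists), the
#' shape constant, TR and a schema version.
#'
#' @param model A \linkS4class{MindyModel}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeModel <- function(model, path) {
  obj <- list(
    schema = "mindyscapes-model-1",
    sparse_weights = model@sparseWeights,
    lowrank_left = model@lowrankLeft,
    lowrank_right = model@lowrankRight,
    curvature = model@curvature,
    decay = model@decay,
    shape_constant = model@shapeConstant,
    tr = model@tr
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a model from JSON
#'
#' @param path File written by \code{\link{writeModel}}.
#' @return A \linkS4class{MindyModel}.
#' @export
readModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "mindyscapes-model-1"))
    stop("unrecognized model schema: ", obj$schema)
  mindyModel(as.matrix(obj$sparse_weights),
             as.matrix(obj$lowrank_left),
             as.matrix(obj$lowrank_right),
             obj$curvature, obj$decay, obj$shape_constant, obj$tr)
}

#' Serialize a landscape summary to JSON
#'
#' Writes the taxonomy, equilibrium states, down-sampled cycles (at most
#' \code{maxCycleSamples} states each), ghost points and speed ratios.
#'
#' @param landscape A \linkS4class{MindyLandscape}.
#' @param path Output file path.
#' @param maxCycleSamples Down-sampling cap per cycle (default 100).
#' @return \code{path}, invisibly.
#' @export
writeLandscape <- function(landscape, path, maxCycleSamples = 100L) {
  cyc <- lapply(landscape@cycles, function(cy) {
    take <- unique(round(seq(1, nrow(cy$samples),
                             length.out = min(maxCycleSamples,
                                              nrow(cy$samples)))))
    list(period = cy$period, speed_ratio = speedRatio(cy),
         samples = cy$samples[take, , drop = FALSE])
  })
  obj <- list(
    schema = "mindyscapes-landscape-1",
    label = landscape@label, n_fp = landscape@nFp, n_lc = landscape@nLc,
    origin_only = landscape@originOnly,
    counts = landscape@counts, flags = landscape@flags,
    equilibria = lapply(landscape@equilibria, function(e)
      list(state = e$state, basin_count = e$basinCount,
           at_origin = e$atOrigin)),
    cycles = cyc,
    ghosts = lapply(landscape@ghosts, function(g)
      list(state = g$state, speed = g$speed))
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
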