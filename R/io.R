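# Serialization: Boltzmann parameters as JSON or whitespace-delimited text,
# spike records as TSV, profiles/activation tables as JSON.

#' Write Boltzmann parameters to JSON
#'
#' Format: `{"K": ..., "b": [...], "W": [[...]]}`.
#'
#' @param params a [BoltzmannParams-class] object.
#' @param path output file.
#' @export
writeParamsJSON <- function(params, path) {
  jsonlite::write_json(
    list(K = nNeurons(params), b = params@b, W = params@W),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Read Boltzmann parameters from JSON
#'
#' @param path JSON file written by [writeParamsJSON()].
#' @return A [BoltzmannParams-class] object.
#' @export
readParamsJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- matrix(as.numeric(x$W), x$K, x$K, byrow = TRUE)
  boltzmannParams(W, as.numeric(x$b))
}

#' Write/read Boltzmann parameters as whitespace-delimited text
#'
#' The first line holds the K biases; the following K lines the weight
#' matrix rows.
#'
#' @param params a [BoltzmannParams-class] object.
#' @param path file path.
#' @export
writeParamsText <- function(params, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(format(params@b, digits = 17), collapse = " "), con)
  utils::write.table(params@W, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeParamsText
#' @export
readParamsText <- function(path) {
  lines <- readLines(path)
  b <- scan(text = lines[1], quiet = TRUE)
  W <- as.matrix(utils::read.table(text = lines[-1]))
  dimnames(W) <- NULL
  boltzmannParams(W, b)
}

#' Write a spike record as TSV
#'
#' Columns `time_ms` (6 decimal places) and `neuron`; header comment lines
#' carry dt, tau and K metadata.
#'
#' @param record a [SpikeRecord-class] object.
#' @param path output file.
#' @export
writeSpikeTSV <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dt_ms=%s", format(record@dt)),
               sprintf("# tau=%s", format(record@tau)),
               sprintf("# K=%d", record@K),
               "time_ms\tneuron"), con)
  if (nrow(record@spikes))
    writeLines(sprintf("%.6f\t%d", record@spikes$time_ms,
                       record@spikes$neuron), con)
  invisible(path)
}

#' Read a spike record from TSV
#'
#' @param path file written by [writeSpikeTSV()].
#' @return A [SpikeRecord-class] (with no state snapshots).
#' @export
readSpikeTSV <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  getMeta <- function(key) {
    m <- sub(paste0("^# ", key, "="), "", grep(paste0("^# ", key, "="),
                                               meta, value = TRUE))
    if (!length(m)) stop("missing metadata line for ", key)
    as.numeric(m[1])
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t")
  if (nrow(df) > 1 && is.unsorted(df$time_ms)) {
    bad <- which(diff(df$time_ms) < 0)[1] + 1L
    stop("spike times out of order at data line ", bad)
  }
  new("SpikeRecord",
      spikes = data.frame(time_ms = as.numeric(df$time_ms),
                          neuron = as.integer(df$neuron)),
      states = matrix(0L, 0, as.integer(getMeta("K"))),
      dt = getMeta("dt_ms"), tau = getMeta("tau"),
      K = as.integer(getMeta("K")))
}

#' Write state snapshots as a binary matrix text file
#'
#' One row per recorded sweep, space-separated 0/1 values.
#'
#' @param record a [SpikeRecord-class] with state snapshots.
#' @param path output file.
#' @export
writeStateMatrix <- function(record, path) {
  utils::write.table(record@states, path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Serialize a solved activation function to JSON
#'
#' Stores the u-grid, f-values, solver tolerance and the readiness profile,
#' so a solved table can be reused across runs.
#'
#' @param af an [ActivationFunction-class] object.
#' @param path output file.
#' @export
writeActivationJSON <- function(af, path) {
  jsonlite::write_json(
    list(u_grid = af@uGrid, f_values = af@fValues, tol = af@tol,
         profile = list(kind = af@profile@kind, values = af@profile@values)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeActivationJSON
#' @export
readActivationJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  prof <- new("RefractoryProfile", values = as.numeric(x$profile$values),
              kind = x$profile$kind)
  new("ActivationFunction", uGrid = as.numeric(x$u_grid),
      fValues = as.numeric(x$f_values), profile = prof, tol = x$tol)
}
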