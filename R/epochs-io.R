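EPOCHS_FORMAT <- "encodeEEG-epochs"
EPOCHS_FORMAT_VERSION <- 1L

#' Write / read the epochs container
#'
#' On-disk format designed for cross-language portability: a JSON header
#' (`<stem>.json`: shapes, sample rate, t0, labels, dtype, rejection mask,
#' format version), a little-endian binary payload (`<stem>.bin`,
#' trial-major: sample index fastest, then sensor, then trial), and the
#' design table as a CSV sidecar (`<stem>.design.csv`). The default dtype
#' `float64` round-trips the tensor bit-exactly; `float32` halves the size
#' at reduced precision.
#'
#' @param epochs an \linkS4class{EpochsArray}.
#' @param stem path stem; the three files are written next to each other.
#' @param dtype `"float64"` or `"float32"`.
#' @return `writeEpochs`: the stem, invisibly. `readEpochs`: the
#'   \linkS4class{EpochsArray}. Malformed containers (version mismatch,
#'   truncated payload, design/trial count mismatch) raise errors naming
#'   the offending field.
#' @export
writeEpochs <- function(epochs, stem, dtype = c("float64", "float32")) {
  dtype <- match.arg(dtype)
  validObject(epochs)
  d <- dim(epochs@data)
  if (nrow(epochs@design) != d[1L])
    stop("design row count (", nrow(epochs@design),
         ") != trial count (", d[1L], "); refusing to write")
  header <- list(
    format = EPOCHS_FORMAT, version = EPOCHS_FORMAT_VERSION,
    dims = d, dim_order = c("trial", "sensor", "sample"),
    dtype = dtype, byte_order = "little",
    sample_rate = epochs@sampleRate, t0 = epochs@t0,
    channel_labels = epochs@channelLabels,
    rejected = epochs@rejected
  )
  jsonlite::write_json(header, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  payload <- as.vector(aperm(epochs@data, c(3L, 2L, 1L)))
  con <- file(paste0(stem, ".bin"), "wb")
  on.exit(close(con))
  writeBin(payload, con, size = if (dtype == "float32") 4L else 8L,
           endian = "little")
  writeDesignCsv(epochs@design, paste0(stem, ".design.csv"))
  invisible(stem)
}

#' @rdname writeEpochs
#' @export
readEpochs <- function(stem) {
  hpath <- paste0(stem, ".json")
  if (!file.exists(hpath)) stop("missing header file: ", hpath)
  h <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  if (!identical(h$format, EPOCHS_FORMAT))
    stop("format error in field 'format': expected '", EPOCHS_FORMAT,
         "', found '", h$format, "'")
  if (!identical(as.integer(h$version), EPOCHS_FORMAT_VERSION))
    stop("format error in field 'version': expected ",
         EPOCHS_FORMAT_VERSION, ", found ", h$version)
  d <- as.integer(h$dims)
  if (length(d) != 3L) stop("format error in field 'dims': need 3 entries")
  bytes <- if (identical(h$dtype, "float32")) 4L else 8L
  bpath <- paste0(stem, ".bin")
  expected <- prod(d) * bytes
  found <- file.size(bpath)
  if (is.na(found)) stop("missing payload file: ", bpath)
  if (found != expected)
    stop("truncated payload: expected ", expected, " bytes, found ", found)
  con <- file(bpath, "rb")
  on.exit(close(con))
  payload <- readBin(con, "double", n = prod(d), size = bytes,
                     endian = "little")
  dat <- aperm(array(payload, dim = d[c(3L, 2L, 1L)]), c(3L, 2L, 1L))
  design <- readDesignCsv(paste0(stem, ".design.csv"))
  if (nrow(design) != d[1L])
    stop("format error in field 'design': ", nrow(design),
         " rows for ", d[1L], " trials")
  new("EpochsArray", data = dat, sampleRate = as.numeric(h$sample_rate),
      t0 = as.numeric(h$t0),
      channelLabels = as.character(h$channel_labels), design = design,
      rejected = as.logical(h$rejected))
}
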