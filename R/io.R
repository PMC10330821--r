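#' @include AllClasses.R
#' @importFrom jsonlite write_json read_json toJSON fromJSON
#' @importFrom tiff writeTIFF readTIFF
#' @importFrom utils write.csv read.csv packageVersion
NULL

#' Write / read a calibrated micrograph as 16-bit TIFF plus JSON sidecar
#'
#' The image is written as a single-channel 16-bit grayscale TIFF; the
#' calibration (nm/px) and metadata go to `<path>.json`. `readMicrograph()`
#' restores the [Micrograph-class] losslessly up to 16-bit quantization.
#'
#' @param img a [Micrograph-class].
#' @param path TIFF file path.
#' @return `writeMicrograph` returns `path` invisibly; `readMicrograph`
#'   returns a [Micrograph-class].
#' @export
writeMicrograph <- function(img, path) {
  stopifnot(is(img, "Micrograph"))
  tiff::writeTIFF(img@intensity, path, bits.per.sample = 16)
  jsonlite::write_json(
    list(nm_per_px = img@nmPerPx, metadata = img@metadata),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMicrograph
#' @export
readMicrograph <- function(path) {
  m <- tiff::readTIFF(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  Micrograph(m, nmPerPx = side$nm_per_px,
             metadata = as.list(side$metadata))
}

#' Write / read ring annotations as JSON polygons
#'
#' Rings are stored as a JSON list of objects {id, points_nm: [[x, y], ...]}
#' with coordinates in nm.
#'
#' @param rings a [GranuleRingSet-class].
#' @param path JSON file path.
#' @return `writeRings` returns `path` invisibly; `readRings` returns a
#'   [GranuleRingSet-class].
#' @export
writeRings <- function(rings, path) {
  stopifnot(is(rings, "GranuleRingSet"))
  obj <- lapply(seq_along(rings@rings), function(j)
    list(id = rings@ids[j], points_nm = unname(rings@rings[[j]])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRings
#' @export
readRings <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  GranuleRingSet(lapply(obj$points_nm, function(p) matrix(unlist(p),
    ncol = 2, byrow = FALSE, dimnames = NULL)),
    ids = obj$id)
}

#' Write / read particle and trace tables as headered CSV
#'
#' CSV dialect: comma separator, '.' decimal, UTF-8, header row.
#'
#' @param table data.frame to write.
#' @param path CSV path.
#' @return `writeTable` returns `path` invisibly; `readTable` returns a
#'   data.frame.
#' @export
writeTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeTable
#' @export
readTable <- function(path) {
  utils::read.csv(path, fileEncoding = "UTF-8")
}

#' Serialize a fitted model to a JSON record
#'
#' Emits the fit parameters together with provenance (class, package
#' version, optional seed) so reports are self-describing.
#'
#' @param fit a [HillFit-class], [ConductanceFit-class],
#'   [InactivationFit-class] or [RadialMixtureFit-class].
#' @param path JSON path.
#' @return `path` invisibly.
#' @export
writeFitJson <- function(fit, path) {
  slots <- methods::slotNames(class(fit))
  rec <- stats::setNames(lapply(slots, function(s) methods::slot(fit, s)),
                         slots)
  rec$.class <- as.character(class(fit))
  rec$.package_version <- as.character(utils::packageVersion("GranulePhys"))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
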