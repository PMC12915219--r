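# File interfaces: SoS maps as single-channel floating-point TIFF or CSV,
# ToF matrices as commented CSV (seconds, full precision), A-scans as a
# waveform table (TSV), phantom specs as JSON, datasets as a directory with
# a JSON manifest.

SPEED_TIFF_SCALE <- 1e-4 # stored value = speed (m/s) * this, keeps [0,1]

#' Write / read a SoS map as single-channel floating-point TIFF
#'
#' Speed-coded maps are stored scaled by 1e-4 (so 1480 m/s is stored as
#' 0.1480, inside the float range the format guarantees); class-coded maps
#' are stored as-is. The caller states the coding on read.
#'
#' @param map a [SoSMap-class].
#' @param path output file.
#' @export
writeSoSMapTiff <- function(map, path) {
  stopifnot(is(map, "SoSMap"))
  v <- map@values
  if (map@coding == "speed") v <- v * SPEED_TIFF_SCALE
  tiff::writeTIFF(v, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname writeSoSMapTiff
#' @param coding coding of the stored map (`"speed"` or `"class"`).
#' @param extent physical extent in mm.
#' @param viewAngle view angle of the stored map.
#' @export
readSoSMapTiff <- function(path, coding = c("speed", "class"), extent = 77.4,
                           viewAngle = 0) {
  coding <- match.arg(coding)
  v <- tiff::readTIFF(path)
  if (coding == "speed") v <- v / SPEED_TIFF_SCALE
  new("SoSMap", values = round(v, 6), grid = sosGrid(nrow(v), extent),
      viewAngle = viewAngle, coding = coding, spec = list())
}

#' Write / read a ToF matrix as CSV
#'
#' Full-precision seconds; header comment lines record the geometry and the
#' view angle.
#'
#' @param tof a [ToFMatrix-class].
#' @param path output file.
#' @export
writeToFCsv <- function(tof, path) {
  stopifnot(is(tof, "ToFMatrix"))
  g <- tof@geometry
  hdr <- c(sprintf("# units: seconds; rows: generation; cols: detection"),
           sprintf("# geometry: nGen=%d nDet=%d pitch_mm=%g plateSeparation_mm=%g",
                   g@nGen, g@nDet, g@pitch, g@plateSeparation),
           sprintf("# viewAngle_deg: %g", tof@viewAngle))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(tof@values, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeToFCsv
#' @export
readToFCsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  geomLine <- hdr[grepl("geometry:", hdr)]
  gv <- as.numeric(regmatches(geomLine,
                              gregexpr("[0-9.]+", geomLine))[[1]])
  view <- as.numeric(sub(".*viewAngle_deg: *", "",
                         hdr[grepl("viewAngle_deg", hdr)]))
  v <- as.matrix(utils::read.table(text = lines[!startsWith(lines, "#")],
                                   sep = ","))
  dimnames(v) <- NULL
  new("ToFMatrix", values = v, viewAngle = view,
      geometry = arrayGeometry(gv[1], gv[2], gv[3], gv[4]))
}

#' Write / read A-scans as a waveform table
#'
#' Tab-separated table, one column per element pair (named `gXXdYY`), all
#' sharing one per-pair time base is not assumed: each column's `t0` is
#' recorded in the header together with the common sampling interval.
#'
#' @param scans list of [AScan-class].
#' @param path output file.
#' @export
writeAScans <- function(scans, path) {
  stopifnot(length(scans) >= 1L)
  dt <- scans[[1]]@dt
  if (any(abs(vapply(scans, slot, 0, "dt") - dt) > 0))
    stop("all scans must share one sampling interval")
  len <- max(vapply(scans, function(s) length(s@samples), 0L))
  cols <- lapply(scans, function(s) c(s@samples, rep(NA, len - length(s@samples))))
  names(cols) <- vapply(scans, function(s)
    sprintf("g%02dd%02d", s@genIndex, s@detIndex), "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dt_s: %.17g", dt),
               paste0("# t0_s: ", paste(sprintf("%.17g",
                 vapply(scans, slot, 0, "t0")), collapse = "\t"))), con)
  utils::write.table(as.data.frame(cols), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeAScans
#' @export
readAScans <- function(path) {
  lines <- readLines(path, n = 2L)
  dt <- as.numeric(sub("# dt_s: *", "", lines[1]))
  t0s <- as.numeric(strsplit(sub("# t0_s: *", "", lines[2]), "\t")[[1]])
  d <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  lapply(seq_along(d), function(k) {
    nm <- names(d)[k]
    idx <- as.integer(regmatches(nm, gregexpr("[0-9]+", nm))[[1]])
    v <- d[[k]][!is.na(d[[k]])]
    new("AScan", samples = v, dt = dt, t0 = t0s[k],
        genIndex = idx[1], detIndex = idx[2])
  })
}

specToList <- function(spec) {
  list(centre_mm = spec@centre, diameter_mm = spec@diameter,
       material = spec@material,
       inclusions = lapply(spec@inclusions, function(i)
         list(centre_mm = i$centre, diameter_mm = i$diameter,
              material = i$material)))
}

listToSpec <- function(l) {
  new("PhantomSpec", centre = as.numeric(l$centre_mm),
      diameter = as.numeric(l$diameter_mm),
      inclusions = lapply(l$inclusions, function(i)
        list(centre = as.numeric(i$centre_mm),
             diameter = as.numeric(i$diameter_mm),
             material = i$material)),
      material = l$material)
}

#' Write / read a phantom specification as JSON
#'
#' Flat key-value record with units in the key names (mm).
#'
#' @param spec a [PhantomSpec-class].
#' @param path output file.
#' @export
writeSpecJson <- function(spec, path) {
  jsonlite::write_json(specToList(spec), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeSpecJson
#' @export
readSpecJson <- function(path) {
  listToSpec(jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE))
}

#' Save / load a training dataset directory
#'
#' The dataset (inputs, targets, specs, normalisation constant) is stored as
#' an R data file next to a human-readable JSON manifest recording sizes,
#' grid, geometry, seed and the stacking convention.
#'
#' @param dataset result of [makeTrainingDataset()].
#' @param dir output directory (created if needed).
#' @param grid,geom,seed metadata recorded in the manifest.
#' @export
saveDataset <- function(dataset, dir, grid = sosGrid(),
                        geom = arrayGeometry(), seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    n = length(dataset$inputs),
    grid = list(nPixels = grid@nPixels, extent_mm = grid@extent),
    geometry = list(nGen = geom@nGen, nDet = geom@nDet, pitch_mm = geom@pitch,
                    plateSeparation_mm = geom@plateSeparation),
    normalisationConstant_s = dataset$constant,
    stacking = "block-diagonal 2x16x16, zero-padded, anchored top-left",
    seed = seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(dataset, file.path(dir, "dataset.rds"))
  invisible(dir)
}

#' @rdname saveDataset
#' @export
loadDataset <- function(dir) {
  readRDS(file.path(dir, "dataset.rds"))
}
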