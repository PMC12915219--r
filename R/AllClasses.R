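#' @import methods
#' @importFrom stats runif rnorm sd quantile setNames
#' @importFrom utils read.table write.table head tail
#' @useDynLib lutomo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------- GridSpec --

#' Square reconstruction grid
#'
#' Cell-centred square pixel grid covering the immersion tank. Pixel `(i, j)`
#' (0-based) has its centre at `((i + 0.5) * pitch - extent/2)` mm in
#' tank-centred coordinates; x is the lateral (scanning) axis, y the axial
#' (propagation) axis.
#'
#' @slot nPixels integer, pixels per side (default 128).
#' @slot extent numeric, physical side length in mm (default 77.4, the
#'   generation-detection plate separation).
#' @export
setClass("GridSpec",
  slots = c(nPixels = "integer", extent = "numeric"),
  prototype = prototype(nPixels = 128L, extent = 77.4))

setValidity("GridSpec", function(object) {
  if (length(object@nPixels) != 1L || object@nPixels < 32L)
    return("nPixels must be a single integer >= 32")
  if (length(object@extent) != 1L || object@extent <= 0)
    return("extent must be a single positive length in mm")
  TRUE
})

#' Construct a reconstruction grid
#'
#' @param nPixels pixels per side (>= 32).
#' @param extent physical side length in mm.
#' @return A [GridSpec-class] object.
#' @examples
#' g <- sosGrid()
#' pixelPitch(g)  # 77.4 / 128 = 0.6047 mm
#' @export
sosGrid <- function(nPixels = 128L, extent = 77.4) {
  new("GridSpec", nPixels = as.integer(nPixels), extent = as.numeric(extent))
}

#' Pixel pitch of a grid in mm
#' @param grid a [GridSpec-class].
#' @return numeric pitch in mm.
#' @export
pixelPitch <- function(grid) grid@extent / grid@nPixels

#' @describeIn sosGrid Number of pixels per side.
#' @param grid a [GridSpec-class].
#' @export
nPixels <- function(grid) grid@nPixels

#' @describeIn sosGrid Physical extent (mm) of the grid.
#' @export
gridExtent <- function(grid) grid@extent

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d pixels, %.1f mm extent (pitch %.4f mm)\n",
              object@nPixels, object@nPixels, object@extent,
              pixelPitch(object)))
})

# ------------------------------------------------------------ PhantomSpec --

#' Phantom specification
#'
#' Geometric and material description of one circular gel phantom with one or
#' two fluid inclusions, in tank-centred mm coordinates.
#'
#' @slot centre numeric length-2, phantom centre (x, y) offset from the tank
#'   centre in mm.
#' @slot diameter numeric, phantom diameter in mm.
#' @slot inclusions list of inclusions; each is a list with elements `centre`
#'   (numeric length-2, mm), `diameter` (mm) and `material`
#'   (`"water"` or `"glycerol10"`).
#' @slot material phantom body material, always `"gel"`.
#' @export
setClass("PhantomSpec",
  slots = c(centre = "numeric", diameter = "numeric",
            inclusions = "list", material = "character"),
  prototype = prototype(material = "gel"))

setValidity("PhantomSpec", function(object) {
  if (length(object@centre) != 2L) return("centre must be length-2 (x, y) mm")
  if (object@diameter <= 0) return("diameter must be positive")
  if (length(object@inclusions) < 1L || length(object@inclusions) > 2L)
    return("phantom must carry 1 or 2 inclusions")
  for (inc in object@inclusions) {
    if (!all(c("centre", "diameter", "material") %in% names(inc)))
      return("each inclusion needs centre, diameter and material")
    if (!inc$material %in% c("water", "glycerol10"))
      return("inclusion material must be 'water' or 'glycerol10'")
    d <- sqrt(sum((inc$centre - object@centre)^2))
    if (d + inc$diameter / 2 > object@diameter / 2 + 1e-9)
      return("inclusion disk must lie fully inside the phantom disk")
  }
  TRUE
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: gel disk %.1f mm at (%+.1f, %+.1f) mm, %d inclusion(s)\n",
              object@diameter, object@centre[1], object@centre[2],
              length(object@inclusions)))
  for (k in seq_along(object@inclusions)) {
    inc <- object@inclusions[[k]]
    cat(sprintf("  inclusion %d: %s, %.1f mm at (%+.1f, %+.1f) mm\n",
                k, inc$material, inc$diameter, inc$centre[1], inc$centre[2]))
  }
})

# ----------------------------------------------------------------- SoSMap --

#' Speed-of-sound map
#'
#' A square grid of local speeds of sound. `coding = "speed"` stores speeds in
#' m/s (soft-tissue envelope 1400--1700 m/s); `coding = "class"` stores the
#' normalised class codes 0 (gel), 0.5 (water), 1 (10 wt% glycerol);
#' `coding = "difference"` stores an unconstrained elementwise difference of
#' two maps. Matrix rows index the axial (y) coordinate, columns the lateral
#' (x) coordinate, both increasing with the physical coordinate.
#'
#' @slot values numeric matrix, n x n.
#' @slot grid the [GridSpec-class] the map lives on.
#' @slot viewAngle numeric, acquisition view in degrees (0 or 90).
#' @slot coding one of `"speed"`, `"class"`, `"difference"`.
#' @slot spec list; the generating [PhantomSpec-class] if any (as a list of
#'   length 1), else empty.
#' @export
setClass("SoSMap",
  slots = c(values = "matrix", grid = "GridSpec", viewAngle = "numeric",
            coding = "character", spec = "list"),
  prototype = prototype(viewAngle = 0, coding = "speed", spec = list()))

setValidity("SoSMap", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("map must be square")
  if (nrow(v) != object@grid@nPixels) return("map size must match its grid")
  if (!all(is.finite(v))) return("map values must be finite")
  if (!object@coding %in% c("speed", "class", "difference"))
    return("coding must be 'speed', 'class' or 'difference'")
  if (object@coding == "speed" && (min(v) < 1400 || max(v) > 1700))
    return("speed map outside the accepted soft-tissue envelope [1400, 1700] m/s")
  if (object@coding == "class" && !all(v %in% c(0, 0.5, 1)))
    return("class-coded map may only contain 0, 0.5 and 1")
  if (!object@viewAngle %in% c(0, 90))
    return("viewAngle must be 0 or 90 degrees")
  TRUE
})

#' Map values as a plain matrix
#' @param x a [SoSMap-class] (or [ToFMatrix-class], [TravelTimeField-class]).
#' @return numeric matrix.
#' @export
mapValues <- function(x) x@values

#' Acquisition view angle in degrees
#' @param x a [SoSMap-class] or [ToFMatrix-class].
#' @export
viewAngle <- function(x) x@viewAngle

#' Grid of a map or travel-time field
#' @param x a [SoSMap-class] or [TravelTimeField-class].
#' @export
mapGrid <- function(x) x@grid

setMethod("show", "SoSMap", function(object) {
  v <- object@values
  cat(sprintf("SoSMap (%s, view %g deg): %d x %d, range [%g, %g]\n",
              object@coding, object@viewAngle, nrow(v), ncol(v),
              min(v), max(v)))
})

setMethod("dim", "SoSMap", function(x) dim(x@values))

# -------------------------------------------------------- TravelTimeField --

#' First-arrival travel-time field
#'
#' Per-source grid of first-arrival times (seconds) from the eikonal solver,
#' on the same cell-centred layout as [SoSMap-class] (possibly refined).
#'
#' @slot times numeric matrix of seconds.
#' @slot grid [GridSpec-class] of the stored field (after any refinement).
#' @slot source numeric length-2, source position (x, y) in mm.
#' @slot refinementFactor integer, 1 for a raw coarse solve.
#' @export
setClass("TravelTimeField",
  slots = c(times = "matrix", grid = "GridSpec", source = "numeric",
            refinementFactor = "integer"),
  prototype = prototype(refinementFactor = 1L))

setValidity("TravelTimeField", function(object) {
  if (nrow(object@times) != ncol(object@times)) return("field must be square")
  if (any(object@times < 0)) return("travel times must be non-negative")
  if (!all(is.finite(object@times))) return("travel times must be finite")
  if (length(object@source) != 2L) return("source must be (x, y) mm")
  TRUE
})

setMethod("show", "TravelTimeField", function(object) {
  cat(sprintf(
    "TravelTimeField: %d x %d, source (%+.2f, %+.2f) mm, t in [%.3f, %.3f] us\n",
    nrow(object@times), ncol(object@times), object@source[1], object@source[2],
    min(object@times) * 1e6, max(object@times) * 1e6))
})

setMethod("dim", "TravelTimeField", function(x) dim(x@times))

#' @describeIn solveEikonal Travel times (seconds) as a matrix.
#' @export
fieldTimes <- function(field) field@times

# ---------------------------------------------------------- ArrayGeometry --

#' Through-transmission array geometry
#'
#' Generation elements sit on the line y = -plateSeparation/2, detection
#' elements on y = +plateSeparation/2, both centred on x = 0 with the given
#' pitch. Aperture = (nGen - 1) * pitch.
#'
#' @slot nGen,nDet integer element counts (default 16 each).
#' @slot pitch numeric, element spacing in mm (default 2).
#' @slot plateSeparation numeric, plate distance in mm (default 77.4).
#' @export
setClass("ArrayGeometry",
  slots = c(nGen = "integer", nDet = "integer", pitch = "numeric",
            plateSeparation = "numeric"),
  prototype = prototype(nGen = 16L, nDet = 16L, pitch = 2,
                        plateSeparation = 77.4))

setValidity("ArrayGeometry", function(object) {
  if (object@nGen < 2L || object@nDet < 2L)
    return("need at least 2 elements per plate")
  if (object@pitch <= 0 || object@plateSeparation <= 0)
    return("pitch and plateSeparation must be positive")
  TRUE
})

#' Construct an array geometry
#'
#' @param nGen,nDet number of generation / detection elements.
#' @param pitch element spacing in mm.
#' @param plateSeparation distance between the two plates in mm.
#' @return An [ArrayGeometry-class].
#' @examples
#' g <- arrayGeometry()
#' apertureWidth(g)  # 30 mm
#' @export
arrayGeometry <- function(nGen = 16L, nDet = 16L, pitch = 2,
                          plateSeparation = 77.4) {
  new("ArrayGeometry", nGen = as.integer(nGen), nDet = as.integer(nDet),
      pitch = as.numeric(pitch), plateSeparation = as.numeric(plateSeparation))
}

elementLine <- function(n, pitch, y) {
  x <- (seq_len(n) - 1 - (n - 1) / 2) * pitch
  cbind(x = x, y = rep(y, n))
}

#' Generation element positions, n x 2 matrix of (x, y) mm
#' @param geom an [ArrayGeometry-class].
#' @export
genPositions <- function(geom)
  elementLine(geom@nGen, geom@pitch, -geom@plateSeparation / 2)

#' Detection element positions, n x 2 matrix of (x, y) mm
#' @param geom an [ArrayGeometry-class].
#' @export
detPositions <- function(geom)
  elementLine(geom@nDet, geom@pitch, +geom@plateSeparation / 2)

#' Array aperture in mm
#' @param geom an [ArrayGeometry-class].
#' @export
apertureWidth <- function(geom) (geom@nGen - 1L) * geom@pitch

setMethod("show", "ArrayGeometry", function(object) {
  cat(sprintf(
    "ArrayGeometry: %d gen + %d det elements, pitch %g mm, aperture %g mm, plates %g mm apart\n",
    object@nGen, object@nDet, object@pitch, apertureWidth(object),
    object@plateSeparation))
})

# -------------------------------------------------------------- ToFMatrix --

#' Time-of-flight matrix
#'
#' First-arrival times (seconds) between every generation element (rows) and
#' detection element (columns) for one acquisition view.
#'
#' @slot values numeric nGen x nDet matrix of seconds.
#' @slot viewAngle numeric degrees (0 or 90).
#' @slot geometry the [ArrayGeometry-class] used.
#' @export
setClass("ToFMatrix",
  slots = c(values = "matrix", viewAngle = "numeric",
            geometry = "ArrayGeometry"),
  prototype = prototype(viewAngle = 0))

setValidity("ToFMatrix", function(object) {
  g <- object@geometry
  if (nrow(object@values) != g@nGen || ncol(object@values) != g@nDet)
    return("ToF matrix shape must match its geometry")
  if (!all(is.finite(object@values))) return("ToF entries must be finite")
  TRUE
})

setMethod("show", "ToFMatrix", function(object) {
  cat(sprintf("ToFMatrix (view %g deg): %d x %d, %.3f - %.3f us\n",
              object@viewAngle, nrow(object@values), ncol(object@values),
              min(object@values) * 1e6, max(object@values) * 1e6))
})

setMethod("dim", "ToFMatrix", function(x) dim(x@values))

# ------------------------------------------------------------------ AScan --

#' Sampled A-scan waveform
#'
#' One time-domain waveform for one generation/detection element pair.
#'
#' @slot samples numeric amplitude sequence (arbitrary units).
#' @slot dt numeric, sampling interval in seconds.
#' @slot t0 numeric, time of the first sample relative to the trigger (s).
#' @slot genIndex,detIndex integer element indices (1-based).
#' @export
setClass("AScan",
  slots = c(samples = "numeric", dt = "numeric", t0 = "numeric",
            genIndex = "integer", detIndex = "integer"),
  prototype = prototype(t0 = 0, genIndex = 1L, detIndex = 1L))

setValidity("AScan", function(object) {
  if (object@dt <= 0) return("dt must be positive")
  if (length(object@samples) < 8L) return("A-scan too short")
  TRUE
})

#' Time axis of an A-scan (seconds)
#' @param scan an [AScan-class].
#' @export
scanTimes <- function(scan)
  scan@t0 + (seq_along(scan@samples) - 1) * scan@dt

#' Samples of an A-scan
#' @param scan an [AScan-class].
#' @export
scanSamples <- function(scan) scan@samples

setMethod("show", "AScan", function(object) {
  cat(sprintf(
    "AScan g%02d-d%02d: %d samples, dt %.1f ns, t0 %.3f us, peak |a| %.3g\n",
    object@genIndex, object@detIndex, length(object@samples),
    object@dt * 1e9, object@t0 * 1e6, max(abs(object@samples))))
})

# ------------------------------------------------------------- PickResult --

#' Result of a time-of-flight pick
#'
#' @slot tof numeric, picked onset time in seconds.
#' @slot coarseIndex integer, sample index (1-based, on the A-scan's own time
#'   base) of the coarse kurtosis onset.
#' @slot kurtosis numeric, the sliding-kurtosis trace (one value per window
#'   placement; `kurtosisStart` gives the signal sample index of the first
#'   window's leading edge).
#' @slot kurtosisStart integer.
#' @slot bestLag integer, refined cross-correlation lag in samples; positive
#'   means later arrival than the water reference.
#' @slot flags character vector of fired fallbacks (may be empty):
#'   `"threshold_crossing"`, `"lag_tie"`, `"clipped"`, `"no_refine"`.
#' @export
setClass("PickResult",
  slots = c(tof = "numeric", coarseIndex = "integer", kurtosis = "numeric",
            kurtosisStart = "integer", bestLag = "integer",
            flags = "character"),
  prototype = prototype(flags = character(0)))

#' Picked time of flight in seconds
#' @param x a [PickResult-class].
#' @export
pickedToF <- function(x) x@tof

#' Fallback flags fired during a pick
#' @param x a [PickResult-class].
#' @export
pickFlags <- function(x) x@flags

setMethod("show", "PickResult", function(object) {
  cat(sprintf("PickResult: ToF %.4f us (coarse index %d, lag %+d)%s\n",
              object@tof * 1e6, object@coarseIndex, object@bestLag,
              if (length(object@flags))
                paste0(" [", paste(object@flags, collapse = ", "), "]")
              else ""))
})
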