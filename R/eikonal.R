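# Isotropic fast-marching travel-time solver, field refinement, bent-ray
# tracing and ToF matrix assembly. Heavy lifting is in src/fmm.cpp; these
# wrappers convert between user-facing mm / m/s / seconds and SI internals.

MM <- 1e-3 # mm -> m

#' Solve the eikonal equation |grad T| = 1/c on a speed map
#'
#' First-order upwind fast marching on the map's cell-centred grid, with
#' exact analytic initialisation (T = distance / local speed) on a disk of
#' `initRadius` pixels around the source. The priority front breaks ties by
#' (time, row-major index), so the accepted order is deterministic.
#'
#' @param map a speed-coded [SoSMap-class] (all speeds > 0).
#' @param source numeric length-2, source (x, y) in tank-centred mm. Must lie
#'   inside the grid (boundary included).
#' @param initRadius analytic initialisation radius in coarse pixels.
#' @return A [TravelTimeField-class] with times in seconds.
#' @examples
#' m <- asSoSMap(matrix(1480, 64, 64))
#' f <- solveEikonal(m, c(0, -38.7))
#' @export
solveEikonal <- function(map, source, initRadius = 3L) {
  stopifnot(is(map, "SoSMap"), map@coding == "speed", length(source) == 2L)
  if (any(map@values <= 0)) stop("all speeds must be strictly positive")
  half <- map@grid@extent / 2
  if (any(abs(source) > half + 1e-9))
    stop("source lies outside the grid bounds")
  times <- .fmm_solve(map@values, pixelPitch(map@grid) * MM,
                      map@grid@extent * MM,
                      source[1] * MM, source[2] * MM, as.integer(initRadius))
  new("TravelTimeField", times = times, grid = map@grid,
      source = as.numeric(source), refinementFactor = 1L)
}

#' Bilinearly refine a travel-time field onto a denser grid
#'
#' Interpolates onto a `factor`-times denser cell-centred grid. For odd
#' factors the coarse node centres coincide with fine node centres and their
#' values are preserved exactly; edge cells extrapolate linearly, so linear
#' fields are reproduced exactly everywhere.
#'
#' @param field a [TravelTimeField-class].
#' @param factor integer >= 1 (5 turns a 128-grid into a 640-grid).
#' @return A refined [TravelTimeField-class].
#' @export
refineField <- function(field, factor = 5L) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("refinement factor must be >= 1")
  fine <- .bilinear_refine(field@times, field@grid@extent * MM, factor)
  fine[fine < 0] <- 0 # edge extrapolation may graze below zero near a source
  new("TravelTimeField", times = fine,
      grid = sosGrid(nPixels = nrow(fine), extent = field@grid@extent),
      source = field@source,
      refinementFactor = field@refinementFactor * factor)
}

#' Trace the first-arrival ray between a detection and a generation point
#'
#' Steepest-descent polyline on the (refined) travel-time field from the
#' detection point back to the source, stepping a quarter fine-pixel with
#' central-difference gradients, terminating within one fine-pixel of the
#' source and closing with an exact straight segment to it. The ray's travel
#' time is the trapezoidal slowness line-integral along the polyline with
#' bilinear speed lookup.
#'
#' @param field a (typically refined) [TravelTimeField-class] solved from a
#'   source at `genXY`.
#' @param detXY,genXY numeric length-2 positions in mm.
#' @param map the speed-coded [SoSMap-class] the field was solved on.
#' @return list with `path` (k x 2 matrix, mm), `time` (seconds) and `ok`
#'   (FALSE if descent failed; an error is raised in that case, carrying the
#'   last position reached).
#' @export
traceRay <- function(field, detXY, genXY, map) {
  stopifnot(is(field, "TravelTimeField"), is(map, "SoSMap"))
  if (any(abs(detXY) > map@grid@extent / 2 + 1e-9))
    stop("detection point lies outside the grid")
  r <- .trace_ray(field@times, field@grid@extent * MM, map@values,
                  detXY[1] * MM, detXY[2] * MM, genXY[1] * MM, genXY[2] * MM)
  if (!r$ok)
    stop(sprintf(
      "ray descent failed to reach the source; last position (%.3f, %.3f) mm",
      r$last_x / MM, r$last_y / MM))
  list(path = r$path / MM, time = r$time, ok = TRUE)
}

#' Compute the generation-by-detection ToF matrix for a speed map
#'
#' One fast-marching solve per generation element, bilinear refinement by
#' `factor`, then one traced ray per detection element; entry (i, j) is the
#' ray slowness integral from generation i to detection j. If a descent
#' fails the interpolated field value at the detector is used instead and a
#' warning is emitted.
#'
#' @param map a speed-coded [SoSMap-class].
#' @param geom an [ArrayGeometry-class] sharing the map's coordinate frame.
#' @param factor fine-grid refinement factor (default 5).
#' @param initRadius analytic initialisation radius in coarse pixels.
#' @return A [ToFMatrix-class] (seconds) with the map's view angle.
#' @export
computeToFMatrix <- function(map, geom = arrayGeometry(), factor = 5L,
                             initRadius = 3L) {
  stopifnot(is(map, "SoSMap"), map@coding == "speed", is(geom, "ArrayGeometry"))
  if (any(map@values <= 0)) stop("all speeds must be strictly positive")
  res <- .tof_matrix(map@values, map@grid@extent * MM,
                     genPositions(geom) * MM, detPositions(geom) * MM,
                     as.integer(factor), as.integer(initRadius))
  if (any(res$fallback > 0L))
    warning(sum(res$fallback), " ray trace(s) failed; ",
            "interpolated field values used for those entries")
  new("ToFMatrix", values = res$tof, viewAngle = map@viewAngle,
      geometry = geom)
}

#' Homogeneous-medium reference ToF matrix
#'
#' Straight-ray times distance / speed for every element pair; used as the
#' water-only reference.
#'
#' @param geom an [ArrayGeometry-class].
#' @param speed homogeneous speed in m/s (1480 for water).
#' @param viewAngle view label for the result.
#' @return A [ToFMatrix-class].
#' @export
referenceToFMatrix <- function(geom = arrayGeometry(), speed = 1480,
                               viewAngle = 0) {
  gp <- genPositions(geom); dp <- detPositions(geom)
  v <- outer(seq_len(nrow(gp)), seq_len(nrow(dp)), function(i, j) {
    sqrt((gp[i, 1] - dp[j, 1])^2 + (gp[i, 2] - dp[j, 2])^2) * MM / speed
  })
  new("ToFMatrix", values = v, viewAngle = viewAngle, geometry = geom)
}

#' Build one network training pair from a phantom specification
#'
#' Renders the phantom at 0 and 90 degrees, computes both ToF matrices,
#' stacks them into the normalised block-diagonal input, and pairs the
#' result with the class-coded 0-degree map as the target.
#'
#' @param spec a [PhantomSpec-class], or `NULL` for the degenerate water-only
#'   case (both views equal the homogeneous reference).
#' @param grid a [GridSpec-class].
#' @param geom an [ArrayGeometry-class].
#' @param constant normalisation constant in seconds or `"auto"`
#'   (see [normaliseToFs()]).
#' @param factor eikonal refinement factor.
#' @param frame side length of the zero-padded input frame (defaults to the
#'   grid size).
#' @return list with `input` (a `StackedInput`, see [stackViews()]), `target`
#'   (class-coded [SoSMap-class] at 0 degrees), `t1`, `t2`
#'   ([ToFMatrix-class]).
#' @export
buildTrainingPair <- function(spec, grid = sosGrid(), geom = arrayGeometry(),
                              constant = "auto", factor = 5L, frame = NULL) {
  if (is.null(frame)) frame <- grid@nPixels
  materials <- materialTable()
  if (is.null(spec)) {
    t1 <- referenceToFMatrix(geom, materials$speeds[["water"]], 0)
    t2 <- referenceToFMatrix(geom, materials$speeds[["water"]], 90)
    target <- new("SoSMap",
                  values = matrix(materials$classCodes[["water"]],
                                  grid@nPixels, grid@nPixels),
                  grid = grid, viewAngle = 0, coding = "class", spec = list())
  } else {
    m0 <- renderSoSMap(spec, grid, 0, materials)
    m90 <- renderSoSMap(spec, grid, 90, materials)
    t1 <- computeToFMatrix(m0, geom, factor)
    t2 <- computeToFMatrix(m90, geom, factor)
    target <- classEncode(m0, materials)
  }
  norm <- normaliseToFs(list(t1, t2), constant)
  input <- stackViews(norm$matrices[[1]], norm$matrices[[2]],
                      norm$constant, frame = frame)
  list(input = input, target = target, t1 = t1, t2 = t2)
}
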