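# Random tissue-phantom generation and rasterisation.
#
# Phantoms are circular gel disks (1455 m/s) immersed in water (1480 m/s)
# carrying one or two circular fluid inclusions (water 1480 m/s or 10 wt%
# glycerol 1538 m/s). Geometric parameters are drawn uniformly from discrete
# 0.6 mm lattices; the two phantom categories (1 vs 2 inclusions) are drawn
# with equal probability.

#' Material speed and class-code table
#'
#' @param backgroundSpeed,gelSpeed,glycerol10Speed speeds in m/s. Background
#'   and the water inclusions share `backgroundSpeed`.
#' @return list with `speeds` (named vector, m/s) and `classCodes` (named
#'   vector in \[0, 1\]: gel 0, water 0.5, 10 wt% glycerol 1).
#' @examples
#' materialTable()$speeds
#' @export
materialTable <- function(backgroundSpeed = 1480, gelSpeed = 1455,
                          glycerol10Speed = 1538) {
  speeds <- c(gel = gelSpeed, water = backgroundSpeed,
              glycerol10 = glycerol10Speed)
  codes <- c(gel = 0, water = 0.5, glycerol10 = 1)
  if (anyDuplicated(speeds)) stop("material speeds must be distinct")
  list(speeds = speeds, classCodes = codes)
}

#' Phantom sampling parameter ranges
#'
#' The discrete parameter lattice used for training-data synthesis: offsets
#' and diameters live on a 0.6 mm increment lattice; the two-inclusion
#' category forces a larger minimum phantom diameter so that both inclusions
#' fit.
#'
#' @param offsetValues lattice of per-axis centre offsets (mm).
#' @param phantomDia1,phantomDia2 (min, max) phantom diameter (mm) for the
#'   1- and 2-inclusion categories.
#' @param inclusionDia (min, max) inclusion diameter (mm).
#' @param increment lattice step (mm).
#' @param gelMargin minimum gel thickness (mm) kept between an inclusion and
#'   the phantom boundary and between the two inclusions (one coarse pixel).
#' @return a named list of ranges, consumed by [samplePhantomSpec()].
#' @export
phantomParams <- function(offsetValues = c(-1.2, -0.6, 0, 0.6, 1.2),
                          phantomDia1 = c(9.7, 29.6),
                          phantomDia2 = c(23.6, 29.6),
                          inclusionDia = c(4.8, 11.5),
                          increment = 0.6,
                          gelMargin = 77.4 / 128) {
  p <- list(offsetValues = offsetValues, phantomDia1 = phantomDia1,
            phantomDia2 = phantomDia2, inclusionDia = inclusionDia,
            increment = increment, gelMargin = gelMargin)
  for (r in list(phantomDia1, phantomDia2, inclusionDia))
    if (r[1] > r[2]) stop("parameter range has min > max")
  p
}

# values of a (min, max) range on the increment lattice anchored at min
latticeValues <- function(range, increment) {
  k <- floor((range[2] - range[1]) / increment + 1e-9)
  range[1] + increment * (0:k)
}

#' Sample one random phantom specification
#'
#' Draws the category (one vs two inclusions, probability 0.5 each), the
#' per-axis centre offset, the phantom diameter, and for each inclusion its
#' diameter, material (water or 10 wt% glycerol, equiprobable) and position.
#' Inclusion centres are drawn uniformly over the admissible disk; placement
#' is rejection-sampled until every inclusion lies fully inside the phantom
#' with at least `gelMargin` of gel to the boundary and (for two inclusions)
#' between the inclusions.
#'
#' @param params ranges from [phantomParams()].
#' @param nInclusions force the category (1 or 2); `NULL` (default) draws it.
#' @param maxAttempts rejection-sampling cap before an error is raised.
#' @return A [PhantomSpec-class].
#' @examples
#' set.seed(1)
#' samplePhantomSpec()
#' @export
samplePhantomSpec <- function(params = phantomParams(), nInclusions = NULL,
                              maxAttempts = 10000L) {
  nInc <- if (is.null(nInclusions)) sample(1:2, 1L) else as.integer(nInclusions)
  stopifnot(nInc %in% 1:2)
  diaRange <- if (nInc == 1L) params$phantomDia1 else params$phantomDia2
  incLattice <- latticeValues(params$inclusionDia, params$increment)
  if (min(incLattice) + 2 * params$gelMargin > diaRange[2])
    stop("infeasible ranges: smallest inclusion cannot fit the largest phantom")

  centre <- c(sample(params$offsetValues, 1L), sample(params$offsetValues, 1L))
  diameter <- sample(latticeValues(diaRange, params$increment), 1L)
  rPh <- diameter / 2

  drawInclusion <- function() {
    d <- sample(incLattice, 1L)
    rMax <- rPh - d / 2 - params$gelMargin
    if (rMax < 0) return(NULL)
    # uniform over the admissible disk of radius rMax around the centre
    u <- runif(1); th <- runif(1, 0, 2 * pi)
    r <- rMax * sqrt(u)
    list(centre = centre + r * c(cos(th), sin(th)), diameter = d,
         material = sample(c("water", "glycerol10"), 1L))
  }

  for (attempt in seq_len(maxAttempts)) {
    incs <- list(drawInclusion())
    if (is.null(incs[[1]])) next
    if (nInc == 2L) {
      incs[[2]] <- drawInclusion()
      if (is.null(incs[[2]])) next
      gap <- sqrt(sum((incs[[1]]$centre - incs[[2]]$centre)^2)) -
        (incs[[1]]$diameter + incs[[2]]$diameter) / 2
      if (gap < params$gelMargin) next
    }
    return(new("PhantomSpec", centre = centre, diameter = diameter,
               inclusions = incs, material = "gel"))
  }
  stop("rejection sampling failed after ", maxAttempts,
       " attempts; parameter ranges look infeasible")
}

# rotate a point 90 deg counter-clockwise about a pivot
rot90ccw <- function(p, pivot) pivot + c(-(p[2] - pivot[2]), p[1] - pivot[1])

#' Render a phantom specification as a speed-of-sound map
#'
#' Pixels whose centres fall inside an inclusion disk take that inclusion's
#' speed; pixels inside the phantom disk take the gel speed; everything else
#' is water. For `viewAngle = 90` the inclusion layout is rotated 90 degrees
#' counter-clockwise about the phantom centre before rasterisation (the
#' phantom disk itself is rotation invariant).
#'
#' @param spec a [PhantomSpec-class].
#' @param grid a [GridSpec-class].
#' @param viewAngle 0 or 90 (degrees).
#' @param materials a [materialTable()].
#' @return A speed-coded [SoSMap-class].
#' @export
renderSoSMap <- function(spec, grid = sosGrid(), viewAngle = 0,
                         materials = materialTable()) {
  stopifnot(viewAngle %in% c(0, 90))
  validObject(spec)
  n <- grid@nPixels
  p <- pixelPitch(grid)
  coords <- (seq_len(n) - 0.5) * p - grid@extent / 2
  X <- matrix(coords, n, n, byrow = TRUE)   # columns = x
  Y <- matrix(coords, n, n, byrow = FALSE)  # rows = y
  sp <- materials$speeds
  v <- matrix(sp[["water"]], n, n)
  inPhantom <- (X - spec@centre[1])^2 + (Y - spec@centre[2])^2 <=
    (spec@diameter / 2)^2
  v[inPhantom] <- sp[["gel"]]
  for (inc in spec@inclusions) {
    ctr <- if (viewAngle == 90) rot90ccw(inc$centre, spec@centre) else inc$centre
    inside <- (X - ctr[1])^2 + (Y - ctr[2])^2 <= (inc$diameter / 2)^2
    v[inside] <- sp[[inc$material]]
  }
  new("SoSMap", values = v, grid = grid, viewAngle = viewAngle,
      coding = "speed", spec = list(spec))
}

#' Recode a speed map to the normalised class coding
#'
#' Bijective recoding of material speeds to the class codes 0 (gel),
#' 0.5 (water), 1 (10 wt% glycerol); [classDecode()] inverts it exactly.
#'
#' @param map a speed-coded [SoSMap-class] whose every pixel value appears in
#'   the material table.
#' @param materials a [materialTable()].
#' @return A class-coded [SoSMap-class].
#' @export
classEncode <- function(map, materials = materialTable()) {
  stopifnot(is(map, "SoSMap"), map@coding == "speed")
  v <- map@values
  idx <- match(v, materials$speeds)
  if (anyNA(idx)) {
    k <- which(is.na(idx))[1]
    i <- (k - 1L) %% nrow(v) + 1L
    j <- (k - 1L) %/% nrow(v) + 1L
    stop(sprintf("pixel [%d, %d] has speed %g m/s, not in the material table",
                 i, j, v[i, j]))
  }
  coded <- matrix(materials$classCodes[names(materials$speeds)[idx]],
                  nrow(v), ncol(v))
  new("SoSMap", values = coded, grid = map@grid, viewAngle = map@viewAngle,
      coding = "class", spec = map@spec)
}

#' @describeIn classEncode Inverse recoding from class codes to speeds.
#' @export
classDecode <- function(map, materials = materialTable()) {
  stopifnot(is(map, "SoSMap"), map@coding == "class")
  v <- map@values
  idx <- match(v, materials$classCodes)
  if (anyNA(idx)) {
    k <- which(is.na(idx))[1]
    i <- (k - 1L) %% nrow(v) + 1L
    j <- (k - 1L) %/% nrow(v) + 1L
    stop(sprintf("pixel [%d, %d] has code %g, not a known class code",
                 i, j, v[i, j]))
  }
  sp <- matrix(materials$speeds[names(materials$classCodes)[idx]],
               nrow(v), ncol(v))
  new("SoSMap", values = sp, grid = map@grid, viewAngle = map@viewAngle,
      coding = "speed", spec = map@spec)
}

#' Wrap a plain matrix as a user-supplied SoS map
#'
#' Validates the soft-tissue speed envelope (1400--1700 m/s).
#'
#' @param values numeric square matrix of speeds in m/s.
#' @param grid a [GridSpec-class]; defaults to one matching `values`.
#' @param viewAngle 0 or 90.
#' @return A speed-coded [SoSMap-class].
#' @export
asSoSMap <- function(values, grid = NULL, viewAngle = 0) {
  if (is.null(grid)) grid <- sosGrid(nPixels = nrow(values))
  new("SoSMap", values = values, grid = grid, viewAngle = viewAngle,
      coding = "speed", spec = list())
}
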