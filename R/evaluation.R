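# Quantitative evaluation of reconstructed class-coded SoS maps: region
# segmentation, diameter (longest axis-aligned pixel run) and centre
# measurement, ground-truth comparison and the aggregate statistics.

#' Round half away from zero at reporting time
#'
#' Metric tables are reported at two decimals with halves rounded up (away
#' from zero); all arithmetic before reporting stays at full precision.
#'
#' @param x numeric.
#' @param digits decimals to keep.
#' @export
reportRound <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Segment phantom and inclusion regions from a class-coded map
#'
#' The phantom is the largest 4-connected component of gel pixels (code 0);
#' inclusions are 4-connected non-gel components that do not touch the image
#' border and whose entire outer boundary is phantom gel (fully enclosed),
#' ranked by area so the largest is inclusion 1. The water background is
#' excluded by its border connectivity.
#'
#' @param map a class-coded [SoSMap-class] (values in 0, 0.5, 1).
#' @param maxInclusions keep at most this many inclusions (by area).
#' @param minArea discard enclosed specks smaller than this many pixels.
#' @return list with `phantomFound` (logical), `phantom` (logical mask of
#'   the gel component or `NULL`), `phantomFilled` (the gel component plus
#'   every region it encloses — the full phantom disk, the mask whose
#'   diameter corresponds to a camera view of the phantom), `inclusions`
#'   (list of logical masks, largest first).
#' @export
segmentRegions <- function(map, maxInclusions = 2L, minArea = 4L) {
  stopifnot(is(map, "SoSMap"), map@coding == "class")
  v <- map@values
  n <- nrow(v)
  gelLab <- EBImage::bwlabel(v == 0)
  if (max(gelLab) == 0)
    return(list(phantomFound = FALSE, phantom = NULL, phantomFilled = NULL,
                inclusions = list()))
  areas <- tabulate(gelLab[gelLab > 0])
  phLab <- which.max(areas)
  phantom <- gelLab == phLab
  othLab <- EBImage::bwlabel(v != 0)
  border <- unique(c(othLab[1, ], othLab[n, ], othLab[, 1], othLab[, n]))
  cand <- setdiff(seq_len(max(othLab)), border)
  masks <- list(); filled <- phantom
  for (lab in cand) {
    m <- othLab == lab
    ring <- neighbourMask(m) & !m # outer boundary must be phantom gel
    if (!all(phantom[ring])) next
    filled <- filled | m # every enclosed cavity is part of the disk
    if (sum(m) >= minArea) masks[[length(masks) + 1L]] <- m
  }
  if (length(masks)) {
    ord <- order(vapply(masks, sum, 0), decreasing = TRUE)
    masks <- masks[ord][seq_len(min(length(masks), maxInclusions))]
  }
  list(phantomFound = TRUE, phantom = phantom, phantomFilled = filled,
       inclusions = masks)
}

# 4-neighbour dilation of a logical mask
neighbourMask <- function(m) {
  n <- nrow(m); p <- ncol(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-n, ]
  out[-n, ] <- out[-n, ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -p]
  out[, -p] <- out[, -p] | m[, -1]
  out
}

#' Measure a segmented region's diameter and centre
#'
#' The diameter is the longest axis-aligned pixel run through the region
#' (maximum over all row-wise and column-wise runs of consecutive region
#' pixels) times the pixel pitch; the centre is the midpoint of that longest
#' run, in tank-centred mm. Rows are scanned before columns; among equal
#' runs the first encountered wins. `method = "feret"` instead returns the
#' orientation-free maximum calliper distance between region pixel centres
#' plus one pitch.
#'
#' @param mask logical matrix marking the region (rows = y, cols = x).
#' @param grid the [GridSpec-class] the mask lives on.
#' @param kind region label, e.g. `"phantom"`, `"inclusion_1"`.
#' @param method `"axis"` (default) or `"feret"`.
#' @return list of class `RegionMeasurement`: `kind`, `diameter` (mm),
#'   `centre` (x, y mm).
#' @export
measureRegion <- function(mask, grid, kind = "region",
                          method = c("axis", "feret")) {
  method <- match.arg(method)
  if (!any(mask)) stop("empty region")
  p <- pixelPitch(grid)
  half <- grid@extent / 2
  if (method == "feret") {
    idx <- which(mask, arr.ind = TRUE)
    xs <- (idx[, 2] - 0.5) * p - half
    ys <- (idx[, 1] - 0.5) * p - half
    hp <- grDevices::chull(xs, ys)
    d <- as.matrix(stats::dist(cbind(xs[hp], ys[hp])))
    dia <- max(d) + p
    ctr <- c(mean(range(xs)), mean(range(ys)))
    return(structure(list(kind = kind, diameter = dia, centre = ctr),
                     class = "RegionMeasurement"))
  }
  bestRun <- function(series) {
    best <- list(len = 0L, mid = NA_real_)
    for (i in seq_along(series)) {
      r <- rle(as.vector(series[[i]]))
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      hits <- which(r$values & r$lengths > best$len)
      if (length(hits)) {
        h <- hits[which.max(r$lengths[hits])]
        best <- list(len = r$lengths[h], mid = (starts[h] + ends[h]) / 2)
      }
    }
    best
  }
  rowRun <- bestRun(asplit(mask, 1)) # runs along x, one per row
  colRun <- bestRun(asplit(mask, 2)) # runs along y, one per column
  # diameter: longest axis-aligned run over both scan directions; centre:
  # along-x coordinate from the longest row run's midpoint, along-y from
  # the longest column run's midpoint
  ctr <- c((rowRun$mid - 0.5) * p - half, (colRun$mid - 0.5) * p - half)
  structure(list(kind = kind, diameter = max(rowRun$len, colRun$len) * p,
                 centre = ctr),
            class = "RegionMeasurement")
}

#' @export
print.RegionMeasurement <- function(x, ...) {
  cat(sprintf("%s: diameter %.2f mm, centre (%+.2f, %+.2f) mm\n",
              x$kind, x$diameter, x$centre[1], x$centre[2]))
  invisible(x)
}

#' Compare a ground-truth and a reconstructed region measurement
#'
#' Change is ground truth minus reconstruction (mm and percent of the
#' ground-truth diameter); the centre offset is the Euclidean norm of the
#' centre difference. All values are kept at full precision; round with
#' [reportRound()] only when printing.
#'
#' @param gt,exp `RegionMeasurement` objects of the same kind.
#' @param label row label carried into aggregate extreme reporting.
#' @return list of class `ComparisonRow`: `label`, `kind`, `gtDiameter`,
#'   `expDiameter`, `changeMm`, `changePct`, `centreDelta`, `offsetMm`.
#' @export
compareRegions <- function(gt, exp, label = gt$kind) {
  if (!identical(gt$kind, exp$kind))
    stop("cannot compare regions of different kinds (", gt$kind, " vs ",
         exp$kind, ")")
  changeMm <- gt$diameter - exp$diameter
  delta <- gt$centre - exp$centre
  structure(list(label = label, kind = gt$kind,
                 gtDiameter = gt$diameter, expDiameter = exp$diameter,
                 changeMm = changeMm,
                 changePct = 100 * changeMm / gt$diameter,
                 centreDelta = delta,
                 offsetMm = sqrt(sum(delta^2))),
            class = "ComparisonRow")
}

#' @export
print.ComparisonRow <- function(x, ...) {
  cat(sprintf("%s [%s]: GT %.2f mm, Exp %.2f mm, change %.2f mm (%.2f%%), offset %.2f mm\n",
              x$label, x$kind, x$gtDiameter, x$expDiameter,
              reportRound(x$changeMm), reportRound(x$changePct),
              reportRound(x$offsetMm)))
  invisible(x)
}

#' Aggregate comparison rows into summary statistics
#'
#' Per-region-kind means of the diameter change (mm and percent) and of the
#' centre offset, the global mean percentage change over all rows, and the
#' extreme diameter changes / centre offsets with their row labels. Means
#' are computed at full precision; apply [reportRound()] when printing.
#'
#' @param rows list of `ComparisonRow` objects.
#' @return list of class `AggregateStats` with elements `perKind` (data
#'   frame), `globalMeanChangePct`, `minChange`, `maxChange`, `minOffset`,
#'   `maxOffset` (each a list of `value` and `label`), `n`.
#' @export
aggregateStats <- function(rows) {
  if (!length(rows)) stop("no comparison rows to aggregate")
  kinds <- vapply(rows, `[[`, "", "kind")
  get <- function(f) vapply(rows, `[[`, 0, f)
  changes <- get("changeMm"); pcts <- get("changePct"); offs <- get("offsetMm")
  labels <- vapply(rows, `[[`, "", "label")
  perKind <- do.call(rbind, lapply(unique(kinds), function(k) {
    i <- kinds == k
    data.frame(kind = k, n = sum(i),
               meanChangeMm = mean(changes[i]),
               meanChangePct = mean(pcts[i]),
               meanOffsetMm = mean(offs[i]))
  }))
  extreme <- function(v, which) {
    i <- if (which == "min") which.min(v) else which.max(v)
    list(value = v[i], label = labels[i])
  }
  structure(list(perKind = perKind,
                 globalMeanChangePct = mean(pcts),
                 minChange = extreme(changes, "min"),
                 maxChange = extreme(changes, "max"),
                 minOffset = extreme(offs, "min"),
                 maxOffset = extreme(offs, "max"),
                 n = length(rows)),
            class = "AggregateStats")
}

#' @export
print.AggregateStats <- function(x, ...) {
  cat("Aggregate reconstruction statistics over", x$n, "regions\n")
  pk <- x$perKind
  for (i in seq_len(nrow(pk)))
    cat(sprintf("  %-12s n=%d  mean change %5.2f mm (%5.2f%%)  mean offset %4.2f mm\n",
                pk$kind[i], pk$n[i], reportRound(pk$meanChangeMm[i]),
                reportRound(pk$meanChangePct[i]),
                reportRound(pk$meanOffsetMm[i])))
  cat(sprintf("  global mean sizing error %.2f%%\n",
              reportRound(x$globalMeanChangePct)))
  cat(sprintf("  change extremes: %.2f mm (%s) to %.2f mm (%s)\n",
              reportRound(x$minChange$value), x$minChange$label,
              reportRound(x$maxChange$value), x$maxChange$label))
  cat(sprintf("  offset extremes: %.2f mm (%s) to %.2f mm (%s)\n",
              reportRound(x$minOffset$value), x$minOffset$label,
              reportRound(x$maxOffset$value), x$maxOffset$label))
  invisible(x)
}

#' Difference SoS map (prediction minus ground truth)
#'
#' @param predicted,groundTruth [SoSMap-class] objects on the same grid.
#' @return A [SoSMap-class] with `coding = "difference"`.
#' @export
differenceMap <- function(predicted, groundTruth) {
  stopifnot(is(predicted, "SoSMap"), is(groundTruth, "SoSMap"))
  if (!all(dim(predicted@values) == dim(groundTruth@values)) ||
      predicted@grid@extent != groundTruth@grid@extent)
    stop("maps must share one grid")
  new("SoSMap", values = predicted@values - groundTruth@values,
      grid = predicted@grid, viewAngle = predicted@viewAngle,
      coding = "difference", spec = list())
}

#' Bundled printed measurements of the four experimental phantoms
#'
#' Ground-truth and CNN-predicted diameters and centres of the phantoms A-D
#' and their inclusions, as printed in the published comparison table.
#'
#' @return data frame with columns `phantom`, `region`, `gt_dia`, `exp_dia`,
#'   `gt_cx`, `gt_cy`, `exp_cx`, `exp_cy` (mm).
#' @export
tableD4 <- function() {
  path <- system.file("extdata", "table_d4.csv", package = "lutomo",
                      mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Comparison rows and aggregates for the bundled phantom measurements
#'
#' Feeds the printed ground-truth/predicted measurements of [tableD4()]
#' through [compareRegions()] and [aggregateStats()].
#'
#' @return list with `rows` (list of `ComparisonRow`) and `stats`
#'   (`AggregateStats`).
#' @examples
#' evaluateTableD4()$stats
#' @export
evaluateTableD4 <- function() {
  d <- tableD4()
  rows <- lapply(seq_len(nrow(d)), function(i) {
    gt <- structure(list(kind = d$region[i], diameter = d$gt_dia[i],
                         centre = c(d$gt_cx[i], d$gt_cy[i])),
                    class = "RegionMeasurement")
    ex <- structure(list(kind = d$region[i], diameter = d$exp_dia[i],
                         centre = c(d$exp_cx[i], d$exp_cy[i])),
                    class = "RegionMeasurement")
    compareRegions(gt, ex, label = paste(d$phantom[i], d$region[i]))
  })
  list(rows = rows, stats = aggregateStats(rows))
}

#' Specifications of the four experimental phantoms
#'
#' [PhantomSpec-class] objects matching the fabricated phantoms A-D
#' (diameters and ground-truth centres of [tableD4()]): A and B carry one
#' 10 mm inclusion (water / 10 wt% glycerol), C and D two inclusions
#' (9.36 mm and 5.82 mm).
#'
#' @return named list of [PhantomSpec-class] objects.
#' @export
experimentalPhantoms <- function() {
  list(
    A = new("PhantomSpec", centre = c(0.08, 0.25), diameter = 30.50,
            inclusions = list(list(centre = c(-5.83, 5.92), diameter = 10,
                                   material = "water")),
            material = "gel"),
    B = new("PhantomSpec", centre = c(0.08, 0.25), diameter = 30.50,
            inclusions = list(list(centre = c(-5.83, 5.92), diameter = 10,
                                   material = "glycerol10")),
            material = "gel"),
    C = new("PhantomSpec", centre = c(-0.65, 0.24), diameter = 30.02,
            inclusions = list(
              list(centre = c(-5.57, 3.95), diameter = 9.36,
                   material = "water"),
              list(centre = c(2.91, -5.00), diameter = 5.82,
                   material = "water")),
            material = "gel"),
    D = new("PhantomSpec", centre = c(-0.65, 0.24), diameter = 30.02,
            inclusions = list(
              list(centre = c(-5.57, 3.95), diameter = 9.36,
                   material = "glycerol10"),
              list(centre = c(2.91, -5.00), diameter = 5.82,
                   material = "water")),
            material = "gel"))
}

#' Measure and compare a reconstructed map against its ground truth
#'
#' Segments both maps, pairs regions (phantom to phantom, inclusions by
#' nearest centre) and returns the comparison rows; unmatched predicted
#' inclusions are reported as false positives.
#'
#' @param predicted,groundTruth class-coded [SoSMap-class] objects.
#' @param label prefix for row labels.
#' @return list with `rows` (list of `ComparisonRow`), `missing` (character:
#'   ground-truth regions absent from the prediction), `falsePositives`
#'   (count of unmatched predicted inclusions).
#' @export
compareMaps <- function(predicted, groundTruth, label = "map") {
  gtSeg <- segmentRegions(groundTruth)
  prSeg <- segmentRegions(predicted)
  grid <- groundTruth@grid
  rows <- list(); missing <- character(0)
  if (!gtSeg$phantomFound) stop("ground truth contains no phantom")
  if (!prSeg$phantomFound) {
    missing <- c(missing, "phantom",
                 paste0("inclusion_", seq_along(gtSeg$inclusions)))
    return(list(rows = rows, missing = missing, falsePositives = 0L))
  }
  gtPh <- measureRegion(gtSeg$phantomFilled, grid, "phantom")
  prPh <- measureRegion(prSeg$phantomFilled, grid, "phantom")
  rows[[1]] <- compareRegions(gtPh, prPh, paste(label, "phantom"))
  gtInc <- lapply(gtSeg$inclusions, measureRegion, grid = grid,
                  kind = "inclusion")
  prInc <- lapply(prSeg$inclusions, measureRegion, grid = grid,
                  kind = "inclusion")
  used <- logical(length(prInc))
  for (k in seq_along(gtInc)) {
    kindK <- paste0("inclusion_", k)
    gtK <- gtInc[[k]]; gtK$kind <- kindK
    if (!length(prInc) || all(used)) {
      missing <- c(missing, kindK); next
    }
    dists <- vapply(seq_along(prInc), function(j) {
      if (used[j]) Inf else sqrt(sum((gtK$centre - prInc[[j]]$centre)^2))
    }, 0)
    j <- which.min(dists)
    if (!is.finite(dists[j])) { missing <- c(missing, kindK); next }
    used[j] <- TRUE
    prK <- prInc[[j]]; prK$kind <- kindK
    rows[[length(rows) + 1L]] <- compareRegions(gtK, prK,
                                                paste(label, kindK))
  }
  list(rows = rows, missing = missing, falsePositives = sum(!used))
}
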