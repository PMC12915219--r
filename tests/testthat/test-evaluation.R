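test_that("the bundled phantom table reproduces every printed aggregate", {
  ev <- evaluateTableD4()
  s <- ev$stats
  pk <- s$perKind
  expect_equal(reportRound(pk$meanChangeMm[pk$kind == "phantom"]), 1.34)
  expect_equal(reportRound(pk$meanChangePct[pk$kind == "phantom"]), 4.41)
  expect_equal(reportRound(pk$meanChangeMm[pk$kind == "inclusion_1"]), 0.35)
  expect_equal(reportRound(pk$meanChangePct[pk$kind == "inclusion_1"]), 3.56)
  expect_equal(reportRound(pk$meanChangeMm[pk$kind == "inclusion_2"]), 0.74)
  expect_equal(reportRound(pk$meanChangePct[pk$kind == "inclusion_2"]), 12.71)
  expect_equal(reportRound(s$globalMeanChangePct), 5.73)
  expect_equal(reportRound(pk$meanOffsetMm[pk$kind == "phantom"]), 0.62)
  expect_equal(reportRound(pk$meanOffsetMm[pk$kind == "inclusion_1"]), 0.85)
  expect_equal(reportRound(pk$meanOffsetMm[pk$kind == "inclusion_2"]), 1.13)
  expect_equal(reportRound(s$minChange$value), 0.01)
  expect_equal(reportRound(s$maxChange$value), 1.91)
  expect_equal(reportRound(s$minOffset$value), 0.34)
  expect_equal(reportRound(s$maxOffset$value), 1.51)
})

test_that("individual comparison rows match the printed table", {
  rows <- evaluateTableD4()$rows
  byLabel <- setNames(rows, vapply(rows, `[[`, "", "label"))
  a <- byLabel[["A phantom"]]
  expect_equal(reportRound(a$changeMm), 1.51)
  expect_equal(reportRound(a$changePct), 4.95)
  b <- byLabel[["B phantom"]]
  expect_equal(reportRound(b$centreDelta), c(-0.23, 0.25))
  expect_equal(reportRound(b$offsetMm), 0.34)
  same <- compareRegions(
    structure(list(kind = "phantom", diameter = 30, centre = c(1, 2)),
              class = "RegionMeasurement"),
    structure(list(kind = "phantom", diameter = 30, centre = c(1, 2)),
              class = "RegionMeasurement"))
  expect_equal(same$changeMm, 0)
  expect_equal(same$changePct, 0)
  expect_equal(same$offsetMm, 0)
  expect_error(compareRegions(
    structure(list(kind = "phantom", diameter = 1, centre = c(0, 0)),
              class = "RegionMeasurement"),
    structure(list(kind = "inclusion_1", diameter = 1, centre = c(0, 0)),
              class = "RegionMeasurement")), "different kinds")
})

test_that("aggregation handles the single-row edge case and rejects empties", {
  rows <- evaluateTableD4()$rows[1]
  s <- aggregateStats(rows)
  expect_equal(s$globalMeanChangePct, rows[[1]]$changePct)
  expect_equal(s$perKind$meanChangeMm, rows[[1]]$changeMm)
  expect_error(aggregateStats(list()), "no comparison rows")
})

test_that("half-up reporting rounds away from zero", {
  expect_equal(reportRound(12.715), 12.72)
  expect_equal(reportRound(0.005), 0.01)
  expect_equal(reportRound(-0.005), -0.01)
  expect_equal(reportRound(1.344), 1.34)
})

test_that("rendered phantoms segment into the expected regions", {
  mC <- classEncode(renderSoSMap(experimentalPhantoms()$C))
  seg <- segmentRegions(mC)
  expect_true(seg$phantomFound)
  expect_length(seg$inclusions, 2L)
  # all-water map: no phantom, not an exception
  water <- new("SoSMap", values = matrix(0.5, 64, 64), grid = sosGrid(64),
               viewAngle = 0, coding = "class", spec = list())
  segW <- segmentRegions(water)
  expect_false(segW$phantomFound)
  # an opening connecting an inclusion to the background voids enclosure
  v <- mapValues(mC)
  incPix <- which(seg$inclusions[[1]], arr.ind = TRUE)
  col <- incPix[1, 2]
  leakyMap <- v
  leakyMap[incPix[1, 1]:nrow(v), col] <- 0.5 # channel to the top border
  lm <- new("SoSMap", values = leakyMap, grid = sosGrid(128), viewAngle = 0,
            coding = "class", spec = list())
  segL <- segmentRegions(lm)
  expect_lt(length(segL$inclusions), 2L)
})

test_that("region measurement matches the digital-disk and brute-force oracles", {
  g <- sosGrid(128)
  p <- pixelPitch(g)
  # digital disk of radius 8 px: longest run 17 px
  ctr <- c(40, 60) # pixel-centred disk: 17-pixel central run
  mask <- outer(seq_len(128), seq_len(128),
                function(i, j) (i - ctr[2])^2 + (j - ctr[1])^2 <= 8^2)
  m <- measureRegion(mask, g, "disk")
  expect_equal(m$diameter, 17 * p, tolerance = 1e-12)
  set.seed(91)
  g24 <- sosGrid(nPixels = 32) # pitch only matters for the comparison
  for (trial in 1:20) {
    rmask <- matrix(runif(24 * 24) < 0.45, 24, 24)
    if (!any(rmask)) next
    mm <- measureRegion(rmask, g24, "r")
    # brute force: maximum run over all rows and columns
    runmax <- function(v) if (!any(v)) 0L else max(rle(v)$lengths[rle(v)$values])
    brute <- max(vapply(seq_len(24), function(i) runmax(rmask[i, ]), 0L),
                 vapply(seq_len(24), function(j) runmax(rmask[, j]), 0L))
    expect_equal(mm$diameter / pixelPitch(g24), brute)
  }
})

test_that("single pixels and translations behave as expected", {
  g <- sosGrid(64)
  p <- pixelPitch(g)
  mk <- matrix(FALSE, 64, 64); mk[20, 30] <- TRUE
  m <- measureRegion(mk, g, "px")
  expect_equal(m$diameter, p)
  expect_equal(m$centre, c((30 - 0.5) * p - 38.7, (20 - 0.5) * p - 38.7))
  # translate by (3, 5) pixels
  mk2 <- matrix(FALSE, 64, 64); mk2[25, 33] <- TRUE
  m2 <- measureRegion(mk2, g, "px")
  expect_equal(m2$diameter, m$diameter)
  expect_equal(m2$centre - m$centre, c(3 * p, 5 * p))
})

test_that("difference maps subtract elementwise with closed class values", {
  a <- new("SoSMap", values = matrix(c(0, 0.5, 1, 0.5), 32, 32),
           grid = sosGrid(32), viewAngle = 0, coding = "class", spec = list())
  b <- new("SoSMap", values = matrix(c(1, 0.5, 0, 0), 32, 32),
           grid = sosGrid(32), viewAngle = 0, coding = "class", spec = list())
  d <- differenceMap(a, b)
  expect_true(all(mapValues(d) %in% c(-1, -0.5, 0, 0.5, 1)))
  expect_equal(mapValues(differenceMap(a, a)), matrix(0, 32, 32))
  expect_equal(mapValues(differenceMap(b, a)), -mapValues(d))
})

test_that("centre offsets are invariant under a quarter-turn of the map", {
  mC <- classEncode(renderSoSMap(experimentalPhantoms()$C))
  segA <- segmentRegions(mC)
  g <- mapGrid(mC)
  rot <- new("SoSMap", values = t(mapValues(mC)[nrow(mapValues(mC)):1, ]),
             grid = g, viewAngle = 0, coding = "class", spec = list())
  segB <- segmentRegions(rot)
  a <- measureRegion(segA$phantom, g, "phantom")
  b <- measureRegion(segB$phantom, g, "phantom")
  expect_equal(sqrt(sum(b$centre^2)), sqrt(sum(a$centre^2)), tolerance = 0.05)
  expect_equal(b$diameter, a$diameter, tolerance = 0.05)
})
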