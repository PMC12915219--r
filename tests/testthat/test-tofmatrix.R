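geom16 <- arrayGeometry()

test_that("the auto normalisation constant is the geometric worst case", {
  ref <- referenceToFMatrix(geom16, 1480)
  norm <- normaliseToFs(ref, "auto")
  expect_equal(norm$constant, sqrt(77.4^2 + 30^2) * 1e-3 / 1455,
               tolerance = 1e-12)
  expect_equal(norm$constant, 57.052e-6, tolerance = 1e-4)
  expect_true(all(norm$matrices[[1]] > 0 & norm$matrices[[1]] <= 1))
})

test_that("normalisation is invertible and scales a chosen entry to one", {
  ref <- referenceToFMatrix(geom16, 1480)
  cmax <- max(mapValues(ref))
  norm <- normaliseToFs(ref, cmax)
  expect_equal(max(norm$matrices[[1]]), 1, tolerance = 1e-12)
  back <- denormaliseToFs(norm$matrices[[1]], norm$constant, geom16)
  expect_equal(mapValues(back), mapValues(ref), tolerance = 1e-12)
  bad <- new("ToFMatrix", values = mapValues(ref) - 60e-6, viewAngle = 0,
             geometry = geom16)
  expect_error(normaliseToFs(bad), "positive")
})

test_that("stacking builds the padded block-diagonal input and round trips", {
  t1 <- matrix(runif(256, 0.85, 0.95), 16, 16)
  t2 <- matrix(runif(256, 0.85, 0.95), 16, 16)
  s <- stackViews(t1, t2, 57e-6, frame = 128L)
  expect_identical(dim(s$values), c(32L, 32L))
  expect_identical(dim(s$padded), c(128L, 128L))
  # off-diagonal blocks exactly zero; 2 * 16 * 16 nonzero entries
  expect_true(all(s$values[1:16, 17:32] == 0))
  expect_true(all(s$values[17:32, 1:16] == 0))
  expect_identical(sum(s$padded != 0), 512L)
  expect_true(all(s$padded >= 0 & s$padded <= 1))
  u <- unstackViews(s)
  expect_identical(u$t1, t1)
  expect_identical(u$t2, t2)
  # the 32x32 block is anchored at the top-left of the frame
  expect_true(all(s$padded[33:128, ] == 0) && all(s$padded[, 33:128] == 0))
  expect_error(stackViews(t1, t2[1:8, 1:8], 57e-6), "equal shape")
  expect_error(stackViews(t1 * 2, t2, 57e-6), "normalised")
})

test_that("ToF differences vanish for water and go negative through gel", {
  w <- referenceToFMatrix(geom16, 1480)
  expect_true(all(mapValues(tofDifference(w, w)) == 0))
  gel <- computeToFMatrix(asSoSMap(matrix(1455, 64, 64)), geom16, 5L)
  wat <- computeToFMatrix(asSoSMap(matrix(1480, 64, 64)), geom16, 5L)
  expect_true(all(mapValues(tofDifference(wat, gel)) < 0))
})

test_that("a fast inclusion on the facing path makes its difference entry positive", {
  # gel disk spanning most of the tank with a glycerol inclusion on the
  # centre facing path; straight-path slowness oracle decides the sign
  m <- diskMap(64, disks = list(
    list(centre = c(0, 0), diameter = 70, speed = 1455),
    list(centre = c(0, 0), diameter = 30, speed = 1538)))
  wat <- asSoSMap(matrix(1480, 64, 64))
  tP <- computeToFMatrix(m, geom16, 5L)
  tW <- computeToFMatrix(wat, geom16, 5L)
  d <- mapValues(tofDifference(tW, tP))
  gp <- genPositions(geom16); dp <- detPositions(geom16)
  oracle <- straightPathTime(wat, gp[8, ], dp[8, ]) -
    straightPathTime(m, gp[8, ], dp[8, ])
  expect_gt(oracle, 0) # the glycerol saving beats the gel delay here
  expect_gt(d[8, 8], 0)
})

test_that("pick-and-assemble round trip recovers simulated ToFs within QC", {
  set.seed(61)
  spec <- samplePhantomSpec(nInclusions = 1L)
  m <- renderSoSMap(spec, sosGrid(64))
  geomSmall <- arrayGeometry(nGen = 4L, nDet = 4L, pitch = 10)
  sim <- synthScan(m, geomSmall, noise = noiseModel(snrDb = 35), seed = 62L)
  refs <- synthScan("water", geomSmall, noise = noiseModel(), seed = 63L)
  picked <- assembleToFMatrix(sim$scans, refs$scans, geomSmall)
  err <- abs(mapValues(picked$tof) - mapValues(sim$tof))
  expect_lt(max(err), 0.01 * mean(mapValues(sim$tof)))
  expect_lt(max(err), 2 * sim$scans[[1]]@dt + 1e-12)
})
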