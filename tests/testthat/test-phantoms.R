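test_that("sampled specs honour the parameter lattice and containment", {
  set.seed(101)
  params <- phantomParams()
  lat1 <- lutomo:::latticeValues(params$phantomDia1, params$increment)
  lat2 <- lutomo:::latticeValues(params$phantomDia2, params$increment)
  latI <- lutomo:::latticeValues(params$inclusionDia, params$increment)
  for (i in 1:1000) {
    s <- samplePhantomSpec(params)
    expect_true(all(s@centre %in% params$offsetValues))
    if (length(s@inclusions) == 1L) {
      expect_true(any(abs(s@diameter - lat1) < 1e-9))
    } else {
      expect_true(any(abs(s@diameter - lat2) < 1e-9))
      gap <- sqrt(sum((s@inclusions[[1]]$centre - s@inclusions[[2]]$centre)^2)) -
        (s@inclusions[[1]]$diameter + s@inclusions[[2]]$diameter) / 2
      expect_gte(gap, params$gelMargin - 1e-9)
    }
    for (inc in s@inclusions) {
      expect_true(any(abs(inc$diameter - latI) < 1e-9))
      expect_true(inc$material %in% c("water", "glycerol10"))
      d <- sqrt(sum((inc$centre - s@centre)^2))
      expect_lte(d + inc$diameter / 2, s@diameter / 2 - params$gelMargin + 1e-9)
    }
  }
})

test_that("forcing the two-inclusion category respects its diameter range", {
  set.seed(5)
  for (i in 1:50) {
    s <- samplePhantomSpec(nInclusions = 2L)
    expect_gte(s@diameter, 23.6)
    expect_length(s@inclusions, 2L)
  }
})

test_that("sampling is deterministic under a fixed seed", {
  set.seed(77); a <- samplePhantomSpec()
  set.seed(77); b <- samplePhantomSpec()
  expect_identical(a, b)
})

test_that("category proportions are near one half", {
  set.seed(300)
  n <- 4000
  k <- sum(vapply(seq_len(n),
                  function(i) length(samplePhantomSpec()@inclusions), 0L) == 2L)
  expect_gt(stats::binom.test(k, n, 0.5)$p.value, 0.01)
})

test_that("infeasible ranges raise instead of looping", {
  bad <- phantomParams(phantomDia1 = c(4.8, 5.4), inclusionDia = c(4.8, 5.4))
  expect_error(samplePhantomSpec(bad, nInclusions = 1L), "infeasible|failed")
})

test_that("rendering uses the three material speeds with correct areas", {
  # phantom B: 30.5 mm gel disk with a 10 mm glycerol inclusion, so all
  # regions are distinguishable by value
  spec <- experimentalPhantoms()$B
  g <- sosGrid()
  m <- renderSoSMap(spec, g)
  expect_s4_class(m, "SoSMap")
  expect_true(all(mapValues(m) %in% c(1455, 1480, 1538)))
  pitch <- pixelPitch(g)
  phantomArea <- sum(mapValues(m) != 1480) # gel + inclusion pixels
  expected <- pi * (spec@diameter / 2)^2 / pitch^2
  expect_lt(abs(phantomArea - expected) / expected, 0.02)
  incArea <- sum(mapValues(m) == 1538)
  expectedInc <- pi * (spec@inclusions[[1]]$diameter / 2)^2 / pitch^2
  expect_lt(abs(incArea - expectedInc) / expectedInc, 0.05)
})

test_that("pixels outside every disk take the background speed", {
  spec <- new("PhantomSpec", centre = c(0, 0), diameter = 12,
              inclusions = list(list(centre = c(0, 0), diameter = 5,
                                     material = "glycerol10")),
              material = "gel")
  m <- renderSoSMap(spec, sosGrid(64))
  expect_identical(mapValues(m)[1, 1], 1480)
  expect_identical(mapValues(m)[32, 32], 1538) # centre pixel in the inclusion
})

test_that("rendering at 90 degrees equals rotating the raster about the phantom centre", {
  # centred phantom: raster rotation about the grid centre is exact
  spec <- new("PhantomSpec", centre = c(0, 0), diameter = 26,
              inclusions = list(list(centre = c(6, 2), diameter = 6,
                                     material = "glycerol10")),
              material = "gel")
  g <- sosGrid(128)
  m0 <- mapValues(renderSoSMap(spec, g, 0))
  m90 <- mapValues(renderSoSMap(spec, g, 90))
  # rotate raster 90 deg CCW: value at (x', y') = original at (y', -x')
  rot <- t(m0[nrow(m0):1, ])
  disagree <- mean(rot != m90)
  expect_lt(disagree, 0.002) # boundary pixels only
})

test_that("class coding is the documented bijection and round trips", {
  spec <- experimentalPhantoms()$D
  m <- renderSoSMap(spec, sosGrid(64))
  coded <- classEncode(m)
  expect_setequal(unique(as.vector(mapValues(coded))), c(0, 0.5, 1))
  back <- classDecode(coded)
  expect_identical(mapValues(back), mapValues(m))

  water <- asSoSMap(matrix(1480, 32, 32))
  expect_true(all(mapValues(classEncode(water)) == 0.5))

  odd <- asSoSMap(matrix(c(1480, 1490), 32, 32))
  expect_error(classEncode(odd), "1490")
})

test_that("user maps outside the soft-tissue envelope are rejected", {
  expect_error(asSoSMap(matrix(1300, 32, 32)), "envelope")
  expect_error(asSoSMap(matrix(1750, 32, 32)), "envelope")
  expect_s4_class(asSoSMap(matrix(1500, 32, 32)), "SoSMap")
})
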