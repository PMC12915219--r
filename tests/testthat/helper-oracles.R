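# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Brute-force two-pass population kurtosis of each sliding window.
bruteKurtosis <- function(x, N) {
  sapply(seq_len(length(x) - N + 1L), function(k) {
    w <- x[k:(k + N - 1L)]
    m <- mean(w)
    m2 <- mean((w - m)^2)
    if (m2 == 0) return(NA_real_)
    mean((w - m)^4) / m2^2
  })
}

# Direct double-loop evaluation of R(m) = sum_j x(j) y(m + j), 1-based,
# out-of-range y treated as zero.
bruteXcorr <- function(x, y, lags) {
  sapply(lags, function(m) {
    acc <- 0
    for (j in seq_along(x)) {
      jj <- m + j
      if (jj >= 1 && jj <= length(y)) acc <- acc + x[j] * y[jj]
    }
    acc
  })
}

# Lattice Dijkstra shortest travel time on a speed map from a source node to
# all nodes, with a configurable neighbourhood stencil. Edge travel time is
# the slowness line-integral along the straight edge (trapezoid over
# `edgeSamples` nearest-node lookups), so each lattice path time is a valid
# upper bound on the continuous first-arrival time up to quadrature error.
# O(n^2) array implementation; fine for the <= 48 x 48 grids used in tests.
latticeDijkstra <- function(speed, pitch, srcIdx, stencil, edgeSamples = 9L) {
  n <- nrow(speed)
  dist <- matrix(Inf, n, n)
  done <- matrix(FALSE, n, n)
  dist[srcIdx[1], srcIdx[2]] <- 0
  slow <- 1 / speed
  frac <- seq(0, 1, length.out = edgeSamples)
  wts <- rep(1, edgeSamples); wts[c(1, edgeSamples)] <- 0.5
  wts <- wts / sum(wts)
  edgeCost <- function(ui, uj, vi, vj, len) {
    ii <- pmin(pmax(round(ui + frac * (vi - ui)), 1L), n)
    jj <- pmin(pmax(round(uj + frac * (vj - uj)), 1L), n)
    len * sum(wts * slow[cbind(ii, jj)])
  }
  for (iter in seq_len(n * n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    ui <- (u - 1L) %% n + 1L
    uj <- (u - 1L) %/% n + 1L
    done[ui, uj] <- TRUE
    for (s in seq_len(nrow(stencil))) {
      vi <- ui + stencil[s, 1]; vj <- uj + stencil[s, 2]
      if (vi < 1 || vi > n || vj < 1 || vj > n) next
      len <- sqrt(sum(stencil[s, ]^2)) * pitch
      w <- edgeCost(ui, uj, vi, vj, len)
      if (dist[ui, uj] + w < dist[vi, vj]) dist[vi, vj] <- dist[ui, uj] + w
    }
  }
  dist
}

# neighbourhood stencils: moves with coprime offsets within a radius
dijkstraStencil <- function(radius) {
  offs <- expand.grid(di = -radius:radius, dj = -radius:radius)
  offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
  keep <- mapply(function(a, b) {
    g <- function(p, q) if (q == 0) abs(p) else g(q, p %% q)
    g(abs(a), abs(b)) == 1 || (abs(a) <= 1 && abs(b) <= 1)
  }, offs$di, offs$dj)
  as.matrix(offs[keep, ])
}

# Fermat two-layer travel time between two points separated by a horizontal
# interface: minimise over the crossing position (closed-form-free golden
# search via optimize()).
twoLayerTime <- function(p1, p2, yInterface, cTop, cBottom) {
  # p1 below the interface, p2 above (y increasing upward), mm and m/s
  f <- function(x) {
    sqrt((x - p1[1])^2 + (yInterface - p1[2])^2) * 1e-3 / cBottom +
      sqrt((p2[1] - x)^2 + (p2[2] - yInterface)^2) * 1e-3 / cTop
  }
  stats::optimize(f, lower = min(p1[1], p2[1]) - 80,
                  upper = max(p1[1], p2[1]) + 80, tol = 1e-10)$objective
}

# straight-segment slowness integral through a SoSMap (trapezoid on a dense
# sampling), independent of the ray tracer
straightPathTime <- function(map, a, b, nStep = 4000L) {
  ts <- seq(0, 1, length.out = nStep)
  xs <- a[1] + ts * (b[1] - a[1])
  ys <- a[2] + ts * (b[2] - a[2])
  v <- mapValues(map)
  n <- nrow(v); p <- lutomo::pixelPitch(mapGrid(map)); half <- mapGrid(map)@extent / 2
  ii <- pmin(pmax(ceiling((ys + half) / p), 1L), n)
  jj <- pmin(pmax(ceiling((xs + half) / p), 1L), n)
  slo <- 1 / v[cbind(ii, jj)]
  len <- sqrt(sum((b - a)^2)) * 1e-3
  len * mean(slo)
}

# quick homogeneous + disk map builders on an arbitrary grid
diskMap <- function(n = 64, extent = 77.4, background = 1480, disks = list()) {
  g <- sosGrid(n, extent)
  p <- extent / n
  coords <- (seq_len(n) - 0.5) * p - extent / 2
  X <- matrix(coords, n, n, byrow = TRUE)
  Y <- matrix(coords, n, n, byrow = FALSE)
  v <- matrix(background, n, n)
  for (d in disks)
    v[(X - d$centre[1])^2 + (Y - d$centre[2])^2 <= (d$diameter / 2)^2] <- d$speed
  asSoSMap(v, g)
}
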