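# Synthetic broadband laser-ultrasound A-scans with controllable arrival
# times and additive white Gaussian noise, so the onset picker and the
# end-to-end pipeline can be exercised without experimental data.

#' Broadband pulse model
#'
#' Spectral description of the synthesised ultrasonic pulse: magnitude is a
#' split Gaussian peaking at `centreFrequency` whose lower and upper halves
#' have their -6 dB points at `bandLow` / `bandHigh`. (A single symmetric
#' Gaussian cannot place an off-centre peak inside an asymmetric band, so
#' the two half-widths are fitted separately.) The pulse is synthesised
#' zero-phase, scaled to unit peak envelope; its onset is defined as the
#' leading point where the envelope reaches -40 dB of its peak.
#'
#' @param centreFrequency spectral peak in Hz (default 6.56 MHz).
#' @param bandLow,bandHigh -6 dB band edges in Hz (defaults 1.94 / 11.98 MHz).
#' @param amplitude peak envelope amplitude (arbitrary units).
#' @return list of class `PulseModel`.
#' @export
pulseModel <- function(centreFrequency = 6.56e6, bandLow = 1.94e6,
                       bandHigh = 11.98e6, amplitude = 1) {
  stopifnot(bandLow > 0, bandLow < centreFrequency,
            centreFrequency < bandHigh, amplitude > 0)
  structure(list(centreFrequency = centreFrequency, bandLow = bandLow,
                 bandHigh = bandHigh, amplitude = amplitude),
            class = "PulseModel")
}

# Dense kernel table for a pulse model: zero-phase waveform, envelope and
# -40 dB onset, on a fine time grid; evaluated once then linearly
# interpolated for sub-sample arrival placement.
pulseKernel <- function(model, dtFine = 1e-9) {
  f0 <- model$centreFrequency
  sLo <- (f0 - model$bandLow) / sqrt(2 * log(2))
  sHi <- (model$bandHigh - f0) / sqrt(2 * log(2))
  fMax <- f0 + 5 * sHi
  f <- seq(0, fMax, by = 2e4)
  A <- ifelse(f < f0, exp(-(f - f0)^2 / (2 * sLo^2)),
              exp(-(f - f0)^2 / (2 * sHi^2)))
  span <- 0.8e-6
  tau <- seq(-span, span, by = dtFine)
  ph <- 2 * pi * outer(tau, f)
  p <- as.vector(cos(ph) %*% A)
  q <- as.vector(sin(ph) %*% A)
  env <- sqrt(p^2 + q^2)
  peak <- max(env)
  p <- p / peak * model$amplitude
  env <- env / peak * model$amplitude
  onIdx <- which(env >= 0.01 * max(env))[1] # -40 dB leading point
  list(tau = tau, p = p, env = env, tauOnset = tau[onIdx])
}

#' Synthesise one pulse waveform
#'
#' @param model a [pulseModel()].
#' @param dt sampling interval in seconds; must satisfy
#'   `dt < 1 / (2 * bandHigh)`.
#' @return numeric waveform sampled at `dt`, with attributes `dt` and
#'   `onset` (seconds from the first sample to the -40 dB envelope onset).
#' @examples
#' p <- synthPulse()
#' @export
synthPulse <- function(model = pulseModel(), dt = 1e-8) {
  if (dt >= 1 / (2 * model$bandHigh))
    stop("undersampled: dt must be below 1/(2 * bandHigh)")
  k <- pulseKernel(model)
  t <- seq(min(k$tau), max(k$tau), by = dt)
  s <- stats::approx(k$tau, k$p, xout = t, rule = 2)$y
  structure(s, dt = dt, onset = k$tauOnset - min(k$tau))
}

#' Noise and artefact model for synthetic A-scans
#'
#' Additive white Gaussian noise whose level is defined as peak pulse
#' amplitude over noise RMS, in dB. An optional reverberation echo (a scaled
#' copy of the pulse arriving `echoDelay` after the first arrival) emulates
#' the multipath events that defeat naive full-trace pickers on experimental
#' data; it is off by default.
#'
#' @param snrDb peak-amplitude-to-noise-RMS ratio in dB (`Inf` = noise free).
#' @param echoAmp echo amplitude relative to the first arrival (0 = none).
#' @param echoDelay echo delay after the first arrival, seconds.
#' @return list of class `NoiseModel`.
#' @export
noiseModel <- function(snrDb = Inf, echoAmp = 0, echoDelay = 0) {
  stopifnot(echoAmp >= 0, echoDelay >= 0)
  structure(list(snrDb = snrDb, echoAmp = echoAmp, echoDelay = echoDelay),
            class = "NoiseModel")
}

withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# shared time base for one element pair: physics window plus margins
pairTimeBase <- function(genXY, detXY, dt, vMin = 1455, vMax = 1538,
                         preMargin = 3e-6, postMargin = 3e-6) {
  d <- sqrt(sum((genXY - detXY)^2)) * 1e-3
  t0 <- d / vMax - preMargin
  t1 <- d / vMin + postMargin
  seq(t0, t1, by = dt)
}

placePulse <- function(t, kernel, tof, amp = 1) {
  shift <- tof - kernel$tauOnset
  amp * stats::approx(kernel$tau + shift, kernel$p, xout = t,
                      yleft = 0, yright = 0)$y
}

#' Synthesise an A-scan for one element pair
#'
#' Places the pulse onset at the first-arrival time through the given medium
#' (the eikonal ToF for a phantom map, `distance / 1480` for `"water"`),
#' then applies the noise model. The time base spans the pair's physics
#' window plus 3 us margins, so the same base is shared by the phantom scan
#' and its water reference.
#'
#' @param map a speed-coded [SoSMap-class], or `"water"`.
#' @param geom an [ArrayGeometry-class].
#' @param genIndex,detIndex 1-based element indices.
#' @param pulse a [pulseModel()].
#' @param noise a [noiseModel()].
#' @param seed optional integer; the RNG state is restored afterwards.
#' @param dt sampling interval (default 10 ns, i.e. 100 MS/s).
#' @param tof optional arrival-time override in seconds (skips the eikonal
#'   solve; used by benches that control the truth directly).
#' @param waterSpeed speed used for the `"water"` reference, m/s.
#' @return An [AScan-class]; the true onset used is attached as attribute
#'   `"tof"`.
#' @export
synthAScan <- function(map, geom = arrayGeometry(), genIndex = 1L,
                       detIndex = 1L, pulse = pulseModel(),
                       noise = noiseModel(), seed = NULL, dt = 1e-8,
                       tof = NULL, waterSpeed = 1480) {
  gp <- genPositions(geom)[genIndex, ]
  dp <- detPositions(geom)[detIndex, ]
  if (is.null(tof)) {
    if (identical(map, "water")) {
      tof <- sqrt(sum((gp - dp)^2)) * 1e-3 / waterSpeed
    } else {
      stopifnot(is(map, "SoSMap"))
      f <- refineField(solveEikonal(map, gp), 5L)
      tof <- traceRay(f, dp, gp, map)$time
    }
  }
  t <- pairTimeBase(gp, dp, dt)
  kernel <- pulseKernel(pulse)
  s <- placePulse(t, kernel, tof)
  if (noise$echoAmp > 0)
    s <- s + placePulse(t, kernel, tof + noise$echoDelay, noise$echoAmp)
  withSeed(seed, {
    if (is.finite(noise$snrDb)) {
      sdn <- pulse$amplitude / 10^(noise$snrDb / 20)
      s <- s + rnorm(length(s), 0, sdn)
    }
    structure(new("AScan", samples = s, dt = dt, t0 = t[1],
                  genIndex = as.integer(genIndex),
                  detIndex = as.integer(detIndex)),
              tof = tof)
  })
}

#' Synthesise the full two-plate scan of a medium
#'
#' One A-scan per generation/detection pair, arrival times taken from a
#' single eikonal ToF matrix computation (or the straight-ray water
#' reference).
#'
#' @inheritParams synthAScan
#' @param factor eikonal refinement factor for the ToF computation.
#' @return list with `scans` (list of [AScan-class], row-major over
#'   generation then detection index) and `tof` (the [ToFMatrix-class] of
#'   true onsets).
#' @export
synthScan <- function(map, geom = arrayGeometry(), pulse = pulseModel(),
                      noise = noiseModel(), seed = NULL, dt = 1e-8,
                      factor = 5L, waterSpeed = 1480) {
  tofm <- if (identical(map, "water"))
    referenceToFMatrix(geom, waterSpeed)
  else computeToFMatrix(map, geom, factor)
  kernel <- pulseKernel(pulse)
  gp <- genPositions(geom); dp <- detPositions(geom)
  withSeed(seed, {
    scans <- vector("list", geom@nGen * geom@nDet)
    idx <- 0L
    for (i in seq_len(geom@nGen)) {
      for (j in seq_len(geom@nDet)) {
        idx <- idx + 1L
        t <- pairTimeBase(gp[i, ], dp[j, ], dt)
        s <- placePulse(t, kernel, tofm@values[i, j])
        if (noise$echoAmp > 0)
          s <- s + placePulse(t, kernel, tofm@values[i, j] + noise$echoDelay,
                              noise$echoAmp)
        if (is.finite(noise$snrDb))
          s <- s + rnorm(length(s), 0, pulse$amplitude / 10^(noise$snrDb / 20))
        scans[[idx]] <- new("AScan", samples = s, dt = dt, t0 = t[1],
                            genIndex = i, detIndex = j)
      }
    }
    list(scans = scans, tof = tofm)
  })
}
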