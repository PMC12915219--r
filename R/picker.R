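# Two-stage time-of-flight picking: zero-phase bandpass, physics-derived
# search window, sliding-window kurtosis onset, then cross-correlation
# against the water reference inside a refined window.

#' Picker configuration
#'
#' @param bandLow,bandHigh bandpass corner frequencies, Hz (1 and 7 MHz).
#' @param vMin,vMax velocity envelope of interest, m/s (1455 and 1538).
#' @param kurtosisWindow sliding-kurtosis window length, seconds (2 us).
#' @param kurtosisThreshold fraction of the peak kurtosis used as the
#'   onset threshold (0.55).
#' @param refinePre,refinePost extent of the refined correlation window
#'   before / after the coarse onset sample, seconds (0.08 / 0.1 us).
#' @param onsetAt where along its window a kurtosis value dates the onset:
#'   `"window_end"` (default; the newest sample entering the window drives
#'   the kurtosis rise, so the trailing edge tracks the pulse onset) or
#'   `"window_start"`.
#' @param waterSpeed reference speed used for the analytic reference ToF.
#' @return list of class `PickerConfig`.
#' @export
pickerConfig <- function(bandLow = 1e6, bandHigh = 7e6, vMin = 1455,
                         vMax = 1538, kurtosisWindow = 2e-6,
                         kurtosisThreshold = 0.55, refinePre = 0.08e-6,
                         refinePost = 0.1e-6,
                         onsetAt = c("window_end", "window_start"),
                         waterSpeed = 1480) {
  onsetAt <- match.arg(onsetAt)
  stopifnot(bandLow > 0, bandLow < bandHigh, vMin < vMax,
            kurtosisThreshold > 0, kurtosisThreshold < 1,
            refinePre + refinePost > 0, kurtosisWindow > 0)
  structure(list(bandLow = bandLow, bandHigh = bandHigh, vMin = vMin,
                 vMax = vMax, kurtosisWindow = kurtosisWindow,
                 kurtosisThreshold = kurtosisThreshold,
                 refinePre = refinePre, refinePost = refinePost,
                 onsetAt = onsetAt, waterSpeed = waterSpeed),
            class = "PickerConfig")
}

#' Zero-phase Butterworth bandpass filter
#'
#' Forward-backward (zero-phase) 4th-order Butterworth bandpass between
#' `bandLow` and `bandHigh`; length and sampling interval are unchanged and
#' the onset position is not biased by group delay.
#'
#' @param scan an [AScan-class].
#' @param config a [pickerConfig()].
#' @return The filtered [AScan-class].
#' @export
bandpass <- function(scan, config = pickerConfig()) {
  stopifnot(is(scan, "AScan"))
  fs <- 1 / scan@dt
  if (config$bandHigh >= fs / 2)
    stop("bandHigh is at or above Nyquist for this sampling rate")
  bf <- signal::butter(4, c(config$bandLow, config$bandHigh) / (fs / 2),
                       type = "pass")
  y <- signal::filtfilt(bf, scan@samples)
  initialize(scan, samples = as.numeric(y))
}

#' Physics-derived admissible arrival window
#'
#' `t_min = distance / vMax`, `t_max = distance / vMin`: the earliest and
#' latest first arrival compatible with the geometry and the velocity
#' envelope.
#'
#' @param genXY,detXY element positions in mm.
#' @param config a [pickerConfig()].
#' @return numeric `c(tMin, tMax)` in seconds.
#' @examples
#' physicsWindow(c(0, -38.7), c(0, 38.7))  # 50.325 us, 53.196 us
#' @export
physicsWindow <- function(genXY, detXY, config = pickerConfig()) {
  d <- sqrt(sum((genXY - detXY)^2)) * 1e-3
  if (d == 0) stop("generation and detection points coincide")
  c(d / config$vMax, d / config$vMin)
}

#' Sliding-window kurtosis trace
#'
#' Population-moment kurtosis of each length-N window of the signal
#' (denominator the squared population variance), stride 1, the window
#' anchored at its leading edge: `kappa[k]` covers samples
#' `k .. k + N - 1`. Zero-variance windows yield `NA` and are excluded from
#' peak search.
#'
#' @param scan an [AScan-class] (or plain numeric vector with `dt`).
#' @param window window length in seconds (default 2 us).
#' @param dt sampling interval if `scan` is a plain vector.
#' @return numeric trace with attribute `"N"` (samples per window).
#' @export
slidingKurtosis <- function(scan, window = 2e-6, dt = NULL) {
  if (is(scan, "AScan")) {
    x <- scan@samples; dt <- scan@dt
  } else {
    x <- as.numeric(scan)
    if (is.null(dt)) stop("dt required for a plain vector")
  }
  N <- as.integer(round(window / dt))
  if (N < 4L) stop("kurtosis window must span at least 4 samples")
  if (N >= length(x)) stop("kurtosis window longer than the signal")
  structure(.sliding_kurtosis(x, N), N = N)
}

#' Coarse kurtosis onset
#'
#' Thresholds the kurtosis trace at `thresholdFraction` of its maximum over
#' the search range and returns the first strict local maximum (3-sample
#' neighbourhood) exceeding it; if no interior local maximum qualifies, the
#' first threshold crossing is returned and flagged.
#'
#' @param kappa kurtosis trace from [slidingKurtosis()].
#' @param thresholdFraction fraction of the in-range maximum (0.55).
#' @param searchRange integer `c(first, last)` indices into `kappa` to
#'   search (default: all).
#' @return list with `k` (index into `kappa`) and `flag`
#'   (`"threshold_crossing"` or `NULL`).
#' @export
coarseOnset <- function(kappa, thresholdFraction = 0.55, searchRange = NULL) {
  if (is.null(searchRange)) searchRange <- c(1L, length(kappa))
  idx <- seq(max(1L, searchRange[1]), min(length(kappa), searchRange[2]))
  kv <- kappa[idx]
  if (all(is.na(kv))) stop("kurtosis trace undefined over the search range")
  thr <- thresholdFraction * max(kv, na.rm = TRUE)
  n <- length(kv)
  isMax <- rep(FALSE, n)
  if (n >= 3) {
    i <- 2:(n - 1)
    isMax[i] <- !is.na(kv[i]) & !is.na(kv[i - 1]) & !is.na(kv[i + 1]) &
      kv[i] > kv[i - 1] & kv[i] > kv[i + 1]
  }
  cand <- which(isMax & kv >= thr)
  if (length(cand))
    return(list(k = idx[cand[1]], flag = NULL))
  cross <- which(!is.na(kv) & kv >= thr)
  if (!length(cross)) stop("no kurtosis value reaches the threshold")
  list(k = idx[cross[1]], flag = "threshold_crossing")
}

#' Refined cross-correlation pick against the water reference
#'
#' Computes the unnormalised cross-correlation `R(m) = sum_j x(j) y(m + j)`
#' (x the detected signal, y the water reference, ends zero-padded),
#' restricted to lags that place the reference onset inside the refined
#' window `[t_k - refinePre, t_k + refinePost]` around the coarse onset
#' sample `k`. The best lag `m*` (positive = later arrival than the
#' reference; ties resolved to the smallest `|m*|` and flagged) gives
#' `tof = referenceTof + m* dt`, with `referenceTof` the analytic
#' straight-ray water time for the pair.
#'
#' @param scan,reference [AScan-class] objects on the same time base (equal
#'   `dt`, `t0` and length); `reference` is the water-only scan of the pair.
#' @param k coarse onset sample index (1-based, on the scan's time base).
#' @param referenceTof reference onset time in seconds.
#' @param config a [pickerConfig()].
#' @param window optional physics window `c(tMin, tMax)` used to clip the
#'   result (clipped results are flagged).
#' @return A [PickResult-class] (kurtosis slots unset).
#' @export
refineAndCorrelate <- function(scan, reference, k, referenceTof,
                               config = pickerConfig(), window = NULL) {
  stopifnot(is(scan, "AScan"), is(reference, "AScan"))
  if (scan@dt != reference@dt)
    stop("signal and reference sampling intervals differ")
  if (abs(scan@t0 - reference@t0) > scan@dt / 100 ||
      length(scan@samples) != length(reference@samples))
    stop("signal and reference must share one time base")
  dt <- scan@dt
  tk <- scan@t0 + (k - 1) * dt
  mLo <- ceiling((tk - config$refinePre - referenceTof) / dt - 1e-9)
  mHi <- floor((tk + config$refinePost - referenceTof) / dt + 1e-9)
  if (mHi < mLo) stop("refined window admits no lag")
  mStar <- mLo:mHi
  # Eq. R(m) with literal lag mhat relates to the arrival shift as
  # mhat = -(shift); evaluate at mhat = -mStar.
  R <- .xcorr_lags(scan@samples, reference@samples, as.integer(-mStar))
  best <- which(R >= max(R) - 1e-12 * max(abs(R)))
  flags <- character(0)
  if (length(best) > 1L) {
    best <- best[which.min(abs(mStar[best]))]
    flags <- c(flags, "lag_tie")
  }
  m <- mStar[best]
  tof <- referenceTof + m * dt
  if (!is.null(window) && (tof < window[1] || tof > window[2])) {
    tof <- min(max(tof, window[1]), window[2])
    flags <- c(flags, "clipped")
  }
  new("PickResult", tof = tof, coarseIndex = as.integer(k),
      kurtosis = numeric(0), kurtosisStart = 1L,
      bestLag = as.integer(m), flags = flags)
}

#' Two-stage time-of-flight pick for one element pair
#'
#' Band-passes signal and reference, restricts attention to the pair's
#' physics window, locates the coarse onset from the sliding-kurtosis trace
#' and refines it by cross-correlation against the water reference.
#'
#' The kurtosis marker of a band-limited pulse sits a pulse-shape-dependent
#' delay after the true (-40 dB envelope) onset. Since signal and reference
#' share one pulse shape, that delay cancels in the difference of their
#' kurtosis markers: the refined window is centred on
#' `referenceTof + (k_signal - k_reference) dt`, i.e. the coarse onset is a
#' differential marker anchored to the analytic reference time, and stage 2
#' then measures the precise lag by cross-correlation inside that window.
#'
#' @inheritParams refineAndCorrelate
#' @param genXY,detXY element positions in mm.
#' @return A [PickResult-class] with all stage outputs populated.
#' @export
pickToF <- function(scan, reference, genXY, detXY, config = pickerConfig()) {
  fs <- bandpass(scan, config)
  fr <- bandpass(reference, config)
  win <- physicsWindow(genXY, detXY, config)
  co <- kurtosisStage(fs, win, config)
  cr <- kurtosisStage(fr, win, config)
  d <- sqrt(sum((genXY - detXY)^2)) * 1e-3
  refTof <- d / config$waterSpeed
  iRef <- round((refTof - fs@t0) / fs@dt) + 1 # reference onset sample
  kCorr <- co$k - cr$k + iRef
  res <- refineAndCorrelate(fs, fr, kCorr, refTof, config, win)
  new("PickResult", tof = res@tof, coarseIndex = as.integer(co$k),
      kurtosis = co$kappa, kurtosisStart = 1L, bestLag = res@bestLag,
      flags = c(co$flags, res@flags))
}

# shared stage-1 logic: kurtosis trace + coarse onset within the physics
# window, honouring the onset-dating convention
kurtosisStage <- function(filtered, win, config) {
  t <- scanTimes(filtered)
  kappa <- slidingKurtosis(filtered, config$kurtosisWindow)
  N <- attr(kappa, "N")
  off <- if (config$onsetAt == "window_end") N - 1L else 0L
  iMin <- which(t >= win[1])[1]
  iMax <- tail(which(t <= win[2]), 1)
  if (is.na(iMin) || !length(iMax))
    stop("physics window outside the sampled trace")
  lo <- max(1L, iMin - off)
  hi <- min(length(kappa), iMax - off)
  if (hi < lo) stop("physics window outside the kurtosis trace")
  co <- coarseOnset(kappa, config$kurtosisThreshold, c(lo, hi))
  list(k = co$k + off, kappa = as.numeric(kappa), flags = co$flag)
}

#' Single-stage pickers (benchmark baselines)
#'
#' `pickKurtosisOnly()` stops after stage 1: the ToF is the time of the
#' coarse kurtosis onset. `pickXcorrOnly()` skips stage 1: the ToF comes
#' from the full-trace argmax of the cross-correlation with the reference,
#' without any windowing.
#'
#' @inheritParams pickToF
#' @return A [PickResult-class].
#' @export
pickKurtosisOnly <- function(scan, reference, genXY, detXY,
                             config = pickerConfig()) {
  fs <- bandpass(scan, config)
  win <- physicsWindow(genXY, detXY, config)
  co <- kurtosisStage(fs, win, config)
  tof <- fs@t0 + (co$k - 1) * fs@dt
  new("PickResult", tof = tof, coarseIndex = as.integer(co$k),
      kurtosis = co$kappa, kurtosisStart = 1L, bestLag = 0L,
      flags = if (is.null(co$flags)) character(0) else co$flags)
}

#' @rdname pickKurtosisOnly
#' @export
pickXcorrOnly <- function(scan, reference, genXY, detXY,
                          config = pickerConfig()) {
  fs <- bandpass(scan, config)
  fr <- bandpass(reference, config)
  d <- sqrt(sum((genXY - detXY)^2)) * 1e-3
  refTof <- d / config$waterSpeed
  L <- length(fs@samples)
  mStar <- (-(L - 1)):(L - 1)
  R <- .xcorr_lags(fs@samples, fr@samples, as.integer(-mStar))
  m <- mStar[which.max(R)]
  new("PickResult", tof = refTof + m * fs@dt, coarseIndex = 1L,
      kurtosis = numeric(0), kurtosisStart = 1L, bestLag = as.integer(m),
      flags = character(0))
}

#' Pick a full ToF matrix from a scan set
#'
#' Applies [pickToF()] to every element pair of a scan list (as produced by
#' [synthScan()]) against the matching water-reference scans.
#'
#' @param scans,references lists of [AScan-class] (row-major over generation
#'   then detection index, as from [synthScan()]).
#' @param geom the [ArrayGeometry-class].
#' @param config a [pickerConfig()].
#' @param viewAngle view label for the assembled matrix.
#' @return list with `tof` (a [ToFMatrix-class]) and `flags` (matrix of
#'   comma-joined flag strings).
#' @export
assembleToFMatrix <- function(scans, references, geom = arrayGeometry(),
                              config = pickerConfig(), viewAngle = 0) {
  gp <- genPositions(geom); dp <- detPositions(geom)
  v <- matrix(NA_real_, geom@nGen, geom@nDet)
  fl <- matrix("", geom@nGen, geom@nDet)
  idx <- 0L
  for (i in seq_len(geom@nGen)) {
    for (j in seq_len(geom@nDet)) {
      idx <- idx + 1L
      p <- pickToF(scans[[idx]], references[[idx]], gp[i, ], dp[j, ], config)
      v[i, j] <- p@tof
      fl[i, j] <- paste(p@flags, collapse = ",")
    }
  }
  list(tof = new("ToFMatrix", values = v, viewAngle = viewAngle,
                 geometry = geom),
       flags = fl)
}
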