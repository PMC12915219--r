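# ToF normalisation, two-view block-diagonal stacking with zero padding,
# and ToF difference matrices.

#' Normalise ToF matrices to unity
#'
#' Divides every matrix by a single dataset-wide constant so entries lie in
#' (0, 1]. With `constant = "auto"` the constant is geometry-derived:
#' the longest element-pair distance divided by the smallest velocity of
#' interest, `sqrt(sep^2 + aperture^2) / vMin` (57.052 us for the default
#' 77.4 mm / 30 mm geometry at 1455 m/s), which makes the scale invertible
#' and identical at training and inference time without rescanning any
#' dataset.
#'
#' @param matrices a [ToFMatrix-class] or list of them (all entries > 0).
#' @param constant seconds, or `"auto"`.
#' @param vMin smallest velocity of interest (m/s), used by `"auto"`.
#' @return list with `matrices` (normalised, plain numeric matrices carrying
#'   the view angle as attribute `"viewAngle"`) and `constant` (seconds).
#' @export
normaliseToFs <- function(matrices, constant = "auto", vMin = 1455) {
  if (is(matrices, "ToFMatrix")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1L, all(vapply(matrices, is, TRUE, "ToFMatrix")))
  for (m in matrices)
    if (any(m@values <= 0)) stop("ToF entries must be strictly positive")
  if (identical(constant, "auto")) {
    geom <- matrices[[1]]@geometry
    diag_mm <- sqrt(geom@plateSeparation^2 +
                      (apertureWidth(geom) + (geom@nDet - geom@nGen) *
                         geom@pitch / 2)^2)
    constant <- diag_mm * 1e-3 / vMin
  }
  stopifnot(is.numeric(constant), constant > 0)
  out <- lapply(matrices, function(m) {
    v <- m@values / constant
    attr(v, "viewAngle") <- m@viewAngle
    v
  })
  list(matrices = out, constant = constant)
}

#' Invert the ToF normalisation
#'
#' @param values normalised numeric matrix.
#' @param constant the normalisation constant (seconds).
#' @param geom geometry to attach to the result.
#' @param viewAngle view angle of the result (taken from the matrix attribute
#'   if present).
#' @return A [ToFMatrix-class] in seconds.
#' @export
denormaliseToFs <- function(values, constant, geom = arrayGeometry(),
                            viewAngle = NULL) {
  if (is.null(viewAngle))
    viewAngle <- if (!is.null(attr(values, "viewAngle")))
      attr(values, "viewAngle") else 0
  v <- unclass(values)
  attr(v, "viewAngle") <- NULL
  new("ToFMatrix", values = v * constant, viewAngle = viewAngle,
      geometry = geom)
}

#' Stack two normalised views into the block-diagonal network input
#'
#' Concatenates the two 16 x 16 views as `[T1 0; 0 T2]` into a 32 x 32
#' matrix (`0` a 16 x 16 zero block) and zero-pads it into a `frame x frame`
#' image, anchored at the top-left corner.
#'
#' @param t1,t2 normalised view matrices (plain matrices from
#'   [normaliseToFs()], entries in \[0, 1\]) or [ToFMatrix-class] objects
#'   together with `constant` to normalise on the fly.
#' @param constant normalisation constant in seconds (stored; also applied
#'   if `t1`/`t2` are un-normalised [ToFMatrix-class] objects).
#' @param frame side of the zero-padded frame (default 128).
#' @return An object of class `StackedInput`: list with `values` (the
#'   block-diagonal matrix), `padded` (frame x frame), `constant`, `blockSize`.
#' @export
stackViews <- function(t1, t2, constant, frame = 128L) {
  if (is(t1, "ToFMatrix")) t1 <- t1@values / constant
  if (is(t2, "ToFMatrix")) t2 <- t2@values / constant
  t1 <- unclass(t1); t2 <- unclass(t2)
  attr(t1, "viewAngle") <- NULL; attr(t2, "viewAngle") <- NULL
  if (!all(dim(t1) == dim(t2))) stop("the two views must have equal shape")
  if (min(t1) < 0 || max(t1) > 1 || min(t2) < 0 || max(t2) > 1)
    stop("stacked views must be normalised to [0, 1]")
  b <- nrow(t1)
  s <- matrix(0, 2 * b, 2 * b)
  s[seq_len(b), seq_len(b)] <- t1
  s[b + seq_len(b), b + seq_len(b)] <- t2
  if (frame < 2 * b) stop("frame smaller than the stacked block")
  padded <- matrix(0, frame, frame)
  padded[seq_len(2 * b), seq_len(2 * b)] <- s
  structure(list(values = s, padded = padded, constant = constant,
                 blockSize = b),
            class = "StackedInput")
}

#' @describeIn stackViews Recover the two views (normalised) from a stack.
#' @param stack a `StackedInput`.
#' @export
unstackViews <- function(stack) {
  stopifnot(inherits(stack, "StackedInput"))
  b <- stack$blockSize
  list(t1 = stack$values[seq_len(b), seq_len(b)],
       t2 = stack$values[b + seq_len(b), b + seq_len(b)])
}

#' @export
print.StackedInput <- function(x, ...) {
  cat(sprintf(
    "StackedInput: %d x %d block-diagonal in a %d x %d frame, constant %.3f us\n",
    nrow(x$values), ncol(x$values), nrow(x$padded), ncol(x$padded),
    x$constant * 1e6))
  invisible(x)
}

#' ToF difference matrix (water minus phantom)
#'
#' Elementwise `tWater - tPhantom`; all-zero when the phantom matrix equals
#' the water-only matrix, negative along paths slowed by gel.
#'
#' @param tWater,tPhantom [ToFMatrix-class] objects for the same geometry and
#'   view.
#' @return A [ToFMatrix-class] holding the differences (seconds).
#' @export
tofDifference <- function(tWater, tPhantom) {
  stopifnot(is(tWater, "ToFMatrix"), is(tPhantom, "ToFMatrix"))
  if (!all(dim(tWater@values) == dim(tPhantom@values)))
    stop("ToF matrices must have equal shape")
  if (tWater@viewAngle != tPhantom@viewAngle)
    stop("ToF matrices must share the view angle")
  new("ToFMatrix", values = tWater@values - tPhantom@values,
      viewAngle = tWater@viewAngle, geometry = tWater@geometry)
}
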