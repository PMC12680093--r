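#' Batched 5-axis volume tensors
#'
#' All neural operations in this package act on `Volume5D` objects: plain
#' numeric arrays with `dim = c(batch, channels, depth, height, width)`.
#' `as_volume5d()` validates (and if needed promotes) an array to that
#' contract; `volume_dim()` returns the five axis sizes.
#'
#' @param x A numeric array. 3-D arrays `(D, H, W)` are promoted to a single
#'   batch/channel; 4-D arrays `(C, D, H, W)` to a single batch.
#' @return A numeric array with five dimensions.
#' @examples
#' v <- as_volume5d(array(rnorm(2 * 3 * 4), c(2, 3, 4)))
#' volume_dim(v)
#' @export
as_volume5d <- function(x) {
  if (!is.numeric(x)) stop("Volume5D must be numeric", call. = FALSE)
  d <- dim(x)
  if (is.null(d)) stop("Volume5D must be an array", call. = FALSE)
  if (length(d) == 3L) dim(x) <- c(1L, 1L, d)
  else if (length(d) == 4L) dim(x) <- c(1L, d)
  else if (length(d) != 5L)
    stop("Volume5D must have 3, 4 or 5 dimensions, got ", length(d),
         call. = FALSE)
  if (any(dim(x) < 1L)) stop("all Volume5D axes must be >= 1", call. = FALSE)
  x
}

#' @rdname as_volume5d
#' @export
volume_dim <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 5L)
    stop("not a Volume5D (need 5 dimensions)", call. = FALSE)
  c(batch = d[1], channels = d[2], depth = d[3], height = d[4], width = d[5])
}

#' Lossless space-to-depth downsampling (pixel unshuffle) and its inverse
#'
#' `pixel_unshuffle()` rearranges each depth slice of a volume so that every
#' `r x r` spatial block becomes `r^2` channels: the output has shape
#' `(B, C * r^2, D, H/r, W/r)` and is a pure index permutation of the input —
#' no value is altered or discarded, which is what makes the downsampling
#' lossless. `pixel_shuffle()` is the exact inverse.
#'
#' The polyphase channel ordering is row-major over the in-block offsets:
#' `out[b, c*r^2 + dh*r + dw, d, i, j] = in[b, c, d, i*r + dh, j*r + dw]`
#' (0-based indices).
#'
#' @param v A `Volume5D` array `(B, C, D, H, W)`.
#' @param r Integer downsampling factor; `H` and `W` must be divisible by `r`
#'   for `pixel_unshuffle()`, and `C` by `r^2` for `pixel_shuffle()`.
#' @return A `Volume5D` array.
#' @examples
#' x <- as_volume5d(array(1:16, c(1, 1, 1, 4, 4)))
#' y <- pixel_unshuffle(x, 2)
#' dim(y)
#' all(pixel_shuffle(y, 2) == x)
#' @export
pixel_unshuffle <- function(v, r = 2L) {
  v <- as_volume5d(v)
  r <- as.integer(r)
  if (r < 1L) stop("r must be >= 1", call. = FALSE)
  d <- dim(v)
  B <- d[1]; C <- d[2]; D <- d[3]; H <- d[4]; W <- d[5]
  if (H %% r != 0L || W %% r != 0L)
    stop("pixel_unshuffle: H (", H, ") and W (", W,
         ") must be divisible by r = ", r, call. = FALSE)
  if (r == 1L) return(v)
  Ho <- H %/% r; Wo <- W %/% r
  # h = dh + r*i, w = dw + r*j  (column-major sub-axis factorisation)
  dim(v) <- c(B, C, D, r, Ho, r, Wo)
  out <- aperm(v, c(1L, 6L, 4L, 2L, 3L, 5L, 7L))  # b, dw, dh, c, d, i, j
  dim(out) <- c(B, C * r * r, D, Ho, Wo)
  out
}

#' @rdname pixel_unshuffle
#' @export
pixel_shuffle <- function(v, r = 2L) {
  v <- as_volume5d(v)
  r <- as.integer(r)
  if (r < 1L) stop("r must be >= 1", call. = FALSE)
  d <- dim(v)
  B <- d[1]; Cr <- d[2]; D <- d[3]; Ho <- d[4]; Wo <- d[5]
  if (Cr %% (r * r) != 0L)
    stop("pixel_shuffle: channel count (", Cr,
         ") must be divisible by r^2 = ", r * r, call. = FALSE)
  if (r == 1L) return(v)
  C <- Cr %/% (r * r)
  dim(v) <- c(B, r, r, C, D, Ho, Wo)              # b, dw, dh, c, d, i, j
  out <- aperm(v, c(1L, 4L, 5L, 3L, 6L, 2L, 7L))  # b, c, d, dh, i, dw, j
  dim(out) <- c(B, C, D, r * Ho, r * Wo)
  out
}
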