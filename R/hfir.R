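#' High-frequency information retention (HFIR) downsampling block
#'
#' A learnable block that halves the in-plane resolution of a single-channel
#' volume without discarding information. Two per-slice 3x3 convolutions first
#' lift the input to `C` shallow feature channels and then compress them to
#' `C / r^2`; a pixel unshuffle then trades an `r x r` spatial block for `r^2`
#' channels, so the output has `C` channels at half the height and width
#' (for `r = 2`) while every value of the compressed feature map is retained
#' exactly. Used to bring a 512x512 T2 grid down onto the 256x256 DWI grid.
#'
#' Both convolutions act per depth slice (kernel `1 x 3 x 3`); no
#' nonlinearity is inserted between them (`activation = "none"`), keeping the
#' block a linear map followed by a permutation. Set `activation = "relu"` to
#' rectify between the two convolutions.
#'
#' @param C Shallow channel width; must be divisible by `r^2`. Default 16.
#' @param r Unshuffle factor (spatial halving for `r = 2`).
#' @param activation `"none"` (default) or `"relu"`.
#' @return `hfir_params()` returns a parameter list; `hfir_forward()` returns
#'   a `Volume5D` of shape `(B, C, D, H/r, W/r)`.
#' @examples
#' p <- hfir_params(C = 8, r = 2)
#' y <- hfir_forward(array(rnorm(1 * 1 * 2 * 8 * 8), c(1, 1, 2, 8, 8)), p)
#' dim(y)
#' @export
hfir_params <- function(C = 16L, r = 2L, activation = c("none", "relu")) {
  C <- as.integer(C); r <- as.integer(r)
  activation <- match.arg(activation)
  if (r < 1L) stop("r must be >= 1", call. = FALSE)
  if (C %% (r * r) != 0L)
    stop("C (", C, ") must be divisible by r^2 = ", r * r, call. = FALSE)
  structure(list(
    C = C, r = r, activation = activation,
    conv_a = nn_conv3d(1L, C, kernel = c(1L, 3L, 3L), pad = c(0L, 1L, 1L)),
    conv_b = nn_conv3d(C, C %/% (r * r), kernel = c(1L, 3L, 3L),
                       pad = c(0L, 1L, 1L))
  ), class = "hfir_params")
}

#' @param x A `Volume5D` with one channel; `H` and `W` divisible by `r`.
#' @param params An `hfir_params` object.
#' @rdname hfir_params
#' @export
hfir_forward <- function(x, params) {
  hfir_fwd(params, as_volume5d(x))$out
}

hfir_fwd <- function(params, x) {
  d <- dim(x)
  if (d[2] != 1L)
    stop("HFIR expects a single-channel input, got ", d[2], " channels",
         call. = FALSE)
  if (d[4] %% params$r != 0L || d[5] %% params$r != 0L)
    stop("HFIR: H and W must be divisible by r = ", params$r, call. = FALSE)
  a <- conv3d_fwd(params$conv_a, x)
  h <- a$out
  rc <- NULL
  if (params$activation == "relu") {
    rr <- relu_fwd(h)
    h <- rr$out
    rc <- rr$cache
  }
  b <- conv3d_fwd(params$conv_b, h)
  out <- pixel_unshuffle(b$out, params$r)
  list(out = out,
       cache = list(a = a$cache, relu = rc, b = b$cache, r = params$r))
}

# need_dx = FALSE by default: in the assembled model the block input is raw
# data, so its gradient is never consumed.
hfir_bwd <- function(params, dout, cache, need_dx = FALSE) {
  db <- pixel_shuffle(dout, cache$r)
  gb <- conv3d_bwd(params$conv_b, db, cache$b)
  dh <- gb$dx
  if (!is.null(cache$relu)) dh <- relu_bwd(dh, cache$relu)
  ga <- conv3d_bwd(params$conv_a, dh, cache$a, need_dx = need_dx)
  list(dx = ga$dx, grads = list(conv_a = ga$grads, conv_b = gb$grads))
}
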