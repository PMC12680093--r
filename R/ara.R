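#' Region-token flattening of a feature map
#'
#' Reshapes a `(B, C, D, H, W)` feature map into a sequence of region tokens,
#' one `C`-vector per spatial position. The token index runs depth-fastest,
#' then rows, then columns, and the layout is exactly invertible:
#' `unflatten_regions(flatten_regions(f), dim(f)[3:5])` restores the map.
#' The depth axis participates in the token set (the only lossless
#' flattening of a 3-D map); for the default branch geometry a
#' `(1, 512, 4, 8, 8)` map becomes a `256 x 512` sequence.
#'
#' @param f A `Volume5D` feature map.
#' @return For a single-sample map, a `(PWH x C)` matrix; for a batch,
#'   a `(B, PWH, C)` array.
#' @examples
#' f <- array(rnorm(1 * 3 * 2 * 2 * 2), c(1, 3, 2, 2, 2))
#' s <- flatten_regions(f)
#' dim(s)
#' all(unflatten_regions(s, c(2, 2, 2)) == f)
#' @export
flatten_regions <- function(f) {
  f <- as_volume5d(f)
  d <- dim(f)
  s <- aperm(f, c(1L, 3L, 4L, 5L, 2L))
  dim(s) <- c(d[1], d[3] * d[4] * d[5], d[2])
  if (d[1] == 1L) {
    dim(s) <- dim(s)[2:3]
  }
  s
}

#' @param s A region sequence: `(PWH x C)` matrix or `(B, PWH, C)` array.
#' @param dhw Integer vector `(D, H, W)` of the target grid;
#'   `prod(dhw)` must equal the token count.
#' @rdname flatten_regions
#' @export
unflatten_regions <- function(s, dhw) {
  if (length(dim(s)) == 2L) dim(s) <- c(1L, dim(s))
  d <- dim(s)
  dhw <- as.integer(dhw)
  if (length(dhw) != 3L || prod(dhw) != d[2])
    stop("target grid (", paste(dhw, collapse = "x"),
         ") is inconsistent with ", d[2], " tokens", call. = FALSE)
  dim(s) <- c(d[1], dhw, d[3])
  aperm(s, c(1L, 5L, 2L, 3L, 4L))
}

#' Adaptive region attention (ARA) parameters
#'
#' The ARA gate scores every region token of the concatenated T2/DWI feature
#' sequence through a two-layer bottleneck applied identically to each token:
#' `Gamma = sigmoid( relu(f Phi1 + b1) Phi2 + b2 )` with
#' `Phi1 (2C x C/2)`, `Phi2 (C/2 x 2C)` — a 4x bottleneck that forces the
#' gate to keep only the most informative cross-modal evidence. The first
#' `C` score columns gate the T2 tokens, the last `C` the DWI tokens, and a
#' residual skip keeps the gated output between 1x and 2x the input.
#'
#' @param C Channel count of each branch's token vectors (512 for the
#'   default backbone); must be even.
#' @return An `ara_params` list with `phi1`, `b1`, `phi2`, `b2`.
#' @export
ara_params <- function(C) {
  C <- as.integer(C)
  if (C < 2L || C %% 2L != 0L) stop("C must be even and >= 2", call. = FALSE)
  bott <- C %/% 2L
  structure(list(
    C = C,
    phi1 = matrix(stats::rnorm(2L * C * bott, sd = kaiming_sd(2 * C)),
                  nrow = 2L * C),
    b1 = numeric(bott),
    phi2 = matrix(stats::rnorm(bott * 2L * C, sd = kaiming_sd(bott)),
                  nrow = bott),
    b2 = numeric(2L * C)
  ), class = "ara_params")
}

#' Cross-modal attention gating of two region sequences
#'
#' Applies the ARA gate to paired T2 and DWI region sequences: tokens are
#' concatenated channel-wise, scored elementwise in `(0, 1)` through the
#' bottleneck described in [ara_params()], and each branch is re-weighted
#' with a residual skip, `alpha_m = Gamma_m * f_m + f_m`. Shapes are
#' preserved; with all parameters zero every score is `sigmoid(0) = 0.5`, so
#' both outputs equal exactly `1.5 *` their inputs.
#'
#' @param fT2,fDWI Region sequences of identical shape (`(PWH x C)` matrix
#'   or `(B, PWH, C)` array), e.g. from [flatten_regions()].
#' @param params An [ara_params()] object with matching `C`.
#' @return A list with elements `t2` and `dwi`, the gated sequences.
#' @export
ara_gate <- function(fT2, fDWI, params) {
  r <- ara_fwd(params, fT2, fDWI)
  list(t2 = r$aT2, dwi = r$aDWI)
}

ara_check_pair <- function(fT2, fDWI, C) {
  to3 <- function(x) {
    if (is.null(dim(x))) stop("region sequences must have dim", call. = FALSE)
    if (length(dim(x)) == 2L) dim(x) <- c(1L, dim(x))
    x
  }
  fT2 <- to3(fT2); fDWI <- to3(fDWI)
  if (!identical(dim(fT2), dim(fDWI)))
    stop("fT2 and fDWI must share (PWH, C): got ",
         paste(dim(fT2), collapse = "x"), " vs ",
         paste(dim(fDWI), collapse = "x"), call. = FALSE)
  if (dim(fT2)[3] != C)
    stop("sequences have C = ", dim(fT2)[3], ", params expect C = ", C,
         call. = FALSE)
  list(fT2 = fT2, fDWI = fDWI)
}

ara_fwd <- function(params, fT2, fDWI) {
  two_d <- length(dim(fT2)) == 2L && length(dim(fDWI)) == 2L
  pr <- ara_check_pair(fT2, fDWI, params$C)
  d <- dim(pr$fT2)                      # (B, P, C)
  B <- d[1]; P <- d[2]; C <- d[3]
  M <- cbind(matrix(pr$fT2, B * P, C), matrix(pr$fDWI, B * P, C))
  h_pre <- sweep(M %*% params$phi1, 2L, params$b1, "+")
  mask <- h_pre > 0
  h <- h_pre * mask
  g_pre <- sweep(h %*% params$phi2, 2L, params$b2, "+")
  G <- sigmoid(g_pre)
  iT2 <- seq_len(C); iDWI <- C + seq_len(C)
  aT2 <- (1 + G[, iT2, drop = FALSE]) * M[, iT2, drop = FALSE]
  aDWI <- (1 + G[, iDWI, drop = FALSE]) * M[, iDWI, drop = FALSE]
  shape <- if (two_d) c(P, C) else c(B, P, C)
  dim(aT2) <- shape; dim(aDWI) <- shape
  list(aT2 = aT2, aDWI = aDWI,
       cache = list(M = M, mask = mask, h = h, G = G, B = B, P = P, C = C,
                    two_d = two_d))
}

ara_bwd <- function(params, daT2, daDWI, cache) {
  C <- cache$C; n <- cache$B * cache$P
  daT2 <- matrix(daT2, n, C); daDWI <- matrix(daDWI, n, C)
  iT2 <- seq_len(C); iDWI <- C + seq_len(C)
  G <- cache$G; M <- cache$M
  dG <- cbind(daT2 * M[, iT2], daDWI * M[, iDWI]) * G * (1 - G)
  dphi2 <- t(cache$h) %*% dG
  db2 <- colSums(dG)
  dh <- (dG %*% t(params$phi2)) * cache$mask
  dphi1 <- t(M) %*% dh
  db1 <- colSums(dh)
  dM <- dh %*% t(params$phi1)
  dM[, iT2] <- dM[, iT2] + daT2 * (1 + G[, iT2])
  dM[, iDWI] <- dM[, iDWI] + daDWI * (1 + G[, iDWI])
  shape <- if (cache$two_d) c(cache$P, C) else c(cache$B, cache$P, C)
  dfT2 <- dM[, iT2]; dfDWI <- dM[, iDWI]
  dim(dfT2) <- shape; dim(dfDWI) <- shape
  list(dfT2 = dfT2, dfDWI = dfDWI,
       grads = list(phi1 = dphi1, b1 = db1, phi2 = dphi2, b2 = db2))
}

#' Fuse two attended region sequences back into a feature map
#'
#' Concatenates the gated T2 and DWI sequences channel-wise and restores the
#' spatial layout, producing the `(B, 2C, D4, H4, W4)` map consumed by the
#' classification head.
#'
#' @param aT2,aDWI Gated region sequences of identical shape.
#' @param target_shape Integer `(D, H, W)` grid of the source feature map.
#' @return A `Volume5D` with `2C` channels.
#' @export
fuse_attended <- function(aT2, aDWI, target_shape) {
  to3 <- function(x) { if (length(dim(x)) == 2L) dim(x) <- c(1L, dim(x)); x }
  aT2 <- to3(aT2); aDWI <- to3(aDWI)
  if (!identical(dim(aT2), dim(aDWI)))
    stop("attended sequences must share (PWH, C)", call. = FALSE)
  d <- dim(aT2)
  fused <- array(0, c(d[1], d[2], 2L * d[3]))
  fused[, , seq_len(d[3])] <- aT2
  fused[, , d[3] + seq_len(d[3])] <- aDWI
  unflatten_regions(fused, target_shape)
}
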