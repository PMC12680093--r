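#' Stride/width plan for a 3D ResNet-18 branch
#'
#' Describes the stem, pooling and per-stage stride geometry of one
#' feature-extraction branch. The default plan takes an `(18, 256, 256)`
#' volume to a final-stage ("layer 4") feature map of shape
#' `(512, 4, 8, 8)`: the stem and pool each halve H and W, stages 2-4 halve
#' them again, and depth is reduced 18 -> 9 -> 4 by stage-3/stage-4 depth
#' strides (stage 3 with depth padding 1, stage 4 with depth padding 0 — the
#' small-integer plan that lands exactly on depth 4).
#'
#' @param in_channels Number of input channels (3 for a stacked-b-value DWI
#'   branch, `C` for an HFIR-processed T2 branch).
#' @param width_multiplier Scales the stage widths `(64, 128, 256, 512)`;
#'   the reduced-width phantom preset uses `1/16`. Must yield integer widths.
#' @param preset `"full"` (default geometry above) or `"tiny"`, a gentler
#'   plan for `(8, 64, 64)` phantom grids (stem stride 1, stage-4 depth
#'   padding 1) whose final stage is `(2, 4, 4)`.
#' @return A `backbone_plan` list with elements `stem`, `pool`, `stages`.
#' @examples
#' plan <- backbone_plan(3)
#' shape_plan(c(18, 256, 256), plan)
#' @export
backbone_plan <- function(in_channels, width_multiplier = 1,
                          preset = c("full", "tiny")) {
  preset <- match.arg(preset)
  widths <- c(64L, 128L, 256L, 512L) * width_multiplier
  if (any(widths != as.integer(widths)) || any(widths < 1))
    stop("width_multiplier must give positive integer stage widths",
         call. = FALSE)
  widths <- as.integer(widths)
  if (preset == "full") {
    stem <- list(kernel = c(3L, 7L, 7L), stride = c(1L, 2L, 2L),
                 pad = c(1L, 3L, 3L))
    pool <- list(kernel = c(1L, 3L, 3L), stride = c(1L, 2L, 2L),
                 pad = c(0L, 1L, 1L))
    stage_strides <- list(c(1L, 1L, 1L), c(1L, 2L, 2L), c(2L, 2L, 2L),
                          c(2L, 2L, 2L))
    stage_pad_d <- c(1L, 1L, 1L, 0L)
  } else {
    # gentler geometry for small phantom grids: halve in-plane at the stem
    # and stages 2-3 only, halve depth at stage 4 — an (8, 64, 64) input
    # lands on a (4, 8, 8) final stage, the same 256-token region grid as
    # the full geometry, keeping Grad-CAM usefully resolved
    stem <- list(kernel = c(3L, 3L, 3L), stride = c(1L, 2L, 2L),
                 pad = c(1L, 1L, 1L))
    pool <- list(kernel = c(1L, 3L, 3L), stride = c(1L, 1L, 1L),
                 pad = c(0L, 1L, 1L))
    stage_strides <- list(c(1L, 1L, 1L), c(1L, 2L, 2L), c(1L, 2L, 2L),
                          c(2L, 1L, 1L))
    stage_pad_d <- c(1L, 1L, 1L, 1L)
  }
  stages <- lapply(1:4, function(i) {
    list(width = widths[i], blocks = 2L, stride = stage_strides[[i]],
         pad = c(stage_pad_d[i], 1L, 1L))
  })
  structure(list(
    in_channels = as.integer(in_channels),
    widths = widths,
    preset = preset,
    stem = stem,
    pool = pool,
    stages = stages
  ), class = "backbone_plan")
}

conv_out_size <- function(n, k, s, p) {
  o <- (n + 2 * p - k) %/% s + 1
  if (any(o < 1))
    stop("stride plan produces an axis of size < 1 (input too small)",
         call. = FALSE)
  o
}

#' Per-stage output shapes of a backbone plan
#'
#' Pure integer bookkeeping: applies
#' `out = floor((in + 2*pad - kernel) / stride) + 1` stage by stage along
#' each of depth, height and width, so the geometry of a plan can be checked
#' without building (or running) the network.
#'
#' @param input_shape Integer vector `(depth, height, width)`.
#' @param plan A [backbone_plan()].
#' @return An integer matrix, one row per stage (`stem`, `pool`,
#'   `stage1`..`stage4`), columns `depth`, `height`, `width`.
#' @export
shape_plan <- function(input_shape, plan) {
  s <- as.integer(input_shape)
  if (length(s) != 3L) stop("input_shape must be (depth, height, width)",
                            call. = FALSE)
  rows <- list()
  s <- conv_out_size(s, plan$stem$kernel, plan$stem$stride, plan$stem$pad)
  rows$stem <- s
  s <- conv_out_size(s, plan$pool$kernel, plan$pool$stride, plan$pool$pad)
  rows$pool <- s
  for (i in seq_along(plan$stages)) {
    st <- plan$stages[[i]]
    s <- conv_out_size(s, c(3L, 3L, 3L), st$stride, st$pad)
    rows[[paste0("stage", i)]] <- s
  }
  out <- do.call(rbind, rows)
  colnames(out) <- c("depth", "height", "width")
  out
}

# Projection shortcut geometry: along axes with pad 1 the usual 1x1 kernel
# (pad 0) gives the same output size as the padded 3-kernel main path; along
# a pad-0 axis it would not, so the shortcut uses kernel 3 there.
shortcut_geometry <- function(stride, pad) {
  kernel <- ifelse(pad == 0L & stride > 1L, 3L, 1L)
  list(kernel = kernel, pad = c(0L, 0L, 0L))
}

new_basic_block <- function(in_channels, width, stride, pad) {
  reduce <- any(stride != 1L) || in_channels != width
  proj <- NULL
  proj_bn <- NULL
  if (reduce) {
    g <- shortcut_geometry(stride, pad)
    proj <- nn_conv3d(in_channels, width, kernel = g$kernel, stride = stride,
                      pad = g$pad, bias = FALSE)
    proj_bn <- nn_bn3d(width)
  }
  list(conv1 = nn_conv3d(in_channels, width, kernel = 3L, stride = stride,
                         pad = pad, bias = FALSE),
       bn1 = nn_bn3d(width),
       conv2 = nn_conv3d(width, width, kernel = 3L, pad = c(1L, 1L, 1L),
                         bias = FALSE),
       bn2 = nn_bn3d(width),
       proj = proj, proj_bn = proj_bn)
}

#' Build a randomly initialized 3D ResNet-18 branch
#'
#' Basic-block residual network (two 3x3x3 convolutions per block, batch
#' normalization, identity or projection shortcuts) following the stage plan.
#' Weights are Kaiming-initialized from `seed`; there is no pretrained-weight
#' import — the network is always trained from scratch.
#'
#' @param plan A [backbone_plan()].
#' @param seed Integer seed for the weight initialization.
#' @return A `backbone` object (nested parameter list).
#' @export
build_backbone <- function(plan, seed = 1L) {
  with_local_seed(seed, {
    stem <- nn_conv3d(plan$in_channels, plan$widths[1],
                      kernel = plan$stem$kernel, stride = plan$stem$stride,
                      pad = plan$stem$pad, bias = FALSE)
    stem_bn <- nn_bn3d(plan$widths[1])
    stages <- list()
    in_ch <- plan$widths[1]
    for (i in seq_along(plan$stages)) {
      st <- plan$stages[[i]]
      blocks <- list()
      for (j in seq_len(st$blocks)) {
        if (j == 1L) {
          blocks[[j]] <- new_basic_block(in_ch, st$width, st$stride, st$pad)
        } else {
          blocks[[j]] <- new_basic_block(st$width, st$width, c(1L, 1L, 1L),
                                         c(1L, 1L, 1L))
        }
      }
      stages[[i]] <- blocks
      in_ch <- st$width
    }
    structure(list(plan = plan, stem = stem, stem_bn = stem_bn,
                   pool = nn_maxpool3d(plan$pool$kernel, plan$pool$stride,
                                       plan$pool$pad),
                   stages = stages),
              class = "backbone")
  })
}

block_fwd <- function(blk, x, train, norm_mode) {
  c1 <- conv3d_fwd(blk$conv1, x)
  b1 <- bn3d_fwd(blk$bn1, c1$out, train, norm_mode)
  r1 <- relu_fwd(b1$out)
  c2 <- conv3d_fwd(blk$conv2, r1$out)
  b2 <- bn3d_fwd(blk$bn2, c2$out, train, norm_mode)
  if (is.null(blk$proj)) {
    idn <- x
    pc <- NULL; pb <- NULL
  } else {
    p <- conv3d_fwd(blk$proj, x)
    pbn <- bn3d_fwd(blk$proj_bn, p$out, train, norm_mode)
    idn <- pbn$out
    pc <- p$cache; pb <- pbn$cache
  }
  r2 <- relu_fwd(b2$out + idn)
  list(out = r2$out,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, proj = pc, proj_bn = pb,
                    r2 = r2$cache))
}

block_bwd <- function(blk, dout, cache) {
  dsum <- relu_bwd(dout, cache$r2)
  g2 <- bn3d_bwd(blk$bn2, dsum, cache$b2)
  gc2 <- conv3d_bwd(blk$conv2, g2$dx, cache$c2)
  dr1 <- relu_bwd(gc2$dx, cache$r1)
  g1 <- bn3d_bwd(blk$bn1, dr1, cache$b1)
  gc1 <- conv3d_bwd(blk$conv1, g1$dx, cache$c1)
  grads <- list(conv1 = gc1$grads, bn1 = g1$grads, conv2 = gc2$grads,
                bn2 = g2$grads)
  if (is.null(blk$proj)) {
    dx <- gc1$dx + dsum
  } else {
    gpb <- bn3d_bwd(blk$proj_bn, dsum, cache$proj_bn)
    gp <- conv3d_bwd(blk$proj, gpb$dx, cache$proj)
    grads$proj <- gp$grads
    grads$proj_bn <- gpb$grads
    dx <- gc1$dx + gp$dx
  }
  list(dx = dx, grads = grads)
}

backbone_fwd <- function(bb, x, train = FALSE, norm_mode = "batch") {
  d <- dim(x)
  if (d[2] != bb$plan$in_channels)
    stop("backbone expects ", bb$plan$in_channels, " input channels, got ",
         d[2], call. = FALSE)
  s <- conv3d_fwd(bb$stem, x)
  sb <- bn3d_fwd(bb$stem_bn, s$out, train, norm_mode)
  sr <- relu_fwd(sb$out)
  p <- maxpool3d_fwd(bb$pool, sr$out)
  h <- p$out
  stage_caches <- list()
  for (i in seq_along(bb$stages)) {
    blk_caches <- list()
    for (j in seq_along(bb$stages[[i]])) {
      r <- block_fwd(bb$stages[[i]][[j]], h, train, norm_mode)
      h <- r$out
      blk_caches[[j]] <- r$cache
    }
    stage_caches[[i]] <- blk_caches
  }
  list(out = h,
       cache = list(stem = s$cache, stem_bn = sb$cache, stem_relu = sr$cache,
                    pool = p$cache, stages = stage_caches))
}

backbone_bwd <- function(bb, dout, cache, need_dx = TRUE) {
  grads <- list(stages = vector("list", length(bb$stages)))
  dh <- dout
  for (i in rev(seq_along(bb$stages))) {
    blk_grads <- vector("list", length(bb$stages[[i]]))
    for (j in rev(seq_along(bb$stages[[i]]))) {
      r <- block_bwd(bb$stages[[i]][[j]], dh, cache$stages[[i]][[j]])
      dh <- r$dx
      blk_grads[[j]] <- r$grads
    }
    grads$stages[[i]] <- blk_grads
  }
  dp <- maxpool3d_bwd(dh, cache$pool)
  dsr <- relu_bwd(dp, cache$stem_relu)
  gsb <- bn3d_bwd(bb$stem_bn, dsr, cache$stem_bn)
  gs <- conv3d_bwd(bb$stem, gsb$dx, cache$stem, need_dx = need_dx)
  grads$stem <- gs$grads
  grads$stem_bn <- gsb$grads
  list(dx = gs$dx, grads = grads)
}

#' Final-stage ("layer 4") feature map of a backbone
#'
#' Runs an eval-mode forward pass and returns the activation of the last
#' residual stage: `(B, 512, 4, 8, 8)` for the default plan on an
#' `(18, 256, 256)` input. The channel count equals the plan's final stage
#' width regardless of input size.
#'
#' @param backbone A [build_backbone()] object.
#' @param v A `Volume5D` whose channel count matches the plan.
#' @return A `Volume5D` feature map.
#' @export
extract_layer4 <- function(backbone, v) {
  backbone_fwd(backbone, as_volume5d(v), train = FALSE)$out
}

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
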