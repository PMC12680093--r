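#' Configuration of the full classification network
#'
#' Assembles the architecture choices for one model: which blocks are
#' instantiated (`variant`), the input geometry (`preset`), the HFIR shallow
#' width, the backbone width multiplier, dropout probability of the head and
#' the normalization mode of the residual branches.
#'
#' Variants mirror the ablation lattice:
#' \describe{
#'   \item{`dwi_only`}{3-channel stacked-b-value DWI into one backbone.}
#'   \item{`t2_only`}{raw single-channel T2 into one backbone (no HFIR).}
#'   \item{`t2_hfir_only`}{HFIR-downsampled T2 into one backbone.}
#'   \item{`concat_no_ara`}{both branches, channel concatenation, no gate.}
#'   \item{`full`}{both branches gated by ARA before fusion.}
#' }
#'
#' The `"tiny"` preset targets `(8, 64, 64)` DWI / `(8, 128, 128)` T2
#' phantom grids with a width-reduced backbone (multiplier 1/16) and HFIR
#' `C = 4`, sized for CPU-scale experiments; `"full"` targets the clinical
#' geometry `(18, 256, 256)` / `(18, 512, 512)` with the standard
#' ResNet-18 widths and HFIR `C = 16`.
#'
#' @param variant One of the five architecture variants.
#' @param preset `"full"` or `"tiny"` input geometry.
#' @param n_classes Number of output classes (3: normal, benign, malignant).
#' @param dropout_p Head dropout probability in `[0, 1)`; default 0.5.
#' @param hfir_C,width_multiplier,hfir_r Override the preset's HFIR width,
#'   backbone width multiplier, or unshuffle factor.
#' @param norm_mode `"batch"` or `"instance"` normalization statistics.
#' @param relu_before_head If `TRUE`, rectify the fused features before the
#'   classifier convolution (the logits themselves are never rectified).
#' @return A `model_config` list.
#' @export
model_config <- function(variant = c("full", "dwi_only", "t2_only",
                                     "t2_hfir_only", "concat_no_ara"),
                         preset = c("full", "tiny"), n_classes = 3L,
                         dropout_p = 0.5, hfir_C = NULL,
                         width_multiplier = NULL, hfir_r = 2L,
                         norm_mode = c("batch", "instance"),
                         relu_before_head = FALSE) {
  variant <- match.arg(variant)
  preset <- match.arg(preset)
  norm_mode <- match.arg(norm_mode)
  if (dropout_p < 0 || dropout_p >= 1)
    stop("dropout_p must be in [0, 1)", call. = FALSE)
  if (is.null(hfir_C)) hfir_C <- if (preset == "tiny") 4L else 16L
  if (is.null(width_multiplier))
    width_multiplier <- if (preset == "tiny") 1 / 16 else 1
  structure(list(variant = variant, preset = preset,
                 n_classes = as.integer(n_classes), dropout_p = dropout_p,
                 hfir_C = as.integer(hfir_C), hfir_r = as.integer(hfir_r),
                 width_multiplier = width_multiplier, norm_mode = norm_mode,
                 relu_before_head = relu_before_head),
            class = "model_config")
}

uses_hfir <- function(config)
  config$variant %in% c("t2_hfir_only", "concat_no_ara", "full")
uses_t2 <- function(config) config$variant != "dwi_only"
uses_dwi <- function(config)
  config$variant %in% c("dwi_only", "concat_no_ara", "full")
dual_branch <- function(config)
  config$variant %in% c("concat_no_ara", "full")

#' Build the assembled network
#'
#' Instantiates (per the config's variant) the HFIR block, one or two
#' backbone branches, the ARA gate and the classification head, all
#' randomly initialized from `seed`.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `fusemri_model` object.
#' @export
build_model <- function(config, seed = 1L) {
  with_local_seed(seed, {
    preset <- config$preset
    hfir <- NULL; bb_t2 <- NULL; bb_dwi <- NULL; ara <- NULL
    if (uses_hfir(config)) hfir <- hfir_params(config$hfir_C, config$hfir_r)
    if (uses_t2(config)) {
      t2_in <- if (uses_hfir(config)) config$hfir_C else 1L
      bb_t2 <- build_backbone(
        backbone_plan(t2_in, config$width_multiplier, preset),
        seed = NULL)
    }
    if (uses_dwi(config)) {
      bb_dwi <- build_backbone(
        backbone_plan(3L, config$width_multiplier, preset),
        seed = NULL)
    }
    c4 <- tail_width(config)
    if (config$variant == "full") ara <- ara_params(c4)
    head_in <- if (dual_branch(config)) 2L * c4 else c4
    head <- list(conv = nn_linear(head_in, config$n_classes,
                                  sd = sqrt(1 / head_in)))
    structure(list(config = config, hfir = hfir, bb_t2 = bb_t2,
                   bb_dwi = bb_dwi, ara = ara, head = head),
              class = "fusemri_model")
  })
}

tail_width <- function(config)
  as.integer(512L * config$width_multiplier)

#' Classification head: dropout, 1x1x1 classifier convolution, global pool
#'
#' Applies dropout to the fused feature map (active only in training mode),
#' a `1x1x1` convolution mapping `2C` channels to the class scores, and a
#' global adaptive average pool to `1x1x1`. Because a `1x1x1` convolution is
#' a per-position linear map, convolving then pooling equals pooling the
#' (dropout-masked) features and applying the same linear map once — the
#' implementation uses that identity.
#'
#' @param fused A `Volume5D` feature map whose channel count matches the
#'   head.
#' @param model A `fusemri_model` (its head and dropout settings are used).
#' @param train_mode Logical; enables dropout.
#' @return A `(B x n_classes)` matrix of logits, columns ordered
#'   (normal, benign, malignant).
#' @export
head_forward <- function(fused, model, train_mode = FALSE) {
  head_fwd(model, as_volume5d(fused), train_mode)$out
}

head_fwd <- function(model, fused, train) {
  if (dim(fused)[2] != ncol(model$head$conv$w))
    stop("head expects ", ncol(model$head$conv$w), " channels, got ",
         dim(fused)[2], call. = FALSE)
  rc <- NULL
  if (isTRUE(model$config$relu_before_head)) {
    r <- relu_fwd(fused)
    fused <- r$out
    rc <- r$cache
  }
  dr <- dropout_fwd(fused, model$config$dropout_p, train)
  g <- gap_fwd(dr$out)
  l <- linear_fwd(model$head$conv, g$out)
  list(out = l$out,
       cache = list(relu = rc, drop = dr$cache, gap = g$cache, lin = l$cache))
}

head_bwd <- function(model, dlogits, cache) {
  gl <- linear_bwd(model$head$conv, dlogits, cache$lin)
  dg <- gap_bwd(gl$dx, cache$gap)
  dd <- dropout_bwd(dg, cache$drop)
  if (!is.null(cache$relu)) dd <- relu_bwd(dd, cache$relu)
  list(dfused = dd, grads = list(conv = gl$grads))
}

flatten_keep_batch <- function(f) {
  s <- flatten_regions(f)
  if (length(dim(s)) == 2L) dim(s) <- c(1L, dim(s))
  s
}

check_model_inputs <- function(model, dwi, t2) {
  cfg <- model$config
  if (uses_dwi(cfg)) {
    if (is.null(dwi)) stop("variant '", cfg$variant, "' needs a DWI input",
                           call. = FALSE)
    dwi <- as_volume5d(dwi)
    if (dim(dwi)[2] != 3L)
      stop("DWI input must have 3 channels (b0, b500, b1000)", call. = FALSE)
  }
  if (uses_t2(cfg)) {
    if (is.null(t2)) stop("variant '", cfg$variant, "' needs a T2 input",
                          call. = FALSE)
    t2 <- as_volume5d(t2)
    if (dim(t2)[2] != 1L)
      stop("T2 input must have 1 channel", call. = FALSE)
    if (uses_hfir(cfg) && uses_dwi(cfg) && !is.null(dwi)) {
      if (!all(dim(t2)[4:5] == model$hfir$r * dim(dwi)[4:5]) ||
          dim(t2)[3] != dim(dwi)[3])
        stop("T2 spatial dims must be r x the DWI dims with equal depth",
             call. = FALSE)
    }
  }
  list(dwi = if (uses_dwi(cfg)) dwi else NULL,
       t2 = if (uses_t2(cfg)) t2 else NULL)
}

model_fwd <- function(model, dwi, t2, train = FALSE) {
  cfg <- model$config
  inp <- check_model_inputs(model, dwi, t2)
  nm <- cfg$norm_mode
  cache <- list()
  fT2_map <- NULL; fDWI_map <- NULL
  if (uses_t2(cfg)) {
    xt2 <- inp$t2
    if (uses_hfir(cfg)) {
      hf <- hfir_fwd(model$hfir, xt2)
      cache$hfir <- hf$cache
      xt2 <- hf$out
    }
    bt <- backbone_fwd(model$bb_t2, xt2, train, nm)
    cache$bb_t2 <- bt$cache
    fT2_map <- bt$out
  }
  if (uses_dwi(cfg)) {
    bd <- backbone_fwd(model$bb_dwi, inp$dwi, train, nm)
    cache$bb_dwi <- bd$cache
    fDWI_map <- bd$out
  }
  if (dual_branch(cfg)) {
    dhw <- dim(fDWI_map)[3:5]
    sT2 <- flatten_keep_batch(fT2_map)
    sDWI <- flatten_keep_batch(fDWI_map)
    if (cfg$variant == "full") {
      ar <- ara_fwd(model$ara, sT2, sDWI)
      cache$ara <- ar$cache
      fused <- fuse_attended(ar$aT2, ar$aDWI, dhw)
    } else {
      fused <- fuse_attended(sT2, sDWI, dhw)
    }
    cache$dhw <- dhw
  } else {
    fused <- if (uses_dwi(cfg)) fDWI_map else fT2_map
    cache$dhw <- dim(fused)[3:5]
  }
  hd <- head_fwd(model, fused, train)
  cache$head <- hd$cache
  cache$feature_maps <- list(t2 = fT2_map, dwi = fDWI_map)
  list(logits = hd$out, cache = cache)
}

# Backward through the whole assembly. Returns gradients mirroring the
# model's parameter tree, plus (for Grad-CAM) the gradient at each branch's
# final feature map.
model_bwd <- function(model, dlogits, cache, stop_at_features = FALSE) {
  cfg <- model$config
  hb <- head_bwd(model, dlogits, cache$head)
  grads <- list(head = hb$grads)
  dfused <- hb$dfused
  if (dual_branch(cfg)) {
    s <- flatten_keep_batch(dfused)
    C <- dim(s)[3] %/% 2L
    daT2 <- s[, , seq_len(C), drop = FALSE]
    daDWI <- s[, , C + seq_len(C), drop = FALSE]
    if (cfg$variant == "full") {
      ab <- ara_bwd(model$ara, daT2, daDWI, cache$ara)
      grads$ara <- ab$grads
      dfT2 <- ab$dfT2; dfDWI <- ab$dfDWI
      if (length(dim(dfT2)) == 2L) { dim(dfT2) <- c(1L, dim(dfT2)) }
      if (length(dim(dfDWI)) == 2L) { dim(dfDWI) <- c(1L, dim(dfDWI)) }
    } else {
      dfT2 <- daT2; dfDWI <- daDWI
    }
    dmap_t2 <- unflatten_regions(dfT2, cache$dhw)
    dmap_dwi <- unflatten_regions(dfDWI, cache$dhw)
  } else if (uses_dwi(cfg)) {
    dmap_dwi <- dfused; dmap_t2 <- NULL
  } else {
    dmap_t2 <- dfused; dmap_dwi <- NULL
  }
  feature_grads <- list(t2 = dmap_t2, dwi = dmap_dwi)
  if (stop_at_features)
    return(list(grads = grads, feature_grads = feature_grads))
  if (uses_dwi(cfg)) {
    bd <- backbone_bwd(model$bb_dwi, dmap_dwi, cache$bb_dwi,
                       need_dx = FALSE)
    grads$bb_dwi <- bd$grads
  }
  if (uses_t2(cfg)) {
    bt <- backbone_bwd(model$bb_t2, dmap_t2, cache$bb_t2,
                       need_dx = uses_hfir(cfg))
    grads$bb_t2 <- bt$grads
    if (uses_hfir(cfg)) {
      hf <- hfir_bwd(model$hfir, bt$dx, cache$hfir)
      grads$hfir <- hf$grads
    }
  }
  list(grads = grads, feature_grads = feature_grads)
}

#' Forward pass of the assembled network
#'
#' Runs the variant-appropriate path: HFIR on the T2 volume (where used),
#' the backbone branch(es), region flattening, the ARA gate (full variant),
#' fusion and the classification head.
#'
#' @param dwi 3-channel DWI `Volume5D`, or `NULL` for T2-only variants.
#' @param t2 1-channel T2 `Volume5D`, or `NULL` for the DWI-only variant.
#' @param model A [build_model()] object.
#' @param train_mode Logical; enables dropout and batch-statistic
#'   normalization.
#' @return A `(B x n_classes)` logits matrix.
#' @export
model_forward <- function(dwi, t2, model, train_mode = FALSE) {
  model_fwd(model, dwi, t2, train = train_mode)$logits
}

#' Save / load a model checkpoint
#'
#' Checkpoints bundle every sub-module's weights, the running normalization
#' statistics and the `model_config`, so a reloaded model reproduces
#' eval-mode forwards exactly.
#'
#' @param model A `fusemri_model`.
#' @param path File path.
#' @return `model_load()` returns the restored model.
#' @export
model_save <- function(model, path) {
  saveRDS(freeze_states(model), path)
  invisible(path)
}

#' @rdname model_save
#' @export
model_load <- function(path) {
  thaw_states(readRDS(path))
}

# bn state environments are converted to plain lists for serialization
freeze_states <- function(x) {
  if (is.environment(x)) return(list(.bn_state = as.list(x)))
  if (is.list(x) && !is.null(x$type) && identical(x$type, "bn3d")) {
    x$state <- list(.bn_state = as.list(x$state))
    return(x)
  }
  if (is.list(x)) {
    out <- lapply(x, freeze_states)
    attributes(out) <- attributes(x)
    return(out)
  }
  x
}

thaw_states <- function(x) {
  if (is.list(x) && !is.null(x$.bn_state)) {
    e <- new.env(parent = emptyenv())
    for (nm in names(x$.bn_state)) assign(nm, x$.bn_state[[nm]], envir = e)
    return(e)
  }
  if (is.list(x)) {
    out <- lapply(x, thaw_states)
    attributes(out) <- attributes(x)
    return(out)
  }
  x
}
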