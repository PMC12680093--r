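#' Volumetric Grad-CAM for a classified sample
#'
#' Computes a gradient-weighted class activation map on the selected
#' branch's final ("layer 4") feature map: the gradient of the target-class
#' logit is taken with respect to that activation, averaged over positions
#' to give one weight per channel, and the rectified weighted channel sum is
#' the raw CAM. The map is normalized to `[0, 1]` (when nonzero) and
#' upsampled trilinearly to the branch's input grid so it can be overlaid on
#' the source volume.
#'
#' @param model A `fusemri_model` (evaluated in eval mode).
#' @param sample A list with elements `dwi` and/or `t2` (`Volume5D`s), e.g. a
#'   [generate_patient()] result.
#' @param target_class Integer class 0 (normal), 1 (benign) or 2 (malignant).
#' @param layer_selector `"dwi"` (default; overlays are usually drawn on
#'   DW-MRI) or `"t2"`.
#' @return A `cam_map` object: `cam_low` (layer-4 grid), `cam` (input grid),
#'   `target_class`, `layer`.
#' @export
gradcam3d <- function(model, sample, target_class,
                      layer_selector = c("dwi", "t2")) {
  layer_selector <- match.arg(layer_selector)
  if (!target_class %in% 0:2 && target_class >= model$config$n_classes)
    stop("target_class must be in 0..", model$config$n_classes - 1,
         call. = FALSE)
  cfg <- model$config
  if (layer_selector == "dwi" && !uses_dwi(cfg))
    stop("variant '", cfg$variant, "' has no DWI branch", call. = FALSE)
  if (layer_selector == "t2" && !uses_t2(cfg))
    stop("variant '", cfg$variant, "' has no T2 branch", call. = FALSE)
  dwi <- if (uses_dwi(cfg)) as_volume5d(sample$dwi) else NULL
  t2 <- if (uses_t2(cfg)) as_volume5d(sample$t2) else NULL
  fw <- model_fwd(model, dwi, t2, train = FALSE)
  dlogits <- matrix(0, nrow(fw$logits), ncol(fw$logits))
  dlogits[, target_class + 1L] <- 1
  bw <- model_bwd(model, dlogits, fw$cache, stop_at_features = TRUE)
  A <- fw$cache$feature_maps[[layer_selector]]
  dA <- bw$feature_grads[[layer_selector]]
  d <- dim(A)
  C <- d[2]; M <- prod(d[3:5])
  Am <- matrix(aperm(A, c(1L, 3L, 4L, 5L, 2L)), M, C)   # B = 1
  dAm <- matrix(aperm(dA, c(1L, 3L, 4L, 5L, 2L)), M, C)
  w <- colMeans(dAm)
  cam <- pmax(as.vector(Am %*% w), 0)
  if (max(cam) > 0) cam <- cam / max(cam)
  dim(cam) <- d[3:5]
  in_shape <- if (layer_selector == "dwi") dim(dwi)[3:5] else dim(t2)[3:5]
  structure(list(cam_low = cam,
                 cam = trilinear_upsample(cam, in_shape),
                 target_class = as.integer(target_class),
                 layer = layer_selector),
            class = "cam_map")
}

# Trilinear resize of a (D, H, W) array; voxel centers are mapped by
# src = (i + 0.5) * n_src / n_dst - 0.5 and clamped at the edges.
trilinear_upsample <- function(vol, out_shape) {
  d <- dim(vol)
  out_shape <- as.integer(out_shape)
  axis_weights <- function(n_src, n_dst) {
    src <- (seq_len(n_dst) - 0.5) * n_src / n_dst - 0.5
    src <- pmin(pmax(src, 0), n_src - 1)
    lo <- floor(src)
    frac <- src - lo
    hi <- pmin(lo + 1, n_src - 1)
    list(lo = lo + 1, hi = hi + 1, frac = frac)
  }
  interp_axis <- function(x, ax) {
    # x: matrix (n_src x rest); returns (n_dst x rest)
    x[ax$lo, , drop = FALSE] * (1 - ax$frac) +
      x[ax$hi, , drop = FALSE] * ax$frac
  }
  ad <- axis_weights(d[1], out_shape[1])
  ah <- axis_weights(d[2], out_shape[2])
  aw <- axis_weights(d[3], out_shape[3])
  x <- vol
  dim(x) <- c(d[1], d[2] * d[3])
  x <- interp_axis(x, ad)                       # (Do, H*W)
  dim(x) <- c(out_shape[1], d[2], d[3])
  x <- aperm(x, c(2L, 1L, 3L))
  dim(x) <- c(d[2], out_shape[1] * d[3])
  x <- interp_axis(x, ah)                       # (Ho, Do*W)
  dim(x) <- c(out_shape[2], out_shape[1], d[3])
  x <- aperm(x, c(3L, 2L, 1L))
  dim(x) <- c(d[3], out_shape[1] * out_shape[2])
  x <- interp_axis(x, aw)                       # (Wo, Do*Ho)
  dim(x) <- c(out_shape[3], out_shape[1], out_shape[2])
  aperm(x, c(2L, 3L, 1L))
}

#' Does the CAM maximum fall inside a (dilated) lesion mask?
#'
#' Localization check: takes the voxel of maximum CAM intensity on the input
#' grid and asks whether it lies within `dilate` voxels (Euclidean) of the
#' lesion mask.
#'
#' @param cam A [gradcam3d()] result.
#' @param mask A binary `(D, H, W)` lesion mask on the same grid.
#' @param dilate Dilation radius in voxels.
#' @return Logical.
#' @export
cam_inside_mask <- function(cam, mask, dilate = 3) {
  stopifnot(identical(dim(cam$cam), dim(mask)))
  if (!any(mask > 0)) return(FALSE)
  top <- arrayInd(which.max(cam$cam), dim(cam$cam))
  mv <- which(mask > 0)
  mi <- arrayInd(mv, dim(mask))
  dd <- sweep(mi, 2L, as.numeric(top))
  min(sqrt(rowSums(dd^2))) <= dilate
}

#' Write a CAM volume as NIfTI aligned to its input grid
#'
#' @param cam A [gradcam3d()] result.
#' @param path Output `.nii.gz` path.
#' @return The path, invisibly.
#' @export
write_cam_nifti <- function(cam, path) {
  # stored (H, W, D) to match the volume storage convention
  RNifti::writeNifti(RNifti::asNifti(aperm(cam$cam, c(2L, 3L, 1L))), path)
  invisible(path)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Slice-mosaic plot of a CAM volume
#'
#' @param object A `cam_map`.
#' @param ... Unused.
#' @return A ggplot object: one tile facet per depth slice.
#' @export
autoplot.cam_map <- function(object, ...) {
  d <- dim(object$cam)
  df <- expand.grid(depth = seq_len(d[1]), row = seq_len(d[2]),
                    col = seq_len(d[3]))
  df$cam <- as.vector(object$cam)
  ggplot2::ggplot(df, ggplot2::aes(x = col, y = row, fill = cam)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~depth) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0("Grad-CAM (class ", object$target_class,
                                 ", ", object$layer, " branch)"),
                  x = NULL, y = NULL)
}
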