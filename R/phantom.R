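#' Configuration of a synthetic multimodal phantom cohort
#'
#' Describes the cohort composition and geometry of a synthetic dataset that
#' stands in for a clinical multimodal acquisition: per patient, a
#' three-channel DWI volume (b0, b500, b1000 stacked as channels) and a T2
#' volume at twice the in-plane resolution with the same slice count. The
#' default composition is 20 normal, 22 benign and 28 malignant patients on
#' `(18, 256, 256)` DWI / `(18, 512, 512)` T2 grids; the `"tiny"` preset
#' keeps the same class structure on `(8, 64, 64)` / `(8, 128, 128)` grids
#' for CPU-scale experiments.
#'
#' @param n_normal,n_benign,n_malignant Class counts (default 20/22/28).
#' @param preset `"full"` or `"tiny"` grid geometry.
#' @param dwi_shape,t2_shape Optional explicit `(depth, height, width)`
#'   overrides; T2 height/width must be exactly twice the DWI values with
#'   equal depth.
#' @param noise_sigma Gaussian intensity noise s.d. (arbitrary units;
#'   intensities are in `[0, 1]` before noise). Default 0.05.
#' @param seed Root seed for the cohort.
#' @return A `phantom_config` list.
#' @examples
#' cfg <- phantom_config(preset = "tiny", n_normal = 2, n_benign = 2,
#'                       n_malignant = 2, seed = 1)
#' @export
phantom_config <- function(n_normal = 20L, n_benign = 22L, n_malignant = 28L,
                           preset = c("full", "tiny"), dwi_shape = NULL,
                           t2_shape = NULL, noise_sigma = 0.05, seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(dwi_shape))
    dwi_shape <- if (preset == "tiny") c(8L, 64L, 64L) else c(18L, 256L, 256L)
  if (is.null(t2_shape))
    t2_shape <- c(dwi_shape[1], 2L * dwi_shape[2], 2L * dwi_shape[3])
  dwi_shape <- as.integer(dwi_shape); t2_shape <- as.integer(t2_shape)
  counts <- c(n_normal, n_benign, n_malignant)
  if (any(counts < 0)) stop("class counts must be >= 0", call. = FALSE)
  if (t2_shape[1] != dwi_shape[1])
    stop("T2 and DWI must have the same depth", call. = FALSE)
  if (!all(t2_shape[2:3] == 2L * dwi_shape[2:3]))
    stop("T2 height/width must be 2x the DWI height/width", call. = FALSE)
  structure(list(n_normal = as.integer(n_normal),
                 n_benign = as.integer(n_benign),
                 n_malignant = as.integer(n_malignant),
                 preset = preset, dwi_shape = dwi_shape, t2_shape = t2_shape,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_config")
}

# Normalized coordinates in [-1, 1] per axis, voxel centers, 1-based grid.
norm_coords <- function(n) (seq_len(n) - (n + 1) / 2) / (n / 2)

BRAIN_SEMI_AXES <- c(0.85, 0.80, 0.75)  # depth, height, width

# Squared ellipsoidal radius q(u) at every voxel of a (D,H,W) grid; the
# brain is q <= 1.
brain_q <- function(shape) {
  ud <- norm_coords(shape[1]) / BRAIN_SEMI_AXES[1]
  uh <- norm_coords(shape[2]) / BRAIN_SEMI_AXES[2]
  uw <- norm_coords(shape[3]) / BRAIN_SEMI_AXES[3]
  q <- outer(outer(ud^2, uh^2, "+"), uw^2, "+")
  q
}

base_tissue <- function(q, base) {
  v <- array(0, dim(q))
  inside <- q < 1
  v[inside] <- base * (0.7 + 0.3 * (1 - q[inside]))
  v
}

# Angular lobe perturbation of the lesion radius: a fixed-seed sum of three
# low-order cosine modes in the in-plane and polar angles, scaled by the
# boundary-irregularity parameter.
lesion_modes <- function() {
  list(a = stats::runif(3, -1, 1), b = stats::runif(3, -1, 1),
       u = stats::runif(3, 0, 2 * pi), v = stats::runif(3, 0, 2 * pi))
}

# Ratio field rho(voxel): distance to lesion center over direction-dependent
# lesion radius; <= 1 is inside the lesion.
lesion_ratio <- function(shape, center, radius, irregularity, modes) {
  dd <- norm_coords(shape[1]) - center[1]
  dh <- norm_coords(shape[2]) - center[2]
  dw <- norm_coords(shape[3]) - center[3]
  D <- shape[1]; H <- shape[2]; W <- shape[3]
  ddv <- array(rep(dd, times = H * W), shape)
  dhv <- array(rep(rep(dh, each = D), times = W), shape)
  dwv <- array(rep(dw, each = D * H), shape)
  dist <- sqrt(ddv^2 + dhv^2 + dwv^2)
  theta <- atan2(dwv, dhv)
  phi <- acos(ifelse(dist > 0, ddv / pmax(dist, 1e-12), 1))
  s <- array(0, shape)
  for (k in 1:3)
    s <- s + modes$a[k] * cos(k * theta + modes$u[k]) +
      modes$b[k] * cos(k * phi + modes$v[k])
  s <- s / 3
  r_dir <- radius * pmax(1 + irregularity * 0.35 * s, 0.3)
  dist / r_dir
}

soft_edge <- function(ratio, edge = 0.08) pmin(pmax((1 - ratio) / edge, 0), 1)

# Per-class lesion contrast and morphology conventions (arbitrary intensity
# units): benign lesions are smooth, bright on T2 and only mildly
# hyperintense on b1000; malignant lesions have irregular boundaries and
# strong b1000 hyperintensity (the diffusion-restriction analogue).
draw_lesion_spec <- function(label) {
  if (label == 1L) {
    list(irregularity = stats::runif(1, 0, 0.2),
         contrast_t2 = stats::runif(1, 0.25, 0.35),
         contrast_b1000 = stats::runif(1, 0.06, 0.10))
  } else {
    list(irregularity = stats::runif(1, 0.5, 0.9),
         contrast_t2 = stats::runif(1, 0.10, 0.20),
         contrast_b1000 = stats::runif(1, 0.30, 0.40))
  }
}

BASE_INTENSITY <- c(b0 = 0.70, b500 = 0.50, b1000 = 0.35, t2 = 0.55)

#' Generate one synthetic patient
#'
#' Deterministically renders one patient's paired DWI and T2 volumes for a
#' given `(label, config, seed)`. The background brain is a smooth ellipsoid
#' with modality-dependent base intensity plus Gaussian noise. Benign and
#' malignant patients additionally carry a lesion: a sphere (benign) or a
#' boundary-perturbed blob (malignant) whose center and radius are sampled
#' inside the brain, rendered with a soft one-voxel edge on both modality
#' grids. Malignant lesions are strongly hyperintense on the b1000 channel;
#' benign lesions are bright on T2 with only mild b1000 contrast — a
#' threshold on (lesion present, b1000 lesion contrast) separates the
#' classes perfectly in the noise-free limit.
#'
#' @param label Class label: 0 normal, 1 benign, 2 malignant.
#' @param config A [phantom_config()].
#' @param seed Integer seed (deterministic output for fixed arguments).
#' @return A `patient_sample`: list with `patient_id`, `dwi`
#'   `(1, 3, D, H, W)`, `t2` `(1, 1, D, 2H, 2W)`, `label`, `lesion_mask`
#'   (binary `(D, H, W)` array on the DWI grid, or `NULL` for normal) and
#'   `lesion` (the sampled lesion spec).
#' @export
generate_patient <- function(label, config, seed = config$seed) {
  if (!label %in% 0:2) stop("label must be 0, 1 or 2", call. = FALSE)
  with_local_seed(seed, {
    ds <- config$dwi_shape; ts <- config$t2_shape
    qd <- brain_q(ds)
    qt <- brain_q(ts)
    dwi_ch <- list(base_tissue(qd, BASE_INTENSITY["b0"]),
                   base_tissue(qd, BASE_INTENSITY["b500"]),
                   base_tissue(qd, BASE_INTENSITY["b1000"]))
    t2v <- base_tissue(qt, BASE_INTENSITY["t2"])
    lesion_mask <- NULL
    lesion <- NULL
    if (label != 0L) {
      radius <- stats::runif(1, 0.18, 0.28)
      spec <- draw_lesion_spec(label)
      # center must keep the (possibly perturbed) lesion inside the brain:
      # sample within the feasible box and accept on the exact ellipsoid
      # bound sum(((|c| + max_r) / a)^2) <= 1
      max_r <- radius * (1 + spec$irregularity * 0.35)
      half <- BRAIN_SEMI_AXES - max_r
      if (any(half <= 0))
        stop("lesion cannot fit inside the brain ellipsoid", call. = FALSE)
      ok <- FALSE
      for (try in 1:500) {
        ctr <- stats::runif(3, -half, half)
        if (sum((abs(ctr) + max_r)^2 / BRAIN_SEMI_AXES^2) <= 1) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("lesion cannot fit inside the brain ellipsoid",
                    call. = FALSE)
      modes <- lesion_modes()
      ratio_d <- lesion_ratio(ds, ctr, radius, spec$irregularity, modes)
      ratio_t <- lesion_ratio(ts, ctr, radius, spec$irregularity, modes)
      wd <- soft_edge(ratio_d)
      wt <- soft_edge(ratio_t)
      dwi_ch[[1]] <- dwi_ch[[1]] + 0.05 * wd
      dwi_ch[[2]] <- dwi_ch[[2]] + (spec$contrast_b1000 / 2) * wd
      dwi_ch[[3]] <- dwi_ch[[3]] + spec$contrast_b1000 * wd
      t2v <- t2v + spec$contrast_t2 * wt
      lesion_mask <- (ratio_d <= 1) * 1L
      storage.mode(lesion_mask) <- "integer"
      lesion <- c(list(center = ctr, radius = radius), spec)
    }
    sigma <- config$noise_sigma
    if (sigma > 0) {
      for (k in 1:3)
        dwi_ch[[k]] <- dwi_ch[[k]] + stats::rnorm(length(dwi_ch[[k]]),
                                                  sd = sigma)
      t2v <- t2v + stats::rnorm(length(t2v), sd = sigma)
    }
    dwi <- array(0, c(1L, 3L, ds))
    for (k in 1:3) dwi[1, k, , , ] <- dwi_ch[[k]]
    t2 <- array(t2v, c(1L, 1L, ts))
    structure(list(patient_id = NA_character_, dwi = dwi, t2 = t2,
                   label = as.integer(label), lesion_mask = lesion_mask,
                   lesion = lesion),
              class = "patient_sample")
  })
}

#' Generate a full synthetic cohort
#'
#' Produces `n_normal + n_benign + n_malignant` patients with unique ids;
#' per-patient seeds are derived deterministically from the config seed, so
#' two cohorts built from the same config are voxelwise identical.
#'
#' @param config A [phantom_config()].
#' @return A list of `patient_sample` objects.
#' @export
generate_cohort <- function(config) {
  labels <- rep(0:2, times = c(config$n_normal, config$n_benign,
                               config$n_malignant))
  n <- length(labels)
  if (n == 0L) return(list())
  seeds <- with_local_seed(config$seed,
                           sample.int(.Machine$integer.max - 1L, n))
  lapply(seq_len(n), function(i) {
    s <- generate_patient(labels[i], config, seed = seeds[i])
    s$patient_id <- sprintf("P%03d", i)
    s
  })
}

#' Write a cohort to NIfTI files plus a manifest
#'
#' Writes one NIfTI file per modality per patient — DWI as a 4-D volume with
#' the three b-value channels stacked on the fourth axis, T2 as 3-D — with
#' identity orientation and the on-disk axis order `(height, width, depth)`.
#' A `manifest.csv` maps `patient_id` to label and file paths. Storage is
#' lossless: [load_sample()] reproduces the voxel data exactly.
#'
#' @param samples A list of `patient_sample` objects (see
#'   [generate_cohort()]).
#' @param directory Output directory (created if missing).
#' @return The manifest path, invisibly a character scalar.
#' @export
write_cohort <- function(samples, directory) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  rows <- lapply(samples, function(s) {
    dwi_path <- file.path(directory, paste0(s$patient_id, "_dwi.nii.gz"))
    t2_path <- file.path(directory, paste0(s$patient_id, "_t2.nii.gz"))
    d <- dim(s$dwi)  # (1, 3, D, H, W)
    dwi_store <- aperm(array(s$dwi[1, , , , ], d[2:5]), c(3L, 4L, 2L, 1L))
    t2_store <- aperm(array(s$t2[1, 1, , , ], dim(s$t2)[3:5]), c(2L, 3L, 1L))
    RNifti::writeNifti(RNifti::asNifti(dwi_store), dwi_path)
    RNifti::writeNifti(RNifti::asNifti(t2_store), t2_path)
    data.frame(patient_id = s$patient_id, label = s$label,
               dwi_path = dwi_path, t2_path = t2_path,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(directory, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
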