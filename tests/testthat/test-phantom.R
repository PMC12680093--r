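# 6-connected binary dilation, repeated `r` times (used to build the
# "2-voxel shell" oracle around a lesion mask)
dilate6 <- function(mask, r = 1L) {
  m <- mask > 0
  d <- dim(m)
  for (k in seq_len(r)) {
    out <- m
    out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
    out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
    out[, , -1] <- out[, , -1] | m[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
    m <- out
  }
  m
}

tiny_cfg <- function(noise = 0, seed = 11)
  phantom_config(n_normal = 1, n_benign = 1, n_malignant = 1,
                 preset = "tiny", noise_sigma = noise, seed = seed)

test_that("normal patients have no lesion and the contracted shapes", {
  s <- generate_patient(0, tiny_cfg(), seed = 5)
  expect_null(s$lesion_mask)
  expect_equal(dim(s$dwi), c(1, 3, 8, 64, 64))
  expect_equal(dim(s$t2), c(1, 1, 8, 128, 128))
  expect_error(generate_patient(5, tiny_cfg()), "label")
})

test_that("generation is voxelwise deterministic in (label, config, seed)", {
  a <- generate_patient(2, tiny_cfg(noise = 0.05), seed = 7)
  b <- generate_patient(2, tiny_cfg(noise = 0.05), seed = 7)
  expect_identical(a$dwi, b$dwi)
  expect_identical(a$t2, b$t2)
  expect_identical(a$lesion_mask, b$lesion_mask)
  c1 <- generate_cohort(tiny_cfg(noise = 0.05))
  c2 <- generate_cohort(tiny_cfg(noise = 0.05))
  expect_identical(lapply(c1, `[[`, "dwi"), lapply(c2, `[[`, "dwi"))
  expect_identical(sapply(c1, `[[`, "label"), sapply(c2, `[[`, "label"))
})

test_that("malignant lesions are b1000-hyperintense vs a 2-voxel shell", {
  s <- generate_patient(2, tiny_cfg(noise = 0), seed = 7)
  mask <- s$lesion_mask > 0
  expect_true(any(mask))
  shell <- dilate6(mask, 2) & !mask
  b1000 <- s$dwi[1, 3, , , ]
  expect_gt(mean(b1000[mask]), mean(b1000[shell]))
})

test_that("noise-free lesion contrast separates the classes perfectly", {
  cfg <- phantom_config(n_normal = 3, n_benign = 3, n_malignant = 3,
                        preset = "tiny", noise_sigma = 0, seed = 23)
  cohort <- generate_cohort(cfg)
  contrast <- vapply(cohort, function(s) {
    if (is.null(s$lesion_mask)) return(0)
    mask <- s$lesion_mask > 0
    shell <- dilate6(mask, 2) & !mask
    b1000 <- s$dwi[1, 3, , , ]
    mean(b1000[mask]) - mean(b1000[shell])
  }, numeric(1))
  labels <- vapply(cohort, `[[`, integer(1), "label")
  # lesion presence separates normal; b1000 contrast separates benign from
  # malignant with a threshold between the class ranges
  expect_true(all(contrast[labels == 0] == 0))
  expect_gt(min(contrast[labels == 1]), 0)
  expect_gt(min(contrast[labels == 2]), max(contrast[labels == 1]))
  # morphology convention: benign smooth, malignant irregular
  irr <- vapply(cohort, function(s)
    if (is.null(s$lesion)) NA_real_ else s$lesion$irregularity, numeric(1))
  expect_true(all(irr[labels == 1] <= 0.2))
  expect_true(all(irr[labels == 2] >= 0.5))
})

test_that("default cohort composition is 20 normal, 22 benign, 28 malignant", {
  cfg <- phantom_config(preset = "tiny", seed = 1)
  cohort <- generate_cohort(cfg)
  expect_length(cohort, 70)
  labels <- vapply(cohort, `[[`, integer(1), "label")
  expect_equal(unname(table(labels)), c(20, 22, 28), ignore_attr = TRUE)
  ids <- vapply(cohort, `[[`, character(1), "patient_id")
  expect_false(anyDuplicated(ids) > 0)
})

test_that("modality geometry invariants are enforced", {
  expect_error(phantom_config(dwi_shape = c(8, 64, 64),
                              t2_shape = c(8, 100, 128)),
               "2x")
  expect_error(phantom_config(dwi_shape = c(8, 64, 64),
                              t2_shape = c(9, 128, 128)),
               "depth")
  expect_error(phantom_config(n_normal = -1), ">= 0")
  cfg <- phantom_config(preset = "tiny")
  expect_equal(cfg$t2_shape[2:3], 2L * cfg$dwi_shape[2:3])
})

test_that("write_cohort stores losslessly and the manifest is complete", {
  dir <- file.path(tempdir(), "fusemri-cohort-test")
  on.exit(unlink(dir, recursive = TRUE))
  cfg <- phantom_config(n_normal = 1, n_benign = 0, n_malignant = 1,
                        preset = "tiny", noise_sigma = 0.05, seed = 13)
  cohort <- generate_cohort(cfg)
  manifest_path <- write_cohort(cohort, dir)
  expect_equal(length(list.files(dir, pattern = "nii\\.gz$")), 4)
  manifest <- read_manifest(manifest_path)
  expect_equal(nrow(manifest), 2)
  # round trip reproduces voxel data exactly (before normalization)
  s <- load_sample(manifest[1, ], normalize = FALSE)
  expect_equal(s$dwi, cohort[[1]]$dwi, tolerance = 1e-12)
  expect_equal(s$t2, cohort[[1]]$t2, tolerance = 1e-12)
  expect_equal(s$label, cohort[[1]]$label)
})
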