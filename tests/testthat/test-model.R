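fm <- asNamespace("fusemri")

tiny_model <- function(variant = "full", seed = 21) {
  build_model(model_config(variant, preset = "tiny"), seed = seed)
}

tiny_inputs <- function(seed = 1) {
  set.seed(seed)
  list(dwi = rand_volume(c(1, 3, 8, 64, 64)),
       t2 = rand_volume(c(1, 1, 8, 128, 128)))
}

test_that("head is dropout -> 1x1x1 conv -> global average pool", {
  cfg <- model_config("full", preset = "tiny")
  head <- list(config = cfg, head = list(conv = fm$nn_linear(4L, 3L)))
  # zero weights, biases (a, b, c): logits are exactly the biases
  head$head$conv$w[] <- 0
  head$head$conv$b <- c(0.3, -1.2, 2.5)
  fused <- rand_volume(c(2, 4, 2, 3, 3))
  expect_equal(head_forward(fused, head),
               matrix(c(0.3, -1.2, 2.5), 2, 3, byrow = TRUE),
               tolerance = 1e-12)
  # constant-per-channel map: 1x1x1 conv + mean pool = W v + b, by hand
  set.seed(6)
  W <- matrix(rnorm(12), 3, 4)
  b <- rnorm(3)
  head$head$conv$w <- W
  head$head$conv$b <- b
  v <- c(1.5, -0.5, 2, 0.25)
  fused <- array(0, c(1, 4, 2, 2, 2))
  for (k in 1:4) fused[1, k, , , ] <- v[k]
  expect_equal(head_forward(fused, head)[1, ], as.vector(W %*% v + b),
               tolerance = 1e-12)
  # eval mode is deterministic (dropout inactive)
  fused <- rand_volume(c(1, 4, 2, 2, 2))
  expect_identical(head_forward(fused, head, train_mode = FALSE),
                   head_forward(fused, head, train_mode = FALSE))
  expect_error(head_forward(rand_volume(c(1, 5, 2, 2, 2)), head),
               "channels")
})

test_that("full-variant forward produces finite, reproducible logits", {
  m <- tiny_model()
  inp <- tiny_inputs()
  l1 <- model_forward(inp$dwi, inp$t2, m)
  expect_equal(dim(l1), c(1, 3))
  expect_true(all(is.finite(l1)))
  expect_identical(l1, model_forward(inp$dwi, inp$t2, m))
})

test_that("full with zero ARA equals concat_no_ara on 1.5x features", {
  m_full <- tiny_model("full")
  m_full$ara$phi1[] <- 0; m_full$ara$b1[] <- 0
  m_full$ara$phi2[] <- 0; m_full$ara$b2[] <- 0
  # share every other weight with a concat_no_ara clone
  m_cat <- m_full
  m_cat$config$variant <- "concat_no_ara"
  m_cat$ara <- NULL
  inp <- tiny_inputs(2)
  lf <- model_forward(inp$dwi, inp$t2, m_full)
  lc <- model_forward(inp$dwi, inp$t2, m_cat)
  # zero-parameter gate scales features by exactly 1.5, and the linear
  # head maps that to 1.5 * (logits - bias) + bias
  b <- m_full$head$conv$b
  expect_equal(lf[1, ], 1.5 * (lc[1, ] - b) + b, tolerance = 1e-9)
})

test_that("single-modality variants accept their modality only", {
  m <- tiny_model("dwi_only")
  inp <- tiny_inputs(3)
  l <- model_forward(inp$dwi, NULL, m)
  expect_equal(dim(l), c(1, 3))
  expect_error(model_forward(NULL, inp$t2, m), "needs a DWI input")
  mt <- tiny_model("t2_only")
  expect_equal(dim(model_forward(NULL, inp$t2, mt)), c(1, 3))
  # geometry contract: T2 must be 2x the DWI in-plane size
  expect_error(model_forward(inp$dwi, rand_volume(c(1, 1, 8, 64, 64)),
                             tiny_model("full")),
               "2 x|r x")
  expect_error(model_forward(rand_volume(c(1, 2, 8, 64, 64)), inp$t2,
                             tiny_model("full")),
               "3 channels")
})

test_that("checkpoints restore eval-mode forwards exactly", {
  m <- tiny_model(seed = 31)
  inp <- tiny_inputs(4)
  l1 <- model_forward(inp$dwi, inp$t2, m)
  path <- tempfile(fileext = ".rds")
  model_save(m, path)
  m2 <- model_load(path)
  expect_equal(model_forward(inp$dwi, inp$t2, m2), l1, tolerance = 1e-15)
  unlink(path)
})

test_that("grad-cam follows the rectified gradient-weighted channel sum", {
  m <- tiny_model("dwi_only", seed = 41)
  inp <- tiny_inputs(5)
  sample <- list(dwi = inp$dwi)
  # logit of the target class reads only feature channel 1: the CAM must
  # equal the rectified channel-1 activation, rescaled to max 1
  m$head$conv$w[] <- 0
  m$head$conv$w[3, 1] <- 1
  cam <- gradcam3d(m, sample, target_class = 2, layer_selector = "dwi")
  A1 <- extract_layer4(m$bb_dwi, inp$dwi)[1, 1, , , ]
  expected <- pmax(A1, 0)
  expected <- expected / max(expected)
  expect_equal(cam$cam_low, expected, tolerance = 1e-9)
  expect_true(all(cam$cam >= 0))
  expect_equal(max(cam$cam_low), 1)
  expect_equal(dim(cam$cam), dim(inp$dwi)[3:5])
  # a logit detached from the map (zero weights) gives an all-zero CAM
  m$head$conv$w[] <- 0
  cam0 <- gradcam3d(m, sample, target_class = 2)
  expect_true(all(cam0$cam_low == 0) && all(cam0$cam == 0))
  expect_error(gradcam3d(tiny_model("dwi_only"), sample, 2, "t2"),
               "no T2 branch")
})

test_that("trilinear upsampling is exact on constants and monotone axes", {
  up <- fm$trilinear_upsample(array(3.5, c(2, 2, 2)), c(4, 8, 6))
  expect_equal(dim(up), c(4, 8, 6))
  expect_true(all(abs(up - 3.5) < 1e-12))
  ramp <- array(rep(1:4, each = 1), c(1, 1, 4))
  up2 <- fm$trilinear_upsample(ramp, c(1, 1, 8))
  expect_true(all(diff(up2[1, 1, ]) >= 0))
  expect_equal(range(up2), c(1, 4))
})
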