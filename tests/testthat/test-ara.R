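fm <- asNamespace("fusemri")

test_that("flatten_regions is a lossless, depth-major tokenization", {
  set.seed(1)
  f <- rand_volume(c(1, 6, 2, 3, 4))
  s <- flatten_regions(f)
  expect_equal(dim(s), c(24, 6))
  expect_identical(unflatten_regions(s, c(2, 3, 4)), f)
  # token index runs depth fastest, then rows, then columns
  expect_equal(s[1, ], f[1, , 1, 1, 1])
  expect_equal(s[2, ], f[1, , 2, 1, 1])
  expect_equal(s[3, ], f[1, , 1, 2, 1])
  expect_equal(s[2 * 3 + 1, ], f[1, , 1, 1, 2])
  # single-voxel map flattens to its channel vector
  g <- rand_volume(c(1, 5, 1, 1, 1))
  expect_equal(flatten_regions(g), matrix(g[1, , 1, 1, 1], 1, 5))
  # the printed layer-4 geometry gives 256 tokens x 512 channels
  expect_equal(dim(flatten_regions(array(0, c(1, 512, 4, 8, 8)))),
               c(256, 512))
  expect_error(unflatten_regions(s, c(2, 3, 5)), "inconsistent")
})

test_that("zero-parameter ARA gates to exactly 1.5x the inputs", {
  p <- ara_params(4)
  p$phi1[] <- 0; p$b1[] <- 0; p$phi2[] <- 0; p$b2[] <- 0
  set.seed(2)
  fT2 <- matrix(rnorm(12), 3, 4)
  fDWI <- matrix(rnorm(12), 3, 4)
  g <- ara_gate(fT2, fDWI, p)
  expect_equal(g$t2, 1.5 * fT2, tolerance = 1e-12)
  expect_equal(g$dwi, 1.5 * fDWI, tolerance = 1e-12)
  # zero inputs give zero outputs for any parameters
  p2 <- ara_params(4)
  z <- matrix(0, 5, 4)
  g2 <- ara_gate(z, z, p2)
  expect_true(all(g2$t2 == 0) && all(g2$dwi == 0))
})

test_that("vectorized gate matches the scalar-loop equation oracle", {
  set.seed(3)
  for (k in 1:100) {
    P <- sample(1:8, 1)
    C <- 2L * sample(1:4, 1)
    p <- ara_params(C)
    fT2 <- matrix(rnorm(P * C), P, C)
    fDWI <- matrix(rnorm(P * C), P, C)
    g <- ara_gate(fT2, fDWI, p)
    o <- ara_scalar_oracle(fT2, fDWI, p)
    expect_equal(g$t2, o$t2, tolerance = 1e-6)
    expect_equal(g$dwi, o$dwi, tolerance = 1e-6)
  }
})

test_that("gating is bounded, sign-preserving and token-equivariant", {
  set.seed(4)
  p <- ara_params(6)
  fT2 <- matrix(rnorm(8 * 6), 8, 6)
  fDWI <- matrix(rnorm(8 * 6), 8, 6)
  g <- ara_gate(fT2, fDWI, p)
  for (m in 1:2) {
    a <- if (m == 1) g$t2 else g$dwi
    f <- if (m == 1) fT2 else fDWI
    expect_true(all(sign(a) == sign(f) | f == 0))
    expect_true(all(abs(a) >= abs(f) - 1e-12))
    expect_true(all(abs(a) <= 2 * abs(f) + 1e-12))
  }
  # permuting tokens of both inputs permutes both outputs identically
  perm <- sample(8)
  gp <- ara_gate(fT2[perm, ], fDWI[perm, ], p)
  expect_equal(gp$t2, g$t2[perm, ], tolerance = 1e-12)
  expect_equal(gp$dwi, g$dwi[perm, ], tolerance = 1e-12)
})

test_that("ara gradients agree with finite differences, skip regime >= 1", {
  set.seed(5)
  p <- ara_params(4)
  fT2 <- matrix(rnorm(3 * 4), 3, 4)
  fDWI <- matrix(rnorm(3 * 4), 3, 4)
  fw <- fm$ara_fwd(p, fT2, fDWI)
  dT2 <- matrix(rnorm(12), 3, 4); dDWI <- matrix(rnorm(12), 3, 4)
  bw <- fm$ara_bwd(p, dT2, dDWI, fw$cache)
  loss <- function(a, b, pp) {
    r <- fm$ara_fwd(pp, a, b)
    sum(r$aT2 * dT2) + sum(r$aDWI * dDWI)
  }
  eps <- 1e-6
  for (j in sample(12, 4)) {
    f1 <- fT2; f1[j] <- f1[j] + eps
    f2 <- fT2; f2[j] <- f2[j] - eps
    expect_equal((loss(f1, fDWI, p) - loss(f2, fDWI, p)) / (2 * eps),
                 bw$dfT2[j], tolerance = 1e-5)
  }
  for (j in sample(length(p$phi1), 4)) {
    p1 <- p; p1$phi1[j] <- p1$phi1[j] + eps
    p2 <- p; p2$phi1[j] <- p2$phi1[j] - eps
    expect_equal((loss(fT2, fDWI, p1) - loss(fT2, fDWI, p2)) / (2 * eps),
                 bw$grads$phi1[j], tolerance = 1e-5)
  }
  # saturated-low gate: with large negative b2 the gate is ~0 and the skip
  # dominates, so d(alpha)/d(f) >= 1 elementwise on the diagonal
  plow <- ara_params(4)
  plow$phi1[] <- 0; plow$phi2[] <- 0; plow$b1[] <- 0; plow$b2[] <- -30
  for (j in sample(12, 3)) {
    f1 <- fT2; f1[j] <- f1[j] + eps
    f2 <- fT2; f2[j] <- f2[j] - eps
    d <- (loss(f1, fDWI, plow) - loss(f2, fDWI, plow)) / (2 * eps)
    # with gate ~ 0, alpha = f exactly, so the derivative equals dT2[j]
    expect_equal(d, dT2[j], tolerance = 1e-6)
  }
})

test_that("fuse_attended concatenates channels and restores the grid", {
  a1 <- matrix(1, 256, 512)
  a2 <- matrix(2, 256, 512)
  fused <- fuse_attended(a1, a2, c(4, 8, 8))
  expect_equal(dim(fused), c(1, 1024, 4, 8, 8))
  expect_true(all(fused[1, 1:512, , , ] == 1))
  expect_true(all(fused[1, 513:1024, , , ] == 2))
  # unflatten . flatten identity on the fused map
  expect_identical(unflatten_regions(flatten_regions(fused), c(4, 8, 8)),
                   fused)
  expect_error(fuse_attended(a1, a2, c(4, 8, 7)), "inconsistent")
  expect_error(ara_gate(matrix(0, 2, 4), matrix(0, 3, 4), ara_params(4)),
               "share")
})
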