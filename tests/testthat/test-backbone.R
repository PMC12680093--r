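fm <- asNamespace("fusemri")

full_backbone <- function() {
  memo("full_backbone", build_backbone(backbone_plan(3), seed = 1))
}

test_that("shape_plan is pure floor((n + 2p - k)/s) + 1 bookkeeping", {
  # an all-stride-1, same-padding plan leaves every stage at the input size
  idplan <- backbone_plan(3)
  idplan$stem <- list(kernel = c(3L, 3L, 3L), stride = c(1L, 1L, 1L),
                      pad = c(1L, 1L, 1L))
  idplan$pool <- list(kernel = c(1L, 3L, 3L), stride = c(1L, 1L, 1L),
                      pad = c(0L, 1L, 1L))
  for (i in 1:4) idplan$stages[[i]]$stride <- c(1L, 1L, 1L)
  idplan$stages[[4]]$pad <- c(1L, 1L, 1L)
  sp <- shape_plan(c(18, 256, 256), idplan)
  expect_true(all(sp[, "depth"] == 18))
  expect_true(all(sp[, "height"] == 256))
  expect_true(all(sp[, "width"] == 256))

  # default plan reproduces the printed final-stage geometry (4, 8, 8)
  sp <- shape_plan(c(18, 256, 256), backbone_plan(3))
  expect_equal(unname(sp["stage4", ]), c(4, 8, 8))

  expect_error(shape_plan(c(2, 8, 8), backbone_plan(3)), "size < 1")
})

test_that("forward-pass shapes match the shape_plan arithmetic", {
  for (shape in list(c(8L, 64L, 64L), c(10L, 96L, 64L))) {
    plan <- backbone_plan(3, width_multiplier = 1 / 16, preset = "tiny")
    bb <- build_backbone(plan, seed = 2)
    f <- extract_layer4(bb, rand_volume(c(1, 3, shape)))
    expect_equal(dim(f)[3:5], unname(shape_plan(shape, plan)["stage4", ]))
    expect_equal(dim(f)[2], plan$widths[4])
  }
})

test_that("layer-4 channel count is 512 regardless of input size", {
  bb <- full_backbone()
  f <- extract_layer4(bb, rand_volume(c(1, 3, 8, 64, 64)))
  expect_equal(dim(f)[2], 512)
})

test_that("backbone building is seed-deterministic and from scratch", {
  plan <- backbone_plan(3, width_multiplier = 1 / 16, preset = "tiny")
  b1 <- build_backbone(plan, seed = 7)
  b2 <- build_backbone(plan, seed = 7)
  expect_identical(b1$stem$w, b2$stem$w)
  expect_identical(b1$stages[[4]][[2]]$conv2$w, b2$stages[[4]][[2]]$conv2$w)
  b3 <- build_backbone(plan, seed = 8)
  expect_false(identical(b1$stem$w, b3$stem$w))
  expect_equal(sapply(b1$stages, function(s) s[[1]]$conv1$out_channels),
               c(4, 8, 16, 32))
  expect_equal(backbone_plan(3)$widths, c(64, 128, 256, 512))
})

test_that("parameter count matches the closed-form block arithmetic", {
  plan <- backbone_plan(3)
  bb <- full_backbone()
  count_tree <- function(x) {
    if (is.numeric(x)) return(length(x))
    if (is.list(x)) {
      n <- 0
      nms <- names(x)
      for (i in seq_along(x)) {
        nm <- if (!is.null(nms)) nms[i] else ""
        if (nm %in% c("plan", "state")) next
        el <- x[[i]]
        if (is.numeric(el) && nm %in% c("w", "b", "gamma", "beta"))
          n <- n + length(el)
        else if (is.list(el)) n <- n + count_tree(el)
      }
      return(n)
    }
    0
  }
  got <- count_tree(bb)
  # independent hand-summed formula: convs carry no bias, each batch-norm
  # has gamma + beta
  w <- c(64, 128, 256, 512)
  expected <- 64 * 3 * prod(c(3, 7, 7)) + 2 * 64         # stem + bn
  in_ch <- 64
  shortcut_k <- list(NULL, c(1, 1, 1), c(1, 1, 1), c(3, 1, 1))
  for (s in 1:4) {
    # first block (possibly reducing)
    expected <- expected + w[s] * in_ch * 27 + 2 * w[s] +  # conv1 + bn1
      w[s] * w[s] * 27 + 2 * w[s]                          # conv2 + bn2
    if (!is.null(shortcut_k[[s]]) || in_ch != w[s])
      expected <- expected + w[s] * in_ch * prod(shortcut_k[[s]]) + 2 * w[s]
    # second block (identity shortcut)
    expected <- expected + 2 * (w[s] * w[s] * 27 + 2 * w[s])
    in_ch <- w[s]
  }
  expect_equal(got, expected)
})

test_that("batch slices are processed independently", {
  plan <- backbone_plan(3, width_multiplier = 1 / 16, preset = "tiny")
  bb <- build_backbone(plan, seed = 3)
  v <- rand_volume(c(1, 3, 8, 32, 32))
  two <- array(0, c(2, 3, 8, 32, 32))
  two[1, , , , ] <- v[1, , , , ]
  two[2, , , , ] <- v[1, , , , ]
  f <- extract_layer4(bb, two)
  expect_equal(f[1, , , , ], f[2, , , , ], tolerance = 1e-12)
})

test_that("a shifted input shifts the layer-4 energy argmax (covariance)", {
  plan <- backbone_plan(1, width_multiplier = 1 / 16, preset = "tiny")
  bb <- build_backbone(plan, seed = 4)
  stride_hw <- 8  # stem 2 x stage-2/3 strides 2*2
  blob <- function(h0) {
    x <- array(0, c(1, 1, 8, 64, 64))
    x[1, 1, 3:6, h0:(h0 + 3), 20:23] <- 1
    x
  }
  energy_h <- function(f) {
    e <- apply(f[1, , , , ]^2, 3, sum)  # sum over channels, depth, width
    which.max(e)
  }
  h1 <- energy_h(extract_layer4(bb, blob(16)))
  h2 <- energy_h(extract_layer4(bb, blob(16 + stride_hw)))
  expect_true(abs((h2 - h1) - 1) <= 1)
})

test_that("channel mismatches are rejected", {
  plan <- backbone_plan(3, width_multiplier = 1 / 16, preset = "tiny")
  bb <- build_backbone(plan, seed = 5)
  expect_error(extract_layer4(bb, rand_volume(c(1, 2, 8, 32, 32))),
               "channels")
})
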