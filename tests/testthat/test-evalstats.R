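test_that("confusion tabulates counts with rows = true, cols = predicted", {
  p <- prediction_set(paste0("p", 1:10),
                      true = c(0, 0, 1, 1, 1, 2, 2, 2, 2, 2),
                      pred = c(0, 0, 1, 1, 1, 2, 2, 2, 2, 2))
  expect_equal(unname(diag(confusion(p))), c(2, 3, 5))
  expect_equal(sum(confusion(p)) - sum(diag(confusion(p))), 0)
  p2 <- prediction_set("a", 1, 2)
  cm2 <- confusion(p2)
  expect_equal(unname(cm2["benign", "malignant"]), 1)
  expect_equal(sum(cm2), 1)
  # random 70-record set: matches the independent tally loop
  set.seed(8)
  true <- sample(0:2, 70, replace = TRUE)
  pred <- sample(0:2, 70, replace = TRUE)
  p3 <- prediction_set(sprintf("q%02d", 1:70), true, pred)
  expect_equal(unclass(confusion(p3)), tally_oracle(true, pred),
               ignore_attr = TRUE)
  expect_equal(unname(rowSums(confusion(p3))),
               unname(as.vector(table(factor(true, levels = 0:2)))))
  expect_error(prediction_set(c("a", "a"), c(0, 1), c(0, 1)), "unique")
  expect_error(prediction_set(c("a", "b"), c(0, 3), c(0, 1)), "labels")
})

test_that("macro metrics match hand-computed one-vs-rest tables", {
  perfect <- matrix(diag(c(2, 3, 5)), 3, 3)
  m <- macro_metrics(perfect)
  expect_equal(m$accuracy, 100)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 100)
  expect_equal(m$f1, 100)

  cm <- matrix(c(1, 1, 0,
                 0, 2, 0,
                 0, 0, 2), 3, 3, byrow = TRUE)
  m <- macro_metrics(cm)
  expect_equal(m$accuracy, 100 * 5 / 6, tolerance = 1e-10)
  # per-class sensitivities 1/2, 1, 1 -> macro 5/6
  expect_equal(m$sensitivity, 100 * 5 / 6, tolerance = 1e-10)
  # specificities: class0 4/4, class1 3/4, class2 4/4 -> macro 11/12
  expect_equal(m$specificity, 100 * 11 / 12, tolerance = 1e-10)
  # F1: class0 2/3 (P=1, R=1/2), class1 4/5 (P=2/3, R=1), class2 1
  expect_equal(m$f1, 100 * mean(c(2 / 3, 4 / 5, 1)), tolerance = 1e-10)
  expect_length(m$flags, 0)

  # an empty predicted class still yields a defined specificity
  cm2 <- matrix(c(2, 0, 0,
                  1, 1, 0,
                  1, 0, 1), 3, 3, byrow = TRUE)
  m2 <- macro_metrics(cm2)
  expect_true(is.finite(m2$specificity))

  # a class absent from the truth is excluded and flagged
  cm3 <- matrix(c(2, 1, 0,
                  1, 2, 0,
                  0, 0, 0), 3, 3, byrow = TRUE)
  m3 <- macro_metrics(cm3)
  expect_equal(m3$sensitivity, 100 * mean(c(2 / 3, 2 / 3)), tolerance = 1e-10)
  expect_gt(length(m3$flags), 0)
  expect_error(macro_metrics(matrix(0, 3, 3)), "no observations")
})

test_that("cohen's kappa matches hand arithmetic and its edge rules", {
  expect_equal(cohen_kappa(diag(c(2, 3, 5))), 100)
  expect_equal(as.numeric(cohen_kappa(matrix(1, 2, 2))), 0)
  cm <- matrix(c(1, 1, 0,
                 0, 2, 0,
                 0, 0, 2), 3, 3, byrow = TRUE)
  po <- 5 / 6
  pe <- (2 * 1 + 2 * 3 + 2 * 2) / 36  # sum of row_i * col_i / total^2
  expect_equal(cohen_kappa(cm), 100 * (po - pe) / (1 - pe),
               tolerance = 1e-10)
  # all mass in a single cell: pe = 1, defined as 0 with a flag
  one <- matrix(0, 3, 3); one[1, 1] <- 4
  k <- cohen_kappa(one)
  expect_equal(as.numeric(k), 0)
  expect_false(is.null(attr(k, "flag")))
  # invariant to simultaneous row/column relabeling
  set.seed(9)
  cmr <- matrix(sample(0:5, 9, replace = TRUE), 3, 3)
  perm <- c(3, 1, 2)
  expect_equal(cohen_kappa(cmr), cohen_kappa(cmr[perm, perm]),
               tolerance = 1e-12)
})

test_that("prediction-order invariance of the metrics", {
  set.seed(10)
  true <- sample(0:2, 30, replace = TRUE)
  pred <- sample(0:2, 30, replace = TRUE)
  p1 <- prediction_set(sprintf("r%02d", 1:30), true, pred)
  perm <- sample(30)
  p2 <- prediction_set(sprintf("r%02d", 1:30)[perm], true[perm], pred[perm])
  expect_equal(glance(macro_metrics(confusion(p1))),
               glance(macro_metrics(confusion(p2))))
})

test_that("bootstrap CI: degenerate all-correct set gives (100, 100)", {
  p <- prediction_set(paste0("p", 1:6), rep(0:2, 2), rep(0:2, 2))
  bs <- bootstrap_ci(p, "macro_f1", B = 200, seed = 4)
  expect_equal(bs$point, 100)
  expect_equal(c(bs$ci_low, bs$ci_high), c(100, 100))
  bk <- bootstrap_ci(p, "kappa", B = 200, seed = 4)
  expect_equal(bk$ci_low, 100)
})

test_that("bootstrap matches exhaustive enumeration on an n = 4 set", {
  true <- c(0L, 1L, 2L, 0L)
  pred <- c(0L, 1L, 2L, 1L)  # one error
  p <- prediction_set(paste0("p", 1:4), true, pred)
  # exact distribution: all 4^4 = 256 equally likely index multisets
  grid <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  exact <- apply(grid, 1, function(idx) macro_f1_oracle(true[idx], pred[idx]))
  exact_ci <- unname(quantile(exact, c(0.025, 0.975)))
  exact_mean <- mean(exact)
  bs <- bootstrap_ci(p, "macro_f1", B = 50000, seed = 2)
  expect_lt(abs(bs$ci_low - exact_ci[1]), 2)
  expect_lt(abs(bs$ci_high - exact_ci[2]), 2)
  expect_lt(abs(bs$point - exact_mean), 2)
  # seeded bootstrap reproduces bit-for-bit; endpoints within resample range
  bs2 <- bootstrap_ci(p, "macro_f1", B = 50000, seed = 2)
  expect_identical(tidy(bs), tidy(bs2))
  expect_gte(bs$ci_low, bs$resample_min)
  expect_lte(bs$ci_high, bs$resample_max)
})

test_that("paired differences use one index multiset for both models", {
  p <- prediction_set(paste0("p", 1:6), rep(0:2, 2), rep(0:2, 2))
  d0 <- paired_diff_ci(p, p, "macro_f1", B = 200, seed = 1)
  expect_equal(c(d0$ci_low, d0$ci_high), c(0, 0))
  expect_false(d0$excludes_zero)
  wrong <- prediction_set(paste0("p", 1:6), rep(0:2, 2),
                          (rep(0:2, 2) + 1L) %% 3L)
  d1 <- paired_diff_ci(p, wrong, "macro_f1", B = 200, seed = 1)
  expect_equal(c(d1$point, d1$ci_low, d1$ci_high), c(100, 100, 100))
  expect_true(d1$excludes_zero)
  expect_error(paired_diff_ci(p, prediction_set("x", 0, 0)), "patient_ids")

  # n = 4 paired enumeration oracle
  true <- c(0L, 1L, 2L, 0L)
  pa <- c(0L, 1L, 2L, 1L)
  pb <- c(0L, 2L, 2L, 1L)
  sa <- prediction_set(paste0("p", 1:4), true, pa)
  sb <- prediction_set(paste0("p", 1:4), true, pb)
  grid <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  exact <- apply(grid, 1, function(idx)
    macro_f1_oracle(true[idx], pa[idx]) - macro_f1_oracle(true[idx], pb[idx]))
  exact_ci <- unname(quantile(exact, c(0.025, 0.975)))
  d <- paired_diff_ci(sa, sb, "macro_f1", B = 50000, seed = 3)
  expect_lt(abs(d$ci_low - exact_ci[1]), 2)
  expect_lt(abs(d$ci_high - exact_ci[2]), 2)
})

test_that("reports round-trip through CSV and JSON", {
  p <- prediction_set(paste0("p", 1:6), rep(0:2, 2), c(0, 1, 2, 0, 1, 1))
  csv <- tempfile(fileext = ".csv")
  write_predictions(p, csv)
  p2 <- read_predictions(csv)
  expect_equal(p2$true, p$true)
  expect_equal(p2$pred, p$pred)
  rep <- eval_report(p, B = 100, seed = 6)
  js <- tempfile(fileext = ".json")
  write_report(rep, js)
  back <- jsonlite::read_json(js)
  expect_equal(back$accuracy, rep$accuracy, tolerance = 1e-9)
  expect_equal(back$kappa, rep$kappa, tolerance = 1e-9)
  unlink(c(csv, js))
})
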