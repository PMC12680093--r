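#' Load one patient's volumes from a manifest row
#'
#' Reads the DWI (4-D, three b-value volumes) and T2 (3-D) NIfTI files,
#' transposes from the on-disk `(height, width, depth)` order to the
#' in-memory `(channels, depth, height, width)` contract, and z-scores each
#' channel (mean 0, s.d. 1 over the volume). Scanner units are arbitrary, so
#' per-volume per-channel standardization is applied at load time; a
#' constant (zero-variance) channel maps to all zeros.
#'
#' @param row A one-row data frame with `patient_id`, `label`, `dwi_path`,
#'   `t2_path` (a manifest row; see [write_cohort()]).
#' @param normalize Apply z-score normalization (default `TRUE`).
#' @return A `patient_sample`.
#' @export
load_sample <- function(row, normalize = TRUE) {
  if (!file.exists(row$dwi_path) || !file.exists(row$t2_path))
    stop("missing volume file(s) for patient ", row$patient_id,
         call. = FALSE)
  dwi_store <- as.array(RNifti::readNifti(row$dwi_path))  # (H, W, D, 3)
  t2_store <- as.array(RNifti::readNifti(row$t2_path))    # (H, W, D)
  if (length(dim(dwi_store)) != 4L || dim(dwi_store)[4] != 3L)
    stop("DWI volume for ", row$patient_id,
         " is not 4-D with 3 b-value channels", call. = FALSE)
  if (length(dim(t2_store)) != 3L)
    stop("T2 volume for ", row$patient_id, " is not 3-D", call. = FALSE)
  if (!all(dim(t2_store)[1:2] == 2L * dim(dwi_store)[1:2]) ||
      dim(t2_store)[3] != dim(dwi_store)[3])
    stop("T2/DWI geometry mismatch for ", row$patient_id, call. = FALSE)
  dwi <- aperm(dwi_store, c(4L, 3L, 1L, 2L))  # (C, D, H, W)
  t2 <- aperm(t2_store, c(3L, 1L, 2L))
  dim(dwi) <- c(1L, dim(dwi))
  dim(t2) <- c(1L, 1L, dim(t2))
  s <- structure(list(patient_id = as.character(row$patient_id),
                      dwi = dwi, t2 = t2, label = as.integer(row$label),
                      lesion_mask = NULL, lesion = NULL),
                 class = "patient_sample")
  if (normalize) normalize_sample(s) else s
}

#' Per-volume per-channel z-score normalization of a patient sample
#'
#' @param s A `patient_sample`.
#' @return The sample with each channel standardized (zero-variance guard:
#'   constant channels become all zeros).
#' @export
normalize_sample <- function(s) {
  zscore <- function(v) {
    m <- mean(v); sd <- stats::sd(as.vector(v))
    if (!is.finite(sd) || sd == 0) return(array(0, dim(v)))
    (v - m) / sd
  }
  for (k in seq_len(dim(s$dwi)[2]))
    s$dwi[1, k, , , ] <- zscore(s$dwi[1, k, , , ])
  s$t2[1, 1, , , ] <- zscore(s$t2[1, 1, , , ])
  s
}

#' Read a cohort manifest CSV
#'
#' @param path Manifest path (columns `patient_id,label,dwi_path,t2_path`;
#'   relative volume paths are resolved against the manifest's directory).
#' @return A tibble.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "label", "dwi_path", "t2_path")
  if (!all(req %in% names(df)))
    stop("manifest needs columns ", paste(req, collapse = ","),
         call. = FALSE)
  base <- dirname(path)
  fix <- function(p) ifelse(file.exists(p), p, file.path(base, basename(p)))
  df$dwi_path <- fix(df$dwi_path)
  df$t2_path <- fix(df$t2_path)
  tibble::as_tibble(df)
}

#' Patient-level leave-one-out folds
#'
#' One fold per patient: the fold's test set is that single patient and the
#' training set is everyone else, so no patient's data can appear on both
#' sides.
#'
#' @param ids Character vector of patient ids (or a manifest data frame with
#'   a `patient_id` column).
#' @return A list of `list(train_ids, test_id)`.
#' @export
loocv_folds <- function(ids) {
  if (is.data.frame(ids)) ids <- ids$patient_id
  ids <- as.character(ids)
  if (length(ids) < 2L) stop("need at least 2 patients", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate patient ids", call. = FALSE)
  lapply(seq_along(ids), function(i)
    list(train_ids = ids[-i], test_id = ids[i]))
}

#' Training configuration
#'
#' Optimization settings for one cross-validation fold: AdamW (decoupled
#' weight decay) at learning rate 0.001, batch size 8, cross-entropy loss
#' and a cosine annealing schedule decaying to zero over the epoch budget.
#' The epoch budget is a fixed per-fold training length (leave-one-out
#' cross-validation leaves no validation split to stop early on): 50 epochs
#' for the full preset, 24 for the reduced-width tiny preset.
#'
#' @param learning_rate Initial learning rate (default 0.001).
#' @param batch_size Batch size; `NULL` picks the preset default (8 for the
#'   full geometry; 4 for the tiny preset, where 11-sample training sets
#'   get three optimizer steps per epoch at identical arithmetic cost).
#'   The last batch keeps the remainder.
#' @param epochs Epoch count; `NULL` picks the preset default.
#' @param weight_decay Decoupled weight decay on convolution/linear weight
#'   matrices (default 0.01).
#' @param augment Seeded random in-plane flips of each training sample,
#'   both modalities flipped together; a standard regularizer for small
#'   cohorts. Default `TRUE`.
#' @param preset `"full"` or `"tiny"`.
#' @param seed Root seed controlling initialization, batching, augmentation
#'   and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = NULL,
                         epochs = NULL, weight_decay = 0.01, augment = TRUE,
                         preset = c("full", "tiny"), seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(batch_size)) batch_size <- if (preset == "tiny") 4L else 8L
  if (is.null(epochs)) epochs <- if (preset == "tiny") 24L else 50L
  if (learning_rate <= 0 || batch_size < 1L || epochs < 0L)
    stop("learning_rate > 0, batch_size >= 1, epochs >= 0 required",
         call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), weight_decay = weight_decay,
                 augment = isTRUE(augment),
                 preset = preset, seed = as.integer(seed)),
            class = "train_config")
}

#' Cosine annealing learning rate
#'
#' `lr(e) = lr0 * (1 + cos(pi * e / (E - 1))) / 2` for epoch
#' `e = 0 .. E-1`: starts at `lr0` and anneals to exactly zero at the final
#' epoch.
#'
#' @param epoch 0-based epoch index.
#' @param epochs Total epoch count.
#' @param lr0 Initial learning rate.
#' @return Numeric learning rate.
#' @export
cosine_lr <- function(epoch, epochs, lr0) {
  if (epochs <= 1L) return(lr0)
  lr0 * 0.5 * (1 + cos(pi * epoch / (epochs - 1)))
}

# ---- parameter-tree utilities -------------------------------------------

TRAINABLE_NAMES <- c("w", "b", "gamma", "beta", "phi1", "phi2", "b1", "b2")
SKIP_SUBTREES <- c("config", "plan", "state", "cache")

# Enumerate paths (character vectors; stage/block indices encoded as
# numbers) of every trainable leaf in a gradient or model tree.
grad_paths <- function(tree, prefix = character()) {
  out <- list()
  nms <- names(tree)
  for (i in seq_along(tree)) {
    nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
    if (nm %in% SKIP_SUBTREES) next
    el <- tree[[i]]
    if (is.null(el)) next
    if (is.numeric(el) && nm %in% TRAINABLE_NAMES) {
      out[[length(out) + 1L]] <- c(prefix, nm)
    } else if (is.list(el)) {
      out <- c(out, grad_paths(el, c(prefix, nm)))
    }
  }
  out
}

tree_get <- function(tree, path) {
  for (nm in path) {
    idx <- suppressWarnings(as.integer(nm))
    tree <- if (!is.na(idx) && is.null(names(tree))) tree[[idx]]
            else tree[[nm]]
  }
  tree
}

tree_set <- function(tree, path, value) {
  nm <- path[1]
  idx <- suppressWarnings(as.integer(nm))
  key <- if (!is.na(idx) && is.null(names(tree))) idx else nm
  if (length(path) == 1L) tree[[key]] <- value
  else tree[[key]] <- tree_set(tree[[key]], path[-1], value)
  tree
}

adamw_state <- function() {
  e <- new.env(parent = emptyenv())
  e$t <- 0L
  e$m <- list()
  e$v <- list()
  e
}

# One AdamW step; decoupled weight decay applied only to weight matrices
# (w/phi1/phi2), never to biases or normalization scales.
adamw_step <- function(model, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (path in grad_paths(grads)) {
    key <- paste(path, collapse = "/")
    g <- tree_get(grads, path)
    p <- tree_get(model, path)
    m <- state$m[[key]]
    v <- state$v[[key]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    state$m[[key]] <- m
    state$v[[key]] <- v
    upd <- (m / bc1) / (sqrt(v / bc2) + eps)
    decay <- if (path[length(path)] %in% c("w", "phi1", "phi2"))
      weight_decay else 0
    p <- p - lr * (upd + decay * p)
    model <- tree_set(model, path, p)
  }
  model
}

# Assemble a batch, optionally applying per-sample augmentation (random
# in-plane flips, both modalities transformed together).
stack_batch <- function(vols, aug = NULL) {
  d1 <- dim(vols[[1]])
  H <- d1[4]; W <- d1[5]
  out <- array(0, c(length(vols), d1[2:5]))
  for (i in seq_along(vols)) {
    v <- vols[[i]][1, , , , , drop = FALSE]
    if (!is.null(aug)) {
      a <- aug[[i]]
      if (a$flip[1]) v <- v[, , , rev(seq_len(H)), , drop = FALSE]
      if (a$flip[2]) v <- v[, , , , rev(seq_len(W)), drop = FALSE]
    }
    out[i, , , , ] <- v[1, , , , ]
  }
  out
}

draw_augment <- function(n, enabled) {
  if (!enabled) return(NULL)
  lapply(seq_len(n), function(i) list(flip = stats::runif(2) < 0.5))
}

#' Train one leave-one-out fold
#'
#' Builds a freshly initialized model for the fold, optimizes cross-entropy
#' on the training patients with AdamW and cosine annealing, and predicts
#' the held-out patient with argmax logits in eval mode. Fully seeded: the
#' same fold, configs and seed reproduce the result exactly.
#'
#' @param fold A `list(train_ids, test_id)` from [loocv_folds()].
#' @param samples Named list of normalized `patient_sample`s covering all
#'   ids.
#' @param config A [model_config()].
#' @param tconf A [train_config()].
#' @param fold_seed Integer seed for this fold.
#' @return A one-row tibble: `patient_id`, `true`, `pred`, per-class
#'   probabilities, `epochs`, `final_loss`.
#' @export
train_fold <- function(fold, samples, config, tconf,
                       fold_seed = tconf$seed) {
  if (fold$test_id %in% fold$train_ids)
    stop("leakage: held-out patient ", fold$test_id,
         " appears in the training set", call. = FALSE)
  with_local_seed(fold_seed, {
    model <- build_model(config, seed = NULL)
    state <- adamw_state()
    train <- samples[fold$train_ids]
    labels_all <- vapply(train, function(s) s$label, integer(1))
    n <- length(train)
    final_loss <- NA_real_
    if (tconf$epochs > 0L && n > 0L) {
      for (epoch in seq_len(tconf$epochs) - 1L) {
        lr <- cosine_lr(epoch, tconf$epochs, tconf$learning_rate)
        ord <- sample.int(n)
        starts <- seq(1L, n, by = tconf$batch_size)
        for (s0 in starts) {
          idx <- ord[s0:min(s0 + tconf$batch_size - 1L, n)]
          flips <- draw_augment(length(idx), tconf$augment)
          dwi <- if (uses_dwi(config))
            stack_batch(lapply(train[idx], `[[`, "dwi"), flips) else NULL
          t2 <- if (uses_t2(config))
            stack_batch(lapply(train[idx], `[[`, "t2"), flips) else NULL
          fw <- model_fwd(model, dwi, t2, train = TRUE)
          ce <- cross_entropy(fw$logits, labels_all[idx])
          if (!is.finite(ce$loss))
            stop("non-finite training loss at epoch ", epoch,
                 " (lr = ", signif(lr, 3), ")", call. = FALSE)
          bw <- model_bwd(model, ce$dlogits, fw$cache)
          model <- adamw_step(model, bw$grads, state, lr,
                              tconf$weight_decay)
          final_loss <- ce$loss
        }
      }
    }
    ts <- samples[[fold$test_id]]
    logits <- model_fwd(model,
                        if (uses_dwi(config)) ts$dwi else NULL,
                        if (uses_t2(config)) ts$t2 else NULL,
                        train = FALSE)$logits
    probs <- exp(logits[1, ] - max(logits[1, ]))
    probs <- probs / sum(probs)
    tibble::tibble(patient_id = fold$test_id, true = ts$label,
                   pred = which.max(logits[1, ]) - 1L,
                   p_normal = probs[1], p_benign = probs[2],
                   p_malignant = probs[3],
                   epochs = tconf$epochs, final_loss = final_loss)
  })
}

#' Run full patient-level LOOCV
#'
#' Normalizes the cohort, builds one fold per patient, trains each fold from
#' scratch and concatenates the held-out predictions into a
#' [prediction_set()]. The fold invariant (held-out patient absent from the
#' training set) is re-asserted before every fold.
#'
#' @param x A manifest data frame (see [read_manifest()]) or a list of
#'   `patient_sample`s (e.g. [generate_cohort()] output).
#' @param config A [model_config()].
#' @param tconf A [train_config()].
#' @param verbose Print per-fold progress lines.
#' @return A `prediction_set` tibble with a `fold` column.
#' @export
run_loocv <- function(x, config, tconf, verbose = FALSE) {
  samples <- if (is.data.frame(x)) {
    lapply(seq_len(nrow(x)), function(i) load_sample(x[i, ]))
  } else {
    lapply(x, normalize_sample)
  }
  names(samples) <- vapply(samples, function(s) s$patient_id, character(1))
  folds <- loocv_folds(names(samples))
  fold_seeds <- with_local_seed(tconf$seed,
                                sample.int(.Machine$integer.max - 1L,
                                           length(folds)))
  rows <- lapply(seq_along(folds), function(i) {
    if (verbose)
      message(sprintf("fold %d/%d: held-out %s", i, length(folds),
                      folds[[i]]$test_id))
    train_fold(folds[[i]], samples, config, tconf, fold_seed = fold_seeds[i])
  })
  res <- do.call(rbind, rows)
  out <- prediction_set(res$patient_id, res$true, res$pred,
                        fold = seq_along(folds))
  out$p_normal <- res$p_normal
  out$p_benign <- res$p_benign
  out$p_malignant <- res$p_malignant
  out
}

#' Train a single model on a whole cohort
#'
#' Convenience wrapper (no cross-validation): trains on every sample, for
#' downstream use such as Grad-CAM inspection.
#'
#' @inheritParams run_loocv
#' @return A trained `fusemri_model`.
#' @export
train_model <- function(x, config, tconf) {
  samples <- if (is.data.frame(x)) {
    lapply(seq_len(nrow(x)), function(i) load_sample(x[i, ]))
  } else {
    lapply(x, normalize_sample)
  }
  names(samples) <- vapply(samples, function(s) s$patient_id, character(1))
  ids <- names(samples)
  # reuse the fold trainer with a dummy held-out patient appended
  with_local_seed(tconf$seed, {
    model <- build_model(config, seed = NULL)
    state <- adamw_state()
    labels_all <- vapply(samples, function(s) s$label, integer(1))
    n <- length(samples)
    if (tconf$epochs > 0L) {
      for (epoch in seq_len(tconf$epochs) - 1L) {
        lr <- cosine_lr(epoch, tconf$epochs, tconf$learning_rate)
        ord <- sample.int(n)
        for (s0 in seq(1L, n, by = tconf$batch_size)) {
          idx <- ord[s0:min(s0 + tconf$batch_size - 1L, n)]
          flips <- draw_augment(length(idx), tconf$augment)
          dwi <- if (uses_dwi(config))
            stack_batch(lapply(samples[idx], `[[`, "dwi"), flips) else NULL
          t2 <- if (uses_t2(config))
            stack_batch(lapply(samples[idx], `[[`, "t2"), flips) else NULL
          fw <- model_fwd(model, dwi, t2, train = TRUE)
          ce <- cross_entropy(fw$logits, labels_all[idx])
          if (!is.finite(ce$loss))
            stop("non-finite training loss at epoch ", epoch, call. = FALSE)
          bw <- model_bwd(model, ce$dlogits, fw$cache)
          model <- adamw_step(model, bw$grads, state, lr,
                              tconf$weight_decay)
        }
      }
    }
    model
  })
}
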