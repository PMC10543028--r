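# Tile feature extraction and autoencoder compression. Every tile is
# represented by a 2,048-vector; a pluggable backend fills it. The bundled
# deterministic "texture" backend summarizes channel statistics, gradient
# histograms, block means and neighbor-difference statistics, zero-padded to
# 2,048 — fully reproducible from tile bytes with no external weights. A
# pretrained CNN backbone (2,048-feature penultimate layer) can be plugged in
# as `backend_fun` for production imaging runs.

FEATURE_DIM <- 2048L
BOTTLENECK_DIM <- 512L

block_means <- function(m, nb) {
  # means over nb row-blocks; contiguous-reshape fast path when nb divides
  rb <- function(m, nb) {
    H <- nrow(m)
    if (H %% nb == 0L) {
      colMeans(array(m, c(H %/% nb, nb, ncol(m))))
    } else {
      ri <- floor((seq_len(H) - 1L) * nb / H) + 1L
      rowsum(m, ri) / as.vector(table(ri))
    }
  }
  t(rb(t(rb(m, nb)), nb))
}

texture_features <- function(pixels) {
  p <- pixels / 255
  gray <- 0.299 * p[, , 1L] + 0.587 * p[, , 2L] + 0.114 * p[, , 3L]
  ch <- lapply(1:3, function(c) p[, , c])

  means <- vapply(ch, mean, numeric(1))
  sds <- vapply(ch, sd, numeric(1))
  qs <- unlist(lapply(ch, quantile, probs = c(0, 0.25, 0.5, 0.75, 1), names = FALSE))

  # gradient-magnitude histogram on gray (finite central differences)
  H <- nrow(gray); W <- ncol(gray)
  gx <- cbind(gray[, 2L] - gray[, 1L],
              (gray[, 3:W, drop = FALSE] - gray[, 1:(W - 2L), drop = FALSE]) / 2,
              gray[, W] - gray[, W - 1L])
  gy <- rbind(gray[2L, ] - gray[1L, ],
              (gray[3:H, , drop = FALSE] - gray[1:(H - 2L), , drop = FALSE]) / 2,
              gray[H, ] - gray[H - 1L, ])
  mag <- pmin(sqrt(gx^2 + gy^2), 1)
  ghist <- tabulate(pmin(floor(mag * 16) + 1L, 16L), 16L) / length(mag)

  blocks8 <- as.vector(block_means(gray, 8L))
  blocks4 <- unlist(lapply(ch, function(m) as.vector(block_means(m, 4L))))
  rprof <- as.vector(block_means(matrix(rowMeans(gray), ncol = 1L), 16L))
  cprof <- as.vector(block_means(matrix(colMeans(gray), nrow = 1L), 16L))

  diffs <- unlist(lapply(ch, function(m) {
    dh <- m[, -1L, drop = FALSE] - m[, -ncol(m), drop = FALSE]
    dv <- m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
    c(mean(abs(dh)), mean(abs(dv)), sd(dh), sd(dv))
  }))

  v <- c(means, sds, qs, ghist, blocks8, blocks4, rprof, cprof, diffs)
  c(v, numeric(FEATURE_DIM - length(v)))
}

#' Extract per-tile feature vectors
#'
#' Computes one 2,048-dimensional feature vector for each retained tile of
#' each tile set. The `"texture"` backend is deterministic and
#' self-contained; a custom backend (e.g. the penultimate layer of a
#' pretrained 50-layer residual network, whose feature width this contract
#' mirrors) is supplied as `backend_fun(pixels) -> numeric(2048)`.
#'
#' @param tilesets a `tile_set` or list of `tile_set`s, resized to the same
#'   edge (224 by default upstream).
#' @param backend `"texture"` or `"custom"`.
#' @param backend_fun function mapping a tile pixel array to a 2,048-vector
#'   (required when `backend = "custom"`).
#' @return a `feature_matrix`: tiles x 2048 matrix with `tile_id` rownames
#'   and attributes `backend_tag` and `tile_info` (slide/patient lineage per
#'   row, in manifest order).
#' @export
extract_features <- function(tilesets, backend = c("texture", "custom"),
                             backend_fun = NULL) {
  backend <- match.arg(backend)
  if (backend == "custom" && !is.function(backend_fun)) {
    stop_input("backend = \"custom\" requires backend_fun")
  }
  if (inherits(tilesets, "tile_set")) tilesets <- list(tilesets)
  fun <- if (backend == "texture") texture_features else backend_fun

  rows <- list(); info <- list()
  for (ts in tilesets) {
    stopifnot(inherits(ts, "tile_set"))
    edge <- ts$tiling_params$resize_edge
    if (is.na(edge)) stop_input("tiles of slide %s have not been resized", ts$slide_id)
    for (tl in ts$tiles) {
      if (!isTRUE(tl$retained)) next
      if (dim(tl$pixels)[1L] != edge) {
        stop_input("tile (%d,%d) of slide %s is not at the resize edge",
                   tl$grid_row, tl$grid_col, ts$slide_id)
      }
      v <- fun(tl$pixels)
      if (length(v) != FEATURE_DIM) {
        stop_input("backend returned %d features (expected %d)", length(v), FEATURE_DIM)
      }
      id <- sprintf("%s_%d_%d", ts$slide_id, tl$grid_row, tl$grid_col)
      rows[[id]] <- v
      info[[id]] <- data.frame(tile_id = id, slide_id = ts$slide_id,
                               patient_id = ts$patient_id,
                               grid_row = tl$grid_row, grid_col = tl$grid_col,
                               stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop_input("no retained tiles to featurize")
  feats <- do.call(rbind, rows)
  feature_matrix(feats, do.call(rbind, info), backend_tag = backend)
}

#' Construct a feature matrix
#'
#' @param features tiles x d numeric matrix.
#' @param tile_info data.frame with at least `tile_id`, `slide_id`,
#'   `patient_id`, one row per feature row.
#' @param backend_tag provenance string for the backend that produced the
#'   features.
#' @return a `feature_matrix`.
#' @export
feature_matrix <- function(features, tile_info, backend_tag = "custom") {
  features <- as.matrix(features)
  stopifnot(nrow(features) == nrow(tile_info), all(is.finite(features)))
  rownames(features) <- tile_info$tile_id
  structure(features, tile_info = tile_info, backend_tag = backend_tag,
            class = c("feature_matrix", "matrix"))
}

tile_info <- function(features) attr(features, "tile_info")

# Row subset that keeps the feature_matrix attributes in step.
fm_rows <- function(features, rows) {
  feature_matrix(unclass(features)[rows, , drop = FALSE],
                 tile_info(features)[rows, , drop = FALSE],
                 backend_tag = attr(features, "backend_tag"))
}

#' Train the feature-compression autoencoder
#'
#' A 2048 -> 512 -> 2048 network (ReLU bottleneck, linear output) trained
#' with Adam on mean squared reconstruction error. A seeded fraction of tiles
#' is held out as the validation set for early stopping (patience on
#' validation loss, best-epoch weights restored). Compressing raw backbone
#' features this way strips always-zero coordinates and noise before
#' regression.
#'
#' @param features a `feature_matrix` of raw (2,048-wide) tile features.
#' @param config a [training_config()].
#' @param val_frac fraction of tiles held out for early stopping.
#' @return an `autoencoder_model` with the fitted weights and final
#'   training/validation MSE.
#' @export
train_autoencoder <- function(features, config = training_config(), val_frac = 0.1) {
  stopifnot(inherits(features, "feature_matrix"))
  if (ncol(features) != FEATURE_DIM) {
    stop_input("autoencoder expects %d input features, got %d", FEATURE_DIM, ncol(features))
  }
  if (nrow(features) < 2L) stop_input("need at least 2 tiles to fit the autoencoder")
  X <- unclass(features); attributes(X) <- attributes(X)["dim"]
  n <- nrow(X)
  vi <- with_seed(derive_seed(config$seed, 77L),
                  sample.int(n, max(1L, floor(n * val_frac))))
  fit <- nn_train(X[-vi, , drop = FALSE], X[-vi, , drop = FALSE],
                  hidden = BOTTLENECK_DIM, config = config,
                  val_x = X[vi, , drop = FALSE], val_y = X[vi, , drop = FALSE],
                  metric = "neg_mse", output = "linear")
  recon <- nn_forward(fit$net, X)
  structure(list(fit = fit, input_dim = FEATURE_DIM, bottleneck = BOTTLENECK_DIM,
                 fitted = TRUE, final_mse = mean((recon - X)^2),
                 val_mse = -fit$best_metric, config = config),
            class = "autoencoder_model")
}

#' @export
print.autoencoder_model <- function(x, ...) {
  cat(sprintf("<autoencoder_model> %d -> %d -> %d, MSE %.4g (val %.4g), %d epochs\n",
              x$input_dim, x$bottleneck, x$input_dim, x$final_mse, x$val_mse,
              x$fit$epochs_run))
  invisible(x)
}

# Cheap deterministic fingerprint of the encoder weights for provenance tags.
model_hash <- function(model) {
  w <- model$fit$net$W[[1L]]
  sprintf("%08x", as.integer(sum(abs(w)) * 1e3) %% 0xFFFFFFF)
}

#' Compress features through a fitted autoencoder
#'
#' @param features a `feature_matrix` of raw 2,048-wide features.
#' @param model a fitted `autoencoder_model`.
#' @return a `feature_matrix` of tiles x 512 bottleneck activations, row
#'   order preserved, `backend_tag` extended with the model fingerprint.
#' @export
compress_features <- function(features, model) {
  stopifnot(inherits(features, "feature_matrix"), inherits(model, "autoencoder_model"))
  if (!isTRUE(model$fitted)) stop_input("autoencoder model is not fitted")
  if (ncol(features) != model$input_dim) {
    stop_input("feature width %d does not match model input %d",
               ncol(features), model$input_dim)
  }
  X <- unclass(features); attributes(X) <- attributes(X)["dim"]
  Z <- relu(sweep(X %*% model$fit$net$W[[1L]], 2L, model$fit$net$b[[1L]], "+"))
  feature_matrix(Z, tile_info(features),
                 backend_tag = paste0(attr(features, "backend_tag"), "+ae:",
                                      model_hash(model)))
}

#' Reconstruct features through a fitted autoencoder
#'
#' Full encode-decode pass (2048 -> 512 -> 2048), mainly for inspecting
#' reconstruction error.
#'
#' @inheritParams compress_features
#' @return tiles x 2048 numeric matrix.
#' @export
reconstruct_features <- function(features, model) {
  stopifnot(inherits(features, "feature_matrix"), inherits(model, "autoencoder_model"))
  X <- unclass(features); attributes(X) <- attributes(X)["dim"]
  nn_forward(model$fit$net, X)
}
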