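# Per-tranche multi-task regression from compressed tile features to bulk
# expression, tile -> slide -> patient aggregation, and the direct supervised
# classification variant.

# Tile-level target matrix: every tile inherits the bulk expression vector of
# its slide's patient (bulk labels exist only at the slide level).
tile_targets <- function(features, expr, gene_ids) {
  info <- tile_info(features)
  missing_genes <- setdiff(gene_ids, rownames(expr))
  if (length(missing_genes)) {
    stop_input("tranche gene(s) absent from expression matrix: %s",
               paste(missing_genes, collapse = ", "))
  }
  missing_pat <- setdiff(unique(info$patient_id), colnames(expr))
  if (length(missing_pat)) {
    stop_input("no expression column for patient(s): %s",
               paste(missing_pat, collapse = ", "))
  }
  t(expr[gene_ids, info$patient_id, drop = FALSE])
}

#' Train one tranche's multi-task regressor
#'
#' Fits a 512 -> 512 -> (tranche genes) perceptron (ReLU hidden layer,
#' dropout, linear output) with Adam on mean squared error. The shared
#' hidden layer is what couples the genes of a tranche: input-to-hidden
#' weights are learned jointly across all of them, hidden-to-output weights
#' per gene. Training stops at `max_epochs`, or earlier when the average
#' per-gene Pearson correlation between predicted and actual expression on
#' the validation tiles has not improved for `patience` consecutive epochs;
#' the best-epoch weights are returned.
#'
#' @param train_features,val_features compressed (512-wide)
#'   `feature_matrix` objects; every tile inherits its slide's bulk
#'   expression as its regression target.
#' @param train_expr,val_expr genes x samples expression matrix with
#'   patient identifiers as colnames (both may be the same matrix).
#' @param tranche a `gene_tranche` from [make_tranches()].
#' @param config a [training_config()].
#' @param hidden hidden-layer width (512 by default).
#' @return a `tranche_regressor`.
#' @export
train_tranche_model <- function(train_features, train_expr, val_features, val_expr,
                                tranche, config = training_config(), hidden = 512L) {
  stopifnot(inherits(tranche, "gene_tranche"), nrow(val_features) >= 1L)
  if (ncol(train_features) != BOTTLENECK_DIM) {
    stop_input("regressor expects %d compressed features, got %d",
               BOTTLENECK_DIM, ncol(train_features))
  }
  ytr <- tile_targets(train_features, train_expr, tranche$gene_ids)
  yva <- tile_targets(val_features, val_expr, tranche$gene_ids)
  # Conditioning: features are standardized and targets centered per gene on
  # the training tiles (statistics stored and reapplied at prediction), so
  # the optimizer budget goes into the image-driven expression variation
  # rather than into baselines and feature scales.
  mu <- colMeans(ytr)
  fstd <- feature_standardizer(train_features)
  fit <- nn_train(fstd$apply(train_features), sweep(ytr, 2L, mu), hidden = hidden,
                  config = config,
                  val_x = fstd$apply(val_features), val_y = sweep(yva, 2L, mu),
                  metric = "gene_cor", output = "linear")
  structure(list(fit = fit, gene_ids = tranche$gene_ids, target_means = mu,
                 feat_center = fstd$center, feat_scale = fstd$scale,
                 tranche_index = tranche$tranche_index,
                 input_dim = BOTTLENECK_DIM, hidden = hidden,
                 val_metric = fit$best_metric, config = config),
            class = "tranche_regressor")
}

strip_fm <- function(x) {
  x <- unclass(x)
  attributes(x) <- attributes(x)["dim"]
  x
}

# Per-column standardization fitted on training tiles; constant columns are
# left at scale 1 so zero-padded feature coordinates pass through unchanged.
feature_standardizer <- function(features) {
  x <- strip_fm(features)
  center <- colMeans(x)
  scale <- apply(x, 2L, sd)
  scale[scale < 1e-8] <- 1
  list(center = center, scale = scale,
       apply = function(f) sweep(sweep(strip_fm(f), 2L, center), 2L, scale, "/"))
}

apply_standardizer <- function(x, center, scale) {
  sweep(sweep(x, 2L, center), 2L, scale, "/")
}

#' @export
print.tranche_regressor <- function(x, ...) {
  cat(sprintf("<tranche_regressor> tranche %d: %d genes, val mean gene cor %.3f (%d epochs)\n",
              x$tranche_index, length(x$gene_ids), x$val_metric, x$fit$epochs_run))
  invisible(x)
}

#' Predict tile-level expression for one tranche
#'
#' @param model a fitted `tranche_regressor`.
#' @param features compressed `feature_matrix` (512-wide).
#' @return tiles x genes matrix (tile ids as rownames, tranche genes as
#'   colnames).
#' @export
predict_tiles <- function(model, features) {
  stopifnot(inherits(model, "tranche_regressor"))
  if (ncol(features) != model$input_dim) {
    stop_input("feature width %d does not match model input %d",
               ncol(features), model$input_dim)
  }
  x <- apply_standardizer(strip_fm(features), model$feat_center, model$feat_scale)
  out <- sweep(nn_forward(model$fit$net, x), 2L, model$target_means, "+")
  dimnames(out) <- list(rownames(features), model$gene_ids)
  out
}

#' Average tile-level predictions to slide level
#'
#' Bulk expression is a slide-level quantity, so per-tile predictions are
#' combined by their unweighted arithmetic mean over each slide's retained
#' tiles.
#'
#' @param tile_preds tiles x genes matrix.
#' @param tile_to_slide character vector, one slide id per row of
#'   `tile_preds`.
#' @param slides optional full slide set; a slide with no tiles raises an
#'   error naming it.
#' @return slides x genes matrix.
#' @export
aggregate_tiles_to_slide <- function(tile_preds, tile_to_slide, slides = NULL) {
  tile_preds <- as.matrix(tile_preds)
  stopifnot(length(tile_to_slide) == nrow(tile_preds))
  if (!is.null(slides)) {
    empty <- setdiff(slides, tile_to_slide)
    if (length(empty)) {
      stop_input("slide(s) with zero retained tiles: %s", paste(empty, collapse = ", "))
    }
  }
  g <- factor(tile_to_slide)
  out <- rowsum(tile_preds, g) / as.vector(table(g))
  rownames(out) <- levels(g)
  out
}

#' Average slide-level predictions to patient level
#'
#' @param slide_preds slides x genes matrix.
#' @param slide_to_patient character vector, one patient id per row.
#' @return patients x genes matrix.
#' @export
aggregate_slides_to_patient <- function(slide_preds, slide_to_patient) {
  aggregate_tiles_to_slide(slide_preds, slide_to_patient)
}

#' Train the direct supervised classifier
#'
#' The end-to-end comparator: the same compressed-feature front end with the
#' regression head replaced by a single logistic output trained with binary
#' cross-entropy. All tiles of a slide inherit the slide's binary response
#' label; tile scores are averaged back to slide scores with
#' [aggregate_tiles_to_slide()].
#'
#' @param train_features compressed `feature_matrix`.
#' @param labels named 0/1 vector of slide-level labels (names are slide
#'   ids covering every slide in `train_features`).
#' @param config a [training_config()].
#' @param val_features,val_labels optional validation set for early
#'   stopping; defaults to a seeded 20% slide-level split of the training
#'   data.
#' @param hidden hidden-layer width.
#' @return a `direct_classifier`.
#' @export
train_direct_classifier <- function(train_features, labels, config = training_config(),
                                    val_features = NULL, val_labels = NULL,
                                    hidden = 512L) {
  if (length(unique(labels)) < 2L) {
    stop_input("training labels contain a single class")
  }
  info <- tile_info(train_features)
  missing <- setdiff(unique(info$slide_id), names(labels))
  if (length(missing)) {
    stop_input("no label for slide(s): %s", paste(missing, collapse = ", "))
  }
  if (is.null(val_features)) {
    slides <- unique(info$slide_id)
    vs <- with_seed(derive_seed(config$seed, 101L),
                    sample(slides, max(1L, floor(length(slides) * 0.2))))
    vrows <- info$slide_id %in% vs
    val_features <- train_features[vrows, , drop = FALSE]
    attr(val_features, "tile_info") <- info[vrows, , drop = FALSE]
    val_labels <- labels
    train_rows <- !vrows
    ti <- info[train_rows, , drop = FALSE]
    train_features2 <- train_features[train_rows, , drop = FALSE]
    attr(train_features2, "tile_info") <- ti
    train_features <- train_features2
    info <- ti
  }
  ytr <- matrix(as.numeric(labels[info$slide_id]), ncol = 1L)
  yva <- matrix(as.numeric(val_labels[tile_info(val_features)$slide_id]), ncol = 1L)
  fstd <- feature_standardizer(train_features)
  fit <- nn_train(fstd$apply(train_features), ytr, hidden = hidden, config = config,
                  val_x = fstd$apply(val_features), val_y = yva,
                  metric = "neg_mse", output = "sigmoid")
  structure(list(fit = fit, input_dim = ncol(train_features), hidden = hidden,
                 feat_center = fstd$center, feat_scale = fstd$scale,
                 config = config),
            class = "direct_classifier")
}

#' Tile-level response scores from a direct classifier
#'
#' @param model a `direct_classifier`.
#' @param features compressed `feature_matrix`.
#' @return numeric vector of scores in `[0, 1]`, one per tile.
#' @export
predict_direct <- function(model, features) {
  stopifnot(inherits(model, "direct_classifier"))
  x <- apply_standardizer(strip_fm(features), model$feat_center, model$feat_scale)
  as.vector(nn_forward(model$fit$net, x, output = "sigmoid"))
}
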