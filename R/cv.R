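# Patient-level nested cross-validation, 25-model ensembling, rotation
# augmentation and leave-one-out evaluation of the direct classifier.

#' Build a patient-level nested fold plan
#'
#' Splits patients into `k_outer` near-equal outer folds and, within each
#' outer training set, `k_inner` inner folds. All splitting is at the
#' patient level: every slide (hence every tile) of a patient lands in its
#' patient's fold, which is what prevents information leakage between
#' training and held-out material.
#'
#' @param patients character vector of patient identifiers.
#' @param k_outer,k_inner fold counts (5 x 5 gives the standard 25-member
#'   ensemble).
#' @param seed integer; the plan is deterministic given the seed.
#' @return a `fold_plan`.
#' @export
make_fold_plan <- function(patients, k_outer = 5L, k_inner = 5L, seed = 1L) {
  patients <- unique(as.character(patients))
  if (length(patients) < k_outer) {
    stop_input("%d patients cannot fill %d outer folds", length(patients), k_outer)
  }
  outer <- with_seed(seed, {
    shuffled <- sample(patients)
    split(shuffled, rep_len(seq_len(k_outer), length(shuffled)))
  })
  inner <- lapply(seq_len(k_outer), function(o) {
    train_pats <- setdiff(patients, outer[[o]])
    if (length(train_pats) < k_inner) {
      stop_input("outer fold %d leaves %d training patients for %d inner folds",
                 o, length(train_pats), k_inner)
    }
    with_seed(derive_seed(seed, o), {
      shuffled <- sample(train_pats)
      split(shuffled, rep_len(seq_len(k_inner), length(shuffled)))
    })
  })
  plan <- structure(list(outer = outer, inner = inner, patients = patients,
                         k_outer = as.integer(k_outer), k_inner = as.integer(k_inner),
                         seed = as.integer(seed)),
                    class = "fold_plan")
  check_fold_plan(plan)
  plan
}

# Leakage / partition assertions, run on every plan.
check_fold_plan <- function(plan) {
  all_outer <- unlist(plan$outer)
  stopifnot(!anyDuplicated(all_outer), setequal(all_outer, plan$patients))
  for (o in seq_along(plan$inner)) {
    inn <- unlist(plan$inner[[o]])
    stopifnot(!anyDuplicated(inn),
              setequal(inn, setdiff(plan$patients, plan$outer[[o]])),
              length(intersect(inn, plan$outer[[o]])) == 0L)
  }
  invisible(TRUE)
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d patients, %d x %d folds, seed %d\n",
              length(x$patients), x$k_outer, x$k_inner, x$seed))
  invisible(x)
}

member_gene_ids <- function(tranches) unlist(lapply(tranches, `[[`, "gene_ids"))

# Full prediction path of one ensemble member: compress through the member's
# autoencoder, predict each tranche, stack, then tile -> slide -> patient.
predict_member <- function(member, features) {
  z <- compress_features(features, member$ae)
  preds <- do.call(cbind, lapply(member$regressors, predict_tiles, features = z))
  info <- tile_info(features)
  slide_pred <- aggregate_tiles_to_slide(preds, info$slide_id)
  s2p <- info$patient_id[match(rownames(slide_pred), info$slide_id)]
  aggregate_slides_to_patient(slide_pred, s2p)
}

#' Train the nested cross-validation ensemble
#'
#' For every outer fold, each of the `k_inner` inner models is trained on
#' the inner-training patients (its own autoencoder plus one regressor per
#' tranche, validated on the inner-validation patients for early stopping)
#' and predicts the outer fold's held-out patients; the inner models'
#' held-out predictions are averaged, and concatenating over outer folds
#' yields exactly one out-of-fold prediction per patient. All
#' `k_outer * k_inner` members (25 in the standard 5x5 plan) are retained
#' for external-cohort prediction.
#'
#' @param features raw (2,048-wide) `feature_matrix` for every retained
#'   tile of the cohort.
#' @param expr genes x samples normalized expression with patient ids as
#'   colnames.
#' @param tranches list from [make_tranches()].
#' @param plan a [make_fold_plan()] covering the cohort's patients.
#' @param config [training_config()] for the regressors; member seeds are
#'   derived from `config$seed` and the fold pair.
#' @param ae_config optional separate [training_config()] for autoencoders.
#' @return a `trained_ensemble` with `members`, `oof` (the patients x genes
#'   out-of-fold prediction matrix) and bookkeeping.
#' @export
nested_cv_train <- function(features, expr, tranches, plan,
                            config = training_config(), ae_config = config) {
  stopifnot(inherits(features, "feature_matrix"), inherits(plan, "fold_plan"))
  check_fold_plan(plan)
  # canonicalize tile order so results do not depend on manifest ordering
  # (minibatch composition would otherwise differ between equivalent inputs)
  info <- tile_info(features)
  features <- fm_rows(features, order(info$patient_id, info$slide_id, info$tile_id))
  info <- tile_info(features)
  missing <- setdiff(plan$patients, info$patient_id)
  if (length(missing)) {
    stop_input("no tiles for patient(s): %s", paste(missing, collapse = ", "))
  }
  genes <- member_gene_ids(tranches)
  members <- list()
  oof <- matrix(NA_real_, length(plan$patients), length(genes),
                dimnames = list(plan$patients, genes))

  for (o in seq_len(plan$k_outer)) {
    test_pat <- plan$outer[[o]]
    test_rows <- info$patient_id %in% test_pat
    fold_preds <- vector("list", plan$k_inner)
    for (i in seq_len(plan$k_inner)) {
      val_pat <- plan$inner[[o]][[i]]
      train_pat <- setdiff(plan$patients, c(test_pat, val_pat))
      tr_rows <- info$patient_id %in% train_pat
      va_rows <- info$patient_id %in% val_pat
      if (!any(tr_rows)) stop_input("outer %d / inner %d has zero training tiles", o, i)
      mseed <- derive_seed(config$seed, o * 100L + i)
      aec <- ae_config; aec$seed <- mseed
      rc <- config; rc$seed <- mseed

      ftr <- fm_rows(features, tr_rows)
      ae <- train_autoencoder(ftr, aec)
      ztr <- compress_features(ftr, ae)
      zva <- compress_features(fm_rows(features, va_rows), ae)
      regressors <- lapply(tranches, function(tr) {
        train_tranche_model(ztr, expr, zva, expr, tr, rc)
      })
      member <- structure(list(ae = ae, regressors = regressors,
                               outer = o, inner = i, seed = mseed),
                          class = "ensemble_member")
      members[[length(members) + 1L]] <- member
      fold_preds[[i]] <- predict_member(member, fm_rows(features, test_rows))
    }
    avg <- Reduce(`+`, fold_preds) / length(fold_preds)
    oof[rownames(avg), colnames(avg)] <- avg
  }

  structure(list(members = members, tranches = tranches, plan = plan,
                 oof = oof, genes = genes,
                 backend_tag = attr(features, "backend_tag"),
                 config = config),
            class = "trained_ensemble")
}

#' @export
print.trained_ensemble <- function(x, ...) {
  cat(sprintf("<trained_ensemble> %d members (%d x %d), %d genes, backend %s\n",
              length(x$members), x$plan$k_outer, x$plan$k_inner,
              length(x$genes), x$backend_tag))
  invisible(x)
}

#' Predict expression for new slides with a trained ensemble
#'
#' External-cohort prediction: the mean over the predictions of all ensemble
#' members (each through its own autoencoder and regressors), followed by
#' slide-to-patient averaging inside each member. `mode = "outer"` restricts
#' to the `k_inner` members of one outer fold (the averaging used for
#' held-out predictions during cross-validation).
#'
#' @param ensemble a `trained_ensemble`.
#' @param features raw `feature_matrix` of the new slides' retained tiles,
#'   produced with the same backend the ensemble was trained on.
#' @param mode `"all"` (default) or `"outer"`.
#' @param outer outer-fold index when `mode = "outer"`.
#' @return patients x genes prediction matrix.
#' @export
ensemble_predict <- function(ensemble, features, mode = c("all", "outer"), outer = 1L) {
  stopifnot(inherits(ensemble, "trained_ensemble"), inherits(features, "feature_matrix"))
  mode <- match.arg(mode)
  tag <- sub("\\+ae:.*$", "", attr(features, "backend_tag"))
  etag <- sub("\\+ae:.*$", "", ensemble$backend_tag)
  if (!identical(tag, etag)) {
    stop_input("feature backend '%s' does not match ensemble backend '%s'", tag, etag)
  }
  members <- ensemble$members
  if (mode == "outer") members <- Filter(function(m) m$outer == outer, members)
  preds <- lapply(members, predict_member, features = features)
  Reduce(`+`, preds) / length(preds)
}

#' Rotation-augmented slide prediction
#'
#' For small cohorts, predictions are averaged over the slide rotated by 0,
#' 90, 180 and 270 degrees (rotation happens at the slide level, before
#' tiling). Square slides yield four tile sets of equal cardinality.
#'
#' @param slide a [slide_image()].
#' @param ensemble a `trained_ensemble`.
#' @param ... pipeline settings passed to [slide_features()] (tile edge,
#'   threshold, color normalization, backend).
#' @return 1 x genes prediction matrix for the slide's patient.
#' @export
augment_and_predict <- function(slide, ensemble, ...) {
  preds <- lapply(c(0, 90, 180, 270), function(deg) {
    sf <- slide_features(rotate_slide(slide, deg), ...)
    if (is.null(sf$features)) stop_input("rotation %d left no retained tiles", deg)
    ensemble_predict(ensemble, sf$features)
  })
  Reduce(`+`, preds) / length(preds)
}

# Stratified 80/20 patient split; returns list(train, val) of patient ids.
stratified_split <- function(patients, labels, val_frac = 0.2) {
  val <- unlist(lapply(split(patients, labels[patients]), function(g) {
    sample(g, max(1L, round(length(g) * val_frac)))
  }), use.names = FALSE)
  list(train = setdiff(patients, val), val = val)
}

#' Leave-one-out evaluation of the direct classifier
#'
#' For each held-out patient, the remaining patients are split 30 times into
#' training (80%) and validation (20%) sets (stratified by class to avoid
#' degenerate splits); one classifier is trained per split and the held-out
#' patient's score is the mean of its slide-level scores over the 30 models.
#' A split that still loses a class is redrawn with a fresh seed and the
#' event is messaged.
#'
#' @param features compressed or raw `feature_matrix` for all retained tiles.
#' @param labels named 0/1 vector of patient-level response labels.
#' @param config a [training_config()].
#' @param n_boot bootstrap models per held-out patient (30 by default).
#' @param trainer optional override returning a function
#'   `(features) -> tile scores` given
#'   `(train_features, slide_labels, config, val_features, val_labels)`;
#'   the default trains [train_direct_classifier()].
#' @return data.frame with `patient_id` and `score`.
#' @export
loocv_direct <- function(features, labels, config = training_config(),
                         n_boot = 30L, trainer = NULL) {
  info <- tile_info(features)
  patients <- unique(info$patient_id)
  stopifnot(all(patients %in% names(labels)))
  if (min(table(labels[patients])) < 3L) {
    stop_input("need at least 3 patients per class for leave-one-out evaluation")
  }
  if (is.null(trainer)) {
    trainer <- function(ftr, slide_labels, config, fva, val_labels) {
      fit <- train_direct_classifier(ftr, slide_labels, config, fva, val_labels)
      function(f) predict_direct(fit, f)
    }
  }
  slide_label <- function(ids) {
    sl <- info$patient_id[match(ids, info$slide_id)]
    setNames(as.numeric(labels[sl]), ids)
  }

  scores <- vapply(seq_along(patients), function(pi) {
    held <- patients[pi]
    rest <- setdiff(patients, held)
    fheld <- fm_rows(features, info$patient_id == held)
    boot_scores <- vapply(seq_len(n_boot), function(b) {
      seed <- derive_seed(config$seed, pi * 1000L + b)
      for (try in 0:10) {
        sp <- with_seed(seed + try, stratified_split(rest, labels))
        cfg <- config; cfg$seed <- seed + try
        tr_rows <- info$patient_id %in% sp$train
        va_rows <- info$patient_id %in% sp$val
        ftr <- fm_rows(features, tr_rows)
        fva <- fm_rows(features, va_rows)
        tr_slides <- unique(tile_info(ftr)$slide_id)
        if (length(unique(labels[sp$train])) < 2L) {
          message(sprintf("degenerate split for patient %s, bootstrap %d; redrawn", held, b))
          next
        }
        score_fun <- trainer(ftr, slide_label(tr_slides), cfg,
                             fva, slide_label(unique(tile_info(fva)$slide_id)))
        tile_scores <- score_fun(fheld)
        hi <- tile_info(fheld)
        slide_scores <- aggregate_tiles_to_slide(matrix(tile_scores, ncol = 1L),
                                                 hi$slide_id)
        return(mean(slide_scores))
      }
      stop_input("could not draw a two-class split for patient %s", held)
    }, numeric(1))
    mean(boot_scores)
  }, numeric(1))

  data.frame(patient_id = patients, score = scores, stringsAsFactors = FALSE)
}
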