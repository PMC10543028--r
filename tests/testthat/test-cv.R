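# Minimal imputation dataset: features with planted patient-level signal so
# nested CV has something to learn, at unit-test size.
cv_dataset <- function(n_patients = 10, n_genes = 8, tiles_per_patient = 3, seed = 50) {
  set.seed(seed)
  patients <- sprintf("P%02d", seq_len(n_patients))
  info <- data.frame(
    tile_id = sprintf("t%03d", seq_len(n_patients * tiles_per_patient)),
    slide_id = rep(paste0(patients, "_S1"), each = tiles_per_patient),
    patient_id = rep(patients, each = tiles_per_patient),
    stringsAsFactors = FALSE)
  z <- matrix(rnorm(n_patients * 2), n_patients, 2, dimnames = list(patients, NULL))
  x <- matrix(rnorm(nrow(info) * 2048, 0, 0.05), nrow(info), 2048)
  x[, 1:2] <- z[info$patient_id, ]
  B <- matrix(rnorm(2 * n_genes), 2, n_genes)
  expr <- t(z %*% B) + matrix(rnorm(n_genes * n_patients, 0, 0.1), n_genes)
  dimnames(expr) <- list(sprintf("G%02d", seq_len(n_genes)), patients)
  list(features = feature_matrix(x, info, "toy"), expr = expr,
       tranches = list(make_tranche(rownames(expr))))
}

test_that("fold plans partition patients evenly, deterministically, without leakage", {
  pats <- sprintf("P%02d", 1:10)
  plan <- make_fold_plan(pats, 5, 5, seed = 3)
  expect_length(plan$outer, 5)
  expect_true(all(lengths(plan$outer) == 2))
  expect_setequal(unlist(plan$outer), pats)

  # determinism
  expect_identical(make_fold_plan(pats, 5, 5, seed = 3), plan)
  expect_false(identical(make_fold_plan(pats, 5, 5, seed = 4)$outer, plan$outer))

  # inner folds partition the outer-training patients and exclude the test fold
  for (o in 1:5) {
    inn <- unlist(plan$inner[[o]])
    expect_setequal(inn, setdiff(pats, plan$outer[[o]]))
    expect_length(intersect(inn, plan$outer[[o]]), 0)
  }

  # near-equal sizes with a non-divisible patient count
  p11 <- make_fold_plan(sprintf("P%02d", 1:11), 5, 5, seed = 1)
  expect_lte(diff(range(lengths(p11$outer))), 1)
  expect_error(make_fold_plan(pats[1:4], 5, 5), "outer folds")
})

test_that("all slides of a patient stay in the same fold by construction", {
  ds <- cv_dataset()
  info <- attr(ds$features, "tile_info")
  plan <- make_fold_plan(unique(info$patient_id), 5, 2, seed = 9)
  fold_of <- rep(seq_along(plan$outer), lengths(plan$outer))
  names(fold_of) <- unlist(plan$outer)
  slide_folds <- tapply(fold_of[info$patient_id], info$slide_id,
                        function(x) length(unique(x)))
  expect_true(all(slide_folds == 1))
})

test_that("nested CV produces k_outer x k_inner members and one out-of-fold row per patient", {
  ds <- cv_dataset()
  plan <- make_fold_plan(colnames(ds$expr), 5, 2, seed = 5)
  cfg <- fast_config(seed = 6, learning_rate = 5e-3, max_epochs = 10, patience = 9)
  aecfg <- fast_config(seed = 6, max_epochs = 2, patience = 1)
  ens <- nested_cv_train(ds$features, ds$expr, ds$tranches, plan, cfg, aecfg)
  expect_length(ens$members, 10)
  expect_identical(sort(rownames(ens$oof)), sort(colnames(ds$expr)))
  expect_true(all(is.finite(ens$oof)))
  outin <- vapply(ens$members, function(m) paste(m$outer, m$inner), character(1))
  expect_length(unique(outin), 10)
})

test_that("a full 5x5 plan yields a 25-member ensemble", {
  ds <- cv_dataset(n_patients = 12, n_genes = 4, tiles_per_patient = 1, seed = 51)
  plan <- make_fold_plan(colnames(ds$expr), 5, 5, seed = 2)
  cfg <- fast_config(seed = 1, max_epochs = 2, patience = 1)
  ens <- nested_cv_train(ds$features, ds$expr, ds$tranches, plan, cfg, cfg)
  expect_length(ens$members, 25)
})

test_that("out-of-fold predictions are invariant to patient ordering in the manifest", {
  ds <- cv_dataset(n_patients = 10, n_genes = 4, tiles_per_patient = 2, seed = 52)
  plan <- make_fold_plan(colnames(ds$expr), 5, 2, seed = 5)
  cfg <- fast_config(seed = 6, max_epochs = 3, patience = 2)
  ens1 <- nested_cv_train(ds$features, ds$expr, ds$tranches, plan, cfg, cfg)
  perm <- rev(seq_len(nrow(ds$features)))
  f2 <- pathtx:::fm_rows(ds$features, perm)
  ens2 <- nested_cv_train(f2, ds$expr, ds$tranches, plan, cfg, cfg)
  expect_equal(ens2$oof[rownames(ens1$oof), ], ens1$oof)
})

test_that("held-out predictions average the inner members; ensembles average all members", {
  ds <- cv_dataset(n_patients = 10, n_genes = 3, tiles_per_patient = 1, seed = 53)
  plan <- make_fold_plan(colnames(ds$expr), 5, 2, seed = 7)
  cfg <- fast_config(seed = 2, max_epochs = 2, patience = 1)
  ens <- nested_cv_train(ds$features, ds$expr, ds$tranches, plan, cfg, cfg)

  # replace every member with a constant predictor c_i and check the averages
  consts <- seq_along(ens$members)
  for (i in seq_along(ens$members)) {
    m <- ens$members[[i]]
    m$regressors[[1]]$fit$net$W <- lapply(m$regressors[[1]]$fit$net$W, function(w) w * 0)
    m$regressors[[1]]$fit$net$b <- lapply(m$regressors[[1]]$fit$net$b, function(b) b * 0)
    m$regressors[[1]]$target_means <- rep(consts[i], 3)
    ens$members[[i]] <- m
  }
  pred <- ensemble_predict(ens, ds$features)
  expect_equal(unname(pred), matrix(mean(consts), nrow(pred), ncol(pred)))

  # member-order permutation invariance and the single-member identity
  ens_perm <- ens; ens_perm$members <- rev(ens$members)
  expect_equal(ensemble_predict(ens_perm, ds$features), pred)
  ens_one <- ens; ens_one$members <- ens$members[1]
  expect_equal(unname(ensemble_predict(ens_one, ds$features)),
               matrix(consts[1], nrow(pred), ncol(pred)))

  # backend mismatch is rejected
  f_other <- feature_matrix(unclass(ds$features), attr(ds$features, "tile_info"),
                            backend_tag = "texture")
  expect_error(ensemble_predict(ens, f_other), "backend")
})

test_that("rotation augmentation averages four symmetries and is exact for constant models", {
  ds <- cv_dataset(n_patients = 10, n_genes = 3, tiles_per_patient = 1, seed = 54)
  plan <- make_fold_plan(colnames(ds$expr), 5, 2, seed = 7)
  cfg <- fast_config(seed = 2, max_epochs = 2, patience = 1)

  # four rotations of a square slide produce tile sets of equal cardinality
  sl <- noise_slide(64, 64, seed = 55, id = "SX", patient = "PX")
  counts <- vapply(c(0, 90, 180, 270), function(d) {
    length(tile_slide(rotate_slide(sl, d), 32))
  }, integer(1))
  expect_true(all(counts == 4))

  # constant-prediction ensemble: augmentation is the identity
  spec <- synthetic_cohort_spec(n_patients = 10, slide_dim = c(64, 64),
                                tile_edge = 32, n_genes = 3,
                                n_driven_genes = 2, seed = 56)
  coh <- generate_cohort(spec)
  cf <- cohort_features(coh$slides, tile_edge = 32, threshold = 15,
                        resize_edge = 32, color_norm = "identity")
  expr <- normalize_expression(coh$counts)
  tranches <- list(make_tranche(rownames(expr)))
  plan2 <- make_fold_plan(colnames(expr), 5, 2, seed = 8)
  ens <- nested_cv_train(cf$features, expr, tranches, plan2, cfg, cfg)
  for (i in seq_along(ens$members)) {
    m <- ens$members[[i]]
    m$regressors[[1]]$fit$net$W <- lapply(m$regressors[[1]]$fit$net$W, function(w) w * 0)
    m$regressors[[1]]$fit$net$b <- lapply(m$regressors[[1]]$fit$net$b, function(b) b * 0)
    m$regressors[[1]]$target_means <- c(1, 2, 3)
    ens$members[[i]] <- m
  }
  aug <- augment_and_predict(coh$slides[[1]], ens, tile_edge = 32, threshold = 15,
                             resize_edge = 32, color_norm = "identity")
  expect_equal(unname(aug), matrix(c(1, 2, 3), 1))
})

test_that("leave-one-out direct evaluation scores every patient from 30 bootstrap models", {
  ds <- cv_dataset(n_patients = 8, n_genes = 2, tiles_per_patient = 2, seed = 57)
  info <- attr(ds$features, "tile_info")
  patients <- unique(info$patient_id)
  labels <- setNames(rep(c(0, 1), each = 4), patients)

  calls <- 0
  trainer <- function(ftr, slide_labels, config, fva, val_labels) {
    calls <<- calls + 1
    function(f) rep(0.7, nrow(f))
  }
  out <- loocv_direct(ds$features, labels, fast_config(seed = 3), n_boot = 30,
                      trainer = trainer)
  expect_identical(nrow(out), length(patients))
  expect_identical(calls, length(patients) * 30)
  expect_equal(out$score, rep(0.7, length(patients)))   # constant models average to 0.7
  expect_error(loocv_direct(ds$features, setNames(c(0, 0, rep(1, 6)), patients),
                            fast_config()), "3 patients")
})
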