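# Scoring imputed expression against measured expression: per-gene Pearson
# correlation with Holm-Sidak control, subsampling stability, hallmark
# enrichment, rank-based signature scores, and Cox survival association.

#' Per-gene correlation between predicted and actual expression
#'
#' Pearson R per gene across samples, with the two-sided p-value from the
#' t-distribution transform of R on n - 2 degrees of freedom. Genes with
#' zero variance in either matrix get `NA` (excluded from multiple-testing
#' correction downstream).
#'
#' @param pred,actual genes x samples matrices with matching dimnames.
#' @return data.frame with `gene`, `r`, `p`.
#' @export
per_gene_correlation <- function(pred, actual) {
  pred <- as.matrix(pred); actual <- as.matrix(actual)
  if (!identical(dim(pred), dim(actual))) stop_input("pred/actual dimensions differ")
  if (!is.null(rownames(pred)) && !is.null(rownames(actual))) {
    stopifnot(identical(rownames(pred), rownames(actual)))
  }
  n <- ncol(pred)
  if (n < 4L) stop_input("need at least 4 samples for per-gene correlation")
  px <- pred - rowMeans(pred)
  ax <- actual - rowMeans(actual)
  sp <- sqrt(rowSums(px^2)); sa <- sqrt(rowSums(ax^2))
  r <- rowSums(px * ax) / (sp * sa)
  r[sp == 0 | sa == 0] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  data.frame(gene = rownames(pred) %||% as.character(seq_len(nrow(pred))),
             r = unname(r), p = unname(p), stringsAsFactors = FALSE)
}

#' Holm-Sidak step-down adjusted p-values
#'
#' Step-down adjustment: with p-values sorted ascending, the i-th adjusted
#' value is `max_{j <= i} 1 - (1 - p_j)^(m - j + 1)`, clipped to 1; a
#' hypothesis is rejected while its adjusted p stays below `alpha`. `NA`
#' p-values are ignored (not counted in m) and returned as `NA`.
#'
#' @param pvals numeric vector in `[0, 1]` (NAs allowed).
#' @param alpha rejection threshold.
#' @return data.frame with `p`, `p_adj`, `significant`, in input order.
#' @export
holm_sidak <- function(pvals, alpha = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop_input("p-values outside [0, 1]")
  adj <- rep(NA_real_, length(pvals))
  ok <- which(!is.na(pvals))
  m <- length(ok)
  if (m > 0) {
    ord <- ok[order(pvals[ok])]
    a <- 1 - (1 - pvals[ord])^(m - seq_len(m) + 1)
    adj[ord] <- pmin(cummax(a), 1)
  }
  data.frame(p = pvals, p_adj = adj,
             significant = !is.na(adj) & adj < alpha)
}

#' Full gene-prediction report
#'
#' Convenience wrapper combining [per_gene_correlation()] and
#' [holm_sidak()]: a gene is "significantly predicted" when its two-sided
#' correlation p-value survives Holm-Sidak correction across all evaluated
#' genes at `alpha`.
#'
#' @inheritParams per_gene_correlation
#' @param alpha significance threshold on adjusted p-values.
#' @return data.frame with `gene`, `r`, `p`, `p_adj`, `significant`.
#' @export
gene_prediction_report <- function(pred, actual, alpha = 0.05) {
  rep_ <- per_gene_correlation(pred, actual)
  cbind(rep_, holm_sidak(rep_$p, alpha)[, c("p_adj", "significant")])
}

#' Significant-gene counts over random subsamples
#'
#' Draws `reps` random subsets of `subset_size` samples and counts the genes
#' declared significantly predicted within each subset, reporting the mean
#' and standard error over repetitions. Used to compare cohorts of unequal
#' size on a common footing.
#'
#' @inheritParams gene_prediction_report
#' @param subset_size samples per subset (cohorts smaller than this are
#'   rejected).
#' @param reps number of subsets.
#' @param seed integer seed.
#' @return list with `counts`, `mean`, `sem` (`NA` when `reps = 1`).
#' @export
subsample_significant_counts <- function(pred, actual, subset_size = 200L,
                                         reps = 30L, seed = 1L, alpha = 0.05) {
  pred <- as.matrix(pred); actual <- as.matrix(actual)
  n <- ncol(pred)
  if (n < subset_size) {
    stop_input("cohort has %d samples, fewer than the subset size %d", n, subset_size)
  }
  counts <- with_seed(seed, vapply(seq_len(reps), function(rp) {
    idx <- sample.int(n, subset_size)
    sum(gene_prediction_report(pred[, idx, drop = FALSE],
                               actual[, idx, drop = FALSE], alpha)$significant)
  }, numeric(1)))
  list(counts = counts, mean = mean(counts),
       sem = if (reps > 1L) sd(counts) / sqrt(reps) else NA_real_)
}

#' Hallmark over-representation of significantly predicted genes
#'
#' One-sided hypergeometric over-representation test of the significant
#' gene set against each hallmark set (intersected with the background, which
#' should be all genes the model evaluated), Holm-Sidak corrected across
#' sets.
#'
#' @param significant_genes character vector.
#' @param hallmark_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param background character vector containing `significant_genes`.
#' @return data.frame with `set`, `set_size`, `overlap`, `p`, `p_adj`,
#'   `significant`, `degenerate`.
#' @export
hallmark_enrichment <- function(significant_genes, hallmark_sets, background) {
  if (!length(background)) stop_input("empty background gene list")
  if (!all(significant_genes %in% background)) {
    stop_input("significant genes must be a subset of the background")
  }
  sig <- unique(significant_genes)
  bg <- unique(background)
  res <- do.call(rbind, lapply(names(hallmark_sets), function(nm) {
    set <- intersect(hallmark_sets[[nm]], bg)
    k <- length(intersect(sig, set))
    # P(X >= k) with X ~ Hypergeom(|set| in bg, draws = |sig|)
    p <- if (length(set) == 0L) 1 else
      phyper(k - 1L, length(set), length(bg) - length(set), length(sig),
             lower.tail = FALSE)
    degenerate <- length(set) == length(bg) || length(sig) == length(bg)
    data.frame(set = nm, set_size = length(set), overlap = k, p = p,
               degenerate = degenerate, stringsAsFactors = FALSE)
  }))
  hs <- holm_sidak(res$p)
  res$p_adj <- hs$p_adj
  res$significant <- hs$significant
  res[, c("set", "set_size", "overlap", "p", "p_adj", "significant", "degenerate")]
}

#' Rank-based signature score
#'
#' For each signature gene, patients are ranked by expression (average ranks
#' on ties) and the ranks normalized to `[0, 1]` as `(rank - 1)/(n - 1)`;
#' the patient's score is the mean normalized rank over the signature genes
#' present in the matrix. Being rank-based, the score is invariant to
#' monotone per-gene transformations of expression.
#'
#' @param expr genes x patients expression matrix.
#' @param gene_set character vector of signature genes.
#' @param name signature name carried in the result.
#' @return a `signature_score`: data.frame with `patient_id`, `score`, plus
#'   attributes `name` and `genes_used`.
#' @export
signature_score <- function(expr, gene_set, name = "signature") {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2L) stop_input("need at least 2 patients for a signature score")
  present <- intersect(gene_set, rownames(expr))
  if (!length(present)) {
    stop_input("no signature gene present in the matrix (set: %s)",
               paste(head(gene_set, 5), collapse = ", "))
  }
  n <- ncol(expr)
  nr <- t(apply(expr[present, , drop = FALSE], 1L,
                function(x) (rank(x, ties.method = "average") - 1) / (n - 1)))
  out <- data.frame(patient_id = colnames(expr) %||% as.character(seq_len(n)),
                    score = unname(colMeans(nr)), stringsAsFactors = FALSE)
  structure(out, name = name, genes_used = present, class = c("signature_score", "data.frame"))
}

#' Cox proportional-hazards association of a score with survival
#'
#' Univariate Cox fit (partial likelihood, Breslow ties) of survival on the
#' score; returns the log hazard ratio of the score covariate and its Wald
#' p-value.
#'
#' @param scores named numeric vector (names are patient ids) or a
#'   `signature_score`.
#' @param survival_data data.frame with `patient_id`, `time` (days, > 0),
#'   `event` (0/1).
#' @return list with `log_hr`, `hr`, `se`, `z`, `p`, `n`, `events`.
#' @export
survival_association <- function(scores, survival_data) {
  if (inherits(scores, "signature_score")) {
    scores <- setNames(scores$score, scores$patient_id)
  }
  stopifnot(all(c("patient_id", "time", "event") %in% names(survival_data)))
  df <- survival_data[survival_data$patient_id %in% names(scores), , drop = FALSE]
  df$score <- scores[df$patient_id]
  if (any(df$time <= 0)) stop_input("survival times must be positive")
  if (nrow(df) < 10L) stop_input("need at least 10 patients with scores and survival")
  if (sum(df$event) < 3L) stop_input("need at least 3 events")
  fit <- survival::coxph(survival::Surv(time, event) ~ score, data = df,
                         ties = "breslow")
  s <- summary(fit)
  if (!is.null(fit$info) && !fit$info == 0) warning("Cox fit flagged non-convergence")
  list(log_hr = unname(coef(fit)[1L]), hr = unname(exp(coef(fit)[1L])),
       se = unname(s$coefficients[1L, "se(coef)"]),
       z = unname(s$coefficients[1L, "z"]),
       p = unname(s$coefficients[1L, "Pr(>|z|)"]),
       n = nrow(df), events = sum(df$event))
}

#' Concordance of hazard ratios between actual and predicted expression
#'
#' For each cohort, fits the survival association of a signature scored on
#' actual and on predicted expression, and reports the Pearson correlation
#' of the paired log hazard ratios across cohorts.
#'
#' @param actual_scores,predicted_scores lists (one element per cohort) of
#'   named score vectors or `signature_score` objects.
#' @param survival_list list of survival data.frames, same cohort order.
#' @return list with `correlation` and the per-cohort `log_hr` table.
#' @export
hr_concordance <- function(actual_scores, predicted_scores, survival_list) {
  k <- length(actual_scores)
  if (k < 3L) stop_input("need at least 3 cohorts for hazard-ratio concordance")
  stopifnot(length(predicted_scores) == k, length(survival_list) == k)
  tab <- do.call(rbind, lapply(seq_len(k), function(i) {
    data.frame(
      cohort = i,
      log_hr_actual = survival_association(actual_scores[[i]], survival_list[[i]])$log_hr,
      log_hr_predicted = survival_association(predicted_scores[[i]], survival_list[[i]])$log_hr
    )
  }))
  list(correlation = cor(tab$log_hr_actual, tab$log_hr_predicted), table = tab)
}
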