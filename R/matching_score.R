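# Drug matching score from a genetic-interaction (GI) network: the score of
# a patient is the fraction of the drug's SL/SR partner genes whose
# activation state favors response, computed on cohort-wide expression
# ranks. A tumor is more susceptible to a drug that makes more SL
# interactions active (partner lowly expressed) and fewer SR interactions
# active (rescuer highly expressed).

#' Construct a drug genetic-interaction network
#'
#' @param drug drug name.
#' @param targets character vector of target gene(s). Target expression is
#'   never consulted by the score (the monoclonal-antibody target-expression
#'   component is excluded by design: it weighs one gene heavily and is
#'   fragile to imputation noise in that gene).
#' @param sl_partners,sr_partners character vectors of synthetic-lethal and
#'   synthetic-rescue partner genes; must be disjoint, union non-empty.
#' @return a `gi_network`.
#' @export
gi_network <- function(drug, targets = character(), sl_partners = character(),
                       sr_partners = character()) {
  sl_partners <- unique(as.character(sl_partners))
  sr_partners <- unique(as.character(sr_partners))
  if (length(intersect(sl_partners, sr_partners))) {
    stop_input("SL and SR partner lists must be disjoint")
  }
  if (!length(c(sl_partners, sr_partners))) {
    stop_input("network needs at least one SL or SR partner")
  }
  structure(list(drug = as.character(drug), targets = as.character(targets),
                 sl_partners = sl_partners, sr_partners = sr_partners),
            class = "gi_network")
}

#' @export
print.gi_network <- function(x, ...) {
  cat(sprintf("<gi_network> %s: %d target(s), %d SL, %d SR partners\n",
              x$drug, length(x$targets), length(x$sl_partners), length(x$sr_partners)))
  invisible(x)
}

#' Cohort-wise rank normalization of expression
#'
#' Per gene, patients are ranked (average ranks on ties) and normalized to
#' `[0, 1]` as `(rank - 1)/(n - 1)`. This is the reference distribution
#' against which partner-gene activation is called; a constant gene maps to
#' rank 0.5 for every patient.
#'
#' @param expr genes x patients expression matrix (>= 3 patients so that
#'   tertiles are definable).
#' @return genes x patients matrix of ranks in `[0, 1]`.
#' @export
rank_normalize_cohort <- function(expr) {
  expr <- as.matrix(expr)
  n <- ncol(expr)
  if (n < 3L) stop_input("need at least 3 patients for a rank reference")
  out <- t(apply(expr, 1L, function(x) (rank(x, ties.method = "average") - 1) / (n - 1)))
  dimnames(out) <- dimnames(expr)
  out
}

#' Matching score of one patient
#'
#' The score is the fraction of present partner genes in a favorable
#' activation state: an SL partner is favorable when its expression rank is
#' in the bottom tertile (rank <= 1/3, the interaction is active); an SR
#' rescuer is favorable when its rank is below the top tertile (rank < 2/3,
#' the rescue is inactive). Partners absent from the matrix are excluded
#' from numerator and denominator alike.
#'
#' @param patient_ranks named numeric vector of the patient's per-gene ranks
#'   in `[0, 1]` (one column of [rank_normalize_cohort()]).
#' @param network a [gi_network()].
#' @param threshold decision threshold; patients with score at or above it
#'   are called matched (0.54, fixed on independent data).
#' @param patient_id identifier carried into the result.
#' @return one-row data.frame with `patient_id`, `ems`, `matched`,
#'   `threshold`, `n_partners`.
#' @export
compute_ems <- function(patient_ranks, network, threshold = 0.54, patient_id = NA) {
  stopifnot(inherits(network, "gi_network"))
  sl <- intersect(network$sl_partners, names(patient_ranks))
  sr <- intersect(network$sr_partners, names(patient_ranks))
  if (!length(c(sl, sr))) {
    stop_input("no SL/SR partner of drug %s present in the expression matrix",
               network$drug)
  }
  favorable <- sum(patient_ranks[sl] <= 1 / 3) + sum(patient_ranks[sr] < 2 / 3)
  ems <- favorable / (length(sl) + length(sr))
  data.frame(patient_id = patient_id, ems = ems, matched = ems >= threshold,
             threshold = threshold, n_partners = length(sl) + length(sr),
             stringsAsFactors = FALSE)
}

#' Matching scores for a whole cohort
#'
#' Rank-normalizes the cohort's expression and scores every patient against
#' the drug's network. Deterministic; identical profiles receive identical
#' scores.
#'
#' @param expr genes x patients expression matrix (measured or imputed).
#' @param network a [gi_network()].
#' @param threshold decision threshold for the matched call.
#' @return data.frame with one row per patient: `patient_id`, `ems`,
#'   `matched`, `threshold`, `n_partners`.
#' @export
score_cohort <- function(expr, network, threshold = 0.54) {
  ranks <- rank_normalize_cohort(expr)
  out <- do.call(rbind, lapply(seq_len(ncol(ranks)), function(j) {
    compute_ems(ranks[, j], network, threshold,
                patient_id = colnames(ranks)[j] %||% as.character(j))
  }))
  rownames(out) <- NULL
  out
}
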