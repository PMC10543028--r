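# Clinical evaluation statistics: 2x2 response tables, odds ratios with
# Woolf intervals, Fisher exact tests, average precision, coverage curves,
# precision-increase and permutation tests, and reconstruction of 2x2 tables
# from printed summary statistics.

#' Construct a 2x2 response table
#'
#' Cells follow the matched-by-response layout: `a` matched responders, `b`
#' matched non-responders, `c` unmatched responders, `d` unmatched
#' non-responders.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return a `response_table` with derived `n`, `orr` (overall response
#'   rate), `precision` (a / (a + b)), `sensitivity` (a / (a + c)) and
#'   `coverage` ((a + b)/n).
#' @export
response_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop_input("cells must be non-negative integers")
  }
  n <- sum(cells)
  structure(list(a = a, b = b, c = c, d = d, n = n,
                 orr = (a + c) / n,
                 precision = if (a + b > 0) a / (a + b) else NA_real_,
                 sensitivity = if (a + c > 0) a / (a + c) else NA_real_,
                 coverage = (a + b) / n),
            class = "response_table")
}

#' @export
print.response_table <- function(x, ...) {
  cat(sprintf("<response_table> a=%d b=%d c=%d d=%d (n=%d, ORR %.1f%%, precision %.1f%%)\n",
              x$a, x$b, x$c, x$d, x$n, 100 * x$orr, 100 * x$precision))
  invisible(x)
}

#' Cross-tabulate matched calls against response labels
#'
#' @param ems_results data.frame from [score_cohort()] (needs `patient_id`
#'   and `matched`).
#' @param response_labels named 0/1 vector of observed response, names are
#'   patient ids. Patients without a label are excluded with a message.
#' @return a [response_table()].
#' @export
build_table <- function(ems_results, response_labels) {
  ids <- intersect(ems_results$patient_id, names(response_labels))
  if (!length(ids)) stop_input("no patient has both a matched call and a label")
  dropped <- nrow(ems_results) - length(ids)
  if (dropped > 0) message(sprintf("%d patient(s) without labels excluded", dropped))
  m <- ems_results$matched[match(ids, ems_results$patient_id)]
  r <- as.logical(response_labels[ids])
  response_table(sum(m & r), sum(m & !r), sum(!m & r), sum(!m & !r))
}

#' Odds ratio with Woolf confidence interval
#'
#' `OR = (a d)/(b c)` with the Woolf (log) interval
#' `exp(log OR +/- z sqrt(1/a + 1/b + 1/c + 1/d))`. When a cell is zero the
#' Haldane correction (+0.5 to every cell) is applied and flagged.
#'
#' @param table a [response_table()].
#' @param z normal quantile (1.96 for 95%).
#' @return list with `or`, `ci_low`, `ci_high`, `z`, `haldane`.
#' @export
odds_ratio_ci <- function(table, z = 1.96) {
  stopifnot(inherits(table, "response_table"))
  if (table$a + table$b == 0 || table$c + table$d == 0) {
    stop_input("odds ratio undefined: a margin of the table is empty")
  }
  cells <- c(table$a, table$b, table$c, table$d)
  haldane <- any(cells == 0)
  if (haldane) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  list(or = or, ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se),
       z = z, haldane = haldane)
}

#' Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric test with fixed margins. The two-sided p-value sums
#' the probabilities of all tables no more probable than the observed one
#' (the common convention); `"greater"` tests OR > 1.
#'
#' @param table a [response_table()].
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return the p-value.
#' @export
fisher_exact <- function(table, alternative = c("two.sided", "greater", "less")) {
  stopifnot(inherits(table, "response_table"))
  alternative <- match.arg(alternative)
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  m1 <- a + c            # responders
  m2 <- b + d            # non-responders
  k <- a + b             # matched group size
  lo <- max(0L, k - m2); hi <- min(k, m1)
  x <- lo:hi
  probs <- dhyper(x, m1, m2, k)
  switch(alternative,
         two.sided = sum(probs[probs <= dhyper(a, m1, m2, k) * (1 + 1e-7)]),
         greater = sum(probs[x >= a]),
         less = sum(probs[x <= a]))
}

#' Average precision
#'
#' Non-interpolated step-wise AP: scores are swept from high to low (tied
#' scores grouped at one threshold) and `AP = sum (recall_i - recall_{i-1})
#' * precision_i`. Equals the mean of precisions at the positives for
#' untied scores.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector (at least one positive).
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1)
  if (npos == 0) stop_input("average precision undefined without positives")
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0; prev_recall <- 0
  for (t in thr) {
    sel <- scores >= t
    prec <- sum(labels[sel]) / sum(sel)
    rec <- sum(labels[sel]) / npos
    ap <- ap + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  ap
}

#' Odds ratio as a function of coverage
#'
#' Sweeps the unique score thresholds; at each threshold with coverage (the
#' fraction of patients at or above it) inside `coverage_range`, the induced
#' matched/unmatched table is built and its odds ratio computed. Degenerate
#' tables (a zero cell) get `NA` with a flag. Extreme coverages are excluded
#' by default because their odds ratios are measurement noise.
#'
#' @param scores numeric vector (>= 10 patients).
#' @param labels 0/1 response labels.
#' @param coverage_range inclusive coverage window, default `c(0.1, 0.9)`.
#' @return data.frame with `threshold`, `coverage`, `or`, `degenerate`.
#' @export
coverage_curve <- function(scores, labels, coverage_range = c(0.1, 0.9)) {
  labels <- as.numeric(labels)
  if (length(scores) < 10L) stop_input("need at least 10 patients for a coverage curve")
  thr <- sort(unique(scores), decreasing = TRUE)
  rows <- lapply(thr, function(t) {
    cov <- mean(scores >= t)
    if (cov < coverage_range[1] || cov > coverage_range[2]) return(NULL)
    m <- scores >= t
    tab <- response_table(sum(m & labels == 1), sum(m & labels == 0),
                          sum(!m & labels == 1), sum(!m & labels == 0))
    degenerate <- any(c(tab$a, tab$b, tab$c, tab$d) == 0)
    or <- if (degenerate) NA_real_ else (tab$a * tab$d) / (tab$b * tab$c)
    data.frame(threshold = t, coverage = cov, or = or, degenerate = degenerate)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  out %||% data.frame(threshold = numeric(0), coverage = numeric(0),
                      or = numeric(0), degenerate = logical(0))
}

#' Precision increase over the overall response rate
#'
#' Relative precision increase `100 (precision - ORR)/ORR` among the matched
#' group, with a one-sided z-test of the matched-group response proportion
#' against the cohort ORR as the null proportion.
#'
#' @param table a [response_table()].
#' @return list with `precision`, `orr`, `increase_pct`, `p`.
#' @export
precision_increase_test <- function(table) {
  stopifnot(inherits(table, "response_table"))
  if (table$a + table$b == 0) stop_input("no matched patients")
  if (table$orr == 0) stop_input("overall response rate is zero; increase undefined")
  m <- table$a + table$b
  p0 <- table$orr
  z <- (table$precision - p0) / sqrt(p0 * (1 - p0) / m)
  list(precision = table$precision, orr = p0,
       increase_pct = 100 * (table$precision - p0) / p0,
       p = pnorm(z, lower.tail = FALSE))
}

#' One-sided permutation test for average precision
#'
#' Permutes the labels `B` times with scores fixed;
#' `p = (1 + #(AP_perm >= AP_obs)) / (B + 1)`.
#'
#' @param scores numeric vector.
#' @param labels 0/1 labels.
#' @param B number of permutations (>= 99).
#' @param seed integer seed.
#' @return list with `ap`, `p`, `B`.
#' @export
permutation_test_ap <- function(scores, labels, B = 999L, seed = 1L) {
  if (B < 99L) stop_input("use at least 99 permutations")
  obs <- average_precision(scores, labels)
  exceed <- with_seed(seed, sum(vapply(seq_len(B), function(b) {
    average_precision(scores, sample(labels)) >= obs
  }, logical(1))))
  list(ap = obs, p = (1 + exceed) / (B + 1), B = B)
}

#' Reconstruct 2x2 tables from printed summary statistics
#'
#' Exhaustively enumerates all tables with `n` patients and `n_responders`
#' responders, over every matched-group size `m` and matched-responder
#' count `a`, and keeps the tables whose statistics round to the supplied
#' targets at their printed precision. Used to recover the exact table
#' behind published aggregate statistics.
#'
#' @param n total patients.
#' @param n_responders total responders.
#' @param constraints named list of rounded targets; supported names:
#'   `precision_pct` (1 decimal), `or` (2 decimals), `ci_low`/`ci_high`
#'   (2 decimals, Woolf 95%), `orr_pct` (1 decimal), `increase_pct`
#'   (1 decimal). Per-constraint digits can be overridden via `digits`.
#' @param digits named list overriding rounding digits per constraint.
#' @return list with `tables` (list of [response_table()]s) and `unique`
#'   (TRUE when exactly one table satisfies everything).
#' @export
reconstruct_table <- function(n, n_responders, constraints,
                              digits = list(precision_pct = 1, or = 2, ci_low = 2,
                                            ci_high = 2, orr_pct = 1, increase_pct = 1)) {
  stopifnot(n >= 2, n_responders >= 0, n_responders <= n, length(constraints) >= 1)
  grid <- expand.grid(m = 1:(n - 1), a = 0:n_responders)
  grid <- grid[grid$a <= grid$m & (n_responders - grid$a) <= (n - grid$m), , drop = FALSE]
  keep <- vapply(seq_len(nrow(grid)), function(i) {
    m <- grid$m[i]; a <- grid$a[i]
    b <- m - a; c <- n_responders - a; d <- n - m - c
    ok <- TRUE
    if (!is.null(constraints$precision_pct)) {
      ok <- ok && rounds_to(100 * a / m, constraints$precision_pct, digits$precision_pct)
    }
    if (ok && !is.null(constraints$orr_pct)) {
      ok <- rounds_to(100 * n_responders / n, constraints$orr_pct, digits$orr_pct)
    }
    if (ok && !is.null(constraints$increase_pct)) {
      ok <- rounds_to(100 * (a / m - n_responders / n) / (n_responders / n),
                      constraints$increase_pct, digits$increase_pct)
    }
    if (ok && (!is.null(constraints$or) || !is.null(constraints$ci_low) ||
               !is.null(constraints$ci_high))) {
      if (b == 0 || c == 0 || a == 0 || d == 0) return(FALSE)
      or <- (a * d) / (b * c)
      if (!is.null(constraints$or)) ok <- rounds_to(or, constraints$or, digits$or)
      if (ok && (!is.null(constraints$ci_low) || !is.null(constraints$ci_high))) {
        se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
        if (!is.null(constraints$ci_low)) {
          ok <- rounds_to(exp(log(or) - 1.96 * se), constraints$ci_low, digits$ci_low)
        }
        if (ok && !is.null(constraints$ci_high)) {
          ok <- rounds_to(exp(log(or) + 1.96 * se), constraints$ci_high, digits$ci_high)
        }
      }
    }
    ok
  }, logical(1))
  hits <- grid[keep, , drop = FALSE]
  tables <- lapply(seq_len(nrow(hits)), function(i) {
    m <- hits$m[i]; a <- hits$a[i]
    response_table(a, m - a, n_responders - a, n - m - (n_responders - a))
  })
  if (!length(tables)) {
    message("no table satisfies the constraints at the stated rounding")
  }
  list(tables = tables, unique = length(tables) == 1L)
}

#' Full evaluation report for matched calls against labels
#'
#' @param ems_results data.frame from [score_cohort()] (needs `patient_id`,
#'   `ems`, `matched`).
#' @param response_labels named 0/1 vector.
#' @param B permutations for the AP test.
#' @param seed integer seed for the permutation test.
#' @return list with the [response_table()], odds ratio and CI, Fisher
#'   p-values (both sidedness conventions), precision/ORR/increase, AP and
#'   its permutation p, and the coverage curve over the EMS.
#' @export
eval_response <- function(ems_results, response_labels, B = 999L, seed = 1L) {
  tab <- build_table(ems_results, response_labels)
  ids <- intersect(ems_results$patient_id, names(response_labels))
  scores <- ems_results$ems[match(ids, ems_results$patient_id)]
  labels <- as.numeric(response_labels[ids])
  or <- odds_ratio_ci(tab)
  pit <- precision_increase_test(tab)
  perm <- permutation_test_ap(scores, labels, B = B, seed = seed)
  list(table = tab, or = or,
       fisher_p_two_sided = fisher_exact(tab, "two.sided"),
       fisher_p_greater = fisher_exact(tab, "greater"),
       precision = pit$precision, orr = pit$orr,
       increase_pct = pit$increase_pct, precision_p = pit$p,
       ap = perm$ap, ap_permutation_p = perm$p,
       coverage = coverage_curve(scores, labels))
}
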