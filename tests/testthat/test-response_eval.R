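test_that("response tables derive rates correctly and build from calls and labels", {
  tab <- response_table(1, 1, 1, 1)
  expect_equal(tab$n, 4)
  expect_equal(tab$orr, 0.5)
  expect_equal(tab$precision, 0.5)
  expect_error(response_table(-1, 0, 0, 0), "non-negative")

  calls <- data.frame(patient_id = c("P1", "P2", "P3", "P4"),
                      matched = c(TRUE, TRUE, FALSE, FALSE))
  labels <- c(P1 = 1, P2 = 0, P3 = 1, P4 = 0)
  tab2 <- build_table(calls, labels)
  expect_equal(c(tab2$a, tab2$b, tab2$c, tab2$d), c(1, 1, 1, 1))
  # order invariance
  tab3 <- build_table(calls[c(3, 1, 4, 2), ], labels[c(2, 4, 3, 1)])
  expect_equal(c(tab3$a, tab3$b, tab3$c, tab3$d), c(1, 1, 1, 1))
  # all matched responders
  tab4 <- build_table(data.frame(patient_id = "P1", matched = TRUE), c(P1 = 1))
  expect_equal(c(tab4$a, tab4$b, tab4$c, tab4$d), c(1, 0, 0, 0))
  # missing labels excluded with a message
  expect_message(build_table(calls, labels[1:3]), "1 patient")
  expect_error(build_table(calls, c(QQ = 1)), "no patient")
})

test_that("odds ratio and Woolf interval match arithmetic and symmetry", {
  tab <- response_table(33, 36, 45, 120)
  or <- odds_ratio_ci(tab)
  expect_equal(or$or, (33 * 120) / (36 * 45))
  expect_equal(round(or$or, 2), 2.44)
  expect_equal(round(c(or$ci_low, or$ci_high), 2), c(1.36, 4.38))
  expect_false(or$haldane)

  # balanced table: OR 1, interval symmetric in log space
  bal <- odds_ratio_ci(response_table(7, 7, 7, 7))
  expect_equal(bal$or, 1)
  expect_equal(log(bal$ci_high), -log(bal$ci_low))

  # zero cell triggers the Haldane flag; empty margin errors
  hz <- odds_ratio_ci(response_table(5, 0, 3, 4))
  expect_true(hz$haldane)
  expect_equal(hz$or, (5.5 * 4.5) / (0.5 * 3.5))
  expect_error(odds_ratio_ci(response_table(0, 0, 3, 4)), "margin")
})

test_that("Fisher exact test matches enumeration and the reference implementation", {
  # (3,0,0,3): enumerate the C(6,3) = 20 assignments -> two-sided p = 1/10
  expect_equal(fisher_exact(response_table(3, 0, 0, 3)), 1 / 10)
  # zero margin: only one table possible
  expect_equal(fisher_exact(response_table(0, 0, 3, 4)), 1)
  expect_equal(fisher_exact(response_table(2, 3, 0, 0)), 1)

  # agreement with stats::fisher.test across random tables
  set.seed(40)
  for (i in 1:25) {
    cells <- as.vector(stats::rmultinom(1, sample(8:50, 1), rep(0.25, 4)))
    tab <- response_table(cells[1], cells[2], cells[3], cells[4])
    m <- matrix(cells, 2, byrow = TRUE)
    expect_equal(fisher_exact(tab), fisher.test(m)$p.value, tolerance = 1e-9)
    expect_equal(fisher_exact(tab, "greater"),
                 fisher.test(m, alternative = "greater")$p.value, tolerance = 1e-9)
  }
})

test_that("average precision matches brute-force sweeps and closed forms", {
  # perfect ranking
  expect_equal(average_precision(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # all scores tied: AP equals prevalence
  expect_equal(average_precision(rep(0.5, 10), c(rep(1, 3), rep(0, 7))), 0.3)
  # worked example: mean of precisions at the positives
  expect_equal(average_precision(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 5 / 6)
  expect_error(average_precision(c(0.1, 0.2), c(0, 0)), "positives")

  # brute-force threshold sweep oracle on random score vectors (with ties)
  ap_oracle <- function(scores, labels) {
    thr <- sort(unique(scores), decreasing = TRUE)
    prec <- vapply(thr, function(t) mean(labels[scores >= t]), numeric(1))
    rec <- vapply(thr, function(t) sum(labels[scores >= t]) / sum(labels), numeric(1))
    sum(diff(c(0, rec)) * prec)
  }
  set.seed(41)
  for (i in 1:30) {
    n <- sample(3:10, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) == 0) labels[1] <- 1
    expect_equal(average_precision(scores, labels), ap_oracle(scores, labels))
  }
})

test_that("random-label AP concentrates near prevalence", {
  set.seed(42)
  n <- 400
  scores <- runif(n)
  aps <- vapply(1:30, function(i) average_precision(scores, sample(rep(c(1, 0), c(120, 280)))),
                numeric(1))
  expect_lt(abs(mean(aps) - 0.3), 0.03)
})

test_that("coverage curves stay in range, fall with threshold, and flag degeneracy", {
  set.seed(43)
  n <- 200
  scores <- round(runif(n), 2)
  labels <- rbinom(n, 1, 0.4)
  cc <- coverage_curve(scores, labels)
  expect_true(all(cc$coverage >= 0.1 & cc$coverage <= 0.9))
  # coverage is non-increasing as the threshold rises
  expect_true(all(diff(cc$coverage[order(cc$threshold)]) <= 0))
  # under random scores the odds ratios hover around 1
  expect_true(median(cc$or, na.rm = TRUE) > 0.6 && median(cc$or, na.rm = TRUE) < 1.6)

  # a perfect classifier at coverage = prevalence has b = 0 -> flagged NA
  sc <- c(rep(0.9, 8), rep(0.1, 12))
  lb <- c(rep(1, 8), rep(0, 12))
  cc2 <- coverage_curve(sc, lb)
  row <- cc2[cc2$threshold == 0.9, ]
  expect_true(row$degenerate)
  expect_true(is.na(row$or))
  expect_error(coverage_curve(sc[1:5], lb[1:5]), "10 patients")
})

test_that("precision increase reproduces the aggregate worked example", {
  tab <- response_table(33, 36, 45, 120)
  out <- precision_increase_test(tab)
  expect_equal(round(100 * out$precision, 1), 47.8)
  expect_equal(round(100 * out$orr, 1), 33.3)
  expect_equal(round(out$increase_pct, 1), 43.5)
  expect_lt(out$p, 0.05)

  # equality and perfect-precision boundary cases
  expect_equal(precision_increase_test(response_table(5, 5, 5, 5))$increase_pct, 0)
  expect_equal(precision_increase_test(response_table(10, 0, 10, 20))$increase_pct, 100)
  expect_error(precision_increase_test(response_table(0, 0, 1, 5)), "no matched")
  expect_error(precision_increase_test(response_table(0, 5, 0, 5)), "undefined")
})

test_that("the AP permutation test attains its minimum p and is seeded", {
  scores <- c(rep(0.9, 5), rep(0.1, 5))
  labels <- c(rep(1, 5), rep(0, 5))
  out <- permutation_test_ap(scores, labels, B = 999, seed = 1)
  expect_equal(out$ap, 1)
  # permutations reproducing the perfect split tie the observed AP, so the
  # attainable minimum is bounded below by 1/(B+1)
  expect_gte(out$p, 1 / 1000)
  expect_lt(out$p, 0.05)
  expect_identical(permutation_test_ap(scores, labels, B = 999, seed = 1)$p, out$p)
  expect_error(permutation_test_ap(scores, labels, B = 10), "99")

  # strictly-minimal p when no permutation can tie: untied scores
  sc <- seq(0.1, 1, length.out = 8)
  lb <- c(0, 0, 0, 0, 1, 1, 1, 1)
  # only the identity assignment of labels to the top scores ties AP = 1;
  # probability of drawing it is small but nonzero, so p is near 1/(B+1)
  p2 <- permutation_test_ap(sc, lb, B = 999, seed = 2)$p
  expect_lt(p2, 0.05)
})

test_that("label-independent scores yield approximately uniform permutation p-values", {
  set.seed(44)
  ps <- vapply(1:60, function(i) {
    scores <- runif(30)
    labels <- rbinom(30, 1, 0.4)
    if (sum(labels) == 0) labels[1] <- 1
    permutation_test_ap(scores, labels, B = 199, seed = i)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("table reconstruction recovers unique and degenerate solution sets", {
  # balanced-OR toy case: (1,1,1,1) among the OR = 1 tables
  res <- reconstruct_table(4, 2, list(or = 1), digits = list(or = 2))
  cells <- vapply(res$tables, function(t) paste(t$a, t$b, t$c, t$d), character(1))
  expect_true("1 1 1 1" %in% cells)

  # inconsistent constraints return nothing
  expect_message(
    res2 <- reconstruct_table(10, 5, list(precision_pct = 100, or = 0.5)),
    "no table")
  expect_length(res2$tables, 0)
})
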