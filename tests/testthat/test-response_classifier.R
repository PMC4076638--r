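test_that("classify_response is a single-threshold step function", {
  expect_equal(as.character(classify_response(0)), "Responder")
  expect_equal(as.character(classify_response(50)), "Responder")
  expect_equal(as.character(classify_response(70)), "NonResponder")
  expect_error(classify_response(-1), "non-negative")
  set.seed(21)
  rel <- sort(stats::runif(200, 0, 200))
  calls <- classify_response(rel)
  expect_true(all(diff(calls == "NonResponder") >= 0))  # monotone step
  expect_equal(calls, classify_response(rel))           # order-free
})

test_that("relative_ki67 divides drug by vehicle at the final time", {
  t4 <- c(0, 24, 48, 72)
  d <- normalize_to_baseline(traj(t4, c(20, 18, 19, 20)))
  expect_equal(relative_ki67(d, d), 100)
  d2 <- normalize_to_baseline(traj(c(0, 72), c(50, 20)))     # -> 40
  v2 <- normalize_to_baseline(traj(c(0, 72), c(25, 20)))     # -> 80
  expect_equal(relative_ki67(d2, v2), 50)
  expect_error(relative_ki67(d2, v2, final_time = 48), "missing")
  expect_equal(relative_ki67(d2, v2, mode = "t0"), 40)
})

test_that("zero-noise synthetic responder recovers the planted value", {
  p <- cohort_params(n_cases = 6, responder_fraction = 0.5,
                     rel_ki67_final_responder_range = c(30, 30),
                     rel_ki67_final_nonresponder_range = c(70, 70),
                     noise_cv = 0, seed = 5)
  co <- generate_cohort(p)
  calls <- call_cohort_responses(co$ihc)
  truth <- reveal_true_class(co)
  resp <- names(truth)[truth == "Responder"]
  expect_equal(
    calls$relative_ki67_final[match(resp, calls$case_id)],
    rep(30, length(resp)))
  expect_equal(as.character(calls$call[match(resp, calls$case_id)]),
               rep("Responder", length(resp)))
})

test_that("unpaired t test: identity, monotonicity, flags, guards", {
  a <- c(1, 2, 3, 4)
  r <- unpaired_t_test(a, a)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  # p decreases monotonically with the shift between samples
  ps <- vapply(c(0.5, 1, 2, 4, 8),
               function(d) unpaired_t_test(a, a + d)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(unpaired_t_test(1, c(1, 2)), "n >= 2")
  expect_error(unpaired_t_test(c(1, 1), c(2, 2)), "degenerate")
  # welch flag reproduces the unequal-variance reference
  b <- c(10, 30, 20, 60, 40)
  expect_equal(unpaired_t_test(a, b, welch = TRUE)$p,
               stats::t.test(a, b)$p.value)
})

test_that("fisher_exact_2x2 handles degenerate and exact cases", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 0), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2)), 1)
  expect_error(fisher_exact_2x2(matrix(c(1.5, 0, 0, 1), 2)), "integer")
  expect_error(fisher_exact_2x2(matrix(0:5, 2, 3)), "2x2")
  # study-sized table against the reference oracle
  tab <- matrix(c(2, 1, 17, 13), 2)
  expect_equal(fisher_exact_2x2(tab),
               stats::fisher.test(tab)$p.value, tolerance = 1e-12)
})

test_that("fisher_exact_2x2 matches the oracle on all tables N <= 8", {
  for (n in 0:8) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      tab <- matrix(c(a, cc, b, n - a - b - cc), 2)
      expect_equal(fisher_exact_2x2(tab),
                   stats::fisher.test(tab)$p.value,
                   tolerance = 1e-12)
    }
  }
})

test_that("association_screen reproduces the cohort fixture statistics", {
  tab <- load_cohort_table()
  out <- association_screen(tab)
  expect_setequal(
    c("histotype", "tumor_size", "nodal_status", "grade", "er", "pr",
      "her2", "p53", "ki67_dichotomy", "ki67_mean"),
    out$feature)
  expect_true(all(out$p > 0 & out$p <= 1))
  km <- ki67_class_means(tab)
  expect_equal(round(unname(km)), c(16, 26))
  pf <- p53_mutation_frequencies(tab)
  expect_equal(floor(unname(pf)), c(10, 7))
  expect_error(association_screen(tab[tab$doxo_class == "Responder", ]),
               "each response class")
})

test_that("a feature perfectly aligned with class attains the minimal p", {
  tab <- load_cohort_table()
  tab$her2 <- ifelse(tab$doxo_class == "Responder", "Pos", "Neg")
  out <- association_screen(tab)
  p_aligned <- out$p[out$feature == "her2"]
  # minimal attainable two-sided p for the 19/14 margins
  p_min <- fisher_exact_2x2(matrix(c(19, 0, 0, 14), 2))
  expect_equal(p_aligned, p_min, tolerance = 1e-12)
  expect_lt(p_aligned, 1e-6)
})

test_that("t-test p on class means is uniform under a null cohort", {
  ps <- vapply(1:200, function(s) {
    p <- cohort_params(n_cases = 20, responder_fraction = 0.5,
                       ki67_mean_responder = 20,
                       ki67_mean_nonresponder = 20, seed = s)
    co <- generate_cohort(p)
    cases <- co$cases
    cases$doxo_class <- unname(reveal_true_class(co)[cases$case_id])
    out <- association_screen(cases)
    out$p[out$feature == "ki67_mean"]
  }, numeric(1))
  # integer-rounded Ki-67 scores can tie occasional p-values across
  # seeds; the approximate KS p remains valid for this check
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  # exact Fisher features are discrete hence conservative: rejection
  # rate at 0.05 should not exceed nominal by more than sampling slack
  ps_f <- vapply(1:200, function(s) {
    p <- cohort_params(n_cases = 20, responder_fraction = 0.5, seed = s)
    co <- generate_cohort(p)
    cases <- co$cases
    cases$doxo_class <- unname(reveal_true_class(co)[cases$case_id])
    out <- association_screen(cases)
    out$p[out$feature == "her2"]
  }, numeric(1))
  expect_lte(mean(ps_f < 0.05), 0.05 + 0.04)
})
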