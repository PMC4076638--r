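make_ct <- function(ct_by_sample, gene = "G1", role = "target",
                    class = NULL, reps = 1) {
  samples <- names(ct_by_sample)
  if (is.null(class)) class <- rep("Responder", length(samples))
  do.call(rbind, lapply(seq_along(samples), function(i) {
    data.frame(sample_id = samples[i], class = class[i], gene = gene,
               role = role, replicate = seq_len(reps),
               ct = ct_by_sample[[i]], stringsAsFactors = FALSE)
  }))
}

test_that("relative_quantity follows the efficiency^(Ctmin - Ct) rule", {
  ct <- make_ct(c(S1 = 24, S2 = 25, S3 = 27.32))
  rq <- relative_quantity(ct)
  expect_equal(rq$rq[rq$sample_id == "S1"], 1)
  expect_equal(rq$rq[rq$sample_id == "S2"], 0.5)
  expect_equal(rq$rq[rq$sample_id == "S3"], 2^-3.32)
  expect_equal(rq$rq[rq$sample_id == "S3"], 0.1, tolerance = 2e-3)
  # replicate averaging on the Ct scale; NA wells ignored
  ct2 <- rbind(make_ct(c(S1 = 24, S2 = 26)),
               make_ct(c(S1 = 26, S2 = NA)))
  rq2 <- relative_quantity(ct2)
  expect_equal(rq2$ct_mean[rq2$sample_id == "S1"], 25)
  expect_equal(rq2$rq[rq2$sample_id == "S2"], 0.5)
  # fully undetermined (gene, sample) propagates NA, not zero
  ct3 <- rbind(make_ct(c(S1 = 24)), make_ct(c(S2 = NA)))
  expect_true(is.na(relative_quantity(ct3)$rq[2]))
  expect_error(relative_quantity(ct, efficiency = 1), "efficiency")
  expect_error(relative_quantity(ct[, setdiff(names(ct), "ct")]),
               "missing column")
})

test_that("genorm stability M is zero for constant-ratio references", {
  s <- c(A = 1, B = 0.5, C = 2, D = 0.1)
  two <- rbind(r1 = s, r2 = 3 * s)
  expect_equal(unname(genorm_stability(two)), c(0, 0))
  three <- rbind(r1 = s, r2 = s, r3 = s)
  expect_equal(unname(genorm_stability(three)), c(0, 0, 0))
  expect_error(genorm_stability(two[1, , drop = FALSE]), ">= 2")
})

test_that("M grows monotonically with noise on one reference", {
  sigmas <- c(0.05, 0.2, 0.5, 1)
  m_noisy <- vapply(seq_along(sigmas), function(i) {
    set.seed(100 + i)
    base <- matrix(1, 3, 40,
                   dimnames = list(c("r1", "r2", "r3"), NULL))
    base[1, ] <- exp(stats::rnorm(40, 0, sigmas[i]))
    genorm_stability(base)[["r1"]]
  }, numeric(1))
  expect_true(all(diff(m_noisy) > 0))
})

test_that("genorm stability is invariant to sample permutation", {
  set.seed(31)
  m <- matrix(exp(stats::rnorm(30)), 3, 10,
              dimnames = list(paste0("r", 1:3), paste0("s", 1:10)))
  expect_equal(unname(genorm_stability(m)),
               unname(genorm_stability(m[, sample(10)])))
})

test_that("iterative reference exclusion drops the unstable gene", {
  set.seed(32)
  m <- matrix(exp(stats::rnorm(40, 0, 0.05)), 4, 10,
              dimnames = list(paste0("r", 1:4), paste0("s", 1:10)))
  m["r4", ] <- exp(stats::rnorm(10, 0, 2))
  expect_false("r4" %in% genorm_select(m, n_keep = 2))
})

test_that("normalization factor is the geometric mean of references", {
  m <- cbind(S1 = c(1, 1, 1), S2 = c(0.25, 1, 4), S3 = c(0.5, 0.5, 0.5))
  rownames(m) <- c("ACTB", "TBP", "HMBS")
  expect_equal(unname(normalization_factor(m)), c(1, 1, 0.5))
  m[2, 2] <- NA
  expect_error(normalization_factor(m), "sample 'S2', gene 'TBP'")
})

test_that("normalize_card yields per-gene median zero and drops sparse genes", {
  set.seed(33)
  rq <- matrix(exp(stats::rnorm(80)), 8, 10,
               dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
  nf <- stats::setNames(rep(1, 10), paste0("s", 1:10))
  v <- normalize_card(rq, nf)
  expect_true(all(abs(apply(v, 1, stats::median)) < 1e-12))
  # constant gene maps to all zeros
  rq["g1", ] <- 3
  expect_equal(unname(normalize_card(rq, nf)["g1", ]), rep(0, 10))
  # sparse gene dropped with a record
  rq["g2", 1:6] <- NA
  v2 <- normalize_card(rq, nf)
  expect_false("g2" %in% rownames(v2))
  expect_equal(attr(v2, "dropped_genes"), "g2")
  rq["g3", 1] <- 0
  expect_error(normalize_card(rq, nf), "positive")
})

test_that("doubling one cell shifts only that cell by ~+1 at large n", {
  set.seed(34)
  n <- 200
  rq <- matrix(exp(stats::rnorm(3 * n)), 3, n,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:n)))
  nf <- stats::setNames(rep(1, n), colnames(rq))
  v1 <- normalize_card(rq, nf)
  rq2 <- rq
  rq2["g2", "s7"] <- 2 * rq2["g2", "s7"]
  v2 <- normalize_card(rq2, nf)
  # exact only as n -> infinity: the re-centering median moves O(1/n)
  expect_equal(v2["g2", "s7"] - v1["g2", "s7"], 1, tolerance = 0.05)
  expect_equal(v2["g1", ], v1["g1", ])
  expect_equal(v2["g3", ], v1["g3", ])
})

test_that("card pipeline is invariant to per-sample scaling", {
  co <- generate_cohort(cohort_params(n_cases = 8,
                                      responder_fraction = 0.5,
                                      seed = 35))
  ct <- generate_ct_table(co, expression_params(n_targets = 10,
                                                seed = 36))
  ex1 <- expression_card_pipeline(ct)
  # scaling every RQ of one sample by c is one cycle off every Ct
  ct2 <- ct
  ct2$ct[ct2$sample_id == ct2$sample_id[1]] <-
    ct2$ct[ct2$sample_id == ct2$sample_id[1]] + 3.7
  ex2 <- expression_card_pipeline(ct2)
  expect_equal(ex1$values, ex2$values, tolerance = 1e-12)
})

test_that("differential_panel conventions and guards", {
  v <- matrix(stats::rnorm(20), 4, 5)
  expect_error(differential_panel(v, rep("Responder", 5)), ">= 2")
  # zero variance and zero difference -> p = 1
  m <- rbind(flat = rep(2, 6), var = c(1, 2, 3, 1, 2, 4))
  colnames(m) <- paste0("s", 1:6)
  cls <- rep(c("Responder", "NonResponder"), each = 3)
  d <- differential_panel(m, stats::setNames(cls, colnames(m)))
  expect_equal(d$p[d$gene == "flat"], 1)
  expect_true(all(diff(d$p) >= 0))             # sorted ascending
  expect_true(all(diff(d$fdr[order(d$rank)]) >= 0))
})

test_that("null panels give nominal false-positive rates", {
  ps <- unlist(lapply(1:20, function(s) {
    co <- generate_cohort(cohort_params(n_cases = 10,
                                        responder_fraction = 0.5,
                                        seed = s))
    ct <- generate_ct_table(co, expression_params(
      effect_genes = numeric(0), ct_sd = 0.3, seed = s))
    ex <- expression_card_pipeline(ct)
    differential_panel(ex$values, ex$classes)$p
  }))
  rate <- mean(ps < 0.05)
  # binomial slack (3.3 sd) widened for the shared per-sample
  # normalization-factor noise that correlates genes within a card
  expect_lt(abs(rate - 0.05), 0.025)
  expect_gt(min(ps), 0)
})

test_that("2^-dCt quantification", {
  expect_equal(delta_ct_quant(22, 22), 1)
  expect_equal(delta_ct_quant(23, 22), 0.5)
  expect_equal(delta_ct_quant(20, 22), 4)
  expect_true(is.na(delta_ct_quant(NA, 22)))
  expect_equal(delta_ct_quant(23, 22, efficiency = 1.9), 1.9^-1)
})
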