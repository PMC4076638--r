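test_that("cohort generator is deterministic and seed-sensitive", {
  p <- cohort_params(seed = 7)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(a$cases, b$cases)
  expect_identical(a$ihc, b$ihc)
  c2 <- generate_cohort(cohort_params(seed = 8))
  expect_false(identical(a$ihc$percent_positive,
                         c2$ihc$percent_positive))
})

test_that("the study split is reproduced by its fraction", {
  co <- generate_cohort(cohort_params(n_cases = 33,
                                      responder_fraction = 0.576,
                                      seed = 3))
  truth <- reveal_true_class(co)
  expect_equal(sum(truth == "Responder"), 19)
  expect_equal(sum(truth == "NonResponder"), 14)
  expect_true(all(co$cases$doxo_class == "Unknown"))
  expect_error(reveal_true_class(load_cohort_table()), "not a synthetic")
})

test_that("parameter validation names the offending class or field", {
  expect_error(cohort_params(n_cases = 1), "n_cases")
  expect_error(cohort_params(responder_fraction = 0), "responder_fraction")
  expect_error(cohort_params(rel_ki67_final_responder_range = c(60, 80)),
               "non-responder range low")
  expect_error(cohort_params(rel_ki67_final_responder_range = c(40, 20)),
               "low <= high")
  expect_error(cohort_params(timepoints = c(24, 48)), "timepoints")
  expect_error(generate_cohort(cohort_params(n_cases = 12,
                                             responder_fraction = 0.01)),
               "no Responder")
  expect_error(generate_cohort(cohort_params(n_cases = 12,
                                             responder_fraction = 0.99)),
               "no NonResponder")
})

test_that("generated observations stay in legal ranges", {
  for (s in 1:5) {
    co <- generate_cohort(cohort_params(noise_cv = 0.4, seed = s))
    ihc <- co$ihc
    expect_true(all(ihc$percent_positive >= 0 &
                      ihc$percent_positive <= 100))
    two_score <- ihc$marker == "CASP3"
    expect_true(all(ihc$intensity[two_score] %in% 0:3))
    expect_true(all(is.na(ihc$intensity[!two_score])))
    expect_true(all(table(ihc$case_id, ihc$marker, ihc$arm) ==
                      length(cohort_params()$timepoints)))
  }
})

test_that("caspase-3 induction is confined to drug-treated responders", {
  co <- generate_cohort(cohort_params(noise_cv = 0, seed = 9))
  truth <- reveal_true_class(co)
  fold <- cohort_params()$casp3_induction_fold_responder
  for (cs in names(truth)) {
    tr <- marker_trajectory(co$ihc, cs, "CASP3", "doxo")
    n <- normalize_to_baseline(tr)
    expected <- if (truth[cs] == "Responder") 100 * fold else 100
    expect_equal(n$norm_score[n$time_h == 72], expected,
                 tolerance = 1e-6)
    v <- normalize_to_baseline(marker_trajectory(co$ihc, cs, "CASP3",
                                                 "vehicle"))
    expect_equal(v$norm_score[v$time_h == 72], 100, tolerance = 1e-6)
  }
})

test_that("ct table generator plants exact class shifts at zero noise", {
  co <- generate_cohort(cohort_params(n_cases = 6,
                                      responder_fraction = 0.5,
                                      seed = 10))
  ep <- expression_params(effect_genes = c(BIRC5 = 2), ct_sd = 0,
                          seed = 11)
  ct <- generate_ct_table(co, ep)
  b5 <- ct[ct$gene == "BIRC5", ]
  expect_equal(unique(b5$ct[b5$class == "Responder"]) -
                 unique(b5$ct[b5$class == "NonResponder"]), 2)
  refs <- ct[ct$role == "reference", ]
  expect_equal(length(unique(refs$ct[refs$gene == "ACTB"])), 1L)
  expect_true(all(ct$ct > 0))
  expect_identical(ct, generate_ct_table(co, ep))
  expect_error(expression_params(effect_genes = c(NOPE = 1)),
               "NOPE")
})

test_that("dose-matrix generator is deterministic with sane geometry", {
  pp <- plate_params(seed = 12)
  a <- generate_dose_matrix(pp)
  expect_identical(a$wells, generate_dose_matrix(pp)$wells)
  expect_equal(nrow(a$wells), (7 + 7 + 49) * 2)
  expect_equal(length(a$pos_controls), 12)
  expect_gt(mean(a$neg_controls), mean(a$pos_controls))
  expect_error(plate_params(doses_a = 1:5), "7 doses")
  expect_error(plate_params(f_neg_mean = 10, f_pos_mean = 20),
               "f_neg_mean")
})

test_that("independent plates have identically zero excess at no noise", {
  g <- synergy_matrix(generate_dose_matrix(plate_params(noise_sd = 0)))
  expect_lt(max(abs(g$X)), 1e-12)
})

test_that("planted labels are recovered on default cohorts (50 seeds)", {
  acc <- vapply(1:50, function(s) {
    co <- generate_cohort(cohort_params(seed = s))
    calls <- call_cohort_responses(co$ihc)
    truth <- reveal_true_class(co)
    mean(as.character(calls$call) == truth[calls$case_id])
  }, numeric(1))
  expect_gte(mean(acc), 0.95)
})

test_that("responder GI at 72 h sits below the non-responder GI", {
  seed_means <- t(vapply(1:20, function(s) {
    co <- generate_cohort(cohort_params(seed = 200 + s))
    truth <- reveal_true_class(co)
    gi72 <- vapply(names(truth), function(cs) {
      gi <- growth_index(marker_trajectory(co$ihc, cs, "Ki67", "doxo"),
                         marker_trajectory(co$ihc, cs, "CASP3", "doxo"))
      gi$gi[gi$time_h == 72]
    }, numeric(1))
    c(resp = mean(gi72[truth == "Responder"]),
      nonr = mean(gi72[truth == "NonResponder"]))
  }, numeric(2)))
  expect_true(all(seed_means[, "resp"] < seed_means[, "nonr"]))
  # rank-sum oracle on the seed-level class means
  expect_lt(stats::wilcox.test(seed_means[, "resp"],
                               seed_means[, "nonr"],
                               alternative = "less")$p.value, 1e-6)
})
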