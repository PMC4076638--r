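#' @title Seeded synthetic cohort, gene-card and dose-matrix generators
#' @description Generates artificial data with the statistical structure
#'   the analysis stages assume: a cohort of tumor cases in two latent
#'   response classes (differing in baseline Ki-67, in drug-arm relative
#'   Ki-67 trajectory and in caspase-3 induction), gene-card Ct tables
#'   with stable references and planted class effects, and two-drug
#'   Hill-response dose-matrix plates with or without a planted Bliss
#'   interaction. Every generator is deterministic given its parameter
#'   set (the seed is a parameter).
#' @name synthetic_cohort
NULL

#' Cohort generator parameters
#'
#' Defaults encode the observed study conditions: a 33-case cohort with
#' a 19/33 responder fraction, baseline Ki-67 class means of 16% and
#' 26%, drug-arm final relative Ki-67 drawn from 0-50% of control for
#' Responders and 70-180% for Non-Responders, caspase-3 induction
#' confined to Responders, and 24-h sampling to 72 h.
#'
#' @param n_cases Number of cases (>= 2).
#' @param responder_fraction Fraction of Responder cases in (0, 1).
#' @param ki67_mean_responder,ki67_mean_nonresponder Baseline diagnostic
#'   Ki-67 class means (percent).
#' @param ki67_sd Baseline Ki-67 standard deviation (percent).
#' @param rel_ki67_final_responder_range,rel_ki67_final_nonresponder_range
#'   `[low, high]` ranges (percent of control) for the drug-arm final
#'   relative Ki-67 of each class; responder high must not exceed
#'   non-responder low.
#' @param casp3_induction_fold_responder Fold rise of the caspase-3
#'   composite at 72 h in Responders under drug (> 0).
#' @param timepoints Ordered sampling times in hours, starting at 0.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal score noise applied at t > 0.
#' @param seed Integer RNG seed.
#' @return A validated list of class `cohort_params`.
#' @export
cohort_params <- function(n_cases = 33,
                          responder_fraction = 19 / 33,
                          ki67_mean_responder = 16,
                          ki67_mean_nonresponder = 26,
                          ki67_sd = 8,
                          rel_ki67_final_responder_range = c(0, 50),
                          rel_ki67_final_nonresponder_range = c(70, 180),
                          casp3_induction_fold_responder = 4,
                          timepoints = c(0, 24, 48, 72),
                          noise_cv = 0.1,
                          seed = 1L) {
  stopifnot(length(rel_ki67_final_responder_range) == 2L,
            length(rel_ki67_final_nonresponder_range) == 2L)
  if (n_cases != round(n_cases) || n_cases < 2) {
    stop("n_cases must be an integer >= 2", call. = FALSE)
  }
  if (responder_fraction <= 0 || responder_fraction >= 1) {
    stop("responder_fraction must lie strictly in (0, 1)", call. = FALSE)
  }
  rr <- rel_ki67_final_responder_range
  nr <- rel_ki67_final_nonresponder_range
  if (rr[1] > rr[2] || nr[1] > nr[2]) {
    stop("relative Ki-67 ranges must have low <= high", call. = FALSE)
  }
  if (rr[2] > nr[1]) {
    stop("responder range high (", rr[2], ") must not exceed ",
         "non-responder range low (", nr[1], ")", call. = FALSE)
  }
  if (any(c(ki67_mean_responder, ki67_mean_nonresponder, ki67_sd,
            rr, nr) < 0) || casp3_induction_fold_responder <= 0) {
    stop("percents must be >= 0 and the caspase-3 fold > 0",
         call. = FALSE)
  }
  if (timepoints[1] != 0 || is.unsorted(timepoints, strictly = TRUE)) {
    stop("timepoints must start at 0 and increase strictly",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "cohort_params")
}

# lognormal multiplier with unit mean and the requested CV
lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# log-linear interpolation from 100% at t=0 to `final` percent at t=T
rel_trajectory <- function(timepoints, final) {
  100 * (final / 100)^(timepoints / max(timepoints))
}

#' Generate a synthetic cohort with latent response classes
#'
#' Each case carries a hidden true class (recoverable only through
#' [reveal_true_class()]). Baseline Ki-67 is normal around the class
#' mean; the vehicle-arm trajectory fluctuates multiplicatively around
#' baseline; the drug-arm Ki-67 declines (or not) log-linearly toward a
#' final relative value drawn uniformly from the class range (values
#' below 0.5% of control are floored to keep the log trajectory
#' defined). The caspase-3 composite rises log-linearly by the stated
#' fold in drug-treated Responders only. Clinicopathological covariates
#' are drawn independently of class.
#'
#' @param params A [cohort_params()] object.
#' @return List with `cases` (one row per case, schema of
#'   [load_cohort_table()] with `doxo_class = "Unknown"`) and `ihc`
#'   (long observation table: `case_id`, `marker`, `arm`, `time_h`,
#'   `percent_positive`, `intensity`). The hidden labels are stored in
#'   the `true_class` attribute of `cases`.
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  p <- params
  n_resp <- round(p$n_cases * p$responder_fraction)
  n_nonr <- p$n_cases - n_resp
  if (n_resp == 0L) stop("no Responder cases after rounding", call. = FALSE)
  if (n_nonr == 0L) stop("no NonResponder cases after rounding",
                         call. = FALSE)
  set.seed(p$seed)
  true_class <- sample(rep(c("Responder", "NonResponder"),
                           c(n_resp, n_nonr)))
  id <- sprintf("SYN%03d", seq_len(p$n_cases))
  is_resp <- true_class == "Responder"

  ki67_base <- stats::rnorm(
    p$n_cases, ifelse(is_resp, p$ki67_mean_responder,
                      p$ki67_mean_nonresponder), p$ki67_sd)
  ki67_base <- pmin(100, pmax(1, ki67_base))

  er <- ifelse(stats::runif(p$n_cases) < 0.85,
               5 * sample(5:19, p$n_cases, replace = TRUE), 0)
  pr <- ifelse(stats::runif(p$n_cases) < 0.70,
               5 * sample(1:19, p$n_cases, replace = TRUE), 0)
  p53_mut_labels <- c("R175H", "R248W", "R273C", "K132N", "R280G")
  cases <- data.frame(
    case_id = id,
    histotype = sample(c("IDC", "ILC", "DLC", "PC"), p$n_cases,
                       replace = TRUE, prob = c(0.80, 0.08, 0.06, 0.06)),
    t_stage = sample(c("pT1c", "pT2", "pT3"), p$n_cases, replace = TRUE,
                     prob = c(0.45, 0.40, 0.15)),
    n_stage = sample(c("N0", "N1a", "N2a", "N3a", "Nx"), p$n_cases,
                     replace = TRUE, prob = c(0.40, 0.25, 0.10, 0.10,
                                              0.15)),
    grade = sample(c("G1", "G2", "G3"), p$n_cases, replace = TRUE,
                   prob = c(0.15, 0.45, 0.40)),
    er_percent = er, pr_percent = pr,
    her2 = sample(c("Pos", "Neg"), p$n_cases, replace = TRUE,
                  prob = c(0.15, 0.85)),
    ki67_diagnosis = round(ki67_base),
    p53_status = ifelse(stats::runif(p$n_cases) < 0.09,
                        sample(p53_mut_labels, p$n_cases, replace = TRUE),
                        "Wt"),
    doxo_class = "Unknown", stringsAsFactors = FALSE)

  rr <- p$rel_ki67_final_responder_range
  nr <- p$rel_ki67_final_nonresponder_range
  rel_final <- ifelse(is_resp, stats::runif(p$n_cases, rr[1], rr[2]),
                      stats::runif(p$n_cases, nr[1], nr[2]))
  rel_final <- pmax(rel_final, 0.5)  # keep the log trajectory defined

  tp <- p$timepoints
  nt <- length(tp)
  casp3_base <- 10  # low apoptotic composite at baseline (H-score units)
  rows <- vector("list", p$n_cases)
  for (i in seq_len(p$n_cases)) {
    ki_v <- ki67_base[i] * c(1, lognoise(nt - 1, p$noise_cv))
    ki_d <- ki67_base[i] * rel_trajectory(tp, rel_final[i]) / 100 *
      c(1, lognoise(nt - 1, p$noise_cv))
    fold <- if (is_resp[i]) p$casp3_induction_fold_responder else 1
    c3_v <- casp3_base * c(1, lognoise(nt - 1, p$noise_cv))
    c3_d <- casp3_base * fold^(tp / max(tp)) *
      c(1, lognoise(nt - 1, p$noise_cv))
    comp <- c(c3_v, c3_d)
    comp <- pmin(comp, 300)
    int3 <- pmax(1, ceiling(comp / 100))
    rows[[i]] <- data.frame(
      case_id = id[i],
      marker = rep(c("Ki67", "CASP3"), each = 2 * nt),
      arm = rep(rep(c("vehicle", "doxo"), each = nt), 2),
      time_h = rep(tp, 4),
      percent_positive = c(pmin(100, pmax(0, c(ki_v, ki_d))),
                           pmin(100, comp / int3)),
      intensity = c(rep(NA_integer_, 2 * nt), int3),
      stringsAsFactors = FALSE)
  }
  ihc <- do.call(rbind, rows)
  rownames(ihc) <- NULL
  attr(cases, "true_class") <- stats::setNames(true_class, id)
  attr(cases, "rel_ki67_final_true") <- stats::setNames(rel_final, id)
  list(cases = cases, ihc = ihc, params = params)
}

#' Reveal the hidden true class labels of a synthetic cohort
#'
#' The generator hides the planted labels behind this accessor so that
#' recovery tests cannot leak truth through the ordinary case table
#' (whose `doxo_class` column is `"Unknown"`).
#'
#' @param cohort The list returned by [generate_cohort()], or its
#'   `cases` element.
#' @return Named character vector of true classes, one per case.
#' @export
reveal_true_class <- function(cohort) {
  cases <- if (is.data.frame(cohort)) cohort else cohort$cases
  tc <- attr(cases, "true_class")
  if (is.null(tc)) {
    stop("no hidden class labels: not a synthetic cohort", call. = FALSE)
  }
  tc
}

#' Gene-card generator parameters
#'
#' Defaults mirror the profiled card layout: 92 apoptosis-related
#' targets (names from [load_apoptosis_panel()]), three reference genes
#' (ACTB, TBP, HMBS), duplicate wells, and one planted class effect
#' (BIRC5 two log2 units higher in Non-Responders).
#'
#' @param n_targets Number of target genes (<= panel size).
#' @param reference_genes Names of the reference genes.
#' @param base_ct Baseline Ct per gene: a named vector covering all
#'   genes, a scalar, or NULL for a deterministic default ladder
#'   (references 19/22/25; targets evenly spaced over 24-34).
#' @param ct_sd Well-level Ct standard deviation (> 0 unless exactly 0
#'   for noiseless construction).
#' @param effect_genes Named numeric vector of log2 fold-changes
#'   (NonResponder minus Responder) planted on target genes; a positive
#'   value lowers the Non-Responder Ct.
#' @param duplicate_wells Replicate wells per (gene, sample).
#' @param seed Integer RNG seed.
#' @return A validated list of class `expression_params`.
#' @export
expression_params <- function(n_targets = 92,
                              reference_genes = c("ACTB", "TBP", "HMBS"),
                              base_ct = NULL,
                              ct_sd = 0.25,
                              effect_genes = c(BIRC5 = 2),
                              duplicate_wells = 2,
                              seed = 1L) {
  panel <- load_apoptosis_panel()$gene
  if (n_targets < 1 || n_targets > length(panel)) {
    stop("n_targets must be between 1 and ", length(panel), call. = FALSE)
  }
  targets <- panel[seq_len(n_targets)]
  if (ct_sd < 0) stop("ct_sd must be >= 0", call. = FALSE)
  if (duplicate_wells < 1) stop("duplicate_wells must be >= 1",
                                call. = FALSE)
  unknown <- setdiff(names(effect_genes), targets)
  if (length(unknown) > 0L) {
    stop("effect gene(s) not on the target panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  genes <- c(targets, reference_genes)
  if (is.null(base_ct)) {
    base_ct <- stats::setNames(
      c(seq(24, 34, length.out = n_targets),
        c(19, 22, 25)[seq_along(reference_genes)]), genes)
  } else if (length(base_ct) == 1L) {
    base_ct <- stats::setNames(rep(base_ct, length(genes)), genes)
  } else if (!all(genes %in% names(base_ct))) {
    stop("base_ct must name every target and reference gene",
         call. = FALSE)
  }
  structure(list(targets = targets, reference_genes = reference_genes,
                 base_ct = base_ct, ct_sd = ct_sd,
                 effect_genes = effect_genes,
                 duplicate_wells = duplicate_wells, seed = seed),
            class = "expression_params")
}

#' Generate a synthetic gene-card Ct table
#'
#' Reference genes get class-independent Ct around their baseline; each
#' planted effect gene's Non-Responder mean Ct is shifted by minus its
#' log2 fold-change (lower Ct = higher expression). Duplicate wells are
#' independent Gaussian draws around the class mean.
#'
#' @param cases Cohort case table (or [generate_cohort()] output); true
#'   classes are taken from the hidden labels when `doxo_class` is
#'   Unknown.
#' @param params An [expression_params()] object.
#' @return Long Ct table: `sample_id`, `class`, `gene`, `role`,
#'   `replicate`, `ct`.
#' @export
generate_ct_table <- function(cases, params = expression_params()) {
  stopifnot(inherits(params, "expression_params"))
  tab <- if (is.data.frame(cases)) cases else cases$cases
  cls <- as.character(tab$doxo_class)
  if (any(cls == "Unknown") && !is.null(attr(tab, "true_class"))) {
    cls <- unname(attr(tab, "true_class")[tab$case_id])
  }
  if (!all(cls %in% c("Responder", "NonResponder"))) {
    stop("every case needs a Responder/NonResponder class", call. = FALSE)
  }
  p <- params
  set.seed(p$seed)
  genes <- c(p$targets, p$reference_genes)
  role <- rep(c("target", "reference"),
              c(length(p$targets), length(p$reference_genes)))
  shift <- stats::setNames(rep(0, length(genes)), genes)
  shift[names(p$effect_genes)] <- p$effect_genes
  grid <- expand.grid(replicate = seq_len(p$duplicate_wells),
                      gene_i = seq_along(genes),
                      sample_i = seq_len(nrow(tab)))
  mu <- p$base_ct[genes[grid$gene_i]] -
    shift[genes[grid$gene_i]] *
    (cls[grid$sample_i] == "NonResponder")
  data.frame(sample_id = tab$case_id[grid$sample_i],
             class = cls[grid$sample_i],
             gene = genes[grid$gene_i],
             role = role[grid$gene_i],
             replicate = grid$replicate,
             ct = stats::rnorm(nrow(grid), mu, p$ct_sd),
             stringsAsFactors = FALSE)
}

#' Dose-matrix plate generator parameters
#'
#' Defaults reproduce the screening layout: 7-point geometric dose
#' ladders spanning 0.0004-0.1 umol/L (drug A, the survivin suppressant
#' range) and 0.004-1 umol/L (drug B, the chemotherapy range), Hill
#' slope 1 with EC50 at the geometric mid-dose, duplicate assay wells,
#' 12 + 12 control wells, and fluorescence noise of 2% of the plate's
#' dynamic range.
#'
#' @param doses_a,doses_b Strictly increasing 7-point dose ladders
#'   (umol/L).
#' @param hill_ec50_a,hill_ec50_b,hill_slope_a,hill_slope_b Hill
#'   midpoints and slopes of the single-agent inhibition curves.
#' @param interaction One of `independent`, `synergistic`,
#'   `antagonistic`.
#' @param interaction_strength Non-negative scaling of the planted
#'   deviation from Bliss independence.
#' @param f_neg_mean,f_pos_mean Mean fluorescence of untreated and
#'   maximal-kill wells; `f_neg_mean > f_pos_mean`.
#' @param replicate_wells Assay replicates per dose pair.
#' @param control_wells Wells per control arm.
#' @param noise_sd Additive Gaussian fluorescence noise SD.
#' @param seed Integer RNG seed.
#' @return A validated list of class `plate_params`.
#' @export
plate_params <- function(doses_a = exp(seq(log(4e-4), log(0.1),
                                           length.out = 7)),
                         doses_b = exp(seq(log(4e-3), log(1),
                                           length.out = 7)),
                         hill_ec50_a = sqrt(4e-4 * 0.1),
                         hill_ec50_b = sqrt(4e-3 * 1),
                         hill_slope_a = 1, hill_slope_b = 1,
                         interaction = c("independent", "synergistic",
                                         "antagonistic"),
                         interaction_strength = 1,
                         f_neg_mean = 10000, f_pos_mean = 1000,
                         replicate_wells = 2, control_wells = 12,
                         noise_sd = 0.02 * (10000 - 1000),
                         seed = 1L) {
  interaction <- match.arg(interaction)
  if (length(doses_a) != 7L || length(doses_b) != 7L) {
    stop("each drug needs exactly 7 doses", call. = FALSE)
  }
  if (any(doses_a <= 0) || any(doses_b <= 0) ||
      is.unsorted(doses_a, strictly = TRUE) ||
      is.unsorted(doses_b, strictly = TRUE)) {
    stop("doses must be positive and strictly increasing", call. = FALSE)
  }
  if (f_neg_mean <= f_pos_mean) {
    stop("f_neg_mean must exceed f_pos_mean", call. = FALSE)
  }
  if (interaction_strength < 0) {
    stop("interaction_strength must be >= 0", call. = FALSE)
  }
  stopifnot(hill_ec50_a > 0, hill_ec50_b > 0, hill_slope_a > 0,
            hill_slope_b > 0, replicate_wells >= 1, control_wells >= 1,
            noise_sd >= 0)
  structure(as.list(environment()), class = "plate_params")
}

hill_inhibition <- function(d, ec50, slope) {
  d^slope / (d^slope + ec50^slope)
}

# true combination inhibition under the planted interaction model:
# the Bliss expectation deformed by strength * sqrt(A*B) * (1 - E)
# (geometric-mean coupling: zero when either agent is inactive, largest
# head-room-weighted deviation near mutual mid-effect; at A = B = 0.5,
# strength 1 this gives 0.75 + 1 * 0.25 * 0.5 = 0.875)
combo_truth <- function(A, B, interaction, strength) {
  E <- A + B - A * B
  dev <- strength * sqrt(A * B) * (1 - E)
  switch(interaction,
         independent = E,
         synergistic = pmin(1, pmax(0, E + dev)),
         antagonistic = pmin(1, pmax(0, E - dev)))
}

#' Generate a synthetic dose-matrix plate
#'
#' Single-agent wells follow Hill inhibition curves; combination wells
#' follow the Bliss expectation, optionally deformed by a planted
#' synergistic or antagonistic interaction
#' (`E +/- strength * A * B * (1 - E)`, clipped to `[0, 1]`).
#' Fluorescence maps inhibition linearly between the control means, with
#' additive Gaussian noise on every well including controls.
#'
#' @param params A [plate_params()] object.
#' @return A `dose_matrix_plate` (see [dose_matrix_plate()]) with the
#'   noiseless truth attached as attribute `truth` (list of `A`, `B`,
#'   `O`).
#' @export
generate_dose_matrix <- function(params = plate_params()) {
  stopifnot(inherits(params, "plate_params"))
  p <- params
  set.seed(p$seed)
  A <- hill_inhibition(p$doses_a, p$hill_ec50_a, p$hill_slope_a)
  B <- hill_inhibition(p$doses_b, p$hill_ec50_b, p$hill_slope_b)
  O <- outer(A, B, combo_truth, interaction = p$interaction,
             strength = p$interaction_strength)
  grid <- rbind(
    data.frame(dose_a = p$doses_a, dose_b = 0, f_true = A),
    data.frame(dose_a = 0, dose_b = p$doses_b, f_true = B),
    data.frame(dose_a = rep(p$doses_a, times = 7),
               dose_b = rep(p$doses_b, each = 7), f_true = as.vector(O)))
  wells <- grid[rep(seq_len(nrow(grid)), each = p$replicate_wells), ]
  wells$replicate <- rep(seq_len(p$replicate_wells), nrow(grid))
  wells$fluorescence <- p$f_neg_mean -
    wells$f_true * (p$f_neg_mean - p$f_pos_mean) +
    stats::rnorm(nrow(wells), 0, p$noise_sd)
  rownames(wells) <- NULL
  plate <- dose_matrix_plate(
    drug_a = "drug_A", drug_b = "drug_B",
    doses_a = p$doses_a, doses_b = p$doses_b,
    wells = wells[, c("dose_a", "dose_b", "replicate", "fluorescence")],
    pos_controls = stats::rnorm(p$control_wells, p$f_pos_mean,
                                p$noise_sd),
    neg_controls = stats::rnorm(p$control_wells, p$f_neg_mean,
                                p$noise_sd))
  attr(plate, "truth") <- list(A = A, B = B, O = O,
                               interaction = p$interaction)
  plate
}
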