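#' @title Responder / Non-Responder classification and association tests
#' @description Implements the drug-response rule used to stratify
#'   organotypic tumors after ex vivo doxorubicin exposure - a tumor is a
#'   Responder when Ki-67 immunoreactivity at the final shared timepoint,
#'   relative to the vehicle arm, has fallen by at least 50% - plus the
#'   group-level statistics (classical unpaired t, exact 2x2 Fisher) used
#'   to screen clinicopathological associations.
#' @name response_classifier
NULL

RULE_VERSION <- "relative-ki67-vs-vehicle/le-50-responder/v1"

#' Relative Ki-67 at the final timepoint
#'
#' Ratio (x100) of the baseline-normalized Ki-67 of the drug arm to the
#' baseline-normalized Ki-67 of the vehicle arm at the final shared
#' timepoint. With `mode = "t0"` the vehicle denominator is dropped and
#' the drug arm's own normalized value is returned (drift-uncorrected).
#'
#' @param doxo,vehicle Baseline-normalized trajectories (data.frames
#'   with `time_h` and `norm_score`; see [normalize_to_baseline()]).
#' @param final_time Timepoint in hours; default is the latest time
#'   present in both arms.
#' @param mode `"vehicle"` (default) or `"t0"`.
#' @return Percent-of-control Ki-67 (100 = no effect).
#' @export
relative_ki67 <- function(doxo, vehicle, final_time = NULL,
                          mode = c("vehicle", "t0")) {
  mode <- match.arg(mode)
  stopifnot(all(c("time_h", "norm_score") %in% names(doxo)),
            all(c("time_h", "norm_score") %in% names(vehicle)))
  shared <- intersect(doxo$time_h, vehicle$time_h)
  if (is.null(final_time)) final_time <- max(shared)
  if (!(final_time %in% doxo$time_h) || !(final_time %in% vehicle$time_h)) {
    stop("final timepoint ", final_time, " h missing from one arm",
         call. = FALSE)
  }
  d <- doxo$norm_score[doxo$time_h == final_time]
  if (mode == "t0") return(d)
  v <- vehicle$norm_score[vehicle$time_h == final_time]
  100 * d / v
}

#' Classify a tumor from its relative Ki-67
#'
#' Responder when the relative Ki-67 (percent of control) is less than
#' or equal to 50, i.e. proliferation fell by at least half; otherwise
#' NonResponder. The boundary value 50 is a Responder ("decrease equal
#' to or greater than 50%").
#'
#' @param rel Relative Ki-67, percent of control (>= 0).
#' @return Factor with levels Responder/NonResponder/Unknown.
#' @export
#' @examples
#' classify_response(c(0, 50, 70))
classify_response <- function(rel) {
  if (any(is.na(rel)) || any(rel < 0)) {
    stop("relative Ki-67 must be non-negative and non-missing",
         call. = FALSE)
  }
  factor(ifelse(rel <= 50, "Responder", "NonResponder"),
         levels = response_levels())
}

#' Classify every case of a long-format IHC table
#'
#' Builds the vehicle- and drug-arm Ki-67 trajectories for each case,
#' normalizes them to baseline, computes the relative Ki-67 at the final
#' shared timepoint and applies [classify_response()].
#'
#' @param ihc Long-format IHC observation table (see
#'   [marker_trajectory()]).
#' @param final_time Final timepoint in hours; default latest shared.
#' @param mode Denominator mode passed to [relative_ki67()].
#' @return A data.frame with columns `case_id`, `relative_ki67_final`,
#'   `call` and `rule_version`.
#' @export
call_cohort_responses <- function(ihc, final_time = NULL,
                                  mode = c("vehicle", "t0")) {
  mode <- match.arg(mode)
  cases <- unique(ihc$case_id[ihc$marker == "Ki67"])
  rel <- vapply(cases, function(cs) {
    doxo <- normalize_to_baseline(marker_trajectory(ihc, cs, "Ki67", "doxo"))
    veh <- normalize_to_baseline(
      marker_trajectory(ihc, cs, "Ki67", "vehicle"))
    relative_ki67(doxo, veh, final_time = final_time, mode = mode)
  }, numeric(1))
  data.frame(case_id = cases, relative_ki67_final = unname(rel),
             call = classify_response(unname(rel)),
             rule_version = RULE_VERSION, stringsAsFactors = FALSE)
}

#' Classical unpaired two-sample t test
#'
#' Two-sided Student t with pooled variance by default (the convention
#' of the source analyses); Welch's unequal-variance form by flag.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param welch Use the Welch correction instead of pooled variance.
#' @return A list with `t`, `p` and `df`.
#' @export
unpaired_t_test <- function(a, b, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs n >= 2", call. = FALSE)
  }
  if (stats::var(a) + stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1,
                                        df = length(a) + length(b) - 2))
    stop("degenerate samples: zero variance in both groups with ",
         "unequal means", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Exact two-sided Fisher test for a 2x2 table
#'
#' Full enumeration of all tables with the observed margins; the
#' two-sided p-value is the sum of hypergeometric probabilities not
#' exceeding that of the observed table (with relative tolerance 1e-7
#' for floating-point ties, the standard convention).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2))
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) {
    stop("a 2x2 table is required", call. = FALSE)
  }
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  if (n == 0L) return(1)
  # support of the (1,1) cell given fixed margins
  klo <- max(0L, r1 + c1 - n)
  khi <- min(r1, c1)
  k <- klo:khi
  logp <- lchoose(c1, k) + lchoose(n - c1, r1 - k) - lchoose(n, r1)
  p <- exp(logp)
  p_obs <- p[k == tab[1, 1]]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

ki67_dichotomy_cutoff <- 15  # percent; low proliferative index is <= 15

#' Screen clinicopathological features for association with response
#'
#' For each categorical feature the class x feature table is collapsed
#' to 2x2 (IDC vs other histotype, pT1 vs higher T stage, node-negative
#' vs positive, G3 vs G1-G2, receptor positive vs negative, HER2, p53
#' mutant vs wild-type) and tested with [fisher_exact_2x2()]. Diagnostic
#' Ki-67 is tested twice: unpaired t on the class means and Fisher on
#' the low/high dichotomy (<= 15% vs > 15% positive cells). Cases with
#' unknown nodal status (Nx) are dropped from the nodal test only.
#'
#' @param cases Cohort data.frame in the schema of
#'   [load_cohort_table()]; `doxo_class` must contain both classes.
#' @return A data.frame with columns `feature`, `test`, `statistic`,
#'   `p` and `detail`.
#' @export
association_screen <- function(cases) {
  cls <- as.character(cases$doxo_class)
  keep <- cls %in% c("Responder", "NonResponder")
  cases <- cases[keep, , drop = FALSE]
  cls <- cls[keep]
  if (length(unique(cls)) < 2L || min(table(cls)) < 2L) {
    stop("association screen needs >= 2 cases in each response class",
         call. = FALSE)
  }
  is_resp <- cls == "Responder"

  fisher_row <- function(feature, flag, detail) {
    ok <- !is.na(flag)
    tab <- table(factor(is_resp[ok], c(TRUE, FALSE)),
                 factor(flag[ok], c(TRUE, FALSE)))
    data.frame(feature = feature, test = "fisher_exact",
               statistic = NA_real_, p = fisher_exact_2x2(tab),
               detail = detail, stringsAsFactors = FALSE)
  }

  rows <- list(
    fisher_row("histotype", cases$histotype == "IDC", "IDC vs other"),
    fisher_row("tumor_size", grepl("^pT1", cases$t_stage),
               "pT1 vs pT2+"),
    fisher_row("nodal_status",
               ifelse(grepl("x$", cases$n_stage, ignore.case = TRUE),
                      NA, grepl("0$", cases$n_stage)),
               "N0 vs N+ (Nx dropped)"),
    fisher_row("grade", cases$grade == "G3", "G3 vs G1-G2"),
    fisher_row("er", cases$er_percent > 0, "ER+ vs ER-"),
    fisher_row("pr", cases$pr_percent > 0, "PR+ vs PR-"),
    fisher_row("her2", cases$her2 == "Pos", "HER2+ vs HER2-"),
    fisher_row("p53", cases$p53_status != "Wt", "mutant vs wild-type"),
    fisher_row("ki67_dichotomy",
               cases$ki67_diagnosis > ki67_dichotomy_cutoff,
               paste0(">", ki67_dichotomy_cutoff, "% vs <=",
                      ki67_dichotomy_cutoff, "%"))
  )
  tt <- unpaired_t_test(cases$ki67_diagnosis[is_resp],
                        cases$ki67_diagnosis[!is_resp])
  rows <- c(rows, list(data.frame(
    feature = "ki67_mean", test = "unpaired_t", statistic = tt$t,
    p = tt$p,
    detail = sprintf("mean Responder %.1f vs NonResponder %.1f",
                     mean(cases$ki67_diagnosis[is_resp]),
                     mean(cases$ki67_diagnosis[!is_resp])),
    stringsAsFactors = FALSE)))
  do.call(rbind, rows)
}

#' Diagnostic Ki-67 mean by response class
#'
#' @param cases Cohort data.frame (schema of [load_cohort_table()]).
#' @return Named numeric vector with the Responder and NonResponder
#'   means of diagnostic Ki-67 (percent).
#' @export
ki67_class_means <- function(cases) {
  cls <- as.character(cases$doxo_class)
  c(Responder = mean(cases$ki67_diagnosis[cls == "Responder"]),
    NonResponder = mean(cases$ki67_diagnosis[cls == "NonResponder"]))
}

#' p53 mutation frequency by response class
#'
#' @param cases Cohort data.frame (schema of [load_cohort_table()]).
#' @return Named numeric vector of mutation frequencies in percent.
#' @export
p53_mutation_frequencies <- function(cases) {
  cls <- as.character(cases$doxo_class)
  mut <- cases$p53_status != "Wt"
  c(Responder = 100 * mean(mut[cls == "Responder"]),
    NonResponder = 100 * mean(mut[cls == "NonResponder"]))
}
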