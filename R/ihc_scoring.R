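#' @title IHC scoring: Ki-67 index, H-score composites, trajectories and
#'   growth index
#' @description Converts raw immunohistochemistry / immunofluorescence
#'   observations (counts, percentages, 0-3 intensity grades) into the
#'   quantitative scores used downstream: Ki-67 proliferation index,
#'   two-score (H-score) composites for apoptosis/p53-pathway markers,
#'   baseline-normalized marker trajectories, the Ki-67/cleaved-caspase-3
#'   growth index, and the gammaH2AX phosphorylation index.
#' @name ihc_scoring
NULL

# markers scored by percent positivity alone; the rest carry an intensity
# grade and are quantified as percent x intensity (H-score, 0-300)
PERCENT_ONLY_MARKERS <- c("Ki67", "gH2AX")
TWO_SCORE_MARKERS <- c("CASP3", "P53", "P21", "MDM2", "ER", "PR")

# scores of exactly 0 are lifted to this floor before any ratio or
# baseline normalization (half the minimal nonzero H-score unit: 1%
# positivity at intensity 1), so growth indices and T0 normalization
# are total functions
ZERO_SCORE_FLOOR <- 0.5

#' Ki-67 proliferation score
#'
#' Percentage of Ki-67-positive cells over the entire tumor cell
#' population of the sample.
#'
#' @param positive_cells Number of positive tumor cells (non-negative
#'   integer-valued).
#' @param total_tumor_cells Total tumor cells counted; must be > 0.
#' @return Percent positive in `[0, 100]`.
#' @export
#' @examples
#' ki67_score(19, 100)
ki67_score <- function(positive_cells, total_tumor_cells) {
  if (any(total_tumor_cells <= 0)) {
    stop("Ki-67 score undefined: total tumor cell count must be > 0",
         call. = FALSE)
  }
  if (any(positive_cells < 0) || any(positive_cells > total_tumor_cells)) {
    stop("positive cell count must lie in [0, total_tumor_cells]",
         call. = FALSE)
  }
  100 * positive_cells / total_tumor_cells
}

#' gammaH2AX phosphorylation index
#'
#' Percentage of cells with nuclear phospho-H2AX staining among the
#' cells scored (100 cells per sample by protocol default).
#'
#' @param positive_cells gammaH2AX-positive cell count.
#' @param cells_scored Cells examined (default 100).
#' @return Percent positive.
#' @export
h2ax_index <- function(positive_cells, cells_scored = 100) {
  ki67_score(positive_cells, cells_scored)
}

#' Two-score (H-score) IHC composite
#'
#' Combines percent positive cells with staining intensity graded 0
#' (absent) to 3 (strong) as their product, giving a 0-300 H-score.
#'
#' @param percent_positive Percent of positive cells in `[0, 100]`.
#' @param intensity Integer staining grade in `{0, 1, 2, 3}`.
#' @return H-score in `[0, 300]`.
#' @export
#' @examples
#' composite_score(40, 2)
composite_score <- function(percent_positive, intensity) {
  if (any(percent_positive < 0) || any(percent_positive > 100)) {
    stop("percent_positive must lie in [0, 100]", call. = FALSE)
  }
  ok <- !is.na(intensity) & intensity %in% 0:3
  if (!all(ok)) {
    stop("intensity grade must be one of 0, 1, 2, 3", call. = FALSE)
  }
  percent_positive * intensity
}

#' Build a marker trajectory from long-format IHC observations
#'
#' Extracts one (case, marker, arm) time series and attaches the score
#' used downstream: percent positivity for percent-only markers (Ki-67,
#' gammaH2AX), the H-score product for two-score markers. For two-score
#' markers the raw (percent, intensity) pair is retained alongside the
#' product.
#'
#' @param ihc Long-format data.frame with columns `case_id`, `marker`,
#'   `arm`, `time_h`, `percent_positive` and (for two-score markers)
#'   `intensity`.
#' @param case_id,marker,arm Selection of one series.
#' @return A data.frame of class `marker_trajectory`, sorted by time,
#'   with columns `case_id`, `marker`, `arm`, `time_h`, `score`.
#' @export
marker_trajectory <- function(ihc, case_id, marker, arm) {
  required <- c("case_id", "marker", "arm", "time_h", "percent_positive")
  missing <- setdiff(required, names(ihc))
  if (length(missing) > 0L) {
    stop("IHC table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sel <- ihc[ihc$case_id == case_id & ihc$marker == marker &
               ihc$arm == arm, , drop = FALSE]
  if (nrow(sel) == 0L) {
    stop("no observations for case ", case_id, ", marker ", marker,
         ", arm ", arm, call. = FALSE)
  }
  if (anyDuplicated(sel$time_h)) {
    stop("duplicate timepoints for case ", case_id, ", marker ", marker,
         ", arm ", arm, call. = FALSE)
  }
  sel <- sel[order(sel$time_h), , drop = FALSE]
  if (marker %in% PERCENT_ONLY_MARKERS) {
    score <- sel$percent_positive
  } else {
    if (!"intensity" %in% names(sel) || anyNA(sel$intensity)) {
      stop("marker ", marker, " requires an intensity grade", call. = FALSE)
    }
    score <- composite_score(sel$percent_positive, sel$intensity)
  }
  out <- data.frame(case_id = sel$case_id, marker = sel$marker,
                    arm = sel$arm, time_h = sel$time_h, score = score,
                    stringsAsFactors = FALSE)
  class(out) <- c("marker_trajectory", "data.frame")
  out
}

floor_scores <- function(score, floor = ZERO_SCORE_FLOOR) {
  pmax(score, floor)
}

#' Normalize a marker trajectory to its baseline (T0)
#'
#' Each timepoint is expressed as percent of the T0 score, so the series
#' starts at exactly 100. Zero scores are lifted to the configurable
#' floor (default 0.5, half the minimal nonzero H-score unit) before the
#' ratio so the normalization is always defined.
#'
#' @param traj A `marker_trajectory` (or data.frame with `time_h` and
#'   `score`).
#' @param t0 Baseline time in hours (default 0); must be present.
#' @param zero_floor Floor applied to raw scores before the ratio.
#' @return The trajectory with an added `norm_score` column; `norm_score`
#'   at T0 is 100.
#' @export
normalize_to_baseline <- function(traj, t0 = 0,
                                  zero_floor = ZERO_SCORE_FLOOR) {
  stopifnot(all(c("time_h", "score") %in% names(traj)))
  if (!t0 %in% traj$time_h) {
    stop("baseline timepoint T0 = ", t0, " h is missing from trajectory",
         call. = FALSE)
  }
  traj <- traj[order(traj$time_h), , drop = FALSE]
  score <- floor_scores(traj$score, zero_floor)
  baseline <- score[traj$time_h == t0]
  traj$norm_score <- 100 * score / baseline
  traj
}

#' Growth index (Ki-67 / cleaved caspase-3 ratio, baseline-normalized)
#'
#' Pointwise ratio of the (zero-floored) Ki-67 score to the cleaved
#' caspase-3 score, renormalized to its own T0 value so GI(T0) = 1.
#' A falling GI reflects a shift from proliferation toward apoptosis.
#'
#' @param ki67 Ki-67 `marker_trajectory`.
#' @param casp3 Cleaved caspase-3 `marker_trajectory` with the same
#'   case, arm and timepoints.
#' @param t0 Baseline time (default 0).
#' @param zero_floor Floor applied to both scores before the ratio.
#' @return A data.frame with columns `case_id`, `arm`, `time_h`, `gi`.
#' @export
growth_index <- function(ki67, casp3, t0 = 0,
                         zero_floor = ZERO_SCORE_FLOOR) {
  stopifnot(all(c("time_h", "score") %in% names(ki67)),
            all(c("time_h", "score") %in% names(casp3)))
  ki67 <- ki67[order(ki67$time_h), , drop = FALSE]
  casp3 <- casp3[order(casp3$time_h), , drop = FALSE]
  if (!identical(as.numeric(ki67$time_h), as.numeric(casp3$time_h))) {
    miss <- union(setdiff(ki67$time_h, casp3$time_h),
                  setdiff(casp3$time_h, ki67$time_h))
    stop("Ki-67 and caspase-3 trajectories disagree on timepoint(s): ",
         paste(sort(miss), collapse = ", "), call. = FALSE)
  }
  if (!t0 %in% ki67$time_h) {
    stop("baseline timepoint T0 = ", t0, " h is missing", call. = FALSE)
  }
  ratio <- floor_scores(ki67$score, zero_floor) /
    floor_scores(casp3$score, zero_floor)
  gi <- ratio / ratio[ki67$time_h == t0]
  data.frame(
    case_id = if ("case_id" %in% names(ki67)) ki67$case_id else NA,
    arm = if ("arm" %in% names(ki67)) ki67$arm else NA,
    time_h = ki67$time_h, gi = gi, stringsAsFactors = FALSE)
}

#' Score every trajectory of an IHC table
#'
#' Convenience wrapper applying [marker_trajectory()] and
#' [normalize_to_baseline()] to every (case, marker, arm) series in a
#' long-format IHC table.
#'
#' @param ihc Long-format IHC observation table.
#' @inheritParams normalize_to_baseline
#' @return A long data.frame of trajectories with `score` and
#'   `norm_score` columns.
#' @export
score_ihc_table <- function(ihc, t0 = 0, zero_floor = ZERO_SCORE_FLOOR) {
  keys <- unique(ihc[, c("case_id", "marker", "arm")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    tr <- marker_trajectory(ihc, keys$case_id[i], keys$marker[i],
                            keys$arm[i])
    normalize_to_baseline(tr, t0 = t0, zero_floor = zero_floor)
  })
  do.call(rbind, out)
}
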