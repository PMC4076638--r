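#' @title Bliss-independence analysis of two-drug dose matrices
#' @description Converts raw viability-assay fluorescence from a 7x7
#'   two-drug concentration grid into fractional growth inhibition
#'   (normalized to on-plate positive/negative controls), computes the
#'   Bliss independence expectation E = A + B - A*B from the single-agent
#'   responses, and scores each combination by its excess over Bliss:
#'   positive excess = synergy, zero = additive, negative = antagonism.
#' @name bliss_synergy
NULL

#' Construct a dose-matrix plate object
#'
#' @param drug_a,drug_b Drug names.
#' @param doses_a,doses_b Strictly increasing positive concentrations
#'   (umol/L), conventionally 7 each.
#' @param wells Data.frame with columns `dose_a`, `dose_b`, `replicate`,
#'   `fluorescence`; dose 0 of one partner marks the single-agent wells
#'   of the other.
#' @param pos_controls,neg_controls Fluorescence of the maximal-kill and
#'   untreated control wells (conventionally 12 each); mean(neg) must
#'   exceed mean(pos).
#' @return A list of class `dose_matrix_plate`.
#' @export
dose_matrix_plate <- function(drug_a, drug_b, doses_a, doses_b, wells,
                              pos_controls, neg_controls) {
  if (any(doses_a <= 0) || any(doses_b <= 0) ||
      is.unsorted(doses_a, strictly = TRUE) ||
      is.unsorted(doses_b, strictly = TRUE)) {
    stop("doses must be positive and strictly increasing", call. = FALSE)
  }
  if (length(pos_controls) == 0L || length(neg_controls) == 0L) {
    stop("control wells must be non-empty", call. = FALSE)
  }
  if (mean(neg_controls) <= mean(pos_controls)) {
    stop("plate-quality error: mean negative-control fluorescence must ",
         "exceed mean positive-control fluorescence", call. = FALSE)
  }
  required <- c("dose_a", "dose_b", "replicate", "fluorescence")
  missing <- setdiff(required, names(wells))
  if (length(missing) > 0L) {
    stop("well table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(drug_a = drug_a, drug_b = drug_b, doses_a = doses_a,
                 doses_b = doses_b, wells = wells,
                 pos_controls = pos_controls,
                 neg_controls = neg_controls),
            class = "dose_matrix_plate")
}

#' Fractional growth inhibition of a well
#'
#' Linear rescaling of fluorescence between the aggregated control
#' means: 0 at the negative (untreated) control mean, 1 at the positive
#' (maximal-kill) control mean. Values outside `[0, 1]` can occur under
#' assay noise and are returned as-is; clamping for the Bliss formula is
#' applied downstream.
#'
#' @param f_well Well fluorescence (vectorized).
#' @param pos,neg Positive / negative control fluorescence values.
#' @return Fractional inhibition (raw, unclamped).
#' @export
fractional_growth_inhibition <- function(f_well, pos, neg) {
  mp <- mean(pos); mn <- mean(neg)
  if (mn <= mp) {
    stop("plate-quality error: mean(neg) must exceed mean(pos)",
         call. = FALSE)
  }
  (mn - f_well) / (mn - mp)
}

#' Bliss independence expectation
#'
#' Expected fractional inhibition of two non-interacting drugs:
#' `E = A + B - A*B`, equivalently `1 - (1-A)(1-B)`.
#'
#' @param A,B Single-agent fractional inhibitions in `[0, 1]`.
#' @return Expected combination inhibition in `[0, 1]`.
#' @export
#' @examples
#' bliss_expectation(0.5, 0.5)  # 0.75
bliss_expectation <- function(A, B) {
  if (any(A < 0 | A > 1) || any(B < 0 | B > 1)) {
    stop("fractional inhibitions must lie in [0, 1] (clamp upstream)",
         call. = FALSE)
  }
  A + B - A * B
}

#' Excess over Bliss
#'
#' Observed combination inhibition minus the Bliss expectation. Positive
#' excess indicates more-than-additive activity (synergy), zero is
#' additive, negative is antagonism.
#'
#' @param observed Observed combination inhibition in `[0, 1]`.
#' @param E Bliss expectation in `[0, 1]`.
#' @return Excess in `[-1, 1]`.
#' @export
excess_over_bliss <- function(observed, E) {
  if (any(observed < 0 | observed > 1) || any(E < 0 | E > 1)) {
    stop("inputs must lie in [0, 1]", call. = FALSE)
  }
  observed - E
}

#' Excess-over-Bliss grid of a dose-matrix plate
#'
#' Replicate wells are normalized to the plate controls individually and
#' averaged on the inhibition scale. Single-agent responses A_i, B_j are
#' read from the dose-0 rows/columns; combination inhibitions O_ij from
#' the full grid. Inhibitions are clamped into `[0, 1]` for the Bliss
#' formula (raw values retained in `O_raw`; clamp count logged in
#' `n_clamped`).
#'
#' @param plate A `dose_matrix_plate`.
#' @return A list of class `bliss_grid` with elements `A`, `B`
#'   (single-agent vectors), `O`, `E`, `X` (7x7 matrices, clamped scale),
#'   `O_raw`, `X_raw`, `n_clamped`, and the dose vectors / drug names.
#' @export
synergy_matrix <- function(plate) {
  stopifnot(inherits(plate, "dose_matrix_plate"))
  w <- plate$wells
  fi <- fractional_growth_inhibition(w$fluorescence, plate$pos_controls,
                                     plate$neg_controls)
  agg <- stats::aggregate(fi, list(dose_a = w$dose_a, dose_b = w$dose_b),
                          mean)
  lookup <- function(da, db) {
    hit <- agg$x[agg$dose_a == da & agg$dose_b == db]
    if (length(hit) != 1L) return(NA_real_)
    hit
  }
  A_raw <- vapply(plate$doses_a, lookup, numeric(1), db = 0)
  B_raw <- vapply(plate$doses_b, function(db) lookup(0, db), numeric(1))
  if (anyNA(A_raw)) {
    stop("missing single-agent well for ", plate$drug_a, " dose(s) ",
         paste(plate$doses_a[is.na(A_raw)], collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(B_raw)) {
    stop("missing single-agent well for ", plate$drug_b, " dose(s) ",
         paste(plate$doses_b[is.na(B_raw)], collapse = ", "),
         call. = FALSE)
  }
  O_raw <- outer(plate$doses_a, plate$doses_b, Vectorize(lookup))
  if (anyNA(O_raw)) {
    stop("missing combination well(s) in the dose grid", call. = FALSE)
  }
  clamp <- function(x) {  # dim-preserving (pmin(1, x) drops dims)
    x[x < 0] <- 0
    x[x > 1] <- 1
    x
  }
  n_clamped <- sum(c(A_raw, B_raw, O_raw) < 0 |
                     c(A_raw, B_raw, O_raw) > 1)
  A <- clamp(A_raw); B <- clamp(B_raw); O <- clamp(O_raw)
  E <- outer(A, B, bliss_expectation)
  dn <- list(paste0(plate$drug_a, "_", signif(plate$doses_a, 4)),
             paste0(plate$drug_b, "_", signif(plate$doses_b, 4)))
  X <- O - E
  E_raw <- outer(A_raw, B_raw, function(a, b) a + b - a * b)
  dimnames(O) <- dimnames(E) <- dimnames(X) <- dn
  structure(list(drug_a = plate$drug_a, drug_b = plate$drug_b,
                 doses_a = plate$doses_a, doses_b = plate$doses_b,
                 A = A, B = B, O = O, E = E, X = X,
                 A_raw = A_raw, B_raw = B_raw, O_raw = O_raw,
                 X_raw = O_raw - E_raw, n_clamped = n_clamped),
            class = "bliss_grid")
}

#' Plate-level combination call
#'
#' Summarizes an excess-over-Bliss grid: mean and maximum excess, the
#' number of wells above the margin, and a call. The default margin
#' `delta = 0` applies the strict sign rule (any positive mean excess is
#' synergy); a positive `delta` gives a noise band within which the
#' plate is called additive.
#'
#' @param grid A `bliss_grid`.
#' @param delta Non-negative noise margin on the mean excess.
#' @return List with `mean_excess`, `max_excess`, `n_above_delta`,
#'   `call` (synergy / additive / antagonism) and `delta`.
#' @export
combination_summary <- function(grid, delta = 0) {
  stopifnot(inherits(grid, "bliss_grid"), delta >= 0)
  mx <- mean(grid$X)
  call <- if (mx > delta) "synergy" else if (mx < -delta) {
    "antagonism"
  } else "additive"
  list(mean_excess = mx, max_excess = max(grid$X),
       n_above_delta = sum(grid$X > delta), call = call, delta = delta)
}

#' @export
print.bliss_grid <- function(x, ...) {
  s <- combination_summary(x)
  cat(sprintf("Bliss grid: %s x %s (%dx%d)\n", x$drug_a, x$drug_b,
              length(x$doses_a), length(x$doses_b)))
  cat(sprintf("  mean excess %.4f, max excess %.4f, call: %s\n",
              s$mean_excess, s$max_excess, s$call))
  cat(sprintf("  wells clamped into [0,1]: %d\n", x$n_clamped))
  invisible(x)
}

#' Read / write a dose-matrix plate file
#'
#' Long comma-separated format with columns `drug_a_dose`, `drug_b_dose`,
#' `replicate`, `fluorescence`, `well_role` (assay / pos_ctrl /
#' neg_ctrl); control rows carry NA doses. Drug names and dose ladders
#' are recovered from the assay wells.
#'
#' @param path File path.
#' @param drug_a,drug_b Drug names to attach on read.
#' @return `read_plate`: a `dose_matrix_plate`; `write_plate`: `path`,
#'   invisibly.
#' @export
read_plate <- function(path, drug_a = "drug_A", drug_b = "drug_B") {
  x <- read_table_checked(path, c("drug_a_dose", "drug_b_dose",
                                  "replicate", "fluorescence",
                                  "well_role"))
  assay <- x[x$well_role == "assay", , drop = FALSE]
  dose_matrix_plate(
    drug_a = drug_a, drug_b = drug_b,
    doses_a = sort(unique(assay$drug_a_dose[assay$drug_a_dose > 0])),
    doses_b = sort(unique(assay$drug_b_dose[assay$drug_b_dose > 0])),
    wells = data.frame(dose_a = assay$drug_a_dose,
                       dose_b = assay$drug_b_dose,
                       replicate = assay$replicate,
                       fluorescence = assay$fluorescence),
    pos_controls = x$fluorescence[x$well_role == "pos_ctrl"],
    neg_controls = x$fluorescence[x$well_role == "neg_ctrl"])
}

#' @rdname read_plate
#' @param plate A `dose_matrix_plate` to serialize.
#' @export
write_plate <- function(plate, path) {
  stopifnot(inherits(plate, "dose_matrix_plate"))
  w <- plate$wells
  assay <- data.frame(drug_a_dose = w$dose_a, drug_b_dose = w$dose_b,
                      replicate = w$replicate,
                      fluorescence = w$fluorescence, well_role = "assay")
  ctrl <- function(f, role) {
    data.frame(drug_a_dose = NA_real_, drug_b_dose = NA_real_,
               replicate = seq_along(f), fluorescence = f,
               well_role = role)
  }
  write_table_checked(rbind(assay, ctrl(plate$pos_controls, "pos_ctrl"),
                            ctrl(plate$neg_controls, "neg_ctrl")), path)
}
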