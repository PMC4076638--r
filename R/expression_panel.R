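#' @title Gene-card normalization and differential ranking
#' @description Converts raw qPCR gene-card Ct values into relative
#'   quantities, weighs reference genes by their pairwise-ratio
#'   stability (M value), scales each sample by the geometric mean of
#'   its references (normalization factor), median-centers the log2
#'   quantities, and ranks targets by a per-gene two-sample t test with
#'   Benjamini-Hochberg FDR. Also provides plain 2^-dCt single-reference
#'   quantification for validation assays.
#' @name expression_panel
NULL

#' Per-gene relative quantities from replicate Ct values
#'
#' Replicate wells are averaged per (gene, sample) on the Ct scale;
#' relative quantity is `efficiency^(Ctmin - Ct)` with `Ctmin` the
#' smallest mean Ct of that gene across samples, so the best-expressed
#' sample of every gene has RQ = 1. Undetermined wells (NA) are ignored
#' in the average; a (gene, sample) with no determined replicate
#' propagates as NA.
#'
#' @param ct_table Long data.frame with columns `sample_id`, `class`,
#'   `gene`, `role` (target/reference) and `ct` (one row per well).
#' @param efficiency Amplification efficiency per cycle (default 2,
#'   perfect doubling); must be > 1.
#' @return Long data.frame with one row per (gene, sample): `sample_id`,
#'   `class`, `gene`, `role`, `ct_mean`, `rq`.
#' @export
relative_quantity <- function(ct_table, efficiency = 2) {
  required <- c("sample_id", "class", "gene", "role", "ct")
  missing <- setdiff(required, names(ct_table))
  if (length(missing) > 0L) {
    stop("Ct table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (efficiency <= 1) stop("efficiency must be > 1", call. = FALSE)
  if (any(ct_table$ct <= 0, na.rm = TRUE)) {
    stop("determined Ct values must be positive", call. = FALSE)
  }
  agg <- stats::aggregate(
    ct ~ sample_id + class + gene + role, data = ct_table,
    FUN = function(x) mean(x, na.rm = TRUE), na.action = stats::na.pass)
  agg$ct[!is.finite(agg$ct)] <- NA_real_
  names(agg)[names(agg) == "ct"] <- "ct_mean"
  ct_min <- tapply(agg$ct_mean, agg$gene,
                   function(x) suppressWarnings(min(x, na.rm = TRUE)))
  agg$rq <- efficiency^(as.numeric(ct_min[agg$gene]) - agg$ct_mean)
  agg[order(agg$gene, agg$sample_id), , drop = FALSE]
}

rq_matrix <- function(rq_long, role) {
  sel <- rq_long[rq_long$role == role, , drop = FALSE]
  genes <- sort(unique(sel$gene))
  samples <- sort(unique(rq_long$sample_id))
  m <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  m[cbind(match(sel$gene, genes), match(sel$sample_id, samples))] <- sel$rq
  m
}

#' Reference-gene stability (M value)
#'
#' For reference gene j, M_j is the mean over all other references k of
#' the standard deviation across samples of log2(RQ_j / RQ_k). A gene
#' whose ratio to every other reference is constant has M = 0; larger M
#' means less stable expression.
#'
#' @param ref_rq Numeric matrix of relative quantities, references in
#'   rows, samples in columns; >= 2 rows and >= 2 columns.
#' @return Named numeric vector of M values, one per reference.
#' @export
genorm_stability <- function(ref_rq) {
  ref_rq <- as.matrix(ref_rq)
  if (nrow(ref_rq) < 2L) {
    stop("stability needs >= 2 reference genes", call. = FALSE)
  }
  if (ncol(ref_rq) < 2L) {
    stop("stability needs >= 2 samples", call. = FALSE)
  }
  if (any(ref_rq <= 0, na.rm = TRUE)) {
    stop("reference RQ values must be positive", call. = FALSE)
  }
  lg <- log2(ref_rq)
  n <- nrow(lg)
  m <- vapply(seq_len(n), function(j) {
    sds <- vapply(setdiff(seq_len(n), j), function(k) {
      stats::sd(lg[j, ] - lg[k, ], na.rm = TRUE)
    }, numeric(1))
    mean(sds)
  }, numeric(1))
  stats::setNames(m, rownames(ref_rq))
}

#' Iterative reference-gene exclusion by stability
#'
#' Repeatedly drops the least stable reference (highest M) until
#' `n_keep` remain. Provided for generality; the default card pipeline
#' uses the full fixed reference set without exclusion.
#'
#' @param ref_rq Reference RQ matrix (references x samples).
#' @param n_keep Number of references to retain (>= 2).
#' @return Character vector of retained reference names, most stable
#'   set first in ranking order of the final M values.
#' @export
genorm_select <- function(ref_rq, n_keep = 2) {
  ref_rq <- as.matrix(ref_rq)
  if (n_keep < 2L || n_keep > nrow(ref_rq)) {
    stop("n_keep must be between 2 and the number of references",
         call. = FALSE)
  }
  while (nrow(ref_rq) > n_keep) {
    m <- genorm_stability(ref_rq)
    ref_rq <- ref_rq[-which.max(m), , drop = FALSE]
  }
  names(sort(genorm_stability(ref_rq)))
}

#' Per-sample normalization factor
#'
#' Geometric mean of the reference-gene relative quantities of each
#' sample.
#'
#' @param ref_rq Reference RQ matrix (references x samples), all values
#'   positive and determined.
#' @return Named numeric vector of normalization factors (one per
#'   sample), all > 0.
#' @export
normalization_factor <- function(ref_rq) {
  ref_rq <- as.matrix(ref_rq)
  if (anyNA(ref_rq)) {
    bad <- which(is.na(ref_rq), arr.ind = TRUE)[1, ]
    stop("missing reference RQ for sample '", colnames(ref_rq)[bad[2]],
         "', gene '", rownames(ref_rq)[bad[1]], "'", call. = FALSE)
  }
  if (any(ref_rq <= 0)) {
    stop("reference RQ values must be positive", call. = FALSE)
  }
  exp(colMeans(log(ref_rq)))
}

#' Normalize a target RQ matrix to log2 median-centered values
#'
#' Each sample's target RQs are divided by its normalization factor,
#' log2-transformed, and each gene is centered on its median across
#' samples, so every gene's median is exactly 0. Genes missing in more
#' than `max_missing` of samples are dropped (count recorded in the
#' `dropped_genes` attribute); remaining NAs are ignored in the median.
#'
#' @param rq Target RQ matrix (genes x samples), positive or NA.
#' @param nf Normalization factors named by sample (see
#'   [normalization_factor()]).
#' @param max_missing Maximum tolerated fraction of missing samples per
#'   gene (default 0.5).
#' @return Matrix of log2 median-centered normalized quantities with
#'   attribute `dropped_genes`.
#' @export
normalize_card <- function(rq, nf, max_missing = 0.5) {
  rq <- as.matrix(rq)
  if (!all(colnames(rq) %in% names(nf))) {
    stop("normalization factor missing for sample(s): ",
         paste(setdiff(colnames(rq), names(nf)), collapse = ", "),
         call. = FALSE)
  }
  if (any(rq <= 0, na.rm = TRUE)) {
    stop("RQ values must be positive (missing values must be NA, not 0)",
         call. = FALSE)
  }
  frac_na <- rowMeans(is.na(rq))
  dropped <- rownames(rq)[frac_na > max_missing]
  rq <- rq[frac_na <= max_missing, , drop = FALSE]
  v <- log2(sweep(rq, 2, nf[colnames(rq)], "/"))
  med <- apply(v, 1, stats::median, na.rm = TRUE)
  out <- sweep(v, 1, med, "-")
  attr(out, "dropped_genes") <- dropped
  out
}

#' Full gene-card normalization pipeline
#'
#' Chains [relative_quantity()], [genorm_stability()],
#' [normalization_factor()] and [normalize_card()].
#'
#' @inheritParams relative_quantity
#' @inheritParams normalize_card
#' @return List with `values` (log2 normalized matrix), `nf`,
#'   `stability` (per-reference M), `classes` (named by sample) and
#'   `dropped_genes`.
#' @export
expression_card_pipeline <- function(ct_table, efficiency = 2,
                                     max_missing = 0.5) {
  rq_long <- relative_quantity(ct_table, efficiency = efficiency)
  refs <- rq_matrix(rq_long, "reference")
  targets <- rq_matrix(rq_long, "target")
  nf <- normalization_factor(refs)
  values <- normalize_card(targets, nf, max_missing = max_missing)
  cls <- unique(rq_long[, c("sample_id", "class")])
  list(values = values, nf = nf, stability = genorm_stability(refs),
       classes = stats::setNames(cls$class, cls$sample_id),
       dropped_genes = attr(values, "dropped_genes"))
}

#' Rank differentially expressed genes between response classes
#'
#' Per-gene two-sided unpaired (pooled-variance) t test on the log2
#' normalized values, Benjamini-Hochberg FDR, genes sorted by ascending
#' p. The reported effect is the mean log2 difference NonResponder minus
#' Responder. A gene with zero variance and zero difference gets p = 1
#' by convention.
#'
#' @param values Log2 normalized matrix, genes x samples (see
#'   [normalize_card()]).
#' @param classes Character vector of class labels (Responder /
#'   NonResponder), named by or aligned with the columns of `values`;
#'   both classes need >= 2 samples.
#' @return Data.frame with `gene`, `mean_log2_diff`, `t`, `p`, `fdr`,
#'   `rank`, sorted ascending by p.
#' @export
differential_panel <- function(values, classes) {
  values <- as.matrix(values)
  if (!is.null(names(classes)) && !is.null(colnames(values))) {
    classes <- classes[colnames(values)]
  }
  classes <- as.character(classes)
  if (length(classes) != ncol(values)) {
    stop("one class label per sample column is required", call. = FALSE)
  }
  nr <- classes == "NonResponder"
  r <- classes == "Responder"
  if (sum(nr) < 2L || sum(r) < 2L) {
    stop("differential ranking needs >= 2 samples per class",
         call. = FALSE)
  }
  res <- t(apply(values, 1, function(x) {
    a <- x[nr][!is.na(x[nr])]
    b <- x[r][!is.na(x[r])]
    d <- mean(a) - mean(b)
    if (length(a) < 2L || length(b) < 2L) return(c(d, NA, NA))
    if (stats::var(a) + stats::var(b) == 0) {
      if (d == 0) return(c(0, 0, 1))
      return(c(d, Inf * sign(d), 0))
    }
    ht <- stats::t.test(a, b, var.equal = TRUE)
    c(d, unname(ht$statistic), ht$p.value)
  }))
  out <- data.frame(gene = rownames(values), mean_log2_diff = res[, 1],
                    t = res[, 2], p = res[, 3],
                    stringsAsFactors = FALSE)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Single-reference 2^-dCt relative expression
#'
#' Relative expression of a target versus a reference gene measured in
#' the same sample: `efficiency^-(Ct_target - Ct_reference)`.
#' Undetermined inputs propagate as NA.
#'
#' @param ct_target,ct_reference Ct values (positive reals or NA).
#' @param efficiency Amplification efficiency (default 2).
#' @return Relative expression (1 = equal abundance with reference).
#' @export
#' @examples
#' delta_ct_quant(24, 22)  # 4x less abundant than the reference
delta_ct_quant <- function(ct_target, ct_reference, efficiency = 2) {
  if (efficiency <= 1) stop("efficiency must be > 1", call. = FALSE)
  efficiency^(-(ct_target - ct_reference))
}
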