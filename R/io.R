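#' Read a delimited table with schema checking
#'
#' All pipeline artifacts are comma-separated text with a header row.
#' The header is matched against `required_cols` order-insensitively;
#' extra columns are kept.
#'
#' @param path Path to a comma-separated file with a header row.
#' @param required_cols Character vector of column names that must be
#'   present.
#' @return A `data.frame` with at least the required columns.
#' @export
read_table_checked <- function(path, required_cols = character()) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (length(required_cols) > 1L && ncol(x) <= 1L) {
    stop("file '", path, "' parsed to a single column; wrong delimiter?",
         call. = FALSE)
  }
  missing <- setdiff(required_cols, names(x))
  if (length(missing) > 0L) {
    stop("file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x
}

#' Write a delimited table
#'
#' Full-precision CSV writer; `write_table_checked(read_table_checked(p))`
#' round-trips numeric values exactly (values are written with
#' `format(..., digits = 17)` semantics of [utils::write.csv()]).
#'
#' @param x A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_checked <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load the packaged breast-tumor cohort table
#'
#' A 33-case clinicopathology fixture (histotype, T/N stage, grade,
#' hormone receptor percentages, HER2, diagnostic Ki-67, p53 status and
#' doxorubicin response class) transcribing the published study cohort.
#' `er_percent`/`pr_percent` of 0 encode negative staining.
#'
#' @return A data.frame with one row per case.
#' @export
#' @examples
#' tab <- load_cohort_table()
#' table(tab$doxo_class)
load_cohort_table <- function() {
  path <- system.file("extdata", "breast_cohort_table1.csv",
                      package = "orgslice", mustWork = TRUE)
  x <- read_table_checked(path, cohort_table_columns())
  x$doxo_class <- factor(x$doxo_class, levels = response_levels())
  x
}

cohort_table_columns <- function() {
  c("case_id", "histotype", "t_stage", "n_stage", "grade",
    "er_percent", "pr_percent", "her2", "ki67_diagnosis",
    "p53_status", "doxo_class")
}

response_levels <- function() c("Responder", "NonResponder", "Unknown")

#' Load the 92-gene apoptosis panel roster
#'
#' Gene names used for the synthetic gene-card generator. Only the genes
#' the study names explicitly (BIRC5, BIRC3, TNF) are real panel members;
#' the remainder of the published 92-gene roster is not public, so the
#' other symbols are plausible apoptosis-pathway placeholders and are
#' flagged `synthetic_placeholder` in the `provenance` column.
#'
#' @return A data.frame with columns `gene` and `provenance`.
#' @export
load_apoptosis_panel <- function() {
  path <- system.file("extdata", "apoptosis_panel_genes.csv",
                      package = "orgslice", mustWork = TRUE)
  read_table_checked(path, c("gene", "provenance"))
}
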