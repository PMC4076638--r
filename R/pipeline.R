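#' @title End-to-end pipeline runner and command-line entry point
#' @description One reproducible chain: simulation -> IHC scoring ->
#'   response classification -> association screen -> gene-card
#'   expression analysis -> Bliss synergy analysis -> report. A single
#'   top-level seed drives every stage (per-module seeds are derived as
#'   `seed * 10 + stage index`), every run writes a manifest echoing the
#'   fully resolved configuration, and all artifacts are comma-separated
#'   text.
#' @name cli_reporting
NULL

default_config <- function() {
  list(
    seed = 1L,
    output_dir = "orgslice_run",
    stages = list(simulate = TRUE, score = TRUE, classify = TRUE,
                  associations = TRUE, expression = TRUE,
                  synergy = TRUE, report = TRUE),
    inputs = list(cohort_table = NULL, ihc_table = NULL,
                  ct_table = NULL, plate_table = NULL),
    cohort = list(),      # overrides for cohort_params()
    expression = list(),  # overrides for expression_params()
    plate = list(),       # overrides for plate_params()
    classify = list(final_time = NULL, mode = "vehicle"),
    synergy = list(delta = 0),
    rule_version = RULE_VERSION
  )
}

#' Build and validate a pipeline run configuration
#'
#' Merges user settings over the defaults and rejects unknown keys
#' (every offending key is reported at once). Parameter blocks `cohort`,
#' `expression` and `plate` take the arguments of [cohort_params()],
#' [expression_params()] and [plate_params()].
#'
#' @param ... Named top-level settings (`seed`, `output_dir`, `stages`,
#'   `inputs`, `cohort`, `expression`, `plate`, `classify`, `synergy`).
#' @return A validated configuration list of class `run_config`.
#' @export
#' @examples
#' cfg <- run_config(seed = 7, stages = list(synergy = FALSE))
run_config <- function(...) {
  user <- list(...)
  if (length(user) == 1L && is.null(names(user)) && is.list(user[[1]])) {
    user <- user[[1]]
  }
  defaults <- default_config()
  bad <- character()
  check <- function(u, d, prefix) {
    if (is.null(names(u)) && length(u) > 0L) {
      bad <<- c(bad, paste0(prefix, "<unnamed>"))
      return()
    }
    for (k in names(u)) {
      if (!k %in% names(d)) {
        bad <<- c(bad, paste0(prefix, k))
      } else if (is.list(d[[k]]) && !k %in%
                   c("cohort", "expression", "plate", "inputs")) {
        if (is.list(u[[k]])) check(u[[k]], d[[k]], paste0(prefix, k, "$"))
      }
    }
  }
  check(user, defaults, "")
  param_fields <- list(cohort = names(formals(cohort_params)),
                       expression = names(formals(expression_params)),
                       plate = names(formals(plate_params)),
                       inputs = names(defaults$inputs))
  for (blk in names(param_fields)) {
    extra <- setdiff(names(user[[blk]]), param_fields[[blk]])
    if (length(extra) > 0L) bad <- c(bad, paste0(blk, "$", extra))
  }
  if (length(bad) > 0L) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, user)
  if (cfg$seed != round(cfg$seed)) stop("seed must be an integer",
                                        call. = FALSE)
  class(cfg) <- c("run_config", "list")
  cfg
}

module_seed <- function(seed, k) as.integer((seed * 10 + k) %% 2^31)

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order, writes every artifact as a
#' comma-separated table under `config$output_dir`, and finishes with a
#' plain-text summary, a machine-readable JSON summary, and a manifest
#' echoing the resolved configuration. Identical configuration and seed
#' give byte-identical artifact tables. Filter counts (cases read,
#' clamped wells, dropped genes) are recorded in the summary.
#'
#' @param config A [run_config()] object.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list bundle with the in-memory results
#'   (`cohort`, `trajectories`, `growth_index`, `calls`, `associations`,
#'   `expression`, `differential`, `bliss`, `summary`).
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  cfg <- config
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  out <- list()
  summary_kv <- list(seed = cfg$seed, rule_version = cfg$rule_version)
  emit <- function(x, name) {
    write_table_checked(x, file.path(cfg$output_dir,
                                     paste0(name, ".csv")))
  }

  # ---- inputs / simulation ------------------------------------------
  cases <- NULL; ihc <- NULL; ct <- NULL; plate <- NULL
  if (isTRUE(cfg$stages$simulate)) {
    say("simulate: generating cohort, gene card and dose matrix")
    cp <- do.call(cohort_params,
                  c(cfg$cohort,
                    list(seed = module_seed(cfg$seed, 1))[
                      !"seed" %in% names(cfg$cohort)]))
    cohort <- generate_cohort(cp)
    cases <- cohort$cases; ihc <- cohort$ihc
    ep <- do.call(expression_params,
                  c(cfg$expression,
                    list(seed = module_seed(cfg$seed, 2))[
                      !"seed" %in% names(cfg$expression)]))
    ct <- generate_ct_table(cohort, ep)
    pp <- do.call(plate_params,
                  c(cfg$plate,
                    list(seed = module_seed(cfg$seed, 3))[
                      !"seed" %in% names(cfg$plate)]))
    plate <- generate_dose_matrix(pp)
    emit(cases, "cohort_cases"); emit(ihc, "ihc_observations")
    emit(ct, "ct_table")
    write_plate(plate, file.path(cfg$output_dir, "plate.csv"))
    out$cohort <- cohort
  }
  if (!is.null(cfg$inputs$cohort_table)) {
    cases <- read_table_checked(cfg$inputs$cohort_table,
                                cohort_table_columns())
  }
  if (!is.null(cfg$inputs$ihc_table)) {
    ihc <- read_table_checked(cfg$inputs$ihc_table,
                              c("case_id", "marker", "arm", "time_h",
                                "percent_positive"))
  }
  if (!is.null(cfg$inputs$ct_table)) {
    ct <- read_table_checked(cfg$inputs$ct_table,
                             c("sample_id", "class", "gene", "role",
                               "ct"))
  }
  if (!is.null(cfg$inputs$plate_table)) {
    plate <- read_plate(cfg$inputs$plate_table)
  }
  if (is.null(cases) && (isTRUE(cfg$stages$associations))) {
    say("associations: no cohort table given, using packaged fixture")
    cases <- load_cohort_table()
  }
  if (!is.null(cases)) summary_kv$n_cases_read <- nrow(cases)

  # ---- scoring -------------------------------------------------------
  if (isTRUE(cfg$stages$score) && !is.null(ihc)) {
    say("score: building baseline-normalized trajectories")
    traj <- score_ihc_table(ihc)
    emit(traj, "trajectories")
    out$trajectories <- traj
    gi_keys <- unique(ihc[ihc$marker == "Ki67", c("case_id", "arm")])
    has_c3 <- unique(ihc$case_id[ihc$marker == "CASP3"])
    gi_keys <- gi_keys[gi_keys$case_id %in% has_c3, , drop = FALSE]
    gi <- do.call(rbind, lapply(seq_len(nrow(gi_keys)), function(i) {
      growth_index(
        marker_trajectory(ihc, gi_keys$case_id[i], "Ki67",
                          gi_keys$arm[i]),
        marker_trajectory(ihc, gi_keys$case_id[i], "CASP3",
                          gi_keys$arm[i]))
    }))
    emit(gi, "growth_index")
    out$growth_index <- gi
  }

  # ---- classification -----------------------------------------------
  if (isTRUE(cfg$stages$classify) && !is.null(ihc)) {
    say("classify: applying the relative Ki-67 response rule")
    calls <- call_cohort_responses(ihc,
                                   final_time = cfg$classify$final_time,
                                   mode = cfg$classify$mode)
    emit(calls, "response_calls")
    out$calls <- calls
    summary_kv$n_responder <- sum(calls$call == "Responder")
    summary_kv$n_nonresponder <- sum(calls$call == "NonResponder")
    if (!is.null(cases) && all(cases$doxo_class == "Unknown")) {
      cases$doxo_class <-
        as.character(calls$call[match(cases$case_id, calls$case_id)])
    }
  }

  # ---- association screen -------------------------------------------
  if (isTRUE(cfg$stages$associations) && !is.null(cases) &&
      sum(cases$doxo_class == "Responder") >= 2 &&
      sum(cases$doxo_class == "NonResponder") >= 2) {
    say("associations: clinicopathological screen")
    assoc <- association_screen(cases)
    emit(assoc, "associations")
    out$associations <- assoc
    km <- ki67_class_means(cases)
    pf <- p53_mutation_frequencies(cases)
    summary_kv$ki67_mean_responder <- round(km[["Responder"]])
    summary_kv$ki67_mean_nonresponder <- round(km[["NonResponder"]])
    summary_kv$p53_mut_pct_responder <- floor(pf[["Responder"]])
    summary_kv$p53_mut_pct_nonresponder <- floor(pf[["NonResponder"]])
  }

  # ---- expression ----------------------------------------------------
  if (isTRUE(cfg$stages$expression) && !is.null(ct)) {
    say("expression: gene-card normalization and differential ranking")
    ex <- expression_card_pipeline(ct)
    diff <- differential_panel(ex$values, ex$classes)
    mat <- data.frame(gene = rownames(ex$values), ex$values,
                      check.names = FALSE)
    emit(mat, "normalized_matrix")
    emit(diff, "differential_results")
    out$expression <- ex
    out$differential <- diff
    summary_kv$n_genes_dropped <- length(ex$dropped_genes)
    summary_kv$top_gene <- diff$gene[1]
  }

  # ---- synergy -------------------------------------------------------
  if (isTRUE(cfg$stages$synergy) && !is.null(plate)) {
    say("synergy: Bliss excess analysis of the dose matrix")
    grid <- synergy_matrix(plate)
    cs <- combination_summary(grid, delta = cfg$synergy$delta)
    long <- expand.grid(dose_a = grid$doses_a, dose_b = grid$doses_b)
    long$observed <- as.vector(grid$O)
    long$expected <- as.vector(grid$E)
    long$excess <- as.vector(grid$X)
    emit(long, "bliss_grid")
    out$bliss <- grid
    summary_kv$n_wells_clamped <- grid$n_clamped
    summary_kv$bliss_mean_excess <- cs$mean_excess
    summary_kv$bliss_call <- cs$call
  }

  # ---- report --------------------------------------------------------
  if (isTRUE(cfg$stages$report)) {
    say("report: writing summary and manifest")
    txt <- c("orgslice pipeline report",
             strrep("-", 24),
             vapply(names(summary_kv), function(k) {
               sprintf("%-28s %s", k, format(summary_kv[[k]]))
             }, character(1)))
    writeLines(txt, file.path(cfg$output_dir, "summary.txt"))
    jsonlite::write_json(summary_kv,
                         file.path(cfg$output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- list(
      config = unclass(cfg),
      artifacts = sort(setdiff(list.files(cfg$output_dir),
                               "manifest.json")))
    jsonlite::write_json(manifest,
                         file.path(cfg$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out$summary <- summary_kv
  invisible(out)
}

#' Command-line entry point
#'
#' Usage: `Rscript -e 'orgslice::orgslice_cli()' <subcommand> [options]`
#' with subcommand one of `simulate`, `score`, `classify`,
#' `associations`, `expression`, `synergy`, `report` or `all` (each
#' subcommand enables its stage plus the stages it depends on). Options:
#' `--seed`, `--out` (output directory), `--config` (JSON file of
#' [run_config()] settings), `--cohort-table` (CSV path; omit to use the
#' packaged fixture where needed).
#'
#' @param args Character vector of command-line arguments.
#' @return The pipeline bundle, invisibly. Exits non-zero on error when
#'   run non-interactively.
#' @export
orgslice_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  subcommands <- list(
    simulate = "simulate",
    score = c("simulate", "score"),
    classify = c("simulate", "score", "classify"),
    associations = c("simulate", "score", "classify", "associations"),
    expression = c("simulate", "expression"),
    synergy = c("simulate", "synergy"),
    report = "report",
    all = names(default_config()$stages))
  if (length(args) == 0L || !args[1] %in% names(subcommands)) {
    stop("usage: orgslice_cli(<subcommand> [--seed N] [--out DIR] ",
         "[--config FILE] [--cohort-table FILE]); subcommands: ",
         paste(names(subcommands), collapse = ", "), call. = FALSE)
  }
  cmd <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character",
                          default = "orgslice_run"),
    optparse::make_option("--config", type = "character",
                          default = NULL),
    optparse::make_option("--cohort-table", type = "character",
                          default = NULL, dest = "cohort_table")))
  opts <- optparse::parse_args(parser, args = args[-1])
  settings <- if (!is.null(opts$config)) {
    jsonlite::read_json(opts$config, simplifyVector = TRUE)
  } else list()
  settings$seed <- opts$seed
  settings$output_dir <- opts$out
  on_stages <- c(subcommands[[cmd]], "report")
  all_stages <- names(default_config()$stages)
  settings$stages <- stats::setNames(
    as.list(all_stages %in% on_stages), all_stages)
  if (!is.null(opts$cohort_table)) {
    settings$inputs <- utils::modifyList(
      settings$inputs %||% list(), list(cohort_table = opts$cohort_table))
  }
  run_pipeline(run_config(settings))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
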