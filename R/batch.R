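# Batch driver: fit every marker of a dataset, write the scores, models and
# QC tables as diffable TSV (fixed column order, 6-decimal floats).

fmt6 <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))

#' Fit a list of markers
#'
#' Applies [fit_marker()] to every marker; per-marker failures become
#' `no_model` results and never abort the run.  With `config$threads > 1`
#' markers are fitted in parallel worker processes; the result order is
#' identical to the serial run.
#'
#' @param signals Named list of [marker_signals()].
#' @param structure A [population_structure()].
#' @param priors Optional parental-prior data.frame.
#' @param config A [run_config()].
#' @return Named list of `marker_result` objects.
#' @export
fit_markers <- function(signals, structure, priors = NULL,
                        config = run_config()) {
  one <- function(s) {
    tryCatch(fit_marker(s, structure, priors, config),
             error = function(e) {
               warning("marker ", s$marker_id, " failed: ",
                       conditionMessage(e), call. = FALSE)
               base::structure(
                 list(marker_id = s$marker_id, status = "no_model",
                      selected_model = NULL,
                      calls = stats::setNames(
                        rep(NA_integer_, length(s$sample_ids)),
                        s$sample_ids),
                      max_posterior = NULL, posteriors = NULL,
                      models_tried = NULL, used_parental_prior = FALSE,
                      reevaluated = FALSE),
                 class = "marker_result")
             })
  }
  res <- if (config$threads > 1L &&
             .Platform$OS.type == "unix" &&
             requireNamespace("parallel", quietly = TRUE)) {
    parallel::mclapply(signals, one, mc.cores = config$threads)
  } else {
    lapply(signals, one)
  }
  stats::setNames(res, vapply(res, `[[`, character(1), "marker_id"))
}

encode_pi <- function(model) {
  paste(vapply(names(model$pi), function(p) {
    paste0(p, "=", paste(fmt6(model$pi[[p]]), collapse = ","))
  }, character(1)), collapse = ";")
}

write_scores_table <- function(results, signals, structure, path) {
  pop <- pop_of(structure)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("marker", "sample", "population", "y", "p_0", "p_1",
                     "p_2", "p_3", "p_4", "max_posterior", "dosage"),
                   collapse = "\t"), con)
  for (r in results) {
    s <- signals[[r$marker_id]]
    obs <- which(!is.na(s$y))
    if (!length(obs)) next
    p <- if (!is.null(r$posteriors)) r$posteriors else
      matrix(NA_real_, length(s$sample_ids), 5)
    maxp <- if (!is.null(r$max_posterior)) r$max_posterior else
      rep(NA_real_, length(s$sample_ids))
    writeLines(paste(r$marker_id, s$sample_ids[obs],
                     unname(pop[s$sample_ids[obs]]), fmt6(s$y[obs]),
                     fmt6(p[obs, 1]), fmt6(p[obs, 2]), fmt6(p[obs, 3]),
                     fmt6(p[obs, 4]), fmt6(p[obs, 5]), fmt6(maxp[obs]),
                     ifelse(is.na(r$calls[obs]), "NA", r$calls[obs]),
                     sep = "\t"), con)
  }
  invisible(path)
}

write_models_table <- function(results, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("marker", "status", "model", "used_parental_prior",
                     "reevaluated", "mu_0", "mu_1", "mu_2", "mu_3", "mu_4",
                     "sigma2", "loglik", "bic", "n_iter", "pi"),
                   collapse = "\t"), con)
  for (r in results) {
    m <- r$selected_model
    if (is.null(m)) {
      writeLines(paste(c(r$marker_id, r$status, "NA", "FALSE", "FALSE",
                         rep("NA", 9), "NA"), collapse = "\t"), con)
    } else {
      label <- paste(m$mu_constraint,
                     paste(unique(unname(m$pi_constraint)), collapse = "+"),
                     sep = "/")
      writeLines(paste(c(r$marker_id, r$status, label,
                         r$used_parental_prior, r$reevaluated,
                         fmt6(m$mu), fmt6(m$sigma2), fmt6(m$loglik),
                         fmt6(m$bic), m$n_iter, encode_pi(m)),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

write_match_reports <- function(reports, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("marker", "verdict", "best_combo", "chi2", "parent1",
                     "parent2", "n_0", "n_1", "n_2", "n_3", "n_4",
                     "ambiguous"), collapse = "\t"), con)
  for (r in reports) {
    writeLines(paste(c(
      r$marker_id, r$verdict,
      if (is.null(r$best_combo)) "NA" else paste(r$best_combo, collapse = "x"),
      fmt6(r$chi2),
      ifelse(is.na(r$called_parents), "NA", r$called_parents),
      r$category_counts,
      if (is.na(r$ambiguous)) "NA" else r$ambiguous), collapse = "\t"), con)
  }
  invisible(path)
}

write_summary_table <- function(summary_df, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("metric\tvalue", con)
  writeLines(paste(summary_df$metric, fmt6(summary_df$value), sep = "\t"),
             con)
  invisible(path)
}

#' Run the full calling pipeline over a dataset on disk
#'
#' Reads the signal table, population structure and optional parental
#' priors, fits every marker, and writes four TSV files to `out_dir`:
#' `scores.tsv` (per sample: transformed ratio, five posteriors, call),
#' `models.tsv` (per marker: status, selected constraints, parameters,
#' BIC), `match_reports.tsv` (per marker parent-offspring matching, when an
#' F1 family is present) and `summary.tsv` (the Table-2 style breakdown).
#'
#' @param signals_path Signal table file (see [read_signal_table()]).
#' @param structure_path Population structure file.
#' @param priors_path Optional parental priors file.
#' @param out_dir Output directory (created if needed).
#' @param config A [run_config()].
#' @param dialect Signal-table dialect passed to [read_signal_table()].
#' @return Invisibly, a list with `results`, `reports`, `summary`.
#' @export
run_batch <- function(signals_path, structure_path, priors_path = NULL,
                      out_dir = ".", config = run_config(),
                      dialect = "auto") {
  signals <- read_signal_table(signals_path, dialect)
  struct <- read_population_structure(structure_path)
  priors <- if (!is.null(priors_path)) read_parental_priors(priors_path)
  known <- struct$assignments$sample
  for (s in signals) {
    unknown <- setdiff(s$sample_ids, known)
    if (length(unknown)) {
      stop("sample(s) not in the population structure: ",
           paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
    }
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  results <- fit_markers(signals, struct, priors, config)
  for (r in results) {
    message(sprintf("marker %s: %s%s", r$marker_id, r$status,
                    if (!is.null(r$selected_model))
                      sprintf(" (BIC %.1f, %d iter)", r$selected_model$bic,
                              r$selected_model$n_iter) else ""))
  }
  reports <- NULL
  if (length(pops_of_type(struct, "F1"))) {
    reports <- lapply(results, classify_marker, structure = struct)
  }
  summary_df <- summarize_run(results, reports)
  write_scores_table(results, signals, struct,
                     file.path(out_dir, "scores.tsv"))
  write_models_table(results, file.path(out_dir, "models.tsv"))
  if (!is.null(reports)) {
    write_match_reports(reports, file.path(out_dir, "match_reports.tsv"))
  }
  write_summary_table(summary_df, file.path(out_dir, "summary.tsv"))
  invisible(list(results = results, reports = reports, summary = summary_df))
}
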