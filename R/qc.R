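# Parent-offspring concordance QC: chi-squared matching of offspring
# dosage proportions against the expectations of all 15 unordered parental
# dosage combinations, and the run-level summary table.

unordered_combos <- function() {
  out <- list()
  for (d1 in 0:4) for (d2 in d1:4) out[[length(out) + 1L]] <- c(d1, d2)
  out
}

#' Best-matching parental combination for observed offspring counts
#'
#' Computes the Pearson chi-squared goodness-of-fit statistic of the
#' observed offspring dosage counts against the expected tetrasomic
#' segregation proportions of each of the 15 unordered parental dosage
#' pairs, and returns the minimizing pair.  A combination whose expectation
#' is zero in a class with observed counts is impossible and scores
#' infinity.  Some patterns are near-indistinguishable (e.g. 1:8:18:8:1 vs
#' 0:1:2:1:0); when the two best statistics differ by less than 10% the
#' result is flagged ambiguous and a warning is raised.
#'
#' @param offspring_counts Integer 5-vector of called offspring dosages
#'   (classes 0..4).
#' @param warn Emit the ambiguity warning (default `TRUE`).
#' @return List with `combo` (sorted dosage pair), `chi2`, `ambiguous`,
#'   and `chi2_all` (named vector over all 15 combos).
#' @export
best_matching_combo <- function(offspring_counts, warn = TRUE) {
  counts <- as.numeric(offspring_counts)
  stopifnot(length(counts) == 5, all(counts >= 0))
  n <- sum(counts)
  if (n <= 0) stop("all offspring counts are zero", call. = FALSE)
  combos <- unordered_combos()
  chi2 <- vapply(combos, function(cb) {
    exp_p <- f1_segregation(cb[1], cb[2])$proportions
    if (any(exp_p == 0 & counts > 0)) return(Inf)
    pos <- exp_p > 0
    sum((counts[pos] - n * exp_p[pos])^2 / (n * exp_p[pos]))
  }, numeric(1))
  names(chi2) <- vapply(combos, paste, character(1), collapse = "x")
  o <- order(chi2)
  best <- chi2[o[1]]
  second <- chi2[o[2]]
  ambiguous <- if (best == 0) second == 0 else
    is.finite(second) && (second - best) / best < 0.1
  if (ambiguous && warn) {
    warning(sprintf("segregation patterns %s and %s are nearly equally good",
                    names(chi2)[o[1]], names(chi2)[o[2]]), call. = FALSE)
  }
  list(combo = combos[[o[1]]], chi2 = unname(best), ambiguous = ambiguous,
       chi2_all = chi2)
}

# modal called dosage among a set of calls; NA when none called;
# ties toward the lower dosage
modal_call <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (!length(calls)) return(NA_integer_)
  tab <- tabulate(calls + 1L, 5L)
  which.max(tab) - 1L
}

#' Match a called marker's offspring segregation against its parents
#'
#' For the marker's F1 family, compares the best-matching parental dosage
#' combination of the called offspring counts ([best_matching_combo()])
#' with the modal called dosages of the two parent populations.  The
#' verdict is `matching` when they agree as unordered pairs,
#' `not_assessable` when one or both parents have no called replicate (this
#' counts as not matching in run totals), and `not_matching` otherwise.
#'
#' @param result A [fit_marker()] result.
#' @param structure A [population_structure()] with an F1 population.
#' @return Object of class `match_report`: list with `marker_id`,
#'   `verdict`, `best_combo`, `chi2`, `called_parents`, `category_counts`,
#'   `ambiguous`.
#' @export
classify_marker <- function(result, structure) {
  f1s <- pops_of_type(structure, "F1")
  if (!length(f1s)) stop("structure has no F1 population", call. = FALSE)
  f1 <- f1s[1]
  parents <- f1_parents(structure, f1)
  pop <- pop_of(structure)
  rep_na <- base::structure(
    list(marker_id = result$marker_id, verdict = "not_assessable",
         best_combo = NULL, chi2 = NA_real_,
         called_parents = c(NA_integer_, NA_integer_),
         category_counts = rep(0L, 5L), ambiguous = NA),
    class = "match_report")
  if (is.null(result$calls)) return(rep_na)
  off <- result$calls[names(result$calls) %in%
                        names(pop)[pop == f1]]
  counts <- tabulate(off[!is.na(off)] + 1L, 5L)
  called_parents <- vapply(parents, function(pp) {
    modal_call(result$calls[names(result$calls) %in% names(pop)[pop == pp]])
  }, integer(1))
  if (sum(counts) == 0 || anyNA(called_parents)) {
    rep_na$called_parents <- unname(called_parents)
    rep_na$category_counts <- counts
    return(rep_na)
  }
  bm <- best_matching_combo(counts, warn = FALSE)
  verdict <- if (identical(bm$combo, sort(unname(called_parents))))
    "matching" else "not_matching"
  base::structure(
    list(marker_id = result$marker_id, verdict = verdict,
         best_combo = bm$combo, chi2 = bm$chi2,
         called_parents = unname(called_parents),
         category_counts = counts, ambiguous = bm$ambiguous),
    class = "match_report")
}

#' Summarize a calling run as a Table-2 style breakdown
#'
#' Produces, as percentages over all markers: Called, Matching,
#' Not matching, Matching rate (= Matching / Called), Not called and its
#' three subcategories (single-category rejection, too-many-NA rejection,
#' no model).  The identities Called + Not called = 100,
#' Matching + Not matching = Called and the subcategory sum hold by
#' construction.
#'
#' @param results List of [fit_marker()] results.
#' @param reports Optional list of [classify_marker()] reports aligned with
#'   `results`; markers without a report (or not called) count as not
#'   matching only through the Called totals.
#' @return data.frame with columns `metric`, `value` (percent).
#' @export
summarize_run <- function(results, reports = NULL) {
  n <- length(results)
  stopifnot(n > 0)
  status <- vapply(results, `[[`, character(1), "status")
  called <- status == "called"
  matching <- rep(FALSE, n)
  if (!is.null(reports)) {
    ids <- vapply(results, `[[`, character(1), "marker_id")
    rep_ids <- vapply(reports, `[[`, character(1), "marker_id")
    verdict <- vapply(reports, `[[`, character(1), "verdict")
    matching <- called & ids %in% rep_ids[verdict == "matching"]
  }
  pct <- function(x) 100 * sum(x) / n
  data.frame(
    metric = c("Called", "Matching", "Not matching", "Matching rate",
               "Not called", "> 90% in single category", "> 25% NAs",
               "No model"),
    value = c(pct(called), pct(matching), pct(called & !matching),
              if (any(called)) 100 * sum(matching) / sum(called) else NA_real_,
              pct(!called), pct(status == "rejected_single_category"),
              pct(status == "rejected_too_many_na"),
              pct(status == "no_model")),
    stringsAsFactors = FALSE)
}
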