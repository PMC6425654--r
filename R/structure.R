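#' Population structure of a genotyping run
#'
#' Maps every sample to exactly one subpopulation and types each
#' subpopulation.  Four population types are supported:
#' \describe{
#'   \item{panel_free}{unstructured collection; mixing proportions freely
#'     estimated.}
#'   \item{panel_HW}{association panel assumed in tetraploid Hardy-Weinberg
#'     equilibrium.}
#'   \item{F1}{full-sib family; links name its two parent populations.}
#'   \item{parent}{replicated samples of one parent of an F1 family; link
#'     names the F1 population.}
#' }
#'
#' @param assignments data.frame with columns `sample`, `population`.
#' @param populations data.frame with columns `population`, `ptype` and
#'   optional `link1`, `link2` (parent populations of an F1; for a parent,
#'   `link1` is its F1 family).
#' @return Object of class `population_structure`.
#' @export
population_structure <- function(assignments, populations) {
  assignments <- data.frame(sample = as.character(assignments$sample),
                            population = as.character(assignments$population),
                            stringsAsFactors = FALSE)
  if (!all(c("population", "ptype") %in% names(populations))) {
    stop("populations needs columns 'population' and 'ptype'", call. = FALSE)
  }
  if (is.null(populations$link1)) populations$link1 <- NA_character_
  if (is.null(populations$link2)) populations$link2 <- NA_character_
  populations <- data.frame(population = as.character(populations$population),
                            ptype = as.character(populations$ptype),
                            link1 = as.character(populations$link1),
                            link2 = as.character(populations$link2),
                            stringsAsFactors = FALSE)
  ok_types <- c("panel_free", "panel_HW", "F1", "parent")
  if (!all(populations$ptype %in% ok_types)) {
    stop("unknown population type(s): ",
         paste(setdiff(populations$ptype, ok_types), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(populations$population)) {
    stop("duplicate population definitions", call. = FALSE)
  }
  dup <- assignments$sample[duplicated(assignments$sample)]
  if (length(dup)) {
    stop("sample(s) assigned more than once: ",
         paste(unique(utils::head(dup, 5L)), collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(assignments$population, populations$population)
  if (length(miss)) {
    stop("sample(s) assigned to undefined population(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ptype <- stats::setNames(populations$ptype, populations$population)
  for (i in which(populations$ptype == "F1")) {
    par <- c(populations$link1[i], populations$link2[i])
    if (anyNA(par) || par[1] == par[2]) {
      stop("F1 population '", populations$population[i],
           "' must link two distinct parent populations", call. = FALSE)
    }
    if (!all(par %in% populations$population) ||
        !all(ptype[par] == "parent")) {
      stop("F1 population '", populations$population[i],
           "' links non-parent population(s)", call. = FALSE)
    }
  }
  f1_links <- unlist(populations[populations$ptype == "F1", c("link1", "link2")],
                     use.names = FALSE)
  orphan <- setdiff(populations$population[populations$ptype == "parent"],
                    f1_links)
  if (length(orphan)) {
    stop("parent population(s) not linked to any F1 family: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  structure(list(assignments = assignments, populations = populations),
            class = "population_structure")
}

#' @export
print.population_structure <- function(x, ...) {
  cat(sprintf("population_structure: %d samples in %d populations\n",
              nrow(x$assignments), nrow(x$populations)))
  for (i in seq_len(nrow(x$populations))) {
    p <- x$populations[i, ]
    n <- sum(x$assignments$population == p$population)
    link <- if (!is.na(p$link1)) {
      paste0(" -> ", paste(stats::na.omit(c(p$link1, p$link2)), collapse = " + "))
    } else ""
    cat(sprintf("  %s (%s): %d samples%s\n", p$population, p$ptype, n, link))
  }
  invisible(x)
}

# named vector sample -> population, in assignment order
pop_of <- function(structure) {
  stats::setNames(structure$assignments$population, structure$assignments$sample)
}

# population ids of one ptype
pops_of_type <- function(structure, type) {
  structure$populations$population[structure$populations$ptype == type]
}

# parent population ids linked to an F1 population
f1_parents <- function(structure, f1_id) {
  i <- match(f1_id, structure$populations$population)
  c(structure$populations$link1[i], structure$populations$link2[i])
}
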