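#' Gamete dosage distribution of a tetraploid parent
#'
#' Under tetrasomic inheritance with random bivalent pairing and no double
#' reduction, a gamete receives 2 of the parent's 4 homologous chromosomes,
#' so the B-allele dosage of a gamete follows a hypergeometric draw of 2
#' chromosomes from a pool containing `dosage` B-carrying homologs.
#'
#' @param dosage Integer parental B-allele dosage in 0..4.
#' @return Numeric vector of length 3: probabilities of gamete dosage 0, 1, 2.
#' @examples
#' gamete_distribution(2)  # 1/6, 4/6, 1/6
#' @export
gamete_distribution <- function(dosage) {
  if (length(dosage) != 1L || is.na(dosage) || dosage != as.integer(dosage) ||
      dosage < 0 || dosage > 4) {
    stop("parental dosage must be a single integer in 0..4", call. = FALSE)
  }
  g <- 0:2
  p <- choose(dosage, g) * choose(4 - dosage, 2 - g) / choose(4, 2)
  names(p) <- as.character(g)
  p
}

#' Expected F1 segregation of a tetraploid cross
#'
#' Convolves the gamete dosage distributions of the two parents to obtain the
#' expected offspring dosage distribution (classes 0..4: nulliplex, simplex,
#' duplex, triplex, quadruplex), together with its smallest-integer ratio
#' representation (e.g. duplex x duplex gives 1:8:18:8:1).
#'
#' @param parent1_dosage,parent2_dosage Integer dosages in 0..4.
#' @return An object of class `segregation_prior`: a list with elements
#'   `parent1_dosage`, `parent2_dosage`, `proportions` (5-vector summing to 1)
#'   and `integer_ratio` (5-vector of smallest nonnegative integers).
#' @examples
#' f1_segregation(2, 2)$integer_ratio  # 1 8 18 8 1
#' @export
f1_segregation <- function(parent1_dosage, parent2_dosage) {
  g1 <- gamete_distribution(parent1_dosage)
  g2 <- gamete_distribution(parent2_dosage)
  prop <- as.numeric(stats::convolve(g1, rev(g2), type = "open"))
  # guard tiny negative fft round-off
  prop[prop < 0] <- 0
  prop <- prop / sum(prop)
  names(prop) <- as.character(0:4)
  structure(
    list(parent1_dosage = parent1_dosage,
         parent2_dosage = parent2_dosage,
         proportions = prop,
         integer_ratio = smallest_integer_ratio(prop)),
    class = "segregation_prior")
}

#' @export
print.segregation_prior <- function(x, ...) {
  cat(sprintf("F1 segregation for cross %d x %d: %s\n",
              x$parent1_dosage, x$parent2_dosage,
              paste(x$integer_ratio, collapse = ":")))
  invisible(x)
}

#' Tetraploid Hardy-Weinberg dosage proportions
#'
#' Genotype (dosage) class proportions for an autotetraploid population in
#' Hardy-Weinberg equilibrium: Binomial(4, p) mass over dosages 0..4, where
#' p is the B-allele frequency.
#'
#' @param allele_freq_b B-allele frequency in \[0, 1\].
#' @return Numeric 5-vector of proportions over dosages 0..4, summing to 1.
#' @examples
#' hw_proportions(0.5)  # (1,4,6,4,1)/16
#' @export
hw_proportions <- function(allele_freq_b) {
  if (length(allele_freq_b) != 1L || is.na(allele_freq_b) ||
      allele_freq_b < 0 || allele_freq_b > 1) {
    stop("allele frequency must be a single value in [0, 1]", call. = FALSE)
  }
  p <- stats::dbinom(0:4, size = 4, prob = allele_freq_b)
  names(p) <- as.character(0:4)
  p
}

#' Smallest-integer representation of a rational proportion vector
#'
#' Rescales a vector of rational proportions (denominator at most 36, which
#' covers every tetrasomic F1 segregation ratio) to the proportional vector
#' of smallest nonnegative integers with gcd 1 over the nonzero entries.
#'
#' @param proportions Numeric vector of nonnegative rationals.
#' @param max_denominator Largest denominator tried (default 36).
#' @return Integer vector proportional to `proportions`.
#' @examples
#' smallest_integer_ratio(c(1, 8, 18, 8, 1) / 36)
#' @export
smallest_integer_ratio <- function(proportions, max_denominator = 36L) {
  if (any(is.na(proportions)) || any(proportions < 0)) {
    stop("proportions must be nonnegative and non-missing", call. = FALSE)
  }
  s <- sum(proportions)
  if (s <= 0) stop("proportions must not all be zero", call. = FALSE)
  prop <- proportions / s
  for (den in seq_len(max_denominator)) {
    ints <- prop * den
    if (all(abs(ints - round(ints)) < 1e-9)) {
      ints <- as.integer(round(ints))
      g <- Reduce(gcd2, ints[ints > 0L])
      return(ints %/% g)
    }
  }
  stop("proportions are not rational with denominator <= ", max_denominator,
       call. = FALSE)
}

gcd2 <- function(a, b) if (b == 0L) a else gcd2(b, a %% b)
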