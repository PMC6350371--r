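#' Disease model for allele-frequency filtering
#'
#' The four parameters defining how common a pathogenic allele for the
#' disease can plausibly be in the general population.
#'
#' @param prevalence Fraction of the population affected (e.g. 1/500 for
#'   hypertrophic cardiomyopathy).
#' @param allelic_heterogeneity Maximum fraction of cases attributable to
#'   any single allele.
#' @param penetrance Probability that a carrier develops disease, in (0, 1].
#' @param inheritance `"monoallelic"` or `"biallelic"`.
#' @return Object of class `disease_model`.
#' @examples
#' disease_model(1/500, 0.02, 0.5, "monoallelic")
#' @export
disease_model <- function(prevalence, allelic_heterogeneity, penetrance,
                          inheritance = c("monoallelic", "biallelic")) {
  inheritance <- match.arg(inheritance)
  frac_ok <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x > 0 && x <= 1
  if (!frac_ok(prevalence) || !frac_ok(allelic_heterogeneity) || !frac_ok(penetrance))
    stop("prevalence, allelic_heterogeneity and penetrance must be in (0, 1]")
  structure(list(prevalence = prevalence,
                 allelic_heterogeneity = allelic_heterogeneity,
                 penetrance = penetrance,
                 inheritance = inheritance),
            class = "disease_model")
}

#' @export
print.disease_model <- function(x, ...) {
  cat(sprintf("disease model: prevalence %g, allelic heterogeneity %g, penetrance %g, %s\n",
              x$prevalence, x$allelic_heterogeneity, x$penetrance, x$inheritance))
  cat(sprintf("maximum credible allele frequency: %g\n", max_credible_af(x)))
  invisible(x)
}

#' Maximum credible allele frequency for a disease model
#'
#' prevalence x allelic heterogeneity x 1/penetrance, halved for
#' monoallelic inheritance (one pathogenic allele per affected genotype).
#' Variants above this population frequency are too common to cause the
#' modelled Mendelian disease.
#'
#' @param model A [disease_model()].
#' @return Allele frequency.
#' @examples
#' max_credible_af(disease_model(1/500, 0.02, 0.5, "monoallelic"))   # 4e-5 (HCM)
#' max_credible_af(disease_model(1/10000, 0.1, 0.5, "monoallelic"))  # 1e-5 (CPVT)
#' @export
max_credible_af <- function(model) {
  stopifnot(inherits(model, "disease_model"))
  allelic_factor <- if (model$inheritance == "monoallelic") 0.5 else 1.0
  model$prevalence * model$allelic_heterogeneity / model$penetrance * allelic_factor
}

#' Per-population allele counts for one variant
#'
#' @param ac Integer vector of allele counts per major reference
#'   sub-population.
#' @param an Integer vector of allele numbers (called chromosomes) per
#'   sub-population, same length.
#' @param populations Optional population names.
#' @return Object of class `population_counts`; `overall_ac`/`overall_an`
#'   are the sums across sub-populations.
#' @export
population_counts <- function(ac, an, populations = names(ac)) {
  if (length(ac) != length(an)) stop("ac and an must have equal length")
  if (length(ac) == 0) stop("at least one population is required")
  if (any(ac < 0) || any(an < 0) || any(ac > an))
    stop("need 0 <= AC <= AN in every population")
  structure(list(ac = as.numeric(ac), an = as.numeric(an),
                 populations = populations,
                 overall_ac = sum(ac), overall_an = sum(an)),
            class = "population_counts")
}

#' Filtering allele frequency (popmax lower confidence bound)
#'
#' For each sub-population the FAF is the one-sided `confidence`-level
#' lower Clopper-Pearson bound on the allele frequency given AC alleles
#' observed out of AN; the variant's FAF is the maximum across
#' sub-populations. The FAF is a conservative estimate of the highest true
#' population frequency consistent with the observations: a variant is
#' confidently too common for a disease when its FAF exceeds the disease's
#' maximum credible allele frequency.
#'
#' Undefined (`NA`) when the variant was detected in at most one
#' individual in every sub-population (all AC <= 1 with at least one
#' observation); 0 when the variant was not observed at all.
#'
#' @param counts A [population_counts()].
#' @param confidence One-sided confidence level (default 0.95).
#' @return Allele frequency, 0, or `NA` when undefined.
#' @export
filtering_allele_frequency <- function(counts, confidence = 0.95) {
  stopifnot(inherits(counts, "population_counts"))
  usable <- counts$an > 0
  if (!any(usable)) return(NA_real_)
  ac <- counts$ac[usable]
  an <- counts$an[usable]
  if (max(ac) == 0) return(0)
  if (max(ac) <= 1) return(NA_real_)
  bounds <- ifelse(ac == 0, 0, stats::qbeta(1 - confidence, ac, an - ac + 1))
  max(bounds)
}

#' Disease-specific rarity decision for a variant
#'
#' Rare when the filtering allele frequency is defined and below the
#' threshold; when the FAF is undefined (singleton in every
#' sub-population), falls back to requiring an overall allele count below
#' `fallback_max_ac`.
#'
#' @param counts A [population_counts()].
#' @param threshold Maximum credible allele frequency for the disease.
#' @param fallback_max_ac Overall-AC fallback cut-off (default 3: AC < 3
#'   is rare when no FAF is available).
#' @param confidence Confidence level passed to
#'   [filtering_allele_frequency()].
#' @return Logical.
#' @export
is_rare <- function(counts, threshold, fallback_max_ac = 3, confidence = 0.95) {
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be positive")
  faf <- filtering_allele_frequency(counts, confidence)
  if (is.na(faf)) counts$overall_ac < fallback_max_ac else faf < threshold
}

#' Coverage-adjusted effective reference cohort size
#'
#' Reference exomes do not cover every site equally, so the nominal sample
#' size overstates the denominator. The effective size for a gene is the
#' mean number of called genotypes across its variant sites, rounded to
#' the nearest integer.
#'
#' @param called_genotypes_per_variant Numeric vector, one entry per
#'   variant site.
#' @return Integer count.
#' @examples
#' effective_reference_n(c(60000, 59000, 58000)) # 59000
#' @export
effective_reference_n <- function(called_genotypes_per_variant) {
  x <- called_genotypes_per_variant
  if (length(x) == 0) stop("need at least one variant site")
  if (any(is.na(x)) || any(x < 0)) stop("called genotype counts must be non-negative")
  round(mean(x))
}
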