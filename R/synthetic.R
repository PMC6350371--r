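#' Specification for a synthetic variant-position simulation
#'
#' Defines the ground truth for a simulated protein: a uniform background
#' rate of distinct rare variants per residue in each cohort, plus planted
#' case-enriched regions at a fold-increased rate.
#'
#' @param protein_length Protein length, residues.
#' @param background_rate Expected distinct variants per residue per
#'   cohort.
#' @param planted_regions data.frame with columns `start`, `end`,
#'   `fold_enrichment` (>= 1), or `NULL` for pure background.
#' @param n_cases,n_reference Cohort sizes (carried along for downstream
#'   burden estimates).
#' @param seed Mandatory RNG seed.
#' @return Object of class `sim_spec`.
#' @export
sim_spec <- function(protein_length, background_rate, planted_regions = NULL,
                     n_cases = 5000L, n_reference = 60000L, seed) {
  if (missing(seed) || length(seed) != 1 || is.na(seed))
    stop("a scalar seed is mandatory")
  if (background_rate < 0) stop("background_rate must be >= 0")
  if (!is.null(planted_regions)) {
    stopifnot(all(c("start", "end", "fold_enrichment") %in% names(planted_regions)))
    if (any(planted_regions$start < 1) || any(planted_regions$end > protein_length) ||
        any(planted_regions$start > planted_regions$end))
      stop("planted regions must lie within the protein")
    if (any(planted_regions$fold_enrichment < 1))
      stop("fold_enrichment must be >= 1")
  }
  structure(list(protein_length = as.integer(protein_length),
                 background_rate = background_rate,
                 planted_regions = planted_regions,
                 n_cases = as.integer(n_cases),
                 n_reference = as.integer(n_reference),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

# Draw positions from a per-residue rate vector: Poisson total, positions
# sampled with replacement proportional to rate, then deduplicated (each
# distinct variant occupies one residue; a residue holds at most one
# simulated variant).
draw_positions <- function(rate) {
  total <- sum(rate)
  if (total <= 0) return(integer())
  n <- stats::rpois(1, total)
  if (n == 0) return(integer())
  sort(unique(sample.int(length(rate), n, replace = TRUE, prob = rate)))
}

#' Simulate case and control variant positions
#'
#' Control positions are uniform at the background rate; case positions
#' are uniform at the background rate outside the planted regions and at
#' `background_rate * fold_enrichment` inside them. Pure function of the
#' spec (including its seed).
#'
#' @param spec A [sim_spec()].
#' @return List with `case` and `control` [variant_positions()].
#' @export
simulate_positions <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  L <- spec$protein_length
  set.seed(spec$seed)
  ctrl_rate <- rep(spec$background_rate, L)
  case_rate <- rep(spec$background_rate, L)
  if (!is.null(spec$planted_regions)) {
    for (i in seq_len(nrow(spec$planted_regions))) {
      idx <- spec$planted_regions$start[i]:spec$planted_regions$end[i]
      case_rate[idx] <- spec$background_rate * spec$planted_regions$fold_enrichment[i]
    }
  }
  if (sum(case_rate) + sum(ctrl_rate) < 1)
    warning("expected total variant count below 1; empty sets are likely")
  case_pos <- draw_positions(case_rate)
  ctrl_pos <- draw_positions(ctrl_rate)
  list(case = variant_positions(L, case_pos, "case"),
       control = variant_positions(L, ctrl_pos, "control"))
}

#' Simulate a case-control carrier contingency table at a known odds ratio
#'
#' Reference carriers are Binomial(`n_reference`, `baseline_carrier_rate`);
#' case carriers are Binomial(`n_cases`, p) where the case carrier odds are
#' `true_or` times the baseline odds.
#'
#' @param n_cases,n_reference Cohort sizes.
#' @param baseline_carrier_rate Carrier probability in the reference
#'   population, in (0, 1).
#' @param true_or True carrier odds ratio (>= 0).
#' @param seed RNG seed.
#' @return A [contingency_table()].
#' @export
simulate_cohort_table <- function(n_cases, n_reference, baseline_carrier_rate,
                                  true_or, seed) {
  if (baseline_carrier_rate <= 0 || baseline_carrier_rate >= 1)
    stop("baseline_carrier_rate must lie in (0, 1)")
  if (true_or <= 0) stop("true_or must be positive")
  odds <- true_or * baseline_carrier_rate / (1 - baseline_carrier_rate)
  p_case <- odds / (1 + odds)
  if (p_case > 1) stop("implied case carrier probability exceeds 1")
  set.seed(seed)
  a <- stats::rbinom(1, n_cases, p_case)
  b <- stats::rbinom(1, n_reference, baseline_carrier_rate)
  contingency_table(a, b, n_cases - a, n_reference - b)
}
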