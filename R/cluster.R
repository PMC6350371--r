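#' Rare-variant residue positions for one protein and cohort
#'
#' Positions are 1-based residue indices of *distinct* rare variants: each
#' distinct variant contributes one position, and two distinct variants may
#' share a residue, so `positions` is a multiset. Carrier multiplicities
#' (how many individuals carry each variant) only enter regional burden
#' estimates, never the positional binomial tests.
#'
#' @param protein_length Protein length in residues.
#' @param positions Integer vector of residue positions, one per distinct
#'   variant.
#' @param cohort `"case"` or `"control"`.
#' @param carriers Integer vector of carrier counts per variant (default 1
#'   each).
#' @return Object of class `variant_positions`.
#' @export
variant_positions <- function(protein_length, positions,
                              cohort = c("case", "control"),
                              carriers = rep(1L, length(positions))) {
  cohort <- match.arg(cohort)
  protein_length <- as.integer(protein_length)
  positions <- as.integer(positions)
  if (is.na(protein_length) || protein_length < 1) stop("protein_length must be >= 1")
  if (length(positions) && (any(positions < 1) || any(positions > protein_length)))
    stop("positions must lie in [1, protein_length]")
  if (length(carriers) != length(positions) || any(carriers < 1))
    stop("carriers must supply a positive count per variant")
  structure(list(protein_length = protein_length,
                 positions = positions,
                 carriers = as.integer(carriers),
                 cohort = cohort),
            class = "variant_positions")
}

#' @export
print.variant_positions <- function(x, ...) {
  cat(sprintf("%s cohort: %d distinct variants (%d carriers) on a %d-residue protein\n",
              x$cohort, length(x$positions), sum(x$carriers), x$protein_length))
  invisible(x)
}

#' Configuration for the sliding-window cluster scan
#'
#' @param initial_fractions Window sizes of the first search pass, as
#'   fractions of the protein length (default 5% to 95% in steps of 5%).
#' @param refinement_factor Each refinement pass searches at this-fold
#'   finer spacing around the incumbent best size (default 10).
#' @param refinement_count Number of candidate sizes per refinement pass
#'   (default 18, nine on each side of the incumbent).
#' @param plateau_tolerance Refinement stops when no candidate improves the
#'   objective by more than this (default 0.001).
#' @param alpha Significance level used throughout the scan (default 0.05).
#' @param step Sliding-window step in residues (default 1).
#' @return Object of class `scan_config`.
#' @export
scan_config <- function(initial_fractions = seq(0.05, 0.95, by = 0.05),
                        refinement_factor = 10, refinement_count = 18,
                        plateau_tolerance = 0.001, alpha = 0.05, step = 1L) {
  if (any(initial_fractions <= 0) || any(initial_fractions >= 1))
    stop("initial_fractions must lie in (0, 1)")
  if (plateau_tolerance <= 0) stop("plateau_tolerance must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(initial_fractions = sort(initial_fractions),
                 refinement_factor = refinement_factor,
                 refinement_count = as.integer(refinement_count),
                 plateau_tolerance = plateau_tolerance,
                 alpha = alpha, step = as.integer(step)),
            class = "scan_config")
}

#' One-sided binomial enrichment p-value for a window
#'
#' Under a uniform placement of `n_total` variants along the protein, the
#' count inside a window of `window_len` residues is Binomial(n_total,
#' window_len/protein_len); returns the upper tail P(X >= k_in).
#'
#' @param k_in Variants inside the window.
#' @param n_total Variants on the whole protein.
#' @param window_len Window length, residues.
#' @param protein_len Protein length, residues.
#' @return p-value (vectorised over `k_in`).
#' @examples
#' window_enrichment_p(5, 5, 10, 100) # 1e-5
#' @export
window_enrichment_p <- function(k_in, n_total, window_len, protein_len) {
  if (protein_len <= 0) stop("protein_len must be positive")
  if (window_len <= 0 || window_len > protein_len)
    stop("window_len must lie in (0, protein_len]")
  if (any(k_in < 0) || any(k_in > n_total)) stop("need 0 <= k_in <= n_total")
  stats::pbinom(k_in - 1, n_total, window_len / protein_len, lower.tail = FALSE)
}

# Variant counts inside every window of size w (step 1), via cumulative sums.
window_counts <- function(positions, protein_len, w) {
  cs <- c(0, cumsum(tabulate(positions, nbins = protein_len)))
  starts <- seq_len(protein_len - w + 1)
  cs[starts + w] - cs[starts]
}

#' Scan a protein with a fixed window size
#'
#' Slides a window of `window_size` residues in steps of 1 and records
#' every window whose one-sided binomial enrichment p-value is below
#' `alpha_corrected`.
#'
#' @param variants A [variant_positions()].
#' @param window_size Window size, residues.
#' @param alpha_corrected Significance threshold applied to the raw
#'   p-values (default 0.05).
#' @return data.frame with columns `start`, `end`, `p_raw` (possibly
#'   zero rows).
#' @export
scan_fixed_window <- function(variants, window_size, alpha_corrected = 0.05) {
  stopifnot(inherits(variants, "variant_positions"))
  L <- variants$protein_length
  w <- as.integer(window_size)
  if (w < 1 || w > L) stop("window_size must lie in [1, protein_length]")
  n <- length(variants$positions)
  empty <- data.frame(start = integer(), end = integer(), p_raw = numeric())
  if (n == 0) return(empty)
  k <- window_counts(variants$positions, L, w)
  p <- window_enrichment_p(k, n, w, L)
  keep <- which(p < alpha_corrected)
  if (!length(keep)) return(empty)
  data.frame(start = keep, end = keep + w - 1L, p_raw = p[keep])
}

# sensitivity = fraction of variant-bearing residues inside clusters;
# specificity = fraction of variant-free residues outside clusters.
sens_spec <- function(intervals, variants) {
  L <- variants$protein_length
  inside <- rep(FALSE, L)
  if (nrow(intervals))
    for (i in seq_len(nrow(intervals)))
      inside[intervals$start[i]:intervals$end[i]] <- TRUE
  has_var <- rep(FALSE, L)
  has_var[variants$positions] <- TRUE
  sens <- if (any(has_var)) mean(inside[has_var]) else NA_real_
  spec <- if (any(!has_var)) mean(!inside[!has_var]) else NA_real_
  c(sensitivity = sens, specificity = spec)
}

#' Sensitivity and specificity of a cluster set for one cohort
#'
#' Sensitivity is the fraction of variant-bearing residues lying inside
#' the clusters; specificity the fraction of variant-free residues lying
#' outside them. The two extremes of the window-size spectrum follow
#' directly: minimal windows (one residue per variant) give specificity 1,
#' a single maximal window covering the protein gives sensitivity 1.
#'
#' @param clusters data.frame with `start`/`end` columns.
#' @param variants A [variant_positions()].
#' @return Named list `sensitivity`, `specificity` (`NA` when a class of
#'   residues is empty).
#' @export
cluster_performance <- function(clusters, variants) {
  stopifnot(inherits(variants, "variant_positions"))
  ss <- sens_spec(clusters, variants)
  list(sensitivity = ss[["sensitivity"]], specificity = ss[["specificity"]])
}

#' Sensitivity/specificity balance objective for a cluster set
#'
#' For each cohort, sensitivity is the fraction of variant-bearing
#' residues inside clusters and specificity the fraction of variant-free
#' residues outside clusters. The objective is the mean over cohorts of
#' |sensitivity - specificity|; lower is better. A cohort with no variants
#' is omitted from the mean. Degenerate extremes: no clusters gives 1
#' (sensitivity 0, specificity 1); a single cluster covering the whole
#' protein gives 1 (sensitivity 1, specificity 0).
#'
#' @param clusters data.frame with `start`/`end` columns (disjoint
#'   intervals).
#' @param case_variants,control_variants [variant_positions()];
#'   `control_variants` may be `NULL`.
#' @return Objective value in \[0, 1\].
#' @export
clustering_objective <- function(clusters, case_variants, control_variants = NULL) {
  cohorts <- Filter(function(v) !is.null(v) && length(v$positions) > 0,
                    list(case_variants, control_variants))
  if (!length(cohorts)) stop("at least one cohort must contain variants")
  diffs <- vapply(cohorts, function(v) {
    ss <- sens_spec(clusters, v)
    abs(ss[["sensitivity"]] - ss[["specificity"]])
  }, numeric(1))
  mean(diffs, na.rm = TRUE)
}

# Scan + merge at one size for one cohort; returns intervals (possibly empty).
scan_and_merge <- function(variants, w, alpha) {
  merge_windows(scan_fixed_window(variants, w, alpha))
}

#' Automatic window-size selection
#'
#' Evaluates the 19 initial fractional window sizes, then repeatedly
#' refines around the incumbent best at a `refinement_factor`-fold finer
#' spacing (`refinement_count` candidates per pass) until no candidate
#' improves the objective by more than `plateau_tolerance`. For each
#' candidate size, each supplied cohort is scanned and its significant
#' windows merged; the objective is the mean over cohorts of
#' |sensitivity - specificity| of the resulting clusters. Candidates are
#' judged at the Bonferroni-corrected threshold implied by the sizes
#' tested so far (see [correct_p()]), so the clusters the objective sees
#' match those the definitive scan will keep. Ties go to the smallest
#' size.
#'
#' @param case_variants Primary cohort, a [variant_positions()].
#' @param control_variants Optional second cohort entering the objective.
#' @param config A [scan_config()].
#' @return Optimal window size in residues (integer), with attributes
#'   `objective` (objective value attained) and `avg_tests_per_residue`
#'   (mean number of windows covering each residue across all sizes
#'   evaluated, the multiple-testing correction factor) and
#'   `fractions_tested` (list of the fractional sizes evaluated per search
#'   pass). `NA` when no candidate size yields any significant window
#'   ("no clustering detected").
#' @export
optimize_window_size <- function(case_variants, control_variants = NULL,
                                 config = scan_config()) {
  cohorts <- Filter(function(v) !is.null(v) && length(v$positions) > 0,
                    list(case_variants, control_variants))
  if (!length(cohorts)) stop("at least one cohort must be non-empty")
  L <- unique(vapply(cohorts, `[[`, integer(1), "protein_length"))
  if (length(L) != 1) stop("cohorts must share the same protein length")

  sizes_seen <- integer()                   # distinct sizes scanned
  passes <- list()                          # fractions evaluated per pass
  any_significant <- FALSE

  coverage <- function(w) (L - w + 1) * w   # residue-coverings of one scan

  frac_to_size <- function(f) pmax(1L, pmin(L, as.integer(round(f * L))))

  # Candidates of a pass are judged at the significance threshold the
  # definitive windows will face: alpha corrected for the average number of
  # times each residue has been tested up to and including this pass.
  evaluate_fracs <- function(fracs) {
    passes[[length(passes) + 1]] <<- fracs
    sizes <- frac_to_size(fracs)
    new_sizes <- setdiff(unique(sizes), sizes_seen)
    sizes_seen <<- c(sizes_seen, new_sizes)
    factor <- max(1, sum(vapply(sizes_seen, coverage, numeric(1))) / L)
    objs <- vapply(sizes, function(w) {
      diffs <- vapply(cohorts, function(v) {
        cl <- scan_and_merge(v, w, config$alpha / factor)
        if (nrow(cl)) any_significant <<- TRUE
        ss <- sens_spec(cl, v)
        abs(ss[["sensitivity"]] - ss[["specificity"]])
      }, numeric(1))
      mean(diffs, na.rm = TRUE)
    }, numeric(1))
    # best candidate of this batch; ties -> smallest size
    ord <- order(objs, sizes)
    list(frac = fracs[ord[1]], size = sizes[ord[1]], obj = objs[ord[1]])
  }

  best <- evaluate_fracs(config$initial_fractions)
  spacing <- if (length(config$initial_fractions) > 1)
    min(diff(config$initial_fractions)) else 0.05

  repeat {
    spacing <- spacing / config$refinement_factor
    half <- config$refinement_count / 2
    offsets <- setdiff(seq(-half, half), 0) * spacing
    fracs <- best$frac + offsets
    fracs <- fracs[fracs > 0 & fracs < 1]
    if (!length(fracs) || spacing * L < 0.5) break
    cand <- evaluate_fracs(fracs)
    improved <- best$obj - cand$obj
    if (improved > config$plateau_tolerance) {
      best <- cand
    } else {
      # same-objective smaller size still preferred, but the plateau is reached
      if (improved >= 0 && cand$size < best$size && cand$obj == best$obj) best <- cand
      break
    }
  }

  if (!any_significant) {
    out <- NA_integer_
  } else {
    out <- best$size
  }
  attr(out, "objective") <- if (is.na(out)) NA_real_ else best$obj
  attr(out, "avg_tests_per_residue") <-
    max(1, sum(vapply(sizes_seen, coverage, numeric(1))) / L)
  attr(out, "fractions_tested") <- passes
  out
}

#' Bonferroni correction of window p-values
#'
#' Corrects each significant window's p-value for the number of tests
#' performed, expressed as the average number of times each protein
#' residue was covered by a tested window over all scan iterations:
#' p_corrected = min(1, p_raw x avg_tests_per_residue).
#'
#' @param windows data.frame with a `p_raw` column (from
#'   [scan_fixed_window()]).
#' @param avg_tests_per_residue Correction factor, >= 1.
#' @return The windows with a `p_corrected` column added.
#' @export
correct_p <- function(windows, avg_tests_per_residue) {
  if (avg_tests_per_residue < 1) stop("avg_tests_per_residue must be >= 1")
  windows$p_corrected <- pmin(1, windows$p_raw * avg_tests_per_residue)
  windows
}

#' Merge overlapping or adjacent significant windows
#'
#' Returns maximal intervals covering the input windows; touching windows
#' (end + 1 == next start) merge. Each merged cluster carries the minimum
#' p-value of its member windows (`p_corrected` when present, else
#' `p_raw`).
#'
#' @param windows data.frame with `start`, `end` and p-value columns.
#' @return data.frame of clusters with `start`, `end` and the carried
#'   p-value column(s).
#' @export
merge_windows <- function(windows) {
  if (!nrow(windows)) {
    out <- data.frame(start = integer(), end = integer())
    for (col in intersect(c("p_raw", "p_corrected"), names(windows)))
      out[[col]] <- numeric()
    return(out)
  }
  rng <- IRanges::IRanges(start = windows$start, end = windows$end)
  red <- IRanges::reduce(rng, min.gapwidth = 1L, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  out <- data.frame(start = IRanges::start(red), end = IRanges::end(red))
  for (col in intersect(c("p_raw", "p_corrected"), names(windows)))
    out[[col]] <- vapply(seq_along(revmap),
                         function(i) min(windows[[col]][revmap[[i]]]),
                         numeric(1))
  out
}

# Depletion p-value of a tail: one-sided lower-tail binomial on the tail's
# variant count against the whole-cluster density.
tail_depletion_p <- function(k_tail, n_cluster, tail_len, cluster_len) {
  stats::pbinom(k_tail, n_cluster, tail_len / cluster_len)
}

#' Boundary trimming of a cluster
#'
#' At each end independently, considers candidate tails of length 1 up to
#' (but never past) the cluster median residue; each tail's variant count
#' is tested for depletion against the whole cluster's variant density
#' (one-sided lower-tail binomial). The most significantly depleted tail
#' (minimum p) is removed if its p-value is below `alpha`. Passes are
#' repeated on the trimmed cluster until neither end has a significantly
#' depleted tail, so the operation is idempotent. The output interval is
#' always contained in the input.
#'
#' @param cluster List or one-row data.frame with `start` and `end`.
#' @param variants A [variant_positions()].
#' @param alpha Significance level for tail removal (default 0.05).
#' @return List with `start`, `end`, `trimmed_left`, `trimmed_right`.
#' @export
trim_cluster <- function(cluster, variants, alpha = 0.05) {
  start <- as.integer(cluster$start)
  end <- as.integer(cluster$end)
  if (start > end) stop("cluster start must be <= end")
  out <- list(start = start, end = end, trimmed_left = FALSE, trimmed_right = FALSE)
  repeat {
    step <- trim_pass(out$start, out$end, variants, alpha)
    if (!step$trimmed_left && !step$trimmed_right) break
    out$start <- step$start
    out$end <- step$end
    out$trimmed_left <- out$trimmed_left || step$trimmed_left
    out$trimmed_right <- out$trimmed_right || step$trimmed_right
  }
  out
}

# One trimming pass: remove the most significantly depleted tail (if any)
# at each end, never extending a tail past the cluster median residue.
trim_pass <- function(start, end, variants, alpha) {
  len <- end - start + 1L
  pos <- variants$positions[variants$positions >= start & variants$positions <= end]
  n <- length(pos)
  max_tail <- (len - 1L) %/% 2L
  out <- list(start = start, end = end, trimmed_left = FALSE, trimmed_right = FALSE)
  if (n == 0 || max_tail < 1) return(out)
  lens <- seq_len(max_tail)
  # counts in left tails [start, start + t - 1] and right tails [end - t + 1, end]
  k_left <- vapply(lens, function(t) sum(pos <= start + t - 1L), integer(1))
  k_right <- vapply(lens, function(t) sum(pos >= end - t + 1L), integer(1))
  p_left <- tail_depletion_p(k_left, n, lens, len)
  p_right <- tail_depletion_p(k_right, n, lens, len)
  iL <- which.min(p_left)
  if (p_left[iL] < alpha) {
    out$start <- start + lens[iL]
    out$trimmed_left <- TRUE
  }
  iR <- which.min(p_right)
  if (p_right[iR] < alpha) {
    out$end <- end - lens[iR]
    out$trimmed_right <- TRUE
  }
  out
}

# Full scan pipeline for one cohort at its own optimal window size.
detect_clusters_one <- function(variants, config) {
  L <- variants$protein_length
  empty <- data.frame(cohort = character(), start = integer(), end = integer(),
                      p_raw = numeric(), p_corrected = numeric(),
                      window_size = integer(),
                      trimmed_left = logical(), trimmed_right = logical())
  if (length(variants$positions) == 0) return(empty)
  w <- optimize_window_size(variants, NULL, config)
  if (is.na(w)) return(empty)
  factor <- max(1, attr(w, "avg_tests_per_residue"))
  windows <- scan_fixed_window(variants, w, config$alpha)
  windows <- correct_p(windows, factor)
  windows <- windows[windows$p_corrected < config$alpha, , drop = FALSE]
  if (!nrow(windows)) return(empty)
  raw <- merge_windows(windows)
  n <- length(variants$positions)
  rows <- lapply(seq_len(nrow(raw)), function(i) {
    tr <- trim_cluster(raw[i, ], variants, config$alpha)
    k <- sum(variants$positions >= tr$start & variants$positions <= tr$end)
    p_final <- window_enrichment_p(k, n, tr$end - tr$start + 1L, L)
    if (p_final >= config$alpha) return(NULL)
    data.frame(cohort = variants$cohort, start = tr$start, end = tr$end,
               p_raw = p_final, p_corrected = raw$p_corrected[i],
               window_size = as.integer(w),
               trimmed_left = tr$trimmed_left, trimmed_right = tr$trimmed_right)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

#' Detect case- and control-enriched clusters on a protein
#'
#' Runs the full pipeline independently for each cohort: automatic window
#' size selection, sliding-window scan, multiple-testing correction,
#' merging of significant windows, boundary trimming, and a final binomial
#' enrichment test (at nominal `alpha`) on each refined cluster.
#'
#' @param case_variants A [variant_positions()] for the case cohort.
#' @param control_variants Optional [variant_positions()] for the
#'   reference/control cohort.
#' @param config A [scan_config()].
#' @return data.frame with one row per final cluster: `cohort`, `start`,
#'   `end`, `p_raw` (final enrichment test), `p_corrected` (minimum
#'   corrected window p), `window_size`, `trimmed_left`, `trimmed_right`.
#'   Clusters are disjoint and sorted within each cohort.
#' @export
detect_clusters <- function(case_variants, control_variants = NULL,
                            config = scan_config()) {
  stopifnot(inherits(case_variants, "variant_positions"))
  if (case_variants$protein_length < 20)
    stop("protein_length must be >= 20 residues")
  out <- detect_clusters_one(case_variants, config)
  if (!is.null(control_variants)) {
    stopifnot(inherits(control_variants, "variant_positions"))
    if (control_variants$protein_length != case_variants$protein_length)
      stop("cohorts must share the same protein length")
    out <- rbind(out, detect_clusters_one(control_variants, config))
  }
  rownames(out) <- NULL
  out
}

#' Regional burden estimate inside (and outside) clusters
#'
#' Counts case and reference carriers of variants located inside the given
#' interval(s) and computes burden estimates for the region and for the
#' remainder of the protein. Each carrier is assumed to carry one variant,
#' so carriers in the region are the summed carrier counts of the variants
#' inside it.
#'
#' @param clusters data.frame (or list) with `start`/`end`; several rows
#'   are treated as a union of intervals.
#' @param case_variants,control_variants [variant_positions()] objects
#'   carrying per-variant carrier counts.
#' @param n_cases Total case cohort size.
#' @param effective_ref_n Effective reference cohort size.
#' @param level Confidence level.
#' @return List with `association_estimate` elements `inside` and
#'   `outside` (`NULL` when a partition has no carriers in either cohort).
#' @export
regional_ef <- function(clusters, case_variants, control_variants,
                        n_cases, effective_ref_n, level = 0.95) {
  starts <- as.integer(clusters$start)
  ends <- as.integer(clusters$end)
  if (any(starts > ends)) stop("cluster start must be <= end")
  L <- case_variants$protein_length
  if (any(starts < 1) || any(ends > L)) stop("clusters must lie within the protein")
  in_region <- function(v) {
    hit <- rep(FALSE, length(v$positions))
    for (i in seq_along(starts))
      hit <- hit | (v$positions >= starts[i] & v$positions <= ends[i])
    hit
  }
  case_hit <- in_region(case_variants)
  ctrl_hit <- in_region(control_variants)
  a_in <- sum(case_variants$carriers[case_hit])
  b_in <- sum(control_variants$carriers[ctrl_hit])
  a_out <- sum(case_variants$carriers[!case_hit])
  b_out <- sum(control_variants$carriers[!ctrl_hit])
  if (a_in + b_in == 0)
    stop("no carriers inside the region in either cohort: estimate undefined")
  est <- function(a, b) {
    if (a + b == 0) return(NULL)
    burden_estimate(a, n_cases, b, effective_ref_n, level)
  }
  list(inside = est(a_in, b_in), outside = est(a_out, b_out))
}

#' Plot variant density with cluster shading
#'
#' Case variants above the axis, control variants below, detected clusters
#' shaded (case clusters red, control clusters yellow).
#'
#' @param case_variants,control_variants [variant_positions()] objects.
#' @param clusters Optional data.frame from [detect_clusters()].
#' @param main Plot title.
#' @export
plot_variant_clusters <- function(case_variants, control_variants = NULL,
                                  clusters = NULL, main = "") {
  L <- case_variants$protein_length
  graphics::plot(NULL, xlim = c(1, L), ylim = c(-1, 1), xlab = "residue",
                 ylab = "", yaxt = "n", main = main)
  if (!is.null(clusters) && nrow(clusters)) {
    for (i in seq_len(nrow(clusters))) {
      up <- clusters$cohort[i] != "control"
      graphics::rect(clusters$start[i], if (up) 0 else -1,
                     clusters$end[i], if (up) 1 else 0,
                     col = if (up) grDevices::adjustcolor("red", 0.25)
                           else grDevices::adjustcolor("gold", 0.35),
                     border = NA)
    }
  }
  graphics::segments(case_variants$positions, 0, case_variants$positions, 0.8,
                     col = "grey25")
  if (!is.null(control_variants))
    graphics::segments(control_variants$positions, 0, control_variants$positions,
                       -0.8, col = "grey55")
  graphics::abline(h = 0)
  graphics::axis(2, at = c(0.5, -0.5), labels = c("case", "control"), las = 1,
                 tick = FALSE)
  invisible(NULL)
}
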