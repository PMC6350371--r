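# Jaccard overlap of two 1-based inclusive intervals
jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2) + 1)
  inter / ((e1 - s1 + 1) + (e2 - s2 + 1) - inter)
}

# Best Jaccard of any detected cluster against a planted interval
best_jaccard <- function(clusters, start, end) {
  if (!nrow(clusters)) return(0)
  max(vapply(seq_len(nrow(clusters)),
             function(i) jaccard(clusters$start[i], clusters$end[i], start, end),
             numeric(1)))
}

# The printed gene-panel burden fixture shipped with the package
burden_fixture_path <- function() {
  system.file("extdata", "hcm_gene_panel_counts.tsv", package = "efburden",
              mustWork = TRUE)
}

# Exhaustive two-sided Fisher p-value by direct enumeration of all tables
# with the observed margins, probabilities from binomial coefficients
# (independent of dhyper and of the package implementation).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- exp(lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(r1 + r2, c1))
  p_obs <- probs[match(a, xs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# ACMG/AMP combining-table oracle: classification from strength counts via
# an explicit list of qualifying requirement combinations.
combine_oracle <- function(strengths) {
  n <- c(vs = sum(strengths == "very_strong"), s = sum(strengths == "strong"),
         m = sum(strengths == "moderate"), p = sum(strengths == "supporting"))
  meets <- function(req) all(n[names(req)] >= req)
  path_reqs <- list(c(vs = 2), c(vs = 1, s = 1), c(vs = 1, m = 1),
                    c(vs = 1, p = 2), c(s = 2), c(s = 1, m = 3),
                    c(s = 1, m = 2, p = 2), c(s = 1, m = 1, p = 4))
  lp_reqs <- list(c(vs = 1, p = 1), c(s = 1, m = 1), c(s = 1, p = 2),
                  c(m = 3), c(m = 2, p = 2), c(m = 1, p = 4))
  if (any(vapply(path_reqs, meets, logical(1)))) return("pathogenic")
  if (any(vapply(lp_reqs, meets, logical(1)))) return("likely_pathogenic")
  "VUS"
}

# Build an evidence data.frame from a vector of strengths (distinct rules)
evidence_of <- function(strengths) {
  rules <- c("PVS1", "PS1", "PS2", "PS4", "PM1", "PM2", "PM4", "PM5", "PM6",
             "PP1", "PP3")
  if (!length(strengths))
    return(data.frame(rule = character(), strength = character()))
  data.frame(rule = rules[seq_along(strengths)], strength = strengths)
}
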