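#' EF-calibrated PM1 tier for a variant's region
#'
#' Maps the etiological fraction applying at a variant's location (the
#' regional EF when the variant falls inside a detected cluster, else the
#' gene-level EF) to a PM1 evidence strength. The `"conservative"` scheme
#' uses EF >= 0.95 (OR >= 20) for strong, 0.90--0.95 (OR >= 10) for
#' moderate and 0.80--0.90 (OR >= 5) for supporting. The `"bayesian"`
#' scheme halves the odds exponent per tier (each ACMG level doubling the
#' weight of evidence): strong at EF >= 0.95 (odds 20), moderate at
#' EF >= 1 - 20^(-1/2) ~ 0.776, supporting at EF >= 1 - 20^(-1/4) ~ 0.527.
#'
#' @param ef Etiological fraction, finite.
#' @param scheme `"conservative"` (default) or `"bayesian"`.
#' @return `"strong"`, `"moderate"`, `"supporting"` or `"none"`.
#' @examples
#' pm1_tier(0.92)              # moderate
#' pm1_tier(0.79, "bayesian")  # moderate
#' @export
pm1_tier <- function(ef, scheme = c("conservative", "bayesian")) {
  scheme <- match.arg(scheme)
  if (!is.finite(ef)) stop("ef must be finite")
  cuts <- if (scheme == "conservative") c(0.80, 0.90, 0.95)
          else c(1 - 20^(-1 / 4), 1 - 20^(-1 / 2), 0.95)
  if (ef >= cuts[3]) "strong"
  else if (ef >= cuts[2]) "moderate"
  else if (ef >= cuts[1]) "supporting"
  else "none"
}

#' Bayesian-scaled PM1 EF thresholds
#'
#' Tier thresholds implied by a strong-evidence odds ratio of
#' `strong_or`, with each lower ACMG tier taking the square root of the
#' odds (halving the log-odds weight), converted to EF = (OR - 1)/OR.
#'
#' @param strong_or Odds ratio anchoring the strong tier (default 20).
#' @return Named numeric vector with `strong`, `moderate`, `supporting`
#'   EF thresholds and matching `or_*` entries.
#' @examples
#' pm1_bayesian_thresholds() # moderate EF 0.776 (OR 4.47), supporting 0.527 (OR 2.11)
#' @export
pm1_bayesian_thresholds <- function(strong_or = 20) {
  ors <- c(strong = strong_or, moderate = strong_or^(1 / 2),
           supporting = strong_or^(1 / 4))
  c(etiological_fraction(ors),
    stats::setNames(ors, paste0("or_", names(ors))))
}

#' A single activated ACMG/AMP evidence item
#'
#' @param rule_id One of PVS1, PS1, PS2, PS4, PM1, PM2, PM4, PM5, PM6,
#'   PP1, PP3.
#' @param strength `"supporting"`, `"moderate"`, `"strong"` or
#'   `"very_strong"`.
#' @return One-row data.frame with columns `rule` and `strength`.
#' @export
evidence_item <- function(rule_id, strength) {
  rules <- c("PVS1", "PS1", "PS2", "PS4", "PM1", "PM2", "PM4", "PM5", "PM6",
             "PP1", "PP3")
  strengths <- c("supporting", "moderate", "strong", "very_strong")
  if (!rule_id %in% rules) stop("unknown rule: ", rule_id)
  if (!strength %in% strengths) stop("unknown strength: ", strength)
  data.frame(rule = rule_id, strength = strength)
}

#' Variant annotation record for the rule engine
#'
#' Collects every input the supported ACMG/AMP rules read. Fields that do
#' not apply may be left `NA`/`NULL`; rules whose inputs are missing are
#' skipped with a notice rather than failing.
#'
#' @param gene Gene symbol.
#' @param consequence_class One of `"truncating"`, `"missense"`,
#'   `"inframe_indel"`, `"stop_lost"`, `"other"`.
#' @param rare Logical rarity verdict (PM2; see [is_rare()]).
#' @param case_count In-cohort carrier count of this exact variant (PS4).
#' @param fisher_p Per-variant Fisher exact p versus the reference (PS4).
#' @param predictor_calls Character vector of per-predictor calls,
#'   `"damaging"`/`"benign"`/`"unknown"` (PP3; 8 predictors expected).
#' @param meioses_observed Informative segregation meioses (PP1).
#' @param de_novo `"confirmed"`, `"assumed"` or `"none"` (PS2/PM6).
#' @param same_residue_pathogenic Different pathogenic missense at the
#'   same residue (PM5).
#' @param same_change_pathogenic Same amino-acid change established
#'   pathogenic (PS1).
#' @param region_ef EF applying at the variant's location (regional EF
#'   inside a cluster, else gene-level EF), or `NA` when unavailable (PM1).
#' @return Object of class `variant_annotation`.
#' @export
variant_annotation <- function(gene, consequence_class,
                               rare = NA, case_count = NA_integer_,
                               fisher_p = NA_real_, predictor_calls = NULL,
                               meioses_observed = NA_integer_,
                               de_novo = c("none", "confirmed", "assumed"),
                               same_residue_pathogenic = NA,
                               same_change_pathogenic = NA,
                               region_ef = NA_real_) {
  consequence_class <- match.arg(consequence_class,
    c("truncating", "missense", "inframe_indel", "stop_lost", "other"))
  de_novo <- match.arg(de_novo)
  structure(list(gene = gene, consequence_class = consequence_class,
                 rare = rare, case_count = case_count, fisher_p = fisher_p,
                 predictor_calls = predictor_calls,
                 meioses_observed = meioses_observed, de_novo = de_novo,
                 same_residue_pathogenic = same_residue_pathogenic,
                 same_change_pathogenic = same_change_pathogenic,
                 region_ef = region_ef),
            class = "variant_annotation")
}

#' Default rule-engine context
#'
#' @param pvs1_genes Genes in which truncating variants activate PVS1
#'   (loss of function an established disease mechanism; default: the HCM
#'   genes with a statistical excess of truncating variants).
#' @param ps4_p_threshold Fisher p threshold for PS4 (default 1.79e-6, a
#'   Bonferroni-corrected level; cohort-specific).
#' @param ps4_min_count Minimum case count (exclusive) for PS4 (default 2,
#'   i.e. case count > 2).
#' @param pm1_scheme PM1 tier scheme, see [pm1_tier()].
#' @return List of engine settings.
#' @export
acmg_context <- function(pvs1_genes = c("MYBPC3", "TNNT2", "TNNI3", "CSRP3",
                                        "FHL1", "PLN"),
                         ps4_p_threshold = 1.79e-6, ps4_min_count = 2,
                         pm1_scheme = c("conservative", "bayesian")) {
  list(pvs1_genes = pvs1_genes, ps4_p_threshold = ps4_p_threshold,
       ps4_min_count = ps4_min_count, pm1_scheme = match.arg(pm1_scheme))
}

# PP3: of the predictors assessed, at most one predicts benign with fewer
# than three unknowns; or, with three or more unknowns, none predicts benign.
pp3_active <- function(calls) {
  n_benign <- sum(calls == "benign")
  n_unknown <- sum(calls == "unknown")
  (n_unknown < 3 && n_benign <= 1) || (n_unknown >= 3 && n_benign == 0)
}

#' Activate ACMG/AMP rules for one variant
#'
#' Evaluates the supported pathogenic-direction rules against a
#' [variant_annotation()]:
#' \describe{
#'   \item{PM2 (moderate)}{rarity verdict true (filtering allele frequency
#'     below the disease threshold).}
#'   \item{PVS1 (very strong)}{truncating variant in a configured
#'     loss-of-function gene.}
#'   \item{PS4 (strong)}{case count above the minimum and per-variant
#'     Fisher p below the threshold.}
#'   \item{PM4 (moderate)}{protein-length-changing variant (inframe indel
#'     or stop lost).}
#'   \item{PP3 (supporting)}{missense with computational consensus (at
#'     most one benign call and fewer than three unknowns, or all
#'     non-unknown damaging when three or more unknowns).}
#'   \item{PS1 (strong) / PM5 (moderate)}{same amino-acid change / same
#'     residue established pathogenic; PS1 takes precedence.}
#'   \item{PP1 (supporting/moderate/strong)}{segregation at >= 3 / >= 5 /
#'     >= 7 informative meioses.}
#'   \item{PS2 (strong) / PM6 (moderate)}{de novo with / without confirmed
#'     parentage.}
#'   \item{PM1 (tiered)}{EF-calibrated region rule via [pm1_tier()]; only
#'     evaluated for non-truncating variants when PM2 is active and a
#'     regional/gene EF is available.}
#' }
#' PS3 (functional data) is never emitted. A rule whose required
#' annotation is missing is skipped with a notice.
#'
#' @param annotation A [variant_annotation()].
#' @param context An [acmg_context()].
#' @return data.frame of activated evidence with columns `rule`,
#'   `strength` (zero rows when nothing activates).
#' @export
activate_rules <- function(annotation, context = acmg_context()) {
  stopifnot(inherits(annotation, "variant_annotation"))
  ev <- list()
  add <- function(rule, strength) ev[[length(ev) + 1]] <<- evidence_item(rule, strength)
  skip <- function(rule, field)
    message("rule ", rule, " skipped: annotation field '", field, "' missing")

  a <- annotation
  pm2 <- isTRUE(a$rare)
  if (is.na(a$rare)) skip("PM2", "rare") else if (pm2) add("PM2", "moderate")

  if (a$consequence_class == "truncating" && a$gene %in% context$pvs1_genes)
    add("PVS1", "very_strong")

  if (is.na(a$case_count) || is.na(a$fisher_p)) {
    skip("PS4", "case_count/fisher_p")
  } else if (a$case_count > context$ps4_min_count &&
             a$fisher_p < context$ps4_p_threshold) {
    add("PS4", "strong")
  }

  if (a$consequence_class %in% c("inframe_indel", "stop_lost"))
    add("PM4", "moderate")

  if (a$consequence_class == "missense") {
    if (is.null(a$predictor_calls)) skip("PP3", "predictor_calls")
    else if (pp3_active(a$predictor_calls)) add("PP3", "supporting")

    if (isTRUE(a$same_change_pathogenic)) add("PS1", "strong")
    else if (isTRUE(a$same_residue_pathogenic)) add("PM5", "moderate")
  }

  if (!is.na(a$meioses_observed)) {
    if (a$meioses_observed >= 7) add("PP1", "strong")
    else if (a$meioses_observed >= 5) add("PP1", "moderate")
    else if (a$meioses_observed >= 3) add("PP1", "supporting")
  }

  if (a$de_novo == "confirmed") add("PS2", "strong")
  if (a$de_novo == "assumed") add("PM6", "moderate")

  if (a$consequence_class != "truncating" && pm2) {
    if (is.na(a$region_ef)) {
      skip("PM1", "region_ef")
    } else {
      tier <- pm1_tier(a$region_ef, context$pm1_scheme)
      if (tier != "none") add("PM1", tier)
    }
  }

  if (!length(ev)) return(data.frame(rule = character(), strength = character()))
  do.call(rbind, ev)
}

#' Combine pathogenic-direction evidence into a five-tier classification
#'
#' Applies the ACMG/AMP combining table along the pathogenic axis
#' (benign-direction rules are out of scope; anything short of likely
#' pathogenic is a VUS):
#' \itemize{
#'   \item Pathogenic: >= 2 very strong; 1 very strong with (>= 1 strong,
#'     or >= 1 moderate, or >= 2 supporting); >= 2 strong; 1 strong with
#'     (>= 3 moderate, or 2 moderate + >= 2 supporting, or 1 moderate +
#'     >= 4 supporting).
#'   \item Likely pathogenic: 1 very strong + 1 supporting; 1 strong with
#'     1--2 moderate; 1 strong + >= 2 supporting; >= 3 moderate;
#'     2 moderate + >= 2 supporting; 1 moderate + >= 4 supporting.
#'   \item Otherwise VUS.
#' }
#'
#' @param evidence data.frame with `rule` and `strength` columns (e.g.
#'   from [activate_rules()]); at most one item per rule.
#' @return `"pathogenic"`, `"likely_pathogenic"` or `"VUS"`.
#' @examples
#' combine_evidence(rbind(evidence_item("PM1", "strong"),
#'                        evidence_item("PM2", "moderate"))) # likely_pathogenic
#' @export
combine_evidence <- function(evidence) {
  if (is.null(evidence) || !nrow(evidence)) return("VUS")
  if (anyDuplicated(evidence$rule)) stop("each rule may appear at most once")
  vs <- sum(evidence$strength == "very_strong")
  s <- sum(evidence$strength == "strong")
  m <- sum(evidence$strength == "moderate")
  p <- sum(evidence$strength == "supporting")
  pathogenic <- vs >= 2 ||
    (vs == 1 && (s >= 1 || m >= 1 || p >= 2)) ||
    s >= 2 ||
    (s == 1 && (m >= 3 || (m == 2 && p >= 2) || (m == 1 && p >= 4)))
  if (pathogenic) return("pathogenic")
  likely <- (vs == 1 && p >= 1) ||
    (s == 1 && m >= 1) ||
    (s == 1 && p >= 2) ||
    m >= 3 ||
    (m == 2 && p >= 2) ||
    (m == 1 && p >= 4)
  if (likely) return("likely_pathogenic")
  "VUS"
}

#' Classify one variant end to end
#'
#' @param annotation A [variant_annotation()].
#' @param context An [acmg_context()].
#' @return List with `classification` and the activated `evidence`.
#' @export
classify_variant <- function(annotation, context = acmg_context()) {
  evidence <- activate_rules(annotation, context)
  list(classification = combine_evidence(evidence), evidence = evidence)
}

#' Reclassification report under EF-calibrated rules
#'
#' Re-evaluates a set of variants with the EF-calibrated tiered PM1 rule
#' and reports which previously assigned classifications change towards
#' pathogenic (typically VUS upgraded to likely pathogenic for missense
#' variants in EF >= 0.95 regions and inframe indels in EF >= 0.90
#' regions).
#'
#' @param annotations List of [variant_annotation()] objects.
#' @param prior Character vector of prior classifications, same length
#'   (`"pathogenic"`, `"likely_pathogenic"`, `"VUS"`, `"likely_benign"`,
#'   `"benign"`).
#' @param context An [acmg_context()].
#' @return List with `n_upgraded`, a data.frame `upgrades` (gene, prior,
#'   revised classification), a per-gene upgrade count table `by_gene`,
#'   and the full per-variant `revised` classifications.
#' @export
upgrade_report <- function(annotations, prior, context = acmg_context()) {
  stopifnot(length(annotations) == length(prior))
  levels5 <- c("benign", "likely_benign", "VUS", "likely_pathogenic", "pathogenic")
  if (!all(prior %in% levels5)) stop("unknown prior classification")
  revised <- vapply(annotations,
                    function(a) classify_variant(a, context)$classification,
                    character(1))
  rank5 <- function(x) match(x, levels5)
  upgraded <- rank5(revised) > rank5(prior)
  genes <- vapply(annotations, `[[`, character(1), "gene")
  upgrades <- data.frame(gene = genes[upgraded], prior = prior[upgraded],
                         revised = revised[upgraded])
  list(n_upgraded = sum(upgraded),
       upgrades = upgrades,
       by_gene = if (nrow(upgrades)) table(upgrades$gene) else table(character()),
       revised = revised)
}
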