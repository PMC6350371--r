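#' Read a per-gene burden count table
#'
#' Tab-separated with header columns `gene`, `variant_class`
#' (`truncating`/`non_truncating`), `case_carriers`, `n_cases`,
#' `ref_carriers`, `ref_n`. Malformed rows are reported with their line
#' numbers.
#'
#' @param path File path.
#' @return data.frame of validated records.
#' @export
read_burden_table <- function(path) {
  req <- c("gene", "variant_class", "case_carriers", "n_cases",
           "ref_carriers", "ref_n")
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(req %in% names(x)))
    stop("burden table must have columns: ", paste(req, collapse = ", "))
  bad <- which(!x$variant_class %in% c("truncating", "non_truncating"))
  count_cols <- c("case_carriers", "n_cases", "ref_carriers", "ref_n")
  for (col in count_cols)
    bad <- union(bad, which(is.na(x[[col]]) | x[[col]] < 0 | x[[col]] != round(x[[col]])))
  bad <- union(bad, which(x$case_carriers > x$n_cases | x$ref_carriers > x$ref_n))
  if (length(bad))
    stop("malformed burden rows (file lines): ",
         paste(sort(bad) + 1L, collapse = ", "))
  x
}

#' Burden estimates for every row of a count table
#'
#' @param counts data.frame from [read_burden_table()].
#' @param level Confidence level.
#' @return data.frame with one row per gene/class: point estimates, CIs,
#'   p-values and formatted report columns (frequencies as
#'   `"x.xx% (a/n)"`, OR to 1 d.p. with CI, EF to 3 d.p. with CI).
#' @export
burden_report <- function(counts, level = 0.95) {
  fmt_freq <- function(k, n) sprintf("%.2f%% (%d/%d)", 100 * k / n, k, n)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    est <- burden_estimate(r$case_carriers, r$n_cases, r$ref_carriers, r$ref_n,
                           level)
    data.frame(
      gene = r$gene, variant_class = r$variant_class,
      case_freq = fmt_freq(r$case_carriers, r$n_cases),
      ref_freq = fmt_freq(r$ref_carriers, r$ref_n),
      p_value = est$p_value,
      odds_ratio = est$odds_ratio,
      or_low = est$or_ci[[1]], or_high = est$or_ci[[2]],
      ef = est$ef, ef_low = est$ef_ci[[1]], ef_high = est$ef_ci[[2]],
      or_formatted = sprintf("%.1f (%.1f-%.1f)",
                             round_half_away(est$odds_ratio, 1),
                             round_half_away(est$or_ci[[1]], 1),
                             round_half_away(est$or_ci[[2]], 1)),
      ef_formatted = sprintf("%.3f (%.3f-%.3f)",
                             round_half_away(est$ef, 3),
                             round_half_away(est$ef_ci[[1]], 3),
                             round_half_away(est$ef_ci[[2]], 3)),
      zero_cell_corrected = est$zero_cell_corrected)
  })
  do.call(rbind, rows)
}

#' Write a burden report
#'
#' @param report data.frame from [burden_report()].
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_burden_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(report, path, dataframe = "rows", digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read per-protein variant positions
#'
#' Tab-separated with header columns `gene`, `protein_length`,
#' `residue_position`, `cohort` (`case`/`control`), `n_carriers` (one row
#' per distinct variant).
#'
#' @param path File path.
#' @return Named list (one element per gene) of lists with `case` and
#'   `control` [variant_positions()] (either may be `NULL`).
#' @export
read_variant_positions <- function(path) {
  req <- c("gene", "protein_length", "residue_position", "cohort", "n_carriers")
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(req %in% names(x)))
    stop("variant position table must have columns: ", paste(req, collapse = ", "))
  bad <- which(is.na(x$residue_position) | x$residue_position < 1 |
                 x$residue_position > x$protein_length |
                 !x$cohort %in% c("case", "control") |
                 is.na(x$n_carriers) | x$n_carriers < 1)
  if (length(bad))
    stop("malformed variant position rows (file lines): ",
         paste(sort(bad) + 1L, collapse = ", "))
  out <- list()
  for (g in unique(x$gene)) {
    xg <- x[x$gene == g, ]
    L <- unique(xg$protein_length)
    if (length(L) != 1) stop("inconsistent protein_length for gene ", g)
    per_cohort <- function(co) {
      xc <- xg[xg$cohort == co, ]
      if (!nrow(xc)) return(NULL)
      variant_positions(L, xc$residue_position, co, xc$n_carriers)
    }
    out[[g]] <- list(case = per_cohort("case"), control = per_cohort("control"))
  }
  out
}

#' Write a variant-position table
#'
#' Inverse of [read_variant_positions()].
#'
#' @param positions Named list as returned by [read_variant_positions()].
#' @param path Output path.
#' @export
write_variant_positions <- function(positions, path) {
  rows <- list()
  for (g in names(positions)) {
    for (v in positions[[g]]) {
      if (is.null(v) || !length(v$positions)) next
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, protein_length = v$protein_length,
        residue_position = v$positions, cohort = v$cohort,
        n_carriers = v$carriers)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), protein_length = integer(),
               residue_position = integer(), cohort = character(),
               n_carriers = integer())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write detected clusters
#'
#' `"tsv"` keeps the internal 1-based inclusive residue coordinates;
#' `"bed"` converts to 0-based half-open intervals at the boundary
#' (start - 1, end), with the corrected p-value in the score column slot.
#'
#' @param clusters data.frame from [detect_clusters()] (optionally with a
#'   `gene` column).
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @export
write_clusters <- function(clusters, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(clusters, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    gene <- if ("gene" %in% names(clusters)) clusters$gene else
      rep(".", nrow(clusters))
    bed <- data.frame(chrom = gene,
                      chromStart = clusters$start - 1L,
                      chromEnd = clusters$end,
                      name = paste0(clusters$cohort, "_cluster"),
                      score = signif(clusters$p_corrected, 4))
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a disease-model configuration (YAML or JSON)
#'
#' Expects fields `prevalence`, `allelic_heterogeneity`, `penetrance`,
#' `inheritance`. Prevalence may be given as a string ratio like
#' `"1/500"`.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A [disease_model()].
#' @export
read_disease_model <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  as_frac <- function(x) {
    if (is.character(x) && grepl("/", x)) {
      parts <- as.numeric(strsplit(x, "/", fixed = TRUE)[[1]])
      return(parts[1] / parts[2])
    }
    as.numeric(x)
  }
  disease_model(as_frac(cfg$prevalence), as_frac(cfg$allelic_heterogeneity),
                as_frac(cfg$penetrance), cfg$inheritance)
}

#' Run the full analysis pipeline
#'
#' Orchestrates burden estimation, cluster detection, regional EFs and
#' (optionally) variant classification from a configuration list or YAML
#' file. Deterministic given the configuration; every threshold used is
#' echoed via `message()`.
#'
#' Configuration fields: `burden_table` (path, required), `positions`
#' (path, optional), `annotations` (JSON path, optional: an array of
#' variant-annotation records, each optionally carrying a `prior`
#' classification), `disease_model` (path, optional, echoed), `alpha`
#' (default 0.05), `level` (default 0.95), `out_dir` (optional: writes
#' `burden.tsv`, `clusters.tsv` and `classifications.json`).
#'
#' @param config List or path to a YAML configuration file.
#' @return List with elements `burden`, `clusters`, `regional`,
#'   `classifications`, `upgrades` (elements `NULL` when the relevant
#'   input was not supplied).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  level <- if (is.null(config$level)) 0.95 else config$level
  message("alpha = ", alpha, "; confidence level = ", level)
  if (!is.null(config$disease_model)) {
    dm <- read_disease_model(config$disease_model)
    message("maximum credible allele frequency = ", max_credible_af(dm))
  }

  counts <- read_burden_table(config$burden_table)
  burden <- burden_report(counts, level)

  clusters <- NULL
  regional <- NULL
  if (!is.null(config$positions)) {
    genes <- read_variant_positions(config$positions)
    cfg <- scan_config(alpha = alpha)
    cl_list <- list()
    regional <- list()
    for (g in names(genes)) {
      cl <- detect_clusters(genes[[g]]$case, genes[[g]]$control, cfg)
      if (nrow(cl)) cl_list[[g]] <- cbind(gene = g, cl)
      case_cl <- cl[cl$cohort == "case", , drop = FALSE]
      idx <- which(counts$gene == g & counts$variant_class == "non_truncating")
      if (nrow(case_cl) && length(idx) == 1 && !is.null(genes[[g]]$control)) {
        regional[[g]] <- regional_ef(case_cl, genes[[g]]$case,
                                     genes[[g]]$control,
                                     counts$n_cases[idx], counts$ref_n[idx],
                                     level)
      }
    }
    clusters <- if (length(cl_list)) do.call(rbind, cl_list) else
      data.frame()
    rownames(clusters) <- NULL
  }

  classifications <- NULL
  upgrades <- NULL
  if (!is.null(config$annotations)) {
    recs <- jsonlite::read_json(config$annotations, simplifyVector = FALSE)
    ctx_args <- config$acmg
    ctx <- do.call(acmg_context, if (is.null(ctx_args)) list() else ctx_args)
    anns <- lapply(recs, function(r) {
      r$prior <- NULL
      do.call(variant_annotation, r)
    })
    prior <- vapply(recs, function(r)
      if (is.null(r$prior)) "VUS" else r$prior, character(1))
    classifications <- data.frame(
      gene = vapply(anns, `[[`, character(1), "gene"),
      prior = prior,
      classification = vapply(anns, function(a)
        classify_variant(a, ctx)$classification, character(1)))
    upgrades <- upgrade_report(anns, prior, ctx)
  }

  out <- list(burden = burden, clusters = clusters, regional = regional,
              classifications = classifications, upgrades = upgrades)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_burden_report(burden, file.path(config$out_dir, "burden.tsv"))
    if (!is.null(clusters))
      write_clusters(clusters, file.path(config$out_dir, "clusters.tsv"))
    if (!is.null(classifications))
      jsonlite::write_json(classifications,
                           file.path(config$out_dir, "classifications.json"),
                           dataframe = "rows", digits = NA, pretty = TRUE)
  }
  out
}
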