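# Candidate-gene screens over differential-expression tables.
#
# DE statistics are consumed, not computed: the screens sit downstream of
# an external (or simulated) per-contrast table of base means, log2 fold
# changes, adjusted p-values and biotypes. All screens are monotone in
# their thresholds: tightening a gate never adds genes.

check_de <- function(records) {
  records <- as_tibble(records)
  check_columns(records, c("gene", "contrast", "base_mean", "log2fc",
                           "padj", "biotype"), "DE table")
  key <- paste(records$gene, records$contrast)
  if (anyDuplicated(key) > 0) {
    abort(sprintf("DE table has duplicated gene x contrast row(s), e.g.: %s",
                  key[anyDuplicated(key)]))
  }
  records
}

#' Expression-floor screen
#'
#' Genes with RPKM strictly above `min_rpkm` in at least `min_conditions`
#' conditions.
#'
#' @param rpkm_cond Long tibble with `gene` and `rpkm` columns (one row per
#'   gene x condition), e.g. from [condition_rpkm()].
#' @param min_rpkm Expression floor (default 1).
#' @param min_conditions Minimum qualifying conditions (default 1).
#' @return Character vector of genes, sorted.
#' @export
screen_expression <- function(rpkm_cond, min_rpkm = 1, min_conditions = 1) {
  check_columns(rpkm_cond, c("gene", "rpkm"), "RPKM table")
  rpkm_cond %>%
    group_by(.data$gene) %>%
    summarise(n_pass = sum(!is.na(.data$rpkm) & .data$rpkm > min_rpkm)) %>%
    filter(.data$n_pass >= min_conditions) %>%
    pull("gene") %>%
    sort()
}

#' Differential-expression screen
#'
#' Per contrast, keeps genes with `padj` strictly below `padj_max`
#' (records with missing `padj` are excluded), `|log2fc| >= lfc_min`,
#' `base_mean >= min_reads`, and -- if `protein_coding_only` --
#' `biotype == "protein_coding"`.
#'
#' @param records DE tibble (`gene`, `contrast`, `base_mean`, `log2fc`,
#'   `padj`, `biotype`).
#' @param padj_max Strict adjusted-p ceiling (default 0.05).
#' @param lfc_min Minimum absolute log2 fold change (default 1.0).
#' @param min_reads Minimum base mean (default 20).
#' @param protein_coding_only Restrict to protein-coding genes
#'   (default `TRUE`).
#' @return Tibble `contrast`, `gene` of passing records.
#' @export
screen_de <- function(records, padj_max = 0.05, lfc_min = 1.0, min_reads = 20,
                      protein_coding_only = TRUE) {
  records <- check_de(records)
  records %>%
    filter(!is.na(.data$padj), .data$padj < padj_max,
           abs(.data$log2fc) >= lfc_min,
           .data$base_mean >= min_reads,
           !protein_coding_only | .data$biotype == "protein_coding") %>%
    select("contrast", "gene") %>%
    arrange(.data$contrast, .data$gene)
}

#' Stage-wise intersection screen
#'
#' Genes meeting `padj < padj_max` in *all* listed contrasts (e.g. every
#' involution stage of one cell type), with non-protein-coding genes
#' removed when `coding_only`.
#'
#' @param records DE tibble.
#' @param contrasts Character vector of contrasts that must all be present.
#' @param padj_max Strict adjusted-p ceiling (default `1e-17`).
#' @param coding_only Drop non-protein-coding genes (default `TRUE`).
#' @return Character vector of genes, sorted.
#' @export
intersect_involution <- function(records, contrasts, padj_max = 1e-17,
                                 coding_only = TRUE) {
  records <- check_de(records)
  missing <- setdiff(contrasts, unique(records$contrast))
  if (length(missing) > 0) {
    abort(sprintf("DE table is missing contrast(s): %s",
                  paste(missing, collapse = ", ")))
  }
  hits <- records %>%
    filter(.data$contrast %in% contrasts,
           !is.na(.data$padj), .data$padj < padj_max,
           !coding_only | .data$biotype == "protein_coding") %>%
    count(.data$gene) %>%
    filter(.data$n == length(contrasts)) %>%
    pull("gene")
  sort(hits)
}

#' Two-stage top-candidate selection
#'
#' Within one contrast: restrict to significant records
#' (`padj < padj_max`), keep the top `ceiling(top_frac * n_significant)`
#' by the first-stage metric (`"padj"`: smallest adjusted p;
#' `"lfc"`: largest `|log2fc|`), then return up to `top_k` of those ranked
#' by `|log2fc|`, ties broken by (`|log2fc|` descending, `padj` ascending,
#' gene id ascending). Deterministic.
#'
#' @param records DE tibble for a single contrast (or pre-filtered).
#' @param top_frac First-stage quantile (default 0.01).
#' @param top_k Final list size (default 50).
#' @param padj_max Significance gate defining the candidate pool
#'   (default 0.05).
#' @param rank_stage1 First-stage metric, `"padj"` (default) or `"lfc"`.
#' @return Tibble of the selected records, in rank order, with a `rank`
#'   column.
#' @export
top_candidates <- function(records, top_frac = 0.01, top_k = 50,
                           padj_max = 0.05, rank_stage1 = c("padj", "lfc")) {
  rank_stage1 <- match.arg(rank_stage1)
  records <- check_de(records)
  if (length(unique(records$contrast)) > 1) {
    abort("top_candidates() expects records from a single contrast")
  }
  sig <- filter(records, !is.na(.data$padj), .data$padj < padj_max)
  if (nrow(sig) == 0) return(mutate(sig, rank = integer(0)))
  n_keep <- ceiling(top_frac * nrow(sig))
  pool <- if (rank_stage1 == "padj") {
    arrange(sig, .data$padj, desc(abs(.data$log2fc)), .data$gene)
  } else {
    arrange(sig, desc(abs(.data$log2fc)), .data$padj, .data$gene)
  }
  pool <- head(pool, n_keep)
  pool %>%
    arrange(desc(abs(.data$log2fc)), .data$padj, .data$gene) %>%
    head(top_k) %>%
    mutate(rank = row_number())
}

#' Average log2 fold change across contrasts
#'
#' Arithmetic mean of `log2fc` over the listed contrasts; fold changes are
#' averaged on the log2 scale.
#'
#' @param records DE tibble.
#' @param gene Gene id (scalar).
#' @param contrasts Contrasts to average over; the gene must be present in
#'   every one.
#' @return Numeric scalar.
#' @export
average_log2fc <- function(records, gene, contrasts) {
  records <- check_de(records)
  sel <- filter(records, .data$gene == !!gene, .data$contrast %in% contrasts)
  missing <- setdiff(contrasts, sel$contrast)
  if (length(missing) > 0) {
    abort(sprintf("gene %s is missing from contrast(s): %s",
                  gene, paste(missing, collapse = ", ")))
  }
  mean(sel$log2fc)
}
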