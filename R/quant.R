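# Read-to-allele assignment at diagnostic positions, and gene-level
# allelic count matrices.
#
# Assignment scores each haplotype by the number of matching bases at the
# diagnostic positions the read covers (alternate-haplotype offsets via the
# coordinate map); the strictly higher score wins, and ties or reads
# covering no diagnostic position are ambiguous. This exact, diagnostic-site
# scoring stands in for EM-based diploid quantification, which distributes
# multi-mapping reads probabilistically; at transcript scale with planted
# SNPs the two agree by construction, on real data they can differ.

#' Assign reads to haplotypes at diagnostic positions
#'
#' @param reads Tibble with columns `gene` (transcript of origin), `start`
#'   (1-based position on the reference haplotype) and `seq`.
#' @param diploid A [build_diploid()] object.
#' @return The input tibble with an `assignment` column
#'   (`"B"`, `"C"` or `"ambiguous"`).
#' @export
assign_reads <- function(reads, diploid) {
  stopifnot(inherits(diploid, "diploid_transcriptome"))
  check_columns(reads, c("gene", "start", "seq"), "reads table")
  if (nrow(reads) == 0) {
    return(mutate(reads, assignment = character(0)))
  }
  out <- character(nrow(reads))
  for (tx in unique(reads$gene)) {
    entry <- diploid[[tx]]
    if (is.null(entry)) {
      abort(sprintf("read references transcript '%s' absent from the diploid transcriptome", tx))
    }
    idx <- which(reads$gene == tx)
    out[idx] <- assign_reads_one_tx(reads$seq[idx], reads$start[idx], entry, tx)
  }
  mutate(reads, assignment = out)
}

#' @rdname assign_reads
#' @param seq,start,transcript A single read's sequence, reference start and
#'   transcript id (scalar interface).
#' @export
assign_read <- function(seq, start, transcript, diploid) {
  assign_reads(tibble(gene = transcript, start = start, seq = seq),
               diploid)$assignment
}

assign_reads_one_tx <- function(seqs, starts, entry, tx) {
  L <- nchar(seqs)
  ref_len <- nchar(entry$ref_seq)
  if (any(starts < 1) || any(starts + L - 1 > ref_len)) {
    abort(sprintf("read outside the bounds of transcript '%s'", tx))
  }
  diag <- entry$diagnostic_positions
  res <- rep("ambiguous", length(seqs))
  if (length(diag) == 0) return(res)
  for (i in seq_along(seqs)) {
    d <- diag[diag >= starts[i] & diag <= starts[i] + L[i] - 1]
    if (length(d) == 0) next
    off_b <- d - starts[i] + 1L
    read_b <- substring(seqs[i], off_b, off_b)
    score_b <- sum(read_b == substring(entry$ref_seq, d, d))
    # anchor the read in alternate coordinates; if its start is deleted on
    # the alternate haplotype, extrapolate from the nearest mapped base
    alt_anchor <- entry$ref_to_alt[starts[i]]
    if (is.na(alt_anchor)) {
      nxt <- starts[i]
      while (nxt <= ref_len && is.na(entry$ref_to_alt[nxt])) nxt <- nxt + 1L
      if (nxt > ref_len) { res[i] <- if (score_b > 0) "B" else "ambiguous"; next }
      alt_anchor <- entry$ref_to_alt[nxt] - (nxt - starts[i])
    }
    alt_pos <- entry$ref_to_alt[d]
    off_c <- alt_pos - alt_anchor + 1L
    keep <- !is.na(off_c) & off_c >= 1 & off_c <= L[i]
    score_c <- if (any(keep)) {
      sum(substring(seqs[i], off_c[keep], off_c[keep]) ==
            substring(entry$alt_seq, alt_pos[keep], alt_pos[keep]))
    } else 0
    res[i] <- if (score_b > score_c) "B" else if (score_c > score_b) "C" else "ambiguous"
  }
  res
}

#' Count allele assignments per gene and sample
#'
#' Sums read assignments into a long allelic count table. With
#' `policy = "discard"` (default) ambiguous reads are recorded in the
#' `ambiguous` layer only, keeping `count_B`/`count_C` integer; with
#' `policy = "split"` each ambiguous read contributes half a count to each
#' allele. In either case
#' `count_B + count_C + ambiguous` equals the number of assigned reads.
#'
#' @param reads Reads tibble (needs `gene`, `sample`, `start`, `seq`); if an
#'   `assignment` column is present it is used, otherwise [assign_reads()]
#'   is called.
#' @param diploid A [build_diploid()] object.
#' @param samples Sample sheet; every read's sample must appear in it.
#' @param policy `"discard"` or `"split"`.
#' @param tx2gene Optional named character vector mapping transcript ids to
#'   gene ids; must be a function (no transcript maps to two genes). Default
#'   is the identity (one transcript per gene).
#' @return Tibble `gene`, `sample`, `count_B`, `count_C`, `ambiguous`,
#'   complete over genes x sheet samples (zeros filled in).
#' @export
count_alleles <- function(reads, diploid, samples, policy = c("discard", "split"),
                          tx2gene = NULL) {
  policy <- match.arg(policy)
  samples <- check_samples(samples)
  check_columns(reads, c("gene", "sample"), "reads table")
  unknown <- setdiff(unique(reads$sample), samples$sample)
  if (length(unknown) > 0) {
    abort(sprintf("read sample(s) absent from the sample sheet: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  if (!is.null(tx2gene)) {
    if (is.null(names(tx2gene)) || anyDuplicated(names(tx2gene)) > 0) {
      abort("tx2gene must be a named vector with unique transcript names")
    }
  }
  if (!"assignment" %in% names(reads)) {
    reads <- assign_reads(reads, diploid)
  }
  map_gene <- function(tx) if (is.null(tx2gene)) tx else unname(tx2gene[tx])
  genes <- sort(unique(map_gene(names(diploid))))
  tallied <- reads %>%
    mutate(gene = map_gene(.data$gene)) %>%
    count(.data$gene, .data$sample, .data$assignment) %>%
    tidyr::pivot_wider(names_from = "assignment", values_from = "n",
                       values_fill = 0L)
  for (col in c("B", "C", "ambiguous")) {
    if (!col %in% names(tallied)) tallied[[col]] <- 0L
  }
  full <- tidyr::expand_grid(gene = genes, sample = samples$sample) %>%
    left_join(tallied, by = c("gene", "sample")) %>%
    mutate(across(c("B", "C", "ambiguous"), ~ tidyr::replace_na(.x, 0L)))
  if (policy == "split") {
    full <- mutate(full,
      count_B = .data$B + .data$ambiguous / 2,
      count_C = .data$C + .data$ambiguous / 2,
      ambiguous = 0
    )
  } else {
    full <- rename(full, count_B = "B", count_C = "C")
  }
  select(full, "gene", "sample", "count_B", "count_C", "ambiguous")
}

#' Load and validate a long-format allelic count table
#'
#' Entry point for precomputed allelic counts (e.g. from an external
#' diploid quantifier). Missing gene x sample pairs are filled with zeros
#' over the full grid of observed genes and sheet samples.
#'
#' @param counts Path to a TSV with columns `gene`, `sample`, `count_B`,
#'   `count_C` (optionally `ambiguous`), or an equivalent data frame.
#' @param samples Sample sheet tibble or TSV path.
#' @return Validated, zero-completed tibble.
#' @export
load_counts <- function(counts, samples) {
  if (is.character(counts)) {
    counts <- readr::read_tsv(counts, show_col_types = FALSE)
  }
  if (is.character(samples)) samples <- read_samples(samples)
  samples <- check_samples(samples)
  counts <- as_tibble(counts)
  check_columns(counts, c("gene", "sample", "count_B", "count_C"), "count table")
  if (any(counts$count_B < 0) || any(counts$count_C < 0)) {
    abort("count table contains negative counts")
  }
  dup <- counts %>% count(.data$gene, .data$sample) %>% filter(n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate (gene, sample) row(s): %s",
                  paste(head(paste0(dup$gene, "/", dup$sample), 5), collapse = ", ")))
  }
  unknown <- setdiff(unique(counts$sample), samples$sample)
  if (length(unknown) > 0) {
    abort(sprintf("count sample(s) absent from the sample sheet: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  if (nrow(counts) == 0) return(counts)
  keep <- intersect(c("gene", "sample", "count_B", "count_C", "ambiguous"),
                    names(counts))
  counts <- select(counts, dplyr::all_of(keep))
  tidyr::expand_grid(gene = sort(unique(counts$gene)), sample = samples$sample) %>%
    left_join(counts, by = c("gene", "sample")) %>%
    mutate(across(-c("gene", "sample"), ~ tidyr::replace_na(.x, 0)))
}
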