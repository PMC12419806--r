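# Shared fixture builders: everything is generated in code at test time.

# A one-condition reciprocal design: n_rep replicates per cross.
tiny_samples <- function(n_rep = 4, cell_type = "basal", stage = "nulliparous") {
  tidyr::expand_grid(cross = c("BC", "CB"), replicate = seq_len(n_rep)) |>
    dplyr::mutate(
      sample = sprintf("%s_r%d", cross, replicate),
      cell_type = cell_type, stage = stage, .before = 1
    ) |>
    dplyr::select(sample, cross, cell_type, stage, replicate)
}

# Counts for one gene from per-replicate (B, C) pairs aligned with a sheet.
counts_from_pairs <- function(gene, samples, b, c) {
  tibble::tibble(gene = gene, sample = samples$sample,
                 count_B = as.integer(b), count_C = as.integer(c))
}

# Deterministic maternal-fraction counts: total reads per replicate and a
# maternal fraction, oriented by each sample's cross.
counts_from_fraction <- function(gene, samples, total, maternal_fraction) {
  m <- round(total * maternal_fraction)
  b <- ifelse(samples$cross == "BC", m, total - m)
  counts_from_pairs(gene, samples, b, total - b)
}

# Random toy transcriptome with SNP-only variants (used by quant tests).
toy_diploid <- function(n_tx = 3, len = 120, n_snp = 4, seed = 1) {
  cfg <- sim_config(n_genes = n_tx, transcript_length_range = c(len, len),
                    snps_per_transcript = n_snp, seed = seed)
  tx <- simulate_transcriptome(cfg)
  list(diploid = build_diploid(tx$reference, tx$variants),
       reference = tx$reference, variants = tx$variants)
}

# Independent oracle: rebuild an edited sequence by slicing between sorted
# variants (no coordinate bookkeeping shared with the implementation).
oracle_apply_variants <- function(ref, variants) {
  variants <- variants[order(variants$pos), , drop = FALSE]
  out <- ""
  cursor <- 1
  for (i in seq_len(nrow(variants))) {
    out <- paste0(out, substr(ref, cursor, variants$pos[i] - 1), variants$alt[i])
    cursor <- variants$pos[i] + nchar(variants$ref[i])
  }
  paste0(out, substr(ref, cursor, nchar(ref)))
}

# Independent oracle: exhaustive two-sided sign-flip p-value by enumerating
# every sign assignment explicitly.
oracle_exhaustive_p <- function(f) {
  dev <- f - 0.5
  n <- length(dev)
  hits <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- ifelse(bitwAnd(mask, 2^(0:(n - 1))) > 0, 1, -1)
    if (abs(mean(signs * dev)) >= abs(mean(dev)) - 1e-12) hits <- hits + 1L
  }
  hits / 2^n
}

# Random non-overlapping variants (SNPs and anchored indels) for round-trip
# tests of the diploid builder.
random_variants <- function(ref, n_var) {
  len <- nchar(ref)
  bases <- c("A", "C", "G", "T")
  vars <- list()
  taken <- rep(FALSE, len)
  tries <- 0
  while (length(vars) < n_var && tries < 200) {
    tries <- tries + 1
    kind <- sample(c("snp", "ins", "del"), 1)
    span <- if (kind == "del") sample(2:4, 1) else 1
    pos <- sample.int(len - span + 1, 1)
    if (any(taken[pos:(pos + span - 1)])) next
    refa <- substr(ref, pos, pos + span - 1)
    alta <- switch(kind,
      snp = sample(setdiff(bases, refa), 1),
      ins = paste0(refa, paste(sample(bases, sample(1:3, 1), replace = TRUE),
                               collapse = "")),
      del = substr(refa, 1, 1)
    )
    taken[pos:(pos + span - 1)] <- TRUE
    vars[[length(vars) + 1]] <- tibble::tibble(pos = pos, ref = refa, alt = alta)
  }
  if (length(vars) == 0) {
    return(tibble::tibble(pos = integer(), ref = character(), alt = character()))
  }
  dplyr::arrange(dplyr::bind_rows(vars), pos)
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
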