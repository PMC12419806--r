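# Strain-aware ("diploid") transcript construction.
#
# Haplotype B is the reference-like strain, haplotype C carries the variants.
# Which haplotype is maternal is decided by each sample's cross label, never
# by the sequence itself. Input variants use 1-based VCF conventions with
# anchored-base indels (ref "A", alt "AGG" is an insertion after the anchor).

#' Apply variants to a reference transcript sequence
#'
#' Builds the alternate haplotype of a single transcript by applying sorted,
#' non-overlapping substitutions, insertions and deletions, and returns the
#' edited sequence together with a bidirectional coordinate map.
#'
#' Variants follow VCF conventions: `pos` is 1-based on the reference
#' sequence, and indels are anchored (the first base of `ref` and `alt`
#' is the unchanged anchor). Deleted reference positions map to a gap
#' (`NA`) in the alternate coordinate system.
#'
#' @param ref_seq A single reference nucleotide sequence (character scalar).
#' @param variants A data frame with columns `pos`, `ref`, `alt` (a
#'   `transcript` column, if present, is ignored here).
#' @param transcript Transcript name used in error messages.
#' @return A list with elements:
#'   \describe{
#'     \item{alt_seq}{the edited sequence;}
#'     \item{ref_to_alt}{integer vector over reference positions; `NA` marks a
#'       deleted position;}
#'     \item{alt_to_ref}{the inverse map over alternate positions; `NA` marks
#'       inserted bases;}
#'     \item{diagnostic_positions}{reference-coordinate positions at which the
#'       two haplotypes differ (for insertions, the anchor position marks the
#'       junction).}
#'   }
#' @examples
#' apply_variants("ACGTACGT", data.frame(pos = 3, ref = "G", alt = "T"))$alt_seq
#' @export
apply_variants <- function(ref_seq, variants, transcript = "<transcript>") {
  stopifnot(is.character(ref_seq), length(ref_seq) == 1)
  ref_len <- nchar(ref_seq)
  variants <- as_tibble(variants)
  if (nrow(variants) == 0) {
    return(list(
      alt_seq = ref_seq,
      ref_to_alt = seq_len(ref_len),
      alt_to_ref = seq_len(ref_len),
      diagnostic_positions = integer(0)
    ))
  }
  check_columns(variants, c("pos", "ref", "alt"), "variant table")
  if (any(nchar(variants$ref) == 0) || any(nchar(variants$alt) == 0)) {
    abort(sprintf("transcript %s: variant ref/alt alleles must be non-empty", transcript))
  }
  variants <- arrange(variants, .data$pos)
  ends <- variants$pos + nchar(variants$ref) - 1
  if (any(variants$pos < 1) || any(ends > ref_len)) {
    abort(sprintf("transcript %s: variant outside sequence bounds", transcript))
  }
  if (nrow(variants) > 1 && any(variants$pos[-1] <= ends[-nrow(variants)])) {
    i <- which(variants$pos[-1] <= ends[-nrow(variants)])[1]
    abort(sprintf("transcript %s: overlapping variants at positions %d and %d",
                  transcript, variants$pos[i], variants$pos[i + 1]))
  }
  observed <- substring(ref_seq, variants$pos, ends)
  if (any(observed != variants$ref)) {
    i <- which(observed != variants$ref)[1]
    abort(sprintf(
      "transcript %s: reference mismatch at position %d (expected '%s', sequence has '%s')",
      transcript, variants$pos[i], variants$ref[i], observed[i]
    ))
  }

  ref_to_alt <- rep(NA_integer_, ref_len)
  pieces <- character(0)
  diagnostics <- integer(0)
  cur_ref <- 1L
  cur_alt <- 1L
  for (i in seq_len(nrow(variants))) {
    pos <- variants$pos[i]
    vref <- variants$ref[i]
    valt <- variants$alt[i]
    lr <- nchar(vref)
    la <- nchar(valt)
    seg <- pos - cur_ref
    if (seg > 0) {
      ref_to_alt[cur_ref:(pos - 1L)] <- cur_alt + 0:(seg - 1L)
      pieces <- c(pieces, substring(ref_seq, cur_ref, pos - 1L))
      cur_alt <- cur_alt + seg
    }
    k <- min(lr, la)
    ref_to_alt[pos:(pos + k - 1L)] <- cur_alt + 0:(k - 1L)
    # aligned prefix: record mismatching bases as diagnostic
    rb <- strsplit(substr(vref, 1, k), "")[[1]]
    ab <- strsplit(substr(valt, 1, k), "")[[1]]
    diagnostics <- c(diagnostics, pos + which(rb != ab) - 1L)
    if (lr > la) {
      ref_to_alt[(pos + k):(pos + lr - 1L)] <- NA_integer_  # deleted
      diagnostics <- c(diagnostics, (pos + k):(pos + lr - 1L))
    } else if (la > lr) {
      diagnostics <- c(diagnostics, pos + k - 1L)  # insertion junction anchor
    }
    pieces <- c(pieces, valt)
    cur_alt <- cur_alt + la
    cur_ref <- pos + lr
  }
  if (cur_ref <= ref_len) {
    seg <- ref_len - cur_ref + 1L
    ref_to_alt[cur_ref:ref_len] <- cur_alt + 0:(seg - 1L)
    pieces <- c(pieces, substring(ref_seq, cur_ref, ref_len))
    cur_alt <- cur_alt + seg
  }
  alt_seq <- paste(pieces, collapse = "")
  alt_len <- nchar(alt_seq)
  alt_to_ref <- rep(NA_integer_, alt_len)
  mapped <- which(!is.na(ref_to_alt))
  alt_to_ref[ref_to_alt[mapped]] <- mapped
  list(
    alt_seq = alt_seq,
    ref_to_alt = ref_to_alt,
    alt_to_ref = alt_to_ref,
    diagnostic_positions = sort(unique(diagnostics))
  )
}

#' Build a diploid transcriptome from a reference and a variant table
#'
#' Applies each transcript's variants with [apply_variants()]. Transcripts
#' without variants get an alternate haplotype identical to the reference and
#' no diagnostic positions.
#'
#' @param reference Named character vector of transcript sequences, a
#'   `Biostrings::DNAStringSet`, or the path to a FASTA file.
#' @param variants Data frame with columns `transcript`, `pos`, `ref`, `alt`;
#'   see [read_variants()] for the VCF/TSV readers.
#' @return An object of class `diploid_transcriptome`: a named list with one
#'   entry per transcript (`ref_seq`, `alt_seq`, `ref_to_alt`, `alt_to_ref`,
#'   `diagnostic_positions`).
#' @export
build_diploid <- function(reference, variants = NULL) {
  seqs <- as_sequence_vector(reference)
  if (is.null(variants)) {
    variants <- tibble(transcript = character(), pos = integer(),
                       ref = character(), alt = character())
  }
  variants <- as_tibble(variants)
  if (nrow(variants) > 0) {
    check_columns(variants, c("transcript", "pos", "ref", "alt"), "variant table")
    unknown <- setdiff(unique(variants$transcript), names(seqs))
    if (length(unknown) > 0) {
      abort(sprintf("variant table references unknown transcript(s): %s",
                    paste(unknown, collapse = ", ")))
    }
  }
  by_tx <- split(variants, variants$transcript)
  entries <- lapply(names(seqs), function(tx) {
    v <- by_tx[[tx]] %||%
      tibble(pos = integer(), ref = character(), alt = character())
    res <- apply_variants(seqs[[tx]], v, transcript = tx)
    c(list(ref_seq = seqs[[tx]]), res)
  })
  names(entries) <- names(seqs)
  structure(entries, class = "diploid_transcriptome")
}

#' @export
print.diploid_transcriptome <- function(x, ...) {
  n_diag <- sum(vapply(x, function(e) length(e$diagnostic_positions), integer(1)))
  cat(sprintf("<diploid_transcriptome> %d transcript(s), %d diagnostic position(s)\n",
              length(x), n_diag))
  invisible(x)
}

#' Lift a position between haplotype coordinate systems
#'
#' Maps a 1-based position through a transcript's coordinate map. Positions
#' deleted on the target haplotype (or inserted bases, in the `alt -> ref`
#' direction) return `NA` (a gap). The map is strictly increasing on non-gap
#' positions, and lifting then inverse-lifting is the identity.
#'
#' @param map A single entry of a `diploid_transcriptome`, or any list with
#'   `ref_to_alt` / `alt_to_ref` integer vectors.
#' @param pos Integer vector of 1-based positions.
#' @param from Coordinate system `pos` lives in: `"ref"` (default) or `"alt"`.
#' @return Integer vector of lifted positions, `NA` at gaps.
#' @export
liftover <- function(map, pos, from = c("ref", "alt")) {
  from <- match.arg(from)
  lut <- if (from == "ref") map$ref_to_alt else map$alt_to_ref
  if (any(pos < 1 | pos > length(lut))) {
    abort(sprintf("position out of range [1, %d]", length(lut)))
  }
  lut[pos]
}

# Coerce FASTA path / DNAStringSet / named character to a named character vector.
as_sequence_vector <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    return(setNames(as.character(reference), names(reference)))
  }
  if (is.character(reference) && length(reference) == 1 && is.null(names(reference)) &&
      file.exists(reference)) {
    return(read_fasta(reference))
  }
  if (is.character(reference)) {
    if (is.null(names(reference)) || any(names(reference) == "")) {
      abort("reference sequences must be named (or given as a FASTA path)")
    }
    return(reference)
  }
  abort("unsupported reference type; use a named character vector, DNAStringSet, or FASTA path")
}

#' Extract the per-transcript diagnostic position index
#'
#' @param diploid A `diploid_transcriptome`.
#' @return A tibble with columns `transcript`, `ref_pos`, `alt_pos`
#'   (`NA` where the position is deleted on the alternate haplotype).
#' @export
diagnostic_positions <- function(diploid) {
  stopifnot(inherits(diploid, "diploid_transcriptome"))
  purrr::map_dfr(names(diploid), function(tx) {
    d <- diploid[[tx]]$diagnostic_positions
    tibble(
      transcript = rep(tx, length(d)),
      ref_pos = as.integer(d),
      alt_pos = if (length(d)) liftover(diploid[[tx]], d) else integer(0)
    )
  })
}
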