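# File I/O: FASTA/FASTQ via Biostrings, the minimal transcript-coordinate
# VCF dialect, and the TSV tables used throughout the pipeline.

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  # keep only the id (first whitespace-delimited token) as the name
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 70
  )
  invisible(path)
}

#' Read a variant table (minimal VCF or TSV dialect)
#'
#' The VCF dialect uses `CHROM` for the transcript id and 1-based `POS`,
#' `REF`, `ALT` on transcript coordinates. The TSV dialect has columns
#' `transcript`, `pos`, `ref`, `alt`. The format is chosen by file
#' extension (`.vcf` vs anything else).
#'
#' @param path Input path.
#' @return Tibble with columns `transcript`, `pos`, `ref`, `alt`.
#' @export
read_variants <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    lines <- readr::read_lines(path)
    body <- lines[!startsWith(lines, "#")]
    if (length(body) == 0) {
      return(tibble(transcript = character(), pos = integer(),
                    ref = character(), alt = character()))
    }
    fields <- stringr::str_split_fixed(body, "\t", 6)
    out <- tibble(
      transcript = fields[, 1],
      pos = as.integer(fields[, 2]),
      ref = fields[, 4],
      alt = fields[, 5]
    )
  } else {
    out <- readr::read_tsv(path, show_col_types = FALSE)
    check_columns(out, c("transcript", "pos", "ref", "alt"), "variant TSV")
    out <- mutate(out, pos = as.integer(.data$pos))
  }
  out
}

#' Write a variant table as a minimal VCF
#'
#' @param variants Tibble with columns `transcript`, `pos`, `ref`, `alt`.
#' @param path Output path (conventionally `.vcf`).
#' @export
write_variants <- function(variants, path) {
  check_columns(variants, c("transcript", "pos", "ref", "alt"), "variant table")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=allelome",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                  variants$transcript, variants$pos, variants$ref, variants$alt)
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Write simulated reads to FASTQ with truth-tagged names
#'
#' Read ids encode the ground truth as `gene|allele|start|sample|serial`
#' (pipe-separated), so assignments can be audited after the fact.
#'
#' @param reads A reads tibble from [simulate_reads()].
#' @param path Output FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  check_columns(reads, c("gene", "allele", "start", "sample", "seq"), "reads table")
  ids <- sprintf("%s|%s|%d|%s|%d", reads$gene, reads$allele, reads$start,
                 reads$sample, seq_len(nrow(reads)))
  seqs <- Biostrings::DNAStringSet(setNames(reads$seq, ids))
  quals <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read truth-tagged FASTQ reads back into a reads tibble
#'
#' @param path FASTQ file written by [write_fastq()].
#' @return Tibble with columns `gene`, `allele`, `start`, `sample`, `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  parts <- stringr::str_split_fixed(names(x), stringr::fixed("|"), 5)
  tibble(
    gene = parts[, 1],
    allele = parts[, 2],
    start = as.integer(parts[, 3]),
    sample = parts[, 4],
    seq = unname(as.character(x))
  )
}

#' Write a long-format allelic count table
#'
#' @param counts Tibble with columns `gene`, `sample`, `count_B`, `count_C`
#'   and optionally `ambiguous`.
#' @param path Output TSV path.
#' @export
write_counts <- function(counts, path) {
  check_columns(counts, c("gene", "sample", "count_B", "count_C"), "count table")
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Write / read a sample sheet
#'
#' @param samples Sample-sheet tibble (`sample`, `cross`, `cell_type`,
#'   `stage`, `replicate`).
#' @param path TSV path.
#' @export
write_samples <- function(samples, path) {
  check_samples(samples)
  readr::write_tsv(samples, path)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  samples <- readr::read_tsv(path, show_col_types = FALSE,
                             col_types = readr::cols(stage = "c", cell_type = "c"))
  check_samples(samples)
}
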