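# Synthetic reciprocal-hybrid data with planted ground truth.
#
# The generator emulates the study design this package targets: two
# reciprocal crosses (BC and CB) with four biological replicates each,
# across six sorted mammary cell types and ten developmental stages.
# Totals are negative-binomial, allelic fractions beta-binomial, and the
# planted class of every gene is returned as a truth table for
# parameter-recovery testing.

#' Default condition labels of the simulated design
#'
#' Six sorted mammary cell populations and ten developmental stages
#' (nulliparous; pregnancy days 5.5/9.5/14.5; lactation days 5/10/15;
#' involution days 1/6/14).
#'
#' @return Character vector of labels.
#' @export
default_cell_types <- function() {
  c("basal", "luminal_progenitor", "luminal_differentiated",
    "stromal", "endothelial", "adipocyte")
}

#' @rdname default_cell_types
#' @export
default_stages <- function() {
  c("nulliparous", "P5.5", "P9.5", "P14.5", "L5", "L10", "L15",
    "I1", "I6", "I14")
}

sim_classes <- c("biallelic", "maternal", "paternal", "strain_B", "strain_C", "silent")

#' Configuration of the synthetic-data generator
#'
#' All knobs of the simulated reciprocal-cross design in one validated
#' object. `bb_overdispersion` is the beta-binomial intraclass correlation
#' of allelic fractions; the study this design mirrors reports no empirical
#' estimate, so its default (0.02) is a deliberate, prominent choice --
#' revisit it for power analyses.
#'
#' @param n_genes Number of simulated genes.
#' @param class_probs Named probabilities over the classes
#'   `biallelic`, `maternal`, `paternal`, `strain_B`, `strain_C`, `silent`;
#'   must sum to 1.
#' @param cell_types,stages Condition labels; defaults are the full
#'   6 x 10 design grid.
#' @param n_cell_types,n_stages Number of cell types / stages used (a prefix
#'   of the label vectors).
#' @param n_reps_per_cross Biological replicates per reciprocal cross
#'   (default 4, i.e. 8 animals per condition).
#' @param mean_log_expression Named vector `c(meanlog=, sdlog=)` of the
#'   log-normal distribution of gene mean counts.
#' @param nb_dispersion Negative-binomial dispersion of totals
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson.
#' @param bb_overdispersion Beta-binomial intraclass correlation in `[0, 1)`.
#' @param maternal_fraction_effect Planted maternal fraction of imprinted
#'   classes, in `[0.5, 1]`.
#' @param strain_fraction_effect Planted strain-B fraction of strain-biased
#'   classes, in `[0, 1]`.
#' @param alignment_bias Multiplicative penalty `delta` in `[0, 1]` on
#'   B-allele assignment: a true B fraction `mu` is distorted to
#'   `mu (1 - delta) / (mu (1 - delta) + (1 - mu))` after cross orientation,
#'   mimicking read loss on the non-reference-like allele.
#' @param transcript_length_range Integer range (min, max) of simulated
#'   transcript lengths in nucleotides.
#' @param snps_per_transcript Diagnostic SNPs planted per transcript.
#' @param gene_length Nominal transcript length (nt) attached to every gene
#'   for RPKM computation on simulated counts.
#' @param seed Integer seed; identical configs are byte-identical.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       class_probs = c(biallelic = 0.70, maternal = 0.05,
                                       paternal = 0.05, strain_B = 0.075,
                                       strain_C = 0.075, silent = 0.05),
                       cell_types = default_cell_types(),
                       stages = default_stages(),
                       n_cell_types = length(cell_types),
                       n_stages = length(stages),
                       n_reps_per_cross = 4,
                       mean_log_expression = c(meanlog = log(100), sdlog = 1),
                       nb_dispersion = 0.1,
                       bb_overdispersion = 0.02,
                       maternal_fraction_effect = 0.9,
                       strain_fraction_effect = 0.9,
                       alignment_bias = 0,
                       transcript_length_range = c(500L, 2000L),
                       snps_per_transcript = 5,
                       gene_length = 1000,
                       seed = 1L) {
  probs <- rep(0, length(sim_classes))
  names(probs) <- sim_classes
  unknown <- setdiff(names(class_probs), sim_classes)
  if (length(unknown) > 0) {
    abort(sprintf("unknown class in class_probs: %s", paste(unknown, collapse = ", ")))
  }
  probs[names(class_probs)] <- class_probs
  if (any(probs < 0) || any(probs > 1) || abs(sum(probs) - 1) > 1e-8) {
    abort("class_probs must be probabilities in [0, 1] summing to 1")
  }
  stopifnot(
    n_genes >= 0,
    n_reps_per_cross >= 1,
    n_cell_types >= 1, n_cell_types <= length(cell_types),
    n_stages >= 1, n_stages <= length(stages),
    nb_dispersion >= 0,
    bb_overdispersion >= 0, bb_overdispersion < 1,
    maternal_fraction_effect >= 0.5, maternal_fraction_effect <= 1,
    strain_fraction_effect >= 0, strain_fraction_effect <= 1,
    alignment_bias >= 0, alignment_bias <= 1,
    length(transcript_length_range) == 2,
    all(transcript_length_range >= 1),
    transcript_length_range[1] <= transcript_length_range[2],
    snps_per_transcript >= 0,
    gene_length > 0
  )
  structure(list(
    n_genes = as.integer(n_genes),
    class_probs = probs,
    cell_types = cell_types[seq_len(n_cell_types)],
    stages = stages[seq_len(n_stages)],
    n_reps_per_cross = as.integer(n_reps_per_cross),
    mean_log_expression = mean_log_expression,
    nb_dispersion = nb_dispersion,
    bb_overdispersion = bb_overdispersion,
    maternal_fraction_effect = maternal_fraction_effect,
    strain_fraction_effect = strain_fraction_effect,
    alignment_bias = alignment_bias,
    transcript_length_range = as.integer(transcript_length_range),
    snps_per_transcript = as.integer(snps_per_transcript),
    gene_length = gene_length,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Distort an allelic fraction by alignment bias
#'
#' Applies the multiplicative B-allele penalty `delta`:
#' `mu (1 - delta) / (mu (1 - delta) + (1 - mu))`. Identity at `delta = 0`.
#'
#' @param mu True B-allele fraction(s).
#' @param delta Penalty in `[0, 1]`.
#' @return Distorted fraction(s).
#' @export
bias_fraction <- function(mu, delta) {
  if (delta == 0) return(mu)
  num <- mu * (1 - delta)
  num / (num + (1 - mu))
}

#' Build the sample sheet of a simulated design
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `sample`, `cross`, `cell_type`, `stage`,
#'   `replicate`; one row per animal x condition.
#' @export
sim_sample_sheet <- function(config) {
  grid <- tidyr::expand_grid(
    cross = c("BC", "CB"),
    cell_type = config$cell_types,
    stage = config$stages,
    replicate = seq_len(config$n_reps_per_cross)
  )
  mutate(grid,
    sample = sprintf("%s_%s_%s_r%d", .data$cross, .data$cell_type,
                     .data$stage, .data$replicate),
    .before = 1
  )
}

#' Simulate reciprocal-hybrid allelic counts with planted truth
#'
#' For every gene x sample, the total count is negative-binomial around the
#' gene's log-normal mean and the B-allele count is beta-binomial around the
#' class-determined fraction, oriented by the sample's cross (a maternal
#' fraction `m` gives B fraction `m` in BC hybrids and `1 - m` in CB
#' hybrids) and then distorted by `alignment_bias`. Silent-class genes have
#' all counts exactly zero.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{counts}{long tibble `gene`, `sample`, `count_B`, `count_C`;}
#'     \item{samples}{the sample sheet;}
#'     \item{truth}{one row per gene: `gene`, `class`,
#'       `planted_maternal_fraction`, `planted_strain_fraction`,
#'       `mean_expression`, `length`.}
#'   }
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 50, n_cell_types = 1,
#'                                   n_stages = 1, seed = 7))
#' dplyr::count(dplyr::left_join(sim$counts, sim$truth, by = "gene"), class)
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  samples <- sim_sample_sheet(config)
  if (config$n_genes == 0) {
    return(list(
      counts = tibble(gene = character(), sample = character(),
                      count_B = integer(), count_C = integer()),
      samples = samples,
      truth = tibble(gene = character(), class = character(),
                     planted_maternal_fraction = double(),
                     planted_strain_fraction = double(),
                     mean_expression = double(), length = double())
    ))
  }
  with_seed(config$seed, {
    ng <- config$n_genes
    gene <- sprintf("gene_%0*d", max(4L, nchar(ng)), seq_len(ng))
    class <- sample(sim_classes, ng, replace = TRUE, prob = config$class_probs)
    m <- config$maternal_fraction_effect
    s <- config$strain_fraction_effect
    truth <- tibble(
      gene = gene,
      class = class,
      planted_maternal_fraction = dplyr::case_when(
        class == "maternal" ~ m,
        class == "paternal" ~ 1 - m,
        TRUE ~ 0.5
      ),
      planted_strain_fraction = dplyr::case_when(
        class == "strain_B" ~ s,
        class == "strain_C" ~ 1 - s,
        TRUE ~ 0.5
      ),
      mean_expression = ifelse(
        class == "silent", 0,
        rlnorm(ng, config$mean_log_expression[["meanlog"]],
               config$mean_log_expression[["sdlog"]])
      ),
      length = config$gene_length
    )
    grid <- tidyr::expand_grid(gene = gene, sample = samples$sample)
    grid <- left_join(grid, truth, by = "gene")
    grid <- left_join(grid, select(samples, "sample", "cross"), by = "sample")
    total <- integer(nrow(grid))
    live <- grid$class != "silent"
    if (config$nb_dispersion > 0) {
      total[live] <- rnbinom(sum(live), mu = grid$mean_expression[live],
                             size = 1 / config$nb_dispersion)
    } else {
      total[live] <- stats::rpois(sum(live), grid$mean_expression[live])
    }
    # effective B fraction: orient the class fraction by cross, then bias it
    f_b <- ifelse(
      grid$class %in% c("strain_B", "strain_C"),
      grid$planted_strain_fraction,
      ifelse(grid$cross == "BC",
             grid$planted_maternal_fraction,
             1 - grid$planted_maternal_fraction)
    )
    f_b <- bias_fraction(f_b, config$alignment_bias)
    count_b <- rbetabinom(nrow(grid), total, f_b, config$bb_overdispersion)
    counts <- tibble(
      gene = grid$gene,
      sample = grid$sample,
      count_B = as.integer(count_b),
      count_C = as.integer(total - count_b)
    )
    list(counts = counts, samples = samples, truth = truth)
  })
}

#' Simulate a toy transcriptome and its strain variant table
#'
#' One transcript per gene, random nucleotides, with `snps_per_transcript`
#' diagnostic SNPs planted at distinct positions (`alt != ref`). Indels are
#' not generated (though [build_diploid()] accepts them from input), keeping
#' read-assignment truth unambiguous.
#'
#' @param config A [sim_config()].
#' @return List with `reference` (named character vector) and `variants`
#'   (tibble `transcript`, `pos`, `ref`, `alt`).
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lo <- config$transcript_length_range[1]
  hi <- config$transcript_length_range[2]
  if (config$snps_per_transcript > lo) {
    abort(sprintf("snps_per_transcript (%d) exceeds the minimum transcript length (%d)",
                  config$snps_per_transcript, lo))
  }
  bases <- c("A", "C", "G", "T")
  with_seed(config$seed + 1L, {
    ng <- config$n_genes
    gene <- sprintf("gene_%0*d", max(4L, nchar(max(ng, 1))), seq_len(ng))
    lens <- if (lo == hi) rep(lo, ng) else sample(lo:hi, ng, replace = TRUE)
    reference <- setNames(vapply(lens, function(L) {
      paste(sample(bases, L, replace = TRUE), collapse = "")
    }, character(1)), gene)
    variants <- purrr::map_dfr(seq_len(ng), function(i) {
      k <- config$snps_per_transcript
      if (k == 0) {
        return(tibble(transcript = character(), pos = integer(),
                      ref = character(), alt = character()))
      }
      pos <- sort(sample.int(lens[i], k))
      ref <- substring(reference[[i]], pos, pos)
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
      tibble(transcript = gene[i], pos = as.integer(pos),
             ref = unname(ref), alt = unname(alt))
    })
    list(reference = reference, variants = variants)
  })
}

#' Simulate truth-tagged reads from a diploid transcriptome
#'
#' Emits, for each gene x sample, exactly `count_B` reads from the
#' reference-like (B) haplotype and `count_C` reads from the
#' variant-carrying (C) haplotype, with start positions uniform over the
#' haplotype and i.i.d. substitution errors at `error_rate`. Read starts are
#' reported in reference transcript coordinates (C-haplotype starts are
#' mapped back through the coordinate map; with the SNP-only simulator the
#' map is the identity).
#'
#' @param diploid A [build_diploid()] object; transcript ids must match the
#'   gene ids of `counts`.
#' @param counts Long allelic count tibble (`gene`, `sample`, `count_B`,
#'   `count_C`).
#' @param read_length Read length (nt); must not exceed any transcript length.
#' @param error_rate Per-base substitution error probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return Tibble `gene`, `sample`, `allele` ("B"/"C"), `start` (1-based,
#'   reference coordinates), `seq`.
#' @export
simulate_reads <- function(diploid, counts, read_length = 80, error_rate = 0.005,
                           seed = 1L) {
  stopifnot(inherits(diploid, "diploid_transcriptome"),
            error_rate >= 0, error_rate <= 1, read_length >= 1)
  check_columns(counts, c("gene", "sample", "count_B", "count_C"), "count table")
  missing_tx <- setdiff(unique(counts$gene), names(diploid))
  if (length(missing_tx) > 0) {
    abort(sprintf("counts reference gene(s) absent from the diploid transcriptome: %s",
                  paste(head(missing_tx, 5), collapse = ", ")))
  }
  too_short <- names(diploid)[vapply(diploid, function(e) {
    nchar(e$ref_seq) < read_length || nchar(e$alt_seq) < read_length
  }, logical(1))]
  too_short <- intersect(too_short, unique(counts$gene))
  if (length(too_short) > 0) {
    abort(sprintf("read_length %d exceeds the length of transcript(s): %s",
                  read_length, paste(head(too_short, 5), collapse = ", ")))
  }
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    long <- tidyr::pivot_longer(counts, c("count_B", "count_C"),
                                names_to = "allele", names_prefix = "count_",
                                values_to = "n_reads")
    long <- filter(long, .data$n_reads > 0)
    out <- purrr::pmap_dfr(long, function(gene, sample, allele, n_reads, ...) {
      entry <- diploid[[gene]]
      hap <- if (allele == "B") entry$ref_seq else entry$alt_seq
      max_start <- nchar(hap) - read_length + 1L
      hap_start <- sample.int(max_start, n_reads, replace = TRUE)
      seqs <- substring(hap, hap_start, hap_start + read_length - 1L)
      if (error_rate > 0) {
        seqs <- vapply(seqs, function(s) {
          hits <- which(runif(read_length) < error_rate)
          if (length(hits) == 0) return(s)
          ch <- strsplit(s, "")[[1]]
          ch[hits] <- vapply(ch[hits], function(b) sample(setdiff(bases, b), 1),
                             character(1))
          paste(ch, collapse = "")
        }, character(1), USE.NAMES = FALSE)
      }
      ref_start <- if (allele == "B") hap_start else entry$alt_to_ref[hap_start]
      # alt starts falling on inserted bases have no reference anchor; walk
      # left to the nearest mapped base (never triggered for SNP-only maps)
      while (anyNA(ref_start)) {
        idx <- which(is.na(ref_start))
        hap_start[idx] <- pmax(hap_start[idx] - 1L, 1L)
        ref_start[idx] <- entry$alt_to_ref[hap_start[idx]]
      }
      tibble(gene = gene, sample = sample, allele = allele,
             start = as.integer(ref_start), seq = seqs)
    })
    if (nrow(out) == 0) {
      out <- tibble(gene = character(), sample = character(),
                    allele = character(), start = integer(), seq = character())
    }
    out
  })
}

#' Simulate truth-labelled differential-expression tables
#'
#' Emits one record per gene x contrast with the fields the candidate-gene
#' screens consume (`base_mean`, `log2fc`, `padj`, `biotype`), plus an
#' `is_de` truth flag. Differentially expressed genes get `|log2fc|` drawn
#' well above 1 and small adjusted p-values; nulls get near-zero fold
#' changes and uniform p-values.
#'
#' @param n_genes Number of genes.
#' @param contrasts Character vector of contrast labels.
#' @param prop_de Proportion of genes differentially expressed per contrast.
#' @param prop_coding Proportion of protein-coding genes.
#' @param seed Integer seed.
#' @return Tibble `gene`, `contrast`, `base_mean`, `log2fc`, `padj`,
#'   `biotype`, `is_de`.
#' @export
simulate_de <- function(n_genes = 1000, contrasts = c("L10_vs_nulliparous"),
                        prop_de = 0.1, prop_coding = 0.9, seed = 1L) {
  with_seed(seed, {
    gene <- sprintf("gene_%0*d", max(4L, nchar(n_genes)), seq_len(n_genes))
    biotype <- sample(c("protein_coding", "other"), n_genes, replace = TRUE,
                      prob = c(prop_coding, 1 - prop_coding))
    purrr::map_dfr(contrasts, function(ct) {
      is_de <- runif(n_genes) < prop_de
      lfc <- ifelse(is_de,
                    sample(c(-1, 1), n_genes, TRUE) * (1.5 + stats::rexp(n_genes, 1)),
                    stats::rnorm(n_genes, 0, 0.2))
      padj <- ifelse(is_de, 10^(-runif(n_genes, 3, 25)), runif(n_genes))
      tibble(gene = gene, contrast = ct,
             base_mean = rlnorm(n_genes, log(200), 1),
             log2fc = lfc, padj = padj, biotype = biotype, is_de = is_de)
    })
  })
}
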