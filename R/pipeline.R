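# Config-driven orchestration: simulate -> build-diploid -> quantify ->
# test -> classify -> atlas -> screens, with a JSON run manifest.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    outdir = "allelome_run",
    log_level = "info",
    simulate = list(
      enabled = TRUE,
      n_genes = 2000L,
      n_cell_types = 1L,
      n_stages = 1L,
      n_reps_per_cross = 4L,
      nb_dispersion = 0.1,
      bb_overdispersion = 0.02,
      maternal_fraction_effect = 0.9,
      strain_fraction_effect = 0.9,
      alignment_bias = 0,
      gene_length = 1000,
      with_reads = FALSE,
      read_length = 80L,
      error_rate = 0.005,
      snps_per_transcript = 5L
    ),
    inputs = list(
      counts = NULL, samples = NULL, fasta = NULL, variants = NULL,
      de_table = NULL, catalogue = NULL
    ),
    filter = list(tolerance = 50, min_count_per_rep = 10),
    test = list(n_resamples = 5000L, alpha = 0.05, min_informative_reps = 2L),
    classify = list(rpkm_min = 1, t_low = 0.2, t_high = 0.7, alpha = 0.05,
                    strain_bias_min = 0.5, strain_min_conditions = 3L),
    screens = list(padj_max = 0.05, lfc_min = 1.0, min_reads = 20,
                   coding_only = TRUE, top_frac = 0.01, top_k = 50L,
                   involution_padj_max = 1e-17)
  )
}

# Merge user values over defaults, rejecting unknown keys with dotted paths.
merge_config <- function(defaults, user, path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) {
    abort(sprintf("config section '%s' must be a mapping", paste(path, collapse = ".")))
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s",
                  paste(paste(c(path, unknown[1]), collapse = "."), collapse = ", ")))
  }
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

check_range <- function(value, lo, hi, path) {
  if (!is.numeric(value) || length(value) != 1 || is.na(value) ||
      value < lo || value > hi) {
    abort(sprintf("config value at %s must be a number in [%s, %s]; got %s",
                  path, format(lo), format(hi),
                  paste(format(value), collapse = ",")))
  }
  invisible(value)
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML/JSON file path or a nested list, fills every default
#' (tolerance 50, 5000 resamples, RPKM floor 1, monoallelic thresholds
#' 0.2/0.7, strain bias 0.5 over at least 3 conditions), rejects unknown
#' keys by dotted path, and range-checks the numeric fields.
#'
#' @param config Path to a `.yaml`/`.yml`/`.json` file, a nested list, or
#'   `NULL` for all defaults.
#' @return A validated `run_config` list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  cfg <- merge_config(pipeline_defaults(), config)
  check_range(cfg$filter$tolerance, 0, 100, "filter.tolerance")
  check_range(cfg$filter$min_count_per_rep, 0, Inf, "filter.min_count_per_rep")
  check_range(cfg$test$n_resamples, 1, Inf, "test.n_resamples")
  check_range(cfg$test$alpha, 1e-12, 1 - 1e-12, "test.alpha")
  check_range(cfg$classify$t_low, 0, 1, "classify.t_low")
  check_range(cfg$classify$t_high, 0, 1, "classify.t_high")
  if (cfg$classify$t_low >= cfg$classify$t_high) {
    abort("config: classify.t_low must be below classify.t_high")
  }
  check_range(cfg$classify$strain_bias_min, 0, 1, "classify.strain_bias_min")
  check_range(cfg$simulate$bb_overdispersion, 0, 1 - 1e-12,
              "simulate.bb_overdispersion")
  check_range(cfg$simulate$alignment_bias, 0, 1, "simulate.alignment_bias")
  check_range(cfg$screens$top_frac, 0, 1, "screens.top_frac")
  for (field in c("counts", "samples", "fasta", "variants", "de_table", "catalogue")) {
    p <- cfg$inputs[[field]]
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("config input path does not exist: inputs.%s = %s", field, p))
    }
  }
  structure(cfg, class = "run_config")
}

pipeline_log <- function(cfg, stage, msg) {
  if (identical(cfg$log_level, "silent")) return(invisible())
  if (identical(cfg$log_level, "json")) {
    message(jsonlite::toJSON(list(stage = stage, message = msg), auto_unbox = TRUE))
  } else {
    message(sprintf("[%s] %s", stage, msg))
  }
}

#' Run the full pipeline
#'
#' Executes simulate (or loads provided inputs), diploid construction and
#' read quantification (when reads are simulated), both orientation scans,
#' classification, atlas assembly, the strain screen, catalogue comparison
#' and DE screens (when the corresponding inputs exist), writing every
#' stage's output under `config$outdir` and a JSON run manifest with
#' checksums, seeds and timings. Identical config and seed give
#' byte-identical data outputs (the manifest's timing fields vary).
#'
#' @param config A [validate_config()] result, or anything it accepts.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  outputs <- character(0)
  stage <- function(name, fun) {
    t0 <- Sys.time()
    pipeline_log(cfg, name, "start")
    res <- tryCatch(fun(), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
    timings[[name]] <<- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
    res
  }
  emit <- function(x, file, writer = readr::write_tsv) {
    path <- file.path(outdir, file)
    writer(x, path)
    outputs <<- c(outputs, path)
    path
  }

  sim <- NULL
  truth <- NULL
  if (isTRUE(cfg$simulate$enabled)) {
    sim <- stage("simulate", function() {
      sc <- sim_config(
        n_genes = cfg$simulate$n_genes,
        n_cell_types = cfg$simulate$n_cell_types,
        n_stages = cfg$simulate$n_stages,
        n_reps_per_cross = cfg$simulate$n_reps_per_cross,
        nb_dispersion = cfg$simulate$nb_dispersion,
        bb_overdispersion = cfg$simulate$bb_overdispersion,
        maternal_fraction_effect = cfg$simulate$maternal_fraction_effect,
        strain_fraction_effect = cfg$simulate$strain_fraction_effect,
        alignment_bias = cfg$simulate$alignment_bias,
        gene_length = cfg$simulate$gene_length,
        snps_per_transcript = cfg$simulate$snps_per_transcript,
        seed = cfg$seed
      )
      out <- simulate_counts(sc)
      emit(out$counts, "counts_simulated.tsv")
      emit(out$samples, "samples.tsv")
      emit(out$truth, "truth.tsv")
      out
    })
    truth <- sim$truth
    counts <- sim$counts
    samples <- sim$samples
  } else {
    if (is.null(cfg$inputs$counts) || is.null(cfg$inputs$samples)) {
      abort("with simulate.enabled = FALSE, inputs.counts and inputs.samples are required")
    }
    samples <- read_samples(cfg$inputs$samples)
    counts <- load_counts(cfg$inputs$counts, samples)
  }

  if (isTRUE(cfg$simulate$enabled) && isTRUE(cfg$simulate$with_reads)) {
    counts <- stage("quantify", function() {
      sc <- sim_config(n_genes = cfg$simulate$n_genes,
                       snps_per_transcript = cfg$simulate$snps_per_transcript,
                       seed = cfg$seed)
      tx <- simulate_transcriptome(sc)
      emit(tx$reference, "reference.fasta", write_fasta)
      emit(tx$variants, "variants.vcf", write_variants)
      diploid <- build_diploid(tx$reference, tx$variants)
      reads <- simulate_reads(diploid, sim$counts,
                              read_length = cfg$simulate$read_length,
                              error_rate = cfg$simulate$error_rate,
                              seed = cfg$seed + 2L)
      emit(reads, "reads.fastq", write_fastq)
      quant <- count_alleles(reads, diploid, samples)
      emit(quant, "counts_quantified.tsv")
      quant
    })
  }

  filt <- filter_config(cfg$filter$tolerance, cfg$filter$min_count_per_rep)
  tcfg <- test_config(cfg$test$n_resamples, cfg$test$alpha, seed = cfg$seed,
                      min_informative_reps = cfg$test$min_informative_reps)
  ccfg <- classifier_config(cfg$classify$rpkm_min, cfg$classify$t_low,
                            cfg$classify$t_high, cfg$classify$alpha,
                            cfg$classify$strain_bias_min,
                            cfg$classify$strain_min_conditions)

  lengths <- if (!is.null(truth) && "length" %in% names(truth)) {
    setNames(truth$length, truth$gene)
  } else cfg$simulate$gene_length

  scans <- stage("test", function() {
    parental <- ase_scan(counts, samples, "parental", filt, tcfg)
    strain <- ase_scan(counts, samples, "strain", filt, tcfg)
    emit(parental, "ase_parental.tsv")
    emit(strain, "ase_strain.tsv")
    list(parental = parental, strain = strain)
  })

  classified <- stage("classify", function() {
    rp <- condition_rpkm(counts, samples, lengths)
    cf <- cross_fractions(counts, samples)
    out <- classify_conditions(scans$parental, scans$strain, rp, cf, ccfg)
    emit(out, "classified.tsv")
    out
  })

  atlas <- stage("atlas", function() {
    at <- build_atlas(classified, ccfg)
    emit(at$long, "atlas_long.tsv")
    emit(at$maternal_fraction, "atlas_maternal_fraction.tsv")
    emit(at$category, "atlas_category.tsv")
    emit(strain_screen(classified, ccfg), "strain_screen.tsv")
    at
  })

  if (!is.null(cfg$inputs$catalogue)) {
    stage("compare-catalogue", function() {
      catalogue <- readr::read_tsv(cfg$inputs$catalogue, show_col_types = FALSE)
      cmp <- compare_catalogue(atlas, catalogue)
      emit(cmp$genes, "catalogue_genes.tsv")
      emit(cmp$totals, "catalogue_totals.tsv")
      cmp
    })
  }

  if (!is.null(cfg$inputs$de_table)) {
    stage("screen", function() {
      de <- readr::read_tsv(cfg$inputs$de_table, show_col_types = FALSE)
      hits <- screen_de(de, cfg$screens$padj_max, cfg$screens$lfc_min,
                        cfg$screens$min_reads, cfg$screens$coding_only)
      emit(hits, "screen_de.tsv")
      hits
    })
  }

  recovery <- NULL
  if (!is.null(truth)) {
    joined <- left_join(classified, select(truth, "gene", "class"), by = "gene")
    rate <- function(cls, cat) {
      sub <- filter(joined, .data$class %in% cls)
      if (nrow(sub) == 0) return(NA_real_)
      mean(sub$category %in% cat)
    }
    recovery <- list(
      maternal_sensitivity = rate("maternal", "maternal"),
      paternal_sensitivity = rate("paternal", "paternal"),
      strain_sensitivity = rate(c("strain_B", "strain_C"), c("strain_B", "strain_C")),
      strain_called_parental = rate(c("strain_B", "strain_C"),
                                    c("maternal", "paternal")),
      biallelic_called_monoallelic = rate("biallelic",
                                          c("maternal", "paternal",
                                            "strain_B", "strain_C"))
    )
  }

  config_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, null = "null")
  manifest <- list(
    tool = "allelome",
    version = as.character(utils::packageVersion("allelome")),
    seed = cfg$seed,
    config = unclass(cfg),
    config_hash = sprintf("%d", derive_seed(0L, config_json)),
    outputs = lapply(setNames(nm = basename(outputs)), function(f) {
      unname(tools::md5sum(file.path(outdir, f)))
    }),
    timings_sec = timings,
    recovery = recovery
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  pipeline_log(cfg, "done", sprintf("%d output file(s) in %s", length(outputs), outdir))
  invisible(manifest)
}
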