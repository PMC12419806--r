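# Reciprocal-cross classification of allelic state, atlas assembly, and
# comparison against a known-imprint catalogue.
#
# A gene x condition is called monoallelic only when three gates agree:
# the resampling test is significant, the pooled fraction clears the
# asymmetric 0.2/0.7 monoallelic thresholds, and both reciprocal crosses
# deviate in the same parental direction (concordance). Significance
# gating can be disabled for threshold-only displays.

#' Classifier configuration
#'
#' @param rpkm_min Expression floor; conditions at or below it are
#'   `not_expressed` (default 1).
#' @param t_low,t_high Monoallelic maternal-fraction cutoffs (defaults 0.2
#'   and 0.7; deliberately asymmetric around 0.5).
#' @param alpha Adjusted-p significance gate (default 0.05).
#' @param strain_bias_min Minimum bias score `|2 f_B - 1|` for a strain
#'   call (default 0.5, i.e. strain-B fraction outside `[0.25, 0.75]`).
#' @param strain_min_conditions Conditions required by the gene-level
#'   strain screen, for both the expression floor and the bias criterion
#'   (default 3).
#' @param gate_significance If `FALSE`, monoallelic and strain calls rely
#'   on thresholds and concordance only.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(rpkm_min = 1, t_low = 0.2, t_high = 0.7,
                              alpha = 0.05, strain_bias_min = 0.5,
                              strain_min_conditions = 3,
                              gate_significance = TRUE) {
  stopifnot(t_low >= 0, t_low < t_high, t_high <= 1,
            strain_bias_min >= 0, strain_bias_min <= 1,
            alpha > 0, alpha < 1, strain_min_conditions >= 1)
  structure(list(rpkm_min = rpkm_min, t_low = t_low, t_high = t_high,
                 alpha = alpha, strain_bias_min = strain_bias_min,
                 strain_min_conditions = as.integer(strain_min_conditions),
                 gate_significance = gate_significance),
            class = "classifier_config")
}

#' Per-cross pooled allelic fractions
#'
#' Pooled maternal and strain-B fractions per gene x condition x cross,
#' used for the reciprocal-concordance gate.
#'
#' @param counts Long allelic count tibble.
#' @param samples Sample sheet.
#' @return Tibble `gene`, `cell_type`, `stage`, `cross`,
#'   `maternal_fraction`, `strainB_fraction` (NA where the cross total is 0).
#' @export
cross_fractions <- function(counts, samples) {
  samples <- check_samples(samples)
  counts %>%
    left_join(select(samples, "sample", "cross", "cell_type", "stage"),
              by = "sample") %>%
    group_by(.data$gene, .data$cell_type, .data$stage, .data$cross) %>%
    summarise(
      total = sum(.data$count_B + .data$count_C),
      maternal = sum(ifelse(.data$cross == "BC", .data$count_B, .data$count_C)),
      B = sum(.data$count_B),
      .groups = "drop"
    ) %>%
    mutate(
      maternal_fraction = if_else(.data$total > 0, .data$maternal / .data$total, NA_real_),
      strainB_fraction = if_else(.data$total > 0, .data$B / .data$total, NA_real_)
    ) %>%
    select("gene", "cell_type", "stage", "cross",
           "maternal_fraction", "strainB_fraction")
}

#' Classify every gene x condition from paired orientation scans
#'
#' Combines a parental-orientation and a strain-orientation [ase_scan()],
#' condition RPKM and per-cross fractions into one category per gene x
#' condition:
#' `not_expressed` (RPKM at or below the floor), `maternal` / `paternal`
#' (significant parental test, fraction beyond `t_high` / `t_low`, both
#' crosses concordant), `strain_B` / `strain_C` (significant strain test,
#' cross-concordant, bias score above `strain_bias_min`), `inconclusive`
#' (both orientations significant, or an untestable orientation), else
#' `biallelic`. Every row receives exactly one category.
#'
#' @param parental,strain [ase_scan()] results in the two orientations.
#' @param rpkm_cond Condition RPKM tibble from [condition_rpkm()].
#' @param crossfrac Per-cross fractions from [cross_fractions()].
#' @param config A [classifier_config()].
#' @return Tibble `gene`, `cell_type`, `stage`, `category`,
#'   `maternal_fraction`, `strainB_fraction`, `rpkm`, `padj_parental`,
#'   `padj_strain`.
#' @export
classify_conditions <- function(parental, strain, rpkm_cond, crossfrac,
                                config = classifier_config()) {
  keys <- c("gene", "cell_type", "stage")
  wide_cross <- crossfrac %>%
    tidyr::pivot_wider(names_from = "cross",
                       values_from = c("maternal_fraction", "strainB_fraction"))
  dat <- parental %>%
    select(dplyr::all_of(keys), "maternal_fraction", "strainB_fraction",
           padj_parental = "padj", testable_parental = "testable") %>%
    inner_join(select(strain, dplyr::all_of(keys), padj_strain = "padj",
                      testable_strain = "testable"),
               by = keys) %>%
    left_join(rpkm_cond, by = keys) %>%
    left_join(wide_cross, by = keys)

  sig_par <- if (config$gate_significance) {
    !is.na(dat$padj_parental) & dat$padj_parental <= config$alpha
  } else dat$testable_parental | TRUE
  sig_str <- if (config$gate_significance) {
    !is.na(dat$padj_strain) & dat$padj_strain <= config$alpha
  } else dat$testable_strain | TRUE

  conc_mat <- !is.na(dat$maternal_fraction_BC) & !is.na(dat$maternal_fraction_CB) &
    dat$maternal_fraction_BC > 0.5 & dat$maternal_fraction_CB > 0.5
  conc_pat <- !is.na(dat$maternal_fraction_BC) & !is.na(dat$maternal_fraction_CB) &
    dat$maternal_fraction_BC < 0.5 & dat$maternal_fraction_CB < 0.5
  conc_str_B <- !is.na(dat$strainB_fraction_BC) & !is.na(dat$strainB_fraction_CB) &
    dat$strainB_fraction_BC > 0.5 & dat$strainB_fraction_CB > 0.5
  conc_str_C <- !is.na(dat$strainB_fraction_BC) & !is.na(dat$strainB_fraction_CB) &
    dat$strainB_fraction_BC < 0.5 & dat$strainB_fraction_CB < 0.5
  bias <- abs(2 * dat$strainB_fraction - 1)

  category <- dplyr::case_when(
    is.na(dat$rpkm) | dat$rpkm <= config$rpkm_min ~ "not_expressed",
    sig_par & !is.na(dat$maternal_fraction) &
      dat$maternal_fraction >= config$t_high & conc_mat ~ "maternal",
    sig_par & !is.na(dat$maternal_fraction) &
      dat$maternal_fraction <= config$t_low & conc_pat ~ "paternal",
    sig_str & !is.na(bias) & bias > config$strain_bias_min &
      dat$strainB_fraction > 0.5 & conc_str_B ~ "strain_B",
    sig_str & !is.na(bias) & bias > config$strain_bias_min &
      dat$strainB_fraction < 0.5 & conc_str_C ~ "strain_C",
    (sig_par & sig_str) | !dat$testable_parental | !dat$testable_strain ~ "inconclusive",
    TRUE ~ "biallelic"
  )
  dat %>%
    mutate(category = category) %>%
    select(dplyr::all_of(keys), "category", "maternal_fraction",
           "strainB_fraction", "rpkm", "padj_parental", "padj_strain")
}

#' One-call classification from counts
#'
#' Convenience wrapper running both orientation scans, condition RPKM,
#' cross fractions and [classify_conditions()].
#'
#' @param counts,samples Long allelic counts and sample sheet.
#' @param lengths Transcript lengths for RPKM (named vector, tibble, or a
#'   single recycled number).
#' @param filter,test,config Stage configurations.
#' @return See [classify_conditions()]; also carries `log_expression`
#'   (log2 of 1 + mean size-factor-normalised total over replicates).
#' @export
classify_ase <- function(counts, samples, lengths = 1000,
                         filter = filter_config(), test = test_config(),
                         config = classifier_config()) {
  samples <- check_samples(samples)
  parental <- ase_scan(counts, samples, "parental", filter, test)
  strain <- ase_scan(counts, samples, "strain", filter, test)
  rp <- condition_rpkm(counts, samples, lengths)
  cf <- cross_fractions(counts, samples)
  out <- classify_conditions(parental, strain, rp, cf, config)
  sf <- size_factors(counts)
  expr <- counts %>%
    left_join(sf, by = "sample") %>%
    left_join(select(samples, "sample", "cell_type", "stage"), by = "sample") %>%
    group_by(.data$gene, .data$cell_type, .data$stage) %>%
    summarise(log_expression = log2(
      1 + mean((.data$count_B + .data$count_C) / .data$size_factor)),
      .groups = "drop")
  left_join(out, expr, by = c("gene", "cell_type", "stage"))
}

#' Gene-level strain-bias screen
#'
#' Flags genes expressed (RPKM above the floor) in at least
#' `strain_min_conditions` conditions, of which at least
#' `strain_min_conditions` also show a strain bias score
#' `|2 f_B - 1|` above `strain_bias_min`.
#'
#' @param classified Output of [classify_conditions()] / [classify_ase()].
#' @param config A [classifier_config()].
#' @return Tibble `gene`, `n_expressed`, `n_biased`, `flagged`.
#' @export
strain_screen <- function(classified, config = classifier_config()) {
  classified %>%
    group_by(.data$gene) %>%
    summarise(
      n_expressed = sum(!is.na(.data$rpkm) & .data$rpkm > config$rpkm_min),
      n_biased = sum(!is.na(.data$rpkm) & .data$rpkm > config$rpkm_min &
                       !is.na(.data$strainB_fraction) &
                       abs(2 * .data$strainB_fraction - 1) > config$strain_bias_min),
      .groups = "drop"
    ) %>%
    mutate(flagged = .data$n_expressed >= config$strain_min_conditions &
             .data$n_biased >= config$strain_min_conditions)
}
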