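# Atlas assembly and catalogue comparison.

#' Assemble the allelome atlas
#'
#' Turns a classified long table into dense gene x condition layers
#' (category, maternal fraction, strain-B fraction, RPKM, expression).
#' Genes expressed nowhere (all conditions at or below the RPKM floor) are
#' dropped from the displayed set but retained in the full export.
#'
#' @param classified Output of [classify_ase()] / [classify_conditions()].
#' @param config A [classifier_config()].
#' @return An `ase_atlas` object: list with `long` (the input, condition
#'   label added), wide `category`, `maternal_fraction`, `strainB_fraction`,
#'   `rpkm` layers (tibbles, genes x conditions), `displayed_genes`, and
#'   `config`.
#' @export
build_atlas <- function(classified, config = classifier_config()) {
  check_columns(classified, c("gene", "cell_type", "stage", "category",
                              "maternal_fraction", "strainB_fraction", "rpkm"),
                "classified table")
  key <- paste(classified$gene, classified$cell_type, classified$stage)
  if (anyDuplicated(key) > 0) {
    abort(sprintf("duplicated condition result(s), e.g.: %s",
                  key[anyDuplicated(key)]))
  }
  long <- classified %>%
    mutate(condition = paste(.data$cell_type, .data$stage, sep = "."))
  layer <- function(col) {
    long %>%
      select("gene", "condition", dplyr::all_of(col)) %>%
      tidyr::pivot_wider(names_from = "condition", values_from = dplyr::all_of(col))
  }
  displayed <- long %>%
    group_by(.data$gene) %>%
    summarise(expressed = any(!is.na(.data$rpkm) & .data$rpkm > config$rpkm_min)) %>%
    filter(.data$expressed) %>%
    pull("gene")
  structure(list(
    long = long,
    category = layer("category"),
    maternal_fraction = layer("maternal_fraction"),
    strainB_fraction = layer("strainB_fraction"),
    rpkm = layer("rpkm"),
    displayed_genes = displayed,
    config = config
  ), class = "ase_atlas")
}

#' @export
print.ase_atlas <- function(x, ...) {
  cat(sprintf("<ase_atlas> %d gene(s) x %d condition(s); %d displayed (RPKM > %g somewhere)\n",
              nrow(x$category), ncol(x$category) - 1,
              length(x$displayed_genes), x$config$rpkm_min))
  tab <- table(x$long$category)
  cat("  categories:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy an allelome atlas back to one row per gene x condition
#'
#' @param x An `ase_atlas`.
#' @param ... Unused.
#' @return The long classified tibble.
#' @export
tidy.ase_atlas <- function(x, ...) {
  x$long
}

#' One-row atlas summary
#'
#' @param x An `ase_atlas`.
#' @param ... Unused.
#' @return Tibble with gene/condition dimensions, displayed-gene count and
#'   per-category cell counts.
#' @export
glance.ase_atlas <- function(x, ...) {
  tab <- table(factor(x$long$category,
                      levels = c("maternal", "paternal", "strain_B", "strain_C",
                                 "biallelic", "not_expressed", "inconclusive")))
  dplyr::bind_cols(
    tibble(n_genes = nrow(x$category), n_conditions = ncol(x$category) - 1,
           n_displayed = length(x$displayed_genes)),
    as_tibble(as.list(tab))
  )
}

#' Heat-map view of an allelome atlas
#'
#' Displays the maternal fraction of every displayed gene across
#' conditions; cells below the expression floor are grey.
#'
#' @param object An `ase_atlas`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ase_atlas <- function(object, ...) {
  dat <- object$long %>%
    filter(.data$gene %in% object$displayed_genes) %>%
    mutate(shown = if_else(.data$category == "not_expressed",
                           NA_real_, .data$maternal_fraction))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$condition, y = .data$gene,
                                    fill = .data$shown)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "#ffffbf",
                                  high = "#b2182b", midpoint = 0.5,
                                  limits = c(0, 1), na.value = "grey80",
                                  name = "maternal\nfraction") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}

#' Compare an atlas against a known-imprint catalogue
#'
#' A catalogue gene is *detected* when expressed above the RPKM floor in at
#' least one condition, and *concordant* when some condition's monoallelic
#' category matches the expected allele while no condition shows the
#' opposite parental category.
#'
#' @param atlas An `ase_atlas`, or the long classified tibble.
#' @param catalogue Tibble `gene`, `expected_allele`
#'   (`"maternal"`/`"paternal"`); genes must be unique.
#' @return List with `genes` (per-gene tibble: `detected`, `best_category`,
#'   `concordant`) and `totals` (one-row tibble: `n_catalogue`, `detected`,
#'   `maternal`, `paternal`, `biallelic_only`, `below_threshold`,
#'   `concordant`).
#' @export
compare_catalogue <- function(atlas, catalogue) {
  long <- if (inherits(atlas, "ase_atlas")) atlas$long else as_tibble(atlas)
  config <- if (inherits(atlas, "ase_atlas")) atlas$config else classifier_config()
  check_columns(catalogue, c("gene", "expected_allele"), "catalogue")
  if (anyDuplicated(catalogue$gene) > 0) abort("catalogue genes must be unique")
  bad <- setdiff(unique(catalogue$expected_allele), c("maternal", "paternal"))
  if (length(bad) > 0) {
    abort(sprintf("expected_allele must be 'maternal' or 'paternal'; found: %s",
                  paste(bad, collapse = ", ")))
  }
  per_gene <- long %>%
    group_by(.data$gene) %>%
    summarise(
      detected = any(!is.na(.data$rpkm) & .data$rpkm > config$rpkm_min),
      any_maternal = any(.data$category == "maternal"),
      any_paternal = any(.data$category == "paternal"),
      any_strain = any(.data$category %in% c("strain_B", "strain_C")),
      .groups = "drop"
    )
  genes <- catalogue %>%
    left_join(per_gene, by = "gene") %>%
    mutate(
      detected = tidyr::replace_na(.data$detected, FALSE),
      across(c("any_maternal", "any_paternal", "any_strain"),
             ~ tidyr::replace_na(.x, FALSE)),
      best_category = dplyr::case_when(
        !.data$detected ~ "below_threshold",
        .data$any_maternal & .data$any_paternal ~ "discordant",
        .data$any_maternal ~ "maternal",
        .data$any_paternal ~ "paternal",
        .data$any_strain ~ "strain",
        TRUE ~ "biallelic"
      ),
      concordant = .data$detected &
        ((.data$expected_allele == "maternal" & .data$any_maternal & !.data$any_paternal) |
           (.data$expected_allele == "paternal" & .data$any_paternal & !.data$any_maternal))
    ) %>%
    select("gene", "expected_allele", "detected", "best_category", "concordant")
  totals <- tibble(
    n_catalogue = nrow(genes),
    detected = sum(genes$detected),
    maternal = sum(genes$best_category == "maternal"),
    paternal = sum(genes$best_category == "paternal"),
    biallelic_only = sum(genes$best_category == "biallelic"),
    below_threshold = sum(genes$best_category == "below_threshold"),
    concordant = sum(genes$concordant)
  )
  list(genes = genes, totals = totals)
}
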