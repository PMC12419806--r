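# Reciprocal-cross classification, atlas assembly, strain screen, catalogue.

# Build the four inputs of classify_conditions() for a single gene x condition.
one_gene_inputs <- function(mf = 0.5, fB = 0.5, padj_par = 1, padj_str = 1,
                            rpkm = 10, mf_bc = mf, mf_cb = mf,
                            fb_bc = fB, fb_cb = fB,
                            testable_par = TRUE, testable_str = TRUE) {
  base <- tibble::tibble(gene = "g", cell_type = "basal", stage = "L10")
  list(
    parental = dplyr::mutate(base, maternal_fraction = mf, strainB_fraction = fB,
                             padj = padj_par, testable = testable_par),
    strain = dplyr::mutate(base, padj = padj_str, testable = testable_str),
    rpkm = dplyr::mutate(base, rpkm = rpkm),
    crossfrac = dplyr::bind_rows(
      dplyr::mutate(base, cross = "BC", maternal_fraction = mf_bc,
                    strainB_fraction = fb_bc),
      dplyr::mutate(base, cross = "CB", maternal_fraction = mf_cb,
                    strainB_fraction = fb_cb)
    )
  )
}

classify_one <- function(...) {
  x <- one_gene_inputs(...)
  classify_conditions(x$parental, x$strain, x$rpkm, x$crossfrac)$category
}

test_that("the category rules fire as stated", {
  expect_equal(classify_one(mf = 0.85, padj_par = 0.001, rpkm = 5,
                            mf_bc = 0.85, mf_cb = 0.86,
                            fb_bc = 0.85, fb_cb = 0.14), "maternal")
  expect_equal(classify_one(mf = 0.85, padj_par = 0.001, rpkm = 0.5), "not_expressed")
  expect_equal(classify_one(mf = 0.15, padj_par = 0.002,
                            mf_bc = 0.15, mf_cb = 0.16,
                            fb_bc = 0.15, fb_cb = 0.84), "paternal")
  expect_equal(classify_one(mf = 0.55, padj_par = 0.4, padj_str = 0.4), "biallelic")
  # strain bias: B fraction 0.9 in both crosses, significant strain test
  expect_equal(classify_one(mf = 0.5, fB = 0.9, padj_str = 0.001,
                            mf_bc = 0.9, mf_cb = 0.1,
                            fb_bc = 0.9, fb_cb = 0.9), "strain_B")
  expect_equal(classify_one(mf = 0.5, fB = 0.1, padj_str = 0.001,
                            mf_bc = 0.1, mf_cb = 0.9,
                            fb_bc = 0.1, fb_cb = 0.1), "strain_C")
  # untestable orientation is inconclusive, not biallelic
  expect_equal(classify_one(padj_par = NA, testable_par = FALSE), "inconclusive")
  # both orientations significant without a clean call
  expect_equal(classify_one(mf = 0.6, fB = 0.6, padj_par = 0.01, padj_str = 0.01),
               "inconclusive")
  # significance gates the call: strong ratio with weak evidence stays biallelic
  expect_equal(classify_one(mf = 0.85, padj_par = 0.2,
                            mf_bc = 0.85, mf_cb = 0.85), "biallelic")
  # discordant crosses block a parental call even when pooled ratio passes
  expect_equal(classify_one(mf = 0.75, padj_par = 0.001,
                            mf_bc = 0.95, mf_cb = 0.40), "biallelic")
})

test_that("every gene x condition receives exactly one valid category", {
  cfg <- sim_config(n_genes = 200, n_cell_types = 2, n_stages = 2,
                    class_probs = c(biallelic = 0.5, maternal = 0.1, paternal = 0.1,
                                    strain_B = 0.1, strain_C = 0.1, silent = 0.1),
                    seed = 211)
  sim <- simulate_counts(cfg)
  res <- classify_ase(sim$counts, sim$samples,
                      test = test_config(n_resamples = 300, seed = 211))
  expect_equal(nrow(res), 200 * 4)
  expect_true(all(res$category %in% c("maternal", "paternal", "strain_B", "strain_C",
                                      "biallelic", "not_expressed", "inconclusive")))
  expect_false(anyNA(res$category))
  # silent genes sit below the expression floor everywhere
  silent <- sim$truth$gene[sim$truth$class == "silent"]
  expect_true(all(res$category[res$gene %in% silent] == "not_expressed"))
})

test_that("the strain screen requires both condition floors", {
  base <- tidyr::expand_grid(gene = "g", cell_type = "basal",
                             stage = paste0("s", 1:6))
  # expressed in only 2 conditions: below the count floor
  two <- dplyr::mutate(base, category = "biallelic", maternal_fraction = 0.5,
                       strainB_fraction = 0.95,
                       rpkm = c(5, 5, 0, 0, 0, 0),
                       padj_parental = 1, padj_strain = 1)
  expect_false(strain_screen(two)$flagged)
  # B fraction 0.9 (bias 0.8) in 5 expressed conditions: flagged
  five <- dplyr::mutate(base, category = "biallelic", maternal_fraction = 0.5,
                        strainB_fraction = 0.9,
                        rpkm = c(5, 5, 5, 5, 5, 0),
                        padj_parental = 1, padj_strain = 1)
  expect_true(strain_screen(five)$flagged)
  # broadly expressed but unbiased: not flagged
  flat <- dplyr::mutate(five, strainB_fraction = 0.55)
  expect_false(strain_screen(flat)$flagged)
})

test_that("planted strain genes are recovered by the screen, biallelic are not", {
  cfg <- sim_config(n_genes = 400, n_cell_types = 1, n_stages = 5,
                    class_probs = c(biallelic = 0.5, strain_B = 0.5),
                    strain_fraction_effect = 0.9,
                    mean_log_expression = c(meanlog = log(200), sdlog = 0),
                    bb_overdispersion = 0.02, seed = 223)
  sim <- simulate_counts(cfg)
  res <- classify_ase(sim$counts, sim$samples,
                      test = test_config(n_resamples = 300, seed = 223))
  flags <- strain_screen(res) |>
    dplyr::left_join(dplyr::select(sim$truth, gene, class), by = "gene")
  expect_gte(mean(flags$flagged[flags$class == "strain_B"]), 0.95)
  expect_lte(mean(flags$flagged[flags$class == "biallelic"]), 0.05)
})

test_that("the atlas has dense layers and drops silent genes from display", {
  cfg <- sim_config(n_genes = 10, n_cell_types = 6, n_stages = 10,
                    class_probs = c(biallelic = 0.8, silent = 0.2), seed = 227)
  sim <- simulate_counts(cfg)
  res <- classify_ase(sim$counts, sim$samples,
                      test = test_config(n_resamples = 200, seed = 227))
  atlas <- build_atlas(res)
  expect_s3_class(atlas, "ase_atlas")
  expect_equal(dim(atlas$category), c(10, 61))  # gene column + 60 conditions
  expect_equal(dim(atlas$maternal_fraction), c(10, 61))
  silent <- sim$truth$gene[sim$truth$class == "silent"]
  expect_true(all(!silent %in% atlas$displayed_genes))
  expect_true(all(silent %in% atlas$category$gene))  # retained in full export
  expect_error(build_atlas(dplyr::bind_rows(res, res[1, ])), "duplicated")

  # broom-style accessors and plotting
  expect_equal(tidy(atlas)[names(res)], res)
  g <- glance(atlas)
  expect_equal(g$n_genes, 10)
  expect_equal(g$n_conditions, 60)
  expect_s3_class(autoplot(atlas), "ggplot")
})

test_that("catalogue comparison tallies detection and concordance", {
  base <- tidyr::expand_grid(gene = c("g1", "g2", "g3"), cell_type = "basal",
                             stage = c("s1", "s2")) |>
    dplyr::mutate(category = "biallelic", maternal_fraction = 0.5,
                  strainB_fraction = 0.5, rpkm = 5,
                  padj_parental = 1, padj_strain = 1)
  base$category[base$gene == "g1" & base$stage == "s1"] <- "maternal"
  base$rpkm[base$gene == "g3"] <- 0  # below threshold everywhere
  catalogue <- tibble::tibble(gene = c("g1", "g2", "g3", "g4"),
                              expected_allele = c("maternal", "paternal",
                                                  "maternal", "paternal"))
  cmp <- compare_catalogue(base, catalogue)
  expect_equal(cmp$totals$n_catalogue, 4)
  expect_equal(cmp$totals$detected, 2)
  expect_equal(cmp$totals$maternal, 1)
  expect_equal(cmp$totals$below_threshold, 2)  # g3 unexpressed, g4 absent
  expect_equal(cmp$totals$concordant, 1)
  g1 <- dplyr::filter(cmp$genes, gene == "g1")
  expect_true(g1$detected && g1$concordant)
  expect_equal(g1$best_category, "maternal")
  expect_error(compare_catalogue(base, catalogue[c(1, 1), ]), "unique")
})

test_that("perfect-information planting gives full catalogue concordance", {
  cfg <- sim_config(n_genes = 60, n_cell_types = 1, n_stages = 1,
                    class_probs = c(maternal = 0.5, paternal = 0.5),
                    maternal_fraction_effect = 1.0, bb_overdispersion = 0,
                    mean_log_expression = c(meanlog = log(300), sdlog = 0),
                    seed = 229)
  sim <- simulate_counts(cfg)
  res <- classify_ase(sim$counts, sim$samples,
                      test = test_config(n_resamples = 300, seed = 229))
  catalogue <- dplyr::transmute(sim$truth, gene, expected_allele = class)
  cmp <- compare_catalogue(build_atlas(res), catalogue)
  expect_equal(cmp$totals$detected, 60)
  expect_equal(cmp$totals$concordant, 60)
})
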