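# Normalisation, tolerance filter, and the sign-flip resampling test.

test_that("size factors follow median-of-ratios", {
  # identical samples are symmetric
  counts <- tidyr::expand_grid(gene = c("g1", "g2", "g3"), sample = c("s1", "s2")) |>
    dplyr::mutate(total = rep(c(10, 20, 30), each = 2))
  expect_equal(size_factors(counts)$size_factor, c(1, 1))

  # hand computation: gene1 (2, 8), gene2 (4, 16) -> factors (0.5, 2)
  hand <- tibble::tibble(gene = c("g1", "g1", "g2", "g2"),
                         sample = c("s1", "s2", "s1", "s2"),
                         total = c(2, 8, 4, 16))
  expect_equal(size_factors(hand)$size_factor, c(0.5, 2))

  # homogeneity: scaling one sample's counts by c scales its factor
  # relative to the others by c (the gene geometric means rescale too, so
  # only the factor ratio is invariant under median-of-ratios)
  scaled <- dplyr::mutate(hand, total = ifelse(sample == "s2", total * 3, total))
  sf0 <- size_factors(hand)$size_factor
  sf1 <- size_factors(scaled)$size_factor
  expect_equal(sf1[2] / sf1[1], 3 * sf0[2] / sf0[1])

  # no gene positive everywhere
  sparse <- tibble::tibble(gene = c("g1", "g1"), sample = c("s1", "s2"),
                           total = c(5, 0))
  expect_error(size_factors(sparse), "positive")
})

test_that("size factors agree with the DESeq2 median-of-ratios estimator", {
  set.seed(97)
  # odd gene count so the median is an order statistic and the arithmetic /
  # geometric handling of midpoints cannot differ between implementations
  mat <- matrix(rnbinom(306, mu = 50, size = 5) + 1, nrow = 51,
                dimnames = list(paste0("g", 1:51), paste0("s", 1:6)))
  mat[, 3] <- mat[, 3] * 4L
  ours <- size_factors(mat)$size_factor
  ref <- unname(DESeq2::estimateSizeFactorsForMatrix(mat))
  # same estimator up to the geometric-mean normalisation DESeq2 applies
  expect_equal(ours / exp(mean(log(ours))), ref / exp(mean(log(ref))),
               tolerance = 1e-8)
})

test_that("rpkm follows the direct formula and its invariances", {
  expect_equal(rpkm(100, 2000, 1e6), 50)
  expect_equal(rpkm(0, 2000, 1e6), 0)
  expect_equal(rpkm(2 * 100, 2000, 2 * 1e6), rpkm(100, 2000, 1e6))
  expect_error(rpkm(1, 0, 1e6), "length")
  expect_error(rpkm(1, 100, 0), "library")
})

test_that("condition RPKM averages replicates of each condition", {
  sheet <- tiny_samples(2)
  counts <- counts_from_pairs("g1", sheet, b = c(10, 20, 10, 20), c = 0) |>
    dplyr::bind_rows(counts_from_pairs("g2", sheet, b = 90, c = 0))
  out <- condition_rpkm(counts, sheet, c(g1 = 1000, g2 = 500))
  lib <- c(100, 110, 100, 110)  # per-sample totals
  expect_equal(out$rpkm[out$gene == "g1"],
               mean(c(10, 20, 10, 20) * 1e9 / (1000 * lib)))
})

test_that("the tolerance filter counts adequately covered replicates", {
  totals <- c(50, 50, 50, 50, 0, 0, 0, 0)
  expect_true(filter_tolerant(totals, filter_config(tolerance = 50)))
  expect_false(filter_tolerant(totals, filter_config(tolerance = 0)))
  expect_true(filter_tolerant(totals, filter_config(tolerance = 100)))
  expect_false(filter_tolerant(numeric(0), filter_config()))
  # boundary: 3 of 8 covered fails at tolerance 50 (needs >= 4)
  expect_false(filter_tolerant(c(50, 50, 50, 0, 0, 0, 0, 0),
                               filter_config(tolerance = 50)))
})

test_that("sign-flip test handles exact nulls and saturated effects", {
  # balanced fractions: exact null
  null <- sign_flip_test(rep(0.5, 8), 1000, seed = 1, method = "resample")
  expect_equal(null$statistic, 0)
  expect_equal(null$p, 1)
  # antisymmetric cancellation
  anti <- sign_flip_test(rep(c(0.8, 0.2), 4), 1000, seed = 1, method = "resample")
  expect_equal(anti$statistic, 0)
  expect_equal(anti$p, 1)
  # saturated monoallelic effect: exhaustive two-sided p is exactly 2/2^8
  exact <- sign_flip_test(rep(1, 8), method = "exhaustive")
  expect_equal(exact$p, 2 / 256)
  res <- sign_flip_test(rep(1, 8), 2000, seed = 5, method = "resample")
  se <- sqrt((2 / 256) * (1 - 2 / 256) / 2000)
  expect_lt(abs(res$p - 2 / 256), 3 * se + 1 / 2001)
})

test_that("resampled p-values track the exhaustive oracle over random genes", {
  set.seed(101)
  n_res <- 1000
  for (i in 1:50) {
    f <- pmin(pmax(rnorm(8, 0.5 + sample(c(0, 0.2), 1), 0.15), 0), 1)
    p_ex <- oracle_exhaustive_p(f)
    p_rs <- sign_flip_test(f, n_res, seed = i, method = "resample")$p
    se <- sqrt(p_ex * (1 - p_ex) / n_res)
    expect_lt(abs(p_rs - p_ex), 3 * se + 2 / (n_res + 1))
  }
})

test_that("p-values respect the permutation floor", {
  set.seed(103)
  for (i in 1:20) {
    f <- runif(6)
    p <- sign_flip_test(f, 200, seed = i, method = "resample")$p
    expect_gte(p, 1 / 201)
    expect_lte(p, 1)
  }
})

test_that("BH adjustment matches the hand-applied step-up", {
  expect_equal(adjust_pvalues(0.03), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_pvalues(rep(1, 5)), rep(1, 5))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(107)
  p <- runif(100)
  expect_true(all(adjust_pvalues(p) >= p))
})

test_that("the scan flags untestable genes instead of forcing p = 1", {
  sheet <- tiny_samples(4)
  counts <- dplyr::bind_rows(
    counts_from_fraction("expressed", sheet, 100, 0.9),
    counts_from_pairs("dead", sheet, b = 0, c = 0),
    counts_from_pairs("sparse", sheet, b = c(40, 0, 0, 0, 0, 0, 0, 0), c = 0)
  )
  res <- ase_scan(counts, sheet, "parental",
                  test = test_config(n_resamples = 500, seed = 1))
  dead <- dplyr::filter(res, gene == "dead")
  expect_false(dead$testable)
  expect_true(is.na(dead$p))
  expect_equal(dead$n_informative_reps, 0)
  sparse <- dplyr::filter(res, gene == "sparse")  # fails tolerance at 50
  expect_false(sparse$filter_pass)
  expect_true(is.na(sparse$p))
  hit <- dplyr::filter(res, gene == "expressed")
  expect_true(hit$testable)
  expect_equal(hit$maternal_fraction, 0.9)
  expect_equal(hit$statistic, 0.4)
  expect_equal(hit$p, 2 / 256)  # enumerable null at 8 replicates
  expect_true(hit$padj >= hit$p)
})

test_that("strain orientation measures the B fraction regardless of cross", {
  sheet <- tiny_samples(4)
  # strain-biased gene: B fraction 0.9 in both crosses
  counts <- counts_from_pairs("g", sheet, b = 90, c = 10)
  par <- ase_scan(counts, sheet, "parental",
                  test = test_config(n_resamples = 500, seed = 1))
  str <- ase_scan(counts, sheet, "strain",
                  test = test_config(n_resamples = 500, seed = 1))
  expect_equal(par$statistic, 0)   # maternal deviations cancel across crosses
  expect_equal(par$p, 1)
  expect_equal(str$statistic, 0.4)
  expect_equal(str$p, 2 / 256)
})

test_that("rejection rate rises with effect size and expression", {
  fracs <- c(0.55, 0.7, 0.9)
  means <- c(20, 80, 320)
  rate <- matrix(NA_real_, 3, 3)
  for (i in seq_along(fracs)) {
    for (j in seq_along(means)) {
      cfg <- sim_config(n_genes = 120, n_cell_types = 1, n_stages = 1,
                        class_probs = c(maternal = 1),
                        maternal_fraction_effect = fracs[i],
                        mean_log_expression = c(meanlog = log(means[j]), sdlog = 0),
                        bb_overdispersion = 0.02, seed = 1000 + 10 * i + j)
      sim <- simulate_counts(cfg)
      sc <- ase_scan(sim$counts, sim$samples, "parental",
                     test = test_config(n_resamples = 500, seed = 7))
      rate[i, j] <- mean(sc$p <= 0.05, na.rm = TRUE)
    }
  }
  slack <- 0.07  # Monte-Carlo slack on 120-gene rates
  expect_true(all(diff(rate[, 3]) >= -slack))  # in effect size
  expect_true(all(diff(rate[3, ]) >= -slack))  # in expression
  expect_gt(rate[3, 3], 0.95)
  expect_lt(rate[1, 1], 0.6)
})
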