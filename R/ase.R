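# Normalisation, tolerance filtering, and the sign-flip resampling test of
# allelic imbalance -- the statistical core.
#
# The test is ISoLDE-style: per replicate i the oriented allelic fraction
# f_i is computed (maternal fraction in parental orientation, strain-B
# fraction in strain orientation), the statistic is the unweighted mean
# deviation S = mean(f_i - 1/2), and the null is built by sign-flip
# resampling of the per-replicate deviations. Replicate-level
# exchangeability justifies the sign-flip null; pooling counts would
# conflate replicates, so pooled fractions are reported for display only.

#' Tolerance-filter configuration
#'
#' The tolerance filter is a pre-test gate: a gene x condition passes when
#' enough replicates are adequately covered. `tolerance` ranges from 0
#' (strict: every replicate must be covered) to 100 (permissive: one
#' suffices); the default 50 balances the two extremes.
#'
#' @param tolerance Integer in `[0, 100]`; default 50.
#' @param min_count_per_rep Reads required for a replicate to count as
#'   covered; default 10.
#' @return A `filter_config` list.
#' @export
filter_config <- function(tolerance = 50, min_count_per_rep = 10) {
  stopifnot(tolerance >= 0, tolerance <= 100, min_count_per_rep >= 0)
  structure(list(tolerance = tolerance, min_count_per_rep = min_count_per_rep),
            class = "filter_config")
}

#' Resampling-test configuration
#'
#' @param n_resamples Number of sign-flip resamples per gene; default 5000.
#' @param alpha Significance level; default 0.05.
#' @param orientation `"parental"` (maternal-fraction deviations) or
#'   `"strain"` (strain-B-fraction deviations).
#' @param seed Global integer seed; per-gene substreams are derived from it
#'   and the gene id, so results do not depend on gene order.
#' @param min_informative_reps Minimum number of replicates with nonzero
#'   total for a gene x condition to be testable; default 2.
#' @param method Null construction passed to [sign_flip_test()]; the
#'   default `"auto"` enumerates the null exactly when `2^n` replicate
#'   sign assignments fit in the resampling budget.
#' @return A `test_config` list.
#' @export
test_config <- function(n_resamples = 5000, alpha = 0.05,
                        orientation = c("parental", "strain"),
                        seed = 1L, min_informative_reps = 2,
                        method = c("auto", "resample", "exhaustive")) {
  orientation <- match.arg(orientation)
  method <- match.arg(method)
  stopifnot(n_resamples >= 1, alpha > 0, alpha < 1, min_informative_reps >= 1)
  structure(list(n_resamples = as.integer(n_resamples), alpha = alpha,
                 orientation = orientation, seed = as.integer(seed),
                 min_informative_reps = as.integer(min_informative_reps),
                 method = method),
            class = "test_config")
}

#' Median-of-ratios size factors
#'
#' Per sample, the median over genes of `count / geometric-mean-across-
#' samples`, restricted to genes with positive counts in every sample.
#'
#' @param counts Long tibble with `gene`, `sample` and either `total` or
#'   `count_B` + `count_C` columns, or a gene x sample numeric matrix.
#' @return Tibble `sample`, `size_factor`.
#' @export
size_factors <- function(counts) {
  mat <- as_total_matrix(counts)
  keep <- rowSums(mat > 0) == ncol(mat)
  if (!any(keep)) {
    abort(paste("no gene has positive counts in every sample;",
                "consider pooling samples or relaxing the input"))
  }
  m <- mat[keep, , drop = FALSE]
  geo <- exp(rowMeans(log(m)))
  sf <- apply(m / geo, 2, median)
  tibble(sample = colnames(mat), size_factor = unname(sf))
}

# Long counts (or matrix) -> gene x sample matrix of totals.
as_total_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  counts <- as_tibble(counts)
  if (!"total" %in% names(counts)) {
    check_columns(counts, c("gene", "sample", "count_B", "count_C"), "count table")
    counts <- mutate(counts, total = .data$count_B + .data$count_C)
  }
  wide <- tidyr::pivot_wider(select(counts, "gene", "sample", "total"),
                             names_from = "sample", values_from = "total",
                             values_fill = 0)
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$gene
  mat
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = count * 1e9 / (length * library_size)`.
#'
#' @param count Read count(s).
#' @param length Transcript length(s) in nucleotides; must be positive.
#' @param library_size Mapped reads in the sample; must be positive.
#' @return Numeric vector of RPKM values.
#' @examples
#' rpkm(100, 2000, 1e6)  # 50
#' @export
rpkm <- function(count, length, library_size) {
  if (any(length <= 0)) abort("transcript lengths must be positive")
  if (any(library_size <= 0)) abort("library sizes must be positive")
  count * 1e9 / (length * library_size)
}

#' Per-sample and per-condition RPKM tables
#'
#' Library sizes are the per-sample total counts (both alleles summed).
#' The condition-level value is the mean over that condition's replicates.
#'
#' @param counts Long allelic count tibble.
#' @param samples Sample sheet.
#' @param lengths Named numeric vector of transcript lengths (nt), or a
#'   tibble with `gene` and `length` columns; a single unnamed number is
#'   recycled to all genes.
#' @return `rpkm_table()`: tibble `gene`, `sample`, `rpkm`;
#'   `condition_rpkm()`: tibble `gene`, `cell_type`, `stage`, `rpkm`.
#' @export
rpkm_table <- function(counts, samples, lengths) {
  samples <- check_samples(samples)
  lengths <- as_length_vector(lengths, unique(counts$gene))
  totals <- counts %>%
    mutate(total = .data$count_B + .data$count_C) %>%
    group_by(.data$sample) %>%
    mutate(library_size = sum(.data$total)) %>%
    ungroup()
  if (any(totals$library_size <= 0)) {
    empty <- unique(totals$sample[totals$library_size <= 0])
    abort(sprintf("sample(s) with zero library size: %s",
                  paste(head(empty, 5), collapse = ", ")))
  }
  totals %>%
    mutate(rpkm = rpkm(.data$total, lengths[.data$gene], .data$library_size)) %>%
    select("gene", "sample", "rpkm")
}

#' @rdname rpkm_table
#' @export
condition_rpkm <- function(counts, samples, lengths) {
  samples <- check_samples(samples)
  rpkm_table(counts, samples, lengths) %>%
    left_join(select(samples, "sample", "cell_type", "stage"), by = "sample") %>%
    group_by(.data$gene, .data$cell_type, .data$stage) %>%
    summarise(rpkm = mean(.data$rpkm), .groups = "drop")
}

as_length_vector <- function(lengths, genes) {
  if (is.data.frame(lengths)) {
    check_columns(lengths, c("gene", "length"), "length table")
    lengths <- setNames(lengths$length, lengths$gene)
  }
  if (is.null(names(lengths))) {
    if (length(lengths) != 1) abort("unnamed lengths must be a single number")
    lengths <- setNames(rep(lengths, length(genes)), genes)
  }
  missing <- setdiff(genes, names(lengths))
  if (length(missing) > 0) {
    abort(sprintf("no length for gene(s): %s", paste(head(missing, 5), collapse = ", ")))
  }
  lengths
}

#' Tolerance filter for one gene x condition
#'
#' Passes when the number of replicates with total coverage at least
#' `min_count_per_rep` reaches `max(1, ceiling(n * (1 - tolerance/100)))`,
#' where `n` is the number of replicates across both crosses. Zero
#' replicates fail.
#'
#' @param totals Per-replicate total counts (both alleles summed).
#' @param filter A [filter_config()].
#' @return Logical scalar.
#' @examples
#' filter_tolerant(c(50, 50, 50, 50, 0, 0, 0, 0), filter_config(tolerance = 50))
#' @export
filter_tolerant <- function(totals, filter = filter_config()) {
  n <- length(totals)
  if (n == 0) return(FALSE)
  needed <- max(1, ceiling(n * (1 - filter$tolerance / 100)))
  sum(totals >= filter$min_count_per_rep) >= needed
}

#' Sign-flip resampling test of allelic imbalance
#'
#' For oriented per-replicate fractions `f`, tests `S = mean(f - 1/2)`
#' against the null obtained by randomly negating each replicate's
#' deviation: `S* = mean(eps_i (f_i - 1/2))`, `eps_i` i.i.d. uniform on
#' `{-1, +1}`. The p-value is `(1 + #{|S*| >= |S|}) / (n_resamples + 1)`,
#' never below `1 / (n_resamples + 1)`. With `method = "exhaustive"` all
#' `2^n` sign assignments are enumerated and `p = #{|S*| >= |S|} / 2^n`.
#'
#' With few replicates the null is fully enumerable; `method = "auto"`
#' (the default) switches to exhaustive enumeration whenever `2^n` does not
#' exceed `n_resamples`, which makes the p-value exact and deterministic at
#' no extra cost.
#'
#' @param f Per-replicate oriented fractions in `[0, 1]` (zero-total
#'   replicates must already be excluded).
#' @param n_resamples Resamples for `method = "resample"`.
#' @param seed Integer seed (ignored for exhaustive enumeration).
#' @param method `"auto"`, `"resample"` or `"exhaustive"`.
#' @return List with `statistic` and `p`.
#' @export
sign_flip_test <- function(f, n_resamples = 5000, seed = 1L,
                           method = c("auto", "resample", "exhaustive")) {
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (length(f) <= 25 && 2^length(f) <= n_resamples) "exhaustive" else "resample"
  }
  dev <- f - 0.5
  n <- length(dev)
  s_obs <- mean(dev)
  tol <- 1e-12
  if (method == "exhaustive") {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    s_null <- as.vector(signs %*% dev) / n
    p <- mean(abs(s_null) >= abs(s_obs) - tol)
  } else {
    p <- with_seed(seed, {
      signs <- matrix(sample(c(-1, 1), n_resamples * n, replace = TRUE),
                      nrow = n_resamples)
      s_null <- as.vector(signs %*% dev) / n
      (1 + sum(abs(s_null) >= abs(s_obs) - tol)) / (n_resamples + 1)
    })
  }
  list(statistic = s_obs, p = p)
}

#' Oriented per-replicate allelic fractions
#'
#' Parental orientation returns the maternal fraction (allele B is maternal
#' in BC hybrids, allele C in CB hybrids); strain orientation returns the
#' strain-B fraction regardless of cross.
#'
#' @param count_B,count_C Allelic counts per replicate.
#' @param cross Cross label per replicate (`"BC"`/`"CB"`).
#' @param orientation `"parental"` or `"strain"`.
#' @return Fractions (NaN where the total is zero).
#' @export
oriented_fraction <- function(count_B, count_C, cross,
                              orientation = c("parental", "strain")) {
  orientation <- match.arg(orientation)
  total <- count_B + count_C
  if (orientation == "strain") return(count_B / total)
  ifelse(cross == "BC", count_B, count_C) / total
}

#' Benjamini-Hochberg adjustment
#'
#' @param p P-values in `[0, 1]` (`NA` allowed for untestable entries).
#' @return Adjusted p-values (elementwise at least `p`).
#' @export
adjust_pvalues <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Tolerance-filtered allelic-imbalance scan over all genes and conditions
#'
#' The full statistical pass: for every gene x cell type x stage, applies
#' the tolerance filter, computes oriented per-replicate fractions
#' (replicates with zero total are dropped, no pseudocounts), runs the
#' sign-flip resampling test, and adjusts p-values by Benjamini-Hochberg
#' within each condition. Gene x conditions failing the filter or with
#' fewer than `min_informative_reps` informative replicates are flagged
#' untestable (`p = NA`), never silently given `p = 1`.
#'
#' @param counts Long allelic count tibble (`gene`, `sample`, `count_B`,
#'   `count_C`).
#' @param samples Sample sheet.
#' @param orientation `"parental"` or `"strain"`; overrides the value in
#'   `test`.
#' @param filter A [filter_config()].
#' @param test A [test_config()].
#' @return Tibble with one row per gene x condition: `gene`, `cell_type`,
#'   `stage`, `orientation`, `n_reps`, `n_informative_reps`, `filter_pass`,
#'   `maternal_fraction` and `strainB_fraction` (pooled, for display),
#'   `statistic`, `p`, `padj`, `testable`.
#' @export
ase_scan <- function(counts, samples, orientation = NULL,
                     filter = filter_config(), test = test_config()) {
  samples <- check_samples(samples)
  orientation <- orientation %||% test$orientation
  orientation <- match.arg(orientation, c("parental", "strain"))
  check_columns(counts, c("gene", "sample", "count_B", "count_C"), "count table")
  unknown <- setdiff(unique(counts$sample), samples$sample)
  if (length(unknown) > 0) {
    abort(sprintf("count sample(s) absent from the sample sheet: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  dat <- counts %>%
    left_join(select(samples, "sample", "cross", "cell_type", "stage"),
              by = "sample") %>%
    mutate(total = .data$count_B + .data$count_C)

  res <- dat %>%
    group_by(.data$gene, .data$cell_type, .data$stage) %>%
    summarise(
      n_reps = n(),
      n_informative_reps = sum(.data$total > 0),
      filter_pass = filter_tolerant(.data$total, filter),
      pooled_total = sum(.data$total),
      pooled_maternal = sum(ifelse(.data$cross == "BC", .data$count_B, .data$count_C)),
      pooled_B = sum(.data$count_B),
      f_list = list(oriented_fraction(
        .data$count_B[.data$total > 0], .data$count_C[.data$total > 0],
        .data$cross[.data$total > 0], orientation)),
      .groups = "drop"
    ) %>%
    mutate(
      maternal_fraction = if_else(.data$pooled_total > 0,
                                  .data$pooled_maternal / .data$pooled_total,
                                  NA_real_),
      strainB_fraction = if_else(.data$pooled_total > 0,
                                 .data$pooled_B / .data$pooled_total,
                                 NA_real_)
    )

  testable <- res$filter_pass & res$n_informative_reps >= test$min_informative_reps
  stat <- rep(NA_real_, nrow(res))
  pval <- rep(NA_real_, nrow(res))
  key <- paste(res$gene, res$cell_type, res$stage)
  for (i in which(res$n_informative_reps > 0)) {
    f <- res$f_list[[i]]
    stat[i] <- mean(f - 0.5)
    if (testable[i]) {
      pval[i] <- sign_flip_test(f, test$n_resamples,
                                seed = derive_seed(test$seed, key[i]),
                                method = test$method %||% "auto")$p
    }
  }
  res %>%
    mutate(orientation = orientation, statistic = stat, p = pval,
           testable = testable) %>%
    group_by(.data$cell_type, .data$stage) %>%
    mutate(padj = adjust_pvalues(.data$p)) %>%
    ungroup() %>%
    select("gene", "cell_type", "stage", "orientation", "n_reps",
           "n_informative_reps", "filter_pass", "testable",
           "maternal_fraction", "strainB_fraction", "statistic", "p", "padj")
}
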