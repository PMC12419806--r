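# Internal helpers shared across modules.

`%||%` <- rlang::`%||%`

#' Derive a reproducible per-gene random seed
#'
#' Combines a global integer seed with a gene identifier through a polynomial
#' rolling hash (mod 2^31 - 1). The derived stream depends only on the gene
#' name and the global seed -- never on sample labels or counts -- so
#' label-permutation symmetries of the data reproduce resampling p-values
#' exactly.
#'
#' @param seed Global integer seed.
#' @param key Character scalar (typically a gene id).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, key) {
  m <- 2147483647
  h <- as.numeric(seed %% m)
  for (code in utf8ToInt(as.character(key))) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# the caller's RNG state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Beta-binomial random draws (intraclass-correlation parameterization)
#'
#' Draws `count ~ BetaBinomial(size, prob, rho)` where `rho` in `[0, 1)` is the
#' intraclass correlation: `rho = 0` reduces exactly to the binomial, and the
#' variance inflates as `size * prob * (1 - prob) * (1 + (size - 1) * rho)`.
#' Degenerate probabilities 0 and 1 return exact 0 and `size`.
#'
#' @param n Number of draws.
#' @param size Integer vector of trial counts (recycled).
#' @param prob Success probability vector (recycled).
#' @param rho Intraclass correlation in `[0, 1)`.
#' @return Integer vector of length `n`.
#' @export
rbetabinom <- function(n, size, prob, rho = 0) {
  stopifnot(rho >= 0, rho < 1)
  size <- rep_len(size, n)
  prob <- rep_len(prob, n)
  out <- integer(n)
  fixed <- prob <= 0 | prob >= 1 | rho == 0
  if (any(fixed)) {
    deg0 <- fixed & prob <= 0
    deg1 <- fixed & prob >= 1
    bin <- fixed & prob > 0 & prob < 1
    out[deg0] <- 0L
    out[deg1] <- as.integer(size[deg1])
    if (any(bin)) out[bin] <- rbinom(sum(bin), size[bin], prob[bin])
  }
  if (any(!fixed)) {
    shape <- (1 - rho) / rho
    p <- rbeta(sum(!fixed), prob[!fixed] * shape, (1 - prob[!fixed]) * shape)
    out[!fixed] <- rbinom(sum(!fixed), size[!fixed], p)
  }
  out
}

# Check that a data frame has the given columns, with a caller-facing error.
check_columns <- function(x, cols, what) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(x)
}

# Validate a sample sheet: sample, cross in {BC, CB}, cell_type, stage, replicate.
check_samples <- function(samples) {
  check_columns(samples, c("sample", "cross", "cell_type", "stage", "replicate"),
                "sample sheet")
  bad <- setdiff(unique(samples$cross), c("BC", "CB"))
  if (length(bad) > 0) {
    abort(sprintf("sample sheet 'cross' must be 'BC' or 'CB'; found: %s",
                  paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample) > 0) {
    abort("sample sheet has duplicated sample ids")
  }
  key <- paste(samples$cross, samples$cell_type, samples$stage, samples$replicate)
  if (anyDuplicated(key) > 0) {
    abort("sample sheet has duplicated (cross, cell_type, stage, replicate) combinations")
  }
  invisible(as_tibble(samples))
}

#' The maternal strain implied by a reciprocal-cross label
#'
#' In a BC hybrid the dam is strain B; in a CB hybrid the dam is strain C.
#'
#' @param cross Character vector of cross labels, `"BC"` or `"CB"`.
#' @return Character vector, `"B"` or `"C"`.
#' @export
maternal_strain <- function(cross) {
  ifelse(cross == "BC", "B", "C")
}
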