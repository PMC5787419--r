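#' Rank-based inverse-normal transform
#'
#' Maps a numeric vector onto standard-normal quantiles of its rank fractions,
#' using the offset `(rank - 0.5) / n` with average ranks for ties. This is the
#' normalisation applied to every gene expression profile and to the scouting
#' variable (age) before any liquid-association computation, so that the
#' standard-normal distributional assumption behind the score holds by
#' construction.
#'
#' Ties map to equal outputs; a constant vector maps to all zeros (the median
#' rank fraction 0.5 has quantile 0). The output preserves the ordering of the
#' input.
#'
#' @param x Numeric vector with no missing or infinite entries.
#' @return Numeric vector of the same length, marginally standard normal up to
#'   rank discreteness.
#' @examples
#' inverse_normal_transform(c(3, 1, 2))
#' inverse_normal_transform(c(5, 5, 5))
#' @export
inverse_normal_transform <- function(x) {
  check_finite_vector(x, "x", min_n = 1L)
  r <- rank(x, ties.method = "average")
  qnorm((r - 0.5) / length(x))
}

#' Liquid-association score
#'
#' The sample liquid-association score of a gene pair (x, y) with respect to a
#' scouting variable z: the mean of elementwise triple products
#' `sum(x * y * z) / n`. When all three inputs are standard normal this
#' estimates E\[g'(Z)\] for g(z) = E(XY | Z = z) by Stein's lemma, i.e. how fast
#' the conditional co-expression of the pair changes along z.
#'
#' Inputs are assumed to be already inverse-normal transformed; this function
#' does not re-transform. The score is symmetric in `x` and `y` and flips sign
#' if any single argument is negated.
#'
#' @param x,y,z Numeric vectors of equal length n >= 3, finite.
#' @return A single numeric score.
#' @examples
#' z <- inverse_normal_transform(1:20)
#' x <- rnorm(20); y <- rnorm(20)
#' liquid_association(x, y, z)
#' @export
liquid_association <- function(x, y, z) {
  check_finite_vector(x, "x")
  check_finite_vector(y, "y")
  check_finite_vector(z, "z")
  if (length(x) != length(y) || length(x) != length(z)) {
    abort(sprintf(
      "x, y and z must have equal length (got %d, %d, %d)",
      length(x), length(y), length(z)
    ))
  }
  mean(x * y * z)
}

#' Generate shared permutation orderings
#'
#' Draws `n_perm` uniformly random index orderings of `1:n`, as rows of an
#' integer matrix. One set of orderings is generated per screening run and
#' reused for every gene pair, which makes results reproducible and comparable
#' across pairs. The identity ordering is not excluded: orderings are sampled
#' uniformly from all n! possibilities.
#'
#' @param n Number of samples.
#' @param n_perm Number of permutations (default 100).
#' @param seed Optional integer seed; when supplied the caller's RNG state is
#'   left untouched.
#' @return An `n_perm` x `n` integer matrix, each row a permutation of `1:n`.
#' @export
make_permutations <- function(n, n_perm = 100, seed = NULL) {
  if (n_perm < 2) abort("at least 2 permutations are required")
  if (n < 3) abort("n must be at least 3")
  with_local_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
  })
}

#' Permutation significance test for a liquid-association score
#'
#' Computes the observed score, re-computes it with the scouting variable
#' reordered by each supplied permutation, fits a normal null
#' N(mu_hat, sigma_hat^2) to the permuted scores, and evaluates the two-tailed
#' p-value
#' `p = 1 - pnorm((|LAS| - mu_hat) / sigma_hat) + pnorm((-|LAS| - mu_hat) / sigma_hat)`,
#' clamped to \[0, 1\]. The normal fit avoids the granularity of an empirical
#' p-value from a modest number of permutations (100 by default).
#'
#' `mu_hat` is the mean and `sigma_hat` the sample standard deviation
#' (n_perm - 1 denominator) of the permuted scores. If `sigma_hat` collapses
#' below 1e-12 the limit of the formula is used: p = 1 when
#' |LAS| <= |mu_hat| + 1e-12, else p = 0.
#'
#' @param x,y,z Numeric vectors of equal length n >= 3, already transformed.
#' @param permutations Integer matrix of index orderings, one per row, as from
#'   [make_permutations()].
#' @return An object of class `las_test`: a list with `las`, `p_value` and
#'   `null` (`permuted_scores`, `mu_hat`, `sigma_hat`). `tidy()` gives a
#'   one-row tibble.
#' @examples
#' z <- inverse_normal_transform(runif(30, 20, 70))
#' x <- rnorm(30); y <- rnorm(30)
#' perms <- make_permutations(30, 100, seed = 1)
#' las_permutation_test(x, y, z, perms)
#' @export
las_permutation_test <- function(x, y, z, permutations) {
  las <- liquid_association(x, y, z)
  permutations <- check_permutations(permutations, length(z))
  xy <- x * y
  scores <- as.vector(matrix(z[t(permutations)],
    nrow = nrow(permutations), byrow = TRUE
  ) %*% xy) / length(z)
  null <- las_null(scores)
  structure(
    list(
      las = las,
      p_value = normal_tail_p(las, null$mu_hat, null$sigma_hat),
      null = null
    ),
    class = "las_test"
  )
}

las_null <- function(scores) {
  list(
    permuted_scores = scores,
    mu_hat = mean(scores),
    sigma_hat = sd(scores)
  )
}

# Two-tailed p from the fitted normal null; degenerate sigma handled as the
# sigma -> 0 limit of the formula.
normal_tail_p <- function(las, mu, sigma) {
  a <- abs(las)
  p <- ifelse(
    sigma < 1e-12,
    ifelse(a <= abs(mu) + 1e-12, 1, 0),
    1 - pnorm((a - mu) / sigma) + pnorm((-a - mu) / sigma)
  )
  pmin(pmax(p, 0), 1)
}

#' @export
print.las_test <- function(x, ...) {
  cat(sprintf(
    "<las_test> LAS = %.4f, p = %.4g (null mu = %.4f, sigma = %.4f, %d permutations)\n",
    x$las, x$p_value, x$null$mu_hat, x$null$sigma_hat,
    length(x$null$permuted_scores)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.las_test <- function(x, ...) {
  tibble(
    las = x$las,
    p_value = x$p_value,
    null_mean = x$null$mu_hat,
    null_sd = x$null$sigma_hat,
    n_perm = length(x$null$permuted_scores)
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with cumulative-minimum
#' enforcement. Adjusted values are always at least the raw values, never
#' exceed 1, preserve the raw ordering, and travel with their input position
#' (the result is equivariant under permutation of the input).
#'
#' @param raw Numeric vector of p-values in \[0, 1\].
#' @return A tibble with columns `raw` and `adjusted`, in input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(raw) {
  if (length(raw) && (anyNA(raw) || any(raw < 0 | raw > 1))) {
    abort("p-values must lie in [0, 1] with no missing values")
  }
  tibble(raw = as.numeric(raw), adjusted = p.adjust(raw, method = "BH"))
}

#' One-sided (enrichment) Fisher's exact test for a 2x2 table
#'
#' Upper-tail exact hypergeometric probability P(X >= a) for the fixed-margin
#' table `[[a, b], [c, d]]`, the over-representation direction used throughout
#' the screen's downstream stages (aging-gene overlap, key-driver neighbourhood
#' enrichment, drug-signature reversal). If any margin of the table is zero no
#' enrichment evidence is possible: p = 1 and `zero_margin` is flagged.
#'
#' @param a,b,c,d Non-negative integer cell counts: `a` = in-query and
#'   in-reference, `b` = in-query only, `c` = in-reference only, `d` = neither.
#' @return One-row tibble: `odds_ratio` (sample odds ratio `ad/bc`, possibly
#'   infinite), `p_value`, `zero_margin`.
#' @examples
#' fisher_one_sided(155, 2408, 150, 13803)
#' @export
fisher_one_sided <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    abort("cell counts must be non-negative integers")
  }
  zero_margin <- (a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0
  p <- if (zero_margin) {
    1
  } else {
    phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  }
  or <- if (b == 0 || c == 0) {
    if (a == 0 || d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  tibble(odds_ratio = or, p_value = p, zero_margin = zero_margin)
}

# ---- internal validation helpers ----

check_finite_vector <- function(x, arg, min_n = 3L) {
  if (!is.numeric(x)) abort(sprintf("`%s` must be numeric", arg))
  if (length(x) < min_n) {
    abort(sprintf("`%s` must have length >= %d (got %d)", arg, min_n, length(x)))
  }
  bad <- which(!is.finite(x))
  if (length(bad)) {
    abort(sprintf(
      "`%s` contains non-finite values (first offending index: %d)",
      arg, bad[1]
    ))
  }
  invisible(x)
}

check_permutations <- function(permutations, n) {
  if (is.list(permutations)) {
    permutations <- do.call(rbind, permutations)
  }
  if (!is.matrix(permutations) || ncol(permutations) != n) {
    abort(sprintf("permutations must be a matrix with %d columns", n))
  }
  if (nrow(permutations) < 2) abort("at least 2 permutations are required")
  storage.mode(permutations) <- "integer"
  rs <- rowSums(permutations)
  if (any(rs != sum(seq_len(n)))) {
    abort("each permutation must be a full index-ordering of 1..n")
  }
  permutations
}

# Evaluate `expr` under a temporary seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
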