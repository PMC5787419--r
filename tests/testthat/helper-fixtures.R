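# Shared fixture builders and independent oracles. Everything is generated in
# code; no stored data.

# A small study of iid standard-normal genes with uniform ages.
null_study <- function(n_genes = 10, n = 100, seed = 1, transformed = FALSE) {
  withr::with_seed(seed, {
    vals <- matrix(rnorm(n_genes * n),
      nrow = n_genes,
      dimnames = list(sprintf("N%03d", seq_len(n_genes)), sprintf("S%03d", seq_len(n)))
    )
    st <- expression_study(vals, runif(n, 20, 70))
    if (transformed) st <- transform_study(st)
    st
  })
}

# Simulation spec with pure liquid-association pairs (no marginal drift on any
# module gene): planted pairs have zero population marginal correlation.
pure_la_spec <- function(seed = 1, beta = 0.8, n_samples = 150) {
  simulation_spec(
    seed = seed, n_samples = n_samples,
    planted_pairs = tibble::tibble(
      gene_a = c("G001", "G003", "G005"),
      gene_b = c("G002", "G004", "G006"),
      beta = beta
    ),
    planted_age_genes = tibble::tibble(
      gene = sprintf("G%03d", 7:10),
      alpha = c(0.6, 0.6, -0.6, -0.6)
    )
  )
}

# Closed-form population LAS of a planted pair with conditional correlation
# clip(beta * Z, -0.95, 0.95), Z standard normal (Stein identity):
# E[clip(beta Z) Z] = beta E[Z^2 1{|Z|<=c}] + 0.95 E[|Z| 1{|Z|>c}], c = 0.95/|beta|.
clipped_las_oracle <- function(beta) {
  if (beta == 0) return(0)
  c_ <- 0.95 / abs(beta)
  tail_second_moment <- 2 * (c_ * dnorm(c_) + (1 - pnorm(c_)))
  beta * (1 - tail_second_moment) + sign(beta) * 0.95 * 2 * dnorm(c_)
}

# Naive loop oracle for the liquid-association score.
las_loop_oracle <- function(x, y, z) {
  s <- 0
  for (i in seq_along(x)) s <- s + x[i] * y[i] * z[i]
  s / length(x)
}

# Step-up BH oracle, written independently of stats::p.adjust.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Enumeration oracle for the upper-tail hypergeometric probability of a 2x2
# table with margins fixed: P(X >= a), X = overlap count.
fisher_enum_oracle <- function(a, b, c, d) {
  n_query <- a + b
  n_ref <- a + c
  total <- a + b + c + d
  xs <- max(0, n_query + n_ref - total):min(n_query, n_ref)
  probs <- choose(n_ref, xs) * choose(total - n_ref, n_query - xs) /
    choose(total, n_query)
  sum(probs[xs >= a])
}

# Write a small expression + metadata fixture pair, returning the two paths.
write_expression_fixture <- function(dir,
                                     genes = paste0("G", 1:5),
                                     samples = paste0("S", 1:4),
                                     ages = c(25, 40, 60, 70),
                                     seed = 42) {
  withr::with_seed(seed, {
    values <- matrix(round(rnorm(length(genes) * length(samples)), 4),
      nrow = length(genes), dimnames = list(genes, samples)
    )
  })
  mat_path <- file.path(dir, "expr.tsv")
  meta_path <- file.path(dir, "meta.tsv")
  readr::write_tsv(
    dplyr::bind_cols(tibble::tibble(gene_id = genes), tibble::as_tibble(values)),
    mat_path, progress = FALSE
  )
  readr::write_tsv(
    tibble::tibble(sample_id = samples, age = ages),
    meta_path, progress = FALSE
  )
  list(matrix = mat_path, metadata = meta_path, values = values, ages = ages)
}
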