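test_that("inverse-normal transform maps ranks to symmetric normal quantiles", {
  out <- inverse_normal_transform(c(1, 2, 3))
  expect_true(all(diff(out) > 0))
  expect_equal(out[2], 0)
  expect_equal(out[1], -out[3])

  expect_equal(inverse_normal_transform(c(5, 5, 5)), c(0, 0, 0))

  # ties collapse to equal outputs, ordering preserved
  x <- c(2, 7, 7, 1, 5)
  out <- inverse_normal_transform(x)
  expect_equal(out[2], out[3])
  expect_equal(order(out[c(4, 1, 5, 2)]), 1:4)

  # a seeded uniform sample lands close to standard normal moments
  u <- withr::with_seed(42, runif(100))
  r <- inverse_normal_transform(u)
  expect_lt(abs(mean(r)), 0.05)
  expect_gt(sd(r), 0.9)
  expect_lt(sd(r), 1.1)
})

test_that("inverse-normal transform rejects non-finite input with the index", {
  expect_error(inverse_normal_transform(c(1, NA, 3)), "index: 2")
  expect_error(inverse_normal_transform(c(Inf, 1, 3)), "index: 1")
})

test_that("liquid-association score is the mean triple product", {
  expect_equal(
    liquid_association(c(1, -1, 0), c(1, 1, 0), c(1, -1, 0)),
    2 / 3
  )
  expect_equal(liquid_association(rnorm(5), rnorm(5), rep(0, 5)), 0)
  expect_error(liquid_association(rnorm(4), rnorm(4), rnorm(5)), "equal length")
  expect_error(liquid_association(1, 1, 1), "length >= 3")
})

test_that("liquid-association score matches a naive loop oracle with its symmetries", {
  withr::with_seed(7, {
    for (i in 1:1000) {
      n <- sample(3:12, 1)
      x <- rnorm(n); y <- rnorm(n); z <- rnorm(n)
      s <- liquid_association(x, y, z)
      expect_equal(s, las_loop_oracle(x, y, z))
      expect_equal(s, liquid_association(y, x, z))
      expect_equal(-s, liquid_association(-x, y, z))
    }
  })
})

test_that("LAS estimates the conditional-correlation slope (Stein identity)", {
  # (X, Y) | Z bivariate normal with correlation 0.4 Z: population LAS = 0.4
  withr::with_seed(13, {
    n <- 10000
    z <- rnorm(n)
    rho <- pmin(pmax(0.4 * z, -0.95), 0.95)
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    expect_lt(abs(liquid_association(x, y, z) - 0.4), 0.05)
  })

  # parameter recovery across replicates at n = 200: the estimator mean
  # matches the closed-form population value (which includes the clipping
  # correction; for beta = 0.2 that value is beta to 6 decimals)
  for (beta in c(0.2, 0.5)) {
    est <- withr::with_seed(100 + round(beta * 10), {
      replicate(500, {
        z <- rnorm(200)
        rho <- pmin(pmax(beta * z, -0.95), 0.95)
        x <- rnorm(200)
        y <- rho * x + sqrt(1 - rho^2) * rnorm(200)
        liquid_association(x, y, z)
      })
    })
    se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - clipped_las_oracle(beta)), 3 * se)
  }
  expect_lt(abs(clipped_las_oracle(0.2) - 0.2), 1e-6)
})

test_that("permutation test reproduces the normal-tail formula and handles degenerate nulls", {
  withr::with_seed(3, {
    n <- 50
    x <- rnorm(n); y <- rnorm(n); z <- rnorm(n)
    perms <- make_permutations(n, 100, seed = 3)
    res <- las_permutation_test(x, y, z, perms)
    mu <- mean(res$null$permuted_scores)
    sigma <- sd(res$null$permuted_scores)
    expect_equal(res$null$mu_hat, mu)
    expect_equal(res$null$sigma_hat, sigma)
    expect_equal(
      res$p_value,
      min(max(1 - pnorm((abs(res$las) - mu) / sigma) +
        pnorm((-abs(res$las) - mu) / sigma), 0), 1)
    )
    # when |LAS| equals mu-hat the formula collapses to 0.5 + pnorm(-2 mu / sigma)
    expect_equal(
      1 - pnorm((mu - mu) / sigma) + pnorm((-mu - mu) / sigma),
      0.5 + pnorm(-2 * mu / sigma)
    )
    td <- tidy(res)
    expect_equal(td$las, res$las)
    expect_equal(td$n_perm, 100)
  })

  # constant z: every permuted score equals the observed score -> p = 1
  withr::with_seed(4, {
    x <- rnorm(10); y <- rnorm(10); z <- rep(2, 10)
    res <- las_permutation_test(x, y, z, make_permutations(10, 50, seed = 4))
    expect_equal(res$null$sigma_hat, 0)
    expect_equal(res$p_value, 1)
  })
})

test_that("permutation test validates its permutation set", {
  x <- rnorm(5); y <- rnorm(5); z <- rnorm(5)
  bad <- matrix(1L, nrow = 3, ncol = 5)
  expect_error(las_permutation_test(x, y, z, bad), "full index-ordering")
  expect_error(
    las_permutation_test(x, y, z, make_permutations(6, 10, seed = 1)),
    "5 columns"
  )
  expect_error(make_permutations(10, n_perm = 1), "at least 2")
})

test_that("permutation test has power against a strong planted pair", {
  hits <- vapply(1:20, function(s) {
    withr::with_seed(900 + s, {
      n <- 150
      z <- rnorm(n)
      rho <- pmin(pmax(0.8 * z, -0.95), 0.95)
      x <- rnorm(n)
      y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
      perms <- make_permutations(n, 100, seed = 900 + s)
      las_permutation_test(x, y, z, perms)$p_value < 0.01
    })
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("BH adjustment matches the step-up oracle and is order-equivariant", {
  out <- bh_adjust(c(0.01, 0.02, 0.03))
  expect_equal(out$adjusted, c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.5)$adjusted, 0.5)
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")

  withr::with_seed(21, {
    for (i in 1:50) {
      p <- runif(sample(1:40, 1))^sample(1:3, 1)
      adj <- bh_adjust(p)$adjusted
      expect_equal(adj, bh_oracle(p))
      expect_true(all(adj >= p))
      expect_true(all(adj <= 1))
      # monotone in the raw ordering
      expect_true(all(diff(adj[order(p)]) >= -1e-12))
      # adjusted values travel with their p under permutation
      perm <- sample(length(p))
      expect_equal(bh_adjust(p[perm])$adjusted, adj[perm])
    }
  })
})

test_that("one-sided Fisher test equals the hypergeometric upper tail", {
  expect_equal(fisher_one_sided(2, 1, 1, 2)$p_value, 0.5)
  expect_equal(fisher_one_sided(0, 5, 7, 11)$p_value, 1)
  zm <- fisher_one_sided(0, 0, 3, 5)
  expect_true(zm$zero_margin)
  expect_equal(zm$p_value, 1)

  # enumeration oracle plus stats::fisher.test cross-check on random tables
  withr::with_seed(31, {
    for (i in 1:200) {
      total <- sample(4:60, 1)
      a <- sample(0:min(10, total - 3), 1)
      rest <- total - a
      b <- sample(0:rest, 1)
      c_ <- sample(0:(rest - b), 1)
      d <- rest - b - c_
      got <- fisher_one_sided(a, b, c_, d)$p_value
      expect_equal(got, fisher_enum_oracle(a, b, c_, d), tolerance = 1e-10)
      if ((a + b) > 0 && (c_ + d) > 0 && (a + c_) > 0 && (b + d) > 0) {
        ft <- stats::fisher.test(
          matrix(c(a, b, c_, d), 2, byrow = TRUE),
          alternative = "greater"
        )
        expect_equal(got, ft$p.value, tolerance = 1e-8)
      }
    }
  })

  # a large-table value agrees with the independent exact implementation
  big <- fisher_one_sided(155, 2408, 150, 13803)$p_value
  ft <- stats::fisher.test(
    matrix(c(155, 2408, 150, 13803), 2, byrow = TRUE),
    alternative = "greater"
  )
  expect_equal(log10(big), log10(ft$p.value), tolerance = 1e-6)
  expect_error(fisher_one_sided(-1, 2, 3, 4), "non-negative")
})
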