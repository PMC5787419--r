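test_that("module screen enumerates all pairs lexicographically with per-module BH", {
  study <- null_study(n_genes = 6, n = 40, seed = 5, transformed = TRUE)
  perms <- make_permutations(40, 50, seed = 5)
  rec <- screen_module(study, study_genes(study), perms, module_id = "M")
  expect_equal(nrow(rec), choose(6, 2))
  expect_true(all(rec$gene_a < rec$gene_b))
  expect_equal(rec$p_adjusted, bh_adjust(rec$p_raw)$adjusted)
  expect_equal(rec$significant, rec$p_adjusted <= 0.1)

  # invariant to gene input order
  shuffled <- screen_module(study, rev(study_genes(study)), perms, module_id = "M")
  expect_equal(rec, shuffled)

  # per-pair records agree with the single-pair permutation test
  one <- las_permutation_test(
    study$values[rec$gene_a[1], ], study$values[rec$gene_b[1], ],
    study$scouting, perms
  )
  expect_equal(rec$las[1], one$las)
  expect_equal(rec$p_raw[1], one$p_value)
})

test_that("module screen rejects bad inputs and degenerate modules", {
  study <- null_study(n_genes = 4, n = 30, seed = 6)
  perms <- make_permutations(30, 10, seed = 6)
  expect_error(
    screen_module(study, study_genes(study), perms),
    "transform_study"
  )
  tstudy <- transform_study(study)
  expect_error(
    screen_module(tstudy, c("N001", "ABSENT"), perms),
    "ABSENT"
  )
  expect_warning(
    empty <- screen_module(tstudy, "N001", perms),
    "fewer than 2"
  )
  expect_equal(nrow(empty), 0)
})

test_that("run_screen is deterministic and module-scoped", {
  spec <- pure_la_spec(seed = 3)
  sim <- simulate_study(spec)
  study <- transform_study(sim$study)

  scr1 <- run_screen(study, spec$modules, n_perm = 100, seed = 3)
  scr2 <- run_screen(study, spec$modules, n_perm = 100, seed = 3)
  expect_identical(scr1$records, scr2$records)
  expect_identical(scr1$significant, scr2$significant)
  expect_equal(scr1$manifest$values_digest, scr2$manifest$values_digest)

  # a pair present in two modules yields one record per module
  shared <- gene_set_collection(list(
    A = c("G001", "G002", sprintf("G%03d", 40:44)),
    B = c("G001", "G002", sprintf("G%03d", 45:49))
  ))
  scr3 <- run_screen(study, shared, n_perm = 100, seed = 3)
  pair_rows <- dplyr::filter(scr3$records, gene_a == "G001", gene_b == "G002")
  expect_equal(nrow(pair_rows), 2)
  expect_setequal(pair_rows$module_id, c("A", "B"))

  expect_warning(
    empty <- run_screen(study, gene_set_collection(setNames(list(), character()))),
    "empty module collection"
  )
  expect_equal(nrow(empty$records), 0)

  gl <- glance(scr1)
  expect_equal(gl$n_pairs, nrow(scr1$records))
  expect_equal(tidy(scr1), scr1$records)
})

test_that("pair occurrences count modules with lexicographic tie-breaks", {
  rec <- tibble::tibble(
    module_id = c("M1", "M2", "M3", "M1", "M2"),
    gene_a = c("A", "A", "A", "B", "B"),
    gene_b = c("B", "B", "B", "C", "C"),
    significant = TRUE
  )
  occ <- pair_occurrences(rec)
  expect_equal(occ$occurrence, c(3, 2))
  expect_equal(occ$gene_a, c("A", "B"))

  tied <- tibble::tibble(
    module_id = c("M1", "M1"),
    gene_a = c("B", "A"), gene_b = c("Z", "C"),
    significant = TRUE
  )
  occ2 <- pair_occurrences(tied)
  expect_equal(occ2$gene_a, c("A", "B"))
  expect_equal(nrow(pair_occurrences(rec[0, ])), 0)
})

test_that("age co-expressed genes are the union over significant pairs", {
  rec <- tibble::tibble(
    module_id = c("M1", "M2", "M2"),
    gene_a = c("A", "B", "C"),
    gene_b = c("B", "C", "D"),
    significant = c(TRUE, TRUE, FALSE)
  )
  expect_equal(age_coexpressed_genes(rec), c("A", "B", "C"))
  expect_equal(age_coexpressed_genes(rec[0, ]), character())
})

test_that("stratum correlations recover the monotone liquid-association pattern", {
  trend_ok <- vapply(1:20, function(s) {
    spec <- pure_la_spec(seed = 400 + s)
    sim <- simulate_study(spec)
    gc <- group_correlations(sim$study, "G001", "G002")
    gc$correlation[gc$group == "old"] > gc$correlation[gc$group == "young"]
  }, logical(1))
  expect_gte(mean(trend_ok), 0.9)

  sim <- simulate_study(pure_la_spec(seed = 1))
  st <- transform_study(sim$study)
  same <- group_correlations(st, "G001", "G001")
  expect_equal(same$correlation, rep(1, 3))

  expect_error(group_correlations(st, "G001", "NOPE"), "NOPE")

  # a stratum with fewer than 3 samples is flagged undefined
  vals <- matrix(rnorm(2 * 5), 2, dimnames = list(c("A", "B"), paste0("S", 1:5)))
  tiny <- expression_study(vals, c(25, 26, 40, 60, 61))
  gc <- group_correlations(tiny, "A", "B")
  expect_false(gc$defined[gc$group == "young"])
  expect_true(is.na(gc$correlation[gc$group == "young"]))
})

test_that("PCC screen uses the exact t reference and flags degenerate genes", {
  n <- 30
  withr::with_seed(8, {
    base <- rnorm(n)
    vals <- rbind(
      A = base, B = base, C = -base, D = rnorm(n), E = rep(0, n)
    )
    colnames(vals) <- paste0("S", 1:n)
  })
  study <- expression_study(vals, seq(20, 70, length.out = n), transformed = TRUE)
  expect_message(
    rec <- pcc_screen_module(study, rownames(vals), module_id = "M"),
    "zero-variance"
  )
  ab <- rec[rec$gene_a == "A" & rec$gene_b == "B", ]
  expect_equal(ab$correlation, 1)
  expect_equal(ab$p_raw, 0)
  expect_true(ab$significant)
  ac <- rec[rec$gene_a == "A" & rec$gene_b == "C", ]
  expect_equal(ac$correlation, -1)
  expect_true(ac$significant)
  e_rows <- rec[rec$gene_a == "E" | rec$gene_b == "E", ]
  expect_true(all(is.na(e_rows$correlation)))
  expect_true(all(e_rows$p_raw == 1))

  # p-values agree with stats::cor.test on a non-degenerate pair
  ad <- rec[rec$gene_a == "A" & rec$gene_b == "D", ]
  ct <- stats::cor.test(vals["A", ], vals["D", ])
  expect_equal(ad$p_raw, ct$p.value, tolerance = 1e-12)
})

test_that("LA/PCC consistency builds per-module Fisher tables with BH across modules", {
  make_rec <- function(module, sig) {
    pairs <- t(combn(LETTERS[1:6], 2))
    tibble::tibble(
      module_id = module,
      gene_a = pairs[, 1], gene_b = pairs[, 2],
      significant = sig
    )
  }
  n_pairs <- choose(6, 2)
  # module CONS: LA-significant subset of PCC-significant (enrichment)
  la_sig <- c(rep(TRUE, 3), rep(FALSE, n_pairs - 3))
  pcc_sig <- c(rep(TRUE, 4), rep(FALSE, n_pairs - 4))
  # module DISJ: disjoint picks
  la2 <- c(rep(TRUE, 3), rep(FALSE, n_pairs - 3))
  pcc2 <- c(rep(FALSE, 3), rep(TRUE, 3), rep(FALSE, n_pairs - 6))
  la <- dplyr::bind_rows(make_rec("CONS", la_sig), make_rec("DISJ", la2))
  pcc <- dplyr::bind_rows(make_rec("CONS", pcc_sig), make_rec("DISJ", pcc2))

  out <- la_pcc_consistency(la, pcc, alpha = 0.05)
  expect_equal(out$n_pairs, c(n_pairs, n_pairs))
  expect_equal(out$n_both, c(3, 0))
  cons <- out[out$module_id == "CONS", ]
  disj <- out[out$module_id == "DISJ", ]
  expect_equal(
    cons$p_raw,
    fisher_one_sided(3, 0, 1, n_pairs - 4)$p_value
  )
  expect_lt(cons$p_raw, 0.01)
  expect_gt(disj$p_raw, 0.5)
  expect_true(all(out$n_both <= pmin(out$n_la, out$n_pcc)))

  expect_error(
    la_pcc_consistency(la, pcc[-1, ]),
    "identical module pair enumerations"
  )
})
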