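#' Specify a synthetic study with known planted structure
#'
#' Defines the generative model used throughout the test-bench: `n_samples`
#' donors with ages uniform on `age_range`; a gene panel in which a minority
#' of pairs have a conditional correlation that varies linearly with
#' (transformed) age, a minority of genes have a marginal mean trend with
#' age, and everything else is independent standard normal. The default spec
#' mirrors a single-tissue study of moderate size: 150 samples, ages 20-70,
#' 60 genes, three 8-gene modules each containing one planted pair with
#' liquid-association slope beta = 0.8.
#'
#' In the default spec, the pair genes of modules one and two additionally
#' carry marginal age slopes (+0.5 / -0.5), so that the directional-set and
#' drug-reversal stages see non-empty inputs end-to-end; the third module's
#' pair is purely liquid (no marginal trend). Standalone drift genes
#' (alpha = ±0.6) live outside all modules.
#'
#' @param n_samples Number of samples (default 150).
#' @param age_range Ages are uniform on this interval (default `c(20, 70)`
#'   years).
#' @param n_genes Size of the gene panel (default 60; genes are named
#'   `G001`, `G002`, ...).
#' @param planted_pairs Tibble `gene_a`, `gene_b`, `beta` of pairs whose
#'   conditional correlation is `clip(beta * z, -0.95, 0.95)` with z the
#'   transformed age; the population liquid-association score of such a pair
#'   is `beta` while its population marginal correlation is 0. A gene may
#'   appear in at most one pair. `|beta| <= 0.95`.
#' @param planted_age_genes Tibble `gene`, `alpha` of genes whose expression
#'   drifts with age (population age correlation `alpha`, `|alpha| < 1`). A
#'   gene may carry both a pair planting and an age slope.
#' @param modules A [gene_set_collection()] of fixture modules mixing planted
#'   and null genes.
#' @param seed Master seed for [simulate_study()] and the fixture builders.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_samples = 150,
                            age_range = c(20, 70),
                            n_genes = 60,
                            planted_pairs = NULL,
                            planted_age_genes = NULL,
                            modules = NULL,
                            seed = 1) {
  genes <- sprintf("G%03d", seq_len(n_genes))
  if (is.null(planted_pairs)) {
    planted_pairs <- tibble(
      gene_a = c("G001", "G003", "G005"),
      gene_b = c("G002", "G004", "G006"),
      beta = 0.8
    )
  }
  if (is.null(planted_age_genes)) {
    planted_age_genes <- tibble(
      gene = c("G001", "G002", "G003", "G004",
               "G007", "G008", "G009", "G010"),
      alpha = c(0.5, 0.5, -0.5, -0.5, 0.6, 0.6, -0.6, -0.6)
    )
  }
  if (is.null(modules)) {
    modules <- gene_set_collection(list(
      MOD1 = c("G001", "G002", sprintf("G%03d", 17:22)),
      MOD2 = c("G003", "G004", sprintf("G%03d", 23:28)),
      MOD3 = c("G005", "G006", sprintf("G%03d", 29:34))
    ))
  }
  stopifnot(inherits(modules, "gene_set_collection"))
  planted_pairs <- as_tibble(planted_pairs)
  planted_age_genes <- as_tibble(planted_age_genes)

  if (n_samples < 3) abort("n_samples must be at least 3")
  if (length(age_range) != 2 || age_range[1] >= age_range[2]) {
    abort("age_range must be an increasing (low, high) pair")
  }
  pair_genes <- c(planted_pairs$gene_a, planted_pairs$gene_b)
  if (anyDuplicated(pair_genes)) {
    abort(sprintf(
      "conflicting plantings: gene %s appears in more than one planted pair",
      pair_genes[duplicated(pair_genes)][1]
    ))
  }
  if (anyDuplicated(planted_age_genes$gene)) {
    abort("a gene may carry only one planted age slope")
  }
  unknown <- setdiff(
    c(pair_genes, planted_age_genes$gene, unlist(modules$sets)),
    genes
  )
  if (length(unknown)) {
    abort(sprintf("planted or module gene not in the panel: %s", unknown[1]))
  }
  if (any(abs(planted_pairs$beta) > 0.95)) abort("|beta| must be <= 0.95")
  if (any(abs(planted_age_genes$alpha) >= 1)) abort("|alpha| must be < 1")

  structure(
    list(
      n_samples = n_samples, age_range = age_range,
      genes = genes, planted_pairs = planted_pairs,
      planted_age_genes = planted_age_genes, modules = modules,
      seed = seed
    ),
    class = "simulation_spec"
  )
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf(
    "<simulation_spec> %d genes x %d samples, ages %g-%g; %d planted pair(s), %d age-drift gene(s), %d module(s); seed %s\n",
    length(x$genes), x$n_samples, x$age_range[1], x$age_range[2],
    nrow(x$planted_pairs), nrow(x$planted_age_genes),
    length(x$modules$sets), format(x$seed)
  ))
  invisible(x)
}

#' Simulate a study from a specification
#'
#' Draws ages uniformly on the spec's range, sets z to the inverse-normal
#' transform of the ages, and generates expression as: planted pair (x, y)
#' conditionally bivariate normal given z with correlation
#' `clip(beta * z, -0.95, 0.95)`; genes with age slope alpha get an added
#' `alpha * z` mean component (scaled to unit marginal variance when the
#' gene is not in a pair); all remaining genes independent standard normal.
#' Under this model the population liquid-association score of a planted
#' pair is beta (where clipping is inactive) and the population age
#' correlation of a pure drift gene is alpha.
#'
#' @param spec A [simulation_spec()].
#' @return List with `study` (untransformed [expression_study()]) and
#'   `truth` (list: `la_pairs`, `age_up`, `age_down`, `hub_kds`).
#' @export
simulate_study <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n_samples
    genes <- spec$genes
    ages <- runif(n, spec$age_range[1], spec$age_range[2])
    z <- inverse_normal_transform(ages)

    values <- matrix(rnorm(length(genes) * n),
      nrow = length(genes),
      dimnames = list(genes, sprintf("S%03d", seq_len(n)))
    )
    alpha_of <- setNames(
      rep(0, length(genes)), genes
    )
    alpha_of[spec$planted_age_genes$gene] <- spec$planted_age_genes$alpha
    pair_genes <- c(spec$planted_pairs$gene_a, spec$planted_pairs$gene_b)

    # standalone drift genes: unit marginal variance
    drift_only <- setdiff(spec$planted_age_genes$gene, pair_genes)
    for (g in drift_only) {
      a <- alpha_of[[g]]
      values[g, ] <- a * z + sqrt(1 - a^2) * rnorm(n)
    }
    # planted pairs: conditional correlation clip(beta * z); optional mean drift
    for (i in seq_len(nrow(spec$planted_pairs))) {
      ga <- spec$planted_pairs$gene_a[i]
      gb <- spec$planted_pairs$gene_b[i]
      rho <- pmin(pmax(spec$planted_pairs$beta[i] * z, -0.95), 0.95)
      e1 <- rnorm(n)
      e2 <- rnorm(n)
      values[ga, ] <- alpha_of[[ga]] * z + e1
      values[gb, ] <- alpha_of[[gb]] * z + rho * e1 + sqrt(1 - rho^2) * e2
    }

    truth <- list(
      la_pairs = spec$planted_pairs,
      age_up = sort(spec$planted_age_genes$gene[spec$planted_age_genes$alpha > 0]),
      age_down = sort(spec$planted_age_genes$gene[spec$planted_age_genes$alpha < 0]),
      hub_kds = "HUB001"
    )
    list(
      study = expression_study(values, ages, scouting_name = "age"),
      truth = truth
    )
  })
}

#' Fixture PPI network for a simulation spec
#'
#' Builds the deterministic companion network: a hub node `HUB001` adjacent
#' to every planted pair gene, five 6-node decoy cliques (`DECxx`), and a
#' chain over the remaining module genes so that every module gene is in the
#' network.
#'
#' @param spec A [simulation_spec()].
#' @return An [igraph::igraph].
#' @export
make_fixture_ppi <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  pair_genes <- sort(unique(c(spec$planted_pairs$gene_a, spec$planted_pairs$gene_b)))
  edges <- tibble(a = "HUB001", b = pair_genes)
  for (k in seq_len(5)) {
    members <- sprintf("DEC%02d%s", k, LETTERS[1:6])
    idx <- t(utils::combn(6, 2))
    edges <- bind_rows(edges, tibble(a = members[idx[, 1]], b = members[idx[, 2]]))
  }
  others <- sort(setdiff(unique(unlist(spec$modules$sets)), pair_genes))
  if (length(others) >= 2) {
    edges <- bind_rows(edges, tibble(
      a = others[-length(others)],
      b = others[-1]
    ))
  }
  igraph::simplify(igraph::graph_from_data_frame(edges, directed = FALSE))
}

#' Fixture aging-gene list for a simulation spec
#'
#' The planted age-drift genes plus deterministic decoys (null module genes),
#' emulating a curated aging-gene list that partially overlaps the study's
#' discoveries.
#'
#' @param spec A [simulation_spec()].
#' @return Character vector of symbols.
#' @export
make_fixture_aging_genes <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  pair_genes <- unique(c(spec$planted_pairs$gene_a, spec$planted_pairs$gene_b))
  nulls <- sort(setdiff(unique(unlist(spec$modules$sets)), pair_genes))
  sort(unique(c(
    spec$planted_age_genes$gene,
    pair_genes,
    head(nulls, 5)
  )))
}

#' Fixture perturbation signatures for a simulation spec
#'
#' One "reverser" perturbation whose up-set is exactly the planted
#' age-repressed co-expressed genes and whose down-set is the planted
#' age-elevated co-expressed genes, plus 50 random decoy perturbations with
#' 12-gene up and down sets drawn from the panel.
#'
#' @param spec A [simulation_spec()].
#' @param n_decoys Number of decoy perturbations (default 50).
#' @return Signature tibble as from [read_signatures()].
#' @export
make_fixture_signatures <- function(spec, n_decoys = 50) {
  stopifnot(inherits(spec, "simulation_spec"))
  pair_genes <- c(spec$planted_pairs$gene_a, spec$planted_pairs$gene_b)
  age <- spec$planted_age_genes
  up_coexpr <- sort(intersect(age$gene[age$alpha > 0], pair_genes))
  down_coexpr <- sort(intersect(age$gene[age$alpha < 0], pair_genes))
  with_local_seed(spec$seed %% 2147483000 + 1L, {
    decoys <- lapply(seq_len(n_decoys), function(i) {
      picked <- sample(spec$genes, 24)
      list(up = sort(picked[1:12]), down = sort(picked[13:24]))
    })
    tibble(
      perturbation_id = c("REVERSER", sprintf("DRUG%02d", seq_len(n_decoys))),
      up_genes = c(list(down_coexpr), lapply(decoys, `[[`, "up")),
      down_genes = c(list(up_coexpr), lapply(decoys, `[[`, "down"))
    )
  })
}

#' Write a complete fixture bundle to disk
#'
#' Simulates the study and writes every pipeline input in its standard
#' format: expression TSV, metadata TSV, module GMT, PPI edge TSV,
#' aging-gene list, signature GMT, and the ground truth as a machine-readable
#' TSV. Regenerating with the same spec (same seed) is byte-identical.
#'
#' @param out_dir Output directory (created if absent).
#' @param spec A [simulation_spec()].
#' @return Named character vector of file paths, invisibly.
#' @export
make_fixture_bundle <- function(out_dir, spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_study(spec)
  paths <- c(
    expression = file.path(out_dir, "expression.tsv"),
    metadata = file.path(out_dir, "metadata.tsv"),
    modules = file.path(out_dir, "modules.gmt"),
    ppi = file.path(out_dir, "ppi.tsv"),
    aging_genes = file.path(out_dir, "aging_genes.txt"),
    signatures = file.path(out_dir, "signatures.gmt"),
    ground_truth = file.path(out_dir, "ground_truth.tsv")
  )

  expr <- dplyr::bind_cols(
    tibble(gene_id = rownames(sim$study$values)),
    as_tibble(sim$study$values)
  )
  readr::write_tsv(expr, paths[["expression"]], progress = FALSE)
  readr::write_tsv(
    tibble(
      sample_id = study_samples(sim$study),
      age = sim$study$scouting_raw
    ),
    paths[["metadata"]],
    progress = FALSE
  )
  write_gmt(spec$modules, paths[["modules"]])

  ppi <- make_fixture_ppi(spec)
  el <- igraph::as_edgelist(ppi)
  readr::write_tsv(
    tibble(a = el[, 1], b = el[, 2]),
    paths[["ppi"]],
    col_names = FALSE, progress = FALSE
  )
  writeLines(make_fixture_aging_genes(spec), paths[["aging_genes"]])

  sigs <- make_fixture_signatures(spec)
  sig_sets <- c(
    setNames(sigs$up_genes, paste0(sigs$perturbation_id, "_up")),
    setNames(sigs$down_genes, paste0(sigs$perturbation_id, "_down"))
  )
  sig_sets <- sig_sets[lengths(sig_sets) > 0]
  write_gmt(
    gene_set_collection(sig_sets[order(names(sig_sets))]),
    paths[["signatures"]]
  )

  truth_tbl <- bind_rows(
    tibble(
      kind = "la_pair",
      gene_a = sim$truth$la_pairs$gene_a,
      gene_b = sim$truth$la_pairs$gene_b,
      effect = sim$truth$la_pairs$beta
    ),
    tibble(kind = "age_up", gene_a = sim$truth$age_up,
      gene_b = NA_character_, effect = NA_real_),
    tibble(kind = "age_down", gene_a = sim$truth$age_down,
      gene_b = NA_character_, effect = NA_real_),
    tibble(kind = "hub_kd", gene_a = sim$truth$hub_kds,
      gene_b = NA_character_, effect = NA_real_)
  )
  readr::write_tsv(truth_tbl, paths[["ground_truth"]], progress = FALSE)
  invisible(paths)
}
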