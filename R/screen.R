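#' Screen one module for liquid-association pairs
#'
#' Enumerates every unordered pair of distinct module genes (in lexicographic
#' symbol order), computes the liquid-association score of each pair with the
#' study's transformed scouting variable, obtains a permutation p-value per
#' pair from the shared permutation set, and applies Benjamini-Hochberg
#' adjustment within the module. A pair is a significant liquid-association
#' pair (LAP) when its adjusted p-value is at most `fdr`.
#'
#' @param study A transformed [expression_study()] (see [transform_study()];
#'   this function does not re-transform).
#' @param module_genes Symbols of the module, all present in the study.
#' @param permutations Shared permutation matrix from [make_permutations()].
#' @param fdr Within-module FDR threshold (default 0.1); the comparison is
#'   inclusive (adjusted p not greater than `fdr`).
#' @param module_id Identifier recorded on every returned row.
#' @return A tibble with one row per gene pair: `module_id`, `gene_a`,
#'   `gene_b` (`gene_a < gene_b`), `las`, `p_raw`, `p_adjusted`,
#'   `significant`. Modules with fewer than two genes yield an empty tibble
#'   with a warning.
#' @export
screen_module <- function(study, module_genes, permutations, fdr = 0.1,
                          module_id = "module") {
  check_screen_inputs(study)
  genes <- sort(unique(toupper(module_genes)))
  missing <- setdiff(genes, study_genes(study))
  if (length(missing)) {
    abort(sprintf("module gene(s) absent from the study: %s", missing[1]))
  }
  if (length(genes) < 2) {
    warn(sprintf("module %s has fewer than 2 usable genes; nothing to screen",
      module_id))
    return(empty_lap_records())
  }
  z <- study$scouting
  n <- length(z)
  permutations <- check_permutations(permutations, n)
  n_perm <- nrow(permutations)
  X <- study$values[genes, , drop = FALSE]
  k <- length(genes)
  pair_idx <- t(utils::combn(k, 2)) # lexicographic for sorted genes
  flat <- (pair_idx[, 2] - 1) * k + pair_idx[, 1]

  las <- (tcrossprod(X * rep(z, each = k), X) / n)[flat]
  s1 <- numeric(length(flat))
  s2 <- numeric(length(flat))
  for (b in seq_len(n_perm)) {
    zp <- z[permutations[b, ]]
    v <- (tcrossprod(X * rep(zp, each = k), X) / n)[flat]
    s1 <- s1 + v
    s2 <- s2 + v * v
  }
  mu <- s1 / n_perm
  sigma <- sqrt(pmax(s2 - n_perm * mu^2, 0) / (n_perm - 1))
  p_raw <- normal_tail_p(las, mu, sigma)
  p_adjusted <- p.adjust(p_raw, method = "BH")
  tibble(
    module_id = module_id,
    gene_a = genes[pair_idx[, 1]],
    gene_b = genes[pair_idx[, 2]],
    las = las,
    p_raw = p_raw,
    p_adjusted = p_adjusted,
    significant = p_adjusted <= fdr
  )
}

empty_lap_records <- function() {
  tibble(
    module_id = character(), gene_a = character(), gene_b = character(),
    las = numeric(), p_raw = numeric(), p_adjusted = numeric(),
    significant = logical()
  )
}

check_screen_inputs <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  if (!study$transformed) {
    abort("study must be inverse-normal transformed first (see transform_study())")
  }
  if (ncol(study$values) < 3) abort("at least 3 samples are required")
  invisible(study)
}

#' Run the full liquid-association screen over a module collection
#'
#' Transforms the study if needed, draws one shared set of permutations from
#' the seed, screens every module (in sorted id order) with [screen_module()],
#' and collects all records plus the significant subset. Given the same seed
#' and inputs the output is bit-reproducible.
#'
#' @param study An [expression_study()]; transformed automatically if not
#'   already.
#' @param collection A [gene_set_collection()], already size-filtered (see
#'   [filter_modules()]).
#' @param n_perm Number of permutations (default 100).
#' @param seed Master seed for the shared permutation set.
#' @param fdr Within-module FDR threshold (default 0.1).
#' @return An object of class `aagci_screen`: list with `records` (all
#'   pairs), `significant` (LAPs only) and `manifest` (seed, thresholds,
#'   input digests). `tidy()` returns the records; `glance()` a one-row
#'   summary; `autoplot()` an LAS vs significance panel.
#' @export
run_screen <- function(study, collection, n_perm = 100, seed = 1, fdr = 0.1) {
  stopifnot(inherits(study, "expression_study"))
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!study$transformed) {
    inform("transforming study (inverse-normal) before screening")
    study <- transform_study(study)
  }
  manifest <- run_manifest(study, collection,
    n_perm = n_perm, seed = seed, fdr = fdr, method = "liquid_association"
  )
  if (!length(collection$sets)) {
    warn("empty module collection; nothing to screen")
    records <- empty_lap_records()
  } else {
    perms <- make_permutations(ncol(study$values), n_perm, seed = seed)
    ids <- sort(names(collection$sets))
    records <- bind_rows(lapply(ids, function(id) {
      screen_module(study, collection$sets[[id]], perms,
        fdr = fdr, module_id = id
      )
    }))
  }
  new_screen_result(records, manifest, class = "aagci_screen")
}

run_manifest <- function(study, collection, ..., method) {
  c(
    list(
      method = method,
      package_version = as.character(utils::packageVersion("aagci")),
      n_genes = nrow(study$values),
      n_samples = ncol(study$values),
      scouting_name = study$scouting_name,
      n_modules = length(collection$sets),
      values_digest = rlang::hash(study$values),
      scouting_digest = rlang::hash(study$scouting_raw),
      modules_digest = rlang::hash(collection$sets)
    ),
    list(...)
  )
}

new_screen_result <- function(records, manifest, class) {
  structure(
    list(
      records = records,
      significant = dplyr::filter(records, .data$significant),
      manifest = manifest
    ),
    class = class
  )
}

#' @export
print.aagci_screen <- function(x, ...) {
  cat(sprintf(
    "<aagci_screen> %d pair(s) in %d module(s); %d significant LAP(s) at FDR %.2g (n_perm = %d, seed = %s)\n",
    nrow(x$records), x$manifest$n_modules, nrow(x$significant),
    x$manifest$fdr, x$manifest$n_perm, format(x$manifest$seed)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.aagci_screen <- function(x, ...) x$records

#' @exportS3Method generics::glance
glance.aagci_screen <- function(x, ...) {
  tibble(
    n_modules = x$manifest$n_modules,
    n_pairs = nrow(x$records),
    n_significant = nrow(x$significant),
    n_coexpressed_genes = length(age_coexpressed_genes(x$significant)),
    fdr = x$manifest$fdr,
    n_perm = x$manifest$n_perm,
    seed = x$manifest$seed
  )
}

#' Count how often each pair is a significant LAP across modules
#'
#' @param records LAP records (a tibble as from [run_screen()]`$significant`,
#'   an `aagci_screen` object, or any record tibble; rows with a
#'   `significant` column are filtered to the significant ones).
#' @return Tibble `gene_a`, `gene_b`, `occurrence`, sorted by occurrence
#'   descending with lexicographic tie-breaks.
#' @export
pair_occurrences <- function(records) {
  records <- as_lap_records(records)
  dplyr::count(records, .data$gene_a, .data$gene_b, name = "occurrence") |>
    arrange(desc(.data$occurrence), .data$gene_a, .data$gene_b)
}

#' Collect age co-expressed genes
#'
#' A gene involved in any significant liquid-association pair in any module
#' is an age co-expressed gene; this returns the union over all records.
#'
#' @inheritParams pair_occurrences
#' @return Sorted character vector of symbols (possibly empty).
#' @export
age_coexpressed_genes <- function(records) {
  records <- as_lap_records(records)
  sort(unique(c(records$gene_a, records$gene_b)))
}

as_lap_records <- function(records) {
  if (inherits(records, "aagci_screen")) records <- records$significant
  stopifnot(is.data.frame(records))
  if ("significant" %in% names(records)) {
    records <- dplyr::filter(records, .data$significant)
  }
  records
}

#' Pearson correlation of a gene pair within age strata
#'
#' Splits samples into young / middle / old strata by the raw scouting values
#' (default cut points 35 and 55 years: young is age <= 35, old is age >= 55,
#' middle is in between) and reports the Pearson correlation of the two genes
#' within each stratum, computed on the transformed values. This is the
#' diagnostic view of a liquid-association pair: a pair with positive LAS
#' shows increasing stratum correlations from young to old.
#'
#' @param study An [expression_study()] (transformed or not; the two gene
#'   profiles are transformed on the fly when needed).
#' @param gene_a,gene_b Gene symbols present in the study.
#' @param cutpoints Numeric `(low, high)` age cut points, default `c(35, 55)`.
#' @return Tibble `group`, `n`, `correlation`, `defined`; strata with fewer
#'   than 3 samples are flagged undefined.
#' @export
group_correlations <- function(study, gene_a, gene_b, cutpoints = c(35, 55)) {
  stopifnot(inherits(study, "expression_study"))
  gene_a <- toupper(gene_a)
  gene_b <- toupper(gene_b)
  for (g in c(gene_a, gene_b)) {
    if (!g %in% study_genes(study)) {
      abort(sprintf("unknown gene symbol: %s", g))
    }
  }
  if (length(cutpoints) != 2 || cutpoints[1] >= cutpoints[2]) {
    abort("`cutpoints` must be an increasing pair (low, high)")
  }
  va <- study$values[gene_a, ]
  vb <- study$values[gene_b, ]
  if (!study$transformed) {
    va <- inverse_normal_transform(va)
    vb <- inverse_normal_transform(vb)
  }
  age <- study$scouting_raw
  group <- ifelse(age <= cutpoints[1], "young",
    ifelse(age >= cutpoints[2], "old", "middle")
  )
  purrr::map_dfr(c("young", "middle", "old"), function(g) {
    idx <- which(group == g)
    ok <- length(idx) >= 3
    r <- NA_real_
    if (ok && sd(va[idx]) > 0 && sd(vb[idx]) > 0) {
      r <- cor(va[idx], vb[idx])
    }
    tibble(
      group = g, n = length(idx),
      correlation = r, defined = ok && !is.na(r)
    )
  })
}
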