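#' Configuration for synthetic benchmark bundles
#'
#' The generator plants functional modules: genes in a module are densely
#' interconnected in the true interactome and share correlated expression,
#' characteristic annotation terms, compartments, domains (whose pairs are
#' seeded as interacting), similar phylogenetic profiles and interolog
#' support — the statistical structure that the six evidence categories
#' assume in real data. Per-category noise rates control how cleanly the
#' modules show through.
#'
#' @param n_genes Total genes (partitioned into modules).
#' @param n_modules Number of modules.
#' @param module_size_range Length-2 integer vector `(min, max)` of genes
#'   per module; `n_genes >= n_modules * min` must hold. Genes beyond the
#'   module allocation form a background pool with no planted signal (the
#'   realistic regime: most genes belong to no densely co-functional
#'   module, so true associations are sparse in the pair universe).
#' @param n_conditions Expression conditions (>= 2).
#' @param n_species Species in the phylogenetic profiles.
#' @param rho_within,rho_between Within-/between-module expression
#'   correlation (block-exchangeable Gaussian factor model);
#'   `rho_within >= rho_between`.
#' @param p_edge_within,p_edge_between Bernoulli edge probabilities of the
#'   true interactome inside and between modules;
#'   `p_edge_within >= p_edge_between`.
#' @param terms_per_module,compartments_per_module,domains_per_module
#'   Characteristic items planted per module.
#' @param domains_per_gene Domains drawn per gene from its module pool.
#' @param annotation_noise,localization_noise,domain_noise,phylo_noise
#'   Per-category corruption rates in `[0, 1]` (dropout of planted items /
#'   bit flips, plus gain of random background items at the same rate).
#' @param interolog_within_rate Probability that a within-module pair has
#'   interolog support; random background pairs appear at
#'   `interolog_noise`.
#' @param interolog_noise Background interolog rate over all pairs.
#' @param gold_fraction Fraction of true edges sampled as gold-standard
#'   interaction records (study counts in `{1,2,3}`, low-throughput flags
#'   Bernoulli(0.5), so the quality filter exercises all branches).
#' @param new_annotation_fraction Per-gene fraction of annotation terms
#'   held out as "new" (post-hoc) annotations for the guilt-by-association
#'   benchmark; the rest are "old".
#' @param seed Integer seed; the whole bundle is a deterministic function
#'   of the config.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(n_genes = 900, n_modules = 5,
                           module_size_range = c(30, 30),
                           n_conditions = 30, n_species = 25,
                           rho_within = 0.7, rho_between = 0,
                           p_edge_within = 0.25, p_edge_between = 0.0001,
                           terms_per_module = 6,
                           compartments_per_module = 2,
                           domains_per_module = 4, domains_per_gene = 2,
                           annotation_noise = 0.1,
                           localization_noise = 0.1,
                           domain_noise = 0.1, phylo_noise = 0.1,
                           interolog_within_rate = 0.25,
                           interolog_noise = 0.002,
                           gold_fraction = 0.12,
                           new_annotation_fraction = 0.3,
                           seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(
    rho_within, rho_between, p_edge_within, p_edge_between,
    annotation_noise, localization_noise, domain_noise, phylo_noise,
    interolog_within_rate, interolog_noise, gold_fraction,
    new_annotation_fraction
  )
  stopifnot(
    all(probs >= 0 & probs <= 1),
    rho_within >= rho_between,
    p_edge_within >= p_edge_between,
    n_conditions >= 2, n_species >= 2, n_modules >= 1
  )
  if (n_genes < n_modules * module_size_range[1]) {
    abort(sprintf(
      "infeasible sizes: %d genes cannot host %d modules of at least %d genes",
      n_genes, n_modules, module_size_range[1]
    ))
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "fixture_config")
}

#' Generate a synthetic benchmark bundle
#'
#' Produces everything the pipeline consumes, self-contained: the true
#' interactome, the six evidence tables, gold-standard interaction records,
#' an old/new annotation corpus, the module gene sets, an alias-mapping
#' table and a manifest. Deterministic for a fixed config.
#'
#' @param cfg A [fixture_config()].
#' @return A list of class `fixture_bundle` with elements `truth`
#'   (`interactome`), `evidence` (`evidence_bundle`), `gold` (tibble),
#'   `corpus` (`annotation_corpus`), `sets` (`gene_set_collection`),
#'   `modules` (named list of gene vectors), `mapping` (alias table) and
#'   `manifest`.
#' @export
generate_fixture <- function(cfg = fixture_config()) {
  stopifnot(inherits(cfg, "fixture_config"))
  withr::with_seed(cfg$seed, generate_fixture_impl(cfg))
}

#' @rdname generate_fixture
#' @details `null_fixture()` generates the matched no-signal bundle: the
#'   same layout with `rho_within = rho_between` and
#'   `p_edge_within = p_edge_between`, so the network carries no module
#'   structure and evidence is independent of the edges. Used for
#'   type-I-error and chance-level-AUC checks.
#' @export
null_fixture <- function(cfg = fixture_config()) {
  cfg$rho_within <- cfg$rho_between
  cfg$p_edge_within <- cfg$p_edge_between
  generate_fixture(cfg)
}

generate_fixture_impl <- function(cfg) {
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))

  # -- module partition: start every module at the minimum size, then
  #    scatter the remaining genes without exceeding the maximum
  sizes <- rep(cfg$module_size_range[1], cfg$n_modules)
  extra <- cfg$n_genes - sum(sizes)
  while (extra > 0 && any(sizes < cfg$module_size_range[2])) {
    open <- which(sizes < cfg$module_size_range[2])
    pick <- open[sample.int(length(open), 1)]
    sizes[pick] <- sizes[pick] + 1
    extra <- extra - 1
  }
  # module 0 = background genes outside any planted module
  module_of <- sample(rep(c(0L, seq_len(cfg$n_modules)), c(extra, sizes)))
  in_module <- module_of > 0
  modules <- split(genes[in_module], module_of[in_module])
  names(modules) <- sprintf("module%02d", seq_len(cfg$n_modules))

  # -- true interactome
  idx <- which(upper.tri(matrix(0, cfg$n_genes, cfg$n_genes)), arr.ind = TRUE)
  same <- in_module[idx[, 1]] & module_of[idx[, 1]] == module_of[idx[, 2]]
  p <- ifelse(same, cfg$p_edge_within, cfg$p_edge_between)
  keep <- runif(nrow(idx)) < p
  truth <- interactome(
    tibble(gene_a = genes[idx[keep, 1]], gene_b = genes[idx[keep, 2]]),
    genes = genes
  )

  # -- expression: block-exchangeable Gaussian factor model
  f0 <- rnorm(cfg$n_conditions)
  fm <- matrix(rnorm(cfg$n_modules * cfg$n_conditions),
    cfg$n_modules, cfg$n_conditions
  )
  eps <- matrix(rnorm(cfg$n_genes * cfg$n_conditions),
    cfg$n_genes, cfg$n_conditions
  )
  fmod <- matrix(0, cfg$n_genes, cfg$n_conditions)
  fmod[in_module, ] <- sqrt(cfg$rho_within - cfg$rho_between) *
    fm[module_of[in_module], , drop = FALSE]
  noise_scale <- ifelse(in_module, sqrt(1 - cfg$rho_within),
    sqrt(1 - cfg$rho_between)
  )
  expr <- sqrt(cfg$rho_between) * matrix(f0, cfg$n_genes, cfg$n_conditions,
    byrow = TRUE
  ) + fmod + noise_scale * eps
  dimnames(expr) <- list(genes, sprintf("cond%02d", seq_len(cfg$n_conditions)))

  # -- annotations: module terms with dropout, plus background noise terms
  module_terms <- lapply(seq_len(cfg$n_modules), function(m) {
    sprintf("TERM:M%02d_%02d", m, seq_len(cfg$terms_per_module))
  })
  bg_terms <- sprintf("TERM:BG_%02d", 1:20)
  ann <- bind_rows(lapply(seq_len(cfg$n_genes), function(i) {
    own <- if (in_module[i]) module_terms[[module_of[i]]] else character()
    own <- own[runif(length(own)) > cfg$annotation_noise]
    gained <- bg_terms[runif(length(bg_terms)) < cfg$annotation_noise / 4]
    if (runif(1) < 0.5) gained <- c(gained, sample(bg_terms, 1))
    tibble(gene = genes[i], term = unique(c(own, gained)))
  }))

  # -- localizations
  module_comp <- lapply(seq_len(cfg$n_modules), function(m) {
    sprintf("COMP:M%02d_%d", m, seq_len(cfg$compartments_per_module))
  })
  common_comp <- c("COMP:cytosol", "COMP:nucleus")
  all_comp <- c(unlist(module_comp), common_comp)
  loc <- bind_rows(lapply(seq_len(cfg$n_genes), function(i) {
    own <- if (in_module[i]) module_comp[[module_of[i]]] else character()
    own <- own[runif(length(own)) > cfg$localization_noise]
    extras <- c(
      common_comp[runif(2) < if (in_module[i]) 0.4 else 0.8],
      if (runif(1) < cfg$localization_noise) sample(all_comp, 1)
    )
    tibble(gene = genes[i], compartment = unique(c(own, extras)))
  }))

  # -- domains and interacting domain pairs
  module_dom <- lapply(seq_len(cfg$n_modules), function(m) {
    sprintf("DOM:M%02d_%d", m, seq_len(cfg$domains_per_module))
  })
  bg_dom <- sprintf("DOM:BG_%d", 1:10)
  all_dom <- c(unlist(module_dom), bg_dom)
  dom <- bind_rows(lapply(seq_len(cfg$n_genes), function(i) {
    pool <- if (in_module[i]) module_dom[[module_of[i]]] else bg_dom
    own <- sample(pool, min(cfg$domains_per_gene, length(pool)))
    gained <- if (runif(1) < cfg$domain_noise) sample(bg_dom, 1)
    tibble(gene = genes[i], domain = unique(c(own, gained)))
  }))
  ddi <- bind_rows(lapply(module_dom, function(pool) {
    grid <- expand.grid(a = pool, b = pool, stringsAsFactors = FALSE)
    grid <- grid[grid$a <= grid$b, , drop = FALSE]
    grid <- grid[runif(nrow(grid)) < 0.7, , drop = FALSE]
    tibble(
      domain_a = grid$a, domain_b = grid$b,
      score = round(runif(nrow(grid), 0.3, 1), 3)
    )
  }))
  n_noise_ddi <- ceiling(0.02 * length(all_dom)^2 / 2)
  noise_ddi <- tibble(
    domain_a = sample(all_dom, n_noise_ddi, replace = TRUE),
    domain_b = sample(all_dom, n_noise_ddi, replace = TRUE),
    score = round(runif(n_noise_ddi, 0.1, 0.6), 3)
  )
  ddi <- bind_rows(ddi, noise_ddi)

  # -- phylogenetic profiles: module prototype with bit flips
  proto <- matrix(
    rbinom(cfg$n_modules * cfg$n_species, 1, 0.5),
    cfg$n_modules, cfg$n_species
  )
  flips <- matrix(
    rbinom(cfg$n_genes * cfg$n_species, 1, cfg$phylo_noise),
    cfg$n_genes, cfg$n_species
  )
  proto_of <- matrix(
    rbinom(cfg$n_genes * cfg$n_species, 1, 0.5),
    cfg$n_genes, cfg$n_species
  )
  proto_of[in_module, ] <- proto[module_of[in_module], , drop = FALSE]
  phylo <- abs(proto_of - flips)
  dimnames(phylo) <- list(genes, sprintf("species%02d", seq_len(cfg$n_species)))

  # -- interologs: within-module pairs at the planted rate + background
  r <- ifelse(same, cfg$interolog_within_rate, cfg$interolog_noise)
  il_keep <- runif(nrow(idx)) < r
  interologs <- tibble(
    gene_a = genes[idx[il_keep, 1]],
    gene_b = genes[idx[il_keep, 2]]
  )

  evidence <- evidence_bundle(
    expression = expr, annotations = ann, localizations = loc,
    domains = dom, domain_interactions = ddi,
    phylo_profiles = phylo, interologs = interologs
  )

  # -- gold standard: a subset of true edges with study metadata
  te <- truth$edges
  n_gold <- floor(cfg$gold_fraction * nrow(te))
  gi <- sort(sample.int(nrow(te), n_gold))
  gold <- tibble(
    gene_a = te$gene_a[gi], gene_b = te$gene_b[gi],
    n_studies = sample(1:3, n_gold, replace = TRUE, prob = c(0.4, 0.4, 0.2)),
    has_low_throughput = runif(n_gold) < 0.5
  )

  # -- annotation corpus: per-gene old/new split
  ann_split <- ann |>
    group_by(.data$gene) |>
    mutate(.new = {
      n_new <- floor(cfg$new_annotation_fraction * n())
      seq_len(n()) %in% sample.int(n(), n_new)
    }) |>
    ungroup()
  corpus <- annotation_corpus(
    old = ann_split[!ann_split$.new, c("gene", "term")],
    new = ann_split[ann_split$.new, c("gene", "term")]
  )

  sets <- gene_sets(modules,
    descriptions = sprintf("planted functional module %d", seq_along(modules))
  )

  mapping <- bind_rows(
    tibble(namespace = "uniprot", alias = paste0("UP_", genes), gene_id = genes),
    tibble(namespace = "entrez", alias = as.character(seq_along(genes) + 1000L), gene_id = genes)
  )

  structure(list(
    truth = truth, evidence = evidence, gold = gold, corpus = corpus,
    sets = sets, modules = modules, mapping = mapping,
    manifest = list(config = unclass(cfg), n_truth_edges = nrow(te))
  ), class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf(
    "<fixture_bundle> %d genes in %d modules, %d true edges, %d gold records\n",
    length(x$truth$genes), length(x$modules), n_edges(x$truth), nrow(x$gold)
  ))
  invisible(x)
}

#' Write a fixture bundle to a directory of plain-text files
#'
#' Emits every input format the pipeline reads: `truth.tsv` (edge list),
#' `evidence/` (TSV tables), `gold.tsv`, `corpus_old.tsv` / `corpus_new.tsv`,
#' `sets.gmt`, `mapping.tsv` and `manifest.json`.
#'
#' @param bundle A `fixture_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_list(bundle$truth, file.path(dir, "truth.tsv"))
  write_evidence_bundle(bundle$evidence, file.path(dir, "evidence"))
  readr::write_tsv(bundle$gold, file.path(dir, "gold.tsv"), progress = FALSE)
  readr::write_tsv(bundle$corpus$old, file.path(dir, "corpus_old.tsv"), progress = FALSE)
  readr::write_tsv(bundle$corpus$new, file.path(dir, "corpus_new.tsv"), progress = FALSE)
  write_gmt(bundle$sets, file.path(dir, "sets.gmt"))
  readr::write_tsv(bundle$mapping, file.path(dir, "mapping.tsv"), progress = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Assemble a labeled training table from a fixture bundle
#'
#' Filters the gold records, samples `neg_ratio` negatives per positive,
#' computes features for all pairs and binds the labels — the standard path
#' from a bundle to [train_association_model()] input.
#'
#' @param bundle A `fixture_bundle`.
#' @param registry A [feature_registry()].
#' @param neg_ratio Negatives per positive.
#' @param seed Integer seed for negative sampling.
#' @return A tibble: `gene_a`, `gene_b`, `label`, then feature columns.
#' @export
labeled_pairs_from_bundle <- function(bundle, registry = feature_registry(),
                                      neg_ratio = 100, seed = 1L) {
  pos <- filter_gold_positives(bundle$gold)[, c("gene_a", "gene_b")]
  neg <- sample_negatives(bundle$truth$genes, pos,
    ratio = neg_ratio, seed = seed
  )
  pairs <- bind_rows(pos, neg)
  feats <- compute_features(pairs, bundle$evidence, registry)
  bind_cols(
    feats[, c("gene_a", "gene_b")],
    tibble(label = rep(c(1L, 0L), c(nrow(pos), nrow(neg)))),
    feats[, setdiff(names(feats), c("gene_a", "gene_b"))]
  )
}
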