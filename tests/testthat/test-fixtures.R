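test_that("bundles are byte-identical for a fixed seed", {
  cfg <- fixture_config(
    n_genes = 100, n_modules = 3, module_size_range = c(25, 30), seed = 7
  )
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture_bundle(generate_fixture(cfg), d1)
  write_fixture_bundle(generate_fixture(cfg), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_true(length(files) >= 10)
  for (f in files) {
    expect_identical(
      readLines(file.path(d1, f)),
      readLines(file.path(d2, f)),
      info = f
    )
  }
  d3 <- withr::local_tempdir()
  cfg$seed <- 8L
  write_fixture_bundle(generate_fixture(cfg), d3)
  expect_false(identical(
    readLines(file.path(d1, "truth.tsv")),
    readLines(file.path(d3, "truth.tsv"))
  ))
})

test_that("emitted files round-trip through the package readers", {
  cfg <- fixture_config(
    n_genes = 100, n_modules = 3, module_size_range = c(25, 30), seed = 9
  )
  b <- generate_fixture(cfg)
  d <- withr::local_tempdir()
  write_fixture_bundle(b, d)

  truth <- read_edge_list(file.path(d, "truth.tsv"))
  expect_equal(truth$edges$gene_a, b$truth$edges$gene_a)
  expect_equal(sort(unique(c(truth$edges$gene_a, truth$edges$gene_b))),
    sort(unique(c(b$truth$edges$gene_a, b$truth$edges$gene_b))))

  ev <- read_evidence_bundle(file.path(d, "evidence"))
  expect_equal(dim(ev$expression), dim(b$evidence$expression))
  expect_equal(ev$expression[1, ], b$evidence$expression[1, ], tolerance = 1e-9)
  expect_equal(ev$annotations, b$evidence$annotations)
  expect_equal(ev$interologs, b$evidence$interologs)
  expect_equal(as.data.frame(ev$domain_interactions),
    as.data.frame(b$evidence$domain_interactions))

  sets <- read_gmt(file.path(d, "sets.gmt"))
  expect_equal(sets$name, b$sets$name)
  expect_equal(sets$genes, b$sets$genes)

  mapping <- read_id_mapping(file.path(d, "mapping.tsv"))
  r <- map_ids(mapping$alias[1:5], mapping)
  expect_equal(length(r$unmapped), 0)
})

test_that("structural invariants hold: gold within truth, corpus split, sets", {
  b <- generate_fixture(fixture_config(seed = 30))
  expect_true(all(
    paste(b$gold$gene_a, b$gold$gene_b) %in% edge_keys(b$truth)
  ))
  expect_true(any(b$gold$n_studies == 1) && any(b$gold$n_studies >= 2))
  expect_true(any(b$gold$has_low_throughput) && any(!b$gold$has_low_throughput))
  both <- dplyr::inner_join(b$corpus$old, b$corpus$new, by = c("gene", "term"))
  expect_equal(nrow(both), 0)
  expect_equal(nrow(b$sets), length(b$modules))
  expect_true(all(unlist(b$sets$genes) %in% b$truth$genes))
})

test_that("no planted cross-module edges when p_edge_between is zero", {
  cfg <- fixture_config(
    n_genes = 90, n_modules = 3, module_size_range = c(30, 30),
    p_edge_between = 0, seed = 31
  )
  b <- generate_fixture(cfg)
  module_of <- rep(names(b$modules), lengths(b$modules))
  names(module_of) <- unlist(b$modules)
  e <- b$truth$edges
  expect_true(all(module_of[e$gene_a] == module_of[e$gene_b]))
})

test_that("null bundles carry no signal linking evidence to edges", {
  cfg <- fixture_config(
    n_genes = 150, n_modules = 3, module_size_range = c(30, 30),
    p_edge_between = 0.05, gold_fraction = 0.8, seed = 32
  )
  nb <- null_fixture(cfg)
  lp <- suppressWarnings(labeled_pairs_from_bundle(nb, neg_ratio = 5, seed = 33))
  aucs <- feature_aucs(lp[, setdiff(names(lp), "label")], lp$label)
  expect_true(all(abs(aucs$auc - 0.5) < 0.12))
})

test_that("stronger planted correlation never hurts feature signal", {
  auc_at <- function(rho, seed) {
    cfg <- fixture_config(
      n_genes = 150, n_modules = 3, module_size_range = c(30, 30),
      rho_within = rho, gold_fraction = 0.5, seed = seed
    )
    b <- generate_fixture(cfg)
    lp <- suppressWarnings(labeled_pairs_from_bundle(b, neg_ratio = 10, seed = seed + 1))
    aucs <- feature_aucs(lp[, setdiff(names(lp), "label")], lp$label)
    aucs$auc[aucs$feature == "coexpr_pearson"]
  }
  for (s in c(51, 52, 53)) {
    expect_gte(auc_at(0.8, s) + 0.03, auc_at(0.3, s))
  }
})

test_that("infeasible module partitions are rejected", {
  expect_error(
    fixture_config(n_genes = 50, n_modules = 3, module_size_range = c(30, 40)),
    "infeasible"
  )
  expect_error(fixture_config(rho_within = 0.2, rho_between = 0.5))
})
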