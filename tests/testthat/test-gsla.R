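test_that("identifier mapping preserves order, collapses aliases, reports misses", {
  mapping <- tibble::tibble(
    namespace = c("uniprot", "uniprot", "entrez"),
    alias = c("P1", "P2", "1001"),
    gene_id = c("GENEA", "GENEB", "GENEA")
  )
  r <- map_ids(c("GENEA", "P2", "nope", "P1", "1001"), mapping)
  expect_equal(r$mapped, c("GENEA", "GENEB")) # aliases of GENEA collapsed
  expect_equal(r$unmapped, "nope")
  expect_error(map_ids(c("x", "y"), mapping), "could be mapped")
})

test_that("inter-set density uses distinct unordered cross pairs", {
  net <- interactome(tibble::tibble(
    gene_a = c("g1", "g2", "g3"), gene_b = c("g2", "g3", "g4")
  ))
  d <- q1_density(net, c("g1", "g2"), c("g3", "g4"))
  expect_equal(d$density, 0.25)
  expect_equal(d$n_possible, 4)

  # overlapping sets: k = 1 shared gene -> 3 possible pairs, 2 edges
  d2 <- q1_density(net, c("g1", "g2"), c("g2", "g3"))
  expect_equal(d2$n_possible, 3)
  expect_equal(d2$density, 2 / 3)

  expect_equal(q1_density(net, "g1", "g4")$density, 0)
  expect_error(q1_density(net, "g1", "g1"), "undefined")
  expect_error(q1_density(net, character(), "g1"), "non-empty")
})

test_that("rewiring preserves the degree sequence and gene set exactly", {
  # triangle is rigid: every swap is rejected
  k3 <- interactome(tibble::tibble(
    gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c")
  ))
  rw <- rewire_degree_preserving(k3, swaps_per_edge = 50, seed = 1)
  expect_equal(rw$edges[, 1:2], k3$edges[, 1:2])

  p3 <- path_net()
  rwp <- rewire_degree_preserving(p3, swaps_per_edge = 25, seed = 2)
  expect_equal(node_degree(rwp), node_degree(p3))

  net <- fixed_edge_net(80, 200, seed = 7)
  rw2 <- rewire_degree_preserving(net, swaps_per_edge = 10, seed = 3)
  expect_identical(node_degree(rw2), node_degree(net))
  expect_identical(rw2$genes, net$genes)
  expect_lt(length(intersect(edge_keys(rw2), edge_keys(net))), 200)
  # reproducible per seed
  rw3 <- rewire_degree_preserving(net, swaps_per_edge = 10, seed = 3)
  expect_identical(rw2$edges, rw3$edges)
})

test_that("rewired nulls match an independent degree-preserving generator", {
  skip_if_not_installed("igraph")
  net <- fixed_edge_net(60, 150, seed = 8)
  g <- igraph::graph_from_edgelist(as.matrix(net$edges[, 1:2]), directed = FALSE)
  a <- sample(net$genes, 15)
  b <- sample(net$genes, 20)
  mine <- replicate(60, {
    s <- sample.int(1e6, 1)
    nrow(inter_set_edges(rewire_degree_preserving(net, 10, seed = s), a, b))
  })
  theirs <- replicate(60, {
    rg <- igraph::rewire(g, igraph::keeping_degseq(niter = 1500))
    em <- igraph::as_edgelist(rg)
    sum((em[, 1] %in% a & em[, 2] %in% b) | (em[, 1] %in% b & em[, 2] %in% a))
  })
  # same null ensemble: mean inter-set edge counts agree within Monte Carlo error
  se <- sqrt(var(mine) / 60 + var(theirs) / 60)
  expect_lt(abs(mean(mine) - mean(theirs)), 4 * se + 1)
})

test_that("add-one p-values respect their attainable bounds", {
  net <- fixed_edge_net(60, 150, seed = 9)
  cfg <- gsla_config(n_permutations = 99, q2_alpha = 0.05, seed = 4)
  withr::with_seed(10, {
    for (i in 1:5) {
      a <- sample(net$genes, 10)
      b <- sample(net$genes, 12)
      z <- q2_pvalue(net, a, b, cfg)
      expect_gte(z$p_value, 1 / 100)
      expect_lte(z$p_value, 1)
      expect_length(z$null_densities, 99)
    }
  })
  # observed density 0: every null is at least as dense
  empty_cross <- q2_pvalue(
    net, net$genes[1], net$genes[2],
    gsla_config(n_permutations = 19, q2_alpha = 0.2, seed = 5)
  )
  if (empty_cross$observed$n_edges == 0) expect_equal(empty_cross$p_value, 1)
})

test_that("early stopping never changes the pass/fail decision", {
  net <- fixed_edge_net(80, 300, seed = 12)
  cfg <- gsla_config(n_permutations = 99, q2_alpha = 0.05, seed = 6)
  withr::with_seed(13, {
    for (i in 1:8) {
      a <- sample(net$genes, 12)
      b <- sample(net$genes, 12)
      full <- q2_pvalue(net, a, b, cfg)
      quick <- q2_pvalue(net, a, b, cfg, early_stop_alpha = 0.05)
      expect_equal(full$p_value < 0.05, quick$p_value < 0.05)
      if (!quick$truncated) expect_equal(quick$p_value, full$p_value)
    }
  })
})

test_that("a planted module is detected with the minimal attainable p", {
  b <- generate_fixture(fixture_config(
    n_genes = 120, n_modules = 2, module_size_range = c(40, 40),
    p_edge_within = 0.3, p_edge_between = 0.01, seed = 17
  ))
  m1 <- b$modules[[1]]
  cfg <- gsla_config(n_permutations = 199, q2_alpha = 0.01, seed = 18)
  z <- q2_pvalue(b$truth, m1[1:20], m1[21:40], cfg)
  expect_equal(z$p_value, 1 / 200)
  expect_gt(z$observed$density, 0.1)
})

test_that("gsla_run reports, sorts and skips Q2 for Q1 failures", {
  b <- generate_fixture(fixture_config(
    n_genes = 150, n_modules = 3, module_size_range = c(40, 40),
    p_edge_within = 0.3, p_edge_between = 0.005, seed = 19
  ))
  query <- b$modules[[1]][1:20]
  refs <- gene_sets(c(
    list(rest_of_module = setdiff(b$modules[[1]], query)),
    list(other_module = b$modules[[2]]),
    list(random = withr::with_seed(20, sample(b$truth$genes, 40)))
  ))
  cfg <- gsla_config(n_permutations = 199, q2_alpha = 0.01, seed = 21)
  res <- suppressWarnings(gsla_run(b$truth, query, refs, cfg))

  expect_s3_class(res, "gsla_result")
  expect_equal(nrow(res), 3)
  expect_equal(res$ref_set[1], "rest_of_module")
  expect_true(res$passes_q1[1] && res$passes_q2[1])
  expect_equal(res$p_value[1], 1 / 200)
  # Q1 failures are not permutation-tested and carry p = 1
  expect_true(all(res$p_value[!res$q2_tested] == 1))
  expect_true(all(res$passes_q1 == (res$density > cfg$q1_min_density)))
  # connecting pairs are real edges with the query gene first
  cp <- res$connecting_pairs[[1]]
  expect_true(all(cp$query_gene %in% query))
  expect_true(all(cp$ref_gene %in% refs$genes[[1]]))

  # self-reference: overlap formula, no crash
  self_res <- suppressWarnings(
    gsla_run(b$truth, query, gene_sets(list(self = query)),
      gsla_config(n_permutations = 19, q2_alpha = 0.2, seed = 22)
    )
  )
  expect_equal(self_res$set_size, 20)

  # bit-reproducible under a fixed seed
  res2 <- suppressWarnings(gsla_run(b$truth, query, refs, cfg))
  expect_identical(tidy(res), tidy(res2))
})

test_that("the report file starts with 10 parameter lines", {
  b <- generate_fixture(fixture_config(
    n_genes = 90, n_modules = 3, module_size_range = c(30, 30),
    p_edge_within = 0.3, p_edge_between = 0.01, seed = 23
  ))
  res <- suppressWarnings(gsla_run(
    b$truth, b$modules[[1]][1:15], b$sets,
    gsla_config(n_permutations = 19, q2_alpha = 0.2, seed = 24)
  ))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_gsla_report(res, tmp)
  lines <- readLines(tmp)
  expect_equal(sum(startsWith(lines[1:10], "#")), 10)
  expect_false(startsWith(lines[11], "#"))
  tab <- readr::read_tsv(tmp, comment = "#", show_col_types = FALSE)
  expect_equal(nrow(tab), nrow(res))
  expect_true("connecting_pairs" %in% names(tab))
})

test_that("an unattainable Q2 threshold triggers a warning", {
  expect_warning(gsla_config(q2_alpha = 0.001, n_permutations = 199), "unattainable")
  expect_silent(gsla_config(q2_alpha = 0.001, n_permutations = 1999))
})
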