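tiny_bundle <- function() {
  expr <- rbind(
    a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1), d = c(1, 1, 2, 1)
  )
  colnames(expr) <- paste0("c", 1:4)
  phylo <- rbind(
    a = c(1, 1, 0, 0, 1), b = c(1, 1, 0, 0, 1),
    c = c(0, 0, 1, 1, 0), d = c(1, 0, 1, 0, 1)
  )
  colnames(phylo) <- paste0("s", 1:5)
  evidence_bundle(
    expression = expr,
    annotations = tibble::tibble(
      gene = c("a", "a", "b", "b", "c", "d"),
      term = c("T1", "T2", "T1", "T2", "T3", "T1")
    ),
    localizations = tibble::tibble(
      gene = c("a", "a", "b", "b", "c"),
      compartment = c("nucleus", "cytosol", "nucleus", "cytosol", "membrane")
    ),
    domains = tibble::tibble(
      gene = c("a", "b", "c"), domain = c("D1", "D2", "D3")
    ),
    domain_interactions = tibble::tibble(
      domain_a = "D1", domain_b = "D2", score = 0.8
    ),
    phylo_profiles = phylo,
    interologs = tibble::tibble(gene_a = "a", gene_b = "b")
  )
}

test_that("representative feature values match closed forms", {
  ev <- tiny_bundle()
  pairs <- tibble::tibble(gene_a = c("a", "a", "c"), gene_b = c("b", "c", "d"))
  f <- suppressWarnings(compute_features(pairs, ev))

  # identical localization sets {nucleus, cytosol}
  expect_equal(f$coloc_jaccard[1], 1)
  expect_equal(f$coloc_any_shared[1], 1)
  expect_equal(f$coloc_jaccard[2], 0)
  # proportional expression vectors
  expect_equal(f$coexpr_pearson[1], 1)
  expect_equal(f$coexpr_spearman[1], 1)
  expect_equal(f$coexpr_pearson[2], -1)
  # interacting domain pair D1-D2 with score 0.8
  expect_equal(f$ddi_count[1], 1)
  expect_equal(f$ddi_score_max[1], 0.8)
  expect_equal(f$ddi_any[1], 1)
  # c-d share no domains and no interacting pairs: whole category is 0
  dom_cols <- grep("^(ddi|dom)_", names(f), value = TRUE)
  expect_true(all(f[3, dom_cols] == 0))
  # identical phylogenetic profiles
  expect_equal(f$phylo_pearson[1], 1)
  expect_equal(f$phylo_jaccard[1], 1)
  # shared annotation: a,b share T1,T2; IC(T1) = -log2(3/4)
  expect_equal(f$annot_shared_count[1], 2)
  expect_equal(f$annot_min_shared_ic[1], -log2(3 / 4))
  expect_equal(f$interolog_indicator, c(1, 0, 0))
})

test_that("features are symmetric in the pair and finite", {
  ev <- tiny_bundle()
  pairs <- tibble::tibble(gene_a = c("a", "b", "c"), gene_b = c("b", "c", "d"))
  f1 <- suppressWarnings(compute_features(pairs, ev))
  f2 <- suppressWarnings(compute_features(
    tibble::tibble(gene_a = pairs$gene_b, gene_b = pairs$gene_a), ev
  ))
  m1 <- as.matrix(f1[, -(1:2)])
  m2 <- as.matrix(f2[, -(1:2)])
  expect_equal(unname(m1), unname(m2))
  expect_true(all(is.finite(m1)))
})

test_that("genes missing from an evidence table yield 0 with a warning", {
  ev <- tiny_bundle()
  pairs <- tibble::tibble(gene_a = "a", gene_b = "zz")
  expect_warning(f <- compute_features(pairs, ev), "absent")
  expect_true(all(as.matrix(f[, -(1:2)]) == 0))
})

test_that("registry census is configurable and sums to the default 36", {
  reg <- feature_registry()
  census <- registry_census(reg)
  expect_equal(sum(census), 36)
  expect_equal(unname(census["domain_interaction"]), 23)
  expect_false(anyDuplicated(reg$name) > 0)

  small <- feature_registry(c(coexpression = 2, colocalization = 1))
  expect_equal(nrow(small), 3)
  expect_error(feature_registry(c(interolog = 5)), "provides")
  expect_error(feature_registry(c(nonsense = 1)), "unknown")
})

test_that("roc_auc equals the tie-aware Mann-Whitney statistic", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)
  # exhaustive pair counting: pos {0.9, 0.4} vs neg {0.6, 0.1} -> 3/4
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("roc_auc properties: complement, monotone invariance, pROC agreement", {
  withr::with_seed(42, {
    for (i in 1:5) {
      s <- c(rnorm(30, 1), rnorm(50))
      y <- rep(c(1, 0), c(30, 50))
      a <- roc_auc(s, y)
      expect_equal(a + roc_auc(s, 1 - y), 1)
      expect_equal(roc_auc(exp(2 * s) + 3, y), a)
      skip_if_not_installed("pROC")
      expect_equal(
        a,
        as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
      )
    }
  })
})

test_that("the AUC gate is strict and keeps registry order", {
  expect_equal(
    select_features(c(f1 = 0.55, f2 = 0.72, f3 = 0.60)),
    "f2"
  )
  expect_equal(select_features(setNames(numeric(0), character(0))), character(0))
  expect_equal(
    select_features(c(a = 0.61, b = 0.9, c = 0.59)),
    c("a", "b")
  )
})

test_that("planted signal passes the gate, shuffled labels do not", {
  b <- generate_fixture(fixture_config(
    n_genes = 300, n_modules = 4, module_size_range = c(30, 30),
    gold_fraction = 0.4, seed = 21
  ))
  lp <- suppressWarnings(labeled_pairs_from_bundle(b, neg_ratio = 20, seed = 22))
  aucs <- feature_aucs(lp[, setdiff(names(lp), "label")], lp$label)
  expect_gt(length(select_features(aucs)), 10)

  shuffled <- withr::with_seed(23, sample(lp$label))
  aucs0 <- feature_aucs(lp[, setdiff(names(lp), "label")], shuffled)
  expect_true(all(abs(aucs0$auc - 0.5) < 0.1))
  expect_lt(length(select_features(aucs0)), 3)
})
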