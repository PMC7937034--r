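# Well-separated two-class pair data in feature space; labels follow a
# known decision boundary so confusion counts have a brute-force oracle.
separable_pairs <- function(n_pos = 40, n_neg = 400, gap = 3, seed = 1,
                            prefix = "p") {
  withr::with_seed(seed, {
    f1 <- c(rnorm(n_pos, gap), rnorm(n_neg, 0))
    f2 <- c(rnorm(n_pos, gap), rnorm(n_neg, 0))
    tibble::tibble(
      gene_a = sprintf("%sa%04d", prefix, seq_len(n_pos + n_neg)),
      gene_b = sprintf("%sb%04d", prefix, seq_len(n_pos + n_neg)),
      label = rep(c(1L, 0L), c(n_pos, n_neg)),
      f1 = f1, f2 = f2
    )
  })
}

test_that("gold filter keeps multi-study or low-throughput interactions", {
  gold <- tibble::tibble(
    gene_a = c("a", "b", "c", "d"), gene_b = c("x", "y", "z", "w"),
    n_studies = c(1L, 2L, 1L, 3L),
    has_low_throughput = c(FALSE, FALSE, TRUE, TRUE)
  )
  kept <- filter_gold_positives(gold)
  expect_equal(kept$gene_a, c("b", "c", "d")) # order preserved
})

test_that("negative sampling is exact, collision-free and seed-reproducible", {
  genes <- sprintf("g%03d", 1:60)
  pos <- tibble::tibble(gene_a = genes[1:10], gene_b = genes[11:20])

  neg <- sample_negatives(genes, pos, ratio = 30, seed = 9)
  expect_equal(nrow(neg), 300)
  keys <- paste(neg$gene_a, neg$gene_b)
  expect_equal(anyDuplicated(keys), 0L)
  expect_false(any(keys %in% paste(pos$gene_a, pos$gene_b)))
  expect_false(any(neg$gene_a == neg$gene_b))
  expect_true(all(neg$gene_a < neg$gene_b))

  neg2 <- sample_negatives(genes, pos, ratio = 30, seed = 9)
  expect_identical(neg, neg2)
  neg3 <- sample_negatives(genes, pos, ratio = 30, seed = 10)
  expect_false(identical(neg, neg3))

  expect_equal(nrow(sample_negatives(genes, pos, ratio = 0, seed = 1)), 0)
  expect_error(
    sample_negatives(genes[1:5], pos[1, ], ratio = 100, seed = 1),
    "cannot sample"
  )
})

test_that("harmonic mean of sensitivity and specificity", {
  expect_equal(harmonic_mean_sens_spec(1, 0), 0)
  expect_equal(harmonic_mean_sens_spec(0, 0), 0)
  expect_equal(harmonic_mean_sens_spec(1, 1), 1)
  expect_equal(harmonic_mean_sens_spec(0.8, 0.6), 2 * 0.8 * 0.6 / 1.4)
})

test_that("grid search learns separable classes and is grid-order invariant", {
  d <- separable_pairs(seed = 31)
  cfg <- training_config(sigma_grid = c(1, 2), c_grid = c(1, 10), seed = 5)
  m <- train_association_model(d, cfg)
  expect_gte(m$cv_harmonic_mean, 0.95)

  cfg_rev <- training_config(
    sigma_grid = rev(cfg$sigma_grid), c_grid = rev(cfg$c_grid), seed = 5
  )
  m_rev <- train_association_model(d, cfg_rev)
  expect_equal(c(m$sigma, m$c), c(m_rev$sigma, m_rev$c))

  m2 <- train_association_model(d, cfg)
  expect_equal(c(m$sigma, m$c), c(m2$sigma, m2$c)) # deterministic per seed
})

test_that("shuffled labels leave the model at chance level", {
  d <- separable_pairs(n_pos = 30, n_neg = 300, seed = 32)
  d$label <- withr::with_seed(33, sample(d$label))
  cfg <- training_config(sigma_grid = c(1, 2), c_grid = c(1, 10), seed = 5)
  m <- train_association_model(d, cfg)
  expect_lt(m$cv_sensitivity, 0.25) # nothing to find at 1:10 imbalance
})

test_that("predictions clip confidence at the margin and check columns", {
  d <- separable_pairs(seed = 34)
  cfg <- training_config(sigma_grid = 1, c_grid = 10, seed = 5)
  m <- train_association_model(d, cfg)
  pred <- predict(m, d)
  expect_equal(pred$predicted, pred$decision_value > 0)
  expect_equal(pred$confidence, pmin(1, abs(pred$decision_value)))
  expect_true(all(pred$confidence[abs(pred$decision_value) > 1] == 1))
  expect_gte(roc_auc(pred$decision_value, d$label), 0.95)
  expect_error(predict(m, d[, -4]), "feature column")
})

test_that("external validation matches a brute-force confusion matrix", {
  d <- separable_pairs(seed = 35)
  cfg <- training_config(sigma_grid = 1, c_grid = 10, seed = 5)
  m <- train_association_model(d, cfg)

  held <- separable_pairs(n_pos = 25, n_neg = 250, seed = 36, prefix = "q")
  v <- external_validate(m, held)
  pred <- predict(m, held)
  expect_equal(v$tp, sum(pred$predicted & held$label == 1))
  expect_equal(v$tn, sum(!pred$predicted & held$label == 0))
  expect_equal(v$sensitivity, v$tp / (v$tp + v$fn))
  expect_equal(v$specificity, v$tn / (v$tn + v$fp))
  expect_gte(v$sensitivity, 0.8)
  expect_gte(v$specificity, 0.95)

  expect_error(external_validate(m, d[1:5, ]), "leakage")
})

test_that("tidy and glance expose the CV grid and the model summary", {
  d <- separable_pairs(seed = 37)
  cfg <- training_config(sigma_grid = c(1, 2), c_grid = 1, seed = 5)
  m <- train_association_model(d, cfg)
  td <- tidy(m)
  expect_equal(nrow(td), 2)
  expect_named(td, c("sigma", "cost", "cv_sensitivity", "cv_specificity", "cv_harmonic_mean"))
  g <- glance(m)
  expect_equal(g$n_positive, 40)
  expect_equal(g$cv_harmonic_mean, max(td$cv_harmonic_mean))
})
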