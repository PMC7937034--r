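#' Filter gold-standard interactions
#'
#' Keeps an experimentally reported interaction when it was reported by at
#' least two independent studies or carries low-throughput evidence;
#' interactions seen in a single high-throughput study only are removed.
#' Order is preserved.
#'
#' @param gold Data frame with columns `gene_a`, `gene_b`, `n_studies`
#'   (positive integer) and `has_low_throughput` (logical).
#' @return The filtered tibble.
#' @export
filter_gold_positives <- function(gold) {
  gold <- as_tibble(gold)
  stopifnot(all(c("gene_a", "gene_b", "n_studies", "has_low_throughput")
  %in% names(gold)))
  if (any(gold$gene_a == gold$gene_b)) {
    abort("gold-standard interactions must not be self-pairs")
  }
  gold[gold$n_studies >= 2 | gold$has_low_throughput, , drop = FALSE]
}

#' Sample negative gene pairs
#'
#' Draws exactly `ratio * n_positives` distinct unordered gene pairs from
#' the given gene universe, excluding self-pairs and every positive pair.
#' Reproducible for a fixed seed.
#'
#' @param genes Character vector: the gene universe.
#' @param positives Data frame with columns `gene_a`, `gene_b`, or a
#'   2-column character matrix of positive pairs.
#' @param ratio Negatives per positive (default 100).
#' @param seed Integer seed.
#' @return A tibble `gene_a`, `gene_b` with `ratio * nrow(positives)` rows.
#' @export
sample_negatives <- function(genes, positives, ratio = 100, seed = 1L) {
  genes <- unique(genes)
  n <- length(genes)
  positives <- as_tibble(positives)
  pos_keys <- unique(pair_key(positives$gene_a, positives$gene_b))
  n_needed <- ratio * nrow(positives)
  if (n_needed == 0) {
    return(tibble(gene_a = character(), gene_b = character()))
  }
  n_pos_inside <- sum(
    positives$gene_a %in% genes & positives$gene_b %in% genes
  )
  capacity <- n * (n - 1) / 2 - n_pos_inside
  if (n_needed > capacity) {
    abort(sprintf(
      "cannot sample %d negatives: only %.0f non-positive pairs exist",
      n_needed, capacity
    ))
  }
  withr::with_seed(seed, {
    keys <- character(0)
    ga <- gb <- character(0)
    while (length(keys) < n_needed) {
      m <- ceiling((n_needed - length(keys)) * 1.3) + 10
      i <- sample.int(n, m, replace = TRUE)
      j <- sample.int(n, m, replace = TRUE)
      keep <- i != j
      a <- pmin(genes[i[keep]], genes[j[keep]])
      b <- pmax(genes[i[keep]], genes[j[keep]])
      k <- pair_key(a, b)
      fresh <- !(k %in% pos_keys) & !(k %in% keys) & !duplicated(k)
      ga <- c(ga, a[fresh])
      gb <- c(gb, b[fresh])
      keys <- c(keys, k[fresh])
    }
    tibble(gene_a = ga[seq_len(n_needed)], gene_b = gb[seq_len(n_needed)])
  })
}

#' Harmonic mean of sensitivity and specificity
#'
#' `2 * sens * spec / (sens + spec)`, defined as 0 when both are 0. This is
#' the model-selection objective of the cross-validated grid search.
#'
#' @param sens,spec Reals in `[0, 1]`.
#' @return The harmonic mean.
#' @export
harmonic_mean_sens_spec <- function(sens, spec) {
  stopifnot(all(sens >= 0 & sens <= 1), all(spec >= 0 & spec <= 1))
  ifelse(sens + spec == 0, 0, 2 * sens * spec / (sens + spec))
}

#' Training configuration for the association classifier
#'
#' @param sigma_grid Gaussian kernel widths to search (the kernel is
#'   `exp(-||x - y||^2 / (2 sigma^2))`).
#' @param c_grid Soft-margin costs to search.
#' @param folds Cross-validation folds (default 5).
#' @param neg_ratio Negatives per positive when assembling training data
#'   (default 100).
#' @param seed Integer seed for fold assignment.
#' @return A list of class `training_config`.
#' @export
training_config <- function(sigma_grid = 2^(-4:4), c_grid = 2^(-2:6),
                            folds = 5, neg_ratio = 100, seed = 1L) {
  stopifnot(
    length(sigma_grid) >= 1, all(sigma_grid > 0),
    length(c_grid) >= 1, all(c_grid > 0), folds >= 2
  )
  structure(
    list(
      sigma_grid = sigma_grid, c_grid = c_grid,
      folds = as.integer(folds), neg_ratio = as.integer(neg_ratio),
      seed = as.integer(seed)
    ),
    class = "training_config"
  )
}

feature_cols <- function(data) {
  setdiff(names(data), c("gene_a", "gene_b", "label"))
}

# Stratified fold ids: positives and negatives are split separately so no
# fold loses all positives under heavy class imbalance.
stratified_folds <- function(labels, k, seed) {
  withr::with_seed(seed, {
    ids <- integer(length(labels))
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      if (length(idx) < k) {
        abort(sprintf(
          "class %s has %d examples; cannot stratify into %d folds",
          cls, length(idx), k
        ))
      }
      ids[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    ids
  })
}

fit_svm <- function(x, y, sigma, cost) {
  e1071::svm(
    x = x, y = y,
    type = "C-classification", kernel = "radial",
    gamma = 1 / (2 * sigma^2), cost = cost, scale = FALSE
  )
}

# Signed decision values oriented so positive = the "1" class, regardless
# of libsvm's internal class ordering.
decision_values <- function(fit, x) {
  pred <- stats::predict(fit, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  ord <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
  if (ord[1] == "1") as.numeric(dv[, 1]) else -as.numeric(dv[, 1])
}

sens_spec <- function(truth, predicted) {
  tp <- sum(truth == 1 & predicted)
  fn <- sum(truth == 1 & !predicted)
  tn <- sum(truth == 0 & !predicted)
  fp <- sum(truth == 0 & predicted)
  c(
    sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  )
}

#' Train the functional-association SVM
#'
#' Grid-searches the Gaussian kernel width and soft-margin cost by
#' stratified k-fold cross-validation, selecting the pair that maximizes
#' the mean per-fold harmonic mean of sensitivity and specificity
#' (macro-averaged across folds, which is stable under the 1:100 class
#' imbalance), then refits on all data. Ties prefer the smaller kernel
#' width, then the smaller cost, so the result does not depend on grid
#' order.
#'
#' @param data A labeled pair table: columns `gene_a`, `gene_b`, `label`
#'   (1 = gold positive, 0 = sampled negative) plus one numeric column per
#'   selected feature, e.g. [compute_features()] output joined to labels.
#' @param config A [training_config()].
#' @return An object of class `assoc_svm`: the fitted model, the selected
#'   `sigma` and `c`, the feature names, the CV grid (`cv`), apparent
#'   training sensitivity/specificity, and the training pair keys (used for
#'   leakage checks).
#' @export
train_association_model <- function(data, config = training_config()) {
  data <- as_tibble(data)
  stopifnot("label" %in% names(data))
  feats <- feature_cols(data)
  if (!length(feats)) abort("no feature columns in training data")
  y <- as.integer(data$label)
  if (length(unique(y)) != 2) abort("both classes must be present")
  x <- as.matrix(data[, feats])
  folds <- stratified_folds(y, config$folds, config$seed)
  grid <- tidyr::expand_grid(
    sigma = sort(config$sigma_grid), cost = sort(config$c_grid)
  )
  yf <- factor(y, levels = c(0, 1))
  cv <- purrr::pmap(grid, function(sigma, cost) {
    fold_stats <- vapply(seq_len(config$folds), function(k) {
      tr <- folds != k
      fit <- fit_svm(x[tr, , drop = FALSE], yf[tr], sigma, cost)
      dv <- decision_values(fit, x[!tr, , drop = FALSE])
      ss <- sens_spec(y[!tr], dv > 0)
      c(ss, hm = unname(harmonic_mean_sens_spec(ss[1], ss[2])))
    }, c(sensitivity = 0, specificity = 0, hm = 0))
    tibble(
      sigma = sigma, cost = cost,
      cv_sensitivity = mean(fold_stats["sensitivity", ]),
      cv_specificity = mean(fold_stats["specificity", ]),
      cv_harmonic_mean = mean(fold_stats["hm", ])
    )
  }) |> bind_rows()
  best <- cv |>
    arrange(desc(.data$cv_harmonic_mean), .data$sigma, .data$cost) |>
    head(1)
  fit <- fit_svm(x, yf, best$sigma, best$cost)
  apparent <- sens_spec(y, decision_values(fit, x) > 0)
  structure(
    list(
      fit = fit,
      selected_features = feats,
      sigma = best$sigma,
      c = best$cost,
      cv = cv,
      cv_sensitivity = best$cv_sensitivity,
      cv_specificity = best$cv_specificity,
      cv_harmonic_mean = best$cv_harmonic_mean,
      apparent_sensitivity = unname(apparent["sensitivity"]),
      apparent_specificity = unname(apparent["specificity"]),
      training_keys = pair_key(data$gene_a, data$gene_b),
      n_positive = sum(y == 1),
      n_negative = sum(y == 0)
    ),
    class = "assoc_svm"
  )
}

#' @export
print.assoc_svm <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<assoc_svm> gaussian-kernel SVM, %d features\n",
      "  sigma = %g, C = %g (CV harmonic mean %.3f)\n",
      "  trained on %d positives / %d negatives\n",
      "  apparent sensitivity %.4f, specificity %.4f\n"
    ),
    length(x$selected_features), x$sigma, x$c, x$cv_harmonic_mean,
    x$n_positive, x$n_negative,
    x$apparent_sensitivity, x$apparent_specificity
  ))
  invisible(x)
}

#' Predict functional associations for gene pairs
#'
#' A pair is predicted associated when its signed decision value is
#' positive. The confidence score is the absolute decision value clipped at
#' 1: values inside the SVM margin score below 1 (lower reliability), values
#' at or beyond the margin score exactly 1.
#'
#' @param object An `assoc_svm`.
#' @param newdata Tibble with `gene_a`, `gene_b` and the model's feature
#'   columns (extra columns are ignored; missing ones are an error).
#' @param ... Unused.
#' @return A tibble: `gene_a`, `gene_b`, `decision_value`, `predicted`
#'   (logical), `confidence` in `[0, 1]`.
#' @export
predict.assoc_svm <- function(object, newdata, ...) {
  newdata <- as_tibble(newdata)
  missing <- setdiff(object$selected_features, names(newdata))
  if (length(missing)) {
    abort(sprintf(
      "newdata lacks model feature column(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  x <- as.matrix(newdata[, object$selected_features])
  dv <- decision_values(object$fit, x)
  tibble(
    gene_a = newdata$gene_a, gene_b = newdata$gene_b,
    decision_value = dv,
    predicted = dv > 0,
    confidence = pmin(1, abs(dv))
  )
}

#' Validate a trained model on held-out labeled pairs
#'
#' Held-out pairs must be disjoint from the training pairs; any overlap is
#' rejected as label leakage.
#'
#' @param model An `assoc_svm`.
#' @param heldout Labeled pair table (same layout as for
#'   [train_association_model()]).
#' @return A one-row tibble: `sensitivity`, `specificity`, plus the
#'   confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
external_validate <- function(model, heldout) {
  heldout <- as_tibble(heldout)
  keys <- pair_key(heldout$gene_a, heldout$gene_b)
  n_leak <- sum(keys %in% model$training_keys)
  if (n_leak > 0) {
    abort(sprintf(
      "%d held-out pair(s) overlap the training set (label leakage)", n_leak
    ))
  }
  pred <- predict(model, heldout)
  truth <- as.integer(heldout$label)
  ss <- sens_spec(truth, pred$predicted)
  tibble(
    sensitivity = unname(ss["sensitivity"]),
    specificity = unname(ss["specificity"]),
    tp = sum(truth == 1 & pred$predicted),
    fp = sum(truth == 0 & pred$predicted),
    tn = sum(truth == 0 & !pred$predicted),
    fn = sum(truth == 1 & !pred$predicted)
  )
}
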