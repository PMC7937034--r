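#' Tidy the cross-validation grid of a fitted association model
#'
#' @param x An `assoc_svm`.
#' @param ... Unused.
#' @return The CV grid as a tibble: `sigma`, `cost`, `cv_sensitivity`,
#'   `cv_specificity`, `cv_harmonic_mean`.
#' @method tidy assoc_svm
#' @export
tidy.assoc_svm <- function(x, ...) x$cv

#' One-row model summary of a fitted association model
#'
#' @param x An `assoc_svm`.
#' @param ... Unused.
#' @return A one-row tibble with the selected hyperparameters, CV and
#'   apparent performance, and training-set composition.
#' @method glance assoc_svm
#' @export
glance.assoc_svm <- function(x, ...) {
  tibble(
    sigma = x$sigma, c = x$c,
    n_features = length(x$selected_features),
    cv_sensitivity = x$cv_sensitivity,
    cv_specificity = x$cv_specificity,
    cv_harmonic_mean = x$cv_harmonic_mean,
    apparent_sensitivity = x$apparent_sensitivity,
    apparent_specificity = x$apparent_specificity,
    n_positive = x$n_positive, n_negative = x$n_negative
  )
}

#' Tidy a GSLA result
#'
#' Drops the list column of connecting pairs, leaving the per-reference-set
#' statistics.
#'
#' @param x A `gsla_result`.
#' @param ... Unused.
#' @return A plain tibble.
#' @method tidy gsla_result
#' @export
tidy.gsla_result <- function(x, ...) {
  out <- as_tibble(x)
  out$connecting_pairs <- NULL
  out
}

#' Summarize a GSLA result
#'
#' @param x A `gsla_result`.
#' @param ... Unused.
#' @return A one-row tibble: number of reference sets, how many passed Q1,
#'   were Q2-tested, and passed both, plus the thresholds used.
#' @method glance gsla_result
#' @export
glance.gsla_result <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(
    n_reference_sets = nrow(x),
    n_passing_q1 = sum(x$passes_q1),
    n_q2_tested = sum(x$q2_tested),
    n_reported = sum(x$passes_q1 & x$passes_q2),
    q1_min_density = cfg$q1_min_density,
    q2_alpha = cfg$q2_alpha,
    n_permutations = cfg$n_permutations
  )
}

#' Glance at a precision-recall curve
#'
#' @param x A `pr_curve`.
#' @param ... Unused.
#' @return A one-row tibble: `auc`, `n_points`, `max_recall`.
#' @method glance pr_curve
#' @export
glance.pr_curve <- function(x, ...) {
  tibble(
    auc = pr_auc(x),
    n_points = nrow(x),
    max_recall = if (nrow(x)) max(x$recall) else NA_real_
  )
}

#' Plot a precision-recall curve
#'
#' @param object A `pr_curve` from [pr_eval()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pr_curve
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$recall, y = .data$precision)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Recall (new annotations recovered)",
      y = "Precision (predictions among known annotations)",
      title = sprintf("Guilt-by-association benchmark, PR-AUC = %.3f", pr_auc(object))
    ) +
    ggplot2::theme_minimal()
}

#' Plot GSLA densities against their permutation thresholds
#'
#' One point per reference set: inter-set density versus permutation
#' p-value (add-one floored), colored by whether both criteria pass.
#'
#' @param object A `gsla_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gsla_result
#' @export
autoplot.gsla_result <- function(object, ...) {
  cfg <- attr(object, "config")
  df <- tidy(object)
  df$reported <- df$passes_q1 & df$passes_q2
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$density, y = -log10(.data$p_value),
    color = .data$reported
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = cfg$q1_min_density, linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(cfg$q2_alpha), linetype = 2) +
    ggplot2::labs(
      x = "Inter-set association density (Q1)",
      y = expression(-log[10] ~ "permutation p (Q2)"),
      color = "Reported"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-feature AUCs against the selection gate
#'
#' @param aucs Output of [feature_aucs()].
#' @param threshold The AUC gate (default 0.6).
#' @return A ggplot.
#' @export
plot_feature_aucs <- function(aucs, threshold = 0.6) {
  df <- as_tibble(aucs)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  df$selected <- df$auc > threshold
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$auc, y = .data$feature, fill = .data$selected
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "ROC AUC vs gold labels", y = NULL, fill = "Selected") +
    ggplot2::theme_minimal()
}
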