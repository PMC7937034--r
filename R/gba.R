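#' Annotation corpus for guilt-by-association evaluation
#'
#' Holds two gene-to-term tables: `old` annotations (the knowledge available
#' when the interactome was built, used to predict) and `new` annotations
#' (reported afterwards, used to score recall). Per gene, the two sets must
#' be disjoint.
#'
#' @param old,new Data frames with columns `gene`, `term`.
#' @return A list of class `annotation_corpus` with elements `old`, `new`
#'   and `universe` (genes carrying at least one old annotation, the
#'   enrichment background).
#' @export
annotation_corpus <- function(old, new) {
  norm <- function(x) {
    x <- as_tibble(x)
    stopifnot(all(c("gene", "term") %in% names(x)))
    distinct(x[, c("gene", "term")])
  }
  old <- norm(old)
  new <- norm(new)
  clash <- dplyr::inner_join(old, new, by = c("gene", "term"))
  if (nrow(clash)) {
    abort(sprintf(
      "%d annotation(s) present in both old and new (e.g. %s / %s)",
      nrow(clash), clash$gene[1], clash$term[1]
    ))
  }
  structure(
    list(old = old, new = new, universe = sort(unique(old$gene))),
    class = "annotation_corpus"
  )
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat(sprintf(
    "<annotation_corpus> %d annotated genes; %d old + %d new annotations\n",
    length(x$universe), nrow(x$old), nrow(x$new)
  ))
  invisible(x)
}

#' Term enrichment among a gene's network neighbours
#'
#' Predicts functions for `gene` by testing, for every term annotated to at
#' least one first-degree neighbour, whether the term is over-represented
#' among the annotated neighbours relative to the annotated-gene universe
#' (one-sided hypergeometric). The gene itself never contributes to the
#' neighbour counts.
#'
#' @param net An `interactome` containing `gene`.
#' @param gene A gene id.
#' @param corpus An [annotation_corpus()]; old annotations drive the
#'   prediction.
#' @return A tibble: `term`, `n_neighbors_with_term`,
#'   `n_universe_with_term`, `n_annotated_neighbors`, `p_value`, sorted by
#'   p-value. Empty when no neighbour is annotated.
#' @export
neighbor_enrichment <- function(net, gene, corpus) {
  if (!gene %in% net$genes) {
    abort(sprintf("gene %s is not in the network", gene))
  }
  e <- net$edges
  nb <- unique(c(
    e$gene_b[e$gene_a == gene],
    e$gene_a[e$gene_b == gene]
  ))
  nb <- setdiff(nb, gene)
  old <- corpus$old
  nb_ann <- old[old$gene %in% nb, , drop = FALSE]
  if (nrow(nb_ann) == 0) {
    return(tibble(
      term = character(), n_neighbors_with_term = integer(),
      n_universe_with_term = integer(), n_annotated_neighbors = integer(),
      p_value = double()
    ))
  }
  n_ann_nb <- length(intersect(nb, corpus$universe))
  n_universe <- length(corpus$universe)
  term_counts_nb <- table(nb_ann$term)
  terms <- names(term_counts_nb)
  term_counts_all <- table(old$term[old$term %in% terms])
  k <- as.integer(term_counts_nb[terms])
  m <- as.integer(term_counts_all[terms])
  p <- phyper(k - 1, m, n_universe - m, n_ann_nb, lower.tail = FALSE)
  tibble(
    term = terms,
    n_neighbors_with_term = k,
    n_universe_with_term = m,
    n_annotated_neighbors = n_ann_nb,
    p_value = p
  ) |> arrange(.data$p_value, .data$term)
}

#' Precision-recall evaluation of an interactome
#'
#' Benchmarks how well a network supports guilt-by-association function
#' prediction. For every gene, neighbour-enriched terms are predicted at a
#' sweep of p-value cutoffs. Recall at a cutoff is the fraction of the
#' *new* annotations recovered; precision is the fraction of predictions
#' consistent with any known annotation (old or new — including old
#' annotations biases precision upward, since shared annotation is itself
#' prediction evidence; the same caveat applies to the resource this
#' benchmark models, and the output documents it). The curve's AUC is the
#' trapezoid over recall.
#'
#' @param net An `interactome`.
#' @param corpus An [annotation_corpus()] with a non-empty `new` table.
#' @param cutoffs Ascending vector of enrichment p-value cutoffs.
#' @return An object of class `pr_curve`: a tibble with `cutoff`,
#'   `n_predictions`, `precision`, `recall`, with the AUC as attribute
#'   `auc` (also via `pr_auc()`). Cutoffs with zero predictions are skipped
#'   with a message.
#' @export
pr_eval <- function(net, corpus,
                    cutoffs = 10^seq(-10, 0, by = 0.5)) {
  if (nrow(corpus$new) == 0) {
    abort("corpus has no new annotations; recall undefined")
  }
  if (is.unsorted(cutoffs)) abort("cutoffs must be ascending")
  preds <- prediction_table(net, corpus)
  new_keys <- paste(corpus$new$gene, corpus$new$term)
  known_keys <- c(new_keys, paste(corpus$old$gene, corpus$old$term))
  pred_keys <- paste(preds$gene, preds$term)
  rows <- lapply(cutoffs, function(cut) {
    sel <- preds$p_value <= cut
    n_pred <- sum(sel)
    if (n_pred == 0) {
      inform(sprintf("cutoff %g yields no predictions; point skipped", cut))
      return(NULL)
    }
    tibble(
      cutoff = cut,
      n_predictions = n_pred,
      precision = sum(pred_keys[sel] %in% known_keys) / n_pred,
      recall = sum(new_keys %in% pred_keys[sel]) / length(new_keys)
    )
  })
  out <- bind_rows(rows)
  attr(out, "auc") <- trapezoid_auc(out$recall, out$precision)
  class(out) <- c("pr_curve", class(out))
  out
}

# All (gene, term, p) neighbour-enrichment predictions for genes in the
# network with at least one annotated neighbour.
prediction_table <- function(net, corpus) {
  genes <- net$genes
  rows <- lapply(genes, function(g) {
    enr <- neighbor_enrichment(net, g, corpus)
    if (nrow(enr) == 0) {
      return(NULL)
    }
    tibble(gene = g, term = enr$term, p_value = enr$p_value)
  })
  bind_rows(rows)
}

trapezoid_auc <- function(x, y) {
  if (length(x) < 2) {
    return(0)
  }
  ord <- order(x, y)
  x <- x[ord]
  y <- y[ord]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' @rdname pr_eval
#' @param curve A `pr_curve`.
#' @export
pr_auc <- function(curve) attr(curve, "auc")
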