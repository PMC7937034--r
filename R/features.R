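#' Feature registry for pair evidence
#'
#' Builds the ordered registry of per-pair feature functions, grouped into
#' the six evidence categories. The default census (1 interolog + 3
#' phylogenetic profile + 23 domain interaction + 4 colocalization + 2
#' coexpression + 3 shared annotation = 36 features) mirrors the category
#' bookkeeping of the interactome this package models. The exact member
#' formulas within each category are representative, documented choices:
#' correlation- and overlap-type statistics per category, with the 23-slot
#' domain category realized as a parameterized family of score aggregations
#' crossed with set-size normalizations.
#'
#' @param census Named integer vector giving the number of features per
#'   category; names must be a subset of the six categories. Requesting more
#'   features than a category's family provides is an error.
#' @return A tibble of class `feature_registry` with columns `name`,
#'   `category` and `fn` (list column of functions).
#' @export
feature_registry <- function(census = c(
                               interolog = 1, phylo_profile = 3,
                               domain_interaction = 23, colocalization = 4,
                               coexpression = 2, shared_annotation = 3
                             )) {
  fams <- feature_families()
  if (!all(names(census) %in% names(fams))) {
    abort(sprintf(
      "unknown feature category: %s",
      paste(setdiff(names(census), names(fams)), collapse = ", ")
    ))
  }
  rows <- lapply(names(census), function(cat) {
    fam <- fams[[cat]]
    k <- census[[cat]]
    if (k > length(fam)) {
      abort(sprintf(
        "category %s provides %d features; %d requested",
        cat, length(fam), k
      ))
    }
    tibble(name = names(fam)[seq_len(k)], category = cat, fn = unname(fam[seq_len(k)]))
  })
  out <- bind_rows(rows)
  if (anyDuplicated(out$name)) abort("feature names must be unique")
  class(out) <- c("feature_registry", class(out))
  out
}

#' @rdname feature_registry
#' @param registry A `feature_registry`.
#' @return `registry_census()`: a named integer vector of per-category
#'   counts, in registry order.
#' @export
registry_census <- function(registry) {
  tab <- table(factor(registry$category, levels = unique(registry$category)))
  setNames(as.integer(tab), names(tab))
}

# Each feature function takes (px, ctx) where px holds per-evidence-table
# row indices for the pair vectors (NA = gene absent -> feature 0) and ctx
# the precomputed evidence structures. All return a finite numeric vector.
feature_families <- function() {
  fill0 <- function(ok, val, n) {
    out <- numeric(n)
    out[ok] <- val
    out[!is.finite(out)] <- 0
    out
  }
  pairwise_rowdot <- function(Z, ia, ib) {
    rowSums(Z[ia, , drop = FALSE] * Z[ib, , drop = FALSE])
  }

  coexpr <- function(which_z) {
    force(which_z)
    function(px, ctx) {
      ok <- !is.na(px$expr_a) & !is.na(px$expr_b)
      if (is.null(ctx[[which_z]])) {
        return(numeric(px$n))
      }
      r <- pairwise_rowdot(ctx[[which_z]], px$expr_a[ok], px$expr_b[ok])
      fill0(ok, r, px$n)
    }
  }

  set_overlap <- function(slot, kind) {
    force(slot)
    force(kind)
    function(px, ctx) {
      ia <- px[[paste0(slot, "_a")]]
      ib <- px[[paste0(slot, "_b")]]
      ok <- !is.na(ia) & !is.na(ib)
      M <- ctx[[paste0(slot, "_mat")]]
      if (is.null(M) || ncol(M) == 0) {
        return(numeric(px$n))
      }
      n11 <- rowSums(M[ia[ok], , drop = FALSE] & M[ib[ok], , drop = FALSE])
      na <- ctx[[paste0(slot, "_size")]][ia[ok]]
      nb <- ctx[[paste0(slot, "_size")]][ib[ok]]
      val <- switch(kind,
        count = n11,
        jaccard = n11 / (na + nb - n11),
        min = n11 / pmin(na, nb),
        max = n11 / pmax(na, nb),
        geom = n11 / sqrt(na * nb),
        product = n11 / (na * nb),
        dice = 2 * n11 / (na + nb),
        any = as.numeric(n11 > 0)
      )
      fill0(ok, val, px$n)
    }
  }

  ddi_linear <- function(stat, norm) {
    force(stat)
    force(norm)
    function(px, ctx) {
      ok <- !is.na(px$dom_a) & !is.na(px$dom_b)
      if (is.null(ctx$dom_mat) || ncol(ctx$dom_mat) == 0) {
        return(numeric(px$n))
      }
      TT <- if (stat == "count") ctx$ddi_count_lhs else ctx$ddi_score_lhs
      raw <- rowSums(TT[px$dom_a[ok], , drop = FALSE] *
        ctx$dom_num[px$dom_b[ok], , drop = FALSE])
      na <- ctx$dom_size[px$dom_a[ok]]
      nb <- ctx$dom_size[px$dom_b[ok]]
      val <- switch(norm,
        none = raw,
        min = raw / pmin(na, nb),
        max = raw / pmax(na, nb),
        product = raw / (na * nb),
        geom = raw / sqrt(na * nb),
        sum = raw / (na + nb)
      )
      fill0(ok, val, px$n)
    }
  }

  ddi_scan <- function(kind) {
    force(kind)
    function(px, ctx) {
      ok <- which(!is.na(px$dom_a) & !is.na(px$dom_b))
      if (is.null(ctx$dom_w) || length(ok) == 0) {
        return(numeric(px$n))
      }
      val <- vapply(ok, function(i) {
        da <- ctx$dom_list[[px$dom_a[i]]]
        db <- ctx$dom_list[[px$dom_b[i]]]
        if (!length(da) || !length(db)) {
          return(0)
        }
        s <- ctx$dom_w[da, db, drop = FALSE]
        s <- s[s > 0]
        if (!length(s)) {
          return(0)
        }
        switch(kind, max = max(s), mean = mean(s), any = 1)
      }, 0)
      out <- numeric(px$n)
      out[ok] <- val
      out
    }
  }

  phylo_mi <- function(px, ctx) {
    ok <- !is.na(px$phy_a) & !is.na(px$phy_b)
    P <- ctx$phylo_bin
    if (is.null(P)) {
      return(numeric(px$n))
    }
    Pa <- P[px$phy_a[ok], , drop = FALSE]
    Pb <- P[px$phy_b[ok], , drop = FALSE]
    s <- ncol(P)
    n11 <- rowSums(Pa & Pb)
    n10 <- rowSums(Pa & !Pb)
    n01 <- rowSums(!Pa & Pb)
    n00 <- s - n11 - n10 - n01
    xlx <- function(nij, ni, nj) {
      p <- nij / s
      term <- p * log2(nij * s / (ni * nj))
      term[!is.finite(term)] <- 0
      term
    }
    na1 <- n11 + n10
    na0 <- n01 + n00
    nb1 <- n11 + n01
    nb0 <- n10 + n00
    mi <- xlx(n11, na1, nb1) + xlx(n10, na1, nb0) +
      xlx(n01, na0, nb1) + xlx(n00, na0, nb0)
    fill0(ok, mi, px$n)
  }

  annot_min_ic <- function(px, ctx) {
    ok <- which(!is.na(px$ann_a) & !is.na(px$ann_b))
    if (!length(ok) || is.null(ctx$ann_list)) {
      return(numeric(px$n))
    }
    val <- vapply(ok, function(i) {
      shared <- intersect(
        ctx$ann_list[[px$ann_a[i]]],
        ctx$ann_list[[px$ann_b[i]]]
      )
      if (!length(shared)) 0 else min(ctx$term_ic[shared])
    }, 0)
    out <- numeric(px$n)
    out[ok] <- val
    out
  }

  interolog_ind <- function(px, ctx) {
    as.numeric(px$key %in% ctx$interolog_keys)
  }

  norms <- c("none", "min", "max", "product", "geom", "sum")
  ddi_family <- c(
    setNames(
      lapply(norms, function(nm) ddi_linear("count", nm)),
      paste0("ddi_count", ifelse(norms == "none", "", paste0("_", norms, "_norm")))
    ),
    setNames(
      lapply(norms, function(nm) ddi_linear("score", nm)),
      paste0("ddi_score_sum", ifelse(norms == "none", "", paste0("_", norms, "_norm")))
    ),
    list(
      ddi_score_max = ddi_scan("max"),
      ddi_score_mean = ddi_scan("mean"),
      ddi_any = ddi_scan("any")
    ),
    list(
      dom_shared_count = set_overlap("dom", "count"),
      dom_jaccard = set_overlap("dom", "jaccard"),
      dom_shared_min_norm = set_overlap("dom", "min"),
      dom_shared_max_norm = set_overlap("dom", "max"),
      dom_shared_geom_norm = set_overlap("dom", "geom"),
      dom_shared_product_norm = set_overlap("dom", "product"),
      dom_dice = set_overlap("dom", "dice"),
      dom_any_shared = set_overlap("dom", "any")
    )
  )

  list(
    interolog = list(interolog_indicator = interolog_ind),
    phylo_profile = list(
      phylo_pearson = function(px, ctx) {
        ok <- !is.na(px$phy_a) & !is.na(px$phy_b)
        if (is.null(ctx$phylo_std)) {
          return(numeric(px$n))
        }
        fill0(ok, pairwise_rowdot(ctx$phylo_std, px$phy_a[ok], px$phy_b[ok]), px$n)
      },
      phylo_jaccard = function(px, ctx) {
        ok <- !is.na(px$phy_a) & !is.na(px$phy_b)
        P <- ctx$phylo_bin
        if (is.null(P)) {
          return(numeric(px$n))
        }
        n11 <- rowSums(P[px$phy_a[ok], , drop = FALSE] & P[px$phy_b[ok], , drop = FALSE])
        nu <- rowSums(P[px$phy_a[ok], , drop = FALSE] | P[px$phy_b[ok], , drop = FALSE])
        fill0(ok, n11 / nu, px$n)
      },
      phylo_mutual_information = phylo_mi
    ),
    domain_interaction = ddi_family,
    colocalization = list(
      coloc_jaccard = set_overlap("loc", "jaccard"),
      coloc_overlap_count = set_overlap("loc", "count"),
      coloc_overlap_min = set_overlap("loc", "min"),
      coloc_any_shared = set_overlap("loc", "any")
    ),
    coexpression = list(
      coexpr_pearson = coexpr("expr_std"),
      coexpr_spearman = coexpr("expr_rank_std")
    ),
    shared_annotation = list(
      annot_shared_count = set_overlap("ann", "count"),
      annot_jaccard = set_overlap("ann", "jaccard"),
      annot_min_shared_ic = annot_min_ic
    )
  )
}

# Standardize matrix rows so that rowSums(Za * Zb) is the Pearson
# correlation of the corresponding rows. Zero-variance rows become 0.
row_standardize <- function(m) {
  mu <- rowMeans(m)
  s <- sqrt(pmax(rowSums((m - mu)^2), 0))
  z <- (m - mu) / s
  z[!is.finite(z)] <- 0
  z
}

indicator_matrix <- function(df, row_col, col_col) {
  rows <- sort(unique(df[[row_col]]))
  cols <- sort(unique(df[[col_col]]))
  m <- matrix(FALSE, length(rows), length(cols), dimnames = list(rows, cols))
  if (nrow(df)) m[cbind(match(df[[row_col]], rows), match(df[[col_col]], cols))] <- TRUE
  m
}

build_feature_context <- function(bundle) {
  ctx <- list()
  if (!is.null(bundle$expression)) {
    if (ncol(bundle$expression) < 2) {
      abort("expression matrix needs at least 2 conditions for coexpression features")
    }
    ctx$expr_genes <- rownames(bundle$expression)
    ctx$expr_std <- row_standardize(bundle$expression)
    ctx$expr_rank_std <- row_standardize(
      t(apply(bundle$expression, 1, rank))
    )
  }
  if (!is.null(bundle$phylo_profiles)) {
    ctx$phy_genes <- rownames(bundle$phylo_profiles)
    ctx$phylo_std <- row_standardize(bundle$phylo_profiles)
    ctx$phylo_bin <- bundle$phylo_profiles > 0
  }
  if (nrow(bundle$localizations)) {
    ctx$loc_mat <- indicator_matrix(bundle$localizations, "gene", "compartment")
    ctx$loc_genes <- rownames(ctx$loc_mat)
    ctx$loc_size <- rowSums(ctx$loc_mat)
  }
  if (nrow(bundle$annotations)) {
    ctx$ann_mat <- indicator_matrix(bundle$annotations, "gene", "term")
    ctx$ann_genes <- rownames(ctx$ann_mat)
    ctx$ann_size <- rowSums(ctx$ann_mat)
    ctx$ann_list <- apply(ctx$ann_mat, 1, which, simplify = FALSE)
    # information content: -log2 of term frequency among annotated genes
    ctx$term_ic <- -log2(colSums(ctx$ann_mat) / nrow(ctx$ann_mat))
  }
  if (nrow(bundle$domains)) {
    ctx$dom_mat <- indicator_matrix(bundle$domains, "gene", "domain")
    ctx$dom_genes <- rownames(ctx$dom_mat)
    ctx$dom_size <- rowSums(ctx$dom_mat)
    ctx$dom_num <- ctx$dom_mat * 1
    ctx$dom_list <- apply(ctx$dom_mat, 1, which, simplify = FALSE)
    doms <- colnames(ctx$dom_mat)
    W <- matrix(0, length(doms), length(doms), dimnames = list(doms, doms))
    di <- bundle$domain_interactions
    di <- di[di$domain_a %in% doms & di$domain_b %in% doms, , drop = FALSE]
    if (nrow(di)) {
      W[cbind(match(di$domain_a, doms), match(di$domain_b, doms))] <- di$score
      W[cbind(match(di$domain_b, doms), match(di$domain_a, doms))] <- di$score
    }
    ctx$dom_w <- W
    ctx$ddi_count_lhs <- ctx$dom_num %*% (W > 0)
    ctx$ddi_score_lhs <- ctx$dom_num %*% W
  }
  ctx$interolog_keys <- pair_key(bundle$interologs$gene_a, bundle$interologs$gene_b)
  ctx
}

#' Compute per-pair evidence features
#'
#' Applies every feature in `registry` to each gene pair, one row per pair
#' in input order. A gene absent from a given evidence table yields 0 for
#' the features drawing on that table (with a warning naming the table):
#' absence of evidence is encoded as "no evidence of association", which
#' keeps feature vectors complete for the margin classifier downstream.
#'
#' @param pairs Data frame with character columns `gene_a`, `gene_b`.
#' @param bundle An [evidence_bundle()].
#' @param registry A [feature_registry()].
#' @return A tibble: `gene_a`, `gene_b`, then one numeric column per
#'   registry feature. All values are finite and symmetric in the pair.
#' @export
compute_features <- function(pairs, bundle, registry = feature_registry()) {
  stopifnot(inherits(bundle, "evidence_bundle"))
  if (nrow(registry) == 0) abort("feature registry is empty")
  pairs <- as_tibble(pairs)
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)))
  ctx <- build_feature_context(bundle)
  a <- pairs$gene_a
  b <- pairs$gene_b
  px <- list(
    n = length(a),
    key = pair_key(a, b),
    expr_a = match(a, ctx$expr_genes), expr_b = match(b, ctx$expr_genes),
    phy_a = match(a, ctx$phy_genes), phy_b = match(b, ctx$phy_genes),
    loc_a = match(a, ctx$loc_genes), loc_b = match(b, ctx$loc_genes),
    ann_a = match(a, ctx$ann_genes), ann_b = match(b, ctx$ann_genes),
    dom_a = match(a, ctx$dom_genes), dom_b = match(b, ctx$dom_genes)
  )
  for (tab in c("expr", "phy", "loc", "ann", "dom")) {
    ia <- px[[paste0(tab, "_a")]]
    ib <- px[[paste0(tab, "_b")]]
    n_missing <- sum(is.na(ia) | is.na(ib))
    if (n_missing > 0 && !is.null(ctx[[c(
      expr = "expr_genes", phy = "phy_genes", loc = "loc_genes",
      ann = "ann_genes", dom = "dom_genes"
    )[[tab]]]])) {
      warn(sprintf(
        "%d pair(s) have a gene absent from the %s evidence; features set to 0",
        n_missing,
        c(
          expr = "expression", phy = "phylogenetic profile",
          loc = "localization", ann = "annotation", dom = "domain"
        )[[tab]]
      ))
    }
  }
  vals <- lapply(registry$fn, function(f) {
    v <- f(px, ctx)
    v[!is.finite(v)] <- 0
    v
  })
  names(vals) <- registry$name
  bind_cols(tibble(gene_a = a, gene_b = b), as_tibble(vals))
}

#' Area under the ROC curve (tie-aware Mann-Whitney form)
#'
#' Equals `P(score_pos > score_neg) + 0.5 * P(tie)`, computed from midranks.
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (1/TRUE = positive), same length.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    abort("AUC undefined: both classes must be present")
  }
  r <- rank(scores) # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Select informative features by AUC gate
#'
#' Keeps the features whose ROC AUC is strictly greater than the threshold,
#' preserving input (registry) order.
#'
#' @param aucs Named numeric vector of per-feature AUCs, or a data frame
#'   with columns `feature` and `auc`.
#' @param threshold AUC gate (default 0.6; strict inequality).
#' @return Character vector of selected feature names.
#' @export
select_features <- function(aucs, threshold = 0.6) {
  if (is.data.frame(aucs)) aucs <- setNames(aucs$auc, aucs$feature)
  names(aucs)[aucs > threshold]
}

#' Per-feature AUCs of a labeled feature table
#'
#' Convenience wrapper: one [roc_auc()] per feature column.
#'
#' @param features Tibble from [compute_features()].
#' @param labels Binary vector, one per row of `features`.
#' @return A tibble with columns `feature` and `auc`, in column order.
#' @export
feature_aucs <- function(features, labels) {
  cols <- setdiff(names(features), c("gene_a", "gene_b"))
  tibble(
    feature = cols,
    auc = vapply(cols, function(cl) roc_auc(features[[cl]], labels), 0)
  )
}
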