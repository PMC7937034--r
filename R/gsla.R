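#' GSLA configuration
#'
#' Defaults follow the two-hypothesis linkage test: a set pair is reported
#' when the inter-set association density exceeds `q1_min_density` (Q1) and
#' the degree-preserving permutation p-value is below `q2_alpha` (Q2).
#' With the add-one empirical p-value the smallest attainable p is
#' `1 / (n_permutations + 1)`, so `q2_alpha = 0.001` needs at least 1999
#' permutations (the default); a config where the threshold is unattainable
#' triggers a warning.
#'
#' @param q1_min_density Density threshold, strict (default 0.01).
#' @param q2_alpha Permutation p-value threshold, strict (default 0.001).
#' @param n_permutations Number of rewired null networks (default 1999).
#' @param swaps_per_edge Attempted double-edge swaps per edge for each null
#'   network (default 10, a common mixing heuristic).
#' @param seed Integer seed for the null streams.
#' @return A list of class `gsla_config`.
#' @export
gsla_config <- function(q1_min_density = 0.01, q2_alpha = 0.001,
                        n_permutations = 1999, swaps_per_edge = 10,
                        seed = 1L) {
  stopifnot(
    q1_min_density >= 0, q2_alpha > 0, q2_alpha < 1,
    n_permutations >= 1, swaps_per_edge >= 1
  )
  if (q2_alpha < 1 / (n_permutations + 1)) {
    warn(sprintf(
      "q2_alpha = %g is unattainable with %d permutations (minimum p = %g)",
      q2_alpha, n_permutations, 1 / (n_permutations + 1)
    ))
  }
  structure(
    list(
      q1_min_density = q1_min_density, q2_alpha = q2_alpha,
      n_permutations = as.integer(n_permutations),
      swaps_per_edge = as.integer(swaps_per_edge), seed = as.integer(seed)
    ),
    class = "gsla_config"
  )
}

n_cross_pairs <- function(a, b) {
  k <- length(intersect(a, b))
  length(a) * length(b) - k - k * (k - 1) / 2
}

#' Inter-set association density (Q1 statistic)
#'
#' Density is the number of network edges connecting the two sets divided
#' by the number of distinct unordered cross pairs,
#' `|A||B| - k - k(k-1)/2` with `k = |A` \eqn{\cap} `B|` (so overlapping and even
#' identical sets are handled).
#'
#' @param net An `interactome`.
#' @param a,b Non-empty character vectors of gene ids.
#' @return A one-row tibble: `density`, `n_edges`, `n_possible`.
#' @export
q1_density <- function(net, a, b) {
  a <- unique(a)
  b <- unique(b)
  if (!length(a) || !length(b)) abort("both gene sets must be non-empty")
  possible <- n_cross_pairs(a, b)
  if (possible == 0) {
    abort("no distinct cross pairs between the sets; density undefined")
  }
  n_e <- nrow(inter_set_edges(net, a, b))
  tibble(density = n_e / possible, n_edges = n_e, n_possible = possible)
}

edges_to_index_matrix <- function(net) {
  cbind(
    match(net$edges$gene_a, net$genes) - 1L,
    match(net$edges$gene_b, net$genes) - 1L
  )
}

#' Degree-preserving network randomization
#'
#' Randomizes an interactome by repeated double-edge swaps (pick edges
#' `{a,b}` and `{c,d}`, replace with `{a,d}` and `{c,b}` unless a self-loop
#' or duplicate would result). The gene set and the degree of every gene
#' are preserved exactly; `swaps_per_edge * n_edges(net)` swaps are
#' attempted, rejected swaps are skipped. Edge scores are not meaningful
#' after rewiring and are reset to 1.
#'
#' @param net An `interactome` with at least 2 edges.
#' @param swaps_per_edge Attempted swaps per edge (default 10).
#' @param seed Integer seed; the same seed reproduces the same null network.
#' @return A rewired `interactome`.
#' @export
rewire_degree_preserving <- function(net, swaps_per_edge = 10, seed = 1L) {
  if (n_edges(net) < 2) abort("rewiring needs at least 2 edges")
  em <- edges_to_index_matrix(net)
  out <- .rewire_edges_cpp(
    em, length(net$genes),
    as.double(swaps_per_edge) * nrow(em), as.double(seed)
  )
  interactome(
    tibble(
      gene_a = net$genes[out[, 1] + 1L],
      gene_b = net$genes[out[, 2] + 1L]
    ),
    genes = net$genes
  )
}

#' Permutation p-value against degree-preserving nulls (Q2 statistic)
#'
#' Generates `n_permutations` independent rewired networks (each randomized
#' afresh from the observed network), recomputes the inter-set density on
#' each, and returns the add-one empirical p-value
#' `(1 + #\{null >= observed\}) / (1 + n_permutations)`, one-sided for high
#' density. The add-one estimator never returns 0; its minimum is
#' `1 / (n_permutations + 1)`.
#'
#' @inheritParams q1_density
#' @param config A [gsla_config()].
#' @param early_stop_alpha Optional significance threshold enabling a
#'   sequential shortcut: permutation generation halts as soon as enough
#'   null densities reach the observed one that the final p-value can no
#'   longer fall below the threshold. The accept/reject decision at that
#'   threshold is identical to the full run (the null stream is the same,
#'   merely truncated), but the reported `p_value` is then only a
#'   conservative estimate from the completed permutations. Default `NULL`
#'   (run every permutation).
#' @return A list with `p_value`, `observed` (one-row tibble from
#'   [q1_density()]), `null_densities` (numeric vector), `n_completed` and
#'   `truncated`.
#' @export
q2_pvalue <- function(net, a, b, config = gsla_config(),
                      early_stop_alpha = NULL) {
  obs <- q1_density(net, a, b)
  em <- edges_to_index_matrix(net)
  in_a <- as.integer(net$genes %in% a)
  in_b <- as.integer(net$genes %in% b)
  # p >= alpha is certain once b = #{null >= obs} reaches alpha*(n+1) - 1
  stop_exceed <- if (is.null(early_stop_alpha)) {
    0L
  } else {
    as.integer(max(1, ceiling(early_stop_alpha * (config$n_permutations + 1) - 1)))
  }
  counts <- .gsla_null_counts_cpp(
    em, length(net$genes), in_a, in_b,
    config$n_permutations,
    as.double(config$swaps_per_edge) * nrow(em),
    as.double(config$seed),
    obs_count = obs$n_edges,
    stop_exceed = stop_exceed
  )
  counts <- counts[!is.na(counts)]
  p <- (1 + sum(counts >= obs$n_edges)) / (1 + length(counts))
  list(
    p_value = p,
    observed = obs,
    null_densities = counts / obs$n_possible,
    n_completed = length(counts),
    truncated = length(counts) < config$n_permutations
  )
}

#' Gene set linkage analysis
#'
#' Tests a query gene set (typically the top differentially expressed genes
#' of an experiment) against each reference set: Q1 asks whether the
#' inter-set association density exceeds a fixed threshold, Q2 whether that
#' density is higher than what degree-matched random networks produce, which
#' removes the confounding effect of hub-rich set compositions. Q2 is only
#' computed for sets passing Q1 (the criteria are conjunctive, so skipping
#' cannot change the reported set); skipped sets carry `p_value = 1` and
#' `q2_tested = FALSE`. No correction across reference sets is applied; raw
#' p-values are exposed.
#'
#' @param net An `interactome`.
#' @param query Character vector of canonical gene ids (see [map_ids()]).
#'   A warning is issued when the size is outside 50-200, the range for
#'   which the test is calibrated in routine use.
#' @param refs A `gene_set_collection` (or anything [gene_sets()] accepts).
#' @param config A [gsla_config()].
#' @return A tibble of class `gsla_result`, one row per reference set, with
#'   columns `ref_set`, `ref_name`, `set_size`, `n_inter_edges`, `density`,
#'   `p_value`, `passes_q1`, `passes_q2`, `q2_tested` and
#'   `connecting_pairs` (list column of query-gene/reference-gene tibbles),
#'   sorted by pass status, then p-value, then density. The configuration
#'   is attached as attribute `config`.
#' @export
gsla_run <- function(net, query, refs, config = gsla_config()) {
  query <- unique(query)
  if (!length(query)) abort("query gene set is empty")
  refs <- gene_sets(refs)
  if (nrow(refs) == 0) abort("reference collection is empty")
  if (length(query) < 50 || length(query) > 200) {
    warn(sprintf(
      "query has %d genes; the test is calibrated for 50-200",
      length(query)
    ))
  }
  ref_seeds <- withr::with_seed(
    config$seed,
    sample.int(.Machine$integer.max, nrow(refs))
  )
  rows <- lapply(seq_len(nrow(refs)), function(i) {
    members <- unique(refs$genes[[i]])
    obs <- q1_density(net, query, members)
    passes_q1 <- obs$density > config$q1_min_density
    if (passes_q1) {
      cfg_i <- config
      cfg_i$seed <- ref_seeds[i]
      q2 <- q2_pvalue(net, query, members, cfg_i)
      p <- q2$p_value
      tested <- TRUE
    } else {
      p <- 1
      tested <- FALSE
    }
    conn <- inter_set_edges(net, query, members)
    in_q_first <- conn$gene_a %in% query
    conn_tbl <- tibble(
      query_gene = ifelse(in_q_first, conn$gene_a, conn$gene_b),
      ref_gene = ifelse(in_q_first, conn$gene_b, conn$gene_a)
    )
    tibble(
      ref_set = refs$name[i],
      ref_name = refs$description[i],
      set_size = length(members),
      n_inter_edges = obs$n_edges,
      density = obs$density,
      p_value = p,
      passes_q1 = passes_q1,
      passes_q2 = tested && p < config$q2_alpha,
      q2_tested = tested,
      connecting_pairs = list(conn_tbl)
    )
  })
  out <- bind_rows(rows) |>
    arrange(
      desc(.data$passes_q1 & .data$passes_q2),
      .data$p_value, desc(.data$density)
    )
  attr(out, "config") <- config
  class(out) <- c("gsla_result", class(out))
  out
}

#' Write a GSLA result report
#'
#' The first 10 lines are `#`-prefixed parameter records (tool version,
#' thresholds, permutation settings, seed, counts), followed by a
#' tab-separated table with the per-reference-set results; connecting pairs
#' are serialized as semicolon-joined `queryGene-refGene` tokens.
#'
#' @param result A `gsla_result` from [gsla_run()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gsla_report <- function(result, path) {
  cfg <- attr(result, "config")
  header <- c(
    sprintf("# tool: gsla %s", as.character(utils::packageVersion("gsla"))),
    sprintf("# generated: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("# q1_min_density: %g", cfg$q1_min_density),
    sprintf("# q2_alpha: %g", cfg$q2_alpha),
    sprintf("# n_permutations: %d", cfg$n_permutations),
    sprintf("# swaps_per_edge: %d", cfg$swaps_per_edge),
    sprintf("# seed: %d", cfg$seed),
    sprintf("# n_reference_sets: %d", nrow(result)),
    sprintf("# n_passing: %d", sum(result$passes_q1 & result$passes_q2)),
    "# criteria: report sets with density > q1_min_density and p < q2_alpha"
  )
  tab <- result |>
    mutate(connecting_pairs = vapply(.data$connecting_pairs, function(cp) {
      paste(cp$query_gene, cp$ref_gene, sep = "-", collapse = ";")
    }, "")) |>
    select(
      "ref_set", "ref_name", "set_size", "n_inter_edges", "density",
      "p_value", "passes_q1", "passes_q2", "connecting_pairs"
    )
  writeLines(header, path)
  suppressWarnings(readr::write_tsv(tab, path, append = TRUE, col_names = TRUE, progress = FALSE))
  invisible(path)
}
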