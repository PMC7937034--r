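#' Construct a functional interactome
#'
#' An interactome is an undirected simple graph over canonical gene
#' identifiers. Each edge carries a reliability score in `[0, 1]` and a
#' `source` tag (`"predicted"` or `"experimental"`). Unordered duplicate
#' pairs are collapsed keeping the maximum score; self-pairs are an error
#' (they almost always signal an upstream identifier-mapping bug and are
#' surfaced rather than dropped).
#'
#' @param edges A data frame with character columns `gene_a` and `gene_b`,
#'   and optionally numeric `score` (default 1) and character `source`
#'   (default `"predicted"`).
#' @param genes Optional character vector of gene ids to include even when
#'   isolated (no incident edge). Endpoints of `edges` are always included.
#' @return An object of class `interactome`: a list with an `edges` tibble
#'   (columns `gene_a`, `gene_b`, `score`, `source`; endpoints stored in
#'   lexicographic order) and a sorted character vector `genes`.
#' @examples
#' net <- interactome(tibble::tibble(
#'   gene_a = c("G1", "G2"), gene_b = c("G2", "G3"), score = c(0.9, 0.4)
#' ))
#' n_edges(net)
#' @export
interactome <- function(edges = NULL, genes = NULL) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble(
      gene_a = character(), gene_b = character(),
      score = double(), source = character()
    )
  }
  edges <- as_tibble(edges)
  if (!all(c("gene_a", "gene_b") %in% names(edges))) {
    abort("`edges` must have columns `gene_a` and `gene_b`")
  }
  if (is.null(edges[["score"]])) edges$score <- 1
  if (is.null(edges[["source"]])) edges$source <- "predicted"
  edges$score[is.na(edges$score)] <- 1
  edges$source[is.na(edges$source)] <- "predicted"
  check_gene_ids(edges$gene_a)
  check_gene_ids(edges$gene_b)
  if (any(edges$gene_a == edges$gene_b)) {
    offender <- edges$gene_a[edges$gene_a == edges$gene_b][1]
    abort(sprintf("self-pair not allowed: %s - %s", offender, offender))
  }
  if (any(edges$score < 0 | edges$score > 1)) {
    abort("edge scores must lie in [0, 1]")
  }
  if (!all(edges$source %in% c("predicted", "experimental"))) {
    abort("edge source must be \"predicted\" or \"experimental\"")
  }
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  edges$gene_a <- a
  edges$gene_b <- b
  # collapse duplicates keeping the strongest evidence; on a score tie an
  # experimental record wins over a predicted one
  edges <- edges |>
    mutate(.exp = .data$source == "experimental") |>
    arrange(.data$gene_a, .data$gene_b, desc(.data$score), desc(.data$.exp)) |>
    distinct(.data$gene_a, .data$gene_b, .keep_all = TRUE) |>
    select("gene_a", "gene_b", "score", "source")
  all_genes <- sort(unique(c(edges$gene_a, edges$gene_b, genes)))
  if (length(all_genes)) check_gene_ids(all_genes)
  structure(list(edges = edges, genes = all_genes), class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf(
    "<interactome> %d genes, %d edges (%d experimental)\n",
    length(x$genes), nrow(x$edges), sum(x$edges$source == "experimental")
  ))
  invisible(x)
}

#' @rdname interactome
#' @param net,x An `interactome`.
#' @export
n_edges <- function(net) nrow(net$edges)

#' @rdname interactome
#' @export
n_genes <- function(net) length(net$genes)

#' @rdname interactome
#' @param ... Unused.
#' @method as_tibble interactome
#' @export
as_tibble.interactome <- function(x, ...) x$edges

#' Number of distinct neighbours of each gene
#'
#' @param net An `interactome`.
#' @param genes Character vector of gene ids; defaults to all genes in the
#'   network. Genes absent from the network have degree 0.
#' @return A named integer vector of neighbour counts.
#' @export
node_degree <- function(net, genes = NULL) {
  genes <- genes %||% net$genes
  counts <- table(c(net$edges$gene_a, net$edges$gene_b))
  out <- as.integer(counts[genes])
  out[is.na(out)] <- 0L
  setNames(out, genes)
}

#' Edges connecting two gene sets
#'
#' Returns every edge with one endpoint in `a` and the other in `b`. Edges
#' whose two endpoints both lie in the intersection of the sets are counted
#' once, as for any other edge.
#'
#' @param net An `interactome`.
#' @param a,b Character vectors of gene ids.
#' @return A tibble of edges, a subset of `as_tibble(net)`.
#' @export
inter_set_edges <- function(net, a, b) {
  e <- net$edges
  keep <- (e$gene_a %in% a & e$gene_b %in% b) |
    (e$gene_a %in% b & e$gene_b %in% a)
  e[keep, , drop = FALSE]
}

#' Read an interactome from a tab-separated edge list
#'
#' The file must have columns `geneA` and `geneB`; `score` and `source` are
#' optional (defaults 1.0 and `"predicted"`). Lines starting with `#` are
#' ignored. Duplicate unordered pairs keep the maximum score; a self-pair is
#' a validation error.
#'
#' @param path Path to a TSV file.
#' @return An `interactome`.
#' @export
read_edge_list <- function(path) {
  raw <- readr::read_tsv(
    path,
    comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  names(raw) <- tolower(names(raw))
  if (!all(c("genea", "geneb") %in% names(raw))) {
    abort(sprintf("%s: edge list needs columns geneA and geneB", path))
  }
  bad <- which(is.na(raw$genea) | is.na(raw$geneb) |
    !nzchar(raw$genea) | !nzchar(raw$geneb))
  if (length(bad)) {
    abort(sprintf("%s: malformed row at data line %d", path, bad[1]))
  }
  edges <- tibble(gene_a = raw$genea, gene_b = raw$geneb)
  if (!is.null(raw[["score"]])) {
    score <- suppressWarnings(as.numeric(raw$score))
    if (anyNA(score) && any(!is.na(raw$score) & is.na(score))) {
      abort(sprintf(
        "%s: non-numeric score at data line %d",
        path, which(!is.na(raw$score) & is.na(score))[1]
      ))
    }
    edges$score <- score
  }
  if (!is.null(raw[["source"]])) edges$source <- raw$source
  interactome(edges)
}

#' Write an interactome as a tab-separated edge list
#'
#' Endpoints are written in lexicographic order so that
#' `read_edge_list(write_edge_list(net, path))` reproduces the graph.
#'
#' @param net An `interactome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  out <- net$edges
  names(out) <- c("geneA", "geneB", "score", "source")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Merge predicted and experimentally reported interactions
#'
#' Forms the union of two interactomes, tagging each edge with its origin.
#' An edge present in both ("collision") keeps the experimental tag and the
#' maximum score. When the inputs are edge-disjoint the total is the plain
#' sum of the two edge counts.
#'
#' @param predicted,experimental `interactome` objects. Edges of
#'   `experimental` are re-tagged `source = "experimental"`.
#' @return A list with `net` (the union `interactome`) and `report`, a
#'   one-row tibble with `n_predicted`, `n_experimental`, `n_collisions`
#'   and `n_total`.
#' @export
assemble_interactome <- function(predicted, experimental) {
  pe <- predicted$edges
  pe$source <- "predicted"
  ee <- experimental$edges
  ee$source <- "experimental"
  n_coll <- length(intersect(
    pair_key(pe$gene_a, pe$gene_b),
    pair_key(ee$gene_a, ee$gene_b)
  ))
  net <- interactome(
    bind_rows(pe, ee),
    genes = union(predicted$genes, experimental$genes)
  )
  report <- tibble(
    n_predicted = nrow(pe),
    n_experimental = nrow(ee),
    n_collisions = n_coll,
    n_total = nrow(net$edges)
  )
  list(net = net, report = report)
}

#' Fraction of one interactome's edges shared with another
#'
#' @param a,b `interactome` objects; `a` must have at least one edge.
#' @return A one-row tibble with `n_shared` (edges of `a` also in `b`, by
#'   unordered pair identity) and `pct` (percent of `a`'s edges, rounded to
#'   one decimal).
#' @export
overlap_fraction <- function(a, b) {
  if (n_edges(a) == 0) abort("`a` has no edges; overlap fraction undefined")
  shared <- sum(pair_key(a$edges$gene_a, a$edges$gene_b) %in%
    pair_key(b$edges$gene_a, b$edges$gene_b))
  tibble(n_shared = shared, pct = round(100 * shared / n_edges(a), 1))
}
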