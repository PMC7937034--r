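#' Bundle the six evidence categories
#'
#' Collects the per-gene evidence tables from which pair features are
#' computed: expression profiles, term annotations, subcellular
#' localizations, protein domains plus domain-pair interactions, phylogenetic
#' profiles, and interologs (interactions transferred from orthologs).
#'
#' @param expression Numeric matrix, genes x conditions (rownames are gene
#'   ids). At least 2 conditions are required for coexpression features.
#' @param annotations Data frame `gene`, `term`.
#' @param localizations Data frame `gene`, `compartment`.
#' @param domains Data frame `gene`, `domain`.
#' @param domain_interactions Data frame `domain_a`, `domain_b`, optional
#'   numeric `score` (default 1).
#' @param phylo_profiles Numeric (typically 0/1) matrix, genes x species.
#' @param interologs Data frame `gene_a`, `gene_b` of unordered pairs.
#' @return A list of class `evidence_bundle`.
#' @export
evidence_bundle <- function(expression = NULL, annotations = NULL,
                            localizations = NULL, domains = NULL,
                            domain_interactions = NULL,
                            phylo_profiles = NULL, interologs = NULL) {
  two_col <- function(x, a, b) {
    if (is.null(x)) {
      return(tibble(!!a := character(), !!b := character()))
    }
    x <- as_tibble(x)
    stopifnot(all(c(a, b) %in% names(x)))
    distinct(x[, c(a, b)])
  }
  di <- if (is.null(domain_interactions)) {
    tibble(domain_a = character(), domain_b = character(), score = double())
  } else {
    di0 <- as_tibble(domain_interactions)
    stopifnot(all(c("domain_a", "domain_b") %in% names(di0)))
    if (is.null(di0[["score"]])) di0$score <- 1
    a <- pmin(di0$domain_a, di0$domain_b)
    b <- pmax(di0$domain_a, di0$domain_b)
    tibble(domain_a = a, domain_b = b, score = as.numeric(di0$score)) |>
      arrange(desc(.data$score)) |>
      distinct(.data$domain_a, .data$domain_b, .keep_all = TRUE)
  }
  il <- if (is.null(interologs)) {
    tibble(gene_a = character(), gene_b = character())
  } else {
    il0 <- as_tibble(interologs)
    stopifnot(all(c("gene_a", "gene_b") %in% names(il0)))
    distinct(tibble(
      gene_a = pmin(il0$gene_a, il0$gene_b),
      gene_b = pmax(il0$gene_a, il0$gene_b)
    ))
  }
  structure(list(
    expression = expression,
    annotations = two_col(annotations, "gene", "term"),
    localizations = two_col(localizations, "gene", "compartment"),
    domains = two_col(domains, "gene", "domain"),
    domain_interactions = di,
    phylo_profiles = phylo_profiles,
    interologs = il
  ), class = "evidence_bundle")
}

#' @export
print.evidence_bundle <- function(x, ...) {
  dim_or <- function(m) if (is.null(m)) "absent" else paste(dim(m), collapse = " x ")
  cat("<evidence_bundle>\n")
  cat("  expression:          ", dim_or(x$expression), "\n")
  cat("  annotations:         ", nrow(x$annotations), "gene-term rows\n")
  cat("  localizations:       ", nrow(x$localizations), "rows\n")
  cat("  domains:             ", nrow(x$domains), "rows\n")
  cat("  domain interactions: ", nrow(x$domain_interactions), "pairs\n")
  cat("  phylo profiles:      ", dim_or(x$phylo_profiles), "\n")
  cat("  interologs:          ", nrow(x$interologs), "pairs\n")
  invisible(x)
}

#' Write / read an evidence bundle as a directory of TSV files
#'
#' @param bundle An `evidence_bundle`.
#' @param dir Directory path (created if needed).
#' @return `dir` (write) or an `evidence_bundle` (read).
#' @export
write_evidence_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  if (!is.null(bundle$expression)) {
    write_matrix_tsv(bundle$expression, p("expression.tsv"))
  }
  readr::write_tsv(bundle$annotations, p("annotations.tsv"), progress = FALSE)
  readr::write_tsv(bundle$localizations, p("localizations.tsv"), progress = FALSE)
  readr::write_tsv(bundle$domains, p("domains.tsv"), progress = FALSE)
  readr::write_tsv(bundle$domain_interactions, p("domain_interactions.tsv"),
    progress = FALSE
  )
  if (!is.null(bundle$phylo_profiles)) {
    write_matrix_tsv(bundle$phylo_profiles, p("phylo_profiles.tsv"))
  }
  readr::write_tsv(bundle$interologs, p("interologs.tsv"), progress = FALSE)
  invisible(dir)
}

#' @rdname write_evidence_bundle
#' @export
read_evidence_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  evidence_bundle(
    expression = if (file.exists(p("expression.tsv"))) read_matrix_tsv(p("expression.tsv")),
    annotations = read_two_col(p("annotations.tsv"), "gene", "term"),
    localizations = read_two_col(p("localizations.tsv"), "gene", "compartment"),
    domains = read_two_col(p("domains.tsv"), "gene", "domain"),
    domain_interactions = readr::read_tsv(p("domain_interactions.tsv"),
      show_col_types = FALSE, progress = FALSE
    ),
    phylo_profiles = if (file.exists(p("phylo_profiles.tsv"))) read_matrix_tsv(p("phylo_profiles.tsv")),
    interologs = read_two_col(p("interologs.tsv"), "gene_a", "gene_b")
  )
}
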