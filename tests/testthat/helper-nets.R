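# Small graph builders shared across test files.

path_net <- function(genes = c("g1", "g2", "g3")) {
  interactome(tibble::tibble(
    gene_a = genes[-length(genes)],
    gene_b = genes[-1]
  ))
}

# Erdos-Renyi interactome over n genes with edge probability p.
er_net <- function(n, p, seed = 1) {
  genes <- sprintf("g%04d", seq_len(n))
  withr::with_seed(seed, {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(idx)) < p
    interactome(
      tibble::tibble(gene_a = genes[idx[keep, 1]], gene_b = genes[idx[keep, 2]]),
      genes = genes
    )
  })
}

# Random interactome with exactly m edges over n genes.
fixed_edge_net <- function(n, m, seed = 1, prefix = "g") {
  genes <- sprintf("%s%05d", prefix, seq_len(n))
  withr::with_seed(seed, {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pick <- sample.int(nrow(idx), m)
    interactome(
      tibble::tibble(gene_a = genes[idx[pick, 1]], gene_b = genes[idx[pick, 2]]),
      genes = genes
    )
  })
}

edge_keys <- function(net) {
  paste(net$edges$gene_a, net$edges$gene_b)
}
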