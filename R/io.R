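#' Gene set collections
#'
#' A gene set collection is a tibble with columns `name` (unique),
#' `description` and `genes` (a list column of character vectors). This is
#' the in-memory form of a GMT file.
#'
#' @param sets A named list of character vectors, or a tibble already in the
#'   collection layout.
#' @param descriptions Optional character vector of descriptions, recycled.
#' @return A tibble of class `gene_set_collection`.
#' @export
gene_sets <- function(sets, descriptions = NULL) {
  if (is.data.frame(sets)) {
    stopifnot(all(c("name", "genes") %in% names(sets)))
    out <- as_tibble(sets)
    if (is.null(out[["description"]])) out$description <- ""
  } else {
    if (is.null(names(sets)) || anyDuplicated(names(sets))) {
      abort("gene sets must have unique names")
    }
    out <- tibble(
      name = names(sets),
      description = descriptions %||% "",
      genes = unname(lapply(sets, as.character))
    )
  }
  if (anyDuplicated(out$name)) abort("gene set names must be unique")
  out <- out[, c("name", "description", "genes")]
  class(out) <- c("gene_set_collection", class(out))
  out
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-delimited.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection` tibble.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 0L) < 3)
  if (length(short)) {
    abort(sprintf("%s: GMT line %d has fewer than 3 fields", path, short[1]))
  }
  gene_sets(
    tibble(
      name = vapply(fields, `[[`, "", 1),
      description = vapply(fields, `[[`, "", 2),
      genes = lapply(fields, function(f) unique(f[-(1:2)]))
    )
  )
}

#' Write gene sets to a GMT file
#'
#' @param sets A `gene_set_collection` (or anything `gene_sets()` accepts).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  sets <- gene_sets(sets)
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$name[i], sets$description[i], sets$genes[[i]]),
      collapse = "\t"
    )
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Map submitted gene identifiers to the canonical namespace
#'
#' Tokens are looked up in an alias table covering the supported input
#' namespaces (gene name, HGNC, UniProt, Ensembl gene/protein, NCBI Entrez).
#' Tokens already canonical map to themselves. Order is preserved and
#' duplicates (after mapping) are collapsed; unmapped tokens are reported,
#' never silently dropped.
#'
#' @param ids Character vector of submitted identifiers.
#' @param mapping A data frame with columns `alias` and `gene_id`
#'   (optionally `namespace`), e.g. from [read_id_mapping()].
#' @return A list with `mapped` (canonical ids, order-preserving, unique)
#'   and `unmapped` (tokens not found). An empty `mapped` result is an
#'   error.
#' @export
map_ids <- function(ids, mapping) {
  stopifnot(all(c("alias", "gene_id") %in% names(mapping)))
  idx <- match(ids, mapping$alias)
  hit <- !is.na(idx)
  # canonical ids pass through even without an alias row
  canon <- !hit & ids %in% mapping$gene_id
  mapped <- character(length(ids))
  mapped[hit] <- mapping$gene_id[idx[hit]]
  mapped[canon] <- ids[canon]
  found <- hit | canon
  out <- list(
    mapped = unique(mapped[found]),
    unmapped = ids[!found]
  )
  if (length(out$mapped) == 0) {
    abort("none of the submitted identifiers could be mapped")
  }
  out
}

#' Read an identifier-mapping table
#'
#' @param path TSV with columns `namespace`, `alias`, `gene_id`.
#' @return A tibble.
#' @export
read_id_mapping <- function(path) {
  readr::read_tsv(path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
}

read_two_col <- function(path, col1, col2) {
  x <- readr::read_tsv(path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (!all(c(col1, col2) %in% names(x))) {
    abort(sprintf("%s: expected columns %s and %s", path, col1, col2))
  }
  as_tibble(x[, c(col1, col2)])
}

read_matrix_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(x[, -1])
  mode(m) <- "numeric"
  rownames(m) <- x[[1]]
  m
}

write_matrix_tsv <- function(m, path, id_col = "gene") {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- bind_cols(tibble(!!id_col := rownames(m)), out)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
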