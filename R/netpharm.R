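#' Gene set container
#'
#' Normalized set of gene symbols: upper-cased, trimmed, deduplicated,
#' empty strings dropped.
#'
#' @param symbols character vector of gene symbols.
#' @param name set name.
#' @param source optional source tag (database of origin).
#' @return a `gene_set` object.
#' @export
gene_set <- function(symbols, name = "genes", source = NA_character_) {
  s <- unique(toupper(stringr::str_trim(as.character(symbols))))
  s <- s[!is.na(s) & s != ""]
  structure(list(name = name, symbols = s, source = source),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set: %s> %d symbols\n", x$name, length(x$symbols)))
  invisible(x)
}

#' Read a one-symbol-per-line gene list
#' @param path text file, one gene symbol per line.
#' @param name set name (defaults to the file name).
#' @param source source tag.
#' @return a [gene_set()].
#' @export
read_gene_list <- function(path, name = basename(path), source = NA_character_) {
  gene_set(readr::read_lines(path, progress = FALSE), name = name, source = source)
}

#' Union of per-source target lists
#'
#' Deduplicating union of target genes collected from several prediction
#' databases, with per-symbol provenance retained in the `provenance`
#' attribute.
#'
#' @param sets list of [gene_set()] objects.
#' @param name name for the union.
#' @return a `gene_set`; `attr(, "provenance")` is a tibble
#'   (`symbol`, `sources`).
#' @export
union_targets <- function(sets, name = "targets") {
  if (!length(sets)) abort("need at least one source gene set")
  tab <- purrr::map_dfr(sets, function(s) {
    tibble::tibble(symbol = s$symbols,
                   source = s$source %||% s$name)
  })
  if (!nrow(tab)) abort("union of target lists is empty")
  prov <- tab |>
    dplyr::group_by(.data$symbol) |>
    dplyr::summarise(sources = paste(sort(unique(.data$source)), collapse = ";"))
  out <- gene_set(prov$symbol, name = name)
  attr(out, "provenance") <- prov
  out
}

#' Drug-disease target intersection (Venn overlap)
#'
#' @param drug,disease [gene_set()] objects.
#' @return a `gene_set` of shared symbols; `attr(, "venn")` holds the
#'   counts `drug_only`, `overlap`, `disease_only`.
#' @export
intersect_targets <- function(drug, disease) {
  if (!length(drug$symbols) || !length(disease$symbols)) {
    abort("both gene sets must be non-empty")
  }
  shared <- intersect(drug$symbols, disease$symbols)
  out <- gene_set(shared, name = paste0(drug$name, "-", disease$name))
  attr(out, "venn") <- c(
    drug_only = length(setdiff(drug$symbols, disease$symbols)),
    overlap = length(shared),
    disease_only = length(setdiff(disease$symbols, drug$symbols))
  )
  out
}

#' Load a STRING-format interaction network
#'
#' Reads a TSV with columns `protein1`, `protein2`, `combined_score`.
#' Integer scores on the STRING 0-1000 dialect are rescaled to `[0, 1]`.
#' Self-loops are dropped, duplicate pairs (either orientation) are
#' collapsed keeping the maximum score, and only edges with score at or
#' above `threshold` are kept. When `genes` is supplied, nodes are
#' restricted to that set (all its symbols become nodes, including
#' isolated ones).
#'
#' @param path edge file (TSV; a header row is required).
#' @param threshold minimum combined score (default 0.4).
#' @param genes optional [gene_set()] restricting (and completing) the
#'   node set.
#' @return an undirected [igraph::graph] with edge attribute `score`,
#'   class-tagged `ppi_graph`.
#' @export
load_ppi <- function(path, threshold = 0.4, genes = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("protein1", "protein2", "combined_score")
  missing <- setdiff(need, tolower(names(raw)))
  if (length(missing)) {
    abort(sprintf("file %s is missing column(s): %s", basename(path),
                  paste(missing, collapse = ", ")))
  }
  names(raw) <- tolower(names(raw))
  score <- suppressWarnings(as.numeric(raw$combined_score))
  bad <- which(is.na(score) | is.na(raw$protein1) | is.na(raw$protein2) |
                 raw$protein1 == "" | raw$protein2 == "")
  if (length(bad)) {
    abort(sprintf("malformed row %d in %s", bad[1] + 1L, basename(path)))
  }
  if (any(score > 1)) score <- score / 1000
  edges <- tibble::tibble(
    from = toupper(stringr::str_trim(raw$protein1)),
    to = toupper(stringr::str_trim(raw$protein2)),
    score = score
  )
  ppi_from_edges(edges, threshold = threshold, genes = genes)
}

ppi_from_edges <- function(edges, threshold = 0.4, genes = NULL) {
  if (!nrow(edges)) {
    verts <- if (is.null(genes)) character(0) else sort(genes$symbols)
    g <- igraph::make_empty_graph(0, directed = FALSE) +
      igraph::vertices(verts)
    igraph::E(g)$score <- numeric(0)
    class(g) <- c("ppi_graph", class(g))
    attr(g, "threshold") <- threshold
    return(g)
  }
  edges <- edges |>
    dplyr::filter(.data$from != .data$to) |>
    dplyr::mutate(a = pmin(.data$from, .data$to), b = pmax(.data$from, .data$to)) |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop") |>
    dplyr::filter(.data$score >= threshold)
  if (!is.null(genes)) {
    edges <- dplyr::filter(edges, .data$a %in% genes$symbols,
                           .data$b %in% genes$symbols)
    verts <- sort(genes$symbols)
  } else {
    verts <- sort(unique(c(edges$a, edges$b)))
  }
  g <- igraph::graph_from_data_frame(
    edges[c("a", "b", "score")], directed = FALSE,
    vertices = data.frame(name = verts))
  class(g) <- c("ppi_graph", class(g))
  attr(g, "threshold") <- threshold
  g
}

#' Write an interaction network back to STRING-format TSV
#'
#' Round-trips with [load_ppi()]: edges and scores are preserved exactly
#' (scores written on the 0-1 scale).
#'
#' @param g a `ppi_graph`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ppi <- function(g, path) {
  el <- igraph::as_data_frame(g, what = "edges")
  out <- tibble::tibble(protein1 = el$from, protein2 = el$to,
                        combined_score = el$score)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a GMT annotation collection
#'
#' Gene-matrix-transposed format: one tab-separated line per term —
#' term id, description, then member symbols.
#'
#' @param path GMT file.
#' @return named list of character vectors (names are term ids);
#'   descriptions kept in the `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[lines != ""]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1)
  desc <- vapply(parts, function(p) if (length(p) > 1) p[[2]] else "", "")
  sets <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  names(sets) <- ids
  attr(sets, "description") <- setNames(desc, ids)
  sets
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of each annotation term against the
#' query set, with Benjamini-Hochberg FDR control across all tested
#' terms. Query symbols outside the universe are dropped with a warning.
#' Terms with no overlap are omitted; rows are sorted by p-value.
#'
#' @param query a [gene_set()] (or character vector) of genes of interest.
#' @param annotations named list of term -> symbols ([read_gmt()] output).
#' @param universe optional [gene_set()]; defaults to all genes appearing
#'   in the annotation collection.
#' @return tibble with `term`, `k` (overlap), `K` (term size in
#'   universe), `n` (query size in universe), `N` (universe size), `p`,
#'   `fdr`, `genes` (overlapping symbols, `";"`-joined).
#' @export
enrich <- function(query, annotations, universe = NULL) {
  q <- if (inherits(query, "gene_set")) query$symbols else
    gene_set(query)$symbols
  uni <- if (is.null(universe)) unique(toupper(unlist(annotations))) else
    universe$symbols
  if (!length(uni)) abort("enrichment universe is empty")
  dropped <- setdiff(q, uni)
  if (length(dropped)) {
    warn(sprintf("%d query symbol(s) outside the universe dropped", length(dropped)))
  }
  q <- intersect(q, uni)
  n <- length(q)
  rows <- purrr::map_dfr(names(annotations), function(term) {
    members <- intersect(unique(toupper(annotations[[term]])), uni)
    hits <- intersect(q, members)
    k <- length(hits); K <- length(members)
    if (k == 0) return(NULL)
    tibble::tibble(
      term = term, k = k, K = K, n = n, N = length(uni),
      p = phyper(k - 1, K, length(uni) - K, n, lower.tail = FALSE),
      genes = paste(sort(hits), collapse = ";")
    )
  })
  if (!nrow(rows)) return(rows)
  rows$fdr <- p.adjust(rows$p, method = "BH")
  dplyr::arrange(rows[c("term", "k", "K", "n", "N", "p", "fdr", "genes")],
                 .data$p, .data$term)
}
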