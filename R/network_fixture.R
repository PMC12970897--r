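#' Synthetic network-pharmacology fixture
#'
#' Builds the full set of inputs for the network stage with known ground
#' truth: per-source drug-target lists whose union has a known size, a
#' disease gene list sharing exactly `n_overlap` symbols with the drug
#' targets, a weighted interaction network over the overlap genes with a
#' planted dense module, and a GMT annotation collection with one
#' enriched term of known composition.
#'
#' @param n_drug_targets size of the drug-target union.
#' @param n_disease_genes size of the disease gene list.
#' @param n_overlap number of shared symbols
#'   (`<= min(n_drug_targets, n_disease_genes)`).
#' @param n_sources number of drug-target source lists the union is
#'   split into (with overlap between sources).
#' @param n_module size of the planted dense module (first overlap
#'   genes).
#' @param p_in edge probability inside the planted module.
#' @param p_out edge probability between other overlap gene pairs.
#' @param n_terms number of annotation terms (the first is the planted
#'   enriched term).
#' @param seed RNG seed (global RNG state restored).
#' @return list with `drug_sources` (list of [gene_set()]),
#'   `drug_targets`, `disease_genes` (gene sets), `ppi` (a `ppi_graph`),
#'   `gmt` (named list), and `truth` (overlap symbols, planted module,
#'   enriched term id).
#' @export
make_network_fixture <- function(n_drug_targets = 553,
                                 n_disease_genes = 3555,
                                 n_overlap = 81,
                                 n_sources = 4,
                                 n_module = 6,
                                 p_in = 0.95,
                                 p_out = 0.03,
                                 n_terms = 10,
                                 seed = 1) {
  if (n_overlap > min(n_drug_targets, n_disease_genes)) {
    abort("n_overlap cannot exceed either list size")
  }
  with_seed(seed, {
    total <- n_drug_targets + n_disease_genes - n_overlap
    pool <- sprintf("GENE%05d", seq_len(total + 200))
    overlap <- pool[seq_len(n_overlap)]
    drug_only <- pool[n_overlap + seq_len(n_drug_targets - n_overlap)]
    disease_only <- pool[n_drug_targets + seq_len(n_disease_genes - n_overlap)]
    drug <- c(overlap, drug_only)
    disease <- c(overlap, disease_only)

    drug_sources <- lapply(seq_len(n_sources), function(i) {
      # each source holds a random two-thirds of the union; jointly they
      # cover it (any straggler is added to the last source)
      take <- drug[runif(length(drug)) < 2 / 3]
      gene_set(take, name = sprintf("source%d", i),
               source = sprintf("source%d", i))
    })
    covered <- unique(unlist(lapply(drug_sources, `[[`, "symbols")))
    left_over <- setdiff(drug, covered)
    if (length(left_over)) {
      drug_sources[[n_sources]] <- gene_set(
        c(drug_sources[[n_sources]]$symbols, left_over),
        name = sprintf("source%d", n_sources),
        source = sprintf("source%d", n_sources))
    }

    module <- overlap[seq_len(min(n_module, n_overlap))]
    edges <- NULL
    if (n_overlap >= 2) {
      pairs <- utils::combn(overlap, 2)
      in_mod <- pairs[1, ] %in% module & pairs[2, ] %in% module
      keep <- runif(ncol(pairs)) < ifelse(in_mod, p_in, p_out)
      # guarantee the module is internally connected: ring through it
      if (length(module) >= 2) {
        ring <- cbind(module, c(module[-1], module[1]))
        edges <- tibble::tibble(
          from = c(pairs[1, keep], ring[, 1]),
          to = c(pairs[2, keep], ring[, 2]),
          score = runif(sum(keep) + nrow(ring), 0.55, 0.99)
        )
      } else {
        edges <- tibble::tibble(from = pairs[1, keep], to = pairs[2, keep],
                                score = runif(sum(keep), 0.55, 0.99))
      }
    } else {
      edges <- tibble::tibble(from = character(), to = character(),
                              score = numeric())
    }
    ppi <- ppi_from_edges(edges, threshold = 0.4,
                          genes = gene_set(overlap, name = "overlap"))

    universe <- unique(c(drug, disease))
    gmt <- list()
    if (n_terms >= 1) {
      extra <- sample(setdiff(universe, module),
                      max(0, min(4, length(universe) - length(module))))
      gmt[["TERM0001"]] <- c(module, extra)
      for (i in seq_len(n_terms - 1)) {
        gmt[[sprintf("TERM%04d", i + 1)]] <-
          sample(universe, min(length(universe), sample(10:40, 1)))
      }
    }
    attr(gmt, "description") <- setNames(
      c("planted module term", rep("background term", max(0, n_terms - 1))),
      names(gmt))

    list(
      drug_sources = drug_sources,
      drug_targets = gene_set(drug, name = "drug_targets"),
      disease_genes = gene_set(disease, name = "disease_genes"),
      ppi = ppi,
      gmt = gmt,
      truth = list(overlap = overlap, module = sort(module),
                   enriched_term = if (n_terms >= 1) "TERM0001" else NULL)
    )
  })
}
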