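# Hand-built KGML snippets and graph constructors used across tests.

minimal_kgml <- function() {
  paste0(
    '<?xml version="1.0"?>\n',
    '<pathway name="path:map99901" org="map" number="99901" title="toy">\n',
    '  <entry id="1" name="cpd:C90001" type="compound"><graphics name="A"/></entry>\n',
    '  <entry id="2" name="cpd:C90002" type="compound"><graphics name="B"/></entry>\n',
    '  <entry id="3" name="cpd:C90003" type="compound"><graphics name="C"/></entry>\n',
    '  <entry id="4" name="ko:K90001" type="ortholog" reaction="rn:R90001"/>\n',
    '  <reaction id="10" name="rn:R90001" type="irreversible">\n',
    '    <substrate id="1" name="cpd:C90001"/><product id="2" name="cpd:C90002"/>\n',
    '  </reaction>\n',
    '  <reaction id="11" name="rn:R90002" type="irreversible">\n',
    '    <substrate id="2" name="cpd:C90002"/><product id="3" name="cpd:C90003"/>\n',
    '  </reaction>\n',
    '</pathway>'
  )
}

reversible_kgml <- function() {
  paste0(
    '<?xml version="1.0"?>\n',
    '<pathway name="path:map99902" org="map" number="99902" title="rev">\n',
    '  <entry id="1" name="cpd:C90001" type="compound"><graphics name="A"/></entry>\n',
    '  <entry id="2" name="cpd:C90002" type="compound"><graphics name="B"/></entry>\n',
    '  <reaction id="10" name="rn:R90001" type="reversible">\n',
    '    <substrate id="1" name="cpd:C90001"/><product id="2" name="cpd:C90002"/>\n',
    '  </reaction>\n',
    '</pathway>'
  )
}

# A pathway_graph built directly from edge pairs (undirected test graphs);
# every edge gets a distinct reaction id and an optional catalyst gene.
graph_from_pairs <- function(pairs, map_id = "map99900", genes = NULL) {
  nodes <- tibble::tibble(
    compound_id = sort(unique(c(pairs[, 1], pairs[, 2]))),
    display_name = sort(unique(c(pairs[, 1], pairs[, 2]))),
    external = FALSE,
    synonyms = list(character(0))
  )
  n <- nrow(pairs)
  edges <- tibble::tibble(
    reaction_id = sprintf("R%05d", seq_len(n)),
    substrate_id = pairs[, 1],
    product_id = pairs[, 2],
    reversible = FALSE,
    self_loop = pairs[, 1] == pairs[, 2],
    genes = if (is.null(genes)) rep(list(character(0)), n) else lapply(genes, identity),
    pfams = rep(list(character(0)), n)
  )
  gcmkit:::new_pathway_graph(map_id, NA_character_, nodes, edges)
}

# Two 4-cliques joined by one bridge edge; bridge carries a named gene.
two_clique_bridge <- function() {
  a <- c("C00001", "C00002", "C00003", "C00004")
  b <- c("C00011", "C00012", "C00013", "C00014")
  cl <- function(v) t(utils::combn(v, 2))
  pairs <- rbind(cl(a), cl(b), c("C00004", "C00011"))
  genes <- c(rep(list(character(0)), nrow(pairs) - 1), list("bridge_gene"))
  graph_from_pairs(pairs, genes = genes)
}

# Random connected-ish pathway graph on <= max_nodes compounds.
random_small_graph <- function(n, p = 0.5) {
  nodes <- sprintf("C%05d", seq_len(n))
  pairs <- t(utils::combn(nodes, 2))
  pairs <- pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
  if (!nrow(pairs)) pairs <- t(utils::combn(nodes, 2))[1, , drop = FALSE]
  graph_from_pairs(pairs)
}

# A bare catalog with genes at the given ranks on one replicon.
catalog_at_ranks <- function(ranks, n = max(ranks) + 20L, circular = FALSE,
                             pfams = NULL, genome_id = "toy") {
  spec <- genome_spec(genome_id, replicons = tibble::tibble(
    replicon_id = "chr", size = as.integer(n), circular = circular
  ), background_density = 0, seed = 7L)
  cat_obj <- make_genome(spec)$catalog
  if (!is.null(pfams)) {
    for (i in seq_along(ranks)) {
      cat_obj$pfams[[which(cat_obj$rank == ranks[i])]] <- pfams[[i]]
    }
  }
  cat_obj
}

locus_at <- function(catalog, rank, replicon = NULL) {
  sub <- if (is.null(replicon)) catalog else catalog[catalog$replicon_id == replicon, ]
  sub$locus_tag[match(rank, sub$rank)]
}
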