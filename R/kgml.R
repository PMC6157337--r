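#' Parse a KGML pathway file into a compound/reaction graph
#'
#' Reads the KEGG XML dialect (KGML) describing a metabolic pathway map and
#' returns a `pathway_graph`: compounds become nodes, `reaction` elements
#' become substrate/product edges, and gene (or ortholog/enzyme) entries whose
#' `reaction` attribute references a reaction populate that edge's catalyst
#' set. Both reference maps (`map*`, catalysts are KO/EC identifiers) and
#' organism-specific files (catalysts are locus tags) are accepted; the
#' database prefix (`cpd:`, `rn:`, `eco:`, ...) is stripped from all
#' identifiers on ingest.
#'
#' Entries of type `"map"` (links to other pathway maps) are kept as nodes but
#' flagged `external`; downstream community detection excludes them, because
#' constitutive sub-pathways referenced from inside a map would otherwise
#' blur module boundaries. Duplicate compound entries carrying the same
#' accession are merged into one node. A reaction of type `"reversible"`
#' yields a single edge with `reversible = TRUE`, never a mirrored pair.
#'
#' `relation` elements do not contribute edges unless `use_relations = TRUE`,
#' in which case a compound-to-compound relation with no backing reaction
#' becomes an irreversible edge with a `rel:`-prefixed reaction id.
#'
#' @param kgml Path to a KGML file, or a single string of KGML XML.
#' @param use_relations Should compound-compound `relation` elements without a
#'   backing `reaction` contribute edges? Default `FALSE`.
#' @return A `pathway_graph` object: a list with `map_id`, `organism`,
#'   `nodes` (tibble: `compound_id`, `display_name`, `external`, `synonyms`
#'   list-column) and `edges` (tibble: `reaction_id`, `substrate_id`,
#'   `product_id`, `reversible`, `self_loop`, `genes` and `pfams`
#'   list-columns).
#' @examples
#' g <- parse_kgml(make_man_suite()$kgml)
#' g
#' to_edge_list(g)
#' @export
parse_kgml <- function(kgml, use_relations = FALSE) {
  doc <- tryCatch(
    xml2::read_xml(kgml),
    error = function(e) abort(paste0("malformed KGML XML: ", conditionMessage(e)))
  )
  root <- xml2::xml_find_first(doc, "/pathway")
  if (is.na(xml2::xml_name(doc)) || xml2::xml_name(doc) != "pathway") {
    abort("not a KGML document: root element must be <pathway>")
  }
  map_id <- strip_kegg_prefix(xml2::xml_attr(doc, "name") %||% NA_character_)
  organism <- xml2::xml_attr(doc, "org")
  if (!is.na(organism) && organism == "map") organism <- NA_character_

  entries <- xml2::xml_find_all(doc, "entry")
  etype <- xml2::xml_attr(entries, "type")
  ename <- xml2::xml_attr(entries, "name")
  eid <- xml2::xml_attr(entries, "id")
  ereact <- xml2::xml_attr(entries, "reaction")
  egraph <- vapply(entries, function(e) {
    gn <- xml2::xml_find_first(e, "graphics")
    if (inherits(gn, "xml_missing")) NA_character_ else xml2::xml_attr(gn, "name")
  }, character(1))

  is_cpd <- etype == "compound"
  is_ext <- etype == "map"
  if (!any(is_cpd)) abort(paste0("empty pathway: KGML for '", map_id, "' declares no compound entries"))

  node_rows <- lapply(which(is_cpd | is_ext), function(i) {
    acc <- strip_kegg_prefix(strsplit(ename[i], " ", fixed = TRUE)[[1]][1])
    gnames <- egraph[i]
    syn <- if (is.na(gnames)) character(0) else {
      trimws(strsplit(gnames, ",", fixed = TRUE)[[1]])
    }
    tibble(
      entry_id = eid[i],
      compound_id = acc,
      display_name = if (length(syn)) syn[1] else acc,
      external = is_ext[i],
      synonyms = list(if (length(syn) > 1) syn[-1] else character(0))
    )
  })
  node_map <- bind_rows(node_rows)
  # entry id -> compound accession lookup (reaction children may use entry ids)
  entry_lookup <- setNames(node_map$compound_id, node_map$entry_id)
  nodes <- node_map |>
    group_by(.data$compound_id) |>
    summarise(
      display_name = first(.data$display_name),
      external = all(.data$external),
      synonyms = list(unique(unlist(.data$synonyms))),
      .groups = "drop"
    )

  # reaction name -> catalyst gene ids, from gene/ortholog/enzyme entries
  is_cat <- etype %in% c("gene", "ortholog", "enzyme") & !is.na(ereact)
  catalysts <- list()
  for (i in which(is_cat)) {
    genes <- strip_kegg_prefix(strsplit(ename[i], " ", fixed = TRUE)[[1]])
    for (rn in strip_kegg_prefix(strsplit(ereact[i], " ", fixed = TRUE)[[1]])) {
      catalysts[[rn]] <- union(catalysts[[rn]], genes)
    }
  }

  resolve_side <- function(node) {
    nm <- xml2::xml_attr(node, "name")
    id <- xml2::xml_attr(node, "id")
    acc <- if (!is.na(nm)) strip_kegg_prefix(strsplit(nm, " ", fixed = TRUE)[[1]][1]) else NA_character_
    if (!is.na(acc) && acc %in% nodes$compound_id) return(acc)
    if (!is.na(id) && id %in% names(entry_lookup)) return(unname(entry_lookup[id]))
    abort(paste0(
      "reaction references an undeclared entry: ",
      if (!is.na(acc)) acc else id %||% "<missing id>"
    ))
  }

  reactions <- xml2::xml_find_all(doc, "reaction")
  edge_rows <- list()
  for (rx in reactions) {
    rid <- strip_kegg_prefix(strsplit(xml2::xml_attr(rx, "name") %||% "", " ", fixed = TRUE)[[1]][1])
    rev <- identical(xml2::xml_attr(rx, "type"), "reversible")
    subs <- vapply(xml2::xml_find_all(rx, "substrate"), resolve_side, character(1))
    prods <- vapply(xml2::xml_find_all(rx, "product"), resolve_side, character(1))
    genes <- catalysts[[rid]] %||% character(0)
    for (s in subs) for (p in prods) {
      edge_rows[[length(edge_rows) + 1L]] <- tibble(
        reaction_id = rid, substrate_id = s, product_id = p,
        reversible = rev, self_loop = s == p, genes = list(genes)
      )
    }
  }
  if (use_relations) {
    for (rel in xml2::xml_find_all(doc, "relation")) {
      e1 <- xml2::xml_attr(rel, "entry1"); e2 <- xml2::xml_attr(rel, "entry2")
      if (e1 %in% names(entry_lookup) && e2 %in% names(entry_lookup)) {
        s <- unname(entry_lookup[e1]); p <- unname(entry_lookup[e2])
        edge_rows[[length(edge_rows) + 1L]] <- tibble(
          reaction_id = paste0("rel:", e1, "-", e2), substrate_id = s,
          product_id = p, reversible = FALSE, self_loop = s == p,
          genes = list(character(0))
        )
      }
    }
  }
  edges <- if (length(edge_rows)) bind_rows(edge_rows) else
    tibble(reaction_id = character(), substrate_id = character(),
           product_id = character(), reversible = logical(),
           self_loop = logical(), genes = list())
  edges <- edges[!duplicated(edges[c("reaction_id", "substrate_id", "product_id")]), ]
  edges$pfams <- rep(list(character(0)), nrow(edges))

  new_pathway_graph(map_id = map_id, organism = organism,
                    nodes = select(nodes, -dplyr::any_of("entry_id")),
                    edges = as_tibble(edges))
}

new_pathway_graph <- function(map_id, organism, nodes, edges) {
  structure(
    list(map_id = map_id, organism = organism, nodes = nodes, edges = edges),
    class = "pathway_graph"
  )
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("<pathway_graph> ", x$map_id,
      if (!is.na(x$organism %||% NA)) paste0(" [", x$organism, "]") else "",
      "\n", sep = "")
  cat("  nodes: ", nrow(x$nodes), " compounds (",
      sum(x$nodes$external), " external)\n", sep = "")
  cat("  edges: ", nrow(x$edges), " reactions (",
      sum(x$edges$reversible), " reversible)\n", sep = "")
  invisible(x)
}

#' @export
tidy.pathway_graph <- function(x, ...) x$edges

#' @export
glance.pathway_graph <- function(x, ...) {
  tibble(
    map_id = x$map_id, n_nodes = nrow(x$nodes),
    n_external = sum(x$nodes$external), n_edges = nrow(x$edges),
    n_reversible = sum(x$edges$reversible)
  )
}

#' Flatten a pathway graph to a deterministic edge list
#'
#' One row per reaction edge, reversible edges emitted once, ordered by
#' `reaction_id` then `substrate_id` (ties by `product_id`) so the output is
#' invariant under reordering of the source KGML elements.
#'
#' @param graph A `pathway_graph`.
#' @return A tibble with columns `substrate_id`, `product_id`, `reaction_id`.
#' @export
to_edge_list <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  graph$edges |>
    select("substrate_id", "product_id", "reaction_id") |>
    arrange(.data$reaction_id, .data$substrate_id, .data$product_id)
}

# internal: igraph view of the non-external compound graph (undirected,
# parallel edges collapsed to weights) used for export/layout
pathway_igraph <- function(graph, drop_external = TRUE) {
  nodes <- graph$nodes
  if (drop_external) nodes <- filter(nodes, !.data$external)
  edges <- filter(graph$edges, .data$substrate_id %in% nodes$compound_id,
                  .data$product_id %in% nodes$compound_id, !.data$self_loop)
  igraph::graph_from_data_frame(
    d = data.frame(from = edges$substrate_id, to = edges$product_id,
                   reaction_id = edges$reaction_id),
    directed = FALSE,
    vertices = data.frame(name = sort(nodes$compound_id))
  )
}

#' Export a pathway graph annotated with module detection calls
#'
#' Writes GraphML (via igraph) or a documented JSON graph serialization in
#' which every node and edge carries a `module_id` attribute and a
#' `present` flag derived from windowed detection calls. A call whose module
#' references a compound missing from the graph raises a warning and that
#' attribute is omitted.
#'
#' @param graph A `pathway_graph`.
#' @param calls A detection-call tibble as returned by [scan_genome()], or
#'   `NULL`/empty for an unannotated export (all nodes flagged absent).
#' @param modules The module catalog the calls refer to (needed for the
#'   module-to-compound mapping).
#' @param format `"graphml"` or `"json"`.
#' @param path Output file; when `NULL` the serialized text is returned.
#' @return The serialized text, invisibly when `path` is given.
#' @export
export_annotated_graph <- function(graph, calls = NULL, modules = NULL,
                                   format = c("graphml", "json"), path = NULL) {
  stopifnot(inherits(graph, "pathway_graph"))
  format <- match.arg(format)
  ann <- annotate_nodes(graph, calls, modules)
  txt <- if (format == "graphml") {
    ig <- pathway_igraph(graph, drop_external = FALSE)
    idx <- match(igraph::V(ig)$name, ann$compound_id)
    ig <- igraph::set_vertex_attr(ig, "module_id", value = ann$module_id[idx])
    ig <- igraph::set_vertex_attr(ig, "present", value = ann$present[idx])
    emod <- edge_module_attr(graph, modules, calls)
    eid <- igraph::edge_attr(ig, "reaction_id")
    ig <- igraph::set_edge_attr(ig, "module_id", value = emod$module_id[match(eid, emod$reaction_id)])
    ig <- igraph::set_edge_attr(ig, "present", value = emod$present[match(eid, emod$reaction_id)])
    tf <- tempfile(fileext = ".graphml")
    on.exit(unlink(tf), add = TRUE)
    igraph::write_graph(ig, tf, format = "graphml")
    paste(readLines(tf, warn = FALSE), collapse = "\n")
  } else {
    emod <- edge_module_attr(graph, modules, calls)
    obj <- list(
      map_id = graph$map_id,
      organism = graph$organism,
      nodes = lapply(seq_len(nrow(ann)), function(i) list(
        id = ann$compound_id[i], name = graph$nodes$display_name[match(ann$compound_id[i], graph$nodes$compound_id)],
        external = graph$nodes$external[match(ann$compound_id[i], graph$nodes$compound_id)],
        module_id = ann$module_id[i], present = ann$present[i]
      )),
      edges = lapply(seq_len(nrow(graph$edges)), function(i) {
        e <- graph$edges[i, ]
        j <- match(e$reaction_id, emod$reaction_id)
        list(reaction_id = e$reaction_id, substrate = e$substrate_id,
             product = e$product_id, reversible = e$reversible,
             module_id = emod$module_id[j], present = emod$present[j])
      })
    )
    jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  if (!is.null(path)) {
    writeLines(as.character(txt), path)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

annotate_nodes <- function(graph, calls, modules) {
  ann <- tibble(compound_id = sort(graph$nodes$compound_id),
                module_id = NA_character_, present = FALSE)
  if (is.null(calls) || !nrow(calls)) return(ann)
  if (is.null(modules)) abort("`modules` is required to map calls onto compounds")
  for (i in seq_len(nrow(calls))) {
    mid <- calls$gcm_id[i]
    j <- match(mid, modules$module_id)
    if (is.na(j)) {
      warn(paste0("call references unknown module '", mid, "'; attribute omitted"))
      next
    }
    cpds <- modules$compounds[[j]]
    missing <- setdiff(cpds, ann$compound_id)
    if (length(missing)) {
      warn(paste0("module '", mid, "' references compounds absent from the graph: ",
                  paste(missing, collapse = ", "), "; attribute omitted for those"))
    }
    hit <- ann$compound_id %in% cpds
    ann$module_id[hit] <- ifelse(is.na(ann$module_id[hit]), mid,
                                 paste(ann$module_id[hit], mid, sep = ";"))
    if (isTRUE(calls$present[i])) ann$present[hit] <- TRUE
  }
  ann
}

edge_module_attr <- function(graph, modules, calls) {
  out <- tibble(reaction_id = unique(graph$edges$reaction_id),
                module_id = NA_character_, present = FALSE)
  if (is.null(modules) || is.null(calls) || !nrow(calls)) return(out)
  for (i in seq_len(nrow(calls))) {
    j <- match(calls$gcm_id[i], modules$module_id)
    if (is.na(j)) next
    cpds <- modules$compounds[[j]]
    hit <- vapply(out$reaction_id, function(r) {
      e <- graph$edges[graph$edges$reaction_id == r, ]
      any(e$substrate_id %in% cpds & e$product_id %in% cpds)
    }, logical(1))
    out$module_id[hit] <- ifelse(is.na(out$module_id[hit]), calls$gcm_id[i],
                                 paste(out$module_id[hit], calls$gcm_id[i], sep = ";"))
    if (isTRUE(calls$present[i])) out$present[hit] <- TRUE
  }
  out
}

#' Serialize a pathway graph back to KGML text
#'
#' Inverse of [parse_kgml()] for round-trip checks and fixture generation.
#' Compound nodes become `entry` elements of type compound (external nodes
#' type `"map"`), each edge becomes a `reaction` element, and catalyst genes
#' become gene entries whose `reaction` attribute references their reaction.
#'
#' @param graph A `pathway_graph`.
#' @param path Optional output file.
#' @return KGML text (invisibly when `path` is given).
#' @export
write_kgml <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "pathway_graph"))
  org <- graph$organism %||% NA_character_
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  lines <- c(
    '<?xml version="1.0"?>',
    sprintf('<pathway name="path:%s" org="%s" number="%s" title="%s">',
            esc(graph$map_id), esc(if (is.na(org)) "map" else org),
            esc(sub("^[a-z]+", "", graph$map_id)), esc(graph$map_id))
  )
  nid <- 0L
  for (i in seq_len(nrow(graph$nodes))) {
    nid <- nid + 1L
    nd <- graph$nodes[i, ]
    nm <- paste(c(nd$display_name, nd$synonyms[[1]]), collapse = ", ")
    lines <- c(lines, sprintf(
      '  <entry id="%d" name="%s%s" type="%s">\n    <graphics name="%s" type="circle"/>\n  </entry>',
      nid, if (nd$external) "path:" else "cpd:", esc(nd$compound_id),
      if (nd$external) "map" else "compound", esc(nm)
    ))
  }
  # one gene entry per (gene, reaction) association
  gene_assoc <- list()
  for (i in seq_len(nrow(graph$edges))) {
    for (g in graph$edges$genes[[i]]) {
      gene_assoc[[g]] <- union(gene_assoc[[g]], graph$edges$reaction_id[i])
    }
  }
  pre <- if (is.na(org)) "ko:" else paste0(org, ":")
  for (g in names(gene_assoc)) {
    nid <- nid + 1L
    lines <- c(lines, sprintf(
      '  <entry id="%d" name="%s%s" type="%s" reaction="%s"/>',
      nid, pre, esc(g), if (is.na(org)) "ortholog" else "gene",
      paste0("rn:", esc(gene_assoc[[g]]), collapse = " ")
    ))
  }
  edges <- graph$edges
  for (i in seq_len(nrow(edges))) {
    e <- edges[i, ]
    lines <- c(lines, sprintf(
      '  <reaction id="%d" name="rn:%s" type="%s">\n    <substrate id="0" name="cpd:%s"/>\n    <product id="0" name="cpd:%s"/>\n  </reaction>',
      i, esc(e$reaction_id), if (e$reversible) "reversible" else "irreversible",
      esc(e$substrate_id), esc(e$product_id)
    ))
  }
  lines <- c(lines, "</pathway>")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
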