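#' Module catalogs
#'
#' Modules of all three kinds — IRM (initial reference module, a pure
#' edge-connectivity community of compounds), IM (intermediate module, after
#' genomic-proximity refinement) and GCM (gene-context based module, an
#' evidence-backed IM with a declared source and target compound) — live in
#' one tidy catalog: a tibble with one row per module and list-columns for
#' the set-valued fields.
#'
#' Columns: `module_id`, `kind` (`"IRM"`/`"IM"`/`"GCM"`), `map_id`,
#' `compounds` (ordered character list-column), `pfams`, `genes` (catalyst
#' gene/ortholog ids from the pathway graph), `linker_genes` (genes
#' catalyzing reactions that straddle two modules, duplicated into both),
#' `gene_assignments` (per-genome locus-tag sets, a named-list column),
#' `source_compound`, `target_compound`, `cyclic`, `unclustered`,
#' `merged_from` (contributing module ids after refinement), `evidence`
#' (PMID character list-column).
#'
#' @param ... Column values; missing columns are filled with defaults.
#' @return A `module_catalog` tibble.
#' @export
module_catalog <- function(...) {
  x <- tibble(...)
  n <- nrow(x)
  defaults <- list(
    module_id = character(n), kind = rep("IRM", n), map_id = rep(NA_character_, n),
    compounds = rep(list(character(0)), n), pfams = rep(list(character(0)), n),
    genes = rep(list(character(0)), n), linker_genes = rep(list(character(0)), n),
    gene_assignments = rep(list(list()), n),
    source_compound = rep(NA_character_, n), target_compound = rep(NA_character_, n),
    cyclic = rep(FALSE, n), unclustered = rep(FALSE, n),
    merged_from = rep(list(character(0)), n), evidence = rep(list(character(0)), n)
  )
  for (col in names(defaults)) {
    if (!col %in% names(x)) x[[col]] <- defaults[[col]]
  }
  x <- x[, names(defaults)]
  if (anyDuplicated(x$module_id)) {
    abort(paste0("duplicate module_id in catalog: ",
                 paste(unique(x$module_id[duplicated(x$module_id)]), collapse = ", ")))
  }
  class(x) <- c("module_catalog", class(tibble()))
  x
}

#' Build initial reference modules from a community partition
#'
#' One IRM per community label. Compounds inside each module are ordered
#' topologically along the intra-community reaction edges when those edges
#' are acyclic, so a linear conversion chain reads source-to-product;
#' communities whose internal edges contain a cycle fall back to
#' lexicographic order and are flagged `cyclic`. Catalyst genes of
#' intra-community edges populate the module's gene set.
#'
#' @param graph A `pathway_graph`.
#' @param partition A tibble from [detect_communities()].
#' @return A `module_catalog` of kind `"IRM"`, module ids
#'   `<map_id>.IRM<label>`.
#' @examples
#' g <- parse_kgml(make_man_suite()$kgml)
#' build_irms(g, detect_communities(g))
#' @export
build_irms <- function(graph, partition) {
  stopifnot(inherits(graph, "pathway_graph"))
  nn <- graph$nodes$compound_id[!graph$nodes$external]
  if (!all(nn %in% partition$compound_id)) {
    abort("partition does not cover all non-external nodes")
  }
  labs <- sort(unique(partition$community))
  rows <- lapply(labs, function(lab) {
    members <- sort(partition$compound_id[partition$community == lab])
    e <- filter(graph$edges, .data$substrate_id %in% members,
                .data$product_id %in% members, !.data$self_loop)
    ord <- topological_or_lexical(members, e)
    tibble(
      module_id = sprintf("%s.IRM%d", graph$map_id, lab),
      kind = "IRM", map_id = graph$map_id,
      compounds = list(ord$order),
      genes = list(sort(unique(unlist(e$genes)))),
      cyclic = ord$cyclic
    )
  })
  module_catalog(!!!bind_rows(rows))
}

# Kahn topological sort over directed intra-community edges (reversible
# edges do not constrain order); lexicographic among ready nodes.
topological_or_lexical <- function(members, edges) {
  dir <- filter(edges, !.data$reversible)
  indeg <- setNames(integer(length(members)), members)
  adj <- lapply(setNames(members, members), function(x) character(0))
  for (i in seq_len(nrow(dir))) {
    s <- dir$substrate_id[i]; p <- dir$product_id[i]
    adj[[s]] <- c(adj[[s]], p)
    indeg[p] <- indeg[p] + 1L
  }
  out <- character(0)
  ready <- sort(names(indeg)[indeg == 0L])
  indeg_left <- indeg
  while (length(ready)) {
    v <- ready[1]
    ready <- ready[-1]
    out <- c(out, v)
    for (p in adj[[v]]) {
      indeg_left[p] <- indeg_left[p] - 1L
      if (indeg_left[p] == 0L) ready <- sort(c(ready, p))
    }
  }
  if (length(out) < length(members)) {
    list(order = sort(members), cyclic = TRUE)
  } else {
    list(order = out, cyclic = FALSE)
  }
}

#' Tag linker genes onto both modules they bridge
#'
#' A gene catalyzing a reaction whose substrate and product fall into two
#' different IRMs belongs to neither community outright; it is added to the
#' gene set of *both* modules and recorded in their `linker_genes`, to be
#' resolved later by genomic context. Tagging only duplicates — it never
#' removes a gene from a module.
#'
#' @param graph A `pathway_graph`.
#' @param irms A `module_catalog` built from this graph.
#' @return The catalog with linker genes added and flagged.
#' @export
tag_linker_genes <- function(graph, irms) {
  stopifnot(inherits(irms, "module_catalog"))
  where <- compound_module_lookup(irms)
  for (i in seq_len(nrow(graph$edges))) {
    e <- graph$edges[i, ]
    ms <- where[[e$substrate_id]] %||% NA_character_
    mp <- where[[e$product_id]] %||% NA_character_
    if (is.na(ms) || is.na(mp) || ms == mp) next
    for (mid in c(ms, mp)) {
      j <- match(mid, irms$module_id)
      irms$genes[[j]] <- sort(union(irms$genes[[j]], e$genes[[1]]))
      irms$linker_genes[[j]] <- sort(union(irms$linker_genes[[j]], e$genes[[1]]))
    }
  }
  irms
}

compound_module_lookup <- function(modules) {
  out <- list()
  for (i in seq_len(nrow(modules))) {
    for (cpd in modules$compounds[[i]]) out[[cpd]] <- modules$module_id[i]
  }
  out
}

#' Attach per-genome locus tags to modules
#'
#' Maps each module's catalyst gene ids onto a genome catalog. With
#' `by = "locus"` (organism-specific pathway files, where catalysts are
#' locus tags already) the gene ids are intersected with the catalog's
#' locus tags; with `by = "pfam"` every catalog gene carrying at least one
#' of the module's Pfams is assigned.
#'
#' @param modules A `module_catalog`.
#' @param catalog A `genome_catalog`.
#' @param by `"locus"` or `"pfam"`.
#' @return The catalog with `gene_assignments[[genome_id]]` filled.
#' @export
assign_module_genes <- function(modules, catalog, by = c("locus", "pfam")) {
  by <- match.arg(by)
  gid <- attr(catalog, "genome_id")
  for (i in seq_len(nrow(modules))) {
    loci <- if (by == "locus") {
      intersect(modules$genes[[i]], catalog$locus_tag)
    } else {
      catalog$locus_tag[map_lgl(catalog$pfams, function(p) any(p %in% modules$pfams[[i]]))]
    }
    ga <- modules$gene_assignments[[i]]
    ga[[gid]] <- sort(loci)
    modules$gene_assignments[[i]] <- ga
  }
  modules
}

#' Read and write module catalogs
#'
#' TSV serialization with semicolon-joined list fields (columns `module_id`,
#' `kind`, `map_id`, `compounds`, `pfams`, `genes`, `linker_genes`,
#' `source`, `target`, `evidence`) and an equivalent JSON form that also
#' carries per-genome gene assignments.
#'
#' @param modules A `module_catalog`.
#' @param path Output file; `NULL` returns the text.
#' @return `write_module_tsv()`/`write_module_json()` return the text
#'   invisibly when `path` is given; the readers return a `module_catalog`.
#' @export
write_module_tsv <- function(modules, path = NULL) {
  flat <- tibble(
    module_id = modules$module_id, kind = modules$kind, map_id = modules$map_id,
    compounds = join_semi(modules$compounds), pfams = join_semi(modules$pfams),
    genes = join_semi(modules$genes), linker_genes = join_semi(modules$linker_genes),
    source = modules$source_compound, target = modules$target_compound,
    evidence = join_semi(modules$evidence)
  )
  lines <- c(paste(names(flat), collapse = "\t"),
             do.call(paste, c(lapply(flat, function(x) ifelse(is.na(x), "", x)), sep = "\t")))
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname write_module_tsv
#' @param text TSV/JSON text or a file path.
#' @export
read_module_tsv <- function(text) {
  lines <- read_text_lines(text)
  if (!length(lines)) abort("empty module TSV")
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- lines[-1]
  body <- body[nzchar(body)]
  cells <- strsplit(body, "\t", fixed = TRUE)
  cells <- lapply(cells, function(x) c(x, rep("", length(hdr) - length(x))))
  get <- function(col) vapply(cells, function(r) r[match(col, hdr)], character(1))
  module_catalog(
    module_id = get("module_id"), kind = get("kind"),
    map_id = dplyr::na_if(get("map_id"), ""),
    compounds = split_semi(get("compounds")), pfams = split_semi(get("pfams")),
    genes = split_semi(get("genes")), linker_genes = split_semi(get("linker_genes")),
    source_compound = dplyr::na_if(get("source"), ""),
    target_compound = dplyr::na_if(get("target"), ""),
    evidence = split_semi(get("evidence"))
  )
}

#' @rdname write_module_tsv
#' @export
write_module_json <- function(modules, path = NULL) {
  obj <- lapply(seq_len(nrow(modules)), function(i) {
    list(
      module_id = modules$module_id[i], kind = modules$kind[i],
      map_id = modules$map_id[i], compounds = modules$compounds[[i]],
      pfams = modules$pfams[[i]], genes = modules$genes[[i]],
      linker_genes = modules$linker_genes[[i]],
      gene_assignments = modules$gene_assignments[[i]],
      source_compound = modules$source_compound[i],
      target_compound = modules$target_compound[i],
      evidence = modules$evidence[[i]]
    )
  })
  txt <- as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, null = "null"))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname write_module_tsv
#' @export
read_module_json <- function(text) {
  obj <- jsonlite::fromJSON(paste(read_text_lines(text), collapse = "\n"),
                            simplifyVector = FALSE)
  as_chr <- function(x) as.character(unlist(x) %||% character(0))
  module_catalog(
    module_id = vapply(obj, function(m) m$module_id, character(1)),
    kind = vapply(obj, function(m) m$kind, character(1)),
    map_id = vapply(obj, function(m) m$map_id %||% NA_character_, character(1)),
    compounds = lapply(obj, function(m) as_chr(m$compounds)),
    pfams = lapply(obj, function(m) as_chr(m$pfams)),
    genes = lapply(obj, function(m) as_chr(m$genes)),
    linker_genes = lapply(obj, function(m) as_chr(m$linker_genes)),
    gene_assignments = lapply(obj, function(m) lapply(m$gene_assignments %||% list(), as_chr)),
    source_compound = vapply(obj, function(m) m$source_compound %||% NA_character_, character(1)),
    target_compound = vapply(obj, function(m) m$target_compound %||% NA_character_, character(1)),
    evidence = lapply(obj, function(m) as_chr(m$evidence))
  )
}

#' Apply a curation overlay to a module catalog
#'
#' Manual-curation outcomes (dropping promiscuous-domain false positives,
#' renaming, adjusting compound or Pfam sets) are recorded as an explicit
#' overlay table rather than code: one row per action with columns
#' `action` (`drop`, `set`, `add`, `remove`), `module_id`, `field`,
#' `value`. `set` assigns a scalar field; `add`/`remove` edit the list
#' fields (`compounds`, `pfams`, `genes`, `evidence`).
#'
#' @param modules A `module_catalog`.
#' @param overlay A data frame with columns `action`, `module_id`, `field`,
#'   `value`.
#' @return The curated `module_catalog`.
#' @export
apply_curation <- function(modules, overlay) {
  list_fields <- c("compounds", "pfams", "genes", "linker_genes", "evidence")
  for (i in seq_len(nrow(overlay))) {
    act <- overlay$action[i]
    mid <- overlay$module_id[i]
    j <- match(mid, modules$module_id)
    if (act == "drop") {
      if (!is.na(j)) modules <- modules[-j, ]
      next
    }
    if (is.na(j)) abort(paste0("curation overlay references unknown module '", mid, "'"))
    fld <- overlay$field[i]
    val <- overlay$value[i]
    if (act == "set") {
      if (fld %in% list_fields) abort(paste0("'set' is for scalar fields, not '", fld, "'"))
      modules[[fld]][j] <- val
    } else if (act == "add") {
      modules[[fld]][[j]] <- sort(union(modules[[fld]][[j]], val))
    } else if (act == "remove") {
      modules[[fld]][[j]] <- setdiff(modules[[fld]][[j]], val)
    } else {
      abort(paste0("unknown curation action '", act, "'"))
    }
  }
  modules
}

# Accept either a file path or text (possibly multi-line) uniformly.
read_text_lines <- function(text) {
  if (length(text) == 1 && !grepl("\n", text, fixed = TRUE) && file.exists(text)) {
    readLines(text, warn = FALSE)
  } else {
    unlist(strsplit(text, "\n", fixed = TRUE))
  }
}
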