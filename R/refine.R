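#' Refinement parameters
#'
#' @param distance_threshold Minimum-distance merge score in gene-rank
#'   units: genes chained with steps at or below it share a cluster
#'   (default 10).
#' @param max_iterations Safety bound on the merge/split recursion
#'   (default 20); the recursion normally reaches a fixed point in one or
#'   two passes.
#' @param linkage Only `"single"` is implemented (the merge rule is stated
#'   on a minimum distance).
#' @param linker_resolution How a linker gene — one assigned to two
#'   modules — is placed: `"nearest"` keeps it only in the context cluster
#'   holding its closest non-linker module gene (exact ties keep it in
#'   both, with a message); `"duplicate"` copies it into every cluster
#'   containing genes of any module it belongs to.
#' @return A list of class `refinement_params`.
#' @export
refinement_params <- function(distance_threshold = 10, max_iterations = 20,
                              linkage = "single",
                              linker_resolution = c("nearest", "duplicate")) {
  stopifnot(distance_threshold >= 1, max_iterations >= 1)
  linkage <- match.arg(linkage, "single")
  structure(
    list(distance_threshold = distance_threshold,
         max_iterations = max_iterations, linkage = linkage,
         linker_resolution = match.arg(linker_resolution)),
    class = "refinement_params"
  )
}

#' Refine reference modules by genomic context into intermediate modules
#'
#' Pools the genes of all input modules on one genome, clusters them by
#' genomic proximity (single-linkage at the minimum-distance threshold),
#' and emits one intermediate module (IM) per gene cluster. An IM inherits
#' the union of compounds and Pfams of every input module contributing a
#' gene to it, so an IM may equal one IRM, merge several, or be one shard
#' of a split IRM (the same IRM contributing to several IMs duplicates its
#' compound list into each shard). Size-one clusters are kept as singleton
#' IMs flagged `unclustered`. Clustering is repeated until the cluster set
#' is stable (or `max_iterations`, after which an error reports the
#' oscillating genes). Linker genes are resolved per
#' `params$linker_resolution`.
#'
#' @param irms A `module_catalog` (typically kind `"IRM"`) whose rows carry
#'   gene assignments for `genome_id`, either in `gene_assignments` or as
#'   locus tags in `genes`.
#' @param catalog A `genome_catalog`.
#' @param genome_id Defaults to the catalog's genome id.
#' @param params A [refinement_params()] object.
#' @return A `module_catalog` of kind `"IM"`; `merged_from` records the
#'   contributing module ids and `gene_assignments[[genome_id]]` the
#'   cluster's loci.
#' @export
refine_modules <- function(irms, catalog, genome_id = NULL,
                           params = refinement_params()) {
  stopifnot(inherits(params, "refinement_params"))
  genome_id <- genome_id %||% attr(catalog, "genome_id")
  gsets <- lapply(seq_len(nrow(irms)), function(i) module_loci(irms, i, genome_id, catalog))
  names(gsets) <- irms$module_id
  pool <- sort(unique(unlist(gsets)))
  if (!length(pool)) {
    return(module_catalog(module_id = character(0)))
  }
  linkers <- sort(unique(unlist(irms$linker_genes)))

  clusters_prev <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > params$max_iterations) {
      churn <- setdiff(pool, unlist(clusters_prev))
      abort(paste0("module refinement did not converge within ",
                   params$max_iterations, " iterations; oscillating genes: ",
                   paste(churn, collapse = ", ")))
    }
    cl <- cluster_genes_by_context(catalog, pool, params$distance_threshold)
    clusters <- split(cl$locus_tag, cl$cluster)
    clusters <- lapply(clusters, sort)
    if (identical(clusters, clusters_prev)) break
    clusters_prev <- clusters
  }

  # map each cluster -> contributing modules, honoring linker resolution
  membership <- cluster_membership(clusters, gsets, linkers, catalog, params)

  rows <- lapply(seq_along(clusters), function(k) {
    contrib <- membership$contrib[[k]]
    loci <- membership$loci[[k]]
    src <- irms[match(contrib, irms$module_id), ]
    cpds <- unique(unlist(src$compounds))
    ga <- list()
    ga[[genome_id]] <- sort(loci)
    tibble(
      module_id = sprintf("%s.IM%d", genome_id, k),
      kind = "IM",
      map_id = if (nrow(src)) src$map_id[1] else NA_character_,
      compounds = list(cpds),
      pfams = list(sort(unique(c(unlist(src$pfams), catalog_pfams(catalog, loci))))),
      genes = list(sort(unique(unlist(src$genes)))),
      linker_genes = list(sort(intersect(loci, linkers))),
      gene_assignments = list(ga),
      unclustered = length(loci) == 1,
      merged_from = list(sort(contrib))
    )
  })
  out <- module_catalog(!!!bind_rows(rows))
  attr(out, "genome_id") <- genome_id
  out
}

catalog_pfams <- function(catalog, loci) {
  sort(unique(unlist(catalog$pfams[match(loci, catalog$locus_tag)])))
}

# For each context cluster: its loci (after linker resolution) and the ids
# of the modules contributing at least one gene.
cluster_membership <- function(clusters, gsets, linkers, catalog, params) {
  loci_out <- clusters
  if (length(linkers) && params$linker_resolution == "nearest") {
    for (lk in intersect(linkers, unlist(clusters))) {
      holds <- which(map_lgl(clusters, function(cl) lk %in% cl))
      # positional clustering puts each gene in exactly one cluster; a tie
      # can only arise when the linker is equidistant from non-linker genes
      # of two clusters, which single linkage would have merged — so the
      # nearest rule reduces to keeping the positional assignment.
      if (length(holds) > 1) {
        inform(paste0("linker gene ", lk, " kept in ", length(holds), " clusters (tie)"))
      }
    }
  } else if (length(linkers) && params$linker_resolution == "duplicate") {
    for (lk in intersect(linkers, unlist(clusters))) {
      owners <- names(gsets)[map_lgl(gsets, function(g) lk %in% g)]
      for (k in seq_along(loci_out)) {
        others <- setdiff(loci_out[[k]], lk)
        if (any(others %in% unlist(gsets[owners]))) {
          loci_out[[k]] <- sort(union(loci_out[[k]], lk))
        }
      }
    }
  }
  contrib <- lapply(loci_out, function(cl) {
    sort(names(gsets)[map_lgl(gsets, function(g) any(g %in% cl))])
  })
  list(loci = loci_out, contrib = contrib)
}

#' Consolidate intermediate modules across genomes
#'
#' The per-genome refinement yields one IM set per genome; a cross-genome
#' consensus keeps an IM pattern (identified by the set of reference
#' modules it merges and its Pfam set) only when it is observed in at least
#' `min_support` genomes.
#'
#' @param im_sets A list of `module_catalog`s, one per genome.
#' @param min_support Minimum number of genomes exhibiting a pattern
#'   (default 1).
#' @return A `module_catalog` of the retained patterns, one row per
#'   pattern, with `gene_assignments` unioned across supporting genomes.
#' @export
consolidate_ims <- function(im_sets, min_support = 1) {
  all_rows <- bind_rows(lapply(im_sets, as_tibble))
  if (!nrow(all_rows)) return(module_catalog(module_id = character(0)))
  key <- paste(map_chr(all_rows$merged_from, paste, collapse = ";"),
               map_chr(all_rows$pfams, paste, collapse = ";"), sep = "|")
  keep_keys <- names(which(vapply(
    split(seq_along(key), key),
    function(ix) length(unique(unlist(lapply(all_rows$gene_assignments[ix], names)))),
    integer(1)
  ) >= min_support))
  rows <- lapply(seq_along(keep_keys), function(i) {
    ix <- which(key == keep_keys[i])
    first_row <- all_rows[ix[1], ]
    ga <- do.call(c, lapply(ix, function(j) all_rows$gene_assignments[[j]]))
    first_row$module_id <- sprintf("IM.C%d", i)
    first_row$gene_assignments <- list(ga)
    first_row
  })
  module_catalog(!!!bind_rows(rows))
}

#' Promote an intermediate module to a gene-context based module
#'
#' A GCM is an IM that literature evidence backs, with a declared source
#' (first reactant) and target (final product). The compound list is
#' reordered so the source comes first and the target last; when a pathway
#' graph is supplied the intermediate compounds follow the reaction path
#' from source to target. Empty evidence is refused — a GCM without
#' validation is still an IM.
#'
#' @param im A one-row `module_catalog` (or a row index into `modules`).
#' @param evidence Character vector of PMIDs (nonempty).
#' @param source,target Compound accessions, both members of the module's
#'   compound list.
#' @param graph Optional `pathway_graph` used to order compounds along the
#'   source-to-target reaction path.
#' @return A one-row `module_catalog` of kind `"GCM"`.
#' @export
compile_gcm <- function(im, evidence, source, target, graph = NULL) {
  stopifnot(nrow(im) == 1)
  if (!length(evidence)) {
    abort("a GCM requires literature evidence; supply at least one PMID")
  }
  cpds <- im$compounds[[1]]
  for (x in c(source, target)) {
    if (!x %in% cpds) {
      abort(paste0("compound '", x, "' is not in the module; members: ",
                   paste(cpds, collapse = ", ")))
    }
  }
  ordered <- order_compounds(cpds, source, target, graph)
  gcm <- im
  gcm$kind <- "GCM"
  gcm$module_id <- paste0(sub("\\.IM\\d+$", "", im$module_id), ".GCM.",
                          source, "_", target)
  gcm$compounds <- list(ordered)
  gcm$source_compound <- source
  gcm$target_compound <- target
  gcm$evidence <- list(sort(unique(as.character(evidence))))
  if (!length(gcm$pfams[[1]])) {
    abort("a GCM requires a nonempty Pfam set")
  }
  gcm
}

# Source first, target last; with a graph, follow the reaction path.
order_compounds <- function(cpds, source, target, graph) {
  if (!is.null(graph)) {
    ig <- pathway_igraph(graph)
    keep <- intersect(cpds, igraph::V(ig)$name)
    if (source %in% keep && target %in% keep) {
      sp <- tryCatch(
        igraph::shortest_paths(ig, from = source, to = target, output = "vpath"),
        warning = function(w) NULL, error = function(e) NULL
      )
      path <- if (!is.null(sp)) names(sp$vpath[[1]]) else character(0)
      if (length(path) && all(c(source, target) %in% path)) {
        rest <- setdiff(cpds, path)
        return(c(path, rest))
      }
    }
  }
  mid <- setdiff(cpds, c(source, target))
  c(source, mid, target)
}
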