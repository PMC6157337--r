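#' Gene-rank distance between two loci
#'
#' Genomic distance in gene-rank (intervening-gene) units, the unit all
#' clustering and window logic uses: on the same replicon it is
#' `|rank(a) - rank(b)|`, corrected to the shorter way around,
#' `min(d, n - d)`, on a circular replicon of `n` genes. Loci on different
#' replicons are infinitely far apart (`Inf`) — genomic context never spans
#' replicons.
#'
#' @param catalog A `genome_catalog`.
#' @param a,b Locus tags present in the catalog.
#' @return A number (0 for identical loci) or `Inf`.
#' @export
gene_distance <- function(catalog, a, b) {
  ia <- match(a, catalog$locus_tag)
  ib <- match(b, catalog$locus_tag)
  if (is.na(ia) || is.na(ib)) {
    abort(paste0("unknown locus tag: ", paste(c(a, b)[is.na(c(ia, ib))], collapse = ", ")))
  }
  if (catalog$replicon_id[ia] != catalog$replicon_id[ib]) return(Inf)
  d <- abs(catalog$rank[ia] - catalog$rank[ib])
  circ <- attr(catalog, "circular")[catalog$replicon_id[ia]]
  if (isTRUE(unname(circ))) {
    n <- sum(catalog$replicon_id == catalog$replicon_id[ia])
    d <- min(d, n - d)
  }
  d
}

#' Inter- and intra-module gene distances on one genome
#'
#' Every pair of modules (all n-choose-2 combinations) is scored by the
#' minimum gene-rank distance over cross-module gene pairs; each module
#' also gets an intra-module score, the largest single-linkage gap inside
#' its own gene set (0 for a single gene, `Inf` when its genes straddle
#' replicons). Average distances are reported alongside as diagnostics;
#' merging decisions use the minimum.
#'
#' @param catalog A `genome_catalog`.
#' @param modules A `module_catalog`.
#' @param genome_id Genome whose gene assignments to use; defaults to the
#'   catalog's.
#' @return A list with `inter` (tibble: `module_a`, `module_b`,
#'   `min_distance`, `mean_distance`) and `intra` (tibble: `module_id`,
#'   `n_genes`, `max_gap`, `absent`).
#' @export
pairwise_module_distances <- function(catalog, modules, genome_id = NULL) {
  genome_id <- genome_id %||% attr(catalog, "genome_id")
  gsets <- lapply(seq_len(nrow(modules)), function(i) {
    module_loci(modules, i, genome_id, catalog)
  })
  names(gsets) <- modules$module_id
  ids <- modules$module_id
  inter <- if (length(ids) >= 2) {
    pairs <- utils::combn(seq_along(ids), 2)
    bind_rows(lapply(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      if (!length(gsets[[i]]) || !length(gsets[[j]])) {
        return(tibble(module_a = ids[i], module_b = ids[j],
                      min_distance = Inf, mean_distance = Inf))
      }
      d <- vapply(gsets[[i]], function(a)
        vapply(gsets[[j]], function(b) gene_distance(catalog, a, b), numeric(1)),
        numeric(length(gsets[[j]])))
      tibble(module_a = ids[i], module_b = ids[j],
             min_distance = min(d), mean_distance = mean(d))
    }))
  } else {
    tibble(module_a = character(), module_b = character(),
           min_distance = numeric(), mean_distance = numeric())
  }
  intra <- bind_rows(lapply(seq_along(ids), function(i) {
    g <- gsets[[i]]
    tibble(module_id = ids[i], n_genes = length(g),
           max_gap = intra_max_gap(catalog, g), absent = length(g) == 0)
  }))
  list(inter = inter, intra = intra)
}

module_loci <- function(modules, i, genome_id, catalog) {
  ga <- modules$gene_assignments[[i]]
  loci <- if (!is.null(ga[[genome_id]])) ga[[genome_id]] else
    intersect(modules$genes[[i]], catalog$locus_tag)
  sort(unique(loci))
}

# Largest single-linkage gap: the maximum edge in the path connecting the
# sorted ranks (Inf across replicons); 0 for <=1 gene.
intra_max_gap <- function(catalog, loci) {
  if (length(loci) <= 1) return(0)
  idx <- match(loci, catalog$locus_tag)
  reps <- catalog$replicon_id[idx]
  if (length(unique(reps)) > 1) return(Inf)
  r <- sort(catalog$rank[idx])
  gaps <- diff(r)
  circ <- attr(catalog, "circular")[reps[1]]
  if (isTRUE(unname(circ)) && length(r) >= 2) {
    n <- sum(catalog$replicon_id == reps[1])
    wrap <- n - (max(r) - min(r))
    # on a circle, single-linkage drops the largest arc gap
    gaps <- sort(c(gaps, wrap), decreasing = TRUE)[-1]
    if (!length(gaps)) gaps <- 0
  }
  max(gaps)
}

#' Cluster genes by genomic proximity (single linkage)
#'
#' Partitions a gene set into single-linkage connected components: two
#' genes share a cluster iff a chain of genes from the set joins them with
#' every step at most `distance_threshold` gene-rank units. On circular
#' replicons the wrap-around step counts. Clusters are numbered by replicon
#' then leftmost rank, deterministically.
#'
#' @param catalog A `genome_catalog`.
#' @param genes Character vector of locus tags (must exist in the catalog).
#' @param distance_threshold Maximum chaining step, in intervening-gene
#'   units (default 10 — the minimum-distance merge score).
#' @return A tibble with columns `cluster` (integer), `replicon_id`,
#'   `rank`, `locus_tag`, ordered by cluster then rank.
#' @export
cluster_genes_by_context <- function(catalog, genes, distance_threshold = 10) {
  genes <- unique(genes)
  if (!length(genes)) {
    return(tibble(cluster = integer(), replicon_id = character(),
                  rank = integer(), locus_tag = character()))
  }
  idx <- match(genes, catalog$locus_tag)
  if (anyNA(idx)) {
    abort(paste0("unknown locus tag(s): ", paste(genes[is.na(idx)], collapse = ", ")))
  }
  df <- tibble(replicon_id = catalog$replicon_id[idx],
               rank = catalog$rank[idx], locus_tag = genes) |>
    arrange(.data$replicon_id, .data$rank)
  out <- list()
  for (rep_id in unique(df$replicon_id)) {
    sub <- df[df$replicon_id == rep_id, ]
    n_rep <- sum(catalog$replicon_id == rep_id)
    circ <- isTRUE(unname(attr(catalog, "circular")[rep_id]))
    grp <- cumsum(c(1, diff(sub$rank) > distance_threshold))
    if (circ && max(grp) > 1) {
      wrap <- n_rep - (max(sub$rank) - min(sub$rank))
      if (wrap <= distance_threshold) {
        grp[grp == max(grp)] <- 1  # close the circle: last joins first
      }
    }
    sub$cluster_key <- grp
    out[[rep_id]] <- sub
  }
  res <- bind_rows(out)
  # renumber clusters by replicon then leftmost rank
  lead <- res |>
    group_by(.data$replicon_id, .data$cluster_key) |>
    summarise(lead_rank = min(.data$rank), .groups = "drop") |>
    arrange(.data$replicon_id, .data$lead_rank) |>
    mutate(cluster = row_number())
  res |>
    left_join(lead, by = c("replicon_id", "cluster_key")) |>
    select("cluster", "replicon_id", "rank", "locus_tag") |>
    arrange(.data$cluster, .data$rank)
}
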