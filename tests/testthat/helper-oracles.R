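# Independent oracles, written against the plain definitions and kept free
# of the implementation paths they check.

# Exhaustive window scan: every contiguous interval of length <= 2w+1
# (wrapping on circular replicons), qualifying intervals trimmed to their
# matched genes and merged into maximal runs. Returns a list with `present`
# (data frame of merged calls) and `best_coverage`.
oracle_scan <- function(catalog, gcm_pfams, window_size, cutoff) {
  gcm_pfams <- sort(unique(gcm_pfams))
  npf <- length(gcm_pfams)
  circ_map <- attr(catalog, "circular")
  best <- 0
  present <- list()
  for (rep_id in unique(catalog$replicon_id)) {
    sub <- catalog[catalog$replicon_id == rep_id, ]
    sub <- sub[order(sub$rank), ]
    n <- nrow(sub)
    circular <- isTRUE(unname(circ_map[rep_id]))
    maxlen <- min(2 * window_size + 1, n)
    matched_per_gene <- lapply(sub$pfams, function(p) intersect(gcm_pfams, p))
    covered <- rep(FALSE, n)
    any_qual <- FALSE
    for (len in 1:maxlen) {
      starts <- if (circular && n > maxlen) 1:n else 1:(n - len + 1)
      for (s in starts) {
        pos <- ((s - 1) + 0:(len - 1)) %% n + 1
        matched <- unique(unlist(matched_per_gene[pos]))
        cov <- 100 * length(matched) / npf
        if (cov > best) best <- cov
        if (length(matched) && cov >= cutoff) {
          any_qual <- TRUE
          hits <- which(lengths(matched_per_gene[pos]) > 0)
          covered[pos[min(hits):max(hits)]] <- TRUE
        }
      }
    }
    if (any_qual) {
      idx <- which(covered)
      breaks <- which(diff(idx) > 1)
      starts_i <- c(1, breaks + 1)
      ends_i <- c(breaks, length(idx))
      runs <- lapply(seq_along(starts_i), function(k) idx[starts_i[k]:ends_i[k]])
      if (circular && length(runs) > 1 && covered[1] && covered[n]) {
        runs[[1]] <- c(runs[[length(runs)]], runs[[1]])
        runs <- runs[-length(runs)]
      }
      for (run in runs) {
        # best coverage among qualifying intervals inside this run
        run_best <- 0
        for (len in 1:maxlen) {
          starts <- if (circular && n > maxlen) 1:n else 1:(n - len + 1)
          for (s in starts) {
            pos <- ((s - 1) + 0:(len - 1)) %% n + 1
            matched <- unique(unlist(matched_per_gene[pos]))
            cov <- 100 * length(matched) / npf
            if (length(matched) && cov >= cutoff) {
              hits <- which(lengths(matched_per_gene[pos]) > 0)
              if (any(pos[min(hits):max(hits)] %in% run) && cov > run_best) run_best <- cov
            }
          }
        }
        present[[length(present) + 1]] <- data.frame(
          replicon_id = rep_id,
          start_rank = sub$rank[run[1]],
          end_rank = sub$rank[run[length(run)]],
          coverage_percent = run_best
        )
      }
    }
  }
  list(
    present = if (length(present)) do.call(rbind, present) else
      data.frame(replicon_id = character(0), start_rank = integer(0),
                 end_rank = integer(0), coverage_percent = numeric(0)),
    best_coverage = best
  )
}

# O(n^2) single-linkage connected components over gene-rank distance,
# straight from the catalog columns (union-find).
oracle_single_linkage <- function(catalog, genes, threshold) {
  idx <- match(genes, catalog$locus_tag)
  rep_ids <- catalog$replicon_id[idx]
  ranks <- catalog$rank[idx]
  circ_map <- attr(catalog, "circular")
  n_by_rep <- table(catalog$replicon_id)
  m <- length(genes)
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (rep_ids[i] != rep_ids[j]) next
      d <- abs(ranks[i] - ranks[j])
      if (isTRUE(unname(circ_map[rep_ids[i]]))) {
        nr <- as.integer(n_by_rep[rep_ids[i]])
        d <- min(d, nr - d)
      }
      if (d <= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  unname(lapply(split(genes, roots), sort))
}

# Exhaustive-partition maximum modularity, evaluated with igraph's own
# modularity function on the collapsed undirected weighted graph.
oracle_max_modularity <- function(graph) {
  nodes <- sort(graph$nodes$compound_id[!graph$nodes$external])
  e <- graph$edges[!graph$edges$self_loop &
                     graph$edges$substrate_id %in% nodes &
                     graph$edges$product_id %in% nodes, ]
  if (!nrow(e)) return(0)
  key <- paste(pmin(e$substrate_id, e$product_id),
               pmax(e$substrate_id, e$product_id))
  tab <- table(key)
  ab <- strsplit(names(tab), " ", fixed = TRUE)
  ig <- igraph::graph_from_data_frame(
    data.frame(from = vapply(ab, `[`, character(1), 1),
               to = vapply(ab, `[`, character(1), 2),
               weight = as.numeric(tab)),
    directed = FALSE, vertices = data.frame(name = nodes)
  )
  n <- length(nodes)
  best <- -Inf
  rg <- integer(n)
  rg[1] <- 1L
  recurse <- function(i, maxlab) {
    if (i > n) {
      q <- igraph::modularity(ig, membership = rg,
                              weights = igraph::E(ig)$weight)
      if (q > best) best <<- q
      return(invisible())
    }
    for (l in seq_len(maxlab + 1L)) {
      rg[i] <<- l
      recurse(i + 1L, max(maxlab, l))
    }
  }
  if (n >= 2) recurse(2L, 1L) else best <- 0
  best
}

# Modularity of a detect_communities() partition, via igraph.
igraph_modularity_of <- function(graph, partition) {
  nodes <- sort(graph$nodes$compound_id[!graph$nodes$external])
  e <- graph$edges[!graph$edges$self_loop &
                     graph$edges$substrate_id %in% nodes &
                     graph$edges$product_id %in% nodes, ]
  if (!nrow(e)) return(0)
  key <- paste(pmin(e$substrate_id, e$product_id),
               pmax(e$substrate_id, e$product_id))
  tab <- table(key)
  ab <- strsplit(names(tab), " ", fixed = TRUE)
  ig <- igraph::graph_from_data_frame(
    data.frame(from = vapply(ab, `[`, character(1), 1),
               to = vapply(ab, `[`, character(1), 2),
               weight = as.numeric(tab)),
    directed = FALSE, vertices = data.frame(name = nodes)
  )
  mem <- partition$community[match(igraph::V(ig)$name, partition$compound_id)]
  igraph::modularity(ig, membership = mem, weights = igraph::E(ig)$weight)
}

# Brute-force membership count consensus.
oracle_consensus <- function(hit_lists, k) {
  cand <- sort(unique(unlist(hit_lists)))
  hits <- vapply(cand, function(p) {
    sum(vapply(hit_lists, function(l) p %in% l, logical(1)))
  }, integer(1))
  cand[hits >= k]
}
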