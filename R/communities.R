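#' Partition a pathway graph into edge-connectivity communities
#'
#' Assigns every non-external compound node to exactly one community by
#' Newman–Girvan modularity. The graph is treated as undirected and simple:
#' reversible reactions count once, parallel reactions between the same
#' compound pair are collapsed with weight equal to their multiplicity, and
#' self-loops are ignored. The result is fully deterministic for a fixed
#' input: node identity, not insertion order, decides every tie.
#'
#' Two search strategies are available under `method = "modularity"`
#' (the default): graphs with at most `exact_max_nodes` non-external nodes
#' are solved exactly, by enumerating all set partitions (restricted-growth
#' strings over lexicographically sorted node ids) and keeping the first
#' partition attaining the maximum modularity — metabolic map graphs pruned
#' of external links are frequently this small, and exactness at small
#' order is what makes module boundaries reproducible. Larger graphs fall
#' back to greedy agglomeration (Clauset–Newman–Moore style): repeatedly
#' merge the adjacent community pair with the largest modularity gain,
#' breaking ties lexicographically on the smallest member ids, until no
#' merge improves modularity. `method = "edge_betweenness"` selects
#' Girvan–Newman divisive clustering (via igraph) cut at the
#' maximum-modularity level.
#'
#' Disconnected singleton nodes form their own communities. Labels are
#' contiguous integers ordered by each community's lexicographically
#' smallest member.
#'
#' @param graph A `pathway_graph`.
#' @param method `"modularity"` (exact below `exact_max_nodes`, greedy
#'   above) or `"edge_betweenness"`.
#' @param seed Unused by the deterministic searches; accepted so callers can
#'   treat all partitioners uniformly.
#' @param exact_max_nodes Largest node count solved by exhaustive partition
#'   enumeration; Bell(9) = 21,147 partitions keeps the default of 9 cheap.
#' @return A tibble with columns `compound_id` and `community` (integer).
#' @examples
#' g <- parse_kgml(make_man_suite()$kgml)
#' detect_communities(g)
#' @export
detect_communities <- function(graph, method = c("modularity", "edge_betweenness"),
                               seed = 1L, exact_max_nodes = 9L) {
  stopifnot(inherits(graph, "pathway_graph"))
  method <- match.arg(method)
  nodes <- sort(graph$nodes$compound_id[!graph$nodes$external])
  if (!length(nodes)) {
    return(tibble(compound_id = character(), community = integer()))
  }
  el <- collapse_edges(graph, nodes)

  labels <- if (method == "edge_betweenness") {
    partition_edge_betweenness(el, nodes)
  } else if (length(nodes) <= exact_max_nodes) {
    partition_exact(el, nodes)
  } else {
    partition_greedy(el, nodes)
  }
  # splitting a community into its connected components never lowers
  # modularity; it also keeps isolated nodes out of foreign communities
  labels <- split_disconnected(el, labels, nodes)
  relabel_contiguous(tibble(compound_id = nodes, community = labels))
}

# Undirected simple weighted edge table over the given nodes.
collapse_edges <- function(graph, nodes) {
  e <- filter(graph$edges, !.data$self_loop,
              .data$substrate_id %in% nodes, .data$product_id %in% nodes)
  if (!nrow(e)) {
    return(tibble(a = character(), b = character(), w = numeric()))
  }
  tibble(a = pmin(e$substrate_id, e$product_id),
         b = pmax(e$substrate_id, e$product_id)) |>
    dplyr::count(.data$a, .data$b, name = "w") |>
    mutate(w = as.numeric(.data$w))
}

# Weighted modularity of a labeling (named by node id).
modularity_of <- function(el, labels, nodes) {
  m <- sum(el$w)
  if (m == 0) return(0)
  deg <- node_strengths(el, nodes)
  win <- sum(el$w[labels[el$a] == labels[el$b]])
  dc <- tapply(deg, labels[nodes], sum)
  win / m - sum(dc^2) / (4 * m^2)
}

node_strengths <- function(el, nodes) {
  deg <- setNames(numeric(length(nodes)), nodes)
  if (nrow(el)) {
    sa <- rowsum(el$w, el$a)
    sb <- rowsum(el$w, el$b)
    deg[rownames(sa)] <- deg[rownames(sa)] + sa[, 1]
    deg[rownames(sb)] <- deg[rownames(sb)] + sb[, 1]
  }
  deg
}

# Exact maximization: canonical restricted-growth-string enumeration; the
# first partition reaching the maximum wins, which makes ties deterministic.
partition_exact <- function(el, nodes) {
  n <- length(nodes)
  m <- sum(el$w)
  if (m == 0 || n == 1) return(setNames(seq_len(n), nodes))
  ia <- match(el$a, nodes)
  ib <- match(el$b, nodes)
  w <- el$w
  deg <- unname(node_strengths(el, nodes))
  best_q <- -Inf
  best <- rep(1L, n)
  rg <- integer(n)
  rg[1] <- 1L
  recurse <- function(i, maxlab) {
    if (i > n) {
      win <- sum(w[rg[ia] == rg[ib]])
      dc <- rowsum(deg, rg)
      q <- win / m - sum(dc^2) / (4 * m^2)
      if (q > best_q + 1e-12) {
        best_q <<- q
        best <<- rg
      }
      return(invisible())
    }
    for (l in seq_len(maxlab + 1L)) {
      rg[i] <<- l
      recurse(i + 1L, max(maxlab, l))
    }
  }
  recurse(2L, 1L)
  setNames(best, nodes)
}

# Greedy CNM-style agglomeration with lexicographic tie-breaking.
partition_greedy <- function(el, nodes) {
  labels <- setNames(seq_along(nodes), nodes)
  repeat {
    coms <- split(nodes, labels[nodes])
    if (length(coms) <= 1) break
    q0 <- modularity_of(el, labels, nodes)
    best_lab <- NULL
    best_dq <- 1e-12
    best_key <- NULL
    keys <- names(coms)
    for (i in seq_len(length(keys) - 1L)) {
      for (j in seq(i + 1L, length(keys))) {
        ma <- coms[[keys[i]]]
        mb <- coms[[keys[j]]]
        touching <- any((el$a %in% ma & el$b %in% mb) | (el$a %in% mb & el$b %in% ma))
        if (!touching) next
        lab2 <- labels
        lab2[mb] <- labels[[ma[1]]]
        dq <- modularity_of(el, lab2, nodes) - q0
        key <- paste(sort(c(min(ma), min(mb))), collapse = "\r")
        if (dq > best_dq + 1e-12 ||
            (abs(dq - best_dq) <= 1e-12 && !is.null(best_lab) && key < best_key)) {
          best_lab <- lab2
          best_dq <- dq
          best_key <- key
        }
      }
    }
    if (is.null(best_lab)) break
    labels <- best_lab
  }
  labels
}

# Replace each community label by one label per connected component of the
# community-induced subgraph (union-find over intra-community edges).
split_disconnected <- function(el, labels, nodes) {
  parent <- setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[[i]] != i) i <- parent[[i]]
    i
  }
  for (i in seq_len(nrow(el))) {
    if (labels[[el$a[i]]] == labels[[el$b[i]]]) {
      ra <- find(match(el$a[i], nodes))
      rb <- find(match(el$b[i], nodes))
      if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  setNames(match(roots, unique(roots)), nodes)
}

partition_edge_betweenness <- function(el, nodes) {
  if (!nrow(el)) return(setNames(seq_along(nodes), nodes))
  ig <- igraph::graph_from_data_frame(
    data.frame(from = el$a, to = el$b, weight = el$w),
    directed = FALSE, vertices = data.frame(name = nodes)
  )
  # igraph notes it cuts the dendrogram at the best-modularity level;
  # that is exactly the intended behavior here
  cl <- suppressWarnings(igraph::cluster_edge_betweenness(ig, weights = NULL))
  setNames(as.integer(igraph::membership(cl)), igraph::V(ig)$name)
}

# Relabel communities as contiguous integers ordered by smallest member id.
relabel_contiguous <- function(partition) {
  firsts <- partition |>
    group_by(.data$community) |>
    summarise(lead = min(.data$compound_id), .groups = "drop") |>
    arrange(.data$lead)
  remap <- setNames(seq_len(nrow(firsts)), firsts$community)
  partition |>
    mutate(community = as.integer(remap[as.character(.data$community)])) |>
    arrange(.data$community, .data$compound_id)
}
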