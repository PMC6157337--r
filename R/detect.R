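#' Detection parameters
#'
#' @param window_size Number of flanking genes on each side of an anchor
#'   gene; a window therefore spans `2 * window_size + 1` consecutive genes
#'   (default 5).
#' @param cutoff_percent Minimum percentage of the module's distinct Pfams
#'   that must be present inside one window for a presence call, in
#'   `(0, 100]` (default 100). Coverage exactly equal to the cutoff passes.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(window_size = 5, cutoff_percent = 100) {
  if (!is.numeric(window_size) || length(window_size) != 1 || window_size < 0 ||
      window_size != round(window_size)) {
    abort("`window_size` must be a single non-negative integer")
  }
  if (!is.numeric(cutoff_percent) || length(cutoff_percent) != 1 ||
      cutoff_percent <= 0 || cutoff_percent > 100) {
    abort("`cutoff_percent` must lie in (0, 100]")
  }
  structure(list(window_size = as.integer(window_size),
                 cutoff_percent = as.numeric(cutoff_percent)),
            class = "detection_params")
}

#' Scan a genome for windowed co-occurrence of a module's domains
#'
#' Slides a window of `2 * window_size + 1` consecutive genes along every
#' replicon (wrapping on circular replicons, clipped at linear ends; a
#' replicon shorter than the window is taken whole) and evaluates every
#' window position containing at least one anchor — a gene carrying at
#' least one of the module's Pfams. Window coverage is the percentage of
#' the module's *distinct* Pfams represented by at least one gene in the
#' window: a Pfam on several genes counts once, and one gene carrying
#' several module Pfams contributes all of them. Strand is recorded but
#' ignored (operons are usually strand-coherent, but strandedness is not
#' imposed).
#'
#' Windows whose coverage reaches `cutoff_percent` qualify; each
#' qualifying window is trimmed to the span of its matched
#' (module-domain-bearing) genes, overlapping trimmed spans are merged
#' into maximal calls, and each call reports the best coverage among its
#' constituent windows. When no window qualifies, the single
#' best-coverage window is still reported with `present = FALSE`, so the
#' extent of partial domain presence is visible; a genome carrying none
#' of the module's Pfams yields one zero-coverage row.
#'
#' @param catalog A `genome_catalog`.
#' @param gcm A one-row `module_catalog` with a nonempty Pfam set.
#' @param params A [detection_params()] object.
#' @return A `gcm_calls` tibble: `gcm_id`, `genome_id`, `replicon_id`,
#'   `start_rank`, `end_rank` (inclusive; `end_rank < start_rank` encodes
#'   a circular wrap), `start_bp`, `end_bp`, `matched_pfams` and
#'   `missing_pfams` list-columns, `coverage_percent`, `present`,
#'   sorted by replicon then start rank.
#' @examples
#' fx <- make_man_suite()
#' scan_genome(fx$ecoli, fx$gcm, detection_params(5, 100))
#' scan_genome(fx$btheta, fx$gcm, detection_params(5, 25))
#' @export
scan_genome <- function(catalog, gcm, params = detection_params()) {
  stopifnot(inherits(params, "detection_params"))
  if (inherits(gcm, "module_catalog") || is.data.frame(gcm)) {
    stopifnot(nrow(gcm) == 1)
    gcm_id <- gcm$module_id[1]
    gcm_pfams <- sort(unique(gcm$pfams[[1]]))
  } else {
    abort("`gcm` must be a one-row module catalog")
  }
  if (!length(gcm_pfams)) abort("the module's Pfam set is empty")
  genome_id <- attr(catalog, "genome_id")
  empty <- new_gcm_calls(tibble(
    gcm_id = character(), genome_id = character(), replicon_id = character(),
    start_rank = integer(), end_rank = integer(), start_bp = integer(),
    end_bp = integer(), matched_pfams = list(), missing_pfams = list(),
    coverage_percent = numeric(), present = logical()
  ))
  if (!nrow(catalog)) return(empty)

  present_calls <- list()
  best_window <- NULL  # best non-qualifying fallback across the genome
  for (rep_id in unique(catalog$replicon_id)) {
    sub <- catalog[catalog$replicon_id == rep_id, ]
    sub <- sub[order(sub$rank), ]
    res <- scan_replicon(sub, gcm_pfams, params,
                         circular = isTRUE(unname(attr(catalog, "circular")[rep_id])))
    if (!is.null(res$calls)) present_calls[[rep_id]] <- res$calls
    if (!is.null(res$best) &&
        (is.null(best_window) || res$best$coverage > best_window$coverage)) {
      best_window <- res$best
    }
  }

  rows <- bind_rows(present_calls)
  if (!nrow(rows)) {
    if (is.null(best_window)) {
      rows <- tibble(
        replicon_id = NA_character_, start_rank = NA_integer_,
        end_rank = NA_integer_, start_bp = NA_integer_, end_bp = NA_integer_,
        matched_pfams = list(character(0)), missing_pfams = list(gcm_pfams),
        coverage_percent = 0, present = FALSE
      )
    } else {
      rows <- tibble(
        replicon_id = best_window$replicon_id,
        start_rank = best_window$start_rank, end_rank = best_window$end_rank,
        start_bp = best_window$start_bp, end_bp = best_window$end_bp,
        matched_pfams = list(best_window$matched),
        missing_pfams = list(setdiff(gcm_pfams, best_window$matched)),
        coverage_percent = best_window$coverage, present = FALSE
      )
    }
  }
  rows <- mutate(rows, gcm_id = gcm_id, genome_id = genome_id %||% NA_character_,
                 .before = 1) |>
    arrange(.data$replicon_id, .data$start_rank)
  new_gcm_calls(select(
    rows, "gcm_id", "genome_id", "replicon_id", "start_rank", "end_rank",
    "start_bp", "end_bp", "matched_pfams", "missing_pfams",
    "coverage_percent", "present"
  ))
}

new_gcm_calls <- function(tbl) {
  class(tbl) <- c("gcm_calls", class(tibble()))
  tbl
}

# One replicon. Returns qualifying merged calls and the best single window.
scan_replicon <- function(sub, gcm_pfams, params, circular) {
  n <- nrow(sub)
  w <- params$window_size
  span <- min(2L * w + 1L, n)
  # per-gene matched module Pfams
  matched_per_gene <- lapply(sub$pfams, function(p) intersect(gcm_pfams, p))
  anchors <- which(lengths(matched_per_gene) > 0)
  if (!length(anchors)) return(list(calls = NULL, best = NULL))

  offsets <- if (circular && n > span) 0:(n - 1L) else 0:(n - span)
  n_pf <- length(gcm_pfams)
  best <- NULL
  qual_cover <- rep(FALSE, n)   # ranks covered by trimmed qualifying spans
  qual_windows <- list()
  for (s in offsets) {
    pos <- (s + 0:(span - 1L)) %% n + 1L   # row indices (1-based)
    if (!any(pos %in% anchors)) next
    matched <- unique(unlist(matched_per_gene[pos]))
    coverage <- 100 * length(matched) / n_pf
    trimmed <- pos[lengths(matched_per_gene[pos]) > 0]
    info <- list(
      replicon_id = sub$replicon_id[1],
      start_rank = sub$rank[trimmed[1]], end_rank = sub$rank[trimmed[length(trimmed)]],
      start_bp = sub$start_bp[trimmed[1]], end_bp = sub$end_bp[trimmed[length(trimmed)]],
      matched = sort(matched), coverage = coverage
    )
    if (coverage >= params$cutoff_percent) {
      # trimmed span = window positions between first and last matched gene
      first_i <- match(trimmed[1], pos)
      last_i <- match(trimmed[length(trimmed)], pos)
      qual_cover[pos[first_i:last_i]] <- TRUE
      qual_windows[[length(qual_windows) + 1L]] <-
        c(info, list(span_pos = pos[first_i:last_i]))
    }
    if (is.null(best) || coverage > best$coverage) best <- info
  }
  if (!length(qual_windows)) return(list(calls = NULL, best = best))

  runs <- covered_runs(qual_cover, circular)
  calls <- bind_rows(lapply(runs, function(run) {
    members <- keep(qual_windows, function(qw) any(qw$span_pos %in% run))
    cov <- vapply(members, function(qw) qw$coverage, numeric(1))
    top <- members[[which.max(cov)]]
    tibble(
      replicon_id = sub$replicon_id[1],
      start_rank = sub$rank[run[1]], end_rank = sub$rank[run[length(run)]],
      start_bp = sub$start_bp[run[1]], end_bp = sub$end_bp[run[length(run)]],
      matched_pfams = list(top$matched),
      missing_pfams = list(setdiff(gcm_pfams, top$matched)),
      coverage_percent = max(cov), present = TRUE
    )
  }))
  list(calls = calls, best = best)
}

# Maximal runs of TRUE positions, joining across the origin when circular.
covered_runs <- function(cover, circular) {
  n <- length(cover)
  idx <- which(cover)
  if (!length(idx)) return(list())
  breaks <- which(diff(idx) > 1)
  starts <- c(1, breaks + 1)
  ends <- c(breaks, length(idx))
  runs <- lapply(seq_along(starts), function(k) idx[starts[k]:ends[k]])
  if (circular && length(runs) > 1 && cover[1] && cover[n]) {
    runs[[1]] <- c(runs[[length(runs)]], runs[[1]])
    runs <- runs[-length(runs)]
  }
  runs
}

#' Scan a genome against every module of a pathway
#'
#' Runs [scan_genome()] for each GCM of the catalog belonging to the
#' pathway map and combines the calls into one table, together with an
#' annotated pathway graph marking each compound with the modules covering
#' it and their presence.
#'
#' @param catalog A `genome_catalog`.
#' @param modules A `module_catalog`; rows of kind `"GCM"` matching
#'   `graph$map_id` are scanned.
#' @param graph A `pathway_graph`.
#' @param params A [detection_params()] object.
#' @return A list of class `pathway_scan`: `calls` (a `gcm_calls` tibble,
#'   empty with a `status` attribute when the map has no modules),
#'   `graph` (the input graph), `params`.
#' @export
scan_pathway <- function(catalog, modules, graph, params = detection_params()) {
  stopifnot(inherits(graph, "pathway_graph"))
  gcms <- filter(as_tibble(modules), .data$kind == "GCM",
                 is.na(.data$map_id) | .data$map_id == graph$map_id)
  gcms <- module_catalog(!!!gcms)
  if (!nrow(gcms)) {
    calls <- new_gcm_calls(tibble(
      gcm_id = character(), genome_id = character(), replicon_id = character(),
      start_rank = integer(), end_rank = integer(), start_bp = integer(),
      end_bp = integer(), matched_pfams = list(), missing_pfams = list(),
      coverage_percent = numeric(), present = logical()
    ))
    attr(calls, "status") <- paste0("no GCMs cataloged for map ", graph$map_id)
    inform(attr(calls, "status"))
    return(structure(list(calls = calls, graph = graph, params = params,
                          modules = gcms),
                     class = "pathway_scan"))
  }
  calls <- bind_rows(lapply(seq_len(nrow(gcms)), function(i) {
    scan_genome(catalog, gcms[i, ], params)
  }))
  structure(list(calls = new_gcm_calls(calls), graph = graph,
                 params = params, modules = gcms),
            class = "pathway_scan")
}

#' @export
print.pathway_scan <- function(x, ...) {
  cat("<pathway_scan> ", x$graph$map_id, ": ", nrow(x$modules),
      " GCM(s), ", sum(x$calls$present), " present at window ",
      x$params$window_size, ", cutoff ", x$params$cutoff_percent, "%\n",
      sep = "")
  print(x$calls)
  invisible(x)
}

#' @export
tidy.pathway_scan <- function(x, ...) as_tibble(x$calls)

#' @export
glance.pathway_scan <- function(x, ...) {
  tibble(
    map_id = x$graph$map_id,
    n_gcms = nrow(x$modules),
    n_present = sum(x$calls$present),
    window_size = x$params$window_size,
    cutoff_percent = x$params$cutoff_percent
  )
}

#' Write detection calls as TSV
#'
#' @param calls A `gcm_calls` tibble.
#' @param path Output file; `NULL` returns the text.
#' @return The TSV text (invisibly when `path` is given).
#' @export
write_calls_tsv <- function(calls, path = NULL) {
  flat <- tibble(
    gcm_id = calls$gcm_id, genome_id = calls$genome_id,
    replicon = calls$replicon_id,
    start_rank = calls$start_rank, end_rank = calls$end_rank,
    start_bp = calls$start_bp, end_bp = calls$end_bp,
    matched_pfams = join_semi(calls$matched_pfams),
    missing_pfams = join_semi(calls$missing_pfams),
    coverage_percent = calls$coverage_percent,
    present = ifelse(calls$present, "true", "false")
  )
  lines <- c(paste(names(flat), collapse = "\t"),
             do.call(paste, c(lapply(flat, function(x) ifelse(is.na(x), "", as.character(x))), sep = "\t")))
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
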