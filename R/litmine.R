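#' Build the six literature queries for a reactant/product pair
#'
#' Constructs the six structured query strings used to seek experimental
#' support for a module converting a source reactant into a target product:
#' the reactant alone (Q1), the product alone (Q2), both together (Q3),
#' and Q3 narrowed by the keywords `bacteria` (Q4), `operon` (Q5) and
#' `"gene cluster"` (Q6). Compound synonyms (e.g. mined from KEGG) are
#' OR-expanded inside each side; multiword names are quoted. Synonym lists
#' are sorted internally, so the queries do not depend on input order.
#'
#' @param reactant,product Primary compound names (nonempty).
#' @param reactant_synonyms,product_synonyms Optional synonym vectors.
#' @param field_tag Optional search-field tag appended to every term
#'   (e.g. `"[tiab]"`); `NULL` leaves terms untagged.
#' @param module_id Optional module identifier carried along.
#' @param consensus_k Consensus threshold stored with the set (default 4).
#' @return A `query_set`: list with `module_id`, `reactant`, `product`,
#'   the synonym vectors, `queries` (character of length 6, named
#'   `q1`..`q6`) and `consensus_k`.
#' @examples
#' qs <- build_queries("D-Mannose", "GDP-L-Fucose")
#' tidy(qs)
#' @export
build_queries <- function(reactant, product, reactant_synonyms = character(0),
                          product_synonyms = character(0), field_tag = NULL,
                          module_id = NA_character_, consensus_k = 4L) {
  if (!nzchar(trimws(reactant %||% ""))) abort("`reactant` must be nonempty")
  if (!nzchar(trimws(product %||% ""))) abort("`product` must be nonempty")
  if (consensus_k < 1 || consensus_k > 6) abort("`consensus_k` must lie in 1..6")
  term <- function(x) {
    x <- trimws(x)
    q <- ifelse(grepl("\\s", x), paste0('"', x, '"'), x)
    if (!is.null(field_tag)) q <- paste0(q, field_tag)
    q
  }
  or_clause <- function(primary, synonyms) {
    names <- unique(c(primary, sort(setdiff(trimws(synonyms), primary))))
    if (length(names) == 1) return(term(names))
    paste0("(", paste(term(names), collapse = " OR "), ")")
  }
  r <- or_clause(reactant, reactant_synonyms)
  p <- or_clause(product, product_synonyms)
  q3 <- paste(r, "AND", p)
  queries <- c(
    q1 = r,
    q2 = p,
    q3 = q3,
    q4 = paste(q3, "AND", term("bacteria")),
    q5 = paste(q3, "AND", term("operon")),
    q6 = paste(q3, "AND", term("gene cluster"))
  )
  structure(
    list(module_id = module_id, reactant = reactant, product = product,
         reactant_synonyms = sort(trimws(reactant_synonyms)),
         product_synonyms = sort(trimws(product_synonyms)),
         queries = queries, consensus_k = as.integer(consensus_k)),
    class = "query_set"
  )
}

#' @export
print.query_set <- function(x, ...) {
  cat("<query_set> ", x$reactant, " -> ", x$product,
      "  (consensus >= ", x$consensus_k, " of 6)\n", sep = "")
  for (i in seq_along(x$queries)) {
    cat("  Q", i, ": ", x$queries[i], "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.query_set <- function(x, ...) {
  tibble(query = names(x$queries),
         keyword = c(NA, NA, NA, "bacteria", "operon", "gene cluster"),
         string = unname(x$queries))
}

#' Consensus PMIDs across the six query hit lists
#'
#' A PMID passes iff it appears in at least `k` of the six lists;
#' duplicates within one list count once.
#'
#' @param hit_lists A list of exactly 6 character vectors of PMIDs (lists
#'   may be empty).
#' @param k Consensus threshold in 1..6 (default 4 — "at least 4 of 6").
#' @return Sorted character vector of consensus PMIDs.
#' @export
consensus_pmids <- function(hit_lists, k = 4) {
  if (length(hit_lists) != 6) abort("`hit_lists` must contain exactly 6 lists")
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > 6) {
    abort("`k` must lie in 1..6")
  }
  uniq <- lapply(hit_lists, function(x) unique(as.character(x)))
  counts <- table(unlist(uniq))
  out <- names(counts)[counts >= k]
  if (is.null(out)) character(0) else sort(out)
}

#' Attach organisms and keyword support to consensus PMIDs
#'
#' Joins consensus PMIDs against an offline PMID-to-organism table (one row
#' per PMID/organism pair); consensus PMIDs missing from the table are
#' listed as unmapped rather than dropped. When the six hit lists are
#' supplied, each PMID also records whether it surfaced under the `operon`
#' (Q5) and `"gene cluster"` (Q6) keyword queries; a module whose evidence
#' carries neither keyword is flagged context-unverified — the genome side
#' must then establish juxtaposition on its own.
#'
#' @param consensus Character vector of consensus PMIDs.
#' @param pmid_organism_table Data frame with columns `pmid`, `organism`.
#' @param hit_lists Optional list of the 6 hit lists (for keyword support).
#' @param module_id Optional module identifier.
#' @return An `evidence_record`: list with `module_id`, `consensus_pmids`,
#'   `organisms` (tibble `pmid`, `organism`), `unmapped`,
#'   `keyword_support` (tibble `pmid`, `operon`, `gene_cluster`) and
#'   `context_verified` (any keyword support at all).
#' @export
attach_organisms <- function(consensus, pmid_organism_table,
                             hit_lists = NULL, module_id = NA_character_) {
  consensus <- sort(unique(as.character(consensus)))
  tab <- as_tibble(pmid_organism_table)
  tab$pmid <- as.character(tab$pmid)
  orgs <- tab |>
    filter(.data$pmid %in% consensus) |>
    distinct(.data$pmid, .data$organism) |>
    arrange(.data$pmid, .data$organism)
  unmapped <- setdiff(consensus, orgs$pmid)
  support <- tibble(pmid = consensus, operon = FALSE, gene_cluster = FALSE)
  if (!is.null(hit_lists)) {
    if (length(hit_lists) != 6) abort("`hit_lists` must contain exactly 6 lists")
    support$operon <- consensus %in% as.character(hit_lists[[5]])
    support$gene_cluster <- consensus %in% as.character(hit_lists[[6]])
  }
  structure(
    list(module_id = module_id, consensus_pmids = consensus,
         organisms = orgs, unmapped = unmapped, keyword_support = support,
         context_verified = any(support$operon | support$gene_cluster)),
    class = "evidence_record"
  )
}

#' @export
print.evidence_record <- function(x, ...) {
  cat("<evidence_record>", if (!is.na(x$module_id)) x$module_id else "", "\n")
  cat("  consensus PMIDs: ", length(x$consensus_pmids),
      " (", length(x$unmapped), " unmapped to organisms)\n", sep = "")
  if (!x$context_verified) {
    cat("  context-unverified in literature: no operon/'gene cluster' hits\n")
  }
  invisible(x)
}

#' @export
tidy.evidence_record <- function(x, ...) {
  left_join(x$keyword_support,
            x$organisms |> group_by(.data$pmid) |>
              summarise(organisms = paste(.data$organism, collapse = ";"),
                        .groups = "drop"),
            by = "pmid")
}

#' Read and write 6Q hit-list files
#'
#' Hit lists live as six plain-text files, one PMID per line, named
#' `<module_id>.q1.txt` .. `<module_id>.q6.txt`.
#'
#' @param dir Directory holding (or receiving) the files.
#' @param module_id Module identifier (file-name stem).
#' @param hit_lists For the writer: list of 6 PMID vectors.
#' @return `read_hitlists()` returns a list of 6 character vectors;
#'   `write_hitlists()` returns the file paths invisibly.
#' @export
read_hitlists <- function(dir, module_id) {
  paths <- file.path(dir, sprintf("%s.q%d.txt", module_id, 1:6))
  missing <- !file.exists(paths)
  if (any(missing)) {
    abort(paste0("missing hit-list file(s): ",
                 paste(basename(paths[missing]), collapse = ", ")))
  }
  lapply(paths, function(p) {
    x <- readLines(p, warn = FALSE)
    x[nzchar(trimws(x))]
  })
}

#' @rdname read_hitlists
#' @export
write_hitlists <- function(hit_lists, dir, module_id) {
  if (length(hit_lists) != 6) abort("`hit_lists` must contain exactly 6 lists")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("%s.q%d.txt", module_id, 1:6))
  for (i in 1:6) writeLines(as.character(hit_lists[[i]]), paths[i])
  invisible(paths)
}
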