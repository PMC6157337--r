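#' Read an NCBI PTT protein table
#'
#' PTT files list the protein-coding genes of one replicon: two header lines
#' (description and protein count), a column-title line, then tab-separated
#' rows `Location` (`start..end`), `Strand`, `Length`, `PID`, `Gene`,
#' `Synonym`, `Code`, `COG`, `Product`. The `Synonym` column supplies the
#' locus tag. Rows are re-sorted by start coordinate regardless of file
#' order; coordinates are 1-based inclusive.
#'
#' @param text PTT text or a file path.
#' @param replicon_id Identifier for the replicon this table describes
#'   (PTT files carry no machine-readable replicon id of their own).
#' @return A tibble of gene records: `replicon_id`, `start_bp`, `end_bp`,
#'   `strand`, `locus_tag`, `product`, and an empty `pfams` list-column.
#' @export
read_ptt <- function(text, replicon_id = "chromosome") {
  lines <- read_text_lines(text)
  if (length(lines) < 3) abort("PTT input too short: expected 2 header lines plus a column-title line")
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) {
    return(tibble(replicon_id = character(), start_bp = integer(), end_bp = integer(),
                  strand = character(), locus_tag = character(), product = character(),
                  pfams = list()))
  }
  cells <- strsplit(body, "\t", fixed = TRUE)
  loc <- vapply(cells, `[`, character(1), 1)
  ok <- grepl("^\\d+\\.\\.\\d+$", loc)
  if (any(!ok)) {
    bad <- which(!ok)[1]
    abort(sprintf("malformed Location field '%s' at PTT line %d (expected start..end)",
                  loc[bad], bad + 3L))
  }
  parts <- strsplit(loc, "..", fixed = TRUE)
  rec <- tibble(
    replicon_id = replicon_id,
    start_bp = as.integer(vapply(parts, `[`, character(1), 1)),
    end_bp = as.integer(vapply(parts, `[`, character(1), 2)),
    strand = vapply(cells, `[`, character(1), 2),
    locus_tag = vapply(cells, `[`, character(1), 6),
    product = vapply(cells, function(x) if (length(x) >= 9) x[9] else NA_character_, character(1))
  )
  if (anyDuplicated(rec$locus_tag)) {
    abort(paste0("duplicate locus_tag in PTT: ",
                 paste(unique(rec$locus_tag[duplicated(rec$locus_tag)]), collapse = ", ")))
  }
  rec <- arrange(rec, .data$start_bp, .data$end_bp, .data$locus_tag)
  rec$pfams <- rep(list(character(0)), nrow(rec))
  rec
}

#' Read HMMER3 per-domain tabular output into a gene-to-Pfam map
#'
#' Parses `domtblout` text from `hmmscan` runs of proteins against Pfam.
#' The query name is taken as the locus tag, the target accession as the
#' Pfam accession (version suffix stripped). A domain hit contributes its
#' accession iff its independent domain E-value (column 13) is at or below
#' `e_threshold`; multiple domains per gene accumulate into a set. Set
#' `e_threshold = Inf` for input already filtered upstream (e.g. by Pfam
#' gathering thresholds). Comment lines are ignored; rows whose E-value
#' does not parse are skipped with a warning.
#'
#' @param text domtblout text or a file path.
#' @param e_threshold Independent-domain E-value inclusion threshold
#'   (default `1e-5`).
#' @return A tibble with columns `locus_tag`, `pfam` (distinct pairs).
#' @export
read_domtbl <- function(text, e_threshold = 1e-5) {
  lines <- read_text_lines(text)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) return(tibble(locus_tag = character(), pfam = character()))
  cells <- strsplit(trimws(lines), "[[:space:]]+")
  short <- vapply(cells, length, integer(1)) < 13
  if (any(short)) {
    warn(sprintf("skipping %d domtblout row(s) with fewer than 13 columns", sum(short)))
    cells <- cells[!short]
  }
  acc <- strip_pfam_version(vapply(cells, `[`, character(1), 2))
  qry <- vapply(cells, `[`, character(1), 4)
  ieval <- suppressWarnings(as.numeric(vapply(cells, `[`, character(1), 13)))
  bad <- is.na(ieval)
  if (any(bad)) {
    warn(sprintf("skipping %d domtblout row(s) with unparseable i-E-value", sum(bad)))
  }
  keep <- !bad & ieval <= e_threshold & is_pfam_accession(acc)
  distinct(tibble(locus_tag = qry[keep], pfam = acc[keep])) |>
    arrange(.data$locus_tag, .data$pfam)
}

#' Assemble a genome catalog from gene records and domain hits
#'
#' The genome catalog is the ordered gene/domain map one genome contributes
#' to context analysis: per replicon, genes sorted by start coordinate and
#' given a 0-based `rank` (all window and distance logic runs in rank —
#' intervening-gene — units). Genes without any domain hit are retained
#' with an empty Pfam set so that rank distances reflect true gene spacing.
#'
#' @param genome_id Genome identifier.
#' @param genes Gene records from one or more [read_ptt()] calls
#'   (`bind_rows()` them for multi-replicon genomes).
#' @param domains Optional tibble (`locus_tag`, `pfam`) from
#'   [read_domtbl()]; locus tags absent from `genes` raise a warning.
#' @param circular Named logical, one entry per replicon id (unnamed single
#'   value recycles); default linear.
#' @return A `genome_catalog` tibble: `replicon_id`, `rank`, `start_bp`,
#'   `end_bp`, `strand`, `locus_tag`, `product`, `pfams` list-column, with
#'   attributes `genome_id` and `circular`.
#' @examples
#' fx <- make_man_suite()
#' fx$ecoli
#' @export
build_catalog <- function(genome_id, genes, domains = NULL, circular = FALSE) {
  reps <- unique(genes$replicon_id)
  circ <- normalize_circular(circular, reps)
  cat_tbl <- genes |>
    arrange(.data$replicon_id, .data$start_bp, .data$end_bp, .data$locus_tag) |>
    group_by(.data$replicon_id) |>
    mutate(rank = row_number() - 1L) |>
    ungroup() |>
    select("replicon_id", "rank", "start_bp", "end_bp", "strand",
           "locus_tag", "product", "pfams")
  if (anyDuplicated(cat_tbl$locus_tag)) {
    abort("duplicate locus_tag across replicons of one genome")
  }
  if (!is.null(domains) && nrow(domains)) {
    extra <- setdiff(unique(domains$locus_tag), cat_tbl$locus_tag)
    if (length(extra)) {
      warn(paste0("domain hits for locus tags absent from the gene table: ",
                  paste(head(extra, 5), collapse = ", "),
                  if (length(extra) > 5) " ..." else ""))
    }
    sets <- split(strip_pfam_version(domains$pfam), domains$locus_tag)
    idx <- match(cat_tbl$locus_tag, names(sets))
    cat_tbl$pfams <- lapply(seq_len(nrow(cat_tbl)), function(i) {
      if (is.na(idx[i])) character(0) else sort(unique(sets[[idx[i]]]))
    })
  }
  new_genome_catalog(cat_tbl, genome_id = genome_id, circular = circ)
}

normalize_circular <- function(circular, replicons) {
  if (is.null(names(circular))) {
    circ <- setNames(rep(as.logical(circular), length.out = length(replicons)), replicons)
  } else {
    circ <- setNames(rep(FALSE, length(replicons)), replicons)
    known <- intersect(names(circular), replicons)
    circ[known] <- circular[known]
  }
  circ
}

new_genome_catalog <- function(tbl, genome_id, circular) {
  structure(
    as_tibble(tbl),
    genome_id = genome_id,
    circular = circular,
    class = c("genome_catalog", class(tibble()))
  )
}

#' @export
print.genome_catalog <- function(x, ...) {
  cat("<genome_catalog> ", attr(x, "genome_id"), ": ",
      length(unique(x$replicon_id)), " replicon(s), ", nrow(x), " genes, ",
      sum(lengths(x$pfams) > 0), " with Pfam domains\n", sep = "")
  NextMethod()
}

#' @export
glance.genome_catalog <- function(x, ...) {
  tibble(
    genome_id = attr(x, "genome_id"),
    n_replicons = length(unique(x$replicon_id)),
    n_genes = nrow(x),
    n_annotated = sum(lengths(x$pfams) > 0),
    n_pfams = length(unique(unlist(x$pfams)))
  )
}

#' Serialize and restore a genome catalog as TSV
#'
#' Columns `genome_id`, `replicon_id`, `rank`, `start_bp`, `end_bp`,
#' `strand`, `locus_tag`, `product`, `pfams` (semicolon-joined), plus a
#' `#circular:` comment line recording replicon topology.
#'
#' @param catalog A `genome_catalog`.
#' @param path Output file; `NULL` returns text.
#' @param text TSV text or file path.
#' @return `write_catalog_tsv()` returns text (invisibly with `path`);
#'   `read_catalog_tsv()` a `genome_catalog`.
#' @export
write_catalog_tsv <- function(catalog, path = NULL) {
  circ <- attr(catalog, "circular")
  hdr <- c(
    paste0("#circular: ", paste(sprintf("%s=%s", names(circ), ifelse(circ, "1", "0")), collapse = ";")),
    paste(c("genome_id", "replicon_id", "rank", "start_bp", "end_bp", "strand",
            "locus_tag", "product", "pfams"), collapse = "\t")
  )
  rows <- sprintf("%s\t%s\t%d\t%d\t%d\t%s\t%s\t%s\t%s",
                  attr(catalog, "genome_id"), catalog$replicon_id, catalog$rank,
                  catalog$start_bp, catalog$end_bp, catalog$strand,
                  catalog$locus_tag,
                  ifelse(is.na(catalog$product), "", catalog$product),
                  join_semi(catalog$pfams))
  txt <- paste(c(hdr, rows), collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname write_catalog_tsv
#' @export
read_catalog_tsv <- function(text) {
  lines <- read_text_lines(text)
  circ_line <- grep("^#circular:", lines, value = TRUE)
  circ <- logical(0)
  if (length(circ_line)) {
    kv <- strsplit(sub("^#circular:\\s*", "", circ_line[1]), ";", fixed = TRUE)[[1]]
    kv <- kv[nzchar(kv)]
    circ <- setNames(vapply(strsplit(kv, "=", fixed = TRUE), `[`, character(1), 2) == "1",
                     vapply(strsplit(kv, "=", fixed = TRUE), `[`, character(1), 1))
  }
  lines <- lines[!grepl("^#", lines)]
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- lines[-1]
  body <- body[nzchar(body)]
  cells <- strsplit(body, "\t", fixed = TRUE)
  cells <- lapply(cells, function(x) c(x, rep("", length(hdr) - length(x))))
  get <- function(col) vapply(cells, function(r) r[match(col, hdr)], character(1))
  tbl <- tibble(
    replicon_id = get("replicon_id"),
    rank = as.integer(get("rank")),
    start_bp = as.integer(get("start_bp")),
    end_bp = as.integer(get("end_bp")),
    strand = get("strand"),
    locus_tag = get("locus_tag"),
    product = dplyr::na_if(get("product"), ""),
    pfams = split_semi(get("pfams"))
  ) |> arrange(.data$replicon_id, .data$rank)
  gid <- unique(get("genome_id"))[1]
  new_genome_catalog(tbl, genome_id = gid,
                     circular = normalize_circular(circ, unique(tbl$replicon_id)))
}
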