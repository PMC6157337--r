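#' Specify a synthetic genome
#'
#' Describes a synthetic bacterial genome for fixture generation: replicon
#' layout, gene clusters planted at chosen ranks with chosen Pfam domains
#' and spacing, and a background of random domain annotations drawn from a
#' pool that never collides with planted families (so false positives can
#' only come from deliberately planted homologs). With a fixed seed the
#' generated files are byte-identical.
#'
#' @param genome_id Genome identifier.
#' @param replicons Tibble/data frame with columns `replicon_id`, `size`
#'   (gene count) and `circular`; or a single integer gene count for one
#'   linear chromosome.
#' @param planted List of planted clusters, each a list with `pfams`
#'   (character, one gene per entry), `replicon`, `start_rank`, `spacing`
#'   (rank step between consecutive planted genes, 1 = contiguous) and
#'   optionally `loci` (explicit locus tags).
#' @param background_pool Pfam accessions for background annotation.
#' @param background_density Fraction of genes given one random background
#'   Pfam (default 0.3).
#' @param seed Integer seed (default 1).
#' @return A list of class `genome_spec`.
#' @export
genome_spec <- function(genome_id = "synthetic", replicons = 500L,
                        planted = list(),
                        background_pool = sprintf("PF98%03d", 1:20),
                        background_density = 0.3, seed = 1L) {
  if (is.numeric(replicons)) {
    replicons <- tibble(replicon_id = "chr", size = as.integer(replicons),
                        circular = FALSE)
  }
  replicons <- as_tibble(replicons)
  planted_pfams <- unique(unlist(lapply(planted, `[[`, "pfams")))
  background_pool <- setdiff(background_pool, planted_pfams)
  for (pl in planted) {
    rep_row <- replicons[replicons$replicon_id == (pl$replicon %||% replicons$replicon_id[1]), ]
    if (!nrow(rep_row)) abort(paste0("planted cluster names unknown replicon '", pl$replicon, "'"))
    top <- (pl$start_rank %||% 0) + (length(pl$pfams) - 1) * (pl$spacing %||% 1)
    if (top >= rep_row$size[1]) {
      abort("planted cluster does not fit inside its replicon")
    }
  }
  occupied <- lapply(planted, function(pl) {
    paste(pl$replicon %||% replicons$replicon_id[1],
          (pl$start_rank %||% 0) + ((seq_along(pl$pfams)) - 1) * (pl$spacing %||% 1))
  })
  if (anyDuplicated(unlist(occupied))) abort("planted clusters overlap")
  structure(
    list(genome_id = genome_id, replicons = replicons, planted = planted,
         background_pool = background_pool,
         background_density = background_density, seed = as.integer(seed)),
    class = "genome_spec"
  )
}

#' Generate a synthetic genome: PTT, domtblout and catalog
#'
#' Materializes a [genome_spec()] into the three mutually consistent forms
#' the pipeline consumes: PTT protein-table text per replicon, HMMER3
#' domtblout text for all domain annotations, and the in-memory
#' `genome_catalog`. Planted genes carry exactly their specified Pfams at
#' their specified ranks; background Pfams never overlap planted families.
#'
#' @param spec A `genome_spec`.
#' @return A list: `ptt` (named character, one PTT text per replicon),
#'   `domtbl` (one domtblout text), `catalog` (a `genome_catalog`),
#'   `spec`.
#' @examples
#' fx <- make_genome(genome_spec("demo", replicons = 50,
#'   planted = list(list(pfams = c("PF90001", "PF90002"), start_rank = 10, spacing = 1))))
#' fx$catalog
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  rs <- local_rng(spec$seed)
  on.exit(rs(), add = TRUE)
  gene_rows <- list()
  for (i in seq_len(nrow(spec$replicons))) {
    rep_id <- spec$replicons$replicon_id[i]
    n <- spec$replicons$size[i]
    start <- 101L + (seq_len(n) - 1L) * 1000L
    gene_rows[[rep_id]] <- tibble(
      replicon_id = rep_id,
      rank = seq_len(n) - 1L,
      start_bp = start,
      end_bp = start + 899L,
      strand = sample(c("+", "-"), n, replace = TRUE),
      locus_tag = sprintf("%s_%s%04d", spec$genome_id, toupper(substr(rep_id, 1, 1)), seq_len(n) - 1L),
      product = "hypothetical protein",
      pfams = rep(list(character(0)), n)
    )
  }
  genes <- bind_rows(gene_rows)
  # background annotation
  if (length(spec$background_pool) && spec$background_density > 0) {
    hit <- stats::runif(nrow(genes)) < spec$background_density
    picks <- sample(spec$background_pool, sum(hit), replace = TRUE)
    genes$pfams[hit] <- as.list(picks)
  }
  # planted clusters override background
  for (pl in spec$planted) {
    rep_id <- pl$replicon %||% spec$replicons$replicon_id[1]
    ranks <- (pl$start_rank %||% 0) + (seq_along(pl$pfams) - 1L) * (pl$spacing %||% 1L)
    idx <- which(genes$replicon_id == rep_id)[ranks + 1L]
    genes$pfams[idx] <- lapply(pl$pfams, identity)
    genes$product[idx] <- "planted module gene"
    if (!is.null(pl$loci)) genes$locus_tag[idx] <- pl$loci
    if (!is.null(pl$strand)) genes$strand[idx] <- pl$strand
  }
  circ <- setNames(spec$replicons$circular, spec$replicons$replicon_id)
  catalog <- new_genome_catalog(
    select(genes, "replicon_id", "rank", "start_bp", "end_bp", "strand",
           "locus_tag", "product", "pfams"),
    genome_id = spec$genome_id, circular = circ
  )
  ptt <- vapply(spec$replicons$replicon_id, function(rep_id) {
    format_ptt(genes[genes$replicon_id == rep_id, ], spec$genome_id, rep_id)
  }, character(1))
  list(ptt = ptt, domtbl = format_domtbl(genes), catalog = catalog, spec = spec)
}

# Scoped RNG: callers' random state is untouched; restores on exit.
local_rng <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

format_ptt <- function(genes, genome_id, rep_id) {
  hdr <- c(
    sprintf("%s %s, synthetic genome - 1..%d", genome_id, rep_id, max(genes$end_bp) + 100L),
    sprintf("%d proteins", nrow(genes)),
    paste(c("Location", "Strand", "Length", "PID", "Gene", "Synonym",
            "Code", "COG", "Product"), collapse = "\t")
  )
  len_aa <- (genes$end_bp - genes$start_bp + 1L) %/% 3L - 1L
  rows <- sprintf("%d..%d\t%s\t%d\t%d\t-\t%s\t-\t-\t%s",
                  genes$start_bp, genes$end_bp, genes$strand, len_aa,
                  90000000L + seq_len(nrow(genes)), genes$locus_tag,
                  genes$product)
  paste(c(hdr, rows), collapse = "\n")
}

format_domtbl <- function(genes) {
  hdr <- c(
    "#                                                                            --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"
  )
  rows <- character(0)
  for (i in seq_len(nrow(genes))) {
    for (pf in genes$pfams[[i]]) {
      rows <- c(rows, sprintf(
        "%-20s %-10s %5d %-20s %-10s %5d %9.1e %6.1f %5.1f %3d %3d %9.1e %9.1e %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f synthetic domain",
        paste0(pf, "_dom"), paste0(pf, ".1"), 200L, genes$locus_tag[i], "-", 300L,
        1e-30, 120.5, 0.1, 1L, 1L, 1e-32, 1e-30, 118.2, 0.1,
        1L, 200L, 10L, 210L, 5L, 215L, 0.98
      ))
    }
  }
  paste(c(hdr, rows, "#", "# Program:         hmmscan", "# [ok]"), collapse = "\n")
}

#' The four-genome dispersal/context scenario suite
#'
#' Generates four 500-gene genomes against one six-domain module to
#' exercise the central claim of context-aware detection: genomes 1 and 2
#' carry all six families but dispersed far apart (two different
#' arrangements), genome 3 carries two dispersed homologs of every family,
#' and genome 4 carries all six on contiguous genes. A homology-only view
#' finds the full domain complement in all four; a windowed context scan
#' at full coverage accepts only genome 4.
#'
#' @param seed Integer seed (default 101).
#' @return A list: `genomes` (four `genome_catalog`s named `genome1` ..
#'   `genome4`), `specs`, and `gcm` (a one-row `module_catalog` with six
#'   synthetic Pfams).
#' @export
make_fig1_suite <- function(seed = 101L) {
  pf6 <- sprintf("PF9%04d", 1:6)
  plant_dispersed <- function(ranks, pfams) {
    lapply(seq_along(ranks), function(i)
      list(pfams = pfams[i], replicon = "chr", start_rank = ranks[i], spacing = 1L))
  }
  specs <- list(
    genome1 = genome_spec("genome1", 500L,
      planted = plant_dispersed(c(30L, 95L, 170L, 250L, 340L, 430L), pf6),
      seed = seed),
    genome2 = genome_spec("genome2", 500L,
      planted = plant_dispersed(c(10L, 120L, 205L, 300L, 380L, 470L), rev(pf6)),
      seed = seed + 1L),
    genome3 = genome_spec("genome3", 500L,
      planted = plant_dispersed(
        c(15L, 58L, 101L, 144L, 187L, 230L, 273L, 316L, 359L, 402L, 445L, 488L),
        c(pf6, pf6)),
      seed = seed + 2L),
    genome4 = genome_spec("genome4", 500L,
      planted = list(list(pfams = pf6, replicon = "chr", start_rank = 200L, spacing = 1L)),
      seed = seed + 3L)
  )
  genomes <- lapply(specs, function(s) make_genome(s)$catalog)
  gcm <- module_catalog(
    module_id = "demo.GCM.A_F", kind = "GCM", map_id = "map90001",
    compounds = list(sprintf("C9%04d", 1:7)),
    pfams = list(pf6),
    source_compound = "C90001", target_compound = "C90007",
    evidence = list("9000001")
  )
  list(genomes = genomes, specs = specs, gcm = gcm)
}

#' The mannose-to-GDP-fucose two-genome suite
#'
#' Builds the classic contrast for context-aware pathway calling: the
#' four-enzyme conversion of D-mannose 6-phosphate to GDP-L-fucose
#' (phosphomannomutase, mannose-1-phosphate guanylyltransferase,
#' GDP-mannose 4,6-dehydratase, GDP-fucose synthase). An
#' Escherichia-coli-like genome carries the four domain families
#' (PF02878, PF00483, PF16363, PF01370) on contiguous genes labeled with
#' the canonical locus tags b2048/b2049/b2052/b2053, while a
#' Bacteroides-thetaiotaomicron-like genome carries the same four families
#' only as homologs dispersed at least 50 genes apart
#' (BT3950/BT2781/BT1224/BT1225). A KGML file encoding the linear
#' four-reaction conversion and the corresponding GCM definition round out
#' the suite. All content is synthetic; locus tags and domain families
#' follow their real counterparts for readability.
#'
#' @param seed Integer seed (default 202).
#' @return A list: `ecoli` and `btheta` (`genome_catalog`s), `gcm`
#'   (one-row `module_catalog`), `kgml` (KGML text), `graph`
#'   (its parsed `pathway_graph`), `specs`.
#' @export
make_man_suite <- function(seed = 202L) {
  man_pfams <- c("PF02878", "PF00483", "PF16363", "PF01370")
  man_cpds <- c("C00275", "C00636", "C00096", "C01222", "C00325")
  man_rxns <- c("R01818", "R00885", "R00888", "R01609")
  man_genes <- c("b2048", "b2049", "b2053", "b2052")
  specs <- list(
    ecoli = genome_spec("ecoli_like", 300L,
      planted = list(list(pfams = man_pfams, replicon = "chr", start_rank = 120L,
                          spacing = 1L, loci = c("b2048", "b2049", "b2053", "b2052"))),
      seed = seed),
    btheta = genome_spec("btheta_like", 300L,
      planted = list(
        list(pfams = man_pfams[1], replicon = "chr", start_rank = 30L, loci = "BT3950"),
        list(pfams = man_pfams[2], replicon = "chr", start_rank = 100L, loci = "BT2781"),
        list(pfams = man_pfams[3], replicon = "chr", start_rank = 170L, loci = "BT1224"),
        list(pfams = man_pfams[4], replicon = "chr", start_rank = 240L, loci = "BT1225")
      ),
      seed = seed + 1L)
  )
  gens <- lapply(specs, make_genome)
  display <- c("D-Mannose 6-phosphate", "D-Mannose 1-phosphate", "GDP-D-mannose",
               "GDP-4-dehydro-6-deoxy-D-mannose", "GDP-L-fucose")
  nodes <- tibble(compound_id = man_cpds, display_name = display,
                  external = FALSE, synonyms = rep(list(character(0)), 5))
  edges <- tibble(
    reaction_id = man_rxns,
    substrate_id = man_cpds[1:4], product_id = man_cpds[2:5],
    reversible = c(TRUE, FALSE, FALSE, FALSE), self_loop = FALSE,
    genes = lapply(man_genes, identity),
    pfams = lapply(man_pfams, identity)
  )
  graph <- new_pathway_graph("map00051", organism = "eco", nodes = nodes, edges = edges)
  kgml <- write_kgml(graph)
  gcm <- module_catalog(
    module_id = "map00051.GCM.C00275_C00325", kind = "GCM", map_id = "map00051",
    compounds = list(man_cpds), pfams = list(sort(man_pfams)),
    genes = list(sort(man_genes)),
    source_compound = "C00275", target_compound = "C00325",
    evidence = list(c("9000051", "9000052"))
  )
  list(ecoli = gens$ecoli$catalog, btheta = gens$btheta$catalog,
       gcm = gcm, kgml = kgml, graph = parse_kgml(kgml), specs = specs,
       files = list(ecoli = gens$ecoli[c("ptt", "domtbl")],
                    btheta = gens$btheta[c("ptt", "domtbl")]))
}

#' Generate six hit-list files from a membership design
#'
#' Test scaffolding for the six-query consensus filter: given a design
#' mapping each PMID to the subset of queries (1..6) returning it, emit the
#' six hit lists such that list *i* contains exactly the PMIDs whose subset
#' includes *i*. The design fully determines the lists; `seed` is accepted
#' for interface uniformity but has no effect.
#'
#' @param module_id Module identifier (used in file names when writing).
#' @param design Named list: PMID -> integer vector of query indices.
#' @param seed Ignored (deterministic by construction).
#' @param dir Optional directory; when given, the six files are written.
#' @return A list of 6 character vectors (and files written when `dir` is
#'   given).
#' @export
make_hitlists <- function(module_id, design, seed = 1L, dir = NULL) {
  bad <- names(design)[!map_lgl(design, function(q) all(q %in% 1:6))]
  if (length(bad)) {
    abort(paste0("design query indices must lie in 1..6; offending PMIDs: ",
                 paste(bad, collapse = ", ")))
  }
  lists <- lapply(1:6, function(i) {
    hit <- map_lgl(design, function(q) i %in% q)
    if (!any(hit)) character(0) else sort(names(design)[hit])
  })
  if (!is.null(dir)) write_hitlists(lists, dir, module_id)
  lists
}

#' Write a fixture suite to disk
#'
#' Materializes the two scenario suites plus hit lists under a directory:
#' PTT and domtblout text per genome, the KGML pathway, module catalogs
#' (TSV + JSON) and six hit-list files for the mannose module.
#'
#' @param dir Target directory (created if needed).
#' @param seed Integer seed forwarded to the suite generators.
#' @return Invisibly, the paths written.
#' @export
write_fixture_suite <- function(dir, seed = 101L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  fig1 <- make_fig1_suite(seed = seed)
  for (nm in names(fig1$specs)) {
    g <- make_genome(fig1$specs[[nm]])
    for (rep_id in names(g$ptt)) {
      p <- file.path(dir, sprintf("%s.%s.ptt", nm, rep_id))
      writeLines(g$ptt[[rep_id]], p)
      paths <- c(paths, p)
    }
    p <- file.path(dir, sprintf("%s.domtblout", nm))
    writeLines(g$domtbl, p)
    paths <- c(paths, p)
  }
  man <- make_man_suite(seed = seed + 101L)
  for (nm in c("ecoli", "btheta")) {
    for (rep_id in names(man$files[[nm]]$ptt)) {
      p <- file.path(dir, sprintf("%s.%s.ptt", nm, rep_id))
      writeLines(man$files[[nm]]$ptt[[rep_id]], p)
      paths <- c(paths, p)
    }
    p <- file.path(dir, sprintf("%s.domtblout", nm))
    writeLines(man$files[[nm]]$domtbl, p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "map00051.kgml")
  writeLines(man$kgml, p)
  paths <- c(paths, p)
  gcms <- module_catalog(!!!bind_rows(as_tibble(fig1$gcm), as_tibble(man$gcm)))
  p <- file.path(dir, "gcm_catalog.tsv")
  write_module_tsv(gcms, p)
  paths <- c(paths, p)
  p <- file.path(dir, "gcm_catalog.json")
  write_module_json(gcms, p)
  paths <- c(paths, p)
  design <- list(`9000051` = 1:6, `9000052` = c(1, 2, 3, 5), `9000053` = 1:3)
  make_hitlists("map00051.GCM.C00275_C00325", design, dir = dir)
  ptab <- file.path(dir, "pmid_organisms.tsv")
  writeLines(c("pmid\torganism",
               "9000051\tEscherichia coli",
               "9000052\tEscherichia coli K-12"), ptab)
  paths <- c(paths, ptab)
  invisible(paths)
}
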