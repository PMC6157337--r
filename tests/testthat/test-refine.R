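# IRMs with explicit per-genome gene assignments on a synthetic catalog.
irms_with_genes <- function(cat_obj, gene_sets, compounds = NULL, linkers = NULL) {
  gid <- attr(cat_obj, "genome_id")
  n <- length(gene_sets)
  module_catalog(
    module_id = sprintf("map1.IRM%d", seq_len(n)), kind = "IRM", map_id = "map1",
    compounds = if (is.null(compounds))
      lapply(seq_len(n), function(i) sprintf("C%d%d", i, 1:2)) else compounds,
    pfams = lapply(seq_len(n), function(i) sprintf("PF9%04d", i)),
    gene_assignments = lapply(gene_sets, function(g) setNames(list(sort(g)), gid)),
    linker_genes = if (is.null(linkers)) rep(list(character(0)), n) else linkers
  )
}

test_that("interleaved reference modules merge into one IM carrying both compound sets", {
  cat_obj <- catalog_at_ranks(0:99, n = 100)
  irms <- irms_with_genes(cat_obj, list(
    locus_at(cat_obj, c(10, 14, 18)),
    locus_at(cat_obj, c(12, 16, 20))
  ))
  ims <- refine_modules(irms, cat_obj)
  expect_equal(nrow(ims), 1)
  expect_equal(ims$kind, "IM")
  expect_setequal(ims$compounds[[1]], c("C11", "C12", "C21", "C22"))
  expect_setequal(ims$merged_from[[1]], irms$module_id)
  expect_false(ims$unclustered)
})

test_that("a reference module split into distant blocks yields two IMs with duplicated compounds", {
  cat_obj <- catalog_at_ranks(0:599, n = 600)
  irms <- irms_with_genes(cat_obj, list(
    locus_at(cat_obj, c(0, 1, 2, 3, 500, 501, 502, 503))
  ))
  ims <- refine_modules(irms, cat_obj)
  expect_equal(nrow(ims), 2)
  expect_equal(ims$compounds[[1]], ims$compounds[[2]])
  expect_true(all(vapply(ims$merged_from, function(x) "map1.IRM1" %in% x, logical(1))))
  spans <- vapply(ims$gene_assignments, function(ga) length(ga[[1]]), integer(1))
  expect_equal(sort(spans), c(4L, 4L))
})

test_that("a tight cluster is a fixed point: the IM equals its IRM", {
  cat_obj <- catalog_at_ranks(0:49, n = 50)
  genes <- locus_at(cat_obj, c(10, 11, 12, 13))
  irms <- irms_with_genes(cat_obj, list(genes))
  ims <- refine_modules(irms, cat_obj)
  expect_equal(nrow(ims), 1)
  expect_equal(ims$gene_assignments[[1]][[attr(cat_obj, "genome_id")]], sort(genes))
  expect_setequal(ims$compounds[[1]], irms$compounds[[1]])
})

test_that("refinement is idempotent and conserves genes", {
  cat_obj <- catalog_at_ranks(0:299, n = 300)
  gid <- attr(cat_obj, "genome_id")
  irms <- irms_with_genes(cat_obj, list(
    locus_at(cat_obj, c(5, 8, 40, 44)),
    locus_at(cat_obj, c(6, 140, 143)),
    locus_at(cat_obj, c(250, 251))
  ))
  ims <- refine_modules(irms, cat_obj)
  again <- refine_modules(ims, cat_obj)
  part <- function(x) sort(vapply(x$gene_assignments,
                                  function(ga) paste(ga[[gid]], collapse = ","), character(1)))
  expect_equal(part(again), part(ims))
  expect_setequal(unlist(lapply(ims$gene_assignments, `[[`, gid)),
                  unlist(lapply(irms$gene_assignments, `[[`, gid)))
})

test_that("raising the distance threshold never increases the IM count", {
  set.seed(77)
  for (trial in 1:10) {
    n <- 400
    cat_obj <- catalog_at_ranks(0:(n - 1), n = n, genome_id = paste0("mono", trial))
    irms <- irms_with_genes(cat_obj, list(
      locus_at(cat_obj, sort(sample(0:(n - 1), 12))),
      locus_at(cat_obj, sort(sample(0:(n - 1), 8)))
    ))
    counts <- vapply(c(2, 5, 10, 25, 60), function(thr) {
      nrow(refine_modules(irms, cat_obj,
                          params = refinement_params(distance_threshold = thr)))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("no IM ever pools genes from two replicons", {
  two <- make_genome(genome_spec("tworep", replicons = tibble::tibble(
    replicon_id = c("chr", "pls"), size = c(60L, 30L), circular = FALSE
  ), background_density = 0, seed = 13L))$catalog
  chr_genes <- two$locus_tag[two$replicon_id == "chr"][c(3, 4, 5)]
  pls_genes <- two$locus_tag[two$replicon_id == "pls"][c(3, 4)]
  irms <- irms_with_genes(two, list(c(chr_genes, pls_genes)))
  ims <- refine_modules(irms, two, params = refinement_params(distance_threshold = 50))
  reps_per_im <- vapply(ims$gene_assignments, function(ga) {
    length(unique(two$replicon_id[match(ga[[1]], two$locus_tag)]))
  }, integer(1))
  expect_true(all(reps_per_im == 1))
  expect_equal(nrow(ims), 2)
})

test_that("singleton leftovers become unclustered IMs", {
  cat_obj <- catalog_at_ranks(0:199, n = 200)
  irms <- irms_with_genes(cat_obj, list(locus_at(cat_obj, c(10, 11, 150))))
  ims <- refine_modules(irms, cat_obj)
  expect_equal(nrow(ims), 2)
  expect_equal(sum(ims$unclustered), 1)
})

test_that("duplicate linker resolution copies the linker into sibling clusters", {
  cat_obj <- catalog_at_ranks(0:199, n = 200)
  gid <- attr(cat_obj, "genome_id")
  lk <- locus_at(cat_obj, 100)
  irms <- irms_with_genes(cat_obj,
    list(c(locus_at(cat_obj, c(10, 12)), lk), c(locus_at(cat_obj, c(104, 106)))),
    linkers = list(lk, character(0)))
  ims_near <- refine_modules(irms, cat_obj,
                             params = refinement_params(linker_resolution = "nearest"))
  holds_near <- vapply(ims_near$gene_assignments, function(ga) lk %in% ga[[gid]], logical(1))
  expect_equal(sum(holds_near), 1)
  ims_dup <- refine_modules(irms, cat_obj,
                            params = refinement_params(linker_resolution = "duplicate"))
  holds_dup <- vapply(ims_dup$gene_assignments, function(ga) lk %in% ga[[gid]], logical(1))
  expect_gte(sum(holds_dup), sum(holds_near))
})

test_that("GCM compilation orders compounds source-to-target and enforces its guards", {
  fx <- make_man_suite()
  im <- fx$gcm
  im$kind <- "IM"
  im$module_id <- "map00051.IM1"
  im$compounds <- list(sample(im$compounds[[1]]))
  gcm <- compile_gcm(im, evidence = "9000051", source = "C00275",
                     target = "C00325", graph = fx$graph)
  expect_equal(gcm$kind, "GCM")
  expect_equal(gcm$compounds[[1]][1], "C00275")
  expect_equal(rev(gcm$compounds[[1]])[1], "C00325")
  expect_equal(gcm$compounds[[1]],
               c("C00275", "C00636", "C00096", "C01222", "C00325"))
  expect_error(compile_gcm(im, character(0), "C00275", "C00325"), "evidence")
  expect_error(compile_gcm(im, "9000051", "C00275", "C99999"), "C99999")
})

test_that("cross-genome consolidation keeps only sufficiently supported patterns", {
  cats <- lapply(1:3, function(i) {
    catalog_at_ranks(0:99, n = 100, genome_id = paste0("g", i))
  })
  im_sets <- lapply(cats, function(cat_obj) {
    irms <- irms_with_genes(cat_obj, list(locus_at(cat_obj, c(10, 11, 12))))
    refine_modules(irms, cat_obj)
  })
  # one genome carries an extra private pattern
  extra_cat <- cats[[1]]
  extra <- refine_modules(
    irms_with_genes(extra_cat, list(locus_at(extra_cat, c(50, 51)))),
    extra_cat)
  extra$module_id <- "g1.IMx"
  extra$merged_from <- list("map1.IRM9")
  im_sets[[1]] <- module_catalog(!!!dplyr::bind_rows(tibble::as_tibble(im_sets[[1]]),
                                                     tibble::as_tibble(extra)))
  all_pat <- consolidate_ims(im_sets, min_support = 1)
  common <- consolidate_ims(im_sets, min_support = 3)
  expect_equal(nrow(all_pat), 2)
  expect_equal(nrow(common), 1)
  expect_equal(length(common$gene_assignments[[1]]), 3)
})
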