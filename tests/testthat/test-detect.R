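four_pfam_gcm <- function(pfams = sprintf("PF9%04d", 1:4)) {
  module_catalog(module_id = "t.GCM1", kind = "GCM",
                 compounds = list(c("C1", "C2")), pfams = list(pfams),
                 source_compound = "C1", target_compound = "C2",
                 evidence = list("9000001"))
}

test_that("contiguous module genes are called present at full coverage", {
  pf <- sprintf("PF9%04d", 1:4)
  cat_obj <- catalog_at_ranks(100:103, n = 500, pfams = as.list(pf))
  calls <- scan_genome(cat_obj, four_pfam_gcm(pf), detection_params(5, 100))
  expect_equal(nrow(calls), 1)
  expect_true(calls$present)
  expect_equal(calls$coverage_percent, 100)
  expect_equal(calls$start_rank, 100)
  expect_equal(calls$end_rank, 103)
  expect_setequal(calls$matched_pfams[[1]], pf)
  expect_equal(calls$missing_pfams[[1]], character(0))
})

test_that("dispersed homologs are reported absent with their best partial coverage", {
  pf <- sprintf("PF9%04d", 1:4)
  cat_obj <- catalog_at_ranks(c(10, 110, 210, 310), n = 500, pfams = as.list(pf))
  calls <- scan_genome(cat_obj, four_pfam_gcm(pf), detection_params(5, 100))
  expect_equal(nrow(calls), 1)
  expect_false(calls$present)
  expect_equal(calls$coverage_percent, 25)
})

test_that("the 3-of-4 boundary respects >= at the cutoff", {
  pf <- sprintf("PF9%04d", 1:4)
  cat_obj <- catalog_at_ranks(c(50, 51, 52, 300), n = 400, pfams = as.list(pf))
  at75 <- scan_genome(cat_obj, four_pfam_gcm(pf), detection_params(5, 75))
  expect_true(any(at75$present & at75$coverage_percent == 75))
  at80 <- scan_genome(cat_obj, four_pfam_gcm(pf), detection_params(5, 80))
  expect_false(any(at80$present))
})

test_that("one gene carrying several module Pfams contributes all; repeats count once", {
  pf <- sprintf("PF9%04d", 1:4)
  cat_obj <- catalog_at_ranks(c(20, 21), n = 100,
                              pfams = list(pf[1:3], c(pf[4], pf[4])))
  calls <- scan_genome(cat_obj, four_pfam_gcm(pf), detection_params(2, 100))
  expect_true(calls$present)
  expect_equal(calls$coverage_percent, 100)
  # a duplicated Pfam alone does not inflate coverage
  cat2 <- catalog_at_ranks(c(20, 21, 22), n = 100,
                           pfams = list(pf[1], pf[1], pf[1]))
  c2 <- scan_genome(cat2, four_pfam_gcm(pf), detection_params(5, 100))
  expect_equal(c2$coverage_percent, 25)
})

test_that("coverage is monotone in window size and present calls shrink as cutoff rises", {
  set.seed(99)
  fx <- make_genome(genome_spec("mono", 300L, planted = list(
    list(pfams = sprintf("PF9%04d", 1:4), start_rank = 50L, spacing = 6L)
  ), seed = 31L))
  gcm <- four_pfam_gcm()
  covs <- vapply(c(0, 2, 5, 9, 15), function(w) {
    max(scan_genome(fx$catalog, gcm, detection_params(w, 100))$coverage_percent)
  }, numeric(1))
  expect_true(all(diff(covs) >= 0))
  key <- function(calls) paste(calls$replicon_id, calls$start_rank)[calls$present]
  loose <- scan_genome(fx$catalog, gcm, detection_params(9, 50))
  tight <- scan_genome(fx$catalog, gcm, detection_params(9, 100))
  expect_true(all(key(tight) %in% key(loose)))
})

test_that("rotating a circular replicon never changes presence or coverage", {
  pf <- sprintf("PF9%04d", 1:4)
  spec <- genome_spec("circ", replicons = tibble::tibble(
    replicon_id = "chr", size = 120L, circular = TRUE
  ), planted = list(list(pfams = pf, start_rank = 20L, spacing = 2L)), seed = 17L)
  cat_obj <- make_genome(spec)$catalog
  gcm <- four_pfam_gcm(pf)
  rotate <- function(cat_obj, k) {
    n <- nrow(cat_obj)
    cat_obj$rank <- (cat_obj$rank + k) %% n
    cat_obj[order(cat_obj$rank), ]
  }
  base <- scan_genome(cat_obj, gcm, detection_params(5, 100))
  for (k in c(1, 17, 100, 115)) {
    rot <- scan_genome(rotate(cat_obj, k), gcm, detection_params(5, 100))
    expect_equal(sum(rot$present), sum(base$present))
    expect_equal(sort(rot$coverage_percent), sort(base$coverage_percent))
  }
  # including rotations that split the cluster across the origin
  rot_split <- scan_genome(rotate(cat_obj, 120 - 22), gcm, detection_params(5, 100))
  expect_equal(sum(rot_split$present), 1)
  expect_equal(max(rot_split$coverage_percent), 100)
})

test_that("a cluster spanning the origin of a circular replicon is one wrapped call", {
  pf <- sprintf("PF9%04d", 1:4)
  spec <- genome_spec("wrap", replicons = tibble::tibble(
    replicon_id = "chr", size = 100L, circular = TRUE
  ), planted = list(
    list(pfams = pf[1:2], start_rank = 98L, spacing = 1L),
    list(pfams = pf[3:4], start_rank = 0L, spacing = 1L)
  ), seed = 23L)
  cat_obj <- make_genome(spec)$catalog
  calls <- scan_genome(cat_obj, four_pfam_gcm(pf), detection_params(5, 100))
  expect_equal(sum(calls$present), 1)
  expect_true(calls$start_rank[calls$present] > calls$end_rank[calls$present])
})

test_that("a window-sized replicon and zero window size behave at the edges", {
  pf <- sprintf("PF9%04d", 1:2)
  tiny <- catalog_at_ranks(c(0, 4), n = 5, pfams = list(pf[1], pf[2]))
  gcm <- four_pfam_gcm(pf)
  # window exceeds replicon: the whole replicon is one window
  calls <- scan_genome(tiny, gcm, detection_params(10, 100))
  expect_true(calls$present)
  # window 0: only the anchor gene itself
  both <- catalog_at_ranks(c(7), n = 20, pfams = list(pf))
  w0 <- scan_genome(both, gcm, detection_params(0, 100))
  expect_true(w0$present)
  expect_equal(w0$start_rank, 7)
  expect_equal(w0$end_rank, 7)
})

test_that("a genome with none of the module's Pfams yields one zero-coverage row", {
  cat_obj <- catalog_at_ranks(0:9, n = 10)
  calls <- scan_genome(cat_obj, four_pfam_gcm(), detection_params(5, 100))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$coverage_percent, 0)
  expect_false(calls$present)
  expect_setequal(calls$missing_pfams[[1]], sprintf("PF9%04d", 1:4))
})

test_that("windowed scanning equals the exhaustive contiguous-interval oracle", {
  set.seed(515)
  for (trial in 1:12) {
    n <- sample(40:120, 1)
    circular <- trial %% 3 == 0
    n_pf <- sample(2:5, 1)
    pf <- sprintf("PF9%04d", 1:n_pf)
    planted <- list(list(
      pfams = sample(pf, sample(n_pf, 1)),
      start_rank = sample(0:(n - 20), 1),
      spacing = sample(1:8, 1)
    ))
    spec <- genome_spec(paste0("orc", trial), replicons = tibble::tibble(
      replicon_id = "chr", size = as.integer(n), circular = circular
    ), planted = planted, background_pool = pf, background_density = 0.15,
    seed = 1000L + trial)
    cat_obj <- make_genome(spec)$catalog
    w <- sample(1:6, 1)
    cutoff <- sample(c(25, 50, 75, 100), 1)
    got <- scan_genome(cat_obj, four_pfam_gcm(pf), detection_params(w, cutoff))
    want <- oracle_scan(cat_obj, pf, w, cutoff)
    got_present <- got[got$present, ]
    expect_equal(nrow(got_present), nrow(want$present))
    if (nrow(want$present)) {
      fmt <- function(df) sort(paste(df$replicon_id, df$start_rank, df$end_rank,
                                     round(df$coverage_percent, 6)))
      expect_equal(fmt(got_present), fmt(want$present))
    } else {
      expect_equal(max(got$coverage_percent), want$best_coverage)
    }
  }
})

test_that("pathway-level scanning aggregates per-module calls and reports empty catalogs", {
  fx <- make_man_suite()
  other <- fx$gcm
  other$module_id <- "map00051.GCM.other"
  other$pfams <- list(c("PF87001", "PF87002"))
  gcms <- module_catalog(!!!dplyr::bind_rows(tibble::as_tibble(fx$gcm),
                                             tibble::as_tibble(other)))
  res <- scan_pathway(fx$ecoli, gcms, fx$graph, detection_params(5, 100))
  expect_s3_class(res, "pathway_scan")
  expect_equal(sum(res$calls$present), 1)
  expect_equal(length(unique(res$calls$gcm_id)), 2)
  gl <- glance(res)
  expect_equal(gl$n_gcms, 2)
  expect_equal(gl$n_present, 1)

  empty <- module_catalog(module_id = character(0))
  expect_message(res0 <- scan_pathway(fx$ecoli, empty, fx$graph), "no GCMs")
  expect_equal(nrow(res0$calls), 0)
  expect_match(attr(res0$calls, "status"), "map00051")
})

test_that("detection parameter bounds are enforced", {
  expect_error(detection_params(-1, 100), "window_size")
  expect_error(detection_params(5, 0), "cutoff_percent")
  expect_error(detection_params(5, 101), "cutoff_percent")
})
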