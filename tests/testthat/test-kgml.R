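test_that("minimal KGML parses to the declared nodes and edges", {
  g <- parse_kgml(minimal_kgml())
  expect_s3_class(g, "pathway_graph")
  expect_equal(sort(g$nodes$compound_id), c("C90001", "C90002", "C90003"))
  expect_equal(nrow(g$edges), 2)
  expect_false(any(g$edges$reversible))
  expect_equal(g$edges$genes[[match("R90001", g$edges$reaction_id)]], "K90001")
  expect_equal(g$map_id, "map99901")
})

test_that("a reversible reaction yields one edge, flagged reversible", {
  g <- parse_kgml(reversible_kgml())
  expect_equal(nrow(g$edges), 1)
  expect_true(g$edges$reversible)
})

test_that("the mannose-conversion fixture KGML is a 5-node path with 4 catalyzed reactions", {
  g <- parse_kgml(make_man_suite()$kgml)
  expect_equal(nrow(g$nodes), 5)
  expect_equal(nrow(g$edges), 4)
  expect_true(all(lengths(g$edges$genes) > 0))
  # hand count of elements in the emitted file
  txt <- make_man_suite()$kgml
  expect_equal(length(gregexpr('type="compound"', txt)[[1]]), 5)
  expect_equal(length(gregexpr("<reaction ", txt)[[1]]), 4)
  expect_equal(length(gregexpr('type="gene"', txt)[[1]]), 4)
})

test_that("parser rejects malformed XML, empty pathways and dangling references", {
  expect_error(parse_kgml("<pathway name='x'"), "malformed")
  expect_error(
    parse_kgml('<?xml version="1.0"?><pathway name="path:map1"><entry id="1" name="ko:K1" type="ortholog"/></pathway>'),
    "compound"
  )
  bad <- paste0(
    '<?xml version="1.0"?><pathway name="path:map1" org="map">',
    '<entry id="1" name="cpd:C00001" type="compound"/>',
    '<reaction id="9" name="rn:R1" type="irreversible">',
    '<substrate id="1" name="cpd:C00001"/><product id="99" name="cpd:C99999"/>',
    '</reaction></pathway>'
  )
  expect_error(parse_kgml(bad), "C99999")
})

test_that("duplicate compound entries merge and map entries are flagged external", {
  txt <- paste0(
    '<?xml version="1.0"?><pathway name="path:map2" org="map">',
    '<entry id="1" name="cpd:C00001" type="compound"><graphics name="A"/></entry>',
    '<entry id="2" name="cpd:C00001" type="compound"><graphics name="A"/></entry>',
    '<entry id="3" name="path:map00010" type="map"/>',
    '</pathway>'
  )
  g <- parse_kgml(txt)
  expect_equal(sum(g$nodes$compound_id == "C00001"), 1)
  expect_true(g$nodes$external[g$nodes$compound_id == "map00010"])
})

test_that("relation elements contribute edges only when asked", {
  txt <- paste0(
    '<?xml version="1.0"?><pathway name="path:map3" org="map">',
    '<entry id="1" name="cpd:C00001" type="compound"/>',
    '<entry id="2" name="cpd:C00002" type="compound"/>',
    '<relation entry1="1" entry2="2" type="ECrel"/>',
    '</pathway>'
  )
  expect_equal(nrow(parse_kgml(txt)$edges), 0)
  expect_equal(nrow(parse_kgml(txt, use_relations = TRUE)$edges), 1)
})

test_that("edge list is deterministic, sorted, and order-invariant", {
  g <- parse_kgml(minimal_kgml())
  el <- to_edge_list(g)
  expect_equal(nrow(el), 2)
  expect_equal(el$reaction_id, sort(el$reaction_id))
  # input element reordering does not change the edge list
  g2 <- g
  g2$edges <- g2$edges[rev(seq_len(nrow(g2$edges))), ]
  expect_equal(to_edge_list(g2), el)
  # duplicate reaction ids on distinct compound pairs both survive, stably
  g3 <- graph_from_pairs(rbind(c("C1", "C2"), c("C2", "C3")))
  g3$edges$reaction_id <- c("R1", "R1")
  el3 <- to_edge_list(g3)
  expect_equal(nrow(el3), 2)
  expect_equal(el3$substrate_id, sort(el3$substrate_id))
  # empty graph
  g0 <- g
  g0$edges <- g0$edges[0, ]
  expect_equal(nrow(to_edge_list(g0)), 0)
})

test_that("KGML round trip preserves the (substrate, product, reversible) multiset", {
  fx <- make_man_suite()
  g1 <- parse_kgml(fx$kgml)
  g2 <- parse_kgml(write_kgml(g1))
  trip <- function(g) sort(paste(g$edges$substrate_id, g$edges$product_id, g$edges$reversible))
  expect_equal(trip(g2), trip(g1))
  expect_equal(sort(g2$nodes$compound_id), sort(g1$nodes$compound_id))
  # catalyst genes survive too
  expect_equal(
    sort(unlist(g2$edges$genes[order(g2$edges$reaction_id)])),
    sort(unlist(g1$edges$genes[order(g1$edges$reaction_id)]))
  )
})

test_that("annotated exports agree across formats and re-read under igraph", {
  fx <- make_man_suite()
  g <- fx$graph
  calls <- scan_genome(fx$ecoli, fx$gcm, detection_params(5, 100))
  gml <- export_annotated_graph(g, calls, fx$gcm, format = "graphml")
  tf <- tempfile(fileext = ".graphml")
  writeLines(gml, tf)
  ig <- igraph::read_graph(tf, format = "graphml")
  expect_setequal(igraph::V(ig)$name, g$nodes$compound_id)
  expect_true(all(igraph::V(ig)$present))
  js <- jsonlite::fromJSON(export_annotated_graph(g, calls, fx$gcm, format = "json"),
                           simplifyVector = FALSE)
  js_attr <- sort(vapply(js$nodes, function(n)
    paste(n$id, n$module_id, tolower(n$present)), character(1)))
  ig_attr <- sort(paste(igraph::V(ig)$name, igraph::V(ig)$module_id, tolower(igraph::V(ig)$present)))
  expect_equal(js_attr, ig_attr)
  unlink(tf)
})

test_that("exports with no calls flag every node absent, and unknown compounds warn", {
  g <- make_man_suite()$graph
  js <- jsonlite::fromJSON(export_annotated_graph(g, NULL, NULL, format = "json"),
                           simplifyVector = FALSE)
  expect_true(all(!vapply(js$nodes, function(n) isTRUE(n$present), logical(1))))
  fx <- make_man_suite()
  bad_gcm <- fx$gcm
  bad_gcm$compounds[[1]] <- c(bad_gcm$compounds[[1]], "C99999")
  calls <- scan_genome(fx$ecoli, bad_gcm, detection_params(5, 100))
  expect_warning(export_annotated_graph(g, calls, bad_gcm, format = "json"), "C99999")
})

test_that("tidy and glance summarize a pathway graph", {
  g <- parse_kgml(minimal_kgml())
  expect_equal(nrow(tidy(g)), 2)
  gl <- glance(g)
  expect_equal(gl$n_nodes, 3)
  expect_equal(gl$n_edges, 2)
})
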