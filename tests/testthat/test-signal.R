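# hand-built complex helper
cx <- function(proteins, filial, full = filial, label = "OC") {
  structure(list(proteins = proteins, filial_functions = filial,
                 full_functions = full, label = label),
            class = "putative_complex")
}

test_that("the retrieval index counts complex-captured carriers over background carriers", {
  dag <- parse_obo(tiny_obo())
  # background of 6 connected proteins; 4 carry the function via descendants
  net <- load_network(edge_file("p1 p2 1", "p3 p4 1", "p5 p6 1"))
  ann <- ann_from(dag, p1 = "GO:0000005", p2 = "GO:0000005",
                  p3 = "GO:0000004", p4 = "GO:0000005")
  sub <- induce_subgraph(net, net$nodes)
  # complexes hold p1, p2 -> 2 of the 4 carriers of GO:0000003
  complexes <- list(cx(c("p1", "p2", "p5"), "GO:0000005"))
  rho <- retrieval_index(sub, complexes, ann, dag)
  rec <- rho[rho$term == "GO:0000003", ]
  expect_equal(rec$numerator, 2L)
  expect_equal(rec$denominator, 4L)
  expect_equal(rec$value, 0.5)

  # full retrieval when the complexes exhaust the background
  full <- retrieval_index(sub, list(cx(net$nodes, "GO:0000005")), ann, dag)
  expect_true(all(full$value[full$defined] == 1))
  # zero complexes: every defined value is 0
  none <- retrieval_index(sub, list(), ann, dag)
  expect_true(all(none$value[none$defined] == 0))
  # term carried by nobody in the background is undefined
  und <- retrieval_index(sub, complexes, ann, dag, terms = "GO:0000006")
  expect_false(und$defined)
  expect_true(is.na(und$value))
})

test_that("retrieval stays in [0,1] and never decreases as complexes accumulate", {
  spec <- fixture_spec(seed = 5)
  net <- make_network(spec)
  onto <- make_ontology_and_annotations(spec)
  for (seed in 1:5) {
    ids <- sample_random_set(net, 36L, seed = seed)
    sub <- induce_subgraph(net, ids)
    cs <- filter_min_size(mcl_cluster(sub))
    complexes <- infer_complexes(cs, sub$background, onto$ann, onto$dag)
    prev <- NULL
    for (m in 0:length(complexes)) {
      rho <- retrieval_index(sub, complexes[seq_len(m)], onto$ann, onto$dag)
      expect_true(all(rho$value[rho$defined] >= 0 & rho$value[rho$defined] <= 1))
      expect_true(all(rho$numerator <= rho$denominator))
      if (!is.null(prev))
        expect_true(all(rho$value[rho$defined] >= prev$value[prev$defined]))
      prev <- rho
    }
  }
})

test_that("the null distribution is seeded, complete and reproducible", {
  spec <- fixture_spec(seed = 3)
  net <- make_network(spec)
  onto <- make_ontology_and_annotations(spec)
  a <- suppressWarnings(build_null(net, 20L, onto$ann, onto$dag,
                                   n_runs = 8L, seed = 100L))
  b <- suppressWarnings(build_null(net, 20L, onto$ann, onto$dag,
                                   n_runs = 8L, seed = 100L))
  expect_identical(a$values, b$values)
  expect_equal(ncol(a$values), 8L)
  expect_true(all(a$values >= 0 & a$values <= 1))
  expect_equal(a$threshold95, apply(a$values, 1L, percentile95))
  # the threshold is an actual sample value (order statistic, no interpolation)
  for (t in rownames(a$values))
    expect_true(a$threshold95[[t]] %in% a$values[t, ])

  one <- suppressWarnings(build_null(net, 20L, onto$ann, onto$dag,
                                     n_runs = 1L, seed = 5L))
  expect_equal(ncol(one$values), 1L)
})

test_that("the upper-percentile order statistic matches its definition", {
  expect_equal(percentile95(1:100), 95)
  expect_equal(percentile95(rep(3.5, 10)), 3.5)
  expect_equal(percentile95(42), 42)
  expect_error(percentile95(numeric(0)), "empty")
})

test_that("the differential rule requires strict dominance over both comparators", {
  rho_df <- function(term, value) data.frame(term = term, numerator = 1L,
                                             denominator = 2L, value = value,
                                             defined = !is.na(value))
  thr <- c(f = 0.5)
  # above both comparators
  expect_equal(orthology_related_functions(rho_df("f", 0.6),
                                           rho_df("f", 0.3), thr), "f")
  # equality with the max is not enough
  expect_length(orthology_related_functions(rho_df("f", 0.5),
                                            rho_df("f", 0.3), thr), 0L)
  # zero retrieval can never be related
  expect_length(orthology_related_functions(rho_df("f", 0),
                                            rho_df("f", 0), c(f = 0)), 0L)
  # undefined global value counts as zero; absent null threshold as zero
  expect_equal(orthology_related_functions(rho_df("g", 0.1),
                                           rho_df("g", NA), c(f = 1)), "g")
})

test_that("complexes are related through any function of the full set", {
  related <- "GO:0000003"
  filial_hit <- cx("p1", "GO:0000003")
  inherited_hit <- cx("p2", "GO:0000005",
                      full = c("GO:0000005", "GO:0000003"))
  miss <- cx("p3", "GO:0000007")
  out <- orthology_related_complexes(list(filial_hit, inherited_hit, miss),
                                     related)
  expect_length(out, 2L)
})

test_that("uniqueness needs one prediction pair no global complex makes", {
  oc <- list(cx(c("p1", "p2", "p3"), "f1"),   # pair (p3, f1) not in GC
             cx(c("p1", "p2"), "f1"),         # fully covered by GC
             cx(c("q1", "q2"), "f2"))         # proteins absent from GC
  gc <- list(cx(c("p1", "p2", "x"), "f1"))
  u <- unique_complexes(oc, gc)
  expect_length(u, 2L)
  expect_equal(attr(u[[1L]], "unique_pairs")$protein, "p3")
  expect_equal(nrow(attr(u[[2L]], "unique_pairs")), 2L)
})

test_that("unique predictions split into verified and novel against the reference", {
  dag <- parse_obo(tiny_obo())
  ref <- ann_from(dag, p1 = "GO:0000005", p2 = "GO:0000007")
  u <- cx(c("p1", "p2"), "GO:0000004")
  attr(u, "unique_pairs") <- data.frame(protein = c("p1", "p2"),
                                        term = "GO:0000004")
  out <- classify_predictions(u, ref)
  # p1 carries a descendant of the predicted term -> verified
  expect_equal(out$verified$protein, "p1")
  expect_equal(out$novel$protein, "p2")
})

test_that("GO-slim roll-up maps related terms to every slim ancestor or self", {
  dag <- parse_obo(tiny_obo())
  slim <- c("GO:0000002", "GO:0000007")
  out <- goslim_summarize(c("GO:0000002", "GO:0000006", "GO:0000005"),
                          slim, dag)
  expect_setequal(out$`GO:0000002`, c("GO:0000002", "GO:0000006", "GO:0000005"))
  # diamond bottom reaches both slim heads
  expect_true("GO:0000006" %in% out$`GO:0000007`)
  none <- goslim_summarize("GO:0000005", "GO:0000007", dag)
  expect_equal(none$unslimmed, "GO:0000005")
})
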