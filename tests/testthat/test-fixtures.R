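test_that("fixture networks honour the planted block structure and seeding", {
  spec <- fixture_spec(n_communities = 4L, community_size = 5L,
                       n_signal_communities = 0L, p_in = 1, p_out = 0,
                       seed = 11)
  net <- make_network(spec)
  expect_length(net$nodes, 20L)
  expect_equal(nrow(net$edges), 4L * choose(5, 2))
  # disjoint cliques are MCL fixed points: the exact partition comes back
  comm <- unname(split(names(orthosignal:::fixture_proteins(spec)),
                       orthosignal:::fixture_proteins(spec)))
  cs <- mcl_cluster(net, inflation = 1.8)
  expect_equal(canon_partition(cs$clusters), canon_partition(comm))
  # same seed, same edges
  expect_identical(make_network(spec)$edges, net$edges)
})

test_that("fixture ontology places markers deep enough and decoys stay incoherent", {
  spec <- fixture_spec(seed = 2)
  onto <- make_ontology_and_annotations(spec)
  dag <- onto$dag
  expect_length(dag$roots, 1L)
  for (m in unlist(onto$markers))
    expect_gte(term_level(dag, m), 4L)
  for (d in onto$decoys)
    expect_gte(term_level(dag, d), 4L)
  expect_equal(term_level(dag, "NEG:LEVEL3"), 3L)
  # slim heads sit directly under the root
  expect_true(all(dag$level[grep("^SLIM:", dag$terms)] == 1L))

  # markers shallower than the coherence level bound are not constructible
  expect_error(fixture_spec(marker_level = 3L), "marker_level")

  # with no signal communities decoys cover all proteins and stay
  # insignificant in community-sized clusters
  flat <- fixture_spec(n_signal_communities = 0L, seed = 4)
  fonto <- make_ontology_and_annotations(flat)
  fnet <- make_network(flat)
  sub <- induce_subgraph(fnet, fnet$nodes)
  comm1 <- names(orthosignal:::fixture_proteins(flat))[1:10]
  res <- enrich(comm1, sub$background, fonto$ann, fonto$dag)
  decoy_rows <- res[res$term %in% fonto$decoys, ]
  expect_true(all(decoy_rows$p_corrected > 0.05))
})

test_that("ortholog sets cover the signal communities plus plain scatter", {
  spec <- fixture_spec(seed = 9)
  net <- make_network(spec)
  orth <- make_ortholog_set(spec, net)
  comm <- orthosignal:::fixture_proteins(spec)
  expect_length(orth, round(0.45 * 80))
  signal <- names(comm)[comm <= 2]
  expect_true(all(signal %in% orth))
  # camouflage partners (communities 3-6) never enter the set
  expect_false(any(comm[setdiff(orth, signal)] %in% 3:6))
  expect_identical(make_ortholog_set(spec, net), orth)
})

test_that("fixtures round-trip bit-exactly through the external formats", {
  spec <- fixture_spec(seed = 12)
  dir <- tempfile()
  fx <- write_fixture(spec, dir)
  on.exit(unlink(dir, recursive = TRUE))

  net <- load_network(fx$network)
  expect_identical(net$edges, make_network(spec)$edges)
  expect_setequal(setdiff(make_network(spec)$nodes, net$nodes), character(0))

  onto <- make_ontology_and_annotations(spec)
  dag <- parse_obo(fx$obo)
  expect_identical(sort(dag$terms), sort(onto$dag$terms))
  expect_identical(dag$level[order(names(dag$level))],
                   onto$dag$level[order(names(onto$dag$level))])

  ann <- parse_gaf(fx$gaf, dag)
  expect_identical(lapply(ann$direct[sort(names(ann$direct))], sort),
                   lapply(onto$ann$direct[sort(names(onto$ann$direct))], sort))

  expect_setequal(read_slim(fx$slim, dag), onto$slim)
  expect_setequal(readLines(fx$orthologs), make_ortholog_set(spec, net))

  # second write is byte-identical (generator determinism end to end)
  dir2 <- tempfile()
  fx2 <- write_fixture(spec, dir2)
  on.exit(unlink(dir2, recursive = TRUE), add = TRUE)
  for (f in c("network", "obo", "gaf", "orthologs", "slim"))
    expect_identical(readLines(fx2[[f]]), readLines(fx[[f]]))
})
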