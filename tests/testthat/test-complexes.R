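test_that("over-representation p-values match direct hypergeometric tails", {
  dag <- parse_obo(tiny_obo())
  # 3-protein cluster fully annotated to d, 3 carriers among 30 background
  carriers <- paste0("c", 1:3)
  others <- paste0("u", 1:27)
  ann <- annotation_set(
    c(stats::setNames(rep(list("GO:0000005"), 3), carriers),
      stats::setNames(rep(list("GO:0000007"), 27), others)), dag)
  res <- enrich(carriers, c(carriers, others), ann, dag)
  p <- res$p_raw[res$term == "GO:0000005"]
  expect_equal(p, 1 / choose(30, 3), tolerance = 1e-12)
  expect_equal(p, fisher_tail_oracle(3L, 3L, 3L, 30L), tolerance = 1e-12)

  # a term carried by the whole background is never enriched
  root_p <- res$p_raw[res$term == "GO:0000001"]
  expect_equal(root_p, 1)

  # Bonferroni: corrected = m * raw, capped at 1
  m <- nrow(res)
  expect_equal(res$p_corrected, pmin(1, m * res$p_raw))
  expect_true(all(res$p_corrected >= res$p_raw))
  expect_true(all(res$k <= pmin(res$cluster_size, res$K)))

  expect_error(enrich(character(0), carriers, ann, dag), "empty")
  expect_error(enrich("nope", carriers, ann, dag), "subset")
})

test_that("coherence demands strict majority, strict alpha and minimum level", {
  dag <- parse_obo(tiny_obo())
  res <- function(term, k, n, p) data.frame(term = term, k = k,
                                            cluster_size = n, K = k, N = 30,
                                            p_raw = p / 2, p_corrected = p)
  # all three criteria met: level-4 term, 3 of 4, p below alpha
  expect_equal(coherent_functions(res("GO:0000005", 3, 4, 5e-4), dag),
               "GO:0000005")
  # exactly half is not "more than half"
  expect_length(coherent_functions(res("GO:0000005", 2, 4, 5e-4), dag), 0L)
  # level 3 rejected regardless of p
  expect_length(coherent_functions(res("GO:0000006", 4, 4, 1e-9), dag), 0L)
  # corrected p equal to alpha fails the strict inequality
  expect_length(coherent_functions(res("GO:0000005", 3, 4, 1e-3), dag), 0L)

  # filial frontier: ancestor of another survivor is dropped
  both <- rbind(res("GO:0000005", 3, 4, 5e-4), res("GO:0000004", 3, 4, 5e-4))
  expect_equal(coherent_functions(both, dag), "GO:0000005")
})

test_that("putative complexes carry filial plus inherited functions, roots excluded", {
  dag <- parse_obo(tiny_obo())
  carriers <- paste0("c", 1:4)
  others <- paste0("u", 1:26)
  ann <- annotation_set(
    c(stats::setNames(rep(list("GO:0000005"), 4), carriers),
      stats::setNames(rep(list("GO:0000007"), 26), others)), dag)
  cs <- structure(list(clusters = list(carriers, paste0("u", 1:3)),
                       label = "OC", inflation = 1.8, tol = 1e-6,
                       converged = TRUE),
                  class = "cluster_set")
  cx <- infer_complexes(cs, c(carriers, others), ann, dag)
  # the u-cluster has no coherent function and is dropped
  expect_length(cx, 1L)
  expect_equal(cx[[1L]]$filial_functions, "GO:0000005")
  expect_setequal(cx[[1L]]$full_functions,
                  c("GO:0000005", "GO:0000004", "GO:0000003", "GO:0000002"))
  expect_false("GO:0000001" %in% cx[[1L]]$full_functions)

  # every member, annotated or not, receives every filial function
  preds <- predict_protein_functions(cx[[1L]])
  expect_named(preds, carriers)
  expect_true(all(vapply(preds, identical, NA, "GO:0000005")))
})

test_that("a fully unannotated protein still receives the complex's prediction", {
  dag <- parse_obo(tiny_obo())
  members <- c(paste0("c", 1:3), "orphan")
  others <- paste0("u", 1:56)
  ann <- annotation_set(
    c(stats::setNames(rep(list("GO:0000005"), 3), paste0("c", 1:3)),
      stats::setNames(rep(list("GO:0000007"), 56), others)), dag)
  cs <- structure(list(clusters = list(members), label = "OC",
                       inflation = 1.8, tol = 1e-6, converged = TRUE),
                  class = "cluster_set")
  cx <- infer_complexes(cs, c(members, others), ann, dag)
  expect_length(cx, 1L)
  expect_equal(predict_protein_functions(cx[[1L]])$orphan, "GO:0000005")
})
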