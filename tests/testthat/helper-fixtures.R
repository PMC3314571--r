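# shared builders for small in-code fixtures

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

edge_file <- function(...) write_lines_tmp(c(...), ".tsv")

# tiny ontology: one BP root with a 4-deep chain and a diamond, plus an
# alt_id alias and an obsolete stanza
tiny_obo <- function() {
  write_lines_tmp(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root", "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: a", "namespace: biological_process",
    "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000003", "name: b", "namespace: biological_process",
    "is_a: GO:0000002", "",
    "[Term]", "id: GO:0000004", "name: c", "namespace: biological_process",
    "is_a: GO:0000003", "alt_id: GO:0000444", "",
    "[Term]", "id: GO:0000005", "name: d", "namespace: biological_process",
    "is_a: GO:0000004", "",
    # diamond: GO:0000006 reachable from root via a 2-edge and a 3-edge path
    "[Term]", "id: GO:0000007", "name: short-arm", "namespace: biological_process",
    "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000006", "name: diamond-bottom", "namespace: biological_process",
    "is_a: GO:0000007", "is_a: GO:0000003", "",
    "[Term]", "id: GO:0000099", "name: gone", "namespace: biological_process",
    "is_obsolete: true", ""
  ), ".obo")
}

gaf_row <- function(protein, term, evidence = "IDA", qualifier = "") {
  paste("DB", protein, protein, qualifier, term, "REF:1", evidence, "",
        "P", protein, "", "protein", "taxon:0", "20100101", "DB", "", "",
        sep = "\t")
}

gaf_file <- function(...) write_lines_tmp(c("!gaf-version: 2.1", ...), ".gaf")

# annotation set built directly from a protein -> terms list
ann_from <- function(dag, ...) annotation_set(list(...), dag)

# exhaustive hypergeometric upper-tail oracle: direct binomial-coefficient
# summation, independent of phyper
fisher_tail_oracle <- function(k, n, K, N) {
  lo <- max(k, max(0L, n + K - N))
  hi <- min(n, K)
  if (lo > hi) return(0)
  i <- lo:hi
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# deterministic small weighted graph generator for oracle comparisons
random_test_graph <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  pairs <- which(upper.tri(diag(n_nodes)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p_edge
  # guarantee at least one edge
  if (!any(keep)) keep[1L] <- TRUE
  data.frame(a = sprintf("n%02d", pairs[keep, 1L]),
             b = sprintf("n%02d", pairs[keep, 2L]),
             weight = round(runif(sum(keep), 0.2, 1), 3),
             stringsAsFactors = FALSE)
}

# canonical form of a partition for set comparison
canon_partition <- function(clusters) {
  s <- lapply(clusters, function(x) sort(as.character(x)))
  s[order(vapply(s, `[[`, "", 1L))]
}
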