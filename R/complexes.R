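#' GO over-representation of a cluster by one-sided Fisher's exact test
#'
#' For every term carried (after true-path propagation) by at least one
#' cluster protein, tests over-representation of the term in the cluster
#' against the background universe with the one-sided Fisher's exact test
#' on the 2x2 table (k, n-k; K-k, N-K-n+k), i.e. the upper hypergeometric
#' tail P(X >= k).  P-values are Bonferroni-corrected with m = number of
#' terms tested for this cluster, capped at 1.
#'
#' @param cluster character vector of protein IDs (subset of `background`).
#' @param background character vector: the enrichment universe, normally
#'   the non-singleton proteins `B(X)` of the induced subnetwork the
#'   cluster came from.
#' @param ann an `annotation_set`.
#' @param dag a `go_dag`.
#' @return data.frame with columns `term`, `k` (cluster proteins carrying
#'   the term), `cluster_size`, `K` (background carriers), `N`
#'   (background size), `p_raw`, `p_corrected`, sorted by `p_raw`.
#' @export
enrich <- function(cluster, background, ann, dag) {
  cluster <- unique(as.character(cluster))
  background <- unique(as.character(background))
  if (length(cluster) == 0L) stop("enrich: empty cluster")
  if (!all(cluster %in% background))
    stop("enrich: cluster must be a subset of the background universe")
  n <- length(cluster)
  N <- length(background)
  k_tab <- term_counts(ann, cluster)
  if (length(k_tab) == 0L)
    return(data.frame(term = character(), k = integer(),
                      cluster_size = integer(), K = integer(), N = integer(),
                      p_raw = numeric(), p_corrected = numeric()))
  K_tab <- term_counts(ann, background)
  terms <- names(k_tab)
  k <- as.integer(k_tab)
  K <- as.integer(K_tab[terms])
  p <- fisher_over(k, n, K, N)
  m <- length(terms)
  out <- data.frame(term = terms, k = k, cluster_size = n, K = K, N = N,
                    p_raw = p, p_corrected = pmin(1, m * p),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_raw, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# counts of proteins (within `ids`) carrying each propagated term
term_counts <- function(ann, ids) {
  ts <- unlist(ann$propagated[intersect(ids, names(ann$propagated))],
               use.names = FALSE)
  if (!length(ts)) return(integer(0))
  table(ts) |> c()
}

# upper-tail hypergeometric probability P(X >= k); vectorised
fisher_over <- function(k, n, K, N) {
  stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Significantly coherent functions of a cluster
#'
#' A term is a significantly coherent function of a cluster when all three
#' criteria hold: (1) its Bonferroni-corrected enrichment p-value is below
#' `alpha`; (2) strictly more than half of the cluster's proteins carry
#' the term; (3) the term sits at level >= `min_level` of the GO
#' hierarchy.  The surviving terms are then reduced to the filial
#' frontier: any term that is an ancestor of another survivor is dropped,
#' so no parent-child pair remains.
#'
#' @param results the data.frame returned by [enrich()] for this cluster.
#' @param dag a `go_dag`.
#' @param alpha significance threshold on the corrected p-value (strict).
#' @param min_level minimum GO level (longest path from the root).
#' @return Character vector of filial coherent terms (possibly empty).
#' @export
coherent_functions <- function(results, dag, alpha = 0.001, min_level = 4L) {
  if (nrow(results) == 0L) return(character(0))
  keep <- results$p_corrected < alpha &
    results$k > results$cluster_size / 2 &
    dag$level[results$term] >= min_level
  terms <- results$term[keep]
  filial_frontier(terms, dag)
}

# drop every term that is an ancestor of another term in the set
filial_frontier <- function(terms, dag) {
  if (length(terms) <= 1L) return(terms)
  anc <- unique(unlist(dag$ancestors[terms], use.names = FALSE))
  sort(setdiff(terms, anc))
}

#' Infer putative complexes from a cluster set
#'
#' Each cluster (already size-filtered) with at least one significantly
#' coherent function becomes a putative protein complex.  The complex
#' carries its filial functions and, by annotation inheritance, the full
#' set: the filial terms plus all their ancestors (ontology roots
#' excluded).  Clusters with no coherent function make no prediction and
#' are dropped.
#'
#' @param cs a `cluster_set` (apply [filter_min_size()] first).
#' @param background enrichment universe, normally `B(X)` of the run.
#' @param ann an `annotation_set`.
#' @param dag a `go_dag`.
#' @param alpha,min_level coherence thresholds, see [coherent_functions()].
#' @return List of `putative_complex` objects: each a list with
#'   `proteins`, `filial_functions`, `full_functions`, `label`.
#' @export
infer_complexes <- function(cs, background, ann, dag,
                            alpha = 0.001, min_level = 4L) {
  stopifnot(inherits(cs, "cluster_set"))
  out <- list()
  for (cl in cs$clusters) {
    res <- enrich(cl, background, ann, dag)
    filial <- coherent_functions(res, dag, alpha = alpha, min_level = min_level)
    if (length(filial) == 0L) next
    full <- setdiff(unique(c(filial,
                             unlist(dag$ancestors[filial], use.names = FALSE))),
                    dag$roots)
    out[[length(out) + 1L]] <- structure(
      list(proteins = sort(cl), filial_functions = sort(filial),
           full_functions = sort(full), label = cs$label),
      class = "putative_complex")
  }
  out
}

#' @export
print.putative_complex <- function(x, ...) {
  cat(sprintf("<putative_complex> [%s] %d proteins; filial: %s\n",
              x$label, length(x$proteins),
              paste(x$filial_functions, collapse = ", ")))
  invisible(x)
}

#' Protein-function predictions of a putative complex
#'
#' Every protein of the complex — including proteins with no prior
#' annotation — is predicted to perform every filial function of the
#' complex.
#'
#' @param cx a `putative_complex`.
#' @return Named list, protein ID -> character vector of predicted terms.
#' @export
predict_protein_functions <- function(cx) {
  stopifnot(inherits(cx, "putative_complex"))
  stats::setNames(rep(list(cx$filial_functions), length(cx$proteins)),
                  cx$proteins)
}

# all (protein, filial function) prediction pairs of a complex list
prediction_pairs <- function(complexes) {
  if (!length(complexes))
    return(data.frame(protein = character(), term = character()))
  do.call(rbind, lapply(complexes, function(cx)
    expand.grid(protein = cx$proteins, term = cx$filial_functions,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
}
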