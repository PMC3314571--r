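#' Markov Cluster algorithm on a weighted PPI network
#'
#' Runs MCL: the weighted adjacency matrix is given one self-loop per node
#' (weight equal to the node's largest incident edge weight), columns are
#' normalised to a stochastic flow matrix, and expansion (matrix squaring)
#' alternates with inflation (entrywise power followed by column
#' renormalisation) until the matrix stops changing.  Clusters are read
#' from the attractor structure of the limit matrix.  The procedure is
#' deterministic: identical input and parameters give an identical
#' partition.
#'
#' @param net a [ppi_network] or an [induced_subnetwork].
#' @param inflation inflation exponent (> 1); granularity knob.  The
#'   default 1.8 is the standard setting for PPI networks.
#' @param max_iters iteration cap; reaching it without convergence gives a
#'   warning and best-effort clusters.
#' @param tol convergence tolerance on the largest absolute entry change.
#' @param prune entries below this value are zeroed each iteration to keep
#'   the flow matrix sparse.
#' @param label tag recorded on the result (e.g. "GYC", "OYC-E").
#' @return An object of class `cluster_set`: list with `clusters` (list of
#'   character vectors, a partition of the clustered nodes), `label`,
#'   `inflation`, `tol` and `converged`.
#' @export
mcl_cluster <- function(net, inflation = 1.8, max_iters = 100L, tol = 1e-6,
                        prune = 1e-8, label = "clusters") {
  if (inherits(net, "induced_subnetwork")) net <- net$graph
  stopifnot(inherits(net, "ppi_network"))
  nodes <- net$nodes
  nv <- length(nodes)
  if (nv == 0L) stop("mcl_cluster: empty network")
  if (inflation <= 1) stop("mcl_cluster: inflation must exceed 1")

  idx <- stats::setNames(seq_len(nv), nodes)
  e <- net$edges
  i <- c(idx[e$a], idx[e$b])
  j <- c(idx[e$b], idx[e$a])
  w <- c(e$weight, e$weight)
  # self-loops: each node gets its maximum incident weight (isolated: 1)
  loop <- rep(1, nv)
  if (nrow(e)) {
    mx <- tapply(w, i, max)
    loop[as.integer(names(mx))] <- mx
  }
  m <- Matrix::sparseMatrix(i = c(i, seq_len(nv)), j = c(j, seq_len(nv)),
                            x = c(w, loop), dims = c(nv, nv))
  m <- normalise_cols(m)

  converged <- FALSE
  for (it in seq_len(max_iters)) {
    m2 <- m %*% m                     # expansion
    m2@x <- m2@x ^ inflation          # inflation
    m2 <- Matrix::drop0(m2)
    m2@x[m2@x < prune] <- 0
    m2 <- normalise_cols(Matrix::drop0(m2))
    delta <- max(abs(m2 - m))
    m <- m2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("MCL did not converge in %d iterations; returning best-effort clusters",
                    max_iters), call. = FALSE)

  clusters <- interpret_attractors(m, nodes)
  structure(list(clusters = clusters, label = label, inflation = inflation,
                 tol = tol, converged = converged),
            class = "cluster_set")
}

normalise_cols <- function(m) {
  cs <- Matrix::colSums(m)
  cs[cs == 0] <- 1
  m %*% Matrix::Diagonal(x = 1 / cs)
}

# Read the partition out of the MCL limit matrix.  Attractor rows are those
# with positive diagonal mass; attractors sharing flow are merged into one
# attractor system, and every node joins the system it sends flow to.  A
# node reached by several systems (tie-induced overlap) is assigned to the
# one receiving the largest flow, ties broken by smallest attractor ID, so
# the result is always a partition.
interpret_attractors <- function(m, nodes) {
  nv <- length(nodes)
  m <- as(m, "TsparseMatrix")
  attract <- which(Matrix::diag(m) > 0)
  if (length(attract) == 0L) attract <- seq_len(nv)  # degenerate safeguard
  # union attractors that appear in each other's rows (attractor systems)
  comp <- seq_len(nv)
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  unite <- function(x, y) { rx <- find(x); ry <- find(y); if (rx != ry) comp[max(rx, ry)] <<- min(rx, ry) }
  on_rows <- (m@i + 1L) %in% attract & (m@j + 1L) %in% attract & m@x > 0
  for (k in which(on_rows)) unite(m@i[k] + 1L, m@j[k] + 1L)
  # flow from column j into each attractor system
  best_sys <- integer(nv); best_flow <- numeric(nv)
  rows_attr <- (m@i + 1L) %in% attract & m@x > 0
  flow_sys <- vapply(which(rows_attr), function(k) find(m@i[k] + 1L), 1L)
  flow_col <- m@j[rows_attr] + 1L
  flow_val <- m@x[rows_attr]
  agg <- tapply(flow_val, list(flow_col, flow_sys), sum)
  for (cn in rownames(agg)) {
    jcol <- as.integer(cn)
    vals <- stats::setNames(as.numeric(agg[cn, ]), colnames(agg))
    vals <- vals[!is.na(vals)]
    sys <- as.integer(names(vals))
    o <- order(-vals, sys)
    best_sys[jcol] <- sys[o[1L]]
    best_flow[jcol] <- vals[o[1L]]
  }
  # columns with no flow to any attractor (fully pruned): own singleton
  orphan <- which(best_sys == 0L)
  best_sys[orphan] <- -seq_along(orphan)
  split(nodes, best_sys) |> unname() |> lapply(sort)
}

#' Drop clusters below a minimum size
#'
#' Putative complexes must contain more than a single interaction, so
#' clusters smaller than `min_size` (default 3, inclusive bound) are
#' removed.  Order of the surviving clusters is preserved.
#'
#' @param cs a `cluster_set`.
#' @param min_size smallest cluster size retained.
#' @return A `cluster_set` with the small clusters removed.
#' @export
filter_min_size <- function(cs, min_size = 3L) {
  stopifnot(inherits(cs, "cluster_set"), min_size >= 1L)
  cs$clusters <- cs$clusters[lengths(cs$clusters) >= min_size]
  cs
}

#' Summary statistics of a cluster set
#'
#' @param cs a `cluster_set`.
#' @return List with `n_clusters`, `mean_size` (0 for an empty set) and
#'   `empty` flag.
#' @export
cluster_stats <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  sz <- lengths(cs$clusters)
  list(n_clusters = length(sz),
       mean_size = if (length(sz)) mean(sz) else 0,
       empty = length(sz) == 0L)
}

#' @export
print.cluster_set <- function(x, ...) {
  st <- cluster_stats(x)
  cat(sprintf("<cluster_set> '%s': %d clusters, mean size %.2f (inflation %.2f%s)\n",
              x$label, st$n_clusters, st$mean_size, x$inflation,
              if (isTRUE(x$converged)) "" else ", NOT converged"))
  invisible(x)
}

#' Write clusters in the mcl "abc" dump dialect
#'
#' One cluster per line, members tab-separated.
#'
#' @param cs a `cluster_set`.
#' @param path output file.
#' @export
write_clusters <- function(cs, path) {
  stopifnot(inherits(cs, "cluster_set"))
  writeLines(vapply(cs$clusters, paste, "", collapse = "\t"), path)
  invisible(path)
}
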