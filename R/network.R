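#' Construct a weighted, undirected PPI network
#'
#' A `ppi_network` stores a set of protein identifiers and a set of
#' undirected, positively weighted edges.  Edges are stored once with
#' endpoints in lexicographic order; self-loops are not representable.
#'
#' @param edges data.frame with columns `a`, `b` (character protein IDs) and
#'   `weight` (positive numeric confidence score).
#' @param nodes optional character vector of node IDs; defaults to the union
#'   of edge endpoints.  Extra IDs become isolated nodes.
#' @return An object of class `ppi_network` with elements `nodes`
#'   (character) and `edges` (data.frame `a`, `b`, `weight`).
#' @export
ppi_network <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges), all(c("a", "b", "weight") %in% names(edges)))
  edges$a <- as.character(edges$a)
  edges$b <- as.character(edges$b)
  edges$weight <- as.numeric(edges$weight)
  edges <- edges[edges$a != edges$b, , drop = FALSE]
  # canonical endpoint order so (a,b) == (b,a)
  swap <- edges$a > edges$b
  tmp <- edges$a[swap]; edges$a[swap] <- edges$b[swap]; edges$b[swap] <- tmp
  # duplicates keep the maximum weight (conservative merge of evidence)
  if (nrow(edges)) {
    key <- paste(edges$a, edges$b, sep = "\r")
    w <- tapply(edges$weight, key, max)
    parts <- strsplit(names(w), "\r", fixed = TRUE)
    edges <- data.frame(
      a = vapply(parts, `[[`, "", 1L),
      b = vapply(parts, `[[`, "", 2L),
      weight = as.numeric(w),
      stringsAsFactors = FALSE
    )
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  all_nodes <- sort(unique(c(edges$a, edges$b, as.character(nodes))))
  structure(list(nodes = all_nodes, edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d proteins, %d interactions\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges))
    cat(sprintf("  weights in [%.3g, %.3g]\n",
                min(x$edges$weight), max(x$edges$weight)))
  invisible(x)
}

#' Read a weighted PPI edge list
#'
#' Reads a whitespace- or tab-separated edge list (two protein ID columns
#' and one numeric confidence weight; `#` starts a comment).  Duplicate
#' edges are collapsed keeping the maximum weight, self-loops are dropped,
#' and, if `min_weight` is given, edges with weight strictly below it are
#' removed followed by any node left without an edge.
#'
#' @param path path to the edge-list file.
#' @param min_weight optional confidence threshold; edges with
#'   `weight < min_weight` are discarded.
#' @return A [ppi_network].
#' @export
load_network <- function(path, min_weight = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(trimws(lines) != "")
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  bad <- which(lengths(fields) != 3L)
  if (length(bad))
    stop(sprintf("malformed edge-list row at line %d of %s (expected 2 IDs and a weight)",
                 keep[bad[1L]], path))
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  w <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(w))
    stop(sprintf("non-numeric weight at line %d of %s",
                 keep[which(is.na(w))[1L]], path))
  n_self <- sum(a == b)
  if (n_self)
    message(sprintf("load_network: dropped %d self-loop(s)", n_self))
  net <- ppi_network(data.frame(a = a, b = b, weight = w,
                                stringsAsFactors = FALSE))
  if (!is.null(min_weight)) {
    e <- net$edges[net$edges$weight >= min_weight, , drop = FALSE]
    net <- ppi_network(e)  # isolated nodes fall away with their edges
  }
  if (length(net$nodes) == 0L)
    stop("network is empty after filtering")
  net
}

#' Induce the subnetwork spanned by a protein set
#'
#' Restricts a network to the nodes in `ids`: the induced graph `G[X]`
#' keeps exactly the edges with both endpoints in `X`.  Proteins of `X`
#' absent from the network are ignored with a warning.  Nodes of `G[X]`
#' with no remaining interaction are the singletons `X0`; the background
#' `B(X)` is the non-singleton remainder, the protein universe used for
#' enrichment and the retrieval index.
#'
#' @param net a [ppi_network].
#' @param ids character vector of protein IDs (the set `X`).
#' @param label free-text tag carried through to downstream reports.
#' @return An object of class `induced_subnetwork`: list with `graph`
#'   (a [ppi_network] over `X`), `source` (the IDs used), `singletons`,
#'   `background` and `label`.
#' @export
induce_subgraph <- function(net, ids, label = "subnetwork") {
  stopifnot(inherits(net, "ppi_network"))
  ids <- unique(as.character(ids))
  unknown <- setdiff(ids, net$nodes)
  if (length(unknown))
    warning(sprintf("induce_subgraph: %d protein(s) not in the network were ignored",
                    length(unknown)), call. = FALSE)
  x <- intersect(ids, net$nodes)
  if (length(x) == 0L)
    stop("induce_subgraph: no protein of the given set occurs in the network")
  e <- net$edges[net$edges$a %in% x & net$edges$b %in% x, , drop = FALSE]
  g <- ppi_network(e, nodes = x)
  connected <- unique(c(g$edges$a, g$edges$b))
  singletons <- setdiff(g$nodes, connected)
  structure(list(graph = g,
                 source = x,
                 singletons = singletons,
                 background = setdiff(g$nodes, singletons),
                 label = label),
            class = "induced_subnetwork")
}

#' @export
print.induced_subnetwork <- function(x, ...) {
  cat(sprintf("<induced_subnetwork> '%s': %d proteins (%d singletons, %d background), %d interactions\n",
              x$label, length(x$graph$nodes), length(x$singletons),
              length(x$background), nrow(x$graph$edges)))
  invisible(x)
}

#' Sample a random protein set from a network
#'
#' Draws `n` proteins uniformly at random, without replacement, from all
#' nodes of the network (singleton-prone nodes included).  A fixed seed
#' yields a reproducible sample without disturbing the caller's RNG state.
#'
#' @param net a [ppi_network].
#' @param n sample size, `1 <= n <= |V|`.
#' @param seed integer seed for the draw.
#' @return Character vector of `n` protein IDs.
#' @export
sample_random_set <- function(net, n, seed) {
  stopifnot(inherits(net, "ppi_network"))
  if (n < 1L || n > length(net$nodes))
    stop(sprintf("sample size n=%d outside 1..%d", n, length(net$nodes)))
  with_seed(seed, sample(net$nodes, n))
}

# Run code under a temporary RNG seed, restoring the global state after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
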