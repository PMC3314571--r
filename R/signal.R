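#' Retrieval index of functions in a protein sample
#'
#' For a sample `X` with background `B(X)` (non-singleton proteins of
#' `G[X]`) and `S(X)` the union of proteins over the putative complexes
#' discovered in `G[X]`, the retrieval index of a function `f` is
#'
#'   rho(f, X) = |P(f, S(X))| / |P(f, B(X))|
#'
#' where `P(f, U) = U` intersected with the candidate set `C(f)` (proteins
#' experimentally annotated to `f` or a descendant).  It measures which
#' fraction of the sample's carriers of `f` the complexes capture.  Terms
#' with an empty denominator are marked undefined and excluded from
#' comparisons.
#'
#' @param sub an `induced_subnetwork`.
#' @param complexes list of `putative_complex` derived from `sub`.
#' @param ann an `annotation_set`.
#' @param dag a `go_dag`.
#' @param terms terms to evaluate; defaults to every term carried by a
#'   background protein.
#' @return data.frame with columns `term`, `numerator`, `denominator`,
#'   `value` (NA where undefined) and `defined`.
#' @export
retrieval_index <- function(sub, complexes, ann, dag, terms = NULL) {
  stopifnot(inherits(sub, "induced_subnetwork"))
  B <- sub$background
  S <- unique(unlist(lapply(complexes, `[[`, "proteins"), use.names = FALSE))
  den_tab <- term_counts(ann, B)
  num_tab <- term_counts(ann, intersect(S, B))
  if (is.null(terms)) terms <- names(den_tab)
  num <- ifelse(terms %in% names(num_tab), num_tab[terms], 0L)
  den <- ifelse(terms %in% names(den_tab), den_tab[terms], 0L)
  data.frame(term = terms,
             numerator = as.integer(num),
             denominator = as.integer(den),
             value = ifelse(den > 0, num / den, NA_real_),
             defined = den > 0,
             stringsAsFactors = FALSE)
}

#' Upper 95th-percentile order statistic
#'
#' Sorts ascending and returns the element at 1-based rank
#' `ceiling(p * N)` — always an actual sample value, never an
#' interpolation, matching the definition of the random-run threshold as
#' one of the observed runs.
#'
#' @param values non-empty numeric vector.
#' @param p percentile in (0, 1]; default 0.95.
#' @return A single element of `values`.
#' @export
percentile95 <- function(values, p = 0.95) {
  if (length(values) == 0L) stop("percentile95: empty vector")
  sort(values)[ceiling(p * length(values))]
}

#' Retrieval-index null distribution from random protein samples
#'
#' Repeats the whole pipeline on random protein samples: draw `n` proteins
#' uniformly from the network, induce the subnetwork, cluster with MCL,
#' size-filter, infer putative complexes, and record the retrieval index
#' of every term annotated in that run's background.  A term absent from a
#' run's defined records contributes rho = 0 for that run (absence of
#' retrieval is zero retrieval), so every term's distribution holds
#' exactly `n_runs` values.  Per-run seeds are `seed + i`, making the null
#' bitwise reproducible.
#'
#' @param net the parent `ppi_network`.
#' @param n random sample size (matched to the ortholog set size).
#' @param ann,dag annotation set and GO DAG.
#' @param n_runs number of random runs.
#' @param seed base seed.
#' @param inflation,min_size,alpha,min_level pipeline parameters.
#' @return An object of class `null_distribution`: list with `values`
#'   (term x run matrix of rho), `threshold95` (named vector, the
#'   rank-ceil(0.95 N) order statistic per term), `n_runs`, `n`, `seed`
#'   and `run_stats` (per-run cluster/complex counts and mean sizes).
#' @export
build_null <- function(net, n, ann, dag, n_runs = 1000L, seed = 1L,
                       inflation = 1.8, min_size = 3L,
                       alpha = 0.001, min_level = 4L) {
  stopifnot(inherits(net, "ppi_network"), n_runs >= 1L)
  per_run <- vector("list", n_runs)
  stats_df <- data.frame(run = seq_len(n_runs), n_clusters = 0L,
                         mean_cluster_size = 0, n_complexes = 0L,
                         mean_complex_size = 0)
  for (i in seq_len(n_runs)) {
    ids <- sample_random_set(net, n, seed = seed + i)
    sub <- induce_subgraph(net, ids, label = sprintf("R%d", i))
    run <- run_branch(sub, ann, dag, inflation = inflation,
                      min_size = min_size, alpha = alpha,
                      min_level = min_level)
    rho <- run$rho
    per_run[[i]] <- stats::setNames(rho$value[rho$defined],
                                    rho$term[rho$defined])
    st <- cluster_stats(run$clusters)
    csz <- lengths(lapply(run$complexes, `[[`, "proteins"))
    stats_df$n_clusters[i] <- st$n_clusters
    stats_df$mean_cluster_size[i] <- st$mean_size
    stats_df$n_complexes[i] <- length(csz)
    stats_df$mean_complex_size[i] <- if (length(csz)) mean(csz) else 0
  }
  terms <- sort(unique(unlist(lapply(per_run, names), use.names = FALSE)))
  values <- matrix(0, nrow = length(terms), ncol = n_runs,
                   dimnames = list(terms, NULL))
  for (i in seq_len(n_runs)) {
    v <- per_run[[i]]
    if (length(v)) values[names(v), i] <- v
  }
  thr <- apply(values, 1L, percentile95)
  structure(list(values = values, threshold95 = thr, n_runs = n_runs,
                 n = n, seed = seed, run_stats = stats_df),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d runs of n=%d: %d terms, mean clusters/run %.1f, mean complexes/run %.1f\n",
              x$n_runs, x$n, nrow(x$values),
              mean(x$run_stats$n_clusters), mean(x$run_stats$n_complexes)))
  invisible(x)
}

# one clustering branch: induce -> MCL -> size filter -> complexes -> rho
run_branch <- function(sub, ann, dag, inflation = 1.8, min_size = 3L,
                       alpha = 0.001, min_level = 4L) {
  cs <- mcl_cluster(sub, inflation = inflation, label = sub$label)
  raw <- cs
  cs <- filter_min_size(cs, min_size)
  cx <- infer_complexes(cs, sub$background, ann, dag,
                        alpha = alpha, min_level = min_level)
  rho <- retrieval_index(sub, cx, ann, dag)
  list(sub = sub, clusters_raw = raw, clusters = cs, complexes = cx, rho = rho)
}

#' Orthology-related functions (differential retrieval rule)
#'
#' A function `f` is orthology-related iff its retrieval in the ortholog
#' sample strictly exceeds both its retrieval in the whole network and the
#' upper 95th percentile of its retrieval over the random runs:
#'
#'   rho(f, O) > max(rho(f, V), rho(f, R95))
#'
#' Only terms with a defined rho(f, O) (at least one candidate protein in
#' `B(O)`) are eligible; an undefined rho(f, V) counts as 0, and a term
#' never seen in the random runs has threshold 0.
#'
#' @param rho_o retrieval data.frame of the ortholog run.
#' @param rho_v retrieval data.frame of the whole-network run.
#' @param null a `null_distribution` (or a named threshold vector).
#' @return Character vector of orthology-related terms.
#' @export
orthology_related_functions <- function(rho_o, rho_v, null) {
  thr <- if (inherits(null, "null_distribution")) null$threshold95 else null
  o <- rho_o[rho_o$defined, , drop = FALSE]
  v <- stats::setNames(rho_v$value[rho_v$defined], rho_v$term[rho_v$defined])
  comp_v <- ifelse(o$term %in% names(v), v[o$term], 0)
  comp_r <- ifelse(o$term %in% names(thr), thr[o$term], 0)
  sort(o$term[o$value > pmax(comp_v, comp_r)])
}

#' Orthology-related complexes
#'
#' An ortholog-class complex is orthology-related when at least one
#' orthology-related function occurs in its full annotation set (filial
#' functions plus inherited ancestors).
#'
#' @param complexes list of `putative_complex` from the ortholog run.
#' @param related character vector of orthology-related terms.
#' @return Sub-list of `complexes`.
#' @export
orthology_related_complexes <- function(complexes, related) {
  Filter(function(cx) length(intersect(cx$full_functions, related)) > 0L,
         complexes)
}

#' Complexes with predictions unique to the ortholog class
#'
#' An ortholog-class complex is unique when it makes at least one
#' (protein, filial function) prediction that no global-class complex
#' containing that protein makes.
#'
#' @param oc list of ortholog-class `putative_complex`.
#' @param gc list of global-class `putative_complex`.
#' @return Sub-list of `oc`: the unique complexes, each with an attribute
#'   `"unique_pairs"` holding its uniqueness-conferring prediction pairs.
#' @export
unique_complexes <- function(oc, gc) {
  gc_pairs <- prediction_pairs(gc)
  gc_key <- paste(gc_pairs$protein, gc_pairs$term, sep = "\r")
  out <- list()
  for (cx in oc) {
    p <- prediction_pairs(list(cx))
    new <- !(paste(p$protein, p$term, sep = "\r") %in% gc_key)
    if (any(new)) {
      attr(cx, "unique_pairs") <- p[new, , drop = FALSE]
      out[[length(out) + 1L]] <- cx
    }
  }
  out
}

#' Classify unique predictions as verified or novel
#'
#' A unique (protein, function) prediction is verified when the reference
#' annotation set (experimental plus computational evidence, i.e. a wider
#' whitelist than the pipeline's) already carries the function — directly
#' or via a descendant term — for that protein; otherwise it is novel.  A
#' complex can hold predictions of both kinds.
#'
#' @param cx a `putative_complex` carrying a `"unique_pairs"` attribute
#'   (as produced by [unique_complexes()]).
#' @param reference an `annotation_set` built with the wider whitelist.
#' @return List with data.frames `verified` and `novel` (columns
#'   `protein`, `term`).
#' @export
classify_predictions <- function(cx, reference) {
  pairs <- attr(cx, "unique_pairs")
  if (is.null(pairs)) pairs <- prediction_pairs(list(cx))
  hit <- vapply(seq_len(nrow(pairs)), function(i) {
    ts <- reference$propagated[[pairs$protein[i]]]
    !is.null(ts) && pairs$term[i] %in% ts
  }, NA)
  list(verified = pairs[hit, , drop = FALSE],
       novel = pairs[!hit, , drop = FALSE])
}

#' Roll related functions up to GO-slim categories
#'
#' Maps each related function to every slim term among its
#' ancestors-or-self; functions with no slim ancestor land in the
#' `"unslimmed"` bucket.
#'
#' @param related character vector of term IDs.
#' @param slim character vector of GO-slim term IDs.
#' @param dag a `go_dag`.
#' @return Named list, slim term -> character vector of related terms.
#' @export
goslim_summarize <- function(related, slim, dag) {
  out <- stats::setNames(vector("list", length(slim)), slim)
  unslimmed <- character(0)
  for (f in related) {
    up <- intersect(c(f, term_ancestors(dag, f)), slim)
    if (length(up) == 0L) unslimmed <- c(unslimmed, f)
    for (s in up) out[[s]] <- c(out[[s]], f)
  }
  out <- out[lengths(out) > 0L]
  if (length(unslimmed)) out$unslimmed <- unslimmed
  out
}
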