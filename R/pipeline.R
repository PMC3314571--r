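#' Assemble a pipeline run configuration
#'
#' Collects the file paths and parameters of a full orthology-signal run.
#' Defaults mirror the published analysis protocol: MCL inflation 1.8,
#' minimum cluster size 3, coherence threshold 0.001 on the
#' Bonferroni-corrected p-value, minimum GO level 4, 1000 random runs and
#' the upper 95th percentile as the random-sample threshold.
#'
#' @param network edge-list file of the weighted PPI network.
#' @param obo GO ontology file (OBO 1.2).
#' @param gaf gene-association file (GAF 2.x) for the experimental
#'   annotation set.
#' @param orthologs named character vector of ortholog ID-list files, one
#'   per comparison species; names become the OC run labels.
#' @param slim optional GO-slim term-list file.
#' @param reference_gaf optional association file for the wider
#'   (experimental + computational) reference set used to classify
#'   verified vs novel predictions; defaults to `gaf` read with the
#'   reference whitelist.
#' @param out_dir directory for reports, cluster dumps and the manifest.
#' @param min_weight optional confidence threshold on edges.
#' @param inflation MCL inflation parameter.
#' @param min_cluster_size smallest cluster kept as a complex candidate.
#' @param alpha significance threshold on the corrected p-value.
#' @param min_level minimum GO level of a coherent function.
#' @param n_runs number of random-sampling runs for the null.
#' @param percentile random-run percentile used as threshold.
#' @param evidence evidence-code whitelist for the pipeline annotations.
#' @param reference_evidence whitelist for the reference set.
#' @param seed base seed; run `i` of each null uses `seed + i` (offset per
#'   ortholog set so no two runs share a seed).
#' @return A list of class `run_config`.
#' @export
run_config <- function(network, obo, gaf, orthologs, slim = NULL,
                       reference_gaf = NULL,
                       out_dir = file.path(tempdir(), "orthosignal_run"),
                       min_weight = NULL, inflation = 1.8,
                       min_cluster_size = 3L, alpha = 0.001, min_level = 4L,
                       n_runs = 1000L, percentile = 0.95,
                       evidence = c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP"),
                       reference_evidence = c("EXP", "IDA", "IPI", "IMP",
                                              "IGI", "IEP", "ISS", "ISO",
                                              "ISA", "ISM", "IGC", "IBA",
                                              "RCA", "TAS", "NAS", "IC",
                                              "IEA"),
                       seed = 1L) {
  orthologs <- unlist(orthologs)
  if (is.null(names(orthologs)) || any(!nzchar(names(orthologs))))
    names(orthologs) <- sprintf("OC-%d", seq_along(orthologs))
  for (p in c(network, obo, gaf, unname(orthologs), slim, reference_gaf))
    if (!file.exists(p)) stop("run_config: missing input file ", p)
  structure(list(network = network, obo = obo, gaf = gaf,
                 orthologs = orthologs, slim = slim,
                 reference_gaf = reference_gaf, out_dir = out_dir,
                 min_weight = min_weight, inflation = inflation,
                 min_cluster_size = as.integer(min_cluster_size),
                 alpha = alpha, min_level = as.integer(min_level),
                 n_runs = as.integer(n_runs), percentile = percentile,
                 evidence = evidence, reference_evidence = reference_evidence,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys are the arguments of [run_config()]; relative paths are resolved
#' against the YAML file's directory.
#'
#' @param path YAML file.
#' @param ... overrides (e.g. `seed`, `n_runs`) applied on top.
#' @return A `run_config`.
#' @export
read_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  for (k in c("network", "obo", "gaf", "slim", "reference_gaf"))
    if (!is.null(y[[k]])) y[[k]] <- rel(y[[k]])
  if (!is.null(y$orthologs)) {
    o <- unlist(y$orthologs)
    y$orthologs <- stats::setNames(rel(unname(o)), names(o))
  }
  over <- list(...)
  y[names(over)] <- over
  do.call(run_config, y)
}

#' Run the full orthology-signal pipeline
#'
#' Executes the five-step protocol: (1) read the network, ontology,
#' annotations and ortholog sets; (2) cluster the whole network (GC
#' class), each ortholog-induced subnetwork (OC class) and `n_runs`
#' random-induced subnetworks per ortholog set (RC class) with MCL;
#' (3) infer putative complexes and their coherent functions for every
#' branch and compute per-function retrieval indexes; (4) select the
#' orthology-related functions by the differential rule
#' rho(f,O) > max(rho(f,V), rho(f,R95)); (5) report the related
#' complexes, the complexes unique to the ortholog class, their
#' verified/novel predictions, and a GO-slim summary.  All outputs are
#' also written as TSV files under `cfg$out_dir` next to a manifest
#' recording every parameter and seed.
#'
#' @param cfg a [run_config()].
#' @param write_files write TSV reports and cluster dumps (default TRUE).
#' @return An object of class `signal_report`.
#' @export
run_pipeline <- function(cfg, write_files = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  net <- load_network(cfg$network, cfg$min_weight)
  dag <- parse_obo(cfg$obo)
  ann <- parse_gaf(cfg$gaf, dag, whitelist = cfg$evidence)
  ref <- parse_gaf(if (is.null(cfg$reference_gaf)) cfg$gaf else cfg$reference_gaf,
                   dag, whitelist = cfg$reference_evidence)
  slim <- if (!is.null(cfg$slim)) read_slim(cfg$slim, dag)

  gc_sub <- induce_subgraph(net, net$nodes, label = "GC")
  gc <- run_branch(gc_sub, ann, dag, inflation = cfg$inflation,
                   min_size = cfg$min_cluster_size, alpha = cfg$alpha,
                   min_level = cfg$min_level)

  sets <- vector("list", length(cfg$orthologs))
  names(sets) <- names(cfg$orthologs)
  for (i in seq_along(cfg$orthologs)) {
    label <- names(cfg$orthologs)[i]
    ids <- readLines(cfg$orthologs[[i]], warn = FALSE)
    ids <- trimws(sub("#.*$", "", ids))
    ids <- ids[nzchar(ids)]
    oc_sub <- induce_subgraph(net, ids, label = label)
    oc <- run_branch(oc_sub, ann, dag, inflation = cfg$inflation,
                     min_size = cfg$min_cluster_size, alpha = cfg$alpha,
                     min_level = cfg$min_level)
    null <- build_null(net, n = length(oc_sub$source), ann, dag,
                       n_runs = cfg$n_runs,
                       seed = cfg$seed + (i - 1L) * cfg$n_runs,
                       inflation = cfg$inflation,
                       min_size = cfg$min_cluster_size,
                       alpha = cfg$alpha, min_level = cfg$min_level)
    related <- orthology_related_functions(oc$rho, gc$rho, null)
    related_cx <- orthology_related_complexes(oc$complexes, related)
    uniq <- unique_complexes(oc$complexes, gc$complexes)
    classes <- lapply(uniq, classify_predictions, reference = ref)
    sets[[i]] <- list(label = label, oc = oc, null = null,
                      related_functions = related,
                      related_complexes = related_cx,
                      unique_complexes = uniq,
                      prediction_classes = classes,
                      slim_summary = if (!is.null(slim))
                        goslim_summarize(related, slim, dag))
  }

  report <- structure(list(config = cfg, network = net, dag = dag,
                           ann = ann, reference = ref, slim = slim,
                           gc = gc, sets = sets),
                      class = "signal_report")
  if (write_files) write_report(report)
  report
}

#' @export
print.signal_report <- function(x, ...) {
  st <- cluster_stats(x$gc$clusters)
  cat(sprintf("<signal_report> network: %d proteins / %d interactions\n",
              length(x$network$nodes), nrow(x$network$edges)))
  cat(sprintf("  GC: %d clusters, %d complexes\n",
              st$n_clusters, length(x$gc$complexes)))
  for (s in x$sets)
    cat(sprintf("  %s: %d complexes, %d related functions, %d related complexes, %d unique\n",
                s$label, length(s$oc$complexes),
                length(s$related_functions), length(s$related_complexes),
                length(s$unique_complexes)))
  invisible(x)
}

#' @export
summary.signal_report <- function(object, ...) {
  list(table1 = make_table1(object),
       table2 = make_table2(object),
       table5 = make_table5(object))
}

#' Ratio of two counts as a rounded percentage
#'
#' The percentage printed in the report tables: `100 * count / total`,
#' rounded to `digits` decimals; 0 when the denominator is 0.
#'
#' @param count,total non-negative counts.
#' @param digits decimals kept.
#' @return Numeric percentage.
#' @export
percent_ratio <- function(count, total, digits = 1L) {
  ifelse(total > 0, round(100 * count / total, digits), 0)
}

#' Cluster/complex summary table (per cluster class)
#'
#' One row per cluster class: number of size-filtered clusters, their mean
#' size, number of putative complexes, mean complex size, and the
#' percentage of clusters that are complexes (1 decimal).  RC rows report
#' means with standard deviations over the random runs.
#'
#' @param report a `signal_report`.
#' @return data.frame with columns `class`, `n_clusters`, `mean_cluster_size`,
#'   `n_complexes`, `mean_complex_size`, `ratio_pct` and the `sd_*`
#'   columns (NA outside RC rows).
#' @export
make_table1 <- function(report) {
  row <- function(class, nc, mc, nx, mx, sdc = NA, sdx = NA, sdnx = NA) {
    data.frame(class = class, n_clusters = nc, sd_clusters = sdc,
               mean_cluster_size = round(mc, 2),
               n_complexes = nx, sd_complexes = sdnx,
               mean_complex_size = round(mx, 2), sd_complex_size = sdx,
               ratio_pct = percent_ratio(nx, nc, 1L))
  }
  gst <- cluster_stats(report$gc$clusters)
  gsz <- lengths(lapply(report$gc$complexes, `[[`, "proteins"))
  out <- row("GC", gst$n_clusters, gst$mean_size, length(gsz),
             if (length(gsz)) mean(gsz) else 0)
  for (s in report$sets) {
    ost <- cluster_stats(s$oc$clusters)
    osz <- lengths(lapply(s$oc$complexes, `[[`, "proteins"))
    out <- rbind(out, row(s$label, ost$n_clusters, ost$mean_size,
                          length(osz), if (length(osz)) mean(osz) else 0))
    rs <- s$null$run_stats
    out <- rbind(out, row(paste0("RC@", s$label),
                          round(mean(rs$n_clusters), 2),
                          mean(rs$mean_cluster_size),
                          round(mean(rs$n_complexes), 2),
                          mean(rs$mean_complex_size),
                          sdc = round(stats::sd(rs$n_clusters), 2),
                          sdx = round(stats::sd(rs$mean_complex_size), 2),
                          sdnx = round(stats::sd(rs$n_complexes), 2)))
  }
  rownames(out) <- NULL
  out
}

# functions associated with a run's complexes that have a defined rho
eligible_functions <- function(set) {
  assoc <- unique(unlist(lapply(set$oc$complexes, `[[`, "full_functions"),
                         use.names = FALSE))
  rho <- set$oc$rho
  intersect(assoc, rho$term[rho$defined])
}

#' Filter-effect table (per ortholog set)
#'
#' Counts the complexes and functions of each OC run surviving the random
#' sample filter (rho(f,O) > rho(f,R95)), the global sample filter
#' (rho(f,O) > rho(f,V)), and their combination (Eq. 2), together with
#' retention percentages (2 decimals).  A complex survives a filter when
#' at least one function of its full annotation set survives it.
#'
#' @param report a `signal_report`.
#' @return data.frame with one complex row and one function row per
#'   ortholog set.
#' @export
make_table2 <- function(report) {
  out <- NULL
  for (s in report$sets) {
    funs <- eligible_functions(s)
    rho <- s$oc$rho
    val <- stats::setNames(rho$value, rho$term)[funs]
    gv <- stats::setNames(report$gc$rho$value[report$gc$rho$defined],
                          report$gc$rho$term[report$gc$rho$defined])
    thr <- s$null$threshold95
    comp_v <- ifelse(funs %in% names(gv), gv[funs], 0)
    comp_r <- ifelse(funs %in% names(thr), thr[funs], 0)
    surv_r <- funs[val > comp_r]
    surv_v <- funs[val > comp_v]
    surv_b <- funs[val > pmax(comp_r, comp_v)]
    n_cx <- function(terms) sum(vapply(s$oc$complexes, function(cx)
      length(intersect(cx$full_functions, terms)) > 0L, NA))
    total_cx <- length(s$oc$complexes)
    out <- rbind(out,
      data.frame(class = s$label, quantity = "complexes",
                 total = total_cx, random_filter = n_cx(surv_r),
                 global_filter = n_cx(surv_v), combined = n_cx(surv_b),
                 retention_pct = percent_ratio(n_cx(surv_b), total_cx, 2L)),
      data.frame(class = s$label, quantity = "functions",
                 total = length(funs), random_filter = length(surv_r),
                 global_filter = length(surv_v), combined = length(surv_b),
                 retention_pct = percent_ratio(length(surv_b), length(funs), 2L)))
  }
  rownames(out) <- NULL
  out
}

#' Unique/verified/novel prediction table (per ortholog set)
#'
#' For all OC complexes and for the orthology-related subset: how many
#' complexes exist, how many are unique (make at least one prediction no
#' GC complex makes for the same protein), and how many of the unique
#' ones carry at least one verified resp. novel prediction.  A complex
#' can be counted as both verified and novel.
#'
#' @param report a `signal_report`.
#' @return data.frame with rows `all` and `related` per ortholog set.
#' @export
make_table5 <- function(report) {
  out <- NULL
  for (s in report$sets) {
    key <- function(cxs) vapply(cxs, function(cx)
      paste(cx$proteins, collapse = ","), "")
    rel_keys <- key(s$related_complexes)
    uniq <- s$unique_complexes
    cls <- s$prediction_classes
    is_rel <- key(uniq) %in% rel_keys
    has_ver <- vapply(cls, function(x) nrow(x$verified) > 0L, NA)
    has_nov <- vapply(cls, function(x) nrow(x$novel) > 0L, NA)
    out <- rbind(out,
      data.frame(class = s$label, scope = "all",
                 total = length(s$oc$complexes), unique = length(uniq),
                 verified = sum(has_ver), novel = sum(has_nov)),
      data.frame(class = s$label, scope = "related",
                 total = length(s$related_complexes),
                 unique = sum(is_rel),
                 verified = sum(has_ver & is_rel),
                 novel = sum(has_nov & is_rel)))
  }
  rownames(out) <- NULL
  out
}

#' Related-function detail table
#'
#' One row per orthology-related function of each ortholog set: term,
#' name, namespace, GO level, rho(f,O), rho(f,V) and the random-run
#' threshold rho(f,R95).
#'
#' @param report a `signal_report`.
#' @return data.frame.
#' @export
related_function_table <- function(report) {
  out <- NULL
  for (s in report$sets) {
    f <- s$related_functions
    if (!length(f)) next
    rho_o <- stats::setNames(s$oc$rho$value, s$oc$rho$term)
    rho_v <- stats::setNames(report$gc$rho$value[report$gc$rho$defined],
                             report$gc$rho$term[report$gc$rho$defined])
    thr <- s$null$threshold95
    out <- rbind(out, data.frame(
      class = s$label, term = f, name = unname(report$dag$name[f]),
      namespace = unname(report$dag$namespace[f]),
      level = unname(report$dag$level[f]),
      rho_O = round(unname(rho_o[f]), 4),
      rho_V = round(ifelse(f %in% names(rho_v), rho_v[f], 0), 4),
      rho_R95 = round(ifelse(f %in% names(thr), thr[f], 0), 4)))
  }
  if (is.null(out))
    out <- data.frame(class = character(), term = character(),
                      name = character(), namespace = character(),
                      level = integer(), rho_O = numeric(),
                      rho_V = numeric(), rho_R95 = numeric())
  rownames(out) <- NULL
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# write all report artifacts and the manifest under cfg$out_dir
write_report <- function(report) {
  cfg <- report$config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_clusters(report$gc$clusters, file.path(cfg$out_dir, "clusters_GC.tsv"))
  for (s in report$sets) {
    write_clusters(s$oc$clusters,
                   file.path(cfg$out_dir, sprintf("clusters_%s.tsv", s$label)))
    write_tsv(s$oc$rho,
              file.path(cfg$out_dir, sprintf("retrieval_%s.tsv", s$label)))
    null_df <- data.frame(term = names(s$null$threshold95),
                          threshold95 = round(unname(s$null$threshold95), 6),
                          mean_rho = round(rowMeans(s$null$values), 6))
    write_tsv(null_df,
              file.path(cfg$out_dir, sprintf("null_%s.tsv", s$label)))
  }
  write_tsv(make_table1(report), file.path(cfg$out_dir, "table1_clusters.tsv"))
  write_tsv(make_table2(report), file.path(cfg$out_dir, "table2_filters.tsv"))
  write_tsv(make_table5(report), file.path(cfg$out_dir, "table5_predictions.tsv"))
  write_tsv(related_function_table(report),
            file.path(cfg$out_dir, "related_functions.tsv"))
  manifest <- unclass(cfg)
  manifest$orthologs <- as.list(manifest$orthologs)
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  invisible(cfg$out_dir)
}
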