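#' Specification of a synthetic benchmark fixture
#'
#' Describes a self-contained toy data set with planted ground truth: a
#' planted-partition PPI network, a small rooted ontology whose marker
#' terms tag the communities, community-correlated annotations, and an
#' ortholog set that fully covers a chosen subset of "signal"
#' communities.  The defaults define the benchmark conditions used
#' throughout the test suite: 8 communities of 10 proteins, within/between
#' edge probabilities 0.9/0.02, annotation coverage 0.9, 2 signal
#' communities, an ortholog set of 35% of the proteins, one marker per
#' community at ontology level 5, and decoy terms annotated uniformly at
#' random over half of all proteins.
#'
#' @param n_communities number of planted communities.
#' @param community_size proteins per community.
#' @param p_in within-community edge probability.
#' @param p_out between-community edge probability (must be `< p_in`).
#' @param weight_range range of the uniform confidence weights.
#' @param n_signal_communities communities placed entirely inside the
#'   ortholog set (the planted orthology signal).  Each signal community
#'   is camouflaged by dense bridge edges to two designated partner
#'   communities, so the whole-network run merges the triple into one
#'   cluster in which no marker passes the majority criterion — the
#'   global topology suppresses the signal complexes, which only the
#'   ortholog-induced subnetwork unveils.  Requires
#'   `n_communities >= 3 * n_signal_communities`.
#' @param p_bridge edge probability between a signal community and its
#'   camouflage partners; defaults to `p_in`.
#' @param ortholog_fraction total ortholog set size as a fraction of the
#'   proteome; the remainder beyond the signal communities is random
#'   scatter from the plain communities (partners are by construction the
#'   non-orthologous context of the signal).
#' @param dag_depth depth of the ontology chains (>= 5, so markers can sit
#'   at level >= 4).
#' @param marker_level level at which community marker terms are placed.
#' @param markers_per_community marker terms per community.
#' @param annotation_coverage probability a community protein is annotated
#'   to its marker.
#' @param n_decoys number of decoy terms (level >= 4).  Decoys are
#'   annotated uniformly at random across the plain communities —
#'   globally retrieved complexes, so `rho(decoy, V) = 1` and no decoy
#'   can pass the strict differential rule.  With
#'   `n_signal_communities = 0` they cover all proteins.
#' @param decoy_coverage probability an eligible protein carries a decoy.
#' @param seed integer seed for all randomness in the fixture.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_communities = 8L, community_size = 10L,
                         p_in = 0.9, p_out = 0.02, p_bridge = NULL,
                         weight_range = c(0.5, 1),
                         n_signal_communities = 2L,
                         ortholog_fraction = 0.45,
                         dag_depth = 6L, marker_level = 5L,
                         markers_per_community = 1L,
                         annotation_coverage = 0.9,
                         n_decoys = 4L, decoy_coverage = 0.5,
                         seed = 1L) {
  stopifnot(p_in > p_out, dag_depth >= 5L, marker_level >= 4L,
            marker_level <= dag_depth,
            3L * n_signal_communities <= n_communities)
  if (is.null(p_bridge)) p_bridge <- p_in
  structure(list(n_communities = n_communities,
                 community_size = community_size,
                 p_in = p_in, p_out = p_out, p_bridge = p_bridge,
                 weight_range = weight_range,
                 n_signal_communities = n_signal_communities,
                 ortholog_fraction = ortholog_fraction,
                 dag_depth = dag_depth, marker_level = marker_level,
                 markers_per_community = markers_per_community,
                 annotation_coverage = annotation_coverage,
                 n_decoys = n_decoys, decoy_coverage = decoy_coverage,
                 seed = seed),
            class = "fixture_spec")
}

# community role masks: signal (planted), partner (camouflage), plain;
# signal community c is bridged to partners ns + 2(c-1) + {1, 2}
fixture_roles <- function(spec) {
  ns <- spec$n_signal_communities
  role <- rep("plain", spec$n_communities)
  if (ns > 0L) {
    role[seq_len(ns)] <- "signal"
    role[ns + seq_len(2L * ns)] <- "partner"
  }
  role
}

fixture_partners <- function(spec, c) {
  ns <- spec$n_signal_communities
  ns + 2L * (c - 1L) + 1:2
}

fixture_proteins <- function(spec) {
  comm <- rep(seq_len(spec$n_communities), each = spec$community_size)
  stats::setNames(comm, sprintf("P%03d", seq_along(comm)))
}

#' Planted-partition network of a fixture
#'
#' Samples each within-community pair with probability `p_in` and each
#' between-community pair with `p_out`, except that pairs linking a
#' signal community to its camouflage partner are sampled with
#' `p_bridge`.  Edge weights are uniform in `weight_range`.
#' Deterministic for a fixed `spec$seed`.
#'
#' @param spec a [fixture_spec()].
#' @return A [ppi_network].
#' @export
make_network <- function(spec) {
  comm <- fixture_proteins(spec)
  prot <- names(comm)
  np <- length(prot)
  ns <- spec$n_signal_communities
  pairs <- which(upper.tri(matrix(0, np, np)), arr.ind = TRUE)
  with_seed(spec$seed, {
    c1 <- comm[pairs[, 1L]]; c2 <- comm[pairs[, 2L]]
    p <- ifelse(c1 == c2, spec$p_in, spec$p_out)
    if (ns > 0L) {
      lo <- pmin(c1, c2); hi <- pmax(c1, c2)
      for (s in seq_len(ns))
        p[lo == s & hi %in% fixture_partners(spec, s)] <- spec$p_bridge
    }
    keep <- stats::runif(nrow(pairs)) < p
    w <- stats::runif(sum(keep), spec$weight_range[1L], spec$weight_range[2L])
    ppi_network(data.frame(a = prot[pairs[keep, 1L]],
                           b = prot[pairs[keep, 2L]],
                           weight = round(w, 4),
                           stringsAsFactors = FALSE),
                nodes = prot)
  })
}

#' Toy ontology and annotations of a fixture
#'
#' Builds a single-rooted DAG: the root branches into one slim head per
#' community plus one decoy branch; each head continues as a chain so that
#' the community marker term sits at `marker_level` and the chain bottoms
#' out at `dag_depth`.  Each community's proteins are annotated to their
#' marker with probability `annotation_coverage`; decoy terms (at level
#' `marker_level`) are annotated uniformly at random across the plain
#' communities with probability `decoy_coverage` (across all proteins
#' when no community is signal).  A level-3 negative-control term
#' (`NEG:LEVEL3`) is annotated alongside every within-community marker
#' annotation, so it is coherent by count but must be rejected by the
#' level criterion.
#'
#' @param spec a [fixture_spec()].
#' @return List with `dag` (a `go_dag`), `ann` (an `annotation_set`),
#'   `slim` (slim term IDs), `markers` (named list community ->
#'   marker terms) and `decoys`.
#' @export
make_ontology_and_annotations <- function(spec) {
  obo <- fixture_obo_lines(spec)
  tmp <- tempfile(fileext = ".obo")
  on.exit(unlink(tmp))
  writeLines(obo, tmp)
  dag <- parse_obo(tmp)
  markers <- lapply(seq_len(spec$n_communities), function(c)
    sprintf("MRK:C%02dM%02d", c, seq_len(spec$markers_per_community)))
  names(markers) <- sprintf("C%02d", seq_len(spec$n_communities))
  decoys <- sprintf("DCY:%04d", seq_len(spec$n_decoys))
  comm <- fixture_proteins(spec)
  prot <- names(comm)
  role <- fixture_roles(spec)
  direct <- with_seed(spec$seed + 7L, {
    d <- stats::setNames(vector("list", length(prot)), prot)
    for (i in seq_along(prot)) {
      ts <- character(0)
      for (mk in markers[[comm[i]]])
        if (stats::runif(1) < spec$annotation_coverage)
          ts <- c(ts, mk, "NEG:LEVEL3")
      if (role[comm[i]] == "plain") {
        for (dc in decoys)
          if (stats::runif(1) < spec$decoy_coverage) ts <- c(ts, dc)
      }
      d[[i]] <- unique(ts)
    }
    d
  })
  ann <- annotation_set(direct, dag)
  list(dag = dag, ann = ann,
       slim = grep("^SLIM:", dag$terms, value = TRUE),
       markers = markers, decoys = decoys)
}

# OBO text for the fixture ontology
fixture_obo_lines <- function(spec) {
  stanza <- function(id, name, is_a = NULL) {
    c("[Term]", paste0("id: ", id), paste0("name: ", name),
      "namespace: biological_process",
      if (length(is_a)) paste0("is_a: ", is_a, " ! ", is_a), "")
  }
  out <- c("format-version: 1.2", "ontology: fixture", "",
           stanza("FIX:0000001", "fixture root"))
  for (c in seq_len(spec$n_communities)) {
    cid <- sprintf("C%02d", c)
    slim <- sprintf("SLIM:%s", cid)
    out <- c(out, stanza(slim, paste("community process", cid), "FIX:0000001"))
    prev <- slim
    for (lv in 2L:spec$dag_depth) {
      # shared level-3 negative-control term hangs off the first branch
      if (lv == 3L && c == 1L)
        out <- c(out, stanza("NEG:LEVEL3", "negative control level 3", prev))
      if (lv == spec$marker_level) {
        mks <- sprintf("MRK:%sM%02d", cid, seq_len(spec$markers_per_community))
        for (m in seq_along(mks))
          out <- c(out, stanza(mks[m], sprintf("marker %s.%d", cid, m), prev))
        prev <- mks[1L]
      } else {
        node <- sprintf("CHN:%sL%02d", cid, lv)
        out <- c(out, stanza(node, paste("chain", cid, lv), prev))
        prev <- node
      }
    }
  }
  # decoy branch: a chain to the decoy level, decoys as siblings
  prev <- "FIX:0000001"
  for (lv in 1L:(spec$marker_level - 1L)) {
    node <- sprintf("CHN:DCYL%02d", lv)
    out <- c(out, stanza(node, paste("decoy chain", lv), prev))
    prev <- node
  }
  for (d in seq_len(spec$n_decoys))
    out <- c(out, stanza(sprintf("DCY:%04d", d), paste("decoy", d), prev))
  out
}

#' Ortholog protein set of a fixture
#'
#' All proteins of the `n_signal_communities` first communities, plus a
#' uniform random scatter from the plain communities, sized so the whole
#' set reaches `ortholog_fraction` of the proteome.  Camouflage partners
#' never enter the set: they model the non-orthologous context that hides
#' the signal communities in the global topology.
#'
#' @param spec a [fixture_spec()].
#' @param net the fixture [ppi_network] (for the protein universe).
#' @return Character vector of protein IDs.
#' @export
make_ortholog_set <- function(spec, net) {
  comm <- fixture_proteins(spec)
  role <- fixture_roles(spec)
  signal <- names(comm)[role[comm] == "signal"]
  target <- round(spec$ortholog_fraction * length(comm))
  extra <- max(0L, target - length(signal))
  pool <- intersect(names(comm)[role[comm] == "plain"], net$nodes)
  scatter <- with_seed(spec$seed + 13L, sample(pool, min(extra, length(pool))))
  sort(c(signal, scatter))
}

#' Write a complete fixture to disk in the real external formats
#'
#' Emits the network as a tab-separated edge list, the ontology as OBO
#' 1.2, the annotations as GAF 2.1 (evidence IDA), the ortholog set and
#' the GO-slim list as plain ID lists — so every parser of the package is
#' exercised when the fixture is read back.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if missing).
#' @return Named list of file paths (`network`, `obo`, `gaf`, `orthologs`,
#'   `slim`) plus the in-memory ground truth (`markers`, `decoys`,
#'   `signal_markers`).
#' @export
write_fixture <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- make_network(spec)
  onto <- make_ontology_and_annotations(spec)
  orth <- make_ortholog_set(spec, net)

  paths <- list(network = file.path(dir, "network.tsv"),
                obo = file.path(dir, "ontology.obo"),
                gaf = file.path(dir, "annotations.gaf"),
                orthologs = file.path(dir, "orthologs.txt"),
                slim = file.path(dir, "goslim.txt"))
  writeLines(c("# fixture PPI edge list",
               sprintf("%s\t%s\t%.4f", net$edges$a, net$edges$b,
                       net$edges$weight)),
             paths$network)
  writeLines(fixture_obo_lines(spec), paths$obo)
  gaf <- character(0)
  for (p in names(onto$ann$direct))
    for (t in onto$ann$direct[[p]])
      gaf <- c(gaf, paste("FIX", p, p, "", t, "FIX:ref", "IDA", "", "P", p,
                          "", "protein", "taxon:0", "20100101", "FIX", "", "",
                          sep = "\t"))
  writeLines(c("!gaf-version: 2.1", gaf), paths$gaf)
  writeLines(orth, paths$orthologs)
  writeLines(onto$slim, paths$slim)

  c(paths,
    list(markers = onto$markers, decoys = onto$decoys,
         signal_markers = as.character(
           unlist(onto$markers[seq_len(spec$n_signal_communities)],
                  use.names = FALSE))))
}
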