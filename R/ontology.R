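#' Parse a Gene Ontology OBO 1.2 file
#'
#' Loads `[Term]` stanzas: term IDs, names, namespaces, `is_a` and
#' (optionally) `part_of` edges, and `alt_id` aliases.  Obsolete terms are
#' dropped.  The DAG is checked for cycles and per-namespace roots; every
#' term's level — the length of the LONGEST path from its namespace root —
#' and its ancestor closure are precomputed.
#'
#' @param path OBO file.
#' @param use_part_of include `relationship: part_of` edges as parent
#'   links (default `FALSE`; level semantics are cleanest over `is_a`).
#' @return An object of class `go_dag`: list with `terms`, `name`,
#'   `namespace`, `parents`, `children`, `roots`, `level`, `ancestors`
#'   (all named by term ID) and `alt` (alt_id -> primary map).
#' @export
parse_obo <- function(path, use_part_of = FALSE) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\[", lines)
  term_starts <- starts[lines[starts] == "[Term]"]
  ends <- c(starts[-1L] - 1L, length(lines))
  ends <- ends[match(term_starts, starts)]

  ids <- character(); nm <- character(); ns <- character()
  parents <- list(); alt <- character()
  for (s in seq_along(term_starts)) {
    block <- lines[(term_starts[s] + 1L):ends[s]]
    val <- function(tag) sub(paste0("^", tag, ": *"), "",
                             grep(paste0("^", tag, ":"), block, value = TRUE))
    if (length(grep("^is_obsolete: *true", block))) next
    id <- val("id")[1L]
    if (is.na(id) || !length(id)) next
    p <- sub(" *!.*$", "", val("is_a"))
    if (use_part_of) {
      rel <- sub(" *!.*$", "", val("relationship"))
      p <- c(p, sub("^part_of +", "", rel[grepl("^part_of ", rel)]))
    }
    a <- val("alt_id")
    ids <- c(ids, id)
    nm <- c(nm, if (length(val("name"))) val("name")[1L] else id)
    ns <- c(ns, if (length(val("namespace"))) val("namespace")[1L] else "default")
    parents[[id]] <- unique(p)
    if (length(a)) alt[a] <- id
  }
  if (!length(ids)) stop("no non-obsolete [Term] stanzas found in ", path)
  names(nm) <- ids; names(ns) <- ids
  # drop dangling parents (e.g. links into obsolete terms)
  parents <- lapply(parents, function(p) p[p %in% ids])

  order <- topo_sort(ids, parents)   # errors on a cycle
  roots <- ids[lengths(parents[ids]) == 0L]
  for (d in unique(ns)) if (!any(ns[roots] == d))
    stop(sprintf("ontology namespace '%s' has no root term", d))
  level <- stats::setNames(integer(length(ids)), ids)
  ancestors <- stats::setNames(vector("list", length(ids)), ids)
  for (id in order) {
    p <- parents[[id]]
    if (length(p)) {
      level[id] <- max(level[p]) + 1L
      ancestors[[id]] <- unique(c(p, unlist(ancestors[p], use.names = FALSE)))
    }
  }
  children <- invert_edges(parents, ids)
  structure(list(terms = ids, name = nm, namespace = ns, parents = parents,
                 children = children, roots = roots, level = level,
                 ancestors = ancestors, alt = alt),
            class = "go_dag")
}

# Kahn topological sort, parents before children; errors on cycles.
topo_sort <- function(ids, parents) {
  indeg <- stats::setNames(lengths(parents[ids]), ids)
  children <- invert_edges(parents, ids)
  queue <- ids[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    id <- queue[1L]; queue <- queue[-1L]
    out <- c(out, id)
    for (ch in children[[id]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != length(ids))
    stop("cycle detected in the ontology graph")
  out
}

invert_edges <- function(parents, ids) {
  children <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) for (p in parents[[id]])
    children[[p]] <- c(children[[p]], id)
  children
}

#' Resolve a term ID through alt_id aliases
#'
#' @param dag a `go_dag`.
#' @param ids character vector of GO IDs (primary or alt).
#' @return Primary IDs; unknown IDs come back as `NA`.
#' @export
resolve_term <- function(dag, ids) {
  out <- ifelse(ids %in% dag$terms, ids, unname(dag$alt[ids]))
  out[!out %in% dag$terms] <- NA_character_
  out
}

#' Level of a GO term
#'
#' The level of a term is the edge count of the longest path from the root
#' of its namespace down to the term; roots are at level 0.  Longest-path
#' semantics guarantee every child sits strictly deeper than all its
#' parents.
#'
#' @param dag a `go_dag`.
#' @param f term ID (alt IDs are resolved).
#' @return Integer level.
#' @export
term_level <- function(dag, f) {
  f <- resolve_term(dag, f)
  if (anyNA(f)) stop("term_level: unknown term")
  unname(dag$level[f])
}

#' Ancestors of a term (excluding itself)
#'
#' @param dag a `go_dag`.
#' @param f term ID.
#' @return Character vector of ancestor term IDs.
#' @export
term_ancestors <- function(dag, f) {
  f <- resolve_term(dag, f)
  if (anyNA(f)) stop("term_ancestors: unknown term")
  unique(unlist(dag$ancestors[f], use.names = FALSE))
}

#' Parse a GAF 2.x gene-association file
#'
#' Keeps rows whose evidence code is in `whitelist` and whose qualifier
#' does not contain `NOT`; GO IDs are mapped through `alt_id`; annotations
#' to terms absent from the DAG are dropped with a message.  The true-path
#' closure (each protein implicitly carries all ancestors of its direct
#' terms) is precomputed.
#'
#' @param path GAF file (`!` comment lines allowed).
#' @param dag a `go_dag`.
#' @param whitelist evidence codes to keep; the default is the GO
#'   experimental set, excluding all computationally assigned codes.
#' @param id_col which GAF column identifies the protein: 2 (DB Object ID)
#'   or 3 (DB Object Symbol).
#' @return An object of class `annotation_set`: list with `direct` and
#'   `propagated` (named lists protein -> term IDs) and `whitelist`.
#' @export
parse_gaf <- function(path, dag,
                      whitelist = c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP"),
                      id_col = 2L) {
  stopifnot(file.exists(path), inherits(dag, "go_dag"))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(trimws(lines))]
  if (!length(lines))
    return(annotation_set(list(), dag, whitelist))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 7L))
    stop("malformed GAF row: fewer than 7 columns")
  prot <- vapply(f, `[[`, "", id_col)
  qual <- vapply(f, `[[`, "", 4L)
  term <- vapply(f, `[[`, "", 5L)
  evid <- vapply(f, `[[`, "", 7L)
  keep <- evid %in% whitelist & !grepl("(^|\\|)NOT($|\\|)", qual)
  prot <- prot[keep]; term <- resolve_term(dag, term[keep])
  unknown <- is.na(term)
  if (any(unknown))
    message(sprintf("parse_gaf: dropped %d annotation(s) to unknown terms",
                    sum(unknown)))
  direct <- split(term[!unknown], prot[!unknown])
  direct <- lapply(direct, unique)
  annotation_set(direct, dag, whitelist)
}

#' Build an annotation set from a direct protein-to-term map
#'
#' @param direct named list, protein ID -> character vector of GO term IDs.
#' @param dag a `go_dag`; used to propagate the true-path closure.
#' @param whitelist evidence codes this set is restricted to (metadata).
#' @return An `annotation_set`.
#' @export
annotation_set <- function(direct, dag,
                           whitelist = c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP")) {
  stopifnot(inherits(dag, "go_dag"))
  direct <- lapply(direct, function(ts) unique(ts[ts %in% dag$terms]))
  direct <- direct[lengths(direct) > 0L]
  propagated <- lapply(direct, function(ts)
    unique(c(ts, unlist(dag$ancestors[ts], use.names = FALSE))))
  structure(list(direct = direct, propagated = propagated,
                 whitelist = whitelist),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d proteins, %d direct / %d propagated annotations (evidence: %s)\n",
              length(x$direct), sum(lengths(x$direct)),
              sum(lengths(x$propagated)), paste(x$whitelist, collapse = ",")))
  invisible(x)
}

#' Candidate proteins for a function
#'
#' `C(f)`: every protein annotated (with whitelisted evidence) to `f` or to
#' any descendant of `f` — equivalently, every protein whose propagated
#' annotation set contains `f`.
#'
#' @param dag a `go_dag`.
#' @param ann an `annotation_set`.
#' @param f term ID.
#' @return Character vector of protein IDs (possibly empty).
#' @export
candidate_set <- function(dag, ann, f) {
  f <- resolve_term(dag, f)
  if (anyNA(f)) stop("candidate_set: unknown term")
  names(ann$propagated)[vapply(ann$propagated, function(ts) f %in% ts, NA)]
}

#' Read a GO-slim term list
#'
#' Plain text, one GO ID per line; `#` comments allowed.
#'
#' @param path file of term IDs.
#' @param dag a `go_dag`; IDs are resolved through alt_ids and unknown IDs
#'   dropped with a message.
#' @return Character vector of slim term IDs.
#' @export
read_slim <- function(path, dag) {
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(sub("#.*$", "", ids))
  ids <- ids[nzchar(ids)]
  res <- resolve_term(dag, ids)
  if (anyNA(res))
    message(sprintf("read_slim: dropped %d unknown term(s)", sum(is.na(res))))
  unique(res[!is.na(res)])
}
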