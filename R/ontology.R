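# Ontology graphs: CURIE-identified terms connected by is_a edges.
#
# Only the is_a (subclass) relation defines the hierarchy; part_of,
# regulates and other relationship types are deliberately ignored so that
# "descendants" means exactly the recursive-subclass closure a subclass
# query over the class hierarchy would return.

#' Construct an ontology graph
#'
#' Low-level constructor used by the OBO parser and the synthetic-ontology
#' generators. Validates CURIEs, uniqueness, parent resolution and
#' acyclicity. Parents that do not resolve to a term in the graph are kept
#' in a `dangling` report (real ontology subsets legitimately reference
#' classes outside the subset) and excluded from the edge set.
#'
#' @param ids character vector of term CURIEs.
#' @param labels character vector of term labels (same length as `ids`).
#' @param parents list of character vectors of parent CURIEs (is_a).
#' @param rank character vector of taxonomic ranks; `"no rank"` where absent.
#' @param obsolete logical vector; obsolete terms carry no parents and are
#'   excluded from all closures.
#' @return an object of class `onto_graph` with elements `ids`, `labels`,
#'   `parents`, `children`, `rank`, `obsolete`, `dangling`.
#' @export
onto_graph <- function(ids, labels = NULL, parents = NULL, rank = NULL,
                       obsolete = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate term ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (length(ids) > 0L) assert_curie(ids)
  n <- length(ids)
  labels <- as.character(labels %||% rep("", n))
  rank <- as.character(rank %||% rep("no rank", n))
  rank[is.na(rank) | rank == ""] <- "no rank"
  obsolete <- as.logical(obsolete %||% rep(FALSE, n))
  parents <- parents %||% rep(list(character()), n)
  stopifnot(length(labels) == n, length(parents) == n,
            length(rank) == n, length(obsolete) == n)
  names(labels) <- names(rank) <- names(obsolete) <- ids
  names(parents) <- ids

  parents <- lapply(parents, function(p) sort(unique(as.character(p))))
  # obsolete terms never keep parents
  parents[obsolete] <- rep(list(character()), sum(obsolete))

  dangling <- data.frame(term_id = character(), parent_id = character(),
                         stringsAsFactors = FALSE)
  for (id in ids) {
    missing <- setdiff(parents[[id]], ids)
    if (length(missing) > 0L) {
      dangling <- rbind(dangling,
                        data.frame(term_id = id, parent_id = missing,
                                   stringsAsFactors = FALSE))
      parents[[id]] <- setdiff(parents[[id]], missing)
    }
  }

  children <- rep(list(character()), n)
  names(children) <- ids
  for (id in ids) {
    for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  }
  children <- lapply(children, sort)

  g <- structure(list(ids = ids, labels = labels, parents = parents,
                      children = children, rank = rank, obsolete = obsolete,
                      dangling = dangling),
                 class = "onto_graph")
  cyc <- find_cycle(g)
  if (!is.null(cyc)) {
    stop("ontology contains an is_a cycle: ",
         paste(cyc, collapse = " -> "), call. = FALSE)
  }
  g
}

# Kahn topological sort; returns NULL if acyclic, else one cycle as a path.
find_cycle <- function(g) {
  indeg <- vapply(g$parents, length, integer(1L))
  queue <- g$ids[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in g$children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == length(g$ids)) return(NULL)
  # walk parent edges inside the residual subgraph until a repeat
  residual <- names(indeg)[indeg > 0L]
  v <- residual[[1L]]; path <- v
  repeat {
    v <- intersect(g$parents[[v]], residual)[[1L]]
    if (v %in% path) {
      i <- match(v, path)
      return(c(path[i:length(path)], v))
    }
    path <- c(path, v)
  }
}

#' @export
print.onto_graph <- function(x, ...) {
  n_edge <- sum(vapply(x$parents, length, integer(1L)))
  cat(sprintf("<onto_graph> %d terms, %d is_a edges, %d obsolete, %d dangling parent refs\n",
              length(x$ids), n_edge, sum(x$obsolete), nrow(x$dangling)))
  invisible(x)
}

#' Number of terms in an ontology graph
#' @param g an `onto_graph`.
#' @return integer count of terms (including obsolete ones).
#' @export
n_terms <- function(g) length(g$ids)

has_term <- function(g, t) t %in% g$ids

assert_term <- function(g, t, what = "term") {
  missing <- setdiff(t, g$ids)
  if (length(missing) > 0L) {
    stop(sprintf("unknown %s: %s", what, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  invisible(t)
}

# BFS over an adjacency list; start excluded from the returned set.
bfs_reach <- function(adj, start, skip = character()) {
  seen <- new.env(parent = emptyenv())
  queue <- adj[[start]]
  out <- character()
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]
    if (!is.null(seen[[v]]) || v %in% skip) next
    seen[[v]] <- TRUE
    out <- c(out, v)
    queue <- c(queue, adj[[v]])
  }
  out
}

#' Recursive subclasses of a term
#'
#' All terms reachable from `t` by walking is_a edges downwards, i.e. every
#' term for which `t` is a (transitive) superclass. This is the
#' recursive-subclass query that drives ontology-based feature discovery:
#' asking for `cellular metabolic process` pulls in `photosynthesis`,
#' `methanogenesis` and every other descendant class. Obsolete terms are
#' never part of a closure.
#'
#' @param g an `onto_graph`.
#' @param t term CURIE present in `g`.
#' @param include_self include `t` itself in the result.
#' @return sorted character vector of term CURIEs.
#' @seealso [ancestors()], [extract_subset()]
#' @export
descendants <- function(g, t, include_self = FALSE) {
  assert_term(g, t)
  out <- bfs_reach(g$children, t, skip = g$ids[g$obsolete])
  if (include_self && !g$obsolete[[t]]) out <- c(out, t)
  sort(unique(out))
}

#' Recursive superclasses of a term
#'
#' All terms reachable from `t` by walking is_a edges upwards, excluding
#' `t` itself. These are the parent classes a subset extraction must retain
#' so the term stays connected to its hierarchy.
#'
#' @inheritParams descendants
#' @return sorted character vector of term CURIEs.
#' @export
ancestors <- function(g, t) {
  assert_term(g, t)
  sort(unique(bfs_reach(g$parents, t, skip = g$ids[g$obsolete])))
}

#' Extract a MIREOT-style ontology subset
#'
#' Returns the subgraph over `used` plus all their recursive parent
#' classes, with is_a edges restricted to the retained nodes. Labels and
#' ranks are preserved. Extraction is idempotent: re-extracting a subset
#' with the same seed terms yields the same graph.
#'
#' @param g an `onto_graph`.
#' @param used character vector of term CURIEs to keep (all must exist).
#' @return an `onto_graph` over `used` and their ancestors.
#' @export
extract_subset <- function(g, used) {
  used <- unique(as.character(used))
  assert_term(g, used, "used term")
  keep <- sort(unique(c(used, unlist(lapply(used, ancestors, g = g)))))
  idx <- match(keep, g$ids)
  onto_graph(ids = keep,
             labels = unname(g$labels[idx]),
             parents = lapply(g$parents[keep], intersect, x = keep),
             rank = unname(g$rank[idx]),
             obsolete = unname(g$obsolete[idx]))
}

#' Resolve a label or CURIE to a term id
#'
#' If `query` is a CURIE present in the graph it is returned as-is;
#' otherwise it is matched case-insensitively and exactly against term
#' labels. Ambiguous labels raise an error listing the candidates; fuzzy
#' matching is deliberately not attempted.
#'
#' @param g an `onto_graph`.
#' @param query a CURIE or a term label.
#' @return a single term CURIE.
#' @export
resolve_term <- function(g, query) {
  stopifnot(is.character(query), length(query) == 1L)
  if (is_curie(query) && has_term(g, query)) return(query)
  hits <- g$ids[!is.na(g$labels) & tolower(g$labels) == tolower(query)]
  if (length(hits) == 0L) {
    stop(sprintf("no term matching '%s'", query), call. = FALSE)
  }
  if (length(hits) > 1L) {
    stop(sprintf("ambiguous label '%s' matches: %s", query,
                 paste(hits, collapse = ", ")), call. = FALSE)
  }
  hits
}

#' Label of one or more terms
#' @param g an `onto_graph`.
#' @param t character vector of term CURIEs.
#' @return character vector of labels (`NA` for unknown terms).
#' @export
term_label <- function(g, t) {
  unname(g$labels[match(t, g$ids)])
}
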