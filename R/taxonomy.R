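# Taxonomy: a rooted forest of named taxonomic concepts with optional ranks
# and per-concept coverage flags.

#' Construct a taxonomy (rooted forest of taxonomic concepts)
#'
#' A taxonomy is one classification's concept hierarchy: named concepts
#' linked by parent/child (*is_a*) edges. Concepts are individuated by the
#' taxonomy id, so the qualified label of concept `Microcebus_murinus` in
#' taxonomy `1993` is `1993.Microcebus_murinus`. Multiple roots are legal
#' (the forest case); distinct roots are treated as mutually exclusive.
#'
#' @param id Short token identifying the taxonomy (e.g. `"2005"`).
#' @param edges Data frame with columns `parent` and `child` (concept names),
#'   one row per edge. A root may also be declared with `child = NA` to admit
#'   single-concept taxonomies.
#' @param label Free-text label, defaults to `id`.
#' @param ranks Optional named character vector mapping concept names to rank
#'   labels; unlisted concepts get `"unranked"`.
#' @param nocoverage Character vector of concept names whose coverage flag is
#'   turned off: such a parent may circumscribe more than the union of its
#'   children.
#' @return An object of class `taxonomy`.
#' @export
taxonomy <- function(id, edges, label = id, ranks = NULL,
                     nocoverage = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("parent", "child") %in% names(edges))) {
    stop("edges must have columns 'parent' and 'child'")
  }
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  real <- !is.na(edges$child)
  bad <- c(edges$parent, edges$child[real])
  bad <- bad[grepl("[.\\s]", bad, perl = TRUE)]
  if (length(bad)) {
    stop("concept names must be single tokens without dots: ",
         paste(unique(bad), collapse = ", "))
  }
  dup <- duplicated(edges$child[real])
  if (any(dup)) {
    stop("duplicate concept name within taxonomy '", id, "': ",
         paste(unique(edges$child[real][dup]), collapse = ", "))
  }
  # concept order: first appearance as parent or child
  order_names <- unique(c(rbind(edges$parent,
                                ifelse(real, edges$child, edges$parent))))
  order_names <- order_names[!is.na(order_names)]
  parent <- stats::setNames(rep(NA_character_, length(order_names)),
                            order_names)
  parent[edges$child[real]] <- edges$parent[real]
  if (any(order_names == parent[order_names], na.rm = TRUE)) {
    stop("cycle in parent/child lists of taxonomy '", id,
         "': a concept is its own parent")
  }
  # cycle detection: follow parent chains
  idx <- stats::setNames(seq_along(order_names), order_names)
  pidx <- ifelse(is.na(parent), 0L, idx[parent])
  state <- integer(length(order_names)) # 0 unseen, 1 in progress, 2 done
  for (s in seq_along(order_names)) {
    v <- s
    chain <- integer(0)
    while (v != 0L && state[v] == 0L) {
      state[v] <- 1L
      chain <- c(chain, v)
      v <- pidx[v]
    }
    if (v != 0L && state[v] == 1L) {
      stop("cycle in parent/child lists of taxonomy '", id, "' involving '",
           order_names[v], "'")
    }
    state[chain] <- 2L
  }
  if (length(order_names) == 0L) stop("taxonomy '", id, "' has no concepts")
  rank <- rep("unranked", length(order_names))
  if (!is.null(ranks)) {
    unknown <- setdiff(names(ranks), order_names)
    if (length(unknown)) {
      stop("rank assigned to unknown concept(s) in taxonomy '", id, "': ",
           paste(unknown, collapse = ", "))
    }
    rank[match(names(ranks), order_names)] <- unname(ranks)
  }
  coverage <- rep(TRUE, length(order_names))
  if (length(nocoverage)) {
    unknown <- setdiff(nocoverage, order_names)
    if (length(unknown)) {
      stop("nocoverage names unknown concept(s) in taxonomy '", id, "': ",
           paste(unknown, collapse = ", "))
    }
    coverage[match(nocoverage, order_names)] <- FALSE
  }
  structure(list(
    id = id,
    label = label,
    concepts = data.frame(name = order_names, parent = unname(parent),
                          rank = rank, coverage = coverage,
                          stringsAsFactors = FALSE, row.names = NULL)
  ), class = "taxonomy")
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("<taxonomy %s: %s>\n", x$id, x$label))
  cat(sprintf("  %d concepts (%d roots, %d leaves)\n",
              nrow(x$concepts), sum(is.na(x$concepts$parent)),
              sum(!x$concepts$name %in% x$concepts$parent)))
  invisible(x)
}

n_concepts <- function(tax) nrow(tax$concepts)

#' Qualified concept labels of a taxonomy
#'
#' @param tax A [taxonomy()].
#' @return Character vector `"<id>.<name>"` in declaration order.
#' @export
qualified_labels <- function(tax) paste(tax$id, tax$concepts$name, sep = ".")

tax_children <- function(tax) {
  split(seq_len(nrow(tax$concepts)),
        factor(tax$concepts$parent, levels = tax$concepts$name))
}

# A concept is eligible as "deepest containing concept" of a candidate Euler
# region iff it has no children or its coverage flag is off.
eligible_concepts <- function(tax) {
  has_child <- tax$concepts$name %in% tax$concepts$parent
  which(!has_child | !tax$concepts$coverage)
}

# For every concept, the eligible concepts at-or-below it (indices).
eligible_descendants <- function(tax) {
  n <- nrow(tax$concepts)
  kids <- tax_children(tax)
  elig <- eligible_concepts(tax)
  is_elig <- logical(n); is_elig[elig] <- TRUE
  res <- vector("list", n)
  # process children before parents: reverse topological by depth
  depth <- integer(n)
  pidx <- match(tax$concepts$parent, tax$concepts$name)
  for (i in seq_len(n)) {
    d <- 0L; v <- i
    while (!is.na(pidx[v])) { d <- d + 1L; v <- pidx[v] }
    depth[i] <- d
  }
  for (i in order(depth, decreasing = TRUE)) {
    below <- unlist(res[kids[[i]]], use.names = FALSE)
    res[[i]] <- sort(unique(c(if (is_elig[i]) i, below)))
  }
  res
}

# For every eligible concept, the concepts at-or-above it (ancestor chain).
ancestors_of <- function(tax) {
  pidx <- match(tax$concepts$parent, tax$concepts$name)
  lapply(seq_len(nrow(tax$concepts)), function(i) {
    chain <- i
    v <- i
    while (!is.na(pidx[v])) { v <- pidx[v]; chain <- c(chain, v) }
    chain
  })
}

#' Within-taxonomy RCC-5 relation between two concepts
#'
#' Cross-taxonomy relations are the business of the reasoner and the MIR;
#' within one taxonomy they are fixed by the hierarchy and the coverage
#' constraint and are derivable directly: an ancestor properly includes a
#' descendant, except along a monotypic coverage chain where parent and child
#' are congruent; non-nested concepts are exclusive (a tree admits no
#' within-taxonomy overlap).
#'
#' @param tax A [taxonomy()].
#' @param a,b Concept names in `tax`.
#' @return One of `"=="`, `">"`, `"<"`, `"!"`.
#' @export
within_taxonomy_relation <- function(tax, a, b) {
  nm <- tax$concepts$name
  ia <- match(a, nm); ib <- match(b, nm)
  if (is.na(ia)) stop("unknown concept: ", a)
  if (is.na(ib)) stop("unknown concept: ", b)
  desc <- eligible_descendants(tax)
  ea <- desc[[ia]]; eb <- desc[[ib]]
  ni <- sum(ea %in% eb)
  code <- if (ni == 0L) 5L
  else if (ni == length(ea) && ni == length(eb)) 1L
  else if (ni == length(eb)) 2L
  else if (ni == length(ea)) 3L
  else 4L
  RCC5_SYMBOLS[code]
}
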