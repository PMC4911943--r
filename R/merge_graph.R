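# Merge taxonomy visual products: reduced containment graph of congruence
# classes with dashed overlap edges, combined-concept view resolving Euler
# subregions, and DOT text output.

#' Build the merge (reduced containment) graph of an alignment
#'
#' Concepts are grouped into congruence classes (the gray nodes of the
#' alignment figures): cross-taxonomy pairs whose relation is `==`, plus
#' within-taxonomy monotypic coverage chains. Containment edges come from
#' `>`/`<` cells and within-taxonomy parenthood and are transitively
#' reduced; `><` cells become dashed overlap edges.
#'
#' @param mir A [mir_table][compute_mir()].
#' @param t2,t1 The input [taxonomy()] objects.
#' @param world Optional world matrix (from [enumerate_worlds()]) selecting
#'   one alignment when the MIR has ambiguous (disjunctive) cells.
#' @return An object of class `merge_graph`: `nodes` (id, label, origin,
#'   members), `edges` (containment, from/to), `overlap` (unordered pairs).
#' @export
build_merge <- function(mir, t2, t1, world = NULL) {
  n2 <- nrow(mir$cells); n1 <- ncol(mir$cells)
  if (is.null(world)) {
    if (!all(is_singleton_bits(mir$cells))) {
      stop("MIR has ambiguous cells (multiple possible worlds); pass one ",
           "world from enumerate_worlds() via the 'world' argument")
    }
    codes <- matrix(match(serialize_bits(mir$cells), RCC5_SYMBOLS), n2, n1)
  } else {
    stopifnot(all(dim(world) == c(n2, n1)))
    codes <- matrix(match(world, RCC5_SYMBOLS), n2, n1)
  }
  q2 <- rownames(mir$cells); q1 <- colnames(mir$cells)
  labels <- c(q2, q1)
  n <- length(labels)
  from_t2 <- c(rep(TRUE, n2), rep(FALSE, n1))

  # union-find over concepts
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }
  eq <- which(codes == 1L, arr.ind = TRUE)
  for (k in seq_len(nrow(eq))) union(eq[k, 1], n2 + eq[k, 2])
  chain_union <- function(tax, offset) {
    desc <- eligible_descendants(tax)
    pidx <- match(tax$concepts$parent, tax$concepts$name)
    for (i in seq_len(n_concepts(tax))) {
      if (!is.na(pidx[i]) && identical(desc[[i]], desc[[pidx[i]]])) {
        union(offset + i, offset + pidx[i]) # monotypic coverage chain
      }
    }
  }
  chain_union(t2, 0L)
  chain_union(t1, n2)

  cls <- vapply(seq_len(n), find, 0L)
  classes <- split(seq_len(n), cls)
  node_of <- match(cls, as.integer(names(classes)))
  node_members <- lapply(classes, function(ix) sort(labels[ix],
                                                    method = "radix"))
  node_id <- vapply(node_members, `[`, "", 1L)
  origin <- vapply(classes, function(ix) {
    both <- any(from_t2[ix]) && any(!from_t2[ix])
    if (both || length(ix) > 1L) "congruent"
    else if (from_t2[ix[1]]) "t2" else "t1"
  }, "")

  edge_key <- character(0); efrom <- integer(0); eto <- integer(0)
  add_edge <- function(a, b) {
    if (a == b) return()
    key <- paste(a, b)
    if (!key %in% edge_key) {
      edge_key <<- c(edge_key, key)
      efrom <<- c(efrom, a); eto <<- c(eto, b)
    }
  }
  gt <- which(codes == 2L, arr.ind = TRUE)
  for (k in seq_len(nrow(gt))) add_edge(node_of[gt[k, 1]],
                                        node_of[n2 + gt[k, 2]])
  lt <- which(codes == 3L, arr.ind = TRUE)
  for (k in seq_len(nrow(lt))) add_edge(node_of[n2 + lt[k, 2]],
                                        node_of[lt[k, 1]])
  add_parenthood <- function(tax, offset) {
    pidx <- match(tax$concepts$parent, tax$concepts$name)
    for (i in seq_len(n_concepts(tax))) {
      if (!is.na(pidx[i])) add_edge(node_of[offset + pidx[i]],
                                    node_of[offset + i])
    }
  }
  add_parenthood(t2, 0L)
  add_parenthood(t1, n2)

  ov <- which(codes == 4L, arr.ind = TRUE)
  okey <- character(0); oa <- integer(0); ob <- integer(0)
  for (k in seq_len(nrow(ov))) {
    a <- node_of[ov[k, 1]]; b <- node_of[n2 + ov[k, 2]]
    if (a == b) next
    key <- paste(min(a, b), max(a, b))
    if (!key %in% okey) { okey <- c(okey, key); oa <- c(oa, min(a, b))
                          ob <- c(ob, max(a, b)) }
  }

  g <- structure(list(
    nodes = data.frame(id = node_id, origin = origin,
                       stringsAsFactors = FALSE, row.names = NULL),
    members = node_members,
    edges = data.frame(from = efrom, to = eto),
    overlap = data.frame(a = oa, b = ob)
  ), class = "merge_graph")
  g$edges <- transitive_reduction(g$edges, nrow(g$nodes))
  g
}

# Transitive reduction of a DAG given as an edge list; drops every edge
# implied by a two-or-more step path. Errors on cycles.
transitive_reduction <- function(edges, n) {
  if (nrow(edges) == 0L) return(edges)
  adj <- lapply(seq_len(n), function(i) edges$to[edges$from == i])
  # reachability by DFS in reverse topological order
  indeg_ok <- TRUE
  reach <- vector("list", n)
  state <- integer(n)
  visit <- function(v) {
    if (state[v] == 1L) stop("containment graph has a cycle")
    if (state[v] == 2L) return()
    state[v] <<- 1L
    for (w in adj[[v]]) visit(w)
    reach[[v]] <<- sort(unique(c(adj[[v]],
                                 unlist(reach[adj[[v]]], use.names = FALSE))))
    state[v] <<- 2L
  }
  for (v in seq_len(n)) visit(v)
  keep <- vapply(seq_len(nrow(edges)), function(k) {
    u <- edges$from[k]; v <- edges$to[k]
    others <- setdiff(adj[[u]], v)
    !any(vapply(others, function(w) v %in% reach[[w]], TRUE))
  }, TRUE)
  edges[keep, , drop = FALSE]
}

#' @export
print.merge_graph <- function(x, ...) {
  cat(sprintf("<merge graph: %d nodes (%d congruent), %d containment edges, %d overlap edges>\n",
              nrow(x$nodes), sum(x$nodes$origin == "congruent"),
              nrow(x$edges), nrow(x$overlap)))
  invisible(x)
}

#' Resolve overlap edges into combined-concept Euler subregions
#'
#' Each overlap edge (A, B) is replaced by labeled subregion nodes: `A*B`
#' (child of both A and B) and, where nonempty in the chosen alignment,
#' `A\B` (child of A only) and `B\A` (child of B only). Since an overlap
#' relation asserts all three subregions nonempty, all three nodes are
#' added for every overlap edge; the emptiness rule matters only for graphs
#' assembled by other means.
#'
#' @param graph A [build_merge()] result.
#' @return The graph with subregion nodes added and overlap edges removed;
#'   attribute `n_added` reports the number of added nodes.
#' @export
combined_concepts <- function(graph) {
  n_added <- 0L
  for (k in seq_len(nrow(graph$overlap))) {
    a <- graph$overlap$a[k]; b <- graph$overlap$b[k]
    la <- graph$nodes$id[a]; lb <- graph$nodes$id[b]
    add_node <- function(id, parents) {
      graph$nodes <<- rbind(graph$nodes,
                            data.frame(id = id, origin = "subregion",
                                       stringsAsFactors = FALSE))
      graph$members <<- c(graph$members, list(id))
      i <- nrow(graph$nodes)
      graph$edges <<- rbind(graph$edges,
                            data.frame(from = parents, to = i))
      n_added <<- n_added + 1L
    }
    add_node(paste0(la, "*", lb), c(a, b))
    add_node(paste0(la, "\\", lb), a)
    add_node(paste0(lb, "\\", la), b)
  }
  graph$overlap <- graph$overlap[integer(0), , drop = FALSE]
  attr(graph, "n_added") <- n_added
  graph
}

dot_escape <- function(s) {
  gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", s))
}

DOT_STYLES <- c(
  t2 = "shape=box, style=filled, fillcolor=palegreen",
  t1 = "shape=octagon, style=filled, fillcolor=lightyellow",
  congruent = "shape=box, style=\"rounded,filled\", fillcolor=gray83",
  subregion = "shape=box, style=dashed")

#' Render a merge graph as DOT text
#'
#' Styling follows the alignment figures' legend: T2-only concepts as green
#' rectangles, T1-only concepts as yellow octagons, congruent concept sets
#' as gray rounded rectangles; containment as solid edges, overlap as blue
#' dashed lines. Output is deterministic.
#'
#' @param graph A [build_merge()] (optionally [combined_concepts()]) result.
#' @param name Graph name.
#' @param styles Named character vector overriding the per-origin node
#'   attribute strings (names `t2`, `t1`, `congruent`, `subregion`).
#' @return DOT source as one string.
#' @export
to_dot <- function(graph, name = "alignment", styles = DOT_STYLES) {
  sty <- DOT_STYLES
  sty[names(styles)] <- styles
  ord <- order(graph$nodes$id, method = "radix")
  lines <- c(sprintf("digraph \"%s\" {", dot_escape(name)),
             "  rankdir=TB;")
  for (i in ord) {
    label <- paste(graph$members[[i]], collapse = "\\n")
    lines <- c(lines, sprintf("  \"%s\" [label=\"%s\", %s];",
                              dot_escape(graph$nodes$id[i]),
                              dot_escape(label),
                              sty[[graph$nodes$origin[i]]]))
  }
  if (nrow(graph$edges)) {
    ek <- order(graph$nodes$id[graph$edges$from],
                graph$nodes$id[graph$edges$to], method = "radix")
    for (k in ek) {
      lines <- c(lines, sprintf("  \"%s\" -> \"%s\";",
                                dot_escape(graph$nodes$id[graph$edges$from[k]]),
                                dot_escape(graph$nodes$id[graph$edges$to[k]])))
    }
  }
  if (nrow(graph$overlap)) {
    ok <- order(graph$nodes$id[graph$overlap$a],
                graph$nodes$id[graph$overlap$b], method = "radix")
    for (k in ok) {
      lines <- c(lines, sprintf(
        "  \"%s\" -> \"%s\" [style=dashed, color=blue, dir=none, constraint=false];",
        dot_escape(graph$nodes$id[graph$overlap$a[k]]),
        dot_escape(graph$nodes$id[graph$overlap$b[k]])))
    }
  }
  paste0(paste(c(lines, "}"), collapse = "\n"), "\n")
}

#' Render the alignment input (both taxonomies plus articulations) as DOT
#'
#' The "input" view: each taxonomy as a cluster of parent->child edges, with
#' the user-provided articulations drawn as labeled dashed edges between
#' them.
#'
#' @param problem An [alignment_problem()].
#' @return DOT source as one string.
#' @export
problem_to_dot <- function(problem) {
  tax_lines <- function(tax, color) {
    q <- qualified_labels(tax)
    out <- c(sprintf("  subgraph \"cluster_%s\" {", dot_escape(tax$id)),
             sprintf("    label=\"%s\";", dot_escape(tax$label)))
    for (i in seq_along(q)) {
      out <- c(out, sprintf("    \"%s\" [shape=box, style=filled, fillcolor=%s];",
                            dot_escape(q[i]), color))
    }
    pidx <- match(tax$concepts$parent, tax$concepts$name)
    for (i in seq_along(q)) {
      if (!is.na(pidx[i])) {
        out <- c(out, sprintf("    \"%s\" -> \"%s\";",
                              dot_escape(q[pidx[i]]), dot_escape(q[i])))
      }
    }
    c(out, "  }")
  }
  arts <- problem$articulations
  art_lines <- character(0)
  for (k in seq_len(nrow(arts))) {
    art_lines <- c(art_lines, sprintf(
      "  \"%s.%s\" -> \"%s.%s\" [label=\"%s\", style=dashed, color=gray40, dir=none, constraint=false];",
      dot_escape(problem$t2$id), dot_escape(arts$left[k]),
      dot_escape(problem$t1$id), dot_escape(arts$right[k]),
      dot_escape(rcc5_format(arts$rels[[k]]))))
  }
  paste0(paste(c("digraph \"input\" {", "  rankdir=TB;",
                 tax_lines(problem$t2, "palegreen"),
                 tax_lines(problem$t1, "lightyellow"),
                 art_lines, "}"), collapse = "\n"), "\n")
}
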