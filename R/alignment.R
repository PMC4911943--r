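# Alignment problems: two taxonomies plus expert RCC-5 articulations.

#' Build an articulation table
#'
#' An articulation is a user-asserted RCC-5 statement between one concept in
#' each input taxonomy, possibly a disjunction of base relations to express
#' uncertainty. By convention the later taxonomy's concept (T2) stands on
#' the left.
#'
#' @param left Character vector of concept names in T2.
#' @param relation Character vector: a relation symbol (`"=="`, `">"`, `"<"`,
#'   `"><"`, `"!"` or `"|"`), word (`equals`, `includes`, `is_included_in`,
#'   `overlaps`, `disjoint`), or brace-delimited disjunction like
#'   `"{== ><}"`.
#' @param right Character vector of concept names in T1.
#' @param label Provenance label(s), recycled.
#' @return A data frame with columns `left`, `rels` (list of integer relation
#'   codes), `right`, `label`.
#' @export
articulations <- function(left, relation, right, label = "input") {
  n <- max(length(left), length(relation), length(right))
  left <- rep_len(as.character(left), n)
  relation <- rep_len(as.character(relation), n)
  right <- rep_len(as.character(right), n)
  label <- rep_len(as.character(label), n)
  out <- data.frame(left = left, right = right, label = label,
                    stringsAsFactors = FALSE)
  out$rels <- lapply(relation, parse_relset)
  out[, c("left", "rels", "right", "label")]
}

#' Construct an alignment problem
#'
#' Bundles the two input taxonomies (T2 the later, T1 the earlier), the
#' expert articulations, and global reasoning options. The nonemptiness,
#' sibling-disjointness and coverage constraints are applied globally by the
#' reasoner; coverage can be relaxed per concept via the taxonomy's
#' `nocoverage` flags.
#'
#' @param t2,t1 [taxonomy()] objects with distinct ids; `t2` is the later
#'   treatment and its concepts stand on the left of every articulation.
#' @param arts Articulation table from [articulations()] (or a data frame
#'   with columns `left`, `relation`, `right` to be converted). May be empty.
#' @param sibling_disjointness Children of one parent are pairwise exclusive.
#'   The region-signature encoding entails this by construction; `FALSE` is
#'   not supported and errors.
#' @param world_cap Maximum number of possible worlds enumerated before
#'   [compute_mir()] falls back to per-pair satisfiability queries.
#' @return An object of class `alignment_problem`.
#' @export
alignment_problem <- function(t2, t1, arts = NULL,
                              sibling_disjointness = TRUE,
                              world_cap = 256L) {
  stopifnot(inherits(t2, "taxonomy"), inherits(t1, "taxonomy"))
  if (t2$id == t1$id) stop("the two taxonomies must have distinct ids")
  if (!isTRUE(sibling_disjointness)) {
    stop("sibling_disjointness = FALSE is not supported: the candidate-",
         "region encoding entails sibling disjointness by construction")
  }
  if (is.null(arts)) {
    arts <- articulations(character(), character(), character())
  }
  if (!is.list(arts$rels) && !is.null(arts$relation)) {
    arts <- articulations(arts$left, arts$relation, arts$right,
                          if (is.null(arts$label)) "input" else arts$label)
  }
  missing2 <- setdiff(arts$left, t2$concepts$name)
  if (length(missing2)) {
    stop("articulation references unknown concept(s) in taxonomy '",
         t2$id, "': ", paste(unique(missing2), collapse = ", "))
  }
  missing1 <- setdiff(arts$right, t1$concepts$name)
  if (length(missing1)) {
    stop("articulation references unknown concept(s) in taxonomy '",
         t1$id, "': ", paste(unique(missing1), collapse = ", "))
  }
  structure(list(
    t2 = t2, t1 = t1, articulations = arts,
    options = list(sibling_disjointness = TRUE,
                   world_cap = as.integer(world_cap))
  ), class = "alignment_problem")
}

#' @export
print.alignment_problem <- function(x, ...) {
  cat(sprintf("<alignment problem: T2 = %s (%d concepts), T1 = %s (%d concepts)>\n",
              x$t2$id, n_concepts(x$t2), x$t1$id, n_concepts(x$t1)))
  cat(sprintf("  %d input articulations; world cap %d\n",
              nrow(x$articulations), x$options$world_cap))
  invisible(x)
}

# Structural equality used by round-trip tests: concept and articulation
# order is canonicalized first (the text format groups children per parent,
# so declaration order is not meaningful), and ranks are carried by the
# sidecar, not the alignment text, so they are compared only when asked.
problems_equal <- function(a, b, ignore_ranks = FALSE) {
  strip <- function(p) {
    canon_tax <- function(tax) {
      o <- order(tax$concepts$name, method = "radix")
      tax$concepts <- tax$concepts[o, , drop = FALSE]
      row.names(tax$concepts) <- NULL
      if (ignore_ranks) tax$concepts$rank <- NULL
      tax
    }
    p$t2 <- canon_tax(p$t2)
    p$t1 <- canon_tax(p$t1)
    arts <- p$articulations
    arts$rels <- lapply(arts$rels, as.integer)
    key <- paste(arts$left, arts$right, vapply(arts$rels, rcc5_format, ""),
                 arts$label)
    arts <- arts[order(key, method = "radix"), , drop = FALSE]
    row.names(arts) <- NULL
    p$articulations <- arts
    p
  }
  isTRUE(all.equal(strip(a), strip(b), check.attributes = FALSE))
}
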