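# Hard-coded and generated alignment fixtures: the Microcebus/Mirza worked
# example, exact-size instances exercising the MIR product law, and an
# evolved-taxonomy-pair generator emulating the typical change operations
# between succeeding classification editions (reassessment splits,
# acquisition additions, lumps, renames).

#' The Microcebus/Mirza worked example
#'
#' Reconstructs the mouse-lemur alignment between the 2005 and 1993
#' treatments: T2 holds the genus *Microcebus* with eight species plus the
#' monotypic genus *Mirza* (11 concepts); T1 holds *Microcebus* with three
#' species (4 concepts). Nine articulations: three 2005 species each
#' included in `1993.Microcebus_murinus` (reassessment splits), four 2005
#' species exclusive of the 1993 genus (acquisitions), and the two
#' congruences for *rufus* and *coquereli*. The alignment is consistent,
#' admits exactly two possible worlds, and its MIR comprises 44 cells.
#'
#' The concept lists are a reconstruction from the published figure of this
#' alignment; node counts are validated against the printed MIR and world
#' counts.
#'
#' @param ranked Attach genus/species ranks (default `TRUE`).
#' @return An [alignment_problem()].
#' @export
fixture_fig1 <- function(ranked = TRUE) {
  sp2 <- c("Microcebus_berthae", "Microcebus_griseorufus",
           "Microcebus_murinus", "Microcebus_myoxinus",
           "Microcebus_ravelobensis", "Microcebus_rufus",
           "Microcebus_sambiranensis", "Microcebus_tavaratra")
  t2 <- taxonomy("2005", data.frame(
    parent = c(rep("Microcebus", 8L), "Mirza"),
    child = c(sp2, "Mirza_coquereli")),
    label = "Microcebus/Mirza sec. 2005",
    ranks = if (ranked) stats::setNames(
      c("genus", rep("species", 8L), "genus", "species"),
      c("Microcebus", sp2, "Mirza", "Mirza_coquereli")))
  sp1 <- c("Microcebus_murinus", "Microcebus_rufus", "Microcebus_coquereli")
  t1 <- taxonomy("1993", data.frame(
    parent = rep("Microcebus", 3L), child = sp1),
    label = "Microcebus sec. 1993",
    ranks = if (ranked) stats::setNames(c("genus", rep("species", 3L)),
                                        c("Microcebus", sp1)))
  arts <- articulations(
    left = c("Microcebus_griseorufus", "Microcebus_murinus",
             "Microcebus_myoxinus",
             "Microcebus_berthae", "Microcebus_ravelobensis",
             "Microcebus_sambiranensis", "Microcebus_tavaratra",
             "Microcebus_rufus", "Mirza_coquereli"),
    relation = c(rep("is_included_in", 3L), rep("disjoint", 4L),
                 rep("equals", 2L)),
    right = c(rep("Microcebus_murinus", 3L), rep("Microcebus", 4L),
              "Microcebus_rufus", "Microcebus_coquereli"),
    label = "fig1")
  alignment_problem(t2, t1, arts)
}

# Balanced-ish tree with exactly n concepts: a root, m internal nodes and
# n - 1 - m leaves distributed round-robin (leaves go under the root when
# m = 0). Returns the edge data frame plus name bookkeeping.
sized_tree_edges <- function(n, n_leaves, prefix = "") {
  m <- n - 1L - n_leaves
  stopifnot(m >= 0L, n_leaves >= 1L)
  root <- paste0(prefix, "Root")
  leaves <- sprintf("%sSpecies_%03d", prefix, seq_len(n_leaves))
  if (m == 0L) {
    edges <- data.frame(parent = root, child = leaves,
                        stringsAsFactors = FALSE)
  } else {
    if (n_leaves < m) stop("too few leaves for ", m, " internal nodes")
    internal <- sprintf("%sClade_%03d", prefix, seq_len(m))
    holder <- internal[((seq_len(n_leaves) - 1L) %% m) + 1L]
    edges <- rbind(
      data.frame(parent = root, child = internal, stringsAsFactors = FALSE),
      data.frame(parent = holder, child = leaves, stringsAsFactors = FALSE))
  }
  list(edges = edges, root = root, leaves = leaves,
       internal = if (m > 0L) internal else character(0))
}

#' Generate an exact-size alignment with a unique world
#'
#' Builds T1 as a tree with exactly `n1_concepts` concepts, clones it into
#' T2 and attaches acquisition leaves (exclusive of the T1 root) until T2
#' has exactly `n2_concepts` concepts. Articulations follow the
#' species-level-plus-root recipe: every shared leaf congruent, every new
#' leaf exclusive of the T1 root, root properly including root; redundant
#' (logically implied) articulations pad the count to `n_articulations`
#' exactly. The result is consistent, has exactly one possible world, and
#' its MIR obeys the product law: `n2_concepts * n1_concepts` cells.
#'
#' @param n2_concepts,n1_concepts Total concept counts (`n2 >= n1 >= 2`).
#' @param n_articulations Exact number of input articulations.
#' @param seed Seed for sampling the padding articulations.
#' @return An [alignment_problem()].
#' @export
make_sized_pair <- function(n2_concepts, n1_concepts, n_articulations,
                            seed = 1L) {
  n2 <- as.integer(n2_concepts); n1 <- as.integer(n1_concepts)
  na <- as.integer(n_articulations)
  if (n2 < n1 || n1 < 2L) stop("need n2_concepts >= n1_concepts >= 2")
  n_new <- n2 - n1
  # choose the T1 leaf count so that leaves + acquisitions + root = target
  # when possible; otherwise max out the leaves and pad. A unique world
  # needs every T1 leaf articulated, plus the root articulation except in
  # the exact-fit case where all (n1 - 1) leaves are articulated anyway.
  root_art <- TRUE
  n_leaves <- min(n1 - 1L, na - n_new - 1L)
  if (n_leaves < 1L && na == (n1 - 1L) + n_new) {
    n_leaves <- n1 - 1L
    root_art <- FALSE
  }
  internal <- n1 - 1L - n_leaves
  if (n_leaves < max(1L, internal)) {
    stop("infeasible size/articulation combination")
  }
  tr <- sized_tree_edges(n1, n_leaves)
  new_leaves <- if (n_new > 0L) sprintf("Species_new_%03d", seq_len(n_new))
  else character(0)
  edges2 <- rbind(tr$edges,
                  if (n_new > 0L) data.frame(parent = tr$root,
                                             child = new_leaves,
                                             stringsAsFactors = FALSE))
  t2 <- taxonomy("t2", edges2, label = "later edition (synthetic)")
  t1 <- taxonomy("t1", tr$edges, label = "earlier edition (synthetic)")

  left <- c(tr$leaves, new_leaves, if (root_art) tr$root)
  rel <- c(rep("equals", n_leaves), rep("disjoint", n_new),
           if (root_art) (if (n_new > 0L) "includes" else "equals"))
  right <- c(tr$leaves, rep(tr$root, n_new), if (root_art) tr$root)
  lab <- c(rep("species", n_leaves), rep("acquisition", n_new),
           if (root_art) "root")

  n_pad <- na - length(left)
  if (n_pad > 0L) {
    # redundant articulations sampled from already-implied cells: clone
    # internal nodes are congruent, distinct shared leaves are exclusive
    pool_left <- c(tr$internal,
                   rep(tr$leaves, each = min(8L, n_leaves - 1L)))
    pool_rel <- c(rep("equals", length(tr$internal)),
                  rep("disjoint", length(pool_left) - length(tr$internal)))
    pool_right <- c(tr$internal, unlist(lapply(seq_len(n_leaves), function(i) {
      others <- setdiff(seq_len(n_leaves), i)
      tr$leaves[others[seq_len(min(8L, n_leaves - 1L))]]
    })))
    if (n_pad > length(pool_left)) {
      stop("cannot pad to ", na, " articulations on this size")
    }
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(as.integer(seed) %% .Machine$integer.max)
    pick <- sort(sample.int(length(pool_left), n_pad))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    left <- c(left, pool_left[pick])
    rel <- c(rel, pool_rel[pick])
    right <- c(right, pool_right[pick])
    lab <- c(lab, rep("padding", n_pad))
  }
  alignment_problem(t2, t1, articulations(left, rel, right, lab))
}

#' Parameters for an evolved taxonomy pair
#'
#' @param leaf_count_t1 Number of species-level (leaf) concepts in T1.
#' @param internal_arity Leaves per internal (genus-like) node; `0` puts all
#'   leaves directly under the root.
#' @param n_split Leaves of T1 split into `split_k` narrower T2 concepts
#'   (reassessment-contingent additions, articulated `<`).
#' @param split_k Split width (children per split leaf).
#' @param n_new Acquisition-contingent T2 additions (articulated `!` against
#'   the T1 root).
#' @param n_lump Pairs of T1 sibling leaves merged into one T2 concept
#'   (articulated `>` against each).
#' @param n_rename Leaves kept congruent but renamed in T2.
#' @param seed Seed choosing which leaves are affected.
#' @return A validated list of class `scenario_params`.
#' @export
scenario_params <- function(leaf_count_t1 = 8L, internal_arity = 0L,
                            n_split = 0L, split_k = 2L, n_new = 0L,
                            n_lump = 0L, n_rename = 0L, seed = 1L) {
  p <- list(leaf_count_t1 = as.integer(leaf_count_t1),
            internal_arity = as.integer(internal_arity),
            n_split = as.integer(n_split), split_k = as.integer(split_k),
            n_new = as.integer(n_new), n_lump = as.integer(n_lump),
            n_rename = as.integer(n_rename), seed = as.integer(seed))
  if (any(unlist(p[c("n_split", "n_new", "n_lump", "n_rename")]) < 0L)) {
    stop("scenario counts must be nonnegative")
  }
  if (p$n_split > 0L && p$split_k < 2L) stop("split_k must be at least 2")
  needed <- p$n_split + 2L * p$n_lump + p$n_rename
  if (needed > p$leaf_count_t1) {
    stop("parameter conflict: ", needed, " distinct target leaves needed ",
         "but only ", p$leaf_count_t1, " available")
  }
  class(p) <- "scenario_params"
  p
}

#' Generate an evolved taxonomy pair with known ground truth
#'
#' Derives T2 from a synthetic T1 by the classification-change operations a
#' later edition typically applies: k-way reassessment splits (each child
#' articulated `<` the old concept), acquisition additions (articulated `!`
#' the T1 root), lumps (`>` each merged leaf), and renames (`==` under a new
#' name); unchanged leaves are articulated `==`. A root articulation is
#' added when it is unambiguous: `>` with acquisitions present, `==` when
#' nothing changes extensions, none when only splits/lumps occur (forcing a
#' root relation there would remove the split-slack ambiguity that makes
#' such alignments have multiple worlds).
#'
#' @param params A [scenario_params()] (or arguments for it as a list).
#' @return List with `problem` (the [alignment_problem()]) and `truth`:
#'   the emitted articulations, `expected_worlds`
#'   (`2^n_lump` with acquisitions present, else `2^(n_split + n_lump)`),
#'   and `expected_mir` (the exact [oracle_mir()] when the instance is
#'   within oracle range, else `NULL`).
#' @export
generate_evolved_pair <- function(params = scenario_params()) {
  if (!inherits(params, "scenario_params")) {
    params <- do.call(scenario_params, as.list(params))
  }
  p <- params
  L <- p$leaf_count_t1
  leaves1 <- sprintf("Species_%02d", seq_len(L))
  if (p$internal_arity >= 2L && L > p$internal_arity) {
    m <- ceiling(L / p$internal_arity)
    internal <- sprintf("Clade_%02d", seq_len(m))
    holder <- internal[((seq_len(L) - 1L) %/% p$internal_arity) + 1L]
    edges1 <- rbind(
      data.frame(parent = "Root", child = internal, stringsAsFactors = FALSE),
      data.frame(parent = holder, child = leaves1, stringsAsFactors = FALSE))
  } else {
    holder <- rep("Root", L)
    edges1 <- data.frame(parent = "Root", child = leaves1,
                         stringsAsFactors = FALSE)
  }
  t1 <- taxonomy("t1", edges1, label = "earlier edition (synthetic)")

  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(p$seed %% .Machine$integer.max)
  # lumped pairs must be siblings: pick pairs adjacent under one holder
  lump_pairs <- list()
  avail <- seq_len(L)
  if (p$n_lump > 0L) {
    by_holder <- split(seq_len(L), holder)
    cand <- list()
    for (ix in by_holder) {
      if (length(ix) >= 2L) {
        cand <- c(cand, lapply(seq_len(length(ix) %/% 2L),
                               function(j) ix[c(2L * j - 1L, 2L * j)]))
      }
    }
    if (length(cand) < p$n_lump) {
      stop("not enough sibling leaf pairs for ", p$n_lump, " lump(s)")
    }
    lump_pairs <- cand[sample.int(length(cand), p$n_lump)]
    avail <- setdiff(avail, unlist(lump_pairs))
  }
  split_targets <- if (p$n_split > 0L) {
    s <- sample(avail, p$n_split); avail <- setdiff(avail, s); s
  } else integer(0)
  rename_targets <- if (p$n_rename > 0L) {
    s <- sample(avail, p$n_rename); avail <- setdiff(avail, s); s
  } else integer(0)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)

  # assemble T2 edges and the articulation recipe
  e2p <- character(0); e2c <- character(0)
  aL <- character(0); aR <- character(0); aRel <- character(0)
  aLab <- character(0)
  add_art <- function(l, r, rel, lab) {
    aL <<- c(aL, l); aR <<- c(aR, r); aRel <<- c(aRel, rel)
    aLab <<- c(aLab, lab)
  }
  if (p$internal_arity >= 2L && L > p$internal_arity) {
    ih <- unique(holder)
    e2p <- c(e2p, rep("Root", length(ih))); e2c <- c(e2c, ih)
  }
  lumped <- unlist(lump_pairs)
  for (i in seq_len(L)) {
    if (i %in% lumped) next
    if (i %in% split_targets) {
      kids <- paste0(leaves1[i], letters[seq_len(p$split_k)])
      e2p <- c(e2p, rep(holder[i], p$split_k)); e2c <- c(e2c, kids)
      for (k in kids) add_art(k, leaves1[i], "is_included_in", "split")
    } else if (i %in% rename_targets) {
      nm <- paste0(leaves1[i], "_ren")
      e2p <- c(e2p, holder[i]); e2c <- c(e2c, nm)
      add_art(nm, leaves1[i], "equals", "rename")
    } else {
      e2p <- c(e2p, holder[i]); e2c <- c(e2c, leaves1[i])
      add_art(leaves1[i], leaves1[i], "equals", "unchanged")
    }
  }
  for (pr in lump_pairs) {
    nm <- paste(leaves1[pr], collapse = "_x_")
    e2p <- c(e2p, holder[pr[1]]); e2c <- c(e2c, nm)
    for (i in pr) add_art(nm, leaves1[i], "includes", "lump")
  }
  if (p$n_new > 0L) {
    new_leaves <- sprintf("Species_new_%02d", seq_len(p$n_new))
    e2p <- c(e2p, rep("Root", p$n_new)); e2c <- c(e2c, new_leaves)
    for (w in new_leaves) add_art(w, "Root", "disjoint", "acquisition")
  }
  if (p$n_new > 0L) {
    add_art("Root", "Root", "includes", "root")
  } else if (p$n_split == 0L && p$n_lump == 0L) {
    add_art("Root", "Root", "equals", "root")
  }
  t2 <- taxonomy("t2", data.frame(parent = e2p, child = e2c,
                                  stringsAsFactors = FALSE),
                 label = "later edition (synthetic)")
  problem <- alignment_problem(t2, t1, articulations(aL, aRel, aR, aLab))

  # Free (unarticulated, unforced) regions each double the world count:
  # one per split (does the old concept exceed its narrowed children?),
  # one per lump (does the merged concept exceed the lumped pair?) unless a
  # root congruence pins it, and one per lump x split pair (nothing relates
  # a lumped concept to a split target). A root `>` articulation absorbs
  # the split slack into the expanded root.
  cross <- p$n_lump * p$n_split
  expected_worlds <- if (p$n_new > 0L) 2L^(p$n_lump + cross)
  else if (p$n_split + p$n_lump > 0L) 2L^(p$n_split + p$n_lump + cross)
  else 1L
  n_regions <- (length(eligible_concepts(t2)) + 1L) *
    (length(eligible_concepts(t1)) + 1L) - 1L
  expected_mir <- if (n_regions <= 20L) oracle_mir(problem) else NULL
  list(problem = problem,
       truth = list(articulations = problem$articulations,
                    expected_worlds = expected_worlds,
                    expected_mir = expected_mir))
}
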