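# Core reasoner: encodes an alignment problem over candidate Euler regions,
# decides consistency, enumerates possible worlds, computes the MIR table,
# and diagnoses inconsistent inputs.
#
# Encoding. A candidate region is a pair (deepest T2 concept or NONE,
# deepest T1 concept or NONE), where a concept is eligible as "deepest" iff
# it has no children or its coverage flag is off; the pair (NONE, NONE) is
# excluded. An interpretation is the set of occupied regions; a concept's
# extension is the union of occupied regions whose deepest node lies
# at-or-below it. Sibling disjointness and within-taxonomy inclusion hold by
# construction of the signatures; coverage holds because a covered parent
# is never a "deepest" node. The remaining constraints are:
#   * nonemptiness - for every concept, at least one occupied region
#     at-or-below it (a positive clause over region atoms);
#   * articulations - for the articulated pair (x, y), with I/L/R the
#     regions inside x-and-y, x-not-y, y-not-x, each base relation is
#     exactly the witness pattern EQ: L,R empty; GT: R empty, L occupied;
#     LT: L empty, R occupied; OV: I,L,R occupied; DJ: I empty.
# For a fixed choice of one base relation per articulation the system is
# monotone: forced-off region sets plus positive clauses. Consistency then
# reduces to "every positive clause retains an allowed region" (the maximal
# model occupies everything not forced off), which this solver exploits;
# disjunctive articulations and world enumeration branch on top of it.

REGION_NONE <- 0L

compile_problem <- function(problem) {
  t2 <- problem$t2; t1 <- problem$t1
  n2 <- n_concepts(t2); n1 <- n_concepts(t1)
  desc2 <- eligible_descendants(t2)
  desc1 <- eligible_descendants(t1)
  elig2 <- eligible_concepts(t2)
  elig1 <- eligible_concepts(t1)
  t2vals <- c(REGION_NONE, elig2)
  t1vals <- c(REGION_NONE, elig1)
  t2r <- rep(t2vals, each = length(t1vals))
  t1r <- rep(t1vals, times = length(t2vals))
  keep <- !(t2r == REGION_NONE & t1r == REGION_NONE)
  t2r <- t2r[keep]; t1r <- t1r[keep]
  K <- length(t2r)

  under2_of <- function(i) t2r %in% desc2[[i]]
  under1_of <- function(i) t1r %in% desc1[[i]]
  onsets <- c(lapply(seq_len(n2), function(i) which(under2_of(i))),
              lapply(seq_len(n1), function(i) which(under1_of(i))))

  under_cache2 <- vector("list", n2)
  under_cache1 <- vector("list", n1)
  env <- new.env(parent = emptyenv())
  env$u2 <- under_cache2; env$u1 <- under_cache1
  under2 <- function(i) {
    v <- env$u2[[i]]
    if (is.null(v)) { v <- under2_of(i); env$u2[[i]] <- v }
    v
  }
  under1 <- function(i) {
    v <- env$u1[[i]]
    if (is.null(v)) { v <- under1_of(i); env$u1[[i]] <- v }
    v
  }

  arts <- problem$articulations
  art_list <- vector("list", nrow(arts))
  if (nrow(arts)) {
    nm2 <- t2$concepts$name; nm1 <- t1$concepts$name
    for (k in seq_len(nrow(arts))) {
      li <- match(arts$left[k], nm2)
      ri <- match(arts$right[k], nm1)
      u2 <- under2_of(li); u1 <- under1_of(ri)
      art_list[[k]] <- list(
        li = li, ri = ri, rels = arts$rels[[k]],
        I = which(u2 & u1), L = which(u2 & !u1), R = which(!u2 & u1))
    }
  }

  # dense 0/1 concept-by-region membership matrices speed up relation-map
  # extraction on small instances; large instances use a sparse path over
  # the occupied regions only
  dense2 <- dense1 <- NULL
  if ((n2 + n1) * K <= 2e6) {
    dense2 <- matrix(0, n2, K)
    for (i in seq_len(n2)) dense2[i, onsets[[i]]] <- 1
    dense1 <- matrix(0, n1, K)
    for (i in seq_len(n1)) dense1[i, onsets[[n2 + i]]] <- 1
  }

  list(t2 = t2, t1 = t1, n2 = n2, n1 = n1,
       q2 = qualified_labels(t2), q1 = qualified_labels(t1),
       desc2 = desc2, desc1 = desc1,
       anc2 = ancestors_of(t2), anc1 = ancestors_of(t1),
       t2r = t2r, t1r = t1r, K = K,
       onsets = onsets, under2 = under2, under1 = under1,
       dense2 = dense2, dense1 = dense1,
       ilr_cache = new.env(parent = emptyenv()),
       arts = art_list)
}

# Witness-pattern constraints for base relation r at a pair with region
# partition I/L/R: list(off = regions forced unoccupied,
#                       on = positive clauses added).
# e_int requirements of EQ/GT/LT follow from the global nonemptiness of the
# pair's concepts once the off-sets are applied, so they are not repeated.
pattern_for <- function(r, I, L, R) {
  switch(r,
         list(off = c(L, R), on = list()),        # ==
         list(off = R, on = list(L)),             # >
         list(off = L, on = list(R)),             # <
         list(off = integer(0), on = list(I, L, R)), # ><
         list(off = I, on = list()))              # !
}

# A state (F = forced-off flags, ons = positive clauses) is consistent iff
# every clause retains a region not in F; the maximal model (occupy all
# regions not in F) then satisfies everything.
state_ok <- function(F, ons) {
  for (p in ons) {
    if (length(p) == 0L || all(F[p])) return(FALSE)
  }
  TRUE
}

# Apply singleton articulations, collect disjunctive ones for branching.
base_state <- function(cp, art_idx) {
  F <- logical(cp$K)
  ons <- cp$onsets
  disj <- integer(0)
  for (k in art_idx) {
    a <- cp$arts[[k]]
    if (length(a$rels) == 1L) {
      pat <- pattern_for(a$rels, a$I, a$L, a$R)
      F[pat$off] <- TRUE
      ons <- c(ons, pat$on)
    } else {
      disj <- c(disj, k)
    }
  }
  list(F = F, ons = ons, disj = disj)
}

# DFS over disjunctive articulations; visit(F, ons) at consistent leaves.
# visit returns FALSE to abort the whole search.
scenario_dfs <- function(cp, F, ons, disj, visit) {
  if (!state_ok(F, ons)) return(TRUE)
  if (length(disj) == 0L) return(visit(F, ons))
  a <- cp$arts[[disj[1]]]
  rest <- disj[-1]
  for (r in a$rels) {
    pat <- pattern_for(r, a$I, a$L, a$R)
    F2 <- F; F2[pat$off] <- TRUE
    if (!scenario_dfs(cp, F2, c(ons, pat$on), rest, visit)) return(FALSE)
  }
  TRUE
}

problem_satisfiable <- function(cp, art_idx, extra_off = integer(0),
                                extra_on = list()) {
  st <- base_state(cp, art_idx)
  st$F[extra_off] <- TRUE
  found <- FALSE
  scenario_dfs(cp, st$F, c(st$ons, extra_on), st$disj,
               function(F, ons) { found <<- TRUE; FALSE })
  found
}

# Region partition of an arbitrary cross pair (concept indices x in T2,
# y in T1); memoised, as world enumeration revisits pairs along branches.
pair_ILR <- function(cp, x, y) {
  key <- paste0(x, ".", y)
  v <- cp$ilr_cache[[key]]
  if (!is.null(v)) return(v)
  u2 <- cp$under2(x); u1 <- cp$under1(y)
  v <- list(I = which(u2 & u1), L = which(u2 & !u1), R = which(!u2 & u1))
  assign(key, v, envir = cp$ilr_cache)
  v
}

# Relation map (integer codes, n2 x n1) induced by an occupancy.
world_from_occupancy <- function(cp, occ) {
  oi <- which(occ)
  n2 <- cp$n2; n1 <- cp$n1
  if (!is.null(cp$dense2)) {
    A2 <- cp$dense2[, oi, drop = FALSE]
    A1 <- cp$dense1[, oi, drop = FALSE]
    Imat <- A2 %*% t(A1)
    Lc <- rowSums(A2) - Imat
    Rc <- matrix(rowSums(A1), n2, n1, byrow = TRUE) - Imat
    codes <- matrix(4L, n2, n1)
    codes[Imat == 0] <- 5L
    codes[Imat > 0 & Lc == 0 & Rc == 0] <- 1L
    codes[Imat > 0 & Lc > 0 & Rc == 0] <- 2L
    codes[Imat > 0 & Lc == 0 & Rc > 0] <- 3L
    return(codes)
  }
  e2 <- cp$t2r[oi]; e1 <- cp$t1r[oi]
  sel2 <- which(e2 > 0L)
  anc2 <- cp$anc2[e2[sel2]]
  U2 <- Matrix::sparseMatrix(i = as.integer(unlist(anc2, use.names = FALSE)),
                             j = rep(sel2, lengths(anc2)),
                             x = 1, dims = c(n2, length(oi)))
  sel1 <- which(e1 > 0L)
  anc1 <- cp$anc1[e1[sel1]]
  U1 <- Matrix::sparseMatrix(i = as.integer(unlist(anc1, use.names = FALSE)),
                             j = rep(sel1, lengths(anc1)),
                             x = 1, dims = c(n1, length(oi)))
  Imat <- as.matrix(U2 %*% Matrix::t(U1))
  Lc <- Matrix::rowSums(U2) - Imat
  Rc <- matrix(Matrix::rowSums(U1), n2, n1, byrow = TRUE) - Imat
  codes <- matrix(4L, n2, n1)
  codes[Imat == 0] <- 5L
  codes[Imat > 0 & Lc == 0 & Rc == 0] <- 1L
  codes[Imat > 0 & Lc > 0 & Rc == 0] <- 2L
  codes[Imat > 0 & Lc == 0 & Rc > 0] <- 3L
  codes
}

# World enumeration below one consistent scenario. Branches on the first
# cross pair admitting more than one realizable relation; a state where
# every allowed region is the sole survivor of some clause has a unique
# model, hence a unique world (fast path that also covers large instances
# whose articulations force everything). emit(codes) returns FALSE to stop.
world_search <- function(cp, F, ons, emit, start = 1L) {
  forced <- logical(cp$K)
  for (p in ons) {
    av <- p[!F[p]]
    if (length(av) == 0L) return(TRUE)     # inconsistent branch
    if (length(av) == 1L) forced[av] <- TRUE
  }
  allowed <- !F
  if (all(forced[allowed])) {
    return(emit(world_from_occupancy(cp, allowed)))
  }
  npair <- cp$n2 * cp$n1
  idx <- start
  while (idx <= npair) {
    x <- ((idx - 1L) %/% cp$n1) + 1L
    y <- ((idx - 1L) %% cp$n1) + 1L
    ilr <- pair_ILR(cp, x, y)
    realizable <- integer(0)
    pats <- vector("list", 5L)
    for (r in 1:5) {
      pat <- pattern_for(r, ilr$I, ilr$L, ilr$R)
      F2 <- F; F2[pat$off] <- TRUE
      if (state_ok(F2, c(ons, pat$on))) {
        realizable <- c(realizable, r)
        pats[[r]] <- pat
      }
    }
    if (length(realizable) > 1L) {
      for (r in realizable) {
        F2 <- F; F2[pats[[r]]$off] <- TRUE
        if (!world_search(cp, F2, c(ons, pats[[r]]$on), emit,
                          start = idx + 1L)) {
          return(FALSE)
        }
      }
      return(TRUE)
    }
    idx <- idx + 1L
  }
  # every pair determined: the maximal model's world is the only one
  emit(world_from_occupancy(cp, allowed))
}

enumerate_worlds_cp <- function(cp, art_idx, cap) {
  st <- base_state(cp, art_idx)
  store <- new.env(parent = emptyenv())
  store$worlds <- list()
  store$seen <- new.env(hash = TRUE, parent = emptyenv())
  store$long_keys <- character(0)   # R symbols cap at 10 kB; huge maps
  store$n <- 0L                     # (few worlds there) use a plain vector
  store$truncated <- FALSE
  emit <- function(codes) {
    key <- paste(codes, collapse = "")
    long <- nchar(key) > 9000L
    dup <- if (long) key %in% store$long_keys
    else !is.null(store$seen[[key]])
    if (dup) return(TRUE)
    if (store$n >= cap) {
      store$truncated <- TRUE
      return(FALSE)
    }
    store$n <- store$n + 1L
    store$worlds[[store$n]] <- codes
    if (long) store$long_keys <- c(store$long_keys, key)
    else store$seen[[key]] <- TRUE
    TRUE
  }
  scenario_dfs(cp, st$F, st$ons, st$disj,
               function(F, ons) world_search(cp, F, ons, emit))
  list(worlds = store$worlds, exhausted = !store$truncated)
}

codes_to_world <- function(cp, codes) {
  w <- matrix(RCC5_SYMBOLS[codes], cp$n2, cp$n1,
              dimnames = list(cp$q2, cp$q1))
  w
}

#' Candidate Euler regions of an alignment problem
#'
#' Every pair (eligible-or-NONE T2 concept, eligible-or-NONE T1 concept)
#' except (NONE, NONE); a concept is eligible as a region's deepest node iff
#' it has no children or its coverage flag is off. With `e2` and `e1`
#' eligible concepts the count is `(e2 + 1) * (e1 + 1) - 1`.
#'
#' @param problem An [alignment_problem()].
#' @return Data frame with columns `t2` and `t1` (qualified labels, `NA` for
#'   NONE).
#' @export
candidate_regions <- function(problem) {
  cp <- compile_problem(problem)
  data.frame(
    t2 = ifelse(cp$t2r == 0L, NA_character_, cp$q2[cp$t2r]),
    t1 = ifelse(cp$t1r == 0L, NA_character_, cp$q1[cp$t1r]),
    stringsAsFactors = FALSE)
}

#' Decide logical consistency of an alignment problem
#'
#' If the input constraints (taxonomy structure, nonemptiness, sibling
#' disjointness, coverage, articulations) admit at least one interpretation,
#' a witness occupancy is returned; if not, no alignment exists and
#' [diagnose()] can locate a minimal conflicting articulation subset.
#'
#' @param problem An [alignment_problem()].
#' @return A list with elements `consistent` (logical) and `witness` (data
#'   frame of occupied candidate regions, or `NULL` when inconsistent).
#' @export
check_consistency <- function(problem) {
  cp <- compile_problem(problem)
  st <- base_state(cp, seq_along(cp$arts))
  witness <- NULL
  scenario_dfs(cp, st$F, st$ons, st$disj, function(F, ons) {
    oi <- which(!F)
    witness <<- data.frame(
      t2 = ifelse(cp$t2r[oi] == 0L, NA_character_, cp$q2[cp$t2r[oi]]),
      t1 = ifelse(cp$t1r[oi] == 0L, NA_character_, cp$q1[cp$t1r[oi]]),
      stringsAsFactors = FALSE)
    FALSE
  })
  list(consistent = !is.null(witness), witness = witness)
}

#' Enumerate the possible worlds of a consistent alignment
#'
#' A possible world is a globally consistent assignment of one base relation
#' to every cross-taxonomy concept pair, realizable by actual sets. Worlds
#' are identified by their induced relation maps (many occupancies may
#' realize the same world). Enumeration is deterministic: branching follows
#' the canonical concept and relation order.
#'
#' @param problem An [alignment_problem()].
#' @param cap Stop after this many worlds (default: the problem's
#'   `world_cap` option). When the cap cuts the search short the result has
#'   `exhausted = FALSE`.
#' @return A list with `worlds` (list of character matrices of relation
#'   symbols, rows = T2 concepts, columns = T1 concepts) and `exhausted`.
#' @export
enumerate_worlds <- function(problem, cap = NULL) {
  cp <- compile_problem(problem)
  if (is.null(cap)) cap <- problem$options$world_cap
  res <- enumerate_worlds_cp(cp, seq_along(cp$arts), as.integer(cap))
  if (length(res$worlds) == 0L) {
    stop("problem is inconsistent: no possible world satisfies the input; ",
         "run diagnose() to locate a minimal conflicting articulation subset")
  }
  list(worlds = lapply(res$worlds, codes_to_world, cp = cp),
       exhausted = res$exhausted)
}

#' Compute the Maximally Informative Relations (MIR)
#'
#' For every cross-taxonomy concept pair, the set of base relations realized
#' in at least one possible world — one cell per pair, `|T2| * |T1|` cells in
#' total. If world enumeration exhausts under the cap the cells are unions
#' over the worlds; otherwise the reasoner falls back to one satisfiability
#' query per pair and relation, so the MIR is exact even when enumeration is
#' truncated.
#'
#' @param problem An [alignment_problem()].
#' @param cap World cap before the per-pair fallback (default: the problem's
#'   `world_cap` option).
#' @return A [mir_table] object.
#' @export
compute_mir <- function(problem, cap = NULL) {
  cp <- compile_problem(problem)
  if (is.null(cap)) cap <- problem$options$world_cap
  res <- enumerate_worlds_cp(cp, seq_along(cp$arts), as.integer(cap))
  if (length(res$worlds) == 0L) {
    stop("problem is inconsistent: no possible world satisfies the input; ",
         "run diagnose() to locate a minimal conflicting articulation subset")
  }
  if (res$exhausted) {
    bits <- Reduce(function(acc, codes) {
      matrix(bitwOr(acc, bitwShiftL(1L, codes - 1L)), cp$n2, cp$n1)
    }, res$worlds, init = matrix(0L, cp$n2, cp$n1))
  } else {
    bits <- matrix(0L, cp$n2, cp$n1)
    all_idx <- seq_along(cp$arts)
    for (x in seq_len(cp$n2)) {
      for (y in seq_len(cp$n1)) {
        ilr <- pair_ILR(cp, x, y)
        cell <- 0L
        for (r in 1:5) {
          pat <- pattern_for(r, ilr$I, ilr$L, ilr$R)
          if (problem_satisfiable(cp, all_idx, pat$off, pat$on)) {
            cell <- bitwOr(cell, bitwShiftL(1L, r - 1L))
          }
        }
        bits[x, y] <- cell
      }
    }
  }
  dimnames(bits) <- list(cp$q2, cp$q1)
  prov <- matrix("inferred", cp$n2, cp$n1, dimnames = list(cp$q2, cp$q1))
  for (a in cp$arts) {
    prov[a$li, a$ri] <- "input"
    stated <- sum(bitwShiftL(1L, a$rels - 1L))
    if (bitwAnd(bits[a$li, a$ri], stated) != bits[a$li, a$ri]) {
      stop("internal error: MIR cell escapes its input articulation")
    }
  }
  if (any(bits == 0L)) stop("internal error: empty MIR cell")
  new_mir_table(bits, prov, worlds_found = length(res$worlds),
                exhausted = res$exhausted, n_input = length(cp$arts),
                t2_id = cp$t2$id, t1_id = cp$t1$id)
}

#' Minimal conflicting articulation subset of an inconsistent problem
#'
#' Deletion-based diagnosis over the articulations (the taxonomy structure
#' is held fixed): the returned subset is unsatisfiable together with the
#' global constraints, while every proper subset of it is satisfiable.
#'
#' @param problem An [alignment_problem()].
#' @return The offending rows of `problem$articulations`; empty (with a
#'   message) when the problem is consistent.
#' @export
diagnose <- function(problem) {
  cp <- compile_problem(problem)
  all_idx <- seq_along(cp$arts)
  if (problem_satisfiable(cp, all_idx)) {
    message("problem is consistent; nothing to diagnose")
    return(problem$articulations[integer(0), ])
  }
  keep <- all_idx
  for (k in all_idx) {
    trial <- setdiff(keep, k)
    if (!problem_satisfiable(cp, trial)) keep <- trial
  }
  problem$articulations[keep, ]
}
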