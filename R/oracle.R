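# Brute-force reference implementation for small instances: exhaustively
# enumerates occupancy subsets of the candidate regions to produce
# ground-truth possible worlds and MIR. Independent of the reasoner's
# witness-pattern machinery: relations are read off the actual extension
# sets, the way rcc5_classify() defines them.

oracle_setup <- function(problem, max_regions) {
  cp <- compile_problem(problem)
  if (cp$K > max_regions) {
    stop("oracle refuses ", cp$K, " candidate regions (max_regions = ",
         max_regions, ")")
  }
  bit <- 2^(seq_len(cp$K) - 1L)
  # extension bitmask per concept: regions at-or-below it
  mask2 <- vapply(seq_len(cp$n2),
                  function(i) sum(bit[cp$t2r %in% cp$desc2[[i]]]), 0)
  mask1 <- vapply(seq_len(cp$n1),
                  function(i) sum(bit[cp$t1r %in% cp$desc1[[i]]]), 0)
  list(cp = cp, mask2 = mask2, mask1 = mask1)
}

# Vectorized relation codes between extension masks ex, ey (same length).
# Uses set identity/containment on the actual extensions, mirroring
# rcc5_classify on explicit sets.
mask_rel <- function(ex, ey) {
  inter <- bitwAnd(ex, ey)
  ifelse(inter == 0L, 5L,
  ifelse(ex == ey, 1L,
  ifelse(inter == ey, 2L,
  ifelse(inter == ex, 3L, 4L))))
}

oracle_models <- function(problem, max_regions) {
  os <- oracle_setup(problem, max_regions)
  cp <- os$cp
  masks <- seq_len(2L^cp$K - 1L)
  ok <- rep(TRUE, length(masks))
  for (m in c(os$mask2, os$mask1)) {       # nonemptiness of every concept
    ok <- ok & bitwAnd(masks, m) > 0L
  }
  arts <- problem$articulations
  if (nrow(arts)) {
    li <- match(arts$left, cp$t2$concepts$name)
    ri <- match(arts$right, cp$t1$concepts$name)
    for (k in seq_len(nrow(arts))) {
      ex <- bitwAnd(masks, os$mask2[li[k]])
      ey <- bitwAnd(masks, os$mask1[ri[k]])
      ok <- ok & mask_rel(ex, ey) %in% arts$rels[[k]]
    }
  }
  list(os = os, masks = masks[ok])
}

# Relation-code matrix (models x pairs) for the surviving occupancies.
oracle_maps <- function(os, masks) {
  cp <- os$cp
  npair <- cp$n2 * cp$n1
  maps <- matrix(0L, length(masks), npair)
  col <- 0L
  for (y in seq_len(cp$n1)) {
    ey <- bitwAnd(masks, os$mask1[y])
    for (x in seq_len(cp$n2)) {
      # column-major over (x, y) to match matrix(cells, n2, n1)
      maps[, (y - 1L) * cp$n2 + x] <- mask_rel(bitwAnd(masks, os$mask2[x]), ey)
    }
  }
  maps
}

#' Brute-force possible worlds (testing oracle)
#'
#' Iterates all nonempty occupancy subsets of the candidate regions, keeps
#' those satisfying nonemptiness and the articulations (relations read off
#' the actual extension sets), and deduplicates by induced cross-pair
#' relation map. Exact, and intentionally restricted to small instances.
#'
#' @param problem An [alignment_problem()].
#' @param max_regions Refuse instances with more candidate regions than this.
#' @return A list of character relation matrices as in [enumerate_worlds()];
#'   empty when the problem is inconsistent.
#' @export
oracle_worlds <- function(problem, max_regions = 20L) {
  om <- oracle_models(problem, max_regions)
  cp <- om$os$cp
  if (length(om$masks) == 0L) return(list())
  maps <- oracle_maps(om$os, om$masks)
  keys <- apply(maps, 1L, paste, collapse = "")
  uniq <- maps[!duplicated(keys), , drop = FALSE]
  lapply(seq_len(nrow(uniq)), function(i) {
    matrix(RCC5_SYMBOLS[uniq[i, ]], cp$n2, cp$n1,
           dimnames = list(cp$q2, cp$q1))
  })
}

#' Brute-force MIR (testing oracle)
#'
#' Union of the per-pair relations over all [oracle_worlds()].
#'
#' @inheritParams oracle_worlds
#' @return A [mir_table][compute_mir()].
#' @export
oracle_mir <- function(problem, max_regions = 20L) {
  om <- oracle_models(problem, max_regions)
  cp <- om$os$cp
  if (length(om$masks) == 0L) {
    stop("problem is inconsistent: the oracle found no model")
  }
  maps <- oracle_maps(om$os, om$masks)
  bits <- apply(maps, 2L, function(col) {
    Reduce(bitwOr, bitwShiftL(1L, unique(col) - 1L), accumulate = FALSE)
  })
  bits <- matrix(as.integer(bits), cp$n2, cp$n1,
                 dimnames = list(cp$q2, cp$q1))
  prov <- matrix("inferred", cp$n2, cp$n1, dimnames = list(cp$q2, cp$q1))
  arts <- problem$articulations
  if (nrow(arts)) {
    li <- match(arts$left, cp$t2$concepts$name)
    ri <- match(arts$right, cp$t1$concepts$name)
    for (k in seq_along(li)) prov[li[k], ri[k]] <- "input"
  }
  keys <- apply(maps, 1L, paste, collapse = "")
  new_mir_table(bits, prov, worlds_found = sum(!duplicated(keys)),
                exhausted = TRUE, n_input = nrow(arts),
                t2_id = cp$t2$id, t1_id = cp$t1$id)
}
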