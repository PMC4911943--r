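# Region encoding, consistency, possible worlds, MIR, diagnosis.

test_that("candidate region counts follow the eligibility rule", {
  expect_identical(nrow(candidate_regions(fixture_fig1())), 39L) # (9+1)(3+1)-1
  expect_identical(nrow(candidate_regions(tiny_problem())), 3L)  # (1+1)(1+1)-1
  # turning coverage off on the 2005 genus makes it eligible too
  p <- fixture_fig1(ranked = FALSE)
  t2nc <- taxonomy("2005", data.frame(
    parent = p$t2$concepts$parent[!is.na(p$t2$concepts$parent)],
    child = p$t2$concepts$name[!is.na(p$t2$concepts$parent)]),
    nocoverage = "Microcebus")
  pnc <- alignment_problem(t2nc, p$t1, p$articulations)
  expect_identical(nrow(candidate_regions(pnc)), 43L)            # (10+1)(3+1)-1
})

test_that("consistency verdicts match the worked example and hand cases", {
  v <- check_consistency(fixture_fig1())
  expect_true(v$consistent)
  expect_s3_class(v$witness, "data.frame")
  expect_gt(nrow(v$witness), 0L)

  # berthae is excluded from the 1993 genus, so equating it with a 1993
  # species is contradictory
  p <- fixture_fig1()
  bad <- alignment_problem(p$t2, p$t1, rbind(
    p$articulations,
    articulations("Microcebus_berthae", "equals", "Microcebus_rufus")))
  expect_false(check_consistency(bad)$consistent)
  expect_error(enumerate_worlds(bad), "inconsistent")
  expect_error(compute_mir(bad), "inconsistent")

  contra <- alignment_problem(
    tiny_problem()$t2, tiny_problem()$t1,
    articulations(c("X", "X"), c("equals", "disjoint"), c("Y", "Y")))
  expect_false(check_consistency(contra)$consistent)

  expect_true(check_consistency(identity_problem(3))$consistent)
  # a disjoint articulation alone is satisfiable: the two concepts occupy
  # regions outside each other
  expect_true(check_consistency(tiny_problem("disjoint"))$consistent)
})

test_that("the worked example has exactly two worlds differing in one cell", {
  ew <- enumerate_worlds(fixture_fig1())
  expect_true(ew$exhausted)
  expect_length(ew$worlds, 2L)
  w1 <- ew$worlds[[1]]; w2 <- ew$worlds[[2]]
  diff <- which(w1 != w2, arr.ind = TRUE)
  expect_identical(nrow(diff), 1L)
  expect_identical(rownames(w1)[diff[1, 1]], "2005.Microcebus")
  expect_identical(colnames(w1)[diff[1, 2]], "1993.Microcebus_murinus")
  expect_setequal(c(w1[diff], w2[diff]), c(">", "><"))
})

test_that("world enumeration respects the cap and reports exhaustion", {
  # an unarticulated 1x1 problem realizes all five base relations
  ew <- enumerate_worlds(tiny_problem(), cap = 100)
  expect_true(ew$exhausted)
  expect_length(ew$worlds, 5L)
  expect_setequal(vapply(ew$worlds, function(w) w[1, 1], ""),
                  rcc5_relations())
  capped <- enumerate_worlds(tiny_problem(), cap = 3)
  expect_false(capped$exhausted)
  expect_length(capped$worlds, 3L)
  expect_length(enumerate_worlds(identity_problem(4))$worlds, 1L)
})

test_that("the worked-example MIR matches the published counts", {
  mir <- compute_mir(fixture_fig1())
  expect_identical(length(mir$cells), 44L)
  expect_identical(tally_relations(mir),
                   c("==" = 3L, ">" = 1L, "<" = 9L, "><" = 1L, "!" = 29L,
                     ambiguous = 1L))
  cells <- mir_cells(mir)
  expect_identical(cells["2005.Microcebus", "1993.Microcebus_murinus"],
                   "{> ><}")
  # monotypic congruence: Mirza and its only child have identical rows
  expect_identical(cells["2005.Mirza", ], cells["2005.Mirza_coquereli", ])
  expect_identical(cells["2005.Mirza", "1993.Microcebus_coquereli"], "==")
  expect_identical(cells["2005.Microcebus", "1993.Microcebus"], "><")
  expect_identical(mir$provenance["2005.Mirza", "1993.Microcebus_coquereli"],
                   "inferred")
  expect_identical(mir$provenance["2005.Microcebus_rufus",
                                  "1993.Microcebus_rufus"], "input")
})

test_that("per-pair fallback MIR agrees with world-union MIR", {
  # multi-world problems: a cap of 1 truncates enumeration and triggers the
  # per-pair satisfiability fallback, which must yield the same cells
  for (p in list(fixture_fig1(), tiny_problem())) {
    full <- compute_mir(p, cap = 1000)
    expect_true(full$exhausted)
    fallback <- compute_mir(p, cap = 1)
    expect_false(fallback$exhausted)
    expect_identical(full$cells, fallback$cells)
  }
  # single-world problems exhaust even at cap 1
  expect_true(compute_mir(identity_problem(3), cap = 1)$exhausted)
})

test_that("MIR invariants hold on random problems", {
  for (s in 1:25) {
    p <- random_problem(s)
    v <- check_consistency(p)
    if (!v$consistent) next
    ew <- enumerate_worlds(p, cap = 50000)
    mir <- compute_mir(p, cap = 50000)
    # MIR-count law: one cell per cross pair
    expect_identical(length(mir$cells),
                     nrow(p$t2$concepts) * nrow(p$t1$concepts))
    tal <- tally_relations(mir)
    expect_identical(sum(tal), length(mir$cells))
    # every input articulation's cell is a nonempty subset of its statement
    for (k in seq_len(nrow(p$articulations))) {
      cell <- mir$cells[paste0(p$t2$id, ".", p$articulations$left[k]),
                        paste0(p$t1$id, ".", p$articulations$right[k])]
      stated <- sum(bitwShiftL(1L, p$articulations$rels[[k]] - 1L))
      expect_gt(cell, 0L)
      expect_identical(bitwAnd(cell, stated), cell)
    }
    # all cells singleton <=> exactly one world
    expect_identical(all(taxalign:::is_singleton_bits(mir$cells)),
                     length(ew$worlds) == 1L)
    # congruence substitutivity: EQ-linked T1 concepts have identical columns
    eqcols <- which(mir$cells == 1L, arr.ind = TRUE)
    for (x in unique(eqcols[, 1])) {
      ys <- eqcols[eqcols[, 1] == x, 2]
      if (length(ys) > 1L) {
        for (y in ys[-1]) expect_identical(mir$cells[, y], mir$cells[, ys[1]])
      }
    }
  }
})

test_that("lower-level exclusivity propagates to the roots", {
  # T2 clones T1's two species and adds one acquisition articulated as
  # exclusive of the T1 root: with the shared species congruent, coverage
  # pins the T1 root and the root pair is forced to proper inclusion
  t1 <- taxonomy("b", data.frame(parent = "R1", child = c("u", "v")))
  t2 <- taxonomy("a", data.frame(parent = "R2", child = c("u", "v", "w")))
  p <- alignment_problem(t2, t1, articulations(
    c("u", "v", "w"), c("equals", "equals", "disjoint"),
    c("u", "v", "R1")))
  mir <- compute_mir(p)
  expect_identical(mir_cells(mir)["a.R2", "b.R1"], ">")
  expect_length(enumerate_worlds(p)$worlds, 1L)
  # pinning the roots congruent instead is inconsistent
  p2 <- alignment_problem(t2, t1, rbind(
    p$articulations, articulations("R2", "equals", "R1")))
  expect_false(check_consistency(p2)$consistent)
  # when a species is only narrowed (split slack), the root pair keeps the
  # expand-or-overlap ambiguity: > or ><, never == or <
  t2s <- taxonomy("a", data.frame(parent = "R2",
                                  child = c("u1", "u2", "v", "w")))
  ps <- alignment_problem(t2s, t1, articulations(
    c("u1", "u2", "v", "w"),
    c("is_included_in", "is_included_in", "equals", "disjoint"),
    c("u", "u", "v", "R1")))
  expect_identical(mir_cells(compute_mir(ps))["a.R2", "b.R1"], "{> ><}")
  expect_length(enumerate_worlds(ps)$worlds, 2L)
  # asserting the propagated relation prunes to the >-world
  ps2 <- alignment_problem(t2s, t1, rbind(
    ps$articulations, articulations("R2", "includes", "R1")))
  expect_identical(mir_cells(compute_mir(ps2))["a.R2", "b.R1"], ">")
})

test_that("within-taxonomy relations are derivable from the hierarchy", {
  # G has two species, M is monotypic under R
  tx <- taxonomy("x", data.frame(parent = c("R", "R", "R", "G", "G", "M"),
                                 child = c("G", "S1", "M", "S2", "S2b", "S3")))
  expect_identical(within_taxonomy_relation(tx, "R", "S1"), ">")
  expect_identical(within_taxonomy_relation(tx, "S2", "G"), "<")
  expect_identical(within_taxonomy_relation(tx, "G", "S1"), "!")
  expect_identical(within_taxonomy_relation(tx, "M", "S3"), "==")
  expect_identical(within_taxonomy_relation(tx, "R", "R"), "==")
})

test_that("diagnosis returns a minimal unsatisfiable articulation core", {
  expect_message(empty <- diagnose(fixture_fig1()), "consistent")
  expect_identical(nrow(empty), 0L)

  contra <- alignment_problem(
    tiny_problem()$t2, tiny_problem()$t1,
    articulations(c("X", "X"), c("equals", "disjoint"), c("Y", "Y")))
  core <- diagnose(contra)
  expect_identical(nrow(core), 2L)

  p <- fixture_fig1()
  bad <- alignment_problem(p$t2, p$t1, rbind(
    p$articulations,
    articulations("Microcebus_berthae", "equals", "Microcebus_rufus")))
  core <- diagnose(bad)
  sub <- function(rows) alignment_problem(p$t2, p$t1, core[rows, ])
  expect_false(check_consistency(sub(seq_len(nrow(core))))$consistent)
  for (k in seq_len(nrow(core))) {
    expect_true(check_consistency(sub(setdiff(seq_len(nrow(core)), k)))$consistent)
  }
  expect_true("Microcebus_berthae" %in% core$left)
})

test_that("a single-concept taxonomy is legal and coverage is vacuous there", {
  p <- tiny_problem("equals")
  mir <- compute_mir(p)
  expect_identical(mir_cells(mir)[1, 1], "==")
  expect_length(enumerate_worlds(p)$worlds, 1L)
})

test_that("relaxing sibling disjointness is rejected as unsupported", {
  expect_error(alignment_problem(tiny_problem()$t2, tiny_problem()$t1,
                                 sibling_disjointness = FALSE),
               "not supported")
})
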