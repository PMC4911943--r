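# Hard-coded fixture, exact-size generator, evolved-pair generator.

test_that("the worked-example fixture has the published shape", {
  p <- fixture_fig1()
  expect_identical(nrow(p$t2$concepts), 11L)
  expect_identical(nrow(p$t1$concepts), 4L)
  expect_identical(nrow(p$articulations), 9L)
  expect_identical(length(compute_mir(p)$cells), 44L)
  expect_length(enumerate_worlds(p)$worlds, 2L)
})

test_that("make_sized_pair hits exact sizes with a unique world", {
  p <- make_sized_pair(2, 2, 1)
  expect_identical(nrow(p$t2$concepts), 2L)
  expect_identical(nrow(p$articulations), 1L)
  mir <- compute_mir(p)
  expect_identical(length(mir$cells), 4L)
  expect_true(all(taxalign:::is_singleton_bits(mir$cells)))

  p <- make_sized_pair(32, 23, 23)
  expect_identical(nrow(p$t2$concepts), 32L)
  expect_identical(nrow(p$t1$concepts), 23L)
  expect_identical(nrow(p$articulations), 23L)
  ew <- enumerate_worlds(p)
  expect_true(ew$exhausted)
  expect_length(ew$worlds, 1L)
  expect_identical(length(compute_mir(p)$cells), 736L)

  # padding with redundant articulations never changes the world set
  p2 <- make_sized_pair(12, 9, 15, seed = 4)
  expect_identical(nrow(p2$articulations), 15L)
  expect_length(enumerate_worlds(p2)$worlds, 1L)
  expect_identical(length(compute_mir(p2)$cells), 108L)

  expect_error(make_sized_pair(5, 8, 10), "n2_concepts >= n1_concepts")
  expect_error(make_sized_pair(30, 20, 3), "infeasible")
})

test_that("make_sized_pair is deterministic under a seed", {
  a <- write_alignment(make_sized_pair(12, 9, 15, seed = 7))
  b <- write_alignment(make_sized_pair(12, 9, 15, seed = 7))
  expect_identical(a, b)
})

test_that("an all-zero scenario is the identity alignment", {
  gp <- generate_evolved_pair(scenario_params(leaf_count_t1 = 5))
  ew <- enumerate_worlds(gp$problem)
  expect_length(ew$worlds, 1L)
  expect_identical(gp$truth$expected_worlds, 1L)
  cells <- mir_cells(compute_mir(gp$problem))
  for (leaf in sprintf("Species_%02d", 1:5)) {
    expect_identical(cells[paste0("t2.", leaf), paste0("t1.", leaf)], "==")
  }
})

test_that("splits reproduce the two-world slack phenomenon", {
  gp <- generate_evolved_pair(scenario_params(leaf_count_t1 = 5, n_split = 1,
                                              split_k = 3, seed = 2))
  ew <- enumerate_worlds(gp$problem)
  expect_length(ew$worlds, 2L)
  # the split target's column holds three inverse inclusions
  cells <- mir_cells(compute_mir(gp$problem))
  target <- gp$problem$articulations$right[
    gp$problem$articulations$label == "split"][1]
  expect_identical(sum(cells[, paste0("t1.", target)] == "<"), 3L)
})

test_that("acquisitions force root expansion and all-exclusive rows", {
  gp <- generate_evolved_pair(scenario_params(leaf_count_t1 = 4, n_new = 2,
                                              seed = 3))
  p <- gp$problem
  cells <- mir_cells(compute_mir(p))
  expect_identical(cells["t2.Root", "t1.Root"], ">")
  for (w in sprintf("Species_new_%02d", 1:2)) {
    expect_true(all(cells[paste0("t2.", w), ] == "!"))
  }
  expect_length(enumerate_worlds(p)$worlds, 1L)
})

test_that("lumps model the merged-concept case", {
  gp <- generate_evolved_pair(scenario_params(leaf_count_t1 = 6, n_lump = 1,
                                              seed = 5))
  p <- gp$problem
  arts <- p$articulations[p$articulations$label == "lump", ]
  expect_identical(nrow(arts), 2L)
  cells <- mir_cells(compute_mir(p, cap = 64))
  for (k in 1:2) {
    expect_identical(cells[paste0("t2.", arts$left[k]),
                           paste0("t1.", arts$right[k])], ">")
  }
})

test_that("scenario parameter conflicts are rejected", {
  expect_error(scenario_params(leaf_count_t1 = 3, n_split = 2, n_lump = 1),
               "parameter conflict")
  expect_error(scenario_params(n_split = 1, split_k = 1), "split_k")
  expect_error(scenario_params(n_new = -1), "nonnegative")
})

test_that("generated problems recover their ground truth", {
  for (ns in 0:2) for (nn in 0:2) for (nl in 0:1) {
    gp <- generate_evolved_pair(scenario_params(
      leaf_count_t1 = 6, n_split = ns, n_new = nn, n_lump = nl, seed = 11))
    p <- gp$problem
    ew <- enumerate_worlds(p, cap = 512)
    expect_true(ew$exhausted)
    expect_length(ew$worlds, gp$truth$expected_worlds)
    mir <- compute_mir(p, cap = 512)
    cells <- mir_cells(mir)
    arts <- gp$truth$articulations
    for (k in seq_len(nrow(arts))) {
      expect_identical(
        cells[paste0("t2.", arts$left[k]), paste0("t1.", arts$right[k])],
        rcc5_format(arts$rels[[k]]))
    }
    if (!is.null(gp$truth$expected_mir)) {
      expect_identical(mir$cells, gp$truth$expected_mir$cells)
    }
  }
})
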