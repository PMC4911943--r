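# Taxonomy model, alignment text dialect, rank sidecar, MIR CSV.

fixture_path <- function(f) system.file("extdata", f, package = "taxalign")

test_that("taxonomy constructor validates structure", {
  expect_error(taxonomy("x", data.frame(parent = "A", child = c("B", "B"))),
               "duplicate concept")
  expect_error(taxonomy("x", data.frame(parent = c("A", "B"),
                                        child = c("B", "A"))), "cycle")
  expect_error(taxonomy("x", data.frame(parent = "A", child = "A")), "cycle")
  expect_error(taxonomy("x", data.frame(parent = "A", child = "B c")),
               "single tokens")
  tx <- taxonomy("x", data.frame(parent = c("A", "A", "B"),
                                 child = c("B", "C", "D")))
  expect_identical(qualified_labels(tx), c("x.A", "x.B", "x.C", "x.D"))
  expect_identical(tx$concepts$rank, rep("unranked", 4L))
})

test_that("the worked-example file parses to 11 + 4 concepts, 9 articulations", {
  p <- parse_alignment(fixture_path("microcebus_mirza.txt"), is_path = TRUE)
  expect_identical(nrow(p$t2$concepts), 11L)
  expect_identical(nrow(p$t1$concepts), 4L)
  expect_identical(nrow(p$articulations), 9L)
  expect_identical(p$t2$id, "2005")   # first block is T2
  expect_true(taxalign:::problems_equal(p, fixture_fig1(), ignore_ranks = TRUE))
})

test_that("a minimal 1x1 alignment parses", {
  txt <- c("taxonomy a later", "(X)", "taxonomy b earlier", "(Y)",
           "articulation m a-b", "[a.X equals b.Y]")
  p <- parse_alignment(txt)
  expect_identical(nrow(p$t2$concepts), 1L)
  expect_identical(nrow(p$t1$concepts), 1L)
  expect_identical(nrow(p$articulations), 1L)
  expect_identical(p$articulations$rels[[1]], 1L)
})

test_that("parser reports malformed input with line numbers", {
  base <- c("taxonomy a later", "(R X)", "taxonomy b earlier", "(S Y)",
            "articulation m a-b")
  expect_error(parse_alignment(c(base, "[a.Z equals b.Y]")),
               "line 6: .*unknown concept 'a.Z'")
  expect_error(parse_alignment(c("taxonomy a later", "(R X)", "(R X)",
                                 "taxonomy b e", "(S Y)")),
               "line 3: duplicate concept name 'X'")
  expect_error(parse_alignment(c("taxonomy a later", "(R X)", "(X R)",
                                 "taxonomy b e", "(S Y)")),
               "cycle")
  expect_error(parse_alignment(c(base, "[a.X {} b.Y]")),
               "line 6: empty relation set")
  expect_error(parse_alignment(c(base, "[a.X near b.Y]")),
               "line 6: unknown RCC-5 relation")
  expect_error(parse_alignment(base[1:2]), "exactly two taxonomies")
  expect_error(parse_alignment(c(base[1:4], "[a.X equals b.Y]")),
               "outside an articulation block")
})

test_that("T1-left statements are normalized by converse; t2 directive works", {
  txt <- c("taxonomy b earlier", "(S Y)", "taxonomy a later", "(R X)",
           "t2: a", "articulation m a-b", "[b.Y includes a.X]")
  p <- parse_alignment(txt)
  expect_identical(p$t2$id, "a")
  expect_identical(p$articulations$left, "X")
  expect_identical(p$articulations$rels[[1]], 3L)  # converse of includes
})

test_that("alignment text round-trips structurally", {
  expect_problem_roundtrip(fixture_fig1(ranked = FALSE))
  expect_problem_roundtrip(tiny_problem("equals"))
  expect_problem_roundtrip(tiny_problem())           # empty articulations
  # disjunctions serialize brace-delimited and survive
  p <- alignment_problem(
    taxonomy("a", data.frame(parent = "R", child = "X"),
             nocoverage = "R"),
    taxonomy("b", data.frame(parent = "S", child = "Y")),
    articulations("X", "{== ><}", "Y"))
  txt <- write_alignment(p)
  expect_match(txt, "[a.X {== ><} b.Y]", fixed = TRUE)
  expect_match(txt, "nocoverage a.R", fixed = TRUE)
  expect_problem_roundtrip(p)
  for (s in 1:20) expect_problem_roundtrip(random_problem(s))
})

test_that("attach_ranks populates, defaults, and validates", {
  p <- fixture_fig1(ranked = FALSE)
  expect_true(all(p$t2$concepts$rank == "unranked"))
  rt <- data.frame(tax = c("2005", "1993"),
                   name = c("Microcebus", "Microcebus_murinus"),
                   rank = c("genus", "species"))
  p2 <- attach_ranks(p, rt)
  expect_identical(p2$t2$concepts$rank[p2$t2$concepts$name == "Microcebus"],
                   "genus")
  expect_identical(sum(p2$t1$concepts$rank == "species"), 1L)
  expect_identical(attach_ranks(p, rt[integer(0), ]), p)
  expect_error(attach_ranks(p, data.frame(tax = "2005", name = "Nonexistens",
                                          rank = "species")),
               "unknown concept.*2005.Nonexistens")
  # the shipped sidecar matches the ranked fixture
  p3 <- attach_ranks(p, read_rank_table(
    fixture_path("microcebus_mirza_ranks.tsv")))
  expect_true(taxalign:::problems_equal(p3, fixture_fig1()))
})

test_that("MIR CSV has the documented layout and round-trips", {
  mir <- compute_mir(fixture_fig1())
  csv <- write_mir_csv(mir)
  lines <- strsplit(csv, "\n")[[1]]
  expect_identical(lines[1], "taxon2,taxon1,relation,provenance")
  expect_length(lines, 45L)  # header + 44 cells
  expect_identical(lines[-1], sort(lines[-1], method = "radix"))
  expect_match(csv, "2005.Microcebus,1993.Microcebus_murinus,{> ><},inferred",
               fixed = TRUE)
  expect_match(csv,
    "2005.Mirza_coquereli,1993.Microcebus_coquereli,==,input", fixed = TRUE)
  df <- read_mir_csv(csv)
  expect_identical(write_mir_csv(df), csv)

  one <- compute_mir(tiny_problem("equals"))
  expect_identical(write_mir_csv(one),
                   "taxon2,taxon1,relation,provenance\na.X,b.Y,==,input\n")
})
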