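# Shared fixtures and generators for the test suite.

# Tiny 1x1 problem: one concept per taxonomy, optional articulation.
tiny_problem <- function(relation = NULL) {
  t2 <- taxonomy("a", data.frame(parent = "X", child = NA))
  t1 <- taxonomy("b", data.frame(parent = "Y", child = NA))
  arts <- if (is.null(relation)) NULL else articulations("X", relation, "Y")
  alignment_problem(t2, t1, arts)
}

# Identity alignment: n congruent leaves under congruent roots.
identity_problem <- function(n = 3L) {
  leaves <- sprintf("Sp_%02d", seq_len(n))
  t2 <- taxonomy("a", data.frame(parent = "R", child = leaves))
  t1 <- taxonomy("b", data.frame(parent = "R", child = leaves))
  alignment_problem(t2, t1, articulations(leaves, "equals", leaves))
}

# Random small alignment problem within oracle range (<= 3 leaves per
# taxonomy, so at most (3+1)*(3+1)-1 = 15 candidate regions). Articulations
# are random pairs with random relation sets (mostly singletons, some
# two-way disjunctions), occasionally targeting internal concepts; some
# instances come out inconsistent on purpose.
random_problem <- function(seed) {
  set.seed(seed)
  mk_tax <- function(id) {
    n_leaves <- sample(1:3, 1L)
    leaves <- sprintf("%s_sp%d", id, seq_len(n_leaves))
    grouped <- n_leaves >= 2L && stats::runif(1) < 0.4
    edges <- if (grouped) {
      rbind(data.frame(parent = "root", child = "mid",
                       stringsAsFactors = FALSE),
            data.frame(parent = c("mid", rep("root", n_leaves - 1L)),
                       child = leaves, stringsAsFactors = FALSE))
    } else {
      data.frame(parent = "root", child = leaves, stringsAsFactors = FALSE)
    }
    nocov <- if (n_leaves <= 2L && stats::runif(1) < 0.2) "root"
    else character(0)
    taxonomy(id, edges, nocoverage = nocov)
  }
  t2 <- mk_tax("a")
  t1 <- mk_tax("b")
  n_art <- sample(1:4, 1L)
  left <- sample(t2$concepts$name, n_art, replace = TRUE)
  right <- sample(t1$concepts$name, n_art, replace = TRUE)
  rel <- vapply(seq_len(n_art), function(i) {
    k <- if (stats::runif(1) < 0.25) 2L else 1L
    rcc5_format(sample(1:5, k))
  }, "")
  alignment_problem(t2, t1, articulations(left, rel, right))
}

# Canonical serialization of a set of world matrices for comparison.
world_keys <- function(worlds) {
  sort(vapply(worlds, function(w) paste(w, collapse = "|"), ""))
}

expect_problem_roundtrip <- function(problem) {
  txt <- write_alignment(problem)
  reparsed <- parse_alignment(txt)
  expect_true(taxalign:::problems_equal(problem, reparsed,
                                        ignore_ranks = TRUE))
}
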