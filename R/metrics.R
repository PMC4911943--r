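# Quantitative analyses of an alignment: relation tallies, information
# expression ratio, relative congruence, per-rank name:meaning categories,
# and the name reliability ratio.

# Printed-table style rounding: one decimal, half away from zero.
round1 <- function(x) sign(x) * floor(abs(x) * 10 + 0.5) / 10

fmt1 <- function(x) {
  if (isTRUE(all.equal(x, round(x)))) sprintf("%d", as.integer(round(x)))
  else sprintf("%.1f", x)
}

NAME_MEANING_CATEGORIES <- c("==:=", "==:!=", ">:=", "<:=", "><:=")

#' Tally MIR cells per base relation
#'
#' Counts the singleton cells per base relation; disjunctive (ambiguous)
#' cells are counted separately. The tallies plus the ambiguous count always
#' sum to the total number of cross-taxonomy pairs.
#'
#' @param mir A [mir_table][compute_mir()].
#' @return Named integer vector: `==`, `>`, `<`, `><`, `!`, `ambiguous`.
#' @export
tally_relations <- function(mir) {
  b <- as.vector(mir$cells)
  single <- is_singleton_bits(b)
  code <- integer(length(b))
  code[single] <- match(b[single], bitwShiftL(1L, 0:4))
  counts <- vapply(1:5, function(r) sum(code == r), 0L)
  stats::setNames(c(counts, sum(!single)),
                  c(RCC5_SYMBOLS, "ambiguous"))
}

#' Information expression ratio
#'
#' The MIR cell count divided by the input articulation count — a measure of
#' how much articulation information the reasoning makes explicit. One
#' decimal, rounded half away from zero.
#'
#' @param mir_count Number of MIR cells, or a [mir_table][compute_mir()]
#'   (then `articulation_count` defaults to its input count).
#' @param articulation_count Number of input articulations (at least 1).
#' @return The ratio, or `NA` with a warning when there are no input
#'   articulations.
#' @export
expression_ratio <- function(mir_count, articulation_count = NULL) {
  if (inherits(mir_count, "mir_table")) {
    if (is.null(articulation_count)) articulation_count <- mir_count$n_input
    mir_count <- length(mir_count$cells)
  }
  if (is.null(articulation_count) || articulation_count < 1L) {
    warning("expression ratio undefined without input articulations")
    return(NA_real_)
  }
  round1(mir_count / articulation_count)
}

#' Relative congruence of an alignment
#'
#' 100 times the number of congruent (`==` singleton) MIR cells divided by
#' the concept count of the concept-poorer taxonomy, one decimal. May exceed
#' 100 when the concept-richer taxonomy carries redundant (monotypic-chain)
#' concepts.
#'
#' @param mir A [mir_table][compute_mir()], or directly the congruent cell
#'   count.
#' @param poorer_concept_count Concept count of the concept-poorer taxonomy;
#'   defaults to the smaller MIR dimension.
#' @return Percentage, one decimal.
#' @export
relative_congruence <- function(mir, poorer_concept_count = NULL) {
  if (inherits(mir, "mir_table")) {
    eq <- unname(tally_relations(mir)["=="])
    if (is.null(poorer_concept_count)) {
      poorer_concept_count <- min(dim(mir$cells))
    }
  } else {
    eq <- mir
    if (is.null(poorer_concept_count)) {
      stop("poorer_concept_count is required when passing a raw count")
    }
  }
  if (poorer_concept_count < 1L) stop("poorer_concept_count must be >= 1")
  round1(100 * eq / poorer_concept_count)
}

#' Per-rank name:meaning category table
#'
#' Classifies cross-taxonomy concept pairs that share a taxonomic rank by
#' the association of taxonomic meaning and name string: `==:=` congruent
#' meaning and identical name (a reliable name), `==:!=` congruent meaning
#' under different names, `>:=`, `<:=`, `><:=` noncongruent meanings under
#' an identical name. "Same name" is exact string identity of the name
#' token. Pairs matching neither same-name nor congruence are not counted.
#' Exclusion with an identical name (`!:=`) cannot occur for Code-compliant,
#' homonym-free inputs; it is checked and warned about. Classification uses
#' singleton MIR cells; ambiguous cells are excluded unless a `world` is
#' given, in which case that alignment's relations are used.
#'
#' @param mir A [mir_table][compute_mir()].
#' @param t2,t1 The input [taxonomy()] objects with ranks attached.
#' @param world Optional world matrix from [enumerate_worlds()].
#' @return Data frame: one row per shared rank (plus a `Total` row), columns
#'   `rank`, the five categories, `total`.
#' @export
name_meaning_table <- function(mir, t2, t1, world = NULL) {
  rank2 <- tolower(trimws(t2$concepts$rank))
  rank1 <- tolower(trimws(t1$concepts$rank))
  if (all(rank2 == "unranked") && all(rank1 == "unranked")) {
    stop("no ranks attached; see attach_ranks()")
  }
  shared <- setdiff(intersect(unique(rank2), unique(rank1)), "unranked")
  shared <- shared[order(match(shared, rank2))] # T2 declaration order
  n2 <- nrow(mir$cells); n1 <- ncol(mir$cells)
  if (is.null(world)) {
    codes <- matrix(0L, n2, n1) # 0 = ambiguous, excluded
    single <- is_singleton_bits(mir$cells)
    codes[single] <- match(mir$cells[single], bitwShiftL(1L, 0:4))
  } else {
    codes <- matrix(match(world, RCC5_SYMBOLS), n2, n1)
  }
  same_name <- outer(t2$concepts$name, t1$concepts$name, "==")
  cat_of <- function(rk) {
    sel <- outer(rank2 == rk, rank1 == rk, "&")
    counts <- c(
      sum(sel & codes == 1L & same_name),
      sum(sel & codes == 1L & !same_name),
      sum(sel & codes == 2L & same_name),
      sum(sel & codes == 3L & same_name),
      sum(sel & codes == 4L & same_name))
    excl_same <- sum(sel & codes == 5L & same_name)
    if (excl_same > 0L) {
      warning("found ", excl_same, " same-name exclusive pair(s) at rank '",
              rk, "' (homonymy?)")
    }
    counts
  }
  m <- t(vapply(shared, cat_of, numeric(5)))
  out <- data.frame(rank = shared, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (j in 1:5) out[[NAME_MEANING_CATEGORIES[j]]] <- as.integer(m[, j])
  out$total <- as.integer(rowSums(m))
  tot <- data.frame(rank = "Total", stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (j in 1:5) tot[[NAME_MEANING_CATEGORIES[j]]] <-
    as.integer(sum(m[, j]))
  tot$total <- as.integer(sum(m))
  rbind(out, tot)
}

#' Name reliability ratio
#'
#' Reliable names are same-rank pairs of the `==:=` category (congruent
#' meaning, identical name); the other four categories are unreliable. The
#' ratio is normalized so the smaller side prints as 1, one decimal — e.g.
#' 203 reliable vs 97 unreliable gives `"2.1 : 1"`.
#'
#' @param x A [name_meaning_table()] result, or the reliable count.
#' @param unreliable The unreliable count when `x` is a raw count.
#' @return A string like `"2.1 : 1"`; attribute `counts` carries the raw
#'   numbers.
#' @export
reliability_ratio <- function(x, unreliable = NULL) {
  if (is.data.frame(x)) {
    tot <- x[x$rank == "Total", , drop = FALSE]
    if (nrow(tot) == 0L) tot <- x
    reliable <- sum(tot[["==:="]])
    unreliable <- sum(tot[["==:!="]], tot[[">:="]], tot[["<:="]],
                      tot[["><:="]])
  } else {
    reliable <- x
    if (is.null(unreliable)) stop("unreliable count required")
  }
  txt <- if (reliable == 0 && unreliable == 0) {
    message("no counted name:meaning pairs; ratio undefined")
    "0 : 0"
  } else if (reliable == 0 || unreliable == 0) {
    sprintf("%d : %d", as.integer(reliable), as.integer(unreliable))
  } else if (reliable >= unreliable) {
    sprintf("%s : 1", fmt1(round1(reliable / unreliable)))
  } else {
    sprintf("1 : %s", fmt1(round1(unreliable / reliable)))
  }
  structure(txt, counts = c(reliable = reliable, unreliable = unreliable))
}

#' Assemble the full metrics report of an alignment
#'
#' @param problem The [alignment_problem()].
#' @param mir Its [mir_table][compute_mir()] (computed if omitted).
#' @param world Optional world matrix for the name:meaning table when the
#'   MIR is ambiguous.
#' @return An object of class `metrics_report` with elements `tallies`,
#'   `expression_ratio`, `relative_congruence`, `name_meaning` (NULL when
#'   no ranks are attached), `reliability`.
#' @export
metrics_report <- function(problem, mir = NULL, world = NULL) {
  if (is.null(mir)) mir <- compute_mir(problem)
  tal <- tally_relations(mir)
  nm <- tryCatch(name_meaning_table(mir, problem$t2, problem$t1, world),
                 error = function(e) NULL)
  structure(list(
    tallies = tal,
    n_cells = length(mir$cells),
    n_input = mir$n_input,
    worlds_found = mir$worlds_found,
    exhausted = mir$exhausted,
    expression_ratio = expression_ratio(mir),
    relative_congruence = relative_congruence(mir),
    name_meaning = nm,
    reliability = if (!is.null(nm)) reliability_ratio(nm) else NULL
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Alignment metrics\n")
  cat(sprintf("  MIR cells: %d (from %d input articulations)\n",
              x$n_cells, x$n_input))
  cat(sprintf("  worlds: %d%s\n", x$worlds_found,
              if (x$exhausted) "" else " (cap hit)"))
  cat("  relation tallies: ",
      paste(sprintf("%s %d", names(x$tallies), x$tallies), collapse = "  "),
      "\n", sep = "")
  cat(sprintf("  expression ratio: %.1f\n", x$expression_ratio))
  cat(sprintf("  relative congruence: %.1f%%\n", x$relative_congruence))
  if (!is.null(x$reliability)) {
    cat(sprintf("  name reliability: %s\n", x$reliability))
  }
  invisible(x)
}

#' Write the metrics report as CSV files plus a text summary
#'
#' Emits `tallies.csv` (relation tallies), `name_meaning.csv` (per-rank
#' categories, when available) and `summary.txt` into a directory.
#'
#' @param report A [metrics_report()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_metrics <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_lf <- function(lines, path) {
    con <- file(path, "wb"); on.exit(close(con))
    writeChar(paste0(paste(lines, collapse = "\n"), "\n"), con, eos = NULL)
  }
  write_lf(c("relation,count",
             paste(names(report$tallies), report$tallies, sep = ",")),
           file.path(dir, "tallies.csv"))
  if (!is.null(report$name_meaning)) {
    nm <- report$name_meaning
    rows <- do.call(paste, c(unname(lapply(nm, as.character)),
                             list(sep = ",")))
    write_lf(c(paste(names(nm), collapse = ","), rows),
             file.path(dir, "name_meaning.csv"))
  }
  summary_lines <- utils::capture.output(print(report))
  write_lf(summary_lines, file.path(dir, "summary.txt"))
  invisible(dir)
}
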