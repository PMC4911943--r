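# Readers and writers for the line-oriented alignment dialect, the rank
# sidecar TSV, and the MIR CSV.
#
# Alignment text grammar ("#" starts a comment):
#   taxonomy <id> <label...>
#   (<parent> <child> ...)          one line per parent; "(X)" declares a
#                                   parentless concept with no children
#   nocoverage <id>.<name>
#   t2: <id>                        optional; default: first taxonomy is T2
#   articulation <label> <id2>-<id1>
#   [<id2>.<name> <rel> <id1>.<name>]
# with <rel> a relation word/symbol or a brace-delimited disjunction.

perr <- function(lineno, ...) {
  stop(sprintf("line %d: %s", lineno, paste0(...)), call. = FALSE)
}

split_qualified <- function(tok, lineno) {
  m <- regmatches(tok, regexec("^([^.]+)\\.(.+)$", tok))[[1]]
  if (length(m) != 3L) {
    perr(lineno, "expected a qualified concept label '<id>.<name>', got '",
         tok, "'")
  }
  m[2:3]
}

#' Parse alignment text into an [alignment_problem()]
#'
#' @param text A single string, a character vector of lines, or a file path
#'   (when `is_path = TRUE`).
#' @param is_path Treat `text` as a file path.
#' @return An [alignment_problem()]. The taxonomy listed first is T2 unless a
#'   `t2: <id>` directive says otherwise.
#' @export
parse_alignment <- function(text, is_path = FALSE) {
  lines <- if (is_path) readLines(text, warn = FALSE)
  else if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
  else text
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)

  taxa <- list()       # id -> list(label, edges (df), lines (per child))
  tax_order <- character()
  cur_tax <- NULL
  nocov <- list()      # list of c(id, name, lineno)
  arts <- list()       # list of c(l, relstring, r, label, lineno)
  cur_art_label <- NULL
  t2_directive <- NULL

  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    if (grepl("^taxonomy\\s", ln)) {
      toks <- strsplit(ln, "\\s+")[[1]]
      if (length(toks) < 2L) perr(i, "taxonomy directive needs an id")
      id <- toks[2]
      if (id %in% names(taxa)) perr(i, "taxonomy '", id, "' declared twice")
      taxa[[id]] <- list(label = if (length(toks) > 2L)
        paste(toks[-(1:2)], collapse = " ") else id,
        parent = character(), child = character(), lineno = integer())
      tax_order <- c(tax_order, id)
      cur_tax <- id
      cur_art_label <- NULL
    } else if (grepl("^\\(", ln)) {
      if (is.null(cur_tax)) perr(i, "parent/child list outside a taxonomy block")
      if (!grepl("\\)$", ln)) perr(i, "unterminated parent/child list")
      inner <- trimws(substr(ln, 2L, nchar(ln) - 1L))
      toks <- strsplit(inner, "\\s+")[[1]]
      toks <- toks[nzchar(toks)]
      if (length(toks) == 0L) perr(i, "empty parent/child list")
      tx <- taxa[[cur_tax]]
      if (length(toks) == 1L) {
        tx$parent <- c(tx$parent, toks[1])
        tx$child <- c(tx$child, NA_character_)
        tx$lineno <- c(tx$lineno, i)
      } else {
        tx$parent <- c(tx$parent, rep(toks[1], length(toks) - 1L))
        tx$child <- c(tx$child, toks[-1])
        tx$lineno <- c(tx$lineno, rep(i, length(toks) - 1L))
      }
      taxa[[cur_tax]] <- tx
    } else if (grepl("^nocoverage\\s", ln)) {
      tok <- strsplit(ln, "\\s+")[[1]][2]
      nocov[[length(nocov) + 1L]] <- c(split_qualified(tok, i), i)
    } else if (grepl("^t2:?\\s", ln)) {
      t2_directive <- strsplit(ln, "\\s+")[[1]][2]
    } else if (grepl("^articulation\\s", ln)) {
      toks <- strsplit(ln, "\\s+")[[1]]
      if (length(toks) < 2L) perr(i, "articulation block needs a label")
      cur_art_label <- toks[2]
      cur_tax <- NULL
    } else if (grepl("^\\[", ln)) {
      if (is.null(cur_art_label)) {
        perr(i, "articulation statement outside an articulation block")
      }
      m <- regmatches(ln,
        regexec("^\\[\\s*(\\S+)\\s+(\\{[^}]*\\}|\\S+)\\s+(\\S+)\\s*\\]$",
                ln))[[1]]
      if (length(m) != 4L) perr(i, "malformed articulation statement: ", ln)
      arts[[length(arts) + 1L]] <- list(l = m[2], rel = m[3], r = m[4],
                                        label = cur_art_label, lineno = i)
    } else {
      perr(i, "unrecognized directive: ", ln)
    }
  }

  if (length(tax_order) != 2L) {
    stop("alignment text must declare exactly two taxonomies (found ",
         length(tax_order), ")", call. = FALSE)
  }
  t2_id <- if (!is.null(t2_directive)) t2_directive else tax_order[1]
  if (!t2_id %in% tax_order) {
    stop("t2 directive names unknown taxonomy '", t2_id, "'", call. = FALSE)
  }
  t1_id <- setdiff(tax_order, t2_id)

  build_tax <- function(id) {
    tx <- taxa[[id]]
    real <- !is.na(tx$child)
    dup <- real & duplicated(tx$child)
    if (any(dup)) {
      k <- which(dup)[1]
      perr(tx$lineno[k], "duplicate concept name '", tx$child[k],
           "' within taxonomy '", id, "'")
    }
    nc <- vapply(nocov, function(x) if (x[1] == id) x[2] else NA_character_,
                 "")
    nc <- nc[!is.na(nc)]
    tryCatch(
      taxonomy(id, data.frame(parent = tx$parent, child = tx$child,
                              stringsAsFactors = FALSE),
               label = tx$label, nocoverage = nc),
      error = function(e) {
        first_line <- if (length(tx$lineno)) tx$lineno[1] else 0L
        perr(first_line, conditionMessage(e))
      })
  }
  t2 <- build_tax(t2_id)
  t1 <- build_tax(t1_id)
  for (x in nocov) {
    tax <- if (x[1] == t2_id) t2 else if (x[1] == t1_id) t1 else
      perr(as.integer(x[3]), "nocoverage names unknown taxonomy '", x[1], "'")
    if (!x[2] %in% tax$concepts$name) {
      perr(as.integer(x[3]), "nocoverage names unknown concept '",
           x[1], ".", x[2], "'")
    }
  }

  left <- character(); right <- character(); relstr <- character()
  labs <- character()
  for (a in arts) {
    lq <- split_qualified(a$l, a$lineno)
    rq <- split_qualified(a$r, a$lineno)
    rel <- tryCatch(parse_relset(a$rel),
                    error = function(e) perr(a$lineno, conditionMessage(e)))
    resolve <- function(q) {
      tax <- if (q[1] == t2$id) t2 else if (q[1] == t1$id) t1 else
        perr(a$lineno, "articulation references unknown taxonomy '",
             q[1], "'")
      if (!q[2] %in% tax$concepts$name) {
        perr(a$lineno, "articulation references unknown concept '",
             q[1], ".", q[2], "'")
      }
      tax$id
    }
    lt <- resolve(lq); rt <- resolve(rq)
    if (lt == rt) perr(a$lineno, "articulation must cross the two taxonomies")
    if (lt == t1$id) { # normalize: T2 concept on the left
      tmp <- lq; lq <- rq; rq <- tmp
      rel <- RCC5_CONVERSE[rel]
    }
    left <- c(left, lq[2]); right <- c(right, rq[2])
    relstr <- c(relstr, rcc5_format(rel)); labs <- c(labs, a$label)
  }
  alignment_problem(t2, t1, articulations(left, relstr, right, labs))
}

#' Serialize an alignment problem to the text dialect
#'
#' Round-trips: `parse_alignment(write_alignment(p))` is structurally equal
#' to `p` (ranks travel in the sidecar, not here). Output ordering is
#' deterministic: T2 block first, concepts in declaration order,
#' articulations grouped by label in input order.
#'
#' @param problem An [alignment_problem()].
#' @param path Optional file path; when given the text is also written there.
#' @return The alignment text as a single string (invisibly when `path` is
#'   given).
#' @export
write_alignment <- function(problem, path = NULL) {
  fmt_tax <- function(tax) {
    out <- sprintf("taxonomy %s %s", tax$id, tax$label)
    kids <- tax_children(tax)
    nm <- tax$concepts$name
    for (i in seq_along(nm)) {
      ch <- kids[[nm[i]]]
      if (length(ch)) {
        out <- c(out, sprintf("(%s %s)", nm[i], paste(nm[ch], collapse = " ")))
      } else if (is.na(tax$concepts$parent[i])) {
        out <- c(out, sprintf("(%s)", nm[i]))
      }
    }
    nc <- nm[!tax$concepts$coverage]
    if (length(nc)) out <- c(out, sprintf("nocoverage %s.%s", tax$id, nc))
    out
  }
  arts <- problem$articulations
  out <- c(fmt_tax(problem$t2), "", fmt_tax(problem$t1), "")
  if (nrow(arts)) {
    labs <- unique(arts$label)
    for (lb in labs) {
      rows <- which(arts$label == lb)
      out <- c(out, sprintf("articulation %s %s-%s", lb, problem$t2$id,
                            problem$t1$id))
      for (k in rows) {
        rel <- arts$rels[[k]]
        reltxt <- if (length(rel) == 1L) RCC5_WORDS[rel] else rcc5_format(rel)
        out <- c(out, sprintf("[%s.%s %s %s.%s]", problem$t2$id,
                              arts$left[k], reltxt, problem$t1$id,
                              arts$right[k]))
      }
    }
  } else {
    out <- c(out, sprintf("articulation none %s-%s", problem$t2$id,
                          problem$t1$id))
  }
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, "wb"); on.exit(close(con))
    writeChar(txt, con, eos = NULL)
    return(invisible(txt))
  }
  txt
}

#' Attach ranks from a sidecar table
#'
#' @param problem An [alignment_problem()].
#' @param rank_table Data frame (or matrix) whose first three columns are
#'   taxonomy id, concept name, rank — the layout of the 3-column TSV sidecar
#'   (no header). See [read_rank_table()].
#' @return The problem with ranks set; unlisted concepts keep `"unranked"`.
#' @export
attach_ranks <- function(problem, rank_table) {
  rt <- as.data.frame(rank_table, stringsAsFactors = FALSE)
  if (nrow(rt) == 0L) return(problem)
  if (ncol(rt) < 3L) stop("rank table needs 3 columns: taxonomy id, name, rank")
  names(rt)[1:3] <- c("tax", "name", "rank")
  known2 <- rt$tax == problem$t2$id & rt$name %in% problem$t2$concepts$name
  known1 <- rt$tax == problem$t1$id & rt$name %in% problem$t1$concepts$name
  bad <- !(known2 | known1)
  if (any(bad)) {
    stop("rank table references unknown concept(s): ",
         paste(sprintf("%s.%s", rt$tax[bad], rt$name[bad]), collapse = ", "))
  }
  i2 <- match(rt$name[known2], problem$t2$concepts$name)
  problem$t2$concepts$rank[i2] <- rt$rank[known2]
  i1 <- match(rt$name[known1], problem$t1$concepts$name)
  problem$t1$concepts$rank[i1] <- rt$rank[known1]
  problem
}

#' Read a rank sidecar TSV
#'
#' Three tab-separated columns (taxonomy id, concept name, rank), no header.
#'
#' @param path File path.
#' @return Data frame suitable for [attach_ranks()].
#' @export
read_rank_table <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE,
                    col.names = c("tax", "name", "rank"),
                    colClasses = "character", quote = "", comment.char = "")
}

#' Write a rank sidecar TSV
#'
#' @param problem An [alignment_problem()] with ranks attached.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_rank_table <- function(problem, path) {
  rows <- rbind(
    data.frame(tax = problem$t2$id, name = problem$t2$concepts$name,
               rank = problem$t2$concepts$rank, stringsAsFactors = FALSE),
    data.frame(tax = problem$t1$id, name = problem$t1$concepts$name,
               rank = problem$t1$concepts$rank, stringsAsFactors = FALSE))
  con <- file(path, "wb"); on.exit(close(con))
  writeChar(paste0(paste(rows$tax, rows$name, rows$rank, sep = "\t",
                         collapse = "\n"), "\n"), con, eos = NULL)
  invisible(path)
}
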