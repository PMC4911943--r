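# MIR table container and CSV serialization.
#
# Cells are stored as an integer bitmask matrix (bit r-1 set iff base
# relation code r is realizable for the pair), rows = T2 concepts, columns =
# T1 concepts, dimnames = qualified labels.

new_mir_table <- function(cells, provenance, worlds_found, exhausted,
                          n_input, t2_id, t1_id) {
  structure(list(cells = cells, provenance = provenance,
                 worlds_found = worlds_found, exhausted = exhausted,
                 n_input = n_input, t2_id = t2_id, t1_id = t1_id),
            class = "mir_table")
}

bits_to_codes <- function(b) which(bitwAnd(b, bitwShiftL(1L, 0:4)) > 0L)

serialize_bits <- function(b) {
  vapply(b, function(x) rcc5_format(bits_to_codes(x)), "")
}

is_singleton_bits <- function(b) b > 0L & bitwAnd(b, b - 1L) == 0L

#' @export
print.mir_table <- function(x, ...) {
  tal <- tally_relations(x)
  cat(sprintf("<MIR table %s x %s: %d cells (%d x %d concepts)>\n",
              x$t2_id, x$t1_id, length(x$cells), nrow(x$cells),
              ncol(x$cells)))
  cat(sprintf("  worlds found: %d%s; input articulations: %d\n",
              x$worlds_found,
              if (x$exhausted) " (exhausted)" else " (cap hit)", x$n_input))
  cat("  ", paste(sprintf("%s %d", names(tal), tal), collapse = "  "), "\n",
      sep = "")
  invisible(x)
}

#' Relation symbols of a MIR table
#'
#' @param mir A [mir_table][compute_mir()].
#' @return Character matrix of serialized relation sets (e.g. `"=="`,
#'   `"{> ><}"`), rows = T2 concepts, columns = T1 concepts.
#' @export
mir_cells <- function(mir) {
  m <- matrix(serialize_bits(mir$cells), nrow(mir$cells), ncol(mir$cells),
              dimnames = dimnames(mir$cells))
  m
}

#' @export
as.data.frame.mir_table <- function(x, ...) {
  q2 <- rownames(x$cells); q1 <- colnames(x$cells)
  df <- data.frame(
    taxon2 = rep(q2, times = length(q1)),
    taxon1 = rep(q1, each = length(q2)),
    relation = serialize_bits(as.vector(x$cells)),
    provenance = as.vector(x$provenance),
    stringsAsFactors = FALSE)
  df[order(df$taxon2, df$taxon1, method = "radix"), , drop = FALSE]
}

#' Write a MIR table as CSV
#'
#' Header `taxon2,taxon1,relation,provenance`; one row per cross-taxonomy
#' pair, sorted by the T2 then T1 qualified label; the relation field is a
#' single symbol or a brace-delimited disjunction; provenance is `input`
#' when the pair was directly articulated, else `inferred`. UTF-8, LF line
#' endings.
#'
#' @param mir A [mir_table][compute_mir()] or a data frame in the same
#'   column layout (as returned by [read_mir_csv()]).
#' @param path Optional file path.
#' @return The CSV text as one string (invisibly when `path` is given).
#' @export
write_mir_csv <- function(mir, path = NULL) {
  df <- if (inherits(mir, "mir_table")) as.data.frame(mir) else {
    stopifnot(all(c("taxon2", "taxon1", "relation", "provenance") %in%
                    names(mir)))
    mir[order(mir$taxon2, mir$taxon1, method = "radix"), , drop = FALSE]
  }
  if (inherits(mir, "mir_table")) {
    expected <- nrow(mir$cells) * ncol(mir$cells)
    if (nrow(df) != expected || any(mir$cells == 0L)) {
      stop("incomplete MIR table: expected ", expected, " nonempty cells")
    }
  }
  lines <- c("taxon2,taxon1,relation,provenance",
             paste(df$taxon2, df$taxon1, df$relation, df$provenance,
                   sep = ","))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, "wb"); on.exit(close(con))
    writeChar(txt, con, eos = NULL)
    return(invisible(txt))
  }
  txt
}

#' Read a MIR CSV
#'
#' @param text CSV text (single string or lines) or a file path when
#'   `is_path = TRUE`.
#' @param is_path Treat `text` as a file path.
#' @return Data frame with columns `taxon2`, `taxon1`, `relation`,
#'   `provenance`.
#' @export
read_mir_csv <- function(text, is_path = FALSE) {
  lines <- if (is_path) readLines(text, warn = FALSE)
  else if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
  else text
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L || lines[1] != "taxon2,taxon1,relation,provenance") {
    stop("not a MIR CSV: missing header")
  }
  if (length(lines) == 1L) {
    return(data.frame(taxon2 = character(), taxon1 = character(),
                      relation = character(), provenance = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines[-1], ",", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad)) stop("malformed MIR CSV row ", bad[1] + 1L)
  m <- do.call(rbind, parts)
  data.frame(taxon2 = m[, 1], taxon1 = m[, 2], relation = m[, 3],
             provenance = m[, 4], stringsAsFactors = FALSE)
}
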