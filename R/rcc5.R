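# RCC-5 base relations on nonempty sets, relation sets (disjunctions),
# converse and composition.
#
# Relations are represented internally as integer codes 1..5 in the fixed
# serialization order:
#   1 "=="  congruence
#   2 ">"   proper inclusion   (left properly includes right)
#   3 "<"   inverse proper inclusion (left properly included in right)
#   4 "><"  overlap
#   5 "!"   exclusion ("|" is accepted on input, "!" is emitted)

RCC5_SYMBOLS <- c("==", ">", "<", "><", "!")
RCC5_WORDS <- c("equals", "includes", "is_included_in", "overlaps", "disjoint")
RCC5_CONVERSE <- c(1L, 3L, 2L, 4L, 5L)

#' The five RCC-5 base relation symbols
#'
#' Returns the canonical serialization order used everywhere in the package
#' (files, CSV, DOT): `==`, `>`, `<`, `><`, `!`.
#'
#' @return Character vector of length five.
#' @export
rcc5_relations <- function() RCC5_SYMBOLS

# Normalise a relation given as symbol, word, or integer code to a code.
rel_code <- function(r) {
  if (is.numeric(r)) {
    r <- as.integer(r)
    if (any(r < 1L | r > 5L)) stop("relation code out of range 1..5")
    return(r)
  }
  r <- as.character(r)
  r[r == "|"] <- "!"
  m <- match(r, RCC5_SYMBOLS)
  w <- match(r, RCC5_WORDS)
  m[is.na(m)] <- w[is.na(m)]
  if (anyNA(m)) {
    stop("unknown RCC-5 relation: ", paste(r[is.na(m)], collapse = ", "))
  }
  m
}

# Validate and canonicalize a relation set: sorted unique codes, nonempty.
relset <- function(r) {
  codes <- sort(unique(rel_code(r)))
  if (length(codes) == 0L) stop("relation set must be nonempty")
  codes
}

#' Serialize an RCC-5 relation set
#'
#' A single base relation is printed as its symbol; a disjunction is printed
#' brace-delimited in the fixed order `==`, `>`, `<`, `><`, `!`, for example
#' `"{> ><}"`.
#'
#' @param r Relation(s) as symbols, words, or integer codes.
#' @return A single string.
#' @export
rcc5_format <- function(r) {
  codes <- relset(r)
  if (length(codes) == 1L) RCC5_SYMBOLS[codes]
  else paste0("{", paste(RCC5_SYMBOLS[codes], collapse = " "), "}")
}

# Parse the text form produced by rcc5_format (plus word forms and "|").
parse_relset <- function(s) {
  s <- trimws(s)
  if (grepl("^\\{", s)) {
    if (!grepl("\\}$", s)) stop("unterminated relation set: ", s)
    inner <- trimws(substr(s, 2L, nchar(s) - 1L))
    toks <- strsplit(inner, "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0L) stop("empty relation set")
    relset(toks)
  } else {
    relset(s)
  }
}

#' Classify the RCC-5 relation between two finite nonempty sets
#'
#' @param x,y Vectors interpreted as finite sets; both must be nonempty.
#' @return One of `"=="`, `">"`, `"<"`, `"><"`, `"!"`.
#' @examples
#' rcc5_classify(1:2, 1:2)  # "=="
#' rcc5_classify(1, 1:2)    # "<"
#' rcc5_classify(1:2, 2:3)  # "><"
#' @export
rcc5_classify <- function(x, y) {
  x <- unique(x); y <- unique(y)
  if (length(x) == 0L || length(y) == 0L) {
    stop("rcc5_classify() requires nonempty sets")
  }
  ni <- sum(x %in% y)
  code <- if (ni == 0L) 5L
  else if (ni == length(x) && ni == length(y)) 1L
  else if (ni == length(y)) 2L
  else if (ni == length(x)) 3L
  else 4L
  RCC5_SYMBOLS[code]
}

#' Converse of an RCC-5 relation set
#'
#' Element-wise converse: `>` and `<` swap, `==`, `><` and `!` are
#' self-converse. Applying the converse twice is the identity.
#'
#' @param r Relation(s) as symbols, words, or integer codes.
#' @return Character vector of symbols in canonical order.
#' @export
rcc5_converse <- function(r) {
  RCC5_SYMBOLS[sort(RCC5_CONVERSE[relset(r)])]
}

# Composition table, derived by brute force over subsets of a 6-element
# universe (derive_composition_table(6), stable against size 7); regenerated
# and checked in the test suite. tab[[r]][[s]] = codes t such that nonempty
# X, Y, Z exist with X r Y, Y s Z, X t Z.
RCC5_COMPOSITION <- list(
  list(1L, 2L, 3L, 4L, 5L),                      # == o s = s
  list(2L, 2L, c(1L, 2L, 3L, 4L), c(2L, 4L), c(2L, 4L, 5L)),
  list(3L, c(1L, 2L, 3L, 4L, 5L), 3L, c(3L, 4L, 5L), 5L),
  list(4L, c(2L, 4L, 5L), c(3L, 4L), c(1L, 2L, 3L, 4L, 5L), c(2L, 4L, 5L)),
  list(5L, 5L, c(3L, 4L, 5L), c(3L, 4L, 5L), c(1L, 2L, 3L, 4L, 5L))
)

#' Compose two RCC-5 base relations
#'
#' Returns every base relation `t` for which nonempty sets X, Y, Z exist with
#' `X r Y`, `Y s Z` and `X t Z`. The table is shipped precomputed and is
#' identical to [derive_composition_table()] run at universe size 6.
#'
#' @param r,s Single base relations (symbol, word, or code).
#' @return Character vector of relation symbols in canonical order.
#' @examples
#' rcc5_compose("<", "<")  # "<"
#' rcc5_compose("!", "!")  # all five
#' @export
rcc5_compose <- function(r, s) {
  rc <- rel_code(r); sc <- rel_code(s)
  if (length(rc) != 1L || length(sc) != 1L) {
    stop("rcc5_compose() composes single base relations")
  }
  RCC5_SYMBOLS[RCC5_COMPOSITION[[rc]][[sc]]]
}

#' Derive the RCC-5 composition table by brute force
#'
#' Enumerates all ordered triples of nonempty subsets of a universe of the
#' given size and records, for each ordered relation pair (r, s), the
#' relations realized between the first and third set. Serves as the
#' independent oracle for the shipped table: the result is stable from
#' universe size 5 upward.
#'
#' @param universe_size Number of elements in the universe (at least 2).
#' @return A 5 x 5 list matrix-like structure: `tab[[r]][[s]]` is an integer
#'   vector of relation codes; dimnames follow [rcc5_relations()].
#' @export
derive_composition_table <- function(universe_size = 6L) {
  n <- as.integer(universe_size)
  if (n < 2L) stop("universe_size must be at least 2")
  if (n > 12L) stop("universe_size above 12 is needlessly expensive")
  nsub <- 2L^n - 1L
  bits <- 2L^(0:(n - 1L))
  # relation codes between every ordered pair of nonempty subsets (bitmasks)
  sz <- vapply(1:nsub, function(m) sum(bitwAnd(m, bits) > 0L), 0L)
  R <- matrix(0L, nsub, nsub)
  for (a in 1:nsub) {
    inter <- vapply(1:nsub, function(b) {
      ab <- bitwAnd(a, b)
      if (ab == 0L) 0L else sum(bitwAnd(ab, bits) > 0L)
    }, 0L)
    R[a, ] <- ifelse(inter == 0L, 5L,
              ifelse(inter == sz[a] & inter == sz, 1L,
              ifelse(inter == sz, 2L,
              ifelse(inter == sz[a], 3L, 4L))))
  }
  seen <- array(FALSE, c(5L, 5L, 5L))
  Rvec <- as.vector(R)
  for (y in 1:nsub) {
    idx <- cbind(rep(R[, y], times = nsub), rep(R[y, ], each = nsub), Rvec)
    seen[idx] <- TRUE
  }
  tab <- lapply(1:5, function(r) lapply(1:5, function(s) which(seen[r, s, ])))
  names(tab) <- RCC5_SYMBOLS
  for (r in 1:5) names(tab[[r]]) <- RCC5_SYMBOLS
  tab
}
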