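## Anchored PROSITE-style motif engine.
##
## Patterns are written in the field's conventional compact syntax, e.g.
## "C-x-x-[CU]-x-x>": residue letters (including U for selenocysteine),
## residue classes in square brackets, "x" wildcards, bounded gaps
## "x(m,n)", optional "-" separators, and a trailing ">" anchoring the
## last element at the C-terminus of the polypeptide.

#' Parse an anchored PROSITE-style motif pattern
#'
#' @param text pattern string, e.g. `"C-x-x-[CU]-x-x>"` or `"C-x(3,10)-C-x-x>"`.
#'   Case-insensitive; `-` separators optional; trailing `>` marks a
#'   C-terminal anchor.
#' @return an object of class `motif_pattern`: a list with `elements` (each
#'   `FIXED` with a residue set, `WILDCARD`, or `RANGE` with `min`/`max`)
#'   and logical `anchored`.
#' @examples
#' p <- parse_pattern("C-x-x-[CU]-x-x>")
#' render_pattern(p)
#' @export
parse_pattern <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("pattern must be a single string")
  raw <- gsub("\\s", "", text)
  if (!nzchar(raw)) stop("empty pattern")
  anchored <- grepl(">$", raw)
  body <- toupper(sub(">+$", "", raw))
  if (!nzchar(body)) stop("pattern has no elements")
  elements <- list()
  i <- 1L
  n <- nchar(body)
  while (i <= n) {
    ch <- substr(body, i, i)
    if (ch == "-") {
      i <- i + 1L
    } else if (ch == "X") {
      rest <- substr(body, i + 1L, n)
      m <- regmatches(rest, regexec("^\\((\\d+)(?:,(\\d+))?\\)", rest))[[1]]
      if (length(m)) {
        lo <- as.integer(m[2])
        hi <- if (is.na(m[3]) || !nzchar(m[3])) lo else as.integer(m[3])
        if (lo > hi)
          stop(sprintf("malformed range 'x(%d,%d)': min exceeds max", lo, hi))
        elements[[length(elements) + 1L]] <- list(type = "RANGE", min = lo, max = hi)
        i <- i + 1L + nchar(m[1])
      } else {
        elements[[length(elements) + 1L]] <- list(type = "WILDCARD")
        i <- i + 1L
      }
    } else if (ch == "[") {
      close <- regexpr("]", substr(body, i, n), fixed = TRUE)
      if (close < 0L) stop("unterminated residue class starting at '['")
      inner <- substr(body, i + 1L, i + close - 2L)
      cls <- unique(strsplit(inner, "")[[1]])
      if (!length(cls)) stop("empty residue class '[]'")
      bad <- setdiff(cls, AA21)
      if (length(bad))
        stop("unknown residue '", paste(bad, collapse = ","), "' in class [", inner, "]")
      elements[[length(elements) + 1L]] <- list(type = "FIXED", residues = sort(cls))
      i <- i + close
    } else if (ch %in% AA21) {
      elements[[length(elements) + 1L]] <- list(type = "FIXED", residues = ch)
      i <- i + 1L
    } else {
      stop("unknown character '", ch, "' in pattern")
    }
  }
  structure(list(elements = elements, anchored = anchored),
            class = "motif_pattern")
}

#' Render a motif pattern to its canonical string form
#'
#' `parse_pattern(render_pattern(p))` is equal to `p` for any valid pattern.
#'
#' @param p a `motif_pattern`.
#' @return canonical pattern string, `-`-separated, lowercase `x`,
#'   trailing `>` when anchored.
#' @export
render_pattern <- function(p) {
  stopifnot(inherits(p, "motif_pattern"))
  tok <- vapply(p$elements, function(e) {
    switch(e$type,
           FIXED = if (length(e$residues) == 1L) e$residues
                   else paste0("[", paste(e$residues, collapse = ""), "]"),
           WILDCARD = "x",
           RANGE = if (e$min == e$max) sprintf("x(%d)", e$min)
                   else sprintf("x(%d,%d)", e$min, e$max))
  }, character(1))
  paste0(paste(tok, collapse = "-"), if (p$anchored) ">" else "")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("<motif_pattern> ", render_pattern(x), "\n", sep = "")
  invisible(x)
}

## Compile a pattern to a regular expression over the validated alphabet.
pattern_regex <- function(p) {
  rx <- vapply(p$elements, function(e) {
    switch(e$type,
           FIXED = if (length(e$residues) == 1L) e$residues
                   else paste0("[", paste(e$residues, collapse = ""), "]"),
           WILDCARD = ".",
           RANGE = sprintf(".{%d,%d}", e$min, e$max))
  }, character(1))
  paste0(paste(rx, collapse = ""), if (p$anchored) "$" else "")
}

#' Match a motif pattern against protein sequences
#'
#' An anchored pattern must cover a suffix of the sequence ending exactly at
#' the C-terminus; an unanchored pattern may cover any substring.  A bare
#' residue letter matches only itself: `C` does not match selenocysteine
#' `U`; use the class `[CU]` where either is acceptable.
#'
#' @param p a `motif_pattern` or pattern string.
#' @param s character vector of protein sequences (21-letter alphabet;
#'   case-insensitive; trailing `*`/`>` stripped with a warning).
#' @return logical vector, one element per sequence.
#' @examples
#' matches("C-x-x-[CU]-x-x>", "MKLCVTUSS")
#' @export
matches <- function(p, s) {
  if (is.character(p)) p <- parse_pattern(p)
  stopifnot(inherits(p, "motif_pattern"))
  s <- validate_protein(s)
  grepl(pattern_regex(p), s, perl = TRUE)
}

## Ring category patterns.  Inner ring: identity of the residue at position
## -3 from the C-terminus (Sec, Cys, or neither).  Outer ring: an
## additional upstream cysteine, with precedence to the smallest gap so the
## categories are mutually exclusive.  The widest pattern, C-x(10)-[CU]-x-x>,
## spans 14 residues, so the outer call depends on at most the final 14.
.ring_patterns <- NULL
ring_patterns <- function() {
  if (is.null(.ring_patterns)) {
    pats <- list(
      CXXC       = parse_pattern("C-x-x-[CU]-x-x>"),
      CXC        = parse_pattern("C-x-[CU]-x-x>"),
      CX_RANGE_C = parse_pattern("C-x(3,10)-[CU]-x-x>")
    )
    utils::assignInMyNamespace(".ring_patterns", pats)
  }
  .ring_patterns
}

#' Classify a protein C-terminus into Cys/Sec motif ring categories
#'
#' The inner category records whether the residue three positions before the
#' C-terminus is selenocysteine (`U_TERM`, the Uxx> motif), cysteine
#' (`C_TERM`, Cxx>), or neither (`NONE`).  When the inner category is
#' non-`NONE`, the outer category records an additional upstream cysteine:
#' `CXXC` (Cxx[CU]xx>), `CXC` (Cx[CU]xx>) or `CX_RANGE_C` (Cx(3,10)[CU]xx>),
#' with precedence to the smallest gap so that the categories are mutually
#' exclusive.
#'
#' @param s character vector of protein sequences, each of length >= 14.
#' @return data frame with columns `seq_id`, `inner`, `outer`.
#' @examples
#' classify_terminus("MEPLAARFENELPALAACVTUSS")
#' @export
classify_terminus <- function(s) {
  s <- validate_protein(s)
  ids <- names(s)
  if (is.null(ids)) ids <- paste0("seq", seq_along(s))
  short <- nchar(s) < 14L
  if (any(short))
    stop("sequences shorter than 14 residues cannot be classified: ",
         paste(ids[short], collapse = ", "))
  res3 <- substr(s, nchar(s) - 2L, nchar(s) - 2L)
  inner <- ifelse(res3 == "U", "U_TERM", ifelse(res3 == "C", "C_TERM", "NONE"))
  outer <- rep("NONE", length(s))
  candidate <- inner != "NONE"
  if (any(candidate)) {
    pats <- ring_patterns()
    for (nm in names(pats)) {   # precedence order: CXXC, CXC, CX_RANGE_C
      todo <- candidate & outer == "NONE"
      if (!any(todo)) break
      outer[todo][matches(pats[[nm]], s[todo])] <- nm
    }
  }
  data.frame(seq_id = ids, inner = inner, outer = outer,
             row.names = NULL, stringsAsFactors = FALSE)
}

## Default census patterns: the ring categories of the family plus the
## generalised single-residue termini.
default_census_patterns <- function() {
  c("[CU]-x-x>", "C-x-x>", "U-x-x>",
    "C-x-x-[CU]-x-x>", "C-x-[CU]-x-x>", "C-x(3,10)-[CU]-x-x>")
}

#' Census of C-terminal motif classes across a sequence set
#'
#' Counts, per registered anchored pattern, the number of sequences
#' matching it (a sequence matches at most once: the motifs are anchored),
#' and tabulates the inner/outer ring classification.
#'
#' @param seqs named character vector of protein sequences.
#' @param patterns character vector of pattern strings to census.
#' @return object of class `motif_census`: list with `n`, `classes`
#'   (the per-sequence classification), `class_counts` (inner-ring table),
#'   and `pattern_counts` (data frame `pattern`, `k`).
#' @export
census <- function(seqs, patterns = default_census_patterns()) {
  if (length(seqs) == 0L) {
    pc <- data.frame(pattern = patterns, k = integer(length(patterns)),
                     stringsAsFactors = FALSE)
    return(structure(list(n = 0L,
                          classes = data.frame(seq_id = character(), inner = character(),
                                               outer = character(), stringsAsFactors = FALSE),
                          class_counts = table(factor(character(),
                                                      levels = c("C_TERM", "U_TERM", "NONE"))),
                          pattern_counts = pc),
                     class = "motif_census"))
  }
  cls <- tryCatch(classify_terminus(seqs), error = function(e)
    stop("census input error: ", conditionMessage(e)))
  seqs <- validate_protein(seqs)
  k <- vapply(patterns, function(pt) sum(matches(pt, seqs)), integer(1))
  structure(list(
    n = length(seqs),
    classes = cls,
    class_counts = table(factor(cls$inner, levels = c("C_TERM", "U_TERM", "NONE"))),
    pattern_counts = data.frame(pattern = patterns, k = unname(k),
                                stringsAsFactors = FALSE)
  ), class = "motif_census")
}

#' @export
print.motif_census <- function(x, ...) {
  cat("C-terminal motif census over", x$n, "sequences\n")
  cat("inner ring:", paste(names(x$class_counts), as.integer(x$class_counts),
                           sep = "=", collapse = "  "), "\n")
  print(x$pattern_counts, row.names = FALSE)
  invisible(x)
}
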