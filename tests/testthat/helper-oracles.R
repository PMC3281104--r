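# Independent oracles used across the suite.  Each re-derives the quantity
# under test by brute force (enumeration or exact integer arithmetic) and
# never calls the implementation path it checks.

# --- motif matching: exhaustive enumeration over all RANGE assignments ----

# Set of end positions (exclusive) reachable when elements[i..] start
# matching s at position pos.
.oracle_ends <- function(elements, s, i, pos) {
  n <- nchar(s)
  if (i > length(elements)) return(pos)
  e <- elements[[i]]
  if (e$type == "FIXED") {
    if (pos <= n && substr(s, pos, pos) %in% e$residues)
      .oracle_ends(elements, s, i + 1L, pos + 1L) else integer(0)
  } else if (e$type == "WILDCARD") {
    if (pos <= n) .oracle_ends(elements, s, i + 1L, pos + 1L) else integer(0)
  } else {
    out <- integer(0)
    for (g in e$min:e$max)
      if (pos + g - 1L <= n)
        out <- c(out, .oracle_ends(elements, s, i + 1L, pos + g))
    unique(out)
  }
}

oracle_matches <- function(p, s) {
  if (is.character(p)) p <- parse_pattern(p)
  n <- nchar(s)
  for (start in seq_len(n + 1L)) {
    ends <- .oracle_ends(p$elements, s, 1L, start)
    if (p$anchored) {
      if ((n + 1L) %in% ends) return(TRUE)
    } else if (length(ends)) return(TRUE)
  }
  FALSE
}

# Random pattern generator for property tests (total span <= max_span).
random_pattern <- function(max_span = 15) {
  elems <- character(0)
  span <- 0L
  repeat {
    kind <- sample(c("fixed", "class", "wild", "range"), 1,
                   prob = c(0.35, 0.2, 0.3, 0.15))
    tok <- switch(kind,
      fixed = sample(c("A", "C", "G", "U", "S", "T"), 1),
      class = paste0("[", paste(sample(c("A", "C", "G", "U", "S"),
                                       sample(2:3, 1)), collapse = ""), "]"),
      wild = "x",
      range = { m <- sample(0:3, 1); sprintf("x(%d,%d)", m, m + sample(0:3, 1)) })
    w <- switch(kind, fixed = 1L, class = 1L, wild = 1L,
                range = as.integer(sub(".*,(\\d+)\\)", "\\1", tok)))
    if (span + w > max_span) break
    elems <- c(elems, tok)
    span <- span + w
    if (length(elems) >= 2 && stats::runif(1) < 0.35) break
  }
  if (!length(elems)) elems <- "x"
  paste0(paste(elems, collapse = "-"), if (stats::runif(1) < 0.7) ">" else "")
}

random_protein <- function(len, alphabet = c("A", "C", "G", "U", "S", "T", "V")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# --- global alignment: exhaustive enumeration -----------------------------

# Identity percentages achievable by optimal-score global alignments,
# and the optimal score itself, by enumerating every alignment.
oracle_align <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste0(i, "_", j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    if (i > length(av) && j > length(bv)) {
      res <- matrix(0, 1, 3)          # score, matches, columns
    } else {
      parts <- list()
      if (i <= length(av) && j <= length(bv)) {
        sub <- rec(i + 1L, j + 1L)
        hit <- av[i] == bv[j]
        parts[[length(parts) + 1L]] <-
          sweep(sub, 2, c(if (hit) match else mismatch, as.integer(hit), 1), "+")
      }
      if (i <= length(av))
        parts[[length(parts) + 1L]] <- sweep(rec(i + 1L, j), 2, c(gap, 0, 1), "+")
      if (j <= length(bv))
        parts[[length(parts) + 1L]] <- sweep(rec(i, j + 1L), 2, c(gap, 0, 1), "+")
      res <- unique(do.call(rbind, parts))
    }
    memo[[key]] <- res
    res
  }
  st <- rec(1L, 1L)
  best <- max(st[, 1])
  opt <- st[st[, 1] == best, , drop = FALSE]
  list(score = best, identities = sort(unique(100 * opt[, 2] / opt[, 3])))
}

# --- exact binomial tail via integer arithmetic ---------------------------

# P(X >= k) for X ~ Binomial(n, num/den), exact for n <= 12 and den <= 10
# (all integer terms below 2^53).
oracle_binom_tail <- function(k, n, num, den) {
  if (k == 0) return(1)
  i <- k:n
  sum(choose(n, i) * num^i * (den - num)^(n - i)) / den^n
}

# --- Fisher two-sided p by exhaustive hypergeometric enumeration ----------

# Exact for margins <= 12: table weights are integers below 2^53, so the
# "at most as probable" comparison is exact.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  supp <- max(0, c1 - r2):min(c1, r1)
  w <- choose(r1, supp) * choose(r2, c1 - supp)
  w_obs <- w[supp == a]
  sum(w[w <= w_obs]) / choose(r1 + r2, c1)
}
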