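## Exact, numerically stable enrichment statistics.
##
## All tail probabilities are computed and reported in log10 space so that
## extreme enrichments (the family's motif nulls reach below 1e-189) are
## represented without underflow.

#' Exact log10 upper tail of the binomial distribution
#'
#' Computes `log10 P(X >= k)` for `X ~ Binomial(n, p_bg)` by log-sum-exp
#' over log-gamma terms, exact and stable far below the smallest double
#' (results down to 1e-500 and beyond are returned as finite log10 values).
#'
#' @param k observed successes, `0 <= k <= n`.
#' @param n number of trials.
#' @param p_bg background success probability, strictly inside (0, 1).
#' @return `log10 P(X >= k)`, a number `<= 0`.
#' @examples
#' log10_binomial_tail(12, 143, 585 / 5e5)  # about -18.3
#' @export
log10_binomial_tail <- function(k, n, p_bg) {
  stopifnot(length(k) == 1L, length(n) == 1L, length(p_bg) == 1L)
  if (!is.finite(p_bg) || p_bg <= 0 || p_bg >= 1)
    stop("p_bg must lie strictly inside (0, 1); got ", p_bg)
  if (k < 0 || k > n || n < 0) stop("need 0 <= k <= n")
  if (k == 0) return(0)
  i <- seq.int(k, n)
  lt <- lchoose(n, i) + i * log(p_bg) + (n - i) * log1p(-p_bg)
  m <- max(lt)
  min((m + log(sum(exp(lt - m)))) / log(10), 0)
}

#' Background probability from a reference database count
#'
#' @param count_in_ref occurrences of the feature in the reference set.
#' @param ref_size size of the reference set (> 0).
#' @return `count_in_ref / ref_size`; a zero count returns 0 with a warning
#'   (the caller decides any pseudo-count policy).
#' @examples
#' background_from_reference(585, 5e5)  # SwissProt-style motif background
#' @export
background_from_reference <- function(count_in_ref, ref_size) {
  stopifnot(ref_size > 0, count_in_ref >= 0, count_in_ref <= ref_size)
  if (count_in_ref == 0) {
    warning("zero count in reference: background probability is 0; ",
            "tests against it are refused unless a pseudo-count is supplied")
    return(0)
  }
  count_in_ref / ref_size
}

#' Expected number of sequences matching an anchored motif under a
#' residue-composition model
#'
#' Under independent residues drawn from `comp$freqs`, the per-sequence
#' probability that an anchored pattern matches is the product over FIXED
#' elements of the residue-class frequency sums (wildcards contribute 1).
#' For a bounded gap `x(m,M)` the match may occur at any of the
#' `M - m + 1` gap widths; treating those placements as independent the
#' probability becomes `1 - prod_g (1 - p_fixed)`.
#'
#' @param p anchored `motif_pattern` (or pattern string).
#' @param comp list with `freqs` (named residue frequencies summing to 1)
#'   and `n_seqs` (reference database size, in sequences).
#' @return expected number of matching sequences, `n_seqs * P(match)`.
#' @export
expected_count <- function(p, comp) {
  if (is.character(p)) p <- parse_pattern(p)
  stopifnot(inherits(p, "motif_pattern"))
  if (!p$anchored) stop("unsupported pattern: expected_count requires an anchored motif")
  stopifnot(is.list(comp), !is.null(comp$freqs), !is.null(comp$n_seqs))
  f <- comp$freqs
  if (abs(sum(f) - 1) > 1e-6) stop("composition frequencies must sum to 1")
  p_fixed <- 1
  n_gap_choices <- 1
  for (e in p$elements) {
    if (e$type == "FIXED") {
      pf <- sum(f[e$residues], na.rm = TRUE)
      p_fixed <- p_fixed * pf
    } else if (e$type == "RANGE") {
      n_gap_choices <- n_gap_choices * (e$max - e$min + 1L)
    }
  }
  p_match <- if (n_gap_choices == 1) p_fixed else 1 - (1 - p_fixed)^n_gap_choices
  comp$n_seqs * p_match
}

#' Fisher's exact test for a 2x2 table (two-sided, probability-mass method)
#'
#' The two-sided p-value is the sum of hypergeometric probabilities, with
#' margins fixed, of all tables at most as probable as the observed one
#' (the definition used by standard statistical software).
#'
#' @param tab 2x2 matrix of non-negative counts, or a length-4 vector
#'   `c(a, b, c, d)` filled row-wise.
#' @return two-sided p-value.
#' @examples
#' fisher_exact(c(10, 20, 5, 10))  # proportional rows: p = 1
#' @export
fisher_exact <- function(tab) {
  if (is.matrix(tab)) {
    stopifnot(all(dim(tab) == c(2L, 2L)))
    a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  } else {
    stopifnot(length(tab) == 4L)
    a <- tab[1]; b <- tab[2]; cc <- tab[3]; d <- tab[4]
  }
  cnt <- c(a, b, cc, d)
  if (any(cnt < 0) || any(cnt != round(cnt))) stop("counts must be non-negative integers")
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    stop("degenerate margins: every row and column total must be positive")
  support <- max(0, c1 - r2):min(c1, r1)
  dens <- stats::dhyper(support, r1, r2, c1)
  p_obs <- dens[support == a]
  ## relative slack absorbs rounding when masses are equal up to the last ulp
  min(sum(dens[dens <= p_obs * (1 + 1e-7)]), 1)
}

#' Bonferroni correction on the log10 scale
#'
#' `corrected = min(1, raw * m_tested)`, computed as
#' `min(0, log10_p + log10(m_tested))` so that extreme raw tails survive
#' the correction without underflow.
#'
#' @param log10_p numeric vector of raw log10 p-values (<= 0).
#' @param m_tested number of hypotheses tested, >= 1.
#' @return corrected log10 p-values.
#' @export
bonferroni_log10 <- function(log10_p, m_tested) {
  if (length(m_tested) != 1L || !is.finite(m_tested) || m_tested < 1)
    stop("m_tested must be a single number >= 1")
  pmin(0, log10_p + log10(m_tested))
}

#' Trait (lifestyle) enrichment in a selected organism subset
#'
#' For each trait with a supplied background frequency, counts the
#' trait-positive organisms among the selected subset and computes the
#' exact binomial upper tail against the background, Bonferroni-corrected
#' over the number of traits tested.  Pairwise Fisher independence tests
#' among significant traits (corrected p < 0.05) are attached as the
#' `independence` attribute.
#'
#' @param traits data frame with column `organism_id` plus 0/1 trait columns
#'   (NA = unknown).
#' @param selected character vector of organism ids (subset of the table).
#' @param backgrounds named numeric vector of background trait frequencies
#'   in `[0, 1]`.
#' @return data frame of class `enrichment_rows` with columns `label`, `k`,
#'   `n`, `p_bg`, `log10_p_raw`, `log10_p_corrected`, `m_tested`, sorted by
#'   corrected p-value.
#' @export
trait_enrichment <- function(traits, selected, backgrounds) {
  stopifnot(is.data.frame(traits), "organism_id" %in% names(traits))
  missing_org <- setdiff(selected, traits$organism_id)
  if (length(missing_org))
    stop("selected organisms absent from the trait table: ",
         paste(utils::head(missing_org, 5), collapse = ", "))
  sel <- traits[traits$organism_id %in% selected, , drop = FALSE]
  tested <- intersect(names(backgrounds), setdiff(names(traits), "organism_id"))
  if (!length(tested)) stop("no testable trait: backgrounds cover none of the table columns")
  rows <- list()
  for (tr in tested) {
    v <- sel[[tr]]
    n <- sum(!is.na(v))
    if (n == 0L) {
      warning("trait '", tr, "' missing for all selected organisms; skipped")
      next
    }
    k <- sum(v, na.rm = TRUE)
    p_bg <- unname(backgrounds[tr])
    if (p_bg == 0) {
      warning("trait '", tr, "' has zero background frequency; skipped ",
              "(supply a pseudo-count upstream to test it)")
      next
    }
    lp <- if (p_bg >= 1) 0 else log10_binomial_tail(k, n, p_bg)
    rows[[tr]] <- data.frame(label = tr, k = k, n = n, p_bg = p_bg,
                             log10_p_raw = lp, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no trait could be tested")
  out <- do.call(rbind, rows)
  out$m_tested <- nrow(out)
  out$log10_p_corrected <- bonferroni_log10(out$log10_p_raw, nrow(out))
  out <- out[order(out$log10_p_corrected, out$log10_p_raw), ]
  out <- out[, c("label", "k", "n", "p_bg", "log10_p_raw",
                 "log10_p_corrected", "m_tested")]
  rownames(out) <- NULL

  sig <- out$label[out$log10_p_corrected < log10(0.05)]
  indep <- NULL
  if (length(sig) >= 2L) {
    pairs <- utils::combn(sig, 2)
    indep <- data.frame(trait1 = pairs[1, ], trait2 = pairs[2, ],
                        fisher_p = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_len(ncol(pairs))) {
      v1 <- sel[[pairs[1, i]]]; v2 <- sel[[pairs[2, i]]]
      ok <- !is.na(v1) & !is.na(v2)
      tab <- c(sum(v1[ok] & v2[ok]), sum(v1[ok] & !v2[ok]),
               sum(!v1[ok] & v2[ok]), sum(!v1[ok] & !v2[ok]))
      indep$fisher_p[i] <- tryCatch(fisher_exact(tab), error = function(e) NA_real_)
    }
  }
  attr(out, "independence") <- indep
  class(out) <- c("enrichment_rows", class(out))
  out
}

#' Render a log10 p-value in scientific notation
#'
#' @param log10_p log10 of a probability (<= 0).
#' @return character such as `"2.3e-11"` or `"<1e-300"` style strings for
#'   values representable only in log space.
#' @export
format_log10_p <- function(log10_p) {
  vapply(log10_p, function(lp) {
    if (is.na(lp)) return(NA_character_)
    expo <- floor(lp)
    mant <- 10^(lp - expo)
    sprintf("%.2ge%+d", mant, as.integer(expo))
  }, character(1))
}
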