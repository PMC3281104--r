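## Kinase-fold fingerprint annotation and alignment-column conservation.

## Ordered motif slots of the protein-kinase-like fold as they read along
## the sequence.  The family carries a Walker-A-like glycine loop (GxxGxG
## rather than the classic GxGxxG), an almost invariant beta3 lysine and
## alphaC glutamate, an HGV/QGN/HGS-type catalytic loop in place of HRD,
## the Mg-binding asparagine, and a strictly conserved D[YF]G ion-binding
## motif.
fingerprint_slots <- function() {
  c(G_LOOP   = "G-x-x-G-x-G",
    BETA3_K  = "K",
    ALPHAC_E = "E",
    CAT_LOOP = "[HQ]-G-[VNS]",
    MG_N     = "N",
    DFG      = "D-[YF]-G")
}

#' Annotate the ordered kinase-fold motif fingerprint of a sequence
#'
#' Finds greedy-earliest, ordered, non-overlapping occurrences of the six
#' kinase fingerprint motifs: glycine-rich loop (`GxxGxG`), beta3 lysine,
#' alphaC glutamate, catalytic-loop variant (`[HQ]G[VNS]`), Mg-binding
#' asparagine, and the `D[YF]G` ion-binding motif.  Each slot is searched
#' strictly after the end of the previous placed slot; a slot that cannot
#' be placed is reported absent and later slots continue from the last
#' placed position.
#'
#' @param s a single protein sequence of length >= 50.
#' @return data frame with one row per slot: `slot`, `pattern`, `start`,
#'   `end`, `hit`, `present`.  Placed positions are strictly increasing.
#' @export
annotate_kinase_fingerprint <- function(s) {
  s <- validate_protein(s, "fingerprint input")
  stopifnot(length(s) == 1L)
  if (nchar(s) < 50L) stop("sequence too short for fingerprint annotation (need >= 50 residues)")
  slots <- fingerprint_slots()
  out <- data.frame(slot = names(slots), pattern = unname(slots),
                    start = NA_integer_, end = NA_integer_,
                    hit = NA_character_, present = FALSE,
                    stringsAsFactors = FALSE)
  cursor <- 0L
  for (i in seq_along(slots)) {
    rx <- pattern_regex(parse_pattern(slots[[i]]))
    tail_s <- substr(s, cursor + 1L, nchar(s))
    m <- regexpr(rx, tail_s, perl = TRUE)
    if (m > 0L) {
      start <- cursor + as.integer(m)
      end <- start + attr(m, "match.length") - 1L
      out$start[i] <- start
      out$end[i] <- end
      out$hit[i] <- substr(s, start, end)
      out$present[i] <- TRUE
      cursor <- end
    }
  }
  out
}

#' Per-column conservation profile of a protein alignment
#'
#' For each alignment column, the residue frequency distribution over
#' non-gap characters and the information content
#' `IC = log2(20) - H` (bits), where `H` is the Shannon entropy of the
#' column distribution — the quantity displayed by sequence logos.
#' Columns with more than 50% gaps are flagged.
#'
#' @param aln named character vector of equal-length gapped sequences
#'   (gap characters `-` or `.`), at least two rows.
#' @return object of class `conservation_profile`: list with `ic` (bits,
#'   clipped to `[0, log2(20)]`), `gap_frac`, `flagged`, and `freqs`
#'   (per-column named frequency vectors summing to 1).
#' @export
column_conservation <- function(aln) {
  aln <- toupper(as.character(aln))
  if (length(aln) < 2L) stop("need at least two aligned sequences")
  widths <- nchar(aln)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment: row lengths ", paste(unique(widths), collapse = ", "))
  mat <- do.call(rbind, strsplit(aln, ""))
  ncol_aln <- ncol(mat)
  ic <- numeric(ncol_aln)
  gap_frac <- numeric(ncol_aln)
  freqs <- vector("list", ncol_aln)
  for (j in seq_len(ncol_aln)) {
    col <- mat[, j]
    is_gap <- col %in% c("-", ".")
    gap_frac[j] <- mean(is_gap)
    res <- col[!is_gap]
    if (!length(res)) {
      ic[j] <- NA_real_
      freqs[[j]] <- numeric(0)
      next
    }
    f <- table(res) / length(res)
    h <- -sum(f * log2(f))
    ic[j] <- min(max(log2(20) - h, 0), log2(20))
    freqs[[j]] <- stats::setNames(as.numeric(f), names(f))
  }
  structure(list(ic = ic, gap_frac = gap_frac,
                 flagged = gap_frac > 0.5, freqs = freqs),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("conservation profile over", length(x$ic), "columns;",
      sum(x$flagged), "flagged (>50% gaps)\n")
  cat("IC (bits): ", paste(sprintf("%.2f", utils::head(x$ic, 20)), collapse = " "),
      if (length(x$ic) > 20) " ...", "\n", sep = "")
  invisible(x)
}
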