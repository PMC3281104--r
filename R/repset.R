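## Representative-set construction: pairwise global percent identity and
## greedy redundancy removal at an identity threshold (CD-HIT-style).

identity_submat <- function(match = 1, mismatch = 0) {
  letters <- c(AA21, "X", "B", "Z", "*")
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  m
}

#' Global percent identity between two protein sequences
#'
#' Needleman-Wunsch global alignment under a simple scheme (match +1,
#' mismatch 0, linear gap -1 by default, via [Biostrings::pairwiseAlignment]);
#' identity is `100 * identical columns / alignment length`, the alignment
#' length counting gap columns.  Symmetric in its arguments.
#'
#' @param a,b protein sequences (non-empty).
#' @param match,mismatch,gap scoring parameters; `gap` is the (non-positive)
#'   per-residue linear gap score.
#' @return percent identity in `[0, 100]`.
#' @export
global_identity <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  a <- validate_protein(a); b <- validate_protein(b)
  stopifnot(length(a) == 1L, length(b) == 1L, gap <= 0, match > mismatch)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = identity_submat(match, mismatch),
    gapOpening = 0, gapExtension = abs(gap))
  aligned_identity(as.character(Biostrings::alignedPattern(al)),
                   as.character(Biostrings::alignedSubject(al)))
}

aligned_identity <- function(pa, sb) {
  x <- strsplit(pa, "")[[1]]
  y <- strsplit(sb, "")[[1]]
  100 * sum(x == y & x != "-") / length(x)
}

## Identities of one sequence against many, in a single vectorised
## alignment call.
identities_to_set <- function(s, set, match = 1, mismatch = 0, gap = -1) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(set), Biostrings::AAString(s), type = "global",
    substitutionMatrix = identity_submat(match, mismatch),
    gapOpening = 0, gapExtension = abs(gap))
  pa <- as.character(Biostrings::alignedPattern(al))
  sb <- as.character(Biostrings::alignedSubject(al))
  vapply(seq_along(set), function(i) aligned_identity(pa[i], sb[i]), numeric(1))
}

#' Greedy redundancy reduction at a percent-identity threshold
#'
#' Sequences are processed longest-first (ties broken by identifier) in the
#' CD-HIT convention: each sequence joins the most similar existing
#' representative if its global identity reaches the threshold, and founds a
#' new representative otherwise.  By construction no two representatives
#' share identity at or above the threshold, and every removed sequence has
#' identity at or above the threshold to its assigned representative.
#'
#' @param seqs named character vector of protein sequences.
#' @param threshold_pct identity threshold in `(0, 100]` (default 70, the
#'   conventional redundancy-removal threshold for building representative
#'   homologue sets).
#' @param match,mismatch,gap alignment scoring parameters, see
#'   [global_identity()].
#' @param verify re-check the output invariants by re-aligning all
#'   representative pairs and memberships (quadratic; for tests).
#' @return object of class `repset`: list with `representatives` (ids, in
#'   admission order), `membership` (data frame `member`, `representative`,
#'   `identity`), and `threshold_pct`.
#' @export
greedy_reduce <- function(seqs, threshold_pct = 70, match = 1, mismatch = 0,
                          gap = -1, verify = FALSE) {
  stopifnot(length(seqs) >= 1L, threshold_pct > 0, threshold_pct <= 100)
  seqs <- validate_protein(seqs)
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids))
    stop("sequences must carry unique names")
  ord <- order(-nchar(seqs), ids)
  reps <- character(0)
  memb <- list()
  for (i in ord) {
    id <- ids[i]
    if (length(reps)) {
      idents <- identities_to_set(seqs[[i]], seqs[reps],
                                  match = match, mismatch = mismatch, gap = gap)
      j <- which.max(idents)
      if (idents[j] >= threshold_pct) {
        memb[[id]] <- data.frame(member = id, representative = reps[j],
                                 identity = idents[j], stringsAsFactors = FALSE)
        next
      }
    }
    reps <- c(reps, id)
  }
  membership <- if (length(memb)) do.call(rbind, memb) else
    data.frame(member = character(), representative = character(),
               identity = numeric(), stringsAsFactors = FALSE)
  rownames(membership) <- NULL
  out <- structure(list(representatives = reps, membership = membership,
                        threshold_pct = threshold_pct),
                   class = "repset")
  if (verify) verify_repset(out, seqs, match, mismatch, gap)
  out
}

## Invariant check: no representative pair at/above threshold; every member
## at/above threshold to its representative.
verify_repset <- function(rs, seqs, match = 1, mismatch = 0, gap = -1) {
  reps <- rs$representatives
  if (length(reps) >= 2L) {
    for (i in seq_len(length(reps) - 1L)) {
      idents <- identities_to_set(seqs[[reps[i]]], seqs[reps[-seq_len(i)]],
                                  match = match, mismatch = mismatch, gap = gap)
      if (any(idents >= rs$threshold_pct))
        stop("repset invariant violated: representatives ", reps[i], " and ",
             reps[-seq_len(i)][which(idents >= rs$threshold_pct)[1]],
             " exceed the threshold")
    }
  }
  if (nrow(rs$membership)) {
    for (r in seq_len(nrow(rs$membership))) {
      m <- rs$membership[r, ]
      if (global_identity(seqs[[m$member]], seqs[[m$representative]],
                          match, mismatch, gap) < rs$threshold_pct)
        stop("repset invariant violated: member ", m$member,
             " below threshold to its representative")
    }
  }
  invisible(TRUE)
}

#' @export
print.repset <- function(x, ...) {
  cat("representative set at ", x$threshold_pct, "% identity: ",
      length(x$representatives), " representatives, ",
      nrow(x$membership), " members removed\n", sep = "")
  invisible(x)
}
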