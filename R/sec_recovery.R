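## Rescue of selenocysteine residues misannotated as stop codons.
##
## In many genome annotations the in-frame UGA encoding Sec is read as a
## stop, truncating the protein.  For families whose members end with a
## conserved [CU]-x-x> terminus, a truncated member betrays itself: its
## annotated terminus aligns three columns short of the family consensus
## terminus, its annotated stop codon is TGA, and reading through that TGA
## (as U) yields exactly two further sense codons followed by a genuine
## TAA/TAG stop.

translate_codons <- function(nt) {
  nt <- toupper(nt)
  if (nchar(nt) %% 3L != 0L) stop("nucleotide length not divisible by 3")
  codons <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
  aa <- Biostrings::GENETIC_CODE[codons]
  if (anyNA(aa)) stop("unknown codon '", codons[which(is.na(aa))[1]], "'")
  unname(aa)
}

#' Build a C-terminal alignment context for misannotation detection
#'
#' @param rows named character vector of gapped, equal-length C-terminal
#'   alignment rows (gap `-` or `.`), one per family member.
#' @return object of class `terminus_alignment`: the rows plus the indices
#'   of consensus columns (gap fraction <= 50%), the consensus terminus
#'   (last consensus column) and the `[CU]` support column at offset -3
#'   from the consensus terminus.
#' @export
terminus_alignment <- function(rows) {
  nms <- names(rows)
  rows <- stats::setNames(toupper(as.character(rows)), nms)
  if (is.null(names(rows)) || anyDuplicated(names(rows)))
    stop("alignment rows must carry unique sequence names")
  if (length(unique(nchar(rows))) != 1L) stop("ragged alignment rows")
  mat <- do.call(rbind, strsplit(rows, ""))
  gap_frac <- colMeans(mat == "-" | mat == ".")
  cons <- which(gap_frac <= 0.5)
  if (length(cons) < 3L) stop("alignment has fewer than 3 consensus columns")
  cu_col <- cons[length(cons) - 2L]
  structure(list(rows = rows, mat = mat, cons_cols = cons,
                 cons_terminus = cons[length(cons)], cu_col = cu_col),
            class = "terminus_alignment")
}

#' Detect a selenocysteine stop-codon misannotation in one protein
#'
#' Verdict `LIKELY_SEC` requires all of: (i) the protein's terminal residue
#' occupies the consensus column exactly three consensus columns upstream of
#' the family consensus terminus; (ii) the annotated stop codon is TGA;
#' (iii) reading through the TGA (as Sec, U) yields exactly two further
#' sense codons followed by an in-frame TAA or TAG (a second TGA is
#' rejected); (iv) the column the readthrough U would occupy holds C or U
#' in at least 50% of its non-gap rows.  The rescued protein appends
#' `U` plus the two readthrough residues, restoring a `[CU]-x-x>` terminus.
#'
#' @param protein_id identifier; must name a row of `aln`.
#' @param protein annotated (possibly truncated) protein sequence.
#' @param cds_nt nucleotide sequence covering the annotated CDS plus at
#'   least 9 bp of downstream genomic context.
#' @param cds_len length in bp of the annotated CDS proper (including its
#'   stop codon); must be divisible by 3.
#' @param aln a [terminus_alignment()] containing `protein_id`.
#' @return list of class `recovery_call`: `protein_id`, `verdict`
#'   (`"LIKELY_SEC"` or `"NOT_CANDIDATE"`), `stop_codon`, `extension`,
#'   `extended_protein` (with U; `NA` unless rescued), `notes`.
#' @export
detect_sec_misannotation <- function(protein_id, protein, cds_nt, cds_len, aln) {
  stopifnot(inherits(aln, "terminus_alignment"))
  protein <- validate_protein(protein, "annotated protein")
  cds_nt <- toupper(cds_nt)
  if (cds_len %% 3L != 0L) stop("annotated CDS length must be divisible by 3")
  if (nchar(cds_nt) < cds_len + 9L)
    stop("CDS record for ", protein_id, " lacks downstream context (need >= 9 bp)")
  if (!protein_id %in% names(aln$rows))
    stop("protein '", protein_id, "' is not a row of the terminus alignment")

  ## translation concordance over the CDS proper (minus its stop codon)
  aa <- translate_codons(substr(cds_nt, 1L, cds_len - 3L))
  prot_res <- strsplit(protein, "")[[1]]
  if (length(aa) != length(prot_res) || any(aa != prot_res)) {
    bad <- if (length(aa) != length(prot_res)) min(length(aa), length(prot_res)) + 1L
           else which(aa != prot_res)[1]
    stop("CDS/protein mismatch for ", protein_id, " at codon ", bad)
  }

  call_out <- function(verdict, stop_codon, extension = NA_character_,
                       extended = NA_character_, notes = "") {
    structure(list(protein_id = protein_id, verdict = verdict,
                   stop_codon = stop_codon, extension = extension,
                   extended_protein = extended, notes = notes),
              class = "recovery_call")
  }

  stop_codon <- substr(cds_nt, cds_len - 2L, cds_len)
  if (stop_codon != "TGA")
    return(call_out("NOT_CANDIDATE", stop_codon,
                    notes = "annotated stop is not TGA"))

  ## (i) terminal residue three consensus columns short of the family terminus
  row <- strsplit(aln$rows[[protein_id]], "")[[1]]
  non_gap <- which(!row %in% c("-", "."))
  if (!length(non_gap))
    return(call_out("NOT_CANDIDATE", stop_codon, notes = "all-gap alignment row"))
  pt <- non_gap[length(non_gap)]
  j <- match(pt, aln$cons_cols)
  if (is.na(j) || length(aln$cons_cols) - j != 3L)
    return(call_out("NOT_CANDIDATE", stop_codon,
                    notes = "terminus not exactly 3 consensus columns short"))

  ## (iii) readthrough: TGA (as U) + exactly 2 sense codons + TAA/TAG
  ext_nt <- substr(cds_nt, cds_len + 1L, cds_len + 9L)
  ext_aa <- translate_codons(ext_nt)
  final_stop <- substr(ext_nt, 7L, 9L)
  if (any(ext_aa[1:2] == "*") || !final_stop %in% c("TAA", "TAG"))
    return(call_out("NOT_CANDIDATE", stop_codon,
                    notes = "readthrough does not yield 2 sense codons then TAA/TAG"))

  ## (iv) family support: the U column carries C/U in >= 50% of non-gap rows
  col <- aln$mat[, aln$cons_cols[j + 1L]]
  col <- col[!col %in% c("-", ".")]
  if (!length(col) || mean(col %in% c("C", "U")) < 0.5)
    return(call_out("NOT_CANDIDATE", stop_codon,
                    notes = "alignment column lacks [CU] majority support"))

  extension <- paste0("U", ext_aa[1], ext_aa[2])
  call_out("LIKELY_SEC", stop_codon, extension,
           paste0(protein, extension),
           notes = "TGA readthrough restores a [CU]-x-x> terminus")
}

#' @export
print.recovery_call <- function(x, ...) {
  cat(x$protein_id, ": ", x$verdict,
      if (x$verdict == "LIKELY_SEC") paste0(" (+", x$extension, ")"),
      " - ", x$notes, "\n", sep = "")
  invisible(x)
}

#' Scan a protein family for Sec stop-codon misannotations
#'
#' Applies [detect_sec_misannotation()] to every protein with a CDS record
#' and an alignment row.
#'
#' @param proteins named character vector of annotated proteins.
#' @param cds data frame with columns `protein_id`, `nt` (CDS plus
#'   downstream context) and `cds_len`.
#' @param aln a [terminus_alignment()] covering the proteins.
#' @return data frame with one row per protein: `protein_id`, `verdict`,
#'   `stop_codon`, `extension`, `extended_protein`, `notes`.
#' @export
sec_recovery_scan <- function(proteins, cds, aln) {
  stopifnot(is.data.frame(cds),
            all(c("protein_id", "nt", "cds_len") %in% names(cds)))
  ids <- intersect(names(proteins), cds$protein_id)
  rows <- lapply(ids, function(id) {
    rec <- cds[cds$protein_id == id, ][1, ]
    cl <- detect_sec_misannotation(id, proteins[[id]], rec$nt, rec$cds_len, aln)
    data.frame(protein_id = id, verdict = cl$verdict, stop_codon = cl$stop_codon,
               extension = cl$extension, extended_protein = cl$extended_protein,
               notes = cl$notes, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
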