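## File formats: FASTA via Biostrings, TSV gene/trait tables, iTOL
## colour-strip annotation, Newick (read-only, via ape).

#' Read a protein or nucleotide FASTA file
#'
#' @param path FASTA file; selenocysteine `U` is accepted in proteins.
#' @param type `"AA"` or `"DNA"`.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param type `"AA"` or `"DNA"`.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(seqs)
         else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a gene table (TSV or GFF3)
#'
#' TSV files carry the header `genome_id gene_id start end strand cog_id`.
#' GFF3 files are parsed for `gene`/`CDS` features; the COG label is taken
#' from a `COG=` attribute, the gene id from `ID=`, and the genome id from
#' the seqid column.  Coordinates are 1-based inclusive in both formats.
#'
#' @param path input file; GFF3 is detected by extension (`.gff`, `.gff3`)
#'   or a `##gff-version` first line.
#' @return validated gene table data frame.
#' @export
read_gene_table <- function(path) {
  first <- readLines(path, n = 1)
  is_gff <- grepl("\\.gff3?$", path, ignore.case = TRUE) ||
    startsWith(first, "##gff-version")
  if (is_gff) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    keep <- vapply(fields, function(f) length(f) >= 9 &&
                     f[3] %in% c("gene", "CDS"), logical(1))
    fields <- fields[keep]
    if (!length(fields)) stop("no gene/CDS features in GFF3 file ", path)
    attr_get <- function(attrs, key) {
      m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))[[1]]
      if (length(m)) m[2] else NA_character_
    }
    genes <- data.frame(
      genome_id = vapply(fields, `[`, character(1), 1),
      gene_id = vapply(fields, function(f) attr_get(f[9], "ID"), character(1)),
      start = as.integer(vapply(fields, `[`, character(1), 4)),
      end = as.integer(vapply(fields, `[`, character(1), 5)),
      strand = vapply(fields, `[`, character(1), 7),
      cog_id = vapply(fields, function(f) attr_get(f[9], "COG"), character(1)),
      stringsAsFactors = FALSE)
  } else {
    genes <- utils::read.delim(path, stringsAsFactors = FALSE)
    if ("cog_id" %in% names(genes)) genes$cog_id <- as.character(genes$cog_id)
  }
  validate_gene_table(genes)
}

#' Write a gene table as TSV
#' @param genes gene table.
#' @param path output file.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes[, c("genome_id", "gene_id", "start", "end",
                               "strand", "cog_id")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a binary trait table (TSV: `organism_id` + 0/1 columns)
#' @param path TSV file.
#' @return data frame.
#' @export
read_trait_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"organism_id" %in% names(tab)) stop("trait table lacks an organism_id column")
  tab
}

#' @rdname read_trait_table
#' @param traits trait table data frame.
#' @export
write_trait_table <- function(traits, path) {
  utils::write.table(traits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Ring-category colours used on annotated phylogenies: inner ring C/U at
## the terminus, outer ring the upstream-cysteine categories.
itol_class_colors <- function() {
  c(C_TERM = "#00a000", U_TERM = "#e00000",       # inner: green / red
    CXXC = "#e000e0", CXC = "#0000e0", CX_RANGE_C = "#000000")
}

#' Write an iTOL colour-strip annotation of C-terminal motif classes
#'
#' Emits an iTOL `DATASET_COLORSTRIP` file keyed by tree leaf identifier:
#' the outer-ring category colour where present, otherwise the inner-ring
#' colour.  When a Newick file is supplied only its leaves are annotated.
#'
#' @param classes data frame from [classify_terminus()].
#' @param path output annotation file.
#' @param newick optional Newick tree file used to restrict and order leaves.
#' @param label dataset label shown in iTOL.
#' @export
write_itol_classes <- function(classes, path, newick = NULL,
                               label = "C-terminal motif class") {
  cols <- itol_class_colors()
  ids <- classes$seq_id
  if (!is.null(newick)) {
    tree <- ape::read.tree(newick)
    keep <- ids %in% tree$tip.label
    classes <- classes[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  color <- ifelse(classes$outer != "NONE", cols[classes$outer],
                  ifelse(classes$inner != "NONE", cols[classes$inner], "#c0c0c0"))
  lines <- c("DATASET_COLORSTRIP", "SEPARATOR TAB",
             paste0("DATASET_LABEL\t", label), "COLOR\t#888888", "DATA",
             paste(ids, color, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write enrichment rows as TSV
#' @param rows `enrichment_rows` data frame.
#' @param path output file.
#' @export
write_enrichment <- function(rows, path) {
  utils::write.table(as.data.frame(rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
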