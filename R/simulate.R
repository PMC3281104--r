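## Seeded synthetic-data generators.
##
## Each generator is a pure function of its configuration: randomness comes
## from a per-generator substream derived from the root seed and a fixed
## label, so adding one generator never perturbs another's output.  The
## generators reproduce the statistical structure the analyses assume —
## i.i.d. residue composition with planted C-terminal motif classes,
## genomes with one focal gene and COGs planted near it at a stated
## co-occurrence rate, binary trait tables with stated background
## frequencies, and CDS records whose annotated stop is an in-frame TGA
## standing for Sec.

#' Average SwissProt-like residue composition
#'
#' Background amino-acid frequencies (selenocysteine excluded; it enters
#' sequences only by planting), normalised to sum to 1.  Cysteine sits at
#' about 1.37%, the value conventionally quoted for SwissProt.
#'
#' @return named numeric vector over the 20 standard amino acids.
#' @export
swissprot_freqs <- function() {
  f <- c(A = 0.0826, R = 0.0553, N = 0.0406, D = 0.0546, C = 0.0137,
         Q = 0.0393, E = 0.0674, G = 0.0708, H = 0.0227, I = 0.0593,
         L = 0.0965, K = 0.0582, M = 0.0241, F = 0.0386, P = 0.0472,
         S = 0.0660, T = 0.0535, W = 0.0110, Y = 0.0292, V = 0.0687)
  f / sum(f)
}

## Supported terminal classes and their fixed residues, as positions
## counted from the C-terminus (1 = last residue).  The planting window is
## 14 residues, the span of the widest class C-x(10)-[CU]-x-x>.
terminal_class_spec <- function() {
  list(
    "Cxx>"         = list(fixed = c("3" = "C")),
    "Uxx>"         = list(fixed = c("3" = "U")),
    "CxxCxx>"      = list(fixed = c("6" = "C", "3" = "C")),
    "CxxUxx>"      = list(fixed = c("6" = "C", "3" = "U")),
    "CxCxx>"       = list(fixed = c("5" = "C", "3" = "C")),
    "CxUxx>"       = list(fixed = c("5" = "C", "3" = "U")),
    "Cx(3,10)Cxx>" = list(fixed = c("3" = "C"), range_inner = "C"),
    "Cx(3,10)Uxx>" = list(fixed = c("3" = "U"), range_inner = "U")
  )
}

check_freqs <- function(f, what = "residue_freqs") {
  if (is.null(names(f)) || any(!nzchar(names(f))))
    stop(what, " must be a named frequency vector")
  if (any(f < 0)) stop(what, " must be non-negative")
  if (abs(sum(f) - 1) > 1e-9) stop(what, " must sum to 1 (got ", sum(f), ")")
  invisible(f)
}

#' Generate a synthetic proteome with planted C-terminal motif classes
#'
#' Sequences have i.i.d. residues from `residue_freqs` and lengths uniform
#' on `[length_min, length_max]`.  For each entry of `terminal_spec` the
#' stated fraction of sequences receives a planted conforming C-terminus:
#' the final 14 residues are overwritten with residues drawn from
#' `residue_freqs` excluding C and U (so no accidental second class
#' arises), then the class's fixed Cys/Sec positions are set.
#'
#' @param n_seqs number of sequences.
#' @param length_min,length_max residue length bounds, `length_min >= 14`.
#' @param residue_freqs named residue frequency vector summing to 1.
#' @param terminal_spec named numeric vector: terminal-class label (see
#'   names of `terminal_class_spec()`) to fraction of sequences planted;
#'   fractions must be >= 0 and sum to <= 1.
#' @param seed integer root seed.
#' @return list with `seqs` (named character vector) and `truth`
#'   (data frame `seq_id`, `planted_class`, `"none"` for unplanted).
#' @export
gen_proteome <- function(n_seqs, length_min = 200, length_max = 800,
                         residue_freqs = swissprot_freqs(),
                         terminal_spec = numeric(0), seed = 1) {
  check_freqs(residue_freqs)
  stopifnot(n_seqs >= 0, length_min >= 14, length_max >= length_min)
  spec_names <- names(terminal_spec)
  if (length(terminal_spec)) {
    unknown <- setdiff(spec_names, names(terminal_class_spec()))
    if (length(unknown))
      stop("unknown terminal class in terminal_spec: ", paste(unknown, collapse = ", "))
    if (any(terminal_spec < 0) || sum(terminal_spec) > 1 + 1e-12)
      stop("terminal_spec fractions must be >= 0 and sum to <= 1")
  }
  ids <- sprintf("seq%04d", seq_len(n_seqs))
  withr::with_seed(sub_seed(seed, "proteome"), {
    lens <- if (n_seqs) sample(length_min:length_max, n_seqs, replace = TRUE) else integer(0)
    seqs <- vapply(lens, function(L)
      paste(sample(names(residue_freqs), L, replace = TRUE, prob = residue_freqs),
            collapse = ""), character(1))
    names(seqs) <- ids
    planted <- rep("none", n_seqs)
    if (length(terminal_spec) && n_seqs) {
      n_per <- diff(c(0, round(cumsum(terminal_spec) * n_seqs)))
      pool <- sample(seq_len(n_seqs))
      taken <- 0L
      tail_freqs <- residue_freqs[setdiff(names(residue_freqs), c("C", "U"))]
      tail_freqs <- tail_freqs / sum(tail_freqs)
      cls_spec <- terminal_class_spec()
      for (ci in seq_along(terminal_spec)) {
        nn <- n_per[ci]
        if (nn == 0L) next
        idx <- pool[taken + seq_len(nn)]
        taken <- taken + nn
        label <- spec_names[ci]
        sp <- cls_spec[[label]]
        for (i in idx) {
          tail14 <- sample(names(tail_freqs), 14, replace = TRUE, prob = tail_freqs)
          for (posname in names(sp$fixed))
            tail14[14L - as.integer(posname) + 1L] <- sp$fixed[[posname]]
          if (!is.null(sp$range_inner)) {
            g <- sample(3:10, 1)
            tail14[14L - (g + 4L) + 1L] <- "C"
          }
          seqs[i] <- paste0(substr(seqs[i], 1, lens[i] - 14L),
                            paste(tail14, collapse = ""))
          planted[i] <- label
        }
      }
    }
    list(seqs = seqs,
         truth = data.frame(seq_id = ids, planted_class = planted,
                            stringsAsFactors = FALSE))
  })
}

#' Generate synthetic genome gene tables with planted neighbourhood COGs
#'
#' Each genome is a single linear replicon of `genes_per_genome`
#' non-overlapping genes (lengths gamma-distributed around
#' `gene_len_mean`, exponential intergenic spacers around
#' `intergenic_len_mean`), COG labels drawn uniformly from a vocabulary of
#' `cog_vocab_size`, and exactly one focal gene (carrying `focal_cog`)
#' placed at the middle gene index.  For each entry of `planted`, with the
#' given probability one gene overlapping the focal window
#' (`[mid - half_width, mid + half_width]`) is relabelled with that COG.
#'
#' @param n_genomes number of genomes.
#' @param genes_per_genome genes per replicon (>= 3).
#' @param gene_len_mean,intergenic_len_mean mean lengths in bp.
#' @param cog_vocab_size size of the background COG vocabulary.
#' @param focal_cog label of the focal gene's COG.
#' @param planted named numeric vector: COG label to probability in `[0,1]`
#'   of placement within the focal window.
#' @param half_width focal window half-width in bp.
#' @param seed integer root seed.
#' @return list with `genes` (gene table over all genomes), `truth`
#'   (data frame `genome_id`, `cog`, `planted`), and `genome_lengths`.
#' @export
gen_genome_tables <- function(n_genomes, genes_per_genome = 30,
                              gene_len_mean = 900, intergenic_len_mean = 150,
                              cog_vocab_size = 400, focal_cog = "COG0397",
                              planted = numeric(0), half_width = 11000,
                              seed = 1) {
  stopifnot(n_genomes >= 0, genes_per_genome >= 3, gene_len_mean > 0,
            intergenic_len_mean >= 0, cog_vocab_size >= 1, half_width > 0)
  if (length(planted) && (any(planted < 0) || any(planted > 1)))
    stop("planted probabilities must lie in [0, 1]")
  if (genes_per_genome * (gene_len_mean + intergenic_len_mean) > 2^31 - 1)
    stop("configuration overflows 32-bit genome coordinates")
  vocab <- sprintf("COG%04d", seq_len(cog_vocab_size))
  if (!length(setdiff(vocab, focal_cog)))
    stop("cog_vocab_size leaves no background COG besides the focal one")
  if (n_genomes == 0L)
    return(list(genes = validate_gene_table(
                  data.frame(genome_id = character(), gene_id = character(),
                             start = integer(), end = integer(),
                             strand = character(), cog_id = character(),
                             stringsAsFactors = FALSE)),
                truth = data.frame(genome_id = character(), cog = character(),
                                   planted = logical(), stringsAsFactors = FALSE),
                genome_lengths = numeric(0)))
  withr::with_seed(sub_seed(seed, "genomes"), {
    per_genome <- vector("list", n_genomes)
    truth <- vector("list", n_genomes)
    glen <- numeric(n_genomes)
    for (g in seq_len(n_genomes)) {
      gid <- sprintf("G%03d", g)
      lens <- pmax(90, round(stats::rgamma(genes_per_genome, shape = 9,
                                           scale = gene_len_mean / 9)))
      gaps <- round(stats::rexp(genes_per_genome, 1 / max(intergenic_len_mean, 1e-9)))
      starts <- cumsum(c(1 + gaps[1], lens[-genes_per_genome] + 1 + gaps[-1]))
      ends <- starts + lens - 1
      ## the focal COG is reserved: background genes never draw it, so each
      ## genome carries exactly one focal gene
      cogs <- sample(setdiff(vocab, focal_cog), genes_per_genome, replace = TRUE)
      focal_idx <- ceiling(genes_per_genome / 2)
      cogs[focal_idx] <- focal_cog
      tab <- data.frame(
        genome_id = gid,
        gene_id = sprintf("%s_g%03d", gid, seq_len(genes_per_genome)),
        start = starts, end = ends,
        strand = sample(c("+", "-"), genes_per_genome, replace = TRUE),
        cog_id = cogs, stringsAsFactors = FALSE)
      mid <- floor((starts[focal_idx] + ends[focal_idx]) / 2)
      in_window <- which(starts <= mid + half_width & ends >= mid - half_width)
      eligible <- setdiff(in_window, focal_idx)
      placed <- logical(length(planted))
      if (length(planted)) {
        for (pi in seq_along(planted)) {
          if (stats::runif(1) < planted[pi]) {
            if (!length(eligible))
              stop("no eligible gene left in the focal window to plant ",
                   names(planted)[pi], " in ", gid)
            pick <- if (length(eligible) == 1L) eligible else sample(eligible, 1)
            tab$cog_id[pick] <- names(planted)[pi]
            eligible <- setdiff(eligible, pick)
            placed[pi] <- TRUE
          }
        }
        truth[[g]] <- data.frame(genome_id = gid, cog = names(planted),
                                 planted = placed, stringsAsFactors = FALSE)
      }
      per_genome[[g]] <- tab
      glen[g] <- ends[genes_per_genome] + round(stats::rexp(1, 1 / max(intergenic_len_mean, 1e-9)))
    }
    list(genes = do.call(rbind, per_genome),
         truth = if (length(planted)) do.call(rbind, truth) else
           data.frame(genome_id = character(), cog = character(),
                      planted = logical(), stringsAsFactors = FALSE),
         genome_lengths = stats::setNames(glen, sprintf("G%03d", seq_len(n_genomes))))
  })
}

#' Generate a synthetic binary trait table with an enriched subset
#'
#' Organisms carry 0/1 traits drawn independently: traits listed in
#' `enriched` occur at their enriched frequency within a designated random
#' subset of `subset_size` organisms and at the background frequency
#' elsewhere; all other traits occur at background frequency throughout.
#'
#' @param n_orgs number of organisms.
#' @param trait_freqs named background frequencies in `[0, 1]`.
#' @param enriched named frequencies within the subset; names must appear
#'   in `trait_freqs`.
#' @param subset_size size of the designated subset (`<= n_orgs`).
#' @param seed integer root seed.
#' @return list with `table` (data frame `organism_id` + trait columns),
#'   `subset` (the designated organism ids).
#' @export
gen_trait_table <- function(n_orgs, trait_freqs, enriched = numeric(0),
                            subset_size = 0, seed = 1) {
  stopifnot(n_orgs >= 0, subset_size >= 0, subset_size <= n_orgs)
  if (any(trait_freqs < 0 | trait_freqs > 1))
    stop("trait frequencies must lie in [0, 1]")
  unknown <- setdiff(names(enriched), names(trait_freqs))
  if (length(unknown))
    stop("enriched trait(s) absent from trait_freqs: ", paste(unknown, collapse = ", "))
  if (length(enriched) && any(enriched < 0 | enriched > 1))
    stop("enriched frequencies must lie in [0, 1]")
  ids <- sprintf("org%04d", seq_len(n_orgs))
  withr::with_seed(sub_seed(seed, "traits"), {
    subset <- sort(sample(ids, subset_size))
    tab <- data.frame(organism_id = ids, stringsAsFactors = FALSE)
    for (tr in names(trait_freqs)) {
      p <- rep(trait_freqs[[tr]], n_orgs)
      if (tr %in% names(enriched)) p[ids %in% subset] <- enriched[[tr]]
      tab[[tr]] <- as.integer(stats::runif(n_orgs) < p)
    }
    list(table = tab, subset = subset)
  })
}

## Inverse genetic code: amino acid -> codons (standard code).
codons_for <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc == aa]
}

#' Generate CDS records with planted Sec stop-codon misannotations
#'
#' Emulates a protein family with a conserved `[CU]-x-x>` terminus.  Every
#' full-length protein ends with C or U at position -3; a `sec_fraction`
#' of records carries Sec (U) there, encoded by TGA, and is annotated
#' truncated: the annotated CDS stops at that TGA and the 3-residue tail
#' (U + 2 residues) lies beyond it, followed by a genuine TAA/TAG stop.
#' Unflagged records end with a TAA/TAG stop and an intact C-x-x terminus.
#' The generator also emits the gapped C-terminal alignment of the
#' annotated proteins (truncated rows end three columns short) that the
#' detector consumes.
#'
#' @param n_proteins number of records.
#' @param sec_fraction fraction of records with the planted misannotation.
#' @param tail_len residues of the rescued tail (only the `Uxx>` geometry,
#'   `tail_len = 3`, is generated).
#' @param seed integer root seed.
#' @return list with `proteins` (annotated, possibly truncated, named
#'   character), `cds` (data frame `protein_id`, `nt`, `cds_len`),
#'   `alignment` (named gapped rows, width 10), and `truth`
#'   (data frame `protein_id`, `is_sec`).
#' @export
gen_readthrough_cds <- function(n_proteins, sec_fraction = 0, tail_len = 3,
                                seed = 1) {
  stopifnot(n_proteins >= 0, sec_fraction >= 0, sec_fraction <= 1)
  if (tail_len != 3L)
    stop("only the Uxx> rescue geometry (tail_len = 3) is supported")
  ids <- sprintf("prot%04d", seq_len(n_proteins))
  aa_pool <- setdiff(AA20, "C")   # terminal-block residues; C reserved for -3
  withr::with_seed(sub_seed(seed, "readthrough"), {
    n_sec <- round(sec_fraction * n_proteins)
    is_sec <- rep(FALSE, n_proteins)
    if (n_sec) is_sec[sample(seq_len(n_proteins), n_sec)] <- TRUE
    proteins <- character(n_proteins)
    aln <- character(n_proteins)
    cds <- vector("list", n_proteins)
    for (i in seq_len(n_proteins)) {
      core_len <- sample(80:120, 1)
      core <- sample(AA20, core_len, replace = TRUE)
      block <- sample(aa_pool, 10, replace = TRUE)   # true residues -10..-1
      block[8] <- if (is_sec[i]) "U" else "C"        # position -3
      true_prot <- c(core, block)
      L <- length(true_prot)
      codon1 <- function(a) {
        cs <- codons_for(a)
        cs[sample.int(length(cs), 1)]
      }
      if (is_sec[i]) {
        annotated <- true_prot[seq_len(L - 3L)]
        nt <- paste0(paste(vapply(annotated, codon1, character(1)), collapse = ""),
                     "TGA",
                     codon1(true_prot[L - 1L]), codon1(true_prot[L]),
                     sample(c("TAA", "TAG"), 1),
                     paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE), collapse = ""))
        cds_len <- 3L * (length(annotated) + 1L)
        aln[i] <- paste0(paste(block[1:7], collapse = ""), "---")
      } else {
        annotated <- true_prot
        nt <- paste0(paste(vapply(annotated, codon1, character(1)), collapse = ""),
                     sample(c("TAA", "TAG"), 1),
                     paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE), collapse = ""))
        cds_len <- 3L * (length(annotated) + 1L)
        aln[i] <- paste(block, collapse = "")
      }
      proteins[i] <- paste(annotated, collapse = "")
      cds[[i]] <- data.frame(protein_id = ids[i], nt = nt, cds_len = cds_len,
                             stringsAsFactors = FALSE)
    }
    names(proteins) <- ids
    names(aln) <- ids
    list(proteins = proteins,
         cds = if (n_proteins) do.call(rbind, cds) else
           data.frame(protein_id = character(), nt = character(),
                      cds_len = integer(), stringsAsFactors = FALSE),
         alignment = aln,
         truth = data.frame(protein_id = ids, is_sec = is_sec,
                            stringsAsFactors = FALSE))
  })
}

#' Generate clustered protein families for redundancy-reduction tests
#'
#' `n_clusters` random centroid sequences; each cluster member is the
#' centroid with an independent `within_mut` fraction of positions mutated
#' to a different residue, so within-cluster identity concentrates near
#' `100 * (1 - within_mut)` percent while between-cluster identity stays at
#' the random-alignment baseline.
#'
#' @param n_clusters number of planted clusters.
#' @param per_cluster members per cluster (the centroid is member 1).
#' @param len sequence length in residues.
#' @param within_mut per-position mutation probability within a cluster.
#' @param seed integer root seed.
#' @return list with `seqs` (named character) and `truth`
#'   (data frame `seq_id`, `cluster`).
#' @export
gen_protein_clusters <- function(n_clusters = 10, per_cluster = 5, len = 60,
                                 within_mut = 0.1, seed = 1) {
  stopifnot(n_clusters >= 1, per_cluster >= 1, len >= 14,
            within_mut >= 0, within_mut <= 1)
  withr::with_seed(sub_seed(seed, "clusters"), {
    seqs <- character(0)
    truth <- list()
    for (k in seq_len(n_clusters)) {
      centroid <- sample(AA20, len, replace = TRUE)
      for (m in seq_len(per_cluster)) {
        s <- centroid
        if (m > 1L) {
          mut <- which(stats::runif(len) < within_mut)
          for (pos in mut)
            s[pos] <- sample(setdiff(AA20, s[pos]), 1)
        }
        id <- sprintf("clust%02d_m%02d", k, m)
        seqs[id] <- paste(s, collapse = "")
        truth[[id]] <- data.frame(seq_id = id, cluster = k,
                                  stringsAsFactors = FALSE)
      }
    }
    list(seqs = seqs, truth = do.call(rbind, truth))
  })
}
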