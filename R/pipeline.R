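## Pipeline orchestration: presence summaries, stage wiring, manifests.

#' Summarise homologue presence per domain of life
#'
#' @param counts data frame with columns `label`, `with_homolog`, `total`.
#' @return data frame with an added `percent` column: integer percentages
#'   rounded half-up (so 79/121 prints as 65, 1101/2780 as 40, 3/107 as 3).
#' @examples
#' summarize_presence(data.frame(label = "Eukaryota", with_homolog = 79, total = 121))
#' @export
summarize_presence <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("label", "with_homolog", "total") %in% names(counts)))
  if (any(counts$total <= 0)) stop("totals must be positive")
  if (any(counts$with_homolog < 0 | counts$with_homolog > counts$total))
    stop("need 0 <= with_homolog <= total")
  ## half-up integer rounding (round() in R rounds half to even)
  counts$percent <- floor(100 * counts$with_homolog / counts$total + 0.5)
  counts
}

#' Run the full analysis pipeline over a configuration
#'
#' Stages run for whichever inputs the configuration names; outputs and a
#' machine-readable manifest of all resolved parameters are written under
#' `outdir`.  All input paths are validated before any output is written,
#' so a missing input leaves no partial results.  Given the same
#' configuration and seed the output files are byte-identical across runs.
#'
#' @param config a named list, or the path to a YAML file holding one.
#'   Recognised fields: `outdir` (required); inputs `proteins` (FASTA),
#'   `gene_table`, `ref_gene_table`, `trait_table`, `selected_organisms`
#'   (one id per line), `cds` (data frame inputs may also be passed
#'   in-memory), `alignment` (aligned FASTA of C-termini), `newick`;
#'   parameters `seed`, `threshold_pct`, `half_width`, `focal_cog`,
#'   `background_mode`, `mc_reps`, `m_tested`, `trait_backgrounds`
#'   (named list).
#' @return (invisibly) the summary list, also written as `summary.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$outdir))
  cfg <- utils::modifyList(list(seed = 1, threshold_pct = 70,
                                half_width = 11000, focal_cog = "COG0397",
                                background_mode = "poisson", mc_reps = 10000,
                                m_tested = NULL), config)
  path_fields <- c("proteins", "gene_table", "ref_gene_table", "trait_table",
                   "selected_organisms", "cds_table", "cds_proteins",
                   "alignment", "newick")
  for (f in path_fields) {
    p <- cfg[[f]]
    if (!is.null(p) && is.character(p) && !file.exists(p))
      stop("pipeline input '", f, "' not found: ", p)
  }
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(cfg$outdir, name)
  summary <- list(seed = cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  manifest <- cfg[order(names(cfg))]
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")

  if (!is.null(cfg$proteins)) {
    seqs <- stage("motif-scan", read_fasta(cfg$proteins, "AA"))
    cen <- stage("motif-scan", census(seqs))
    utils::write.table(cen$classes, out("classification.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(cen$pattern_counts, out("census.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$n_seqs <- cen$n
    summary$inner_ring <- as.list(stats::setNames(as.integer(cen$class_counts),
                                                  names(cen$class_counts)))
    summary$pattern_counts <- as.list(stats::setNames(cen$pattern_counts$k,
                                                      cen$pattern_counts$pattern))
    if (!is.null(cfg$newick))
      stage("itol", write_itol_classes(cen$classes, out("itol_classes.txt"),
                                       newick = cfg$newick))

    rs <- stage("repset", greedy_reduce(seqs, cfg$threshold_pct))
    write_fasta(seqs[rs$representatives], out("repset.fasta"), "AA")
    utils::write.table(rs$membership, out("repset_membership.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$n_representatives <- length(rs$representatives)
  }

  if (!is.null(cfg$gene_table)) {
    genes <- stage("neighborhood", read_gene_table(cfg$gene_table))
    refg <- if (!is.null(cfg$ref_gene_table))
      stage("neighborhood", read_gene_table(cfg$ref_gene_table)) else genes
    cenw <- stage("neighborhood",
                  neighbourhood_census(genes, cfg$focal_cog, cfg$half_width))
    bg <- stage("neighborhood",
                estimate_background(refg, cfg$half_width,
                                    mode = cfg$background_mode,
                                    reps = cfg$mc_reps, seed = cfg$seed))
    enr <- stage("neighborhood",
                 suppressWarnings(cog_enrichment(cenw, bg, cfg$m_tested)))
    write_enrichment(enr, out("neighbourhood_enrichment.tsv"))
    summary$n_windows <- cenw$n_windows
    summary$top_cog <- if (nrow(enr)) enr$label[1] else NA
    summary$top_cog_log10_p_corrected <- if (nrow(enr)) enr$log10_p_corrected[1] else NA
  }

  if (!is.null(cfg$trait_table) && !is.null(cfg$trait_backgrounds)) {
    traits <- stage("lifestyle", read_trait_table(cfg$trait_table))
    selected <- if (!is.null(cfg$selected_organisms))
      readLines(cfg$selected_organisms) else traits$organism_id
    lrows <- stage("lifestyle",
                   trait_enrichment(traits, selected,
                                    unlist(cfg$trait_backgrounds)))
    write_enrichment(lrows, out("lifestyle_enrichment.tsv"))
    summary$top_trait <- lrows$label[1]
    summary$top_trait_log10_p <- lrows$log10_p_raw[1]
  }

  if (!is.null(cfg$cds_table) && !is.null(cfg$alignment) &&
      !is.null(cfg$cds_proteins)) {
    cds <- stage("sec-rescue", utils::read.delim(cfg$cds_table,
                                                 stringsAsFactors = FALSE))
    ## gapped rows: Biostrings reads '-' fine in an AAStringSet
    aln_rows <- chartr(".", "-", stage("sec-rescue",
                                       read_fasta(cfg$alignment, "AA")))
    aln <- stage("sec-rescue", terminus_alignment(aln_rows))
    prot <- stage("sec-rescue", read_fasta(cfg$cds_proteins, "AA"))
    calls <- stage("sec-rescue", sec_recovery_scan(prot, cds, aln))
    utils::write.table(calls, out("sec_calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    rescued <- calls[calls$verdict == "LIKELY_SEC", , drop = FALSE]
    if (nrow(rescued))
      write_fasta(stats::setNames(rescued$extended_protein, rescued$protein_id),
                  out("rescued_proteins.fasta"), "AA")
    summary$n_rescued <- nrow(rescued)
  }

  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(summary)
}

#' Write a complete synthetic input bundle for the pipeline
#'
#' Generates a proteome with planted terminal classes, genome gene tables
#' with a planted neighbourhood COG, a trait table with an enriched subset,
#' and readthrough CDS records, all under one root seed, and writes them in
#' the formats [run_pipeline()] consumes, with ground-truth sidecar TSVs.
#'
#' @param dir output directory.
#' @param seed integer root seed.
#' @param n_seqs,n_genomes,n_orgs,n_cds sizes of each component.
#' @return (invisibly) the list of written paths.
#' @export
simulate_inputs <- function(dir, seed = 1, n_seqs = 60, n_genomes = 40,
                            n_orgs = 300, n_cds = 40) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(name) file.path(dir, name)
  prot <- gen_proteome(n_seqs, length_min = 120, length_max = 400,
                       terminal_spec = c("Cxx>" = 0.3, "CxxUxx>" = 0.1,
                                         "CxxCxx>" = 0.1),
                       seed = seed)
  write_fasta(prot$seqs, p("proteins.fasta"), "AA")
  utils::write.table(prot$truth, p("proteins_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gen <- gen_genome_tables(n_genomes, planted = c(COG0009 = 0.9), seed = seed)
  write_gene_table(gen$genes, p("genes.tsv"))
  utils::write.table(gen$truth, p("genes_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ref <- gen_genome_tables(n_genomes, seed = seed + 1)
  write_gene_table(ref$genes, p("ref_genes.tsv"))
  tr <- gen_trait_table(n_orgs, trait_freqs = c(aquatic = 0.16, aerobic = 0.32),
                        enriched = c(aquatic = 0.47),
                        subset_size = max(1, round(n_orgs / 3)), seed = seed)
  write_trait_table(tr$table, p("traits.tsv"))
  writeLines(tr$subset, p("selected_organisms.txt"))
  rt <- gen_readthrough_cds(n_cds, sec_fraction = 6 / 143, seed = seed)
  write_fasta(rt$proteins, p("cds_proteins.fasta"), "AA")
  utils::write.table(rt$cds, p("cds.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_fasta(rt$alignment, p("cds_termini.aln.fasta"), "AA")
  utils::write.table(rt$truth, p("cds_truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(dir = dir,
                 paths = list(proteins = p("proteins.fasta"),
                              gene_table = p("genes.tsv"),
                              ref_gene_table = p("ref_genes.tsv"),
                              trait_table = p("traits.tsv"),
                              selected_organisms = p("selected_organisms.txt"),
                              cds_table = p("cds.tsv"),
                              cds_proteins = p("cds_proteins.fasta"),
                              alignment = p("cds_termini.aln.fasta"))))
}
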