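## Genomic-neighbourhood extraction and COG enrichment.
##
## Windows of fixed half-width (default 11 kbp in both directions, i.e. a
## 22 kbp window) are anchored at the midpoint of each focal gene; a gene
## belongs to the window when its interval overlaps it.  Enrichment is
## presence/absence per window against a per-COG background window
## probability estimated from reference genomes.

validate_gene_table <- function(genes) {
  need <- c("genome_id", "gene_id", "start", "end")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("gene table lacks columns: ", paste(miss, collapse = ", "))
  if (!"strand" %in% names(genes)) genes$strand <- "+"
  if (!"cog_id" %in% names(genes)) genes$cog_id <- NA_character_
  genes$cog_id[!is.na(genes$cog_id) & genes$cog_id == ""] <- NA_character_
  if (any(genes$start < 1 | genes$end < genes$start))
    stop("gene coordinates must be 1-based inclusive with start <= end")
  genes
}

#' Extract the genomic neighbourhood of a focal gene
#'
#' The window is `[mid - half_width, mid + half_width]` around the focal
#' gene's midpoint; members are the genes of the same genome whose interval
#' overlaps the window (by at least 1 bp), the focal gene itself excluded.
#' Strand is ignored.
#'
#' @param genes gene table (`genome_id`, `gene_id`, `start`, `end`,
#'   optional `strand`, `cog_id`), 1-based inclusive coordinates.
#' @param focal_gene_id identifier of the focal gene.
#' @param half_width window half-width in bp (default 11000, a 22 kbp
#'   window).
#' @return the member rows of `genes`; the window bounds are attached as
#'   the `window` attribute.
#' @export
extract_neighbourhood <- function(genes, focal_gene_id, half_width = 11000) {
  genes <- validate_gene_table(genes)
  stopifnot(half_width > 0)
  hit <- which(genes$gene_id == focal_gene_id)
  if (length(hit) != 1L)
    stop("focal gene '", focal_gene_id, "' not found (or not unique) in the gene table")
  focal <- genes[hit, ]
  g <- genes[genes$genome_id == focal$genome_id, , drop = FALSE]
  mid <- floor((focal$start + focal$end) / 2)
  lo <- mid - half_width
  hi <- mid + half_width
  member <- g$start <= hi & g$end >= lo & g$gene_id != focal_gene_id
  out <- g[member, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "window") <- c(lo = lo, hi = hi, mid = mid)
  out
}

#' Census COG presence across focal-gene neighbourhoods
#'
#' One window per focal gene (genes carrying `focal_cog`); for every COG,
#' `k` counts the windows containing at least one gene of that COG —
#' presence, not gene count, so duplicated neighbours never inflate the
#' census.  Genomes without a focal gene are skipped with a warning.
#'
#' @param genes gene table covering one or more genomes.
#' @param focal_cog COG label identifying focal genes.
#' @param half_width window half-width in bp.
#' @param exclude_focal_cog drop the focal gene's own COG from the census
#'   (default TRUE, avoiding trivial self-enrichment).
#' @return object of class `window_census`: list with `n_windows`, `counts`
#'   (named integer vector of per-COG presence counts), `focal_cog`,
#'   `half_width`.
#' @export
neighbourhood_census <- function(genes, focal_cog, half_width = 11000,
                                 exclude_focal_cog = TRUE) {
  genes <- validate_gene_table(genes)
  genomes <- unique(genes$genome_id)
  no_focal <- genomes[!genomes %in%
                        unique(genes$genome_id[!is.na(genes$cog_id) &
                                                 genes$cog_id == focal_cog])]
  if (length(no_focal))
    warning(length(no_focal), " genome(s) without a focal '", focal_cog,
            "' gene skipped: ", paste(utils::head(no_focal, 5), collapse = ", "))
  focal_rows <- which(!is.na(genes$cog_id) & genes$cog_id == focal_cog)
  counts <- integer(0)
  n_windows <- 0L
  for (i in focal_rows) {
    nb <- extract_neighbourhood(genes, genes$gene_id[i], half_width)
    n_windows <- n_windows + 1L
    cogs <- unique(nb$cog_id[!is.na(nb$cog_id)])
    if (exclude_focal_cog) cogs <- setdiff(cogs, focal_cog)
    for (cg in cogs) counts[cg] <- if (cg %in% names(counts)) counts[[cg]] + 1L else 1L
  }
  if (length(counts)) counts <- counts[order(names(counts))]
  structure(list(n_windows = n_windows, counts = counts,
                 focal_cog = focal_cog, half_width = half_width),
            class = "window_census")
}

#' @export
print.window_census <- function(x, ...) {
  cat("neighbourhood census:", x$n_windows, "windows of",
      2 * x$half_width / 1000, "kbp around", x$focal_cog, "-",
      length(x$counts), "distinct COGs\n")
  invisible(x)
}

#' Estimate per-COG background window-presence probabilities
#'
#' Probability that a random genomic window of width `2 * half_width`
#' contains at least one gene of each COG, from reference genomes.
#' `poisson` mode uses the closed form `p_c = 1 - exp(-lambda_c)` with
#' `lambda_c = n_c * W / L_total` (COG gene density times window width);
#' `montecarlo` mode drops `reps` seeded random windows (uniform over the
#' concatenated replicons, truncated at replicon ends) and reports the
#' empirical presence fraction.
#'
#' @param ref_genes reference gene table.
#' @param half_width window half-width in bp.
#' @param mode `"poisson"` or `"montecarlo"`.
#' @param reps number of random windows for Monte-Carlo mode.
#' @param seed integer seed for Monte-Carlo mode.
#' @param genome_lengths optional named vector of replicon lengths; by
#'   default the maximum gene end per genome.
#' @return object of class `cog_background`: list with `p` (named per-COG
#'   probabilities), `mode`, `n_genomes`.
#' @export
estimate_background <- function(ref_genes, half_width = 11000,
                                mode = c("poisson", "montecarlo"),
                                reps = 10000, seed = 1, genome_lengths = NULL) {
  mode <- match.arg(mode)
  ref_genes <- validate_gene_table(ref_genes)
  genomes <- unique(ref_genes$genome_id)
  if (!length(genomes)) stop("empty reference genome set")
  if (is.null(genome_lengths)) {
    genome_lengths <- vapply(split(ref_genes$end, ref_genes$genome_id), max, numeric(1))
  }
  genome_lengths <- genome_lengths[genomes]
  W <- 2 * half_width
  ann <- ref_genes[!is.na(ref_genes$cog_id), , drop = FALSE]
  all_cogs <- sort(unique(ann$cog_id))

  if (mode == "poisson") {
    n_c <- table(ann$cog_id)
    lambda <- as.numeric(n_c) * W / sum(genome_lengths)
    p <- stats::setNames(1 - exp(-lambda), names(n_c))
    p <- p[all_cogs]
  } else {
    p <- withr::with_seed(as.integer(seed), {
      gsel <- sample(seq_along(genomes), reps, replace = TRUE,
                     prob = genome_lengths / sum(genome_lengths))
      centers <- floor(stats::runif(reps, min = 1, max = genome_lengths[gsel] + 1))
      hit_keys <- vector("list", length(genomes))
      cog_index <- stats::setNames(seq_along(all_cogs), all_cogs)
      for (gi in seq_along(genomes)) {
        in_g <- which(gsel == gi)
        if (!length(in_g)) next
        cs <- centers[in_g]
        o <- order(cs)
        cs_sorted <- cs[o]
        gg <- ann[ann$genome_id == genomes[gi], , drop = FALSE]
        if (!nrow(gg)) next
        keys <- vector("list", nrow(gg))
        for (r in seq_len(nrow(gg))) {
          ## window centers whose [c-hw, c+hw] overlaps gene [s, e]
          i1 <- findInterval(gg$start[r] - half_width - 0.5, cs_sorted) + 1L
          i2 <- findInterval(gg$end[r] + half_width + 0.5, cs_sorted)
          if (i1 > i2) next
          reps_idx <- in_g[o][i1:i2]
          keys[[r]] <- reps_idx * (length(all_cogs) + 1) + cog_index[[gg$cog_id[r]]]
        }
        hit_keys[[gi]] <- unlist(keys)
      }
      keys <- unique(unlist(hit_keys))
      ci <- keys %% (length(all_cogs) + 1)
      tab <- tabulate(ci, nbins = length(all_cogs))
      stats::setNames(tab / reps, all_cogs)
    })
  }
  structure(list(p = p, mode = mode, n_genomes = length(genomes),
                 half_width = half_width, reps = if (mode == "montecarlo") reps else NA),
            class = "cog_background")
}

#' COG enrichment of focal-gene neighbourhoods
#'
#' Per COG observed in the windows, the raw upper-tail probability is
#' `log10_binomial_tail(k, n_windows, p_c)` with `p_c` the background
#' window-presence probability, Bonferroni-corrected over `m_tested`
#' hypotheses (default: the number of distinct COGs censused).  COGs with
#' zero or missing background are reported unscored with a warning.
#'
#' @param census a `window_census`.
#' @param bg a `cog_background` (or named probability vector).
#' @param m_tested Bonferroni factor; defaults to the number of censused COGs.
#' @return `enrichment_rows` data frame sorted by corrected p-value.
#' @export
cog_enrichment <- function(census, bg, m_tested = NULL) {
  stopifnot(inherits(census, "window_census"))
  pvec <- if (inherits(bg, "cog_background")) bg$p else bg
  cogs <- names(census$counts)
  if (is.null(m_tested)) m_tested <- length(cogs)
  if (length(cogs) && m_tested < length(cogs))
    stop("m_tested must be at least the number of censused COGs")
  n <- census$n_windows
  p_c <- ifelse(cogs %in% names(pvec), pvec[cogs], 0)
  unscored <- cogs[p_c == 0 | is.na(p_c)]
  if (length(unscored))
    warning(length(unscored), " COG(s) with zero/unknown background left unscored: ",
            paste(utils::head(unscored, 5), collapse = ", "))
  lp <- vapply(seq_along(cogs), function(i) {
    if (is.na(p_c[i]) || p_c[i] == 0) return(NA_real_)
    if (p_c[i] >= 1) return(0)
    log10_binomial_tail(census$counts[[i]], n, p_c[i])
  }, numeric(1))
  out <- data.frame(label = cogs, k = as.integer(census$counts), n = n,
                    p_bg = as.numeric(p_c), log10_p_raw = lp,
                    log10_p_corrected = bonferroni_log10(lp, max(m_tested, 1)),
                    m_tested = m_tested, stringsAsFactors = FALSE)
  out <- out[order(out$log10_p_corrected, out$log10_p_raw, out$label), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_rows", class(out))
  out
}
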