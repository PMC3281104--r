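make_genes <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(genome_id = r[[1]], gene_id = r[[2]], start = as.integer(r[[3]]),
               end = as.integer(r[[4]]), strand = "+",
               cog_id = if (length(r) >= 5) r[[5]] else NA_character_,
               stringsAsFactors = FALSE)))
}

test_that("window extraction uses midpoint anchoring and 1-bp overlap", {
  genes <- make_genes(
    list("G1", "focal", 20000, 21000, "COG0397"),  # midpoint 20500
    list("G1", "inside", 15000, 15500, "COG0001"),
    list("G1", "edge", 8000, 9500, "COG0002"),     # window lo = 9500: 1 bp overlap
    list("G1", "out", 8000, 9499, "COG0003"),      # ends 1 bp short of the window
    list("G1", "far", 40000, 41000, "COG0004"))
  nb <- extract_neighbourhood(genes, "focal", half_width = 11000)
  expect_setequal(nb$gene_id, c("inside", "edge"))
  w <- attr(nb, "window")
  expect_equal(unname(w["lo"]), 9500)
  expect_equal(unname(w["hi"]), 31500)
  expect_error(extract_neighbourhood(genes, "nope"), "not found")
})

test_that("window membership equals a brute-force interval-overlap check", {
  withr::local_seed(17)
  for (rep in 1:20) {
    n <- 40
    starts <- sort(sample(1:60000, n))
    genes <- data.frame(genome_id = "G1", gene_id = paste0("g", 1:n),
                        start = starts, end = starts + sample(100:2000, n, TRUE),
                        strand = "+", cog_id = paste0("COG", 1:n),
                        stringsAsFactors = FALSE)
    focal <- sample(genes$gene_id, 1)
    hw <- sample(c(2000, 5000, 11000), 1)
    nb <- extract_neighbourhood(genes, focal, hw)
    frow <- genes[genes$gene_id == focal, ]
    mid <- floor((frow$start + frow$end) / 2)
    brute <- genes$gene_id[pmax(genes$start, mid - hw) <= pmin(genes$end, mid + hw) &
                             genes$gene_id != focal]
    expect_setequal(nb$gene_id, brute)
  }
})

test_that("census counts COG presence per window, not gene copies", {
  g <- gen_genome_tables(8, planted = c(COG0009 = 1.0), seed = 4)
  cen <- neighbourhood_census(g$genes, "COG0397")
  expect_identical(cen$n_windows, 8L)
  expect_identical(cen$counts[["COG0009"]], 8L)

  # duplicating a member gene of an already-present COG never changes k
  dup_row <- g$genes[g$genes$cog_id == "COG0009", ][1, ]
  dup_row$gene_id <- paste0(dup_row$gene_id, "_dup")
  dup_row$start <- dup_row$start + 1; dup_row$end <- dup_row$end + 1
  cen2 <- neighbourhood_census(rbind(g$genes, dup_row), "COG0397")
  expect_identical(cen2$counts[["COG0009"]], cen$counts[["COG0009"]])

  # census equals a per-window brute-force recount
  brute <- integer(0)
  for (fg in g$genes$gene_id[g$genes$cog_id == "COG0397"]) {
    nb <- extract_neighbourhood(g$genes, fg)
    for (cg in setdiff(unique(na.omit(nb$cog_id)), "COG0397"))
      brute[cg] <- if (cg %in% names(brute)) brute[[cg]] + 1L else 1L
  }
  expect_identical(cen$counts, brute[order(names(brute))])

  # genomes without focal gene are skipped with a warning
  g2 <- g$genes[g$genes$cog_id != "COG0397" | g$genes$genome_id != "G001", ]
  expect_warning(cen3 <- neighbourhood_census(g2, "COG0397"), "skipped")
  expect_identical(cen3$n_windows, 7L)

  # empty annotations: windows exist, census has no COGs
  g3 <- g$genes
  g3$cog_id[g3$cog_id != "COG0397"] <- NA
  cen4 <- neighbourhood_census(g3, "COG0397")
  expect_identical(length(cen4$counts), 0L)
  expect_identical(cen4$n_windows, 8L)
})

test_that("poisson background matches the closed form and flags absent COGs", {
  # density tuned so lambda = ln 2 gives p = 1/2 exactly
  W <- 22000
  L <- W / log(2)
  genes <- make_genes(list("G1", "g1", 1000, 1500, "COGX"))
  bg <- estimate_background(genes, half_width = 11000, mode = "poisson",
                            genome_lengths = c(G1 = L))
  expect_equal(unname(bg$p["COGX"]), 0.5, tolerance = 1e-12)

  # a COG absent from the references gets background 0 and is left unscored
  cen <- structure(list(n_windows = 5L, counts = c(COGY = 3L),
                        focal_cog = "F", half_width = 11000),
                   class = "window_census")
  expect_warning(rows <- cog_enrichment(cen, bg), "unscored")
  expect_true(is.na(rows$log10_p_raw[rows$label == "COGY"]))

  expect_error(estimate_background(genes[0, ]), "empty reference")
})

test_that("poisson and Monte-Carlo backgrounds agree on uniform synthetic genomes", {
  g <- gen_genome_tables(30, genes_per_genome = 60, cog_vocab_size = 50, seed = 21)
  po <- estimate_background(g$genes, genome_lengths = g$genome_lengths)
  reps <- 4e4
  mc <- estimate_background(g$genes, mode = "montecarlo", reps = reps, seed = 99,
                            genome_lengths = g$genome_lengths)
  common <- intersect(names(po$p), names(mc$p))
  expect_gt(length(common), 40)
  se <- sqrt(pmax(mc$p[common] * (1 - mc$p[common]), 1e-6) / reps)
  ## Monte-Carlo windows truncate at replicon ends, the closed form does not;
  ## allow that systematic edge deficit (window/genome ~ a few percent) on top
  ## of 3 SE.
  edge_bias <- po$p[common] * (22000 / mean(g$genome_lengths))
  agree <- abs(po$p[common] - mc$p[common]) <= 3 * se + edge_bias
  expect_gt(mean(agree), 0.95)
})

test_that("enrichment is ranked, order-invariant, and null at k = 0", {
  g <- gen_genome_tables(40, planted = c(COG0009 = 0.9), seed = 11)
  ref <- gen_genome_tables(60, seed = 12)
  cen <- neighbourhood_census(g$genes, "COG0397")
  bg <- estimate_background(ref$genes, genome_lengths = ref$genome_lengths)
  rows <- suppressWarnings(cog_enrichment(cen, bg))
  expect_identical(rows$label[1], "COG0009")

  # invariance to genome input order
  shuf <- g$genes[sample(nrow(g$genes)), ]
  cen_s <- neighbourhood_census(shuf, "COG0397")
  rows_s <- suppressWarnings(cog_enrichment(cen_s, bg))
  expect_identical(rows_s$label, rows$label)
  expect_equal(rows_s$log10_p_raw, rows$log10_p_raw)

  # all-absent census: every raw p is 1
  cen0 <- structure(list(n_windows = 10L, counts = c(COG0001 = 0L),
                         focal_cog = "COG0397", half_width = 11000),
                    class = "window_census")
  bg0 <- structure(list(p = c(COG0001 = 0.3), mode = "poisson", n_genomes = 1),
                   class = "cog_background")
  expect_identical(cog_enrichment(cen0, bg0)$log10_p_raw, 0)
})

test_that("focal-window COG presence without planting sits at its background rate", {
  # Monte-Carlo oracle: presence probability of one COG in full-width
  # windows dropped uniformly over the same genomes
  g <- gen_genome_tables(300, genes_per_genome = 60, cog_vocab_size = 50,
                         planted = c(COG0009 = 0.0), seed = 303)
  cen <- neighbourhood_census(g$genes, "COG0397")
  k <- if ("COG0009" %in% names(cen$counts)) cen$counts[["COG0009"]] else 0L
  hw <- 11000
  withr::local_seed(55)
  R <- 20000
  gl <- g$genome_lengths
  gi <- sample(seq_along(gl), R, replace = TRUE, prob = gl / sum(gl))
  centers <- floor(runif(R, hw, gl[gi] - hw))
  hitn <- 0L
  target <- g$genes[g$genes$cog_id == "COG0009", ]
  by_gen <- split(target, target$genome_id)
  for (r in seq_len(R)) {
    tg <- by_gen[[names(gl)[gi[r]]]]
    if (!is.null(tg) && any(tg$start <= centers[r] + hw & tg$end >= centers[r] - hw))
      hitn <- hitn + 1L
  }
  p_hat <- hitn / R
  lo <- qbinom(0.005, cen$n_windows, p_hat)
  hi <- qbinom(0.995, cen$n_windows, p_hat)
  # widen by the Monte-Carlo uncertainty of p_hat itself
  slack <- ceiling(3 * cen$n_windows * sqrt(p_hat * (1 - p_hat) / R)) + 2
  expect_gte(k, lo - slack)
  expect_lte(k, hi + slack)
})
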