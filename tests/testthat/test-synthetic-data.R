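test_that("simulated genomes hit the requested GC fraction and are seed-reproducible", {
  cfg <- sim_config(seed = 1, n_chrom = 1, chrom_length = 5e4, gc_fraction = 0.5,
                    control_length = 0)
  g <- simulate_genome(cfg)
  expect_equal(length(g), 1L)
  expect_equal(Biostrings::width(g), 50000L)
  freq <- Biostrings::alphabetFrequency(g[[1]], as.prob = TRUE)
  expect_gte(sum(freq[c("C", "G")]), 0.48)
  expect_lte(sum(freq[c("C", "G")]), 0.52)
  g2 <- simulate_genome(cfg)
  expect_identical(as.character(g), as.character(g2))

  pure <- simulate_genome(sim_config(seed = 2, n_chrom = 1, chrom_length = 2000,
                                     gc_fraction = 1, control_length = 0))
  expect_true(all(strsplit(as.character(pure[[1]]), "")[[1]] %in% c("G", "C")))

  expect_error(sim_config(chrom_length = -5), "chrom_length")
})

test_that("simulated annotations are disjoint, flanked, stranded, with valid exons", {
  cfg <- sim_config(seed = 3, n_chrom = 1, chrom_length = 1e5, n_genes = 10,
                    control_length = 0)
  ann <- simulate_annotation(simulate_genome(cfg), cfg)
  g <- ann$genes
  expect_equal(length(g), 10L)
  expect_true(all(GenomicRanges::start(g) > 2000))
  expect_true(all(GenomicRanges::end(g) <= 1e5 - 2000))
  expect_equal(sum(GenomicRanges::countOverlaps(g, g)), 10L)  # only self-overlaps
  expect_setequal(as.character(unique(GenomicRanges::strand(g))), c("+", "-"))
  # exons sorted, non-overlapping, inside the gene span
  ex <- data.table(gene_id = S4Vectors::mcols(ann$exons)$gene_id,
                   start = GenomicRanges::start(ann$exons),
                   end = GenomicRanges::end(ann$exons))
  gd <- data.table(gene_id = S4Vectors::mcols(g)$gene_id,
                   gs = GenomicRanges::start(g), ge = GenomicRanges::end(g))
  ex <- merge(ex, gd, by = "gene_id")
  expect_true(all(ex$start >= ex$gs & ex$end <= ex$ge))
  bad <- ex[order(gene_id, start),
            any(start[-1] <= end[-.N]), by = gene_id][V1 == TRUE]
  expect_equal(nrow(bad), 0L)

  empty <- simulate_annotation(simulate_genome(cfg),
                               sim_config(seed = 3, n_chrom = 1,
                                          chrom_length = 1e5, n_genes = 0,
                                          control_length = 0))
  expect_equal(length(empty$genes), 0L)
  tiny <- sim_config(seed = 3, n_chrom = 1, chrom_length = 20000, n_genes = 50,
                     control_length = 0)
  expect_error(simulate_annotation(simulate_genome(tiny), tiny), "capacity")
})

test_that("methylome pairs honour degenerate parameters and are deterministic", {
  cfg <- sim_config(seed = 4, n_chrom = 1, chrom_length = 2e4, n_genes = 0,
                    n_dmrs = 0, conversion_error = 0,
                    baseline_levels = c(CG = 1, CHG = 0.4, CHH = 0.15),
                    control_length = 0)
  g <- simulate_genome(cfg)
  m <- simulate_methylome_pair(g, NULL, cfg)
  cg <- m$parent[context == "CG"]
  expect_true(all(cg$n_unmeth == 0L))
  expect_true(all(methylation_level(cg$n_meth, cg$n_unmeth) == 100))
  m2 <- simulate_methylome_pair(g, NULL, cfg)
  expect_identical(m$parent, m2$parent)
  expect_identical(m$sport, m2$sport)
})

test_that("a planted hyper-DMR shows the expected pooled level contrast", {
  cfg <- sim_config(seed = 5, n_chrom = 1, chrom_length = 1e5, n_genes = 0,
                    n_dmrs = 1, dmr_length = 1000, conversion_error = 0,
                    control_length = 0)
  g <- simulate_genome(cfg)
  m <- simulate_methylome_pair(g, NULL, cfg)
  tr <- m$truth
  expect_equal(nrow(tr), 1L)
  pool <- function(tab) {
    w <- tab[chrom == tr$chrom & pos >= tr$start & pos <= tr$end & context == "CG"]
    methylation_level(sum(w$n_meth), sum(w$n_unmeth))
  }
  hi <- if (tr$direction == "hyper") pool(m$sport) else pool(m$parent)
  lo <- if (tr$direction == "hyper") pool(m$parent) else pool(m$sport)
  # analytic expectation 80% vs 10%; ~70 CG sites x depth 20 reads pooled,
  # so binomial sampling error is well under 3 percentage points
  expect_lt(abs(hi - 80), 3)
  expect_lt(abs(lo - 10), 3)
  expect_gte(hi / lo, 2)
})

test_that("with no plants and no conversion error, genome-wide levels match the baselines", {
  cfg <- sim_config(seed = 6, n_chrom = 1, chrom_length = 4e5, n_genes = 0,
                    n_dmrs = 0, conversion_error = 0, control_length = 0)
  m <- simulate_methylome_pair(simulate_genome(cfg), NULL, cfg)
  s <- methylome_summary(m$parent, min_depth = 1, conversion_error = 0)
  expect_gte(min(s$n_sites_covered), 1e4)
  expect_lt(abs(s$level_by_context[["CG"]] - 52), 1)
  expect_lt(abs(s$level_by_context[["CHG"]] - 38), 1)
  expect_lt(abs(s$level_by_context[["CHH"]] - 15), 1)
})

test_that("with zero baselines the observed level is the conversion error floor", {
  cfg <- sim_config(seed = 7, n_chrom = 1, chrom_length = 2e5, n_genes = 0,
                    n_dmrs = 0, conversion_error = 0.005,
                    baseline_levels = c(CG = 0, CHG = 0, CHH = 0),
                    control_length = 0)
  m <- simulate_methylome_pair(simulate_genome(cfg), NULL, cfg)
  lev <- with(m$parent, 100 * sum(n_meth) / sum(n_meth + n_unmeth))
  # ~1.4e5 sites x ~20 reads: 3 binomial SEs around 0.5%
  se <- 100 * sqrt(0.005 * 0.995 / sum(m$parent$n_meth + m$parent$n_unmeth))
  expect_lt(abs(lev - 0.5), 3 * se + 1e-9)
})

test_that("planted DMRs never overlap and capacity violations error", {
  cfg <- test_cfg(n_dmrs = 20, dmr_length = 500)
  g <- simulate_genome(cfg)
  ann <- simulate_annotation(g, cfg)
  m <- simulate_methylome_pair(g, ann, cfg)
  tr <- m$truth
  gr <- GenomicRanges::GRanges(tr$chrom, IRanges::IRanges(tr$start, tr$end))
  expect_equal(sum(GenomicRanges::countOverlaps(gr, gr)), nrow(tr))
  expect_true(all(tr$direction %in% c("hyper", "hypo")))
  big <- sim_config(seed = 1, n_chrom = 1, chrom_length = 5e4, n_genes = 0,
                    n_dmrs = 100, dmr_length = 1000, control_length = 0)
  expect_error(simulate_methylome_pair(simulate_genome(big), NULL, big),
               "capacity")
})

test_that("expression generator plants the requested fold change (Poisson limit)", {
  cfg <- sim_config(seed = 8, n_genes = 300, n_reps = 3, nb_dispersion = 0,
                    n_degs = 100, deg_fold = 4, expr_mean = 1000, expr_log_sd = 0)
  e <- simulate_expression(NULL, cfg)
  expect_true(all(e$counts >= 0))
  expect_true(all(e$counts == floor(e$counts)))
  cm <- rowMeans(e$counts[, e$conditions == "parent"])
  sm <- rowMeans(e$counts[, e$conditions == "sport"])
  fold <- (sm / cm)[e$truth$gene_id]
  fold <- ifelse(e$truth$direction == "up", fold, 1 / fold)
  # Poisson at mean 1000, 3 reps: folds concentrate tightly around 4
  expect_gte(mean(fold >= 3.5 & fold <= 4.5), 0.95)
  expect_lt(abs(mean(fold) - 4), 0.2)

  null <- simulate_expression(NULL, sim_config(seed = 9, n_genes = 50, n_degs = 0))
  expect_equal(nrow(null$truth), 0L)
})

test_that("simulate_comparison writes a complete, reloadable fixture set", {
  dir <- withr::local_tempdir()
  cfg <- test_cfg(chrom_length = 5e4, n_genes = 5, n_dmrs = 2, n_degs = 3)
  sim <- simulate_comparison(cfg, dir)
  for (p in sim$paths) {
    expect_true(file.exists(p))
    expect_gt(file.size(p), 0)
  }
  back <- read_cytosine_report(sim$paths$methylome_parent)
  expect_equal(back, sim$methylomes$parent, ignore_attr = TRUE)
  ann <- read_annotation(sim$paths$annotation)
  expect_equal(length(ann$genes), length(sim$annotation$genes))
  expect_setequal(S4Vectors::mcols(ann$genes)$gene_id,
                  S4Vectors::mcols(sim$annotation$genes)$gene_id)
})
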