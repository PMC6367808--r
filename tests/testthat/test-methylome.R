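test_that("cytosine reports parse, validate with line numbers, and round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t5\t+\t3\t2\tCG",
               "chr1\t9\t-\t0\t7\tCHH",
               "chr2\t2\t+\t1\t1\tCHG"), f)
  tab <- read_cytosine_report(f)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab[chrom == "chr1" & pos == 5, n_meth], 3L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t5\t+\t3\t2\tCG", "chr1\t9\t+\t1\t1\tCHT"), bad)
  expect_error(read_cytosine_report(bad), "CHT.*line 2")
  writeLines(c("chr1\t5\t+\t-3\t2\tCG"), bad)
  expect_error(read_cytosine_report(bad), "n_meth.*line 1")
  writeLines(c("chr1\t5\t+\t3\t2\tCG", "chr1\t5\t+\t3\t2\tCG"), bad)
  expect_error(read_cytosine_report(bad), "duplicate.*line 2")

  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_warning(et <- read_cytosine_report(empty), "empty")
  expect_equal(nrow(et), 0L)

  out <- withr::local_tempfile(fileext = ".tsv")
  write_cytosine_report(tab, out)
  expect_equal(read_cytosine_report(out), tab, ignore_attr = TRUE)
})

test_that("context classification follows the CG/CHG/CHH rules on both strands", {
  expect_equal(classify_context("ACGT", 2, "+"), "CG")
  expect_equal(classify_context("ACTGA", 2, "+"), "CHG")
  expect_equal(classify_context("ACTTA", 2, "+"), "CHH")
  expect_equal(classify_context("TCGA", 3, "-"), "CG")
  expect_equal(classify_context("ACAGT", 4, "-"), "CHG")  # - strand reads C,T,G
  expect_equal(classify_context("AC", 2, "+"), "undetermined")
  expect_equal(classify_context("ACT", 2, "+"), "undetermined")
  expect_equal(classify_context("ACG", 2, "+"), "CG")  # one downstream base suffices
  expect_error(classify_context("AAAA", 2, "+"), "not a cytosine")
})

test_that("context classification agrees with a brute-force trinucleotide scan", {
  withr::with_seed(42, {
    seqs <- replicate(3, paste(sample(c("A", "C", "G", "T"), 10000, TRUE,
                                      prob = c(0.3, 0.2, 0.2, 0.3)),
                               collapse = ""))
  })
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (s in seqs) {
    chars <- strsplit(s, "")[[1]]
    L <- length(chars)
    # brute force: build the 5'->3' dinucleotide context per strand by hand
    brute <- function(i, strand) {
      tri <- if (strand == "+") chars[i:min(i + 2, L)] else
        rev(comp[chars[max(i - 2, 1):i]])
      if (length(tri) >= 2 && tri[2] == "G") return("CG")
      if (length(tri) < 3) return("undetermined")
      if (tri[3] == "G") "CHG" else "CHH"
    }
    got <- sportmethyl:::.cytosine_contexts(s, "chr")
    for (k in sample(nrow(got), 200)) {
      row <- got[k]
      expect_equal(row$context, brute(row$pos, row$strand),
                   info = sprintf("pos %d strand %s", row$pos, row$strand))
    }
    # boundary sites with short context are excluded by the table builder
    expect_true(all(got$context %in% c("CG", "CHG", "CHH")))
  }
})

test_that("methylation_level implements the pooled-read formula", {
  expect_equal(methylation_level(5, 5), 50)
  expect_equal(methylation_level(0, 12), 0)
  expect_equal(methylation_level(38, 62), 38)
  expect_true(is.na(methylation_level(0, 0)))
  expect_error(methylation_level(-1, 2), "non-negative")
})

test_that("conversion rate is read-weighted over the control sequence", {
  tab <- meth_table("ctl", c(1, 5), "+", "CG", c(1, 0), c(49, 50))
  expect_equal(conversion_rate(tab, "ctl"), 99)
  all_conv <- meth_table("ctl", 1, "+", "CG", 0, 10)
  expect_equal(conversion_rate(all_conv, "ctl"), 100)
  expect_error(conversion_rate(tab, "lambda"), "configuration")

  cfg <- test_cfg(seed = 21, chrom_length = 1e4, n_genes = 0, n_dmrs = 0,
                  control_length = 50000)
  m <- simulate_methylome_pair(simulate_genome(cfg), NULL, cfg)
  cr <- conversion_rate(m$parent, "chrC")
  tot <- m$parent[chrom == "chrC", sum(n_meth + n_unmeth)]
  se <- 100 * sqrt(0.005 * 0.995 / tot)
  expect_lt(abs(cr - 99.5), 3 * se + 1e-9)
})

test_that("genome summaries weight by coverage and respect the mC call rule", {
  tab <- meth_table("chr1", c(1, 3, 7, 11), "+",
                    c("CG", "CG", "CHH", "CHH"),
                    c(10, 10, 0, 0), c(0, 0, 10, 10))
  s <- methylome_summary(tab, min_depth = 1, conversion_error = 0)
  expect_equal(s$level_by_context[["CG"]], 100)
  expect_equal(s$level_by_context[["CHH"]], 0)
  expect_equal(s$mc_proportions[["CG"]], 1)
  expect_equal(s$n_sites_covered[["CHG"]], 0)

  deep <- methylome_summary(tab, min_depth = 100)
  expect_true(all(deep$n_sites_covered == 0))
  expect_true(all(is.na(deep$level_by_context)))
})

test_that("pooled level equals the coverage-weighted mean of any partition", {
  cfg <- test_cfg(seed = 31, chrom_length = 5e4, n_genes = 0, n_dmrs = 0,
                  control_length = 0)
  m <- simulate_methylome_pair(simulate_genome(cfg), NULL, cfg)
  tab <- m$parent[context == "CG"]
  global <- methylation_level(sum(tab$n_meth), sum(tab$n_unmeth))
  withr::with_seed(1, parts <- sample(5, nrow(tab), replace = TRUE))
  by_part <- tab[, .(m = sum(n_meth), u = sum(n_unmeth)), by = .(part = parts)]
  weighted <- with(by_part, sum(methylation_level(m, u) * (m + u)) / sum(m + u))
  expect_equal(weighted, global, tolerance = 1e-12)
})

test_that("metagene profiles are flat for uniform methylomes and ordered for flank contrast", {
  seqs <- simulate_genome(sim_config(seed = 41, n_chrom = 1, chrom_length = 3e4,
                                     control_length = 0))
  tab <- uniform_methylome(seqs[[1]], "chr1", 5L, 5L)
  genes <- gene_gr("chr1", c(5000, 15000), c(8999, 20999), c("+", "-"),
                   c("g1", "g2"), 3e4)
  prof <- metagene_profile(tab, genes, n_bins_body = 10, flank_bp = 1000,
                           n_bins_flank = 5)
  expect_true(all(abs(prof[is.finite(prof)] - 50) < 1e-9))

  # flanks at 80%, bodies at 20%
  tab2 <- copy(tab)
  inside <- tab2[, (pos >= 5000 & pos <= 8999) | (pos >= 15000 & pos <= 20999)]
  tab2[inside, `:=`(n_meth = 2L, n_unmeth = 8L)]
  tab2[!inside, `:=`(n_meth = 8L, n_unmeth = 2L)]
  prof2 <- metagene_profile(tab2, genes, n_bins_body = 10, flank_bp = 1000,
                            n_bins_flank = 5)
  body_cols <- grepl("^body_", colnames(prof2))
  expect_lt(max(prof2[, body_cols], na.rm = TRUE),
            min(prof2[, !body_cols], na.rm = TRUE))
})

test_that("metagene binning is exactly strand-symmetric", {
  withr::with_seed(52, {
    L <- 12000
    s <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  })
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  tab_f <- uniform_methylome(s, "chr1")
  withr::with_seed(7, tab_f[, n_meth := rbinom(.N, 10L, 0.3)])
  tab_f[, n_unmeth := 10L - n_meth]
  # mirror the methylome onto the reverse-complemented genome
  tab_r <- copy(tab_f)
  tab_r[, pos := L + 1L - pos]
  tab_r[, strand := fifelse(strand == "+", "-", "+")]
  setkey(tab_r, chrom, pos, strand)
  gene_f <- gene_gr("chr1", 4001, 8000, "+", "g", L)
  gene_r <- gene_gr("chr1", L + 1 - 8000, L + 1 - 4001, "-", "g", L)
  pf <- metagene_profile(tab_f, gene_f, n_bins_body = 10, flank_bp = 1000,
                         n_bins_flank = 4)
  pr <- metagene_profile(tab_r, gene_r, n_bins_body = 10, flank_bp = 1000,
                         n_bins_flank = 4)
  expect_equal(pf, pr)
})

test_that("bisulfite clone scoring calls methylated/converted/mismatch cytosines", {
  r <- score_bisulfite_clone("ACGACG", "ACGATG")
  expect_equal(r$calls[pos == 2, call], "methylated")
  expect_equal(r$calls[pos == 5, call], "unmethylated")

  full <- score_bisulfite_clone("ACGACG", "ACGACG")
  expect_true(all(full$calls$call == "methylated"))
  expect_equal(full$summary[context == "CG", pct_methylated], 100)

  mm <- score_bisulfite_clone("ACGT", "AAGT")
  expect_equal(mm$calls[pos == 2, call], "mismatch")
  expect_true(is.na(mm$summary[context == "CG", pct_methylated]))
  expect_error(score_bisulfite_clone("ACG", "AC"), "equal length")
})
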