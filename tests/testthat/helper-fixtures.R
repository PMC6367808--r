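library(data.table)

# small, fast simulation configuration for unit tests
test_cfg <- function(...) {
  args <- list(...)
  defaults <- list(seed = 11L, n_chrom = 1L, chrom_length = 2e5, n_genes = 20L,
                   n_dmrs = 6L, n_degs = 20L, control_length = 5000L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# hand-built methylome table
meth_table <- function(chrom, pos, strand, context, n_meth, n_unmeth) {
  dt <- data.table(chrom = chrom, pos = as.integer(pos), strand = strand,
                   context = context, n_meth = as.integer(n_meth),
                   n_unmeth = as.integer(n_unmeth))
  setkey(dt, chrom, pos, strand)
  dt[]
}

# uniform methylome: every context site of `sequence` at n_meth/n_unmeth
uniform_methylome <- function(sequence, chrom = "chr1", n_meth = 5L, n_unmeth = 5L) {
  ctx <- sportmethyl:::.cytosine_contexts(sequence, chrom)
  ctx[, `:=`(n_meth = as.integer(n_meth), n_unmeth = as.integer(n_unmeth))]
  setkey(ctx, chrom, pos, strand)
  ctx[]
}

# independent brute-force two-sided Fisher p via choose() enumeration
# (tables with probability <= observed, 1e-7 relative tolerance)
fisher_oracle <- function(m1, u1, m2, u2) {
  N <- m1 + u1 + m2 + u2
  if (N == 0) return(1)
  K <- m1 + m2
  n1 <- m1 + u1
  ks <- max(0, n1 - (N - K)):min(n1, K)
  pr <- choose(K, ks) * choose(N - K, n1 - ks) / choose(N, n1)
  obs <- pr[ks == m1]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# GRanges for a single gene
gene_gr <- function(chrom, start, end, strand, gene_id, seqlen = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand,
                               gene_id = gene_id)
  if (!is.null(seqlen)) {
    GenomeInfoDb::seqlengths(gr) <- setNames(seqlen, chrom)
  }
  gr
}
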