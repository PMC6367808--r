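#' Parameters for sliding-window DMR calling
#'
#' The thresholds mirror the published rule — a differentially methylated
#' region holds at least `min_sites` context sites, a `min_fold` change in
#' methylation level, and a Fisher exact test at `alpha` — while window and
#' step size, which the rule leaves open, default to the conventional WGBS
#' values of 200/50 bp and are fully configurable.
#'
#' @param window_bp,step_bp Sliding-window width and step (bp); `step_bp <=
#'   window_bp`.
#' @param min_sites Minimum shared covered context sites per window (default 5).
#' @param min_fold Minimum fold change `max(Rm1, Rm2) / min(Rm1, Rm2)` on the
#'   percent scale, with a zero level substituted by 0.001 (default 2).
#' @param alpha Significance threshold for the Fisher p (default 0.05).
#' @param fdr_mode `"raw"` applies `p <= alpha` exactly as published;
#'   `"BH"` applies Benjamini-Hochberg across all testable windows instead.
#' @param merge Merge overlapping/book-ended significant windows of the same
#'   context and direction (default `TRUE`).
#' @return A `dmr_params` list.
#' @export
dmr_params <- function(window_bp = 200L, step_bp = 50L, min_sites = 5L,
                       min_fold = 2, alpha = 0.05,
                       fdr_mode = c("raw", "BH"), merge = TRUE) {
  fdr_mode <- match.arg(fdr_mode)
  .assert_scalar_number(window_bp, "window_bp", 1)
  .assert_scalar_number(step_bp, "step_bp", 1)
  .assert_scalar_number(min_sites, "min_sites", 1)
  .assert_scalar_number(min_fold, "min_fold", 0)
  .assert_scalar_number(alpha, "alpha", 1e-300, 1)
  if (step_bp > window_bp) {
    stop("config error: 'step_bp' must not exceed 'window_bp'", call. = FALSE)
  }
  structure(list(window_bp = as.integer(window_bp), step_bp = as.integer(step_bp),
                 min_sites = as.integer(min_sites), min_fold = min_fold,
                 alpha = alpha, fdr_mode = fdr_mode, merge = isTRUE(merge)),
            class = "dmr_params")
}

#' Tile sliding windows over chromosomes
#'
#' Windows of `window_bp` advance by `step_bp` from position 1; the trailing
#' windows are clipped to the chromosome end (a chromosome shorter than the
#' step yields a single clipped window).
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param params A [dmr_params()].
#' @return `data.table` chrom, start, end (1-based inclusive), sorted.
#' @export
make_windows <- function(chrom_lengths, params = dmr_params()) {
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive", call. = FALSE)
  dt <- rbindlist(lapply(names(chrom_lengths), function(ch) {
    L <- as.integer(chrom_lengths[[ch]])
    starts <- seq.int(1L, L, by = params$step_bp)
    data.table(chrom = ch, start = starts,
               end = pmin(starts + params$window_bp - 1L, L))
  }))
  setorder(dt, chrom, start)
  dt[]
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p for the table `rbind(c(m1, u1), c(m2, u2))`: the sum of
#' hypergeometric probabilities, over all tables with the observed margins, of
#' outcomes no more probable than the observed one (with a relative tolerance
#' of 1e-7 on the comparison). An all-zero table returns 1 by convention.
#' Vectorised over its arguments.
#'
#' @param m1,u1,m2,u2 Non-negative integer counts (methylated/unmethylated
#'   reads of samples 1 and 2).
#' @return p-value(s) in `[0, 1]`.
#' @export
fisher_exact_2x2 <- function(m1, u1, m2, u2) {
  n <- max(length(m1), length(u1), length(m2), length(u2))
  m1 <- rep_len(m1, n); u1 <- rep_len(u1, n)
  m2 <- rep_len(m2, n); u2 <- rep_len(u2, n)
  if (any(c(m1, u1, m2, u2) < 0) || any(c(m1, u1, m2, u2) != floor(c(m1, u1, m2, u2)))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  vapply(seq_len(n), function(i) {
    a <- m1[i]; b <- u1[i]; c_ <- m2[i]; d <- u2[i]
    N <- a + b + c_ + d
    if (N == 0) return(1)
    K <- a + c_          # methylated margin
    n1 <- a + b          # sample-1 margin
    lo <- max(0, n1 - (N - K))
    hi <- min(n1, K)
    dens <- dhyper(lo:hi, K, N - K, n1)
    min(1, sum(dens[dens <= dens[a - lo + 1] * (1 + 1e-7)]))
  }, numeric(1))
}

#' Degree of difference between two methylation levels
#'
#' `log2(Rm1) / log2(Rm2)` on the percent scale exactly as published, with a
#' level of 0 adjusted to 0.001 before taking logs. When the adjusted `Rm2`
#' equals 1 (log2 = 0) the ratio is undefined: those entries are returned as
#' `NA` and flagged with a warning rather than silently dropped.
#'
#' @param rm1,rm2 Methylation levels in percent, `[0, 100]` (vectorised).
#' @return Numeric vector.
#' @export
degree_of_difference <- function(rm1, rm2) {
  if (any(rm1 < 0 | rm1 > 100 | rm2 < 0 | rm2 > 100, na.rm = TRUE)) {
    stop("'rm1'/'rm2' must be percentages in [0, 100]", call. = FALSE)
  }
  a1 <- ifelse(rm1 == 0, 0.001, rm1)
  a2 <- ifelse(rm2 == 0, 0.001, rm2)
  undef <- a2 == 1
  if (any(undef, na.rm = TRUE)) {
    warning(sprintf("degree of difference undefined for %d value(s) with Rm2 = 1 (log2 = 0)",
                    sum(undef, na.rm = TRUE)), call. = FALSE)
  }
  ifelse(undef, NA_real_, log2(a1) / log2(a2))
}

# fold change of two percent levels with the published 0 -> 0.001 substitution
.level_fold <- function(rm1, rm2) {
  a1 <- ifelse(rm1 == 0, 0.001, rm1)
  a2 <- ifelse(rm2 == 0, 0.001, rm2)
  pmax(a1, a2) / pmin(a1, a2)
}

# sites covered (depth >= 1) in BOTH samples, with both samples' counts
.shared_sites <- function(table_a, table_b) {
  a <- as.data.table(table_a)[n_meth + n_unmeth > 0L]
  b <- as.data.table(table_b)[n_meth + n_unmeth > 0L]
  sh <- merge(a, b, by = c("chrom", "pos", "strand", "context"),
              suffixes = c("_1", "_2"))
  setkey(sh, chrom, pos)
  sh
}

# pooled counts of shared context sites per window (no filtering)
.aggregate_windows <- function(shared, windows, contexts) {
  win <- as.data.table(windows)[, .(chrom, start, end)]
  win[, window_id := .I]
  sgr <- GRanges(shared$chrom, IRanges(shared$pos, shared$pos))
  wgr <- GRanges(win$chrom, IRanges(win$start, win$end))
  hits <- findOverlaps(sgr, wgr)
  dt <- data.table(window_id = subjectHits(hits),
                   context = shared$context[queryHits(hits)],
                   m1 = shared$n_meth_1[queryHits(hits)],
                   u1 = shared$n_unmeth_1[queryHits(hits)],
                   m2 = shared$n_meth_2[queryHits(hits)],
                   u2 = shared$n_unmeth_2[queryHits(hits)])
  dt <- dt[context %in% contexts]
  agg <- dt[, .(n_sites = .N, m1 = sum(m1), u1 = sum(u1),
                m2 = sum(m2), u2 = sum(u2)), by = .(window_id, context)]
  out <- merge(win, agg, by = "window_id", allow.cartesian = TRUE)
  out[, `:=`(rm1 = methylation_level(m1, u1), rm2 = methylation_level(m2, u2))]
  setorder(out, chrom, start, context)
  out[]
}

#' Per-window pooled methylation statistics
#'
#' Pools methylated/unmethylated counts of `context` sites covered in both
#' samples over each supplied window, and derives the two pooled levels.
#' Windows without context sites are returned with `n_sites = 0` and
#' undefined (`NA`) levels.
#'
#' @param table_a,table_b Methylome tables (sample 1 = parent, sample 2 =
#'   sport/mutant).
#' @param windows `data.table` with chrom, start, end (e.g. from
#'   [make_windows()]).
#' @param context Context(s) to tabulate (default all three, one row per
#'   window and context present).
#' @return `data.table` with chrom, start, end, context, n_sites, m1, u1, m2,
#'   u2, rm1, rm2.
#' @export
window_stats <- function(table_a, table_b, windows,
                         context = METH_CONTEXTS) {
  .assert_methylome(table_a, "table_a"); .assert_methylome(table_b, "table_b")
  shared <- .shared_sites(table_a, table_b)
  agg <- .aggregate_windows(shared, windows, context)
  win <- as.data.table(windows)[, .(chrom, start, end)]
  ctxs <- context
  grid <- win[, .(context = ctxs), by = .(chrom, start, end)]
  out <- merge(grid, agg[, -"window_id"], by = c("chrom", "start", "end", "context"),
               all.x = TRUE)
  for (cl in c("n_sites", "m1", "u1", "m2", "u2")) {
    set(out, which(is.na(out[[cl]])), cl, 0L)
  }
  setorder(out, chrom, start, context)
  out[]
}

#' Fisher tests over all testable sliding windows
#'
#' Builds the sliding windows, pools counts per window and context, keeps the
#' windows with at least `min_sites` shared covered sites, and computes the
#' two-sided Fisher p on the pooled 2x2 table of each. This is the complete
#' windowwise test surface; [call_dmrs()] applies the fold-change and
#' significance thresholds on top of it.
#'
#' @inheritParams window_stats
#' @param params A [dmr_params()].
#' @param contexts Contexts to test.
#' @param chrom_lengths Optional named chromosome lengths; inferred from the
#'   right-most covered position when absent.
#' @return `data.table` with window coordinates, pooled counts, levels,
#'   `fold` and `p_value`.
#' @export
window_tests <- function(table_a, table_b, params = dmr_params(),
                         contexts = METH_CONTEXTS, chrom_lengths = NULL) {
  .assert_methylome(table_a, "table_a"); .assert_methylome(table_b, "table_b")
  stopifnot(inherits(params, "dmr_params"))
  if (is.null(chrom_lengths)) chrom_lengths <- .infer_chrom_lengths(table_a, table_b)
  shared <- .shared_sites(table_a, table_b)
  windows <- make_windows(chrom_lengths, params)
  agg <- .aggregate_windows(shared, windows, contexts)
  cand <- agg[n_sites >= params$min_sites]
  cand[, fold := .level_fold(rm1, rm2)]
  cand[, p_value := fisher_exact_2x2(m1, u1, m2, u2)]
  cand[]
}

#' Call differentially methylated regions between two methylomes
#'
#' Sliding-window DMR identification: per context, windows holding at least
#' `min_sites` context sites covered in both samples, with a fold change of at
#' least `min_fold` between the pooled levels and a two-sided Fisher exact
#' p at most `alpha`, are significant; overlapping or book-ended significant
#' windows of the same context and direction are merged, with pooled counts,
#' levels, fold, p and degree of difference recomputed over the merged span.
#' Direction is mutant-relative: "hyper" where the sport (sample 2) is the
#' more methylated, "hypo" otherwise.
#'
#' @inheritParams window_tests
#' @return `data.table` of DMRs: chrom, start, end, context, n_sites, m1, u1,
#'   m2, u2, rm1, rm2, fold, p_value, direction, degree_of_difference,
#'   merged_from; the applied `dmr_params` are attached as attribute
#'   `"params"`.
#' @export
call_dmrs <- function(table_a, table_b, params = dmr_params(),
                      contexts = METH_CONTEXTS, chrom_lengths = NULL) {
  stopifnot(inherits(params, "dmr_params"))
  if (is.null(chrom_lengths)) chrom_lengths <- .infer_chrom_lengths(table_a, table_b)
  shared <- .shared_sites(table_a, table_b)
  windows <- make_windows(chrom_lengths, params)
  agg <- .aggregate_windows(shared, windows, contexts)
  cand <- agg[n_sites >= params$min_sites]
  cand[, fold := .level_fold(rm1, rm2)]
  cand[, p_value := fisher_exact_2x2(m1, u1, m2, u2)]
  sig <- if (params$fdr_mode == "BH") {
    cand[, p_adj := p.adjust(p_value, "BH")]
    cand[fold >= params$min_fold & p_adj <= params$alpha]
  } else {
    cand[fold >= params$min_fold & p_value <= params$alpha]
  }
  sig <- sig[, .(chrom, start, end, context, n_sites, m1, u1, m2, u2, rm1, rm2,
                 fold, p_value)]
  sig[, direction := ifelse(rm2 > rm1, "hyper", "hypo")]
  dmrs <- if (params$merge && nrow(sig)) {
    .merge_dmr_windows(sig, shared)
  } else {
    sig[, merged_from := 1L]
    sig
  }
  suppressWarnings(
    dmrs[, degree_of_difference := degree_of_difference(rm1, rm2)])
  setorder(dmrs, chrom, start, context)
  setattr(dmrs, "params", params)
  dmrs[]
}

# merge overlapping/book-ended significant windows per (context, direction),
# recomputing pooled statistics on each merged span; idempotent
.merge_dmr_windows <- function(sig, shared) {
  groups <- unique(sig[, .(context, direction)])
  out <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    g <- sig[context == groups$context[i] & direction == groups$direction[i]]
    gr <- GRanges(g$chrom, IRanges(g$start, g$end))
    red <- reduce(gr)
    hits <- findOverlaps(gr, red)
    nwin <- tabulate(subjectHits(hits), nbins = length(red))
    span <- data.table(chrom = as.character(seqnames(red)),
                       start = start(red), end = end(red),
                       merged_from = nwin)
    ss <- shared[context == groups$context[i]]
    sgr <- GRanges(ss$chrom, IRanges(ss$pos, ss$pos))
    sh <- findOverlaps(sgr, red)
    agg <- data.table(region = subjectHits(sh),
                      m1 = ss$n_meth_1[queryHits(sh)],
                      u1 = ss$n_unmeth_1[queryHits(sh)],
                      m2 = ss$n_meth_2[queryHits(sh)],
                      u2 = ss$n_unmeth_2[queryHits(sh)])[
      , .(n_sites = .N, m1 = sum(m1), u1 = sum(u1), m2 = sum(m2), u2 = sum(u2)),
      by = region]
    span[, region := .I]
    span <- merge(span, agg, by = "region")[, -"region"]
    span[, `:=`(rm1 = methylation_level(m1, u1),
                rm2 = methylation_level(m2, u2),
                context = groups$context[i],
                direction = groups$direction[i])]
    span[, fold := .level_fold(rm1, rm2)]
    span[, p_value := fisher_exact_2x2(m1, u1, m2, u2)]
    out[[i]] <- span
  }
  rbindlist(out, use.names = TRUE)
}

#' Write DMRs as BED6+
#'
#' 0-based half-open coordinates with name = context, score = `-10 log10(p)`
#' capped at 1000, strand ".", then Rm1, Rm2, fold, p, direction, degree of
#' difference and site count as extra columns.
#'
#' @param dmrs Output of [call_dmrs()].
#' @param path Output file.
#' @export
write_dmr_bed <- function(dmrs, path) {
  dmrs <- as.data.table(dmrs)
  score <- ifelse(dmrs$p_value <= 0, 1000,
                  pmin(1000, round(-10 * log10(dmrs$p_value))))
  bed <- data.table(chrom = dmrs$chrom, start = dmrs$start - 1L, end = dmrs$end,
                    name = dmrs$context, score = score, strand = ".",
                    rm1 = dmrs$rm1, rm2 = dmrs$rm2, fold = dmrs$fold,
                    p_value = dmrs$p_value, direction = dmrs$direction,
                    degree_of_difference = dmrs$degree_of_difference,
                    n_sites = dmrs$n_sites)
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Associate DMRs with gene bodies and promoters
#'
#' A DMR associates with a gene body on any (>= 1 bp) overlap with the gene
#' span, and with a promoter on any overlap with the strand-aware interval of
#' `promoter_bp` upstream of the transcription start site (clipped to the
#' chromosome). One DMR may associate with several genes and with both
#' locations.
#'
#' @param dmrs Output of [call_dmrs()] (needs chrom, start, end, context,
#'   direction).
#' @param genes `GRanges` of gene spans with a `gene_id` column (strand-aware).
#' @param promoter_bp Promoter length upstream of the TSS (default 2000).
#' @return `data.table`: gene_id, location ("body"/"promoter"), direction,
#'   chrom, start, end, context — one row per distinct association.
#' @export
associate_dmrs <- function(dmrs, genes, promoter_bp = 2000L) {
  dmrs <- as.data.table(dmrs)
  empty <- data.table(gene_id = character(), location = character(),
                      direction = character(), chrom = character(),
                      start = integer(), end = integer(), context = character())
  if (!nrow(dmrs) || length(genes) == 0L) return(empty)
  dgr <- GRanges(dmrs$chrom, IRanges(dmrs$start, dmrs$end))
  prom <- suppressWarnings(
    GenomicRanges::trim(promoters(genes, upstream = promoter_bp, downstream = 0)))
  take <- function(target, location) {
    h <- findOverlaps(dgr, target)
    if (!length(h)) return(NULL)
    data.table(gene_id = mcols(genes)$gene_id[subjectHits(h)],
               location = location,
               direction = dmrs$direction[queryHits(h)],
               chrom = dmrs$chrom[queryHits(h)],
               start = dmrs$start[queryHits(h)],
               end = dmrs$end[queryHits(h)],
               context = dmrs$context[queryHits(h)])
  }
  out <- rbindlist(list(take(genes, "body"), take(prom, "promoter")))
  if (!nrow(out)) return(empty)
  out <- unique(out)
  setorder(out, gene_id, location, start)
  out[]
}

#' Count DMR-associated genes and promoters by direction
#'
#' Distinct genes with at least one body (respectively promoter) association,
#' split by hyper/hypo DMR direction.
#'
#' @param associations Output of [associate_dmrs()].
#' @return `data.table`: location, direction, n_genes.
#' @export
dmr_association_counts <- function(associations) {
  as.data.table(associations)[
    , .(n_genes = uniqueN(gene_id)), by = .(location, direction)][
      order(location, direction)]
}

#' Compare called DMRs against a planted truth set
#'
#' Sensitivity is the fraction of planted regions overlapped (>= 1 bp, same
#' context) by at least one call; the false-plant rate is the fraction of
#' calls overlapping no planted region.
#'
#' @param dmrs Output of [call_dmrs()].
#' @param truth Truth table from the simulator (chrom, start, end, context).
#' @return List: sensitivity, false_plant_rate, n_called, n_truth.
#' @export
evaluate_dmr_recovery <- function(dmrs, truth) {
  dmrs <- as.data.table(dmrs); truth <- as.data.table(truth)
  if (!nrow(truth)) {
    return(list(sensitivity = NA_real_,
                false_plant_rate = if (nrow(dmrs)) 1 else NA_real_,
                n_called = nrow(dmrs), n_truth = 0L))
  }
  hit_truth <- logical(nrow(truth))
  hit_call <- logical(nrow(dmrs))
  for (ctx in unique(truth$context)) {
    ti <- which(truth$context == ctx)
    ci <- which(dmrs$context == ctx)
    if (!length(ci)) next
    tgr <- GRanges(truth$chrom[ti], IRanges(truth$start[ti], truth$end[ti]))
    cgr <- GRanges(dmrs$chrom[ci], IRanges(dmrs$start[ci], dmrs$end[ci]))
    h <- findOverlaps(tgr, cgr)
    hit_truth[ti[unique(queryHits(h))]] <- TRUE
    hit_call[ci[unique(subjectHits(h))]] <- TRUE
  }
  list(sensitivity = mean(hit_truth),
       false_plant_rate = if (nrow(dmrs)) mean(!hit_call) else NA_real_,
       n_called = nrow(dmrs), n_truth = nrow(truth))
}
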