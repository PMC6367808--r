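#' Read a per-cytosine methylation report
#'
#' Parses the six-column cytosine-report TSV produced by bisulfite mapping
#' tools (and by [simulate_comparison()]): chrom, 1-based position, strand,
#' methylated read count, unmethylated read count, context (CG/CHG/CHH).
#' Malformed rows are rejected with their line number; duplicate
#' (chrom, pos, strand) keys are an error. The returned table is sorted by
#' (chrom, pos, strand).
#'
#' @param path Path to the TSV (no header).
#' @return A `data.table` with columns chrom, pos, strand, n_meth, n_unmeth,
#'   context.
#' @export
read_cytosine_report <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  empty <- data.table(chrom = character(), pos = integer(), strand = character(),
                      context = character(), n_meth = integer(), n_unmeth = integer())
  if (file.size(path) == 0) {
    warning(sprintf("empty cytosine report: %s", path), call. = FALSE)
    return(empty)
  }
  raw <- fread(path, header = FALSE, sep = "\t", colClasses = "character")
  if (ncol(raw) != 6L) {
    stop(sprintf("cytosine report must have 6 columns, found %d: %s",
                 ncol(raw), path), call. = FALSE)
  }
  setnames(raw, c("chrom", "pos", "strand", "n_meth", "n_unmeth", "context"))
  fail <- function(what, lines) {
    stop(sprintf("parse error in %s: %s on line %s", path, what,
                 paste(head(lines, 5), collapse = ", ")), call. = FALSE)
  }
  bad <- which(!raw$context %in% METH_CONTEXTS)
  if (length(bad)) fail(sprintf("unknown context '%s'", raw$context[bad[1]]), bad)
  bad <- which(!raw$strand %in% c("+", "-"))
  if (length(bad)) fail(sprintf("invalid strand '%s'", raw$strand[bad[1]]), bad)
  num <- function(col) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad)) fail(sprintf("invalid %s '%s'", col, raw[[col]][bad[1]]), bad)
    v
  }
  tab <- data.table(chrom = raw$chrom, pos = num("pos"), strand = raw$strand,
                    n_meth = num("n_meth"), n_unmeth = num("n_unmeth"),
                    context = raw$context)
  bad <- which(tab$pos < 1L)
  if (length(bad)) fail("position < 1", bad)
  dup <- which(duplicated(tab, by = c("chrom", "pos", "strand")))
  if (length(dup)) fail("duplicate (chrom, pos, strand) key", dup)
  setcolorder(tab, c("chrom", "pos", "strand", "context", "n_meth", "n_unmeth"))
  setkey(tab, chrom, pos, strand)
  tab[]
}

#' @rdname read_cytosine_report
#' @param tab A methylome table.
#' @export
write_cytosine_report <- function(tab, path) {
  .assert_methylome(tab)
  fwrite(as.data.table(tab)[, .(chrom, pos, strand, n_meth, n_unmeth, context)],
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Methylation level from read counts
#'
#' `Rm (%) = Nm / (Nm + Nnm) * 100`, the fraction of methylated reads at a
#' cytosine or over pooled region counts. Sites with zero total reads are
#' undefined and return `NA` (they are excluded from summaries, never imputed
#' as 0).
#'
#' @param n_meth,n_unmeth Non-negative read counts (vectorised).
#' @return Percent in `[0, 100]`, `NA` where `n_meth + n_unmeth == 0`.
#' @export
methylation_level <- function(n_meth, n_unmeth) {
  if (any(n_meth < 0 | n_unmeth < 0, na.rm = TRUE)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  tot <- n_meth + n_unmeth
  ifelse(tot > 0, 100 * n_meth / tot, NA_real_)
}

#' Bisulfite conversion rate from an unmethylated control sequence
#'
#' The fraction of reads over the control cytosines that were successfully
#' converted: `100 * sum(n_unmeth) / sum(n_meth + n_unmeth)`.
#'
#' @param tab A methylome table.
#' @param control_chrom Name of the unmethylated control sequence.
#' @return Percent.
#' @export
conversion_rate <- function(tab, control_chrom) {
  .assert_methylome(tab)
  ctl <- as.data.table(tab)[chrom == control_chrom]
  if (!nrow(ctl)) {
    stop(sprintf("configuration error: no control records for '%s'", control_chrom),
         call. = FALSE)
  }
  100 * sum(ctl$n_unmeth) / sum(ctl$n_meth + ctl$n_unmeth)
}

#' Genome-wide methylation summary
#'
#' Coverage-weighted methylation level per context (pooled counts over sites
#' with depth >= `min_depth`), counts of covered sites, and the relative
#' proportion of called methylcytosines per context. A covered site is called
#' a methylcytosine when a one-sided binomial test of its methylated count
#' against the conversion-error rate rejects at p < 0.05 (with
#' `conversion_error = 0` this degrades to "any methylated read").
#'
#' @param tab A methylome table.
#' @param min_depth Minimum depth for site-level summaries (default 4).
#' @param conversion_error Error rate for the methylcytosine call.
#' @param control_chrom Optional control-sequence name; its records are used
#'   for [conversion_rate()] and excluded from genome-wide statistics.
#' @return A `methylome_summary` list: `level_by_context` (percent),
#'   `n_sites_covered`, `n_mc`, `mc_proportions` (fractions summing to 1 when
#'   any mC is called), `conversion_rate` (or `NA`), `min_depth`.
#' @export
methylome_summary <- function(tab, min_depth = 4L, conversion_error = 0.005,
                              control_chrom = NULL) {
  .assert_methylome(tab)
  tab <- as.data.table(tab)
  conv <- NA_real_
  if (!is.null(control_chrom) && any(tab$chrom == control_chrom)) {
    conv <- conversion_rate(tab, control_chrom)
    tab <- tab[chrom != control_chrom]
  }
  if (min_depth < 1) stop("'min_depth' must be >= 1", call. = FALSE)
  cov <- tab[n_meth + n_unmeth >= min_depth]
  per <- cov[, .(
    m = sum(as.numeric(n_meth)), u = sum(as.numeric(n_unmeth)), n_sites = .N,
    n_mc = sum(pbinom(n_meth - 1L, n_meth + n_unmeth, conversion_error,
                      lower.tail = FALSE) < 0.05)
  ), by = context]
  per <- per[match(METH_CONTEXTS, context)]
  per[, context := METH_CONTEXTS]
  for (cl in c("m", "u", "n_sites", "n_mc")) {
    set(per, which(is.na(per[[cl]])), cl, as(0, class(per[[cl]])))
  }
  level <- with(per, ifelse(m + u > 0, 100 * m / (m + u), NA_real_))
  total_mc <- sum(per$n_mc)
  structure(list(
    level_by_context = setNames(level, METH_CONTEXTS),
    n_sites_covered = setNames(per$n_sites, METH_CONTEXTS),
    n_mc = setNames(per$n_mc, METH_CONTEXTS),
    mc_proportions = setNames(
      if (total_mc > 0) per$n_mc / total_mc else rep(NA_real_, 3), METH_CONTEXTS),
    conversion_rate = conv,
    min_depth = as.integer(min_depth)
  ), class = "methylome_summary")
}

#' @export
print.methylome_summary <- function(x, ...) {
  cat("methylome summary (min depth", x$min_depth, "):\n")
  for (ctx in METH_CONTEXTS) {
    cat(sprintf("  %-3s level %6.2f%%  sites %9d  mC share %s\n", ctx,
                x$level_by_context[[ctx]], x$n_sites_covered[[ctx]],
                ifelse(is.na(x$mc_proportions[[ctx]]), "NA",
                       sprintf("%.3f", x$mc_proportions[[ctx]]))))
  }
  if (!is.na(x$conversion_rate)) {
    cat(sprintf("  conversion rate %.2f%%\n", x$conversion_rate))
  }
  invisible(x)
}
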