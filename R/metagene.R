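#' Metagene methylation profile
#'
#' Pools read counts across genes into a fixed number of scaled gene-body bins
#' plus fixed-width upstream and downstream flank bins, oriented 5'->3' so
#' that bin 1 is always the far upstream flank regardless of strand, and
#' reports the pooled-count methylation level per context and bin.
#'
#' Minus-strand genes are binned natively by distance from their (genomic
#' right) transcription start, which makes the profile exactly
#' strand-symmetric: a gene and its reverse-complement mirror produce
#' identical rows.
#'
#' @param tab A methylome table.
#' @param genes A `GRanges` of gene spans (strand-aware), e.g.
#'   `annotation$genes`.
#' @param n_bins_body Number of scaled bins across the gene body (default 60).
#' @param flank_bp Flank width in bp on each side (default 2000).
#' @param n_bins_flank Number of bins per flank (default 20).
#' @return Numeric matrix contexts x bins (percent; `NaN` where a bin has no
#'   reads), columns named `up_*`, `body_*`, `down_*`.
#' @export
metagene_profile <- function(tab, genes, n_bins_body = 60L, flank_bp = 2000L,
                             n_bins_flank = 20L) {
  .assert_methylome(tab)
  if (length(genes) == 0L) stop("'genes' must be non-empty", call. = FALSE)
  tab <- as.data.table(tab)
  setkey(tab, chrom, pos)
  B <- 2L * n_bins_flank + n_bins_body
  acc <- vector("list", length(genes))
  skipped <- 0L
  for (i in seq_along(genes)) {
    ch <- as.character(seqnames(genes))[i]
    gs <- start(genes)[i]; ge <- end(genes)[i]
    w <- ge - gs + 1L
    if (w < n_bins_body) { skipped <- skipped + 1L; next }
    minus <- as.character(strand(genes))[i] == "-"
    lo <- gs - flank_bp; hi <- ge + flank_bp
    s <- tab[chrom == ch & pos >= lo & pos <= hi]
    if (!nrow(s)) next
    # 0-based distance from the 5' end of the extended region
    d <- if (minus) hi - s$pos else s$pos - lo
    bin <- integer(nrow(s))
    up <- d < flank_bp
    bin[up] <- pmin(floor(d[up] * n_bins_flank / flank_bp), n_bins_flank - 1L) + 1L
    body <- d >= flank_bp & d < flank_bp + w
    bin[body] <- n_bins_flank +
      pmin(floor((d[body] - flank_bp) * n_bins_body / w), n_bins_body - 1L) + 1L
    down <- d >= flank_bp + w
    bin[down] <- n_bins_flank + n_bins_body +
      pmin(floor((d[down] - flank_bp - w) * n_bins_flank / flank_bp),
           n_bins_flank - 1L) + 1L
    acc[[i]] <- data.table(context = s$context, bin = bin,
                           m = s$n_meth, u = s$n_unmeth)
  }
  if (skipped > 0L) {
    warning(sprintf("%d gene(s) shorter than n_bins_body skipped", skipped),
            call. = FALSE)
  }
  dt <- rbindlist(acc)
  out <- matrix(NaN, 3L, B,
                dimnames = list(METH_CONTEXTS,
                                c(sprintf("up_%d", seq_len(n_bins_flank)),
                                  sprintf("body_%d", seq_len(n_bins_body)),
                                  sprintf("down_%d", seq_len(n_bins_flank)))))
  if (nrow(dt)) {
    agg <- dt[, .(m = sum(as.numeric(m)), u = sum(as.numeric(u))),
              by = .(context, bin)]
    agg <- agg[m + u > 0]
    out[cbind(match(agg$context, METH_CONTEXTS), agg$bin)] <-
      100 * agg$m / (agg$m + agg$u)
  }
  out
}

#' Score a bisulfite-PCR clone against its reference
#'
#' For equal-length, pre-aligned (no indels) reference and clone sequences:
#' at each reference cytosine a clone C is a methylated call, a clone T an
#' unmethylated call (converted), anything else a mismatch (excluded from
#' level estimates). Non-C reference positions are ignored. Contexts come
#' from [classify_context()] on the reference (plus strand).
#'
#' @param reference,clone Character sequences of equal length.
#' @return List: `calls` (`data.table` pos, context, ref, clone, call) and
#'   `summary` (per context: n_methylated, n_unmethylated, n_mismatch,
#'   pct_methylated over informative calls).
#' @export
score_bisulfite_clone <- function(reference, clone) {
  ref <- strsplit(toupper(as.character(reference)), "", fixed = TRUE)[[1]]
  cl <- strsplit(toupper(as.character(clone)), "", fixed = TRUE)[[1]]
  if (length(ref) != length(cl)) {
    stop("reference and clone must be pre-aligned to equal length", call. = FALSE)
  }
  pos <- which(ref == "C")
  if (!length(pos)) {
    calls <- data.table(pos = integer(), context = character(),
                        ref = character(), clone = character(), call = character())
  } else {
    call <- fifelse(cl[pos] == "C", "methylated",
                    fifelse(cl[pos] == "T", "unmethylated", "mismatch"))
    calls <- data.table(pos = pos,
                        context = classify_context(reference, pos, "+"),
                        ref = ref[pos], clone = cl[pos], call = call)
  }
  summary <- calls[context %in% METH_CONTEXTS,
                   .(n_methylated = sum(call == "methylated"),
                     n_unmethylated = sum(call == "unmethylated"),
                     n_mismatch = sum(call == "mismatch")),
                   by = context]
  summary[, pct_methylated :=
            ifelse(n_methylated + n_unmethylated > 0,
                   100 * n_methylated / (n_methylated + n_unmethylated),
                   NA_real_)]
  list(calls = calls, summary = summary[])
}
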