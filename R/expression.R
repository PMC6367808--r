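#' FPKM normalisation
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' `1e9 * count / (gene_length * sample_total)`.
#'
#' @param counts Non-negative matrix, genes x samples (rownames = gene ids).
#' @param lengths Gene (transcript) lengths in bp, recycled/matched by
#'   position or by name when both are named.
#' @return Matrix of FPKM values with the same dimensions.
#' @export
fpkm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    lengths <- lengths[rownames(counts)]
  }
  if (length(lengths) != nrow(counts) || any(is.na(lengths))) {
    stop("'lengths' must supply one length per gene", call. = FALSE)
  }
  if (any(lengths <= 0)) stop("domain error: zero-length gene", call. = FALSE)
  totals <- colSums(counts)
  if (any(totals <= 0)) {
    stop("every sample needs a positive total count", call. = FALSE)
  }
  1e9 * sweep(sweep(counts, 1, lengths, "/"), 2, totals, "/")
}

# fraction of noise points strictly dominated in both coordinates
# (ties count against the gene: conservative)
.noise_probability <- function(m_abs, d, noise_m_abs, noise_d) {
  vapply(seq_along(m_abs), function(i) {
    mean(noise_m_abs < m_abs[i] & noise_d < d[i])
  }, numeric(1))
}

#' Nonparametric divergence probability for differential expression
#'
#' For each gene, on FPKM-normalised values: the signal pair is
#' `M = log2((mean2 + k) / (mean1 + k))` and `D = |mean2 - mean1|`, where the
#' means are over the replicates of each condition and `k` is a pseudocount
#' in FPKM units. The noise distribution collects the same `(|M|, D)` pair
#' from every within-condition replicate pair of every gene; the divergence
#' probability is the fraction of noise points strictly below the gene's
#' signal in both coordinates. Condition 2 (the sport) is contrasted against
#' condition 1 (the parent), taken in order of first appearance in
#' `conditions` unless it is a factor.
#'
#' When a condition has a single library, `n_sim_reps` technical replicates
#' are simulated for the noise set by multinomial resampling of its counts
#' (seeded, deterministic).
#'
#' @param counts Integer matrix genes x samples.
#' @param lengths Gene lengths (bp) for [fpkm()].
#' @param conditions Condition label per column (exactly two levels).
#' @param pseudocount FPKM pseudocount `k` (default 1).
#' @param n_sim_reps Simulated technical replicates for single-library
#'   conditions (default 5).
#' @param seed Seed for the simulated-replicate fallback.
#' @return `data.table`: gene_id, mean1, mean2 (FPKM), M, D, fold_change
#'   (`2^M`), probability.
#' @export
divergence_probability <- function(counts, lengths, conditions, pseudocount = 1,
                                   n_sim_reps = 5L, seed = 1L) {
  counts <- as.matrix(counts)
  conditions <- as.character(conditions)
  if (length(conditions) != ncol(counts)) {
    stop("config error: one condition label per sample required", call. = FALSE)
  }
  lv <- unique(conditions)
  if (length(lv) != 2L) {
    stop("config error: exactly two conditions required", call. = FALSE)
  }
  idx1 <- which(conditions == lv[1]); idx2 <- which(conditions == lv[2])
  f <- fpkm(counts, lengths)
  x1 <- rowMeans(f[, idx1, drop = FALSE])
  x2 <- rowMeans(f[, idx2, drop = FALSE])
  k <- pseudocount
  M <- log2((x2 + k) / (x1 + k))
  D <- abs(x2 - x1)
  noise <- .noise_set(counts, f, lengths, list(idx1, idx2), k, n_sim_reps, seed)
  prob <- .noise_probability(abs(M), D, noise$m_abs, noise$d)
  data.table(gene_id = rownames(counts) %||% sprintf("gene_%d", seq_len(nrow(counts))),
             mean1 = x1, mean2 = x2, M = M, D = D,
             fold_change = 2^M, probability = prob)
}

# (|M|, D) pairs over all within-condition replicate pairs of all genes;
# single-library conditions contribute multinomial technical resamples
.noise_set <- function(counts, f, lengths, idx_list, k, n_sim_reps, seed) {
  ms <- list(); ds <- list()
  for (idx in idx_list) {
    cols <- if (length(idx) >= 2L) {
      f[, idx, drop = FALSE]
    } else {
      withr::with_seed(seed, {
        x <- counts[, idx]
        tot <- sum(x)
        if (tot == 0) stop("config error: empty condition", call. = FALSE)
        sim <- rmultinom(n_sim_reps, tot, x / tot)
        rownames(sim) <- rownames(counts)
        fpkm(sim, lengths)
      })
    }
    nrep <- ncol(cols)
    for (i in seq_len(nrep - 1L)) {
      for (j in seq(i + 1L, nrep)) {
        ms[[length(ms) + 1L]] <- abs(log2((cols[, j] + k) / (cols[, i] + k)))
        ds[[length(ds) + 1L]] <- abs(cols[, j] - cols[, i])
      }
    }
  }
  list(m_abs = unlist(ms, use.names = FALSE), d = unlist(ds, use.names = FALSE))
}

#' Flag differentially expressed genes
#'
#' A gene is a DEG when `|M| >= log2(min_fold)` and its divergence
#' probability is at least `min_prob` — the published rule with defaults
#' fold >= 2 and probability >= 0.8. Direction follows the sign of M
#' (up = higher in the sport).
#'
#' @param results Output of [divergence_probability()].
#' @param min_fold Fold-change threshold (default 2).
#' @param min_prob Probability threshold (default 0.8).
#' @return The input with `is_deg` and `direction` ("up"/"down"/"none")
#'   columns added.
#' @export
call_degs <- function(results, min_fold = 2, min_prob = 0.8) {
  res <- as.data.table(results)
  res[, is_deg := abs(M) >= log2(min_fold) & probability >= min_prob]
  res[, direction := fifelse(!is_deg, "none", fifelse(M > 0, "up", "down"))]
  res[]
}

#' Up/down counts among called DEGs
#'
#' @param results Output of [call_degs()].
#' @return `data.table` with n_up, n_down, n_deg, n_genes.
#' @export
deg_counts <- function(results) {
  res <- as.data.table(results)
  data.table(n_up = sum(res$direction == "up"),
             n_down = sum(res$direction == "down"),
             n_deg = sum(res$is_deg),
             n_genes = nrow(res))
}
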