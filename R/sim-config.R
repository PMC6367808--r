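#' Simulation configuration for a parent/sport benchmark data set
#'
#' Bundles every knob of the synthetic-data generator. The defaults describe the
#' study conditions the package is benchmarked under: context baselines in the
#' middle of the ranges reported for apple peel methylomes (CG ~52%, CHG ~38%,
#' CHH ~15%), read depth peaking near 10-20x (negative-binomial with mean 20),
#' bisulfite conversion error ~0.5%, strongly contrasted planted DMRs (80% vs
#' 10%), and negative-binomial RNA-seq counts with three replicates per
#' condition and planted >= 2-fold DEGs.
#'
#' @param seed Master seed. Every generator derives a deterministic sub-stream
#'   from it (`+0` genome, `+1` annotation, `+2` methylomes, `+3` expression),
#'   so identical configurations give bit-identical output.
#' @param n_chrom,chrom_length Number and length (bp) of simulated chromosomes.
#' @param gc_fraction GC content of the simulated genome, in `[0, 1]`.
#' @param n_genes Number of non-overlapping genes to place (with >= 2 kb flanks).
#' @param gene_length_range,exon_range Ranges (bp / count) for gene lengths and
#'   exons per gene.
#' @param baseline_levels Named fractions: true methylation level per context
#'   outside planted DMRs.
#' @param depth_mean,depth_dispersion Negative-binomial read-depth model per
#'   cytosine (`size = 1/depth_dispersion`; dispersion 0 gives Poisson).
#' @param conversion_error Probability that an unmethylated cytosine escapes
#'   bisulfite conversion and is read as methylated.
#' @param n_dmrs,dmr_length Number and length (bp) of planted DMRs.
#' @param dmr_levels Named fractions `c(high=, low=)`: the two true levels used
#'   inside planted DMRs (must differ).
#' @param dmr_context Context(s) of planted DMRs, recycled across plants.
#' @param n_reps RNA-seq replicates per condition.
#' @param nb_dispersion Negative-binomial dispersion of counts (0 = Poisson).
#' @param n_degs,deg_fold Number of planted DEGs and their true fold change
#'   (>= 1; the DEG caller's threshold is 2).
#' @param expr_mean,expr_log_sd Per-gene baseline means are
#'   `rlnorm(log(expr_mean), expr_log_sd)`; `expr_log_sd = 0` fixes all means.
#' @param couple_expression If `TRUE`, gene-targeted DMR plants are placed over
#'   promoters with direction "hypo" (sport-hypomethylated) and their target
#'   genes are planted as upregulated DEGs, giving true joint positives for the
#'   integration stage.
#' @param control_length,control_chrom Length and name of a fully unmethylated
#'   spike-in chromosome used to estimate the bisulfite conversion rate
#'   (`0` disables it).
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L,
                       chrom_length = 1e6,
                       gc_fraction = 0.38,
                       n_genes = 200L,
                       gene_length_range = c(1000L, 4000L),
                       exon_range = c(1L, 4L),
                       baseline_levels = c(CG = 0.52, CHG = 0.38, CHH = 0.15),
                       depth_mean = 20,
                       depth_dispersion = 0.2,
                       conversion_error = 0.005,
                       n_dmrs = 100L,
                       dmr_length = 1000L,
                       dmr_levels = c(high = 0.8, low = 0.1),
                       dmr_context = "CG",
                       n_reps = 3L,
                       nb_dispersion = 0.05,
                       n_degs = 100L,
                       deg_fold = 2,
                       expr_mean = 500,
                       expr_log_sd = 1,
                       couple_expression = FALSE,
                       control_length = 20000L,
                       control_chrom = "chrC") {
  .assert_scalar_number(seed, "seed", 0, 2^31 - 10)
  .assert_scalar_number(n_chrom, "n_chrom", 1)
  if (!is.numeric(chrom_length) || any(chrom_length <= 0)) {
    stop("invalid config: 'chrom_length' must be positive", call. = FALSE)
  }
  .assert_scalar_number(gc_fraction, "gc_fraction", 0, 1)
  .assert_scalar_number(n_genes, "n_genes", 0)
  .assert_scalar_number(depth_mean, "depth_mean", 1e-9)
  .assert_scalar_number(depth_dispersion, "depth_dispersion", 0)
  .assert_scalar_number(conversion_error, "conversion_error", 0, 1)
  .assert_scalar_number(n_dmrs, "n_dmrs", 0)
  .assert_scalar_number(dmr_length, "dmr_length", 1)
  .assert_scalar_number(n_reps, "n_reps", 1)
  .assert_scalar_number(nb_dispersion, "nb_dispersion", 0)
  .assert_scalar_number(n_degs, "n_degs", 0)
  .assert_scalar_number(expr_mean, "expr_mean", 1e-9)
  .assert_scalar_number(expr_log_sd, "expr_log_sd", 0)
  .assert_scalar_number(control_length, "control_length", 0)
  if (deg_fold < 1) stop("invalid config: 'deg_fold' must be >= 1", call. = FALSE)
  if (!all(METH_CONTEXTS %in% names(baseline_levels)) ||
      any(baseline_levels < 0 | baseline_levels > 1)) {
    stop("invalid config: 'baseline_levels' needs CG/CHG/CHH fractions in [0, 1]",
         call. = FALSE)
  }
  if (!all(c("high", "low") %in% names(dmr_levels)) ||
      any(dmr_levels < 0 | dmr_levels > 1) ||
      dmr_levels[["high"]] == dmr_levels[["low"]]) {
    stop("invalid config: 'dmr_levels' needs distinct 'high' and 'low' fractions in [0, 1]",
         call. = FALSE)
  }
  if (!all(dmr_context %in% METH_CONTEXTS)) {
    stop("invalid config: 'dmr_context' must be CG, CHG or CHH", call. = FALSE)
  }
  cfg <- list(
    seed = as.integer(seed), n_chrom = as.integer(n_chrom),
    chrom_length = as.integer(rep_len(chrom_length, n_chrom)),
    gc_fraction = gc_fraction, n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    exon_range = as.integer(exon_range),
    baseline_levels = baseline_levels[METH_CONTEXTS],
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    conversion_error = conversion_error,
    n_dmrs = as.integer(n_dmrs), dmr_length = as.integer(dmr_length),
    dmr_levels = dmr_levels, dmr_context = dmr_context,
    n_reps = as.integer(n_reps), nb_dispersion = nb_dispersion,
    n_degs = as.integer(n_degs), deg_fold = deg_fold,
    expr_mean = expr_mean, expr_log_sd = expr_log_sd,
    couple_expression = isTRUE(couple_expression),
    control_length = as.integer(control_length), control_chrom = control_chrom
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      sprintf("%d chrom x %s bp (gc %.2f), %d genes,", x$n_chrom,
              paste(unique(x$chrom_length), collapse = "/"), x$gc_fraction, x$n_genes),
      sprintf("%d DMRs (%s, %d bp, %.2f vs %.2f),", x$n_dmrs,
              paste(unique(x$dmr_context), collapse = "/"),
              x$dmr_length, x$dmr_levels[["high"]], x$dmr_levels[["low"]]),
      sprintf("%d DEGs (fold %.1f, %d reps), seed %d\n",
              x$n_degs, x$deg_fold, x$n_reps, x$seed))
  invisible(x)
}
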