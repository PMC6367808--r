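#' Simulate a replicated RNA-seq count matrix with planted DEGs
#'
#' Per-gene baseline means are log-normal around `expr_mean`
#' (`expr_log_sd = 0` fixes every mean); counts are negative-binomial
#' (`size = 1/nb_dispersion`, Poisson in the limit) with `n_reps` replicates
#' per condition. Planted DEGs have their condition-2 (sport) mean multiplied
#' or divided by `deg_fold`.
#'
#' @param annotation A `gene_annotation`, or `NULL` to use `cfg$n_genes`
#'   synthetic gene ids with lengths drawn uniformly from
#'   `gene_length_range`.
#' @param cfg A [sim_config()].
#' @param coupled_genes Gene ids to plant as upregulated DEGs first (used by
#'   [simulate_comparison()] to couple promoter-hypo DMR plants to up-DEGs).
#' @return List: `counts` (integer matrix genes x 2*n_reps, columns
#'   `parent_*`/`sport_*`), `gene_lengths` (named bp vector), `conditions`
#'   (character per column), `truth` (`data.table` gene_id, true_log2fc,
#'   direction).
#' @export
simulate_expression <- function(annotation = NULL, cfg, coupled_genes = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 3L, {
    if (!is.null(annotation)) {
      lens <- gene_lengths(annotation)
    } else {
      ids <- sprintf("gene_%04d", seq_len(cfg$n_genes))
      lens <- setNames(sample(seq(cfg$gene_length_range[1], cfg$gene_length_range[2]),
                              cfg$n_genes, replace = TRUE), ids)
    }
    ids <- names(lens)
    n <- length(ids)
    if (cfg$n_degs > n) {
      stop("invalid config: more planted DEGs than genes", call. = FALSE)
    }
    base <- if (cfg$expr_log_sd > 0) {
      rlnorm(n, log(cfg$expr_mean), cfg$expr_log_sd)
    } else {
      rep(cfg$expr_mean, n)
    }
    deg_ids <- character(0)
    dirs <- character(0)
    if (cfg$n_degs > 0L) {
      coupled <- intersect(coupled_genes %||% character(0), ids)
      coupled <- head(coupled, cfg$n_degs)
      extra <- sample(setdiff(ids, coupled), cfg$n_degs - length(coupled))
      deg_ids <- c(coupled, extra)
      dirs <- c(rep("up", length(coupled)),
                rep_len(c("up", "down"), length(extra)))
    }
    mult <- setNames(rep(1, n), ids)
    mult[deg_ids] <- ifelse(dirs == "up", cfg$deg_fold, 1 / cfg$deg_fold)
    mu <- cbind(matrix(base, n, cfg$n_reps),
                matrix(base * mult, n, cfg$n_reps))
    counts <- if (cfg$nb_dispersion > 0) {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
             n, ncol(mu))
    } else {
      matrix(rpois(length(mu), mu), n, ncol(mu))
    }
    conditions <- rep(c("parent", "sport"), each = cfg$n_reps)
    colnames(counts) <- paste0(conditions, "_", rep(seq_len(cfg$n_reps), 2))
    rownames(counts) <- ids
    truth <- data.table(gene_id = deg_ids,
                        true_log2fc = ifelse(dirs == "up", 1, -1) * log2(cfg$deg_fold),
                        direction = dirs)
    list(counts = counts, gene_lengths = lens, conditions = conditions,
         truth = truth)
  })
}

#' Simulate and write a complete parent/sport benchmark data set
#'
#' Runs the genome, annotation, methylome and expression generators under one
#' master seed and writes every artefact as plain text: genome FASTA,
#' annotation GFF3, two cytosine-report TSVs, a counts TSV (gene_id + sample
#' columns), gene lengths, and machine-readable truth tables for the planted
#' DMRs and DEGs.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the simulated objects and a `paths` list.
#' @export
simulate_comparison <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genome <- simulate_genome(cfg)
  annotation <- simulate_annotation(genome, cfg)
  meth <- simulate_methylome_pair(genome, annotation, cfg)
  coupled <- if (cfg$couple_expression) {
    meth$truth[target_location == "promoter" & direction == "hypo", target_gene]
  }
  expr <- simulate_expression(annotation, cfg, coupled_genes = coupled)
  p <- list(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "annotation.gff3"),
    methylome_parent = file.path(dir, "methylome_parent.tsv"),
    methylome_sport = file.path(dir, "methylome_sport.tsv"),
    counts = file.path(dir, "counts.tsv"),
    gene_lengths = file.path(dir, "gene_lengths.tsv"),
    truth_dmrs = file.path(dir, "truth_dmrs.tsv"),
    truth_degs = file.path(dir, "truth_degs.tsv")
  )
  writeXStringSet(genome, p$genome)
  write_annotation(annotation, p$annotation)
  write_cytosine_report(meth$parent, p$methylome_parent)
  write_cytosine_report(meth$sport, p$methylome_sport)
  fwrite(data.table(gene_id = rownames(expr$counts), expr$counts),
         p$counts, sep = "\t")
  fwrite(data.table(gene_id = names(expr$gene_lengths),
                    length = as.integer(expr$gene_lengths)),
         p$gene_lengths, sep = "\t")
  fwrite(meth$truth, p$truth_dmrs, sep = "\t")
  fwrite(expr$truth, p$truth_degs, sep = "\t")
  invisible(list(genome = genome, annotation = annotation, methylomes = meth,
                 expression = expr, paths = p))
}
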