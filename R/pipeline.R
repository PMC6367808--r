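#' Default pipeline configuration
#'
#' Every knob of [run_comparison()] with its default. Supply overrides as a
#' nested list (or a YAML file of the same shape); unknown keys are rejected.
#'
#' @return Nested list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    outdir = "sportmethyl_run",
    simulate = TRUE,
    sim = list(),                # overrides forwarded to sim_config()
    inputs = list(genome = NULL, annotation = NULL, methylome_parent = NULL,
                  methylome_sport = NULL, counts = NULL, gene_lengths = NULL,
                  term_map = NULL),
    control_chrom = "chrC",
    min_depth = 4L,
    conversion_error = 0.005,
    dmr = list(window_bp = 200L, step_bp = 50L, min_sites = 5L, min_fold = 2,
               alpha = 0.05, fdr_mode = "raw", merge = TRUE,
               contexts = c("CG", "CHG", "CHH")),
    promoter_bp = 2000L,
    deg = list(min_fold = 2, min_prob = 0.8, pseudocount = 1),
    metagene = list(n_bins_body = 60L, flank_bp = 2000L, n_bins_flank = 20L),
    stages = list(summary = TRUE, dmrs = TRUE, degs = TRUE,
                  integration = TRUE, enrichment = TRUE)
  )
}

.merge_config <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) && !identical(names(defaults), NULL)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) && nm != "sim") {
      defaults[[nm]] <- .merge_config(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Run the full parent-vs-sport comparison pipeline
#'
#' Orchestrates simulate -> methylome summary -> DMR calling -> DEG calling ->
#' integration -> enrichment, writing every stage product plus a JSON run
#' manifest (package version, config hash, per-stage record counts and wall
#' clock, all thresholds) to `outdir`. The manifest is written even when a
#' stage fails, recording the failure point. With `simulate = FALSE` the
#' input files named under `inputs` are used and must exist before any
#' compute starts. Fully deterministic given the config (including seed).
#'
#' @param config A nested list of overrides over [default_run_config()], or
#'   the path to a YAML file holding one.
#' @param outdir,seed Convenience overrides of the config fields.
#' @return Invisibly, the run manifest (list).
#' @export
run_comparison <- function(config = list(), outdir = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(default_run_config(), config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(cfg$outdir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  manifest <- list(
    package = "sportmethyl",
    version = as.character(utils::packageVersion("sportmethyl")),
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = cfg$seed,
    thresholds = list(dmr = cfg$dmr, deg = cfg$deg, promoter_bp = cfg$promoter_bp,
                      min_depth = cfg$min_depth),
    stages = list(),
    status = "running"
  )
  manifest_path <- file.path(cfg$outdir, "manifest.json")
  flush_manifest <- function() {
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, force = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      manifest$status <<- "failed"
      manifest$failed_stage <<- name
      manifest$error <<- conditionMessage(e)
      flush_manifest()
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      n_records = if (is.data.frame(res)) nrow(res) else length(res),
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    flush_manifest()
    res
  }

  # --- inputs -------------------------------------------------------------
  if (isTRUE(cfg$simulate)) {
    sim <- stage("simulate", {
      sc <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
      simulate_comparison(sc, file.path(cfg$outdir, "fixtures"))
    })
    paths <- sim$paths
  } else {
    paths <- cfg$inputs
    need <- c("annotation", "methylome_parent", "methylome_sport", "counts",
              "gene_lengths")
    for (nm in need) {
      if (is.null(paths[[nm]]) || !file.exists(paths[[nm]])) {
        stop(sprintf("missing input '%s': %s", nm,
                     paths[[nm]] %||% "(not set)"), call. = FALSE)
      }
    }
  }
  annotation <- read_annotation(paths$annotation)
  parent <- read_cytosine_report(paths$methylome_parent)
  sport <- read_cytosine_report(paths$methylome_sport)
  counts_dt <- fread(paths$counts)
  counts <- as.matrix(counts_dt[, -1])
  rownames(counts) <- counts_dt[[1]]
  lens_dt <- fread(paths$gene_lengths)
  lens <- setNames(lens_dt$length, lens_dt$gene_id)
  conditions <- sub("_[0-9]+$", "", colnames(counts))

  # --- methylome summaries ------------------------------------------------
  if (isTRUE(cfg$stages$summary)) {
    stage("summary", {
      rows <- rbindlist(lapply(list(parent = parent, sport = sport), function(t) {
        s <- methylome_summary(t, cfg$min_depth, cfg$conversion_error,
                               cfg$control_chrom)
        data.table(context = METH_CONTEXTS,
                   level_pct = unname(s$level_by_context),
                   n_sites = unname(s$n_sites_covered),
                   mc_proportion = unname(s$mc_proportions),
                   conversion_rate_pct = s$conversion_rate)
      }), idcol = "sample")
      fwrite(rows, file.path(cfg$outdir, "methylome_summary.tsv"), sep = "\t")
      for (nm in c("parent", "sport")) {
        prof <- metagene_profile(get(nm), annotation$genes,
                                 cfg$metagene$n_bins_body, cfg$metagene$flank_bp,
                                 cfg$metagene$n_bins_flank)
        fwrite(data.table(context = rownames(prof), prof),
               file.path(cfg$outdir, sprintf("metagene_%s.tsv", nm)), sep = "\t")
      }
      rows
    })
  }

  # --- DMRs ---------------------------------------------------------------
  dmrs <- associations <- NULL
  if (isTRUE(cfg$stages$dmrs)) {
    dmrs <- stage("dmrs", {
      dp <- dmr_params(cfg$dmr$window_bp, cfg$dmr$step_bp, cfg$dmr$min_sites,
                       cfg$dmr$min_fold, cfg$dmr$alpha, cfg$dmr$fdr_mode,
                       cfg$dmr$merge)
      # the conversion control is a spike-in, not part of the genome under test
      d <- call_dmrs(parent[chrom != cfg$control_chrom],
                     sport[chrom != cfg$control_chrom],
                     dp, contexts = cfg$dmr$contexts)
      fwrite(d, file.path(cfg$outdir, "dmrs.tsv"), sep = "\t")
      write_dmr_bed(d, file.path(cfg$outdir, "dmrs.bed"))
      d
    })
    associations <- stage("associations", {
      a <- associate_dmrs(dmrs, annotation$genes, cfg$promoter_bp)
      fwrite(a, file.path(cfg$outdir, "dmr_associations.tsv"), sep = "\t")
      fwrite(dmr_association_counts(a),
             file.path(cfg$outdir, "dmr_association_counts.tsv"), sep = "\t")
      a
    })
  }

  # --- DEGs ---------------------------------------------------------------
  degs <- NULL
  if (isTRUE(cfg$stages$degs)) {
    degs <- stage("degs", {
      r <- divergence_probability(counts, lens, conditions,
                                  pseudocount = cfg$deg$pseudocount,
                                  seed = cfg$seed)
      r <- call_degs(r, cfg$deg$min_fold, cfg$deg$min_prob)
      fwrite(r, file.path(cfg$outdir, "degs.tsv"), sep = "\t")
      r
    })
  }

  # --- integration --------------------------------------------------------
  if (isTRUE(cfg$stages$integration)) {
    if (is.null(dmrs) || is.null(degs)) {
      manifest$status <- "failed"
      manifest$failed_stage <- "integration"
      manifest$error <- "integration requires the DMR and DEG stages"
      flush_manifest()
      stop("dependency error: integration requires the DMR and DEG stages",
           call. = FALSE)
    }
    stage("integration", {
      ct <- cross_tabulate(degs, associations)
      flat <- as.data.table(as.table(ct$counts))
      setnames(flat, c("deg", "dmr", "location", "n"))
      flat <- rbind(flat, data.table(deg = "any", dmr = "any", location = "any",
                                     n = round(ct$fraction * ct$n_deg)))
      fwrite(flat, file.path(cfg$outdir, "deg_dmr_crosstab.tsv"), sep = "\t")
      contrast <- suppressWarnings(
        methylation_expression_contrast(degs, associations))
      fwrite(contrast, file.path(cfg$outdir, "methylation_expression_contrast.tsv"),
             sep = "\t")
      flat
    })
  }

  # --- enrichment ---------------------------------------------------------
  if (isTRUE(cfg$stages$enrichment) && !is.null(paths$term_map)) {
    stage("enrichment", {
      tm <- fread(paths$term_map, col.names = c("term_id", "gene_id"))
      sel <- intersect(as.data.table(degs)[is_deg == TRUE, gene_id],
                       unique(tm$gene_id))
      e <- enrich_terms(sel, tm)
      fwrite(e, file.path(cfg$outdir, "enrichment.tsv"), sep = "\t")
      e
    })
  }

  manifest$status <- "ok"
  flush_manifest()
  invisible(manifest)
}
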