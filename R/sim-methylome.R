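#' Simulate a parent/sport methylome pair with planted DMRs
#'
#' Every cytosine of the genome (both strands) receives a context via
#' [classify_context()], a read depth drawn from a negative binomial with mean
#' `depth_mean`, and a methylated read count drawn binomially at the site's
#' true level. Outside planted regions the true level is
#' `baseline_levels[context]` in both samples; inside a planted DMR the two
#' samples sit at `dmr_levels["high"]` and `dmr_levels["low"]` — the sport
#' (sample 2) takes the high level for "hyper" plants and the low level for
#' "hypo" plants, matching the mutant-relative direction convention of the DMR
#' caller. Bisulfite conversion error reads unmethylated cytosines as
#' methylated at rate `conversion_error`. The conversion-control chromosome is
#' simulated fully unmethylated. Sites with zero simulated depth are omitted
#' (they are unobservable).
#'
#' Plants are placed uniformly, rejected on overlap; half are forced to
#' overlap a gene body or promoter (all promoters, direction "hypo", when
#' `couple_expression` is set) so the annotation and integration stages see
#' true positives, the rest are intergenic.
#'
#' @param genome A `DNAStringSet` from [simulate_genome()].
#' @param annotation A `gene_annotation`, or `NULL` for all-intergenic plants.
#' @param cfg A [sim_config()].
#' @return List with `parent` and `sport` methylome tables (`data.table` with
#'   columns chrom, pos, strand, context, n_meth, n_unmeth, sorted) and
#'   `truth` (`data.table` chrom, start, end, context, direction, target_gene,
#'   target_location).
#' @export
simulate_methylome_pair <- function(genome, annotation = NULL, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 2L, {
    sites <- rbindlist(lapply(names(genome), function(ch) {
      .cytosine_contexts(genome[[ch]], ch)
    }))
    setkey(sites, chrom, pos, strand)
    truth <- .place_dmrs(genome, annotation, cfg)
    base <- cfg$baseline_levels
    sites[, `:=`(p1 = base[context], p2 = base[context])]
    if (cfg$control_length > 0) {
      sites[chrom == cfg$control_chrom, `:=`(p1 = 0, p2 = 0)]
    }
    hi <- cfg$dmr_levels[["high"]]
    lo <- cfg$dmr_levels[["low"]]
    if (nrow(truth)) {
      for (i in seq_len(nrow(truth))) {
        tr <- truth[i]
        idx <- sites[chrom == tr$chrom & pos >= tr$start & pos <= tr$end &
                       context == tr$context, which = TRUE]
        if (tr$direction == "hyper") {
          sites[idx, `:=`(p1 = lo, p2 = hi)]
        } else {
          sites[idx, `:=`(p1 = hi, p2 = lo)]
        }
      }
    }
    n <- nrow(sites)
    err <- cfg$conversion_error
    draw_depth <- function() {
      if (cfg$depth_dispersion > 0) {
        rnbinom(n, mu = cfg$depth_mean, size = 1 / cfg$depth_dispersion)
      } else {
        rpois(n, cfg$depth_mean)
      }
    }
    mk <- function(depth, p) {
      m <- rbinom(n, depth, p + (1 - p) * err)
      tab <- sites[, .(chrom, pos, strand, context)]
      tab[, `:=`(n_meth = m, n_unmeth = depth - m)]
      tab <- tab[n_meth + n_unmeth > 0L]
      setkey(tab, chrom, pos, strand)
      tab[]
    }
    parent <- mk(draw_depth(), sites$p1)
    sport <- mk(draw_depth(), sites$p2)
    list(parent = parent, sport = sport, truth = truth)
  })
}

# uniform rejection placement of planted DMRs; returns truth table
.place_dmrs <- function(genome, annotation, cfg) {
  empty <- data.table(chrom = character(), start = integer(), end = integer(),
                      context = character(), direction = character(),
                      target_gene = character(), target_location = character())
  if (cfg$n_dmrs == 0L) return(empty)
  chroms <- setdiff(names(genome), cfg$control_chrom)
  lens <- .genome_lengths(genome)[chroms]
  len <- cfg$dmr_length
  if (cfg$n_dmrs * len > 0.5 * sum(lens)) {
    stop(sprintf("capacity error: %d DMRs x %d bp exceed half the genome (%d bp)",
                 cfg$n_dmrs, len, sum(lens)), call. = FALSE)
  }
  genes <- if (!is.null(annotation) && length(annotation$genes)) annotation$genes
  ctxs <- rep_len(cfg$dmr_context, cfg$n_dmrs)
  dirs <- rep_len(c("hyper", "hypo"), cfg$n_dmrs)
  n_genic <- if (is.null(genes)) 0L else cfg$n_dmrs %/% 2L
  if (cfg$couple_expression && n_genic > 0L) dirs[seq_len(n_genic)] <- "hypo"
  gdt <- if (!is.null(genes)) {
    data.table(chrom = as.character(seqnames(genes)), start = start(genes),
               end = end(genes), strand = as.character(strand(genes)),
               gene_id = mcols(genes)$gene_id)
  }
  placed <- data.table(chrom = character(), start = integer(), end = integer())
  out <- vector("list", cfg$n_dmrs)
  for (i in seq_len(cfg$n_dmrs)) {
    genic <- i <= n_genic
    ok <- FALSE
    for (try in seq_len(2000L)) {
      if (genic) {
        g <- gdt[sample(.N, 1L)]
        loc <- if (cfg$couple_expression) "promoter" else sample(c("body", "promoter"), 1L)
        tgt <- if (loc == "body") {
          c(g$start, g$end)
        } else if (g$strand == "+") {
          c(max(1L, g$start - 2000L), g$start - 1L)
        } else {
          c(g$end + 1L, g$end + 2000L)
        }
        if (tgt[2] < tgt[1]) next
        L <- lens[[g$chrom]]
        lo <- max(1L, tgt[1] - len + 1L)
        hi <- min(tgt[2], L - len + 1L)
        if (hi < lo) next
        s <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        ch <- g$chrom
      } else {
        ch <- sample(chroms, 1L, prob = lens)
        L <- lens[[ch]]
        if (L < len) next
        s <- sample.int(L - len + 1L, 1L)
      }
      e <- s + len - 1L
      if (nrow(placed[chrom == ch & start <= e & end >= s])) next
      if (!genic && !is.null(gdt) &&
          nrow(gdt[chrom == ch & start - 2000L <= e & end + 2000L >= s])) next
      placed <- rbind(placed, data.table(chrom = ch, start = s, end = e))
      out[[i]] <- data.table(
        chrom = ch, start = s, end = e, context = ctxs[i], direction = dirs[i],
        target_gene = if (genic) g$gene_id else NA_character_,
        target_location = if (genic) loc else "intergenic")
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("capacity error: could not place all planted DMRs without overlap",
           call. = FALSE)
    }
  }
  res <- rbindlist(out)
  setorder(res, chrom, start)
  res[]
}
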