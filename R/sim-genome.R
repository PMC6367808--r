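#' Simulate a genome
#'
#' Draws `n_chrom` i.i.d. nucleotide sequences at the configured GC fraction,
#' plus (when `control_length > 0`) one extra chromosome used downstream as the
#' fully unmethylated conversion control.
#'
#' @param cfg A [sim_config()].
#' @return A [Biostrings::DNAStringSet] named `chr1..chrN` (and the control
#'   chromosome last).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    gc <- cfg$gc_fraction
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    lens <- cfg$chrom_length
    nms <- paste0("chr", seq_len(cfg$n_chrom))
    if (cfg$control_length > 0) {
      lens <- c(lens, cfg$control_length)
      nms <- c(nms, cfg$control_chrom)
    }
    seqs <- vapply(lens, function(L) {
      paste(sample(names(probs), L, replace = TRUE, prob = probs), collapse = "")
    }, character(1))
    DNAStringSet(setNames(seqs, nms))
  })
}

#' Simulate a gene annotation
#'
#' Places `n_genes` non-overlapping, strand-assigned genes (about half per
#' strand) on the non-control chromosomes, each with at least one exon and at
#' least 2 kb of clearance from neighbours and chromosome ends so that every
#' gene owns an intact promoter interval.
#'
#' @param genome A `DNAStringSet` from [simulate_genome()].
#' @param cfg A [sim_config()].
#' @return A `gene_annotation`: list with `genes` (a `GRanges` carrying
#'   `gene_id`) and `exons` (a `GRanges` carrying `gene_id`, sorted,
#'   non-overlapping, inside the gene span).
#' @export
simulate_annotation <- function(genome, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  flank <- 2000L
  chroms <- setdiff(names(genome), cfg$control_chrom)
  lens <- .genome_lengths(genome)[chroms]
  withr::with_seed(cfg$seed + 1L, {
    n <- cfg$n_genes
    if (n == 0L) {
      genes <- GRanges(seqlengths = .genome_lengths(genome))
      mcols(genes)$gene_id <- character(0)
      return(structure(list(genes = genes, exons = genes), class = "gene_annotation"))
    }
    max_len <- max(cfg$gene_length_range)
    # proportional allocation of genes to chromosomes
    alloc <- floor(n * lens / sum(lens))
    rem <- n - sum(alloc)
    if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
    rows <- list()
    for (ch in chroms) {
      k <- alloc[[ch]]
      if (k == 0L) next
      need <- k * max_len + (k + 1L) * flank
      if (need > lens[[ch]]) {
        stop(sprintf("capacity error: cannot fit %d genes (+2 kb flanks) on %s (%d bp)",
                     k, ch, lens[[ch]]), call. = FALSE)
      }
      glen <- sample(seq(cfg$gene_length_range[1], cfg$gene_length_range[2]), k,
                     replace = TRUE)
      free <- lens[[ch]] - sum(glen) - (k + 1L) * flank
      extra <- as.vector(rmultinom(1, free, rep(1 / (k + 1L), k + 1L)))
      gaps <- flank + extra
      starts <- 1L + cumsum(gaps[seq_len(k)]) +
        c(0L, cumsum(glen))[seq_len(k)]
      rows[[ch]] <- data.table(chrom = ch, start = starts, end = starts + glen - 1L)
    }
    gdt <- rbindlist(rows)
    gdt[, gene_id := sprintf("gene_%04d", seq_len(.N))]
    gdt[, strand := sample(rep_len(c("+", "-"), .N))]
    # exon structure: alternate exon/intron segments, each >= 30 bp
    ex <- gdt[, {
      glen <- end - start + 1L
      n_ex <- sample(seq(cfg$exon_range[1], cfg$exon_range[2]), 1L)
      m <- 2L * n_ex - 1L
      while (m > 1L && glen < 30L * m) { n_ex <- n_ex - 1L; m <- 2L * n_ex - 1L }
      seg <- 30L + as.vector(rmultinom(1, glen - 30L * m, rep(1 / m, m)))
      off <- cumsum(c(0L, seg[-m]))
      is_exon <- seq_len(m) %% 2L == 1L
      .(exon_start = start + off[is_exon],
        exon_end = start + off[is_exon] + seg[is_exon] - 1L)
    }, by = .(chrom, gene_id, strand)]
    sl <- .genome_lengths(genome)
    genes <- GRanges(gdt$chrom, IRanges(gdt$start, gdt$end), strand = gdt$strand,
                     gene_id = gdt$gene_id, seqlengths = sl)
    exons <- GRanges(ex$chrom, IRanges(ex$exon_start, ex$exon_end), strand = ex$strand,
                     gene_id = ex$gene_id, seqlengths = sl)
    structure(list(genes = genes, exons = exons), class = "gene_annotation")
  })
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes, %d exons on %d sequence(s)\n",
              length(x$genes), length(x$exons),
              length(unique(as.character(seqnames(x$genes))))))
  invisible(x)
}

#' Transcript lengths from an annotation
#'
#' Sum of exon widths per gene, the length used by [fpkm()].
#'
#' @param annotation A `gene_annotation`.
#' @return Named integer vector of lengths (bp).
#' @export
gene_lengths <- function(annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  dt <- data.table(gene_id = mcols(annotation$exons)$gene_id,
                   w = width(annotation$exons))
  v <- dt[, .(len = sum(w)), by = gene_id]
  setNames(v$len, v$gene_id)
}

#' Write / read a gene annotation as GFF3
#'
#' Standard 1-based inclusive GFF3 with `gene` and `exon` features linked by
#' `ID`/`Parent` attributes, via \pkg{rtracklayer}.
#'
#' @param annotation A `gene_annotation`.
#' @param path Output/input file path.
#' @return `write_annotation` returns `path` invisibly; `read_annotation`
#'   returns a `gene_annotation`.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "gene_annotation"))
  g <- annotation$genes
  e <- annotation$exons
  mcols(g) <- S4Vectors::DataFrame(type = "gene", ID = mcols(g)$gene_id)
  ord <- order(as.character(seqnames(e)), start(e))
  e <- e[ord]
  mcols(e) <- S4Vectors::DataFrame(
    type = "exon",
    ID = sprintf("%s.exon%d", mcols(annotation$exons)$gene_id[ord],
                 seq_along(e)),
    Parent = as(as.list(mcols(annotation$exons)$gene_id[ord]), "CharacterList"))
  rtracklayer::export(c(g, e), path, format = "gff3")
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  exons <- gr[gr$type == "exon"]
  gid <- genes$ID
  eid <- as.character(unlist(exons$Parent))
  mcols(genes) <- S4Vectors::DataFrame(gene_id = gid)
  mcols(exons) <- S4Vectors::DataFrame(gene_id = eid)
  structure(list(genes = genes, exons = exons), class = "gene_annotation")
}
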