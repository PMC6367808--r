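#' Cross-tabulate DEGs against DMR associations
#'
#' Counts, for each combination of DEG direction (up/down), DMR direction
#' (hyper/hypo) and location (body/promoter), the DEG genes carrying at least
#' one matching DMR link; a gene with several link types counts in every
#' matching cell. Also reports the fraction of DEGs carrying any DMR link.
#'
#' @param deg_results Output of [call_degs()].
#' @param associations Output of [associate_dmrs()].
#' @return List: `counts` (2 x 2 x 2 array, deg x dmr x location),
#'   `fraction` (DMR-associated DEGs / DEGs), `n_deg`.
#' @export
cross_tabulate <- function(deg_results, associations) {
  degs <- as.data.table(deg_results)[is_deg == TRUE]
  links <- unique(as.data.table(associations)[, .(gene_id, location, direction)])
  counts <- array(0L, dim = c(2, 2, 2),
                  dimnames = list(deg = c("up", "down"),
                                  dmr = c("hyper", "hypo"),
                                  location = c("body", "promoter")))
  if (nrow(degs) && nrow(links)) {
    joined <- merge(degs[, .(gene_id, deg_direction = direction)], links,
                    by = "gene_id")
    cell <- joined[, .(n = uniqueN(gene_id)), by = .(deg_direction, direction, location)]
    for (r in seq_len(nrow(cell))) {
      counts[cell$deg_direction[r], cell$direction[r], cell$location[r]] <- cell$n[r]
    }
  }
  fraction <- if (nrow(degs)) {
    length(intersect(degs$gene_id, links$gene_id)) / nrow(degs)
  } else 0
  list(counts = counts, fraction = fraction, n_deg = nrow(degs))
}

#' Contrast expression change of gene sets against the background
#'
#' Five-number summaries (box-plot quartiles) of log2 fold change for each
#' supplied gene set and a two-sided Wilcoxon rank-sum test of each set
#' against all genes. Sets smaller than 3 get their summary but the test is
#' skipped with a warning.
#'
#' @param M Named numeric vector of per-gene log2 fold changes (all genes).
#' @param sets Named list of gene-id character vectors; every member must
#'   have an M value.
#' @return `data.table`: set, n, min, q1, median, q3, max, p_value.
#' @export
expression_contrast <- function(M, sets) {
  if (is.null(names(M))) stop("'M' must be named by gene id", call. = FALSE)
  rows <- lapply(names(sets), function(nm) {
    ids <- sets[[nm]]
    missing <- setdiff(ids, names(M))
    if (length(missing)) {
      stop(sprintf("set '%s' has members without an M value: %s", nm,
                   paste(head(missing, 3), collapse = ", ")), call. = FALSE)
    }
    x <- M[ids]
    fn <- if (length(x)) fivenum(x) else rep(NA_real_, 5)
    p <- if (length(x) < 3L) {
      warning(sprintf("set '%s' smaller than 3: rank test skipped", nm),
              call. = FALSE)
      NA_real_
    } else {
      suppressWarnings(wilcox.test(x, M, alternative = "two.sided")$p.value)
    }
    data.table(set = nm, n = length(x), min = fn[1], q1 = fn[2], median = fn[3],
               q3 = fn[4], max = fn[5], p_value = p)
  })
  rbindlist(rows)
}

#' Expression change of DMR-associated gene classes
#'
#' Builds the four canonical DMR gene sets (hyper/hypo x body/promoter) from
#' the association table plus the all-gene background, and runs
#' [expression_contrast()].
#'
#' @param results Output of [divergence_probability()] / [call_degs()].
#' @param associations Output of [associate_dmrs()].
#' @return `data.table` as for [expression_contrast()] (the "all" row has no
#'   test).
#' @export
methylation_expression_contrast <- function(results, associations) {
  res <- as.data.table(results)
  M <- setNames(res$M, res$gene_id)
  links <- unique(as.data.table(associations)[, .(gene_id, location, direction)])
  sets <- list()
  for (dir in c("hyper", "hypo")) {
    for (loc in c("body", "promoter")) {
      sets[[paste(dir, loc, sep = "-")]] <-
        links[direction == dir & location == loc, unique(gene_id)]
    }
  }
  sets$all <- names(M)
  expression_contrast(M, sets)
}

#' Flat gene-set enrichment with Bonferroni correction
#'
#' Hypergeometric upper-tail enrichment of a selected gene list against flat
#' term-to-gene maps (serving GO-style and pathway-style inputs alike; no
#' ontology traversal). Terms without selected members are reported as
#' untested; the Bonferroni factor is the number of tested terms; terms with
#' `p_bonferroni <= 0.05` are significant.
#'
#' @param selected Character vector of selected gene ids (must lie in the
#'   universe).
#' @param term_map `data.frame`/`data.table` with columns term_id, gene_id.
#' @param universe Background gene ids; defaults to all genes in `term_map`.
#' @return `data.table` sorted by p: term_id, k (selected in term), K (term
#'   size in universe), n (selected), N (universe), p_raw, p_bonferroni,
#'   significant, tested.
#' @export
enrich_terms <- function(selected, term_map, universe = NULL) {
  tm <- as.data.table(term_map)
  if (!all(c("term_id", "gene_id") %in% names(tm))) {
    stop("'term_map' needs columns term_id and gene_id", call. = FALSE)
  }
  universe <- unique(universe %||% tm$gene_id)
  tm <- unique(tm[gene_id %in% universe])
  selected <- unique(selected)
  off <- setdiff(selected, universe)
  if (length(off)) {
    stop(sprintf("domain error: selected genes outside the universe: %s",
                 paste(head(off, 5), collapse = ", ")), call. = FALSE)
  }
  N <- length(universe)
  n <- length(selected)
  per <- tm[, .(K = uniqueN(gene_id), k = sum(unique(gene_id) %in% selected)),
            by = term_id]
  per[, tested := k >= 1L]
  n_tested <- sum(per$tested)
  per[, p_raw := ifelse(tested, phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                        NA_real_)]
  per[, p_bonferroni := pmin(1, p_raw * n_tested)]
  per[, `:=`(n = n, N = N, significant = !is.na(p_bonferroni) & p_bonferroni <= 0.05)]
  setorder(per, -tested, p_raw, na.last = TRUE)
  per[, .(term_id, k, K, n, N, p_raw, p_bonferroni, significant, tested)]
}
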