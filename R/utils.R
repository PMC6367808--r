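# internal helpers shared across modules

METH_CONTEXTS <- c("CG", "CHG", "CHH")

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    stop(sprintf("'%s' must be a single finite number in [%s, %s]", name, min, max),
         call. = FALSE)
  }
  invisible(x)
}

.assert_methylome <- function(tab, name = "methylome table") {
  req <- c("chrom", "pos", "strand", "n_meth", "n_unmeth", "context")
  if (!is.data.frame(tab) || !all(req %in% names(tab))) {
    stop(sprintf("%s must contain columns: %s", name, paste(req, collapse = ", ")),
         call. = FALSE)
  }
  invisible(tab)
}

# chromosome lengths inferred from the right-most covered position of either sample;
# only used when the caller does not supply true lengths (trailing empty windows
# carry no sites and cannot change any call)
.infer_chrom_lengths <- function(...) {
  tabs <- list(...)
  dt <- rbindlist(lapply(tabs, function(t) as.data.table(t)[, .(chrom, pos)]))
  v <- dt[, .(len = max(pos)), by = chrom]
  setNames(v$len, v$chrom)
}

.genome_lengths <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}
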