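#' Classify the sequence context of a cytosine
#'
#' Plant methylomes distinguish CG, CHG and CHH contexts (H = A, T or C),
#' read 5'->3' on the strand carrying the cytosine. On the minus strand the
#' reference shows a G and the two following bases are the complements of the
#' reference bases immediately upstream.
#'
#' A site whose next base is G is CG (one downstream base suffices); otherwise
#' two downstream bases are required and the call is CHG if the second-next
#' base is G, else CHH; with insufficient sequence the result is
#' `"undetermined"`.
#'
#' @param sequence A single reference sequence (character or `DNAString`).
#' @param pos 1-based position(s) of the cytosine on the reference.
#' @param strand `"+"` or `"-"`, recycled along `pos`.
#' @return Character vector in `c("CG","CHG","CHH","undetermined")`.
#' @export
classify_context <- function(sequence, pos, strand = "+") {
  chars <- strsplit(toupper(as.character(sequence)), "", fixed = TRUE)[[1]]
  L <- length(chars)
  strand <- rep_len(strand, length(pos))
  if (any(pos < 1L | pos > L)) stop("'pos' out of range", call. = FALSE)
  base <- chars[pos]
  bad <- (strand == "+" & base != "C") | (strand == "-" & base != "G")
  if (any(bad)) {
    stop(sprintf("position %d is not a cytosine on strand %s (reference base %s)",
                 pos[bad][1], strand[bad][1], base[bad][1]), call. = FALSE)
  }
  out <- character(length(pos))
  plus <- strand == "+"
  nxt <- ifelse(plus, pos + 1L, pos - 1L)
  nxt2 <- ifelse(plus, pos + 2L, pos - 2L)
  n1 <- ifelse(nxt >= 1L & nxt <= L, chars[pmin(pmax(nxt, 1L), L)], NA_character_)
  n2 <- ifelse(nxt2 >= 1L & nxt2 <= L, chars[pmin(pmax(nxt2, 1L), L)], NA_character_)
  # on the minus strand a G in the reference reads as C 5'->3'
  is_g1 <- ifelse(plus, n1 == "G", n1 == "C")
  is_g2 <- ifelse(plus, n2 == "G", n2 == "C")
  out[is.na(n1)] <- "undetermined"
  cg <- !is.na(n1) & is_g1
  out[cg] <- "CG"
  rest <- !is.na(n1) & !is_g1
  out[rest & is.na(n2)] <- "undetermined"
  out[rest & !is.na(n2) & is_g2] <- "CHG"
  out[rest & !is.na(n2) & !is_g2] <- "CHH"
  out
}

# all cytosines of one chromosome sequence, both strands, with context;
# boundary sites with undetermined context are dropped
.cytosine_contexts <- function(sequence, chrom = "chr") {
  chars <- strsplit(toupper(as.character(sequence)), "", fixed = TRUE)[[1]]
  L <- length(chars)
  res <- list()
  ip <- which(chars == "C")
  if (length(ip)) {
    n1 <- c(chars[-1], NA)[ip]
    n2 <- c(chars[-(1:2)], NA, NA)[ip]
    ctx <- fifelse(!is.na(n1) & n1 == "G", "CG",
                   fifelse(!is.na(n2) & n2 == "G", "CHG",
                           fifelse(!is.na(n2), "CHH", NA_character_)))
    res$plus <- data.table(chrom = chrom, pos = ip, strand = "+", context = ctx)
  }
  im <- which(chars == "G")
  if (length(im)) {
    p1 <- c(NA, chars[-L])[im]
    p2 <- c(NA, NA, chars[seq_len(max(L - 2L, 0L))])[im]
    ctx <- fifelse(!is.na(p1) & p1 == "C", "CG",
                   fifelse(!is.na(p2) & p2 == "C", "CHG",
                           fifelse(!is.na(p2), "CHH", NA_character_)))
    res$minus <- data.table(chrom = chrom, pos = im, strand = "-", context = ctx)
  }
  dt <- rbindlist(res)
  if (!nrow(dt)) {
    return(data.table(chrom = character(), pos = integer(),
                      strand = character(), context = character()))
  }
  dt <- dt[!is.na(context)]
  setorder(dt, pos, strand)
  dt[]
}
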