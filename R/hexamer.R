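## Hexamer log-odds coding-potential model.
##
## The score of a coding sequence is the mean, over its in-frame hexamers
## (offsets 0, 3, 6, ... from the first base of the first codon), of
## log2 f_coding(h) / f_background(h). Coding frequencies are estimated from
## in-frame hexamer counts of a training set; background frequencies from
## every offset of both strands of a background sequence. Both are smoothed
## with an additive pseudocount.

ALL_HEXAMERS <- local({
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)[, 6:1]
  do.call(paste0, g)
})

count_hexamers <- function(seqs, step) {
  tot <- setNames(numeric(4096L), ALL_HEXAMERS)
  for (s in seqs) {
    L <- nchar(s)
    if (L < 6L) next
    pos <- seq.int(1L, L - 5L, by = step)
    h <- substring(s, pos, pos + 5L)
    tab <- table(factor(h, levels = ALL_HEXAMERS))  # N-containing drop out
    tot <- tot + as.numeric(tab)
  }
  tot
}

#' Train a hexamer log-odds coding model
#'
#' Coding hexamers are counted in frame (codon offsets 0, 3, 6, ...);
#' background hexamers at every offset of both strands of the background
#' sequence. Entries are `log2(f_coding / f_background)` in bits, with
#' additive-pseudocount smoothing of both frequency estimates.
#'
#' @param coding Character vector of coding nucleotide sequences (each read
#'   from the first base of a codon).
#' @param background A background nucleotide string (typically the genome).
#' @param pseudocount Additive smoothing count (default 1).
#' @return An object of class `hexamer_model`: a named numeric vector of
#'   4096 finite log-odds entries, with training metadata attributes.
#' @export
train_hexamer_model <- function(coding, background, pseudocount = 1) {
  if (!length(coding) || all(nchar(coding) == 0L))
    stop("empty coding training input", call. = FALSE)
  if (!is.character(background) || nchar(background[1]) == 0L)
    stop("empty background training input", call. = FALSE)
  coding <- toupper(coding)
  background <- toupper(background[1])
  total_coding <- sum(nchar(coding))
  if (total_coding < 6000L)
    warning("coding training set is short (", total_coding,
            " nt < 6 kb); estimates will be noisy", call. = FALSE)
  cc <- count_hexamers(coding, step = 3L)
  cb <- count_hexamers(c(background, revcomp(background)), step = 1L)
  fc <- (cc + pseudocount) / (sum(cc) + pseudocount * 4096)
  fb <- (cb + pseudocount) / (sum(cb) + pseudocount * 4096)
  structure(log2(fc / fb), class = "hexamer_model",
            pseudocount = pseudocount,
            n_coding_nt = total_coding,
            n_background_nt = nchar(background))
}

#' @export
print.hexamer_model <- function(x, ...) {
  cat(sprintf(
    "<hexamer_model> 4096 log-odds entries (bits); trained on %s coding nt vs %s background nt\n",
    format(attr(x, "n_coding_nt"), big.mark = ","),
    format(attr(x, "n_background_nt"), big.mark = ",")))
  invisible(x)
}

#' Score a coding sequence under a hexamer model
#'
#' Returns the mean model entry over the in-frame hexamers of `orf_seq`
#' (positions 0, 3, ..., L-6), in bits per hexamer. Hexamers containing N
#' are excluded from the mean and flagged with a warning.
#'
#' @param model A `hexamer_model`.
#' @param orf_seq Nucleotide string, length divisible by 3, at least 2 codons.
#' @return Numeric scalar (bits/hexamer).
#' @export
score_orf <- function(model, orf_seq) {
  stopifnot(inherits(model, "hexamer_model"))
  orf_seq <- toupper(orf_seq)
  L <- nchar(orf_seq)
  if (L %% 3L != 0L)
    stop("sequence length not divisible by 3", call. = FALSE)
  if (L < 6L)
    stop("need at least 2 codons", call. = FALSE)
  pos <- seq.int(1L, L - 5L, by = 3L)
  h <- substring(orf_seq, pos, pos + 5L)
  e <- unname(model[h])
  if (anyNA(e)) {
    warning("sequence contains ambiguous bases; ",
            sum(is.na(e)), " hexamers skipped", call. = FALSE)
    e <- e[!is.na(e)]
  }
  mean(e)
}
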