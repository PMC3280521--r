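## Tandem direct-repeat discovery by consensus scoring.
##
## A candidate array at (start, unit_size, count) is scored against the
## per-column majority consensus of its units: score = matches - mismatches.
## This is the classical tandem-array statistic reported with a cutoff score
## (100 by default) alongside span, unit size, copy number, percent identity
## and the consensus string.

encode_dna <- function(seq) {
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  code <- match(x, c("A", "C", "G", "T", "N")) - 1L
  if (anyNA(code))
    stop("illegal characters in sequence", call. = FALSE)
  code
}

#' Score a tandem array against its column consensus
#'
#' The window starting at `start` is cut into `count` consecutive units of
#' `unit_size` bases. The consensus base of column j is the most frequent
#' base at position j across units (ties to the alphabetically first);
#' `score = matches - mismatches` and `pct_id = 100 * matches / (unit_size *
#' count)`.
#'
#' @param seq Nucleotide string.
#' @param start 1-based start of the array.
#' @param unit_size Repeat unit length in bp.
#' @param count Number of copies (at least 2).
#' @return A list with `score`, `pct_id`, `consensus` (lower case) and
#'   `matches`.
#' @examples
#' score_array(strrep("ACGT", 3), 1, 4, 3)   # perfect: score 12, 100%
#' @export
score_array <- function(seq, start, unit_size, count) {
  if (count < 2L) stop("count must be >= 2", call. = FALSE)
  L <- nchar(seq)
  if (start < 1L || start + unit_size * count - 1L > L)
    stop("array window out of range", call. = FALSE)
  win <- substr(seq, start, start + unit_size * count - 1L)
  code <- encode_dna(win) + 1L
  m <- matrix(code, nrow = unit_size)          # columns = units
  counts <- vapply(1:5, function(b) rowSums(m == b), numeric(unit_size))
  counts <- matrix(counts, nrow = unit_size)   # unit_size x 5
  matches <- sum(apply(counts, 1L, max))
  cons <- c("a", "c", "g", "t", "n")[max.col(counts, ties.method = "first")]
  total <- unit_size * count
  list(score = as.integer(2L * matches - total),
       pct_id = 100 * matches / total,
       consensus = paste(cons, collapse = ""),
       matches = as.integer(matches))
}

#' Find tandem direct repeats
#'
#' For every unit size in `[min_unit, max_unit]` and every phase, maximal
#' arrays (grown by whole units while the consensus score increases) with
#' score at least `min_score` are collected. Overlapping reports are reduced
#' to local maxima: among reports with overlapping footprints only the
#' highest-scoring is kept, ties resolved by smaller unit size then smaller
#' start. The search is linear (origin-wrapping arrays are not reported).
#'
#' @param seq Nucleotide string or `circular_genome`.
#' @param min_unit,max_unit Unit-size range in bp (defaults 10 and 100).
#' @param min_score Score cutoff (default 100).
#' @return A data frame of class `tandem_repeats` with columns `start`,
#'   `end`, `score`, `unit_size`, `count`, `pct_id`, `consensus`, sorted by
#'   start.
#' @export
find_tandem_repeats <- function(seq, min_unit = 10L, max_unit = 100L,
                                min_score = 100L) {
  if (inherits(seq, "circular_genome")) seq <- seq$sequence
  seq <- toupper(seq)
  if (min_unit > max_unit)
    stop("min_unit > max_unit", call. = FALSE)
  if (nchar(seq) < 2L * min_unit)
    stop("sequence shorter than two units", call. = FALSE)
  raw <- tandem_scan_cpp(encode_dna(seq), as.integer(min_unit),
                         as.integer(max_unit), as.integer(min_score))
  raw <- as.data.frame(raw)
  empty <- data.frame(start = integer(0), end = integer(0),
                      score = integer(0), unit_size = integer(0),
                      count = integer(0), pct_id = numeric(0),
                      consensus = character(0))
  if (!nrow(raw))
    return(structure(empty, class = c("tandem_repeats", "data.frame")))
  raw$end <- raw$start + raw$unit_size * raw$count - 1L
  ## local-maxima reduction over overlapping footprints
  o <- order(-raw$score, raw$unit_size, raw$start)
  raw <- raw[o, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(raw))) {
    if (!length(kept) ||
        all(raw$start[i] > raw$end[kept] | raw$end[i] < raw$start[kept]))
      kept <- c(kept, i)
  }
  out <- raw[kept, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  det <- lapply(seq_len(nrow(out)), function(i)
    score_array(seq, out$start[i], out$unit_size[i], out$count[i]))
  out$pct_id <- round(vapply(det, `[[`, numeric(1), "pct_id"), 1)
  out$consensus <- vapply(det, `[[`, character(1), "consensus")
  out <- out[, c("start", "end", "score", "unit_size", "count",
                 "pct_id", "consensus")]
  rownames(out) <- NULL
  structure(out, class = c("tandem_repeats", "data.frame"))
}

#' Validate a tandem-repeat table row by row
#'
#' Checks the structural invariants of each reported array: the span equals
#' `unit_size * count`, the copy number is at least 2, percent identity lies
#' in \[0, 100\], the score does not exceed `unit_size * count`, and the
#' consensus (when present) has `unit_size` characters.
#'
#' @param table Data frame with columns `start`, `end`, `unit_size`, `count`,
#'   and optionally `score`, `pct_id`, `consensus`.
#' @return A data frame of per-row logical checks plus an overall `pass`.
#' @export
verify_repeat_table <- function(table) {
  n <- nrow(table)
  span_ok <- table$end - table$start + 1L == table$unit_size * table$count
  count_ok <- table$count >= 2L
  pct_ok <- if (!is.null(table$pct_id))
    table$pct_id >= 0 & table$pct_id <= 100 else rep(TRUE, n)
  score_ok <- if (!is.null(table$score))
    table$score <= table$unit_size * table$count else rep(TRUE, n)
  cons_ok <- if (!is.null(table$consensus))
    nchar(table$consensus) == table$unit_size else rep(TRUE, n)
  out <- data.frame(span_ok = span_ok, count_ok = count_ok,
                    pct_id_ok = pct_ok, score_ok = score_ok,
                    consensus_ok = cons_ok)
  out$pass <- Reduce(`&`, out)
  if (!is.null(table$dr_id)) rownames(out) <- table$dr_id
  out
}
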