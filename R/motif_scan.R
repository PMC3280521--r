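## Degenerate motif scanning for proteins and DNA.
##
## One grammar normalizes the notations in which such motifs are commonly
## written: literals match themselves; x/X is a wildcard; `x4`, `X2`, `(2x)`
## and `(x)` denote wildcard repeats; `Q/N` is an alternative at one
## position; in protein mode `U` is the bulky-hydrophobic class
## {F,I,L,M,V,W,Y}; in DNA mode IUPAC ambiguity codes expand to their base
## classes; dashes and parentheses are separators.

protein_class <- function(letter) {
  if (letter %in% AMINO_ACIDS) return(letter)
  if (letter == "U") return(BULKY_HYDROPHOBIC)
  NULL
}

dna_class <- function(letter) IUPAC_DNA[[letter]]

#' Parse a degenerate motif notation
#'
#' @param notation Motif string, e.g. `"YxDTD"`, `"K(3x)NS(x)YG(2x)G"`,
#'   `"GxKx4HGQ/NKG"`, `"G-X2-G-X-G-K"` or (DNA mode) `"DTAAG"`.
#' @param alphabet `"protein"` or `"dna"`.
#' @param name Optional pattern name (defaults to the notation).
#' @return An object of class `motif_pattern`: a list with one residue-class
#'   character vector per position.
#' @export
parse_pattern <- function(notation, alphabet = c("protein", "dna"),
                          name = notation) {
  alphabet <- match.arg(alphabet)
  if (!is.character(notation) || !nzchar(notation))
    stop("empty motif notation", call. = FALSE)
  s <- gsub("-", "", notation)
  full <- if (alphabet == "protein") AMINO_ACIDS else DNA_BASES
  classify <- if (alphabet == "protein") protein_class else dna_class
  elements <- list()
  while (nzchar(s)) {
    if (grepl("^\\(\\d*[xX]\\)", s)) {          # (3x), (x)
      tok <- regmatches(s, regexpr("^\\(\\d*[xX]\\)", s))
      n <- suppressWarnings(as.integer(gsub("\\D", "", tok)))
      if (is.na(n)) n <- 1L
      elements <- c(elements, rep(list(full), n))
    } else if (grepl("^[xX]", s)) {
      tok <- regmatches(s, regexpr("^[xX]\\d*", s))
      n <- suppressWarnings(as.integer(gsub("\\D", "", tok)))
      if (is.na(n)) n <- 1L
      elements <- c(elements, rep(list(full), n))
    } else if (grepl("^[A-Za-z](/[A-Za-z])*", s)) {
      tok <- regmatches(s, regexpr("^[A-Za-z](/[A-Za-z])*", s))
      letters <- toupper(strsplit(tok, "/", fixed = TRUE)[[1]])
      cls <- unlist(lapply(letters, function(l) {
        cl <- classify(l)
        if (is.null(cl))
          stop("unparseable token '", l, "' in motif '", notation, "'",
               call. = FALSE)
        cl
      }))
      elements <- c(elements, list(sort(unique(cls))))
    } else {
      stop("unparseable token '", substr(s, 1L, 1L), "' in motif '",
           notation, "'", call. = FALSE)
    }
    s <- substr(s, nchar(tok) + 1L, nchar(s))
  }
  if (!length(elements))
    stop("motif '", notation, "' has no positions", call. = FALSE)
  structure(list(name = name, notation = notation, alphabet = alphabet,
                 elements = elements),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s (%s, %d positions)\n", x$notation,
              x$alphabet, length(x$elements)))
  invisible(x)
}

#' @export
length.motif_pattern <- function(x) length(x$elements)

#' Scan a sequence for a degenerate motif
#'
#' Reports all (possibly overlapping) matches, left to right, with 1-based
#' residue coordinates.
#'
#' @param pattern A `motif_pattern` or a notation string (parsed with the
#'   default alphabet `"protein"`).
#' @param seq Residue string.
#' @param seq_id Identifier recorded in the hits.
#' @return A data frame with columns `pattern`, `seq_id`, `start`, `end`,
#'   `match`.
#' @examples
#' scan_motif("KxDG", "AKLDGA")   # hit at 2..5
#' @export
scan_motif <- function(pattern, seq, seq_id = "seq") {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  k <- length(pattern$elements)
  n <- length(chars)
  empty <- data.frame(pattern = character(0), seq_id = character(0),
                      start = integer(0), end = integer(0),
                      match = character(0))
  if (n < k) return(empty)
  ok <- rep(TRUE, n - k + 1L)
  for (j in seq_len(k)) {
    m <- chars %in% pattern$elements[[j]]
    ok <- ok & m[j:(n - k + j)]
  }
  hits <- which(ok)
  if (!length(hits)) return(empty)
  data.frame(pattern = pattern$name, seq_id = seq_id,
             start = hits, end = hits + k - 1L,
             match = substring(toupper(seq), hits, hits + k - 1L))
}

#' Search the upstream region of an ORF for a DNA motif
#'
#' Scans the `window` bases immediately 5' of the start codon on the ORF's
#' coding strand (circular-aware) and returns hits in genome coordinates,
#' oriented along the coding strand (so reverse-strand hits print start >
#' end).
#'
#' @param genome A `circular_genome`.
#' @param orf One row of a `feature_table`.
#' @param motif DNA pattern notation or `motif_pattern` (default `"TAAG"`).
#' @param window Upstream window size in bp (default 500).
#' @return A data frame of hits with genome coordinates `start`, `end` and
#'   the upstream offset `upstream_pos` (1 = window's 5' end).
#' @export
upstream_search <- function(genome, orf, motif = "TAAG", window = 500L) {
  if (is.character(motif)) motif <- parse_pattern(motif, alphabet = "dna")
  L <- genome$length
  if (window >= L)
    stop("window must be smaller than the genome", call. = FALSE)
  if (orf$strand == "F") {
    from <- orf$start - window
    wrap <- from < 1L
    if (wrap && !genome$circular) { from <- 1L; wrap <- FALSE }
    from <- wrap_coord(from, L)
    up <- fetch(genome, from, wrap_coord(orf$start - 1L, L), "F", wrap = wrap)
  } else {
    to <- orf$start + window
    wrap <- to > L
    if (wrap && !genome$circular) { to <- L; wrap <- FALSE }
    to <- wrap_coord(to, L)
    up <- fetch(genome, to, wrap_coord(orf$start + 1L, L), "R", wrap = wrap)
  }
  hits <- scan_motif(motif, up, seq_id = genome$id)
  if (!nrow(hits)) {
    hits$upstream_pos <- integer(0)
    return(hits)
  }
  w <- nchar(up)
  hits$upstream_pos <- hits$start
  if (orf$strand == "F") {
    g0 <- orf$start - w                       # coordinate of upstream_pos 1
    hits$start <- wrap_coord(g0 + hits$upstream_pos - 1L, L)
    hits$end <- wrap_coord(g0 + hits$end - 1L, L)
  } else {
    g0 <- orf$start + w
    ends <- wrap_coord(g0 - (hits$upstream_pos + length(motif) - 1L) + 1L, L)
    hits$start <- wrap_coord(g0 - hits$upstream_pos + 1L, L)
    hits$end <- ends
  }
  hits
}

#' Hydrophobic segments by sliding-window hydropathy
#'
#' Computes the Kyte-Doolittle sliding-window mean and merges maximal runs of
#' windows whose mean exceeds `threshold` into segments. A plain hydropathy
#' heuristic for transmembrane-like stretches; no topology or signal-peptide
#' prediction is attempted.
#'
#' @param protein Residue string, length at least `window`.
#' @param window Window size in residues (default 19).
#' @param threshold Window-mean threshold (default 1.6).
#' @return A data frame with `start`, `end` (residue coordinates of the
#'   merged segment) and `mean_hydropathy` over the segment.
#' @export
hydropathy_segments <- function(protein, window = 19L, threshold = 1.6) {
  chars <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < window)
    stop("protein shorter than the window", call. = FALSE)
  h <- unname(KD_HYDROPATHY[chars])
  if (anyNA(h))
    stop("unknown residues in protein sequence", call. = FALSE)
  cs <- c(0, cumsum(h))
  wm <- (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
  above <- wm > threshold
  if (!any(above))
    return(data.frame(start = integer(0), end = integer(0),
                      mean_hydropathy = numeric(0)))
  r <- rle(above)
  stops <- cumsum(r$lengths)
  starts <- c(1L, head(stops, -1L) + 1L)
  seg <- which(r$values)
  out <- data.frame(start = starts[seg],
                    end = stops[seg] + window - 1L)
  out$mean_hydropathy <- vapply(seq_len(nrow(out)), function(i)
    mean(h[out$start[i]:out$end[i]]), numeric(1))
  out
}

#' Conserved cysteine columns of a protein alignment
#'
#' @param aln Character vector of equal-length gapped rows (named by taxon),
#'   or a `protein_alignment`.
#' @param min_frac Minimum fraction of non-gap residues that must be C for a
#'   column to be reported (default 1, full conservation).
#' @return Integer vector of 1-based alignment columns.
#' @export
cysteine_profile <- function(aln, min_frac = 1) {
  rows <- as.character(aln)
  if (length(unique(nchar(rows))) != 1L)
    stop("ragged alignment", call. = FALSE)
  m <- do.call(rbind, strsplit(toupper(rows), "", fixed = TRUE))
  nongap <- colSums(m != "-")
  ncys <- colSums(m == "C")
  which(nongap > 0L & ncys / pmax(nongap, 1L) >= min_frac)
}

#' Catalog of degenerate motifs used in nudivirus genome annotation
#'
#' Returns the packaged motif catalog: promoter and enzymatic signature
#' motifs reported for HzNV-2 proteins, one notation per row with its
#' alphabet and the ORF context in which it occurs.
#'
#' @return A data frame with columns `name`, `notation`, `alphabet`, `context`.
#' @export
motif_catalog <- function() {
  path <- system.file("extdata", "motif_catalog.tsv", package = "nudiannot",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
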