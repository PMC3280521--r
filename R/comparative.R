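## Two-genome comparison: ortholog parity/colinearity, windowed identity
## profiles over a pairwise alignment, core-gene audits and local gene-layout
## comparison.

#' Gene parity (colinearity) analysis of an ortholog mapping
#'
#' Pairs are ordered by query ordinal; the colinear count is the length of
#' the longest run of strictly increasing subject ordinals (a longest
#' increasing subsequence, so duplicated subjects cannot both contribute).
#' Descending adjacent steps are counted as inversions; the query ordinals at
#' which monotonicity breaks are reported as breakpoints.
#'
#' @param pairs Data frame with columns `query` and `subject` (positive
#'   ordinals; queries unique).
#' @return An object of class `parity_result` with fields `n_pairs`,
#'   `n_colinear`, `inversions`, `breakpoints` and a plot-ready `xy` table.
#' @export
parity <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("query", "subject") %in% names(pairs)))
  if (!nrow(pairs)) stop("need at least one pair", call. = FALSE)
  if (anyDuplicated(pairs$query))
    stop("duplicate query ordinals", call. = FALSE)
  if (any(pairs$query < 1L) || any(pairs$subject < 1L))
    stop("ordinals must be positive", call. = FALSE)
  o <- order(pairs$query)
  y <- pairs$subject[o]
  ## patience-style longest strictly increasing subsequence
  tails <- integer(0)
  for (v in y) {
    k <- findInterval(v - 1L, tails) + 1L   # first tail >= v
    if (k > length(tails)) tails <- c(tails, v) else tails[k] <- v
  }
  d <- diff(y)
  structure(list(
    n_pairs = nrow(pairs),
    n_colinear = length(tails),
    inversions = sum(d < 0L),
    breakpoints = pairs$query[o][which(d <= 0L)],
    xy = data.frame(query = pairs$query[o], subject = y)),
    class = "parity_result")
}

#' @export
print.parity_result <- function(x, ...) {
  cat(sprintf(
    "Gene parity: %d of %d pairs colinear; %d inversions, %d breakpoints\n",
    x$n_colinear, x$n_pairs, x$inversions, length(x$breakpoints)))
  invisible(x)
}

#' Windowed percent identity over a pairwise alignment
#'
#' Windows are consecutive tiles of the ungapped base sequence; the identity
#' of a window is computed over all alignment columns it spans, counting gap
#' columns as mismatches. Windows at or above `threshold` are flagged.
#'
#' @param base,partner Equal-length gapped sequences; `base` is the
#'   coordinate frame.
#' @param window Tile size in base-sequence bp (default 100).
#' @param threshold Highlight threshold in percent (default 95).
#' @return A data frame of class `window_identity` with columns `start`,
#'   `end` (base coordinates), `identity` and `flagged`.
#' @export
window_identity <- function(base, partner, window = 100L, threshold = 95) {
  if (nchar(base) != nchar(partner))
    stop("ragged alignment", call. = FALSE)
  a <- strsplit(toupper(base), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(partner), "", fixed = TRUE)[[1]]
  base_cols <- which(a != "-")
  nb <- length(base_cols)
  if (!nb) stop("base sequence is all gaps", call. = FALSE)
  match_col <- as.integer(a == b & a != "-")
  cs <- c(0L, cumsum(match_col))
  starts <- seq.int(1L, nb, by = window)
  ends <- pmin(starts + window - 1L, nb)
  c1 <- base_cols[starts]
  c2 <- base_cols[ends]
  ## a window spans from its first base's column to the column before the
  ## next window's first base, so insertions in the partner are charged to
  ## the window they interrupt
  c2span <- c(base_cols[starts[-1L]] - 1L, base_cols[nb])
  matched <- cs[c2span + 1L] - cs[c1]
  span <- c2span - c1 + 1L
  id <- 100 * matched / span
  structure(data.frame(start = starts, end = ends, identity = id,
                       flagged = id >= threshold),
            class = c("window_identity", "data.frame"),
            window = window, threshold = threshold)
}

#' Percent identity of a gapped sequence pair
#'
#' Both conventions are reported: identity over all alignment columns and
#' identity over base-sequence positions (gap columns in the base excluded).
#'
#' @param base,partner Equal-length gapped sequences.
#' @return Named numeric vector `c(over_columns =, over_base =)` in percent.
#' @export
alignment_identity <- function(base, partner) {
  if (nchar(base) != nchar(partner))
    stop("ragged alignment", call. = FALSE)
  a <- strsplit(toupper(base), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(partner), "", fixed = TRUE)[[1]]
  m <- a == b & a != "-"
  c(over_columns = 100 * sum(m) / length(a),
    over_base = 100 * sum(m) / sum(a != "-"))
}

#' Global pairwise alignment with affine gaps
#'
#' Optimal global (Needleman-Wunsch) alignment with affine gap penalties; a
#' gap of length k costs `gap_open + k * gap_extend`. Intended for sequences
#' up to ~100 kb; for genome-scale comparisons supply an externally produced
#' alignment to [window_identity()] instead.
#'
#' @param a,b Nucleotide strings.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters (defaults
#'   +1/-1/-5/-1).
#' @return A list with `score`, `aligned_a`, `aligned_b` and `identity`
#'   (percent over alignment columns).
#' @export
global_align <- function(a, b, match = 1, mismatch = -1,
                         gap_open = -5, gap_extend = -1) {
  if (!nzchar(a) || !nzchar(b)) stop("empty input", call. = FALSE)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(a)), Biostrings::DNAString(toupper(b)),
    type = "global", substitutionMatrix = mat,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend))
  pa <- as.character(Biostrings::alignedPattern(aln))
  ps <- as.character(Biostrings::alignedSubject(aln))
  list(score = Biostrings::score(aln), aligned_a = pa, aligned_b = ps,
       identity = unname(alignment_identity(pa, ps)["over_columns"]))
}

#' Packaged ORF table of the HzNV-2 genome
#'
#' The 113-row annotation table of the 231,621 bp circular HzNV-2 genome
#' (GenBank JN418988): strand, coding-orientation coordinates, lengths and
#' predicted-function annotations.
#'
#' @return A `feature_table`.
#' @export
hznv2_orf_table <- function() {
  path <- system.file("extdata", "hznv2_orfs.tsv", package = "nudiannot",
                      mustWork = TRUE)
  read_feature_table(path, genome_id = "HzNV-2", genome_length = 231621L)
}

#' Packaged direct-repeat table of the HzNV-2 genome
#'
#' The six tandem direct-repeat arrays (dr1..dr6) of HzNV-2 with their
#' reported span, score, unit size, copy number, percent identity and
#' consensus.
#'
#' @return A data frame.
#' @export
hznv2_repeat_table <- function() {
  path <- system.file("extdata", "hznv2_drs.tsv", package = "nudiannot",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Packaged baculovirus core-gene catalog
#'
#' The 30 genes conserved across all sequenced baculovirus genomes, with
#' their ac-number aliases, functional category (replication, transcription,
#' virus entry, structural, auxiliary, unknown) and the free-text aliases
#' used to match predicted-function annotations.
#'
#' @return A data frame with columns `gene`, `ac_alias`, `category`,
#'   `match_aliases` (pipe-separated).
#' @export
baculovirus_core_genes <- function() {
  path <- system.file("extdata", "core_gene_catalog.tsv",
                      package = "nudiannot", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$category <- factor(df$category,
                        levels = c("replication", "transcription",
                                   "virus entry", "structural",
                                   "auxiliary", "unknown"))
  df
}

#' Audit an annotation against a core-gene catalog
#'
#' Marks each catalog gene present iff at least one annotation row's
#' predicted-function text matches its name or one of its aliases
#' (case-insensitive, at word boundaries). Output is grouped by the six
#' functional categories.
#'
#' @param annotations A `feature_table` with a `predicted_function` column.
#' @param catalog A catalog as returned by [baculovirus_core_genes()].
#' @return A data frame of class `core_gene_audit` with `gene`, `ac_alias`,
#'   `category`, `present` and `matched_orfs`.
#' @export
core_gene_audit <- function(annotations, catalog = baculovirus_core_genes()) {
  text <- annotations$predicted_function
  if (is.null(text)) text <- character(0)
  ids <- annotations$orf_id %||% rep(NA_character_, length(text))
  res <- lapply(seq_len(nrow(catalog)), function(i) {
    aliases <- strsplit(catalog$match_aliases[i], "|", fixed = TRUE)[[1]]
    pat <- paste0("\\b(", paste(vapply(aliases, function(x)
      gsub("([][\\\\^$.|?*+(){}-])", "\\\\\\1", x),
      character(1)), collapse = "|"), ")\\b")
    hit <- grepl(pat, text, ignore.case = TRUE, perl = TRUE)
    list(present = any(hit),
         matched = paste(ids[hit], collapse = ","))
  })
  out <- data.frame(gene = catalog$gene, ac_alias = catalog$ac_alias,
                    category = catalog$category,
                    present = vapply(res, `[[`, logical(1), "present"),
                    matched_orfs = vapply(res, `[[`, character(1), "matched"))
  out <- out[order(out$category), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("core_gene_audit", "data.frame"))
}

#' @export
print.core_gene_audit <- function(x, ...) {
  cat(sprintf("Core-gene audit: %d of %d present\n",
              sum(x$present), nrow(x)))
  for (cat_ in unique(as.character(x$category))) {
    sub <- x[x$category == cat_, ]
    cat(sprintf("  %-13s present: %s | absent: %s\n", cat_,
                paste(sub$gene[sub$present], collapse = ", "),
                paste(sub$gene[!sub$present], collapse = ", ")))
  }
  invisible(x)
}

circ_dist <- function(from, to, L) {
  fwd <- (to - from) %% L
  c(downstream = fwd, upstream = (L - fwd) %% L)
}

#' Compare the layout of a gene neighborhood between two genomes
#'
#' For every gene shared between the two layouts, reports whether its
#' relative order among the shared genes changed, whether its strand
#' (relative to the anchor gene, the first shared gene of `layout_a`)
#' flipped, and its distance to the anchor in each genome. When genome
#' lengths are given, circular distances are reported both ways.
#'
#' @param layout_a,layout_b Data frames with columns `gene`, `strand`
#'   (F/R or +/-), `position` (representative coordinate, e.g. coding start).
#' @param genome_length_a,genome_length_b Optional circular genome lengths.
#' @return A data frame of class `neighborhood_comparison` with one row per
#'   shared gene.
#' @export
compare_gene_neighborhood <- function(layout_a, layout_b,
                                      genome_length_a = NULL,
                                      genome_length_b = NULL) {
  norm_strand <- function(s) ifelse(s %in% c("F", "+"), 1L, -1L)
  shared <- intersect(layout_a$gene, layout_b$gene)
  if (!length(shared)) stop("no shared genes", call. = FALSE)
  a <- layout_a[match(shared, layout_a$gene), ]
  b <- layout_b[match(shared, layout_b$gene), ]
  anchor <- shared[1L]
  sa <- norm_strand(a$strand); sb <- norm_strand(b$strand)
  rel_a <- sa * sa[1L]; rel_b <- sb * sb[1L]
  rank_a <- rank(a$position); rank_b <- rank(b$position)
  da <- a$position - a$position[1L]
  db <- b$position - b$position[1L]
  out <- data.frame(gene = shared,
                    anchor = shared == anchor,
                    order_a = rank_a, order_b = rank_b,
                    order_changed = rank_a != rank_b,
                    strand_flipped = rel_a != rel_b,
                    dist_a = da, dist_b = db)
  if (!is.null(genome_length_a)) {
    cd <- vapply(a$position, function(p)
      circ_dist(a$position[1L], p, genome_length_a), numeric(2))
    out$dist_a_downstream <- cd[1, ]; out$dist_a_upstream <- cd[2, ]
  }
  if (!is.null(genome_length_b)) {
    cd <- vapply(b$position, function(p)
      circ_dist(b$position[1L], p, genome_length_b), numeric(2))
    out$dist_b_downstream <- cd[1, ]; out$dist_b_upstream <- cd[2, ]
  }
  structure(out, class = c("neighborhood_comparison", "data.frame"),
            anchor = anchor)
}
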