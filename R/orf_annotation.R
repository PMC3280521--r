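## ORF enumeration, filtering and summary statistics on circular genomes.
##
## Conventions (matching the tabulated-ORF format this package reproduces):
##  * start = first base of the ATG on the coding strand, in forward-genome
##    coordinates; end = last base of the last sense codon (stop excluded);
##  * length_nt = |start - end| + 1 for non-wrapping ORFs, always 3*length_aa;
##  * reverse-strand ORFs therefore print start > end.

## scan one strand (given as its coding-direction string); returns positions
## in that strand's own 5'->3' coordinates
scan_orfs_strand <- function(seqstr, circular, min_aa) {
  L <- nchar(seqstr)
  scanned <- if (circular) paste0(seqstr, seqstr, substr(seqstr, 1L, 4L)) else seqstr
  out <- vector("list", 3L)
  for (frame in 0:2) {
    cs <- seq.int(frame + 1L, nchar(scanned) - 2L, by = 3L)
    codons <- substring(scanned, cs, cs + 2L)
    stop_i <- which(codons %in% STOP_CODONS)
    if (length(stop_i) < 1L) next
    atg_i <- which(codons == "ATG")
    if (!length(atg_i)) next
    ## first in-frame ATG after each stop. Intervals are bounded by stops on
    ## both sides; the doubled sequence supplies the wrap-around interval for
    ## circular genomes, while a linear genome additionally admits the
    ## leading interval before its first stop.
    if (circular) {
      if (length(stop_i) < 2L) next
      prev_stop <- stop_i[-length(stop_i)]
      next_stop <- stop_i[-1L]
    } else {
      prev_stop <- c(0L, stop_i[-length(stop_i)])
      next_stop <- stop_i
    }
    first_atg <- atg_i[findInterval(prev_stop, atg_i) + 1L]
    keep <- !is.na(first_atg) & first_atg < next_stop
    a <- first_atg[keep]; t <- next_stop[keep]
    aa <- t - a
    p <- (a - 1L) * 3L + frame + 1L      # base position of the ATG
    sel <- aa >= min_aa & p <= L & aa * 3L <= L
    out[[frame + 1L]] <- data.frame(pos = p[sel], aa = aa[sel])
  }
  do.call(rbind, c(out, list(data.frame(pos = integer(0), aa = integer(0)))))
}

#' Enumerate candidate ORFs on both strands of a genome
#'
#' Scans all six reading frames, including frames running through the origin
#' of a circular genome. An ORF runs from an ATG to the codon before the next
#' in-frame stop; for each stop-bounded interval only the longest ORF (the
#' first in-frame ATG) is emitted. On a linear genome, runs missing an
#' upstream or downstream in-frame stop are not called.
#'
#' @param genome A [circular_genome()].
#' @param min_aa Minimum protein length in amino acids (start Met included,
#'   stop excluded). Default 60.
#' @return A `feature_table` with columns `orf_id`, `strand`, `start`, `end`,
#'   `length_nt`, `length_aa`, `wraps`.
#' @export
enumerate_orfs <- function(genome, min_aa = 60L) {
  stopifnot(inherits(genome, "circular_genome"))
  L <- genome$length
  if (L < 3L * (min_aa + 1L))
    stop("genome shorter than ", 3L * (min_aa + 1L),
         " bp cannot hold a ", min_aa, " aa ORF", call. = FALSE)
  fw <- scan_orfs_strand(genome$sequence, genome$circular, min_aa)
  rv <- scan_orfs_strand(revcomp(genome$sequence), genome$circular, min_aa)
  rec <- function(pos, aa, strand) {
    if (!length(pos))
      return(data.frame(strand = character(0), start = integer(0),
                        end = integer(0), length_nt = integer(0),
                        length_aa = integer(0), wraps = logical(0)))
    end_s <- pos + aa * 3L - 1L           # strand-local coordinates
    wraps <- end_s > L
    if (strand == "F") {
      start_g <- pos
      end_g <- wrap_coord(end_s, L)
    } else {
      start_g <- L - pos + 1L
      end_g <- L - wrap_coord(end_s, L) + 1L
    }
    data.frame(strand = strand, start = start_g, end = end_g,
               length_nt = aa * 3L, length_aa = aa, wraps = wraps)
  }
  df <- rbind(rec(fw$pos, fw$aa, "F"), rec(rv$pos, rv$aa, "R"))
  df <- df[order(pmin(df$start, df$end), df$strand), , drop = FALSE]
  df <- cbind(orf_id = sprintf("orf%04d", seq_len(nrow(df))), df)
  as_feature_table(df, genome$id, L)
}

#' Extract the nucleotide sequence of an ORF
#'
#' Returns the coding-strand sequence (stop codon excluded), honouring the
#' wrap flag on circular genomes.
#'
#' @param genome A `circular_genome`.
#' @param orf One row of a `feature_table`.
#' @return A nucleotide string of length `length_nt`.
#' @export
orf_sequence <- function(genome, orf) {
  fetch(genome, orf$start, orf$end, orf$strand,
        wrap = isTRUE(orf$wraps))
}

## circular footprint: arc start (forward coordinate of the lowest-coordinate
## end when linear; entry point of the arc when wrapping) and arc length
orf_arcs <- function(orfs) {
  list(a = ifelse(orfs$strand == "F", orfs$start, orfs$end),
       len = orfs$length_nt)
}

#' Remove ORFs nested inside longer ORFs
#'
#' An ORF is dropped iff its genomic footprint (unordered interval,
#' circular-aware) lies entirely within the footprint of a strictly longer
#' ORF on either strand. Equal-length ORFs are never dropped against each
#' other.
#'
#' @param orfs A `feature_table`.
#' @param genome_length Genome length in bp (defaults to the table attribute).
#' @return The filtered `feature_table`.
#' @export
remove_nested <- function(orfs, genome_length = attr(orfs, "genome_length")) {
  n <- nrow(orfs)
  if (n < 2L) return(orfs)
  L <- genome_length
  arc <- orf_arcs(orfs)
  drop <- logical(n)
  for (i in seq_len(n)) {
    off <- (arc$a[i] - arc$a) %% L
    contained <- arc$len > arc$len[i] & off + arc$len[i] <= arc$len
    contained[i] <- FALSE
    if (any(contained)) drop[i] <- TRUE
  }
  out <- orfs[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## pairwise circular arc overlap (bp)
arc_overlap <- function(a1, l1, a2, l2, L) {
  off <- (a2 - a1) %% L
  ov1 <- pmax(0L, pmin(l1, off + l2) - off) * (off < l1)
  tail_len <- pmax(0L, off + l2 - L)
  ov2 <- pmin(l1, tail_len)
  ov <- ov1 + ov2
  pmin(ov, pmin(l1, l2))
}

#' Resolve significantly overlapping ORFs by coding score
#'
#' While any pair of ORFs overlaps by more than `max_overlap_frac` of the
#' shorter member's length, the lower-scoring member of the worst-offending
#' pair is removed. Score ties are broken by keeping the longer ORF, then the
#' one with the smaller start coordinate; the procedure is deterministic.
#'
#' @param orfs A scored `feature_table` (column `coding_score`).
#' @param genome_length Genome length in bp.
#' @param max_overlap_frac Maximum tolerated overlap as a fraction of the
#'   shorter ORF. Default 0.30.
#' @return The filtered `feature_table`.
#' @export
resolve_overlaps <- function(orfs, genome_length = attr(orfs, "genome_length"),
                             max_overlap_frac = 0.30) {
  if (is.null(orfs$coding_score) || anyNA(orfs$coding_score))
    stop("every ORF must carry a coding_score", call. = FALSE)
  n <- nrow(orfs)
  if (n < 2L) return(orfs)
  L <- genome_length
  arc <- orf_arcs(orfs)
  frac <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ov <- arc_overlap(arc$a[i], arc$len[i], arc$a, arc$len, L)
    frac[i, ] <- ov / pmin(arc$len[i], arc$len)
  }
  diag(frac) <- 0
  alive <- rep(TRUE, n)
  repeat {
    f <- frac
    f[!alive, ] <- 0; f[, !alive] <- 0
    worst <- max(f)
    if (worst <= max_overlap_frac) break
    idx <- which(f == worst, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    ## remove the lower-scoring member; ties keep the longer, then the
    ## smaller start coordinate
    si <- orfs$coding_score[i]; sj <- orfs$coding_score[j]
    loser <-
      if (si < sj) i else if (sj < si) j
      else if (orfs$length_nt[i] > orfs$length_nt[j]) j
      else if (orfs$length_nt[j] > orfs$length_nt[i]) i
      else if (orfs$start[i] <= orfs$start[j]) j else i
    alive[loser] <- FALSE
  }
  out <- orfs[alive, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summary statistics of an annotated genome
#'
#' Gene density is genome kb per gene (2 decimals); coding density is the
#' percentage of the genome covered by ORF spans, overlaps not merged,
#' rounded to an integer; mean length is in kb (1 decimal). Clusters are
#' maximal runs of genome-ordered ORFs on a common strand whose inter-ORF gap
#' is at most `cluster_gap_bp`.
#'
#' @param orfs A `feature_table`.
#' @param genome_length Genome length in bp.
#' @param cluster_gap_bp Maximum within-cluster gap (default 2000).
#' @return An object of class `annotation_summary`.
#' @export
summarize_annotation <- function(orfs,
                                 genome_length = attr(orfs, "genome_length"),
                                 cluster_gap_bp = 2000L) {
  if (!nrow(orfs)) stop("no ORFs to summarize", call. = FALSE)
  arc <- orf_arcs(orfs)
  o <- order(arc$a)
  a <- arc$a[o]; len <- arc$len[o]; strand <- orfs$strand[o]
  gap <- a[-1L] - (a[-length(a)] + len[-length(len)])
  new_cluster <- c(TRUE, strand[-1L] != strand[-length(strand)] |
                           gap > cluster_gap_bp)
  cluster_id <- cumsum(new_cluster)
  sizes <- as.integer(table(cluster_id))
  structure(list(
    n_orfs = nrow(orfs),
    n_forward = sum(orfs$strand == "F"),
    n_reverse = sum(orfs$strand == "R"),
    gene_density_kb_per_gene = round(genome_length / 1000 / nrow(orfs), 2),
    coding_density_pct = round(100 * sum(orfs$length_nt) / genome_length),
    mean_length_kb = round(mean(orfs$length_nt) / 1000, 1),
    n_clusters = length(sizes),
    cluster_sizes = sizes,
    genome_length = genome_length), class = "annotation_summary")
}

#' @export
print.annotation_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Annotation summary: %d ORFs (%d forward / %d reverse)\n",
           "  gene density  %.2f kb/gene\n",
           "  coding density  %d%%\n",
           "  mean ORF length %.1f kb\n",
           "  %d clusters of %d to %d ORFs\n"),
    x$n_orfs, x$n_forward, x$n_reverse, x$gene_density_kb_per_gene,
    x$coding_density_pct, x$mean_length_kb, x$n_clusters,
    min(x$cluster_sizes), max(x$cluster_sizes)))
  invisible(x)
}

#' Annotate a genome end to end
#'
#' Runs the full selection pipeline: six-frame ORF enumeration, removal of
#' nested ORFs, hexamer coding-potential scoring (self-trained: the seed
#' coding set is all candidates of at least `train_min_nt` bases, with one
#' re-estimation pass over the candidates that score above `score_min`),
#' score filtering, and overlap resolution.
#'
#' @param genome A `circular_genome`.
#' @param min_aa Minimum ORF length in aa (default 60).
#' @param score_min Minimum coding score in bits/hexamer (default 0).
#' @param max_overlap_frac Overlap threshold passed to [resolve_overlaps()].
#' @param train_min_nt Minimum candidate length for the seed training set.
#' @param pseudocount Hexamer model pseudocount.
#' @return A list of class `genome_annotation` with elements `orfs` (final
#'   `feature_table` including `coding_score`), `model` (the hexamer model),
#'   `stage_counts` (candidates surviving each stage) and `summary`.
#' @export
annotate_genome <- function(genome, min_aa = 60L, score_min = 0,
                            max_overlap_frac = 0.30, train_min_nt = 900L,
                            pseudocount = 1) {
  cand <- enumerate_orfs(genome, min_aa = min_aa)
  counts <- c(enumerated = nrow(cand))
  cand <- remove_nested(cand)
  counts["unnested"] <- nrow(cand)
  seqs <- vapply(seq_len(nrow(cand)),
                 function(i) orf_sequence(genome, cand[i, ]), character(1))
  seed <- seqs[cand$length_nt >= train_min_nt]
  if (!length(seed)) seed <- seqs
  model <- train_hexamer_model(seed, genome$sequence,
                               pseudocount = pseudocount)
  sc <- vapply(seqs, function(s) score_orf(model, s), numeric(1),
               USE.NAMES = FALSE)
  retrain <- seqs[sc > score_min]
  if (length(retrain) >= 2L) {
    model <- train_hexamer_model(retrain, genome$sequence,
                                 pseudocount = pseudocount)
    sc <- vapply(seqs, function(s) score_orf(model, s), numeric(1),
                 USE.NAMES = FALSE)
  }
  cand$coding_score <- sc
  kept <- cand[sc >= score_min, , drop = FALSE]
  counts["scored"] <- nrow(kept)
  final <- resolve_overlaps(kept, genome$length,
                            max_overlap_frac = max_overlap_frac)
  counts["final"] <- nrow(final)
  final$orf_id <- sprintf("orf%04d", seq_len(nrow(final)))
  rownames(final) <- NULL
  structure(list(orfs = as_feature_table(final, genome$id, genome$length),
                 model = model, stage_counts = counts,
                 summary = summarize_annotation(final, genome$length)),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation>\n  stage counts: ",
      paste(sprintf("%s=%d", names(x$stage_counts), x$stage_counts),
            collapse = " -> "), "\n", sep = "")
  print(x$summary)
  invisible(x)
}
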