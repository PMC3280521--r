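## Sequence and annotation-table I/O, circular-coordinate access.
##
## Coordinates are 1-based inclusive throughout. Reverse-strand features keep
## the coding-strand orientation (start = first base of the start codon, so
## start > end for non-wrapping reverse ORFs); conversion to start <= end
## happens only when writing GFF3.

#' Construct a circular genome object
#'
#' A `circular_genome` is a nucleotide sequence over `{A,C,G,T,N}` together
#' with its topology. It is the coordinate frame for every other operation in
#' the package.
#'
#' @param sequence Character scalar, the nucleotide sequence. Lower case is
#'   folded to upper case.
#' @param id Sequence identifier.
#' @param circular Logical; `TRUE` for a circular topology.
#' @return An object of class `circular_genome` with fields `id`, `sequence`,
#'   `circular` and `length`.
#' @examples
#' g <- circular_genome("ACGTACGT", id = "toy")
#' g$length
#' @export
circular_genome <- function(sequence, id = "genome", circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L)
    stop("empty sequence", call. = FALSE)
  bad <- gsub("[ACGTN]", "", sequence)
  if (nchar(bad) > 0L)
    stop("illegal characters in sequence: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "),
         call. = FALSE)
  structure(
    list(id = as.character(id), sequence = sequence,
         circular = isTRUE(circular), length = nchar(sequence)),
    class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %s bp (%s)\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' Reads the first record of a FASTA file as a [circular_genome()]. Characters
#' outside `{A,C,G,T,N}` are rejected; multi-record files require explicit
#' selection via `record`.
#'
#' @param path Path to a FASTA file.
#' @param circular Logical topology flag.
#' @param record Index of the record to read (default 1).
#' @return A `circular_genome`.
#' @export
read_genome <- function(path, circular = TRUE, record = 1L) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    stop("no FASTA records in ", path, call. = FALSE)
  if (record > length(set))
    stop("record ", record, " requested but file has ", length(set),
         call. = FALSE)
  circular_genome(as.character(set[[record]]),
                  id = sub("\\s.*$", "", names(set)[record]),
                  circular = circular)
}

#' Write a genome to a FASTA file
#'
#' @param genome A `circular_genome`.
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  x <- Biostrings::DNAStringSet(genome$sequence)
  names(x) <- genome$id
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## wrap a coordinate onto 1..L
wrap_coord <- function(x, L) ((x - 1L) %% L) + 1L

#' Fetch a sequence segment in genome coordinates
#'
#' For `strand = "F"` the forward bases `start..end` are returned. For
#' `strand = "R"` the reverse complement of the segment `end..start` is
#' returned, so that the string begins with the base at coordinate `start` on
#' the coding strand (the orientation in which reverse-strand ORFs are
#' tabulated, with start > end). Segments through the origin of a circular
#' genome are requested with the explicit `wrap` flag, never by coordinate
#' order.
#'
#' @param genome A `circular_genome`.
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"F"` or `"R"`.
#' @param wrap Logical; segment passes through the origin.
#' @return A nucleotide string.
#' @examples
#' g <- circular_genome("ACGTT")
#' fetch(g, 1, 3)             # "ACG"
#' fetch(g, 3, 1, "R")        # "CGT"
#' @export
fetch <- function(genome, start, end, strand = c("F", "R"), wrap = FALSE) {
  strand <- match.arg(strand)
  L <- genome$length
  if (start < 1L || end < 1L || start > L || end > L)
    stop("coordinates out of range [1, ", L, "]", call. = FALSE)
  if (wrap && !genome$circular)
    stop("wrap requested on a linear genome", call. = FALSE)
  seg <- function(a, b) {           # forward segment a..b, a <= b unless wrap
    if (!wrap) {
      substr(genome$sequence, a, b)
    } else {
      paste0(substr(genome$sequence, a, L), substr(genome$sequence, 1L, b))
    }
  }
  if (strand == "F") {
    if (!wrap && start > end)
      stop("start > end on the forward strand requires wrap = TRUE",
           call. = FALSE)
    seg(start, end)
  } else {
    if (!wrap && end > start)
      stop("end > start on the reverse strand requires wrap = TRUE",
           call. = FALSE)
    revcomp(seg(end, start))
  }
}

## ---- feature tables -------------------------------------------------------

ORF_COLUMNS <- c("orf_id", "strand", "start", "end", "length_nt", "length_aa")

as_feature_table <- function(df, genome_id = "genome", genome_length = NA_integer_) {
  stopifnot(all(ORF_COLUMNS %in% names(df)))
  if (anyDuplicated(df$orf_id))
    stop("duplicate orf ids", call. = FALSE)
  df <- df[order(pmin(df$start, df$end)), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("feature_table", "data.frame"),
            genome_id = genome_id, genome_length = genome_length)
}

#' Read a feature table (TSV)
#'
#' Columns follow the tabulated ORF convention: `orf_id`, `strand` (F/R),
#' `start`, `end` (1-based inclusive, coding orientation), `length_nt`,
#' `length_aa`, plus free annotation columns.
#'
#' @param path TSV path.
#' @param genome_id,genome_length Provenance attributes.
#' @return A `feature_table` (data frame).
#' @export
read_feature_table <- function(path, genome_id = "genome",
                               genome_length = NA_integer_) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                   na.strings = NULL)
  for (col in intersect(c("start", "end", "length_nt", "length_aa"),
                        names(df)))
    df[[col]] <- as.integer(df[[col]])
  if (!is.null(df$wraps)) df$wraps <- as.logical(df$wraps)
  if (!is.null(df$coding_score)) df$coding_score <- as.numeric(df$coding_score)
  as_feature_table(df, genome_id, genome_length)
}

#' Write a feature table as TSV or GFF3
#'
#' The TSV format round-trips the table unchanged. GFF3 uses 1-based
#' inclusive coordinates with start <= end and strand +/-; the coding-start
#' side of reverse-strand records is preserved in a `coding_start` attribute.
#'
#' @param table A `feature_table` or compatible data frame.
#' @param path Output path.
#' @param format `"tsv"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  seqid <- attr(table, "genome_id") %||% "genome"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(table)) {
    lo <- pmin(table$start, table$end)
    hi <- pmax(table$start, table$end)
    attrs <- sprintf("ID=%s;coding_start=%d%s", table$orf_id, table$start,
                     if (!is.null(table$wraps))
                       ifelse(table$wraps, ";wraps=true", "") else "")
    writeLines(sprintf("%s\tnudiannot\tCDS\t%d\t%d\t%s\t%s\t0\t%s",
                       seqid, lo, hi,
                       if (!is.null(table$coding_score))
                         formatC(table$coding_score, format = "g") else ".",
                       ifelse(table$strand == "F", "+", "-"), attrs),
               con)
  }
  invisible(path)
}
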