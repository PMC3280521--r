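## Synthetic genomes, ortholog pairs and protein families with known ground
## truth, so that every pipeline stage can be validated without downloads.
##
## Default spec values emulate the HzNV-2 study system: a 231,621 bp circular
## genome at 41.9% G+C carrying 113 codon-biased genes, tandem direct-repeat
## arrays of tens of bp repeated a handful to dozens of times, and an
## ortholog diverged by point substitution plus one unique inserted block.

default_codon_weights <- function() {
  code <- Biostrings::GENETIC_CODE
  sense <- code[code != "*"]
  ## deterministic biased usage: within each amino acid, codons (in fixed
  ## alphabetical order) get geometrically decaying weights, giving genes a
  ## strong hexamer signature against iid background
  w <- numeric(length(sense))
  names(w) <- names(sense)
  for (aa in unique(sense)) {
    idx <- which(sense == aa)
    w[idx] <- 0.45 ^ seq(0, length(idx) - 1L)
    w[idx] <- w[idx] / sum(w[idx])
  }
  split(setNames(w, names(sense)), sense)
}

#' Specification of a synthetic genome
#'
#' Defaults describe the study system this package targets: a circular
#' 231,621 bp genome at 41.9% G+C with 113 genes averaging about 1.4 kb.
#'
#' @param length Genome length in bp.
#' @param gc G+C fraction of the intergenic background.
#' @param n_genes Number of planted genes.
#' @param gene_len_aa Function drawing gene lengths in amino acids (Met
#'   included, stop excluded), or an integer vector to sample from.
#' @param repeats List of repeat plants, each a list with `unit` (string),
#'   `copies`, `mut_rate` and optional `position`.
#' @param min_gap Minimum intergenic gap in bp.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(length = 231621L, gc = 0.419, n_genes = 113L,
                        gene_len_aa = function(n) pmax(63L, pmin(1900L,
                          round(rlnorm(n, log(360), 0.55)))),
                        repeats = list(), min_gap = 60L, seed = 1L) {
  stopifnot(length > 0L, gc >= 0, gc <= 1, n_genes >= 0L)
  for (rp in repeats)
    stopifnot(!is.null(rp$unit), rp$copies >= 2L,
              rp$mut_rate >= 0, rp$mut_rate <= 1)
  structure(list(length = as.integer(length), gc = gc,
                 n_genes = as.integer(n_genes), gene_len_aa = gene_len_aa,
                 repeats = repeats, min_gap = as.integer(min_gap),
                 seed = as.integer(seed)),
            class = "genome_spec")
}

random_dna <- function(n, gc) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(list(seq = seq, positions = integer(0)))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- which(runif(length(chars)) < rate)
  for (p in pos)
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  list(seq = paste(chars, collapse = ""), positions = pos)
}

## draw one coding sequence: ATG + biased codons + stop
draw_cds <- function(aa_len, codon_weights) {
  aas <- sample(names(codon_weights), aa_len - 1L, replace = TRUE)
  codons <- vapply(aas, function(aa) {
    w <- codon_weights[[aa]]
    sample(names(w), 1L, prob = w)
  }, character(1), USE.NAMES = FALSE)
  paste0("ATG", paste(codons, collapse = ""),
         sample(STOP_CODONS, 1L))
}

#' Generate a synthetic genome with known truth
#'
#' Intergenic sequence is drawn i.i.d. at the target G+C; genes are drawn
#' from a biased codon-usage table, start with ATG, contain no internal
#' stop and are stop-terminated (an in-frame TAA is planted directly
#' upstream of each gene so the planted ATG is the first of its
#' stop-bounded interval); repeat arrays are planted in intergenic gaps and
#' mutated at their stated per-base rate. Deterministic given the seed.
#'
#' @param spec A [genome_spec()].
#' @return A list with `genome` (a `circular_genome`) and `truth` (planted
#'   `orfs` feature table, planted `repeats` table, the spec and seed).
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  L <- spec$length
  cw <- default_codon_weights()
  aa_len <- if (is.function(spec$gene_len_aa)) spec$gene_len_aa(spec$n_genes)
            else sample(spec$gene_len_aa, spec$n_genes, replace = TRUE)
  blocks <- list(); truth_orfs <- list(); truth_reps <- list()
  ## a planted gene block = upstream in-frame TAA + cds(with stop)
  gene_nt <- if (spec$n_genes) 3L + 3L * (aa_len + 1L) else integer(0)
  rep_nt <- vapply(spec$repeats, function(rp)
    nchar(rp$unit) * rp$copies, integer(1))
  n_blk <- spec$n_genes + length(spec$repeats)
  need <- sum(gene_nt) + sum(rep_nt) + (n_blk + 1L) * spec$min_gap
  if (need > L)
    stop("infeasible packing: ", need, " bp needed in a ", L, " bp genome",
         call. = FALSE)
  ## distribute the slack over the n_blk+1 gaps
  slack <- L - sum(gene_nt) - sum(rep_nt) - (n_blk + 1L) * spec$min_gap
  cuts <- if (n_blk) sort(sample.int(slack + 1L, n_blk, replace = TRUE) - 1L)
          else integer(0)
  gaps <- diff(c(0L, cuts, slack)) + spec$min_gap
  strands <- if (spec$n_genes) sample(c("F", "R"), spec$n_genes,
                                      replace = TRUE) else character(0)
  pieces <- character(0)
  pos <- 0L
  gi <- 0L; ri <- 0L
  for (b in seq_len(n_blk)) {
    pieces <- c(pieces, random_dna(gaps[b], spec$gc))
    pos <- pos + gaps[b]
    if (b <= spec$n_genes) {
      gi <- gi + 1L
      cds <- draw_cds(aa_len[gi], cw)
      blk <- paste0("TAA", cds)
      p <- pos + 1L                      # block start (the planted TAA)
      q <- pos + nchar(blk)              # block end (last stop base)
      if (strands[gi] == "F") {
        start <- p + 3L; end <- p + 3L + 3L * aa_len[gi] - 1L
      } else {
        blk <- revcomp(blk)
        start <- q - 3L; end <- q - 3L - 3L * aa_len[gi] + 1L
      }
      truth_orfs[[gi]] <- data.frame(
        orf_id = sprintf("gene%03d", gi), strand = strands[gi],
        start = start, end = end, length_nt = 3L * aa_len[gi],
        length_aa = aa_len[gi], wraps = FALSE)
      pieces <- c(pieces, blk)
      pos <- q
    } else {
      ri <- ri + 1L
      rp <- spec$repeats[[ri]]
      arr <- strrep(toupper(rp$unit), rp$copies)
      mut <- mutate_dna(arr, rp$mut_rate)
      truth_reps[[ri]] <- data.frame(
        start = pos + 1L, end = pos + nchar(arr),
        unit_size = nchar(rp$unit), count = rp$copies,
        unit = toupper(rp$unit), n_mutations = length(mut$positions))
      pieces <- c(pieces, mut$seq)
      pos <- pos + nchar(arr)
    }
  }
  pieces <- c(pieces, random_dna(L - pos, spec$gc))
  genome <- circular_genome(paste(pieces, collapse = ""), id = "synthetic")
  stopifnot(genome$length == L)
  orfs <- if (length(truth_orfs)) do.call(rbind, truth_orfs) else
    data.frame(orf_id = character(0), strand = character(0),
               start = integer(0), end = integer(0),
               length_nt = integer(0), length_aa = integer(0),
               wraps = logical(0))
  list(genome = genome,
       truth = list(orfs = if (nrow(orfs)) as_feature_table(orfs, "synthetic", L)
                           else orfs,
                    repeats = do.call(rbind, truth_reps),
                    spec = spec, seed = spec$seed))
}

#' Derive a diverged ortholog genome
#'
#' Applies i.i.d. point substitutions at the given per-base rate (each
#' substituted base becomes one of the three alternatives uniformly) and
#' inserts one block of novel random sequence at a recorded position. Every
#' edit is logged, and the implied pairwise alignment is returned so that
#' genome-scale identity profiles need no alignment step.
#'
#' @param genome A `circular_genome`.
#' @param divergence Per-base substitution rate in `[0, 0.5)`.
#' @param insert_len Length of the unique inserted block (0 for none).
#' @param seed Integer seed.
#' @return A list with `genome` (the ortholog), `mutation_log` (data frame
#'   of `pos`, `ref`, `alt`), `insert_pos`, `insert_len`, and `alignment`
#'   (named character vector `base`/`derived`, gapped).
#' @export
make_ortholog <- function(genome, divergence, insert_len = 0L, seed = 1L) {
  stopifnot(inherits(genome, "circular_genome"),
            divergence >= 0, divergence < 0.5)
  L <- genome$length
  if (insert_len > L)
    stop("insert longer than the genome", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  pos <- which(runif(L) < divergence)
  ref <- chars[pos]
  alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L),
                character(1), USE.NAMES = FALSE)
  chars[pos] <- alt
  derived <- paste(chars, collapse = "")
  insert_pos <- NA_integer_
  base_gapped <- genome$sequence
  if (insert_len > 0L) {
    insert_pos <- sample.int(L - 1L, 1L)
    block <- random_dna(insert_len, 0.5)
    derived <- paste0(substr(derived, 1L, insert_pos), block,
                      substr(derived, insert_pos + 1L, L))
    base_gapped <- paste0(substr(genome$sequence, 1L, insert_pos),
                          strrep("-", insert_len),
                          substr(genome$sequence, insert_pos + 1L, L))
  }
  list(genome = circular_genome(derived, id = paste0(genome$id, "_ortholog"),
                                circular = genome$circular),
       mutation_log = data.frame(pos = pos, ref = ref, alt = alt),
       insert_pos = insert_pos, insert_len = as.integer(insert_len),
       alignment = c(base = base_gapped, derived = derived))
}

#' Simulate a gap-free protein family on a tree
#'
#' The root sequence is uniform over the 20 amino acids; along each branch
#' every site substitutes with probability `1 - exp(-rate * branch_length)`
#' (branch length 1 if the tree has none), the replacement drawn uniformly
#' from the other 19 residues.
#'
#' @param tree A `phylo` object.
#' @param root_length_aa Sequence length (default 300).
#' @param rate Expected substitutions per site per unit branch length.
#' @param seed Integer seed.
#' @return A `protein_alignment` of the leaf sequences, with the generating
#'   tree in attribute `tree`.
#' @export
make_protein_family <- function(tree, root_length_aa = 300L, rate = 0.1,
                                seed = 1L) {
  stopifnot(inherits(tree, "phylo"), rate >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  root <- ntip + 1L
  seqs <- vector("list", ntip + nnode)
  seqs[[root]] <- sample(AMINO_ACIDS, root_length_aa, replace = TRUE)
  elen <- tree$edge.length %||% rep(1, nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    s <- seqs[[parent]]
    p <- 1 - exp(-rate * elen[e])
    hit <- which(runif(root_length_aa) < p)
    for (h in hit) s[h] <- sample(setdiff(AMINO_ACIDS, s[h]), 1L)
    seqs[[child]] <- s
  }
  rows <- setNames(vapply(seq_len(ntip),
                          function(i) paste(seqs[[i]], collapse = ""),
                          character(1)),
                   tree$tip.label)
  out <- protein_alignment(rows)
  attr(out, "tree") <- tree
  out
}
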