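## Independent oracles used across the suite. These deliberately take
## different routes than the package implementation: translated-protein
## regexes for ORFs, per-column table() tallies for repeat consensus, O(n^2)
## DP for LIS and textbook three-state DP for affine alignment.

random_dna_str <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_protein_str <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

## --- ORF enumeration oracle: regex over six-frame translations ------------
oracle_orfs <- function(genome, min_aa = 60L) {
  L <- genome$length
  out <- list()
  for (strand in c("F", "R")) {
    s <- if (strand == "F") genome$sequence else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(genome$sequence)))
    dd <- if (genome$circular) paste0(s, s, substr(s, 1L, 4L)) else s
    for (f in 0:2) {
      ncod <- (nchar(dd) - f) %/% 3L
      if (ncod < 2L) next
      sub <- substr(dd, f + 1L, f + 3L * ncod)
      prot <- as.character(Biostrings::translate(
        Biostrings::DNAString(sub), no.init.codon = TRUE))
      ## maximal M..* runs; regex restarts after each '*', which is exactly
      ## "first Met after a stop"
      m <- gregexpr("M[^*]*\\*", prot)[[1]]
      if (m[1] == -1L) next
      starts <- as.integer(m)
      lens <- attr(m, "match.length") - 1L     # aa count, stop excluded
      if (genome$circular) {
        first_star <- regexpr("*", prot, fixed = TRUE)
        keep <- starts > as.integer(first_star)
        starts <- starts[keep]; lens <- lens[keep]
      }
      for (k in seq_along(starts)) {
        aa <- lens[k]
        p <- (starts[k] - 1L) * 3L + f + 1L
        if (aa < min_aa || p > L || aa * 3L > L) next
        end_s <- p + aa * 3L - 1L
        wraps <- end_s > L
        end_s <- ((end_s - 1L) %% L) + 1L
        if (strand == "F") {
          out[[length(out) + 1L]] <- data.frame(
            strand = "F", start = p, end = end_s,
            length_aa = aa, wraps = wraps)
        } else {
          out[[length(out) + 1L]] <- data.frame(
            strand = "R", start = L - p + 1L, end = L - end_s + 1L,
            length_aa = aa, wraps = wraps)
        }
      }
    }
  }
  df <- do.call(rbind, c(out, list(data.frame(
    strand = character(0), start = integer(0), end = integer(0),
    length_aa = integer(0), wraps = logical(0)))))
  df[order(df$strand, df$start), , drop = FALSE]
}

orf_key <- function(df) {
  sort(sprintf("%s:%d-%d(%d)", df$strand, df$start, df$end, df$length_aa))
}

## --- repeat-array oracle ---------------------------------------------------
oracle_score_array <- function(seq, start, u, cnt) {
  win <- substr(seq, start, start + u * cnt - 1L)
  m <- matrix(strsplit(win, "")[[1]], nrow = u)
  cons <- apply(m, 1L, function(r) {
    tb <- table(factor(r, levels = c("A", "C", "G", "T", "N")))
    names(tb)[which.max(tb)]
  })
  matches <- sum(m == matrix(cons, nrow = u, ncol = cnt))
  list(score = 2L * matches - u * cnt,
       pct_id = 100 * matches / (u * cnt),
       consensus = tolower(paste(cons, collapse = "")))
}

oracle_tandem <- function(seq, min_unit, max_unit, min_score) {
  L <- nchar(seq)
  rep_rows <- list()
  for (u in min_unit:max_unit) {
    if (2L * u > L) break
    for (s in 1:(L - 2L * u + 1L)) {
      cnt <- 2L
      sc <- oracle_score_array(seq, s, u, cnt)$score
      while (s + (cnt + 1L) * u - 1L <= L) {
        sc2 <- oracle_score_array(seq, s, u, cnt + 1L)$score
        if (sc2 > sc) { cnt <- cnt + 1L; sc <- sc2 } else break
      }
      if (sc >= min_score)
        rep_rows[[length(rep_rows) + 1L]] <-
          data.frame(start = s, end = s + u * cnt - 1L, score = sc,
                     unit_size = u, count = cnt)
    }
  }
  if (!length(rep_rows))
    return(data.frame(start = integer(0), end = integer(0),
                      score = integer(0), unit_size = integer(0),
                      count = integer(0)))
  df <- do.call(rbind, rep_rows)
  df <- df[order(-df$score, df$unit_size, df$start), , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(df))) {
    if (!length(kept) ||
        all(df$start[i] > df$end[kept] | df$end[i] < df$start[kept]))
      kept <- c(kept, i)
  }
  df <- df[kept, , drop = FALSE]
  df[order(df$start), , drop = FALSE]
}

## --- longest strictly increasing subsequence, O(n^2) DP -------------------
oracle_lis <- function(y) {
  n <- length(y)
  dp <- integer(n)
  for (i in seq_len(n)) {
    prev <- dp[seq_len(i - 1L)][y[seq_len(i - 1L)] < y[i]]
    dp[i] <- 1L + if (length(prev)) max(prev) else 0L
  }
  max(dp)
}

## --- textbook affine-gap global alignment DP (score only) -----------------
oracle_global_score <- function(a, b, match = 1, mismatch = -1,
                                gap_open = -5, gap_extend = -1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)   # gap in b (consume a)
  Y <- matrix(NEG, n + 1L, m + 1L)   # gap in a (consume b)
  M[1, 1] <- 0
  for (i in 2:(n + 1L)) X[i, 1] <- gap_open + gap_extend * (i - 1L)
  for (j in 2:(m + 1L)) Y[1, j] <- gap_open + gap_extend * (j - 1L)
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      s <- if (A[i - 1L] == B[j - 1L]) match else mismatch
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                     Y[i - 1L, j - 1L]) + s
      X[i, j] <- max(M[i - 1L, j] + gap_open + gap_extend,
                     X[i - 1L, j] + gap_extend,
                     Y[i - 1L, j] + gap_open + gap_extend)
      Y[i, j] <- max(M[i, j - 1L] + gap_open + gap_extend,
                     Y[i, j - 1L] + gap_extend,
                     X[i, j - 1L] + gap_open + gap_extend)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

## --- regex oracle for motif scanning ---------------------------------------
oracle_motif_hits <- function(pattern, seq) {
  rx <- paste0("(?=(", paste(vapply(pattern$elements, function(cls)
    paste0("[", paste(cls, collapse = ""), "]"), character(1)),
    collapse = ""), "))")
  m <- gregexpr(rx, toupper(seq), perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

## random motif notation built from the grammar's token types
random_notation <- function() {
  k <- sample(2:6, 1L)
  toks <- vapply(seq_len(k), function(i) {
    switch(sample(4L, 1L),
           sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 1L),
           "x",
           paste0("x", sample(2:4, 1L)),
           paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 2L),
                 collapse = "/"))
  }, character(1))
  paste(toks, collapse = "")
}

## genome with a coding block planted at a fixed position (in-frame TAA
## guard + ATG..stop), possibly crossing the origin
plant_gene <- function(bg, blk_start, aa, strand = "F", seed = 1L) {
  set.seed(seed)
  cds_aa <- sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "M"),
                   aa - 1L, replace = TRUE)
  back <- Biostrings::GENETIC_CODE
  codons <- vapply(cds_aa, function(x)
    sample(names(back)[back == x], 1L), character(1))
  blk <- paste0("TAA", "ATG", paste(codons, collapse = ""), "TAA")
  L <- nchar(bg)
  chars <- strsplit(bg, "")[[1]]
  idx <- (((blk_start - 1L) + seq_len(nchar(blk)) - 1L) %% L) + 1L
  chars[idx] <- strsplit(blk, "")[[1]]
  g <- paste(chars, collapse = "")
  if (strand == "R")
    g <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
  g
}
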