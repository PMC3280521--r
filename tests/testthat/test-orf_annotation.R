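test_that("ORF enumeration matches the six-frame translation oracle", {
  set.seed(101)
  for (L in c(5000, 8000)) {
    g <- circular_genome(random_dna_str(L), id = "rand")
    got <- enumerate_orfs(g, min_aa = 60)
    exp <- oracle_orfs(g, min_aa = 60)
    expect_equal(orf_key(got), orf_key(exp))
    expect_true(all(got$length_nt == 3L * got$length_aa))
  }
  ## linear genome: no wrap calls, still oracle-identical
  gl <- circular_genome(random_dna_str(6000), circular = FALSE)
  expect_equal(orf_key(enumerate_orfs(gl, 60)), orf_key(oracle_orfs(gl, 60)))
  expect_false(any(enumerate_orfs(gl, 60)$wraps))
})

test_that("a genome without ATG yields no ORFs and short genomes error", {
  g <- circular_genome(strrep("C", 400))
  expect_equal(nrow(enumerate_orfs(g, min_aa = 60)), 0L)
  expect_error(enumerate_orfs(circular_genome("ACGACG"), min_aa = 60),
               "shorter")
})

test_that("a planted gene crossing the origin is recovered with its wrap flag", {
  set.seed(7)
  L <- 6000L
  bg <- random_dna_str(L)
  ## block of 3 (TAA) + 3*301 nt starting 400 bp before the origin
  blk_start <- L - 400L
  g <- circular_genome(plant_gene(bg, blk_start, aa = 300, seed = 8))
  got <- enumerate_orfs(g, min_aa = 250)
  hit <- got[got$length_aa == 300 & got$strand == "F", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, blk_start + 3L)
  expect_true(hit$wraps)
  expect_equal(hit$end, ((blk_start + 3L + 900L - 1L - 1L) %% L) + 1L)
  ## and the oracle agrees on the whole genome
  expect_equal(orf_key(got), orf_key(oracle_orfs(g, min_aa = 250)))
})

test_that("nested-ORF removal equals the pairwise containment oracle", {
  ## deterministic containment cases
  orfs <- data.frame(
    orf_id = c("A", "B", "C", "D"),
    strand = c("F", "R", "F", "F"),
    start = c(100L, 300L, 350L, 600L),
    end = c(400L, 150L, 500L, 700L),
    length_nt = c(301L, 151L, 151L, 101L),
    length_aa = c(100L, 50L, 50L, 33L), wraps = FALSE)
  kept <- remove_nested(orfs, genome_length = 1000L)
  expect_setequal(kept$orf_id, c("A", "C", "D"))   # B inside A; C overlaps only

  ## random candidate sets vs O(n^2) oracle
  set.seed(21)
  for (rep in 1:25) {
    n <- 30L; L <- 5000L
    len <- 3L * sample(20:300, n, replace = TRUE)
    a <- sample(L, n, replace = TRUE)
    strand <- sample(c("F", "R"), n, replace = TRUE)
    start <- ifelse(strand == "F", a, ((a + len - 2L) %% L) + 1L)
    end <- ifelse(strand == "F", ((a + len - 2L) %% L) + 1L, a)
    df <- data.frame(orf_id = sprintf("o%02d", 1:n), strand = strand,
                     start = start, end = end, length_nt = len,
                     length_aa = len / 3L, wraps = FALSE)
    kept <- remove_nested(df, genome_length = L)
    ## oracle: position-set containment on the circle
    posset <- lapply(1:n, function(i)
      (( (a[i] - 1L) + seq_len(len[i]) - 1L) %% L) + 1L)
    drop <- vapply(1:n, function(i) any(vapply(1:n, function(j)
      j != i && len[j] > len[i] && all(posset[[i]] %in% posset[[j]]),
      logical(1))), logical(1))
    expect_setequal(kept$orf_id, df$orf_id[!drop])
  }
})

test_that("partial overlaps survive nested removal", {
  orfs <- data.frame(orf_id = c("A", "B"), strand = "F",
                     start = c(1L, 200L), end = c(300L, 500L),
                     length_nt = c(300L, 301L), length_aa = c(100L, 100L),
                     wraps = FALSE)
  expect_equal(nrow(remove_nested(orfs, 1000L)), 2L)
})

test_that("overlap resolution removes low scorers until no pair exceeds the threshold", {
  mk <- function(start, end, score, strand = "F")
    data.frame(strand = strand, start = start, end = end,
               length_nt = abs(end - start) + 1L,
               length_aa = (abs(end - start) + 1L) / 3,
               wraps = FALSE, coding_score = score)
  ## disjoint pair: both kept
  two <- do.call(rbind, list(mk(1, 300, 1), mk(400, 600, 2)))
  two$orf_id <- c("a", "b")
  expect_equal(nrow(resolve_overlaps(two, 1000L)), 2L)
  ## identical duplicates: one kept
  dup <- do.call(rbind, list(mk(1, 300, 1), mk(1, 300, 1)))
  dup$orf_id <- c("a", "b")
  expect_equal(nrow(resolve_overlaps(dup, 1000L)), 1L)

  ## random scored sets: post-condition + greedy-oracle equality
  set.seed(33)
  for (rep in 1:20) {
    n <- 15L; L <- 3000L
    len <- 3L * sample(30:200, n, replace = TRUE)
    a <- sample(L, n, replace = TRUE)
    df <- data.frame(orf_id = sprintf("o%02d", 1:n), strand = "F",
                     start = a, end = ((a + len - 2L) %% L) + 1L,
                     length_nt = len, length_aa = len / 3L, wraps = FALSE,
                     coding_score = round(runif(n), 3))
    got <- resolve_overlaps(df, L, max_overlap_frac = 0.3)
    ## post-condition: no surviving pair overlaps > 30% of the shorter
    pos <- lapply(seq_len(nrow(got)), function(i)
      (((got$start[i] - 1L) + seq_len(got$length_nt[i]) - 1L) %% L) + 1L)
    if (nrow(got) > 1) {
      for (i in 1:(nrow(got) - 1)) for (j in (i + 1):nrow(got)) {
        ov <- length(intersect(pos[[i]], pos[[j]]))
        expect_lte(ov / min(got$length_nt[i], got$length_nt[j]), 0.3)
      }
    }
    ## determinism
    expect_identical(got, resolve_overlaps(df, L, max_overlap_frac = 0.3))
  }
})

test_that("annotation summary reproduces the packaged-table statistics", {
  tab <- hznv2_orf_table()
  s <- summarize_annotation(tab, genome_length = 231621L)
  expect_equal(s$n_orfs, 113L)
  expect_equal(s$n_forward, 66L)
  expect_equal(s$n_reverse, 47L)
  expect_equal(s$gene_density_kb_per_gene, 2.05)
  expect_equal(s$coding_density_pct, 68)
  expect_equal(s$mean_length_kb, 1.4)
  expect_equal(sum(s$cluster_sizes), 113L)

  ## single ORF covering the whole genome
  one <- data.frame(orf_id = "x", strand = "F", start = 1L, end = 999L,
                    length_nt = 999L, length_aa = 333L, wraps = FALSE)
  s1 <- summarize_annotation(one, genome_length = 999L)
  expect_equal(s1$coding_density_pct, 100)
  expect_equal(s1$n_clusters, 1L)
})
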