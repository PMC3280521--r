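test_that("parity statistics match the LIS oracle and handle trivial maps", {
  id10 <- data.frame(query = 1:10, subject = 1:10)
  p <- parity(id10)
  expect_equal(p$n_colinear, 10L)
  expect_equal(p$inversions, 0L)

  rev10 <- data.frame(query = 1:10, subject = 10:1)
  pr <- parity(rev10)
  expect_equal(pr$n_colinear, 1L)
  expect_equal(pr$inversions, 9L)

  expect_error(parity(data.frame(query = c(1, 1), subject = 1:2)),
               "duplicate")

  set.seed(91)
  for (rep in 1:500) {
    n <- sample(5:200, 1)
    y <- sample(n)
    got <- parity(data.frame(query = 1:n, subject = y))$n_colinear
    expect_equal(got, oracle_lis(y))
  }
})

test_that("windowed identity profiles tile the base sequence", {
  a <- random_dna_str(350)
  prof <- window_identity(a, a, window = 100)
  expect_equal(nrow(prof), 4L)
  expect_true(all(prof$identity == 100))
  expect_true(all(prof$flagged))
  expect_equal(prof$end[4], 350L)

  ## all-gap partner scores zero everywhere
  prof0 <- window_identity(a, paste(rep("-", 350), collapse = ""))
  expect_true(all(prof0$identity == 0))

  ## window size does not matter for self-identity
  for (w in c(7, 50, 128))
    expect_true(all(window_identity(a, a, window = w)$identity == 100))

  expect_error(window_identity("ACGT", "AC"), "ragged")
})

test_that("global alignment equals the textbook DP oracle and is symmetric", {
  perfect <- global_align("ACGT", "ACGT")
  expect_equal(perfect$score, 4)
  expect_equal(perfect$identity, 100)
  single <- global_align("A", "G")
  expect_equal(single$score, -1)

  set.seed(92)
  for (rep in 1:15) {
    a <- random_dna_str(sample(40:200, 1))
    b <- random_dna_str(sample(40:200, 1))
    got <- global_align(a, b)
    expect_equal(got$score, oracle_global_score(a, b))
    expect_equal(got$score, global_align(b, a)$score)
    ## the reported alignment realizes the reported score
    A <- strsplit(got$aligned_a, "")[[1]]
    B <- strsplit(got$aligned_b, "")[[1]]
    sc <- 0; gapa <- FALSE; gapb <- FALSE
    for (k in seq_along(A)) {
      if (A[k] == "-") { sc <- sc + ifelse(gapa, -1, -6); gapa <- TRUE }
      else gapa <- FALSE
      if (B[k] == "-") { sc <- sc + ifelse(gapb, -1, -6); gapb <- TRUE }
      else gapb <- FALSE
      if (A[k] != "-" && B[k] != "-")
        sc <- sc + ifelse(A[k] == B[k], 1, -1)
    }
    expect_equal(sc, got$score)
  }
  expect_error(global_align("", "ACGT"), "empty")
})

test_that("core-gene audit reproduces the 16/30 presence pattern", {
  audit <- core_gene_audit(hznv2_orf_table())
  expect_equal(sum(audit$present), 16L)
  absent <- audit$gene[!audit$present]
  expect_setequal(absent,
                  c("lef-1", "lef-2", "p47", "ld130", "odv-e27", "gp41",
                    "p6.9", "vp39", "vp1054", "alk-exo", "ac68", "ac92",
                    "ac109", "ac142"))
  ## grouping follows the six functional categories
  expect_equal(levels(audit$category),
               c("replication", "transcription", "virus entry",
                 "structural", "auxiliary", "unknown"))

  ## empty annotation: everything absent; single named function: one present
  none <- core_gene_audit(data.frame(orf_id = character(0),
                                     predicted_function = character(0)))
  expect_equal(sum(none$present), 0L)
  one <- core_gene_audit(data.frame(orf_id = "x",
                                    predicted_function = "helicase"))
  expect_equal(sum(one$present), 1L)
  expect_equal(one$gene[one$present], "helicase")
})

test_that("gene-neighborhood comparison flags strand flips and relocations", {
  ## synthetic baculovirus-like core cluster: helicase/ac96 oriented as in
  ## the reference layout, 38K between ac96 and lef-5 on the opposite strand
  baculo <- data.frame(
    gene = c("helicase", "ac96", "38K", "lef-5"),
    strand = c("R", "F", "R", "F"),
    position = c(1000L, 6000L, 8500L, 10000L))
  hz <- data.frame(
    gene = c("helicase", "ac96", "lef-5", "38K"),
    strand = c("R", "F", "R", "R"),
    position = c(83046L, 83048L, 86584L, 221727L))
  cmp <- compare_gene_neighborhood(baculo, hz,
                                   genome_length_b = 231621L)
  expect_equal(attr(cmp, "anchor"), "helicase")
  expect_false(cmp$strand_flipped[cmp$gene == "ac96"])
  expect_true(cmp$strand_flipped[cmp$gene == "lef-5"])
  expect_true(cmp$order_changed[cmp$gene == "38K"])
  ## circular distances are reported both ways and sum to the genome length
  k38 <- cmp[cmp$gene == "38K", ]
  expect_equal(k38$dist_b_downstream + k38$dist_b_upstream, 231621)

  ## identical layouts: nothing flagged
  same <- compare_gene_neighborhood(baculo, baculo)
  expect_false(any(same$order_changed))
  expect_false(any(same$strand_flipped))

  ## one strand flip: exactly that gene flagged
  flip <- baculo
  flip$strand[flip$gene == "ac96"] <- "R"
  f <- compare_gene_neighborhood(baculo, flip)
  expect_equal(f$gene[f$strand_flipped], "ac96")

  expect_error(compare_gene_neighborhood(
    baculo, data.frame(gene = "zzz", strand = "F", position = 1L)),
    "no shared genes")
})
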