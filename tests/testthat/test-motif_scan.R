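test_that("the pattern grammar parses both bracketed and suffix repeat styles", {
  p1 <- parse_pattern("YxDTD")
  expect_equal(length(p1), 5L)
  expect_equal(p1$elements[[2]], sort(unique(c(strsplit(
    "ACDEFGHIKLMNPQRSTVWY", "")[[1]]))))
  expect_equal(length(parse_pattern("K(3x)NS(x)YG(2x)G")), 12L)
  expect_equal(length(parse_pattern("GxKx4HGQ/NKG")), 12L)
  expect_equal(length(parse_pattern("G-X2-G-X-G-K")), 7L)
  expect_equal(length(parse_pattern("HEXXHXUGUXH")), 11L)
  ## U expands to the bulky hydrophobics in protein mode
  p <- parse_pattern("HEXXHXUGUXH")
  expect_setequal(p$elements[[7]], c("F", "I", "L", "M", "V", "W", "Y"))
  ## DNA mode understands IUPAC ambiguity
  d <- parse_pattern("DTAAG", alphabet = "dna")
  expect_setequal(d$elements[[1]], c("A", "G", "T"))
  expect_error(parse_pattern("K#DG"), "unparseable token")
  expect_error(parse_pattern("", alphabet = "protein"), "empty")
  ## single-wildcard pattern matches every residue
  expect_equal(nrow(scan_motif(parse_pattern("x"), "ACDEF")), 5L)
})

test_that("alternative positions match each expansion", {
  p <- parse_pattern("GxKx4HGQ/NKG")
  hitQ <- scan_motif(p, "AAGAKAAAAHGQKGAA")
  hitN <- scan_motif(p, "AAGAKAAAAHGNKGAA")
  expect_equal(hitQ$start, 3L)
  expect_equal(hitN$start, 3L)
  expect_equal(nrow(scan_motif(p, "AAGAKAAAAHGAKGAA")), 0L)
})

test_that("scan reports all overlapping hits and matches the regex oracle", {
  h <- scan_motif("KxDG", "AKLDGA")
  expect_equal(h$start, 2L)
  expect_equal(h$end, 5L)
  expect_equal(h$match, "KLDG")
  expect_equal(nrow(scan_motif("KxDG", "KD")), 0L)

  set.seed(81)
  for (rep in 1:1000) {
    notation <- random_notation()
    p <- tryCatch(parse_pattern(notation), error = function(e) NULL)
    if (is.null(p)) next
    s <- random_protein_str(sample(20:60, 1))
    expect_equal(scan_motif(p, s)$start, oracle_motif_hits(p, s),
                 info = notation)
  }
})

test_that("upstream promoter search is strand- and origin-aware", {
  set.seed(82)
  L <- 3000L
  bg <- gsub("TAAG", "CCCC", random_dna_str(L))     # scrub chance hits
  chars <- strsplit(bg, "")[[1]]
  chars[920:923] <- c("T", "A", "A", "G")
  g <- circular_genome(paste(chars, collapse = ""))
  orf <- data.frame(orf_id = "x", strand = "F", start = 1000L, end = 1500L,
                    wraps = FALSE)
  hits <- upstream_search(g, orf, "TAAG", window = 500L)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 920L)
  expect_equal(hits$end, 923L)

  ## mirror genome: reverse-complement with the ORF flipped to R
  gm <- circular_genome(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(g$sequence))))
  orf_m <- data.frame(orf_id = "x", strand = "R", start = L - 1000L + 1L,
                      end = L - 1500L + 1L, wraps = FALSE)
  hits_m <- upstream_search(gm, orf_m, "TAAG", window = 500L)
  expect_equal(nrow(hits_m), 1L)
  expect_equal(hits_m$start, L - 920L + 1L)
  expect_equal(hits_m$end, L - 923L + 1L)

  ## negative finding: no TAAG within the upstream window
  g0 <- circular_genome(gsub("TAAG", "CCCC", random_dna_str(L)))
  orf0 <- data.frame(orf_id = "y", strand = "F", start = 1000L, end = 1500L,
                     wraps = FALSE)
  expect_equal(nrow(upstream_search(g0, orf0, "TAAG", 500L)), 0L)
  expect_error(upstream_search(g0, orf0, "TAAG", window = L), "window")
})

test_that("hydropathy segmentation finds planted hydrophobic stretches", {
  expect_equal(hydropathy_segments(strrep("I", 30))$start, 1L)
  expect_equal(hydropathy_segments(strrep("I", 30))$end, 30L)
  expect_equal(nrow(hydropathy_segments(strrep("D", 30))), 0L)
  ## 12 transmembrane-like 23-mers separated by charged linkers
  tm <- strrep("I", 23)
  linker <- strrep("DKERDKERDKERDKERDKERDKER", 1)
  prot <- paste0(linker,
                 paste(rep(paste0(tm, linker), 12), collapse = ""))
  seg <- hydropathy_segments(prot)
  expect_equal(nrow(seg), 12L)
  expect_true(all(seg$mean_hydropathy > 1.6))
})

test_that("cysteine profiling reports conserved columns only", {
  aln <- c(a = "ACDEC", b = "ACDEC")
  expect_equal(cysteine_profile(aln), c(2L, 5L))
  expect_equal(length(cysteine_profile(c(a = "ADE", b = "ADE"))), 0L)
  expect_error(cysteine_profile(c(a = "AC", b = "ACD")), "ragged")

  ## simulated family: C columns fixed, other positions mutated at 30%
  set.seed(83)
  base <- strsplit(random_protein_str(120), "")[[1]]
  cpos <- sort(sample(120, 8))
  base[cpos] <- "C"
  base[setdiff(seq_len(120), cpos)][
    base[setdiff(seq_len(120), cpos)] == "C"] <- "A"
  rows <- vapply(1:6, function(i) {
    x <- base
    mut <- setdiff(which(runif(120) < 0.3), cpos)
    for (p in mut) x[p] <- sample(setdiff(strsplit(
      "ADEFGHIKLMNPQRSTVWY", "")[[1]], x[p]), 1)
    paste(x, collapse = "")
  }, character(1))
  names(rows) <- paste0("t", 1:6)
  expect_equal(cysteine_profile(rows), cpos)
})

test_that("the packaged motif catalog parses end to end", {
  cat <- motif_catalog()
  expect_gte(nrow(cat), 16L)
  for (i in seq_len(nrow(cat))) {
    p <- parse_pattern(cat$notation[i], alphabet = cat$alphabet[i])
    expect_gte(length(p), 1L)
  }
  ## the corrected metalloprotease active-site span is 11 residues wide
  mmp <- cat[cat$name == "mmp_active_site", ]
  expect_equal(length(parse_pattern(mmp$notation)), 422L - 412L + 1L)
})
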