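test_that("reverse_complement handles both alphabets, empty input, and bad characters", {
  expect_identical(reverse_complement("GAGGUAG", "RNA"), "CUACCUC")
  expect_identical(reverse_complement("", "RNA"), "")
  expect_identical(reverse_complement("ACGT", "DNA"), "ACGT")  # palindrome
  expect_error(reverse_complement("ACGT", "RNA"), "position 4")
  expect_error(reverse_complement("ACXU", "RNA"), "position 3")
})

test_that("guide_rna validates alphabet and length", {
  g <- guide_let7()
  expect_s3_class(g, "guide_rna")
  expect_identical(g$length, 22L)
  expect_identical(g$chars[1], "U")        # g1 is the 5' nucleotide
  expect_error(guide_rna("x", "ACGU"), "length")
  expect_error(guide_rna("x", strrep("ACGX", 5)), "non-RNA")
})

## the full printed nomenclature; parse -> print must be the identity
printed_names <- c(
  "8mer", "7mer-m8", "7mer-A1", "6mer", "6mer-m8", "6mer-A1", "5mer-A1",
  "8mer-w8", "7mer-w8", "7mer-m8,w2", "8mer-x4C", "8mer-x4R",
  "8mer-b5.6A", "8mer-b5.6G", "8mer-b5.6CA",
  "5mer-m2.6", "6mer-m4.9", "5mer-m4.8",
  paste0("10mer-m", 9:14, ".", 18:23), "11mer-m4.14", "11mer-m5.15")

test_that("site-name parse/print round-trips over the printed nomenclature", {
  for (nm in printed_names) {
    sp <- parse_site_name(nm)
    expect_identical(sp$name, nm)
  }
  ## structural spot checks
  expect_identical(unlist(parse_site_name("7mer-m8")[c("g_start", "g_end", "t1A")]),
                   c(g_start = 2L, g_end = 8L, t1A = 0L))
  b <- parse_site_name("8mer-b5.6A")
  expect_true(b$t1A && b$g_start == 2L && b$g_end == 8L)
  expect_identical(b$bulges, c("5" = "A"))
  c11 <- parse_site_name("11mer-m4.14")
  expect_identical(c(c11$g_start, c11$g_end), c(4L, 14L))
  expect_identical(parse_site_name("8mer-x4R")$mismatches, c("4" = "R"))
})

test_that("unparseable names are rejected with the offending token", {
  expect_error(parse_site_name("7mer"), "plain")
  expect_error(parse_site_name("8mer-q4"), "offending token 'q4'")
  expect_error(parse_site_name("notasite"), "prefix")
  expect_error(parse_site_name("5mer-m2.7"), "inconsistent")
  expect_error(parse_site_name("8mer-b5.7A"), "adjacent")
})

test_that("site_spec enforces its invariants", {
  expect_error(site_spec(1, 8), "g_start")
  expect_error(site_spec(3, 8, t1A = TRUE), "t1A requires")
  expect_error(site_spec(2, 8, wobbles = 9L), "outside")
  expect_error(site_spec(2, 8, mismatches = c("4" = "Z")), "invalid mismatch")
})

test_that("motif_for_site applies the edit algebra and the length invariant", {
  g <- guide_let7()
  ## 8mer = reverse_complement(g2..g8) + A, checked against the rc oracle
  expect_identical(motif_for_site(g, "8mer"),
                   paste0(rna_to_dna(reverse_complement(substr(g$sequence, 2, 8), "RNA")), "A"))
  expect_identical(motif_for_site(g, "6mer"),
                   rna_to_dna(reverse_complement(substr(g$sequence, 2, 7), "RNA")))
  expect_identical(motif_for_site(g, "10mer-m13.22"),
                   rna_to_dna(reverse_complement(substr(g$sequence, 13, 22), "RNA")))
  ## motif length = span + bulges - deletions + t1A
  for (nm in c("8mer", "7mer-m8", "8mer-b5.6A", "8mer-w8", "8mer-d4", "5mer-A1")) {
    sp <- parse_site_name(nm)
    expect_identical(nchar(motif_for_site(g, sp)), motif_length(sp), label = nm)
  }
  ## wobble replaces the complement so the pair is G:U
  expect_identical(substr(motif_for_site(g, "8mer-w8"), 1, 1), "T")  # opposite g8 = G
  ## wobble at a guide A/C position is impossible
  expect_error(motif_for_site(g, site_spec(2, 8, wobbles = 3L)), "admits no G:U")
  ## alphabet is the caller's choice
  expect_identical(motif_for_site(g, "6mer", "RNA"), "UACCUC")
})

test_that("classify_kmer recovers each catalog motif exactly (round trip)", {
  cases <- list(
    list(guide_let7(), c("8mer", "7mer-m8", "7mer-A1", "6mer", "6mer-m8",
                         "6mer-A1", "5mer-A1", "8mer-w8", "7mer-w8",
                         "7mer-m8,w2", "8mer-b5.6A", "5mer-m2.6",
                         "6mer-m4.9", "5mer-m4.8", "10mer-m9.18",
                         "10mer-m13.22", "11mer-m4.14", "11mer-m5.15")),
    list(guide_mir184(), c("8mer-x4C", "8mer", "6mer")),
    list(guide_mir11(), c("8mer-b5.6G", "8mer-w8", "6mer-m4.9", "5mer-m4.8")))
  for (cs in cases) {
    for (nm in cs[[2]]) {
      m <- motif_for_site(cs[[1]], nm)
      sp <- classify_kmer(cs[[1]], m)
      expect_identical(sp$name, nm,
                       label = paste(cs[[1]]$name, nm, "->", sp$name))
    }
  }
  ## 2-nt bulge needs the wider bulge ceiling
  m <- motif_for_site(guide_mir184(), "8mer-b5.6CA")
  expect_identical(classify_kmer(guide_mir184(), m, max_bulge_len = 2)$name,
                   "8mer-b5.6CA")
})

test_that("classify_kmer handles padding, no-site and edge cases", {
  g <- guide_let7()
  ## non-extending pads leave the site call unchanged
  expect_identical(classify_kmer(g, paste0("T", motif_for_site(g, "8mer"), "T"))$name,
                   "8mer")
  expect_null(classify_kmer(g, "CCCCCCCCCC"))
  expect_null(classify_kmer(g, "ACGA"))               # below min_len
  expect_error(classify_kmer(g, "ACG"), "length")
  ## a constructed wobble edit is recovered as a w-annotated spec
  m <- motif_for_site(g, "7mer-m8,w2")
  sp <- classify_kmer(g, m)
  expect_identical(sp$wobbles, 2L)
  expect_false(sp$t1A)
})
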