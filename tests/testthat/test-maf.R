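# MAF parsing and ancestral-sequence projection

test_that("an empty MAF yields no blocks", {
  p <- withr::local_tempfile(lines = c("##maf version=1", ""))
  expect_length(parse_maf(p), 0)
})

test_that("malformed s lines are rejected with their line number", {
  p <- withr::local_tempfile(lines = c("a", "s sp.chr1 0 5 + 10 ACGTA", "s bad 0 5 +"))
  expect_error(parse_maf(p), "line 3")
  p2 <- withr::local_tempfile(lines = c("a", "s sp.chr1 0 5 + 10 ACG-A"))
  expect_error(parse_maf(p2), "size 5 but 4 non-gap")
  p3 <- withr::local_tempfile(lines = c("a", "s sp.chr1 8 5 + 10 ACGTA"))
  expect_error(parse_maf(p3), "exceed")
})

test_that("fixture-written MAF round-trips through parse and re-serialisation", {
  cfg <- synth_config(genome_length = 5000, block_size = 1000, n_pop_sites = 10,
                      seed = 5)
  g <- make_genome(cfg)
  anc <- make_ancestor_and_maf(g, cfg)
  p1 <- withr::local_tempfile()
  write_maf(anc$blocks, p1)
  b1 <- parse_maf(p1)
  p2 <- withr::local_tempfile()
  write_maf(b1, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(parse_maf(p2), b1)
})

test_that("minus-strand rows convert coordinates as src_size - start - size", {
  # 10-bp source GATTACACGT; forward span [3,7] 1-based is TTACA.
  # On the minus strand that span reads TGTAA, start = 10 - (3-1) - 5 = 3.
  g <- as_genome(c(c1 = "GATTACACGT"))
  blk <- data.frame(src = c("sp.c1", "anc.c1"), species = c("sp", "anc"),
                    chrom = "c1", start = c(3L, 0L), size = 5L, strand = "-",
                    src_size = c(10L, 5L), text = c("TGTAA", "TGTCA"),
                    stringsAsFactors = FALSE)
  map <- build_ancestor_map(list(blk), g, "sp", ancestor_label = "anc")
  # ancestor text differs from ref at its 4th minus-strand column (C vs A),
  # which is forward position 10 - 3 - 4 + 1 = 4 and complements to G
  expect_identical(map$c1[3:7], c("T", "G", "A", "C", "A"))
  expect_identical(map$c1[4], "G")
  expect_identical(unname(map$c1[c(1, 2, 8, 9, 10)]), rep(".", 5))
})

test_that("ancestor identical to the reference reproduces it over the block", {
  g <- as_genome(c(c1 = strrep("ACGT", 15)))
  txt <- paste(strsplit(unclass(g)[["c1"]], "")[[1]][1:40], collapse = "")
  blk <- data.frame(src = c("sp.c1", "anc.c1"), species = c("sp", "anc"),
                    chrom = "c1", start = 0L, size = 40L, strand = "+",
                    src_size = c(60L, 40L), text = txt, stringsAsFactors = FALSE)
  map <- build_ancestor_map(list(blk), g, "sp", ancestor_label = "anc")
  expect_identical(map$c1[1:40], strsplit(txt, "")[[1]])
  expect_true(all(map$c1[41:60] == "."))
})

test_that("a single planted mismatch and an ancestor gap are projected faithfully", {
  g <- as_genome(c(c1 = strrep("ACGT", 15)))
  rch <- strsplit(unclass(g)[["c1"]], "")[[1]]
  ach <- rch[1:60]
  ach[13] <- "C"   # ref at 13 is A; plant ancestor C
  ach[20] <- "-"   # ancestor gap -> unaligned
  blk <- data.frame(src = c("sp.c1", "anc.c1"), species = c("sp", "anc"),
                    chrom = "c1", start = 0L, size = c(60L, 59L), strand = "+",
                    src_size = c(60L, 59L),
                    text = c(paste(rch, collapse = ""), paste(ach, collapse = "")),
                    stringsAsFactors = FALSE)
  map <- build_ancestor_map(list(blk), g, "sp", ancestor_label = "anc")
  expect_identical(map$c1[13], "C")
  expect_identical(map$c1[20], ".")
  expect_identical(map$c1[-c(13, 20)], rch[-c(13, 20)])
})

test_that("overlapping blocks asserting different bases become ambiguous", {
  g <- as_genome(c(c1 = "AAAAAAAAAA"))
  mk <- function(anc_txt) data.frame(
    src = c("sp.c1", "anc.c1"), species = c("sp", "anc"), chrom = "c1",
    start = 0L, size = c(4L, nchar(gsub("-", "", anc_txt))), strand = "+",
    src_size = c(10L, 4L), text = c("AAAA", anc_txt), stringsAsFactors = FALSE)
  map <- build_ancestor_map(list(mk("AAGA"), mk("AACA")), g, "sp",
                            ancestor_label = "anc")
  expect_identical(map$c1[3], "?")
  expect_identical(map$c1[c(1, 2, 4)], c("A", "A", "A"))
  # agreeing blocks stay concrete; a gap never overrides a concrete base
  map2 <- build_ancestor_map(list(mk("AAGA"), mk("AAGA"), mk("AA-A")), g, "sp",
                             ancestor_label = "anc")
  expect_identical(map2$c1[3], "G")
})

test_that("missing reference species or ancestor label raise errors", {
  fx <- hand_maf_fixture()
  blocks <- parse_maf(fx$maf)
  expect_error(build_ancestor_map(blocks, fx$genome, "nosuch",
                                  ancestor_label = "anc"), "nosuch")
  expect_error(build_ancestor_map(blocks, fx$genome, "sp",
                                  ancestor_label = "Anc0"), "Anc0")
})

test_that("outgroup consensus modes agree and disagree as specified", {
  g <- as_genome(c(c1 = "ACGTACGTAC"))
  blk <- data.frame(
    src = c("sp.c1", "o1.c1", "o2.c1", "o3.c1"),
    species = c("sp", "o1", "o2", "o3"), chrom = "c1", start = 0L,
    size = c(10L, 10L, 10L, 9L), strand = "+", src_size = c(10L, 10L, 10L, 9L),
    text = c("ACGTACGTAC",
             "ACGTACGTAC",
             "ACGTTCGTAC",
             "ACGTTCGT-C"), stringsAsFactors = FALSE)
  strict <- build_ancestor_map(list(blk), g, "sp",
                               outgroup_labels = c("o1", "o2", "o3"),
                               strategy = "strict_consensus")
  expect_identical(strict$c1[1], "A")
  expect_identical(strict$c1[5], "?")   # A/T/T disagreement
  expect_identical(strict$c1[9], ".")   # gap breaks strict consensus
  maj <- build_ancestor_map(list(blk), g, "sp",
                            outgroup_labels = c("o1", "o2", "o3"),
                            strategy = "majority")
  expect_identical(maj$c1[5], "T")      # modal base T (2 of 3)
  expect_identical(maj$c1[9], "A")      # two concrete A votes remain
  # two-way tie -> ambiguous
  blk2 <- blk[1:3, ]
  maj2 <- build_ancestor_map(list(blk2), g, "sp",
                             outgroup_labels = c("o1", "o2"),
                             strategy = "majority")
  expect_identical(maj2$c1[5], "?")
})

test_that("strand property: reverse-complementing a whole block leaves the map unchanged", {
  cfg <- synth_config(genome_length = 2000, block_size = 500, n_pop_sites = 0,
                      minus_strand_block = 0L, seed = 21)
  g <- make_genome(cfg)
  anc <- make_ancestor_and_maf(g, cfg)
  map_fwd <- build_ancestor_map(anc$blocks, g, "ref", ancestor_label = "anc")
  flipped <- lapply(anc$blocks, function(b) {
    b$text <- revcomp(b$text)
    b$start <- b$src_size - b$start - b$size
    b$strand <- ifelse(b$strand == "+", "-", "+")
    b
  })
  map_rev <- build_ancestor_map(flipped, g, "ref", ancestor_label = "anc")
  expect_identical(map_fwd, map_rev)
})

test_that("coverage fractions count concrete bases and respect the genome", {
  g <- as_genome(c(c1 = strrep("A", 1000), c2 = strrep("C", 500)))
  map <- structure(list(c1 = c(rep("G", 800), rep(".", 150), rep("?", 50)),
                        c2 = rep(".", 500)), class = "ancestor_map")
  cov <- coverage_stats(map, g)
  expect_equal(cov$by_chrom$fraction, c(0.8, 0))
  expect_equal(cov$total, 800 / 1500)
  expect_equal(cov$total,
               sum(cov$by_chrom$covered) / sum(cov$by_chrom$length))
  full <- structure(list(c1 = rep("A", 1000), c2 = rep("T", 500)),
                    class = "ancestor_map")
  expect_equal(coverage_stats(full, g)$total, 1)
  bad <- structure(list(cX = rep("A", 10)), class = "ancestor_map")
  expect_error(coverage_stats(bad, g), "cX")
})

test_that("ancestor maps round-trip through both serialisations", {
  cfg <- synth_config(genome_length = 3000, block_size = 1000, n_pop_sites = 0,
                      seed = 9)
  g <- make_genome(cfg)
  anc <- make_ancestor_and_maf(g, cfg)
  map <- anc$ancestor_truth
  for (fmt in c("fasta", "tsv")) {
    p <- withr::local_tempfile()
    write_ancestor_map(map, p, format = fmt)
    back <- read_ancestor_map(p, g)
    expect_identical(unclass(back), unclass(map), label = fmt)
  }
})
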