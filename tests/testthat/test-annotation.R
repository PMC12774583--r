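# annotation tracks, sequence context, Grantham scores, encoding/imputation

toy_variants <- function(chrom, pos, from = "A", to = "C") {
  data.frame(chrom = chrom, pos = as.integer(pos), from = from, to = to,
             stringsAsFactors = FALSE)
}

test_that("bedGraph intervals are half-open on disk and expanded per position", {
  g <- as_genome(c(chr1 = strrep("A", 30)))
  p <- withr::local_tempfile(lines = "chr1\t10\t12\t0.5")
  tr <- load_track(p, "bedGraph", name = "t", kind = "numeric", genome = g)
  v <- track_lookup(tr, toy_variants("chr1", c(10, 11, 12, 13)))
  expect_equal(v, c(NA, 0.5, 0.5, NA))
})

test_that("an empty bedGraph yields a track where every lookup is missing", {
  g <- as_genome(c(chr1 = strrep("A", 10)))
  p <- withr::local_tempfile(lines = character(0))
  tr <- load_track(p, "bedGraph", name = "t", kind = "numeric", genome = g)
  expect_true(all(is.na(track_lookup(tr, toy_variants("chr1", 1:10)))))
})

test_that("out-of-genome track records are skipped with a warning and counted", {
  g <- as_genome(c(chr1 = strrep("A", 20)))
  p <- withr::local_tempfile(lines = c("chr1\t0\t5\t1", "chr1\t18\t25\t2",
                                       "chrX\t0\t5\t3"))
  expect_warning(tr <- load_track(p, "bedGraph", name = "t", kind = "numeric",
                                  genome = g), "skipped 2")
  expect_equal(attr(tr, "skipped"), 2L)
  expect_equal(track_lookup(tr, toy_variants("chr1", c(3, 19))), c(1, NA))
})

test_that("BED interval states become per-position categorical lookups", {
  g <- as_genome(c(chr1 = strrep("A", 50)))
  p <- withr::local_tempfile(lines = c("chr1\t4\t10\tenhancer\t0\t+",
                                       "chr1\t20\t30\tpromoter\t0\t+"))
  tr <- load_track(p, "bed", name = "state", kind = "categorical", genome = g)
  v <- track_lookup(tr, toy_variants("chr1", c(5, 10, 11, 25, 40)))
  expect_equal(v, c("enhancer", "enhancer", NA, "promoter", NA))
})

test_that("per-variant TSV tracks key on the allele pair", {
  g <- as_genome(c(chr1 = strrep("ACGT", 5)))
  p <- withr::local_tempfile(lines = c("chrom\tpos\tref\talt\tvalue",
                                       "chr1\t3\tG\tT\thigh",
                                       "chr1\t3\tG\tA\tlow"))
  tr <- load_track(p, "tsv", name = "csq", kind = "categorical", genome = g)
  v <- track_lookup(tr, toy_variants("chr1", c(3, 3, 3), from = "G",
                                     to = c("T", "A", "C")))
  expect_equal(v, c("high", "low", NA))
})

test_that("sequence context features match hand counts and clip at edges", {
  g <- as_genome(c(c1 = "ACGCGT", c2 = strrep("G", 9), c3 = "NNNNN"))
  # window 2 around position 3 covers the whole 6-mer minus the last base?
  # positions 1..5: A C G C G -> GC 4/5; full window at pos 3 is 1..5
  cf <- sequence_context_features(g, "c1", 3, window = 2)
  expect_equal(cf$gc_fraction, 4 / 5)
  expect_equal(cf$cpg_count, 2)  # CG at 2-3 and 4-5
  # whole sequence ACGCGT: GC fraction 4/6, still 2 CpGs
  cf_all <- sequence_context_features(g, "c1", 3, window = 5)
  expect_equal(cf_all$gc_fraction, 4 / 6)
  expect_equal(cf_all$cpg_count, 2)
  # all-G window
  cfg_ <- sequence_context_features(g, "c2", 5, window = 3)
  expect_equal(cfg_$gc_fraction, 1)
  expect_equal(cfg_$cpg_count, 0)
  # left clipping: denominator is the realised window length
  cf1 <- sequence_context_features(g, "c1", 1, window = 2)
  expect_equal(cf1$gc_fraction, 2 / 3)  # ACG
  # all-N window: defined 0 with the missing flag raised
  cfn <- sequence_context_features(g, "c3", 3, window = 2)
  expect_equal(cfn$gc_fraction, 0)
  expect_true(cfn$gc_missing)
  expect_error(sequence_context_features(g, "c1", 99), "outside")
})

test_that("the Grantham table matches the bundled published fixture and is symmetric", {
  m <- grantham_matrix()
  fixture <- read.delim(system.file("extdata", "grantham1974.tsv",
                                    package = "caddforge"), row.names = 1)
  fixture <- as.matrix(fixture)
  expect_equal(unname(m[rownames(fixture), colnames(fixture)]), unname(fixture))
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 0L))
  expect_true(all(m >= 0L))
  expect_identical(grantham("L", "L"), 0L)
  expect_identical(grantham("L", "I"), 5L)
  expect_identical(grantham("W", "C"), 215L)
  aa <- rownames(m)
  pairs <- expand.grid(a = aa, b = aa, stringsAsFactors = FALSE)
  expect_identical(grantham(pairs$a, pairs$b), grantham(pairs$b, pairs$a))
  expect_true(is.na(grantham("L", "*")))
})

test_that("the built-in consequence caller classifies a toy gene correctly", {
  # chr1: gene 11-40 on +, exon1 11-20, exon2 31-40, CDS = both exons.
  # CDS sequence = bases 11..20 + 31..40 = ATGGCCAAAG AATTTGGGCC,
  # codons ATG GCC AAA GAA TTT GGG (+2 trailing bases) = M A K E F G.
  g <- as_genome(c(chr1 = paste0("TTTTTTTTTT", "ATGGCCAAAG",
                                 "TTTTTTTTTT", "AATTTGGGCC",
                                 "TTTTTTTTTT")))
  gff <- withr::local_tempfile(lines = c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t11\t40\t.\t+\t.\tID=g1",
    "chr1\ttoy\tmRNA\t11\t40\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\ttoy\texon\t11\t20\t.\t+\t.\tParent=t1",
    "chr1\ttoy\texon\t31\t40\t.\t+\t.\tParent=t1",
    "chr1\ttoy\tCDS\t11\t20\t.\t+\t0\tID=c1;Parent=t1",
    "chr1\ttoy\tCDS\t31\t40\t.\t+\t0\tID=c1;Parent=t1"))
  v <- toy_variants("chr1",
                    pos = c(5, 25, 21, 14, 19, 17, 33),
                    from = c("T", "T", "T", "G", "A", "A", "T"),
                    to = c("A", "A", "A", "A", "G", "T", "A"))
  cons <- call_consequences(v, gff, g)
  expect_equal(cons$consequence,
               c("intergenic", "intronic", "splice_site", "missense",
                 "synonymous", "stop_gained", "missense"))
  # missense at pos 14: codon 2 GCC -> ACC is Ala -> Thr
  expect_equal(cons$aa_ref[4], "A")
  expect_equal(cons$aa_alt[4], "T")
  # stop gained at pos 17: codon 3 AAA -> TAA
  expect_equal(cons$aa_alt[6], "*")
})

test_that("assemble_features joins tracks and builtins, leaving absences missing", {
  g <- as_genome(c(chr1 = strrep("ACGT", 10)))
  bg <- withr::local_tempfile(lines = c("chr1\t0\t10\t1.5"))
  tr <- load_track(bg, "bedGraph", name = "cons", kind = "numeric", genome = g)
  specs <- list(
    feature_spec("cons", source = "track", kind = "numeric", imputation = "indicator"),
    feature_spec("gc_fraction", source = "gc_fraction", kind = "numeric",
                 imputation = "fixed", value = 0.5),
    feature_spec("ref_base", source = "ref_base", kind = "categorical",
                 levels = c("A", "C", "G", "T")))
  v <- toy_variants("chr1", c(5, 25), from = c("A", "A"), to = "G")
  rec <- assemble_features(v, specs, tracks = list(cons = tr), genome = g)
  expect_equal(rec$cons, c(1.5, NA))
  expect_false(anyNA(rec$gc_fraction))
  expect_equal(rec$ref_base, c("A", "A"))
  expect_error(assemble_features(v, list(feature_spec("ghost", source = "track",
                                                      kind = "numeric")),
                                 tracks = list()), "not loaded")
})

test_that("imputation strategies behave exactly as declared", {
  specs <- list(
    feature_spec("num_ind", kind = "numeric", imputation = "indicator"),
    feature_spec("num_mean", kind = "numeric", imputation = "mean_from_simulated"),
    feature_spec("num_fix", kind = "numeric", imputation = "fixed", value = -7),
    feature_spec("cat", kind = "categorical", levels = c("a", "b", "c")))
  rec <- data.frame(chrom = "c", pos = 1:4, from = "A", to = "C",
                    num_ind = c(1, NA, 3, 4),
                    num_mean = c(9, 1, 2, 3),     # derived 9 must not leak
                    num_fix = c(NA, NA, 1, 1),
                    cat = c("a", NA, "zzz", "c"), stringsAsFactors = FALSE)
  rec$num_mean[1] <- NA  # derived-class missing cell
  labels <- c(0, 1, 1, 1)
  fm <- encode_and_impute(rec, specs, labels = labels)
  expect_equal(unname(fm$X[, "num_ind"]), c(1, 0, 3, 4))
  expect_equal(unname(fm$X[, "num_ind_missing"]), c(0, 1, 0, 0))
  expect_equal(fm$imputation_stats$num_mean, 2)      # mean of simulated {1,2,3}
  expect_equal(unname(fm$X[, "num_mean"]), c(2, 1, 2, 3))
  expect_equal(unname(fm$X[, "num_fix"]), c(-7, -7, 1, 1))
  onehot <- fm$X[, c("cat.a", "cat.b", "cat.c")]
  expect_equal(unname(rowSums(onehot)), c(1, 0, 0, 1))  # unknown level -> all zero
  expect_equal(unname(fm$X[, "cat_missing"]), c(0, 1, 1, 0))
  expect_true(all(is.finite(fm$X)))
  # column layout: numeric(1 [+1 indicator]) + categorical(levels + indicator)
  expect_identical(ncol(fm$X), 2L + 1L + 1L + 3L + 1L)
  # mean never computed from derived rows: plant class-separated values
  rec2 <- rec
  rec2$num_mean <- c(100, 1, 2, NA)
  fm2 <- encode_and_impute(rec2, specs, labels = labels)
  expect_equal(fm2$imputation_stats$num_mean, 1.5)
  # an error when the feature is missing in every simulated record
  rec3 <- rec
  rec3$num_mean <- c(5, NA, NA, NA)
  expect_error(encode_and_impute(rec3, specs, labels = labels),
               "missing in every simulated record")
})

test_that("scoring-time encoding reuses stored statistics verbatim", {
  specs <- list(feature_spec("f", kind = "numeric",
                             imputation = "mean_from_simulated"))
  rec <- data.frame(chrom = "c", pos = 1:3, from = "A", to = "C",
                    f = c(NA, 10, 20), stringsAsFactors = FALSE)
  fm <- encode_and_impute(rec, specs, labels = c(0, 1, 1))
  expect_equal(fm$imputation_stats$f, 15)
  newrec <- data.frame(chrom = "c", pos = 4:5, from = "A", to = "C",
                       f = c(NA, 99), stringsAsFactors = FALSE)
  fm2 <- encode_and_impute(newrec, specs, labels = NULL,
                           stats = fm$imputation_stats)
  expect_equal(unname(fm2$X[, "f"]), c(15, 99))
  expect_error(encode_and_impute(newrec, specs, labels = NULL), "stored stats")
})

test_that("encoding is a pure function of records, specs and stats", {
  specs <- list(feature_spec("f", kind = "numeric", imputation = "indicator"),
                feature_spec("g", kind = "categorical", levels = c("x", "y")))
  rec <- data.frame(chrom = "c", pos = 1:50, from = "A", to = "C",
                    f = ifelse(seq_len(50) %% 7 == 0, NA, seq_len(50)),
                    g = rep(c("x", "y", NA, "x", "y"), 10),
                    stringsAsFactors = FALSE)
  y <- rep(c(0, 1), 25)
  f1 <- encode_and_impute(rec, specs, labels = y)
  f2 <- encode_and_impute(rec, specs, labels = y)
  expect_identical(f1$X, f2$X)
})
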