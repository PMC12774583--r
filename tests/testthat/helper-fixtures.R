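# Fixture builders shared across test files. Everything is constructed in
# code; no binary or downloaded data.

revcomp <- function(s) {
  vapply(s, function(one) {
    paste(rev(strsplit(chartr("ACGT-", "TGCA-", one), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

as_genome <- function(x) structure(x, class = c("genome", "character"))

# a 300-bp toy chromosome with a fully hand-enumerable alignment:
#   block 1 (+): positions 1-100, ancestor differs at pos 10 (anc T, ref C)
#     and pos 70 (anc A, ref C); ancestor gap at pos 40
#   block 2 (-): positions 151-250 written on the minus strand, ancestor
#     differs at pos 180 (anc C, ref T) and pos 200 (anc G, ref T)
#   positions 101-150 and 251-300 are covered by no block
# population VCF: chrT:70 alt A at AF 0.5 (so the reference allele is only
# at 0.5 and the difference is NOT nearly fixed) and chrT:200 alt G at
# AF 0.05 (reference allele at 0.95, kept).
hand_maf_fixture <- function(dir = tempfile("handmaf")) {
  dir.create(dir, showWarnings = FALSE)
  ref <- strrep("ACGT", 75)  # pos p has base c(A,C,G,T)[(p-1) %% 4 + 1]
  genome <- as_genome(c(chrT = ref))

  rchars <- strsplit(ref, "")[[1]]
  stopifnot(rchars[10] == "C", rchars[40] == "T", rchars[70] == "C",
            rchars[180] == "T", rchars[200] == "T")

  a1 <- rchars[1:100]
  a1[10] <- "T"; a1[70] <- "A"; a1[40] <- "-"
  a2 <- rchars[151:250]
  a2[180 - 150] <- "C"; a2[200 - 150] <- "G"
  anc_src_len <- 99L + 100L  # ungapped ancestor bases over both blocks

  b1 <- data.frame(
    src = c("sp.chrT", "anc.chrT"), species = c("sp", "anc"),
    chrom = "chrT", start = c(0L, 0L), size = c(100L, 99L),
    strand = "+", src_size = c(300L, anc_src_len),
    text = c(paste(rchars[1:100], collapse = ""), paste(a1, collapse = "")),
    stringsAsFactors = FALSE)
  b2 <- data.frame(
    src = c("sp.chrT", "anc.chrT"), species = c("sp", "anc"),
    chrom = "chrT",
    start = c(300L - 250L, anc_src_len - 99L - 100L),
    size = c(100L, 100L), strand = "-",
    src_size = c(300L, anc_src_len),
    text = revcomp(c(paste(rchars[151:250], collapse = ""),
                     paste(a2, collapse = ""))),
    stringsAsFactors = FALSE)
  maf_path <- file.path(dir, "hand.maf")
  write_maf(list(b1, b2), maf_path)

  pop <- data.frame(chrom = "chrT", pos = c(70L, 200L), ref = c("C", "T"),
                    alt = c("A", "G"), af = c(0.5, 0.05),
                    stringsAsFactors = FALSE)
  vcf_path <- file.path(dir, "pop.vcf")
  write_population_vcf(pop, genome, vcf_path)

  expected_derived <- data.frame(
    chrom = "chrT", pos = c(10L, 180L, 200L),
    from = c("T", "C", "G"), to = c("C", "T", "T"),
    class = "derived", af = c(NA, NA, 0.95), stringsAsFactors = FALSE)

  list(genome = genome, maf = maf_path, vcf = vcf_path,
       expected_derived = expected_derived)
}

# O(n^2) all-pairs Mann-Whitney AUC, the brute-force oracle for roc_auc()
auc_brute <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# a small labelled feature matrix with planted signal, for model tests
toy_feature_matrix <- function(n = 2000, beta = c(1.5, -1, 0.5), seed = 11) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * length(beta)), n,
                dimnames = list(NULL, paste0("x", seq_along(beta))))
    y <- rbinom(n, 1, plogis(drop(X %*% beta)))
    structure(list(X = X, y = y,
                   row_keys = data.frame(chrom = "c", pos = seq_len(n),
                                         from = "A", to = "C"),
                   column_names = colnames(X), imputation_stats = list()),
              class = "feature_matrix")
  })
}

# single-window rate model over an all-A genome, built from planted counts
planted_rate_model <- function(genome_len, rates = c(G = 2e-4, C = 1e-4, T = 0)) {
  counts <- array(0, dim = c(4, 4, 1),
                  dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T"), NULL))
  for (to in names(rates)) counts["A", to, 1] <- rates[[to]] * genome_len
  bc <- matrix(c(genome_len, 0, 0, 0), nrow = 4,
               dimnames = list(c("A", "C", "G", "T"), NULL))
  structure(list(window_size = as.integer(genome_len), min_window_bases = 1,
                 chroms = list(chr1 = list(counts = counts, base_counts = bc,
                                           fallback = FALSE, n_windows = 1L)),
                 genome_counts = counts[, , 1], genome_bases = bc[, 1]),
            class = "mutation_rate_model")
}
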