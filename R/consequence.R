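#' Minimal built-in variant consequence caller
#'
#' Classifies SNVs against a GFF3 gene annotation into
#' `stop_gained`, `missense`, `synonymous`, `splice_site` (intronic within
#' 2 bp of an exon end), `exonic` (non-coding exon), `intronic` or
#' `intergenic`, and reports the reference/alternate amino acids for coding
#' variants. It assumes each transcript's CDS starts in frame (the GFF phase
#' column is ignored) and uses the first annotated transcript overlapping a
#' variant; it is intended for compact annotations and synthetic fixtures,
#' not as a replacement for a full effect predictor.
#'
#' @param variants SNV data frame (`chrom, pos, from, to`; `to` is read on
#'   the forward genome strand).
#' @param gff path to a GFF3 file or an imported `GRanges`.
#' @param genome reference genome.
#' @param splice_bp intronic distance from an exon end treated as splice
#'   region.
#' @return data frame `consequence, aa_ref, aa_alt` aligned with `variants`.
#' @export
call_consequences <- function(variants, gff, genome, splice_bp = 2L) {
  check_snv_frame(variants)
  gr <- if (is.character(gff)) rtracklayer::import(gff, format = "gff3") else gff
  typ <- as.character(GenomicRanges::mcols(gr)$type)
  genes <- gr[typ == "gene"]
  exons <- gr[typ == "exon"]
  cds <- gr[typ == "CDS"]
  cds_parent <- as.character(unlist(GenomicRanges::mcols(cds)$Parent))
  n <- nrow(variants)
  cons <- rep("intergenic", n)
  aa_ref <- rep(NA_character_, n)
  aa_alt <- rep(NA_character_, n)
  if (n == 0L)
    return(data.frame(consequence = cons, aa_ref = aa_ref, aa_alt = aa_alt))
  vgr <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(variants$pos, variants$pos))
  in_gene <- IRanges::overlapsAny(vgr, genes)
  in_exon <- IRanges::overlapsAny(vgr, exons)
  cons[in_gene] <- "intronic"
  # splice region: intronic, within splice_bp of an exon boundary
  if (length(exons) > 0L) {
    near <- IRanges::overlapsAny(
      vgr, GenomicRanges::resize(exons, GenomicRanges::width(exons) + 2L * splice_bp,
                                 fix = "center"))
    cons[in_gene & !in_exon & near] <- "splice_site"
  }
  cons[in_exon] <- "exonic"
  hit <- GenomicRanges::findOverlaps(vgr, cds)
  if (length(hit) > 0L) {
    first <- !duplicated(S4Vectors::queryHits(hit))
    qh <- S4Vectors::queryHits(hit)[first]
    sh <- S4Vectors::subjectHits(hit)[first]
    code <- Biostrings::GENETIC_CODE
    for (k in seq_along(qh)) {
      i <- qh[k]
      tx <- cds_parent[sh[k]]
      pieces <- cds[cds_parent == tx]
      strand <- as.character(GenomicRanges::strand(pieces))[1L]
      st <- GenomicRanges::start(pieces); en <- GenomicRanges::end(pieces)
      o <- if (strand == "-") order(-st) else order(st)
      st <- st[o]; en <- en[o]
      # CDS-relative offset of the variant position
      p <- variants$pos[i]
      off <- 0L; found <- FALSE
      for (seg in seq_along(st)) {
        if (p >= st[seg] && p <= en[seg]) {
          off <- off + if (strand == "-") en[seg] - p + 1L else p - st[seg] + 1L
          found <- TRUE
          break
        }
        off <- off + (en[seg] - st[seg] + 1L)
      }
      if (!found) next
      codon_i <- (off - 1L) %/% 3L
      within <- (off - 1L) %% 3L  # 0-based position within codon
      # genomic positions of the codon, in translation order
      cds_pos <- unlist(lapply(seq_along(st), function(seg) {
        if (strand == "-") seq(en[seg], st[seg]) else seq(st[seg], en[seg])
      }))
      idx <- codon_i * 3L + 1:3
      if (max(idx) > length(cds_pos)) next  # truncated trailing codon
      cpos <- cds_pos[idx]
      bases <- ref_base_at(genome, variants$chrom[i], cpos)
      if (strand == "-") bases <- comp_base(bases)
      ref_codon <- paste(bases, collapse = "")
      altb <- variants$to[i]
      if (strand == "-") altb <- comp_base(altb)
      alt_bases <- bases
      alt_bases[within + 1L] <- altb
      alt_codon <- paste(alt_bases, collapse = "")
      r_aa <- unname(code[ref_codon]); a_aa <- unname(code[alt_codon])
      if (is.na(r_aa) || is.na(a_aa)) next
      aa_ref[i] <- r_aa; aa_alt[i] <- a_aa
      cons[i] <- if (a_aa == "*" && r_aa != "*") "stop_gained"
                 else if (a_aa == r_aa) "synonymous" else "missense"
    }
  }
  data.frame(consequence = cons, aa_ref = aa_ref, aa_alt = aa_alt,
             stringsAsFactors = FALSE)
}

#' Consequence levels used by the built-in caller
#'
#' @return character vector of the seven consequence categories.
#' @export
consequence_levels <- function() {
  c("intergenic", "intronic", "splice_site", "exonic",
    "synonymous", "missense", "stop_gained")
}
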