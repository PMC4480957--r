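# Small fixtures shared across test files; everything is generated in code.

# The hand-checked haplotype configuration used throughout: p_a = 0.3,
# p_b = 0.4, D = 0.08, and forward OR 3 -> 1.5.
hf_hand <- function() haplotype_freqs(0.5, 0.2, 0.1, 0.2)

# A tiny deterministic panel written by explicit haplotype rows.
panel_from_rows <- function(rows, ids, chrom = "chr1",
                            pos = seq(1000L, by = 1000L,
                                      length.out = length(ids))) {
  haps <- do.call(rbind, rows)
  colnames(haps) <- ids
  hap_panel(haps, data.frame(id = ids, chrom = chrom, pos = pos,
                             allele1 = "A", allele0 = "G",
                             stringsAsFactors = FALSE))
}

# Random valid haplotype frequencies with both SNPs polymorphic and D != 0
# (rejection-sampled from a flat Dirichlet).
random_hf <- function() {
  repeat {
    h <- stats::rgamma(4, 1)
    h <- h / sum(h)
    hf <- haplotype_freqs(h[1], h[2], h[3], h[4])
    if (hf$p_a > 0.02 && hf$p_a < 0.98 && hf$p_b > 0.02 && hf$p_b < 0.98 &&
        abs(hf$h_ab - hf$p_a * hf$p_b) > 1e-4)
      return(hf)
  }
}

# One marker row as used by candidate selection.
marker_row <- function(id = "snp_marker", chrom = "chr1", pos = 500000L,
                       odds_ratio = 1.5, p_value = 1e-8,
                       source = "catalog", disease = "disease_A") {
  data.frame(id = id, chrom = chrom, pos = pos, risk_allele = "A",
             other_allele = "G", odds_ratio = odds_ratio, p_value = p_value,
             source = source, disease = disease, stringsAsFactors = FALSE)
}

# Independent brute-force oracle for the direct splice-site rules: lay the
# transcript out base by base in transcription order and label the
# splice-relevant positions with head/tail operations on explicit base
# vectors (the detector uses coordinate arithmetic instead).
brute_force_splice_sites <- function(gene) {
  ex <- gene$exons
  n <- nrow(ex)
  if (n < 2L) return(data.frame(pos = integer(0), site = character(0),
                                region = character(0)))
  exon_vecs <- lapply(seq_len(n), function(j) ex$start[j]:ex$end[j])
  intron_vecs <- lapply(seq_len(n - 1L), function(j)
    (ex$end[j] + 1L):(ex$start[j + 1L] - 1L))
  if (gene$strand == "-") {
    exon_vecs <- rev(lapply(exon_vecs, rev))
    intron_vecs <- rev(lapply(intron_vecs, rev))
  }
  out <- list()
  for (j in seq_len(n - 1L)) {
    up <- exon_vecs[[j]]; dn <- exon_vecs[[j + 1L]]; iv <- intron_vecs[[j]]
    out[[length(out) + 1L]] <- data.frame(
      pos = c(utils::tail(up, 3L), utils::head(iv, 2L),
              utils::tail(iv, 2L), utils::head(dn, 1L)),
      site = c(rep("donor", 3L + 2L), rep("acceptor", 2L + 1L)),
      region = c(rep("exonic", 3L), rep("intronic", 4L), "exonic"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
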