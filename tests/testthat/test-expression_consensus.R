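test_that("consensus requires two independent studies", {
  g <- make_haplotype_panel(n_hap = 200, p_causal = 0.3, target_r2 = 0.9,
                            n_neutral = 2, seed = 21)
  recs <- data.frame(snp_id = "snp_causal", gene_id = "G",
                     study_id = c("s1", "s2"), direction = "down",
                     stringsAsFactors = FALSE)
  cons <- build_consensus_eqtls(recs, g$panel, mech_config())
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$n_studies, 2L)
  expect_false(cons$direction_conflict)

  solo <- recs[1, ]
  expect_equal(nrow(build_consensus_eqtls(solo, g$panel, mech_config())), 0L)

  # same SNP reported twice by one study is still one study
  dup <- recs; dup$study_id <- "s1"; dup$snp_id <- c("snp_causal", "snp_marker")
  expect_equal(nrow(build_consensus_eqtls(dup, g$panel, mech_config())), 0L)
})

test_that("markers in strong LD cluster into one consensus", {
  # panel with r2(marker, causal) ~ 0.9 > 0.8: two studies reporting the
  # two different SNPs still form one consensus
  g <- make_haplotype_panel(n_hap = 5000, p_causal = 0.3, target_r2 = 0.9,
                            n_neutral = 2, seed = 22)
  recs <- data.frame(snp_id = c("snp_causal", "snp_marker"),
                     gene_id = "G", study_id = c("s1", "s2"),
                     direction = c("down", "up"), stringsAsFactors = FALSE)
  cons <- build_consensus_eqtls(recs, g$panel, mech_config())
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$n_snps, 2L)
  expect_true(cons$direction_conflict)

  # weak LD (independent neutral SNP): two clusters, neither replicated
  recs2 <- data.frame(snp_id = c("snp_causal", "snp_n2"),
                      gene_id = "G", study_id = c("s1", "s2"),
                      direction = "down", stringsAsFactors = FALSE)
  expect_equal(nrow(build_consensus_eqtls(recs2, g$panel, mech_config())),
               0L)

  # SNPs missing from the panel are non-linkable and warned about
  recs3 <- data.frame(snp_id = c("ghost", "ghost2"), gene_id = "G",
                      study_id = c("s1", "s2"), direction = "down",
                      stringsAsFactors = FALSE)
  expect_warning(out <- build_consensus_eqtls(recs3, g$panel, mech_config()),
                 "non-linkable")
  expect_equal(nrow(out), 0L)
})

test_that("consensus clustering is invariant to record order", {
  g <- make_haplotype_panel(n_hap = 3000, p_causal = 0.3, target_r2 = 0.95,
                            n_neutral = 4, seed = 23)
  recs <- data.frame(
    snp_id = c("snp_causal", "snp_marker", "snp_n2", "snp_n3"),
    gene_id = "G", study_id = c("s1", "s2", "s3", "s1"),
    direction = "unknown", stringsAsFactors = FALSE)
  c1 <- build_consensus_eqtls(recs, g$panel, mech_config())
  set.seed(1)
  for (i in 1:5) {
    c2 <- build_consensus_eqtls(recs[sample(nrow(recs)), ], g$panel,
                                mech_config())
    expect_equal(c2, c1)
  }
})

test_that("cM interpolation and distances behave on a linear map", {
  map <- make_genetic_map("chr1", 1e6, 1)
  expect_equal(as.numeric(cm_position("chr1", 500000, map)), 0.5)
  expect_equal(cm_distance("chr1", 500000, "chr1", 540000, map), 0.04)
  expect_error(cm_distance("chr1", 1, "chr2", 1, map),
               "undefined across chromosomes")
  # beyond-anchor positions clamp with a warning
  expect_warning(x <- cm_position("chr1", 2e6, map), "clamped")
  expect_equal(as.numeric(x), 1)
  expect_error(cm_position("chr9", 1, map), "no genetic map anchors")
})

test_that("disease markers match consensus eQTLs by identity or 0.05 cM", {
  map <- make_genetic_map("chr1", 1e6, 1)
  sites <- data.frame(id = c("e1", "e2"), chrom = "chr1",
                      pos = c(540000L, 560001L),
                      allele1 = "A", allele0 = "G", stringsAsFactors = FALSE)
  cons <- data.frame(gene_id = "G", cluster = "e1,e2", n_studies = 2L,
                     n_snps = 2L, direction_conflict = FALSE,
                     stringsAsFactors = FALSE)
  mk <- list(id = "e1", chrom = "chr1", pos = 123L)
  expect_true(match_disease_eqtl(mk, cons[1, ], sites, map,
                                 mech_config())$match)  # identical id

  mk2 <- list(id = "m", chrom = "chr1", pos = 500000L)
  # nearest member e1 at 0.04 cM: match
  res <- match_disease_eqtl(mk2, cons[1, ], sites, map, mech_config())
  expect_true(res$match)
  expect_equal(res$snp_id, "e1")

  # nearest member at 0.06 cM: no match
  cons2 <- cons; cons2$cluster <- "e2"
  expect_false(match_disease_eqtl(mk2, cons2[1, ], sites, map,
                                  mech_config())$match)

  # cluster on another chromosome never matches
  sites3 <- sites; sites3$chrom <- "chr2"
  expect_false(match_disease_eqtl(mk2, cons[1, ], sites3, map,
                                  mech_config())$match)
})

test_that("single-study planted eQTLs are never called, two-study always", {
  sc <- simulate_scenario(n_loci = 10, n_hap = 300, seed = 17)
  res <- run_pipeline(sc, quiet = TRUE)
  gt <- sc$ground_truth
  expr_calls <- res$mechanism_calls[
    res$mechanism_calls$mechanism == "expression", ]
  # every decoy single-study relation is absent
  expect_false(any(grepl("_decoy", expr_calls$gene_id)))
  expect_false(any(grepl("_decoy", res$consensus_eqtls$gene_id)))
  # every planted two-study relation is recovered in its locus
  planted <- gt[gt$mechanism_class == "expression", ]
  for (i in seq_len(nrow(planted)))
    expect_true(any(expr_calls$locus_id == planted$locus_id[i] &
                      expr_calls$gene_id == planted$gene_id[i]))
})
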