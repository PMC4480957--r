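test_that("marker selection applies source-specific strict thresholds", {
  mk <- rbind(marker_row("m1", source = "catalog", p_value = 2e-6),
              marker_row("m2", source = "primary_scan", p_value = 2e-6),
              marker_row("m3", source = "primary_scan", p_value = 4e-7),
              marker_row("m4", source = "catalog", p_value = 1e-5),
              marker_row("m5", source = "primary_scan", p_value = 5e-7))
  kept <- select_markers(mk, mech_config())
  # catalog threshold 1e-5 admits 2e-6; primary threshold 5e-7 rejects it;
  # values exactly at a threshold are dropped (strict inequality)
  expect_setequal(kept$id, c("m1", "m3"))

  bad <- marker_row("mx"); bad$source <- "weird"
  expect_error(select_markers(bad, mech_config()), "unknown marker source")
})

test_that("candidate enumeration applies window and MAF rules inclusively", {
  set.seed(1)
  n <- 200L
  mk_col <- stats::rbinom(n, 1L, 0.4)
  mk <- marker_row("mk", pos = 500000L)
  # edge SNP exactly at +200 kb with MAF exactly 0.05; one beyond the
  # window; one below the MAF floor
  cols <- list(mk = mk_col,
               edge = sample(c(rep(1L, 10L), rep(0L, n - 10L))),
               far = stats::rbinom(n, 1L, 0.3),
               rare = sample(c(rep(1L, 4L), rep(0L, n - 4L))))
  haps <- do.call(cbind, cols)
  colnames(haps) <- names(cols)
  panel <- hap_panel(haps, data.frame(
    id = names(cols), chrom = "chr1",
    pos = c(500000L, 700000L, 750001L, 510000L),
    allele1 = "A", allele0 = "G", stringsAsFactors = FALSE))
  cand <- enumerate_candidates(mk, panel, mech_config())
  expect_true("edge" %in% cand$snp_id)   # 200 kb and MAF 0.05: inclusive
  expect_false("far" %in% cand$snp_id)   # 250 kb away
  expect_false("rare" %in% cand$snp_id)  # MAF 0.02
  expect_true("mk" %in% cand$snp_id)     # the marker itself qualifies
  expect_error(enumerate_candidates(marker_row("zz"), panel, mech_config()),
               "absent from panel")
})

test_that("acceptance requires feasibility and the r2 floor", {
  # candidate in perfect LD with the marker: implied OR equals marker OR
  rows <- c(rep(list(c(1L, 1L)), 40L), rep(list(c(0L, 0L)), 60L))
  p <- panel_from_rows(rows, c("cand", "mk"),
                       pos = c(501000L, 500000L))
  mk <- marker_row("mk", pos = 500000L, odds_ratio = 1.5)
  cand <- enumerate_candidates(mk, p, mech_config())
  cand <- accept_candidates(cand, mk, mech_config())
  crow <- cand[cand$snp_id == "cand", ]
  expect_true(crow$accepted)
  expect_equal(crow$implied_or, 1.5, tolerance = 1e-9)

  # hand-checked LD configuration: marker OR 1.5 implies candidate OR 3.
  # Its r2 is ~0.127, so under the literal feasibility-only rule
  # (r2_floor = 0) it is accepted, while the default 0.2 floor screens it
  # out even though the inversion is feasible.
  rows2 <- c(rep(list(c(0L, 0L)), 5), rep(list(c(0L, 1L)), 2),
             rep(list(c(1L, 0L)), 1), rep(list(c(1L, 1L)), 2))
  rows2 <- rep(rows2, 20L)  # MAF-safe panel size
  p2 <- panel_from_rows(rows2, c("cand", "mk"), pos = c(501000L, 500000L))
  literal <- mech_config(r2_floor = 0)
  cand2 <- accept_candidates(enumerate_candidates(mk, p2, literal),
                             mk, literal)
  crow2 <- cand2[cand2$snp_id == "cand", ]
  expect_true(crow2$accepted)
  expect_equal(crow2$implied_or, 3.0, tolerance = 1e-9)
  cand2f <- accept_candidates(enumerate_candidates(mk, p2, mech_config()),
                              mk, mech_config())
  crow2f <- cand2f[cand2f$snp_id == "cand", ]
  expect_true(crow2f$feasible)
  expect_false(crow2f$accepted)

  # D = 0: the marker carries no information, candidate rejected
  set.seed(2)
  indep <- lapply(1:400, function(i) c(stats::rbinom(1, 1, 0.5),
                                       stats::rbinom(1, 1, 0.4)))
  # force exact independence by crossing the two alleles in equal blocks
  blocks <- expand.grid(a = 0:1, b = 0:1)
  indep <- rep(lapply(seq_len(4), function(i)
    c(blocks$a[i], blocks$b[i])), 25L)
  p3 <- panel_from_rows(indep, c("cand", "mk"), pos = c(501000L, 500000L))
  cand3 <- accept_candidates(enumerate_candidates(mk, p3, mech_config()),
                             mk, mech_config())
  expect_false(cand3$accepted[cand3$snp_id == "cand"])
})

test_that("locus extent spans accepted candidates or degenerates to marker", {
  mk <- marker_row("mk", pos = 500000L)
  cand <- data.frame(pos = c(100000L, 250000L, 380000L),
                     accepted = c(TRUE, TRUE, TRUE))
  expect_equal(unname(locus_extent(cand, mk)), c(100000, 380000))
  cand$accepted <- FALSE
  expect_equal(unname(locus_extent(cand, mk)), c(500000, 500000))
  one <- data.frame(pos = 150000L, accepted = TRUE)
  expect_equal(unname(locus_extent(one, mk)), c(150000, 150000))
})

test_that("planted causal SNPs at r2 >= 0.5 are always accepted", {
  for (seed in 1:10) {
    g <- make_haplotype_panel(n_hap = 400, p_causal = 0.25,
                              target_r2 = 0.5 + 0.05 * seed,
                              n_neutral = 4, seed = seed)
    hf <- haplotype_freqs_from_panel(g$panel, g$causal_id, g$marker_id)
    or_m <- forward_marker_or(hf, 2.0)
    mk <- marker_row(g$marker_id, pos = 500000L, odds_ratio = or_m)
    cand <- accept_candidates(enumerate_candidates(mk, g$panel,
                                                   mech_config()),
                              mk, mech_config())
    crow <- cand[cand$snp_id == g$causal_id, ]
    expect_true(crow$accepted)
    expect_equal(crow$implied_or, 2.0, tolerance = 1e-9)
  }
})

test_that("acceptance is monotone in r2 at fixed allele frequencies", {
  # family of haplotype configurations with p_a = p_b = 0.3 and growing D
  p <- 0.3
  accepted_at <- function(D) {
    h_ab <- p * p + D
    hf <- haplotype_freqs(1 - 2 * p + h_ab, p - h_ab, p - h_ab, h_ab)
    s <- ld_stats(hf)
    res <- implied_candidate_or(hf, 1.4)
    list(r2 = s$r2, ok = res$feasible && s$r2 >= 0.2)
  }
  Ds <- seq(0.02, 0.20, by = 0.02)
  states <- vapply(Ds, function(D) accepted_at(D)$ok, logical(1))
  r2s <- vapply(Ds, function(D) accepted_at(D)$r2, numeric(1))
  expect_true(all(diff(r2s) > 0))
  # once accepted, stays accepted as r2 grows
  first <- which(states)[1]
  expect_true(all(states[first:length(states)]))
})

test_that("markers within one window merge into the lowest-p locus", {
  g <- make_haplotype_panel(n_hap = 200, p_causal = 0.3, target_r2 = 0.9,
                            n_neutral = 2, seed = 11)
  hf <- haplotype_freqs_from_panel(g$panel, g$causal_id, g$marker_id)
  or_m <- forward_marker_or(hf, 2.0)
  m1 <- marker_row(g$marker_id, pos = 500000L, odds_ratio = or_m,
                   p_value = 1e-8)
  # weaker, nearby marker of the same disease: merged, not its own locus;
  # it is absent from the panel, which must not matter once merged
  m2 <- marker_row("weaker", pos = 560000L, p_value = 1e-6)
  out <- build_loci(rbind(m1, m2), g$panel, mech_config())
  expect_equal(nrow(out$loci), 1L)
  expect_equal(out$loci$marker_id, g$marker_id)
  expect_match(out$loci$merged_markers, "weaker")
  # a representative marker missing from the panel is dropped with warning
  expect_warning(build_loci(m2, g$panel, mech_config()),
                 "absent from panel")
})
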