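calls_df <- function(mechs, gene = "G", locus = "L1") {
  if (length(mechs) == 0L)
    return(data.frame(locus_id = character(0), gene_id = character(0),
                      snp_id = character(0), mechanism = character(0),
                      evidence = character(0)))
  data.frame(locus_id = locus, gene_id = gene,
             snp_id = paste0("s", seq_along(mechs)), mechanism = mechs,
             evidence = "", stringsAsFactors = FALSE)
}

test_that("locus profiles collapse missense and cap at four types", {
  p <- locus_mechanism_profile(calls_df(c("missense_high", "missense_low",
                                          "expression")))
  expect_setequal(p$mechanisms_present, c("missense_high", "expression"))
  expect_equal(p$n_mechanism_types, 2L)

  expect_equal(locus_mechanism_profile(calls_df(character(0)))$n_mechanism_types,
               0L)

  all5 <- locus_mechanism_profile(calls_df(mechanism_classes()))
  expect_equal(all5$n_mechanism_types, 4L)
  expect_false(all(c("missense_high", "missense_low") %in%
                     all5$mechanisms_present))
})

test_that("locus categories follow A > B > C precedence with MHC separate", {
  expect_equal(locus_category(c("A", "C")), "A")
  expect_equal(locus_category(c("B", "C")), "B")
  expect_equal(locus_category(c("C", "C")), "C")
  expect_equal(locus_category(character(0)), "none")
  expect_equal(locus_category(c("A", "B"), is_mhc = TRUE), "D")
  # permutation invariance
  set.seed(3)
  labs <- c("C", "B", "A", "C", "B")
  for (i in 1:5)
    expect_equal(locus_category(sample(labs)), "A")
})

test_that("overlap fractions reproduce set arithmetic", {
  pt <- data.frame(gene_id = paste0("g", 1:10), disease = "d",
                   missense_high = FALSE, missense_low = FALSE,
                   expression = c(rep(TRUE, 3), rep(FALSE, 7)),
                   aux_splice = c(rep(TRUE, 10)),
                   direct_splice = FALSE, relevance = "B", known = TRUE,
                   stringsAsFactors = FALSE)
  expect_equal(overlap_fraction(pt, "aux_splice", "expression"), 0.3)
  expect_equal(overlap_fraction(pt, "expression", "aux_splice"), 1)
  expect_equal(overlap_fraction(pt, "expression", "missense_high"), 0)
  expect_true(is.na(overlap_fraction(pt, "direct_splice", "expression")))
})

test_that("sensitivity-model primitives follow their closed forms", {
  expect_equal(delta_a_from_fold(5), -0.8)
  expect_equal(delta_a_from_fold(1), 0)
  expect_equal(delta_a_from_fold(2), -0.5)
  expect_equal(delta_a_from_fold(5, gain = TRUE), 4)
  expect_error(delta_a_from_fold(0.5), "fold")

  expect_equal(delta_p_from_or(1.84), 0.84)
  expect_equal(delta_p_from_or(1), 0)
  expect_equal(delta_p_from_or(2.5), 1.5)

  expect_equal(sensitivity_coefficient(0.84, -0.8), 1.05)
  expect_equal(sensitivity_coefficient(0, -0.3), 0)
  expect_equal(sensitivity_coefficient(0.84, -0.8, use_magnitude = FALSE),
               -1.05)
  expect_error(sensitivity_coefficient(1, 0), "non-zero")

  expect_equal(linear_phenotype(c(1, 2), c(0.1, -0.05)), 0)
  expect_equal(linear_phenotype(1.05, -0.8), -0.84)
  expect_equal(linear_phenotype(numeric(0), numeric(0)), 0)

  expect_equal(selection_threshold(10000), 5e-5)
  expect_equal(selection_threshold(1), 0.5)
  expect_equal(selection_threshold(500), 1e-3)
  expect_error(selection_threshold(0.5), "n_e")
})

test_that("fold-change and activity-change transforms are mutual inverses", {
  folds <- c(1, 1.5, 2, 5, 10, 100)
  for (f in folds) {
    da <- delta_a_from_fold(f)
    expect_equal(1 / (da + 1), f, tolerance = 1e-12)
    dg <- delta_a_from_fold(f, gain = TRUE)
    expect_equal(dg + 1, f, tolerance = 1e-12)
  }
})

test_that("two-tailed Fisher test matches hand-enumerated tables", {
  expect_equal(fisher_two_tailed(5, 5, 5, 5), 1.0)
  # margins 4/4, N = 8: tables at probability <= P(obs) are x in
  # {0, 1, 3, 4} with counts 1 + 16 + 16 + 1 = 34 of C(8,4) = 70
  expect_equal(fisher_two_tailed(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
  expect_equal(fisher_two_tailed(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_error(fisher_two_tailed(0, 0, 1, 1), "margins")
  expect_error(fisher_two_tailed(-1, 1, 1, 1), "non-negative")
})

test_that("Fisher test equals stats::fisher.test across random tables", {
  set.seed(13)
  for (i in 1:200) {
    n <- sample(2:40, 1)
    a <- sample(0:n, 1); b <- sample(0:n, 1)
    c_ <- sample(0:n, 1); d <- sample(0:n, 1)
    if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0) next
    expect_equal(fisher_two_tailed(a, b, c_, d),
                 stats::fisher.test(matrix(c(a, c_, b, d), 2))$p.value,
                 tolerance = 1e-10)
  }
})

test_that("enrichment p-values respond to planted association", {
  # mechanisms planted only in known genes: small p
  elig <- data.frame(gene_id = paste0("g", 1:40), disease = "d",
                     known = rep(c(TRUE, FALSE), each = 20),
                     stringsAsFactors = FALSE)
  pt <- data.frame(gene_id = paste0("g", 1:18), disease = "d",
                   missense_high = TRUE, missense_low = FALSE,
                   expression = FALSE, aux_splice = FALSE,
                   direct_splice = FALSE, relevance = "B",
                   known = TRUE, stringsAsFactors = FALSE)
  enr <- enrichment_by_mechanism(pt, elig)
  p_strong <- enr$p_value[enr$mechanism == "missense_high"]
  expect_lt(p_strong, 1e-4)
  # mechanism independent of the known label: p near 1
  pt2 <- pt
  pt2$gene_id <- paste0("g", seq(2, 36, by = 2))
  enr2 <- enrichment_by_mechanism(pt2, elig)
  expect_gt(enr2$p_value[enr2$mechanism == "missense_high"], 0.5)
  # a mechanism no protein carries degenerates to p = 1
  expect_equal(enr$p_value[enr$mechanism == "direct_splice"], 1)

  # weaker planted effects give larger p (monotone in effect strength)
  p_at_k <- function(k) {
    ptk <- pt[seq_len(k), , drop = FALSE]
    enrichment_by_mechanism(ptk, elig)$p_value[1]
  }
  ps <- vapply(c(18, 12, 6), p_at_k, numeric(1))
  expect_true(all(diff(ps) > 0))
})

test_that("null enrichment p-values are roughly uniform", {
  set.seed(29)
  reps <- 200
  ps <- numeric(reps)
  for (r in seq_len(reps)) {
    known <- sample(c(rep(TRUE, 20), rep(FALSE, 20)))
    has <- sample(c(rep(TRUE, 12), rep(FALSE, 28)))
    elig <- data.frame(gene_id = paste0("g", 1:40), disease = "d",
                       known = known, stringsAsFactors = FALSE)
    pt <- data.frame(gene_id = paste0("g", 1:40)[has], disease = "d",
                     missense_high = TRUE, missense_low = FALSE,
                     expression = FALSE, aux_splice = FALSE,
                     direct_splice = FALSE, relevance = "B",
                     known = known[has], stringsAsFactors = FALSE)
    ps[r] <- enrichment_by_mechanism(pt, elig)$p_value[1]
  }
  # exact-test p-values are super-uniform under the null; check both the
  # type-I error level and that small p-values do occur
  expect_lt(mean(ps < 0.05), 0.08)
  expect_gt(mean(ps < 0.5), 0.2)
})

test_that("locus summaries count mechanism types consistently", {
  sc <- simulate_scenario(n_loci = 8, n_hap = 200, seed = 19)
  res <- run_pipeline(sc, quiet = TRUE)
  ls <- res$locus_summaries
  for (i in seq_len(nrow(ls))) {
    flags <- unlist(ls[i, mechanism_classes()])
    expect_false(flags[["missense_high"]] && flags[["missense_low"]])
    expect_equal(sum(flags), ls$n_mechanism_types[i])
    expect_lte(ls$n_mechanism_types[i], 4L)
  }
  # scenario relevance labels: loci 1-3 planted as category A, rest B
  gt <- sc$ground_truth
  cat_by_locus <- ls$category[match(gt$locus_id, ls$locus_id)]
  expect_true(all(cat_by_locus[1:3] == "A"))
  expect_true(all(cat_by_locus[-(1:3)] == "B"))
})
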