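#' Generate a two-SNP-plus-neutrals haplotype panel with controlled LD
#'
#' Builds a phased panel containing a planted causal SNP, a marker SNP in
#' LD with it, and independent neutral SNPs. The causal column is drawn at
#' exact allele count `round(n_hap * p_causal)`; the marker column copies
#' the causal column with probability `sqrt(target_r2)` per haplotype and
#' otherwise redraws an independent Bernoulli(`p_causal`) allele, a
#' symmetric allele-flip construction whose expected squared correlation
#' with the causal column is `target_r2`.
#'
#' @param n_hap Number of haplotypes (>= 100).
#' @param p_causal Causal risk-allele frequency, in `[0.05, 0.5]`.
#' @param target_r2 Target marker-causal r-squared, in `(0, 1]`.
#' @param n_neutral Number of independent neutral SNPs.
#' @param seed RNG seed.
#' @param chrom Chromosome label for all sites.
#' @param marker_pos,causal_pos Base-pair positions of marker and causal SNP.
#' @param neutral_span Half-width (bp) over which neutral SNPs are spread
#'   around the marker; the default extends past the 200 kb candidate
#'   window so the window filter is exercised.
#' @param n_low_maf How many of the neutral SNPs are given a 2% allele
#'   frequency (below the default 5% MAF floor).
#' @param prefix Prefix for generated SNP ids.
#' @return List with `panel` (a [hap_panel()]), `marker_id`, `causal_id`,
#'   `realized_r2`, and realized allele frequencies `p_causal_real`,
#'   `p_marker_real`. All sites code the risk allele as base "A" (= 1).
#' @export
make_haplotype_panel <- function(n_hap = 400L, p_causal = 0.3,
                                 target_r2 = 0.8, n_neutral = 8L,
                                 seed = 1L, chrom = "chr1",
                                 marker_pos = 500000L,
                                 causal_pos = 501000L,
                                 neutral_span = 240000L,
                                 n_low_maf = 1L,
                                 prefix = "snp_") {
  if (n_hap < 100L) stop("n_hap must be >= 100", call. = FALSE)
  if (p_causal < 0.05 || p_causal > 0.5)
    stop("infeasible p_causal: must lie in [0.05, 0.5]", call. = FALSE)
  if (target_r2 <= 0 || target_r2 > 1)
    stop("infeasible target_r2: must lie in (0, 1]", call. = FALSE)
  set.seed(seed)
  k <- round(n_hap * p_causal)
  causal <- sample(c(rep(1L, k), rep(0L, n_hap - k)))
  theta <- sqrt(target_r2)
  marker <- causal
  if (theta < 1) {
    for (attempt in 1:50) {
      redraw <- stats::runif(n_hap) >= theta
      marker <- ifelse(redraw, stats::rbinom(n_hap, 1L, p_causal), causal)
      if (any(marker == 1L) && any(marker == 0L)) break
    }
    if (all(marker == marker[1L]))
      stop("could not generate a polymorphic marker column", call. = FALSE)
  }
  cols <- list(marker, causal)
  ids <- c(paste0(prefix, "marker"), paste0(prefix, "causal"))
  pos <- c(marker_pos, causal_pos)
  if (n_neutral > 0L) {
    npos <- round(seq(marker_pos - neutral_span, marker_pos + neutral_span,
                      length.out = n_neutral))
    npos[npos %in% pos] <- npos[npos %in% pos] + 7L
    pn <- stats::runif(n_neutral, 0.1, 0.45)
    if (n_low_maf > 0L) pn[seq_len(min(n_low_maf, n_neutral))] <- 0.02
    for (j in seq_len(n_neutral))
      cols[[2L + j]] <- stats::rbinom(n_hap, 1L, pn[j])
    ids <- c(ids, paste0(prefix, "n", seq_len(n_neutral)))
    pos <- c(pos, npos)
  }
  haps <- do.call(cbind, cols)
  colnames(haps) <- ids
  sites <- data.frame(id = ids, chrom = chrom, pos = as.integer(pos),
                      allele1 = "A", allele0 = "G",
                      stringsAsFactors = FALSE)
  panel <- hap_panel(haps, sites)
  r <- stats::cor(as.numeric(causal), as.numeric(marker))
  list(panel = panel,
       marker_id = ids[1L], causal_id = ids[2L],
       realized_r2 = r^2,
       p_causal_real = mean(causal), p_marker_real = mean(marker))
}

#' Simulate a retrospective case/control cohort with a planted causal SNP
#'
#' Samples case and control haplotypes conditional on disease status under
#' a multiplicative per-allele odds model at the causal SNP, matching the
#' retrospective design of a GWA study under the rare-disease
#' approximation: control haplotypes are drawn uniformly from the
#' population panel, case haplotypes carry the causal risk allele with
#' frequency `q_a = or p_a / (1 - p_a + or p_a)` and are otherwise drawn
#' from the panel conditional on that allele, so linked SNPs inherit the
#' population LD structure.
#'
#' @param panel A [hap_panel()].
#' @param causal_snp_id Id of the causal SNP in the panel.
#' @param causal_or Per-allele odds ratio at the causal SNP (> 0).
#' @param n_case,n_control Numbers of diploid individuals per arm.
#' @param seed RNG seed.
#' @return List with `genotypes` (individuals x SNPs, 0/1/2 risk-allele
#'   counts), `status` (1 = case), and `snp_ids`.
#' @export
plant_causal_cohort <- function(panel, causal_snp_id, causal_or,
                                n_case, n_control, seed = 1L) {
  stopifnot(inherits(panel, "hap_panel"))
  if (!causal_snp_id %in% colnames(panel$haps))
    stop("causal SNP '", causal_snp_id, "' absent from panel", call. = FALSE)
  if (causal_or <= 0) stop("causal_or must be > 0", call. = FALSE)
  x <- panel$haps[, causal_snp_id]
  p_a <- mean(x)
  if (p_a <= 0 || p_a >= 1)
    stop("degenerate allele frequency at causal SNP", call. = FALSE)
  set.seed(seed)
  idx1 <- which(x == 1L); idx0 <- which(x == 0L)
  q_a <- causal_or * p_a / (1 - p_a + causal_or * p_a)
  draw_arm <- function(n_ind, q) {
    n_h <- 2L * n_ind
    allele <- stats::rbinom(n_h, 1L, q)
    rows <- integer(n_h)
    rows[allele == 1L] <- sample(idx1, sum(allele == 1L), replace = TRUE)
    rows[allele == 0L] <- sample(idx0, sum(allele == 0L), replace = TRUE)
    h <- panel$haps[rows, , drop = FALSE]
    h[seq(1L, n_h, by = 2L), , drop = FALSE] +
      h[seq(2L, n_h, by = 2L), , drop = FALSE]
  }
  g_case <- draw_arm(n_case, q_a)
  g_ctrl <- draw_arm(n_control, p_a)
  list(genotypes = rbind(g_case, g_ctrl),
       status = c(rep(1L, n_case), rep(0L, n_control)),
       snp_ids = colnames(panel$haps))
}

#' Allelic odds ratio estimated from a cohort
#'
#' 2x2 allele-count odds ratio with a Woolf (log-scale) 95% confidence
#' interval; the Haldane 0.5 correction is applied only when a cell is 0.
#'
#' @param cohort Output of [plant_causal_cohort()].
#' @param snp_id SNP to estimate at.
#' @return List with `or`, `ci_lo`, `ci_hi`, and the allele-count table.
#' @export
estimate_allelic_or <- function(cohort, snp_id) {
  g <- cohort$genotypes[, snp_id]
  case <- cohort$status == 1L
  # doubles: allele counts of large cohorts overflow integer products
  a <- as.numeric(sum(g[case])); b <- 2 * sum(case) - a
  c_ <- as.numeric(sum(g[!case])); d <- 2 * sum(!case) - c_
  tab <- c(case_risk = a, case_other = b, control_risk = c_,
           control_other = d)
  if (any(tab == 0)) tab <- tab + 0.5
  or <- (tab[1L] * tab[4L]) / (tab[2L] * tab[3L])
  se <- sqrt(sum(1 / tab))
  list(or = unname(or),
       ci_lo = unname(or * exp(-1.959964 * se)),
       ci_hi = unname(or * exp(1.959964 * se)),
       counts = c(a, b, c_, d))
}

#' Generate random gene models
#'
#' Genes with `exons_per_gene` exons each, random exon lengths of 100-300
#' bp and introns of 200-1000 bp, laid out head to tail from `start` with
#' 10 kb spacing, alternating strand.
#'
#' @param n_genes Number of genes.
#' @param exons_per_gene Exons per gene (>= 1).
#' @param seed RNG seed.
#' @param chrom Chromosome label.
#' @param start Genomic start of the first gene.
#' @return Named list of [gene_model()] objects.
#' @export
make_gene_models <- function(n_genes, exons_per_gene = 3L, seed = 1L,
                             chrom = "chr1", start = 10000L) {
  set.seed(seed)
  cur <- start
  models <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    ex_len <- sample(100:300, exons_per_gene, replace = TRUE)
    in_len <- if (exons_per_gene > 1L)
      sample(200:1000, exons_per_gene - 1L, replace = TRUE) else integer(0)
    s <- cur
    starts <- ends <- integer(exons_per_gene)
    for (j in seq_len(exons_per_gene)) {
      starts[j] <- s
      ends[j] <- s + ex_len[j] - 1L
      if (j < exons_per_gene) s <- ends[j] + in_len[j] + 1L
    }
    models[[i]] <- gene_model(paste0("gene", i), chrom,
                              if (i %% 2L == 1L) "+" else "-",
                              data.frame(start = starts, end = ends))
    cur <- ends[exons_per_gene] + 10000L
  }
  names(models) <- vapply(models, `[[`, character(1), "gene_id")
  models
}

#' Generate multi-study eQTL catalogs with planted relations
#'
#' @param n_studies Number of study tables to emit.
#' @param planted_relations Data frame with one row per planted relation:
#'   `gene_id`; `snp_ids` (comma-separated list of reporting marker SNPs;
#'   a single id means all reporting studies use the identical marker,
#'   several ids mean study k reports the k-th SNP, which the caller must
#'   ensure are in mutual LD for the relation to be linkable);
#'   `n_studies_reporting` (1, 2, ...); optional `direction`.
#' @param seed RNG seed (reporting studies are the first
#'   `n_studies_reporting` for determinism; the seed is reserved for
#'   future noise models).
#' @return List with `records` (combined data frame, columns `snp_id`,
#'   `gene_id`, `study_id`, `direction`) and `truth` (the planted table
#'   with a `replicated` flag).
#' @export
make_eqtl_catalogs <- function(n_studies, planted_relations, seed = 1L) {
  need <- c("gene_id", "snp_ids", "n_studies_reporting")
  if (!is.data.frame(planted_relations) ||
      !all(need %in% names(planted_relations)))
    stop("planted_relations needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (max(planted_relations$n_studies_reporting) > n_studies)
    stop("a planted relation reports in more studies than exist",
         call. = FALSE)
  if (is.null(planted_relations$direction))
    planted_relations$direction <- "unknown"
  studies <- paste0("study", seq_len(n_studies))
  rows <- list()
  for (i in seq_len(nrow(planted_relations))) {
    rel <- planted_relations[i, ]
    snps <- strsplit(rel$snp_ids, ",", fixed = TRUE)[[1L]]
    ns <- rel$n_studies_reporting
    use_snps <- if (length(snps) == 1L) rep(snps, ns)
                else rep(snps, length.out = ns)
    rows[[i]] <- data.frame(snp_id = use_snps, gene_id = rel$gene_id,
                            study_id = studies[seq_len(ns)],
                            direction = rel$direction,
                            stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  truth <- planted_relations
  truth$replicated <- truth$n_studies_reporting >= 2L
  list(records = records, truth = truth)
}

#' Generate a missense impact annotation table from planted labels
#'
#' @param planted_labels Data frame with `snp_id`, `gene_id`, `impact`
#'   (`high`/`low`).
#' @param candidates Optional character vector of valid SNP ids; planted
#'   labels referencing other SNPs are an error.
#' @return The validated annotation data frame.
#' @export
make_missense_annotations <- function(planted_labels, candidates = NULL) {
  need <- c("snp_id", "gene_id", "impact")
  if (!is.data.frame(planted_labels) || !all(need %in% names(planted_labels)))
    stop("planted_labels needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(planted_labels$impact %in% c("high", "low")))
    stop("impact must be 'high' or 'low'", call. = FALSE)
  if (!is.null(candidates)) {
    missing <- setdiff(planted_labels$snp_id, candidates)
    if (length(missing))
      stop("planted label references absent SNP: ", missing[1L],
           call. = FALSE)
  }
  planted_labels[need]
}

#' Generate a linear genetic map for one chromosome
#'
#' Two anchors, (0 bp, 0 cM) and (`chrom_length`, `chrom_length` scaled by
#' `cm_per_mb`), so that `cM(pos) = pos / 1e6 * cm_per_mb` exactly under
#' linear interpolation.
#'
#' @param chrom Chromosome label.
#' @param chrom_length Chromosome length in bp.
#' @param cm_per_mb Recombination rate in cM per Mb.
#' @return A `genetic_map` data frame.
#' @export
make_genetic_map <- function(chrom, chrom_length = 1e6, cm_per_mb = 1) {
  df <- data.frame(chrom = chrom, bp = c(0, chrom_length),
                   cM = c(0, chrom_length / 1e6 * cm_per_mb),
                   stringsAsFactors = FALSE)
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' Simulate a complete study scenario with planted mechanisms
#'
#' Generates the full input bundle for the pipeline - markers, haplotype
#' panel, gene models, genetic map, eQTL catalogs, missense annotations,
#' splice scores and relevance labels - with one planted mechanism per
#' locus and a ground-truth table. Each locus lives on its own chromosome
#' with the marker at 500 kb and the causal SNP 1 kb away (0.001 cM on the
#' 1 cM/Mb map). The marker odds ratio is the one the forward LD model
#' implies from the planted causal odds ratio, so the inverse model
#' recovers the causal effect exactly. Expression loci plant a two-study
#' eQTL with identical markers; every locus also carries a single-study
#' decoy eQTL on a decoy gene, which the consensus rule must discard.
#' Labels are noise-free: only the planted causal SNP carries mechanism
#' annotations.
#'
#' @param n_loci Number of loci (default 20).
#' @param n_hap Haplotypes per locus panel.
#' @param seed RNG seed.
#' @param mechanisms Mechanism class per locus; default cycles through the
#'   five classes.
#' @param config Pipeline configuration; the scenario replaces the
#'   placeholder splicing thresholds with calibrated ones (donor intervals
#'   \[-3,6\]/\[-80,-4\]/\[7,80\] at thresholds 0.5/0.8/0.8; acceptor
#'   intervals \[-3,3\]/\[-20,-4\]/\[-80,-21\]/\[4,80\] at
#'   0.5/0.7/0.9/0.9) and planted auxiliary-splice SNPs score 1.0 at donor
#'   distance +2.
#' @return List of class `mech_scenario` with elements `markers`, `panel`,
#'   `gene_models`, `map`, `eqtl_records`, `annotations`, `splice_scores`,
#'   `relevance`, `ground_truth`, `config`, `seed`.
#' @export
simulate_scenario <- function(n_loci = 20L, n_hap = 400L, seed = 1L,
                              mechanisms = NULL,
                              config = mech_config()) {
  classes <- mechanism_classes()
  if (is.null(mechanisms))
    mechanisms <- rep(classes, length.out = n_loci)
  stopifnot(length(mechanisms) == n_loci, all(mechanisms %in% classes))
  config$splice_thresholds <- scenario_splice_thresholds()
  config$rng_seed <- as.integer(seed)
  set.seed(seed)
  locus_seeds <- sample.int(2^30, n_loci)

  panels <- vector("list", n_loci)
  markers <- vector("list", n_loci)
  genes <- list()
  maps <- vector("list", n_loci)
  eqtl_rel <- list()
  annot <- list()
  splice <- list()
  relevance <- list()
  truth <- vector("list", n_loci)

  for (i in seq_len(n_loci)) {
    set.seed(locus_seeds[i])
    p_causal <- stats::runif(1, 0.10, 0.40)
    target_r2 <- stats::runif(1, 0.60, 0.95)
    causal_or <- stats::runif(1, 1.5, 2.5)
    chrom <- paste0("chr", i)
    mech <- mechanisms[i]
    gene_id <- paste0("G", i)
    marker_pos <- 500000L
    causal_pos <- 501000L

    gen <- make_haplotype_panel(n_hap = n_hap, p_causal = p_causal,
                                target_r2 = target_r2, n_neutral = 8L,
                                seed = locus_seeds[i], chrom = chrom,
                                marker_pos = marker_pos,
                                causal_pos = causal_pos,
                                prefix = paste0("L", i, "_"))
    panels[[i]] <- gen$panel
    hf <- haplotype_freqs_from_panel(gen$panel, gen$causal_id, gen$marker_id)
    or_m <- forward_marker_or(hf, causal_or)
    source <- if (i %% 4L == 0L) "primary_scan" else "catalog"
    p_val <- 10^-stats::runif(1, 6.5, 9)
    disease <- if (i %% 2L == 1L) "disease_A" else "disease_B"
    markers[[i]] <- data.frame(id = gen$marker_id, chrom = chrom,
                               pos = marker_pos, risk_allele = "A",
                               other_allele = "G", odds_ratio = or_m,
                               p_value = p_val, source = source,
                               disease = disease, stringsAsFactors = FALSE)

    # gene placement: only direct_splice loci put a splice junction on the
    # causal SNP; all other genes sit in an SNP-free part of the locus
    if (mech == "direct_splice") {
      ex <- data.frame(start = c(causal_pos - 200L, causal_pos + 300L),
                       end = c(causal_pos - 1L, causal_pos + 450L))
    } else {
      ex <- data.frame(start = c(310001L, 310401L),
                       end = c(310150L, 310550L))
    }
    g <- gene_model(gene_id, chrom, "+", ex)
    snp_pos <- gen$panel$sites$pos
    if (mech != "direct_splice" &&
        any(!is.na(match(snp_pos, splice_site_positions(g)))))
      stop("internal: non-splice gene overlaps an SNP splice position")
    genes[[gene_id]] <- g

    maps[[i]] <- make_genetic_map(chrom, 1e6, 1)

    if (mech %in% c("missense_high", "missense_low"))
      annot[[length(annot) + 1L]] <-
        data.frame(snp_id = gen$causal_id, gene_id = gene_id,
                   impact = sub("missense_", "", mech),
                   stringsAsFactors = FALSE)
    if (mech == "aux_splice")
      splice[[length(splice) + 1L]] <-
        data.frame(snp_id = gen$causal_id, gene_id = gene_id,
                   site_type = "donor", signed_distance = 2L,
                   score_change = 1.0, stringsAsFactors = FALSE)
    if (mech == "expression")
      eqtl_rel[[length(eqtl_rel) + 1L]] <-
        data.frame(gene_id = gene_id, snp_ids = gen$causal_id,
                   n_studies_reporting = 2L, direction = "down",
                   stringsAsFactors = FALSE)
    # single-study decoy in every locus: must never reach a consensus
    eqtl_rel[[length(eqtl_rel) + 1L]] <-
      data.frame(gene_id = paste0(gene_id, "_decoy"),
                 snp_ids = gen$causal_id, n_studies_reporting = 1L,
                 direction = "up", stringsAsFactors = FALSE)

    relevance[[length(relevance) + 1L]] <- data.frame(
      gene_id = c(gene_id, paste0(gene_id, "_decoy")),
      disease = disease,
      relevance = c(if (i <= 3L) "A" else "B", "C"),
      known = c(TRUE, FALSE), stringsAsFactors = FALSE)

    truth[[i]] <- data.frame(locus_id = gen$marker_id,
                             marker_id = gen$marker_id,
                             causal_snp = gen$causal_id,
                             gene_id = gene_id, mechanism_class = mech,
                             disease = disease,
                             target_r2 = target_r2,
                             realized_r2 = gen$realized_r2,
                             causal_or = causal_or, marker_or = or_m,
                             stringsAsFactors = FALSE)
  }

  relations <- do.call(rbind, eqtl_rel)
  eqtl <- make_eqtl_catalogs(n_studies = 3L, planted_relations = relations,
                             seed = seed)
  out <- list(markers = do.call(rbind, markers),
              panel = bind_panels(panels),
              gene_models = genes,
              map = {
                m <- do.call(rbind, maps)
                class(m) <- c("genetic_map", "data.frame"); m
              },
              eqtl_records = eqtl$records,
              annotations = if (length(annot)) do.call(rbind, annot) else
                data.frame(snp_id = character(0), gene_id = character(0),
                           impact = character(0)),
              splice_scores = if (length(splice)) do.call(rbind, splice) else
                data.frame(snp_id = character(0), gene_id = character(0),
                           site_type = character(0),
                           signed_distance = integer(0),
                           score_change = numeric(0)),
              relevance = do.call(rbind, relevance),
              ground_truth = do.call(rbind, truth),
              config = config, seed = as.integer(seed))
  class(out) <- "mech_scenario"
  out
}

scenario_splice_thresholds <- function() {
  data.frame(
    site_type = c("donor", "donor", "donor",
                  "acceptor", "acceptor", "acceptor", "acceptor"),
    lo = c(-3, -80, 7, -3, -20, -80, 4),
    hi = c(6, -4, 80, 3, -4, -21, 80),
    threshold = c(0.5, 0.8, 0.8, 0.5, 0.7, 0.9, 0.9),
    stringsAsFactors = FALSE)
}

#' @export
print.mech_scenario <- function(x, ...) {
  cat(sprintf("mech_scenario: %d loci, %d haplotypes, seed %d\n",
              nrow(x$ground_truth), nrow(x$panel$haps), x$seed))
  print(table(x$ground_truth$mechanism_class))
  invisible(x)
}

#' Write a scenario bundle to disk
#'
#' Emits every pipeline input as plain text (markers.tsv, panel.tsv +
#' panel.tsv.sites, genes.bed, map.tsv, eqtl_<study>.tsv, annotations.tsv,
#' splice_scores.tsv, relevance.tsv) together with ground_truth.tsv.
#'
#' @param scenario A `mech_scenario` from [simulate_scenario()].
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "mech_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_marker_table(scenario$markers, file.path(dir, "markers.tsv"))
  write_haplotype_panel(scenario$panel, file.path(dir, "panel.tsv"))
  write_gene_models(scenario$gene_models, file.path(dir, "genes.bed"))
  write_genetic_map(scenario$map, file.path(dir, "map.tsv"))
  for (sid in unique(scenario$eqtl_records$study_id)) {
    sub <- scenario$eqtl_records[scenario$eqtl_records$study_id == sid, ]
    write_tsv(sub, file.path(dir, paste0("eqtl_", sid, ".tsv")))
  }
  write_tsv(scenario$annotations, file.path(dir, "annotations.tsv"))
  write_tsv(scenario$splice_scores, file.path(dir, "splice_scores.tsv"))
  write_tsv(scenario$relevance, file.path(dir, "relevance.tsv"))
  write_tsv(scenario$ground_truth, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}

#' Read a scenario bundle written by [write_scenario()]
#' @param dir Bundle directory.
#' @param config Configuration to attach (defaults to the scenario
#'   thresholds used by [simulate_scenario()]).
#' @return A `mech_scenario` list.
#' @export
read_scenario <- function(dir, config = NULL) {
  if (is.null(config)) {
    config <- mech_config()
    config$splice_thresholds <- scenario_splice_thresholds()
  }
  eqtl_files <- list.files(dir, pattern = "^eqtl_.*\\.tsv$",
                           full.names = TRUE)
  out <- list(markers = read_marker_table(file.path(dir, "markers.tsv")),
              panel = read_haplotype_panel(file.path(dir, "panel.tsv")),
              gene_models = read_gene_models(file.path(dir, "genes.bed")),
              map = read_genetic_map(file.path(dir, "map.tsv")),
              eqtl_records = read_eqtl_tables(
                eqtl_files, sub("^eqtl_", "",
                                tools::file_path_sans_ext(basename(eqtl_files)))),
              annotations = read_annotation_table(
                file.path(dir, "annotations.tsv")),
              splice_scores = read_splice_scores(
                file.path(dir, "splice_scores.tsv")),
              relevance = read_relevance_table(
                file.path(dir, "relevance.tsv")),
              ground_truth = utils::read.delim(
                file.path(dir, "ground_truth.tsv"),
                stringsAsFactors = FALSE),
              config = config, seed = config$rng_seed)
  class(out) <- "mech_scenario"
  out
}
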