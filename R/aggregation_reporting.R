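#' Per-locus mechanism profile
#'
#' Collapses the mechanism calls of one locus into the set of mechanism
#' classes present and the number of mechanism types. High- and low-impact
#' missense are mutually exclusive at the locus level (high wins), and the
#' missense pair occupies a single type slot, so at most four types can be
#' operative in a locus: missense, expression, auxiliary splicing, direct
#' splice-site.
#'
#' @param calls Data frame of mechanism calls for one locus (needs a
#'   `mechanism` column; may be empty).
#' @return List with `mechanisms_present` (character vector) and
#'   `n_mechanism_types` (0-4).
#' @export
locus_mechanism_profile <- function(calls) {
  mech <- unique(calls$mechanism)
  stopifnot(all(mech %in% mechanism_classes()))
  impacts <- sub("missense_", "", mech[grepl("^missense_", mech)])
  ms <- classify_missense_locus(impacts)
  present <- character(0)
  if (ms != "none") present <- paste0("missense_", ms)
  present <- c(present,
               intersect(c("expression", "aux_splice", "direct_splice"),
                         mech))
  n_types <- (ms != "none") + ("expression" %in% mech) +
    ("aux_splice" %in% mech) + ("direct_splice" %in% mech)
  list(mechanisms_present = present, n_mechanism_types = as.integer(n_types))
}

#' Relevance category of a locus
#'
#' Precedence rule over the relevance labels of the proteins with
#' mechanisms in the locus: A beats B beats C. MHC loci are category D,
#' reported separately. With no labelled protein the category is "none".
#'
#' @param relevances Character vector of protein relevance labels
#'   (`A`/`B`/`C`/`D`).
#' @param is_mhc Whether the locus lies in the MHC region.
#' @return One of `"A"`, `"B"`, `"C"`, `"D"`, `"none"`.
#' @export
locus_category <- function(relevances, is_mhc = FALSE) {
  if (isTRUE(is_mhc)) return("D")
  for (cat in c("A", "B", "C"))
    if (cat %in% relevances) return(cat)
  "none"
}

#' Per-protein mechanism table
#'
#' Aggregates mechanism calls per (gene, disease) with one logical column
#' per mechanism class, joined with relevance labels.
#'
#' @param calls Mechanism call data frame (from [call_mechanisms()]).
#' @param loci Locus table (to recover each locus's disease).
#' @param relevance Relevance label data frame (`gene_id`, `disease`,
#'   `relevance`, `known`); proteins without a label get relevance `NA`
#'   and `known = FALSE`.
#' @return Data frame, one row per (gene, disease).
#' @export
protein_mechanism_table <- function(calls, loci, relevance = NULL) {
  if (nrow(calls) == 0L)
    return(data.frame(gene_id = character(0), disease = character(0),
                      missense_high = logical(0), missense_low = logical(0),
                      expression = logical(0), aux_splice = logical(0),
                      direct_splice = logical(0), relevance = character(0),
                      known = logical(0)))
  disease <- loci$disease[match(calls$locus_id, loci$locus_id)]
  key <- paste(calls$gene_id, disease, sep = "\r")
  rows <- lapply(sort(unique(key)), function(k) {
    idx <- which(key == k)
    g <- calls$gene_id[idx[1L]]
    d <- disease[idx[1L]]
    mech <- unique(calls$mechanism[idx])
    out <- data.frame(gene_id = g, disease = d, stringsAsFactors = FALSE)
    for (m in mechanism_classes()) out[[m]] <- m %in% mech
    out
  })
  out <- do.call(rbind, rows)
  if (!is.null(relevance)) {
    i <- match(paste(out$gene_id, out$disease),
               paste(relevance$gene_id, relevance$disease))
    out$relevance <- relevance$relevance[i]
    out$known <- ifelse(is.na(i), FALSE, relevance$known[i])
  } else {
    out$relevance <- NA_character_
    out$known <- FALSE
  }
  rownames(out) <- NULL
  out
}

#' Fraction of proteins sharing a second mechanism
#'
#' Of the proteins carrying `mech1`, the fraction that also carry
#' `mech2`. Undefined (NA) when no protein carries `mech1`.
#'
#' @param protein_table Data frame from [protein_mechanism_table()].
#' @param mech1,mech2 Mechanism class names.
#' @return A fraction in `[0, 1]`, or `NA` when the denominator is 0.
#' @export
overlap_fraction <- function(protein_table, mech1, mech2) {
  stopifnot(all(c(mech1, mech2) %in% names(protein_table)))
  has1 <- protein_table[[mech1]]
  if (sum(has1) == 0L) return(NA_real_)
  sum(has1 & protein_table[[mech2]]) / sum(has1)
}

#' Fractional activity change from a fold change
#'
#' A variant reducing a protein's activity `fold`-fold corresponds to
#' `deltaA = 1/fold - 1` (e.g. a five-fold loss gives -0.8, an 80% loss of
#' activity); a `fold`-fold gain corresponds to `deltaA = fold - 1`.
#'
#' @param fold Fold change, `>= 1`.
#' @param gain `FALSE` (default) for loss of function, `TRUE` for gain.
#' @return The fractional activity change.
#' @export
delta_a_from_fold <- function(fold, gain = FALSE) {
  if (any(fold < 1)) stop("fold must be >= 1", call. = FALSE)
  if (isTRUE(gain)) fold - 1 else 1 / fold - 1
}

#' Fractional phenotype change from an odds ratio
#'
#' `deltaP = OR - 1`: an odds ratio of 1.84 for disease corresponds to a
#' fractional risk change of 0.84.
#'
#' @param odds_ratio Odds ratio, `> 0`.
#' @return The fractional phenotype change.
#' @export
delta_p_from_or <- function(odds_ratio) {
  if (any(odds_ratio <= 0)) stop("odds_ratio must be > 0", call. = FALSE)
  odds_ratio - 1
}

#' Sensitivity coefficient S coupling activity to phenotype
#'
#' `S = deltaP / deltaA`, the dimensionless local sensitivity of phenotype
#' `q` to the activity of gene `i`. By default the magnitude of `deltaA`
#' is used (the convention of quoting S as a positive coupling strength
#' for a loss-of-function variant that increases risk); set
#' `use_magnitude = FALSE` for the signed ratio.
#'
#' @param delta_p Fractional phenotype change.
#' @param delta_a Fractional activity change, non-zero.
#' @param use_magnitude Divide by `|deltaA|` (default) or by signed
#'   `deltaA`.
#' @return The sensitivity coefficient.
#' @export
sensitivity_coefficient <- function(delta_p, delta_a, use_magnitude = TRUE) {
  if (any(delta_a == 0))
    stop("delta_a must be non-zero", call. = FALSE)
  if (isTRUE(use_magnitude)) delta_p / abs(delta_a) else delta_p / delta_a
}

#' Linear phenotype model
#'
#' The first-order coupling of activity changes to a phenotype:
#' `deltaP_q = sum_i S_iq * deltaA_i` (higher-order and epistatic terms
#' are omitted; they are generally undetectable at GWAS sample sizes).
#'
#' @param s_list Sensitivity coefficients.
#' @param delta_a_list Activity changes, same length.
#' @return The total fractional phenotype change.
#' @export
linear_phenotype <- function(s_list, delta_a_list) {
  if (length(s_list) != length(delta_a_list))
    stop("s_list and delta_a_list must have equal length", call. = FALSE)
  if (length(s_list) == 0L) return(0)
  sum(s_list * delta_a_list)
}

#' Drift threshold below which selection is inoperative
#'
#' `1 / (2 Ne)`: selection on a variant with |s| below this bound is
#' overwhelmed by genetic drift at effective population size `Ne`.
#'
#' @param n_e Effective population size, `>= 1`.
#' @return The minimal operative |s|.
#' @export
selection_threshold <- function(n_e) {
  if (any(n_e < 1)) stop("n_e must be >= 1", call. = FALSE)
  1 / (2 * n_e)
}

#' Two-tailed Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value under the probability-mass criterion: with all
#' margins fixed, the p-value is the sum of hypergeometric probabilities
#' of every table at least as extreme as (i.e. with probability no larger
#' than) the observed one. A relative tolerance of 1e-7 guards the
#' equality comparison against floating-point ties, and the summation runs
#' over the full support so no catastrophic cancellation occurs.
#'
#' @param a,b,c,d Non-negative integer cell counts of the table
#'   `rbind(c(a, b), c(c, d))`; all four margins must be positive.
#' @return The two-sided p-value.
#' @export
fisher_two_tailed <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    stop("all margins of the 2x2 table must be positive", call. = FALSE)
  lo <- max(0, c1 - r2)
  hi <- min(c1, r1)
  support <- lo:hi
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Mechanism enrichment in known disease-relevant proteins
#'
#' For each mechanism class, tests whether proteins carrying the mechanism
#' are enriched among proteins already known to be disease relevant,
#' against all eligible proteins (those with at least one qualified
#' candidate SNP, MHC excluded). The 2x2 table crosses mechanism presence
#' with known/unknown status; raw two-tailed Fisher p-values are reported
#' without multiplicity adjustment.
#'
#' @param protein_table Data frame from [protein_mechanism_table()].
#' @param eligible Data frame with `gene_id`, `disease`, `known` covering
#'   every eligible protein (including those with no mechanism assigned).
#' @return Data frame with one row per mechanism: counts
#'   `known_with`, `known_without`, `unknown_with`, `unknown_without`, and
#'   `p_value`.
#' @export
enrichment_by_mechanism <- function(protein_table, eligible) {
  stopifnot(all(c("gene_id", "disease", "known") %in% names(eligible)))
  if (nrow(eligible) == 0L)
    stop("no eligible proteins", call. = FALSE)
  key_elig <- paste(eligible$gene_id, eligible$disease)
  key_mech <- paste(protein_table$gene_id, protein_table$disease)
  rows <- lapply(mechanism_classes(), function(m) {
    has <- key_elig %in% key_mech[protein_table[[m]]]
    known <- eligible$known
    a <- sum(known & has); b <- sum(known & !has)
    c_ <- sum(!known & has); d <- sum(!known & !has)
    p <- if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0)
      1 else fisher_two_tailed(a, b, c_, d)
    data.frame(mechanism = m, known_with = a, known_without = b,
               unknown_with = c_, unknown_without = d, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise loci: mechanism profiles and relevance categories
#'
#' @param loci Locus table from [build_loci()].
#' @param calls Mechanism calls from [call_mechanisms()].
#' @param relevance Relevance label data frame (or `NULL`).
#' @return Data frame, one row per locus: mechanisms present (comma
#'   joined), per-class presence flags, `n_mechanism_types`, `category`.
#' @export
summarize_loci <- function(loci, calls, relevance = NULL) {
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    lc <- calls[calls$locus_id == loci$locus_id[i], , drop = FALSE]
    prof <- locus_mechanism_profile(lc)
    rel <- character(0)
    if (!is.null(relevance) && nrow(lc)) {
      j <- match(paste(unique(lc$gene_id), loci$disease[i]),
                 paste(relevance$gene_id, relevance$disease))
      rel <- relevance$relevance[j[!is.na(j)]]
    }
    out <- data.frame(locus_id = loci$locus_id[i],
                      disease = loci$disease[i],
                      mechanisms = paste(prof$mechanisms_present,
                                         collapse = ","),
                      stringsAsFactors = FALSE)
    for (m in mechanism_classes())
      out[[m]] <- m %in% prof$mechanisms_present
    out$n_mechanism_types <- prof$n_mechanism_types
    out$category <- locus_category(rel, loci$is_mhc[i])
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise mechanism overlap table
#'
#' All ordered mechanism pairs with the fraction of proteins carrying the
#' first mechanism that also carry the second.
#'
#' @param protein_table Data frame from [protein_mechanism_table()].
#' @return Data frame with `mech1`, `mech2`, `n_mech1`, `n_both`,
#'   `fraction`.
#' @export
mechanism_overlap_table <- function(protein_table) {
  mechs <- mechanism_classes()
  rows <- list()
  for (m1 in mechs) for (m2 in setdiff(mechs, m1)) {
    n1 <- sum(protein_table[[m1]])
    nb <- sum(protein_table[[m1]] & protein_table[[m2]])
    rows[[length(rows) + 1L]] <- data.frame(
      mech1 = m1, mech2 = m2, n_mech1 = n1, n_both = nb,
      fraction = if (n1 == 0L) NA_real_ else nb / n1,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
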