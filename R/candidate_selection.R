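#' Filter GWAS markers by source-specific p-value thresholds
#'
#' Markers from a primary genome-wide scan are kept when
#' `p < p_threshold_primary`; markers taken from an association catalog
#' are kept when `p < p_threshold_catalog`. Both comparisons are strict.
#'
#' @param markers Marker data frame (see [read_marker_table()]).
#' @param config A [mech_config()].
#' @return The retained marker rows.
#' @export
select_markers <- function(markers, config = mech_config()) {
  bad <- setdiff(unique(markers$source), c("primary_scan", "catalog"))
  if (length(bad))
    stop("unknown marker source tag: ", bad[1L], call. = FALSE)
  thr <- ifelse(markers$source == "primary_scan",
                config$p_threshold_primary, config$p_threshold_catalog)
  out <- markers[markers$p_value < thr, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate pre-acceptance candidate SNPs around a marker
#'
#' All panel SNPs on the marker's chromosome within `window_bp` of the
#' marker (boundary inclusive) with minor allele frequency at least
#' `maf_min` (inclusive), each with its two-SNP haplotype frequencies to
#' the marker. The candidate's putative risk allele is oriented by the
#' sign of D: the allele positively associated with the marker risk allele
#' is taken as the risk allele, the only orientation consistent with a
#' shared disease mechanism.
#'
#' @param marker One marker row (data frame or list with `id`, `chrom`,
#'   `pos`, `risk_allele`).
#' @param panel A [hap_panel()] containing the marker.
#' @param config A [mech_config()].
#' @return Data frame, one row per candidate, with the four haplotype
#'   frequencies (`h_AB`, `h_Ab`, `h_aB`, `h_ab`), `maf`, `D`, `r2`, and
#'   the oriented `risk_allele`.
#' @export
enumerate_candidates <- function(marker, panel, config = mech_config()) {
  stopifnot(inherits(panel, "hap_panel"))
  if (!marker$id %in% colnames(panel$haps))
    stop("marker '", marker$id, "' absent from panel", call. = FALSE)
  sites <- panel$sites
  msite <- sites[sites$id == marker$id, , drop = FALSE]
  y <- panel$haps[, marker$id]
  if (identical(marker$risk_allele, msite$allele0[1L])) y <- 1L - y
  else if (!identical(marker$risk_allele, msite$allele1[1L]))
    stop("marker risk allele does not match panel coding", call. = FALSE)
  p_b <- mean(y)
  in_window <- sites$chrom == marker$chrom &
    abs(sites$pos - marker$pos) <= config$window_bp
  freqs <- colMeans(panel$haps)
  maf <- pmin(freqs, 1 - freqs)
  keep <- which(in_window & maf >= config$maf_min)
  n <- nrow(panel$haps)
  rows <- lapply(keep, function(j) {
    x <- panel$haps[, j]
    p_x <- freqs[j]
    h11 <- sum(x == 1L & y == 1L) / n
    D <- h11 - p_x * p_b
    risk <- sites$allele1[j]
    if (D < 0) {            # orient so the risk allele covaries with b
      x <- 1L - x
      risk <- sites$allele0[j]
    }
    m <- length(x)
    data.frame(snp_id = sites$id[j], chrom = sites$chrom[j],
               pos = sites$pos[j], maf = unname(maf[j]),
               risk_allele = risk,
               h_AB = sum(x == 0L & y == 0L) / m,
               h_Ab = sum(x == 0L & y == 1L) / m,
               h_aB = sum(x == 1L & y == 0L) / m,
               h_ab = sum(x == 1L & y == 1L) / m,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(snp_id = character(0), chrom = character(0),
                      pos = integer(0), maf = numeric(0),
                      risk_allele = character(0), h_AB = numeric(0),
                      h_Ab = numeric(0), h_aB = numeric(0),
                      h_ab = numeric(0), D = numeric(0), r2 = numeric(0)))
  out$D <- out$h_ab - (out$h_aB + out$h_ab) * (out$h_Ab + out$h_ab)
  p_a <- out$h_aB + out$h_ab
  out$r2 <- ifelse(p_a <= 0 | p_a >= 1, 0,
                   out$D^2 / (p_a * (1 - p_a) * p_b * (1 - p_b)))
  rownames(out) <- NULL
  out
}

#' Apply the acceptance rule to enumerated candidates
#'
#' A candidate is accepted when the implied case/control odds ratio at its
#' own alleles is feasible (the case allele frequency solved from the
#' marker odds ratio and the LD relationship is a proper frequency) and
#' its r-squared with the marker is at least the configured floor.
#' Candidates in linkage equilibrium with the marker (D = 0) are rejected,
#' not errored: the marker carries no information about them.
#'
#' @param candidates Data frame from [enumerate_candidates()].
#' @param marker The marker row (needs `odds_ratio`).
#' @param config A [mech_config()].
#' @return The data frame with `implied_or`, `feasible` and `accepted`
#'   columns added.
#' @export
accept_candidates <- function(candidates, marker, config = mech_config()) {
  n <- nrow(candidates)
  implied <- rep(NA_real_, n)
  feasible <- rep(FALSE, n)
  for (i in seq_len(n)) {
    hf <- haplotype_freqs(candidates$h_AB[i], candidates$h_Ab[i],
                          candidates$h_aB[i], candidates$h_ab[i])
    if (hf$p_a <= 0 || hf$p_a >= 1) next
    if (abs(candidates$D[i]) < 1e-12) next
    res <- implied_candidate_or(hf, marker$odds_ratio)
    feasible[i] <- res$feasible
    implied[i] <- res$or_c
  }
  candidates$implied_or <- implied
  candidates$feasible <- feasible
  candidates$accepted <- feasible & candidates$r2 >= config$r2_floor
  candidates
}

#' Locus extent from accepted candidates
#'
#' The locus spans the minimum to maximum position of its accepted
#' candidates; with no accepted candidate it degenerates to a point
#' interval at the marker.
#'
#' @param candidates Data frame with `pos` and `accepted` columns.
#' @param marker The marker row (needs `pos`).
#' @return Length-2 numeric `(start, end)`.
#' @export
locus_extent <- function(candidates, marker) {
  acc <- candidates$pos[candidates$accepted]
  if (length(acc) == 0L) return(c(start = marker$pos, end = marker$pos))
  c(start = min(acc), end = max(acc))
}

#' Build loci with accepted candidates from markers and a panel
#'
#' Applies the marker p-value filters, merges markers of the same disease
#' and chromosome lying within one window into a single locus keyed by the
#' lowest-p marker (the representative marker), then enumerates and
#' accepts candidates for each locus and computes its extent. Loci whose
#' representative marker is absent from the panel are dropped with a
#' warning (nothing is dropped silently).
#'
#' @param markers Marker data frame.
#' @param panel A [hap_panel()].
#' @param config A [mech_config()].
#' @return List with `loci` (one row per locus: `locus_id`, `disease`,
#'   `marker_id`, `chrom`, `marker_pos`, `odds_ratio`, `start`, `end`,
#'   `n_candidates`, `n_accepted`, `is_mhc`, `merged_markers`) and
#'   `candidates` (per-candidate rows tagged with `locus_id`).
#' @export
build_loci <- function(markers, panel, config = mech_config()) {
  kept <- select_markers(markers, config)
  loci_rows <- list()
  cand_rows <- list()
  dropped <- character(0)
  for (dis in unique(kept$disease)) {
    sub <- kept[kept$disease == dis, , drop = FALSE]
    sub <- sub[order(sub$p_value, sub$id), , drop = FALSE]
    while (nrow(sub) > 0L) {
      rep_m <- sub[1L, ]
      same <- sub$chrom == rep_m$chrom &
        abs(sub$pos - rep_m$pos) <= config$window_bp
      merged <- sub$id[same]
      sub <- sub[!same, , drop = FALSE]
      if (!rep_m$id %in% colnames(panel$haps)) {
        dropped <- c(dropped, rep_m$id)
        next
      }
      cand <- enumerate_candidates(rep_m, panel, config)
      cand <- accept_candidates(cand, rep_m, config)
      ext <- locus_extent(cand, rep_m)
      locus_id <- rep_m$id
      cand$locus_id <- locus_id
      iv <- config$mhc_interval
      loci_rows[[length(loci_rows) + 1L]] <- data.frame(
        locus_id = locus_id, disease = dis, marker_id = rep_m$id,
        chrom = rep_m$chrom, marker_pos = rep_m$pos,
        odds_ratio = rep_m$odds_ratio, p_value = rep_m$p_value,
        start = unname(ext[1L]), end = unname(ext[2L]),
        n_candidates = nrow(cand), n_accepted = sum(cand$accepted),
        is_mhc = (rep_m$chrom == iv$chrom &&
                    ext[1L] <= iv$end && ext[2L] >= iv$start),
        merged_markers = paste(merged, collapse = ","),
        stringsAsFactors = FALSE)
      cand_rows[[length(cand_rows) + 1L]] <- cand
    }
  }
  if (length(dropped))
    warning(length(dropped), " marker(s) absent from panel and dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  loci <- do.call(rbind, loci_rows)
  candidates <- do.call(rbind, cand_rows)
  if (!is.null(loci)) rownames(loci) <- NULL
  if (!is.null(candidates)) rownames(candidates) <- NULL
  list(loci = loci, candidates = candidates)
}
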