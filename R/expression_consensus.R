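#' Build consensus eQTLs from multi-study records
#'
#' For each gene, the reporting marker SNPs are clustered under the
#' relation "identical or in LD at r-squared above the consensus
#' threshold" (single linkage by default; a strict complete-linkage mode
#' is available). Clusters whose records come from at least two distinct
#' studies become consensus eQTLs; single-study relations never do. SNPs
#' absent from the panel cannot be linked to any other SNP (they are
#' counted and warned about, never silently dropped: they still form
#' their own cluster).
#'
#' @param records eQTL record data frame (`snp_id`, `gene_id`, `study_id`,
#'   `direction`; see [read_eqtl_tables()]).
#' @param panel A [hap_panel()] used to compute r-squared between marker
#'   SNPs.
#' @param config A [mech_config()].
#' @return Data frame with one row per consensus eQTL: `gene_id`,
#'   `cluster` (comma-joined sorted SNP ids), `n_studies`, `n_snps`,
#'   `direction_conflict` (TRUE when distinct studies report opposite
#'   directions).
#' @export
build_consensus_eqtls <- function(records, panel, config = mech_config()) {
  stopifnot(inherits(panel, "hap_panel"))
  uncovered <- setdiff(unique(records$snp_id), colnames(panel$haps))
  if (length(uncovered))
    warning(length(uncovered),
            " eQTL SNP(s) not covered by the panel (treated as ",
            "non-linkable): ", paste(uncovered, collapse = ", "),
            call. = FALSE)
  out <- list()
  for (gene in sort(unique(records$gene_id))) {
    sub <- records[records$gene_id == gene, , drop = FALSE]
    snps <- sort(unique(sub$snp_id))          # canonical order
    k <- length(snps)
    cl <- cluster_linked_snps(snps, panel, config)
    for (cid in sort(unique(cl))) {
      members <- snps[cl == cid]
      rows <- sub[sub$snp_id %in% members, , drop = FALSE]
      n_studies <- length(unique(rows$study_id))
      if (n_studies < 2L) next
      dirs <- setdiff(unique(rows$direction), "unknown")
      out[[length(out) + 1L]] <- data.frame(
        gene_id = gene, cluster = paste(members, collapse = ","),
        n_studies = n_studies, n_snps = length(members),
        direction_conflict = length(dirs) > 1L,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene_id = character(0), cluster = character(0),
                      n_studies = integer(0), n_snps = integer(0),
                      direction_conflict = logical(0))
  rownames(res) <- NULL
  res
}

# Cluster SNP ids under {identical OR r2 > threshold}; returns integer
# cluster labels aligned with `snps` (which must be in canonical sorted
# order so results are independent of record arrangement).
cluster_linked_snps <- function(snps, panel, config) {
  k <- length(snps)
  if (k == 1L) return(1L)
  in_panel <- snps %in% colnames(panel$haps)
  link <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      if (!in_panel[i] || !in_panel[j]) next
      x <- panel$haps[, snps[i]]; y <- panel$haps[, snps[j]]
      px <- mean(x); py <- mean(y)
      if (px <= 0 || px >= 1 || py <= 0 || py >= 1) next
      r2 <- (mean(x * y) - px * py)^2 / (px * (1 - px) * py * (1 - py))
      link[i, j] <- link[j, i] <- r2 > config$eqtl_consensus_r2
    }
  }
  d <- stats::as.dist(1 - link)
  method <- if (config$eqtl_linkage == "complete") "complete" else "single"
  stats::cutree(stats::hclust(d, method = method), h = 0.5)
}

#' Interpolated centiMorgan position
#'
#' Piecewise-linear interpolation of the genetic map anchors; positions
#' beyond the outermost anchors are clamped to the end anchor's cM value.
#'
#' @param chrom Chromosome.
#' @param pos Base-pair position(s).
#' @param map A `genetic_map`.
#' @return Numeric cM position(s), with attribute `n_clamped` counting
#'   positions outside the anchored range.
#' @export
cm_position <- function(chrom, pos, map) {
  anchors <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(anchors) < 2L)
    stop("no genetic map anchors for chromosome ", chrom, call. = FALSE)
  out <- stats::approx(anchors$bp, anchors$cM, xout = pos, rule = 2,
                       ties = "ordered")$y
  n_clamped <- sum(pos < min(anchors$bp) | pos > max(anchors$bp))
  if (n_clamped > 0L)
    warning(n_clamped, " position(s) beyond map anchors clamped",
            call. = FALSE)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' centiMorgan distance between two positions on one chromosome
#'
#' @param chrom1,pos1,chrom2,pos2 Positions; the chromosomes must be
#'   identical (genetic distance across chromosomes is undefined).
#' @param map A `genetic_map`.
#' @return Non-negative cM distance.
#' @export
cm_distance <- function(chrom1, pos1, chrom2, pos2, map) {
  if (!identical(as.character(chrom1), as.character(chrom2)))
    stop("cM distance undefined across chromosomes (", chrom1, " vs ",
         chrom2, ")", call. = FALSE)
  as.numeric(abs(cm_position(chrom1, pos1, map) -
                   cm_position(chrom2, pos2, map)))
}

#' Match a disease marker to a consensus eQTL
#'
#' The two are taken to tag the same underlying expression mechanism when
#' the marker is itself a member of the eQTL marker cluster, or when the
#' nearest cluster member lies within `eqtl_match_cm` centiMorgans of the
#' marker. Cluster members on another chromosome, or absent from the site
#' table, cannot match.
#'
#' @param marker List or one-row data frame with `id`, `chrom`, `pos`.
#' @param consensus One consensus eQTL row (needs `cluster`).
#' @param sites Panel site table (`id`, `chrom`, `pos`).
#' @param map A `genetic_map`.
#' @param config A [mech_config()].
#' @return List with `match` (logical), `snp_id` (matching cluster member)
#'   and `how` (text description).
#' @export
match_disease_eqtl <- function(marker, consensus, sites, map,
                               config = mech_config()) {
  members <- strsplit(consensus$cluster, ",", fixed = TRUE)[[1L]]
  if (marker$id %in% members)
    return(list(match = TRUE, snp_id = marker$id, how = "identical marker"))
  best <- NULL
  for (m in members) {
    srow <- sites[sites$id == m, , drop = FALSE]
    if (nrow(srow) == 0L || is.na(srow$pos[1L])) next
    if (!identical(srow$chrom[1L], as.character(marker$chrom))) next
    d <- cm_distance(marker$chrom, marker$pos, srow$chrom[1L],
                     srow$pos[1L], map)
    if (is.null(best) || d < best$d) best <- list(snp_id = m, d = d)
  }
  if (!is.null(best) && best$d <= config$eqtl_match_cm)
    return(list(match = TRUE, snp_id = best$snp_id,
                how = sprintf("%.4g cM from marker", best$d)))
  list(match = FALSE, snp_id = NA_character_, how = "no match")
}
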