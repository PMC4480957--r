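#' Collapse missense calls at one locus
#'
#' High- and low-impact missense are mutually exclusive at the locus
#' level: a locus with at least one high-impact missense candidate is
#' "high"; otherwise one with at least one low-impact candidate is "low";
#' otherwise "none".
#'
#' @param impacts Character vector of per-candidate impact labels
#'   (`"high"`/`"low"`), possibly empty.
#' @return `"high"`, `"low"` or `"none"`.
#' @export
classify_missense_locus <- function(impacts) {
  if (any(impacts == "high")) "high"
  else if (any(impacts == "low")) "low"
  else "none"
}

# All genomic positions of a gene that the direct splice-site rule covers,
# with their site/region labels. Rules are transcript-relative and applied
# only at internal junctions: the first two bases of each intron (donor)
# and its last two bases (acceptor) on the intronic side; the last three
# bases of the upstream exon (donor side) and the first base of the
# downstream exon (acceptor side) on the exonic side, all in transcription
# order.
splice_site_table <- function(gene) {
  ex <- gene$exons            # genomic ascending
  n <- nrow(ex)
  if (n < 2L) return(NULL)
  rows <- list()
  add <- function(pos, site, region, junction)
    rows[[length(rows) + 1L]] <<- data.frame(
      pos = pos, site = site, region = region, junction = junction,
      stringsAsFactors = FALSE)
  if (gene$strand == "+") {
    for (j in seq_len(n - 1L)) {
      e <- ex$end[j]; s2 <- ex$start[j + 1L]
      add(max(ex$start[j], e - 2L):e, "donor", "exonic", j)
      add(c(e + 1L, e + 2L), "donor", "intronic", j)
      add(c(s2 - 2L, s2 - 1L), "acceptor", "intronic", j)
      add(s2, "acceptor", "exonic", j)
    }
  } else {
    # transcription order runs from the highest-coordinate exon downward
    for (j in seq_len(n - 1L)) {
      up <- n - j + 1L; dn <- n - j    # genomic indices of flanking exons
      s_up <- ex$start[up]; e_dn <- ex$end[dn]
      add(s_up:min(ex$end[up], s_up + 2L), "donor", "exonic", j)
      add(c(s_up - 1L, s_up - 2L), "donor", "intronic", j)
      add(c(e_dn + 2L, e_dn + 1L), "acceptor", "intronic", j)
      add(e_dn, "acceptor", "exonic", j)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

splice_site_positions <- function(gene) {
  tab <- splice_site_table(gene)
  if (is.null(tab)) integer(0) else tab$pos
}

#' Direct splice-site hit test for one position
#'
#' Checks whether a genomic position falls on one of the bases whose
#' substitution directly disrupts splicing at an internal exon junction:
#' within introns, the two bases at the transcription 5' end (donor) and
#' the two bases at the 3' end (acceptor); within exons, the single base
#' at the 5' end of the downstream exon (acceptor side) and the three
#' bases at the 3' end of the upstream exon (donor side). Minus-strand
#' genes apply the rules in transcription order. Single-exon genes have no
#' internal junction and never hit.
#'
#' @param pos Genomic position (1-based), assumed on the gene's chromosome.
#' @param gene A [gene_model()].
#' @return `NULL` for no hit, else a list with `site`
#'   (`"donor"`/`"acceptor"`), `region` (`"intronic"`/`"exonic"`) and
#'   `junction` (index in transcription order).
#' @export
direct_splice_hit <- function(pos, gene) {
  stopifnot(inherits(gene, "gene_model"))
  tab <- splice_site_table(gene)
  if (is.null(tab)) return(NULL)
  i <- which(tab$pos == pos)
  if (length(i) == 0L) return(NULL)
  i <- i[1L]
  list(site = tab$site[i], region = tab$region[i],
       junction = tab$junction[i])
}

#' Auxiliary splicing flag for a score record
#'
#' A score record is flagged when its score change is at least (>=) the
#' threshold of the configured interval containing its signed distance for
#' its site type. Records whose distance falls outside all configured
#' intervals are never flagged; their count is returned as an attribute so
#' callers can report them.
#'
#' @param records Data frame of splice score records (see
#'   [read_splice_scores()]); a single record as a one-row data frame or
#'   list also works.
#' @param config A [mech_config()] carrying `splice_thresholds`.
#' @return Logical vector, one flag per record, with attribute
#'   `n_unmatched` counting records outside all intervals.
#' @export
auxiliary_splice_flag <- function(records, config = mech_config()) {
  if (!is.data.frame(records)) records <- as.data.frame(records)
  thr <- config$splice_thresholds
  n <- nrow(records)
  flag <- logical(n)
  unmatched <- 0L
  for (i in seq_len(n)) {
    sub <- thr[thr$site_type == records$site_type[i] &
                 thr$lo <= records$signed_distance[i] &
                 thr$hi >= records$signed_distance[i], , drop = FALSE]
    if (nrow(sub) == 0L) {
      unmatched <- unmatched + 1L
      next
    }
    flag[i] <- records$score_change[i] >= sub$threshold[1L]
  }
  attr(flag, "n_unmatched") <- unmatched
  flag
}

#' Assign mechanism calls to accepted candidates
#'
#' Produces one row per (locus, gene, SNP, mechanism) item of evidence:
#' missense calls from the impact annotation table, direct splice calls
#' from positional overlap of accepted candidates with gene-model splice
#' sites, auxiliary splice calls from thresholded score changes, and
#' expression calls from consensus eQTLs matched to the locus marker by
#' identity or centiMorgan distance. An SNP may yield several calls
#' (e.g. both missense and auxiliary splicing): calls are evidence, not a
#' partition.
#'
#' @param loci,candidates Output of [build_loci()].
#' @param annotations Missense annotation data frame (may be empty).
#' @param splice_scores Splice score data frame (may be empty).
#' @param gene_models Named list of [gene_model()] objects.
#' @param consensus Consensus eQTL data frame from
#'   [build_consensus_eqtls()].
#' @param panel A [hap_panel()] (for eQTL marker positions).
#' @param map A `genetic_map`.
#' @param config A [mech_config()].
#' @return Data frame with columns `locus_id`, `gene_id`, `snp_id`,
#'   `mechanism`, `evidence`.
#' @export
call_mechanisms <- function(loci, candidates, annotations, splice_scores,
                            gene_models, consensus, panel, map,
                            config = mech_config()) {
  acc <- candidates[candidates$accepted, , drop = FALSE]
  calls <- list()
  add <- function(locus_id, gene_id, snp_id, mechanism, evidence)
    calls[[length(calls) + 1L]] <<- data.frame(
      locus_id = locus_id, gene_id = gene_id, snp_id = snp_id,
      mechanism = mechanism, evidence = evidence, stringsAsFactors = FALSE)

  # missense: annotation labels joined onto accepted candidates
  if (nrow(annotations) && nrow(acc)) {
    m <- merge(acc[c("locus_id", "snp_id")], annotations, by = "snp_id")
    for (i in seq_len(nrow(m)))
      add(m$locus_id[i], m$gene_id[i], m$snp_id[i],
          paste0("missense_", m$impact[i]),
          paste0("impact=", m$impact[i]))
  }

  # direct splice: accepted candidate positions vs gene-model junctions
  if (length(gene_models) && nrow(acc)) {
    for (g in gene_models) {
      tab <- splice_site_table(g)
      if (is.null(tab)) next
      sub <- acc[acc$chrom == g$chrom, , drop = FALSE]
      hit <- match(sub$pos, tab$pos)
      for (i in which(!is.na(hit)))
        add(sub$locus_id[i], g$gene_id, sub$snp_id[i], "direct_splice",
            sprintf("%s %s site, junction %d", tab$region[hit[i]],
                    tab$site[hit[i]], tab$junction[hit[i]]))
    }
  }

  # auxiliary splicing: thresholded score changes on accepted candidates
  if (nrow(splice_scores) && nrow(acc)) {
    s <- merge(acc[c("locus_id", "snp_id")], splice_scores, by = "snp_id")
    if (nrow(s)) {
      flag <- auxiliary_splice_flag(s, config)
      if (attr(flag, "n_unmatched") > 0L)
        warning(attr(flag, "n_unmatched"),
                " splice score record(s) outside all configured intervals",
                call. = FALSE)
      for (i in which(flag))
        add(s$locus_id[i], s$gene_id[i], s$snp_id[i], "aux_splice",
            sprintf("%s %+d, score change %.3g", s$site_type[i],
                    s$signed_distance[i], s$score_change[i]))
    }
  }

  # expression: consensus eQTLs matched to the locus marker
  if (!is.null(consensus) && nrow(consensus) && !is.null(loci) && nrow(loci)) {
    for (li in seq_len(nrow(loci))) {
      marker <- list(id = loci$marker_id[li], chrom = loci$chrom[li],
                     pos = loci$marker_pos[li])
      for (ci in seq_len(nrow(consensus))) {
        mres <- match_disease_eqtl(marker, consensus[ci, ], panel$sites,
                                   map, config)
        if (mres$match)
          add(loci$locus_id[li], consensus$gene_id[ci], mres$snp_id,
              "expression",
              sprintf("consensus eQTL (%d studies), %s",
                      consensus$n_studies[ci], mres$how))
      }
    }
  }

  out <- do.call(rbind, calls)
  if (is.null(out))
    out <- data.frame(locus_id = character(0), gene_id = character(0),
                      snp_id = character(0), mechanism = character(0),
                      evidence = character(0))
  # deterministic order regardless of input arrangement
  out <- out[order(out$locus_id, out$mechanism, out$gene_id, out$snp_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
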