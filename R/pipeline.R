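#' Run the full mechanism-annotation pipeline
#'
#' Sequences the pipeline stages on an input bundle: marker filtering and
#' locus construction with implied-odds-ratio candidate acceptance,
#' consensus eQTL building, mechanism calling, and per-locus/per-protein
#' aggregation with enrichment statistics. One log line per stage reports
#' input and output record counts.
#'
#' @param inputs A list (e.g. a `mech_scenario` from [simulate_scenario()]
#'   or [read_scenario()]) with elements `markers`, `panel`, `gene_models`,
#'   `map`, `eqtl_records`, `annotations`, `splice_scores`, `relevance`.
#' @param config A [mech_config()]; defaults to `inputs$config` when
#'   present.
#' @param quiet Suppress stage log lines.
#' @return List of class `mech_results` with `loci`, `candidates`,
#'   `consensus_eqtls`, `mechanism_calls`, `locus_summaries`,
#'   `protein_mechanisms`, `enrichment`, `overlaps`.
#' @export
run_pipeline <- function(inputs, config = NULL, quiet = FALSE) {
  if (is.null(config)) config <- inputs$config
  if (is.null(config)) config <- mech_config()
  log_line <- function(...) if (!quiet) message(sprintf(...))

  gene_models <- flag_mhc_genes(inputs$gene_models, config)

  sel <- build_loci(inputs$markers, inputs$panel, config)
  log_line("select: %d markers in -> %d loci, %d candidates (%d accepted)",
           nrow(inputs$markers),
           if (is.null(sel$loci)) 0L else nrow(sel$loci),
           if (is.null(sel$candidates)) 0L else nrow(sel$candidates),
           if (is.null(sel$candidates)) 0L else sum(sel$candidates$accepted))
  if (is.null(sel$loci) || nrow(sel$loci) == 0L)
    stop("no loci survive marker selection", call. = FALSE)

  consensus <- build_consensus_eqtls(inputs$eqtl_records, inputs$panel,
                                     config)
  log_line("consensus: %d eQTL records in -> %d consensus eQTLs",
           nrow(inputs$eqtl_records), nrow(consensus))

  calls <- call_mechanisms(sel$loci, sel$candidates, inputs$annotations,
                           inputs$splice_scores, gene_models, consensus,
                           inputs$panel, inputs$map, config)
  log_line("assign: %d mechanism calls over %d loci", nrow(calls),
           length(unique(calls$locus_id)))

  summaries <- summarize_loci(sel$loci, calls, inputs$relevance)
  proteins <- protein_mechanism_table(calls, sel$loci, inputs$relevance)
  mhc_genes <- names(gene_models)[vapply(gene_models, `[[`, logical(1),
                                         "is_mhc")]
  eligible <- eligible_proteins(sel, inputs, gene_models, mhc_genes)
  enr <- if (nrow(eligible))
    enrichment_by_mechanism(proteins[!proteins$gene_id %in% mhc_genes, ,
                                     drop = FALSE], eligible)
  else NULL
  overlaps <- mechanism_overlap_table(proteins)
  log_line("aggregate: %d locus summaries, %d proteins, %d enrichment rows",
           nrow(summaries), nrow(proteins),
           if (is.null(enr)) 0L else nrow(enr))

  structure(list(loci = sel$loci, candidates = sel$candidates,
                 consensus_eqtls = consensus, mechanism_calls = calls,
                 locus_summaries = summaries,
                 protein_mechanisms = proteins, enrichment = enr,
                 overlaps = overlaps),
            class = "mech_results")
}

# Eligible proteins for enrichment: every labelled (gene, disease) pair
# whose locus has at least one accepted candidate, MHC excluded. The
# relevance table is the label source; genes without labels are treated
# as unknown.
eligible_proteins <- function(sel, inputs, gene_models, mhc_genes) {
  rel <- inputs$relevance
  if (is.null(rel) || nrow(rel) == 0L)
    return(data.frame(gene_id = character(0), disease = character(0),
                      known = logical(0)))
  rel <- rel[!rel$gene_id %in% mhc_genes, , drop = FALSE]
  rel[c("gene_id", "disease", "known")]
}

#' @export
print.mech_results <- function(x, ...) {
  cat(sprintf("mech_results: %d loci, %d accepted candidates, %d calls\n",
              nrow(x$loci), sum(x$candidates$accepted),
              nrow(x$mechanism_calls)))
  with_mech <- sum(x$locus_summaries$n_mechanism_types > 0)
  cat(sprintf("  loci with >= 1 mechanism: %d/%d (%.0f%%)\n", with_mech,
              nrow(x$locus_summaries),
              100 * with_mech / nrow(x$locus_summaries)))
  invisible(x)
}
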