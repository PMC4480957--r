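#' Pipeline configuration
#'
#' Builds a validated configuration object holding every tunable cutoff used
#' by the pipeline. Defaults follow common practice for GWAS locus
#' dissection: a +/-200 kb candidate window around each association marker,
#' a 5% minor-allele-frequency floor (below which panel LD estimates are
#' unreliable), genome-wide significance thresholds of 5.0e-7 for
#' primary-scan markers and 1.0e-5 for catalog markers, a 0.05 centiMorgan
#' matching radius between disease and eQTL markers, and an r-squared
#' threshold of 0.8 for declaring two eQTL markers to tag the same signal.
#'
#' @param window_bp Candidate search window half-width around a marker, in
#'   base pairs. Boundaries are inclusive.
#' @param maf_min Minimum minor allele frequency for a candidate (inclusive).
#' @param p_threshold_primary Strict upper p-value bound for markers from a
#'   primary genome-wide scan.
#' @param p_threshold_catalog Strict upper p-value bound for markers taken
#'   from an association catalog (follow-up studies and meta-analyses).
#' @param eqtl_match_cm Maximum centiMorgan distance at which a disease
#'   marker and an eQTL marker are considered to tag the same mechanism.
#' @param eqtl_consensus_r2 r-squared above which two eQTL marker SNPs are
#'   linked when clustering multi-study eQTL reports (strict inequality).
#' @param eqtl_linkage `"single"` (default) or `"complete"` linkage when
#'   clustering eQTL markers of one gene.
#' @param r2_floor Minimum candidate-to-marker r-squared for acceptance.
#'   Set to 0 to apply only the implied-odds-ratio feasibility rule.
#' @param splice_thresholds Data frame with columns `site_type`
#'   (`"donor"`/`"acceptor"`), `lo`, `hi` (signed-distance interval, bases,
#'   negative = exonic side, boundaries inclusive) and `threshold` (minimum
#'   score change that flags an auxiliary splicing candidate). The shipped
#'   default is a single all-covering interval with threshold 0 per site
#'   type, i.e. any reported score change flags; real analyses must supply
#'   thresholds calibrated on known splicing mutations.
#' @param mhc_interval List with `chrom`, `start`, `end` delimiting the MHC
#'   region (default: the hg19 extended MHC on chr6). Genes and loci inside
#'   it are reported separately as category D.
#' @param prevalence Disease prevalence assumed by the cohort simulator
#'   (the analysis itself uses the rare-disease approximation and never
#'   applies a prevalence correction).
#' @param rng_seed Integer seed recorded in run manifests.
#'
#' @return A list of class `mech_config`.
#' @export
mech_config <- function(window_bp = 200000L,
                        maf_min = 0.05,
                        p_threshold_primary = 5.0e-7,
                        p_threshold_catalog = 1.0e-5,
                        eqtl_match_cm = 0.05,
                        eqtl_consensus_r2 = 0.8,
                        eqtl_linkage = c("single", "complete"),
                        r2_floor = 0.2,
                        splice_thresholds = default_splice_thresholds(),
                        mhc_interval = list(chrom = "chr6",
                                            start = 28477797L,
                                            end = 33448354L),
                        prevalence = 0.01,
                        rng_seed = 1L) {
  eqtl_linkage <- match.arg(eqtl_linkage)
  num1 <- function(x, nm, positive = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
      stop("config field '", nm, "' must be a single number", call. = FALSE)
    if (positive && x <= 0)
      stop("config field '", nm, "' must be strictly positive", call. = FALSE)
    x
  }
  num1(window_bp, "window_bp")
  num1(maf_min, "maf_min")
  num1(p_threshold_primary, "p_threshold_primary")
  num1(p_threshold_catalog, "p_threshold_catalog")
  num1(eqtl_match_cm, "eqtl_match_cm")
  num1(eqtl_consensus_r2, "eqtl_consensus_r2")
  num1(r2_floor, "r2_floor", positive = FALSE)
  num1(prevalence, "prevalence")
  if (r2_floor < 0 || r2_floor >= 1)
    stop("r2_floor must lie in [0, 1)", call. = FALSE)
  validate_splice_thresholds(splice_thresholds)
  if (!is.list(mhc_interval) ||
      !all(c("chrom", "start", "end") %in% names(mhc_interval)))
    stop("mhc_interval must be a list with chrom, start, end", call. = FALSE)
  cfg <- list(window_bp = as.integer(window_bp),
              maf_min = maf_min,
              p_threshold_primary = p_threshold_primary,
              p_threshold_catalog = p_threshold_catalog,
              eqtl_match_cm = eqtl_match_cm,
              eqtl_consensus_r2 = eqtl_consensus_r2,
              eqtl_linkage = eqtl_linkage,
              r2_floor = r2_floor,
              splice_thresholds = splice_thresholds,
              mhc_interval = mhc_interval,
              prevalence = prevalence,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "mech_config"
  cfg
}

#' Placeholder auxiliary-splicing thresholds
#'
#' One all-covering interval per site type with threshold 0. This is a
#' deliberately inert placeholder: calibrated per-interval thresholds (e.g.
#' medians of score changes over known splice-affecting mutations) must be
#' supplied for real analyses.
#'
#' @return Data frame with columns `site_type`, `lo`, `hi`, `threshold`.
#' @export
default_splice_thresholds <- function() {
  data.frame(site_type = c("donor", "acceptor"),
             lo = c(-80, -80), hi = c(80, 80),
             threshold = c(0, 0),
             stringsAsFactors = FALSE)
}

validate_splice_thresholds <- function(x) {
  need <- c("site_type", "lo", "hi", "threshold")
  if (!is.data.frame(x) || !all(need %in% names(x)))
    stop("splice_thresholds needs columns site_type, lo, hi, threshold",
         call. = FALSE)
  if (!all(x$site_type %in% c("donor", "acceptor")))
    stop("splice_thresholds site_type must be donor or acceptor",
         call. = FALSE)
  if (any(x$lo > x$hi))
    stop("splice_thresholds intervals must have lo <= hi", call. = FALSE)
  for (st in unique(x$site_type)) {
    sub <- x[x$site_type == st, , drop = FALSE]
    sub <- sub[order(sub$lo), , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$lo[-1L] <= sub$hi[-nrow(sub)]))
      stop("splice_thresholds intervals overlap for site_type ", st,
           call. = FALSE)
  }
  invisible(x)
}

#' @export
print.mech_config <- function(x, ...) {
  cat("mechanista pipeline configuration\n")
  cat(sprintf("  candidate window     : +/- %d bp\n", x$window_bp))
  cat(sprintf("  MAF floor            : %.3f\n", x$maf_min))
  cat(sprintf("  marker p thresholds  : primary < %g, catalog < %g\n",
              x$p_threshold_primary, x$p_threshold_catalog))
  cat(sprintf("  acceptance r2 floor  : %.2f\n", x$r2_floor))
  cat(sprintf("  eQTL match radius    : %.3f cM; consensus r2 > %.2f (%s linkage)\n",
              x$eqtl_match_cm, x$eqtl_consensus_r2, x$eqtl_linkage))
  cat(sprintf("  splice threshold rows: %d\n", nrow(x$splice_thresholds)))
  invisible(x)
}

# Serialize a config to a plain named list (for manifests / YAML round trips)
config_as_list <- function(config) {
  stopifnot(inherits(config, "mech_config"))
  out <- unclass(config)
  out$splice_thresholds <- as.list(out$splice_thresholds)
  out
}

#' The five mechanism classes
#'
#' @return Character vector: high- and low-impact missense, expression,
#'   auxiliary splicing, direct splice-site.
#' @export
mechanism_classes <- function() {
  c("missense_high", "missense_low", "expression", "aux_splice",
    "direct_splice")
}
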