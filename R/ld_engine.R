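#' Two-SNP haplotype frequencies
#'
#' Container for the joint haplotype frequencies of a candidate SNP and a
#' marker SNP. Lower-case letters denote the risk alleles: `a` is the
#' candidate's putative risk allele and `b` the marker's risk allele, so
#' `h_ab` is the frequency of the haplotype carrying both risk alleles.
#'
#' @param h_AB,h_Ab,h_aB,h_ab Frequencies of the four haplotypes; must be
#'   non-negative and sum to 1 (tolerance 1e-9).
#' @return List of class `haplotype_freqs` with the four frequencies plus
#'   the marginal risk-allele frequencies `p_a` (candidate) and `p_b`
#'   (marker).
#' @export
#' @examples
#' hf <- haplotype_freqs(0.5, 0.2, 0.1, 0.2)
#' ld_stats(hf)
haplotype_freqs <- function(h_AB, h_Ab, h_aB, h_ab) {
  h <- c(h_AB = h_AB, h_Ab = h_Ab, h_aB = h_aB, h_ab = h_ab)
  if (any(!is.finite(h)) || any(h < -1e-12))
    stop("haplotype frequencies must be finite and non-negative",
         call. = FALSE)
  if (abs(sum(h) - 1) > 1e-9)
    stop("haplotype frequencies must sum to 1 (got ",
         format(sum(h), digits = 12), ")", call. = FALSE)
  hf <- list(h_AB = h_AB, h_Ab = h_Ab, h_aB = h_aB, h_ab = h_ab,
             p_a = h_aB + h_ab, p_b = h_Ab + h_ab)
  class(hf) <- "haplotype_freqs"
  hf
}

#' @export
print.haplotype_freqs <- function(x, ...) {
  cat(sprintf("haplotype freqs: h_AB=%.4g h_Ab=%.4g h_aB=%.4g h_ab=%.4g (p_a=%.4g, p_b=%.4g)\n",
              x$h_AB, x$h_Ab, x$h_aB, x$h_ab, x$p_a, x$p_b))
  invisible(x)
}

check_polymorphic <- function(hf) {
  eps <- 1e-12
  if (hf$p_a <= eps || hf$p_a >= 1 - eps ||
      hf$p_b <= eps || hf$p_b >= 1 - eps)
    stop("monomorphic SNP: allele frequencies must lie strictly in (0,1)",
         call. = FALSE)
  invisible(hf)
}

#' Two-locus linkage disequilibrium statistics
#'
#' Computes the classical LD measures from two-SNP haplotype frequencies:
#' the covariance `D = h_ab - p_a * p_b`, its range-normalised form
#' `D'` (Lewontin), and the squared allelic correlation
#' `r2 = D^2 / (p_a (1-p_a) p_b (1-p_b))`.
#'
#' @param hf A [haplotype_freqs()] object with both SNPs polymorphic.
#' @return List of class `ld_stats` with `D`, `D_prime`, `r2`.
#' @export
ld_stats <- function(hf) {
  stopifnot(inherits(hf, "haplotype_freqs"))
  check_polymorphic(hf)
  p_a <- hf$p_a; p_b <- hf$p_b
  D <- hf$h_ab - p_a * p_b
  D_max <- if (D > 0) min(p_a * (1 - p_b), (1 - p_a) * p_b)
           else       min(p_a * p_b, (1 - p_a) * (1 - p_b))
  D_prime <- if (D == 0) 0 else D / D_max
  r2 <- D^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
  structure(list(D = D, D_prime = D_prime, r2 = r2), class = "ld_stats")
}

#' Marker odds ratio implied by a causal candidate (forward model)
#'
#' Given the two-SNP haplotype structure and a per-allele case/control odds
#' ratio `or_c` acting at the candidate SNP, predicts the allelic odds
#' ratio that would be observed at the marker. The model is the standard
#' retrospective one under a multiplicative allelic risk and the
#' rare-disease approximation: controls carry the population haplotype
#' frequencies, the case frequency of the candidate risk allele is
#' `q_a = or_c p_a / (1 - p_a + or_c p_a)`, and the candidate-to-marker
#' conditional allele probabilities are unchanged in cases (the marker is
#' associated with disease only through the candidate).
#'
#' @param hf A [haplotype_freqs()] object.
#' @param or_c Candidate per-allele odds ratio (> 0).
#' @return The marker per-allele odds ratio.
#' @export
forward_marker_or <- function(hf, or_c) {
  stopifnot(inherits(hf, "haplotype_freqs"))
  check_polymorphic(hf)
  if (!is.numeric(or_c) || length(or_c) != 1L || !is.finite(or_c) || or_c <= 0)
    stop("or_c must be a single positive number", call. = FALSE)
  p_a <- hf$p_a; p_b <- hf$p_b
  q_a <- or_c * p_a / (1 - p_a + or_c * p_a)
  # P(b | a) and P(b | A) from the population haplotypes
  b_given_a <- hf$h_ab / p_a
  b_given_A <- hf$h_Ab / (1 - p_a)
  q_b <- q_a * b_given_a + (1 - q_a) * b_given_A
  (q_b * (1 - p_b)) / ((1 - q_b) * p_b)
}

#' Candidate odds ratio implied by a marker association (inverse model)
#'
#' Inverts [forward_marker_or()]: given the observed marker odds ratio
#' `or_m` and the two-SNP haplotype structure, solves for the case
#' frequency `q_a` the candidate risk allele would need so that involvement
#' of the candidate in mechanism reproduces the marker's case/control
#' frequency difference. The solution is feasible only when `q_a` is a
#' proper frequency (`0 < q_a < 1`); infeasibility is a legitimate outcome
#' meaning the SNP cannot be the mechanism variant, not an error.
#'
#' @param hf A [haplotype_freqs()] object with `D != 0` (in linkage
#'   equilibrium the marker carries no information about the candidate and
#'   the inversion is undefined).
#' @param or_m Observed marker per-allele odds ratio (> 0).
#' @return List with `feasible` (logical), `or_c` (implied candidate odds
#'   ratio, `NA` when infeasible) and `q_a` (implied case frequency of the
#'   candidate risk allele).
#' @export
implied_candidate_or <- function(hf, or_m) {
  stopifnot(inherits(hf, "haplotype_freqs"))
  check_polymorphic(hf)
  if (!is.numeric(or_m) || length(or_m) != 1L || !is.finite(or_m) || or_m <= 0)
    stop("or_m must be a single positive number", call. = FALSE)
  p_a <- hf$p_a; p_b <- hf$p_b
  b_given_a <- hf$h_ab / p_a
  b_given_A <- hf$h_Ab / (1 - p_a)
  denom <- b_given_a - b_given_A   # = D / (p_a (1 - p_a))
  if (abs(denom) < 1e-12)
    stop("D = 0: marker carries no information about the candidate",
         call. = FALSE)
  q_b <- or_m * p_b / (1 - p_b + or_m * p_b)
  q_a <- (q_b - b_given_A) / denom
  if (!is.finite(q_a) || q_a <= 0 || q_a >= 1)
    return(list(feasible = FALSE, or_c = NA_real_, q_a = q_a))
  or_c <- (q_a / (1 - q_a)) / (p_a / (1 - p_a))
  list(feasible = TRUE, or_c = or_c, q_a = q_a)
}

#' Haplotype frequencies counted from a phased panel
#'
#' Counts the four two-SNP haplotype classes over a phased haplotype panel
#' and orients them so that the lower-case alleles of the result are the
#' declared risk alleles.
#'
#' @param panel A [hap_panel()] object.
#' @param snp_i Candidate SNP id (allele `a` of the result).
#' @param snp_j Marker SNP id (allele `b` of the result).
#' @param risk_i,risk_j Risk-allele bases for the two SNPs, matched against
#'   the panel's allele coding. Default `NULL` takes the allele coded 1.
#' @return A [haplotype_freqs()] object.
#' @export
haplotype_freqs_from_panel <- function(panel, snp_i, snp_j,
                                       risk_i = NULL, risk_j = NULL) {
  stopifnot(inherits(panel, "hap_panel"))
  for (s in c(snp_i, snp_j))
    if (!s %in% colnames(panel$haps))
      stop("SNP '", s, "' absent from panel", call. = FALSE)
  orient <- function(snp, risk) {
    x <- panel$haps[, snp]
    if (is.null(risk)) return(x)
    site <- panel$sites[panel$sites$id == snp, , drop = FALSE]
    if (identical(risk, site$allele1[1L])) x
    else if (identical(risk, site$allele0[1L])) 1L - x
    else stop("risk allele '", risk, "' does not match panel coding of '",
              snp, "'", call. = FALSE)
  }
  x <- orient(snp_i, risk_i)   # 1 = candidate risk allele a
  y <- orient(snp_j, risk_j)   # 1 = marker risk allele b
  n <- length(x)
  haplotype_freqs(h_AB = sum(x == 0L & y == 0L) / n,
                  h_Ab = sum(x == 0L & y == 1L) / n,
                  h_aB = sum(x == 1L & y == 0L) / n,
                  h_ab = sum(x == 1L & y == 1L) / n)
}
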