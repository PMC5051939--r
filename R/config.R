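#' Penalty configuration for alignment likelihoods
#'
#' Bundles the log10-scale penalty scores applied to each alignment status,
#' together with the phred scaling factor, the mapping-quality cap and a few
#' operational knobs.  Each `gamma_*` penalty can be read as the relative
#' chance of that status occurring compared to a plain mismatch, in log10
#' units: `gamma = 1` means ten-fold less likely than a mismatch at the same
#' base quality.
#'
#' @param gamma_open gap-open penalty (log10 units).
#' @param gamma_ext gap-extension penalty.
#' @param gamma_soft soft-clip penalty, applied per clipped base.
#' @param gamma_hard hard-clip penalty, applied per clipped base using the
#'   estimated quality of the unobserved bases.
#' @param gamma_snp penalty for a mismatch explained by a known SNV (used
#'   when the variant has no allele frequency).
#' @param gamma_indel penalty for a gap run explained by a known indel.
#' @param gamma_mnp penalty for a mismatch block explained by a known MNP.
#' @param mapq_cap maximum reported mapping quality.  255 is reserved by the
#'   SAM specification for "unavailable", so the cap defaults below it.
#' @param clip_window number of observed bases adjacent to a hard clip whose
#'   mean quality estimates the quality of the clipped (unobserved) bases.
#' @param min_frag_n minimum number of uniquely-mapped concordant pairs
#'   required before the Gaussian fragment-size model is considered reliable.
#' @param constant_density pairing density used when the fragment-size model
#'   is unreliable (or for orphan/cross-reference pairs).  Its value cancels
#'   within any group where all pairs use it.
#' @param genome_size effective genome size `L_G`.  Documentation only: the
#'   prior `Pr(loc) = L / L_G` enters every candidate of a read with the same
#'   `1 / L_G`, which cancels in the posterior normalization.
#'
#' @return An object of class `penalty_config`.
#' @examples
#' cfg <- penalty_config(gamma_open = 3)
#' cfg$gamma_open
#' @export
penalty_config <- function(gamma_open = 2, gamma_ext = 1, gamma_soft = 1,
                           gamma_hard = 1, gamma_snp = 1, gamma_indel = 2,
                           gamma_mnp = 2, mapq_cap = 250L, clip_window = 5L,
                           min_frag_n = 1000L, constant_density = 1,
                           genome_size = 3.1e9) {
  gammas <- c(gamma_open = gamma_open, gamma_ext = gamma_ext,
              gamma_soft = gamma_soft, gamma_hard = gamma_hard,
              gamma_snp = gamma_snp, gamma_indel = gamma_indel,
              gamma_mnp = gamma_mnp)
  if (any(!is.finite(gammas)) || any(gammas < 0))
    stop("all penalty scores must be finite and >= 0")
  if (mapq_cap < 0 || mapq_cap > 254)
    stop("mapq_cap must be in [0, 254]")
  if (clip_window < 1) stop("clip_window must be >= 1")
  structure(list(
    gamma_open = gamma_open, gamma_ext = gamma_ext, gamma_soft = gamma_soft,
    gamma_hard = gamma_hard, gamma_snp = gamma_snp, gamma_indel = gamma_indel,
    gamma_mnp = gamma_mnp,
    phred_scale = -10,                 # fixed by the phred definition
    mapq_cap = as.integer(mapq_cap), clip_window = as.integer(clip_window),
    min_frag_n = as.integer(min_frag_n), constant_density = constant_density,
    genome_size = genome_size
  ), class = "penalty_config")
}

#' @export
print.penalty_config <- function(x, ...) {
  cat("Penalty configuration (log10 units):\n")
  cat(sprintf("  gap open %g, gap ext %g, soft clip %g, hard clip %g\n",
              x$gamma_open, x$gamma_ext, x$gamma_soft, x$gamma_hard))
  cat(sprintf("  known SNV %g, known indel %g, known MNP %g\n",
              x$gamma_snp, x$gamma_indel, x$gamma_mnp))
  cat(sprintf("  mapQ cap %d, clip window %d\n", x$mapq_cap, x$clip_window))
  invisible(x)
}

#' Per-position score configuration for insert-range estimation
#'
#' Scores used by the maximum-scoring insert-range dynamic program
#' ([best_insert_range()]): a positive reward for a match, a (typically
#' negative) score for a mismatch, and the gap/clip penalties reused from a
#' [penalty_config()] as subtractive scores.
#'
#' @param match score of a matched base (`a_m > 0`).
#' @param mismatch score of a mismatched base (`a_x`).
#' @param penalties a [penalty_config()] supplying the gap and clip
#'   penalties.
#' @return An object of class `score_config`.
#' @examples
#' score_config(match = 1, mismatch = -2)
#' @export
score_config <- function(match = 1, mismatch = -2,
                         penalties = penalty_config()) {
  if (!is.finite(match) || match <= 0) stop("match score must be > 0")
  structure(list(
    match = match, mismatch = mismatch,
    gamma_open = penalties$gamma_open, gamma_ext = penalties$gamma_ext,
    gamma_soft = penalties$gamma_soft, gamma_hard = penalties$gamma_hard
  ), class = "score_config")
}
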