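# Alignment likelihoods in log10 scale.
#
# The likelihood of a candidate alignment is a sum of independent
# per-position terms: a matched base contributes lg(1 - Q2P(Q)), a mismatch
# contributes Q/s (s = -10, i.e. -Q/10 = lg of the error probability), and
# gap/clip positions contribute Q/s minus a status-specific penalty.  N/P
# positions contribute nothing.  Variant-aware scoring lets a known
# SNV/indel/MNP explain an apparent edit: per variant, the larger of the
# plain and the variant-aware term is used, treating multiple variants in
# one alignment as independent.

#' Convert a phred quality to an error probability
#'
#' @param q phred score(s), `>= 0`.
#' @return `10^(-q/10)`.
#' @examples
#' q2p(c(0, 10, 30))
#' @export
q2p <- function(q) {
  if (any(q < 0)) stop("phred scores must be >= 0")
  10^(-q / 10)
}

#' Penalty implied by an allele frequency
#'
#' A known variant with population allele frequency `AF` replaces the flat
#' per-kind penalty with `-lg(AF)`: a common allele costs little, a rare one
#' costs more.
#'
#' @param af allele frequency in `(0, 1]`.
#' @return `-log10(af)`, a non-negative penalty.
#' @examples
#' af_penalty(c(1, 0.1, 0.5))
#' @export
af_penalty <- function(af) {
  if (any(af <= 0) || any(af > 1)) stop("allele frequency must be in (0, 1]")
  -log10(af)
}

# Per-position plain likelihood terms (log10).
position_loglik_terms <- function(cand, config) {
  st <- cand$status
  q <- cand$qual
  s <- config$phred_scale
  term <- numeric(length(st))
  m <- st == "MATCH"
  term[m] <- log10(1 - q2p(q[m]))
  i <- st == "MISMATCH";  term[i] <- q[i] / s
  i <- st == "GAP_OPEN";  term[i] <- q[i] / s - config$gamma_open
  i <- st == "GAP_EXT";   term[i] <- q[i] / s - config$gamma_ext
  i <- st == "SOFT_CLIP"; term[i] <- q[i] / s - config$gamma_soft
  i <- st == "HARD_CLIP"; term[i] <- q[i] / s - config$gamma_hard
  term
}

#' Log10 likelihood of a candidate alignment
#'
#' Sums the per-position terms over all non-ignored positions of an expanded
#' candidate.  The result is stored on the returned candidate in `log_lik`
#' (use `value_only = TRUE` for just the number).
#'
#' @param cand a `candidate_alignment` from [expand_alignment()].
#' @param config a [penalty_config()].
#' @param value_only return the numeric value instead of the candidate.
#' @return The candidate with `log_lik` set, or a numeric scalar.
#' @examples
#' rec <- list(qname = "r", flag = 0L, rname = "chr1", pos = 1L, mapq = 255L,
#'             cigar = "5M", rnext = "*", pnext = 0L, tlen = 0L,
#'             seq = "ACGTA", qual = "55555", tags = c(MD = "Z:5"))
#' log_likelihood(expand_alignment(rec), value_only = TRUE)
#' @export
log_likelihood <- function(cand, config = penalty_config(),
                           value_only = FALSE) {
  ll <- sum(position_loglik_terms(cand, config))
  if (value_only) return(ll)
  cand$log_lik <- ll
  cand
}

#' Variant-aware log10 likelihood
#'
#' Recomputes the alignment likelihood allowing known variants to explain
#' apparent edits.  For every known variant whose alternate allele matches
#' the observed difference (SNV base, MNP block, or inserted/deleted
#' sequence at the left-aligned position), the affected positions may take a
#' variant-aware term instead of the plain one, and the larger of the two is
#' used -- independently per variant, so the result is never below the plain
#' likelihood.  The variant-aware term treats the bases as correctly
#' sequenced and charges only the variant prior: `lg(1 - Q2P(Q)) - gamma`
#' for an SNV, the block analogue (with a single `gamma`) for MNPs, and for
#' indels the run keeps its `Q/s` terms but replaces the gap-open/extension
#' penalties with a single `gamma`.  `gamma` is the per-kind penalty from
#' `config`, or [af_penalty()] of the allele frequency when available.
#' With `strict_literal = TRUE` the SNV/MNP term is `Q/s - gamma` instead
#' (the printed form of the model); since that never beats the plain
#' mismatch term `Q/s`, strict mode reduces to the plain likelihood for
#' substitution variants and is provided for comparison only.
#'
#' A variant whose reference allele contradicts the reference base implied
#' by the MD tag is skipped with a warning.
#'
#' @inheritParams log_likelihood
#' @param variants a `variant_index` from [read_known_variants()] /
#'   [variant_index()].
#' @param strict_literal use the literal `Q/s - gamma` form for known
#'   SNVs/MNPs.
#' @return The candidate with `log_lik` set, or a numeric scalar.
#' @export
log_likelihood_variant_aware <- function(cand, variants,
                                         config = penalty_config(),
                                         strict_literal = FALSE,
                                         value_only = FALSE) {
  term <- position_loglik_terms(cand, config)
  s <- config$phred_scale
  vgamma <- function(v, default) if (is.na(v$af)) default else af_penalty(v$af)

  # --- SNVs at mismatch positions -------------------------------------
  mm <- which(cand$status == "MISMATCH")
  for (j in mm) {
    g <- cand$ref_pos[j]
    if (is.na(g)) next
    for (v in lookup_variants(variants, cand$rname, g)) {
      if (v$kind != "SNV") next
      if (!identical(v$alt, cand$read_base[j])) next
      if (!is.na(cand$ref_base[j]) && !identical(v$ref, cand$ref_base[j])) {
        warning("known SNV at ", cand$rname, ":", g + 1L,
                " has REF ", v$ref, " but alignment implies ",
                cand$ref_base[j], "; variant skipped")
        next
      }
      gmma <- vgamma(v, config$gamma_snp)
      vterm <- if (strict_literal) cand$qual[j] / s - gmma
               else log10(1 - q2p(cand$qual[j])) - gmma
      term[j] <- max(term[j], vterm)
    }
  }

  # --- MNPs over consecutive mismatch runs ----------------------------
  delta <- 0
  runs <- split(mm, cumsum(c(TRUE, diff(mm) != 1L)))
  for (run in runs) {
    if (length(run) < 2L) next
    g <- cand$ref_pos[run[1L]]
    if (is.na(g)) next
    obs_alt <- paste(cand$read_base[run], collapse = "")
    obs_ref <- paste(cand$ref_base[run], collapse = "")
    for (v in lookup_variants(variants, cand$rname, g)) {
      if (v$kind != "MNP" || nchar(v$alt) != length(run)) next
      if (!identical(v$alt, obs_alt)) next
      if (!grepl("N", obs_ref, fixed = TRUE) && !anyNA(cand$ref_base[run]) &&
          !identical(v$ref, obs_ref)) {
        warning("known MNP at ", cand$rname, ":", g + 1L,
                " has REF ", v$ref, " but alignment implies ", obs_ref,
                "; variant skipped")
        next
      }
      gmma <- vgamma(v, config$gamma_mnp)
      q <- cand$qual[run]
      vblock <- if (strict_literal) sum(q / s) - gmma
                else sum(log10(1 - q2p(q))) - gmma
      plain <- sum(position_loglik_terms(cand, config)[run])
      delta <- delta + max(0, vblock - plain)
    }
  }

  # --- indel runs ------------------------------------------------------
  is_gap <- cand$status %in% c("GAP_OPEN", "GAP_EXT")
  gp <- which(is_gap)
  if (length(gp)) {
    runs <- split(gp, cumsum(cand$status[gp] == "GAP_OPEN"))
    for (run in runs) {
      op <- cand$ops[run[1L]]
      len <- length(run)
      if (op == "I") {
        # left-aligned insertion point: coordinate of the next reference base
        after <- cand$ref_pos[run[length(run)]:length(cand$ref_pos)]
        g <- if (any(!is.na(after))) after[!is.na(after)][1L] else cand$end
        vseq <- paste(cand$read_base[run], collapse = "")
      } else {
        g <- cand$ref_pos[run[1L]]
        vseq <- if (anyNA(cand$ref_base[run])) NA_character_
                else paste(cand$ref_base[run], collapse = "")
      }
      if (is.na(g)) next
      for (v in lookup_variants(variants, cand$rname, g)) {
        if (v$kind != "INDEL") next
        if (!identical(v$indel_type, if (op == "I") "ins" else "del")) next
        if (is.na(vseq) || !identical(v$seq, vseq)) next
        gmma <- vgamma(v, config$gamma_indel)
        # plain run penalty: one gap-open + (len-1) extensions; variant-aware
        # replaces the whole run's penalty with a single gamma, keeping Q/s.
        plain_pen <- config$gamma_open + (len - 1L) * config$gamma_ext
        delta <- delta + max(0, plain_pen - gmma)
      }
    }
  }

  ll <- sum(term) + delta
  if (value_only) return(ll)
  cand$log_lik <- ll
  cand
}

# --- known variants ----------------------------------------------------

#' Build an index of known variants
#'
#' `variant_index()` builds a position-indexed store of known variants from
#' a data frame; `read_known_variants()` reads them from a VCF/gVCF file via
#' `VariantAnnotation` (multi-allelic records are expanded to one entry per
#' alternate allele, with per-allele `AF` from the INFO field when present;
#' symbolic alleles and breakends are skipped with a warning).
#'
#' Variants are stored left-aligned and anchor-stripped in 0-based
#' coordinates: an SNV/MNP is keyed by its start position; an insertion by
#' the position of the reference base following the insertion point; a
#' deletion by the position of its first deleted base.  `seq` holds the
#' inserted/deleted bases for indels.
#'
#' @param df data frame with columns `rname`, `pos` (1-based VCF position of
#'   the record, anchor included for indels), `ref`, `alt`, and optionally
#'   `af`.
#' @return An object of class `variant_index`.
#' @examples
#' idx <- variant_index(data.frame(rname = "chr1", pos = 100,
#'                                 ref = "A", alt = "G", af = 0.3))
#' lookup_variants(idx, "chr1", 99)
#' @export
variant_index <- function(df) {
  env <- new.env(parent = emptyenv(), hash = TRUE)
  n_kept <- 0L
  for (i in seq_len(nrow(df))) {
    v <- normalize_variant(df$rname[i], df$pos[i], df$ref[i], df$alt[i],
                           if ("af" %in% names(df)) df$af[i] else NA_real_)
    if (is.null(v)) next
    key <- paste0(v$rname, ":", v$pos)
    env[[key]] <- c(env[[key]], list(v))
    n_kept <- n_kept + 1L
  }
  structure(list(env = env, n = n_kept), class = "variant_index")
}

normalize_variant <- function(rname, pos, ref, alt, af = NA_real_) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (grepl("[^ACGTN]", ref) || grepl("[^ACGTN]", alt)) {
    warning("skipping symbolic/complex allele at ", rname, ":", pos,
            " (", ref, ">", alt, ")")
    return(NULL)
  }
  pos0 <- as.integer(pos) - 1L
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == 1L && na == 1L) {
    list(rname = rname, pos = pos0, kind = "SNV", ref = ref, alt = alt,
         af = af)
  } else if (nr == na) {
    list(rname = rname, pos = pos0, kind = "MNP", ref = ref, alt = alt,
         af = af)
  } else if (nr < na && startsWith(alt, ref)) {
    # insertion after the anchor: keyed by the next reference base
    list(rname = rname, pos = pos0 + nr, kind = "INDEL", indel_type = "ins",
         ref = ref, alt = alt, seq = substring(alt, nr + 1L), af = af)
  } else if (nr > na && startsWith(ref, alt)) {
    list(rname = rname, pos = pos0 + na, kind = "INDEL", indel_type = "del",
         ref = ref, alt = alt, seq = substring(ref, na + 1L), af = af)
  } else {
    warning("skipping complex substitution at ", rname, ":", pos,
            " (", ref, ">", alt, ")")
    NULL
  }
}

#' @rdname variant_index
#' @param path VCF/gVCF file path.
#' @export
read_known_variants <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  af <- tryCatch(VariantAnnotation::info(vcf)$AF, error = function(e) NULL)
  df <- data.frame(
    rname = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    af = if (is.null(af)) NA_real_ else as.numeric(af)
  )
  variant_index(df)
}

#' @rdname variant_index
#' @param idx a `variant_index`.
#' @param rname reference name.
#' @param pos 0-based position.
#' @return `lookup_variants()` returns a (possibly empty) list of variant
#'   records at that exact position.
#' @export
lookup_variants <- function(idx, rname, pos) {
  v <- idx$env[[paste0(rname, ":", pos)]]
  if (is.null(v)) list() else v
}

#' @export
print.variant_index <- function(x, ...) {
  cat(sprintf("variant index: %d variant(s)\n", x$n))
  invisible(x)
}
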