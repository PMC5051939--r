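# End-to-end filtering: group candidate alignments, score, select best
# hits, annotate and write.

#' Recompute mapping qualities and select best hits
#'
#' The main entry point: takes a name-grouped SAM set containing all
#' candidate alignments per read (single-end) or per fragment (paired-end),
#' computes per-candidate likelihoods and posterior mapping probabilities,
#' selects the best hit per read, rewrites MAPQ, flags the remaining
#' candidates secondary and annotates diagnostic tags:
#' `XL:f` log10 alignment likelihood, `XP:f` posterior probability,
#' `XN:i` number of candidates in the group, `XM:i` mismatches,
#' `XO:i` indel runs.  Optionally each candidate is first trimmed to its
#' maximum-scoring insert range (`enable_1dp`), and known variants can
#' absolve mismatches/indels that match a population polymorphism.
#'
#' Duplicated candidates (same reference, start, CIGAR and strand) are
#' collapsed before scoring; secondary/supplementary input flags are
#' otherwise ignored, every record being treated as an ordinary candidate.
#' Reads whose only records are unmapped pass through untouched.
#'
#' @param input a `sam_set` from [read_sam()] or a SAM file path.
#' @param output optional path to write the filtered SAM.
#' @param mode `"se"` or `"pe"`.
#' @param config a [penalty_config()].
#' @param scores a [score_config()] for 1DP trimming.
#' @param enable_1dp trim each candidate to its best insert range before
#'   likelihood computation.
#' @param variants optional `variant_index` (or VCF path) of known variants.
#' @param strict_literal see [log_likelihood_variant_aware()].
#' @param min_mapq_out drop output records with `mapq` below this.
#' @param max_report keep at most this many non-primary hits per read.
#' @param fragment_model optional precomputed [estimate_fragment_model()];
#'   by default it is estimated from the input's uniquely-mapped concordant
#'   pairs (paired-end mode only).
#' @return Invisibly, a list with the filtered `sam` (a `sam_set`) and a
#'   `stats` list (group counts, drop counts, fragment model).
#' @export
boost_alignments <- function(input, output = NULL, mode = c("se", "pe"),
                             config = penalty_config(),
                             scores = score_config(penalties = config),
                             enable_1dp = FALSE, variants = NULL,
                             strict_literal = FALSE,
                             min_mapq_out = 0L, max_report = 10L,
                             fragment_model = NULL) {
  mode <- match.arg(mode)
  sam <- if (is.character(input)) read_sam(input) else input
  if (is.character(variants)) variants <- read_known_variants(variants)
  groups <- group_sam(sam)

  score_cand <- function(cand) {
    if (enable_1dp)
      cand <- trim_to_insert(cand,
                             best_insert_range(position_scores(cand, scores)))
    if (isTRUE(cand$unmapped)) return(cand)
    if (is.null(variants)) log_likelihood(cand, config)
    else log_likelihood_variant_aware(cand, variants, config,
                                      strict_literal = strict_literal)
  }

  expand_group <- function(recs) {
    mapped <- Filter(function(r) !has_flag(r$flag, FLAG_UNMAPPED), recs)
    cands <- lapply(mapped, expand_alignment, config = config)
    sig <- vapply(cands, function(cc)
      paste(cc$rname, cc$start, candidate_cigar(cc), cc$strand), "")
    cands <- cands[!duplicated(sig)]
    cands <- lapply(cands, score_cand)
    Filter(function(cc) !isTRUE(cc$unmapped), cands)
  }

  stats <- list(n_groups = length(groups), n_unmapped_through = 0L,
                n_dropped = 0L, fragment_model = NULL)
  out_records <- list()
  emit <- function(recs) out_records[[length(out_records) + 1L]] <<- recs

  if (mode == "pe") {
    expanded <- lapply(groups, function(recs) {
      list(m1 = expand_group(Filter(function(r) has_flag(r$flag, FLAG_FIRST) ||
                                      !has_flag(r$flag, FLAG_SECOND), recs)),
           m2 = expand_group(Filter(function(r) has_flag(r$flag, FLAG_SECOND),
                                    recs)),
           raw = recs)
    })
    if (is.null(fragment_model)) {
      d <- unlist(lapply(expanded, function(g) {
        if (length(g$m1) == 1L && length(g$m2) == 1L &&
            identical(g$m1[[1L]]$rname, g$m2[[1L]]$rname) &&
            !identical(g$m1[[1L]]$strand, g$m2[[1L]]$strand))
          max(g$m1[[1L]]$end, g$m2[[1L]]$end) -
            min(g$m1[[1L]]$start, g$m2[[1L]]$start)
      }))
      fragment_model <- estimate_fragment_model(
        d, min_n = config$min_frag_n,
        constant_density = config$constant_density)
    }
    stats$fragment_model <- fragment_model
    for (qn in names(expanded)) {
      g <- expanded[[qn]]
      if (!length(g$m1) && !length(g$m2)) {
        emit(g$raw); stats$n_unmapped_through <- stats$n_unmapped_through + 1L
        next
      }
      pairs <- build_pairs(g$m1, g$m2, g$raw, config)
      pg <- select_best(pe_posteriors(pair_group(pairs), fragment_model,
                                      config), config)
      res <- pair_records(pg, max_report, min_mapq_out)
      stats$n_dropped <- stats$n_dropped + res$dropped
      emit(res$records)
    }
  } else {
    for (qn in names(groups)) {
      cands <- expand_group(groups[[qn]])
      if (!length(cands)) {
        emit(groups[[qn]])
        stats$n_unmapped_through <- stats$n_unmapped_through + 1L
        next
      }
      rg <- select_best(se_posteriors(read_group(cands), config), config)
      res <- se_records(rg, max_report, min_mapq_out)
      stats$n_dropped <- stats$n_dropped + res$dropped
      emit(res$records)
    }
  }

  out <- structure(list(header = append_pg_line(sam$header),
                        records = do.call(c, c(out_records, list(list())))),
                   class = "sam_set")
  if (!is.null(output)) write_sam(out, output)
  invisible(list(sam = out, stats = stats))
}

# All candidate pairs of a fragment: the cross product of mate candidates,
# or orphan pairs against a soft-masked pseudo-mate when one side is empty.
build_pairs <- function(m1, m2, raw, config) {
  if (length(m1) && length(m2)) {
    pairs <- list()
    for (a in m1) for (b in m2)
      pairs[[length(pairs) + 1L]] <- candidate_pair(a, b)
    return(pairs)
  }
  mapped <- if (length(m1)) m1 else m2
  other_unmapped <- Filter(function(r) has_flag(r$flag, FLAG_UNMAPPED),
                           raw)
  template <- if (length(other_unmapped)) other_unmapped[[1L]] else NULL
  lapply(mapped, orphan_to_pair, mate_template = template, config = config)
}

annotate_record <- function(cand, n_cands, primary, min_mapq_out) {
  rec <- candidate_to_record(cand)
  rec$mapq <- cand$mapq
  rec$flag <- if (primary) bitwAnd(rec$flag, bitwNot(FLAG_SECONDARY))
              else bitwOr(rec$flag, FLAG_SECONDARY)
  rec <- set_tag(rec, "XL", "f", sprintf("%.4f", cand$log_lik))
  rec <- set_tag(rec, "XP", "f", sprintf("%.6g", cand$posterior))
  rec <- set_tag(rec, "XN", "i", n_cands)
  rec <- set_tag(rec, "XM", "i", cand$mismatch_count)
  rec <- set_tag(rec, "XO", "i", cand$indel_count)
  rec
}

se_records <- function(rg, max_report, min_mapq_out) {
  n <- length(rg$candidates)
  keep <- seq_len(min(n, 1L + max_report))
  recs <- list(); dropped <- 0L
  for (i in keep) {
    cand <- rg$candidates[[i]]
    if (cand$mapq < min_mapq_out) { dropped <- dropped + 1L; next }
    recs[[length(recs) + 1L]] <-
      annotate_record(cand, n, primary = (i == 1L), min_mapq_out)
  }
  list(records = recs, dropped = dropped)
}

pair_records <- function(pg, max_report, min_mapq_out) {
  n <- length(pg$pairs)
  keep <- seq_len(min(n, 1L + max_report))
  recs <- list(); dropped <- 0L
  for (i in keep) {
    p <- pg$pairs[[i]]
    if (p$mapq < min_mapq_out) { dropped <- dropped + 1L; next }
    for (m in list(p$mate1, p$mate2)) {
      if (isTRUE(m$synthetic)) next
      m$posterior <- p$posterior
      m$mapq <- p$mapq
      m$log_lik <- if (is.na(m$log_lik)) p$pair_log_lik else m$log_lik
      recs[[length(recs) + 1L]] <-
        annotate_record(m, n, primary = (i == 1L), min_mapq_out)
    }
  }
  list(records = recs, dropped = dropped)
}
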