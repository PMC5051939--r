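# Precision / sensitivity / FDR evaluation over mapQ cutoffs.

#' Is an alignment correct relative to its true locus?
#'
#' A mapping is correct when it is on the same reference and strand as the
#' truth and both aligned boundaries fall within 20% of the alignment
#' length of the true boundaries.
#'
#' @param rname,start,end,strand aligned locus (0-based half-open);
#'   vectorized.
#' @param truth data frame from [parse_truth()] (recycled row-wise).
#' @param L alignment length(s) used to scale the boundary tolerance.
#' @param tol boundary tolerance as a fraction of `L`.
#' @return Logical vector.
#' @examples
#' tr <- data.frame(rname = "chr1", start = 100, end = 200, strand = "+")
#' is_correct("chr1", 110, 210, "+", tr, L = 100)
#' @export
is_correct <- function(rname, start, end, strand, truth, L, tol = 0.2) {
  ok <- rname == truth$rname & strand == truth$strand &
    abs(start - truth$start) <= tol * L &
    abs(end - truth$end) <= tol * L
  ok & !is.na(ok)
}

#' Sweep mapping-quality cutoffs over evaluated primary alignments
#'
#' For each cutoff, reads whose primary alignment has `mapQ >= cutoff` are
#' judged by [is_correct()]; reads filtered out, unmapped or missing count
#' as false negatives, so TP + FP + FN equals the number of simulated reads
#' at every cutoff.
#'
#' @param results data frame with one row per simulated read: `name`,
#'   `mapped` (logical), `rname`, `start`, `end`, `strand`, `mapq`, `L`.
#' @param n_total total number of simulated reads (defaults to
#'   `nrow(results)`; pass explicitly if some reads are absent from
#'   `results`).
#' @param cutoffs mapQ thresholds to evaluate.
#' @return Data frame of class `mapq_sweep` with columns `cutoff`, `TP`,
#'   `FP`, `FN`, `precision`, `sensitivity`, `FDR`.
#' @export
sweep_mapq <- function(results, n_total = nrow(results),
                       cutoffs = c(0, 3, 6, 10, 13, 20, 30, 40, 50)) {
  truth <- parse_truth(results$name)
  correct <- results$mapped &
    is_correct(results$rname, results$start, results$end, results$strand,
               truth, results$L)
  rows <- lapply(cutoffs, function(cut) {
    kept <- results$mapped & results$mapq >= cut
    TP <- sum(kept & correct)
    FP <- sum(kept & !correct)
    FN <- n_total - TP - FP
    data.frame(cutoff = cut, TP = TP, FP = FP, FN = FN,
               precision = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
               sensitivity = TP / (TP + FN),
               FDR = if (TP + FP > 0) 1 - TP / (TP + FP) else NA_real_)
  })
  structure(do.call(rbind, rows), class = c("mapq_sweep", "data.frame"))
}

#' @export
print.mapq_sweep <- function(x, ...) {
  cat("mapQ cutoff sweep:\n")
  print.data.frame(format(x, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Summarize primary alignments of a filtered SAM set for evaluation
#'
#' Extracts, per read name, the primary alignment's locus, mapQ and
#' alignment length into the table [sweep_mapq()] consumes.
#'
#' @param sam a `sam_set` whose records carry computed MAPQ (output of
#'   [boost_alignments()]), or any name-grouped SAM.
#' @return Data frame with one row per read name.
#' @export
primary_results <- function(sam) {
  groups <- group_sam(sam)
  rows <- lapply(names(groups), function(qn) {
    recs <- groups[[qn]]
    prim <- Filter(function(r) !has_flag(r$flag, FLAG_SECONDARY) &&
                     !has_flag(r$flag, FLAG_SUPPLEMENTARY), recs)
    r <- if (length(prim)) prim[[1L]] else recs[[1L]]
    if (has_flag(r$flag, FLAG_UNMAPPED)) {
      data.frame(name = qn, mapped = FALSE, rname = NA_character_,
                 start = NA_integer_, end = NA_integer_,
                 strand = NA_character_, mapq = 0L, L = NA_integer_)
    } else {
      ct <- parse_cigar(r$cigar)
      data.frame(name = qn, mapped = TRUE, rname = r$rname,
                 start = r$pos - 1L,
                 end = r$pos - 1L + sum(ct$len[ct$op %in% OPS_REF]),
                 strand = if (has_flag(r$flag, FLAG_REVERSE)) "-" else "+",
                 mapq = r$mapq, L = sum(ct$len[ct$op != "P"]))
    }
  })
  do.call(rbind, rows)
}

#' Random-hit baseline over candidate groups
#'
#' Picks one candidate uniformly at random per read (the naive
#' multi-mapping resolution strategy) and summarizes the picks like
#' [primary_results()], for comparison against posterior-based selection.
#'
#' @param sam a name-grouped `sam_set` of all candidate alignments.
#' @return Data frame with one row per read name.
#' @export
random_results <- function(sam) {
  groups <- group_sam(sam)
  rows <- lapply(names(groups), function(qn) {
    recs <- Filter(function(r) !has_flag(r$flag, FLAG_UNMAPPED), groups[[qn]])
    if (!length(recs))
      return(data.frame(name = qn, mapped = FALSE, rname = NA_character_,
                        start = NA_integer_, end = NA_integer_,
                        strand = NA_character_, mapq = 0L, L = NA_integer_))
    r <- recs[[sample.int(length(recs), 1L)]]
    ct <- parse_cigar(r$cigar)
    data.frame(name = qn, mapped = TRUE, rname = r$rname, start = r$pos - 1L,
               end = r$pos - 1L + sum(ct$len[ct$op %in% OPS_REF]),
               strand = if (has_flag(r$flag, FLAG_REVERSE)) "-" else "+",
               mapq = 0L, L = sum(ct$len[ct$op != "P"]))
  })
  do.call(rbind, rows)
}
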