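# Maximum-scoring insert range (one-dimensional dynamic programming).
#
# Each expanded position gets a score (match reward, mismatch/gap/clip
# penalties, zero for N/P); the contiguous range maximizing the score sum is
# the estimated true insert of the read.  The recurrence
# S(i) = max(S(i-1) + A_i, 0) runs in linear time; positions outside the
# best range are soft-clipped and the record's CIGAR/MD rewritten.

#' Per-position insert scores
#'
#' @param cand a `candidate_alignment`.
#' @param config a [score_config()].
#' @return Numeric vector of per-position scores `A_i`: match `a_m`,
#'   mismatch `a_x`, gaps/clips minus their penalties, ignored positions 0
#'   (so introns bridge rather than break a range).
#' @export
position_scores <- function(cand, config = score_config()) {
  st <- cand$status
  sc <- numeric(length(st))
  sc[st == "MATCH"] <- config$match
  sc[st == "MISMATCH"] <- config$mismatch
  sc[st == "GAP_OPEN"] <- -config$gamma_open
  sc[st == "GAP_EXT"] <- -config$gamma_ext
  sc[st == "SOFT_CLIP"] <- -config$gamma_soft
  sc[st == "HARD_CLIP"] <- -config$gamma_hard
  sc
}

#' Maximum-scoring contiguous range
#'
#' Linear-time dynamic program over a score vector: returns the contiguous
#' range with the largest score sum.  An all-negative input yields the empty
#' range with score 0.  Ties are broken deterministically: leftmost start,
#' then longest range.
#'
#' @param scores numeric vector.
#' @return An object of class `insert_range`: list with `start`, `end`
#'   (0-based half-open indices) and `score`.
#' @examples
#' best_insert_range(c(1, -3, 2, 2, -1))   # [2, 4), score 4
#' @export
best_insert_range <- function(scores) {
  best_s <- 0; best_i <- 0L; best_j <- 0L
  s <- 0; cur <- 0L
  for (i in seq_along(scores)) {
    s <- s + scores[i]
    if (s < 0) {
      s <- 0
      cur <- i
    } else if (s > best_s) {
      best_s <- s; best_i <- cur; best_j <- i
    } else if (s == best_s && best_s > 0 && cur == best_i && i > best_j) {
      best_j <- i                      # same score, same start: keep longest
    }
  }
  structure(list(start = best_i, end = best_j, score = best_s),
            class = "insert_range")
}

#' @export
print.insert_range <- function(x, ...) {
  cat(sprintf("insert range [%d, %d), score %g\n", x$start, x$end, x$score))
  invisible(x)
}

#' Trim a candidate alignment to an insert range
#'
#' Read bases outside the range become soft clips; reference-consuming
#' positions outside are dropped and the start coordinate advances; CIGAR
#' and MD are rewritten consistently.  A range boundary falling inside a
#' deletion run is extended to the run boundary (a deletion cannot be half
#' kept), and leading/trailing deletions or introns inside the range are
#' trimmed off since an alignment cannot begin or end with them.  An empty
#' range marks the record unmapped.  Trimming to the full range is the
#' identity; trimming is idempotent.
#'
#' @param cand a `candidate_alignment`.
#' @param range an [best_insert_range()] result (or list with `start`/`end`).
#' @return The trimmed `candidate_alignment`.
#' @export
trim_to_insert <- function(cand, range) {
  n <- length(cand$status)
  s <- range$start; e <- range$end
  if (s < 0 || e > n || s > e) stop("invalid insert range")

  if (e > s) {
    # never cut a deletion run: shrink the range to exclude a partially
    # covered run, then strip leading/trailing non-read positions (D/N/P)
    repeat {
      changed <- FALSE
      if (s < e && cand$ops[s + 1L] == "D" && s > 0 &&
          cand$ops[s] == "D") { s <- s + 1L; changed <- TRUE }
      if (e > s && cand$ops[e] == "D" && e < n &&
          cand$ops[e + 1L] == "D") { e <- e - 1L; changed <- TRUE }
      if (s < e && is.na(cand$read_pos[s + 1L]) &&
          cand$ops[s + 1L] != "H") { s <- s + 1L; changed <- TRUE }
      if (e > s && is.na(cand$read_pos[e]) &&
          cand$ops[e] != "H") { e <- e - 1L; changed <- TRUE }
      if (!changed) break
    }
  }

  inside_ref <- seq_len(n) > s & seq_len(n) <= e & !is.na(cand$ref_pos)
  if (e <= s || !any(inside_ref)) {
    cand$unmapped <- TRUE
    cand$rec <- candidate_to_record(cand)
    return(cand)
  }

  idx <- seq_len(n)
  inside <- idx > s & idx <= e
  outside_read <- !inside & !is.na(cand$read_pos)
  keep <- inside | outside_read | cand$ops == "H"

  ops <- cand$ops
  ops[outside_read] <- "S"
  status <- cand$status
  status[outside_read] <- "SOFT_CLIP"
  # outside positions lose their reference context
  ref_base <- cand$ref_base; ref_pos <- cand$ref_pos
  ref_base[outside_read] <- NA_character_
  ref_pos[outside_read] <- NA_integer_

  new <- cand
  new$ops <- ops[keep]; new$status <- status[keep]
  new$qual <- cand$qual[keep]
  new$read_base <- cand$read_base[keep]; new$ref_base <- ref_base[keep]
  new$ref_pos <- ref_pos[keep]; new$read_pos <- cand$read_pos[keep]

  # re-derive gap-open/extension within what is kept
  gap <- new$status %in% c("GAP_OPEN", "GAP_EXT")
  if (any(gap)) {
    g <- which(gap)
    run_start <- c(TRUE, diff(g) != 1L) |
      c(TRUE, new$ops[g[-1L]] != new$ops[g[-length(g)]])
    new$status[g] <- ifelse(run_start, "GAP_OPEN", "GAP_EXT")
  }

  refc <- !is.na(new$ref_pos)
  new$start <- min(new$ref_pos[refc])
  new$end <- max(new$ref_pos[refc]) + 1L
  new$L <- sum(new$status != "IGNORED")
  new$mismatch_count <- sum(new$status == "MISMATCH")
  new$indel_count <- sum(new$status == "GAP_OPEN")
  new$unmapped <- FALSE
  new$rec <- candidate_to_record(new)
  new
}

#' Apply insert-range trimming to a candidate
#'
#' Convenience wrapper: score the positions, find the best range, trim.
#'
#' @param cand a `candidate_alignment`.
#' @param config a [score_config()].
#' @return The trimmed candidate (or the original if the full range wins).
#' @export
apply_1dp <- function(cand, config = score_config()) {
  trim_to_insert(cand, best_insert_range(position_scores(cand, config)))
}
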