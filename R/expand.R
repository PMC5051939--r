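# Per-position expansion of SAM records.
#
# A candidate alignment is the unit every likelihood and insert-range
# computation consumes: one row per expanded alignment position carrying the
# original CIGAR op, an alignment status, the base quality, the read and
# reference base (where known) and the reference coordinate.  Statuses follow
# the seven-way classification: MATCH, MISMATCH, GAP_OPEN, GAP_EXT,
# SOFT_CLIP, HARD_CLIP and IGNORED (N introns and P padding, which carry no
# likelihood contribution).

STATUS_LEVELS <- c("MATCH", "MISMATCH", "GAP_OPEN", "GAP_EXT",
                   "SOFT_CLIP", "HARD_CLIP", "IGNORED")

CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")
OPS_QUERY <- c("M", "I", "S", "=", "X")        # consume read bases
OPS_REF   <- c("M", "D", "N", "=", "X")        # consume reference bases

parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*") stop("record has no CIGAR")
  toks <- regmatches(cigar, gregexpr("\\d+[A-Z=]", cigar))[[1]]
  if (!nchar(cigar) || paste(toks, collapse = "") != cigar)
    stop("malformed CIGAR: ", cigar)
  op <- substring(toks, nchar(toks))
  if (!all(op %in% CIGAR_OPS)) stop("unknown CIGAR op in: ", cigar)
  list(op = op, len = as.integer(substring(toks, 1L, nchar(toks) - 1L)))
}

parse_md <- function(md) {
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Za-z]+|[A-Za-z]", md))[[1]]
  if (paste(toks, collapse = "") != md) stop("malformed MD tag: ", md)
  toks
}

phred_from_string <- function(qual) {
  if (qual == "*") return(NULL)
  as.integer(utf8ToInt(qual)) - 33L
}

phred_to_string <- function(q) intToUtf8(as.integer(round(q)) + 33L)

#' Expand a SAM record into a per-position candidate alignment
#'
#' Builds the per-base representation of one candidate alignment: aligned
#' positions are classified as match or mismatch using the MD tag (or `=`/`X`
#' CIGAR ops), the first base of every insertion or deletion run is
#' `GAP_OPEN` and subsequent bases `GAP_EXT`, clipped bases are `SOFT_CLIP`
#' or `HARD_CLIP`, and `N`/`P` positions are `IGNORED`.  Deleted reference
#' bases carry a synthesized quality (mean of the flanking read-base
#' qualities) and hard-clipped bases carry the per-end clip quality estimate
#' from [estimate_clip_quality()], so that the likelihood sum is total over
#' all non-ignored positions.
#'
#' @param rec a mapped SAM record (list as produced by [read_sam()]), with
#'   CIGAR and base qualities; mismatches must be resolvable through an
#'   `MD` tag or `=`/`X` CIGAR ops.
#' @param config a [penalty_config()] (supplies the clip window).
#' @return An object of class `candidate_alignment` with fields `qname`,
#'   `rname`, `start`/`end` (0-based half-open), `strand`, per-position
#'   vectors `ops`, `status`, `qual`, `read_base`, `ref_base`, `ref_pos`,
#'   `read_pos`, the alignment length `L` (non-ignored positions),
#'   `mismatch_count`, `indel_count`, `clip_qual` (per-end estimates), and
#'   slots `log_lik`, `posterior`, `mapq` filled by later stages.
#' @examples
#' rec <- list(qname = "r", flag = 0L, rname = "chr1", pos = 10L, mapq = 255L,
#'             cigar = "5M", rnext = "*", pnext = 0L, tlen = 0L,
#'             seq = "ACGTA", qual = "IIIII", tags = c(MD = "Z:5"))
#' cand <- expand_alignment(rec)
#' cand$status
#' @export
expand_alignment <- function(rec, config = penalty_config()) {
  if (has_flag(rec$flag, FLAG_UNMAPPED)) stop("record is unmapped")
  ct <- parse_cigar(rec$cigar)
  seqc <- if (rec$seq == "*") NULL else strsplit(rec$seq, "")[[1]]
  quals <- phred_from_string(rec$qual)
  qlen <- sum(ct$len[ct$op %in% OPS_QUERY])
  if (is.null(seqc) || is.null(quals))
    stop("record lacks SEQ or QUAL; cannot expand")
  if (length(seqc) != qlen || length(quals) != qlen)
    stop("CIGAR implies ", qlen, " read bases but SEQ/QUAL have ",
         length(seqc), "/", length(quals))

  n <- sum(ct$len)
  ops <- rep.int(ct$op, ct$len)
  status <- character(n)
  qual <- rep(NA_real_, n)
  read_base <- rep(NA_character_, n)
  ref_base <- rep(NA_character_, n)
  ref_pos <- rep(NA_integer_, n)
  read_pos <- rep(NA_integer_, n)

  pos0 <- rec$pos - 1L
  i <- 1L; r <- 0L; g <- pos0
  for (k in seq_along(ct$op)) {
    op <- ct$op[k]; len <- ct$len[k]; idx <- i:(i + len - 1L)
    if (op %in% c("M", "=", "X")) {
      read_pos[idx] <- r + seq_len(len)
      ref_pos[idx] <- g + seq_len(len) - 1L
      read_base[idx] <- seqc[r + seq_len(len)]
      qual[idx] <- quals[r + seq_len(len)]
      status[idx] <- if (op == "=") "MATCH" else if (op == "X") "MISMATCH"
                     else "ALIGNED"
      if (op == "=") ref_base[idx] <- read_base[idx]
      r <- r + len; g <- g + len
    } else if (op == "I") {
      read_pos[idx] <- r + seq_len(len)
      read_base[idx] <- seqc[r + seq_len(len)]
      qual[idx] <- quals[r + seq_len(len)]
      status[idx] <- c("GAP_OPEN", rep("GAP_EXT", len - 1L))
      r <- r + len
    } else if (op == "D") {
      ref_pos[idx] <- g + seq_len(len) - 1L
      status[idx] <- c("GAP_OPEN", rep("GAP_EXT", len - 1L))
      g <- g + len
    } else if (op == "N") {
      ref_pos[idx] <- g + seq_len(len) - 1L
      status[idx] <- "IGNORED"
      g <- g + len
    } else if (op == "P") {
      status[idx] <- "IGNORED"
    } else if (op == "S") {
      read_pos[idx] <- r + seq_len(len)
      read_base[idx] <- seqc[r + seq_len(len)]
      qual[idx] <- quals[r + seq_len(len)]
      status[idx] <- "SOFT_CLIP"
      r <- r + len
    } else if (op == "H") {
      status[idx] <- "HARD_CLIP"
    }
    i <- i + len
  }

  md <- get_tag(rec, "MD")
  if (!is.na(md)) {
    resolved <- apply_md(ops, status, read_base, md)
    status <- resolved$status
    ref_base <- ifelse(is.na(resolved$ref_base), ref_base, resolved$ref_base)
  } else if (any(status == "ALIGNED")) {
    stop("record has CIGAR 'M' ops but no MD tag; ",
         "cannot classify match vs mismatch (qname ", rec$qname, ")")
  }

  # synthesize deletion qualities: mean of the flanking read-base qualities
  del <- which(ops == "D")
  if (length(del)) {
    obs <- which(!is.na(read_pos))
    for (j in del) {
      lo <- obs[obs < j]; hi <- obs[obs > j]
      fl <- c(if (length(lo)) qual[max(lo)], if (length(hi)) qual[min(hi)])
      if (!length(fl)) stop("alignment has no read bases to flank a deletion")
      qual[j] <- mean(fl)
    }
  }

  cand <- structure(list(
    qname = rec$qname, rname = rec$rname, start = pos0,
    end = pos0 + sum(ct$len[ct$op %in% OPS_REF]),
    strand = if (has_flag(rec$flag, FLAG_REVERSE)) "-" else "+",
    flag = rec$flag,
    ops = ops, status = status, qual = qual,
    read_base = read_base, ref_base = ref_base,
    ref_pos = ref_pos, read_pos = read_pos,
    L = sum(status != "IGNORED"),
    mismatch_count = sum(status == "MISMATCH"),
    indel_count = sum(status == "GAP_OPEN"),
    clip_qual = c(left = NA_real_, right = NA_real_),
    log_lik = NA_real_, posterior = NA_real_, mapq = NA_integer_,
    rec = rec
  ), class = "candidate_alignment")

  if (any(ops == "H")) {
    cand$clip_qual <- estimate_clip_quality(cand, config)
    first_obs <- match(TRUE, !is.na(read_pos))
    last_obs <- length(read_pos) + 1L - match(TRUE, rev(!is.na(read_pos)))
    cand$qual[ops == "H" & seq_len(n) < first_obs] <- cand$clip_qual["left"]
    cand$qual[ops == "H" & seq_len(n) > last_obs] <- cand$clip_qual["right"]
  }
  stopifnot(!anyNA(cand$qual[cand$status != "IGNORED"]),
            all(cand$status %in% STATUS_LEVELS))
  cand
}

# Resolve 'ALIGNED' (CIGAR M) positions into MATCH/MISMATCH and recover
# reference bases at mismatches and deletions, walking the MD tokens over
# aligned (M/=/X) and deleted (D) positions in order.
apply_md <- function(ops, status, read_base, md) {
  toks <- parse_md(md)
  covered <- which(ops %in% c("M", "=", "X", "D"))
  ref_base <- rep(NA_character_, length(ops))
  p <- 1L   # index into `covered`
  for (tk in toks) {
    if (grepl("^[0-9]+$", tk)) {
      nmatch <- as.integer(tk)
      if (nmatch == 0L) next
      idx <- covered[p:(p + nmatch - 1L)]
      if (p + nmatch - 1L > length(covered) || any(ops[idx] == "D"))
        stop("MD tag inconsistent with CIGAR: ", md)
      if (any(status[idx] == "MISMATCH"))
        stop("MD match run overlaps CIGAR 'X' positions: ", md)
      status[idx][status[idx] == "ALIGNED"] <- "MATCH"
      ref_base[idx] <- read_base[idx]
      p <- p + nmatch
    } else if (startsWith(tk, "^")) {
      bases <- strsplit(substring(tk, 2L), "")[[1]]
      idx <- covered[p:(p + length(bases) - 1L)]
      if (p + length(bases) - 1L > length(covered) || any(ops[idx] != "D"))
        stop("MD deletion inconsistent with CIGAR: ", md)
      ref_base[idx] <- toupper(bases)
      p <- p + length(bases)
    } else {
      if (p > length(covered)) stop("MD tag longer than CIGAR: ", md)
      idx <- covered[p]
      if (ops[idx] == "D" || status[idx] == "MATCH")
        stop("MD mismatch inconsistent with CIGAR: ", md)
      status[idx] <- "MISMATCH"
      ref_base[idx] <- toupper(tk)
      p <- p + 1L
    }
  }
  if (p != length(covered) + 1L)
    stop("MD tag covers ", p - 1L, " of ", length(covered),
         " aligned/deleted positions: ", md)
  if (any(status == "ALIGNED"))
    stop("MD tag leaves aligned positions unresolved: ", md)
  list(status = status, ref_base = ref_base)
}

#' Estimate the base quality of hard-clipped bases
#'
#' Hard-clipped bases are absent from the stored read, so their quality is
#' unobserved.  It is estimated per clipped end as the mean phred quality of
#' up to `clip_window` observed bases immediately adjacent to that end's
#' clip; if no adjacent window exists the mean of all observed qualities is
#' used.
#'
#' @param cand a `candidate_alignment`.
#' @param config a [penalty_config()] supplying `clip_window`.
#' @return Named numeric vector `c(left = , right = )` of per-end estimates.
#' @export
estimate_clip_quality <- function(cand, config = penalty_config()) {
  obs <- which(!is.na(cand$read_pos))
  if (!length(obs)) stop("candidate has no observed bases")
  w <- config$clip_window
  qs <- cand$qual[obs]
  left <- mean(qs[seq_len(min(w, length(qs)))])
  right <- mean(qs[seq.int(max(1L, length(qs) - w + 1L), length(qs))])
  c(left = left, right = right)
}

# --- serialization -----------------------------------------------------

candidate_cigar <- function(cand) {
  r <- rle(cand$ops)
  paste0(r$lengths, r$values, collapse = "")
}

# Canonical MD per the SAMtags grammar: a number (possibly 0) precedes and
# follows every mismatch letter or ^deletion element.
candidate_md <- function(cand) {
  keep <- cand$ops %in% c("M", "=", "X", "D")
  st <- cand$status[keep]; op <- cand$ops[keep]; rb <- cand$ref_base[keep]
  out <- character(0)
  nmatch <- 0L
  j <- 1L
  while (j <= length(st)) {
    if (op[j] == "D") {
      run_end <- j
      while (run_end < length(st) && op[run_end + 1L] == "D") run_end <- run_end + 1L
      if (anyNA(rb[j:run_end])) return(NA_character_)
      out <- c(out, as.character(nmatch),
               paste0("^", paste(rb[j:run_end], collapse = "")))
      nmatch <- 0L
      j <- run_end + 1L
    } else if (st[j] == "MISMATCH") {
      if (is.na(rb[j])) return(NA_character_)
      out <- c(out, as.character(nmatch), rb[j])
      nmatch <- 0L
      j <- j + 1L
    } else {
      nmatch <- nmatch + 1L
      j <- j + 1L
    }
  }
  paste(c(out, as.character(nmatch)), collapse = "")
}

# Rebuild a SAM record from a (possibly modified) candidate.  Carries the
# original record's fields through, replacing coordinate, CIGAR, MD and NM.
candidate_to_record <- function(cand) {
  rec <- cand$rec
  rec$qname <- cand$qname
  rec$rname <- cand$rname
  rec$flag <- cand$flag
  if (isTRUE(cand$unmapped)) {
    rec$flag <- bitwOr(as.integer(rec$flag), FLAG_UNMAPPED)
    rec$pos <- 0L; rec$mapq <- 0L; rec$cigar <- "*"; rec$rname <- "*"
    rec$tags <- rec$tags[!names(rec$tags) %in% c("MD", "NM")]
    return(rec)
  }
  rec$pos <- cand$start + 1L
  rec$cigar <- candidate_cigar(cand)
  keep <- !is.na(cand$read_pos)
  ord <- order(cand$read_pos[keep])
  rb <- cand$read_base[keep][ord]
  rec$seq <- paste(rb, collapse = "")
  rec$qual <- phred_to_string(cand$qual[keep][ord])
  md <- candidate_md(cand)
  if (!is.na(md)) rec <- set_tag(rec, "MD", "Z", md)
  rec <- set_tag(rec, "NM", "i",
                 cand$mismatch_count + sum(cand$ops %in% c("I", "D")))
  rec
}

# Internal validity checks used by tests and the writer: CIGAR/SEQ length
# agreement and MD consistency under re-expansion.
validate_sam_record <- function(rec, config = penalty_config()) {
  if (has_flag(rec$flag, FLAG_UNMAPPED)) {
    if (rec$cigar != "*") stop("unmapped record with CIGAR")
    return(invisible(TRUE))
  }
  ct <- parse_cigar(rec$cigar)
  qlen <- sum(ct$len[ct$op %in% OPS_QUERY])
  if (rec$seq != "*" && nchar(rec$seq) != qlen)
    stop("SEQ length ", nchar(rec$seq), " != CIGAR query length ", qlen)
  if (!grepl("^H?S?[MIDNP=X]+S?H?$", paste(ct$op, collapse = "")))
    stop("clips must be at alignment ends: ", rec$cigar)
  cand <- expand_alignment(rec, config)   # errors on MD inconsistency
  invisible(TRUE)
}

#' @export
print.candidate_alignment <- function(x, ...) {
  cat(sprintf("candidate %s @ %s:%d-%d(%s) L=%d mism=%d indel=%d",
              x$qname, x$rname, x$start, x$end, x$strand, x$L,
              x$mismatch_count, x$indel_count))
  if (!is.na(x$log_lik)) cat(sprintf(" logLik=%.4f", x$log_lik))
  if (!is.na(x$posterior)) cat(sprintf(" post=%.4f mapQ=%d", x$posterior, x$mapq))
  cat("\n")
  invisible(x)
}
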