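# Shared fixture builders and independent oracles.

qs <- function(q, n = 1L) remapq:::phred_to_string(rep(q, n))

make_rec <- function(qname = "r", flag = 0L, rname = "chr1", pos = 1L,
                     cigar = "5M", seq = "ACGTA", qual = NULL, md = NULL,
                     tags = character(0)) {
  if (is.null(qual)) qual <- qs(30L, nchar(seq))
  if (!is.null(md)) tags <- c(tags, MD = paste0("Z:", md))
  list(qname = qname, flag = as.integer(flag), rname = rname,
       pos = as.integer(pos), mapq = 255L, cigar = cigar, rnext = "*",
       pnext = 0L, tlen = 0L, seq = seq, qual = qual, tags = tags)
}

# Minimal candidate stub: enough for likelihood/posterior arithmetic.
stub_cand <- function(status, qual, qname = "r", rname = "chr1", start = 0L,
                      strand = "+", log_lik = NA_real_) {
  structure(list(qname = qname, rname = rname, start = as.integer(start),
                 end = as.integer(start + length(status)), strand = strand,
                 status = status, qual = qual, L = sum(status != "IGNORED"),
                 log_lik = log_lik, posterior = NA_real_),
            class = "candidate_alignment")
}

rand_stub <- function(len) {
  st <- sample(c("MATCH", "MISMATCH", "GAP_OPEN", "GAP_EXT", "SOFT_CLIP",
                 "HARD_CLIP", "IGNORED"), len, replace = TRUE,
               prob = c(0.6, 0.1, 0.05, 0.05, 0.1, 0.05, 0.05))
  stub_cand(st, sample(2:41, len, replace = TRUE))
}

# Independent per-position summation oracle for the log10 likelihood.
naive_loglik <- function(cand, cfg = penalty_config()) {
  tot <- 0
  for (j in seq_along(cand$status)) {
    q <- cand$qual[j]
    tot <- tot + switch(cand$status[j],
      MATCH = log10(1 - 10^(-q / 10)),
      MISMATCH = -q / 10,
      GAP_OPEN = -q / 10 - cfg$gamma_open,
      GAP_EXT = -q / 10 - cfg$gamma_ext,
      SOFT_CLIP = -q / 10 - cfg$gamma_soft,
      HARD_CLIP = -q / 10 - cfg$gamma_hard,
      IGNORED = 0)
  }
  tot
}

# Exhaustive O(n^2) maximum-subrange oracle with the leftmost-then-longest
# tie rule; empty range scores 0.
brute_best_range <- function(scores) {
  n <- length(scores)
  best <- list(start = 0L, end = 0L, score = 0)
  for (i in seq_len(n)) {
    s <- 0
    for (j in i:n) {
      s <- s + scores[j]
      better <- s > best$score ||
        (s == best$score && s > 0 &&
           (i - 1L < best$start ||
              (i - 1L == best$start && j > best$end)))
      if (better) best <- list(start = i - 1L, end = j, score = s)
    }
  }
  best
}

# Naive linear-space single-end posterior (direct formula).
brute_se_posteriors <- function(L, ll) {
  w <- L * 10^ll
  w / sum(w)
}

# Build a random mapped record consistent with a reference string: plant
# substitutions/indels/clips, return the record (MD included).  Used by the
# round-trip and trimming property tests.
random_record <- function(ref_chars, id = "r", maxlen = 60L) {
  n <- length(ref_chars)
  alen <- sample(20:maxlen, 1L)
  start <- sample.int(n - alen - 10L, 1L)
  ref <- ref_chars[start:(start + alen - 1L)]
  read <- ref
  status <- rep("M", alen)
  nmut <- sample(0:3, 1L)
  if (nmut > 0) {
    for (p in sample(2:(alen - 1L), nmut)) {
      read[p] <- sample(setdiff(c("A", "C", "G", "T"), ref[p]), 1L)
    }
  }
  # optional deletion (drop read bases) or insertion (extra read bases)
  ops <- NULL
  segs <- list()
  mk_md <- function(ref, read) {
    # matches/mismatch/deletion walk is done by the package on expansion;
    # here build MD directly for an ungapped block
    out <- character(0); cnt <- 0L
    for (k in seq_along(ref)) {
      if (ref[k] == read[k]) cnt <- cnt + 1L
      else { out <- c(out, as.character(cnt), ref[k]); cnt <- 0L }
    }
    paste(c(out, as.character(cnt)), collapse = "")
  }
  kind <- sample(c("plain", "del", "ins", "clip"), 1L)
  if (kind == "plain") {
    cigar <- paste0(alen, "M")
    md <- mk_md(ref, read)
    seqs <- read
  } else if (kind == "del") {
    cut <- sample(5:(alen - 6L), 1L); dlen <- sample(1:3, 1L)
    keep <- setdiff(seq_len(alen), cut:(cut + dlen - 1L))
    seqs <- read[keep]
    left <- sum(keep < cut)
    cigar <- paste0(left, "M", dlen, "D", alen - left - dlen, "M")
    md <- paste0(mk_md(ref[keep[seq_len(left)]], read[keep[seq_len(left)]]),
                 "^", paste(ref[cut:(cut + dlen - 1L)], collapse = ""),
                 mk_md(ref[keep[-seq_len(left)]], read[keep[-seq_len(left)]]))
  } else if (kind == "ins") {
    cut <- sample(5:(alen - 6L), 1L); ilen <- sample(1:3, 1L)
    seqs <- c(read[seq_len(cut)], sample(c("A", "C", "G", "T"), ilen,
                                         replace = TRUE),
              read[(cut + 1L):alen])
    cigar <- paste0(cut, "M", ilen, "I", alen - cut, "M")
    md <- mk_md(ref, read)
  } else {
    cl <- sample(1:4, 1L); cr <- sample(1:4, 1L)
    seqs <- c(sample(c("A", "C", "G", "T"), cl, replace = TRUE), read,
              sample(c("A", "C", "G", "T"), cr, replace = TRUE))
    cigar <- paste0(cl, "S", alen, "M", cr, "S")
    md <- mk_md(ref, read)
  }
  make_rec(qname = id, rname = "chrT", pos = start,
           cigar = cigar, seq = paste(seqs, collapse = ""),
           qual = remapq:::phred_to_string(sample(2:41, length(seqs),
                                                  replace = TRUE)),
           md = md)
}
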