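# Small reference aligner for fixtures and simulation studies.
#
# Reports every locus (both strands) where a read aligns with at most
# `max_edits` edits, as name-grouped SAM records with CIGAR and MD tags.
# The search is seed-and-extend with an exhaustiveness guarantee by the
# pigeonhole principle: each read is split into at least `max_edits + 1`
# disjoint segments, so any alignment with <= max_edits edits contains at
# least one segment matching the reference exactly.  All exact segment hits
# are found in one pass per chromosome (Biostrings::matchPDict), and each
# implied locus is verified -- by direct comparison when ungapped, or by a
# windowed pairwise alignment when indels are involved.  Intended for small
# references (up to ~1 Mb); it is a test instrument, not a production
# aligner.

#' Align reads exhaustively against a small reference
#'
#' @param reads a `sim_reads` data frame (columns `name`, `seq`, `qual`),
#'   or a named character vector of sequences (qualities then default to
#'   phred 40).
#' @param genome a [Biostrings::DNAStringSet].
#' @param max_edits maximum edit distance (substitutions + inserted +
#'   deleted bases) of a reported alignment.  Every locus with at most this
#'   many edits is reported, including the true one for simulated reads
#'   whose accumulated errors stay within the bound.
#' @return A `sam_set` (see [read_sam()]): name-grouped records, one
#'   primary per read (fewest edits, then leftmost), additional hits
#'   flagged secondary, reads without any hit emitted as unmapped.
#' @examples
#' genome <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGTTGCA", 30)))
#' toy_align(c(r1 = "ACGTTGCAACGTTGCAACGTTGCA"), genome)$records[[1]]$cigar
#' @export
toy_align <- function(reads, genome, max_edits = 3L) {
  if (is.character(reads))
    reads <- data.frame(name = names(reads), seq = unname(reads),
                        qual = strrep("I", nchar(reads)))
  n <- nrow(reads)
  k <- as.integer(max_edits)
  seqs <- toupper(reads$seq)
  lens <- nchar(seqs)
  rcseqs <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
  segw <- min(lens %/% (k + 1L))
  if (segw < 5L)
    stop("reads too short to guarantee exhaustive search at max_edits = ", k)

  # one constant-width segment dictionary over both strands of every read
  seg_seq <- character(0); seg_read <- integer(0)
  seg_off <- integer(0); seg_strand <- character(0)
  for (i in seq_len(n)) {
    nseg <- lens[i] %/% segw
    offs <- (seq_len(nseg) - 1L) * segw
    for (str in c("+", "-")) {
      src <- if (str == "+") seqs[i] else rcseqs[i]
      seg_seq <- c(seg_seq, substring(src, offs + 1L, offs + segw))
      seg_read <- c(seg_read, rep(i, nseg))
      seg_off <- c(seg_off, offs)
      seg_strand <- c(seg_strand, rep(str, nseg))
    }
  }
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seg_seq))

  # candidate read-start loci per (read, strand, chromosome)
  cands <- new.env(parent = emptyenv(), hash = TRUE)
  for (ci in seq_along(genome)) {
    hits <- Biostrings::matchPDict(pd, genome[[ci]])
    st <- Biostrings::startIndex(hits)
    for (h in which(lengths(st) > 0L)) {
      key <- paste0(seg_read[h], "|", seg_strand[h], "|", ci)
      cands[[key]] <- c(cands[[key]], st[[h]] - 1L - seg_off[h])
    }
  }

  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  chr_chars <- lapply(genome, function(x) strsplit(as.character(x), "")[[1]])
  chr_names <- names(genome)
  alphabet4 <- c("A", "C", "G", "T")

  records <- vector("list", n)
  for (i in seq_len(n)) {
    hits <- list()
    for (str in c("+", "-")) {
      qseq <- if (str == "+") seqs[i] else rcseqs[i]
      qchars <- strsplit(qseq, "")[[1]]
      L <- lens[i]
      for (ci in seq_along(genome)) {
        key <- paste0(i, "|", str, "|", ci)
        starts <- cands[[key]]
        if (is.null(starts)) next
        starts <- sort(unique(starts))
        # cluster starts within k bases: shifted seeds of one indel locus
        cl <- cumsum(c(TRUE, diff(starts) > k))
        for (s0 in starts[!duplicated(cl)]) {
          aln <- verify_locus(qchars, qseq, chr_chars[[ci]], genome[[ci]],
                              s0, L, k, submat)
          if (is.null(aln)) next
          aln$rname <- chr_names[ci]; aln$strand <- str
          hits[[length(hits) + 1L]] <- aln
        }
      }
    }
    records[[i]] <- hits_to_records(hits, reads$name[i], seqs[i], rcseqs[i],
                                    reads$qual[i])
  }
  structure(list(
    header = c("@HD\tVN:1.6\tSO:queryname",
               sprintf("@SQ\tSN:%s\tLN:%d", chr_names,
                       Biostrings::width(genome))),
    records = do.call(c, records)
  ), class = "sam_set")
}

# Verify one candidate locus; returns NULL or a list with pos (0-based),
# ops/status/ref_base vectors (for MD), cigar and edit count.
verify_locus <- function(qchars, qseq, gchars, gdna, s0, L, k, submat) {
  glen <- length(gchars)
  if (s0 >= 0L && s0 + L <= glen) {
    ref <- gchars[(s0 + 1L):(s0 + L)]
    mm <- qchars != ref
    if (sum(mm) <= k) {
      return(list(pos = s0, cigar = paste0(L, "M"),
                  md = md_from_vectors(rep("M", L),
                                       ifelse(mm, "MISMATCH", "MATCH"), ref),
                  edits = sum(mm), nm = sum(mm)))
    }
  }
  lo <- max(0L, s0 - k); hi <- min(glen, s0 + L + k)
  if (hi - lo < L - k) return(NULL)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(qseq), Biostrings::subseq(gdna, lo + 1L, hi),
    type = "global-local", substitutionMatrix = submat,
    gapOpening = 0, gapExtension = 1)
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ops <- ifelse(pat == "-", "D", ifelse(sub == "-", "I", "M"))
  status <- ifelse(ops == "D" | ops == "I", "GAP",
                   ifelse(pat == sub, "MATCH", "MISMATCH"))
  edits <- sum(status == "MISMATCH") + sum(ops != "M")
  if (edits > k) return(NULL)
  cig <- rle(ops)
  list(pos = lo + BiocGenerics::start(Biostrings::subject(pa)) - 1L,
       cigar = paste0(cig$lengths, cig$values, collapse = ""),
       md = md_from_vectors(ops, status, sub),
       edits = edits, nm = edits)
}

# Canonical MD from per-position ops / match status / reference bases
# (insertions are skipped; deletions emit ^bases).
md_from_vectors <- function(ops, status, ref) {
  keep <- ops != "I"
  ops <- ops[keep]; status <- status[keep]; ref <- ref[keep]
  out <- character(0); nmatch <- 0L; j <- 1L
  while (j <= length(ops)) {
    if (ops[j] == "D") {
      e <- j
      while (e < length(ops) && ops[e + 1L] == "D") e <- e + 1L
      out <- c(out, as.character(nmatch),
               paste0("^", paste(ref[j:e], collapse = "")))
      nmatch <- 0L; j <- e + 1L
    } else if (status[j] == "MISMATCH") {
      out <- c(out, as.character(nmatch), ref[j])
      nmatch <- 0L; j <- j + 1L
    } else {
      nmatch <- nmatch + 1L; j <- j + 1L
    }
  }
  paste(c(out, as.character(nmatch)), collapse = "")
}

hits_to_records <- function(hits, name, seq, rcseq, qual) {
  if (!length(hits)) {
    return(list(list(qname = name, flag = FLAG_UNMAPPED, rname = "*",
                     pos = 0L, mapq = 0L, cigar = "*", rnext = "*",
                     pnext = 0L, tlen = 0L, seq = seq, qual = qual,
                     tags = character(0))))
  }
  # drop duplicate final loci (several seed clusters converging)
  sig <- vapply(hits, function(h)
    paste(h$rname, h$pos, h$cigar, h$strand), "")
  hits <- hits[!duplicated(sig)]
  ord <- order(vapply(hits, `[[`, 0L, "edits"),
               vapply(hits, `[[`, "", "rname"),
               vapply(hits, `[[`, 0L, "pos"),
               vapply(hits, `[[`, "", "strand"))
  hits <- hits[ord]
  lapply(seq_along(hits), function(j) {
    h <- hits[[j]]
    flag <- 0L
    if (h$strand == "-") flag <- bitwOr(flag, FLAG_REVERSE)
    if (j > 1L) flag <- bitwOr(flag, FLAG_SECONDARY)
    list(qname = name, flag = flag, rname = h$rname, pos = h$pos + 1L,
         mapq = 255L, cigar = h$cigar, rnext = "*", pnext = 0L, tlen = 0L,
         seq = if (h$strand == "-") rcseq else seq,
         qual = if (h$strand == "-") reverse_string(qual) else qual,
         tags = c(MD = paste0("Z:", h$md), NM = paste0("i:", h$nm)))
  })
}

reverse_string <- function(x)
  paste(rev(strsplit(x, "")[[1]]), collapse = "")
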