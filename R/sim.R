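# Synthetic NGS read simulation.
#
# The generator mimics an Illumina-like error profile: fragments are drawn
# from uniform genomic locations with truncated-Gaussian sizes, base
# qualities are Gaussian around a fixed seed-region mean that decays
# linearly afterwards, and reads are then mutated (substitution, insertion,
# deletion) with per-base probability equal to the error probability implied
# by their own quality.  The true locus of every read is encoded losslessly
# in its name, so no sidecar truth file is needed.

#' Simulation configuration
#'
#' @param read_length read length in bp.
#' @param paired simulate read pairs (one read from each fragment end).
#' @param region_size_mean,region_size_sd mean/sd (bp) of the truncated
#'   Gaussian fragment-size distribution.
#' @param region_size_min,region_size_max truncation bounds (bp); the lower
#'   bound must be at least `read_length`.
#' @param seed_length length (bp) of the high-quality seed region.
#' @param seed_quality_mean mean phred quality within the seed.
#' @param quality_decay linear drop in mean quality (phred per base) after
#'   the seed.
#' @param quality_sd per-base quality standard deviation (phred).
#' @param quality_min,quality_max clamp bounds for drawn qualities.
#' @param sub_fraction,ins_fraction,del_fraction how a mutation event splits
#'   into substitution/insertion/deletion; must sum to 1.
#' @param seed optional RNG seed applied by [simulate_reads()] for
#'   reproducible datasets.
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(read_length = 75, seed = 1)
#' @export
sim_config <- function(read_length = 100L, paired = FALSE,
                       region_size_mean = 300, region_size_sd = 50,
                       region_size_min = 150, region_size_max = 600,
                       seed_length = 25L, seed_quality_mean = 30,
                       quality_decay = 0.1, quality_sd = 3,
                       quality_min = 2L, quality_max = 41L,
                       sub_fraction = 0.90, ins_fraction = 0.05,
                       del_fraction = 0.05, seed = NULL) {
  fr <- c(sub_fraction, ins_fraction, del_fraction)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9)
    stop("mutation fractions must be non-negative and sum to 1")
  if (region_size_min < read_length)
    stop("region_size_min must be >= read_length")
  if (region_size_min > region_size_max || region_size_min <= 0)
    stop("invalid region size truncation bounds")
  structure(list(
    read_length = as.integer(read_length), paired = isTRUE(paired),
    region_size_mean = region_size_mean, region_size_sd = region_size_sd,
    region_size_min = region_size_min, region_size_max = region_size_max,
    seed_length = as.integer(seed_length),
    seed_quality_mean = seed_quality_mean, quality_decay = quality_decay,
    quality_sd = quality_sd, quality_min = quality_min,
    quality_max = quality_max,
    sub_fraction = sub_fraction, ins_fraction = ins_fraction,
    del_fraction = del_fraction, seed = seed
  ), class = "sim_config")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n - length(out), mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out
}

#' Sample random genomic regions
#'
#' Draws `n` intervals with uniformly distributed locations and
#' truncated-Gaussian sizes, either genome-wide (chromosomes weighted by
#' length) or restricted to supplied feature intervals.
#'
#' @param genome a [Biostrings::DNAStringSet] of reference sequences.
#' @param n number of regions.
#' @param config a [sim_config()].
#' @param features optional data frame with columns `rname`, `start`, `end`
#'   (0-based half-open) restricting where regions may fall; features
#'   shorter than the sampled size are not used, and it is an error if no
#'   feature can hold even the minimum region size.
#' @return Data frame with columns `rname`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @export
sample_regions <- function(genome, n, config = sim_config(),
                           features = NULL) {
  if (!length(genome) || n == 0L)
    return(data.frame(rname = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  sizes <- round(rtrunc_norm(n, config$region_size_mean,
                             config$region_size_sd,
                             config$region_size_min, config$region_size_max))
  chrlen <- Biostrings::width(genome)
  names(chrlen) <- names(genome)
  if (is.null(features)) {
    features <- data.frame(rname = names(genome), start = 0L, end = chrlen)
  }
  fwidth <- features$end - features$start
  if (max(fwidth) < config$region_size_min)
    stop("no feature interval can hold the minimum region size")
  rname <- character(n); start <- integer(n)
  for (i in seq_len(n)) {
    ok <- which(fwidth >= sizes[i])
    if (!length(ok)) {                 # resample a size that fits somewhere
      sizes[i] <- max(fwidth)
      ok <- which(fwidth >= sizes[i])
    }
    f <- ok[sample.int(length(ok), 1L, prob = fwidth[ok])]
    rname[i] <- features$rname[f]
    start[i] <- features$start[f] +
      sample.int(fwidth[f] - sizes[i] + 1L, 1L) - 1L
  }
  data.frame(rname = rname, start = start, end = start + sizes,
             strand = sample(c("+", "-"), n, replace = TRUE))
}

#' Simulate positional base qualities
#'
#' Quality at position `j` is Gaussian with standard deviation `quality_sd`
#' around a mean that is `seed_quality_mean` within the seed region and
#' decays linearly by `quality_decay` per base afterwards; draws are clamped
#' to `[quality_min, quality_max]` and rounded to integer phred scores.
#' Forward and reverse reads draw independently.
#'
#' @param read_length read length.
#' @param config a [sim_config()].
#' @return Integer phred vector of length `read_length`.
#' @export
simulate_qualities <- function(read_length, config = sim_config()) {
  j <- seq_len(read_length)
  mean_j <- ifelse(j <= config$seed_length, config$seed_quality_mean,
                   config$seed_quality_mean -
                     config$quality_decay * (j - config$seed_length))
  q <- stats::rnorm(read_length, mean_j, config$quality_sd)
  as.integer(round(pmin(pmax(q, config$quality_min), config$quality_max)))
}

#' Mutate a read according to its base qualities
#'
#' Each base mutates with probability `q2p(Q_j)`; an event is a
#' substitution, insertion or deletion with the configured fractions.
#' Substitutions pick uniformly among the three other bases; insertions add
#' a random base after the position (its quality copied); deletions drop
#' the base and its quality.
#'
#' @param seq character scalar (read sequence).
#' @param qual integer phred vector, same length as `seq`.
#' @param config a [sim_config()].
#' @return List with `seq`, `qual`, and event counts `n_sub`, `n_ins`,
#'   `n_del`.
#' @export
mutate_read <- function(seq, qual, config = sim_config()) {
  bases <- strsplit(seq, "")[[1]]
  stopifnot(length(bases) == length(qual))
  hit <- stats::runif(length(bases)) < q2p(qual)
  n_sub <- n_ins <- n_del <- 0L
  if (any(hit)) {
    out_b <- as.list(bases); out_q <- as.list(qual)
    types <- sample(c("sub", "ins", "del"), sum(hit), replace = TRUE,
                    prob = c(config$sub_fraction, config$ins_fraction,
                             config$del_fraction))
    alphabet <- c("A", "C", "G", "T")
    for (k in seq_along(which(hit))) {
      j <- which(hit)[k]
      if (types[k] == "sub") {
        out_b[[j]] <- sample(setdiff(alphabet, bases[j]), 1L)
        n_sub <- n_sub + 1L
      } else if (types[k] == "ins") {
        out_b[[j]] <- c(bases[j], sample(alphabet, 1L))
        out_q[[j]] <- c(qual[j], qual[j])
        n_ins <- n_ins + 1L
      } else {
        out_b[[j]] <- character(0)
        out_q[[j]] <- integer(0)
        n_del <- n_del + 1L
      }
    }
    bases <- unlist(out_b); qual <- unlist(out_q)
  }
  list(seq = paste(bases, collapse = ""), qual = as.integer(qual),
       n_sub = n_sub, n_ins = n_ins, n_del = n_del)
}

encode_truth <- function(id, rname, start, end, strand)
  sprintf("%s:%s:%d-%d:%s", id, rname, start, end, strand)

#' Parse the true locus encoded in a simulated read name
#'
#' Read names carry `id:rname:start-end:strand` (0-based half-open), the
#' interval the read was extracted from before mutation.
#'
#' @param name read name(s).
#' @return Data frame with columns `rname`, `start`, `end`, `strand` (`NA`
#'   rows for names that do not encode a truth).
#' @export
parse_truth <- function(name) {
  m <- regmatches(name,
                  regexec("^.*:([^:]+):([0-9]+)-([0-9]+):([+-])$", name))
  bad <- lengths(m) != 5L
  get <- function(i) vapply(m, function(x) if (length(x) == 5L) x[i + 1L]
                            else NA_character_, "")
  data.frame(rname = get(1), start = as.integer(get(2)),
             end = as.integer(get(3)), strand = get(4))
}

#' Simulate reads from a reference
#'
#' Runs the full generation procedure: sample fragment regions
#' ([sample_regions()]), extract single-end reads (or a pair, one read from
#' each fragment end) of `read_length`, draw positional qualities
#' ([simulate_qualities()]) and mutate ([mutate_read()]).  For a `-` strand
#' fragment the read sequence is the reverse complement.  Read names encode
#' the true (pre-mutation) genomic interval and strand of each read; for
#' pairs, mate 1 is the fragment's 5' read and mate 2 the 3' read on the
#' opposite strand, each carrying its own truth interval.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param n number of fragments.
#' @param config a [sim_config()]; if `config$seed` is set the RNG is
#'   seeded, making output fully deterministic.
#' @param features optional feature intervals (see [sample_regions()]).
#' @return Data frame with columns `name`, `seq`, `qual` (phred+33 string)
#'   and, when paired, `seq2`/`qual2`; class `sim_reads`.
#' @export
simulate_reads <- function(genome, n, config = sim_config(),
                           features = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  regions <- sample_regions(genome, n, config, features)
  rl <- config$read_length
  one_read <- function(rname, rs, re, strand, id) {
    if (strand == "+") { s <- rs; e <- rs + rl } else { s <- re - rl; e <- re }
    frag <- as.character(Biostrings::subseq(genome[[rname]], s + 1L, e))
    if (strand == "-")
      frag <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(frag)))
    q <- simulate_qualities(rl, config)
    mut <- mutate_read(frag, q, config)
    list(name = encode_truth(id, rname, s, e, strand),
         seq = mut$seq, qual = phred_to_string(mut$qual))
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    r <- regions[i, ]
    id <- sprintf("sim%06d", i)
    if (!config$paired) {
      out[[i]] <- one_read(r$rname, r$start, r$end, r$strand, id)
    } else {
      m1 <- one_read(r$rname, r$start, r$end, r$strand, id)
      flip <- if (r$strand == "+") "-" else "+"
      m2 <- one_read(r$rname, r$start, r$end, flip, id)
      out[[i]] <- list(name = m1$name, seq = m1$seq, qual = m1$qual,
                       name2 = m2$name, seq2 = m2$seq, qual2 = m2$qual)
    }
  }
  df <- do.call(rbind, lapply(out, function(x) as.data.frame(x)))
  class(df) <- c("sim_reads", class(df))
  df
}

#' Write simulated reads to FASTQ
#'
#' @param reads a `sim_reads` data frame from [simulate_reads()].
#' @param path output FASTQ path (single-end / mate 1).
#' @param path2 output path for mate 2 when paired.
#' @return The path(s), invisibly.
#' @export
write_sim_fastq <- function(reads, path, path2 = NULL) {
  fq <- function(names, seqs, quals, p) {
    writeLines(as.vector(rbind(paste0("@", names), seqs, "+", quals)), p)
  }
  fq(reads$name, reads$seq, reads$qual, path)
  if (!is.null(reads$seq2)) {
    if (is.null(path2)) stop("paired reads need path2")
    fq(reads$name2, reads$seq2, reads$qual2, path2)
    return(invisible(c(path, path2)))
  }
  invisible(path)
}

#' Generate a synthetic genome with planted duplications
#'
#' Builds one random chromosome and plants `n_dup` duplicated segments:
#' each source segment is copied to a random non-overlapping destination
#' with per-base substitution rate `1 - identity`, creating the ambiguous
#' multi-mapping structure repetitive genomes exhibit.
#'
#' @param size chromosome length (bp).
#' @param n_dup number of duplicated segments.
#' @param dup_len segment length (bp).
#' @param identity sequence identity between copies (e.g. 0.95).
#' @return A [Biostrings::DNAStringSet] with one sequence named `chr1`.
#' @export
sim_genome <- function(size = 200000L, n_dup = 10L, dup_len = 2000L,
                       identity = 0.95) {
  alphabet <- c("A", "C", "G", "T")
  g <- sample(alphabet, size, replace = TRUE)
  if (n_dup > 0L) {
    # one block per copy keeps segments non-overlapping by construction
    block <- size %/% (2L * n_dup)
    if (block <= dup_len) stop("genome too small for the requested duplications")
    offs <- sample.int(block - dup_len, 2L * n_dup, replace = TRUE)
    sel <- (seq_len(2L * n_dup) - 1L) * block + offs
    ord <- sample.int(2L * n_dup)      # random pairing of blocks
    src <- sel[ord[seq_len(n_dup)]]
    dst <- sel[ord[n_dup + seq_len(n_dup)]]
    for (k in seq_len(n_dup)) {
      seg <- g[src[k]:(src[k] + dup_len - 1L)]
      mut <- stats::runif(dup_len) > identity
      seg[mut] <- vapply(seg[mut],
                         function(b) sample(setdiff(alphabet, b), 1L), "")
      g[dst[k]:(dst[k] + dup_len - 1L)] <- seg
    }
  }
  Biostrings::DNAStringSet(stats::setNames(paste(g, collapse = ""), "chr1"))
}
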