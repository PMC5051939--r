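test_that("phred conversion and allele-frequency penalty closed forms", {
  expect_equal(q2p(c(0, 10, 30)), c(1, 0.1, 0.001))
  expect_error(q2p(-1), ">= 0")
  expect_equal(af_penalty(1), 0)
  expect_equal(af_penalty(0.1), 1)
  expect_equal(af_penalty(0.5), 0.30103, tolerance = 1e-5)
  expect_error(af_penalty(0), "\\(0, 1\\]")
  expect_error(af_penalty(1.2), "\\(0, 1\\]")
})

test_that("log likelihood matches hand-computed cases", {
  cfg <- penalty_config()
  expect_equal(log_likelihood(stub_cand("MISMATCH", 20), cfg,
                              value_only = TRUE), -2)
  expect_equal(log_likelihood(stub_cand(rep("MATCH", 10), rep(20, 10)), cfg,
                              value_only = TRUE),
               10 * log10(0.99), tolerance = 1e-12)
  expect_equal(log_likelihood(stub_cand("GAP_OPEN", 20), cfg,
                              value_only = TRUE), -4)  # -2 - gamma_open
  # ignored positions contribute nothing
  expect_equal(log_likelihood(stub_cand(c("MATCH", "IGNORED"), c(30, 30)),
                              cfg, value_only = TRUE),
               log10(1 - 0.001))
})

test_that("log likelihood equals the naive per-position oracle", {
  set.seed(202)
  cfg <- penalty_config(gamma_open = 2.5, gamma_ext = 0.7, gamma_soft = 1.3,
                        gamma_hard = 0.9)
  for (i in 1:200) {
    cand <- rand_stub(sample(1:100, 1))
    expect_equal(log_likelihood(cand, cfg, value_only = TRUE),
                 naive_loglik(cand, cfg), tolerance = 1e-12)
  }
})

test_that("likelihood is negative, permutation-invariant, and one extra mismatch costs Q/10 plus the lost match term", {
  set.seed(203)
  cfg <- penalty_config()
  for (i in 1:50) {
    cand <- rand_stub(sample(5:80, 1))
    ll <- log_likelihood(cand, cfg, value_only = TRUE)
    expect_lt(ll, 0)
    perm <- sample(length(cand$status))
    shuffled <- stub_cand(cand$status[perm], cand$qual[perm])
    expect_equal(log_likelihood(shuffled, cfg, value_only = TRUE), ll,
                 tolerance = 1e-12)
    q <- sample(2:41, 1)
    more <- stub_cand(c(cand$status, "MISMATCH"), c(cand$qual, q))
    fewer <- stub_cand(c(cand$status, "MATCH"), c(cand$qual, q))
    expect_equal(log_likelihood(more, cfg, value_only = TRUE) -
                   log_likelihood(fewer, cfg, value_only = TRUE),
                 -q / 10 - log10(1 - q2p(q)), tolerance = 1e-12)
  }
})

# A 9-base reference 'ACGTACGTA' on chrV, alignment starting at position 11
# (1-based), read carrying a G where the reference has an A at offset 4.
va_fixture <- function(read = "ACGTGCGTA", md = "4A4", qual = qs(30, 9),
                       cigar = "9M") {
  expand_alignment(make_rec(rname = "chrV", pos = 11, cigar = cigar,
                            seq = read, qual = qual, md = md))
}

test_that("a known SNV absolves a matching mismatch", {
  cand <- va_fixture()
  cfg <- penalty_config()
  plain <- log_likelihood(cand, cfg, value_only = TRUE)
  # SNV at 0-based 14 with matching alt and AF 0.5
  idx <- variant_index(data.frame(rname = "chrV", pos = 15, ref = "A",
                                  alt = "G", af = 0.5))
  va <- log_likelihood_variant_aware(cand, idx, cfg, value_only = TRUE)
  # mismatch term -3.0 replaced by lg(1-0.001) - (-lg 0.5)
  expect_equal(va - plain, (log10(1 - 0.001) - 0.30103) - (-3),
               tolerance = 1e-5)

  # no AF: flat gamma_snp
  idx2 <- variant_index(data.frame(rname = "chrV", pos = 15, ref = "A",
                                   alt = "G"))
  va2 <- log_likelihood_variant_aware(cand, idx2, cfg, value_only = TRUE)
  expect_equal(va2 - plain, (log10(1 - 0.001) - cfg$gamma_snp) - (-3),
               tolerance = 1e-9)

  # non-matching alt allele leaves the likelihood unchanged
  idx3 <- variant_index(data.frame(rname = "chrV", pos = 15, ref = "A",
                                   alt = "C"))
  expect_equal(log_likelihood_variant_aware(cand, idx3, cfg,
                                            value_only = TRUE), plain)

  # REF disagreeing with the MD-implied base: skipped with a warning
  idx4 <- variant_index(data.frame(rname = "chrV", pos = 15, ref = "T",
                                   alt = "G"))
  expect_warning(va4 <- log_likelihood_variant_aware(cand, idx4, cfg,
                                                     value_only = TRUE),
                 "REF")
  expect_equal(va4, plain)
})

test_that("strict-literal mode reduces to the plain likelihood for SNVs", {
  cand <- va_fixture()
  cfg <- penalty_config()
  idx <- variant_index(data.frame(rname = "chrV", pos = 15, ref = "A",
                                  alt = "G", af = 0.5))
  expect_equal(log_likelihood_variant_aware(cand, idx, cfg,
                                            strict_literal = TRUE,
                                            value_only = TRUE),
               log_likelihood(cand, cfg, value_only = TRUE))
})

test_that("known indels replace the gap penalties with a single gamma", {
  cfg <- penalty_config()          # gamma_open 2, gamma_ext 1, gamma_indel 2
  # insertion of 'TT' after 3 aligned bases; alignment starts at 1-based 21
  cand <- expand_alignment(make_rec(rname = "chrV", pos = 21,
                                    cigar = "3M2I4M", seq = "ACGTTACGT",
                                    qual = qs(30, 9), md = "7"))
  plain <- log_likelihood(cand, cfg, value_only = TRUE)
  # VCF style: anchor base at 1-based 23, REF A, ALT ATT
  idx <- variant_index(data.frame(rname = "chrV", pos = 23, ref = "A",
                                  alt = "ATT"))
  va <- log_likelihood_variant_aware(cand, idx, cfg, value_only = TRUE)
  # run penalty gamma_open + gamma_ext = 3 replaced by gamma_indel = 2
  expect_equal(va - plain, 1, tolerance = 1e-9)

  # with AF present the penalty is -lg(AF)
  idx_af <- variant_index(data.frame(rname = "chrV", pos = 23, ref = "A",
                                     alt = "ATT", af = 0.1))
  va_af <- log_likelihood_variant_aware(cand, idx_af, cfg, value_only = TRUE)
  expect_equal(va_af - plain, 2, tolerance = 1e-9)

  # wrong inserted sequence: no effect
  idx_wrong <- variant_index(data.frame(rname = "chrV", pos = 23, ref = "A",
                                        alt = "AGG"))
  expect_equal(log_likelihood_variant_aware(cand, idx_wrong, cfg,
                                            value_only = TRUE), plain)

  # deletion: 'CG' deleted, anchor at 1-based 33
  cand_d <- expand_alignment(make_rec(rname = "chrV", pos = 31,
                                      cigar = "3M2D4M", seq = "ACGTACG",
                                      qual = qs(30, 7), md = "3^CG4"))
  plain_d <- log_likelihood(cand_d, cfg, value_only = TRUE)
  idx_d <- variant_index(data.frame(rname = "chrV", pos = 33, ref = "GCG",
                                    alt = "G"))
  va_d <- log_likelihood_variant_aware(cand_d, idx_d, cfg, value_only = TRUE)
  expect_equal(va_d - plain_d, 1, tolerance = 1e-9)
})

test_that("known MNPs are matched as whole blocks", {
  cfg <- penalty_config()
  # two adjacent mismatches at offsets 4-5 (read CC over ref AT)
  cand <- expand_alignment(make_rec(rname = "chrV", pos = 41, cigar = "8M",
                                    seq = "ACGTCCGT", qual = qs(30, 8),
                                    md = "4A0T2"))
  plain <- log_likelihood(cand, cfg, value_only = TRUE)
  idx <- variant_index(data.frame(rname = "chrV", pos = 45, ref = "AT",
                                  alt = "CC"))
  va <- log_likelihood_variant_aware(cand, idx, cfg, value_only = TRUE)
  delta <- (2 * log10(1 - 0.001) - cfg$gamma_mnp) - 2 * (-3)
  expect_equal(va - plain, delta, tolerance = 1e-9)
  # a block of the wrong length does not match
  idx_short <- variant_index(data.frame(rname = "chrV", pos = 45, ref = "A",
                                        alt = "C"))
  va_s <- log_likelihood_variant_aware(cand, idx_short, cfg,
                                       value_only = TRUE)
  # the single-base SNV still matches the first mismatch individually
  expect_gte(va_s, plain)
})

test_that("variant-aware likelihood is never below the plain one", {
  set.seed(204)
  cfg <- penalty_config()
  ref <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
  for (i in 1:60) {
    len <- sample(20:60, 1)
    start <- sample(1:200, 1)
    refseg <- strsplit(substring(ref, start, start + len - 1), "")[[1]]
    read <- refseg
    nmm <- sample(0:3, 1)
    mmpos <- if (nmm) sample(seq_len(len), nmm) else integer(0)
    for (p in mmpos)
      read[p] <- sample(setdiff(c("A", "C", "G", "T"), refseg[p]), 1)
    md <- {
      out <- character(0); cnt <- 0L
      for (k in seq_len(len)) {
        if (k %in% mmpos) { out <- c(out, cnt, refseg[k]); cnt <- 0L }
        else cnt <- cnt + 1L
      }
      paste(c(out, cnt), collapse = "")
    }
    cand <- expand_alignment(make_rec(rname = "chrP", pos = start,
                                      cigar = paste0(len, "M"),
                                      seq = paste(read, collapse = ""),
                                      qual = qs(30, len), md = md))
    # plant a matching SNV for a random subset of the mismatches
    planted <- mmpos[stats::runif(length(mmpos)) < 0.5]
    vdf <- data.frame(rname = character(0), pos = integer(0),
                      ref = character(0), alt = character(0))
    for (p in planted)
      vdf <- rbind(vdf, data.frame(rname = "chrP", pos = start + p - 1L,
                                   ref = refseg[p], alt = read[p]))
    idx <- variant_index(vdf)
    plain <- log_likelihood(cand, cfg, value_only = TRUE)
    va <- log_likelihood_variant_aware(cand, idx, cfg, value_only = TRUE)
    if (length(planted)) expect_gt(va, plain) else expect_equal(va, plain)
  }
})

test_that("VCF input is indexed with per-allele frequencies", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
    "##contig=<ID=chr1,length=10000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tA\tG\t.\t.\tAF=0.25",
    "chr1\t200\t.\tT\tC,G\t.\t.\tAF=0.10,0.05",
    "chr1\t300\t.\tC\tCTT\t.\t.\tAF=0.5",
    "chr1\t400\t.\tGAC\tG\t.\t.\t.",
    "chr1\t500\t.\tAT\tGC\t.\t.\t."
  ), vcf)
  idx <- read_known_variants(vcf)
  v <- lookup_variants(idx, "chr1", 99)
  expect_length(v, 1)
  expect_equal(v[[1]]$kind, "SNV")
  expect_equal(v[[1]]$af, 0.25)
  # multi-allelic record expands to one variant per alternate allele
  v2 <- lookup_variants(idx, "chr1", 199)
  expect_length(v2, 2)
  expect_setequal(vapply(v2, `[[`, 0, "af"), c(0.10, 0.05))
  # insertion keyed by the base after the anchor, sequence stripped
  v3 <- lookup_variants(idx, "chr1", 300)
  expect_equal(v3[[1]]$kind, "INDEL")
  expect_equal(v3[[1]]$indel_type, "ins")
  expect_equal(v3[[1]]$seq, "TT")
  # deletion keyed by the first deleted base
  v4 <- lookup_variants(idx, "chr1", 400)
  expect_equal(v4[[1]]$indel_type, "del")
  expect_equal(v4[[1]]$seq, "AC")
  expect_true(is.na(v4[[1]]$af))
  # MNP at its start
  expect_equal(lookup_variants(idx, "chr1", 499)[[1]]$kind, "MNP")
})
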