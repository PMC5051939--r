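test_that("single-end posteriors match the closed forms", {
  g <- se_posteriors(read_group(list(stub_cand(rep("MATCH", 5), rep(30, 5),
                                               log_lik = -1))))
  expect_equal(g$candidates[[1]]$posterior, 1)

  two <- function(ll1, ll2, L1 = 50, L2 = 50) {
    a <- stub_cand(rep("MATCH", L1), rep(30, L1), log_lik = ll1)
    b <- stub_cand(rep("MATCH", L2), rep(30, L2), log_lik = ll2,
                   start = 100L)
    vapply(se_posteriors(read_group(list(a, b)))$candidates,
           `[[`, 0, "posterior")
  }
  expect_equal(two(-2, -2), c(0.5, 0.5))
  expect_equal(two(-2, -3), c(10 / 11, 1 / 11), tolerance = 1e-12)
  # the length prior: double length doubles the weight
  expect_equal(two(-2, -2, L1 = 100, L2 = 50), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
})

test_that("posteriors agree with the naive linear-space formula and are stable in extreme ranges", {
  set.seed(301)
  for (i in 1:100) {
    k <- sample(2:10, 1)
    L <- sample(20:100, k, replace = TRUE)
    ll <- -stats::runif(k, 0, 50)
    cands <- lapply(seq_len(k), function(j)
      stub_cand(rep("MATCH", L[j]), rep(30, L[j]), log_lik = ll[j],
                start = j * 10L))
    p <- vapply(se_posteriors(read_group(cands))$candidates,
                `[[`, 0, "posterior")
    expect_equal(p, brute_se_posteriors(L, ll), tolerance = 1e-9)
    expect_equal(sum(p), 1, tolerance = 1e-9)
  }
  # far beyond double-precision range of 10^ll: still normalized
  cands <- lapply(c(-1000, -1001), function(ll)
    stub_cand(rep("MATCH", 10), rep(30, 10), log_lik = ll))
  p <- vapply(se_posteriors(read_group(cands))$candidates,
              `[[`, 0, "posterior")
  expect_equal(p, c(10 / 11, 1 / 11), tolerance = 1e-12)
})

test_that("mapQ is the rounded, capped phred of the error probability", {
  expect_equal(mapq_from_posterior(c(0, 0.9, 0.5)), c(0L, 10L, 3L))
  expect_equal(mapq_from_posterior(1), 250L)
  expect_equal(mapq_from_posterior(1 - 1e-200), 250L)
  cfg <- penalty_config(mapq_cap = 60)
  expect_equal(mapq_from_posterior(1, cfg), 60L)
  # monotone non-decreasing in the posterior
  p <- seq(0, 1, by = 0.001)
  expect_true(all(diff(mapq_from_posterior(p)) >= 0))
  expect_error(mapq_from_posterior(1.5), "\\[0, 1\\]")
})

test_that("fragment model recovers seeded Gaussian distances and flags unreliable inputs", {
  set.seed(302)
  d <- rnorm(10000, 300, 30)
  m <- estimate_fragment_model(d, min_n = 1000)
  expect_true(m$reliable)
  expect_lt(abs(m$mean - 300), 3 * 30 / sqrt(10000))
  expect_lt(abs(m$sd - 30), 3 * 30 / sqrt(2 * 10000))

  expect_false(estimate_fragment_model(rnorm(10, 300, 30),
                                       min_n = 1000)$reliable)
  expect_false(estimate_fragment_model(rep(250, 5000))$reliable)  # sd = 0
})

test_that("pairing density is Gaussian when reliable, constant otherwise", {
  m <- estimate_fragment_model(rnorm(5000, 300, 50), min_n = 1000)
  expect_equal(pairing_density(m$mean, m), 1 / (m$sd * sqrt(2 * pi)))
  expect_equal(pairing_density(m$mean + m$sd, m) / pairing_density(m$mean, m),
               exp(-1 / 2))
  expect_equal(pairing_density(NA, m), m$constant_density)  # cross-reference
  un <- estimate_fragment_model(numeric(0))
  expect_equal(pairing_density(c(100, 5000), un), c(1, 1))
})

pe_mate <- function(start, end, ll, L = 100L, strand = "+", rname = "c1")
  structure(list(qname = "p", rname = rname, start = start, end = end,
                 strand = strand, L = L, log_lik = ll,
                 posterior = NA_real_),
            class = "candidate_alignment")

test_that("paired-end posteriors weigh the fragment-size density", {
  m <- structure(list(mean = 300, sd = 50, n = 5000, reliable = TRUE,
                      constant_density = 1), class = "fragment_model")
  # two pairs identical except mate distance 300 vs 400 (mu vs mu + 2 sd)
  p1 <- candidate_pair(pe_mate(0, 100, -2), pe_mate(200, 300, -2, strand = "-"))
  p2 <- candidate_pair(pe_mate(1000, 1100, -2),
                       pe_mate(1300, 1400, -2, strand = "-"))
  expect_equal(p1$d_mate, 300)
  expect_equal(p2$d_mate, 400)
  g <- pe_posteriors(pair_group(list(p1, p2)), m)
  post <- vapply(g$pairs, `[[`, 0, "posterior")
  expect_equal(post[1] / post[2], exp(2), tolerance = 1e-9)
  expect_equal(post, c(exp(2), 1) / (exp(2) + 1), tolerance = 1e-9)
  expect_equal(sum(post), 1, tolerance = 1e-12)

  # single pair normalizes to 1
  g1 <- pe_posteriors(pair_group(list(p1)), m)
  expect_equal(g1$pairs[[1]]$posterior, 1)
})

test_that("constant pairing density reduces the pair model to the single-end formula", {
  un <- estimate_fragment_model(numeric(0))
  set.seed(303)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    L1 <- sample(30:100, k, TRUE); L2 <- sample(30:100, k, TRUE)
    ll1 <- -runif(k, 0, 20); ll2 <- -runif(k, 0, 20)
    pairs <- lapply(seq_len(k), function(j)
      candidate_pair(pe_mate(j * 10, j * 10 + L1[j], ll1[j], L = L1[j]),
                     pe_mate(j * 500, j * 500 + L2[j], ll2[j], L = L2[j])))
    post <- vapply(pe_posteriors(pair_group(pairs), un)$pairs,
                   `[[`, 0, "posterior")
    # single-end run on concatenated pseudo-reads: L = L1*L2, ll = ll1+ll2
    pseudo <- lapply(seq_len(k), function(j)
      structure(list(qname = "p", rname = "c1", start = j, strand = "+",
                     L = L1[j] * L2[j], log_lik = ll1[j] + ll2[j],
                     posterior = NA_real_), class = "candidate_alignment"))
    pse <- vapply(se_posteriors(read_group(pseudo))$candidates,
                  `[[`, 0, "posterior")
    expect_equal(post, pse, tolerance = 1e-9)
  }
})

test_that("orphan mates are soft-masked and lose to true concordant pairs", {
  cfg <- penalty_config()   # gamma_soft = 1
  mapped <- expand_alignment(make_rec(cigar = "10M", seq = "ACGTACGTAC",
                                      qual = qs(20, 10), md = "10"))
  mapped <- log_likelihood(mapped, cfg)
  template <- make_rec(flag = 4L + 8L, cigar = "*", seq = "ACGTACGTAC",
                       qual = qs(20, 10))
  op <- orphan_to_pair(mapped, template, cfg)
  expect_equal(op$mate2$log_lik, 10 * (-2 - 1))
  expect_true(is.na(op$d_mate))

  # no template: pseudo-mate takes the mapped mate's length and mean quality
  op2 <- orphan_to_pair(mapped, NULL, cfg)
  expect_equal(op2$mate2$L, 10)
  expect_equal(op2$mate2$qual, rep(20, 10))

  # a concordant mate at the same fwd locus always outscores the orphan
  m <- estimate_fragment_model(rnorm(5000, 300, 50), min_n = 1000)
  rev_mate <- pe_mate(290, 390, -0.5, strand = "-")
  conc <- candidate_pair(mapped, rev_mate)
  g <- pe_posteriors(pair_group(list(conc, op)), m)
  expect_gt(g$pairs[[1]]$posterior, g$pairs[[2]]$posterior)
})

test_that("selection orders by posterior with deterministic tie-breaks", {
  cands <- list(
    stub_cand(rep("MATCH", 10), rep(30, 10), rname = "chr2", start = 5),
    stub_cand(rep("MATCH", 10), rep(30, 10), rname = "chr1", start = 50),
    stub_cand(rep("MATCH", 10), rep(30, 10), rname = "chr1", start = 9))
  for (p in list(c(0.7, 0.2, 0.1))) {
    for (i in 1:3) cands[[i]]$posterior <- p[i]
    g <- select_best(read_group(cands))
    expect_equal(vapply(g$candidates, `[[`, 0, "posterior"), sort(p, TRUE))
    expect_equal(g$candidates[[1]]$mapq,
                 as.integer(round(-10 * log10(1 - 0.7))))  # 5
  }
  # exact tie: lexicographically smaller locus wins; both mapQ 3
  a <- stub_cand(rep("MATCH", 10), rep(30, 10), rname = "chr2", start = 1)
  b <- stub_cand(rep("MATCH", 10), rep(30, 10), rname = "chr1", start = 999)
  a$posterior <- b$posterior <- 0.5
  g <- select_best(read_group(list(a, b)))
  expect_equal(g$candidates[[1]]$rname, "chr1")
  expect_equal(vapply(g$candidates, `[[`, 0L, "mapq"), c(3L, 3L))

  # permuting candidate order changes neither posteriors nor the primary
  set.seed(304)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    cands <- lapply(seq_len(k), function(j)
      stub_cand(rep("MATCH", 20), rep(30, 20), start = j * 7L,
                log_lik = -runif(1, 0, 10)))
    g1 <- select_best(se_posteriors(read_group(cands)))
    g2 <- select_best(se_posteriors(read_group(cands[sample(k)])))
    expect_equal(g1$candidates[[1]]$start, g2$candidates[[1]]$start)
    expect_equal(vapply(g1$candidates, `[[`, 0, "posterior"),
                 vapply(g2$candidates, `[[`, 0, "posterior"))
  }
})
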