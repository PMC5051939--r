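# Posterior mapping probabilities and mapQ.
#
# Within the set of candidate alignments of one read, the posterior of
# candidate i is proportional to L_i * 10^loglik_i: the prior of a locus is
# proportional to its alignment length (the effective genome size cancels),
# and the normalization constant cancels too.  Computation happens in log
# space with max-subtraction so groups with very different likelihoods stay
# stable.  mapQ is the phred-scaled probability that the mapping is wrong:
# -10 * lg(1 - posterior), rounded half-up and capped.

#' Read groups and pair groups
#'
#' A `read_group` holds all candidate alignments of one single-end read; a
#' `pair_group` holds all candidate pairs of one fragment.  They are the
#' units over which posterior probabilities normalize.
#'
#' @param candidates non-empty list of `candidate_alignment` objects sharing
#'   one read name.
#' @return An object of class `read_group`.
#' @export
read_group <- function(candidates) {
  if (!length(candidates)) stop("a read group needs at least one candidate")
  qn <- unique(vapply(candidates, `[[`, "", "qname"))
  if (length(qn) != 1L) stop("candidates span several read names: ",
                             paste(qn, collapse = ", "))
  structure(list(qname = qn, candidates = candidates), class = "read_group")
}

#' Single-end posterior probabilities
#'
#' Fills `posterior` on every candidate of a group:
#' `posterior_i = L_i 10^ll_i / sum_k L_k 10^ll_k`, evaluated in log space.
#'
#' @param group a [read_group()] whose candidates all carry `log_lik`.
#' @param config a [penalty_config()] (unused in the normalization itself;
#'   accepted for interface symmetry).
#' @return The group, candidates updated with `posterior`.
#' @examples
#' # two equal-length candidates whose log-likelihoods differ by 1 unit
#' cand <- function(ll) structure(list(qname = "r", rname = "c", start = 0,
#'   strand = "+", L = 50, log_lik = ll), class = "candidate_alignment")
#' g <- se_posteriors(read_group(list(cand(-2), cand(-3))))
#' vapply(g$candidates, `[[`, 0, "posterior")   # 10/11, 1/11
#' @export
se_posteriors <- function(group, config = penalty_config()) {
  ll <- vapply(group$candidates, `[[`, 0, "log_lik")
  L <- vapply(group$candidates, `[[`, 0, "L")
  if (anyNA(ll)) stop("all candidates need log_lik before normalization")
  p <- normalize_log10(log10(L) + ll)
  for (i in seq_along(group$candidates))
    group$candidates[[i]]$posterior <- p[i]
  group
}

normalize_log10 <- function(w) {
  m <- max(w)
  x <- 10^(w - m)
  x / sum(x)
}

#' Phred-scaled mapping quality of a posterior
#'
#' `round(-10 * lg(1 - posterior))` (half-up), capped at `mapq_cap`.  A
#' posterior so close to 1 that `1 - p` underflows maps to the cap.
#'
#' @param posterior probability in `[0, 1]`.
#' @param config a [penalty_config()] supplying the cap.
#' @return Integer mapping qualities.
#' @examples
#' mapq_from_posterior(c(0, 0.5, 0.9, 1))
#' @export
mapq_from_posterior <- function(posterior, config = penalty_config()) {
  if (any(posterior < 0 | posterior > 1)) stop("posterior must be in [0, 1]")
  q <- -10 * log10(1 - posterior)
  q <- floor(q + 0.5)                     # round half-up
  q[!is.finite(q)] <- config$mapq_cap
  as.integer(pmin(q, config$mapq_cap))
}

# --- paired-end model ---------------------------------------------------

#' Fragment-size model for read pairs
#'
#' Estimates the mean and standard deviation of the sequenced fragment size
#' from the mate distances of reads that map uniquely and concordantly.  The
#' Gaussian model is used only when `reliable`: enough observations and a
#' sane dispersion (`0 < sd` and `sd/mean < 2`).  Otherwise the pairing
#' density is a constant, which cancels within any group where every pair
#' uses it (e.g. RNA-seq mates separated by introns).
#'
#' @param distances numeric vector of outer mate distances (bp) from
#'   uniquely-mapped concordant pairs.
#' @param min_n minimum number of observations for reliability.
#' @param constant_density density used when unreliable.
#' @return An object of class `fragment_model` with fields `mean`, `sd`,
#'   `n`, `reliable`, `constant_density`.
#' @examples
#' m <- estimate_fragment_model(rnorm(5000, 300, 30), min_n = 1000)
#' m$reliable
#' @export
estimate_fragment_model <- function(distances, min_n = 1000L,
                                    constant_density = 1) {
  distances <- distances[is.finite(distances)]
  n <- length(distances)
  mu <- if (n) mean(distances) else NA_real_
  sigma <- if (n > 1L) stats::sd(distances) else NA_real_
  reliable <- n >= min_n && !is.na(sigma) && sigma > 0 &&
    !is.na(mu) && mu > 0 && sigma / mu < 2
  structure(list(mean = mu, sd = sigma, n = n, reliable = reliable,
                 constant_density = constant_density),
            class = "fragment_model")
}

#' @export
print.fragment_model <- function(x, ...) {
  if (x$reliable)
    cat(sprintf("fragment model: Normal(mean = %.1f, sd = %.1f) from %d pairs\n",
                x$mean, x$sd, x$n))
  else
    cat(sprintf("fragment model: unreliable (n = %d); constant density %g\n",
                x$n, x$constant_density))
  invisible(x)
}

#' Pairing probability density of a mate distance
#'
#' Gaussian density under a reliable [estimate_fragment_model()], otherwise
#' the model's constant density.
#'
#' @param d_mate outer mate distance(s) in bp (may be `NA` for pairs on
#'   different references, which get the constant density).
#' @param model a `fragment_model`.
#' @return Positive densities.
#' @export
pairing_density <- function(d_mate, model) {
  if (!model$reliable) return(rep(model$constant_density, length(d_mate)))
  out <- stats::dnorm(d_mate, model$mean, model$sd)
  out[is.na(d_mate)] <- model$constant_density
  out
}

#' Candidate pairs and pair groups
#'
#' `candidate_pair()` joins one candidate per mate into a scored pair; the
#' outer mate distance is the span from the leftmost start to the rightmost
#' end when both mates sit on the same reference, `NA` otherwise (constant
#' pairing density).  Either mate may be a synthetic soft-masked pseudo-mate
#' from [orphan_to_pair()].
#'
#' @param mate1,mate2 `candidate_alignment` objects (one may be synthetic).
#' @return An object of class `candidate_pair`.
#' @export
candidate_pair <- function(mate1, mate2) {
  same_ref <- !isTRUE(mate1$synthetic) && !isTRUE(mate2$synthetic) &&
    identical(mate1$rname, mate2$rname)
  d <- if (same_ref)
    max(mate1$end, mate2$end) - min(mate1$start, mate2$start)
  else NA_real_
  structure(list(qname = mate1$qname %||% mate2$qname,
                 mate1 = mate1, mate2 = mate2, d_mate = d,
                 pair_log_lik = NA_real_, posterior = NA_real_,
                 mapq = NA_integer_),
            class = "candidate_pair")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname candidate_pair
#' @param pairs non-empty list of `candidate_pair` objects.
#' @return `pair_group()` returns an object of class `pair_group`.
#' @export
pair_group <- function(pairs) {
  if (!length(pairs)) stop("a pair group needs at least one pair")
  structure(list(qname = pairs[[1L]]$qname, pairs = pairs),
            class = "pair_group")
}

#' Paired-end posterior probabilities
#'
#' Joint posterior over the candidate pairs of one fragment:
#' `posterior_i` is proportional to
#' `L1_i * L2_i * 10^(ll1_i + ll2_i) * pairing_density(d_i)`, normalized in
#' log space over the group.  With a constant pairing density this reduces
#' exactly to the single-end formula applied to the concatenated mates.
#'
#' @param group a [pair_group()]; both mates of every pair must carry
#'   `log_lik`.
#' @param model a `fragment_model`.
#' @param config a [penalty_config()].
#' @return The group, pairs updated with `pair_log_lik` and `posterior`.
#' @export
pe_posteriors <- function(group, model, config = penalty_config()) {
  w <- vapply(group$pairs, function(p) {
    ll1 <- p$mate1$log_lik; ll2 <- p$mate2$log_lik
    if (is.na(ll1) || is.na(ll2)) stop("pair mates need log_lik")
    log10(p$mate1$L) + log10(p$mate2$L) + ll1 + ll2 +
      log10(pairing_density(p$d_mate, model))
  }, 0)
  p <- normalize_log10(w)
  for (i in seq_along(group$pairs)) {
    group$pairs[[i]]$pair_log_lik <- w[i]
    group$pairs[[i]]$posterior <- p[i]
  }
  group
}

#' Synthesize a soft-masked pseudo-mate for an orphan alignment
#'
#' When one mate of a pair has no candidate alignment, the pair still
#' competes in the joint normalization: the missing mate is treated as if
#' every base were soft-clipped.  If the unmapped mate's record is available
#' its own qualities are used; otherwise the pseudo-mate takes the mapped
#' mate's read length and mean quality.  Pairs holding a pseudo-mate always
#' use the constant pairing density.
#'
#' @param mapped a `candidate_alignment` for the mate that did align.
#' @param mate_template optional unmapped SAM record of the missing mate
#'   (supplies length and qualities).
#' @param config a [penalty_config()].
#' @return A `candidate_pair` of the mapped candidate and the synthetic
#'   mate (mapped mate first).
#' @export
orphan_to_pair <- function(mapped, mate_template = NULL,
                           config = penalty_config()) {
  if (!is.null(mate_template) && mate_template$qual != "*") {
    q <- phred_from_string(mate_template$qual)
  } else {
    len <- sum(!is.na(mapped$read_pos))
    q <- rep(mean(mapped$qual[!is.na(mapped$read_pos)]), len)
  }
  ll <- sum(q / config$phred_scale - config$gamma_soft)
  pseudo <- structure(list(
    qname = mapped$qname, rname = NA_character_, start = NA_integer_,
    end = NA_integer_, strand = NA_character_,
    status = rep("SOFT_CLIP", length(q)), qual = q,
    L = length(q), log_lik = ll, posterior = NA_real_,
    synthetic = TRUE
  ), class = "candidate_alignment")
  candidate_pair(mapped, pseudo)
}

#' Order candidates by posterior and assign mapping qualities
#'
#' Sorts the candidates (or pairs) of a scored group by decreasing
#' posterior, breaking ties deterministically by reference name, start and
#' strand, so repeated runs always pick the same primary.  Every candidate
#' receives `mapq = mapq_from_posterior(posterior)`; the first is the
#' primary hit.
#'
#' @param group a scored `read_group` or `pair_group`.
#' @param config a [penalty_config()].
#' @return The group with candidates/pairs reordered and `mapq` filled.
#' @export
select_best <- function(group, config = penalty_config()) {
  items <- if (inherits(group, "pair_group")) group$pairs else group$candidates
  post <- vapply(items, `[[`, 0, "posterior")
  if (anyNA(post)) stop("posteriors must be computed before selection")
  key <- vapply(items, function(it) {
    if (inherits(it, "candidate_pair"))
      sprintf("%s:%012d:%s|%s:%012d", it$mate1$rname,
              it$mate1$start %||% 0L, it$mate1$strand,
              if (isTRUE(it$mate2$synthetic)) "*" else it$mate2$rname,
              (if (isTRUE(it$mate2$synthetic)) 0L else it$mate2$start) %||% 0L)
    else sprintf("%s:%012d:%s", it$rname, it$start, it$strand)
  }, "")
  ord <- order(-post, key, method = "radix")
  items <- items[ord]
  for (i in seq_along(items))
    items[[i]]$mapq <- mapq_from_posterior(items[[i]]$posterior, config)
  if (inherits(group, "pair_group")) group$pairs <- items
  else group$candidates <- items
  group
}
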