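#' Shannon entropy of a methylation profile
#'
#' Entropy (in bits) of the methylation levels of one region across N
#' samples, after normalising the levels to a probability vector
#' `p_s = m_s / sum(m_s)`. Low entropy means the methylation mass is
#' concentrated in few samples, i.e. a large between-sample difference.
#' The all-zero profile is treated as uniform (`H0 = log2(N)`), and
#' `0 * log2(0)` is 0 throughout.
#'
#' @param levels numeric vector of methylation fractions in `[0,1]`,
#'   length N >= 2.
#' @return entropy in bits, in `[0, log2(N)]`.
#' @export
shannon_entropy <- function(levels) {
  if (length(levels) < 2) stop("need at least 2 samples")
  if (any(levels < 0 | levels > 1)) stop("levels must lie in [0,1]")
  s <- sum(levels)
  if (s == 0) return(log2(length(levels)))
  p <- levels / s
  -sum(ifelse(p > 0, p * log2(p), 0))
}

#' One-step Tukey biweight robust mean
#'
#' Weighted mean in which each observation is down-weighted by its
#' distance from the median: `u = (m - median) / (c * MAD + eps_t)`,
#' weight `(1 - u^2)^2` for `|u| < 1` and 0 otherwise, with `c = 5` and
#' `MAD` the median absolute deviation from the median. One step means
#' the weights are computed once from the median rather than iterated.
#' For N = 2 the two weights are equal by symmetry, so the result is
#' the plain mean.
#'
#' @param levels numeric vector, length >= 2.
#' @param c_tuning tuning constant (default 5).
#' @param eps_t regulariser added to the scale (default 1e-4) so the
#'   all-equal profile returns its common value.
#' @return the robust mean.
#' @export
tukey_biweight <- function(levels, c_tuning = 5, eps_t = 1e-4) {
  if (length(levels) < 2) stop("need at least 2 samples")
  med <- stats::median(levels)
  mad_r <- stats::median(abs(levels - med))
  u <- (levels - med) / (c_tuning * mad_r + eps_t)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  sum(w * levels) / sum(w)
}

#' Adjusted (quantitative DMR) entropy of one region
#'
#' The entropy stack used to call differentially methylated regions:
#' replace each level by its distance from the one-step Tukey biweight
#' mean, `m'_s = |m_s - T_br|`; compute the Shannon entropy `H_P` of the
#' normalised distances; and scale by the log-range weight
#' `w_r = |log2((max(m) - min(m)) / (MAX - MIN) + eps)|` with
#' `MAX = 1`, `MIN = 0`. The adjusted entropy `H_Q = H_P * w_r` is small
#' when one or few samples deviate strongly (0 when exactly one sample
#' carries all the deviation) and returns the `+Inf` sentinel for
#' exactly uniform profiles, which can never be called differential.
#'
#' @param levels numeric vector of methylation fractions, length N >= 2.
#' @param eps range regulariser in the weight (default 1e-4).
#' @return list with `H0`, `T_br`, `H_P`, `w_r`, `H_Q`.
#' @export
adjusted_entropy <- function(levels, eps = 1e-4) {
  if (any(levels < 0 | levels > 1)) stop("levels must lie in [0,1]")
  h0 <- shannon_entropy(levels)
  tbr <- tukey_biweight(levels)
  d <- abs(levels - tbr)
  w_r <- abs(log2(max(levels) - min(levels) + eps))
  if (sum(d) == 0)
    return(list(H0 = h0, T_br = tbr, H_P = NA_real_, w_r = w_r,
                H_Q = Inf))
  p <- d / sum(d)
  h_p <- -sum(ifelse(p > 0, p * log2(p), 0))
  list(H0 = h0, T_br = tbr, H_P = h_p, w_r = w_r, H_Q = h_p * w_r)
}

#' Adjusted entropy for every region of a methylation matrix
#'
#' Row-wise [adjusted_entropy()] with a closed-form fast path for the
#' two-sample case, where the biweight mean is the plain mean, the
#' distance profile is symmetric (`H_P = 1` whenever the levels differ)
#' and `H_Q = |log2(|m_1 - m_2| + eps)|`. Rows with missing entries are
#' skipped (`NA` results).
#'
#' @param m numeric matrix, regions x samples (N >= 2 columns), entries
#'   in `[0,1]` or `NA`.
#' @param eps range regulariser (default 1e-4).
#' @return data.frame with columns `region, H0, T_br, H_P, w_r, H_Q`.
#' @export
qdmr_entropy <- function(m, eps = 1e-4) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need at least 2 samples")
  n <- nrow(m)
  ok <- stats::complete.cases(m)
  res <- data.frame(region = if (is.null(rownames(m))) as.character(seq_len(n))
                    else rownames(m),
                    H0 = NA_real_, T_br = NA_real_, H_P = NA_real_,
                    w_r = NA_real_, H_Q = NA_real_,
                    stringsAsFactors = FALSE)
  if (!any(ok)) return(res)
  if (ncol(m) == 2) {
    a <- m[ok, 1]; b <- m[ok, 2]
    s <- a + b
    p <- ifelse(s > 0, a / s, 0.5)
    h0 <- -(ifelse(p > 0, p * log2(p), 0) +
              ifelse(1 - p > 0, (1 - p) * log2(1 - p), 0))
    d <- abs(a - b)
    w_r <- abs(log2(d + eps))
    res$H0[ok] <- h0
    res$T_br[ok] <- (a + b) / 2
    res$H_P[ok] <- ifelse(d > 0, 1, NA_real_)
    res$w_r[ok] <- w_r
    res$H_Q[ok] <- ifelse(d > 0, w_r, Inf)
  } else {
    mm <- m[ok, , drop = FALSE]
    k <- ncol(mm)
    row_sorted <- function(x) matrix(x[order(row(x), x)], ncol = k,
                                     byrow = TRUE)
    srt <- row_sorted(mm)
    med <- if (k %% 2 == 1) srt[, (k + 1) / 2] else
      (srt[, k / 2] + srt[, k / 2 + 1]) / 2
    dev <- abs(mm - med)
    dsrt <- row_sorted(dev)
    mad_r <- if (k %% 2 == 1) dsrt[, (k + 1) / 2] else
      (dsrt[, k / 2] + dsrt[, k / 2 + 1]) / 2
    u <- (mm - med) / (5 * mad_r + 1e-4)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    tbr <- rowSums(w * mm) / rowSums(w)

    s0 <- rowSums(mm)
    p0 <- mm / ifelse(s0 > 0, s0, 1)
    h0 <- -rowSums(ifelse(p0 > 0, p0 * log2(p0), 0))
    h0[s0 == 0] <- log2(k)

    d <- abs(mm - tbr)
    sd_ <- rowSums(d)
    uniform <- sd_ == 0
    pp <- d / ifelse(uniform, 1, sd_)
    h_p <- -rowSums(ifelse(pp > 0, pp * log2(pp), 0))
    w_r <- abs(log2(srt[, k] - srt[, 1] + eps))
    h_q <- h_p * w_r
    h_p[uniform] <- NA_real_
    h_q[uniform] <- Inf
    res$H0[ok] <- h0
    res$T_br[ok] <- tbr
    res$H_P[ok] <- h_p
    res$w_r[ok] <- w_r
    res$H_Q[ok] <- h_q
  }
  res
}

#' Simulate the null adjusted-entropy distribution and derive a call
#' threshold
#'
#' The null model is a uniformly methylated region observed in N
#' samples with intrinsic biological variation: a region mean
#' `mu ~ Uniform(0,1)` and per-sample levels
#' `clip(Normal(mu, sd), 0, 1)`. The call threshold is the low-tail
#' `percentile` of the simulated `H_Q` distribution, so by construction
#' the stated fraction of null regions is called differential. `sd`
#' controls stringency: the conventional choices are 0.03 for
#' two-replica comparisons and 0.015 (most conservative) for
#' multi-sample, inter-cell-line calling. For N = 2 the threshold is
#' equivalent to a cut on the semi-difference `|m_1 - m_2| / 2`.
#'
#' @param n_samples number of samples N (>= 2).
#' @param sd biological-variation SD of the null (> 0).
#' @param percentile low-tail probability defining the threshold
#'   (default 0.05).
#' @param n_sim number of simulated null regions (default 1e5; a
#'   warning is issued below 1e3).
#' @param eps range regulariser passed to [qdmr_entropy()].
#' @param seed integer seed.
#' @return object of class `"qdmr_threshold"`: list with `n_samples,
#'   sd, percentile, threshold_hq, n_sim, seed, null_hq`.
#' @export
derive_threshold <- function(n_samples, sd, percentile = 0.05,
                             n_sim = 1e5, eps = 1e-4, seed = 1L) {
  stopifnot(sd > 0, n_samples >= 2, percentile >= 0, percentile <= 1)
  if (n_sim < 1e3) warning("n_sim < 1000: threshold will be noisy")
  set.seed(seed)
  mu <- stats::runif(n_sim)
  m <- matrix(pmin(1, pmax(0, stats::rnorm(n_sim * n_samples, mu, sd))),
              nrow = n_sim)
  hq <- qdmr_entropy(m, eps)$H_Q
  thr <- if (percentile == 0) min(hq) else
    as.numeric(stats::quantile(hq, percentile, type = 1, names = FALSE))
  structure(list(n_samples = n_samples, sd = sd, percentile = percentile,
                 threshold_hq = thr, n_sim = n_sim, seed = seed,
                 null_hq = hq),
            class = "qdmr_threshold")
}

#' Call differentially methylated regions by adjusted entropy
#'
#' A region is differentially methylated when its `H_Q` falls strictly
#' below the simulated null threshold. With `percentile = 0` the
#' threshold is the null minimum and no null region is called.
#'
#' @param m methylation matrix (regions x samples) or the data.frame
#'   returned by [qdmr_entropy()].
#' @param threshold a `"qdmr_threshold"` whose `n_samples` matches the
#'   matrix sample count.
#' @param eps range regulariser, used when `m` is a matrix.
#' @return data.frame `region, H_Q, is_dmr` (rows with missing data get
#'   `NA` flags).
#' @export
call_dmr <- function(m, threshold, eps = 1e-4) {
  stopifnot(inherits(threshold, "qdmr_threshold"))
  if (is.data.frame(m) && "H_Q" %in% names(m)) {
    ent <- m
  } else {
    m <- as.matrix(m)
    if (ncol(m) != threshold$n_samples)
      stop("matrix has ", ncol(m), " samples but threshold was derived for ",
           threshold$n_samples)
    ent <- qdmr_entropy(m, eps)
  }
  data.frame(region = ent$region, H_Q = ent$H_Q,
             is_dmr = ent$H_Q < threshold$threshold_hq,
             stringsAsFactors = FALSE)
}
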