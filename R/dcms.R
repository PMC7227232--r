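#' Genome-wide rank-based one-tailed p-values
#'
#' Converts a statistic track to empirical one-tailed p-values over the n
#' defined values: right tail p_i = rank of x_i from the top / (n + 1), left
#' tail p_i = rank from the bottom / (n + 1). The n + 1 denominator keeps p
#' strictly inside (0, 1) so the log-odds transform of the composite stays
#' finite. Ties take midranks by default — half of the tied mass counts as
#' extreme — which matters for granular statistics (a window haplotype
#' statistic over few haplotypes takes few distinct values, and counting a
#' large tied mass as fully non-extreme would turn small fluctuations into
#' jumps of the composite). `ties = "extreme"` counts every tied value as
#' extreme instead (p_i = #\{x_j >= x_i\} / (n + 1) for the right tail).
#' Sentinels propagate.
#'
#' @param track a [stat_track()]
#' @param tail "right" (large values extreme: H1, H12, FST) or "left" (small
#'   values extreme: pi, Tajima's D)
#' @param ties "midrank" (default) or "extreme"
#' @return a p-value [stat_track()] with `stat = "P"` and the `tail` field set
#' @export
rank_pvalues <- function(track, tail = c("right", "left"),
                         ties = c("midrank", "extreme")) {
  tail <- match.arg(tail)
  ties <- match.arg(ties)
  x <- track$values
  def <- !is.na(x)
  n <- sum(def)
  if (n < 2) stop("need at least 2 defined values")
  xd <- x[def]
  if (length(unique(xd)) == 1L)
    warning("all values identical: degenerate statistic")
  p <- rep(NA_real_, length(x))
  if (ties == "midrank") {
    r <- rank(xd, ties.method = "average")
    p[def] <- if (tail == "right") (n - r + 1) / (n + 1) else r / (n + 1)
  } else {
    p[def] <- if (tail == "right")
      (n - rank(xd, ties.method = "min") + 1) / (n + 1)
    else rank(xd, ties.method = "max") / (n + 1)
  }
  stat_track(p, track$variants, "P", track$breed, tail = tail)
}

# Exact univariate MCD: variance of the contiguous sorted subset of size h
# with the smallest variance (MASS's MCD is multivariate-only), rescaled by
# the usual consistency factor so it estimates the variance at the normal.
mcd_univariate <- function(x, h) {
  x <- sort(x)
  n <- length(x)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  i <- seq_len(n - h + 1)
  sums <- cs[i + h] - cs[i]
  vars <- (cs2[i + h] - cs2[i]) - sums^2 / h
  best <- which.min(vars)
  alpha <- h / n
  consistency <- alpha / stats::pchisq(stats::qchisq(alpha, 1), 3)
  list(center = sums[best] / h,
       cov = vars[best] / (h - 1) * consistency)
}

#' Robust covariance/correlation model of the combined statistics
#'
#' Estimates the k x k covariance of the statistics on a random sample of
#' SNPs with the Minimum Covariance Determinant estimator (subset fraction
#' `alpha`), derives the correlation matrix R and the DCMS weights
#' s_i = sum_j |r_ij|. Rows containing any sentinel are dropped before
#' sampling. Reproducible under a fixed seed.
#'
#' @param stat_matrix numeric matrix, variants x k statistics (column names
#'   label the statistics)
#' @param n_sample number of SNPs sampled for the estimate (capped at the
#'   available complete rows)
#' @param alpha MCD subset fraction in (0.5, 1]
#' @param seed integer seed for the SNP sampling and the MCD resampling
#' @return a list of class `CorrelationModel` with elements `stats`, `Sigma`,
#'   `R`, `s`, `n_sampled`, `alpha`, `seed`
#' @export
fit_robust_covariance <- function(stat_matrix, n_sample = 300000,
                                  alpha = 0.75, seed = 1) {
  stat_matrix <- as.matrix(stat_matrix)
  k <- ncol(stat_matrix)
  if (k < 1) stop("need at least one statistic")
  if (is.null(colnames(stat_matrix)))
    colnames(stat_matrix) <- paste0("S", seq_len(k))
  complete <- stats::complete.cases(stat_matrix)
  X <- stat_matrix[complete, , drop = FALSE]
  if (nrow(X) < 10 * k)
    stop("fewer than 10k complete rows available for covariance estimation")
  set.seed(seed)
  if (nrow(X) > n_sample)
    X <- X[sample.int(nrow(X), n_sample), , drop = FALSE]
  n <- nrow(X)
  h <- max(floor(alpha * n), floor((n + k + 1) / 2))
  # guard against exactly collinear columns, which MCD cannot invert:
  # estimate on the distinct-column representatives and expand back
  key <- apply(X, 2, function(col) paste(signif(col, 12), collapse = "\r"))
  rep_idx <- match(unique(key), key)
  group <- match(key, key[rep_idx])
  Xr <- X[, rep_idx, drop = FALSE]
  if (ncol(Xr) == 1) {
    m <- mcd_univariate(Xr[, 1], h)
    Sigma_r <- matrix(m$cov, 1, 1)
  } else {
    # MCD needs a non-singular h-subset; a heavily zero-inflated statistic
    # (e.g. median-smoothed FST truncated at zero) can defeat it, in which
    # case the plain covariance of the sampled rows is used instead
    Sigma_r <- tryCatch(
      MASS::cov.rob(Xr, method = "mcd",
                    quantile.used = h, nsamp = "sample")$cov,
      error = function(e) {
        warning("MCD failed (", conditionMessage(e),
                "); falling back to the classical covariance")
        stats::cov(Xr)
      })
  }
  # expand to full k x k: duplicated columns are perfectly correlated
  Sigma <- Sigma_r[group, group, drop = FALSE]
  dimnames(Sigma) <- list(colnames(stat_matrix), colnames(stat_matrix))
  R <- stats::cov2cor(Sigma)
  s <- rowSums(abs(R))
  structure(list(stats = colnames(stat_matrix), Sigma = Sigma, R = R, s = s,
                 n_sampled = n, alpha = alpha, seed = seed),
            class = "CorrelationModel")
}

#' @exportS3Method base::print
print.CorrelationModel <- function(x, ...) {
  cat("CorrelationModel over", length(x$stats), "statistics (",
      paste(x$stats, collapse = ", "), ") from", x$n_sampled,
      "SNPs, alpha =", x$alpha, "\n")
  cat("weights s_i:", paste(sprintf("%.3f", x$s), collapse = " "), "\n")
  invisible(x)
}

#' Combine p-value tracks into the DCMS composite
#'
#' The de-correlated composite of multiple signals at locus l is
#' DCMS_l = sum_i log((1 - p_\{l,i\}) / p_\{l,i\}) / s_i: each statistic's
#' one-tailed p-value enters as a log-odds score, down-weighted by the sum of
#' that statistic's absolute correlations with all statistics, so duplicated
#' (perfectly correlated) evidence is not double counted. A SNP with any
#' sentinel p-value gets a sentinel composite.
#'
#' @param p_tracks list of k p-value tracks, variant-aligned, in the order of
#'   `model$stats`
#' @param model a [fit_robust_covariance()] result
#' @return a [stat_track()] named `DCMS`
#' @export
dcms_combine <- function(p_tracks, model) {
  k <- length(p_tracks)
  if (k != length(model$stats))
    stop("track count does not match the correlation model")
  P <- sapply(p_tracks, function(tr) tr$values)
  if (is.null(dim(P))) P <- matrix(P, ncol = k)
  bad <- !is.na(P) & (P <= 0 | P >= 1)
  if (any(bad)) stop("p-values must lie strictly in (0, 1)")
  score <- log((1 - P) / P)
  dcms <- score %*% (1 / model$s)
  dcms[!stats::complete.cases(P)] <- NA_real_
  stat_track(as.numeric(dcms), p_tracks[[1]]$variants, "DCMS",
             p_tracks[[1]]$breed)
}

#' Robust normal fit of a statistic track
#'
#' Fits location and scale of the genome-wide statistic distribution by
#' intercept-only M-estimation with Huber weighting (tuning constant 1.345,
#' iterated to relative tolerance 1e-8, at most 50 iterations), so that the
#' small fraction of outlying SNPs in selected regions does not inflate the
#' fit. The scale is the MAD-anchored robust residual scale of the fit.
#'
#' @param track a [stat_track()] or numeric vector (at least 100 defined
#'   values)
#' @return a list of class `NormalFit` with elements `mu`, `sigma`, `method`
#' @export
fit_normal_robust <- function(track) {
  x <- if (inherits(track, "stat_track")) track$values else as.numeric(track)
  x <- x[!is.na(x)]
  if (any(!is.finite(x))) stop("non-finite values present")
  if (length(x) < 100) stop("need at least 100 defined values")
  fit <- MASS::rlm(x ~ 1, psi = MASS::psi.huber, k = 1.345,
                   maxit = 50, acc = 1e-8)
  structure(list(mu = unname(stats::coef(fit)[1]), sigma = fit$s,
                 method = "huber-M"),
            class = "NormalFit")
}

#' @exportS3Method base::print
print.NormalFit <- function(x, ...) {
  cat(sprintf("NormalFit (%s): mu = %.6g, sigma = %.6g\n",
              x$method, x$mu, x$sigma))
  invisible(x)
}

#' Upper-tail normal p-values from a robust fit
#'
#' p = P(Z > (x - mu) / sigma) under the standard normal; the Z-transform
#' uses the robust location/scale so only genuinely outlying SNPs reach small
#' p-values.
#'
#' @param track a [stat_track()]
#' @param fit a [fit_normal_robust()] result
#' @return a p-value [stat_track()] (`stat = "P"`, right tail)
#' @export
normal_pvalues <- function(track, fit) {
  stopifnot(fit$sigma > 0)
  p <- stats::pnorm((track$values - fit$mu) / fit$sigma, lower.tail = FALSE)
  stat_track(p, track$variants, "P", track$breed, tail = "right")
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 on the lambda grid 0.05, 0.10, ...,
#' 0.95 with a cubic smoother extrapolated to lambda -> 1 (clamped to
#' (0, 1]), then q_i = pi0 * min over t >= p_i of n t / #\{p <= t\},
#' enforced monotone. With fewer than 100 p-values pi0 falls back to 1
#' (the Benjamini-Hochberg reduction) with a warning.
#'
#' @param pvals a p-value [stat_track()] or numeric vector of p in (0, 1]
#' @param pi0 optionally force the null proportion (pi0 = 1 gives BH)
#' @return a q-value [stat_track()] with the `pi0` field set (or, for numeric
#'   input, a numeric vector with attribute `pi0`)
#' @export
storey_qvalues <- function(pvals, pi0 = NULL) {
  is_track <- inherits(pvals, "stat_track")
  p_all <- if (is_track) pvals$values else as.numeric(pvals)
  def <- !is.na(p_all)
  p <- p_all[def]
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  n <- length(p)
  if (is.null(pi0)) {
    if (n < 100) {
      warning("fewer than 100 p-values; falling back to pi0 = 1 (BH)")
      pi0 <- 1
    } else {
      lambda <- seq(0.05, 0.95, by = 0.05)
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      sp <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(sp, x = max(lambda))$y
      pi0 <- min(max(pi0, .Machine$double.eps), 1)
    }
  }
  ord <- order(p, decreasing = TRUE)
  q <- rep(NA_real_, n)
  q[ord] <- pi0 * n * p[ord] / rank(p, ties.method = "max")[ord]
  q[ord] <- cummin(q[ord])
  q <- pmin(q, 1)
  out <- rep(NA_real_, length(p_all))
  out[def] <- q
  if (!is_track) {
    attr(out, "pi0") <- pi0
    return(out)
  }
  stat_track(out, pvals$variants, "Q", pvals$breed, pi0 = pi0)
}
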