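# Independent brute-force oracles. These deliberately avoid the package's
# code paths: scalar loops, direct formula transcription, no shared helpers.

bf_spectrum <- function(Hw) {
  keys <- character(0)
  for (j in seq_len(ncol(Hw))) keys <- c(keys, paste(Hw[, j], collapse = "|"))
  sort(as.numeric(table(keys)), decreasing = TRUE) / ncol(Hw)
}

bf_h1 <- function(p) sum(p * p)

bf_h12 <- function(p) {
  if (length(p) == 1) return(p[1]^2)
  (p[1] + p[2])^2 + if (length(p) > 2) sum(p[3:length(p)]^2) else 0
}

# windowed H1/H12 by per-window recomputation
bf_h_scan <- function(H, chrom, w) {
  half <- (w - 1) / 2
  n <- length(chrom)
  h1 <- h12 <- rep(NA_real_, n)
  for (centre in seq_len(n)) {
    lo <- centre - half; hi <- centre + half
    if (lo < 1 || hi > n) next
    if (length(unique(chrom[lo:hi])) > 1) next
    if (chrom[lo] != chrom[centre]) next
    p <- bf_spectrum(H[lo:hi, , drop = FALSE])
    h1[centre] <- bf_h1(p)
    h12[centre] <- bf_h12(p)
  }
  list(H1 = h1, H12 = h12)
}

# Tajima's D for one window, constants transcribed step by step
bf_tajima_window <- function(Hw) {
  n <- ncol(Hw)
  S <- 0
  pihat <- 0
  for (l in seq_len(nrow(Hw))) {
    c1 <- sum(Hw[l, ])
    if (c1 > 0 && c1 < n) S <- S + 1
    # mean pairwise difference at this site
    npairs <- n * (n - 1) / 2
    pihat <- pihat + c1 * (n - c1) / npairs
  }
  if (S == 0) return(NA_real_)
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  cc1 <- b1 - 1 / a1
  cc2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- cc1 / a1
  e2 <- cc2 / (a1^2 + a2)
  (pihat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Weir & Cockerham (1984) two-population theta-hat, scalar transcription.
# n1/n2 diploid sample sizes, p1/p2 alt frequencies, h1/h2 observed
# heterozygosities.
bf_wc_theta <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  CV2 <- ((n1 - nbar)^2 + (n2 - nbar)^2) / (r * nbar^2)  # unused, clarity
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cv <- hbar / 2
  a / (a + b + cv)
}

# one-vs-rest W&C theta per SNP from a GenotypeDataset, truncated at zero
bf_fst_track <- function(ds, focal) {
  vals <- rep(NA_real_, nrow(ds$variants))
  for (l in seq_len(nrow(ds$variants))) {
    g1 <- ds$G[l, ds$breed_of == focal]
    g2 <- ds$G[l, ds$breed_of != focal]
    g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
    if (length(g1) < 1 || length(g2) < 1) next
    th <- bf_wc_theta(length(g1), mean(g1) / 2, mean(g1 == 1),
                      length(g2), mean(g2) / 2, mean(g2 == 1))
    if (is.finite(th)) vals[l] <- min(max(th, 0), 1)
  }
  vals
}

bf_reynolds <- function(pa, pb, ma = NULL, mb = NULL) {
  num <- 0; den <- 0
  for (l in seq_along(pa)) {
    nl <- (pa[l] - pb[l])^2
    if (!is.null(ma))
      nl <- nl - pa[l] * (1 - pa[l]) / (ma[l] - 1) -
        pb[l] * (1 - pb[l]) / (mb[l] - 1)
    num <- num + nl
    den <- den + (1 - pa[l] * pb[l] - (1 - pa[l]) * (1 - pb[l]))
  }
  max(num / den, 0)
}

# running median with constant end rule, direct median computation
bf_runmed <- function(x, k) {
  half <- (k - 1) / 2
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in (half + 1):(n - half)) out[i] <- median(x[(i - half):(i + half)])
  out[1:half] <- out[half + 1]
  out[(n - half + 1):n] <- out[n - half]
  out
}

bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- rep(NA_real_, n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, n * p[o[i]] / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# neutral coalescent-like window: allele counts drawn from the standard
# neutral site-frequency spectrum P(c) proportional to 1/c, c = 1..n-1
bf_coalescent_window <- function(n_hap, n_sites) {
  probs <- 1 / seq_len(n_hap - 1)
  probs <- probs / sum(probs)
  H <- matrix(0L, n_sites, n_hap)
  for (l in seq_len(n_sites)) {
    c1 <- sample(seq_len(n_hap - 1), 1, prob = probs)
    H[l, sample(n_hap, c1)] <- 1L
  }
  H
}
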