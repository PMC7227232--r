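#' SNP-window specification for haplotype statistics
#'
#' Window statistics are computed over fixed-length windows of consecutive
#' SNVs and anchored at the window's centre SNP, so a centre exists only for
#' odd sizes. The defaults — 25-SNV windows advanced one SNV at a time with
#' no tolerated mismatching/missing SNVs — are the standard settings for
#' H1/H12 scans on dense array data.
#'
#' @param size_snps window length in SNVs (odd)
#' @param step_snps step between successive windows
#' @param mismatch_allow allowed missing/mismatching SNVs per window; 0 means
#'   any window touching a missing haplotype entry is undefined rather than
#'   imputed
#' @return a list of class `WindowSpec`
#' @export
window_spec <- function(size_snps = 25, step_snps = 1, mismatch_allow = 0) {
  stopifnot(size_snps %% 2 == 1, step_snps >= 1, mismatch_allow >= 0)
  structure(list(size_snps = as.integer(size_snps),
                 step_snps = as.integer(step_snps),
                 mismatch_allow = as.integer(mismatch_allow)),
            class = "WindowSpec")
}

#' Haplotype frequency spectrum of a SNP window
#'
#' Haplotypes are compared as exact allele strings over the window.
#'
#' @param H_window binary matrix, window SNPs x haplotypes, no missing entries
#' @return descending haplotype frequencies (sum to 1)
#' @export
haplotype_spectrum <- function(H_window) {
  H_window <- as.matrix(H_window)
  if (anyNA(H_window)) stop("window contains missing haplotype entries")
  if (ncol(H_window) == 0) stop("no haplotypes")
  key <- apply(H_window, 2, paste, collapse = "")
  cnt <- tabulate(match(key, unique(key)))
  sort(cnt, decreasing = TRUE) / ncol(H_window)
}

#' Haplotype homozygosity statistics H1 and H12
#'
#' H1 = sum of squared haplotype frequencies; H12 pools the two most frequent
#' haplotypes: H12 = (p1 + p2)^2 + sum over the rest of p_i^2, equivalently
#' H1 + 2 p1 p2. H12 gains power for incomplete/soft sweeps where the swept
#' lineage segregates as two frequent haplotypes.
#'
#' @param spectrum descending haplotype frequencies summing to 1
#' @return named numeric vector `c(H1 = ..., H12 = ...)`
#' @export
h1_h12 <- function(spectrum) {
  if (length(spectrum) == 0) stop("empty spectrum")
  h1 <- sum(spectrum^2)
  p2 <- if (length(spectrum) >= 2) spectrum[2] else 0
  c(H1 = h1, H12 = h1 + 2 * spectrum[1] * p2)
}

#' Sliding-window H1/H12 scan
#'
#' Computes H1 and H12 over sliding SNP windows of one breed's phased
#' haplotypes, chromosome by chromosome, anchoring each window at its centre
#' SNP. The first and last `(size - 1)/2` SNPs of every chromosome carry the
#' undefined sentinel; a chromosome with fewer SNPs than the window size
#' yields an all-sentinel track with a warning.
#'
#' @param H binary haplotype matrix, variants x haplotypes (no missing)
#' @param variants variant table aligned to `H`
#' @param spec a [window_spec()]
#' @param breed label recorded on the returned tracks
#' @return list of two [stat_track()]s named `H1` and `H12`
#' @export
scan_h_stats <- function(H, variants, spec = window_spec(), breed = "pop") {
  if (anyNA(H)) stop("haplotype matrix contains missing entries")
  w <- spec$size_snps
  half <- (w - 1L) %/% 2L
  nh <- ncol(H)
  h1 <- h12 <- rep(NA_real_, nrow(variants))
  for (ch in unique(variants$chrom)) {
    idx <- which(variants$chrom == ch)
    if (length(idx) < w) {
      warning("chromosome ", ch, " has fewer SNPs than the window size")
      next
    }
    hapstr <- apply(H[idx, , drop = FALSE], 2, paste, collapse = "")
    starts <- seq.int(1L, length(idx) - w + 1L, by = spec$step_snps)
    for (s in starts) {
      key <- substring(hapstr, s, s + w - 1L)
      p <- sort(tabulate(match(key, unique(key))), decreasing = TRUE) / nh
      centre <- idx[s + half]
      h1[centre] <- sum(p^2)
      h12[centre] <- h1[centre] +
        2 * p[1] * (if (length(p) >= 2) p[2] else 0)
    }
  }
  list(H1 = stat_track(h1, variants, "H1", breed),
       H12 = stat_track(h12, variants, "H12", breed))
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Sliding-window Tajima's D
#'
#' D contrasts the mean number of pairwise differences (pi-hat) with
#' Watterson's theta (S / a1) within each SNP window, normalised by the
#' standard variance constants; sweeps and expansions push D negative.
#' Windows follow the same centre-anchored convention as [scan_h_stats()];
#' monomorphic windows (S = 0) are undefined.
#'
#' @param H binary haplotype matrix, variants x haplotypes (no missing,
#'   at least 4 haplotypes)
#' @param variants variant table aligned to `H`
#' @param spec a [window_spec()]
#' @param breed label recorded on the returned track
#' @return a [stat_track()] named `TajimaD`
#' @export
tajima_d_windows <- function(H, variants, spec = window_spec(),
                             breed = "pop") {
  if (anyNA(H)) stop("haplotype matrix contains missing entries")
  n <- ncol(H)
  if (n < 4) stop("Tajima's D needs at least 4 haplotypes")
  k <- tajima_constants(n)
  w <- spec$size_snps
  half <- (w - 1L) %/% 2L
  out <- rep(NA_real_, nrow(variants))
  for (ch in unique(variants$chrom)) {
    idx <- which(variants$chrom == ch)
    if (length(idx) < w) next
    cnt <- rowSums(H[idx, , drop = FALSE])
    seg <- as.numeric(cnt > 0 & cnt < n)
    pairdiff <- cnt * (n - cnt) / choose(n, 2)
    cs <- c(0, cumsum(seg)); cp <- c(0, cumsum(pairdiff))
    starts <- seq.int(1L, length(idx) - w + 1L, by = spec$step_snps)
    S <- cs[starts + w] - cs[starts]
    pihat <- cp[starts + w] - cp[starts]
    D <- ifelse(S > 0,
                (pihat - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1)),
                NA_real_)
    out[idx[starts + half]] <- D
  }
  stat_track(out, variants, "TajimaD", breed)
}

# Weir & Cockerham (1984) two-population theta-hat components, vectorised
# over SNPs. n1/n2: called diploid counts; p1/p2: alt frequencies;
# h1/h2: observed heterozygote proportions.
wc_theta_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Per-SNP one-vs-rest Weir-Cockerham FST
#'
#' Treats the focal breed and the pooled remainder of the dataset as two
#' populations and computes the Weir & Cockerham (1984) variance-component
#' estimator theta-hat = a / (a + b + c) at every SNP. Missing genotypes are
#' excluded from the counts per SNP; negative estimates are truncated to
#' zero; SNPs monomorphic across both pools (zero denominator) or with fewer
#' than 2 called alleles in either pool are undefined.
#'
#' @param ds a `GenotypeDataset` with at least two breeds
#' @param focal_breed the breed contrasted against all others
#' @return a [stat_track()] named `FST` for the focal breed
#' @export
fst_one_vs_rest <- function(ds, focal_breed) {
  if (!focal_breed %in% ds$breed_of) stop("unknown breed: ", focal_breed)
  if (length(unique(ds$breed_of)) < 2) stop("need at least two breeds")
  in1 <- ds$breed_of == focal_breed
  G1 <- ds$G[, in1, drop = FALSE]
  G2 <- ds$G[, !in1, drop = FALSE]
  pool <- function(G) {
    n <- rowSums(!is.na(G))
    list(n = n,
         p = rowSums(G, na.rm = TRUE) / (2 * n),
         h = rowSums(G == 1L, na.rm = TRUE) / n)
  }
  s1 <- pool(G1); s2 <- pool(G2)
  comp <- wc_theta_components(s1$n, s1$p, s1$h, s2$n, s2$p, s2$h)
  den <- comp$a + comp$b + comp$c
  theta <- ifelse(s1$n >= 1 & s2$n >= 1 & is.finite(den) & den != 0,
                  comp$a / den, NA_real_)
  theta <- pmax(theta, 0)
  theta <- pmin(theta, 1)
  stat_track(theta, ds$variants, "FST", focal_breed)
}

#' Per-site nucleotide diversity
#'
#' pi at a site is the mean pairwise difference among the breed's called
#' alleles: n_ref * n_alt / choose(n, 2). Sites with fewer than 2 called
#' alleles are undefined; monomorphic sites are 0.
#'
#' @param ds a `GenotypeDataset`
#' @param breed breed to compute pi for
#' @return a [stat_track()] named `PI`
#' @export
site_pi <- function(ds, breed) {
  G <- breed_slice(ds, breed)$G
  n <- 2 * rowSums(!is.na(G))
  nalt <- rowSums(G, na.rm = TRUE)
  pi <- ifelse(n >= 2, nalt * (n - nalt) / choose(n, 2), NA_real_)
  stat_track(pi, ds$variants, "PI", breed)
}

#' Running-median smoothing of a track
#'
#' Applies a k-SNP running median per chromosome with the "constant" end
#' rule (the first and last (k-1)/2 values are set to the nearest interior
#' median). Undefined values are excluded before smoothing and reinserted as
#' sentinels; a chromosome with fewer than `k` defined values is returned
#' unsmoothed with a warning.
#'
#' @param track a [stat_track()]
#' @param k odd window size in SNPs
#' @return the smoothed [stat_track()]
#' @export
smooth_runmed <- function(track, k = 31) {
  stopifnot(k %% 2 == 1)
  out <- track$values
  for (ch in unique(track$variants$chrom)) {
    idx <- which(track$variants$chrom == ch)
    def <- idx[!is.na(track$values[idx])]
    if (length(def) == 0) next
    if (length(def) < k) {
      warning("chromosome ", ch, " has fewer than k defined values; ",
              "returned unsmoothed")
      next
    }
    out[def] <- as.numeric(stats::runmed(track$values[def], k,
                                         endrule = "constant"))
  }
  stat_track(out, track$variants, track$stat, track$breed,
             tail = track$tail, pi0 = track$pi0)
}
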