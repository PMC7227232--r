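# A tree counts as rooted if ape says so, or if it is a pure star (the
# basal node's children are all tips), which is the unambiguous rooted
# reading of a polytomy over populations. An unrooted tree with internal
# structure is rejected.
assert_rooted <- function(tree) {
  if (ape::is.rooted(tree)) return(invisible(tree))
  root <- ape::Ntip(tree) + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  if (all(kids <= ape::Ntip(tree))) return(invisible(tree))
  stop("tree must be rooted")
}

#' Per-population allele frequencies
#'
#' Alt-allele frequency and called allele count per population per SNP,
#' computed from observed genotypes (missing excluded). A SNP with no called
#' genotype in a population gets the sentinel.
#'
#' @param ds a `GenotypeDataset`
#' @param pops population labels (default: all breeds); each may also be a
#'   group label when `ds$group_of` is set, pooling that group's breeds
#' @return a list of class `AlleleFreqMatrix` with `freq` and `counts`
#'   matrices (variants x populations) and the `variants` table
#' @export
allele_frequencies <- function(ds, pops = breeds(ds)) {
  freq <- counts <- matrix(NA_real_, n_variants(ds), length(pops),
                           dimnames = list(NULL, pops))
  for (j in seq_along(pops)) {
    keep <- ds$breed_of == pops[j]
    if (!any(keep) && !is.null(ds$group_of))
      keep <- ds$group_of[ds$breed_of] == pops[j]
    if (!any(keep)) stop("empty population: ", pops[j])
    G <- ds$G[, keep, drop = FALSE]
    m <- 2 * rowSums(!is.na(G))
    counts[, j] <- m
    freq[, j] <- ifelse(m > 0, rowSums(G, na.rm = TRUE) / m, NA_real_)
  }
  structure(list(freq = freq, counts = counts, pops = pops,
                 variants = ds$variants),
            class = "AlleleFreqMatrix")
}

#' Reynolds genetic distances between populations
#'
#' Pairwise coancestry distance
#' D_R(a, b) = sum_l num_l / sum_l den_l with
#' num_l = (p_al - p_bl)^2 and den_l = p_al + p_bl - 2 p_al p_bl
#' (the biallelic form of the allele-shared-variance ratio). By default the
#' numerator subtracts the finite-sample terms p(1-p)/(m-1) for each
#' population, removing the O(1/m) upward bias that sample frequencies
#' otherwise add to every distance; `correct = FALSE` gives the plug-in
#' estimator. Loci with a sentinel frequency in either population are
#' skipped pairwise. Under pure drift E[D_R] is approximately half the
#' drift-scale patristic distance between the populations.
#'
#' @param freqs an [allele_frequencies()] result
#' @param correct subtract the finite-sample bias terms (default TRUE)
#' @return symmetric distance matrix with zero diagonal
#' @export
reynolds_distances <- function(freqs, correct = TRUE) {
  P <- freqs$freq
  M <- freqs$counts
  k <- ncol(P)
  D <- matrix(0, k, k, dimnames = list(freqs$pops, freqs$pops))
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    ok <- !is.na(P[, a]) & !is.na(P[, b])
    if (!any(ok)) stop("no loci with defined frequencies for pair ",
                       freqs$pops[a], "/", freqs$pops[b])
    pa <- P[ok, a]; pb <- P[ok, b]
    num <- (pa - pb)^2
    if (correct) {
      ma <- M[ok, a]; mb <- M[ok, b]
      num <- num - pa * (1 - pa) / (ma - 1) - pb * (1 - pb) / (mb - 1)
    }
    den <- sum(pa + pb - 2 * pa * pb)
    if (den == 0) stop("zero denominator: populations fixed identically")
    D[a, b] <- D[b, a] <- max(sum(num) / den, 0)
  }
  D
}

#' Neighbour-joining tree and midpoint rooting
#'
#' `nj_tree` builds the standard neighbour-joining tree from a symmetric
#' distance matrix (negative branch lengths clamped to zero with a warning);
#' two populations yield a single midpoint-split edge. `midpoint_root`
#' places the root at the centre of the longest leaf-to-leaf path.
#'
#' @param D symmetric distance matrix with population labels
#' @return an `ape::phylo` tree (unrooted from `nj_tree`, rooted from
#'   `midpoint_root`)
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix not symmetric")
  if (nrow(D) == 2) {
    tr <- ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                        rownames(D)[1], D[1, 2] / 2,
                                        rownames(D)[2], D[1, 2] / 2))
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(D))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    tr$edge.length <- pmax(tr$edge.length, 0)
  }
  tr
}

#' @rdname nj_tree
#' @param tree an `ape::phylo` tree
#' @export
midpoint_root <- function(tree) {
  if (ape::Ntip(tree) == 2) {
    tree$root.edge <- NULL
    return(tree)
  }
  phangorn::midpoint(tree)
}

#' Kinship matrix from a rooted drift tree
#'
#' F_ij is the summed length of the branches shared by the root-to-i and
#' root-to-j paths (the drift accumulated by both populations' lineages
#' before they split); F_ii is the total root-to-leaf drift. Computed as the
#' root-to-MRCA distance for every leaf pair.
#'
#' @param tree a rooted `ape::phylo` with non-negative branch lengths
#' @return symmetric kinship matrix with population labels
#' @export
kinship_from_tree <- function(tree) {
  assert_rooted(tree)
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  nt <- ape::Ntip(tree)
  root <- nt + 1L
  dn <- ape::dist.nodes(tree)
  mr <- ape::mrca(tree)
  Fm <- matrix(dn[root, mr], nt, nt,
               dimnames = list(tree$tip.label, tree$tip.label))
  diag(Fm) <- dn[root, seq_len(nt)]
  Fm
}

#' Full kinship model from allele frequencies
#'
#' Convenience pipeline: Reynolds distances, doubled onto the drift scale
#' (E[D_R] is half the patristic drift distance), neighbour joining, midpoint
#' rooting, kinship extraction.
#'
#' @param freqs an [allele_frequencies()] result
#' @param correct passed to [reynolds_distances()]
#' @return a list of class `KinshipModel` with `pops`, `D_R`, `tree`
#'   (rooted, drift-scale branch lengths) and `F`
#' @export
kinship_model <- function(freqs, correct = TRUE) {
  D_R <- reynolds_distances(freqs, correct = correct)
  tree <- midpoint_root(nj_tree(2 * D_R))
  structure(list(pops = freqs$pops, D_R = D_R, tree = tree,
                 F = kinship_from_tree(tree)[freqs$pops, freqs$pops]),
            class = "KinshipModel")
}

#' @exportS3Method base::print
print.KinshipModel <- function(x, ...) {
  cat("KinshipModel over", length(x$pops), "populations\n")
  cat("tree:", ape::write.tree(x$tree), "\n")
  print(round(x$F, 4))
  invisible(x)
}

#' Single-SNP FLK test
#'
#' Tests per-SNP allele-frequency differentiation against the neutral drift
#' expectation encoded in the kinship matrix F. The ancestral frequency is
#' the generalised-least-squares estimate
#' p0 = (1' V^-1 p) / (1' V^-1 1) and the statistic
#' T = (p - p0 1)' \[p0 (1 - p0) V\]^-1 (p - p0 1), chi-square with
#' n_pops - 1 degrees of freedom under neutrality. When per-population
#' allele counts are supplied, V = F + diag((1 - F_ii) / m_i) so the
#' binomial sampling variance of the observed frequencies is part of the
#' null; with `counts = NULL`, V = F (population frequencies assumed known).
#' SNPs with estimated p0 of exactly 0 or 1 (ancestrally monomorphic) or any
#' sentinel frequency are undefined.
#'
#' @param freqs an [allele_frequencies()] result
#' @param F kinship matrix over `freqs$pops`
#' @param counts per-population called allele counts used for the sampling
#'   variance term: `"auto"` (default) takes the median counts from `freqs`,
#'   `NULL` omits the term, or a numeric vector of length n_pops
#' @return a list of class `FLKResult` with per-SNP `stat` and `p0`, the
#'   degrees of freedom `df`, the chi-square p-values `p_chisq`, and the
#'   `variants` table
#' @export
flk_test <- function(freqs, F, counts = "auto") {
  P <- freqs$freq[, freqs$pops, drop = FALSE]
  F <- F[freqs$pops, freqs$pops, drop = FALSE]
  k <- ncol(P)
  if (identical(counts, "auto"))
    counts <- apply(freqs$counts, 2, stats::median, na.rm = TRUE)
  V <- F
  if (!is.null(counts))
    V <- V + diag((1 - diag(F)) / counts, k)
  Vi <- tryCatch(solve(V), error = function(e) {
    zero <- which(diag(V) == 0)
    stop("singular kinship matrix",
         if (length(zero)) paste0(" (zero drift branch for ",
                                  paste(freqs$pops[zero], collapse = ", "), ")"))
  })
  one <- rep(1, k)
  w <- as.vector(Vi %*% one)
  w <- w / sum(w)
  complete <- stats::complete.cases(P)
  p0 <- rep(NA_real_, nrow(P))
  p0[complete] <- P[complete, , drop = FALSE] %*% w
  T <- rep(NA_real_, nrow(P))
  ok <- complete & !is.na(p0) & p0 > 0 & p0 < 1
  Dm <- P[ok, , drop = FALSE] - p0[ok]
  T[ok] <- rowSums((Dm %*% Vi) * Dm) / (p0[ok] * (1 - p0[ok]))
  structure(list(stat = T, p0 = p0, df = k - 1,
                 p_chisq = stats::pchisq(T, k - 1, lower.tail = FALSE),
                 variants = freqs$variants),
            class = "FLKResult")
}

#' Track view of an FLK result
#'
#' @param res an [flk_test()] result
#' @param unit label recorded on the track (analysis unit)
#' @return a [stat_track()] named `FLK`
#' @export
flk_track <- function(res, unit = "all") {
  stat_track(res$stat, res$variants, "FLK", unit)
}

#' Read an externally computed hapFLK statistic track
#'
#' Whitespace-delimited file with columns rs, chr, pos, hapflk (a header
#' line is tolerated). Rows are matched to the loaded variant table by
#' chromosome and position; unmatched rows are dropped and counted in the
#' `n_dropped` attribute; a duplicated position is an error.
#'
#' @param path path to the track file
#' @param variants variant table to align to
#' @param unit label recorded on the track
#' @return a [stat_track()] named `HAPFLK`
#' @export
read_hapflk_track <- function(path, variants, unit = "all") {
  tb <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(tb) < 4) stop("expected columns rs, chr, pos, hapflk")
  if (suppressWarnings(is.na(as.numeric(tb[1, 4])))) tb <- tb[-1, , drop = FALSE]
  key <- paste(tb[[2]], tb[[3]])
  if (anyDuplicated(key)) stop("duplicated position in hapFLK track")
  vkey <- paste(variants$chrom, variants$pos)
  idx <- match(key, vkey)
  n_dropped <- sum(is.na(idx))
  if (all(is.na(idx))) stop("no hapFLK positions overlap the variant table")
  vals <- rep(NA_real_, nrow(variants))
  vals[idx[!is.na(idx)]] <- as.numeric(tb[[4]][!is.na(idx)])
  out <- stat_track(vals, variants, "HAPFLK", unit)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Robust-normal p- and q-values for an FLK-family track
#'
#' The genome-wide FLK (or hapFLK) distribution is modelled as normal except
#' for the outlying selected fraction: a robust M-estimated fit
#' ([fit_normal_robust()]) supplies mu and sigma, Z-transformed upper-tail
#' normal p-values follow ([normal_pvalues()]), and Storey q-values correct
#' for multiple testing ([storey_qvalues()]).
#'
#' @param track an FLK or hapFLK [stat_track()]
#' @return list with elements `fit`, `p` (p-value track) and `q` (q-value
#'   track)
#' @export
flk_pvalues <- function(track) {
  fit <- fit_normal_robust(track)
  p <- normal_pvalues(track, fit)
  list(fit = fit, p = p, q = storey_qvalues(p))
}
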