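test_that("allele frequencies count alleles per population", {
  G <- rbind(c(0L, 1L, 2L, 0L, 0L),
             c(2L, 2L, 2L, 1L, 1L),
             c(0L, 0L, 0L, 2L, 2L),
             c(NA, NA, NA, 1L, 0L),
             c(1L, 0L, 1L, NA, 2L))
  colnames(G) <- paste0("s", 1:5)
  b <- setNames(c("A", "A", "A", "B", "B"), colnames(G))
  ds <- toy_dataset(G, breed_of = b)
  af <- allele_frequencies(ds)
  # hand counting
  expect_equal(unname(af$freq[, "A"]), c(3 / 6, 6 / 6, 0, NA, 2 / 6))
  expect_equal(unname(af$freq[, "B"]), c(0, 2 / 4, 4 / 4, 1 / 4, 2 / 2))
  expect_equal(unname(af$counts[, "A"]), c(6, 6, 6, 0, 6))
  expect_true(is.na(af$freq[4, "A"]))
  expect_error(allele_frequencies(ds, pops = c("A", "Z")), "empty population")
})

test_that("Reynolds distances match the oracle and are relabeling-invariant", {
  # identical frequency vectors -> 0
  mk <- function(freq, counts) structure(
    list(freq = freq, counts = counts, pops = colnames(freq),
         variants = NULL), class = "AlleleFreqMatrix")
  f <- cbind(A = c(0.2, 0.5, 0.8), B = c(0.2, 0.5, 0.8))
  cnt <- matrix(40, 3, 2, dimnames = list(NULL, c("A", "B")))
  expect_equal(unname(reynolds_distances(mk(f, cnt))["A", "B"]), 0)
  # single fixed-difference locus -> 1 (uncorrected and corrected agree)
  f1 <- cbind(A = 1, B = 0)
  c1 <- matrix(40, 1, 2, dimnames = list(NULL, c("A", "B")))
  expect_equal(unname(reynolds_distances(mk(f1, c1))["A", "B"]), 1)
  expect_equal(unname(reynolds_distances(mk(f1, c1), correct = FALSE)["A", "B"]), 1)
  # 3-pop, 10-locus fixture vs brute force, both variants
  set.seed(16)
  f3 <- cbind(A = runif(10), B = runif(10), C = runif(10))
  c3 <- matrix(sample(c(20, 40, 60), 30, replace = TRUE), 10, 3,
               dimnames = list(NULL, c("A", "B", "C")))
  D <- reynolds_distances(mk(f3, c3))
  Du <- reynolds_distances(mk(f3, c3), correct = FALSE)
  for (a in 1:2) for (b in (a + 1):3) {
    expect_equal(D[a, b], bf_reynolds(f3[, a], f3[, b], c3[, a], c3[, b]))
    expect_equal(Du[a, b], bf_reynolds(f3[, a], f3[, b]))
  }
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 3))
  # relabeling p -> 1 - p at a subset of loci leaves D unchanged
  f3r <- f3; f3r[c(2, 5, 9), ] <- 1 - f3[c(2, 5, 9), ]
  expect_equal(reynolds_distances(mk(f3r, c3)), D)
  # identically fixed everywhere -> zero denominator error
  ffix <- cbind(A = c(1, 0), B = c(1, 0))
  cfix <- matrix(40, 2, 2, dimnames = list(NULL, c("A", "B")))
  expect_error(reynolds_distances(mk(ffix, cfix)), "denominator")
})

test_that("NJ recovers additive trees; midpoint rooting behaves", {
  # additive 4-taxon matrix from a known tree ((A:1,B:2):1.5,(C:0.5,D:3))
  D <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  bl <- c(A = 1, B = 2, C = 0.5, D = 3); int <- 1.5
  D["A", "B"] <- D["B", "A"] <- bl["A"] + bl["B"]
  D["C", "D"] <- D["D", "C"] <- bl["C"] + bl["D"]
  for (x in c("A", "B")) for (y in c("C", "D"))
    D[x, y] <- D[y, x] <- bl[x] + int + bl[y]
  tr <- nj_tree(D)
  expect_equal(sort(ape::dist.nodes(tr)[1:4, 1:4][upper.tri(diag(4))]),
               sort(D[upper.tri(D)]), tolerance = 1e-10)
  # patristic distances of the rooted tree still match the input
  rt <- midpoint_root(tr)
  pd <- ape::cophenetic.phylo(rt)[rownames(D), colnames(D)]
  expect_equal(pd, D, tolerance = 1e-10)
  # 2 populations at distance d -> two branches of d/2
  D2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- midpoint_root(nj_tree(D2))
  expect_equal(sort(t2$edge.length), c(0.15, 0.15))
  # ultrametric 3-taxon: midpoint root equidistant from all leaves
  D3 <- matrix(0.2, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(D3) <- 0
  r3 <- midpoint_root(nj_tree(D3))
  dr <- ape::dist.nodes(r3)[ape::Ntip(r3) + 1, 1:3]
  expect_equal(unname(dr), rep(0.1, 3), tolerance = 1e-10)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("kinship from a rooted tree is the shared root-path drift", {
  # star tree with equal branches f: F = f * I
  star <- ape::read.tree(text = "(A:0.07,B:0.07,C:0.07);")
  Fs <- kinship_from_tree(star)
  expect_equal(unname(Fs), diag(0.07, 3))
  # caterpillar ((A:1,B:1):1,C:2)
  cat3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  Fc <- kinship_from_tree(cat3)
  expect_equal(Fc["A", "B"], 1)
  expect_equal(Fc["A", "C"], 0)
  expect_equal(Fc["B", "C"], 0)
  expect_equal(unname(diag(Fc[c("A", "B", "C"), c("A", "B", "C")])),
               c(2, 2, 2))
  # F_ii + F_jj - 2 F_ij equals the patristic distance, any random tree
  set.seed(17)
  rt <- ape::rtree(6)
  Fm <- kinship_from_tree(rt)
  pd <- ape::cophenetic.phylo(rt)
  for (i in 1:5) for (j in (i + 1):6) {
    a <- rt$tip.label[i]; b <- rt$tip.label[j]
    expect_equal(Fm[a, a] + Fm[b, b] - 2 * Fm[a, b], pd[a, b],
                 tolerance = 1e-10)
  }
  expect_error(kinship_from_tree(ape::unroot(ape::rtree(4))), "rooted")
})

test_that("FLK statistic: zero on shared frequencies, symmetric to relabeling", {
  pops <- c("A", "B", "C")
  mkf <- function(freq, m = 40) structure(
    list(freq = freq, counts = matrix(m, nrow(freq), ncol(freq)),
         pops = pops,
         variants = data.frame(chrom = "1", pos = seq_len(nrow(freq)) * 10,
                               vid = paste0("v", seq_len(nrow(freq))),
                               ref = "A", alt = "G")),
    class = "AlleleFreqMatrix")
  Fm <- diag(0.05, 3); dimnames(Fm) <- list(pops, pops)
  shared <- matrix(rep(c(0.3, 0.6), 3), 2, 3, dimnames = list(NULL, pops))
  res <- flk_test(mkf(shared), Fm, counts = NULL)
  expect_equal(res$stat, c(0, 0))
  expect_equal(res$df, 2)
  # allele relabeling p -> 1 - p leaves T unchanged
  set.seed(18)
  P <- matrix(runif(30, 0.1, 0.9), 10, 3, dimnames = list(NULL, pops))
  t1 <- flk_test(mkf(P), Fm)
  t2 <- flk_test(mkf(1 - P), Fm)
  expect_equal(t1$stat, t2$stat)
  expect_equal(t1$p0, 1 - t2$p0)
  # 2-population star kinship reduces to the closed form
  pops2 <- c("A", "B")
  F2 <- diag(c(0.1, 0.2)); dimnames(F2) <- list(pops2, pops2)
  P2 <- matrix(c(0.7, 0.4), 1, 2, dimnames = list(NULL, pops2))
  f2 <- structure(list(freq = P2, counts = matrix(40, 1, 2), pops = pops2,
                       variants = data.frame(chrom = "1", pos = 10,
                                             vid = "v1", ref = "A",
                                             alt = "G")),
                  class = "AlleleFreqMatrix")
  got <- flk_test(f2, F2, counts = NULL)
  # closed form: p0 = GLS mean with V = diag(F); T = (p - p0)' V^-1 (p - p0)
  # / (p0 (1 - p0)) which for 2 pops is (p1 - p2)^2 / ((F1 + F2) p0 q0)
  w <- (1 / diag(F2)) / sum(1 / diag(F2))
  p0 <- sum(w * P2)
  Tc <- (P2[1] - P2[2])^2 / ((0.1 + 0.2) * p0 * (1 - p0))
  expect_equal(got$stat, unname(Tc))
  # singular kinship names the zero-drift population
  F0 <- diag(c(0.1, 0)); dimnames(F0) <- list(pops2, pops2)
  expect_error(flk_test(f2, F0, counts = NULL), "B")
})

test_that("hapFLK track reader aligns by position and logs drops", {
  v <- data.frame(chrom = c("1", "1", "2"), pos = c(100L, 200L, 50L),
                  vid = paste0("v", 1:3), ref = "A", alt = "G")
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("rs chr pos hapflk",
               "v1 1 100 1.5", "v2 1 200 2.5", "v3 2 50 3.5"), path)
  tr <- read_hapflk_track(path, v)
  expect_equal(tr$values, c(1.5, 2.5, 3.5))
  writeLines(c("v1 1 100 1.5", "vX 9 999 9.9"), path)
  tr2 <- read_hapflk_track(path, v)
  expect_equal(attr(tr2, "n_dropped"), 1)
  expect_equal(tr2$values, c(1.5, NA, NA))
  writeLines(c("v1 1 100 1.5", "v1b 1 100 2.0"), path)
  expect_error(read_hapflk_track(path, v), "duplicated")
  writeLines("vX 9 999 9.9", path)
  expect_error(read_hapflk_track(path, v), "overlap")
})

test_that("robust-normal FLK post-processing is calibrated and shift-invariant", {
  set.seed(19)
  x <- rnorm(20000, mean = 5, sd = 2)
  tr <- toy_track(x, chrom = rep("1", length(x)),
                  pos = seq_along(x) * 100L, stat = "HAPFLK")
  out <- flk_pvalues(tr)
  expect_lt(mean(out$q$values < 0.01), 0.01)
  # outliers receive the smallest p-values
  x2 <- x; x2[1:200] <- x[1:200] + 15
  out2 <- flk_pvalues(toy_track(x2, pos = seq_along(x) * 100L))
  expect_lt(max(out2$p$values[1:200]), min(out2$p$values[-(1:200)]))
  # constant shift leaves p unchanged
  out3 <- flk_pvalues(toy_track(x + 100, pos = seq_along(x) * 100L))
  expect_equal(out3$p$values, out$p$values, tolerance = 1e-6)
})
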