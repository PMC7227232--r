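test_that("region calling follows the seed/boundary run rule", {
  # single significant SNP -> 1-bp region
  r1 <- call_regions(toy_qtrack(c(0.5, 0.005, 0.5)))
  expect_equal(nrow(r1), 1)
  expect_equal(r1$start, r1$end)
  expect_equal(r1$start, 2000L)
  expect_equal(r1$n_snps, 1)
  # run of q <= 0.1 around a seed spans SNPs 2-4
  r2 <- call_regions(toy_qtrack(c(0.5, 0.05, 0.005, 0.08, 0.5)))
  expect_equal(nrow(r2), 1)
  expect_equal(c(r2$start, r2$end), c(2000L, 4000L))
  expect_equal(r2$n_snps, 3)
  expect_equal(r2$q_min, 0.005)
  # no SNP below seed_q -> no regions
  expect_equal(nrow(call_regions(toy_qtrack(c(0.5, 0.05, 0.02)))), 0)
  # runs never span chromosomes; sentinels break runs
  q <- c(0.005, 0.05, 0.05, 0.005)
  r3 <- call_regions(toy_qtrack(q, chrom = c("1", "1", "2", "2")))
  expect_equal(nrow(r3), 2)
  r4 <- call_regions(toy_qtrack(c(0.005, NA, 0.005)))
  expect_equal(nrow(r4), 2)
  # unsorted positions error
  expect_error(call_regions(toy_qtrack(c(0.5, 0.005), pos = c(200L, 100L))),
               "sorted")
  # peak is the largest statistic when a stat track is given
  st <- toy_track(c(0, 5, 9, 2, 0))
  r5 <- call_regions(toy_qtrack(c(0.5, 0.05, 0.005, 0.08, 0.5)), st)
  expect_equal(r5$peak_pos, 3000L)
  expect_equal(r5$peak_stat, 9)
})

test_that("region counts are monotone in the two thresholds", {
  set.seed(20)
  q <- runif(500)^3
  qt <- toy_qtrack(q)
  base <- call_regions(qt, seed_q = 0.01, bound_q = 0.1)
  stricter <- call_regions(qt, seed_q = 0.002, bound_q = 0.1)
  expect_lte(nrow(stricter), nrow(base))
  wider <- call_regions(qt, seed_q = 0.01, bound_q = 0.3)
  expect_lte(nrow(wider), nrow(base))  # runs merge, never split
  # every base region is contained in some wider region
  for (i in seq_len(nrow(base))) {
    hit <- wider$start <= base$start[i] & wider$end >= base$end[i]
    expect_true(any(hit))
  }
  # regions pairwise disjoint and sorted
  if (nrow(base) > 1) {
    expect_true(all(diff(base$start) > 0))
    expect_true(all(base$start[-1] > base$end[-nrow(base)]))
  }
})

test_that("gene windows follow the 1-sigma drop-from-peak rule", {
  ann <- toy_annotation(
    list(name = "G1", chrom = "1", start = 1500, end = 2500),
    list(name = "G2", chrom = "1", start = 3500, end = 4500),
    list(name = "G3", chrom = "1", start = 8200, end = 8900))
  # flat statistic: gene window = whole region
  st <- toy_track(c(1, 5, 5, 5, 1, 1, 1, 1, 1))
  region <- data.frame(chrom = "1", start = 2000, end = 4000,
                       peak_pos = 3000, stringsAsFactors = FALSE)
  g <- identify_genes(region, st, ann, sigma = 1)
  expect_setequal(g$name, c("G1", "G2"))
  # sharp peak: neighbours below peak - sigma, window shrinks to the peak
  # SNP (pos 3000), which no fixture gene spans -> empty
  st2 <- toy_track(c(1, 1, 9, 1, 1, 1, 1, 1, 1))
  g2 <- identify_genes(region, st2, ann, sigma = 1)
  expect_equal(nrow(g2), 0)
  # plateau within sigma: genes on the plateau returned, distal excluded
  st3 <- toy_track(c(1, 8.5, 9, 8.6, 1, 1, 1, 1, 1))
  region3 <- data.frame(chrom = "1", start = 2000, end = 4000,
                        peak_pos = 3000, stringsAsFactors = FALSE)
  g3 <- identify_genes(region3, st3, ann, sigma = 1)
  expect_setequal(g3$name, c("G1", "G2"))
  expect_false("G3" %in% g3$name)
  # annotation on another chromosome: empty with warning
  ann9 <- toy_annotation(list(name = "GX", chrom = "9", start = 1, end = 10))
  expect_warning(gx <- identify_genes(region, st, ann9, sigma = 1), "absent")
  expect_equal(nrow(gx), 0)
})

test_that("gene window check: sharp single-SNP peak keeps only spanning genes", {
  ann <- toy_annotation(
    list(name = "SPAN", chrom = "1", start = 2900, end = 3100),
    list(name = "NEAR", chrom = "1", start = 2000, end = 2600))
  st2 <- toy_track(c(1, 1, 9, 1, 1))
  region <- data.frame(chrom = "1", start = 1000, end = 5000,
                       peak_pos = 3000, stringsAsFactors = FALSE)
  g <- identify_genes(region, st2, ann, sigma = 1)
  expect_equal(g$name, "SPAN")
})

test_that("gene ranking is by distance with deterministic tie-breaks", {
  peak <- 10000
  # distances from the peak: span 0 (contains it), tieA 500 (end 9500),
  # tieB 500 (start 10500), far 10000
  genes <- toy_annotation(
    list(name = "span", chrom = "1", start = 9000, end = 11000),
    list(name = "tieB", chrom = "1", start = 10500, end = 12000),
    list(name = "tieA", chrom = "1", start = 8000, end = 9500),
    list(name = "far", chrom = "1", start = 20000, end = 21000))
  ranked <- rank_genes(genes, peak)
  expect_equal(ranked$rank, 1:4)
  expect_equal(ranked$name, c("span", "tieA", "tieB", "far"))
  expect_equal(ranked$distance, c(0, 500, 500, 10000))
  # reversing input order leaves output identical
  ranked2 <- rank_genes(genes[4:1, ], peak)
  expect_equal(ranked2$name, ranked$name)
  expect_error(rank_genes(genes[0, ], peak), "empty")
})

test_that("overlap report counts regions and shared base pairs", {
  a <- data.frame(chrom = "1", start = 100, end = 200)
  b <- data.frame(chrom = "1", start = 150, end = 300)
  rep1 <- overlap_regions(a, b)
  expect_equal(rep1$shared_bp, 51)   # 1-based inclusive
  expect_equal(rep1$fraction, 1)
  expect_equal(overlap_regions(a, a),
               list(n_a = 1L, n_overlapping = 1L, fraction = 1,
                    shared_bp = 101))
  disj <- data.frame(chrom = "1", start = 500, end = 600)
  expect_equal(overlap_regions(a, disj)$fraction, 0)
  expect_equal(overlap_regions(a, disj)$shared_bp, 0)
  # 3/5 overlapping fixture
  a5 <- data.frame(chrom = "1", start = c(1, 100, 200, 300, 400) * 10,
                   end = c(1, 100, 200, 300, 400) * 10 + 5)
  b3 <- data.frame(chrom = "1", start = c(10, 1000, 4000), end = c(12, 1003, 4002))
  expect_equal(overlap_regions(a5, b3)$fraction, 0.6)
})

test_that("regions round-trip through TSV and BED conversion is 0-based", {
  regions <- data.frame(chrom = c("1", "2"), start = c(100L, 5000L),
                        end = c(200L, 5000L), peak_vid = c("v1", "v2"),
                        peak_pos = c(150L, 5000L), peak_stat = c(9.1, 3.3),
                        q_min = c(1e-5, 0.004), unit = "B1",
                        method = "DCMS", n_snps = c(12L, 1L),
                        stringsAsFactors = FALSE)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_regions(regions, NULL, bed_path = bed, tsv_path = tsv)
  back <- read_regions(tsv)
  for (col in c("chrom", "start", "end", "q_min", "unit", "method",
                "n_snps", "peak_pos"))
    expect_equal(back[[col]], regions[[col]])
  bed_tb <- utils::read.table(bed, sep = "\t")
  expect_equal(bed_tb$V2, regions$start - 1L)
  expect_equal(bed_tb$V3, regions$end)
  expect_equal(bed_tb$V5[1], 50)   # -10 log10(1e-5)
  # empty set writes a header-only TSV
  write_regions(regions[0, ], NULL, tsv_path = tsv)
  expect_equal(nrow(read_regions(tsv)), 0)
})

test_that("candidate gene strings collapse same-prefix runs of three or more", {
  ranked <- data.frame(gene_id = c("KRT71", "KRT72", "KRT74"),
                       name = c("KRT71", "KRT72", "KRT74"),
                       chrom = "1", start = c(1, 10, 20) * 1000,
                       end = c(1, 10, 20) * 1000 + 100, strand = "+",
                       distance = c(0, 100, 200), rank = 1:3,
                       stringsAsFactors = FALSE)
  expect_equal(sweepscan:::gene_label_string(ranked), "KRT@ (1-3)")
  ranked2 <- ranked[1:2, ]
  expect_equal(sweepscan:::gene_label_string(ranked2), "KRT71(1);KRT72(2)")
  mixed <- ranked
  mixed$name <- c("KRT71", "ABCB1", "KRT74")
  expect_equal(sweepscan:::gene_label_string(mixed),
               "KRT71(1);ABCB1(2);KRT74(3)")
})

test_that("GFF3 annotation round trip preserves gene records", {
  ann <- toy_annotation(
    list(name = "GENE0001", chrom = "1", start = 100, end = 900),
    list(name = "KRT71", chrom = "2", start = 5000, end = 5600))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gene_annotation(ann, path)
  back <- read_gene_annotation(path)
  expect_equal(back$name, ann$name)
  expect_equal(back$start, ann$start)
  expect_equal(back$end, ann$end)
  expect_equal(back$chrom, ann$chrom)
})
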