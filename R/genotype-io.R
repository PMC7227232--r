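#' Read a breed membership table
#'
#' Two-column TSV (sample, breed) with an optional third column giving the
#' analysis group of the breed. A header line is tolerated when its first
#' field is "sample".
#'
#' @param path path to the TSV file
#' @return data.frame with columns `sample`, `breed` and optionally `group`
#' @export
read_breed_table <- function(path) {
  tb <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (tolower(tb[1, 1]) == "sample") tb <- tb[-1, , drop = FALSE]
  names(tb) <- c("sample", "breed", "group")[seq_len(ncol(tb))]
  rownames(tb) <- NULL
  tb
}

breed_map_from_table <- function(breed_table) {
  if (is.character(breed_table)) breed_table <- read_breed_table(breed_table)
  stats::setNames(breed_table$breed, breed_table$sample)
}

group_map_from_table <- function(breed_table) {
  if (is.character(breed_table)) breed_table <- read_breed_table(breed_table)
  if (!"group" %in% names(breed_table)) return(NULL)
  g <- breed_table[!duplicated(breed_table$breed), ]
  stats::setNames(g$group, g$breed)
}

#' Read genotypes from a VCF file
#'
#' Only the GT field is used. Records with more than one ALT allele are
#' skipped (their count is attached to the result as attribute
#' `skipped_multiallelic`). When every genotype in the file is phased (`|`)
#' and called, the phased haplotype matrix `H` is populated alongside the
#' dosage matrix `G`; any unphased or missing genotype leaves the dataset
#' unphased (`H = NULL`), since haplotype matrices never carry missing
#' entries.
#'
#' @param path path to a VCF 4.x file (plain text or bgzipped)
#' @param breed_table breed membership: a data.frame as returned by
#'   [read_breed_table()] or a path to one. Every VCF sample must appear.
#' @return a [genotype_dataset()]
#' @export
read_vcf <- function(path, breed_table) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix[, c("CHROM", "POS", "ID", "REF", "ALT"),
                             drop = FALSE],
                       stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE) | nchar(fix$ALT) != 1L |
    nchar(fix$REF) != 1L
  n_skip <- sum(multi)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  samples <- colnames(gt)
  bmap <- breed_map_from_table(breed_table)
  offenders <- setdiff(samples, names(bmap))
  if (length(offenders) > 0)
    stop("VCF samples absent from breed table: ",
         paste(offenders, collapse = ", "))
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         vid = ifelse(is.na(fix$ID) | fix$ID == ".",
                                      paste0(fix$CHROM, ":", fix$POS), fix$ID),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (any(diff(p) <= 0))
      stop("VCF positions not strictly increasing on chromosome ", ch)
  }
  a1 <- substr(gt, 1, 1)
  sep <- substr(gt, 2, 2)
  a2 <- substr(gt, 3, 3)
  miss <- is.na(gt) | a1 == "." | a2 == "."
  G <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  G[!miss] <- as.integer(a1[!miss]) + as.integer(a2[!miss])
  H <- NULL
  if (!any(miss) && all(sep == "|")) {
    H <- matrix(0L, nrow(gt), 2L * ncol(gt))
    H[, seq(1L, ncol(H), 2L)] <- as.integer(a1)
    H[, seq(2L, ncol(H), 2L)] <- as.integer(a2)
    colnames(H) <- paste0(rep(samples, each = 2L), "_", c(1L, 2L))
  }
  ds <- genotype_dataset(variants, G, bmap,
                         H = H, group_of = group_map_from_table(breed_table))
  attr(ds, "skipped_multiallelic") <- n_skip
  ds
}

#' Read genotypes from PLINK text files (.ped / .map)
#'
#' Alleles are recoded to alt-allele dosages with the alt allele taken as the
#' minor allele computed across all samples; when the two alleles are equally
#' frequent the lexicographically larger symbol becomes alt. The PLINK
#' missing code `0` yields a missing dosage. The result is unphased.
#'
#' @param ped_path whitespace-delimited .ped file (FID IID PAT MAT SEX PHENO
#'   followed by two allele columns per SNP)
#' @param map_path whitespace-delimited .map file (chrom, vid, cM, pos)
#' @param breed_table as in [read_vcf()]; samples are the .ped IID column
#' @return a [genotype_dataset()]
#' @export
read_plink_text <- function(ped_path, map_path, breed_table) {
  map <- utils::read.table(map_path, header = FALSE, colClasses = "character")
  names(map) <- c("chrom", "vid", "cm", "pos")
  ped <- utils::read.table(ped_path, header = FALSE, colClasses = "character")
  n_snp <- nrow(map)
  if (ncol(ped) != 6L + 2L * n_snp)
    stop(".ped has ", (ncol(ped) - 6L) / 2, " SNPs but .map has ", n_snp)
  samples <- ped[[2]]
  A1 <- t(as.matrix(ped[, 6L + 2L * seq_len(n_snp) - 1L, drop = FALSE]))
  A2 <- t(as.matrix(ped[, 6L + 2L * seq_len(n_snp), drop = FALSE]))
  G <- matrix(NA_integer_, n_snp, length(samples),
              dimnames = list(NULL, samples))
  ref <- alt <- character(n_snp)
  for (j in seq_len(n_snp)) {
    al <- c(A1[j, ], A2[j, ])
    obs <- al != "0"
    tab <- sort(table(al[obs]))
    sym <- names(tab)
    if (length(sym) > 2L)
      stop("SNP ", map$vid[j], " has more than two alleles")
    if (length(sym) == 0L) { ref[j] <- alt[j] <- "N"; next }
    if (length(sym) == 1L) {
      ref[j] <- sym; alt[j] <- sym
    } else if (tab[1] == tab[2]) {
      # tie: lexicographically larger allele is alt
      alt[j] <- max(sym); ref[j] <- min(sym)
    } else {
      alt[j] <- sym[1]; ref[j] <- sym[2]
    }
    d <- (A1[j, ] == alt[j]) + (A2[j, ] == alt[j])
    d[A1[j, ] == "0" | A2[j, ] == "0"] <- NA
    G[j, ] <- as.integer(d)
  }
  variants <- data.frame(chrom = map$chrom, pos = as.integer(map$pos),
                         vid = map$vid, ref = ref, alt = alt,
                         stringsAsFactors = FALSE)
  ord <- order(match(variants$chrom, unique(variants$chrom)), variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  genotype_dataset(variants, G[ord, , drop = FALSE],
                   breed_map_from_table(breed_table),
                   group_of = group_map_from_table(breed_table))
}

#' QC filter configuration
#'
#' Defaults follow standard SNP-array practice for selection scans:
#' minor-allele frequency at least 0.05, loci called in at least 99% of
#' samples, samples called at at least 95% of loci, autosomes 1-26 (the ovine
#' autosome set).
#'
#' @param maf_min minimum minor-allele frequency retained
#' @param locus_missing_max maximum per-locus missing fraction retained
#' @param sample_missing_max maximum per-sample missing fraction retained
#' @param autosomes chromosome labels retained
#' @return a list of class `QCConfig`
#' @export
qc_config <- function(maf_min = 0.05, locus_missing_max = 0.01,
                      sample_missing_max = 0.05,
                      autosomes = as.character(1:26)) {
  stopifnot(maf_min >= 0, maf_min <= 1,
            locus_missing_max >= 0, locus_missing_max <= 1,
            sample_missing_max >= 0, sample_missing_max <= 1)
  structure(list(maf_min = maf_min, locus_missing_max = locus_missing_max,
                 sample_missing_max = sample_missing_max,
                 autosomes = as.character(autosomes)),
            class = "QCConfig")
}

#' Apply QC filters to a genotype dataset
#'
#' Filters are applied in a fixed order: (1) restriction to the configured
#' autosome set (a coordinate restriction, applied first), (2) removal of
#' samples whose missing fraction exceeds `sample_missing_max`, (3) removal
#' of loci whose missing fraction — recomputed on the surviving samples —
#' exceeds `locus_missing_max`, (4) removal of loci with minor-allele
#' frequency below `maf_min`. The order mirrors how standard genotype
#' toolkits stage their filters; the attached report records the count
#' removed at every step so other orders can be audited.
#'
#' MAF is computed across the dataset being filtered, so per-group QC is
#' obtained by slicing to the analysis unit before calling `apply_qc`.
#'
#' @param ds a `GenotypeDataset`
#' @param qc a [qc_config()]
#' @return the filtered `GenotypeDataset`, with a `qc_report` element (a list
#'   of per-step removal counts) added
#' @export
apply_qc <- function(ds, qc = qc_config()) {
  if (n_variants(ds) == 0 || n_samples(ds) == 0) stop("empty dataset")
  report <- list(n_variants_in = n_variants(ds), n_samples_in = n_samples(ds))

  keep_v <- ds$variants$chrom %in% qc$autosomes
  report$removed_nonautosomal <- sum(!keep_v)
  if (!any(keep_v)) stop("QC removed all variants (autosome restriction)")
  ds <- subset_variants(ds, keep_v)

  smiss <- colMeans(is.na(ds$G))
  keep_s <- smiss <= qc$sample_missing_max
  report$removed_sample_missingness <- sum(!keep_s)
  if (!any(keep_s)) stop("QC removed all samples (sample missingness)")
  if (!all(keep_s)) ds <- subset_samples(ds, ds$samples[keep_s])

  lmiss <- rowMeans(is.na(ds$G))
  keep_v <- lmiss <= qc$locus_missing_max
  report$removed_locus_missingness <- sum(!keep_v)
  if (!any(keep_v)) stop("QC removed all variants (locus missingness)")
  ds <- subset_variants(ds, keep_v)

  f <- alt_freq(ds)
  maf <- pmin(f, 1 - f)
  keep_v <- !is.na(maf) & maf >= qc$maf_min
  report$removed_maf <- sum(!keep_v)
  if (!any(keep_v)) stop("QC removed all variants (MAF)")
  ds <- subset_variants(ds, keep_v)

  report$n_variants_out <- n_variants(ds)
  report$n_samples_out <- n_samples(ds)
  ds$qc_report <- report
  ds
}

#' Write a dataset as a plain-text VCF
#'
#' Emits a minimal VCF 4.2 with the GT field only: phased `a|b` genotypes
#' when the dataset carries haplotypes, `a/b` (and `./.` for missing)
#' otherwise. Readable back with [read_vcf()].
#'
#' @param ds a `GenotypeDataset`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_vcf <- function(ds, path) {
  n <- n_variants(ds)
  if (!is.null(ds$H)) {
    a1 <- ds$H[, seq(1L, ncol(ds$H), 2L), drop = FALSE]
    a2 <- ds$H[, seq(2L, ncol(ds$H), 2L), drop = FALSE]
    gt <- matrix(paste0(a1, "|", a2), n)
  } else {
    g <- ds$G
    gt <- matrix("./.", n, ncol(g))
    gt[!is.na(g) & g == 0L] <- "0/0"
    gt[!is.na(g) & g == 1L] <- "0/1"
    gt[!is.na(g) & g == 2L] <- "1/1"
  }
  body <- paste(ds$variants$chrom, ds$variants$pos, ds$variants$vid,
                ds$variants$ref, ds$variants$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ds$samples), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the breed membership table of a dataset
#'
#' @param ds a `GenotypeDataset`
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_breed_table <- function(ds, path) {
  tb <- data.frame(sample = ds$samples, breed = unname(ds$breed_of))
  if (!is.null(ds$group_of)) tb$group <- unname(ds$group_of[tb$breed])
  utils::write.table(tb, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
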