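#' Multi-breed genotype dataset
#'
#' The central container of the package: a variant table plus a variants x
#' samples matrix of alt-allele dosages, an optional phased haplotype matrix,
#' and a sample-to-breed membership map. All downstream statistics operate on
#' breed slices of this object.
#'
#' @param variants data.frame with columns `chrom` (character), `pos`
#'   (integer, 1-based), `vid` (variant identifier), `ref`, `alt` (allele
#'   symbols). Positions must be strictly increasing within each chromosome
#'   and every variant biallelic.
#' @param G integer matrix, variants x samples, of alt-allele dosages in
#'   `{0, 1, 2}` with `NA` marking a missing genotype.
#' @param breed_of named character vector mapping every sample (names) to
#'   exactly one breed.
#' @param H optional integer matrix, variants x (2 * samples), of phased
#'   binary haplotypes. Columns `2i - 1` and `2i` belong to sample `i` and
#'   must sum to `G[, i]` wherever `G` is observed. `H` never contains `NA`.
#' @param group_of optional named character vector mapping breeds to analysis
#'   groups.
#'
#' @return An object of class `GenotypeDataset`: a list with elements
#'   `variants`, `samples`, `breed_of`, `group_of`, `G`, `H`.
#' @export
genotype_dataset <- function(variants, G, breed_of, H = NULL, group_of = NULL) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "vid", "ref", "alt") %in% names(variants)))
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  G <- as.matrix(G)
  storage.mode(G) <- "integer"
  rownames(G) <- NULL
  if (nrow(G) != nrow(variants))
    stop("G must have one row per variant")
  samples <- colnames(G)
  if (is.null(samples)) stop("G must carry sample identifiers as colnames")
  missing_breed <- setdiff(samples, names(breed_of))
  if (length(missing_breed) > 0)
    stop("samples without a breed assignment: ",
         paste(missing_breed, collapse = ", "))
  breed_of <- breed_of[samples]
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  ok <- is.na(G) | (G >= 0L & G <= 2L)
  if (!all(ok)) stop("G entries must be 0, 1, 2 or NA")
  if (!is.null(H)) {
    H <- as.matrix(H)
    storage.mode(H) <- "integer"
    if (nrow(H) != nrow(variants) || ncol(H) != 2L * length(samples))
      stop("H must be variants x (2 * samples)")
    if (anyNA(H)) stop("H must not contain missing entries")
    if (!all(H %in% c(0L, 1L))) stop("H entries must be 0 or 1")
    hs <- H[, seq(1L, ncol(H), by = 2L), drop = FALSE] +
      H[, seq(2L, ncol(H), by = 2L), drop = FALSE]
    obs <- !is.na(G)
    if (any(hs[obs] != G[obs]))
      stop("H column pairs do not sum to G")
  }
  structure(list(variants = variants, samples = samples, breed_of = breed_of,
                 group_of = group_of, G = G, H = H),
            class = "GenotypeDataset")
}

#' @exportS3Method base::print
print.GenotypeDataset <- function(x, ...) {
  cat("GenotypeDataset:", nrow(x$variants), "variants x",
      length(x$samples), "samples,",
      length(unique(x$breed_of)), "breeds,",
      if (is.null(x$H)) "unphased" else "phased", "\n")
  invisible(x)
}

#' Number of variants / samples / breed labels
#'
#' @param ds a `GenotypeDataset`
#' @return `n_variants` and `n_samples` return integers; `breeds` returns the
#'   sorted unique breed labels.
#' @export
n_variants <- function(ds) nrow(ds$variants)

#' @rdname n_variants
#' @export
n_samples <- function(ds) length(ds$samples)

#' @rdname n_variants
#' @export
breeds <- function(ds) sort(unique(unname(ds$breed_of)))

#' Subset a dataset by variant index or by samples
#'
#' Both subsets keep `G`, `H` and the variant table aligned; `subset_samples`
#' keeps only the breed assignments of the retained samples.
#'
#' @param ds a `GenotypeDataset`
#' @param idx integer or logical index into the variant table
#' @return a new `GenotypeDataset`
#' @export
subset_variants <- function(ds, idx) {
  v <- ds$variants[idx, , drop = FALSE]
  rownames(v) <- NULL
  genotype_dataset(v, ds$G[idx, , drop = FALSE], ds$breed_of,
                   H = if (is.null(ds$H)) NULL else ds$H[idx, , drop = FALSE],
                   group_of = ds$group_of)
}

#' @rdname subset_variants
#' @param samples character vector of sample identifiers to keep
#' @export
subset_samples <- function(ds, samples) {
  keep <- ds$samples %in% samples
  if (!any(keep)) stop("no samples retained")
  hidx <- rep(which(keep) * 2L, each = 2L) - c(1L, 0L)
  genotype_dataset(ds$variants, ds$G[, keep, drop = FALSE],
                   ds$breed_of[keep],
                   H = if (is.null(ds$H)) NULL else ds$H[, hidx, drop = FALSE],
                   group_of = ds$group_of)
}

#' Slice a dataset to one breed
#'
#' @param ds a `GenotypeDataset`
#' @param breed breed label
#' @return a `GenotypeDataset` holding only that breed's samples
#' @export
breed_slice <- function(ds, breed) {
  if (!breed %in% ds$breed_of) stop("unknown breed: ", breed)
  subset_samples(ds, ds$samples[ds$breed_of == breed])
}

#' Phased haplotype matrix of one breed
#'
#' @param ds a phased `GenotypeDataset`
#' @param breed breed label
#' @return integer matrix, variants x (2 * breed samples)
#' @export
breed_haplotypes <- function(ds, breed) {
  if (is.null(ds$H)) stop("dataset is unphased; haplotype-based statistics need phased input")
  keep <- which(ds$breed_of == breed)
  if (length(keep) == 0) stop("unknown breed: ", breed)
  hidx <- rep(keep * 2L, each = 2L) - c(1L, 0L)
  ds$H[, hidx, drop = FALSE]
}

#' Per-variant alt-allele frequency
#'
#' Computed from observed genotypes only (missing entries excluded from both
#' numerator and denominator). For phased data this equals the haplotype-based
#' frequency because `H` carries no missing entries.
#'
#' @param ds a `GenotypeDataset`
#' @param breed optional breed label; default uses all samples
#' @return numeric vector of frequencies (`NaN` where no genotype is called)
#' @export
alt_freq <- function(ds, breed = NULL) {
  G <- if (is.null(breed)) ds$G else breed_slice(ds, breed)$G
  cnt <- rowSums(G, na.rm = TRUE)
  called <- 2L * rowSums(!is.na(G))
  cnt / called
}
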