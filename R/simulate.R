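#' Simulation configuration
#'
#' Describes a multi-breed SNP dataset drawn from the Balding-Nichols model:
#' every SNP has an ancestral frequency shared by all breeds, and each breed
#' drifts away from it with Beta-distributed population frequencies whose
#' variance is governed by the drift parameter F. Defaults mirror a
#' desk-scale version of a dense-array multi-breed study: 20 diploid
#' individuals per breed (40 autosomes, the minimum for stable
#' haplotype-window statistics), several thousand SNPs spread over a few
#' chromosomes at array-like spacing, and a 0.05 ancestral MAF floor
#' matching the QC threshold applied to real data.
#'
#' @param n_breeds number of breeds
#' @param n_per_breed diploid individuals per breed
#' @param n_snps total SNPs (split evenly over chromosomes)
#' @param n_chroms number of chromosomes (labelled "1", "2", ...)
#' @param spacing_bp mean inter-SNP spacing in bp (geometric gaps)
#' @param drift per-breed Balding-Nichols F in (0, 1): scalar (recycled) or
#'   vector over breeds; for tree-structured drift use
#'   [simulate_tree_drift()]
#' @param maf_floor ancestral frequencies are Uniform(maf_floor,
#'   1 - maf_floor)
#' @param missing_rate genotype missingness applied by
#'   [inject_missingness()]
#' @param seed integer seed; every source of randomness flows from it
#' @return a list of class `SimConfig`
#' @export
sim_config <- function(n_breeds = 4, n_per_breed = 20, n_snps = 20000,
                       n_chroms = 4, spacing_bp = 4000, drift = 0.05,
                       maf_floor = 0.05, missing_rate = 0, seed = 1) {
  stopifnot(n_breeds >= 1, n_per_breed >= 1, n_snps >= 1, n_chroms >= 1,
            all(drift > 0), all(drift < 1),
            maf_floor >= 0, maf_floor < 0.5,
            missing_rate >= 0, missing_rate < 1)
  structure(list(n_breeds = n_breeds, n_per_breed = n_per_breed,
                 n_snps = n_snps, n_chroms = n_chroms,
                 spacing_bp = spacing_bp,
                 drift = rep_len(drift, n_breeds), maf_floor = maf_floor,
                 missing_rate = missing_rate, seed = seed),
            class = "SimConfig")
}

sim_variant_table <- function(cfg) {
  per_chrom <- rep(cfg$n_snps %/% cfg$n_chroms, cfg$n_chroms)
  per_chrom[1] <- per_chrom[1] + cfg$n_snps %% cfg$n_chroms
  chrom <- rep(as.character(seq_len(cfg$n_chroms)), per_chrom)
  pos <- unlist(lapply(per_chrom, function(m)
    cumsum(stats::rgeom(m, 1 / cfg$spacing_bp) + 1L)))
  data.frame(chrom = chrom, pos = as.integer(pos),
             vid = sprintf("snp%06d", seq_len(cfg$n_snps)),
             ref = "A", alt = "G", stringsAsFactors = FALSE)
}

bn_step <- function(p_parent, d) {
  # one Balding-Nichols drift step: Beta with mean p, variance d p(1-p)
  out <- p_parent
  seg <- p_parent > 0 & p_parent < 1
  if (d < 1e-12) return(out)
  out[seg] <- stats::rbeta(sum(seg), p_parent[seg] * (1 - d) / d,
                           (1 - p_parent[seg]) * (1 - d) / d)
  out
}

sim_dataset_from_freqs <- function(cfg, variants, popf, breed_names) {
  n_hap_pb <- 2L * cfg$n_per_breed
  H <- matrix(0L, cfg$n_snps, n_hap_pb * cfg$n_breeds)
  for (b in seq_len(cfg$n_breeds)) {
    cols <- (b - 1L) * n_hap_pb + seq_len(n_hap_pb)
    H[, cols] <- stats::rbinom(cfg$n_snps * n_hap_pb, 1L, popf[, b])
  }
  samples <- paste0(rep(breed_names, each = cfg$n_per_breed), "_i",
                    sprintf("%02d", seq_len(cfg$n_per_breed)))
  colnames(H) <- paste0(rep(samples, each = 2L), "_", c(1L, 2L))
  G <- H[, seq(1L, ncol(H), 2L), drop = FALSE] +
    H[, seq(2L, ncol(H), 2L), drop = FALSE]
  colnames(G) <- samples
  breed_of <- stats::setNames(rep(breed_names, each = cfg$n_per_breed),
                              samples)
  genotype_dataset(variants, G, breed_of, H = H)
}

#' Simulate a neutral multi-breed dataset
#'
#' Balding-Nichols draw: ancestral frequency p0 per SNP, per-breed
#' population frequencies Beta(p0 (1-F)/F, (1-p0)(1-F)/F), haplotype alleles
#' Bernoulli(p_b) independently per site (linkage-equilibrium baseline),
#' genotypes as haplotype-pair sums, fully phased, geometric inter-SNP
#' spacing. Deterministic under the config seed.
#'
#' @param cfg a [sim_config()]
#' @return list with `dataset` (a phased `GenotypeDataset`) and `truth`
#'   (ancestral `p0`, per-breed `pop_freq` matrix, the `config`)
#' @export
simulate_neutral <- function(cfg) {
  set.seed(cfg$seed)
  variants <- sim_variant_table(cfg)
  p0 <- stats::runif(cfg$n_snps, cfg$maf_floor, 1 - cfg$maf_floor)
  breed_names <- paste0("B", seq_len(cfg$n_breeds))
  popf <- sapply(seq_len(cfg$n_breeds),
                 function(b) bn_step(p0, cfg$drift[b]))
  colnames(popf) <- breed_names
  ds <- sim_dataset_from_freqs(cfg, variants, popf, breed_names)
  if (cfg$missing_rate > 0)
    ds <- inject_missingness(ds, cfg$missing_rate, seed = cfg$seed + 1L)
  list(dataset = ds,
       truth = list(p0 = p0, pop_freq = popf, config = cfg))
}

#' Simulate tree-structured drift
#'
#' Population frequencies evolve from the root frequency along a rooted
#' drift tree: each branch of length d applies one Balding-Nichols step
#' (Beta with mean of the parent frequency and variance d p (1 - p)). The
#' true kinship matrix of the simulated populations is the shared-branch sum
#' of the tree, as computed by [kinship_from_tree()].
#'
#' @param cfg a [sim_config()]; `n_breeds` must match the tree's leaf count
#' @param tree a rooted `ape::phylo` (or newick string) whose tip labels
#'   name the breeds and whose branch lengths are drift amounts in (0, 0.5)
#' @return list with `dataset`, and `truth` holding `p0`, `pop_freq`, the
#'   `tree`, the true kinship `F`, and the `config`
#' @export
simulate_tree_drift <- function(cfg, tree) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  assert_rooted(tree)
  if (any(tree$edge.length >= 0.5))
    stop("branch drift must be < 0.5 per branch")
  if (ape::Ntip(tree) != cfg$n_breeds)
    stop("tree has ", ape::Ntip(tree), " leaves but config has ",
         cfg$n_breeds, " breeds")
  set.seed(cfg$seed)
  variants <- sim_variant_table(cfg)
  p0 <- stats::runif(cfg$n_snps, cfg$maf_floor, 1 - cfg$maf_floor)
  nt <- ape::Ntip(tree)
  node_freq <- vector("list", nt + tree$Nnode)
  node_freq[[nt + 1L]] <- p0
  edges <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
  # preorder: parents always precede children in reorder(tree)$edge
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  lens <- tree$edge.length[match(paste(ord[, 1], ord[, 2]),
                                 paste(tree$edge[, 1], tree$edge[, 2]))]
  for (e in seq_len(nrow(ord)))
    node_freq[[ord[e, 2]]] <- bn_step(node_freq[[ord[e, 1]]], lens[e])
  popf <- sapply(seq_len(nt), function(i) node_freq[[i]])
  colnames(popf) <- tree$tip.label
  ds <- sim_dataset_from_freqs(cfg, variants, popf, tree$tip.label)
  list(dataset = ds,
       truth = list(p0 = p0, pop_freq = popf, tree = tree,
                    F = kinship_from_tree(tree), config = cfg))
}

#' Hard-sweep specification
#'
#' @param chrom chromosome label
#' @param start_snp_index 1-based index of the first swept SNP within the
#'   chromosome
#' @param width_snps number of consecutive SNPs in the sweep window
#' @param breeds character vector of affected breeds
#' @param final_freq frequency the swept haplotype is driven to, in
#'   (0.5, 1]
#' @return a list of class `SweepSpec`
#' @export
sweep_spec <- function(chrom, start_snp_index, width_snps, breeds,
                       final_freq = 0.95) {
  stopifnot(final_freq > 0.5, final_freq <= 1, width_snps >= 1,
            start_snp_index >= 1)
  structure(list(chrom = as.character(chrom),
                 start_snp_index = as.integer(start_snp_index),
                 width_snps = as.integer(width_snps),
                 breeds = breeds, final_freq = final_freq),
            class = "SweepSpec")
}

#' Inject a hard sweep into a phased dataset
#'
#' Emulates a completed or nearly completed hard sweep by haplotype copying:
#' within the window, one randomly chosen carrier haplotype's allele string
#' is copied onto a random subset of the affected breeds' haplotypes until
#' its frequency reaches `final_freq`. Nothing changes outside the window or
#' in unaffected breeds, so the truth window is exact. Truth records
#' accumulate in `attr(ds, "sweeps")` (chrom, start_bp, end_bp, breeds);
#' a window overlapping a previously injected sweep is an error.
#'
#' @param ds a phased `GenotypeDataset`
#' @param spec a [sweep_spec()]
#' @param seed integer seed for carrier and target choice
#' @return the modified dataset (truth attached as attribute `sweeps`)
#' @export
inject_sweep <- function(ds, spec, seed = 1) {
  if (is.null(ds$H)) stop("sweeps require a phased dataset")
  idx_chrom <- which(ds$variants$chrom == spec$chrom)
  if (spec$start_snp_index + spec$width_snps - 1L > length(idx_chrom))
    stop("sweep window extends past chromosome ", spec$chrom)
  win <- idx_chrom[spec$start_snp_index +
                     seq_len(spec$width_snps) - 1L]
  prev <- attr(ds, "sweeps")
  if (!is.null(prev)) {
    clash <- prev$chrom == spec$chrom &
      prev$start_bp <= ds$variants$pos[win[length(win)]] &
      prev$end_bp >= ds$variants$pos[win[1]]
    if (any(clash)) stop("sweep window overlaps a previous sweep")
  }
  set.seed(seed)
  for (breed in spec$breeds) {
    cols <- which(rep(ds$breed_of, each = 2L) == breed)
    nh <- length(cols)
    carrier <- sample(cols, 1)
    target <- ceiling(spec$final_freq * nh)
    recipients <- sample(setdiff(cols, carrier), target - 1L)
    ds$H[win, recipients] <- ds$H[win, carrier]
  }
  # re-derive G for the window from the updated haplotypes
  ds$G[win, ] <- ds$H[win, seq(1L, ncol(ds$H), 2L), drop = FALSE] +
    ds$H[win, seq(2L, ncol(ds$H), 2L), drop = FALSE]
  rec <- data.frame(chrom = spec$chrom,
                    start_bp = ds$variants$pos[win[1]],
                    end_bp = ds$variants$pos[win[length(win)]],
                    breeds = paste(spec$breeds, collapse = ","),
                    stringsAsFactors = FALSE)
  attr(ds, "sweeps") <- rbind(prev, rec)
  ds
}

#' Inject genotype missingness
#'
#' Each genotype is set missing independently with probability `rate`. A
#' positive rate drops the haplotype matrix (haplotypes never carry missing
#' entries), leaving the dataset unphased.
#'
#' @param ds a `GenotypeDataset`
#' @param rate missingness probability in \[0, 1)
#' @param seed integer seed
#' @return the modified dataset
#' @export
inject_missingness <- function(ds, rate, seed = 1) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(ds)
  set.seed(seed)
  mask <- stats::runif(length(ds$G)) < rate
  ds$G[mask] <- NA_integer_
  ds$H <- NULL
  sweeps <- attr(ds, "sweeps")
  ds <- genotype_dataset(ds$variants, ds$G, ds$breed_of,
                         group_of = ds$group_of)
  attr(ds, "sweeps") <- sweeps
  ds
}

#' Generate a toy gene annotation over simulated coordinates
#'
#' Places non-overlapping gene intervals uniformly over the simulated
#' coordinate space, forcing at least one gene inside every truth sweep
#' window so region-to-gene assignment is always exercised. Gene names are
#' GENE0001, GENE0002, ... except for `n_cluster_blocks` triples of
#' consecutive genes renamed with a shared prefix and consecutive numbers
#' (KRT71/KRT72/KRT73 style) to exercise the cluster shorthand.
#'
#' @param variants variant table defining the coordinate space
#' @param n_genes total genes to place
#' @param seed integer seed
#' @param truth_sweeps optional truth data.frame (chrom, start_bp, end_bp)
#'   from [inject_sweep()]
#' @param n_cluster_blocks number of same-prefix triples
#' @param gene_bp gene interval width in bp
#' @return annotation data.frame (gene_id, name, chrom, start, end, strand)
#' @export
make_annotation <- function(variants, n_genes, seed = 1,
                            truth_sweeps = NULL, n_cluster_blocks = 1,
                            gene_bp = 20000) {
  set.seed(seed)
  chroms <- unique(variants$chrom)
  span <- vapply(chroms, function(ch) max(variants$pos[variants$chrom == ch]),
                 numeric(1))
  rows <- list()
  if (!is.null(truth_sweeps)) {
    for (t in seq_len(nrow(truth_sweeps))) {
      mid <- (truth_sweeps$start_bp[t] + truth_sweeps$end_bp[t]) %/% 2L
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = truth_sweeps$chrom[t],
        start = max(1L, as.integer(mid - gene_bp %/% 2L)),
        end = as.integer(mid + gene_bp %/% 2L), stringsAsFactors = FALSE)
    }
  }
  tries <- 0
  while (length(rows) < n_genes && tries < n_genes * 200) {
    tries <- tries + 1
    ch <- sample(chroms, 1, prob = span / sum(span))
    start <- sample.int(max(span[ch] - gene_bp, 1), 1)
    cand <- data.frame(chrom = ch, start = start,
                       end = start + gene_bp - 1L, stringsAsFactors = FALSE)
    clash <- vapply(rows, function(r)
      r$chrom == ch && r$start <= cand$end && r$end >= cand$start,
      logical(1))
    if (!any(clash)) rows[[length(rows) + 1L]] <- cand
  }
  ann <- do.call(rbind, rows)
  ord <- order(match(ann$chrom, chroms), ann$start)
  ann <- ann[ord, , drop = FALSE]
  ann$name <- sprintf("GENE%04d", seq_len(nrow(ann)))
  prefixes <- c("KRT", "HOXA", "OLR", "MYH", "WNT")
  if (n_cluster_blocks > 0 && nrow(ann) >= 3) {
    starts <- seq(1, max(nrow(ann) - 2, 1),
                  length.out = min(n_cluster_blocks, length(prefixes)))
    for (b in seq_along(starts)) {
      i <- as.integer(starts[b])
      ann$name[i:(i + 2)] <- sprintf("%s%d", prefixes[b], 70 + 1:3)
    }
  }
  ann$gene_id <- ann$name
  ann$strand <- rep_len(c("+", "-"), nrow(ann))
  rownames(ann) <- NULL
  ann[, c("gene_id", "name", "chrom", "start", "end", "strand")]
}

#' Serialise truth records as JSON
#'
#' @param truth any truth list/data.frame produced by the simulators
#' @param path output path
#' @return `path`, invisibly
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
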