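#' Serialise a correlation model as JSON
#'
#' @param model a [fit_robust_covariance()] result
#' @param path output path
#' @return `path`, invisibly
#' @export
write_correlation_model <- function(model, path) {
  jsonlite::write_json(list(stats = model$stats, Sigma = model$Sigma,
                            R = model$R, s = model$s, alpha = model$alpha,
                            seed = model$seed, n_sampled = model$n_sampled),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Five-statistic tracks for one breed
#'
#' Computes the per-breed statistic panel the composite is built from:
#' windowed H1/H12 and Tajima's D on the breed's phased haplotypes,
#' one-vs-rest Weir-Cockerham FST and per-site pi (both smoothed by a k-SNP
#' running median, the noise-reduction step applied to the two per-site
#' statistics).
#'
#' @param ds a phased `GenotypeDataset`
#' @param breed breed to compute the panel for
#' @param window a [window_spec()]
#' @param k_smooth running-median window (odd; 31 by default)
#' @return named list of five [stat_track()]s: H1, H12, TajimaD, FST, PI
#' @export
breed_stat_panel <- function(ds, breed, window = window_spec(),
                             k_smooth = 31) {
  H <- breed_haplotypes(ds, breed)
  hh <- scan_h_stats(H, ds$variants, window, breed = breed)
  list(H1 = hh$H1, H12 = hh$H12,
       TajimaD = tajima_d_windows(H, ds$variants, window, breed = breed),
       FST = smooth_runmed(fst_one_vs_rest(ds, breed), k = k_smooth),
       PI = smooth_runmed(site_pi(ds, breed), k = k_smooth))
}

# statistic -> one-tailed direction: small pi / Tajima's D and large
# H1 / H12 / FST are sweep-like
dcms_tails <- c(H1 = "right", H12 = "right", TajimaD = "left",
                FST = "right", PI = "left")

#' Run the DCMS genome scan
#'
#' For every breed: the five statistic tracks, genome-wide rank-based
#' one-tailed p-values (pi and Tajima's D left-tailed; H1, H12 and FST
#' right-tailed), a robust MCD correlation model over the statistics, the
#' DCMS composite, a robust-normal fit with upper-tail p-values, Storey
#' q-values, called selection regions, and (when an annotation is supplied)
#' distance-ranked candidate genes per region.
#'
#' @param ds a phased `GenotypeDataset` after QC
#' @param scan_breeds breeds to scan (default all)
#' @param window a [window_spec()]
#' @param k_smooth running-median window for FST and pi
#' @param n_sample,alpha,seed MCD parameters, see [fit_robust_covariance()]
#' @param seed_q,bound_q region thresholds, see [call_regions()]
#' @param annotation optional gene annotation data.frame
#' @param sigma_multiplier gene-window width, see [identify_genes()]
#' @param out_dir optional directory for TSV/JSON artefacts
#' @return named list per breed: `tracks`, `model`, `dcms`, `fit`, `p`, `q`,
#'   `regions`, `genes` (list per region row)
#' @export
run_dcms_scan <- function(ds, scan_breeds = breeds(ds),
                          window = window_spec(), k_smooth = 31,
                          n_sample = 300000, alpha = 0.75, seed = 1,
                          seed_q = 0.01, bound_q = 0.1, annotation = NULL,
                          sigma_multiplier = 1, out_dir = NULL) {
  if (is.null(ds$H))
    stop("unphased input: H1, H12 and Tajima's D require phased haplotypes")
  out <- list()
  for (b in scan_breeds) {
    tracks <- breed_stat_panel(ds, b, window, k_smooth)
    ptracks <- lapply(names(tracks), function(nm)
      rank_pvalues(tracks[[nm]], dcms_tails[[nm]]))
    stat_matrix <- sapply(tracks, function(tr) tr$values)
    model <- fit_robust_covariance(stat_matrix, n_sample = n_sample,
                                   alpha = alpha, seed = seed)
    dcms <- dcms_combine(ptracks, model)
    fit <- fit_normal_robust(dcms)
    p <- normal_pvalues(dcms, fit)
    q <- storey_qvalues(p)
    regions <- call_regions(q, dcms, seed_q = seed_q, bound_q = bound_q,
                            method = "DCMS")
    genes <- NULL
    if (!is.null(annotation) && nrow(regions) > 0) {
      genes <- lapply(seq_len(nrow(regions)), function(i) {
        g <- identify_genes(regions[i, ], dcms, annotation, fit$sigma,
                            sigma_multiplier)
        if (nrow(g) == 0) g else rank_genes(g, regions$peak_pos[i])
      })
    }
    out[[b]] <- list(tracks = tracks, model = model, dcms = dcms,
                     fit = fit, p = p, q = q, regions = regions,
                     genes = genes)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_stat_tracks(c(tracks, list(dcms, q)),
                        file.path(out_dir, paste0("dcms_tracks_", b, ".tsv")))
      write_correlation_model(model,
                              file.path(out_dir, paste0("dcms_model_", b, ".json")))
      write_regions(regions, genes,
                    bed_path = file.path(out_dir, paste0("dcms_regions_", b, ".bed")),
                    tsv_path = file.path(out_dir, paste0("dcms_regions_", b, ".tsv")))
    }
  }
  out
}

#' Run the FLK genome scan
#'
#' For every analysis unit (all breeds and/or each breed group): population
#' allele frequencies, Reynolds distances, neighbour-joining tree with
#' midpoint rooting, tree-derived kinship, the single-SNP FLK test, the
#' robust-normal p/q post-processing, region calling, and candidate genes.
#' An externally computed hapFLK track can be post-processed with the same
#' machinery via [read_hapflk_track()] + [flk_pvalues()] + [call_regions()].
#'
#' @param ds a `GenotypeDataset` after QC (phase not required)
#' @param units named list mapping unit labels to breed vectors; default one
#'   unit "all" over every breed
#' @param seed_q,bound_q region thresholds
#' @param annotation optional gene annotation
#' @param sigma_multiplier gene-window width in sigmas
#' @param out_dir optional directory for artefacts
#' @return named list per unit: `kinship` (a `KinshipModel`), `flk` (an
#'   `FLKResult`), `track`, `fit`, `p`, `q`, `regions`, `genes`
#' @export
run_flk_scan <- function(ds, units = list(all = breeds(ds)),
                         seed_q = 0.01, bound_q = 0.1, annotation = NULL,
                         sigma_multiplier = 1, out_dir = NULL) {
  out <- list()
  for (u in names(units)) {
    sub <- subset_samples(ds, ds$samples[ds$breed_of %in% units[[u]]])
    if (length(unique(sub$breed_of)) < 2)
      stop("unit ", u, " has fewer than 2 populations")
    freqs <- allele_frequencies(sub)
    km <- kinship_model(freqs)
    res <- flk_test(freqs, km$F)
    tr <- flk_track(res, unit = u)
    pq <- flk_pvalues(tr)
    regions <- call_regions(pq$q, tr, seed_q = seed_q, bound_q = bound_q,
                            method = "FLK")
    genes <- NULL
    if (!is.null(annotation) && nrow(regions) > 0) {
      genes <- lapply(seq_len(nrow(regions)), function(i) {
        g <- identify_genes(regions[i, ], tr, annotation, pq$fit$sigma,
                            sigma_multiplier)
        if (nrow(g) == 0) g else rank_genes(g, regions$peak_pos[i])
      })
    }
    out[[u]] <- list(kinship = km, flk = res, track = tr, fit = pq$fit,
                     p = pq$p, q = pq$q, regions = regions, genes = genes)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      ape::write.tree(km$tree, file.path(out_dir, paste0("flk_tree_", u, ".nwk")))
      utils::write.table(km$F, file.path(out_dir, paste0("flk_kinship_", u, ".tsv")),
                         sep = "\t", quote = FALSE)
      write_regions(regions, genes,
                    bed_path = file.path(out_dir, paste0("flk_regions_", u, ".bed")),
                    tsv_path = file.path(out_dir, paste0("flk_regions_", u, ".tsv")))
    }
  }
  out
}

#' Overlap report between two scans
#'
#' Applies [overlap_regions()] to the pooled region sets of two scan results
#' (or plain region data.frames), reporting how much of the first scan's
#' region set is independently supported by the second.
#'
#' @param scan_a,scan_b [run_dcms_scan()] / [run_flk_scan()] results, or
#'   region data.frames
#' @return the [overlap_regions()] report
#' @export
run_overlap <- function(scan_a, scan_b) {
  pool <- function(x) {
    if (is.data.frame(x)) return(x)
    do.call(rbind, lapply(x, function(el) el$regions))
  }
  overlap_regions(pool(scan_a), pool(scan_b))
}
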