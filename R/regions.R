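#' Call selection regions from a q-value track
#'
#' A region is a maximal run of consecutive SNPs with q <= `bound_q` that
#' contains at least one SNP with q < `seed_q`; its boundaries are the
#' positions of the first and last SNP of the run (a single-SNP run yields a
#' 1-bp region). Runs never span chromosomes; sentinel q-values break runs.
#' The region peak is the SNP with the largest statistic value when
#' `stat_track` is given, otherwise the SNP with the smallest q.
#'
#' @param qtrack a q-value [stat_track()]
#' @param stat_track optional aligned statistic track used for the peak
#' @param seed_q significance threshold a region must reach (default 0.01)
#' @param bound_q boundary threshold ending the run (default 0.1)
#' @param method label recorded on the regions (default: the statistic name)
#' @return data.frame with columns chrom, start, end (1-based inclusive bp),
#'   peak_vid, peak_pos, peak_stat, q_min, unit, method, n_snps
#' @export
call_regions <- function(qtrack, stat_track = NULL,
                         seed_q = 0.01, bound_q = 0.1, method = NULL) {
  v <- qtrack$variants
  for (ch in unique(v$chrom))
    if (any(diff(v$pos[v$chrom == ch]) <= 0))
      stop("positions not sorted on chromosome ", ch)
  if (is.null(method))
    method <- if (!is.null(stat_track)) stat_track$stat else "DCMS"
  q <- qtrack$values
  svals <- if (is.null(stat_track)) -q else stat_track$values
  rows <- list()
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    inrun <- !is.na(q[idx]) & q[idx] <= bound_q
    r <- rle(inrun)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      run <- idx[starts[j]:ends[j]]
      if (!any(q[run] < seed_q, na.rm = TRUE)) next
      pk <- run[which.max(svals[run])]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = v$pos[run[1]], end = v$pos[run[length(run)]],
        peak_vid = v$vid[pk], peak_pos = v$pos[pk],
        peak_stat = if (is.null(stat_track)) NA_real_ else svals[pk],
        q_min = min(q[run], na.rm = TRUE), unit = qtrack$breed,
        method = method, n_snps = length(run), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), peak_vid = character(),
                      peak_pos = integer(), peak_stat = numeric(),
                      q_min = numeric(), unit = character(),
                      method = character(), n_snps = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Candidate genes around a region peak
#'
#' The gene window is the maximal contiguous run of SNPs containing the peak
#' in which every SNP's statistic stays within `sigma_multiplier * sigma` of
#' the peak value, never extending beyond the region; genes whose intervals
#' overlap the window's first-to-last SNP span are returned. This balances
#' gene reporting between sharp single-SNP peaks (only peak-spanning genes)
#' and plateaus of uniformly extreme SNPs (the whole region).
#'
#' @param region one row of a [call_regions()] data.frame
#' @param stat_track the statistic track the region was called on
#' @param annotation gene annotation data.frame (see
#'   [read_gene_annotation()])
#' @param sigma genome-wide robust scale of the statistic (from
#'   [fit_normal_robust()])
#' @param sigma_multiplier width of the drop-from-peak rule in sigmas
#' @return the overlapping rows of `annotation` (possibly empty; chromosome
#'   absent from the annotation gives an empty result with a warning)
#' @export
identify_genes <- function(region, stat_track, annotation, sigma,
                           sigma_multiplier = 1) {
  v <- stat_track$variants
  run <- which(v$chrom == region$chrom & v$pos >= region$start &
                 v$pos <= region$end)
  pk <- run[which.max(stat_track$values[run])]
  thresh <- stat_track$values[pk] - sigma_multiplier * sigma
  ok <- !is.na(stat_track$values[run]) & stat_track$values[run] >= thresh
  i <- match(pk, run)
  lo <- i; while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- i; while (hi < length(run) && ok[hi + 1]) hi <- hi + 1
  wstart <- v$pos[run[lo]]; wend <- v$pos[run[hi]]
  if (!region$chrom %in% annotation$chrom) {
    warning("chromosome ", region$chrom, " absent from annotation")
    return(annotation[0, , drop = FALSE])
  }
  hit <- annotation$chrom == region$chrom &
    annotation$end >= wstart & annotation$start <= wend
  annotation[hit, , drop = FALSE]
}

#' Rank candidate genes by distance from the region peak
#'
#' Distance is 0 when the gene interval spans the peak, otherwise the
#' shorter of the two endpoint distances. Genes are sorted by increasing
#' distance (more distant genes get larger ranks); ties are broken by gene
#' start, then gene_id, so the ranking is deterministic.
#'
#' @param genes gene annotation rows (from [identify_genes()])
#' @param peak_pos peak SNP position
#' @return `genes` with `distance` and `rank` columns, sorted by rank
#' @export
rank_genes <- function(genes, peak_pos) {
  if (nrow(genes) == 0) stop("empty gene list")
  d <- ifelse(genes$start <= peak_pos & genes$end >= peak_pos, 0,
              pmin(abs(genes$start - peak_pos), abs(genes$end - peak_pos)))
  ord <- order(d, genes$start, genes$gene_id)
  out <- genes[ord, , drop = FALSE]
  out$distance <- d[ord]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

regions_granges <- function(regions) {
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(regions$start, regions$end))
}

#' Overlap report between two region sets
#'
#' Counts the regions of `set_a` sharing at least one bp with `set_b` and
#' the total shared sequence (the width of the union of all pairwise
#' intersections). Both sets must use 1-based inclusive coordinates.
#'
#' @param set_a,set_b [call_regions()] data.frames
#' @return list with `n_a`, `n_overlapping`, `fraction`, `shared_bp`
#' @export
overlap_regions <- function(set_a, set_b) {
  if (nrow(set_a) == 0)
    return(list(n_a = 0L, n_overlapping = 0L, fraction = NA_real_,
                shared_bp = 0))
  if (nrow(set_b) == 0)
    return(list(n_a = nrow(set_a), n_overlapping = 0L, fraction = 0,
                shared_bp = 0))
  ga <- regions_granges(set_a)
  gb <- regions_granges(set_b)
  hits <- GenomicRanges::countOverlaps(ga, gb) > 0
  shared <- GenomicRanges::intersect(GenomicRanges::reduce(ga),
                                     GenomicRanges::reduce(gb))
  list(n_a = nrow(set_a), n_overlapping = sum(hits),
       fraction = mean(hits),
       shared_bp = sum(GenomicRanges::width(shared)))
}

# Collapse runs of >= 3 same-prefix numbered genes to "PREFIX@ (i-j)".
gene_label_string <- function(ranked) {
  if (is.null(ranked) || nrow(ranked) == 0) return("")
  prefix <- ifelse(grepl("^[A-Za-z]+[0-9]+$", ranked$name),
                   sub("[0-9]+$", "", ranked$name), NA_character_)
  labels <- character(0)
  i <- 1
  while (i <= nrow(ranked)) {
    j <- i
    if (!is.na(prefix[i]))
      while (j < nrow(ranked) && !is.na(prefix[j + 1]) &&
             prefix[j + 1] == prefix[i]) j <- j + 1
    if (j - i + 1 >= 3) {
      labels <- c(labels, sprintf("%s@ (%d-%d)", prefix[i],
                                  ranked$rank[i], ranked$rank[j]))
    } else {
      labels <- c(labels, sprintf("%s(%d)", ranked$name[i:j],
                                  ranked$rank[i:j]))
    }
    i <- j + 1
  }
  paste(labels, collapse = ";")
}

#' Write called regions as BED and TSV
#'
#' The TSV mirrors a per-region results table: chrom, start_bp, end_bp,
#' q_min, unit, method, n_snps, peak_pos, candidate_genes (name(rank)
#' semicolon-joined, with runs of three or more same-prefix numbered genes
#' collapsed to the cluster shorthand "PREFIX@ (i-j)"). The BED6 uses
#' 0-based half-open coordinates, name unit:method and score
#' -10 log10(q_min) capped at 1000. An empty region set writes header-only
#' files.
#'
#' @param regions a [call_regions()] data.frame
#' @param ranked_genes list (one element per region row) of [rank_genes()]
#'   data.frames, or NULL
#' @param bed_path,tsv_path output paths (either may be NULL to skip)
#' @return invisibly, the TSV data.frame
#' @export
write_regions <- function(regions, ranked_genes = NULL,
                          bed_path = NULL, tsv_path = NULL) {
  genes_str <- if (is.null(ranked_genes)) rep("", nrow(regions)) else
    vapply(ranked_genes, gene_label_string, character(1))
  tsv <- data.frame(chrom = regions$chrom, start_bp = regions$start,
                    end_bp = regions$end, q_min = regions$q_min,
                    unit = regions$unit, method = regions$method,
                    n_snps = regions$n_snps, peak_pos = regions$peak_pos,
                    candidate_genes = genes_str, stringsAsFactors = FALSE)
  if (!is.null(tsv_path))
    utils::write.table(tsv, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = regions$chrom, start = regions$start - 1L,
                      end = regions$end,
                      name = paste0(regions$unit, ":", regions$method),
                      score = pmin(round(-10 * log10(regions$q_min), 2), 1000),
                      strand = ".")
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(tsv)
}

#' Read a regions TSV written by [write_regions()]
#'
#' @param tsv_path path to the TSV
#' @return a [call_regions()]-shaped data.frame (peak_vid and peak_stat are
#'   not stored in the TSV and come back as NA)
#' @export
read_regions <- function(tsv_path) {
  tb <- utils::read.table(tsv_path, header = TRUE, sep = "\t",
                          colClasses = c(chrom = "character",
                                         unit = "character",
                                         method = "character",
                                         candidate_genes = "character"))
  data.frame(chrom = tb$chrom, start = tb$start_bp, end = tb$end_bp,
             peak_vid = rep(NA_character_, nrow(tb)), peak_pos = tb$peak_pos,
             peak_stat = rep(NA_real_, nrow(tb)), q_min = tb$q_min,
             unit = tb$unit, method = tb$method, n_snps = tb$n_snps,
             candidate_genes = tb$candidate_genes, stringsAsFactors = FALSE)
}

#' Read a gene annotation from GFF3 or BED
#'
#' GFF3: only `gene` features are used; the display name comes from the
#' `Name` attribute with `ID` as fallback. BED: the name column is used for
#' both identifier and name. Coordinates are returned 1-based inclusive.
#'
#' @param path annotation path (.gff3/.gff or .bed)
#' @return data.frame with columns gene_id, name, chrom, start, end, strand
#' @export
read_gene_annotation <- function(path) {
  fmt <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  if (fmt == "gff3") {
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    id <- if (!is.null(gr$ID)) gr$ID else gr$Name
    nm <- if (!is.null(gr$Name)) gr$Name else id
    nm[is.na(nm)] <- id[is.na(nm)]
  } else {
    id <- nm <- if (!is.null(gr$name)) gr$name else
      paste0("gene", seq_along(gr))
  }
  data.frame(gene_id = as.character(id), name = as.character(nm),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write a gene annotation as GFF3
#'
#' @param annotation data.frame as from [read_gene_annotation()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gene_annotation <- function(annotation, path) {
  strand <- ifelse(annotation$strand %in% c("+", "-"), annotation$strand, ".")
  lines <- sprintf("%s\tsweepscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                   annotation$chrom, annotation$start, annotation$end,
                   strand, annotation$gene_id, annotation$name)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Match called regions against truth sweep windows
#'
#' The deterministic matcher used by recovery tests: a truth window is
#' recovered when some region whose unit is an affected breed has its peak
#' inside the window; a region is a false call when its peak lies inside no
#' truth window affecting its unit.
#'
#' @param regions a [call_regions()] data.frame
#' @param truth data.frame with columns chrom, start_bp, end_bp, breeds
#'   (comma-joined affected breeds), as produced by [inject_sweep()]
#' @return list with `recovered` (logical per truth row), `n_recovered`,
#'   `false_per_unit` (named integer vector over units present in `regions`)
#' @export
match_regions_to_truth <- function(regions, truth) {
  truth_breeds <- strsplit(truth$breeds, ",", fixed = TRUE)
  recovered <- logical(nrow(truth))
  is_false <- rep(TRUE, nrow(regions))
  for (t in seq_len(nrow(truth))) {
    hit <- regions$chrom == truth$chrom[t] &
      regions$peak_pos >= truth$start_bp[t] &
      regions$peak_pos <= truth$end_bp[t] &
      regions$unit %in% truth_breeds[[t]]
    recovered[t] <- any(hit)
    is_false[hit] <- FALSE
  }
  units <- unique(regions$unit)
  false_per_unit <- vapply(units, function(u)
    sum(is_false & regions$unit == u), integer(1))
  list(recovered = recovered, n_recovered = sum(recovered),
       false_per_unit = false_per_unit)
}
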