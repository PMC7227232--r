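#' Variant-aligned statistic track
#'
#' One real value per variant for one breed (or analysis group). `NA` is the
#' undefined sentinel, used e.g. at chromosome edges where a centred window
#' does not exist. p-value and q-value tracks reuse the same container with
#' the `tail` / `pi0` fields set.
#'
#' @param values numeric vector, one entry per variant (`NA` allowed)
#' @param variants the variant table the values align to
#' @param stat statistic label (e.g. "H1", "H12", "TajimaD", "FST", "PI",
#'   "DCMS", "FLK", "HAPFLK", "P", "Q")
#' @param breed breed or group label
#' @param tail for p-value tracks: "left" or "right"
#' @param pi0 for q-value tracks: the estimated null proportion
#' @return an object of class `stat_track`
#' @export
stat_track <- function(values, variants, stat, breed,
                       tail = NULL, pi0 = NULL) {
  stopifnot(length(values) == nrow(variants))
  structure(list(stat = stat, breed = breed, values = as.numeric(values),
                 variants = variants, tail = tail, pi0 = pi0),
            class = "stat_track")
}

#' @exportS3Method base::print
print.stat_track <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat("stat_track", x$stat, "[", x$breed, "]:", length(x$values), "variants,",
      length(v), "defined", if (length(v)) sprintf("(range %.4g..%.4g)",
                                                   min(v), max(v)), "\n")
  invisible(x)
}

#' Serialise statistic tracks to TSV
#'
#' Columns: chrom, pos, vid, breed, statistic, value; the undefined sentinel
#' is printed as `NA`.
#'
#' @param tracks a `stat_track` or list of them (must share a variant table)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_stat_tracks <- function(tracks, path) {
  if (inherits(tracks, "stat_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr)
    data.frame(chrom = tr$variants$chrom, pos = tr$variants$pos,
               vid = tr$variants$vid, breed = tr$breed, statistic = tr$stat,
               value = tr$values, stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read statistic tracks written by [write_stat_tracks()]
#'
#' @param path TSV path
#' @return a list of `stat_track` objects, one per (breed, statistic) pair
#' @export
read_stat_tracks <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(chrom = "character",
                                         vid = "character",
                                         breed = "character",
                                         statistic = "character"))
  out <- list()
  for (key in unique(paste(tb$breed, tb$statistic, sep = "\r"))) {
    part <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sel <- tb$breed == part[1] & tb$statistic == part[2]
    sub <- tb[sel, , drop = FALSE]
    variants <- data.frame(chrom = sub$chrom, pos = sub$pos, vid = sub$vid,
                           ref = NA_character_, alt = NA_character_,
                           stringsAsFactors = FALSE)
    out[[paste(part[1], part[2], sep = ".")]] <-
      stat_track(sub$value, variants, part[2], part[1])
  }
  out
}
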