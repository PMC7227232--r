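# Fixture builders: everything generated in code at test time.

# small phased/unphased dataset built directly
toy_dataset <- function(G, chrom = NULL, pos = NULL, breed_of = NULL,
                        H = NULL) {
  n <- nrow(G)
  if (is.null(chrom)) chrom <- rep("1", n)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(colnames(G)))
    colnames(G) <- paste0("s", seq_len(ncol(G)))
  if (is.null(breed_of))
    breed_of <- stats::setNames(rep("P1", ncol(G)), colnames(G))
  v <- data.frame(chrom = chrom, pos = pos,
                  vid = paste0("v", seq_len(n)), ref = "A", alt = "G",
                  stringsAsFactors = FALSE)
  genotype_dataset(v, G, breed_of, H = H)
}

# write a small VCF by hand (independent of the package's writer)
write_tiny_vcf <- function(path, samples, records) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

write_tiny_breeds <- function(path, samples, breeds, groups = NULL) {
  tb <- data.frame(samples, breeds)
  if (!is.null(groups)) tb$g <- groups
  utils::write.table(tb, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

# q-value track over a single chromosome from a plain numeric vector
toy_qtrack <- function(q, chrom = rep("1", length(q)),
                       pos = seq_along(q) * 1000L, breed = "P1") {
  v <- data.frame(chrom = chrom, pos = pos,
                  vid = paste0("v", seq_along(q)), ref = "A", alt = "G",
                  stringsAsFactors = FALSE)
  stat_track(q, v, "Q", breed)
}

toy_track <- function(x, chrom = rep("1", length(x)),
                      pos = seq_along(x) * 1000L, stat = "S", breed = "P1") {
  v <- data.frame(chrom = chrom, pos = pos,
                  vid = paste0("v", seq_along(x)), ref = "A", alt = "G",
                  stringsAsFactors = FALSE)
  stat_track(x, v, stat, breed)
}

toy_annotation <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(gene_id = r$name, name = r$name, chrom = r$chrom,
               start = r$start, end = r$end, strand = "+",
               stringsAsFactors = FALSE)
  }))
}
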