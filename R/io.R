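# Standard-format I/O at the package edges: FASTA/FASTQ through Biostrings,
# truth/call tables as BED (0-based half-open) and VCF 4.2 text.

#' Write sequences to FASTA
#' @param seqs named character vector/list, or a \code{genome}.
#' @param path output file.
#' @return path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "genome")) seqs <- seqs$seq
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file into a \code{genome}
#' @param path FASTA file.
#' @return a \code{genome}.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*", "", names(x))
  genome(setNames(as.list(as.character(x)), nm))
}

#' Write reads to FASTQ (gzip when the path ends in .gz)
#' @param reads named character vector.
#' @param path output file.
#' @param qual constant base quality character (flat quality model).
#' @return path, invisibly.
#' @export
write_fastq <- function(reads, path, qual = "I") {
  x <- Biostrings::DNAStringSet(unname(reads))
  names(x) <- names(reads)
  q <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep(qual, n), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Read a FASTQ file
#' @param path FASTQ file (optionally gzipped).
#' @return named character vector of reads.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub("\\s.*", "", names(x)))
}

#' Write intervals to BED (0-based half-open)
#' @param df data.frame with chrom, start, end (1-based inclusive) and an
#'   optional name column.
#' @param path output file.
#' @param name_col column used for the BED name field.
#' @return path, invisibly.
#' @export
write_bed <- function(df, path, name_col = NULL) {
  bed <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end,
                    name = if (!is.null(name_col)) df[[name_col]] else ".")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# Minimal VCF 4.2 writer for our own call sets.
# records: data.frame(chrom, pos, ref, alt, qual, filter, info[, genotypes])
write_vcf <- function(records, path, sample_cols = NULL, contigs = NULL,
                      extra_header = character()) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=tdnascout",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                     unname(contigs)),
           extra_header,
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO",
                   if (length(sample_cols)) c("FORMAT", sample_cols)),
                 collapse = "\t"))
  if (nrow(records)) {
    body <- sprintf("%s\t%.0f\t%s\t%s\t%s\t%s\t%s\t%s",
                    records$chrom, records$pos,
                    records$id %||% rep(".", nrow(records)),
                    records$ref, records$alt,
                    records$qual %||% rep(".", nrow(records)),
                    records$filter %||% rep("PASS", nrow(records)),
                    records$info %||% rep(".", nrow(records)))
    if (length(sample_cols)) {
      fmt <- records$format %||% rep("GT", nrow(records))
      gt <- do.call(paste, c(lapply(sample_cols, function(s) records[[s]]),
                             sep = "\t"))
      body <- paste(body, fmt, gt, sep = "\t")
    }
  } else body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Export simulation truth tables
#'
#' Writes the ground truth of a realized scenario: insert and deletion
#' intervals as BED, small variants (plus shared parental variants) as
#' VCF 4.2.
#'
#' @param realized result of \code{\link{realize_scenario}}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_truth <- function(realized, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  contigs <- setNames(as.integer(genome_lengths(realized$reference)),
                      names(realized$reference$seq))
  for (pl in names(realized$plants)) {
    tr <- realized$plants[[pl]]$truth
    if (nrow(tr$inserts))
      write_bed(data.frame(chrom = tr$inserts$chrom,
                           start = tr$inserts$left_bp,
                           end = tr$inserts$right_bp,
                           name = tr$inserts$expected_class),
                file.path(dir, paste0(pl, ".inserts.bed")), "name")
    if (nrow(tr$deletions))
      write_bed(tr$deletions, file.path(dir, paste0(pl, ".deletions.bed")))
    v <- tr$variants
    if (nrow(v))
      write_vcf(data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref,
                           alt = v$alt,
                           info = sprintf("TYPE=%s;HAP=%d", v$type,
                                          v$haplotype)),
                file.path(dir, paste0(pl, ".variants.vcf")),
                contigs = contigs)
  }
  pv <- realized$parent$variants
  if (nrow(pv))
    write_vcf(data.frame(chrom = pv$chrom, pos = pv$pos, ref = pv$ref,
                         alt = pv$alt, info = "PARENT=1"),
              file.path(dir, "parent.variants.vcf"), contigs = contigs)
  invisible(dir)
}
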