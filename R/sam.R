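# SAM interop: lossless round-trip of alignment records over the hybrid
# reference, so external tools can consume our alignments and externally
# produced alignments over the same reference can be imported.

sam_flags <- function(aln) {
  f <- rep(1L, nrow(aln))                       # paired
  f <- f + ifelse(aln$proper %||% FALSE, 2L, 0L)
  f <- f + ifelse(!aln$mapped, 4L, 0L)
  mate_unmapped <- is.na(aln$mate_ref %||% rep(NA_character_, nrow(aln)))
  f <- f + ifelse(mate_unmapped, 8L, 0L)
  f <- f + ifelse(aln$mapped & !is.na(aln$strand) & aln$strand < 0, 16L, 0L)
  f <- f + ifelse(!is.na(aln$mate_strand %||% rep(NA, nrow(aln))) &
                    (aln$mate_strand %||% rep(NA, nrow(aln))) < 0, 32L, 0L)
  f + ifelse(aln$mate == 1L, 64L, 128L)
}

#' Write alignments to SAM
#'
#' @param aln a \code{tdna_alignments} (from \code{\link{map_pairs}}).
#' @param hybrid the \code{hybrid_ref} the records were mapped to.
#' @param path output path (plain text SAM).
#' @return the path, invisibly.
#' @export
write_sam <- function(aln, hybrid, path) {
  bad <- aln$mapped & !(aln$ref %in% hybrid$names)
  if (any(bad)) stop("alignment reference not in hybrid reference header")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", hybrid$names,
                   unname(hybrid$lengths)),
           "@PG\tID:tdnascout\tPN:tdnascout")
  flag <- sam_flags(aln)
  rname <- ifelse(aln$mapped, aln$ref, "*")
  pos <- ifelse(aln$mapped, aln$pos, 0)
  cig <- ifelse(aln$mapped, aln$cigar, "*")
  mrn <- aln$mate_ref %||% rep(NA_character_, nrow(aln))
  rnext <- ifelse(is.na(mrn), "*", ifelse(mrn == rname, "=", mrn))
  pnext <- ifelse(is.na(mrn), 0, aln$mate_pos)
  rec <- sprintf("%s\t%d\t%s\t%.0f\t%d\t%s\t%s\t%.0f\t0\t%s\t*\tNM:i:%d\tAS:i:%d",
                 aln$read_id, flag, rname, pos, aln$mq, cig, rnext, pnext,
                 aln$seq, ifelse(is.na(aln$nm), 0L, aln$nm),
                 ifelse(is.na(aln$score), 0L, aln$score))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read alignments from SAM
#'
#' Parses a SAM file produced over the same hybrid reference back into a
#' \code{tdna_alignments}. Reference names must match the header, which
#' must match the hybrid reference.
#'
#' @param path SAM file.
#' @param hybrid the matching \code{hybrid_ref}.
#' @return a \code{tdna_alignments}.
#' @export
read_sam <- function(path, hybrid) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  sn <- sub(".*SN:([^\t]+).*", "\\1", sq)
  if (!all(sn %in% hybrid$names))
    stop("SAM header references sequences not in the hybrid reference")
  rec <- lines[!startsWith(lines, "@")]
  f <- strsplit(rec, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, "", i)
  flag <- as.integer(get(2))
  rname <- get(3)
  mapped <- bitwAnd(flag, 4L) == 0L
  if (any(mapped & !(rname %in% hybrid$names)))
    stop("alignment reference not present in hybrid reference")
  cig <- get(6)
  cig[!mapped] <- NA_character_
  st <- cpp_cigar_stats(cig)
  tags <- vapply(f, function(x) paste(x[-(1:11)], collapse = "\t"), "")
  nm <- suppressWarnings(as.integer(sub(".*NM:i:(-?\\d+).*", "\\1", tags)))
  as <- suppressWarnings(as.integer(sub(".*AS:i:(-?\\d+).*", "\\1", tags)))
  nm[!mapped] <- NA_integer_
  as[!mapped] <- NA_integer_
  pos <- as.numeric(get(4))
  rnext <- get(7)
  mate_ref <- ifelse(rnext == "=", rname, rnext)
  mate_ref[rnext == "*"] <- NA_character_
  aln <- data.frame(
    read_id = get(1), mate = ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L),
    ref = ifelse(mapped, rname, NA_character_),
    pos = ifelse(mapped, pos, NA_real_),
    end = ifelse(mapped, pos + st$ref_len - 1, NA_real_),
    strand = ifelse(mapped, ifelse(bitwAnd(flag, 16L) > 0L, -1L, 1L),
                    NA_integer_),
    cigar = cig, mq = as.integer(get(5)), score = as, nm = nm,
    ties = NA_integer_, clip_left = st$clip_left, clip_right = st$clip_right,
    seq = get(10), mapped = mapped, mate_ref = mate_ref,
    mate_pos = ifelse(rnext == "*", NA_real_, as.numeric(get(8))),
    mate_strand = ifelse(bitwAnd(flag, 32L) > 0L, -1L, 1L),
    proper = bitwAnd(flag, 2L) > 0L,
    orphan = bitwAnd(flag, 8L) > 0L & mapped,
    stringsAsFactors = FALSE)
  aln$mate_strand[is.na(aln$mate_ref)] <- NA_integer_
  class(aln) <- c("tdna_alignments", "data.frame")
  aln
}
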