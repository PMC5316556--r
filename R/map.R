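# Read mapping against the hybrid reference: seed (exact k-mer hits) ->
# diagonal chaining -> ungapped/banded extension with free end clips.
# Mapping quality is 60 for a unique best hit, 0 for ties, and interpolated
# by the score gap otherwise; reads whose aligned window is mostly masked
# are capped at MQ 50.

#' Map a batch of (single-end) reads
#'
#' @param hybrid a \code{hybrid_ref}.
#' @param reads named character vector of read sequences.
#' @param mate mate number recorded in the output (1 or 2).
#' @return a \code{tdna_alignments} data.frame; unmapped reads keep a row
#'   with \code{mapped = FALSE}.
#' @export
map_reads <- function(hybrid, reads, mate = 1L) {
  m <- cpp_map_batch(hybrid$index, unname(reads))
  st <- cpp_cigar_stats(m$cigar)
  ref <- ifelse(is.na(m$ref_idx), NA_character_, hybrid$names[m$ref_idx])
  seq_or <- unname(reads)
  neg <- !is.na(m$strand) & m$strand < 0
  seq_or[neg] <- cpp_revcomp(seq_or[neg])
  aln <- data.frame(
    read_id = names(reads) %||% paste0("r", seq_along(reads)),
    mate = mate, ref = ref, pos = m$pos,
    end = m$pos + st$ref_len - 1, strand = m$strand, cigar = m$cigar,
    mq = m$mq, score = m$score, nm = m$nm, ties = m$ties,
    clip_left = st$clip_left, clip_right = st$clip_right,
    seq = seq_or, mapped = !is.na(m$ref_idx),
    stringsAsFactors = FALSE)
  # MQ calibration against the uniqueness mask
  ok <- aln$mapped
  if (any(ok)) {
    frac <- rep(0, nrow(aln))
    for (rf in unique(aln$ref[ok])) {
      ii <- which(ok & aln$ref == rf)
      frac[ii] <- masked_fraction(hybrid, rf, aln$pos[ii], aln$end[ii])
    }
    cap <- ok & frac >= 0.5 & aln$mq > 50
    aln$mq[cap] <- 50L
  }
  class(aln) <- c("tdna_alignments", "data.frame")
  aln
}

#' Map one read (convenience wrapper)
#' @inheritParams map_reads
#' @param read single read sequence.
#' @return single-row \code{tdna_alignments}.
#' @export
map_read <- function(hybrid, read) {
  map_reads(hybrid, setNames(read, names(read) %||% "read1"))
}

#' Map read pairs and mate them
#'
#' Both mates are mapped independently, then mated: mate reference/position
#' fields are filled in and the proper-pair flag set when both mates map to
#' the same host sequence in FR orientation with an implied fragment within
#' \code{frag_mean} +/- 4 \code{frag_sd}. Orphan mates (one side unmapped)
#' are flagged, not dropped.
#'
#' @param hybrid a \code{hybrid_ref}.
#' @param r1,r2 named character vectors (same names = read ids).
#' @param frag_mean,frag_sd fragment-size model used for the proper-pair
#'   bound.
#' @return a \code{tdna_alignments} data.frame with both mates
#'   (2 rows/pair), carrying \code{mate_ref}, \code{mate_pos},
#'   \code{proper} and \code{orphan} columns.
#' @export
map_pairs <- function(hybrid, r1, r2, frag_mean = 625, frag_sd = 30) {
  if (!identical(names(r1), names(r2)))
    stop("mates must share read ids (identical names of r1 and r2)")
  a1 <- map_reads(hybrid, r1, mate = 1L)
  a2 <- map_reads(hybrid, r2, mate = 2L)
  a1$mate_ref <- a2$ref; a1$mate_pos <- a2$pos; a1$mate_strand <- a2$strand
  a2$mate_ref <- a1$ref; a2$mate_pos <- a1$pos; a2$mate_strand <- a1$strand
  host <- !hybrid$is_construct[match(a1$ref, hybrid$names)]
  fr <- !is.na(a1$strand) & !is.na(a2$strand) & a1$strand * a2$strand == -1
  lo <- pmin(a1$pos, a2$pos)
  hi <- pmax(a1$end, a2$end)
  plus_first <- ifelse(a1$strand == 1, a1$pos, a2$pos) == lo
  frag <- hi - lo + 1
  proper <- a1$mapped & a2$mapped & !is.na(host) & host &
    a1$ref == a2$ref & fr & plus_first &
    abs(frag - frag_mean) <= 4 * frag_sd
  proper[is.na(proper)] <- FALSE
  a1$proper <- a2$proper <- proper
  a1$orphan <- a1$mapped & !a2$mapped
  a2$orphan <- a2$mapped & !a1$mapped
  out <- rbind(a1, a2)
  class(out) <- c("tdna_alignments", "data.frame")
  out
}

#' Sort alignments by (reference, position)
#' @param aln a \code{tdna_alignments}.
#' @param hybrid hybrid reference providing the sequence order.
#' @return sorted \code{tdna_alignments}.
#' @export
sort_alignments <- function(aln, hybrid) {
  o <- order(match(aln$ref, hybrid$names), aln$pos, aln$read_id, aln$mate,
             na.last = TRUE)
  out <- aln[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.tdna_alignments <- function(x, ...) {
  cat("tdna_alignments:", nrow(x), "records,",
      sum(x$mapped), "mapped", if (!is.null(x$proper))
        paste0("(", sum(x$proper), " proper-paired)"), "\n")
  NextMethod()
}

#' Smith-Waterman local alignment (oracle-grade, exhaustive)
#'
#' Plain local alignment of a query against one reference sequence with
#' the mapper's scoring (match +1, mismatch -4, gap 5+l capped at
#' \code{gap_cap}); clips are free at query ends. Exhaustive over the
#' reference, so usable as an independent check of the seeded mapper on
#' small instances.
#'
#' @param query,ref sequences.
#' @param gap_cap maximum single gap length.
#' @return list(score, pos, cigar, nm, qstart, qend).
#' @export
local_align <- function(query, ref, gap_cap = 6L) {
  cpp_sw(query, ref, gap_cap)
}
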