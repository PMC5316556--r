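# Junction evidence: broken read pairs (mates on different references) and
# split reads (one read partially aligned to two loci, the remainder as a
# soft clip). Each record ties a genomic breakpoint to a construct segment
# (or to a second host locus for translocation/deletion support).
#
# `side` is the side of the breakpoint occupied by host sequence: "left"
# means the host flank is left of the junction and the insert continues to
# the right.

empty_evidence <- function() {
  data.frame(kind = character(), pair_class = character(), plant = character(),
             chrom = character(), breakpoint = numeric(), side = character(),
             construct_start = numeric(), construct_end = numeric(),
             construct_strand = character(), target_ref = character(),
             target_pos = numeric(), filler = character(),
             resolved = logical(), read_id = character(), mq = integer(),
             precise = logical(), stringsAsFactors = FALSE)
}

#' Classify mated alignments into broken-pair evidence
#'
#' Mates on host + construct become construct-class broken pairs (construct
#' span = the mate's alignment); mates on two different host chromosomes
#' become inter-chromosomal pairs (translocation candidates); same-
#' chromosome pairs whose implied fragment exceeds the proper-pair bound
#' become long-range pairs (deletion support). Concordant pairs yield
#' nothing.
#'
#' @param aln \code{tdna_alignments} from \code{\link{map_pairs}}.
#' @param hybrid the \code{hybrid_ref}.
#' @param min_mq minimum host-side mapping quality.
#' @param frag_mean,frag_sd fragment model (long-range bound).
#' @param plant_id sample label carried in the records.
#' @return evidence data.frame (see \code{\link{collect_evidence}}).
#' @export
classify_pairs <- function(aln, hybrid, min_mq = 20L, frag_mean = 625,
                           frag_sd = 30, plant_id = "sample") {
  a1 <- aln[aln$mate == 1L, ]
  a2 <- aln[aln$mate == 2L, ][match(aln$read_id[aln$mate == 1L],
                                    aln$read_id[aln$mate == 2L]), ]
  cn <- construct_name(hybrid)
  out <- list()
  emit_host_side <- function(h, o, pair_class, target_is_construct) {
    # h: host-side rows; o: other-side rows
    bp <- ifelse(h$strand == 1, h$end, h$pos)
    side <- ifelse(h$strand == 1, "left", "right")
    data.frame(kind = "broken_pair", pair_class = pair_class,
               plant = plant_id, chrom = h$ref, breakpoint = bp, side = side,
               construct_start = if (target_is_construct) o$pos else NA_real_,
               construct_end = if (target_is_construct) o$end else NA_real_,
               construct_strand = if (target_is_construct)
                 ifelse(h$strand != o$strand, "+", "-") else NA_character_,
               target_ref = o$ref, target_pos = o$pos,
               filler = NA_character_, resolved = TRUE,
               read_id = h$read_id, mq = pmin(h$mq, o$mq),
               precise = FALSE, stringsAsFactors = FALSE)
  }
  both <- a1$mapped & a2$mapped
  c1 <- !is.na(a1$ref) & a1$ref == cn
  c2 <- !is.na(a2$ref) & a2$ref == cn
  # host + construct
  hc <- both & xor(c1, c2)
  if (any(hc)) {
    hostfirst <- hc & c2
    if (any(hostfirst))
      out[[length(out) + 1L]] <- emit_host_side(a1[hostfirst, ],
                                                a2[hostfirst, ],
                                                "construct", TRUE)
    hostsecond <- hc & c1
    if (any(hostsecond))
      out[[length(out) + 1L]] <- emit_host_side(a2[hostsecond, ],
                                                a1[hostsecond, ],
                                                "construct", TRUE)
  }
  # two different host chromosomes
  ic <- both & !c1 & !c2 & a1$ref != a2$ref
  if (any(ic)) {
    out[[length(out) + 1L]] <- emit_host_side(a1[ic, ], a2[ic, ],
                                              "inter_chrom", FALSE)
    out[[length(out) + 1L]] <- emit_host_side(a2[ic, ], a1[ic, ],
                                              "inter_chrom", FALSE)
  }
  # same chromosome, fragment far beyond any plausible library tail
  # (8 sd: the 4-sd proper-pair bound flags rare honest tail fragments,
  # which must not become deletion evidence)
  sc <- both & !c1 & !c2 & a1$ref == a2$ref & !(a1$proper %||% FALSE)
  if (any(sc)) {
    frag <- pmax(a1$end, a2$end)[sc] - pmin(a1$pos, a2$pos)[sc] + 1
    lr <- sc
    lr[sc] <- frag > frag_mean + 8 * frag_sd
    if (any(lr)) {
      out[[length(out) + 1L]] <- emit_host_side(a1[lr, ], a2[lr, ],
                                                "long_range", FALSE)
      out[[length(out) + 1L]] <- emit_host_side(a2[lr, ], a1[lr, ],
                                                "long_range", FALSE)
    }
  }
  ev <- if (length(out)) do.call(rbind, out) else empty_evidence()
  # require decent mapping on the emitting (host) side
  ev[ev$mq >= min_mq | ev$mq == 0L, , drop = FALSE]
}

#' Extract split-read evidence from soft-clipped alignments
#'
#' The clipped substring of every alignment with a soft clip of at least
#' \code{min_clip} bases is locally realigned against the hybrid reference
#' (small-k seed index). A hit of at least \code{min_clip} aligned bases at
#' \code{min_ident} identity yields split-read evidence; unaligned residue
#' between the two segments is retained as candidate filler DNA (records
#' with residue beyond \code{max_filler} are marked unresolved). Clips
#' aligning equally well to several loci are emitted with MQ 0 so the
#' caller can filter them.
#'
#' @param aln \code{tdna_alignments}.
#' @param hybrid the \code{hybrid_ref}.
#' @param min_clip minimum informative clip length (default 12).
#' @param min_ident minimum identity of the clip realignment.
#' @param max_filler longest residue accepted as filler DNA.
#' @param min_mq minimum mapping quality of the primary (host) alignment.
#' @param plant_id sample label.
#' @return evidence data.frame.
#' @export
extract_splits <- function(aln, hybrid, min_clip = 12L, min_ident = 0.90,
                           max_filler = 20L, min_mq = 20L,
                           plant_id = "sample") {
  cn <- construct_name(hybrid)
  cand <- aln[aln$mapped & !is.na(aln$ref) & aln$mq >= min_mq &
                (aln$clip_left >= min_clip | aln$clip_right >= min_clip), ,
              drop = FALSE]
  out <- list()

  # best accepted hit of a (sub)clip against the hybrid reference
  clip_hits <- function(s) {
    if (nchar(s) < min_clip) return(NULL)
    hits <- cpp_map_hits(hybrid$clip_index, s)
    if (!nrow(hits)) return(NULL)
    alen <- hits$qend - hits$qstart + 1L
    ident <- (alen - hits$nm) / alen
    keep <- alen >= min_clip & ident >= min_ident
    if (!any(keep)) return(NULL)
    hits <- hits[keep, , drop = FALSE]
    st <- cpp_cigar_stats(hits$cigar)
    hits$ref_len <- st$ref_len
    # qstart/qend of minus-strand hits refer to the reversed query;
    # convert to query-forward coordinates
    n <- nchar(s)
    neg <- hits$strand < 0
    qs <- ifelse(neg, n - hits$qend + 1L, hits$qstart)
    qe <- ifelse(neg, n - hits$qstart + 1L, hits$qend)
    hits$qstart <- qs
    hits$qend <- qe
    hits$tie <- hits$score == hits$score[1] &
      (hits$ref_idx != hits$ref_idx[1] | abs(hits$pos - hits$pos[1]) > 15)
    hits
  }

  for (i in seq_len(nrow(cand))) {
    row <- cand[i, ]
    con_primary <- row$ref == cn
    for (sideclip in c("left", "right")) {
      cl <- if (sideclip == "left") row$clip_left else row$clip_right
      if (cl < min_clip) next
      clip <- if (sideclip == "left") substr(row$seq, 1L, cl)
              else substr(row$seq, nchar(row$seq) - cl + 1L, nchar(row$seq))
      hits <- clip_hits(clip)
      if (is.null(hits)) next
      h <- hits[1, ]
      tie <- sum(hits$tie) > 0L
      h_off <- 0L

      if (con_primary) {
        # primary on the plasmid: the clip must land in host sequence
        if (hybrid$is_construct[h$ref_idx]) next
        hs <- h$strand
        if (sideclip == "left") {
          side <- if (hs > 0) "left" else "right"
          bp <- if (hs > 0) h$pos + h$ref_len - 1 else h$pos
        } else {
          side <- if (hs > 0) "right" else "left"
          bp <- if (hs > 0) h$pos else h$pos + h$ref_len - 1
        }
        out[[length(out) + 1L]] <- data.frame(
          kind = "split_read", pair_class = NA_character_, plant = plant_id,
          chrom = hybrid$names[h$ref_idx], breakpoint = bp, side = side,
          construct_start = row$pos, construct_end = row$end,
          construct_strand = ifelse(hs > 0, "+", "-"),
          target_ref = cn, target_pos = row$pos,
          filler = NA_character_, resolved = TRUE, read_id = row$read_id,
          mq = if (tie) 0L else as.integer(pmin(row$mq, 60L)),
          precise = TRUE, stringsAsFactors = FALSE)
        next
      }

      # primary on host: prefer a construct hit; when the top hit is host
      # (e.g. the resuming flank of a short insert), realign the residue
      # between the primary alignment and that hit
      ch <- NULL
      if (hybrid$is_construct[h$ref_idx]) {
        ch <- h
      } else {
        residue0 <- if (sideclip == "right") substr(clip, 1L, h$qstart - 1L)
                    else substr(clip, h$qend + 1L, cl)
        sub_hits <- clip_hits(residue0)
        if (!is.null(sub_hits) && hybrid$is_construct[sub_hits$ref_idx[1]]) {
          ch <- sub_hits[1, ]
          tie <- tie || sum(sub_hits$tie) > 0L
          h_off <- if (sideclip == "right") 0L else h$qend
        }
      }
      if (sideclip == "right") {
        bp <- row$end
        side <- "left"
      } else {
        bp <- row$pos
        side <- "right"
      }
      if (!is.null(ch)) {
        qs <- ch$qstart + h_off
        qe <- ch$qend + h_off
        residue <- if (side == "left") substr(clip, 1L, qs - 1L)
                   else substr(clip, qe + 1L, cl)
        out[[length(out) + 1L]] <- data.frame(
          kind = "split_read", pair_class = NA_character_, plant = plant_id,
          chrom = row$ref, breakpoint = bp, side = side,
          construct_start = ch$pos, construct_end = ch$pos + ch$ref_len - 1,
          construct_strand = ifelse(ch$strand > 0, "+", "-"),
          target_ref = cn, target_pos = ch$pos,
          filler = residue, resolved = nchar(residue) <= max_filler,
          read_id = row$read_id,
          mq = if (tie) 0L else as.integer(pmin(row$mq, 60L)),
          precise = TRUE, stringsAsFactors = FALSE)
      } else {
        # host-host split (translocation / deletion junction support)
        residue <- if (side == "left") substr(clip, 1L, h$qstart - 1L)
                   else substr(clip, h$qend + 1L, cl)
        out[[length(out) + 1L]] <- data.frame(
          kind = "split_read", pair_class = NA_character_, plant = plant_id,
          chrom = row$ref, breakpoint = bp, side = side,
          construct_start = NA_real_, construct_end = NA_real_,
          construct_strand = NA_character_,
          target_ref = hybrid$names[h$ref_idx], target_pos = h$pos,
          filler = residue, resolved = nchar(residue) <= max_filler,
          read_id = row$read_id,
          mq = if (tie) 0L else as.integer(pmin(row$mq, 60L)),
          precise = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else empty_evidence()
}

#' Pool and index junction evidence
#'
#' Combines broken-pair and split-read evidence, removes duplicates
#' (one record per read, kind and breakpoint), and applies the
#' host-derived-promoter exclusion: evidence whose construct span lies
#' wholly inside a \code{host_derived} construct feature is dropped, since
#' such reads cannot distinguish plasmid from host origin.
#'
#' @param aln \code{tdna_alignments} of one sample.
#' @param hybrid the \code{hybrid_ref}.
#' @param plant_id sample label.
#' @param min_mq,frag_mean,frag_sd,min_clip,min_ident,max_filler see
#'   \code{\link{classify_pairs}} and \code{\link{extract_splits}}.
#' @return an \code{evidence_set} data.frame sorted by locus.
#' @export
collect_evidence <- function(aln, hybrid, plant_id = "sample", min_mq = 20L,
                             frag_mean = 625, frag_sd = 30, min_clip = 12L,
                             min_ident = 0.90, max_filler = 20L) {
  ev <- rbind(
    classify_pairs(aln, hybrid, min_mq = min_mq, frag_mean = frag_mean,
                   frag_sd = frag_sd, plant_id = plant_id),
    extract_splits(aln, hybrid, min_clip = min_clip, min_ident = min_ident,
                   max_filler = max_filler, min_mq = min_mq,
                   plant_id = plant_id))
  # promoter (host-derived) exclusion
  hd <- host_derived_intervals(hybrid$construct)
  if (nrow(hd) && nrow(ev)) {
    excl <- rep(FALSE, nrow(ev))
    has_span <- !is.na(ev$construct_start)
    for (j in seq_len(nrow(hd)))
      excl <- excl | (has_span & ev$construct_start >= hd$start[j] &
                        ev$construct_end <= hd$end[j])
    ev <- ev[!excl, , drop = FALSE]
  }
  ev <- ev[!duplicated(ev[, c("read_id", "kind", "chrom", "breakpoint")]), ,
           drop = FALSE]
  ev <- ev[order(ev$chrom, ev$breakpoint), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("evidence_set", "data.frame")
  attr(ev, "params") <- list(min_mq = min_mq, frag_mean = frag_mean,
                             frag_sd = frag_sd, min_clip = min_clip)
  ev
}

#' Write an evidence set as TSV (debugging aid)
#' @param ev evidence_set.
#' @param path output path.
#' @return path, invisibly.
#' @export
write_evidence_tsv <- function(ev, path) {
  write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
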