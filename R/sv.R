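# Structural variation associated with T-DNA integration: large
# heterozygous deletions (depth drop to ~50% of the control-normalized
# coverage, boundaries refined by junction evidence) and insert-flanking
# translocations (inserts whose two flanks map to different chromosomes).
# Emitted calls satisfy the reporting filters: >= 10 supporting broken
# pairs, mean mapping quality > 50, genotype quality > 30, alternative
# allele fraction >= 0.4, heterozygous in the transgenic sample and
# homozygous-reference in the control pool.

#' Binned depth track normalized against the control pool
#'
#' @param pu,pu_ctrl \code{host_pileup} of the plant and of the control
#'   pool over the same reference.
#' @param bin bin size (bp).
#' @return \code{depth_track} data.frame: chrom, bin_start, bin_end,
#'   depth, ctrl_depth, ratio (each sample scaled by its genome-wide
#'   median bin depth), flagged (control bin empty).
#' @export
build_depth_track <- function(pu, pu_ctrl, bin = 500L) {
  stopifnot(identical(pu$chroms, pu_ctrl$chroms))
  rows <- list()
  for (ch in pu$chroms) {
    d <- pu$depth[[ch]]
    dc <- pu_ctrl$depth[[ch]]
    L <- length(d)
    nb <- ceiling(L / bin)
    idx <- rep(seq_len(nb), each = bin, length.out = L)
    bs <- (seq_len(nb) - 1L) * bin + 1L
    rows[[ch]] <- data.frame(
      chrom = ch, bin_start = bs, bin_end = pmin(bs + bin - 1L, L),
      depth = as.numeric(tapply(d, idx, mean)),
      ctrl_depth = as.numeric(tapply(dc, idx, mean)))
  }
  tr <- do.call(rbind, rows)
  rownames(tr) <- NULL
  mp <- median(tr$depth[tr$depth > 0])
  mc <- median(tr$ctrl_depth[tr$ctrl_depth > 0])
  tr$flagged <- tr$ctrl_depth == 0
  tr$ratio <- ifelse(tr$flagged, NA_real_,
                     (tr$depth / mp) / (tr$ctrl_depth / mc))
  class(tr) <- c("depth_track", "data.frame")
  attr(tr, "bin") <- bin
  tr
}

#' Binomial structural-variant genotyper
#'
#' Likelihoods of hom-ref / het / hom-alt assume alt-read probabilities
#' 0.05 / 0.5 / 0.95; the genotype is the maximum-likelihood state and GQ
#' the phred-scaled difference between the best and second-best
#' likelihood.
#'
#' @param supporting alt-supporting read (pair) count.
#' @param spanning reference-spanning read (pair) count.
#' @return list(genotype, gq, alt_frac); genotype "no-call" when both
#'   counts are zero.
#' @export
genotype_sv <- function(supporting, spanning) {
  n <- supporting + spanning
  if (n == 0) return(list(genotype = "no-call", gq = 0, alt_frac = NA_real_))
  ll <- dbinom(supporting, n, c(0.05, 0.5, 0.95), log = TRUE)
  names(ll) <- c("hom_ref", "het", "hom_alt")
  o <- order(ll, decreasing = TRUE)
  list(genotype = names(ll)[o[1]],
       gq = 10 * (ll[o[1]] - ll[o[2]]) / log(10),
       alt_frac = supporting / n)
}

empty_sv <- function() {
  data.frame(type = character(), chrom = character(), start = numeric(),
             end = numeric(), chrom2 = character(), pos2 = numeric(),
             size = numeric(), genotype = character(), gq = numeric(),
             n_supporting_pairs = integer(), mean_mq = numeric(),
             alt_frac = numeric(), ctrl_genotype = character(),
             linked_insert = character(), filter = character(),
             plant = character(), stringsAsFactors = FALSE)
}

# evidence rows (pairs or splits) near a position
ev_near <- function(ev, chrom, pos, window, kind = NULL, side = NULL) {
  k <- ev$chrom == chrom & abs(ev$breakpoint - pos) <= window & ev$mq > 0
  if (!is.null(kind)) k <- k & ev$kind == kind
  if (!is.null(side)) k <- k & ev$side == side
  ev[k, , drop = FALSE]
}

# fragment-level reference-spanning count at a breakpoint
spanning_pairs <- function(aln, chrom, bp, exclude_ids, margin = 10L) {
  m1 <- aln[aln$mate == 1L & (aln$proper %||% FALSE) & aln$ref == chrom, ,
            drop = FALSE]
  if (!nrow(m1)) return(0L)
  lo <- pmin(m1$pos, m1$mate_pos)
  hi <- pmax(m1$end, m1$mate_pos + (m1$end - m1$pos))
  sum(lo <= bp - margin & hi >= bp + margin & !(m1$read_id %in% exclude_ids))
}

#' Call large deletions from the depth track plus junction evidence
#'
#' Runs of at least \code{min_run} bins with normalized ratio inside
#' \code{het_window} seed heterozygous-deletion candidates; boundaries
#' are refined to the nearest split-read cluster (any evidence class)
#' within \code{refine_window}, falling back to broken pairs and then bin
#' edges. Candidates failing any reporting filter are retained with the
#' failed filters named. Deletions shorter than \code{min_sv_size} at
#' insert sites are the insert caller's domain and are not emitted here.
#'
#' @param track \code{depth_track}.
#' @param ev plant \code{evidence_set}.
#' @param aln plant alignments.
#' @param ev_ctrl,aln_ctrl control-pool evidence and alignments.
#' @param min_sv_size smallest reportable deletion (bp).
#' @param het_window normalized-ratio window seeding heterozygous
#'   candidates.
#' @param min_run minimum consecutive bins.
#' @param refine_window boundary-refinement search window (bp).
#' @param min_pairs,min_mean_mq,min_gq,min_alt_frac reporting filters.
#' @param plant_id sample label.
#' @return \code{sv_calls} data.frame (column \code{filter}: "PASS" or
#'   semicolon-joined reasons).
#' @export
call_deletions <- function(track, ev, aln, ev_ctrl, aln_ctrl,
                           min_sv_size = 300L, het_window = c(0.3, 0.7),
                           min_run = 3L, refine_window = 2000L,
                           min_pairs = 10L, min_mean_mq = 50,
                           min_gq = 30, min_alt_frac = 0.4,
                           insert_calls = NULL, plant_id = "sample") {
  out <- empty_sv()
  bin <- attr(track, "bin")
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    inwin <- !is.na(tr$ratio) & tr$ratio >= het_window[1] &
      tr$ratio <= het_window[2]
    # close short gaps: a single noisy bin must not fragment a long run
    r0 <- rle(inwin)
    if (length(r0$lengths) > 2) {
      interior <- seq(2L, length(r0$lengths) - 1L)
      fill <- interior[!r0$values[interior] & r0$lengths[interior] <= 2L]
      r0$values[fill] <- TRUE
      inwin <- inverse.rle(r0)
    }
    r <- rle(inwin)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= min_run)) {
      cand_start <- tr$bin_start[starts[j]]
      cand_end <- tr$bin_end[ends[j]]
      refine <- function(pos, side) {
        sp <- ev_near(ev, ch, pos, refine_window, kind = "split_read",
                      side = side)
        if (nrow(sp)) return(round(median(sp$breakpoint)))
        pr <- ev_near(ev, ch, pos, refine_window, kind = "broken_pair",
                      side = side)
        if (nrow(pr)) {
          return(if (side == "left") max(pr$breakpoint)
                 else min(pr$breakpoint))
        }
        pos
      }
      left_bp <- refine(cand_start - 1L, "left")
      right_bp <- refine(cand_end + 1L, "right")
      if (right_bp <= left_bp + 1) next
      size <- right_bp - left_bp - 1
      supp <- unique(rbind(
        ev_near(ev, ch, left_bp, 1000L, kind = "broken_pair"),
        ev_near(ev, ch, right_bp, 1000L, kind = "broken_pair")))
      n_supp <- length(unique(supp$read_id))
      mean_mq <- if (n_supp) mean(supp$mq) else 0
      n_span <- spanning_pairs(aln, ch, left_bp, supp$read_id)
      gt <- genotype_sv(n_supp, n_span)
      csupp <- unique(rbind(
        ev_near(ev_ctrl, ch, left_bp, 1000L, kind = "broken_pair"),
        ev_near(ev_ctrl, ch, right_bp, 1000L, kind = "broken_pair")))
      n_csupp <- length(unique(csupp$read_id))
      cgt <- genotype_sv(n_csupp, spanning_pairs(aln_ctrl, ch, left_bp,
                                                 csupp$read_id))
      fails <- character()
      # site deletions bridged into a both-sided insert call belong to the
      # insert caller's report, not the SV track
      if (!is.null(insert_calls) && nrow(insert_calls)) {
        ic <- insert_calls
        owned <- !is.na(ic$left_bp) & !is.na(ic$right_bp) &
          ic$chrom == ic$right_chrom & ic$chrom == ch &
          abs(ic$left_bp - left_bp) <= 50 & abs(ic$right_bp - right_bp) <= 50
        if (any(owned)) fails <- c(fails, "insert_site_deletion")
      }
      if (size < min_sv_size) fails <- c(fails, "min_size")
      if (n_supp < min_pairs) fails <- c(fails, "min_pairs")
      if (mean_mq <= min_mean_mq) fails <- c(fails, "mapping_quality")
      if (gt$gq <= min_gq) fails <- c(fails, "genotype_quality")
      if (is.na(gt$alt_frac) || gt$alt_frac < min_alt_frac)
        fails <- c(fails, "alt_frac")
      if (gt$genotype != "het") fails <- c(fails, "not_heterozygous")
      if (cgt$genotype != "hom_ref") fails <- c(fails, "control_not_homref")
      out <- rbind(out, data.frame(
        type = "DEL", chrom = ch, start = left_bp + 1, end = right_bp - 1,
        chrom2 = NA_character_, pos2 = NA_real_, size = size,
        genotype = gt$genotype, gq = gt$gq, n_supporting_pairs = n_supp,
        mean_mq = mean_mq, alt_frac = gt$alt_frac,
        ctrl_genotype = cgt$genotype, linked_insert = NA_character_,
        filter = if (length(fails)) paste(fails, collapse = ";") else "PASS",
        plant = plant_id, stringsAsFactors = FALSE))
    }
  }
  class(out) <- c("sv_calls", "data.frame")
  out
}

#' Call insert-flanking translocations
#'
#' Every insert call whose two flanks map to different chromosomes yields
#' a translocation candidate linking the two breakpoints, annotated with
#' the insert id and subjected to the reporting filters (supporting
#' pairs, mapping quality, genotype quality, heterozygous in plant,
#' absent in control).
#'
#' @param calls plant \code{insert_calls}.
#' @param ev plant \code{evidence_set}.
#' @param aln plant alignments (pair-level genotyping).
#' @param ev_ctrl control-pool evidence.
#' @param aln_ctrl control-pool alignments.
#' @param min_pairs,min_mean_mq,min_gq reporting filters.
#' @param plant_id sample label.
#' @return \code{sv_calls} data.frame of TRA records.
#' @export
call_translocations <- function(calls, ev, aln, ev_ctrl, aln_ctrl,
                                min_pairs = 10L, min_mean_mq = 50,
                                min_gq = 30, plant_id = "sample") {
  out <- empty_sv()
  cand <- calls[!is.na(calls$right_chrom) & calls$chrom != calls$right_chrom, ,
                drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    cc <- cand[i, ]
    suppA <- ev_near(ev, cc$chrom, cc$left_bp, 1000L, kind = "broken_pair")
    suppB <- ev_near(ev, cc$right_chrom, cc$right_bp, 1000L,
                     kind = "broken_pair")
    supp <- unique(rbind(suppA, suppB))
    n_supp <- length(unique(supp$read_id))
    mean_mq <- if (n_supp) mean(supp$mq) else 0
    # pair-level genotype per junction; report the better-supported side
    # (the donor locus of a copied fragment stays fully covered and
    # dilutes its own junction fraction)
    gt_side <- function(sp, chrom, bp) {
      ns <- length(unique(sp$read_id))
      genotype_sv(ns, spanning_pairs(aln, chrom, bp, sp$read_id))
    }
    gtA <- gt_side(suppA, cc$chrom, cc$left_bp)
    gtB <- gt_side(suppB, cc$right_chrom, cc$right_bp)
    gt <- if (gtA$gq >= gtB$gq) gtA else gtB
    ctrl <- unique(rbind(
      ev_near(ev_ctrl, cc$chrom, cc$left_bp, 1000L),
      ev_near(ev_ctrl, cc$right_chrom, cc$right_bp, 1000L)))
    n_ctrl <- length(unique(ctrl$read_id))
    fails <- character()
    if (n_supp < min_pairs) fails <- c(fails, "min_pairs")
    if (mean_mq <= min_mean_mq) fails <- c(fails, "mapping_quality")
    if (gt$gq <= min_gq) fails <- c(fails, "genotype_quality")
    if (gt$genotype != "het") fails <- c(fails, "not_heterozygous")
    if (n_ctrl > 2) fails <- c(fails, "control_support")
    out <- rbind(out, data.frame(
      type = "TRA", chrom = cc$chrom, start = cc$left_bp, end = NA_real_,
      chrom2 = cc$right_chrom, pos2 = cc$right_bp, size = NA_real_,
      genotype = gt$genotype, gq = gt$gq, n_supporting_pairs = n_supp,
      mean_mq = mean_mq, alt_frac = gt$alt_frac,
      ctrl_genotype = if (n_ctrl > 2) "supported" else "hom_ref",
      linked_insert = cc$call_id,
      filter = if (length(fails)) paste(fails, collapse = ";") else "PASS",
      plant = plant_id, stringsAsFactors = FALSE))
  }
  class(out) <- c("sv_calls", "data.frame")
  out
}

#' Write structural-variant calls as VCF 4.2
#'
#' Deletions as symbolic \code{<DEL>} records with END/SVLEN;
#' translocations as breakend (BND) record pairs.
#'
#' @param svs \code{sv_calls} (only PASS records are written).
#' @param hybrid hybrid reference (contig headers).
#' @param path output path.
#' @return path, invisibly.
#' @export
write_sv_vcf <- function(svs, hybrid, path) {
  hn <- host_names(hybrid)
  contigs <- setNames(as.integer(hybrid$lengths[hn]), hn)
  p <- svs[svs$filter == "PASS", , drop = FALSE]
  recs <- list()
  for (i in seq_len(nrow(p))) {
    s <- p[i, ]
    if (s$type == "DEL") {
      recs[[length(recs) + 1L]] <- data.frame(
        chrom = s$chrom, pos = s$start - 1, id = sprintf("DEL%04d", i),
        ref = "N", alt = "<DEL>", qual = round(s$gq), filter = "PASS",
        info = sprintf("SVTYPE=DEL;END=%.0f;SVLEN=-%.0f;PE=%d;MAPQ=%.0f;GT=%s",
                       s$end + 1, s$size, s$n_supporting_pairs, s$mean_mq,
                       s$genotype))
    } else {
      id1 <- sprintf("TRA%04d_1", i); id2 <- sprintf("TRA%04d_2", i)
      recs[[length(recs) + 1L]] <- data.frame(
        chrom = c(s$chrom, s$chrom2), pos = c(s$start, s$pos2),
        id = c(id1, id2), ref = c("N", "N"),
        alt = c(sprintf("N]%s:%.0f]", s$chrom2, s$pos2),
                sprintf("N]%s:%.0f]", s$chrom, s$start)),
        qual = round(s$gq), filter = "PASS",
        info = sprintf("SVTYPE=BND;MATEID=%s;PE=%d;MAPQ=%.0f;GT=%s",
                       c(id2, id1), s$n_supporting_pairs, s$mean_mq,
                       s$genotype))
    }
  }
  df <- if (length(recs)) do.call(rbind, recs) else
    data.frame(chrom = character(), pos = numeric(), ref = character(),
               alt = character())
  write_vcf(df, path, contigs = contigs, extra_header = c(
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend\">",
    "##INFO=<ID=PE,Number=1,Type=Integer,Description=\"Supporting pairs\">",
    "##INFO=<ID=MAPQ,Number=1,Type=Float,Description=\"Mean mapping quality\">",
    "##INFO=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"))
}
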