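# Insert calling: cluster junction evidence into locus-level calls with
# T-DNA segment coordinates, orientation, zygosity, insert-site deletion,
# filler DNA, and a class (full / partial / inverted_repeat / backbone /
# splinter / unresolved).

#' Cluster construct-linked junction evidence
#'
#' Split-read breakpoints within \code{split_window} on one chromosome and
#' junction side are merged (cluster position = median); broken pairs are
#' assigned to the nearest split cluster within \code{pair_window}, or form
#' pair-only clusters otherwise.
#'
#' @param ev an \code{evidence_set}.
#' @param split_window merge window for split breakpoints (bp).
#' @param pair_window assignment window for broken pairs (bp); default
#'   frag_mean + 3*frag_sd of the evidence set.
#' @param min_mq minimum evidence mapping quality used for clustering.
#' @return data.frame of clusters with list-columns of member evidence.
#' @export
cluster_evidence <- function(ev, split_window = 5L, pair_window = NULL,
                             min_mq = 20L) {
  pp <- attr(ev, "params")
  if (is.null(pair_window))
    pair_window <- (pp$frag_mean %||% 625) + 3 * (pp$frag_sd %||% 30)
  con <- ev[!is.na(ev$construct_start) & ev$mq >= min_mq, , drop = FALSE]
  clusters <- list()
  for (key in unique(paste(con$chrom, con$side))) {
    chrom <- sub(" .*", "", key)
    side <- sub(".* ", "", key)
    sub_ev <- con[con$chrom == chrom & con$side == side, , drop = FALSE]
    sp <- sub_ev[sub_ev$kind == "split_read", , drop = FALSE]
    pr <- sub_ev[sub_ev$kind == "broken_pair", , drop = FALSE]
    grp <- list()
    if (nrow(sp)) {
      o <- order(sp$breakpoint)
      sp <- sp[o, , drop = FALSE]
      gid <- cumsum(c(1L, diff(sp$breakpoint) > split_window))
      for (g in unique(gid)) {
        m <- sp[gid == g, , drop = FALSE]
        grp[[length(grp) + 1L]] <- list(pos = round(median(m$breakpoint)),
                                        splits = m, pairs = m[0, ],
                                        precise = TRUE)
      }
    }
    if (nrow(pr)) {
      cpos <- vapply(grp, `[[`, 0, "pos")
      for (i in seq_len(nrow(pr))) {
        d <- if (length(cpos)) abs(cpos - pr$breakpoint[i]) else numeric()
        if (length(d) && min(d) <= pair_window) {
          j <- which.min(d)
          grp[[j]]$pairs <- rbind(grp[[j]]$pairs, pr[i, ])
        } else {
          # open/extend a pair-only cluster
          placed <- FALSE
          for (j in seq_along(grp)) {
            if (!grp[[j]]$precise &&
                abs(grp[[j]]$pos - pr$breakpoint[i]) <= pair_window) {
              grp[[j]]$pairs <- rbind(grp[[j]]$pairs, pr[i, ])
              grp[[j]]$pos <- if (side == "left")
                max(grp[[j]]$pairs$breakpoint) else
                  min(grp[[j]]$pairs$breakpoint)
              placed <- TRUE
              break
            }
          }
          if (!placed)
            grp[[length(grp) + 1L]] <- list(pos = pr$breakpoint[i],
                                            splits = pr[0, ], pairs = pr[i, ],
                                            precise = FALSE)
        }
      }
    }
    for (g in grp) {
      memb <- rbind(g$splits, g$pairs)
      strand <- names(sort(table(memb$construct_strand), decreasing = TRUE))[1]
      # construct boundary adjacent to the junction, from split evidence
      bsrc <- if (nrow(g$splits)) g$splits else g$pairs
      # junction-adjacent construct coordinate:
      #   side left,  '+': segment begins at its start  -> min coord
      #   side left,  '-': segment begins at its end    -> max coord
      #   side right, '+': segment ends at its end      -> max coord
      #   side right, '-': segment ends at its start    -> min coord
      boundary <- if ((side == "left") == (strand == "+"))
        round(median(bsrc$construct_start))
      else
        round(median(bsrc$construct_end))
      fill <- g$splits$filler[g$splits$resolved & !is.na(g$splits$filler)]
      filler <- if (length(fill))
        names(sort(table(fill), decreasing = TRUE))[1] else ""
      clusters[[length(clusters) + 1L]] <- data.frame(
        chrom = chrom, side = side, pos = g$pos, precise = g$precise,
        n_split = nrow(g$splits), n_pair = nrow(g$pairs),
        strand = strand, boundary = boundary,
        cs_min = min(memb$construct_start), cs_max = max(memb$construct_end),
        filler = filler, plant = memb$plant[1],
        reads = I(list(unique(memb$read_id))),
        split_reads = I(list(unique(g$splits$read_id))),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(clusters))
    return(data.frame(chrom = character(), side = character(),
                      pos = numeric(), precise = logical(),
                      n_split = integer(), n_pair = integer(),
                      strand = character(), boundary = numeric(),
                      cs_min = numeric(), cs_max = numeric(),
                      filler = character(), plant = character(),
                      reads = I(list()), split_reads = I(list())))
  out <- do.call(rbind, clusters)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

# construct read-depth vector for one sample (used to extend inverted-
# repeat segments beyond their junction boundary)
construct_depth <- function(aln, hybrid) {
  cn <- construct_name(hybrid)
  rows <- aln$mapped & aln$ref == cn
  if (!any(rows)) return(integer(hybrid$lengths[[cn]]))
  p <- cpp_pileup(hybrid$seqs[[cn]],
                  rep(1L, sum(rows)), aln$pos[rows], aln$cigar[rows],
                  aln$seq[rows], aln$mq[rows], rep(FALSE, sum(rows)),
                  min_mq = 1L)
  p$depth[[1]]
}

depth_run_bounds <- function(depth, at, min_depth) {
  ok <- depth >= min_depth
  at <- max(1L, min(length(ok), as.integer(at)))
  if (!ok[at]) return(c(at, at))
  lo <- at
  while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
  hi <- at
  while (hi < length(ok) && ok[hi + 1L]) hi <- hi + 1L
  c(lo, hi)
}

#' Call inserts from evidence clusters
#'
#' Left- and right-side clusters on one chromosome within
#' \code{max_site_del} are paired into both-sided calls (site deletion =
#' right breakpoint - left breakpoint - 1); remaining single-sided
#' clusters on different chromosomes with complementary construct
#' boundaries and equal orientation are paired into translocation-candidate
#' calls (flanking chromosomes of size 2); the rest become single-sided
#' calls with "at least" size semantics. Zygosity comes from the fraction
#' of junction-supporting versus reference-spanning reads at the
#' breakpoint (heterozygous when the fraction lies in [0.2, 0.8] and a
#' two-sided binomial test against 0.5 has p >= 0.01).
#'
#' @param clusters output of \code{\link{cluster_evidence}}.
#' @param construct the \code{construct_map}.
#' @param aln the sample's \code{tdna_alignments} (zygosity, depth runs).
#' @param hybrid the \code{hybrid_ref}.
#' @param min_split,min_pair minimum evidence: a call needs
#'   \code{n_split >= min_split} or \code{n_pair >= min_pair}.
#' @param max_site_del largest site deletion bridged into one both-sided
#'   call.
#' @param plant_id sample label.
#' @return an \code{insert_calls} data.frame.
#' @export
call_inserts <- function(clusters, construct, aln, hybrid, min_split = 3L,
                         min_pair = 5L, max_site_del = 3000L,
                         plant_id = NULL) {
  cl <- clusters
  cl$used <- logical(nrow(cl))
  calls <- list()
  cdep <- NULL
  host_depth <- {
    hrows <- aln$mapped & aln$ref %in% host_names(hybrid)
    sum(aln$end[hrows] - aln$pos[hrows] + 1, na.rm = TRUE) /
      sum(hybrid$lengths[!hybrid$is_construct])
  }

  seg_str <- function(s, e, st) sprintf("%d-%d:%s", round(s), round(e), st)

  make_call <- function(left, right, cross = FALSE) {
    n_split <- sum(cl$n_split[c(left, right)], na.rm = TRUE)
    n_pair <- sum(cl$n_pair[c(left, right)], na.rm = TRUE)
    L <- if (length(left)) cl[left, ] else NULL
    R <- if (length(right)) cl[right, ] else NULL
    chrom <- if (!is.null(L)) L$chrom else R$chrom
    right_chrom <- if (cross) R$chrom else chrom
    left_bp <- if (!is.null(L)) L$pos else NA_real_
    right_bp <- if (!is.null(R)) R$pos else NA_real_
    site_del <- if (!cross && !is.null(L) && !is.null(R))
      max(0, right_bp - left_bp - 1) else NA_real_
    both <- !is.null(L) && !is.null(R) && !cross
    # segments
    unresolved <- FALSE
    if (both || (cross && !is.null(L) && !is.null(R))) {
      sL <- L$strand; sR <- R$strand
      if (sL == sR) {
        segs <- data.frame(start = min(L$boundary, R$boundary),
                           end = max(L$boundary, R$boundary), strand = sL)
      } else if (!cross) {
        if (is.null(cdep)) cdep <<- construct_depth(aln, hybrid)
        thr <- max(3, 0.25 * host_depth)
        rL <- depth_run_bounds(cdep, L$boundary, thr)
        rR <- depth_run_bounds(cdep, R$boundary, thr)
        eL <- if ((L$side == "left") == (sL == "+")) rL[2] else rL[1]
        eR <- if ((R$side == "left") == (sR == "+")) rR[2] else rR[1]
        segs <- data.frame(start = c(min(L$boundary, eL), min(R$boundary, eR)),
                           end = c(max(L$boundary, eL), max(R$boundary, eR)),
                           strand = c(sL, sR))
      } else {
        segs <- data.frame(start = numeric(), end = numeric(),
                           strand = character())
        unresolved <- TRUE
      }
    } else {
      S <- if (!is.null(L)) L else R
      segs <- data.frame(start = S$cs_min, end = S$cs_max, strand = S$strand)
    }
    at_least <- cross || !both
    min_size <- sum(segs$end - segs$start + 1)
    # zygosity
    precise <- n_split >= 3L
    side_ids <- function(S) {
      if (is.null(S)) return(NULL)
      ids <- if (precise) unlist(S$split_reads) else unlist(S$reads)
      list(chrom = S$chrom, bp = S$pos, ids = unique(ids))
    }
    zy <- zygosity_at(aln, hybrid, side_l = side_ids(L),
                      side_r = side_ids(R), precise = precise,
                      cross = cross)
    cls <- if (unresolved) "unresolved"
           else classify_segments(segs, construct, both_sided = both)
    data.frame(
      plant = plant_id %||% (if (!is.null(L)) L$plant else R$plant),
      chrom = chrom, left_bp = left_bp, right_bp = right_bp,
      right_chrom = right_chrom, site_deletion = site_del,
      segments = paste(seg_str(segs$start, segs$end, segs$strand),
                       collapse = ","),
      n_segments = nrow(segs),
      strand = if (nrow(segs)) segs$strand[1] else NA_character_,
      insert_class = cls,
      zygosity = zy$genotype, junction_frac = zy$frac,
      n_junction = zy$n_junction, n_refspan = zy$n_refspan,
      n_split_reads = n_split, n_broken_pairs = n_pair,
      flanking_chroms = paste(unique(c(chrom, right_chrom)), collapse = ","),
      min_insert_size = min_size, at_least = at_least,
      filler_left = if (!is.null(L)) L$filler else "",
      filler_right = if (!is.null(R)) R$filler else "",
      stringsAsFactors = FALSE)
  }

  # 1. both-sided pairing on one chromosome
  for (ch in unique(cl$chrom)) {
    repeat {
      li <- which(!cl$used & cl$chrom == ch & cl$side == "left")
      ri <- which(!cl$used & cl$chrom == ch & cl$side == "right")
      if (!length(li) || !length(ri)) break
      combo <- expand.grid(l = li, r = ri)
      combo$del <- cl$pos[combo$r] - cl$pos[combo$l] - 1
      combo <- combo[combo$del >= -25 & combo$del <= max_site_del, ,
                     drop = FALSE]
      if (!nrow(combo)) break
      combo <- combo[order(combo$del), ]
      b <- combo[1, ]
      calls[[length(calls) + 1L]] <- make_call(b$l, b$r)
      cl$used[c(b$l, b$r)] <- TRUE
    }
  }
  # 2. cross-chromosome pairing of leftover single-sided clusters
  repeat {
    li <- which(!cl$used & cl$side == "left")
    ri <- which(!cl$used & cl$side == "right")
    cand <- expand.grid(l = li, r = ri)
    if (nrow(cand)) {
      ok <- cl$chrom[cand$l] != cl$chrom[cand$r] &
        cl$strand[cand$l] == cl$strand[cand$r] &
        ifelse(cl$strand[cand$l] == "+",
               cl$boundary[cand$l] < cl$boundary[cand$r],
               cl$boundary[cand$l] > cl$boundary[cand$r])
      cand <- cand[ok, , drop = FALSE]
    }
    if (!nrow(cand)) break
    cand$ev <- cl$n_split[cand$l] + cl$n_pair[cand$l] +
      cl$n_split[cand$r] + cl$n_pair[cand$r]
    b <- cand[which.max(cand$ev), ]
    calls[[length(calls) + 1L]] <- make_call(b$l, b$r, cross = TRUE)
    cl$used[c(b$l, b$r)] <- TRUE
  }
  # 3. leftover single-sided clusters; satellites of an accepted call
  # (within the pair-assignment window of one of its breakpoints) are
  # stray evidence of that junction, not a separate locus
  absorb_window <- 800L
  for (i in which(!cl$used)) {
    near <- FALSE
    for (cc in calls) {
      if (!is.na(cc$left_bp) && cc$chrom == cl$chrom[i] &&
          abs(cc$left_bp - cl$pos[i]) <= absorb_window) near <- TRUE
      if (!is.na(cc$right_bp) && cc$right_chrom == cl$chrom[i] &&
          abs(cc$right_bp - cl$pos[i]) <= absorb_window) near <- TRUE
    }
    if (near) next
    calls[[length(calls) + 1L]] <-
      if (cl$side[i] == "left") make_call(i, integer())
      else make_call(integer(), i)
  }
  out <- if (length(calls)) do.call(rbind, calls) else NULL
  if (is.null(out)) {
    out <- data.frame(plant = character(), chrom = character(),
                      left_bp = numeric(), right_bp = numeric(),
                      right_chrom = character(), site_deletion = numeric(),
                      segments = character(), n_segments = integer(),
                      strand = character(), insert_class = character(),
                      zygosity = character(), junction_frac = numeric(),
                      n_junction = integer(), n_refspan = integer(),
                      n_split_reads = integer(), n_broken_pairs = integer(),
                      flanking_chroms = character(),
                      min_insert_size = numeric(), at_least = logical(),
                      filler_left = character(), filler_right = character())
  } else {
    out <- out[out$n_split_reads >= min_split | out$n_broken_pairs >= min_pair,
               , drop = FALSE]
    o <- order(out$chrom, ifelse(is.na(out$left_bp), out$right_bp,
                                 out$left_bp))
    out <- out[o, , drop = FALSE]
    out$call_id <- sprintf("%s_call%02d", out$plant, seq_len(nrow(out)))
  }
  rownames(out) <- NULL
  class(out) <- c("insert_calls", "data.frame")
  out
}

# Junction-supporting vs reference-spanning reads at the breakpoint(s).
# For translocation-candidate calls (flanks on two chromosomes) the sides
# are evaluated separately and the cleaner junction (larger fraction) is
# genotyped: a copy-type translocation leaves the donor locus fully
# covered, which would dilute a pooled fraction.
zygosity_at <- function(aln, hybrid, side_l, side_r, precise, cross = FALSE,
                        margin = 10L, min_mq = 20L) {
  count_ref <- function(chrom, bp, junction_reads) {
    if (precise) {
      rows <- aln$mapped & aln$ref == chrom & aln$mq >= min_mq &
        aln$pos <= bp - margin & aln$end >= bp + margin &
        aln$clip_left < 12L & aln$clip_right < 12L
      length(unique(aln$read_id[rows & !(aln$read_id %in% junction_reads)]))
    } else {
      m1 <- aln[aln$mate == 1L & (aln$proper %||% FALSE) &
                  aln$ref == chrom, , drop = FALSE]
      if (!nrow(m1)) return(0L)
      lo <- pmin(m1$pos, m1$mate_pos)
      hi <- pmax(m1$end, m1$mate_pos + (m1$end - m1$pos))
      sum(lo <= bp - margin & hi >= bp + margin &
            !(m1$read_id %in% junction_reads))
    }
  }
  sides <- Filter(Negate(is.null), list(side_l, side_r))
  if (cross && length(sides) == 2L) {
    st <- lapply(sides, function(s) {
      nr <- count_ref(s$chrom, s$bp, s$ids)
      nj <- length(s$ids)
      list(n_junc = nj, n_ref = nr,
           frac = if (nj + nr > 0) nj / (nj + nr) else NA_real_)
    })
    # genotype the better-behaved junction: the binomial genotyper's
    # confidence picks the side least distorted by the copied fragment
    gq <- vapply(st, function(x)
      genotype_sv(x$n_junc, round(x$n_ref))$gq, 0)
    best <- st[[which.max(gq)]]
    n_junc <- best$n_junc
    n_ref <- best$n_ref
  } else {
    n_junc <- length(unique(unlist(lapply(sides, `[[`, "ids"))))
    n_ref <- mean(vapply(sides, function(s)
      count_ref(s$chrom, s$bp, s$ids), 0))
  }
  n <- n_junc + n_ref
  if (n == 0)
    return(list(genotype = "unresolved", frac = NA_real_,
                n_junction = 0L, n_refspan = 0L))
  frac <- n_junc / n
  p <- tryCatch(stats::binom.test(round(n_junc), round(n), 0.5)$p.value,
                error = function(e) 1)
  gt <- if (frac >= 0.2 && frac <= 0.8 && p >= 0.01) "heterozygous"
        else if (frac > 0.8) "homozygous"
        else "heterozygous"
  list(genotype = gt, frac = frac, n_junction = n_junc,
       n_refspan = round(n_ref))
}

parse_segments <- function(s) {
  if (is.na(s) || !nchar(s))
    return(data.frame(start = numeric(), end = numeric(),
                      strand = character()))
  parts <- strsplit(s, ",")[[1]]
  data.frame(start = as.numeric(sub("^(\\d+)-(\\d+):([+-])$", "\\1", parts)),
             end = as.numeric(sub("^(\\d+)-(\\d+):([+-])$", "\\2", parts)),
             strand = sub("^(\\d+)-(\\d+):([+-])$", "\\3", parts),
             stringsAsFactors = FALSE)
}

#' Classify an insert call
#'
#' full: segments cover >= 95\% of the LB-RB span in one orientation;
#' inverted_repeat: >= 2 segments with opposing strands; backbone: any
#' segment outside the T-DNA interval; splinter: both-sided call whose
#' total construct length is <= \code{splinter_max} with every segment at
#' least \code{border_margin} from both borders; otherwise partial.
#'
#' @param call one row of an \code{insert_calls} data.frame.
#' @param construct the \code{construct_map}.
#' @param splinter_max,border_margin splinter definition knobs.
#' @return character class.
#' @export
classify_insert <- function(call, construct, splinter_max = 300L,
                            border_margin = 100L) {
  segs <- parse_segments(call$segments)
  both <- !is.na(call$left_bp) && !is.na(call$right_bp) &&
    call$chrom == call$right_chrom
  classify_segments(segs, construct, both_sided = both,
                    splinter_max = splinter_max,
                    border_margin = border_margin)
}

#' Reconstruct the inserted sequence at a both-sided call
#'
#' Builds a consensus of the clipped sequences of the call's split reads:
#' reads spanning the whole insert define the full inserted sequence; the
#' best placement of the construct segment inside the consensus defines
#' the left and right filler DNA. Falls back to per-side fillers when no
#' read spans the insert (large inserts).
#'
#' @param call one row of \code{insert_calls}.
#' @param ev the sample's \code{evidence_set}.
#' @param aln the sample's alignments.
#' @param hybrid the \code{hybrid_ref}.
#' @param min_pair_ident consensus agreement below which the junction is
#'   reported unresolved.
#' @return list(insert_seq, insert_len, filler_left, filler_right,
#'   segment_start, segment_end, segment_strand, n_spanning, resolved).
#' @export
reconstruct_junction <- function(call, ev, aln, hybrid,
                                 min_pair_ident = 0.90) {
  con <- hybrid$construct
  out <- list(insert_seq = NA_character_, insert_len = NA_real_,
              filler_left = call$filler_left, filler_right = call$filler_right,
              segment_start = NA_real_, segment_end = NA_real_,
              segment_strand = NA_character_, n_spanning = 0L,
              resolved = FALSE)
  if (is.na(call$left_bp) || is.na(call$right_bp) ||
      call$chrom != call$right_chrom)
    return(out)
  # every evidence read at this locus, taken in genome-forward frame;
  # reads reaching both flanks span the whole insert
  sp <- ev[ev$kind == "split_read" & ev$chrom == call$chrom &
             ((ev$side == "left" & abs(ev$breakpoint - call$left_bp) <= 5) |
              (ev$side == "right" & abs(ev$breakpoint - call$right_bp) <= 5)) &
             ev$mq > 0, , drop = FALSE]
  if (!nrow(sp)) return(out)
  strand <- names(sort(table(sp$construct_strand), decreasing = TRUE))[1]
  rows <- aln[aln$read_id %in% sp$read_id & aln$mapped, , drop = FALSE]
  if (!nrow(rows)) return(out)
  cn <- construct_name(hybrid)
  wl <- 160L
  lflank <- substr(hybrid$seqs[[call$chrom]],
                   max(1L, call$left_bp - wl + 1L), call$left_bp)
  rflank <- substr(hybrid$seqs[[call$chrom]], call$right_bp,
                   min(call$right_bp + wl - 1L,
                       hybrid$lengths[[call$chrom]]))
  inserts <- character()
  for (i in seq_len(nrow(rows))) {
    gseq <- rows$seq[i]
    if (rows$ref[i] == cn && strand == "-") gseq <- revcomp(gseq)
    else if (rows$ref[i] != cn && rows$ref[i] != call$chrom) next
    lh <- cpp_sw(gseq, lflank)
    rh <- cpp_sw(gseq, rflank)
    # the left-flank hit must reach the flank's last base, the right-flank
    # hit its first base, with the insert in between
    if (lh$score >= 15 && rh$score >= 15 &&
        lh$pos + (lh$qend - lh$qstart) == nchar(lflank) &&
        rh$pos == 1 && rh$qstart > lh$qend + 1) {
      inserts <- c(inserts, substr(gseq, lh$qend + 1L, rh$qstart - 1L))
    }
  }
  if (!length(inserts)) return(out)
  lens <- nchar(inserts)
  modal <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
  grp <- inserts[lens == modal]
  cons <- consensus_string(grp)
  out$n_spanning <- length(inserts)
  if (length(grp) >= 2) {
    agree <- vapply(grp, function(s)
      mean(strsplit(s, "")[[1]] == strsplit(cons, "")[[1]]), 0)
    if (mean(agree) < min_pair_ident) return(out)
  }
  fwd <- cpp_sw(cons, con$seq)
  rev <- cpp_sw(revcomp(cons), con$seq)
  if (max(fwd$score, rev$score) < 12) return(out)
  if (fwd$score >= rev$score) {
    st <- "+"
    qs <- fwd$qstart; qe <- fwd$qend
    ss <- fwd$pos
    se <- fwd$pos + (qe - qs)
  } else {
    st <- "-"
    qs <- nchar(cons) - rev$qend + 1L
    qe <- nchar(cons) - rev$qstart + 1L
    ss <- rev$pos
    se <- rev$pos + (rev$qend - rev$qstart)
  }
  out$insert_seq <- cons
  out$insert_len <- nchar(cons)
  out$filler_left <- substr(cons, 1L, qs - 1L)
  out$filler_right <- substr(cons, qe + 1L, nchar(cons))
  out$segment_start <- ss
  out$segment_end <- se
  out$segment_strand <- st
  out$resolved <- TRUE
  out
}

consensus_string <- function(x) {
  if (length(x) == 1L) return(x)
  m <- do.call(rbind, strsplit(x, ""))
  paste(apply(m, 2, function(col)
    names(sort(table(col), decreasing = TRUE))[1]), collapse = "")
}

#' Render insert calls as a report table
#'
#' One row per call with the reporting columns of the per-plant insert
#' table: positions, flanking sides, construct positions, orientation,
#' estimated size ("at least" for single-sided and translocation-flanked
#' calls), site deletion, evidence counts, class.
#'
#' @param calls an \code{insert_calls} data.frame (possibly several plants).
#' @return data.frame.
#' @export
inserts_table <- function(calls) {
  data.frame(
    plant = calls$plant,
    chrom = ifelse(calls$chrom == calls$right_chrom, calls$chrom,
                   paste(calls$chrom, calls$right_chrom, sep = ",")),
    position_left = calls$left_bp, position_right = calls$right_bp,
    flanking = ifelse(!is.na(calls$left_bp) & !is.na(calls$right_bp),
                      ifelse(calls$chrom == calls$right_chrom, "both sides",
                             "two chromosomes"),
                      ifelse(is.na(calls$right_bp), "left side",
                             "right side")),
    construct_positions = calls$segments,
    orientation = calls$strand,
    estimated_size = ifelse(calls$at_least,
                            paste("at least", calls$min_insert_size),
                            as.character(calls$min_insert_size)),
    site_deletion = calls$site_deletion,
    n_broken_pairs = calls$n_broken_pairs,
    n_split_reads = calls$n_split_reads,
    class = calls$insert_class,
    zygosity = calls$zygosity,
    stringsAsFactors = FALSE)
}
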