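# Genome-wide small-variant detection: stringent per-plant calling
# (coverage > 10x, variant fraction >= 40%, non-unique regions ignored),
# lenient (>= 10%) support maps for shared-variant exclusion across the
# control pool and the other transformants, heterozygosity selection, and
# the insert-proximal rescue scan for variants hidden by construct-linked
# read exclusion.

#' Pileup over host sequences
#'
#' Builds per-position depth and allele counts over the host chromosomes.
#' With \code{exclude_construct_linked} (the default), any read whose mate
#' maps to the construct, or whose clipped end realigns to the construct,
#' is excluded from the counts and tallied separately — this reproduces
#' the "excluding read pairs with T-DNA sequences" step, which also hides
#' true variants sitting next to an insert (recovered later by
#' \code{\link{rescue_insert_proximal}}).
#'
#' @param aln \code{tdna_alignments} of one sample.
#' @param hybrid the \code{hybrid_ref}.
#' @param evidence optional \code{evidence_set} of the sample, used to
#'   identify reads whose clips align to the construct.
#' @param exclude_construct_linked logical.
#' @param min_mq minimum mapping quality for counted reads.
#' @return object of class \code{host_pileup}.
#' @export
pileup_host <- function(aln, hybrid, evidence = NULL,
                        exclude_construct_linked = TRUE, min_mq = 20L) {
  cn <- construct_name(hybrid)
  hn <- host_names(hybrid)
  rows <- which(aln$mapped & aln$ref %in% hn)
  linked_ids <- character()
  if (exclude_construct_linked) {
    linked_ids <- unique(c(
      aln$read_id[aln$mapped & aln$ref == cn],
      aln$read_id[!is.na(aln$mate_ref) & aln$mate_ref == cn],
      if (!is.null(evidence))
        evidence$read_id[!is.na(evidence$construct_start)]))
  }
  excl <- aln$read_id[rows] %in% linked_ids
  p <- cpp_pileup(unlist(hybrid$seqs[hn]),
                  match(aln$ref[rows], hn), aln$pos[rows], aln$cigar[rows],
                  aln$seq[rows], aln$mq[rows], excl, min_mq = min_mq)
  names(p$depth) <- hn
  names(p$counts) <- hn
  names(p$excluded) <- hn
  p$indels$chrom <- hn[p$indels$ref_idx]
  obj <- list(chroms = hn, depth = p$depth, counts = p$counts,
              excluded = p$excluded, indels = p$indels,
              excluded_reads = sum(excl), min_mq = min_mq,
              construct_linked_excluded = exclude_construct_linked)
  class(obj) <- "host_pileup"
  obj
}

#' @export
print.host_pileup <- function(x, ...) {
  cat("host_pileup over", length(x$chroms), "chromosome(s); mean depth",
      round(mean(unlist(x$depth)), 1), "- construct-linked reads",
      if (x$construct_linked_excluded) "excluded" else "included", "\n")
  invisible(x)
}

ref_codes <- function(seq) {
  match(as.integer(charToRaw(seq)), c(65L, 67L, 71L, 84L))  # A C G T
}

#' Stringent variant calling
#'
#' Emits alleles with coverage strictly above \code{min_depth} and variant
#' fraction at least \code{min_vaf}, skipping positions masked as
#' non-unique in the hybrid reference. Indel alleles must be supported by
#' at least \code{min_vaf} of the reads spanning the anchor.
#'
#' @param pu a \code{host_pileup} (construct-linked exclusion on).
#' @param hybrid the \code{hybrid_ref} (reference bases + uniqueness mask).
#' @param min_depth coverage threshold (exclusive).
#' @param min_vaf variant-fraction threshold (inclusive).
#' @return data.frame(chrom, pos, ref, alt, type, depth, alt_count, vaf).
#' @export
call_stringent <- function(pu, hybrid, min_depth = 10L, min_vaf = 0.40) {
  out <- list()
  for (ch in pu$chroms) {
    cnt <- pu$counts[[ch]]
    dep <- pu$depth[[ch]]
    rc <- ref_codes(hybrid$seqs[[ch]])
    mask <- hybrid$mask[[ch]]
    # per-position maximum non-reference allele count
    alt <- matrix(0L, 4L, ncol(cnt))
    for (b in 1:4) {
      v <- cnt[b, ]
      v[rc == b] <- 0L
      alt[b, ] <- v
    }
    alt_cnt <- pmax(alt[1, ], alt[2, ], alt[3, ], alt[4, ])
    cand <- which(dep > min_depth & alt_cnt >= min_vaf * dep &
                    alt_cnt > 0L & !mask)
    if (length(cand)) {
      ab <- apply(alt[, cand, drop = FALSE], 2, which.max)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, pos = cand,
        ref = c("A", "C", "G", "T")[rc[cand]],
        alt = c("A", "C", "G", "T")[ab], type = "SNP",
        depth = dep[cand], alt_count = alt_cnt[cand],
        vaf = alt_cnt[cand] / dep[cand], stringsAsFactors = FALSE)
    }
    idl <- pu$indels[pu$indels$chrom == ch, , drop = FALSE]
    if (nrow(idl)) {
      d <- dep[idl$pos]
      keep <- d > min_depth & idl$count >= min_vaf * d &
        !mask[idl$pos]
      idl <- idl[keep, , drop = FALSE]
      if (nrow(idl))
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, pos = idl$pos, ref = idl$ref, alt = idl$alt,
          type = ifelse(nchar(idl$alt) < nchar(idl$ref), "deletion",
                        "insertion"),
          depth = d[keep], alt_count = idl$count,
          vaf = idl$count / d[keep], stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), type = character(), depth = integer(),
               alt_count = integer(), vaf = numeric())
  res[order(res$chrom, res$pos), , drop = FALSE]
}

variant_key <- function(chrom, pos, ref, alt) {
  paste0(chrom, ":", pos, ":", ref, ">", alt)
}

#' Lenient allele-support map
#'
#' Records every allele present at a fraction of at least \code{min_vaf}
#' in a sample — the cross-check used to reject candidate variants that
#' are present elsewhere below the stringent thresholds (the automated
#' replacement for by-eye re-inspection).
#'
#' @param pu a \code{host_pileup}.
#' @param hybrid the \code{hybrid_ref}.
#' @param min_vaf support threshold (default 0.10).
#' @return character vector of supported allele keys
#'   ("chrom:pos:ref>alt").
#' @export
call_lenient <- function(pu, hybrid, min_vaf = 0.10) {
  keys <- character()
  for (ch in pu$chroms) {
    cnt <- pu$counts[[ch]]
    dep <- pu$depth[[ch]]
    rc <- ref_codes(hybrid$seqs[[ch]])
    for (b in 1:4) {
      v <- cnt[b, ]
      hit <- which(rc != b & dep > 0L & v >= pmax(1L, min_vaf * dep))
      if (length(hit))
        keys <- c(keys, variant_key(ch, hit, c("A", "C", "G", "T")[rc[hit]],
                                    c("A", "C", "G", "T")[b]))
    }
    idl <- pu$indels[pu$indels$chrom == ch, , drop = FALSE]
    if (nrow(idl)) {
      d <- dep[idl$pos]
      keep <- d > 0L & idl$count >= pmax(1L, min_vaf * d)
      if (any(keep))
        keys <- c(keys, variant_key(ch, idl$pos[keep], idl$ref[keep],
                                    idl$alt[keep]))
    }
  }
  unique(keys)
}

#' Filter candidates to transformant-unique heterozygous variants
#'
#' Keeps candidates with no lenient support in the control pool nor in any
#' other transformant, and heterozygous allele balance (fraction in
#' [0.2, 0.8] with a two-sided binomial test against 0.5 not rejected at
#' p < 0.01). Rejected candidates are retained with a status.
#'
#' @param cands stringent candidates of one plant
#'   (\code{\link{call_stringent}}).
#' @param plant_id the plant's label.
#' @param support named list of lenient key vectors; the entry named
#'   \code{control_id} is the control pool, all others are transformants
#'   (the plant's own entry is ignored).
#' @param control_id name of the control entry.
#' @param het_window allele-fraction window for heterozygosity.
#' @param het_p binomial p-value threshold.
#' @return data.frame of \code{VariantCall} rows with \code{status} and
#'   \code{zygosity}; unique calls have \code{status == "unique"}.
#' @export
filter_unique <- function(cands, plant_id, support, control_id = "control",
                          het_window = c(0.2, 0.8), het_p = 0.01) {
  if (!nrow(cands)) {
    cands$status <- character()
    cands$zygosity <- character()
    cands$length_difference <- integer()
    return(cands)
  }
  key <- variant_key(cands$chrom, cands$pos, cands$ref, cands$alt)
  in_control <- key %in% (support[[control_id]] %||% character())
  others <- setdiff(names(support), c(control_id, plant_id))
  in_other <- rep(FALSE, nrow(cands))
  for (o in others) in_other <- in_other | key %in% support[[o]]
  pbin <- mapply(function(x, n)
    stats::binom.test(x, n, 0.5)$p.value, cands$alt_count, cands$depth)
  het <- cands$vaf >= het_window[1] & cands$vaf <= het_window[2] &
    pbin >= het_p
  cands$zygosity <- ifelse(cands$vaf > het_window[2], "homozygous",
                           "heterozygous")
  cands$status <- ifelse(in_control, "control-supported",
                         ifelse(in_other, "shared",
                                ifelse(het, "unique", "non-heterozygous")))
  cands$length_difference <- nchar(cands$alt) - nchar(cands$ref)
  cands
}

#' Rescue variants adjacent to T-DNA inserts
#'
#' Within \code{window} bp of each insert breakpoint, re-piles the host
#' alignments \emph{without} construct-linked exclusion (host-aligned read
#' portions only), applies the stringent thresholds and the uniqueness/
#' heterozygosity filters, and returns new calls with status "rescued".
#'
#' @param calls the plant's \code{insert_calls}.
#' @param aln the plant's alignments.
#' @param hybrid the \code{hybrid_ref}.
#' @param plant_id plant label.
#' @param support lenient support maps (as in \code{\link{filter_unique}}).
#' @param already keys of variants already called in this plant.
#' @param window rescue window around insert breakpoints (bp).
#' @param min_depth,min_vaf stringent thresholds.
#' @return data.frame of rescued VariantCall rows.
#' @export
rescue_insert_proximal <- function(calls, aln, hybrid, plant_id, support,
                                   already = character(), window = 500L,
                                   min_depth = 10L, min_vaf = 0.40) {
  empty <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      type = character(), depth = integer(),
                      alt_count = integer(), vaf = numeric(),
                      status = character(), zygosity = character(),
                      length_difference = integer())
  if (!nrow(calls)) return(empty)
  pu <- rescue_pileup(aln, hybrid)
  cands <- call_stringent(pu, hybrid, min_depth = min_depth,
                          min_vaf = min_vaf)
  if (!nrow(cands)) return(empty)
  near <- rep(FALSE, nrow(cands))
  for (i in seq_len(nrow(calls))) {
    for (side in c("left", "right")) {
      bp <- if (side == "left") calls$left_bp[i] else calls$right_bp[i]
      ch <- if (side == "left") calls$chrom[i] else calls$right_chrom[i]
      if (is.na(bp)) next
      near <- near | (cands$chrom == ch & abs(cands$pos - bp) <= window)
    }
  }
  cands <- cands[near, , drop = FALSE]
  if (!nrow(cands)) return(empty)
  cands <- filter_unique(cands, plant_id, support)
  key <- variant_key(cands$chrom, cands$pos, cands$ref, cands$alt)
  cands <- cands[cands$status == "unique" & !(key %in% already), ,
                 drop = FALSE]
  if (nrow(cands)) cands$status <- "rescued"
  cands
}

# Pileup for the rescue scan: construct-linked exclusion off, and the
# host-aligned clip segments of plasmid-primary junction reads projected
# back onto the host (their bases are host-aligned information that the
# standard pileup loses to soft clips).
rescue_pileup <- function(aln, hybrid, min_clip = 12L) {
  cn <- construct_name(hybrid)
  rows <- aln[aln$mapped & aln$ref == cn &
                (aln$clip_left >= min_clip | aln$clip_right >= min_clip), ,
              drop = FALSE]
  extra <- list()
  for (i in seq_len(nrow(rows))) {
    for (sideclip in c("left", "right")) {
      cl <- if (sideclip == "left") rows$clip_left[i] else rows$clip_right[i]
      if (cl < min_clip) next
      clip <- if (sideclip == "left") substr(rows$seq[i], 1L, cl)
              else substr(rows$seq[i], nchar(rows$seq[i]) - cl + 1L,
                          nchar(rows$seq[i]))
      hits <- cpp_map_hits(hybrid$clip_index, clip)
      if (!nrow(hits)) next
      h <- hits[1, ]
      if (hybrid$is_construct[h$ref_idx]) next
      if (sum(hits$score == h$score) > 1L) next
      st <- cpp_cigar_stats(h$cigar)
      if (st$ref_len < min_clip || h$nm > 0.1 * st$ref_len) next
      extra[[length(extra) + 1L]] <- data.frame(
        read_id = rows$read_id[i], ref = hybrid$names[h$ref_idx],
        pos = h$pos, cigar = h$cigar,
        seq = if (h$strand > 0) clip else as.character(revcomp(clip)),
        mq = rows$mq[i], stringsAsFactors = FALSE)
    }
  }
  hn <- host_names(hybrid)
  host_rows <- aln[aln$mapped & aln$ref %in% hn, , drop = FALSE]
  cols <- c("ref", "pos", "cigar", "seq", "mq")
  allr <- rbind(host_rows[, cols],
                if (length(extra)) do.call(rbind, extra)[, cols])
  p <- cpp_pileup(unlist(hybrid$seqs[hn]), match(allr$ref, hn), allr$pos,
                  allr$cigar, allr$seq, allr$mq,
                  rep(FALSE, nrow(allr)), min_mq = 20L)
  names(p$depth) <- hn
  names(p$counts) <- hn
  names(p$excluded) <- hn
  p$indels$chrom <- hn[p$indels$ref_idx]
  obj <- list(chroms = hn, depth = p$depth, counts = p$counts,
              excluded = p$excluded, indels = p$indels,
              excluded_reads = 0L, min_mq = 20L,
              construct_linked_excluded = FALSE)
  class(obj) <- "host_pileup"
  obj
}

#' Table-style report of small-variant calls
#' @param calls combined VariantCall rows with a \code{plant} column.
#' @return data.frame with per-variant reporting columns.
#' @export
snvs_table <- function(calls) {
  data.frame(plant = calls$plant,
             region = ifelse(nchar(calls$ref) > 1,
                             sprintf("%s: %d-%d", calls$chrom, calls$pos,
                                     calls$pos + nchar(calls$ref) - 1L),
                             sprintf("%s: %d", calls$chrom, calls$pos)),
             type = ifelse(calls$type == "SNP", "SNP",
                           tools::toTitleCase(calls$type)),
             reference = calls$ref, allele = calls$alt,
             length_difference = calls$length_difference,
             zygosity = tools::toTitleCase(calls$zygosity),
             status = calls$status, stringsAsFactors = FALSE)
}

#' Write small-variant calls as VCF 4.2 (one sample column per plant)
#' @param calls combined VariantCall rows with \code{plant} column
#'   (unique/rescued calls).
#' @param plants plant labels (sample column order).
#' @param hybrid hybrid reference (contig header lines).
#' @param path output path.
#' @return path, invisibly.
#' @export
write_snv_vcf <- function(calls, plants, hybrid, path) {
  hn <- host_names(hybrid)
  contigs <- setNames(as.integer(hybrid$lengths[hn]), hn)
  if (nrow(calls)) {
    rec <- calls[order(match(calls$chrom, hn), calls$pos), , drop = FALSE]
    df <- data.frame(chrom = rec$chrom, pos = rec$pos, ref = rec$ref,
                     alt = rec$alt, qual = ".", filter = "PASS",
                     info = sprintf("TYPE=%s;STATUS=%s", rec$type,
                                    rec$status),
                     format = "GT")
    for (p in plants)
      df[[p]] <- ifelse(rec$plant == p, "0/1", "0/0")
  } else df <- data.frame(chrom = character(), pos = numeric(),
                          ref = character(), alt = character())
  write_vcf(df, path, sample_cols = plants, contigs = contigs,
            extra_header = c(
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Variant type\">",
              "##INFO=<ID=STATUS,Number=1,Type=String,Description=\"unique or rescued\">"))
}
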