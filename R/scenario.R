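# Declarative scenario specifications: the events engineered into per-plant
# diploid genomes, and the bundled five-transformant scenario with its
# 12 T-DNA/vector inserts, 10 unique small variants, large heterozygous
# deletions and insert-flanking translocations.

#' T-DNA/vector insert event
#'
#' Describes one heterozygous integration: at \code{site} (the last retained
#' host base), \code{site_deletion} bp of host sequence are removed and
#' replaced by \code{filler_left} + the construct segments (each
#' reverse-complemented for "-" strand) + \code{filler_right}. Multiple
#' segments model inverted repeats and composite inserts.
#'
#' @param chrom host chromosome name.
#' @param site last retained host base before the insert (1-based).
#' @param segments data.frame(start, end, strand) in plasmid coordinates,
#'   start <= end, strand "+" or "-".
#' @param site_deletion bp of host sequence deleted at the site (>= 0).
#' @param filler_left,filler_right filler DNA strings (possibly empty).
#' @param haplotype 1 or 2 (all transgenic events are heterozygous; the
#'   homologous haplotype is left untouched).
#' @param flank_repeat NULL, "left" or "right": marks which flank lies in a
#'   repeated reference block (used by scenario builders to engineer
#'   single-sided calls).
#' @param id event identifier (unique within a plant).
#' @return object of class \code{insert_event}.
#' @export
insert_event <- function(chrom, site, segments, site_deletion = 0L,
                         filler_left = "", filler_right = "", haplotype = 1L,
                         flank_repeat = NULL, id = NULL) {
  stopifnot(site_deletion >= 0, haplotype %in% c(1L, 2L))
  segments <- as.data.frame(segments)
  names(segments) <- c("start", "end", "strand")[seq_along(segments)]
  stopifnot(all(segments$start <= segments$end),
            all(segments$strand %in% c("+", "-")))
  structure(list(chrom = chrom, site = as.integer(site),
                 site_deletion = as.integer(site_deletion),
                 segments = segments, filler_left = filler_left,
                 filler_right = filler_right, haplotype = as.integer(haplotype),
                 flank_repeat = flank_repeat, id = id),
            class = "insert_event")
}

#' Large deletion event
#' @param chrom,start,end deleted interval (1-based, inclusive); end >= start.
#' @param haplotype 1 or 2.
#' @return object of class \code{large_deletion_event}.
#' @export
large_deletion_event <- function(chrom, start, end, haplotype = 1L) {
  stopifnot(end >= start, haplotype %in% c(1L, 2L))
  structure(list(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), haplotype = as.integer(haplotype)),
            class = "large_deletion_event")
}

#' Translocation event: a donor-chromosome fragment placed adjacent to an
#' insert
#'
#' The donor interval is copied (in \code{donor_strand} orientation) next to
#' the referenced insert on the same haplotype: \code{side = "right"} places
#' it between the construct segments and the right host flank.
#'
#' @param donor_chrom,donor_start,donor_end donor interval.
#' @param insert_id id of the recipient \code{insert_event} (same plant).
#' @param side "left" or "right" of the insert.
#' @param donor_strand orientation of the placed fragment.
#' @param haplotype 1 or 2 (must match the recipient insert).
#' @return object of class \code{translocation_event}.
#' @export
translocation_event <- function(donor_chrom, donor_start, donor_end, insert_id,
                                side = "right", donor_strand = "+",
                                haplotype = 1L) {
  stopifnot(donor_end >= donor_start, side %in% c("left", "right"),
            donor_strand %in% c("+", "-"))
  structure(list(donor_chrom = donor_chrom, donor_start = as.integer(donor_start),
                 donor_end = as.integer(donor_end), insert_id = insert_id,
                 side = side, donor_strand = donor_strand,
                 haplotype = as.integer(haplotype)),
            class = "translocation_event")
}

#' Small variant event (SNP or short indel)
#'
#' Alleles are materialized from the parent sequence when the scenario is
#' applied: a SNP substitutes one base (alt drawn if not given); a deletion
#' of \code{len} bp is stored in anchored ref/alt convention.
#'
#' @param chrom,pos chromosome and position (anchor base for indels).
#' @param type "SNP", "deletion" or "insertion".
#' @param len indel length in bp (ignored for SNPs).
#' @param alt optional explicit alternate allele (SNP only).
#' @param haplotype 1 or 2.
#' @param near_insert logical: marks variants engineered adjacent to an
#'   insert (expected to need the insert-proximal rescue scan).
#' @return object of class \code{small_variant_event}.
#' @export
small_variant_event <- function(chrom, pos, type = "SNP", len = 1L, alt = NULL,
                                haplotype = 1L, near_insert = FALSE) {
  stopifnot(type %in% c("SNP", "deletion", "insertion"))
  structure(list(chrom = chrom, pos = as.integer(pos), type = type,
                 len = as.integer(len), alt = alt,
                 haplotype = as.integer(haplotype), near_insert = near_insert),
            class = "small_variant_event")
}

#' Per-plant event specification
#' @param plant_id label (unique within a scenario).
#' @param inserts,deletions,translocations,snvs lists of event objects.
#' @return object of class \code{plant_spec}.
#' @export
plant_spec <- function(plant_id, inserts = list(), deletions = list(),
                       translocations = list(), snvs = list()) {
  ids <- vapply(inserts, function(e) e$id %||% "", "")
  if (anyDuplicated(ids[ids != ""]))
    stop("duplicate insert ids in plant ", plant_id)
  for (tr in translocations)
    if (!(tr$insert_id %in% ids))
      stop("translocation in ", plant_id, " references unknown insert '",
           tr$insert_id, "'")
  structure(list(plant_id = plant_id, inserts = inserts, deletions = deletions,
                 translocations = translocations, snvs = snvs),
            class = "plant_spec")
}

#' Scenario specification
#'
#' @param plants list of \code{plant_spec}.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param n_parent_variants homozygous variants shared via the common
#'   parent; default density-matched to ~45 variants/Mb.
#' @param ref_duplications data.frame(src_chrom, src_start, src_end,
#'   dest_chrom, dest_start) of engineered reference repeats (or NULL).
#' @param gc reference GC fraction.
#' @return object of class \code{scenario_spec}.
#' @export
scenario_spec <- function(plants, chrom_lengths,
                          n_parent_variants = NULL,
                          ref_duplications = NULL, gc = 0.36) {
  ids <- vapply(plants, function(p) p$plant_id, "")
  if (anyDuplicated(ids)) stop("duplicate plant ids")
  if (is.null(n_parent_variants))
    n_parent_variants <- round(45e-6 * sum(chrom_lengths))
  obj <- structure(list(plants = plants, chrom_lengths = chrom_lengths,
                        n_parent_variants = as.integer(n_parent_variants),
                        ref_duplications = ref_duplications, gc = gc),
                   class = "scenario_spec")
  validate_scenario(obj)
  obj
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("scenario_spec:", length(x$plants), "plant(s),",
      length(x$chrom_lengths), "chromosome(s),",
      sum(x$chrom_lengths), "bp haploid\n")
  for (p in x$plants)
    cat(sprintf("  %s: %d insert(s), %d deletion(s), %d translocation(s), %d small variant(s)\n",
                p$plant_id, length(p$inserts), length(p$deletions),
                length(p$translocations), length(p$snvs)))
  invisible(x)
}

# Event footprint on the parent coordinate system: [start, end] replaced.
event_footprint <- function(e) {
  if (inherits(e, "insert_event"))
    c(e$site + 1L, e$site + max(1L, e$site_deletion))
  else if (inherits(e, "large_deletion_event"))
    c(e$start, e$end)
  else
    c(e$pos, e$pos + (if (e$type == "deletion") e$len else 0L))
}

validate_scenario <- function(sc) {
  lens <- sc$chrom_lengths
  for (p in sc$plants) {
    evs <- c(p$inserts, p$deletions, p$snvs)
    key <- data.frame(chrom = vapply(evs, function(e) e$chrom, ""),
                      hap = vapply(evs, function(e) e$haplotype, 0L),
                      lab = vapply(seq_along(evs), function(i) {
                        e <- evs[[i]]
                        cls <- class(e)[1]
                        paste0(cls, "@", e$chrom, ":",
                               if (cls == "insert_event") e$site
                               else if (cls == "large_deletion_event") e$start
                               else e$pos)
                      }, ""))
    fp <- t(vapply(evs, event_footprint, c(0L, 0L)))
    for (i in seq_along(evs)) {
      if (!evs[[i]]$chrom %in% names(lens))
        stop("unknown chromosome ", evs[[i]]$chrom)
      if (fp[i, 2] > lens[[evs[[i]]$chrom]])
        stop("event outside chromosome: ", key$lab[i])
    }
    if (length(evs) > 1) {
      for (i in seq_len(length(evs) - 1L)) for (j in (i + 1L):length(evs)) {
        if (key$chrom[i] == key$chrom[j] && key$hap[i] == key$hap[j] &&
            fp[i, 1] <= fp[j, 2] && fp[j, 1] <= fp[i, 2])
          stop("overlapping events in plant ", p$plant_id, ": ",
               key$lab[i], " and ", key$lab[j])
      }
    }
    for (tr in p$translocations)
      if (tr$donor_end > lens[[tr$donor_chrom]])
        stop("translocation donor outside chromosome in ", p$plant_id)
  }
  invisible(sc)
}

# ---------------------------------------------------------------------------
# The bundled five-transformant scenario.
#
# Event inventory (positions below are given on the published genome and
# divided by `scale`, rank-preserving, with bp-exact local geometry:
# site deletions, fillers, segment coordinates and insert-adjacent variant
# offsets never scale):
#   At1: translocation-flanked partial (bar, '-', >=594), near-complete
#        T-DNA (252-7262, '-', 2,393-bp site deletion), and two
#        single-sided partials (RB-side 463 bp; LB-side 442 bp) whose
#        hidden flanks lie in repeated blocks.
#   At2: translocation-flanked full insert (249-8243), full + partial
#        inverted repeat (34-bp site deletion), and the 50-bp gfp splinter
#        (fillers 1 and 6 bp, 11-bp site deletion, '-' orientation).
#   At3: translocation-flanked insert (250-8030) and a single-sided
#        backbone-only insert (303 bp).
#   At4: inverted repeat including backbone (15-bp site deletion) and a
#        full 8,244-bp LB-RB insert with a 90-bp site deletion flanked by
#        two SNPs 45 bp outside each breakpoint.
#   At5: single LB-side insert with a donor fragment from another
#        chromosome, a 736,487/scale bp heterozygous deletion starting at
#        the insert, and a ~182,859/scale bp deletion at the donor
#        chromosome start.
# Small variants: At1 four deletions (3/4/5/1 bp); At3 one SNP; At4 three
# SNPs (two insert-adjacent) plus 2- and 4-bp deletions; none in At2/At5.
# ---------------------------------------------------------------------------

#' The bundled five-transformant scenario
#'
#' Emits the full event inventory for plants At1..At5 (12 inserts, 10
#' unique heterozygous small variants, one large deletion starting at the
#' At5 insert plus one at the donor chromosome start, and four
#' translocation-flanked inserts) on a genome scaled down by \code{scale}.
#' Coordinates are divided by \code{scale} (rank-preserving) while all
#' within-junction geometry (segment coordinates, fillers, site deletions,
#' insert-adjacent variant offsets) stays bp-exact. At \code{scale = 1}
#' coordinates are the published ones.
#'
#' @param scale coordinate divisor (default 150: five chromosomes of
#'   124-203 kb, ~0.8 Mb haploid).
#' @param min_sep minimum separation enforced between distinct event loci
#'   on one chromosome after scaling (rank-preserving push; an error is
#'   raised if a pushed locus leaves its chromosome).
#' @return a \code{scenario_spec}.
#' @export
transformant_scenario <- function(scale = 150, min_sep = 2000L) {
  true_len <- c(Chr1 = 30427671, Chr2 = 19698289, Chr3 = 23459830,
                Chr4 = 18585056, Chr5 = 26975502)
  lens <- setNames(as.integer(ceiling(true_len / scale)), names(true_len))
  sc <- function(x) as.integer(pmax(1, round(x / scale)))
  donor_len <- max(400L, sc(150000))
  rep_len_ <- 2500L

  # scaled event loci, clamped into [10 kb, len - 10 kb] and pushed apart
  place <- local({
    used <- list()
    function(chrom, true_pos, clampable = TRUE) {
      p <- sc(true_pos)
      if (clampable)
        p <- min(max(p, 10000L), lens[[chrom]] - 10000L)
      prev <- used[[chrom]] %||% integer()
      repeat {
        conf <- prev[abs(prev - p) < min_sep]
        if (!length(conf)) break
        p <- max(conf) + min_sep
      }
      if (p > lens[[chrom]] - 5000L)
        stop("scale too aggressive: locus on ", chrom, " pushed off the end")
      used[[chrom]] <<- c(prev, p)
      p
    }
  })

  seg <- function(s, e, st) data.frame(start = s, end = e, strand = st)

  # At1
  at1_i1 <- insert_event("Chr5", place("Chr5", 25247865),
                         seg(260, 853, "-"), id = "At1_i1")
  at1_d1 <- place("Chr1", 8704528)
  at1_t1 <- translocation_event("Chr1", at1_d1, at1_d1 + donor_len - 1L, "At1_i1")
  at1_i2 <- insert_event("Chr3", place("Chr3", 1735974), seg(252, 7262, "-"),
                         site_deletion = 2393L, id = "At1_i2")
  at1_i3 <- insert_event("Chr5", place("Chr5", 6216781), seg(7782, 8244, "+"),
                         flank_repeat = "left", id = "At1_i3")
  at1_i4 <- insert_event("Chr5", place("Chr5", 6221171), seg(242, 683, "+"),
                         flank_repeat = "right", id = "At1_i4")
  at1_snv <- list(
    small_variant_event("Chr2", place("Chr2", 11595707), "deletion", 3L),
    small_variant_event("Chr2", place("Chr2", 18967242), "deletion", 4L),
    small_variant_event("Chr5", place("Chr5", 23122680), "deletion", 5L),
    small_variant_event("Chr5", place("Chr5", 24549125), "deletion", 1L))
  at1 <- plant_spec("At1", list(at1_i1, at1_i2, at1_i3, at1_i4),
                    translocations = list(at1_t1), snvs = at1_snv)

  # At2
  at2_i1 <- insert_event("Chr1", place("Chr1", 23607701), seg(249, 8243, "+"),
                         id = "At2_i1")
  at2_d1 <- place("Chr2", 12291248)
  at2_t1 <- translocation_event("Chr2", at2_d1, at2_d1 + donor_len - 1L, "At2_i1")
  at2_i2 <- insert_event("Chr2", place("Chr2", 12598505),
                         rbind(seg(313, 7967, "+"), seg(215, 3914, "-")),
                         site_deletion = 34L, id = "At2_i2")
  at2_i3 <- insert_event("Chr2", place("Chr2", 16311370), seg(5841, 5890, "-"),
                         site_deletion = 11L, filler_left = "T",
                         filler_right = "ATCGGA", id = "At2_i3")
  at2 <- plant_spec("At2", list(at2_i1, at2_i2, at2_i3),
                    translocations = list(at2_t1))

  # At3
  at3_i1 <- insert_event("Chr2", place("Chr2", 15559585), seg(250, 8030, "+"),
                         id = "At3_i1")
  at3_d1 <- place("Chr3", 23000811)
  at3_t1 <- translocation_event("Chr3", at3_d1, at3_d1 + donor_len - 1L, "At3_i1")
  at3_i2 <- insert_event("Chr5", place("Chr5", 14491644), seg(12904, 13206, "+"),
                         flank_repeat = "left", id = "At3_i2")
  at3 <- plant_spec("At3", list(at3_i1, at3_i2),
                    translocations = list(at3_t1),
                    snvs = list(small_variant_event("Chr5", place("Chr5", 5539059), "SNP")))

  # At4
  at4_i1 <- insert_event("Chr2", place("Chr2", 272511),
                         rbind(seg(8762, 14119, "+"), seg(8762, 14119, "-")),
                         site_deletion = 15L, id = "At4_i1")
  at4_i2_site <- place("Chr3", 45791)
  at4_i2 <- insert_event("Chr3", at4_i2_site, seg(1, 8244, "+"),
                         site_deletion = 90L, id = "At4_i2")
  at4_snv <- list(
    small_variant_event("Chr2", place("Chr2", 4023449), "SNP"),
    small_variant_event("Chr3", at4_i2_site - 45L, "SNP", near_insert = TRUE),
    small_variant_event("Chr3", at4_i2_site + 90L + 45L, "SNP", near_insert = TRUE),
    small_variant_event("Chr4", place("Chr4", 652049), "deletion", 2L),
    small_variant_event("Chr5", place("Chr5", 18641150), "deletion", 4L))
  at4 <- plant_spec("At4", list(at4_i1, at4_i2), snvs = at4_snv)

  # At5: deletion starts at the insert; a donor fragment sits between the
  # T-DNA and the resuming host sequence.
  at5_site <- sc(29443606)
  at5_del <- sc(30180093) - at5_site
  at5_i1 <- insert_event("Chr1", at5_site, seg(242, 736, "+"),
                         site_deletion = at5_del, id = "At5_i1")
  at5_dend <- sc(276696)
  at5_t1 <- translocation_event("Chr3", max(1L, at5_dend - donor_len + 1L),
                                at5_dend, "At5_i1")
  at5_del2 <- large_deletion_event("Chr3", 1L, sc(182859))
  at5 <- plant_spec("At5", list(at5_i1), deletions = list(at5_del2),
                    translocations = list(at5_t1))

  # reference repeats hiding one flank of the single-sided inserts
  rep_src <- function(ev) {
    if (ev$flank_repeat == "left")
      c(ev$site - rep_len_ + 1L, ev$site)
    else
      c(ev$site + ev$site_deletion + 1L, ev$site + ev$site_deletion + rep_len_)
  }
  singles <- list(at1_i3, at1_i4, at3_i2)
  dest0 <- as.integer(round(lens[["Chr4"]] * seq(0.45, 0.60, by = 0.03)))
  dups <- do.call(rbind, lapply(seq_along(singles), function(i) {
    s <- rep_src(singles[[i]])
    data.frame(src_chrom = singles[[i]]$chrom, src_start = s[1], src_end = s[2],
               dest_chrom = "Chr4", dest_start = dest0[(2 * i - 1):(2 * i)])
  }))

  scenario_spec(list(at1, at2, at3, at4, at5), lens, ref_duplications = dups)
}

#' Full-length large-deletion scenario (single plant)
#'
#' One 1.5-Mb chromosome carrying a heterozygous T-DNA insert at position
#' 600,000 followed by a 736,487-bp deletion, with a donor fragment from a
#' second 300-kb chromosome placed between the T-DNA and the resuming host
#' sequence — the full-scale geometry of the At5 rearrangement.
#'
#' @return a \code{scenario_spec} with one plant ("At5full").
#' @export
at5_deletion_scenario <- function() {
  lens <- c(ChrA = 1500000L, ChrB = 1200000L)
  ins <- insert_event("ChrA", 600000L, data.frame(start = 242, end = 736,
                                                  strand = "+"),
                      site_deletion = 736487L, id = "At5full_i1")
  tr <- translocation_event("ChrB", 220000L, 220999L, "At5full_i1")
  scenario_spec(list(plant_spec("At5full", list(ins),
                                translocations = list(tr))),
                lens)
}
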