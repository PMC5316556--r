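# Realizing scenarios into diploid transgenic genomes and simulating
# paired-end reads with recorded ground truth.

#' Apply a scenario to a diploid parent
#'
#' For each plant, the haplotype carrying an insert event receives, at the
#' site, left flank + filler_left + construct segments (reverse-complemented
#' for "-" strand) + any right-side donor fragment + filler_right + right
#' flank, with \code{site_deletion} bp of parental sequence removed; the
#' homologous haplotype is untouched. Large deletions and anchored small
#' variants are applied the same way. Truth tables for every event class
#' are returned per plant.
#'
#' @param parent result of \code{\link{make_parent}} (or a
#'   \code{diploid_genome}).
#' @param construct a \code{construct_map}.
#' @param scenario a \code{scenario_spec}.
#' @param seed seed used to materialize unspecified alleles (SNP alt bases,
#'   filler content already fixed in the events).
#' @return named list (one entry per plant): \code{genome}
#'   (\code{diploid_genome}) and \code{truth} (list of data.frames:
#'   \code{inserts}, \code{variants}, \code{deletions},
#'   \code{translocations}).
#' @export
apply_scenario <- function(parent, construct, scenario, seed = 1L) {
  g <- if (inherits(parent, "diploid_genome")) parent else parent$genome
  validate_scenario(scenario)
  set.seed(seed + 7L)
  out <- list()
  for (p in scenario$plants) {
    hap <- g$hap
    tr_by_insert <- split(p$translocations,
                          vapply(p$translocations, function(t) t$insert_id, ""))

    # materialize small-variant alleles from the parent haplotype
    vars <- lapply(p$snvs, function(v) {
      s <- hap[[v$haplotype]][[v$chrom]]
      if (v$type == "SNP") {
        rb <- substr(s, v$pos, v$pos)
        alt <- v$alt %||% sample(setdiff(c("A", "C", "G", "T"), rb), 1L)
        data.frame(chrom = v$chrom, pos = v$pos, ref = rb, alt = alt,
                   type = "SNP", haplotype = v$haplotype,
                   near_insert = v$near_insert)
      } else if (v$type == "deletion") {
        ra <- substr(s, v$pos, v$pos + v$len)
        data.frame(chrom = v$chrom, pos = v$pos, ref = ra,
                   alt = substr(ra, 1, 1), type = "deletion",
                   haplotype = v$haplotype, near_insert = v$near_insert)
      } else {
        rb <- substr(s, v$pos, v$pos)
        ins <- paste(sample(c("A", "C", "G", "T"), v$len, TRUE), collapse = "")
        data.frame(chrom = v$chrom, pos = v$pos, ref = rb,
                   alt = paste0(rb, ins), type = "insertion",
                   haplotype = v$haplotype, near_insert = v$near_insert)
      }
    })
    vdf <- if (length(vars)) do.call(rbind, vars) else
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), type = character(), haplotype = integer(),
                 near_insert = logical())

    # build replacement edits (site, del, insert string) per haplotype/chrom
    edits <- list()
    add_edit <- function(hapi, chrom, site, del, ins, kind, id) {
      edits[[length(edits) + 1L]] <<- list(hap = hapi, chrom = chrom,
                                           site = site, del = del, ins = ins,
                                           kind = kind, id = id)
    }
    ins_truth <- list()
    tra_truth <- list()
    for (ev in p$inserts) {
      segs <- ev$segments
      body <- paste(vapply(seq_len(nrow(segs)), function(i)
        construct_segment_seq(construct, segs$start[i], segs$end[i],
                              segs$strand[i]), ""), collapse = "")
      left_extra <- ""
      right_extra <- ""
      for (tr in tr_by_insert[[ev$id %||% ""]] %||% list()) {
        dseq <- substr(g$hap[[tr$haplotype]][[tr$donor_chrom]],
                       tr$donor_start, tr$donor_end)
        if (tr$donor_strand == "-") dseq <- revcomp(dseq)
        if (tr$side == "right") right_extra <- paste0(right_extra, dseq)
        else left_extra <- paste0(dseq, left_extra)
        # junction reported at the donor edge adjacent to the construct
        adj <- if (tr$side == "right") {
          if (tr$donor_strand == "+") tr$donor_start else tr$donor_end
        } else {
          if (tr$donor_strand == "+") tr$donor_end else tr$donor_start
        }
        far <- if (adj == tr$donor_start) tr$donor_end else tr$donor_start
        tra_truth[[length(tra_truth) + 1L]] <- data.frame(
          recipient_chrom = ev$chrom, recipient_pos = ev$site,
          donor_chrom = tr$donor_chrom, donor_pos = adj, donor_far = far,
          recipient_resume = ev$site + ev$site_deletion + 1L,
          insert_id = ev$id %||% NA_character_)
      }
      full <- paste0(left_extra, ev$filler_left, body, ev$filler_right,
                     right_extra)
      add_edit(ev$haplotype, ev$chrom, ev$site, ev$site_deletion, full,
               "insert", ev$id)
      ins_truth[[length(ins_truth) + 1L]] <- data.frame(
        plant = p$plant_id, chrom = ev$chrom, left_bp = ev$site,
        right_bp = ev$site + ev$site_deletion + 1L,
        site_deletion = ev$site_deletion,
        segments = paste(sprintf("%d-%d:%s", segs$start, segs$end,
                                 segs$strand), collapse = ","),
        filler_left = ev$filler_left, filler_right = ev$filler_right,
        filler_left_len = nchar(ev$filler_left),
        filler_right_len = nchar(ev$filler_right),
        segment_len = sum(segs$end - segs$start + 1L),
        inserted_len = nchar(full),
        flank_repeat = ev$flank_repeat %||% "",
        donor_chrom = if (length(tr_by_insert[[ev$id %||% ""]]))
          tr_by_insert[[ev$id]][[1]]$donor_chrom else "",
        id = ev$id %||% NA_character_,
        expected_class = classify_segments(segs, construct,
                                           both_sided = is.null(ev$flank_repeat) &&
                                             !length(tr_by_insert[[ev$id %||% ""]])))
    }
    for (ev in p$deletions)
      add_edit(ev$haplotype, ev$chrom, ev$start - 1L,
               ev$end - ev$start + 1L, "", "large_deletion", NA)
    if (nrow(vdf))
      for (i in seq_len(nrow(vdf)))
        add_edit(vdf$haplotype[i], vdf$chrom[i], vdf$pos[i] - 1L,
                 nchar(vdf$ref[i]), vdf$alt[i], "small_variant", NA)

    # apply right-to-left per haplotype/chromosome
    if (length(edits)) {
      key <- vapply(edits, function(e) paste(e$hap, e$chrom), "")
      for (kk in unique(key)) {
        es <- edits[key == kk]
        es <- es[order(-vapply(es, function(e) e$site, 0))]
        for (e in es)
          hap[[e$hap]][[e$chrom]] <- apply_replacement(
            hap[[e$hap]][[e$chrom]], e$site, e$del, e$ins)
      }
    }

    del_truth <- do.call(rbind, c(
      lapply(p$deletions, function(ev)
        data.frame(plant = p$plant_id, chrom = ev$chrom, start = ev$start,
                   end = ev$end, size = ev$end - ev$start + 1L)),
      lapply(p$inserts[vapply(p$inserts, function(e)
        e$site_deletion >= 300L, TRUE)], function(ev)
          data.frame(plant = p$plant_id, chrom = ev$chrom, start = ev$site,
                     end = ev$site + ev$site_deletion,
                     size = ev$site_deletion))))

    out[[p$plant_id]] <- list(
      genome = diploid_genome(hap[[1]], hap[[2]]),
      truth = list(
        inserts = do.call(rbind, ins_truth) %||% data.frame(),
        variants = vdf,
        deletions = del_truth %||% data.frame(plant = character(),
                                              chrom = character(),
                                              start = integer(),
                                              end = integer(),
                                              size = integer()),
        translocations = do.call(rbind, tra_truth) %||% data.frame()))
  }
  out
}

# expected insert class from true segments (same rules as the caller)
classify_segments <- function(segs, construct, both_sided = TRUE,
                              splinter_max = 300L, border_margin = 100L) {
  tspan <- c(construct$tdna_start, construct$tdna_end)
  tlen <- tspan[2] - tspan[1] + 1L
  for (st in c("+", "-")) {
    s <- segs[segs$strand == st, , drop = FALSE]
    if (nrow(s)) {
      cov <- sum(pmin(s$end, tspan[2]) - pmax(s$start, tspan[1]) + 1L)
      if (cov / tlen >= 0.95) return("full")
    }
  }
  if (length(unique(segs$strand)) > 1L) return("inverted_repeat")
  if (any(segs$start > construct$tdna_end | segs$end < construct$tdna_start))
    return("backbone")
  tot <- sum(segs$end - segs$start + 1L)
  if (both_sided && tot <= splinter_max &&
      all(segs$start - construct$tdna_start >= border_margin) &&
      all(construct$tdna_end - segs$end >= border_margin))
    return("splinter")
  "partial"
}

#' Simulate paired-end reads from a genome
#'
#' Fragments are drawn uniformly from all haplotypes (probability
#' proportional to length), lengths Normal(\code{frag_mean},
#' \code{frag_sd}) truncated below at 2x\code{read_len}; mates are read
#' inward from the fragment ends (FR orientation) with i.i.d. substitution
#' errors at rate \code{err}. Identical seeds give byte-identical output.
#'
#' @param genome a \code{diploid_genome} or (haploid) \code{genome}.
#' @param depth target fold coverage relative to the haploid genome length.
#' @param read_len read length in nt.
#' @param frag_mean,frag_sd fragment-size distribution.
#' @param err per-base substitution error rate (no indel errors).
#' @param seed integer seed (applied via \code{set.seed} when not NULL).
#' @param id_prefix read-name prefix.
#' @return list with \code{r1}, \code{r2} (named character vectors) and
#'   \code{truth}: data.frame(read_id, chrom, haplotype, frag_start,
#'   frag_end, start1, end1, strand1, start2, end2, strand2).
#' @export
simulate_reads <- function(genome, depth, read_len = 101L, frag_mean = 625,
                           frag_sd = 30, err = 0.001, seed = NULL,
                           id_prefix = "rd") {
  if (depth <= 0) stop("depth must be positive")
  if (frag_mean <= 2 * read_len) stop("frag_mean must exceed 2*read_len")
  if (!is.null(seed)) set.seed(seed)
  if (inherits(genome, "diploid_genome")) {
    seqs <- c(unlist(genome$hap[[1]]), unlist(genome$hap[[2]]))
    chroms <- rep(genome$chroms, 2L)
    haps <- rep(1:2, each = length(genome$chroms))
    haploid_len <- sum(vapply(genome$hap[[1]], nchar, 0L))
  } else {
    seqs <- unlist(genome$seq)
    chroms <- names(genome$seq)
    haps <- rep(1L, length(seqs))
    haploid_len <- sum(nchar(seqs))
  }
  n_pairs <- as.integer(round(depth * haploid_len / (2 * read_len)))
  sim <- cpp_sim_frags(unname(seqs), n_pairs, as.integer(read_len),
                       frag_mean, frag_sd, err)
  ids <- paste0(id_prefix, seq_len(n_pairs))
  truth <- data.frame(
    read_id = ids, chrom = chroms[sim$seq_idx], haplotype = haps[sim$seq_idx],
    frag_start = sim$start, frag_end = sim$end,
    start1 = sim$start, end1 = sim$start + read_len - 1L, strand1 = "+",
    start2 = sim$end - read_len + 1L, end2 = sim$end, strand2 = "-",
    stringsAsFactors = FALSE)
  list(r1 = setNames(sim$r1, ids), r2 = setNames(sim$r2, ids), truth = truth)
}

#' Realize a scenario end to end
#'
#' Orchestrates reference + engineered repeats + construct + parent +
#' per-plant genomes, all from one master seed (stage seeds are derived
#' deterministically).
#'
#' @param scenario a \code{scenario_spec}.
#' @param seed master seed.
#' @param construct optional pre-built \code{construct_map}.
#' @return list: \code{reference}, \code{construct}, \code{parent} (with
#'   \code{$variants}), \code{plants} (per-plant genome + truth),
#'   \code{scenario}, \code{seed}.
#' @export
realize_scenario <- function(scenario, seed = 1L, construct = NULL) {
  seeds <- derive_seeds(seed, 4L)
  ref <- make_reference(length(scenario$chrom_lengths),
                        scenario$chrom_lengths, gc = scenario$gc,
                        seed = seeds[1], names = names(scenario$chrom_lengths))
  ref <- apply_duplications(ref, scenario$ref_duplications)
  if (is.null(construct))
    construct <- default_construct(ref, seed = seeds[2])
  fixed <- dehomologize_junctions(ref, construct, scenario)
  ref <- fixed$reference
  construct <- fixed$construct
  parent <- make_parent(ref, scenario$n_parent_variants, seed = seeds[3])
  plants <- apply_scenario(parent, construct, scenario, seed = seeds[4])
  list(reference = ref, construct = construct, parent = parent,
       plants = plants, scenario = scenario, seed = seed)
}

# Remove single-base homology between engineered junction termini and their
# flanking sequence, so every engineered junction has one identifiable
# breakpoint. Two kinds of adjacency are resampled when they collide:
# deleted host bases adjacent to the inserted sequence (first/last deleted
# base vs the insert's terminal bases), and the plasmid base just outside
# each junction-defining segment boundary vs the neighbouring inserted base.
# Positions receive a base differing from every constraint jointly, chosen
# deterministically.
dehomologize_junctions <- function(reference, construct, scenario) {
  ref_forbid <- list()   # chrom -> pos -> forbidden bases
  con_forbid <- list()   # pos -> forbidden bases
  bases <- c("A", "C", "G", "T")
  plasmid <- construct$seq
  add_ref <- function(chrom, pos, base) {
    key <- paste0(chrom, ":", pos)
    ref_forbid[[key]] <<- unique(c(ref_forbid[[key]], base))
  }
  add_con <- function(pos, base) {
    key <- as.character(pos)
    con_forbid[[key]] <<- unique(c(con_forbid[[key]], base))
  }
  seg_base <- function(s, e, st, which) {
    # first/last base of the oriented segment
    if (which == "first") {
      if (st == "+") substr(plasmid, s, s) else
        chartr("ACGT", "TGCA", substr(plasmid, e, e))
    } else {
      if (st == "+") substr(plasmid, e, e) else
        chartr("ACGT", "TGCA", substr(plasmid, s, s))
    }
  }
  for (p in scenario$plants) {
    has_tr <- vapply(p$translocations, function(t) t$insert_id, "")
    for (ev in p$inserts) {
      segs <- ev$segments
      n <- nrow(segs)
      tr_sides <- vapply(p$translocations[has_tr == (ev$id %||% "")],
                         function(t) t$side, "")
      ins_first <- if (nchar(ev$filler_left)) substr(ev$filler_left, 1, 1)
                   else seg_base(segs$start[1], segs$end[1], segs$strand[1],
                                 "first")
      ins_last <- if (nchar(ev$filler_right))
        substr(ev$filler_right, nchar(ev$filler_right),
               nchar(ev$filler_right))
      else seg_base(segs$start[n], segs$end[n], segs$strand[n], "last")
      # host side: deleted bases flanking the junctions
      if (ev$site_deletion >= 1L && !("left" %in% tr_sides))
        add_ref(ev$chrom, ev$site + 1L, ins_first)
      if (ev$site_deletion >= 2L && !("right" %in% tr_sides))
        add_ref(ev$chrom, ev$site + ev$site_deletion, ins_last)
      # construct side: plasmid base just outside each outer boundary
      ref_seq <- reference$seq[[ev$chrom]]
      prev_b <- if (nchar(ev$filler_left))
        substr(ev$filler_left, nchar(ev$filler_left), nchar(ev$filler_left))
      else substr(ref_seq, ev$site, ev$site)
      next_b <- if (nchar(ev$filler_right)) substr(ev$filler_right, 1, 1)
                else substr(ref_seq, ev$site + ev$site_deletion + 1L,
                            ev$site + ev$site_deletion + 1L)
      if (segs$strand[1] == "+") {
        if (segs$start[1] > 1L) add_con(segs$start[1] - 1L, prev_b)
      } else {
        if (segs$end[1] < nchar(plasmid))
          add_con(segs$end[1] + 1L, chartr("ACGT", "TGCA", prev_b))
      }
      if (segs$strand[n] == "+") {
        if (segs$end[n] < nchar(plasmid))
          add_con(segs$end[n] + 1L, next_b)
      } else {
        if (segs$start[n] > 1L)
          add_con(segs$start[n] - 1L, chartr("ACGT", "TGCA", next_b))
      }
    }
  }
  pick <- function(cur, forbidden) {
    ok <- setdiff(bases, unique(c(cur, forbidden)))
    if (!length(ok)) cur else ok[1]
  }
  for (key in names(ref_forbid)) {
    chrom <- sub(":.*", "", key)
    pos <- as.integer(sub(".*:", "", key))
    cur <- substr(reference$seq[[chrom]], pos, pos)
    if (cur %in% ref_forbid[[key]])
      substr(reference$seq[[chrom]], pos, pos) <- pick(cur, ref_forbid[[key]])
  }
  for (key in names(con_forbid)) {
    pos <- as.integer(key)
    cur <- substr(plasmid, pos, pos)
    if (cur %in% con_forbid[[key]])
      substr(plasmid, pos, pos) <- pick(cur, con_forbid[[key]])
  }
  construct$seq <- plasmid
  list(reference = reference, construct = construct)
}

# deterministic per-stage seeds below 2^31
derive_seeds <- function(master, n) {
  as.integer((as.double(master) * 48271 + 1000 * seq_len(n)) %% 2147483587)
}
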