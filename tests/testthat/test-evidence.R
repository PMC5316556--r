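# Junction evidence: broken pairs, split reads, filler residues, and the
# host-derived-promoter exclusion.

test_that("pairs classify into construct, inter-chromosomal and long-range", {
  res <- mini_run()
  ev <- res$samples$P1$evidence
  con <- ev[ev$kind == "broken_pair" & ev$pair_class == "construct" &
              ev$mq > 0, ]
  expect_gt(nrow(con), 20)
  expect_true(all(con$construct_start >= 1 &
                    con$construct_end <= res$realized$construct$length))
  # inter-chromosomal pairs cluster at the one engineered translocation
  ic <- ev[ev$pair_class %in% "inter_chrom" & ev$mq > 0, ]
  expect_gt(nrow(ic), 5)
  on_a <- ic[ic$chrom == "ChrA", ]
  # donor fragment sits right of the m2 insert at ChrA 80,000
  expect_true(all(abs(on_a$breakpoint - 80001) < 800))
  # concordant pairs yield nothing: all evidence reads are non-proper
  aln <- res$samples$P1$aln
  expect_false(any(aln$proper[aln$read_id %in% ev$read_id[ev$kind ==
                                                            "broken_pair"]]))
})

test_that("split extraction recovers segment, strand and filler residue", {
  fx <- small_hybrid()
  hyb <- fx$hybrid
  con <- fx$construct
  # one synthetic split read: 60 nt host, 6 nt residue, 35 nt of the gfp
  # window in reverse orientation
  host <- substr(fx$ref$seq$c1, 35001, 35060)
  rd <- paste0(host, "GGATCC",
               as.character(revcomp(substr(con$seq, 5841, 5875))))
  aln <- map_reads(hyb, setNames(rd, "sp1"))
  ev <- extract_splits(aln, hyb, plant_id = "t")
  hit <- ev[!is.na(ev$construct_start), ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$construct_start, 5841)
  expect_equal(hit$construct_end, 5875)
  expect_equal(hit$construct_strand, "-")
  expect_equal(hit$side, "left")
  expect_equal(hit$breakpoint, 35060)
  expect_equal(hit$filler, "GGATCC")
  expect_true(hit$resolved)
})

test_that("the informative-clip threshold is a real knob", {
  fx <- small_hybrid()
  hyb <- fx$hybrid
  host <- substr(fx$ref$seq$c1, 35001, 35090)   # 90 nt host
  rd <- paste0(host, substr(fx$construct$seq, 6000, 6010))  # 11-nt clip
  aln <- map_reads(hyb, setNames(rd, "sp2"))
  expect_equal(aln$clip_right, 11L)
  ev12 <- extract_splits(aln, hyb)
  expect_equal(nrow(ev12), 0L)
  ev8 <- extract_splits(aln, hyb, min_clip = 8L)
  expect_equal(sum(!is.na(ev8$construct_start)), 1L)
})

test_that("evidence wholly inside a host-derived feature is excluded", {
  # construct with a host_derived feature that is nevertheless unique
  # sequence, so the exclusion rule itself (not mapping ambiguity) acts
  ref <- make_reference(1, 40000, seed = 31, names = "c1")
  set.seed(32)
  pseq <- paste(sample(c("A", "C", "G", "T"), 9000, TRUE), collapse = "")
  feats <- data.frame(name = c("LB", "Phost", "RB"),
                      start = c(1L, 2000L, 7800L),
                      end = c(25L, 4000L, 7824L),
                      host_derived = c(FALSE, TRUE, FALSE))
  con <- construct_map(pseq, 1L, 7824L, feats)
  hyb <- build_hybrid_reference(ref, con)
  mk <- function(cs) paste0(substr(ref$seq$c1, 12001, 12050),
                            substr(pseq, cs, cs + 50))
  r1 <- c(inP = mk(2500), outP = mk(5000))
  r2 <- setNames(as.character(revcomp(
    c(substr(ref$seq$c1, 11500, 11600), substr(ref$seq$c1, 11500, 11600)))),
    names(r1))
  aln <- map_pairs(hyb, r1, r2)
  ev <- collect_evidence(aln, hyb)
  expect_false(any(ev$construct_start >= 2000 & ev$construct_end <= 4000,
                   na.rm = TRUE))
  # junction extension by chance matches can shift the boundary a base
  expect_true(any(!is.na(ev$construct_start) &
                    abs(ev$construct_start - 5000) <= 2))
})

test_that("no evidence record is double counted", {
  res <- mini_run()
  ev <- res$samples$P1$evidence
  expect_false(any(duplicated(ev[, c("read_id", "kind", "chrom",
                                     "breakpoint")])))
})

test_that("a non-transgenic control yields no confident evidence", {
  for (seed in 41:45) {
    fx <- small_hybrid(seed = seed, len = 40000L)
    g <- diploid_genome(fx$ref$seq, fx$ref$seq)
    sim <- simulate_reads(g, depth = 12, seed = seed + 50,
                          id_prefix = "c_")
    aln <- map_pairs(fx$hybrid, sim$r1, sim$r2)
    ev <- collect_evidence(aln, fx$hybrid, plant_id = "ctrl")
    expect_equal(sum(ev$mq > 0), 0L,
                 label = sprintf("confident control evidence (seed %d)",
                                 seed))
  }
})

test_that("every two-flanked insert yields both split and pair evidence", {
  for (s in 1:3) {
    res <- full_run(s)
    for (pl in names(res$samples)) {
      truth <- res$realized$plants[[pl]]$truth$inserts
      both <- truth[truth$flank_repeat == "" & truth$donor_chrom == "" &
                      truth$site_deletion < 3000, , drop = FALSE]
      ev <- res$samples[[pl]]$evidence
      for (i in seq_len(nrow(both))) {
        near <- ev$chrom == both$chrom[i] & ev$mq > 0 &
          abs(ev$breakpoint - both$left_bp[i]) < 800
        expect_gte(sum(ev$kind[near] == "split_read"), 1)
        expect_gte(sum(ev$kind[near] == "broken_pair"), 1)
      }
    }
  }
})

test_that("split breakpoints sit within 2 bp of the engineered junction", {
  res <- full_run(1)
  for (pl in c("At2", "At4")) {
    truth <- res$realized$plants[[pl]]$truth$inserts
    ev <- res$samples[[pl]]$evidence
    sp <- ev[ev$kind == "split_read" & ev$mq > 0 &
               !is.na(ev$construct_start), ]
    for (i in seq_len(nrow(truth))) {
      if (nzchar(truth$flank_repeat[i]) || nzchar(truth$donor_chrom[i]))
        next
      d <- abs(sp$breakpoint[sp$chrom == truth$chrom[i] &
                               sp$side == "left"] - truth$left_bp[i])
      d <- d[d < 50]
      if (length(d)) expect_lte(median(d), 2)
    }
  }
})
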