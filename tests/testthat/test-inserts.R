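# Clustering and insert calling: breakpoints, site deletions, fillers,
# classes, zygosity, and junction reconstruction.

fake_split <- function(chrom, bp, n, side = "left", cs = 100, ce = 200,
                       strand = "+") {
  data.frame(kind = "split_read", pair_class = NA_character_, plant = "P",
             chrom = chrom, breakpoint = bp, side = side,
             construct_start = cs, construct_end = ce,
             construct_strand = strand, target_ref = "pConstruct",
             target_pos = cs, filler = "", resolved = TRUE,
             read_id = paste0("r", seq_len(n), "_", bp[1]),
             mq = 60L, precise = TRUE, stringsAsFactors = FALSE)[seq_len(n), ]
}

test_that("split clusters merge within the window at the median", {
  ev <- rbind(fake_split("c1", c(999, 1000, 1001), 9),
              fake_split("c1", 1000, 3))
  ev$read_id <- paste0("r", seq_len(nrow(ev)))
  class(ev) <- c("evidence_set", "data.frame")
  cl <- cluster_evidence(ev)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$pos, 1000)
  expect_equal(cl$n_split, 12L)
})

test_that("clustering is invariant to evidence order", {
  res <- mini_run()
  ev <- res$samples$P1$evidence
  base <- cluster_evidence(ev)
  key <- function(cl) cl[order(cl$chrom, cl$pos, cl$side),
                         c("chrom", "side", "pos", "n_split", "n_pair")]
  for (i in 1:20) {
    set.seed(i)
    shuf <- ev[sample.int(nrow(ev)), ]
    class(shuf) <- class(ev)
    attr(shuf, "params") <- attr(ev, "params")
    expect_equal(key(cluster_evidence(shuf)), key(base),
                 ignore_attr = TRUE)
  }
})

test_that("nearby but distinct inserts stay separable", {
  res <- full_run(1)
  at1 <- res$inserts[res$inserts$plant == "At1" &
                       res$inserts$chrom == "Chr5" &
                       res$inserts$right_chrom == "Chr5", ]
  # the two single-sided partials sit ~2 kb apart
  expect_equal(nrow(at1), 2L)
})

test_that("insert classification follows the segment rules", {
  con <- default_construct(seed = 51)
  mk <- function(segments, left = 100, right = 200, chrom2 = "c1") {
    data.frame(chrom = "c1", right_chrom = chrom2, left_bp = left,
               right_bp = right, segments = segments)
  }
  expect_equal(classify_insert(mk("1-8244:+"), con), "full")
  expect_equal(classify_insert(mk("5841-5890:-"), con), "splinter")
  expect_equal(classify_insert(mk("8762-14119:+,8762-14119:-"), con),
               "inverted_repeat")
  expect_equal(classify_insert(mk("8762-14119:+"), con), "backbone")
  expect_equal(classify_insert(mk("260-853:-"), con), "partial")
  # single-sided: a border-distant short fragment is not a splinter
  one_sided <- mk("5841-5890:-", right = NA)
  expect_equal(classify_insert(one_sided, con), "partial")
})

test_that("site deletions and fillers are recovered exactly", {
  for (s in 1:3) {
    res <- full_run(s)
    for (pl in names(res$samples)) {
      truth <- res$realized$plants[[pl]]$truth$inserts
      calls <- res$inserts[res$inserts$plant == pl, ]
      both <- truth[truth$flank_repeat == "" & truth$donor_chrom == "" &
                      truth$site_deletion < 3000, , drop = FALSE]
      for (i in seq_len(nrow(both))) {
        hit <- calls[calls$chrom == both$chrom[i] &
                       !is.na(calls$left_bp) &
                       abs(calls$left_bp - both$left_bp[i]) <= 2, ,
                     drop = FALSE]
        expect_equal(nrow(hit), 1L,
                     label = sprintf("%s %s:%d call count", pl,
                                     both$chrom[i], both$left_bp[i]))
        if (hit$n_split_reads >= 6)
          expect_equal(hit$site_deletion, both$site_deletion[i],
                       label = sprintf("%s site deletion", pl))
      }
    }
    spl <- res$inserts[res$inserts$insert_class == "splinter", ]
    expect_equal(nchar(spl$filler_left), 1L)
    expect_equal(nchar(spl$filler_right), 6L)
  }
})

test_that("single-sided calls report lower-bound sizes", {
  res <- full_run(1)
  at1 <- res$inserts[res$inserts$plant == "At1", ]
  single <- at1[is.na(at1$left_bp) | is.na(at1$right_bp), ]
  expect_true(all(single$at_least))
  expect_setequal(single$min_insert_size, c(463, 442))
  expect_true(all(grepl("at least", inserts_table(single)$estimated_size)))
})

test_that("an insert on both haplotypes is called homozygous", {
  lens <- c(ChrA = 80000L)
  segs <- data.frame(start = 6300, end = 7200, strand = "+")
  ins1 <- insert_event("ChrA", 55000L, segs, haplotype = 1L, id = "h1")
  ins2 <- insert_event("ChrA", 55000L, segs, haplotype = 2L, id = "h2")
  sc <- scenario_spec(list(plant_spec("H", list(ins1, ins2))), lens,
                      n_parent_variants = 0L)
  res <- run_scenario_pipeline(sc, seed = 61, quiet = TRUE)
  call <- res$inserts[1, ]
  expect_equal(call$zygosity, "homozygous")
  expect_gt(call$junction_frac, 0.8)
})

test_that("heterozygous events are never called homozygous", {
  for (s in 1:3) {
    res <- full_run(s)
    expect_true(all(res$inserts$zygosity == "heterozygous"))
  }
})

test_that("junction reconstruction matches the engineered haplotype", {
  res <- mini_run()
  calls <- res$inserts
  short <- calls[calls$insert_class %in% c("splinter", "partial") &
                   !is.na(calls$site_deletion) &
                   calls$min_insert_size < 100, ]
  expect_equal(nrow(short), 1L)
  rec <- reconstruct_junction(short[1, ], res$samples$P1$evidence,
                              res$samples$P1$aln, res$hybrid)
  expect_true(rec$resolved)
  truth <- res$realized$plants$P1$truth$inserts[1, ]
  expect_equal(rec$insert_len, truth$inserted_len)
  expect_equal(rec$filler_left, "GG")
  expect_equal(rec$filler_right, "TTT")
  # the consensus equals the haplotype substring at the locus
  hap <- res$realized$plants$P1$genome$hap[[1]]$ChrA
  expect_identical(rec$insert_seq, substr(hap, 40001, 40045))
})

test_that("a no-filler insert reconstructs with empty fillers", {
  lens <- c(ChrA = 60000L)
  segs <- data.frame(start = 6350, end = 6399, strand = "+")
  sc <- scenario_spec(list(plant_spec("N", list(
    insert_event("ChrA", 25000L, segs, site_deletion = 5L, id = "n1")))),
    lens, n_parent_variants = 0L)
  res <- run_scenario_pipeline(sc, seed = 62, quiet = TRUE)
  call <- res$inserts[1, ]
  expect_equal(call$site_deletion, 5)
  expect_equal(call$filler_left, "")
  expect_equal(call$filler_right, "")
  expect_equal(call$insert_len, 50)
})
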