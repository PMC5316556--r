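# The hybrid reference and the seed-and-extend mapper, checked against
# exhaustive local alignment and simulation truth.

test_that("hybrid reference indexes host plus flagged construct", {
  fx <- small_hybrid()
  hyb <- fx$hybrid
  expect_equal(length(hyb$names), 3L)
  expect_identical(hyb$is_construct, c(FALSE, FALSE, TRUE))
  expect_error(build_hybrid_reference(
    genome(list(pConstruct = fx$ref$seq[[1]])), fx$construct), "duplicate")
  expect_error(build_hybrid_reference(fx$ref, fx$construct, k = 22),
               "odd")
})

test_that("k-mer index holds one entry per k-mer start", {
  g <- make_reference(1, 10000, seed = 11)
  con <- default_construct(seed = 12)
  hyb <- build_hybrid_reference(g, con, k = 21)
  expect_equal(tdnascout:::hybrid_index_size(hyb),
               (10000 - 21 + 1) + (con$length - 21 + 1))
})

test_that("uniqueness mask marks exactly the duplicated windows", {
  set.seed(13)
  base <- paste(sample(c("A", "C", "G", "T"), 12000, TRUE), collapse = "")
  block <- substr(base, 3001, 3300)
  seq <- paste0(substr(base, 1, 8000), block, substr(base, 8301, 12000))
  g <- genome(list(c1 = seq))
  con <- default_construct(seed = 14)
  hyb <- build_hybrid_reference(g, con, k = 21, read_len = 101)
  # brute-force oracle: which read-length windows occur more than once
  L <- nchar(seq)
  wins <- substring(seq, 1:(L - 100), 101:L)
  dupw <- which(wins %in% wins[duplicated(wins)])
  expect_gt(length(dupw), 300)
  expect_true(all(hyb$mask$c1[dupw]))
  # positions far from any duplicated window stay unmasked
  far <- setdiff(seq_len(L), unlist(lapply(dupw, function(i) (i - 120):(i + 120))))
  expect_false(any(hyb$mask$c1[far]))
})

test_that("exact reads map to their origin with MQ 60 and no clips", {
  fx <- small_hybrid()
  hyb <- fx$hybrid
  rd <- substr(fx$ref$seq$c1, 20001, 20101)
  a <- map_read(hyb, rd)
  expect_equal(a$ref, "c1")
  expect_equal(a$pos, 20001)
  expect_equal(a$cigar, "101M")
  expect_equal(a$mq, 60L)
  # reverse complement: same locus, flipped strand
  b <- map_read(hyb, as.character(revcomp(rd)))
  expect_equal(b$pos, 20001)
  expect_equal(b$strand, -1L)
})

test_that("junction reads surface as soft clips into the construct", {
  fx <- small_hybrid()
  hyb <- fx$hybrid
  gfp <- substr(fx$construct$seq, 5841, 5901)
  rd <- paste0(substr(fx$ref$seq$c2, 30001, 30040), gfp)
  a <- map_read(hyb, rd)
  expect_true((a$ref == "c2" && a$clip_right == 61) ||
                (a$ref == fx$construct$name && a$clip_left == 40))
})

test_that("error-free simulated reads recover their truth positions", {
  fx <- small_hybrid()
  g <- diploid_genome(fx$ref$seq, fx$ref$seq)
  sim <- simulate_reads(g, depth = 9, err = 0, seed = 15)
  idx <- seq_len(min(10000, length(sim$r1)))
  a <- map_reads(fx$hybrid, sim$r1[idx])
  tru <- sim$truth[idx, ]
  ok <- !fx$hybrid$mask[["c1"]][pmin(tru$start1, 60000)]
  agree <- a$ref == tru$chrom & a$pos == tru$start1 & a$strand == 1L
  expect_equal(mean(agree[ok & tru$chrom == "c1"]), 1)
})

test_that("seeded mapper agrees with the exhaustive aligner oracle", {
  g <- make_reference(1, 30000, seed = 16, names = "c1")
  con <- default_construct(seed = 17)
  hyb <- build_hybrid_reference(g, con)
  gd <- diploid_genome(g$seq, g$seq)
  sim <- simulate_reads(gd, depth = 1.4, err = 0, seed = 18)
  reads <- sim$r1[seq_len(100)]
  m <- map_reads(hyb, reads)
  oracle <- vapply(reads, function(r)
    max(local_align(r, g$seq$c1)$score,
        local_align(as.character(revcomp(r)), g$seq$c1)$score), 0)
  expect_gte(mean(m$score == oracle), 0.99)
})

test_that("pair mating sets the proper flag per the fragment model", {
  res <- mini_run()
  aln <- res$samples$P1$aln
  tr <- res$samples$P1$truth
  # concordant pairs away from all events are proper
  quiet <- tr$chrom == "ChrB" & tr$haplotype == 2 & tr$frag_start > 40000 &
    tr$frag_end < 55000
  expect_true(all(aln$proper[aln$read_id %in% tr$read_id[quiet]]))
  # a mate pair straddling an insert has mates on different references
  ev <- res$samples$P1$evidence
  bp <- ev[ev$kind == "broken_pair" & ev$pair_class == "construct", ]
  expect_gt(nrow(bp), 10)
  rows <- aln[aln$read_id %in% bp$read_id, ]
  expect_false(any(rows$proper))
})

test_that("reads from masked regions never exceed MQ 50", {
  res <- full_run(1)
  hyb <- res$hybrid
  aln <- res$samples$At1$aln
  ok <- aln$mapped & aln$ref %in% tdnascout:::host_names(hyb)
  frac <- rep(0, nrow(aln))
  for (rf in unique(aln$ref[ok])) {
    ii <- which(ok & aln$ref == rf)
    frac[ii] <- tdnascout:::masked_fraction(hyb, rf, aln$pos[ii],
                                            aln$end[ii])
  }
  expect_true(all(aln$mq[ok & frac >= 0.9] <= 50))
})

test_that("SAM round trip is lossless and externally parseable", {
  res <- mini_run()
  aln <- head(res$samples$P1$aln, 1000)
  hyb <- res$hybrid
  f <- tempfile(fileext = ".sam")
  write_sam(aln, hyb, f)
  back <- read_sam(f, hyb)
  for (col in c("read_id", "ref", "pos", "strand", "cigar", "mq", "seq",
                "mapped", "proper", "clip_left", "clip_right", "nm",
                "score"))
    expect_identical(back[[col]], aln[[col]], label = col)
  # clip invariant holds after the round trip
  st <- cpp_cigar_stats(back$cigar[back$mapped])
  expect_true(all(st$q_len == nchar(back$seq[back$mapped])))
  # an independent SAM consumer accepts the file
  if (nzchar(Sys.which("samtools"))) {
    n <- as.integer(system2("samtools", c("view", "-c", f), stdout = TRUE))
    expect_equal(n, nrow(aln))
  }
  unlink(f)
})
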