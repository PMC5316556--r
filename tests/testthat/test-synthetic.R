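# The simulator: references, diploid parents, scenario application and
# read generation, with string-level oracles.

test_that("reference generation is deterministic and length-conserving", {
  a <- make_reference(1, 100000, seed = 1)
  b <- make_reference(1, 100000, seed = 1)
  expect_identical(a$seq, b$seq)
  g <- make_reference(5, rep(200000, 5), seed = 7)
  expect_equal(length(g$seq), 5L)
  expect_equal(sum(vapply(g$seq, nchar, 0L)), 1000000L)
  expect_error(make_reference(1, 500), "10 kb")
})

test_that("two seeds differ at about three quarters of positions", {
  a <- strsplit(make_reference(1, 50000, seed = 1)$seq[[1]], "")[[1]]
  b <- strsplit(make_reference(1, 50000, seed = 2)$seq[[1]], "")[[1]]
  d <- sum(a != b)
  # expectation for i.i.d. bases at equal composition would be 0.75; with
  # GC 0.36 the collision probability is sum(p^2) = 0.2696
  p <- 1 - (2 * 0.32^2 + 2 * 0.18^2)
  bound <- 2.58 * sqrt(50000 * p * (1 - p))
  expect_lt(abs(d - 50000 * p), bound)
})

test_that("parent carries the same homozygous variants on both haplotypes", {
  ref <- make_reference(1, 50000, seed = 3)
  p0 <- make_parent(ref, 0, seed = 1)
  expect_identical(p0$genome$hap[[1]], ref$seq)
  expect_identical(p0$genome$hap[[2]], ref$seq)
  p <- make_parent(ref, 100, seed = 4)
  expect_equal(nrow(p$variants), 100L)
  expect_identical(p$genome$hap[[1]], p$genome$hap[[2]])
  # brute-force diff against the reference recovers every variant position
  a <- strsplit(ref$seq[[1]], "")[[1]]
  b <- strsplit(p$genome$hap[[1]][[1]], "")[[1]]
  expect_identical(which(a != b), as.integer(sort(p$variants$pos)))
})

test_that("scenario application edits exactly the specified haplotype", {
  sc <- mini_scenario(with_translocation = FALSE)
  r <- realize_scenario(sc, seed = 9)
  tr <- r$plants$P1$truth$inserts
  # splinter-style event: 40-bp segment, fillers 2 and 3, 9-bp deletion
  expect_equal(tr$inserted_len[1], 2 + 40 + 3)
  delta <- nchar(r$plants$P1$genome$hap[[1]]$ChrA) -
    nchar(r$parent$genome$hap[[1]]$ChrA)
  expect_equal(delta, (45 - 9) + (8300 - 6400 + 1))
  # inserted sequence is in place: filler + reverse complement of segment
  s <- r$plants$P1$genome$hap[[1]]$ChrA
  expect_identical(substr(s, 40001, 40002), "GG")
  expect_identical(substr(s, 40003, 40042),
                   as.character(revcomp(substr(r$construct$seq, 5841, 5880))))
  # untouched homologous haplotype
  expect_identical(r$plants$P1$genome$hap[[2]]$ChrA,
                   r$parent$genome$hap[[2]]$ChrA)
})

test_that("an empty scenario reproduces the parent byte for byte", {
  lens <- c(ChrA = 30000L)
  sc <- scenario_spec(list(plant_spec("P1")), lens, n_parent_variants = 5L)
  r <- realize_scenario(sc, seed = 2)
  expect_identical(r$plants$P1$genome$hap, r$parent$genome$hap)
})

test_that("overlapping events on one haplotype are rejected by name", {
  lens <- c(ChrA = 30000L)
  segs <- data.frame(start = 100, end = 200, strand = "+")
  e1 <- insert_event("ChrA", 15000, segs, site_deletion = 500, id = "a")
  e2 <- insert_event("ChrA", 15200, segs, id = "b")
  expect_error(scenario_spec(list(plant_spec("P1", list(e1, e2))), lens),
               "overlapping events.*insert_event@ChrA:15000.*insert_event@ChrA:15200")
})

test_that("read simulation respects coverage, errors and determinism", {
  g <- make_reference(1, 500000, seed = 5)
  gd <- diploid_genome(g$seq, g$seq)
  s1 <- simulate_reads(gd, depth = 25, err = 0, seed = 8)
  total <- sum(nchar(s1$r1)) + sum(nchar(s1$r2))
  expect_lt(abs(total - 25 * 500000) / (25 * 500000), 0.05)
  # err = 0: every read is an exact substring of its truth haplotype
  idx <- sample.int(length(s1$r1), 200)
  tru <- s1$truth[idx, ]
  expect_true(all(substring(g$seq[[1]], tru$start1, tru$end1) ==
                    s1$r1[idx]))
  expect_true(all(substring(g$seq[[1]], tru$start2, tru$end2) ==
                    revcomp(s1$r2[idx])))
  s2 <- simulate_reads(gd, depth = 25, err = 0, seed = 8)
  expect_identical(s1, s2)
  # substitution errors at the requested rate
  s3 <- simulate_reads(gd, depth = 5, err = 0.001, seed = 9)
  mm <- sum(mapply(function(r, a, b) {
    sum(utf8ToInt(r) != utf8ToInt(substr(g$seq[[1]], a, b)))
  }, s3$r1, s3$truth$start1, s3$truth$end1))
  n <- sum(nchar(s3$r1))
  bound <- 2.58 * sqrt(n * 0.001 * 0.999)
  expect_lt(abs(mm - n * 0.001), bound)
  expect_error(simulate_reads(gd, depth = 0), "positive")
  expect_error(simulate_reads(gd, depth = 5, frag_mean = 150), "frag_mean")
})

test_that("fragments sample both haplotypes evenly at an event locus", {
  res <- mini_run()
  tr <- res$samples$P1$truth
  ov <- tr[tr$chrom == "ChrA" & tr$frag_start <= 40800 &
             tr$frag_end >= 39200, ]
  expect_gte(nrow(ov), 200)
  p <- binom.test(sum(ov$haplotype == 1), nrow(ov), 0.5)$p.value
  expect_gte(p, 0.01)
})

test_that("the bundled scenario encodes the full event inventory", {
  sc <- transformant_scenario()
  expect_equal(sum(vapply(sc$plants, function(p) length(p$inserts), 0L)), 12L)
  snv_by_plant <- vapply(sc$plants, function(p) length(p$snvs), 0L)
  expect_equal(sum(snv_by_plant), 10L)
  expect_equal(unname(snv_by_plant[c(2, 5)]), c(0L, 0L))   # At2, At5
  tra <- vapply(sc$plants, function(p) length(p$translocations), 0L)
  expect_equal(sum(tra), 4L)
  # full-coordinate arithmetic: the At5 deletion spans the two published
  # breakpoints
  s1 <- transformant_scenario(1)
  at5 <- s1$plants[[5]]$inserts[[1]]
  expect_equal(at5$site_deletion, 30180093 - 29443606)
  expect_equal(at5$site, 29443606)
  # over-aggressive scaling collides and errors
  expect_error(transformant_scenario(5000), "aggressive|outside|chromosome")
})

test_that("scenario realization is reproducible end to end", {
  r1 <- realize_scenario(mini_scenario(), seed = 21)
  r2 <- realize_scenario(mini_scenario(), seed = 21)
  expect_identical(r1$plants$P1$genome, r2$plants$P1$genome)
  expect_identical(r1$construct$seq, r2$construct$seq)
})
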