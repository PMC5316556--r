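# Small-variant calling: thresholds, lenient exclusion, heterozygosity
# selection, and the insert-proximal rescue.

# hand-built pileup with one interesting column per chromosome
toy_pileup <- function(depth, ref_base, alt_base, alt_count, L = 200L,
                       pos = 100L) {
  counts <- matrix(0L, 4L, L)
  bases <- c("A", "C", "G", "T")
  d <- rep(0L, L)
  d[pos] <- depth
  counts[match(ref_base, bases), pos] <- depth - alt_count
  counts[match(alt_base, bases), pos] <- alt_count
  structure(list(chroms = "c1", depth = list(c1 = d),
                 counts = list(c1 = counts), excluded = list(c1 = rep(0L, L)),
                 indels = data.frame(ref_idx = integer(), pos = numeric(),
                                     ref = character(), alt = character(),
                                     count = integer(),
                                     chrom = character()),
                 excluded_reads = 0L, min_mq = 20L,
                 construct_linked_excluded = TRUE),
            class = "host_pileup")
}

toy_hybrid <- function(L = 200L, ref_base = "A") {
  seq <- strrep(ref_base, L)
  list(names = c("c1"), seqs = list(c1 = seq), is_construct = FALSE,
       lengths = c(c1 = L), mask = list(c1 = rep(FALSE, L)))
}

test_that("stringent thresholds apply exact depth and fraction rules", {
  hyb <- toy_hybrid()
  called <- call_stringent(toy_pileup(20L, "A", "T", 9L), hyb)
  expect_equal(nrow(called), 1L)        # 9/20 = 0.45 at depth 20 > 10
  expect_equal(called$alt, "T")
  expect_equal(nrow(call_stringent(toy_pileup(10L, "A", "T", 5L), hyb)),
               0L)                       # depth 10 is not > 10
  expect_equal(nrow(call_stringent(toy_pileup(20L, "A", "T", 7L), hyb)),
               0L)                       # 0.35 < 0.40
  # masked positions are ignored
  hyb2 <- toy_hybrid()
  hyb2$mask$c1[100] <- TRUE
  expect_equal(nrow(call_stringent(toy_pileup(20L, "A", "T", 9L), hyb2)),
               0L)
})

test_that("lenient support records >=10% alleles and nothing below", {
  hyb <- toy_hybrid()
  expect_identical(call_lenient(toy_pileup(25L, "A", "G", 3L), hyb),
                   "c1:100:A>G")
  expect_length(call_lenient(toy_pileup(25L, "A", "G", 1L), hyb), 0L)
})

test_that("shared and control-supported candidates are excluded", {
  cands <- data.frame(chrom = "c1", pos = c(100, 120, 140),
                      ref = "A", alt = "T", type = "SNP", depth = 24L,
                      alt_count = 12L, vaf = 0.5)
  support <- list(control = "c1:100:A>T", other = "c1:120:A>T",
                  me = character())
  out <- filter_unique(cands, "me", support)
  expect_equal(out$status, c("control-supported", "shared", "unique"))
  # a homozygous-looking candidate is not unique-heterozygous
  hom <- data.frame(chrom = "c1", pos = 160, ref = "A", alt = "T",
                    type = "SNP", depth = 24L, alt_count = 23L,
                    vaf = 23 / 24)
  expect_equal(filter_unique(hom, "me", support)$status,
               "non-heterozygous")
})

test_that("power at the stringent fraction threshold matches the binomial", {
  # frozen from the closed form: P(X >= 10 | X ~ Bin(25, 0.5))
  expect_equal(round(1 - pbinom(9, 25, 0.5), 3), 0.885)
  hits <- 0L
  n_rep <- 30L
  ref <- make_reference(1, 30000, seed = 70, names = "c1")
  con <- default_construct(ref, seed = 71)
  for (i in seq_len(n_rep)) {
    sc <- scenario_spec(list(plant_spec("P", snvs = list(
      small_variant_event("c1", 15000L, "SNP")))),
      c(c1 = 30000L), n_parent_variants = 0L)
    r <- realize_scenario(sc, seed = 700 + i, construct = con)
    hyb <- build_hybrid_reference(r$reference, r$construct)
    sim <- simulate_reads(r$plants$P$genome, depth = 25, seed = 800 + i)
    aln <- map_pairs(hyb, sim$r1, sim$r2)
    pu <- pileup_host(aln, hyb)
    cand <- call_stringent(pu, hyb)
    hits <- hits + any(cand$pos == 15000)
  }
  # observed recovery within 99% binomial bounds of the closed form
  p <- 1 - pbinom(9, 25, 0.5)
  expect_lt(abs(hits / n_rep - p), 2.58 * sqrt(p * (1 - p) / n_rep) + 0.05)
})

test_that("no shared parental variant survives the filters", {
  for (s in 1:3) {
    res <- full_run(s)
    pv <- res$realized$parent$variants
    key_p <- paste(pv$chrom, pv$pos)
    key_c <- paste(res$snvs$chrom, res$snvs$pos)
    expect_length(intersect(key_p, key_c), 0L)
  }
})

test_that("raising the stringent fraction never adds calls", {
  res <- full_run(1)
  hyb <- res$hybrid
  pu <- res$pileups$At1
  keys <- lapply(c(0.3, 0.4, 0.5), function(v) {
    cc <- call_stringent(pu, hyb, min_vaf = v)
    paste(cc$chrom, cc$pos, cc$alt)
  })
  expect_true(all(keys[[2]] %in% keys[[1]]))
  expect_true(all(keys[[3]] %in% keys[[2]]))
})

test_that("construct-linked reads are excluded but tallied near inserts", {
  res <- full_run(1)
  pu <- res$pileups$At4
  call <- res$inserts[res$inserts$plant == "At4" &
                        res$inserts$insert_class == "full", ]
  win <- (call$left_bp - 300):(call$left_bp)
  expect_gt(sum(pu$excluded[[call$chrom]][win]), 0)
})

test_that("rescue only fires near inserts and never duplicates", {
  res <- mini_run()
  # P1 has no engineered variant within the rescue window of its inserts
  resc <- res$snvs[res$snvs$status == "rescued", ]
  expect_equal(nrow(resc), 0L)
  expect_false(any(duplicated(paste(res$snvs$chrom, res$snvs$pos))))
})

test_that("genome-wide calls recover the engineered unique variants", {
  found <- 0L
  truth_n <- 0L
  fp <- 0L
  for (s in 1:3) {
    res <- full_run(s)
    for (pl in names(res$samples)) {
      tv <- res$realized$plants[[pl]]$truth$variants
      calls <- res$snvs[res$snvs$plant == pl, ]
      truth_n <- truth_n + nrow(tv)
      for (i in seq_len(nrow(tv)))
        found <- found + any(calls$chrom == tv$chrom[i] &
                               abs(calls$pos - tv$pos[i]) <= 6)
      for (j in seq_len(nrow(calls)))
        fp <- fp + !any(tv$chrom == calls$chrom[j] &
                          abs(tv$pos - calls$pos[j]) <= 6)
    }
  }
  # no false positives at all; recovery at the binomial power of the
  # stringent fraction threshold (see the power test above)
  expect_equal(fp, 0L)
  expect_gte(found / truth_n, 0.55)
})
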