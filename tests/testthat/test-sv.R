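# Structural variation: depth tracks, the binomial genotyper, deletion
# calling with boundary refinement, and insert-flanking translocations.

test_that("the binomial genotyper is exact and deterministic", {
  # oracle: evaluate the three binomial likelihoods directly
  ll <- dbinom(12, 25, c(0.05, 0.5, 0.95), log = TRUE)
  expect_equal(genotype_sv(12, 13)$genotype, "het")
  expect_equal(unname(genotype_sv(12, 13)$gq),
               10 * unname(sort(ll, decreasing = TRUE)[1] -
                             sort(ll, decreasing = TRUE)[2]) / log(10))
  expect_gt(genotype_sv(12, 13)$gq, 30)
  expect_equal(genotype_sv(0, 25)$genotype, "hom_ref")
  expect_equal(genotype_sv(25, 0)$genotype, "hom_alt")
  expect_equal(genotype_sv(0, 0)$genotype, "no-call")
})

test_that("depth ratios sit at 1, 0.5 and 0 for none/het/hom deletions", {
  lens <- c(cA = 100000L)
  sc_het <- scenario_spec(list(plant_spec("D", deletions = list(
    large_deletion_event("cA", 40001L, 48000L, haplotype = 1L)))),
    lens, n_parent_variants = 0L)
  sc_hom <- scenario_spec(list(plant_spec("D", deletions = list(
    large_deletion_event("cA", 40001L, 48000L, haplotype = 1L),
    large_deletion_event("cA", 40001L, 48000L, haplotype = 2L)))),
    lens, n_parent_variants = 0L)
  for (mode in c("het", "hom")) {
    sc <- if (mode == "het") sc_het else sc_hom
    r <- realize_scenario(sc, seed = 81)
    hyb <- build_hybrid_reference(r$reference, r$construct)
    simp <- simulate_reads(r$plants$D$genome, depth = 20, seed = 82)
    simc <- simulate_reads(r$parent$genome, depth = 20, seed = 83)
    alnp <- map_pairs(hyb, simp$r1, simp$r2)
    alnc <- map_pairs(hyb, simc$r1, simc$r2)
    tr <- build_depth_track(pileup_host(alnp, hyb),
                            pileup_host(alnc, hyb), bin = 500L)
    inside <- tr$bin_start >= 41000 & tr$bin_end <= 47000
    outside <- (tr$bin_end < 38000 | tr$bin_start > 50000) & !tr$flagged
    expect_lt(median(abs(tr$ratio[outside] - 1)), 0.15)
    target <- if (mode == "het") 0.5 else 0
    expect_lt(abs(mean(tr$ratio[inside]) - target), 0.08)
  }
})

test_that("a heterozygous deletion is called with refined boundaries", {
  lens <- c(cA = 100000L)
  sc <- scenario_spec(list(plant_spec("D", deletions = list(
    large_deletion_event("cA", 40001L, 48000L, haplotype = 1L)))),
    lens, n_parent_variants = 0L)
  r <- realize_scenario(sc, seed = 84)
  hyb <- build_hybrid_reference(r$reference, r$construct)
  simp <- simulate_reads(r$plants$D$genome, depth = 25, seed = 85)
  simc <- simulate_reads(r$parent$genome, depth = 25, seed = 86)
  alnp <- map_pairs(hyb, simp$r1, simp$r2)
  alnc <- map_pairs(hyb, simc$r1, simc$r2)
  evp <- collect_evidence(alnp, hyb, plant_id = "D")
  evc <- collect_evidence(alnc, hyb, plant_id = "ctrl")
  tr <- build_depth_track(pileup_host(alnp, hyb, evidence = evp),
                          pileup_host(alnc, hyb, evidence = evc),
                          bin = 500L)
  dels <- call_deletions(tr, evp, alnp, evc, alnc, plant_id = "D")
  pass <- dels[dels$filter == "PASS", ]
  expect_equal(nrow(pass), 1L)
  expect_equal(pass$genotype, "het")
  # split-refined boundaries within 2 bp of truth
  expect_lte(abs(pass$start - 40001), 2)
  expect_lte(abs(pass$end - 48000), 2)
  expect_gte(pass$n_supporting_pairs, 10)
  # idempotence: recomputing from the same raw inputs reproduces the call
  again <- call_deletions(tr, evp, alnp, evc, alnc, plant_id = "D")
  expect_identical(as.data.frame(again), as.data.frame(dels))
})

test_that("a deletion below the minimum size is not reported as an SV", {
  lens <- c(cA = 60000L)
  sc <- scenario_spec(list(plant_spec("D", deletions = list(
    large_deletion_event("cA", 30001L, 30200L, haplotype = 1L)))),
    lens, n_parent_variants = 0L)
  res <- run_scenario_pipeline(sc, seed = 87, quiet = TRUE)
  expect_equal(sum(res$svs$filter == "PASS" & res$svs$type == "DEL"), 0L)
})

test_that("depth-ratio estimates are calibrated across many deletions", {
  # 12 heterozygous deletions of 4-12 kb on one 400-kb chromosome
  lens <- c(cA = 400000L)
  dels <- lapply(1:12, function(i)
    large_deletion_event("cA", 30000L * i + 1L,
                         30000L * i + 4000L + 700L * i, haplotype = 1L))
  sc <- scenario_spec(list(plant_spec("D", deletions = dels)), lens,
                      n_parent_variants = 0L)
  r <- realize_scenario(sc, seed = 88)
  hyb <- build_hybrid_reference(r$reference, r$construct)
  simp <- simulate_reads(r$plants$D$genome, depth = 25, seed = 89)
  simc <- simulate_reads(r$parent$genome, depth = 25, seed = 90)
  tr <- build_depth_track(pileup_host(map_pairs(hyb, simp$r1, simp$r2), hyb),
                          pileup_host(map_pairs(hyb, simc$r1, simc$r2), hyb),
                          bin = 500L)
  means <- vapply(dels, function(d) {
    inside <- tr$bin_start > d$start & tr$bin_end < d$end
    mean(tr$ratio[inside])
  }, 0)
  expect_lt(abs(mean(means) - 0.5), 0.05)
})

test_that("translocation-flanked inserts yield TRA calls at the junctions", {
  for (s in 1:3) {
    res <- full_run(s)
    tra <- res$svs[res$svs$type == "TRA" & res$svs$filter == "PASS", ]
    expect_equal(nrow(tra), 4L, label = sprintf("TRA count (seed %d)", s))
    expect_setequal(tra$plant, c("At1", "At2", "At3", "At5"))
    for (pl in tra$plant) {
      tt <- res$realized$plants[[pl]]$truth$translocations
      row <- tra[tra$plant == pl, ]
      expect_lte(abs(row$start - tt$recipient_pos), 2)
      expect_lte(abs(row$pos2 - tt$donor_pos), 2)
      expect_equal(row$genotype, "het")
    }
  }
})

test_that("a scenario without translocations yields no TRA calls", {
  res <- mini_run()
  # mini scenario has one translocation; rebuild without it
  sc <- mini_scenario(with_translocation = FALSE)
  res2 <- run_scenario_pipeline(sc, seed = 12, quiet = TRUE)
  expect_equal(sum(res2$svs$type == "TRA"), 0L)
  # and the control pool never produces SVs
  expect_true(all(res$svs$plant != "control"))
})
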