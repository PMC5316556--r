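# Shared fixtures. Heavy simulations are computed once per session and
# cached; everything is generated in code under fixed seeds.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# full desk-scale five-transformant run (the workhorse fixture)
full_run <- function(seed) {
  memo(paste0("full_", seed),
       run_scenario_pipeline(transformant_scenario(), seed = seed, quiet = TRUE))
}

# full-length At5 deletion chromosome at 10x
at5_full_run <- function(seed = 5) {
  memo(paste0("at5_", seed), {
    r <- realize_scenario(at5_deletion_scenario(), seed = seed)
    hyb <- build_hybrid_reference(r$reference, r$construct)
    p <- tdnascout:::default_params()
    p$depth <- 10
    sim <- simulate_reads(r$plants[[1]]$genome, depth = 10,
                          seed = seed + 100, id_prefix = "p_")
    smp <- tdnascout:::analyze_sample(hyb, sim$r1, sim$r2, "At5full", p,
                                      r$construct)
    simc <- simulate_reads(r$parent$genome, depth = 10, seed = seed + 101,
                           id_prefix = "c_")
    ctl <- tdnascout:::analyze_sample(hyb, simc$r1, simc$r2, "control", p,
                                      r$construct)
    pu <- pileup_host(smp$aln, hyb, evidence = smp$evidence)
    puc <- pileup_host(ctl$aln, hyb, evidence = ctl$evidence)
    track <- build_depth_track(pu, puc, bin = 5000L)
    dels <- call_deletions(track, smp$evidence, smp$aln, ctl$evidence,
                           ctl$aln, insert_calls = smp$inserts,
                           plant_id = "At5full")
    tras <- call_translocations(smp$inserts, smp$evidence, smp$aln,
                                ctl$evidence, ctl$aln,
                                plant_id = "At5full")
    list(realized = r, hybrid = hyb, sample = smp, control = ctl,
         track = track, dels = dels, tras = tras)
  })
}

# a minimal one-plant scenario: one short insert with fillers and site
# deletion, one translocation-flanked insert, two small variants
mini_scenario <- function(with_translocation = TRUE) {
  lens <- c(ChrA = 120000L, ChrB = 80000L)
  segs <- function(s, e, st) data.frame(start = s, end = e, strand = st)
  ins1 <- insert_event("ChrA", 40000L, segs(5841, 5880, "-"),
                       site_deletion = 9L, filler_left = "GG",
                       filler_right = "TTT", id = "m1")
  ins2 <- insert_event("ChrA", 80000L, segs(6400, 8300, "+"), id = "m2")
  trs <- if (with_translocation)
    list(translocation_event("ChrB", 45000L, 46499L, "m2")) else list()
  snvs <- list(small_variant_event("ChrA", 20000L, "SNP"),
               small_variant_event("ChrB", 60000L, "deletion", 3L))
  scenario_spec(list(plant_spec("P1", list(ins1, ins2),
                                translocations = trs, snvs = snvs)),
                lens, n_parent_variants = 10L)
}

mini_run <- function(seed = 11) {
  memo(paste0("mini_", seed),
       run_scenario_pipeline(mini_scenario(), seed = seed, quiet = TRUE))
}

# small random reference + hybrid, no events (negative control material)
small_hybrid <- function(seed = 3, len = 60000L) {
  memo(paste0("hyb_", seed, "_", len), {
    ref <- make_reference(2, c(len, len), seed = seed,
                          names = c("c1", "c2"))
    con <- default_construct(ref, seed = seed + 1)
    list(ref = ref, construct = con,
         hybrid = build_hybrid_reference(ref, con))
  })
}

expect_segments_equal <- function(segments_string, start, end, strand) {
  segs <- tdnascout:::parse_segments(segments_string)
  expect_equal(nrow(segs), length(start))
  expect_equal(segs$start, as.numeric(start))
  expect_equal(segs$end, as.numeric(end))
  expect_equal(segs$strand, strand)
}
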