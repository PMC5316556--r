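# End-to-end orchestration: simulate (or load) -> map -> evidence ->
# insert calls -> small variants -> structural variants -> summary report,
# from one configuration with one master seed.

default_params <- function() {
  list(k = 21L, read_len = 101L, frag_mean = 625, frag_sd = 30,
       err = 0.001, depth = 25, min_mq = 20L, min_clip = 12L,
       min_ident = 0.90, max_filler = 20L, split_window = 5L,
       min_split = 3L, min_pair = 5L, max_site_del = 3000L,
       splinter_max = 300L, border_margin = 100L,
       snv_min_depth = 10L, snv_min_vaf = 0.40, lenient_vaf = 0.10,
       rescue_window = 500L, sv_bin = 500L, min_sv_size = 300L,
       sv_min_pairs = 10L, sv_min_mq = 50, sv_min_gq = 30,
       sv_min_alt_frac = 0.4)
}

#' Pipeline configuration
#'
#' @param reference path to the host reference FASTA (or NULL in scenario
#'   mode).
#' @param plasmid path to the plasmid FASTA.
#' @param tdna_start,tdna_end T-DNA interval on the plasmid.
#' @param plants named list: plant id -> list(r1 =, r2 =) FASTQ paths.
#' @param control list(r1 =, r2 =) FASTQ paths of the control pool.
#' @param outdir output directory.
#' @param seed master seed.
#' @param params named list overriding entries of the default parameter
#'   set (see \code{\link{run_pipeline}}).
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(reference = NULL, plasmid = NULL,
                            tdna_start = 1L, tdna_end = NULL,
                            plants = list(), control = NULL,
                            outdir = NULL, seed = 1L, params = list()) {
  p <- default_params()
  unknown <- setdiff(names(params), names(p))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(params)] <- params
  obj <- list(reference = reference, plasmid = plasmid,
              tdna_start = as.integer(tdna_start),
              tdna_end = if (is.null(tdna_end)) NULL else as.integer(tdna_end),
              plants = plants, control = control, outdir = outdir,
              seed = as.integer(seed), params = p)
  class(obj) <- "pipeline_config"
  obj
}

#' Write / read a pipeline configuration (YAML)
#' @param config a \code{pipeline_config}.
#' @param path file path.
#' @return \code{write_config}: the path; \code{read_config}: the
#'   configuration.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(reference = x$reference, plasmid = x$plasmid,
                  tdna_start = x$tdna_start, tdna_end = x$tdna_end,
                  plants = x$plants, control = x$control,
                  outdir = x$outdir, seed = x$seed,
                  params = x$params %||% list())
}

# One sample through mapping, evidence and insert calling.
analyze_sample <- function(hybrid, r1, r2, plant_id, p, construct) {
  aln <- map_pairs(hybrid, r1, r2, frag_mean = p$frag_mean,
                   frag_sd = p$frag_sd)
  ev <- collect_evidence(aln, hybrid, plant_id = plant_id,
                         min_mq = p$min_mq, frag_mean = p$frag_mean,
                         frag_sd = p$frag_sd, min_clip = p$min_clip,
                         min_ident = p$min_ident, max_filler = p$max_filler)
  cls <- cluster_evidence(ev, split_window = p$split_window,
                          min_mq = p$min_mq)
  calls <- call_inserts(cls, construct, aln, hybrid,
                        min_split = p$min_split, min_pair = p$min_pair,
                        max_site_del = p$max_site_del, plant_id = plant_id)
  calls$insert_len <- rep(NA_real_, nrow(calls))
  calls$insert_seq <- rep(NA_character_, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    rec <- reconstruct_junction(calls[i, ], ev, aln, hybrid)
    if (rec$resolved) {
      calls$filler_left[i] <- rec$filler_left
      calls$filler_right[i] <- rec$filler_right
      calls$insert_len[i] <- rec$insert_len
      calls$insert_seq[i] <- rec$insert_seq
    }
  }
  list(aln = aln, evidence = ev, clusters = cls, inserts = calls)
}

#' Run the pipeline on a simulated scenario
#'
#' Realizes the scenario, simulates reads for every plant and the control
#' pool, and runs the full detection pipeline. Randomness flows from one
#' master seed through derived per-stage seeds; identical seeds reproduce
#' identical results.
#'
#' @param scenario a \code{scenario_spec}.
#' @param seed master seed.
#' @param params named list overriding default parameters.
#' @param outdir optional output directory (reports are written when
#'   given).
#' @param quiet suppress progress messages.
#' @return list: \code{realized}, \code{hybrid}, per-plant \code{samples}
#'   (alignments, evidence, insert calls), \code{snvs}, \code{svs},
#'   \code{summary}.
#' @export
run_scenario_pipeline <- function(scenario, seed = 1L, params = list(),
                                  outdir = NULL, quiet = FALSE) {
  p <- default_params()
  p[names(params)] <- params
  say <- function(...) if (!quiet) message(...)
  realized <- realize_scenario(scenario, seed = seed)
  hybrid <- build_hybrid_reference(realized$reference, realized$construct,
                                   k = p$k, read_len = p$read_len)
  plant_ids <- names(realized$plants)
  rseeds <- derive_seeds(seed + 17L, length(plant_ids) + 1L)
  samples <- list()
  for (i in seq_along(plant_ids)) {
    pid <- plant_ids[i]
    say("simulating and analyzing ", pid)
    sim <- simulate_reads(realized$plants[[pid]]$genome, depth = p$depth,
                          read_len = p$read_len, frag_mean = p$frag_mean,
                          frag_sd = p$frag_sd, err = p$err,
                          seed = rseeds[i], id_prefix = paste0(pid, "_"))
    samples[[pid]] <- analyze_sample(hybrid, sim$r1, sim$r2, pid, p,
                                     realized$construct)
    samples[[pid]]$truth <- sim$truth
  }
  say("simulating and analyzing control pool")
  simc <- simulate_reads(realized$parent$genome, depth = p$depth,
                         read_len = p$read_len, frag_mean = p$frag_mean,
                         frag_sd = p$frag_sd, err = p$err,
                         seed = rseeds[length(rseeds)],
                         id_prefix = "ctrl_")
  control <- analyze_sample(hybrid, simc$r1, simc$r2, "control", p,
                            realized$construct)
  res <- call_all_variants(hybrid, samples, control, p)
  out <- c(list(realized = realized, hybrid = hybrid, samples = samples,
                control = control, seed = seed, params = p), res)
  out$summary <- summarize(out$inserts, out$snvs, out$svs,
                           plant_ids = plant_ids)
  if (!is.null(outdir)) write_reports(out, outdir)
  invisible(out)
}

# SNV + SV stages over analyzed samples (shared by scenario and file mode)
call_all_variants <- function(hybrid, samples, control, p) {
  plant_ids <- names(samples)
  pileups <- lapply(plant_ids, function(pid)
    pileup_host(samples[[pid]]$aln, hybrid,
                evidence = samples[[pid]]$evidence, min_mq = p$min_mq))
  names(pileups) <- plant_ids
  ctrl_pu <- pileup_host(control$aln, hybrid, evidence = control$evidence,
                         min_mq = p$min_mq)
  support <- lapply(pileups, call_lenient, hybrid = hybrid,
                    min_vaf = p$lenient_vaf)
  support$control <- call_lenient(ctrl_pu, hybrid, min_vaf = p$lenient_vaf)
  snvs <- list()
  for (pid in plant_ids) {
    cand <- call_stringent(pileups[[pid]], hybrid,
                           min_depth = p$snv_min_depth,
                           min_vaf = p$snv_min_vaf)
    flt <- filter_unique(cand, pid, support)
    genome_wide <- flt[flt$status == "unique", , drop = FALSE]
    resc <- rescue_insert_proximal(
      samples[[pid]]$inserts, samples[[pid]]$aln, hybrid, pid, support,
      already = variant_key(genome_wide$chrom, genome_wide$pos,
                            genome_wide$ref, genome_wide$alt),
      window = p$rescue_window, min_depth = p$snv_min_depth,
      min_vaf = p$snv_min_vaf)
    keep <- rbind(genome_wide, resc)
    if (nrow(keep)) keep$plant <- pid
    snvs[[pid]] <- keep
  }
  nz <- snvs[vapply(snvs, nrow, 0L) > 0]
  snv_all <- if (length(nz))
    do.call(rbind, c(nz, list(make.row.names = FALSE)))
  else
    data.frame(chrom = character(), pos = numeric(), ref = character(),
               alt = character(), type = character(), depth = integer(),
               alt_count = integer(), vaf = numeric(), status = character(),
               zygosity = character(), length_difference = integer(),
               plant = character(), stringsAsFactors = FALSE)
  svs <- list()
  for (pid in plant_ids) {
    track <- build_depth_track(pileups[[pid]], ctrl_pu, bin = p$sv_bin)
    dels <- call_deletions(track, samples[[pid]]$evidence,
                           samples[[pid]]$aln, control$evidence,
                           control$aln, min_sv_size = p$min_sv_size,
                           min_pairs = p$sv_min_pairs,
                           min_mean_mq = p$sv_min_mq, min_gq = p$sv_min_gq,
                           min_alt_frac = p$sv_min_alt_frac,
                           insert_calls = samples[[pid]]$inserts,
                           plant_id = pid)
    tras <- call_translocations(samples[[pid]]$inserts,
                                samples[[pid]]$evidence,
                                samples[[pid]]$aln, control$evidence,
                                control$aln, min_pairs = p$sv_min_pairs,
                                min_mean_mq = p$sv_min_mq,
                                min_gq = p$sv_min_gq, plant_id = pid)
    svs[[pid]] <- rbind(dels, tras)
  }
  sv_all <- do.call(rbind, c(svs, list(make.row.names = FALSE)))
  class(sv_all) <- c("sv_calls", "data.frame")
  ins_all <- do.call(rbind, c(lapply(samples, `[[`, "inserts"),
                              list(make.row.names = FALSE)))
  class(ins_all) <- c("insert_calls", "data.frame")
  list(inserts = ins_all, snvs = snv_all, svs = sv_all,
       pileups = pileups, control_pileup = ctrl_pu, support = support)
}

#' Summarize call sets into a per-plant and cohort report
#'
#' @param inserts combined \code{insert_calls}.
#' @param snvs combined unique/rescued variant calls.
#' @param svs combined \code{sv_calls}.
#' @param plant_ids cohort plant labels (plants with zero calls count as
#'   zero).
#' @return object of class \code{summary_report}: \code{per_plant}
#'   data.frame, cohort \code{mean_snvs} and \code{sd_snvs}, and
#'   \code{snv_insert_distance} (nearest insert breakpoint per variant).
#' @export
summarize <- function(inserts, snvs, svs, plant_ids = NULL) {
  if (is.null(plant_ids))
    plant_ids <- sort(unique(c(inserts$plant, snvs$plant, svs$plant)))
  if (!length(plant_ids)) stop("empty cohort")
  per <- do.call(rbind, lapply(plant_ids, function(pid) {
    ins <- inserts[inserts$plant == pid, , drop = FALSE]
    sv <- svs[svs$plant == pid & svs$filter == "PASS", , drop = FALSE]
    data.frame(plant = pid, n_inserts = nrow(ins),
               n_full = sum(ins$insert_class == "full"),
               n_partial = sum(ins$insert_class == "partial"),
               n_inverted = sum(ins$insert_class == "inverted_repeat"),
               n_backbone = sum(ins$insert_class == "backbone"),
               n_splinter = sum(ins$insert_class == "splinter"),
               n_unique_snvs = sum(snvs$plant == pid),
               n_del = sum(sv$type == "DEL"), n_tra = sum(sv$type == "TRA"),
               largest_deletion = if (any(sv$type == "DEL"))
                 max(sv$size[sv$type == "DEL"]) else 0,
               stringsAsFactors = FALSE)
  }))
  dist <- rep(NA_real_, nrow(snvs))
  for (i in seq_len(nrow(snvs))) {
    ins <- inserts[inserts$plant == snvs$plant[i], , drop = FALSE]
    d <- Inf
    for (j in seq_len(nrow(ins))) {
      if (!is.na(ins$left_bp[j]) && ins$chrom[j] == snvs$chrom[i])
        d <- min(d, abs(snvs$pos[i] - ins$left_bp[j]))
      if (!is.na(ins$right_bp[j]) && ins$right_chrom[j] == snvs$chrom[i])
        d <- min(d, abs(snvs$pos[i] - ins$right_bp[j]))
    }
    dist[i] <- if (is.finite(d)) d else NA_real_
  }
  obj <- list(per_plant = per,
              mean_snvs = mean(per$n_unique_snvs),
              sd_snvs = if (nrow(per) > 1) sd(per$n_unique_snvs) else
                NA_real_,
              snv_insert_distance = data.frame(
                plant = snvs$plant, chrom = snvs$chrom, pos = snvs$pos,
                nearest_insert = dist))
  class(obj) <- "summary_report"
  obj
}

#' @export
print.summary_report <- function(x, ...) {
  print(x$per_plant, row.names = FALSE)
  cat(sprintf("cohort: %.1f +/- %s small mutations per plant\n",
              x$mean_snvs,
              if (is.na(x$sd_snvs)) "NA" else sprintf("%.1f", x$sd_snvs)))
  invisible(x)
}

write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

# Write the report files of a pipeline result
write_reports <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hybrid <- res$hybrid
  plant_ids <- names(res$samples)
  write_atomic(function(f)
    write.table(inserts_table(res$inserts), f, sep = "\t", quote = FALSE,
                row.names = FALSE), file.path(outdir, "inserts.tsv"))
  ins <- res$inserts
  bed <- data.frame(chrom = ins$chrom,
                    start = ifelse(is.na(ins$left_bp), ins$right_bp,
                                   ins$left_bp),
                    end = ifelse(is.na(ins$right_bp) |
                                   ins$chrom != ins$right_chrom,
                                 ifelse(is.na(ins$left_bp), ins$right_bp,
                                        ins$left_bp) + 1,
                                 ins$right_bp),
                    name = paste(ins$plant, ins$insert_class, sep = "_"))
  write_atomic(function(f) write_bed(bed, f, "name"),
               file.path(outdir, "inserts.bed"))
  snv <- res$snvs
  snv_tab <- if (nrow(snv)) cbind(snvs_table(snv),
                                  nearest_insert =
                                    res$summary$snv_insert_distance$nearest_insert)
             else data.frame()
  write_atomic(function(f)
    write.table(snv_tab, f, sep = "\t", quote = FALSE, row.names = FALSE),
    file.path(outdir, "snvs.tsv"))
  write_atomic(function(f) write_snv_vcf(snv, plant_ids, hybrid, f),
               file.path(outdir, "snvs.vcf"))
  write_atomic(function(f) write_sv_vcf(res$svs, hybrid, f),
               file.path(outdir, "svs.vcf"))
  write_atomic(function(f)
    write.table(res$svs[res$svs$filter != "PASS", , drop = FALSE], f,
                sep = "\t", quote = FALSE, row.names = FALSE),
    file.path(outdir, "svs_rejected.tsv"))
  write_atomic(function(f)
    write.table(res$summary$per_plant, f, sep = "\t", quote = FALSE,
                row.names = FALSE), file.path(outdir, "summary.tsv"))
  par_str <- paste(names(res$params), unlist(res$params), sep = "=",
                   collapse = " ")
  log <- c(sprintf("tdnascout %s", as.character(utils::packageVersion("tdnascout"))),
           sprintf("seed: %d", res$seed),
           sprintf("parameter checksum: %d", sum(utf8ToInt(par_str))),
           sprintf("params: %s", par_str),
           sprintf("plants: %s", paste(plant_ids, collapse = ",")))
  write_atomic(function(f) writeLines(log, f),
               file.path(outdir, "run_log.txt"))
  invisible(outdir)
}

#' Run the pipeline from a configuration of input files
#'
#' Reads the host reference and plasmid FASTA, the per-plant and control
#' FASTQ pairs, and runs mapping, evidence extraction, insert calling,
#' small-variant and structural-variant detection, writing reports to the
#' configured output directory.
#'
#' @param config a \code{pipeline_config} (file paths set).
#' @return the pipeline result list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$params
  for (f in c(config$reference, config$plasmid,
              unlist(config$plants), unlist(config$control)))
    if (!file.exists(f)) stop("input path does not exist: ", f)
  host <- read_fasta(config$reference)
  plasmid <- read_fasta(config$plasmid)
  tdna_end <- config$tdna_end %||% nchar(plasmid$seq[[1]])
  construct <- construct_map(
    plasmid$seq[[1]], config$tdna_start, tdna_end,
    data.frame(name = c("LB", "RB"),
               start = c(config$tdna_start, tdna_end - 24L),
               end = c(config$tdna_start + 24L, tdna_end),
               host_derived = FALSE),
    name = names(plasmid$seq)[1])
  hybrid <- build_hybrid_reference(host, construct, k = p$k,
                                   read_len = p$read_len)
  samples <- list()
  for (pid in names(config$plants)) {
    message("analyzing ", pid)
    r1 <- read_fastq(config$plants[[pid]]$r1)
    r2 <- read_fastq(config$plants[[pid]]$r2)
    samples[[pid]] <- analyze_sample(hybrid, r1, r2, pid, p, construct)
  }
  control <- analyze_sample(hybrid, read_fastq(config$control$r1),
                            read_fastq(config$control$r2), "control", p,
                            construct)
  res <- call_all_variants(hybrid, samples, control, p)
  out <- c(list(hybrid = hybrid, samples = samples, control = control,
                seed = config$seed, params = p), res)
  out$summary <- summarize(out$inserts, out$snvs, out$svs,
                           plant_ids = names(samples))
  if (!is.null(config$outdir)) write_reports(out, config$outdir)
  invisible(out)
}
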