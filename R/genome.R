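# Genome containers and the haplotype-editing machinery used by the
# simulator: references, diploid parents with shared homozygous variants,
# and sequence edits (substitutions, indels, inserts, large deletions).

#' Construct a (haploid) genome object
#'
#' @param seqs named character vector or list of chromosome sequences.
#' @return object of class \code{genome}.
#' @export
genome <- function(seqs) {
  seqs <- as.list(seqs)
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("chromosomes must be named")
  obj <- list(seq = seqs)
  class(obj) <- "genome"
  obj
}

#' Construct a diploid genome from two haplotype sets
#'
#' @param hap1,hap2 named lists of chromosome sequences (same names).
#' @return object of class \code{diploid_genome}.
#' @export
diploid_genome <- function(hap1, hap2) {
  stopifnot(identical(names(hap1), names(hap2)))
  obj <- list(hap = list(as.list(hap1), as.list(hap2)), chroms = names(hap1))
  class(obj) <- "diploid_genome"
  obj
}

#' @export
print.genome <- function(x, ...) {
  cat("genome:", length(x$seq), "sequence(s),",
      sum(vapply(x$seq, nchar, 0L)), "bp\n")
  invisible(x)
}

#' @export
print.diploid_genome <- function(x, ...) {
  cat("diploid genome:", length(x$chroms), "chromosome(s), haploid",
      sum(vapply(x$hap[[1]], nchar, 0L)), "bp\n")
  invisible(x)
}

genome_lengths <- function(g) {
  if (inherits(g, "diploid_genome")) vapply(g$hap[[1]], nchar, 0L)
  else vapply(g$seq, nchar, 0L)
}

#' Generate a random reference genome
#'
#' Bases are drawn i.i.d. with the requested GC content. Calls with the
#' same arguments and seed are byte-identical.
#'
#' @param n_chrom number of chromosomes.
#' @param lengths integer vector of chromosome lengths (recycled to
#'   \code{n_chrom}); each must be at least 10 kb.
#' @param gc GC fraction (default 0.36, Arabidopsis-like).
#' @param seed integer seed.
#' @param names chromosome names (default Chr1..ChrN).
#' @return a \code{genome}.
#' @export
make_reference <- function(n_chrom, lengths, gc = 0.36, seed = 1L,
                           names = paste0("Chr", seq_len(n_chrom))) {
  lengths <- rep_len(as.integer(lengths), n_chrom)
  if (any(lengths < 10000L)) stop("chromosome lengths must be >= 10 kb")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- lapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = p),
          collapse = ""))
  names(seqs) <- names
  genome(seqs)
}

# Copy blocks of reference sequence to other locations (engineered repeats).
# dups: data.frame(src_chrom, src_start, src_end, dest_chrom, dest_start)
apply_duplications <- function(reference, dups) {
  if (is.null(dups) || nrow(dups) == 0L) return(reference)
  for (i in seq_len(nrow(dups))) {
    d <- dups[i, ]
    block <- substr(reference$seq[[d$src_chrom]], d$src_start, d$src_end)
    w <- nchar(block)
    dest_end <- d$dest_start + w - 1L
    if (dest_end > nchar(reference$seq[[d$dest_chrom]]))
      stop("duplication destination outside chromosome")
    substr(reference$seq[[d$dest_chrom]], d$dest_start, dest_end) <- block
  }
  reference
}

#' Derive a diploid parent carrying shared homozygous variants
#'
#' Models a parental stock deviating from the published reference: the same
#' variants are placed on both haplotypes, so they are shared by every
#' descendant plant and by the non-transgenic control pool.
#'
#' @param reference a \code{genome}.
#' @param n_variants number of parental variants.
#' @param seed integer seed.
#' @param min_gap minimum spacing between variants and from chromosome ends.
#' @param indel_frac fraction of parental variants that are 1-3 bp
#'   deletions. The default is 0 (SNPs only), which keeps parent and
#'   reference coordinates identical so that engineered event coordinates
#'   are exact on the reference frame.
#' @return list with \code{genome} (a \code{diploid_genome}) and
#'   \code{variants} (data.frame chrom, pos, ref, alt, type).
#' @export
make_parent <- function(reference, n_variants, seed = 1L, min_gap = 300L,
                        indel_frac = 0) {
  set.seed(seed)
  lens <- genome_lengths(reference)
  vars <- NULL
  if (n_variants > 0) {
    vars <- place_variants(reference, n_variants, min_gap, indel_frac)
    if (is.null(vars)) stop("could not place parental variants without collision")
  }
  hap <- reference$seq
  if (!is.null(vars) && nrow(vars) > 0) {
    for (ch in unique(vars$chrom)) {
      v <- vars[vars$chrom == ch, ]
      hap[[ch]] <- apply_small_variants(hap[[ch]], v)
    }
  }
  g <- diploid_genome(hap, hap)
  list(genome = g,
       variants = vars %||% data.frame(chrom = character(), pos = integer(),
                                       ref = character(), alt = character(),
                                       type = character()))
}

# Sample variant sites avoiding homopolymers (keeps indel placement
# unambiguous) and enforcing spacing.
place_variants <- function(reference, n, min_gap, indel_frac = 0) {
  lens <- genome_lengths(reference)
  chroms <- names(lens)
  out <- list()
  taken <- lapply(chroms, function(x) integer())
  names(taken) <- chroms
  tries <- 0L
  while (length(out) < n && tries < n * 200L) {
    tries <- tries + 1L
    ch <- sample(chroms, 1L, prob = lens)
    pos <- sample.int(lens[[ch]] - 2L * min_gap, 1L) + min_gap
    if (any(abs(taken[[ch]] - pos) < min_gap)) next
    ctx <- substr(reference$seq[[ch]], pos - 1L, pos + 6L)
    bs <- strsplit(ctx, "")[[1]]
    if (any(rle(bs)$lengths >= 3L)) next  # skip homopolymer context
    is_indel <- runif(1) < indel_frac
    rb <- substr(reference$seq[[ch]], pos, pos)
    if (!is_indel) {
      alt <- sample(setdiff(c("A", "C", "G", "T"), rb), 1L)
      out[[length(out) + 1L]] <- data.frame(chrom = ch, pos = pos, ref = rb,
                                            alt = alt, type = "SNP")
    } else {
      l <- sample(1:3, 1L)
      ref_a <- substr(reference$seq[[ch]], pos, pos + l)
      out[[length(out) + 1L]] <- data.frame(chrom = ch, pos = pos, ref = ref_a,
                                            alt = rb, type = "deletion")
    }
    taken[[ch]] <- c(taken[[ch]], pos)
  }
  if (length(out) < n) return(NULL)
  v <- do.call(rbind, out)
  v[order(v$chrom, v$pos), , drop = FALSE]
}

# Apply anchored small variants (VCF-style ref/alt at pos) to one sequence.
# Applied right-to-left so stored coordinates stay valid.
apply_small_variants <- function(seq, vars) {
  if (nrow(vars) == 0L) return(seq)
  vars <- vars[order(-vars$pos), , drop = FALSE]
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, ]
    have <- substr(seq, v$pos, v$pos + nchar(v$ref) - 1L)
    if (have != v$ref)
      stop(sprintf("ref allele mismatch at %s:%d (expected %s, found %s)",
                   v$chrom, v$pos, v$ref, have))
    seq <- paste0(substr(seq, 1L, v$pos - 1L), v$alt,
                  substr(seq, v$pos + nchar(v$ref), nchar(seq)))
  }
  seq
}

# Generic large edit: replace [site+1, site+del] with an insert string.
apply_replacement <- function(seq, site, del, insert) {
  paste0(substr(seq, 1L, site), insert, substr(seq, site + del + 1L, nchar(seq)))
}
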