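# The hybrid reference: host chromosomes plus the plasmid as one additional
# sequence, with a k-mer seed index and a per-position uniqueness mask.

#' Build a hybrid host + construct reference
#'
#' Appends the plasmid to the host chromosomes as an additional sequence
#' (flagged \code{is_construct}), builds the k-mer seed index used by the
#' mapper, a second small-k index used to realign clipped sequences, and a
#' uniqueness mask marking positions whose read-length window occurs more
#' than once in the hybrid reference (such positions can never yield
#' confidently mapped reads and are ignored by the variant caller).
#'
#' @param host a \code{genome} (haploid reference).
#' @param construct a \code{construct_map}.
#' @param k seed k-mer size (odd, 15-31).
#' @param read_len read length used for the uniqueness window.
#' @param clip_k k-mer size of the clip-realignment index.
#' @return object of class \code{hybrid_ref}.
#' @export
build_hybrid_reference <- function(host, construct, k = 21L, read_len = 101L,
                                   clip_k = 11L) {
  if (k %% 2L == 0L || k < 15L || k > 31L) stop("k must be odd and in [15, 31]")
  nm <- c(names(host$seq), construct$name)
  if (anyDuplicated(nm)) stop("duplicate sequence names in hybrid reference")
  seqs <- c(unlist(host$seq, use.names = FALSE), construct$seq)
  obj <- list(names = nm, seqs = setNames(as.list(seqs), nm),
              is_construct = c(rep(FALSE, length(host$seq)), TRUE),
              construct = construct, k = as.integer(k),
              read_len = as.integer(read_len),
              lengths = setNames(nchar(seqs), nm))
  obj$index <- cpp_build_index(seqs, nm, as.integer(k))
  obj$clip_index <- cpp_build_index(seqs, nm, as.integer(clip_k))
  obj$mask <- cpp_kmer_mask(obj$index, as.integer(read_len))
  obj$mask_cum <- lapply(obj$mask, function(m) c(0, cumsum(m)))
  class(obj) <- "hybrid_ref"
  obj
}

#' @export
print.hybrid_ref <- function(x, ...) {
  cat("hybrid_ref:", length(x$names), "sequences (",
      sum(!x$is_construct), "host +", sum(x$is_construct), "construct ),",
      sum(x$lengths), "bp, k =", x$k, "\n")
  cat("masked (non-unique) positions:",
      sum(vapply(x$mask, sum, 0L)), "\n")
  invisible(x)
}

# number of indexed seed positions (structural diagnostics)
hybrid_index_size <- function(hybrid) cpp_index_size(hybrid$index)

host_names <- function(hybrid) hybrid$names[!hybrid$is_construct]

construct_name <- function(hybrid) hybrid$names[hybrid$is_construct][1]

# fraction of masked positions in [start, end] of sequence `ref`
masked_fraction <- function(hybrid, ref, start, end) {
  cs <- hybrid$mask_cum[[ref]]
  n <- length(cs) - 1L
  s <- pmax(pmin(start, n), 1L)
  e <- pmax(pmin(end, n), s)
  (cs[e + 1L] - cs[s]) / (e - s + 1L)
}
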