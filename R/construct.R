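# The transformation construct: plasmid sequence, T-DNA interval, and named
# internal features. This is the frame of reference for all "positions on
# T-DNA vector" in insert calls.

#' Build a construct map
#'
#' A construct map holds the plasmid sequence, the T-DNA interval delimited
#' by the left and right border (LB/RB), and named internal features. A
#' feature flagged \code{host_derived} (typically a promoter amplified from
#' the host genome) is excluded from downstream junction evidence, since
#' reads matching it cannot distinguish plasmid from host origin.
#'
#' @param seq plasmid sequence (single string).
#' @param tdna_start,tdna_end 1-based T-DNA interval (LB at the start, RB at
#'   the end).
#' @param features data.frame with columns \code{name}, \code{start},
#'   \code{end}, \code{host_derived} (logical).
#' @param name sequence name used in the hybrid reference.
#' @return an object of class \code{construct_map}.
#' @export
construct_map <- function(seq, tdna_start, tdna_end, features, name = "pConstruct") {
  stopifnot(is.character(seq), length(seq) == 1L)
  len <- nchar(seq)
  if (tdna_start < 1 || tdna_end > len || tdna_start >= tdna_end)
    stop("T-DNA interval must lie within the plasmid")
  stopifnot(all(c("name", "start", "end", "host_derived") %in% names(features)))
  if (any(features$start < 1 | features$end > len))
    stop("feature outside plasmid")
  obj <- list(name = name, seq = seq, length = len,
              tdna_start = tdna_start, tdna_end = tdna_end,
              features = features)
  class(obj) <- "construct_map"
  obj
}

#' Synthetic binary-vector construct used by the bundled scenario
#'
#' A 14,200-bp plasmid with an 8,379-bp T-DNA (positions 1-8,379; LB at the
#' start, RB at the end), carrying \code{bar}, a host-derived promoter, a
#' \code{gfp} gene placed so that its central 50-bp window (5,841-5,890) is
#' more than 2 kb from either border, and \code{GUS}; positions above 8,379
#' are vector backbone. The promoter segment is copied verbatim from the
#' supplied host reference so that reads from it are genuinely ambiguous
#' between plasmid and host, as for a real host-derived promoter.
#'
#' @param reference optional host \code{genome}; when given, the promoter
#'   feature is a copy of host sequence starting at \code{promoter_src}.
#' @param promoter_src list(chrom, start) giving the host origin of the
#'   promoter copy; defaults to a mid-chromosome window of the second
#'   chromosome (or the first if only one).
#' @param seed integer seed for the random plasmid backbone.
#' @return a \code{construct_map}.
#' @export
default_construct <- function(reference = NULL, promoter_src = NULL, seed = 97L) {
  len <- 14200L
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                      prob = c(.32, .18, .18, .32)), collapse = "")
  feats <- data.frame(
    name = c("LB", "bar", "Ppromoter", "gfp", "GUS", "RB", "backbone"),
    start = c(1L, 260L, 950L, 5500L, 6300L, 8355L, 8380L),
    end = c(25L, 853L, 4650L, 6220L, 8100L, 8379L, 14200L),
    host_derived = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  if (!is.null(reference)) {
    chroms <- names(reference$seq)
    if (is.null(promoter_src)) {
      ch <- chroms[min(2L, length(chroms))]
      promoter_src <- list(chrom = ch,
                           start = max(1L, nchar(reference$seq[[ch]]) %/% 3L))
    }
    p <- feats[feats$name == "Ppromoter", ]
    w <- p$end - p$start + 1L
    src <- substr(reference$seq[[promoter_src$chrom]],
                  promoter_src$start, promoter_src$start + w - 1L)
    if (nchar(src) == w)
      substr(seq, p$start, p$end) <- src
  }
  construct_map(seq, 1L, 8379L, feats)
}

#' @export
print.construct_map <- function(x, ...) {
  cat("construct_map:", x$name, "-", x$length, "bp, T-DNA",
      x$tdna_start, "-", x$tdna_end, "\n")
  cat("features:", paste0(x$features$name, "[", x$features$start, "-",
                          x$features$end, "]",
                          ifelse(x$features$host_derived, "*", "")),
      "\n")
  invisible(x)
}

# Sequence of a construct segment, reverse-complemented for '-' strand.
construct_segment_seq <- function(construct, start, end, strand) {
  s <- substr(construct$seq, start, end)
  if (strand == "-") revcomp(s) else s
}

# host_derived intervals (promoter exclusion)
host_derived_intervals <- function(construct) {
  construct$features[construct$features$host_derived, c("start", "end"), drop = FALSE]
}
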