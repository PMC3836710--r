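# Pluggable nucleosome-affinity / occupancy scoring.
#
# A scorer is any function(genome, pos) vectorised over 0-based positions
# that returns one finite score per position (NA where the score is
# undefined, e.g. a window overrunning a linear contig). The default
# scorer is mean GC content over a centred window, reflecting the higher
# average GC of sequence bound by histones in vivo.

#' GC-content occupancy scorer
#'
#' Returns a scorer function giving, for each 0-based position, the mean
#' GC fraction of the window of width `window` centred there. On linear
#' contigs positions whose window overruns an end score `NA`; on circular
#' contigs the window wraps.
#'
#' @param window Odd window width in nt (typically the nucleosome
#'   footprint: 147 eukaryotic, 85 archaeal).
#' @return A function `(genome, pos) -> numeric`.
#' @examples
#' sc <- gc_scorer(5)
#' sc(genome_seq("AAGGGGGAA"), 0:8)
#' @export
gc_scorer <- function(window = 147) {
  stopifnot(window >= 1, window %% 2 == 1)
  half <- (window - 1L) %/% 2L
  force(half)
  function(genome, pos) {
    window_gc_count(genome, pos, half) / window
  }
}

# integer count of S (G/C) bases in the window [pos - half, pos + half];
# NA where the window does not fit (linear contigs)
window_gc_count <- function(genome, pos, half) {
  b <- base_ints(genome)
  n <- length(b)
  out <- rep(NA_real_, length(pos))
  if (n == 0L) return(out)
  s <- as.integer(strong_mask(b))
  if (isTRUE(genome$circular)) {
    if (2L * half + 1L > n) return(out)
    s2 <- c(s, s[seq_len(min(n, 2L * half))])
    cs <- c(0L, cumsum(s2))
    lo <- ((pos - half) %% n)            # 0-based start, wrapped
    out <- as.numeric(cs[lo + 2L * half + 2L] - cs[lo + 1L])
  } else {
    ok <- pos - half >= 0L & pos + half <= n - 1L
    cs <- c(0L, cumsum(s))
    out[ok] <- as.numeric(cs[pos[ok] + half + 2L] - cs[pos[ok] - half + 1L])
  }
  out
}

#' Score nucleosome affinity at a single position
#'
#' Convenience wrapper around a scorer for one position; the default GC
#' scorer gives the mean GC fraction of the footprint window centred at
#' `pos`.
#'
#' @param genome A [genome_seq()].
#' @param pos 0-based position.
#' @param footprint Odd window width in nt.
#' @param scorer Optional scorer function; defaults to
#'   `gc_scorer(footprint)`.
#' @return Numeric score.
#' @export
affinity_score <- function(genome, pos, footprint = 147, scorer = NULL) {
  if (is.null(scorer)) scorer <- gc_scorer(footprint)
  sc <- scorer(genome, pos)
  if (anyNA(sc) && !isTRUE(genome$circular))
    stop("affinity_score: scoring window out of bounds on a linear contig")
  sc
}

#' Scorer backed by a precomputed per-nucleotide score track
#'
#' Adapter for externally computed occupancy models: scores are read from
#' a table of (pos, score) rather than computed from sequence.
#'
#' @param track Data frame with columns `pos` (0-based) and `score`.
#' @return A scorer function `(genome, pos) -> numeric` (NA for positions
#'   absent from the track).
#' @export
track_scorer <- function(track) {
  stopifnot(is.data.frame(track), all(c("pos", "score") %in% names(track)))
  lut <- track$score[order(track$pos)]
  keys <- sort(track$pos)
  function(genome, pos) {
    idx <- match(pos, keys)
    lut[idx]
  }
}

#' Per-nucleotide occupancy track over a region
#'
#' Evaluates a scorer at every position of `[start, end]` (0-based,
#' inclusive). Positions whose scoring window would overrun the contig are
#' reported with score `NA`.
#'
#' @param genome A [genome_seq()].
#' @param start,end 0-based inclusive region bounds; default the whole
#'   contig.
#' @param scorer A scorer function; default `gc_scorer(window)`.
#' @param window Window width for the default scorer.
#' @return Data frame of class `occupancy_track` with columns `pos`,
#'   `score`.
#' @export
occupancy_track <- function(genome, start = 0L, end = genome_length(genome) - 1L,
                            scorer = NULL, window = 147) {
  n <- genome_length(genome)
  if (start < 0L || end > n - 1L || start > end)
    stop("occupancy_track: region outside contig")
  if (is.null(scorer)) scorer <- gc_scorer(window)
  pos <- seq.int(start, end)
  out <- data.frame(pos = pos, score = scorer(genome, pos))
  class(out) <- c("occupancy_track", "data.frame")
  attr(out, "contig") <- genome$id
  out
}
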