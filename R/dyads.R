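# Dyad call container and distance computations.

#' Dyad call table
#'
#' Single-nucleotide dyad positions on a contig, kept sorted by position.
#'
#' @param pos Integer vector of 0-based dyad positions (unique).
#' @param contig Contig label (recycled).
#' @param score Optional numeric score per dyad.
#' @return Data frame of class `dyad_calls` with columns `contig`, `pos`,
#'   `score`, sorted by `pos`.
#' @export
dyad_calls <- function(pos, contig = "contig", score = NA_real_) {
  pos <- as.integer(pos)
  contig <- rep_len(contig, length(pos))
  if (anyDuplicated(paste(contig, pos)))
    stop("dyad_calls: duplicated dyad positions on a contig")
  out <- data.frame(contig = contig,
                    pos = pos,
                    score = rep_len(as.numeric(score), length(pos)))
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dyad_calls", "data.frame")
  out
}

dyad_positions <- function(dyads) {
  if (is.data.frame(dyads)) as.integer(dyads$pos) else as.integer(dyads)
}

#' Distance to the nearest dyad
#'
#' Absolute (folded) distance from each query position to its nearest
#' dyad on the same contig. Ties between two equidistant dyads resolve to
#' the lower-coordinate dyad (the distance is identical either way).
#'
#' @param pos Integer vector of 0-based positions.
#' @param dyads A [dyad_calls()] table or integer vector of dyad
#'   positions.
#' @param max_dist Distances greater than this are reported as `NA`.
#' @param signed If `TRUE` return the signed offset `pos - dyad` instead
#'   of the absolute distance.
#' @return Numeric vector of distances (`NA` beyond `max_dist` or when
#'   there are no dyads).
#' @examples
#' distance_to_nearest_dyad(c(500, 507, 700), dyads = c(500L), max_dist = 100)
#' @export
distance_to_nearest_dyad <- function(pos, dyads, max_dist = Inf,
                                     signed = FALSE) {
  d <- sort(dyad_positions(dyads))
  if (length(d) == 0L) return(rep(NA_real_, length(pos)))
  idx <- findInterval(pos, d)                 # last dyad <= pos (0 if none)
  left <- ifelse(idx >= 1L, d[pmax(idx, 1L)], NA_integer_)
  right <- ifelse(idx < length(d), d[pmin(idx + 1L, length(d))], NA_integer_)
  dl <- abs(pos - left)
  dr <- abs(right - pos)
  dl[is.na(dl)] <- Inf
  dr[is.na(dr)] <- Inf
  # tie -> left (lower-coordinate) dyad
  use_left <- dl <= dr
  off <- ifelse(use_left, pos - left, pos - right)
  dist <- abs(off)
  out <- if (signed) as.numeric(off) else as.numeric(dist)
  out[dist > max_dist] <- NA_real_
  out
}

#' Place nucleosomes greedily by sequence affinity
#'
#' Repeatedly takes the highest-scoring admissible dyad position and
#' excludes all positions closer than `footprint + min_linker` to it, so
#' consecutive dyads are separated by at least that many nt. Exact score
#' ties are broken by a seed-determined random order.
#'
#' @param genome A [genome_seq()].
#' @param footprint Odd footprint width in nt (147 eukaryotic, 85
#'   archaeal).
#' @param min_linker Minimum linker length in nt between footprints.
#' @param scorer Scorer function; default `gc_scorer(footprint)`.
#' @param seed Optional integer seed (used only to break exact ties).
#' @return A [dyad_calls()] table; empty when the contig is shorter than
#'   the footprint.
#' @export
place_nucleosomes <- function(genome, footprint = 147, min_linker = 30,
                              scorer = NULL, seed = NULL) {
  stopifnot(footprint >= 3, footprint %% 2 == 1, min_linker >= 0)
  n <- genome_length(genome)
  half <- (footprint - 1L) %/% 2L
  if (n < footprint) return(dyad_calls(integer(0), contig = genome$id))
  if (is.null(scorer)) scorer <- gc_scorer(footprint)
  if (!is.null(seed)) set.seed(seed)
  centers <- if (isTRUE(genome$circular)) seq.int(0L, n - 1L)
             else seq.int(half, n - 1L - half)
  sc <- scorer(genome, centers)
  keep <- !is.na(sc)
  centers <- centers[keep]
  sc <- sc[keep]
  if (length(centers) == 0L) return(dyad_calls(integer(0), contig = genome$id))
  ord <- order(-sc, sample.int(length(sc)))
  excl <- as.integer(footprint + min_linker)
  blocked <- logical(n)
  acc_pos <- integer(0)
  acc_sc <- numeric(0)
  for (k in ord) {
    p <- centers[k]
    if (blocked[p + 1L]) next
    acc_pos <- c(acc_pos, p)
    acc_sc <- c(acc_sc, sc[k])
    lo <- p - excl + 1L
    hi <- p + excl - 1L
    if (isTRUE(genome$circular)) {
      blocked[(seq.int(lo, hi) %% n) + 1L] <- TRUE
    } else {
      blocked[seq.int(max(0L, lo), min(n - 1L, hi)) + 1L] <- TRUE
    }
  }
  dyad_calls(acc_pos, contig = genome$id, score = acc_sc)
}

#' Re-optimise dyad positions after sequence change
#'
#' Each dyad moves to the position of maximum scorer value within
#' `search_halfwidth` nt of its current position; score ties resolve
#' toward the smaller absolute offset, then the lower coordinate.
#' Non-overlap (`footprint + min_linker` spacing) is then re-enforced in
#' order of descending new score: a dyad whose best position conflicts
#' with an already-placed dyad takes its best admissible in-window
#' position and is dropped if none remains.
#'
#' @param dyads A [dyad_calls()] table.
#' @param genome The (derived) [genome_seq()] to score on.
#' @param scorer Scorer function; default `gc_scorer(footprint)`.
#' @param search_halfwidth Search radius in nt (`0` leaves dyads
#'   unchanged).
#' @param footprint,min_linker Spacing geometry, as in
#'   [place_nucleosomes()].
#' @return A [dyad_calls()] table of re-optimised dyads.
#' @export
reposition_dyads <- function(dyads, genome, scorer = NULL,
                             search_halfwidth = 73, footprint = 147,
                             min_linker = 30) {
  stopifnot(search_halfwidth >= 0)
  pos0 <- dyad_positions(dyads)
  if (length(pos0) == 0L || search_halfwidth == 0L) return(dyads)
  n <- genome_length(genome)
  if (is.null(scorer)) scorer <- gc_scorer(footprint)
  track <- scorer(genome, seq.int(0L, n - 1L))
  hw <- as.integer(search_halfwidth)
  # ordered candidate lists per dyad: score desc, |offset| asc, coord asc
  cands <- lapply(pos0, function(d) {
    p <- seq.int(max(0L, d - hw), min(n - 1L, d + hw))
    s <- track[p + 1L]
    ok <- !is.na(s)
    p <- p[ok]; s <- s[ok]
    if (length(p) == 0L) return(NULL)
    o <- order(-s, abs(p - d), p)
    list(pos = p[o], score = s[o])
  })
  best <- vapply(cands, function(cc) if (is.null(cc)) -Inf else cc$score[1L],
                 numeric(1))
  excl <- as.integer(footprint + min_linker)
  blocked <- logical(n)
  out_pos <- integer(0)
  out_sc <- numeric(0)
  for (k in order(-best, pos0)) {
    cc <- cands[[k]]
    if (is.null(cc)) next
    free <- which(!blocked[cc$pos + 1L])
    if (length(free) == 0L) next                 # no admissible position: drop
    p <- cc$pos[free[1L]]
    out_pos <- c(out_pos, p)
    out_sc <- c(out_sc, cc$score[free[1L]])
    rng <- seq.int(max(0L, p - excl + 1L), min(n - 1L, p + excl - 1L))
    blocked[rng + 1L] <- TRUE
  }
  dyad_calls(out_pos, contig = genome$id, score = out_sc)
}

#' Substitution-coupled (biased) repositioning
#'
#' The repositioning model used during branch evolution: nucleosomes
#' shift in response to the sequence changes themselves. A dyad with at
#' least one affinity-increasing (W>S) change within `search_halfwidth`
#' re-optimises over the admissible in-window positions centred within
#' `attract_radius` nt (one helical turn by default) of any such change
#' — the strengthened contact is most effective near the dyad axis, so
#' changed sites attract the dyad to a rotationally nearby centre, the
#' scorer picking among the attractor neighbourhoods. A dyad with only affinity-decreasing (S>W) changes under its
#' footprint re-optimises over in-window positions whose footprint
#' excludes all of them, when any exist (the weakened site repels).
#' GC-conserving changes trigger no movement; dyads without triggering
#' changes keep their position. Within the chosen candidate set the
#' scorer decides, ties resolving toward the smaller move, then the
#' lower coordinate; footprint + linker spacing is re-enforced in
#' descending score order as in [reposition_dyads()].
#'
#' @param dyads A [dyad_calls()] table.
#' @param genome The derived [genome_seq()].
#' @param subs Substitutions on this branch (data frame with `pos`,
#'   `anc`, `der`).
#' @param scorer Scorer function; default `gc_scorer(footprint)`.
#' @param search_halfwidth Search radius in nt.
#' @param footprint,min_linker Spacing geometry.
#' @param attract_radius Radius (nt) around an attracting W>S change
#'   within which the re-optimised dyad centre must fall (default 10,
#'   one helical turn).
#' @return A [dyad_calls()] table.
#' @export
reposition_biased <- function(dyads, genome, subs, scorer = NULL,
                              search_halfwidth = 73, footprint = 147,
                              min_linker = 30, attract_radius = 10) {
  stopifnot(search_halfwidth >= 0)
  pos0 <- dyad_positions(dyads)
  n <- genome_length(genome)
  if (length(pos0) == 0L || search_halfwidth == 0L || nrow(subs) == 0L)
    return(dyads)
  if (is.null(scorer)) scorer <- gc_scorer(footprint)
  half_fp <- footprint %/% 2L
  hw <- as.integer(search_halfwidth)
  W <- c("A", "T"); S <- c("C", "G")
  ws_pos <- sort(subs$pos[subs$anc %in% W & subs$der %in% S])
  sw_pos <- sort(subs$pos[subs$anc %in% S & subs$der %in% W])
  track <- scorer(genome, seq.int(0L, n - 1L))
  in_range <- function(sorted, lo, hi) {
    if (length(sorted) == 0L) return(integer(0))
    i <- findInterval(c(lo - 1L, hi), sorted)
    if (i[2L] <= i[1L]) integer(0) else sorted[(i[1L] + 1L):i[2L]]
  }
  cands <- lapply(pos0, function(d) {
    win <- seq.int(max(0L, d - hw), min(n - 1L, d + hw))
    ws <- in_range(ws_pos, d - hw, d + hw)
    if (length(ws)) {
      r <- min(attract_radius, half_fp)
      near_ws <- vapply(win, function(q) any(abs(q - ws) <= r), logical(1))
      p <- win[near_ws]
    } else {
      sw <- in_range(sw_pos, d - half_fp, d + half_fp)
      if (length(sw)) {
        p <- win[vapply(win, function(q) all(abs(q - sw) > half_fp),
                        logical(1))]
        if (length(p) == 0L) p <- d          # cannot escape: stay
      } else p <- d
    }
    s <- track[p + 1L]
    ok <- !is.na(s)
    p <- p[ok]; s <- s[ok]
    if (length(p) == 0L) { p <- d; s <- track[d + 1L] }
    o <- order(-s, abs(p - d), p)
    list(pos = p[o], score = s[o])
  })
  best <- vapply(cands, function(cc) {
    sc <- cc$score[1L]
    if (is.na(sc)) -Inf else sc
  }, numeric(1))
  excl <- as.integer(footprint + min_linker)
  blocked <- logical(n)
  out_pos <- integer(0)
  out_sc <- numeric(0)
  for (k in order(-best, pos0)) {
    cc <- cands[[k]]
    free <- which(!blocked[cc$pos + 1L])
    if (length(free) == 0L) next
    p <- cc$pos[free[1L]]
    out_pos <- c(out_pos, p)
    out_sc <- c(out_sc, cc$score[free[1L]])
    rng <- seq.int(max(0L, p - excl + 1L), min(n - 1L, p + excl - 1L))
    blocked[rng + 1L] <- TRUE
  }
  dyad_calls(out_pos, contig = genome$id, score = out_sc)
}
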