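# Ancestral-vs-extant repositioning metrics: delta-occupancy at dyads,
# signed dyad offsets D, their difference dD, the single-substitution
# window filter and a ~10-nt periodicity descriptor.

#' Change in occupancy score at a dyad between two sequences
#'
#' `score(derived, dyad) - score(ancestral, dyad)` under the given
#' scorer. With the default GC scorer a single W>S substitution inside
#' the window changes the score by exactly +1/window.
#'
#' @param anc_seq,der_seq [genome_seq()]s of equal length (gapless
#'   alignment).
#' @param dyad 0-based dyad position.
#' @param scorer Scorer function; default `gc_scorer(window)`.
#' @param window Window width for the default scorer.
#' @return Numeric score difference (`NA` with a warning when the window
#'   is out of bounds).
#' @export
delta_occupancy_at_dyad <- function(anc_seq, der_seq, dyad, scorer = NULL,
                                    window = 147) {
  if (is.null(scorer)) scorer <- gc_scorer(window)
  sa <- scorer(anc_seq, dyad)
  sd <- scorer(der_seq, dyad)
  out <- sd - sa
  if (anyNA(out))
    warning("delta_occupancy_at_dyad: scoring window out of bounds; NA returned")
  out
}

#' Signed offset to the highest-occupancy position near a dyad
#'
#' Finds the position of maximum scorer value within `halfwidth` nt
#' either side of the dyad and returns its signed offset D from the
#' dyad. Score ties resolve to the smallest absolute offset, then to the
#' negative (lower-coordinate) side.
#'
#' @param genome A [genome_seq()].
#' @param dyad 0-based dyad position.
#' @param halfwidth Search halfwidth in nt (default 100).
#' @param scorer Scorer function; default `gc_scorer(window)`.
#' @param window Window width for the default scorer.
#' @return Signed integer offset, or `NA` if no position in the window
#'   has a defined score.
#' @export
compute_offset_D <- function(genome, dyad, halfwidth = 100, scorer = NULL,
                             window = 147) {
  stopifnot(halfwidth >= 0)
  if (is.null(scorer)) scorer <- gc_scorer(window)
  n <- genome_length(genome)
  cand <- seq.int(max(0L, dyad - halfwidth), min(n - 1L, dyad + halfwidth))
  s <- scorer(genome, cand)
  ok <- !is.na(s)
  if (!any(ok)) return(NA_integer_)
  cand <- cand[ok]; s <- s[ok]
  off <- cand - dyad
  o <- order(-s, abs(off), off)
  as.integer(off[o[1L]])
}

#' Local repositioning measure dD between ancestor and extant sequence
#'
#' Computes the signed offsets D_extant and D_ancestral around the same
#' dyad coordinate on the two (gapless) sequences and returns
#' `delta = D_ancestral - D_extant`, together with the number of
#' focal-lineage substitutions inside the window when `subs` is
#' supplied.
#'
#' @param anc_seq,der_seq [genome_seq()]s of equal length.
#' @param dyad 0-based dyad position.
#' @param halfwidth Search halfwidth in nt (default 100).
#' @param scorer,window As in [compute_offset_D()].
#' @param subs Optional substitutions data frame used to count in-window
#'   changes.
#' @return List with `dyad`, `D_extant`, `D_ancestral`, `delta`,
#'   `n_subs_in_window` (`NA` delta when either offset is undefined).
#' @export
delta_D <- function(anc_seq, der_seq, dyad, halfwidth = 100, scorer = NULL,
                    window = 147, subs = NULL) {
  if (is.null(scorer)) scorer <- gc_scorer(window)
  dh <- compute_offset_D(der_seq, dyad, halfwidth, scorer)
  da <- compute_offset_D(anc_seq, dyad, halfwidth, scorer)
  nsub <- if (is.null(subs)) NA_integer_
          else sum(subs$pos >= dyad - halfwidth & subs$pos <= dyad + halfwidth)
  list(dyad = dyad, D_extant = dh, D_ancestral = da,
       delta = if (is.na(dh) || is.na(da)) NA_integer_ else da - dh,
       n_subs_in_window = nsub)
}

#' dD over a dyad set
#'
#' Vectorised convenience wrapper: one [delta_D()] row per dyad.
#'
#' @param anc_seq,der_seq [genome_seq()]s of equal length.
#' @param dyads [dyad_calls()] or integer positions.
#' @param halfwidth,scorer,window As in [delta_D()].
#' @param subs Optional substitutions data frame (focal lineage) for the
#'   in-window counts.
#' @return Data frame with columns `dyad`, `D_extant`, `D_ancestral`,
#'   `delta`, `n_subs_in_window`.
#' @export
delta_D_table <- function(anc_seq, der_seq, dyads, halfwidth = 100,
                          scorer = NULL, window = 147, subs = NULL) {
  if (is.null(scorer)) scorer <- gc_scorer(window)
  pos <- dyad_positions(dyads)
  n <- genome_length(der_seq)
  # score whole-genome tracks once; per-dyad work is then a window slice
  ta <- scorer(anc_seq, seq.int(0L, n - 1L))
  td <- scorer(der_seq, seq.int(0L, n - 1L))
  argmax_off <- function(track, d) {
    cand <- seq.int(max(0L, d - halfwidth), min(n - 1L, d + halfwidth))
    s <- track[cand + 1L]
    ok <- !is.na(s)
    if (!any(ok)) return(NA_integer_)
    cand <- cand[ok]; s <- s[ok]
    off <- cand - d
    as.integer(off[order(-s, abs(off), off)[1L]])
  }
  sp <- if (is.null(subs)) integer(0) else sort(subs$pos)
  rows <- lapply(pos, function(d) {
    dh <- argmax_off(td, d)
    da <- argmax_off(ta, d)
    nsub <- if (is.null(subs)) NA_integer_
            else sum(sp >= d - halfwidth & sp <= d + halfwidth)
    data.frame(dyad = d, D_extant = dh, D_ancestral = da,
               delta = if (is.na(dh) || is.na(da)) NA_integer_ else da - dh,
               n_subs_in_window = nsub)
  })
  if (length(rows)) do.call(rbind, rows)
  else data.frame(dyad = integer(0), D_extant = integer(0),
                  D_ancestral = integer(0), delta = integer(0),
                  n_subs_in_window = integer(0))
}

#' Dyads with exactly one focal substitution in the window
#'
#' The single-substitution filter: retains dyads with exactly one
#' focal-lineage substitution within `halfwidth` nt either side, so the
#' effect of an individual substitution on local positioning can be
#' read off.
#'
#' @param subs Substitutions data frame (pass the focal lineage only,
#'   or any lineage subset of interest).
#' @param dyads [dyad_calls()].
#' @param halfwidth Window halfwidth in nt (default 100).
#' @return The retained rows of `dyads`.
#' @export
single_substitution_windows <- function(subs, dyads, halfwidth = 100) {
  pos <- dyad_positions(dyads)
  sp <- sort(subs$pos)
  nlo <- findInterval(pos - halfwidth - 1L, sp)
  nhi <- findInterval(pos + halfwidth, sp)
  keep <- (nhi - nlo) == 1L
  out <- dyads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Periodicity descriptor of repositioning shift sizes
#'
#' Describes whether nonzero shift magnitudes `|delta|` are enriched at
#' (within `tol` nt of) multiples of `period` — the rotational spacing
#' of ~10 nt — relative to the remaining lags. Because no well-defined
#' random expectation exists, a permutation reference (uniform
#' resampling of lags over `1..max_lag`) is reported as a descriptive
#' interval, not a p-value.
#'
#' @param deltas Numeric vector of dD values (or a [delta_D_table()]
#'   result), zeros ignored.
#' @param period Period in nt (default 10).
#' @param tol Tolerance around multiples (default 1 nt).
#' @param max_lag Maximum possible lag (2 x halfwidth for dD values);
#'   default `max(abs(deltas))`.
#' @param n_perm Permutation resamples for the reference interval.
#' @param seed Optional seed for the permutation reference.
#' @return Object of class `periodicity_descriptor`: list with the lag
#'   histogram, observed near-multiple fraction, expected fraction under
#'   uniform lags, fold `enrichment`, the permutation interval, and a
#'   `degenerate` flag (period beyond `max_lag`).
#' @export
periodicity_profile <- function(deltas, period = 10, tol = 1,
                                max_lag = NULL, n_perm = 1000, seed = NULL) {
  if (is.data.frame(deltas)) deltas <- deltas$delta
  lag <- abs(deltas[!is.na(deltas) & deltas != 0])
  if (length(lag) == 0L)
    stop("periodicity_profile: no nonzero shifts")
  if (is.null(max_lag)) max_lag <- max(lag)
  degenerate <- period > max_lag
  near <- function(x) {
    k <- round(x / period)
    k >= 1 & abs(x - k * period) <= tol
  }
  obs_frac <- mean(near(lag))
  all_lags <- seq_len(max_lag)
  exp_frac <- mean(near(all_lags))
  enrichment <- if (exp_frac > 0) obs_frac / exp_frac else NA_real_
  if (!is.null(seed)) set.seed(seed)
  perm <- replicate(n_perm, {
    x <- sample(all_lags, length(lag), replace = TRUE)
    f <- mean(near(x))
    if (exp_frac > 0) f / exp_frac else NA_real_
  })
  structure(list(histogram = table(factor(lag, levels = all_lags)),
                 n = length(lag), period = period, tol = tol,
                 observed_fraction = obs_frac, expected_fraction = exp_frac,
                 enrichment = enrichment,
                 permutation_interval = stats::quantile(perm, c(0.025, 0.975),
                                                        na.rm = TRUE),
                 degenerate = degenerate),
            class = "periodicity_descriptor")
}

#' @export
print.periodicity_descriptor <- function(x, ...) {
  cat(sprintf("<periodicity_descriptor> %d nonzero shifts; near-multiple-of-%g fraction = %.3f (uniform expectation %.3f)\n",
              x$n, x$period, x$observed_fraction, x$expected_fraction))
  cat(sprintf("  fold enrichment = %.2f (permutation 95%% interval %.2f-%.2f)%s\n",
              x$enrichment, x$permutation_interval[1L],
              x$permutation_interval[2L],
              if (x$degenerate) " [degenerate: period exceeds max lag]" else ""))
  invisible(x)
}
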