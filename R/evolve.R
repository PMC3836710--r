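# Forward evolution of one branch: per-site substitution sampling with a
# directed 12-rate spectrum, optional dyad-proximity mutation bias,
# optional purifying selection on nucleosome position, and optional
# sequence-driven repositioning of dyads afterwards.

DIRECTED_CHANGES <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
                      "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")

#' Branch evolution parameters
#'
#' @param mu Expected substitutions per site over the whole branch (with
#'   a uniform spectrum and no bias).
#' @param spectrum Named numeric vector of the 12 directed relative rates
#'   (names like `"A>G"`); missing entries default to 1. Internally
#'   normalised to mean 1, so `mu` keeps its interpretation. `NULL` means
#'   uniform.
#' @param dyad_bias Multiplicative rate factor for sites within half a
#'   footprint of a dyad: a scalar applied to all changes, or a named
#'   vector over base-change categories (`CATEGORY_LEVELS`, plus pooled
#'   `"W>S"`/`"S>W"`), unnamed categories defaulting to 1.
#' @param selection_s Probability of rejecting a candidate substitution
#'   whose post-substitution optimal dyad offset exceeds
#'   `sel_threshold` (0 = neutral).
#' @param sel_threshold Offset threshold (nt) for selection, default 10
#'   (one helical turn).
#' @param reposition Logical; re-optimise dyad positions on the derived
#'   sequence after all substitutions.
#' @param search_halfwidth Search radius (nt) for re-optimisation and for
#'   the selection check.
#' @return An object of class `branch_params`.
#' @export
branch_params <- function(mu = 0, spectrum = NULL, dyad_bias = 1,
                          selection_s = 0, sel_threshold = 10,
                          reposition = FALSE, search_halfwidth = 73) {
  stopifnot(mu >= 0, selection_s >= 0, selection_s <= 1,
            sel_threshold >= 0, search_halfwidth >= 0)
  spec <- rep(1, 12)
  names(spec) <- DIRECTED_CHANGES
  if (!is.null(spectrum)) {
    if (is.null(names(spectrum)) || !all(names(spectrum) %in% DIRECTED_CHANGES))
      stop("branch_params: spectrum must be named with directed changes like 'A>G'")
    if (any(spectrum < 0)) stop("branch_params: spectrum entries must be >= 0")
    spec[names(spectrum)] <- spectrum
  }
  if (mean(spec) <= 0 && mu > 0)
    stop("branch_params: spectrum sums to zero with mu > 0")
  if (mean(spec) > 0) spec <- spec / mean(spec)
  bias <- rep(1, 6)
  names(bias) <- CATEGORY_LEVELS
  if (length(dyad_bias) == 1L && is.null(names(dyad_bias))) {
    bias[] <- dyad_bias
  } else {
    if (is.null(names(dyad_bias)))
      stop("branch_params: vector dyad_bias must be named by category")
    for (nm in names(dyad_bias))
      bias[expand_category(nm)] <- dyad_bias[[nm]]
  }
  if (any(bias <= 0)) stop("branch_params: dyad_bias must be > 0")
  structure(list(mu = mu, spectrum = spec, dyad_bias = bias,
                 selection_s = selection_s, sel_threshold = sel_threshold,
                 reposition = isTRUE(reposition),
                 search_halfwidth = as.integer(search_halfwidth)),
            class = "branch_params")
}

#' @export
print.branch_params <- function(x, ...) {
  cat(sprintf(
    "<branch_params> mu = %g; selection_s = %g (threshold %d nt); %s\n",
    x$mu, x$selection_s, x$sel_threshold,
    if (x$reposition) sprintf("repositioning on (halfwidth %d nt)",
                              x$search_halfwidth) else "repositioning off"))
  if (any(x$dyad_bias != 1)) {
    b <- x$dyad_bias[x$dyad_bias != 1]
    cat("  dyad bias:", paste(sprintf("%s x%g", names(b), b), collapse = ", "),
        "\n")
  }
  invisible(x)
}

# 4x4 directed-rate matrix (diag 0) from the named 12-vector
.spectrum_matrix <- function(spec) {
  m <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  for (nm in names(spec)) {
    a <- substr(nm, 1, 1); d <- substr(nm, 3, 3)
    m[a, d] <- spec[[nm]]
  }
  m
}

# 4x4 matrix of bias factors by (anc, der) from per-category bias
.bias_matrix <- function(bias) {
  m <- matrix(1, 4, 4)
  idx <- which(!is.na(.category_matrix))
  m[idx] <- bias[.category_matrix[idx]]
  m
}

#' Evolve one descendant branch from an ancestor
#'
#' Each site independently acquires at most one substitution (star-like,
#' no within-branch multiple hits). The probability of the directed
#' change X>Y at a site is `(mu/3) * spectrum(X>Y)`, multiplied by the
#' category's `dyad_bias` when the site lies within half a footprint of
#' its nearest dyad. With `selection_s > 0` each candidate is evaluated
#' on the ancestral background plus that single change: if the
#' best-scoring position within `search_halfwidth` of the nearest dyad
#' then lies more than `sel_threshold` nt from the dyad, the candidate is
#' rejected with probability `selection_s`. With `reposition = TRUE`,
#' after all substitutions, dyads shift in response to them under the
#' substitution-coupled model of [reposition_biased()] (W>S changes
#' attract the footprint, S>W changes repel it).
#'
#' @param ancestor A [genome_seq()].
#' @param dyads Ancestral [dyad_calls()].
#' @param params A [branch_params()].
#' @param footprint,min_linker Nucleosome geometry (nt).
#' @param scorer Scorer for selection/repositioning; default
#'   `gc_scorer(footprint)`.
#' @param seed Optional integer seed.
#' @param lineage Label recorded on the returned substitutions.
#' @param id Contig id of the derived sequence.
#' @return List with elements `genome` (derived [genome_seq()]), `subs`
#'   (data frame `contig, pos, anc, der, lineage`) and `dyads`
#'   ([dyad_calls()] of the derived sequence).
#' @export
evolve_branch <- function(ancestor, dyads, params, footprint = 147,
                          min_linker = 30, scorer = NULL, seed = NULL,
                          lineage = "focal", id = lineage) {
  stopifnot(inherits(params, "branch_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- genome_length(ancestor)
  empty_subs <- data.frame(contig = character(0), pos = integer(0),
                           anc = character(0), der = character(0),
                           lineage = character(0))
  derived_id <- id
  if (n == 0L || params$mu == 0) {
    g <- ancestor; g$id <- derived_id
    return(list(genome = g, subs = empty_subs, dyads = dyads))
  }
  if (is.null(scorer)) scorer <- gc_scorer(footprint)
  b <- base_ints(ancestor)
  spec_m <- .spectrum_matrix(params$spectrum)
  bias_m <- .bias_matrix(params$dyad_bias)
  dist <- distance_to_nearest_dyad(seq.int(0L, n - 1L), dyads)
  inside <- !is.na(dist) & dist <= footprint %/% 2L
  P <- matrix(0, n, 4)
  for (y in 1:4) {
    v <- (params$mu / 3) * spec_m[cbind(b, y)]
    bm <- bias_m[cbind(b, y)]
    v[inside] <- v[inside] * bm[inside]
    P[, y] <- v
  }
  ptot <- rowSums(P)
  if (any(ptot > 1))
    stop("evolve_branch: per-site substitution probability exceeds 1; ",
         "reduce mu or dyad_bias")
  u <- stats::runif(n)
  hit <- which(u < ptot)
  if (length(hit)) {
    r <- u[hit]
    c1 <- P[hit, 1]
    c2 <- c1 + P[hit, 2]
    c3 <- c2 + P[hit, 3]
    tgt <- 1L + (r >= c1) + (r >= c2) + (r >= c3)
  } else {
    tgt <- integer(0)
  }
  # purifying selection on nucleosome position: rejection sampling against
  # the single-candidate re-optimised dyad offset
  if (params$selection_s > 0 && length(hit)) {
    off_sgn <- distance_to_nearest_dyad(hit - 1L, dyads, signed = TRUE)
    keep <- logical(length(hit))
    for (i in seq_along(hit)) {
      if (is.na(off_sgn[i])) { keep[i] <- TRUE; next }
      nd <- (hit[i] - 1L) - off_sgn[i]
      gm <- ancestor
      substr(gm$seq, hit[i], hit[i]) <- BASES[tgt[i]]
      cand <- seq.int(max(0L, nd - params$search_halfwidth),
                      min(n - 1L, nd + params$search_halfwidth))
      s <- scorer(gm, cand)
      ok <- !is.na(s)
      if (!any(ok)) { keep[i] <- TRUE; next }
      cand <- cand[ok]; s <- s[ok]
      o <- order(-s, abs(cand - nd), cand)
      best_off <- cand[o[1L]] - nd
      keep[i] <- !(abs(best_off) > params$sel_threshold &&
                     stats::runif(1) < params$selection_s)
    }
    hit <- hit[keep]
    tgt <- tgt[keep]
  }
  der <- b
  der[hit] <- tgt
  g <- genome_seq(ints_to_seq(der), id = derived_id,
                  circular = ancestor$circular)
  subs <- data.frame(contig = rep(ancestor$id, length(hit)),
                     pos = hit - 1L,
                     anc = BASES[b[hit]],
                     der = BASES[tgt],
                     lineage = rep(lineage, length(hit)))
  out_dyads <- if (params$reposition)
    reposition_biased(dyads, g, subs, scorer = scorer,
                      search_halfwidth = params$search_halfwidth,
                      footprint = footprint, min_linker = min_linker)
  else dyads
  list(genome = g, subs = subs, dyads = out_dyads)
}
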