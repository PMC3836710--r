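# Dyad-anchored substitution-rate profiles per base-change category,
# eligible-site-weighted linear trend tests, LOWESS smoothing and the
# focal-vs-sister trend-pair classification.

#' Dyad-anchored substitution-rate profile for one category
#'
#' For each absolute distance d = 0..max_dist from the nearest dyad,
#' counts the category's substitutions at d and the eligible sites at d
#' (mask-eligible ancestral positions carrying the category's source
#' state, W or S), and forms the per-opportunity rate
#' `subs[d] / eligible[d]`. Sites within reach of two dyads are counted
#' once, at the nearest dyad.
#'
#' @param subs A `substitutions` data frame (one lineage; filter with
#'   `subs[subs$lineage == "focal", ]` first if needed).
#' @param dyads [dyad_calls()] (typically the focal species' dyads).
#' @param ancestral The ancestral [genome_seq()] supplying source-state
#'   eligibility.
#' @param category One of `CATEGORY_LEVELS`, or pooled `"W>S"` /
#'   `"S>W"`.
#' @param max_dist Maximum distance from the dyad (nt); default 100
#'   (147-nt footprint plus linker; use 60 for the 85-nt archaeal
#'   geometry).
#' @param mask Optional [site_mask()] restricting eligible sites and
#'   substitutions (e.g. a 4-fold degenerate mask).
#' @param dist_all Optional precomputed distance vector for all
#'   positions (internal use, avoids recomputation across categories).
#' @return Data frame of class `category_profile` with columns
#'   `distance`, `subs`, `eligible`, `rate` (`NA` where no eligible
#'   sites).
#' @export
build_profile <- function(subs, dyads, ancestral, category, max_dist = 100,
                          mask = NULL, dist_all = NULL) {
  cats <- expand_category(category)
  src <- category_source_state(category)
  n <- genome_length(ancestral)
  if (is.null(dist_all))
    dist_all <- distance_to_nearest_dyad(seq.int(0L, n - 1L), dyads,
                                         max_dist = max_dist)
  empty <- nrow(dyads) == 0L
  b <- base_ints(ancestral)
  src_ok <- if (src == "W") b == 1L | b == 4L else b == 2L | b == 3L
  if (!is.null(mask)) src_ok <- src_ok & mask$mask
  el_d <- dist_all[src_ok]
  el_d <- el_d[!is.na(el_d)]
  eligible <- tabulate(el_d + 1L, nbins = max_dist + 1L)
  if (!is.null(mask)) subs <- mask_substitutions(subs, mask)
  if (nrow(subs) > 0) {
    keep <- as.character(categorize_substitution(subs$anc, subs$der)) %in% cats
    sd <- dist_all[subs$pos[keep] + 1L]
    sd <- sd[!is.na(sd)]
  } else sd <- numeric(0)
  sub_counts <- tabulate(sd + 1L, nbins = max_dist + 1L)
  rate <- ifelse(eligible > 0, sub_counts / eligible, NA_real_)
  out <- data.frame(distance = seq.int(0L, max_dist), subs = sub_counts,
                    eligible = eligible, rate = rate)
  class(out) <- c("category_profile", "data.frame")
  attr(out, "category") <- as.character(category)
  attr(out, "source_state") <- src
  attr(out, "n_subs") <- sum(sub_counts)
  attr(out, "empty") <- empty
  out
}

#' @export
print.category_profile <- function(x, ...) {
  cat(sprintf("<category_profile> %s: %d substitutions within %d nt of a dyad%s\n",
              attr(x, "category"), attr(x, "n_subs"), max(x$distance),
              if (isTRUE(attr(x, "empty"))) " (no dyads: empty profile)" else ""))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...", nrow(x) - 5, "more distances\n")
  invisible(x)
}

#' Plot a category profile with its LOWESS fit
#'
#' @param x A `category_profile`.
#' @param f LOWESS span.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.category_profile <- function(x, f = 0.6, ...) {
  ok <- !is.na(x$rate)
  graphics::plot(x$distance[ok], x$rate[ok], pch = 16, col = "grey50",
                 xlab = "distance from dyad (nt)",
                 ylab = "substitutions per eligible site",
                 main = attr(x, "category"), ...)
  if (sum(ok) >= 3) {
    lw <- lowess_profile(x, f = f)
    graphics::lines(lw$distance, lw$fitted, col = "red", lwd = 2)
  }
  invisible(x)
}

#' Eligible-site-weighted linear trend of a profile
#'
#' Weighted least squares of `rate` on `distance`, weights equal to the
#' number of eligible sites at each distance; two-sided t-test p-value
#' for slope = 0.
#'
#' @param profile A [build_profile()] result (or any data frame with
#'   `distance`, `rate`, `eligible`).
#' @return Object of class `trend_fit`: list with `slope` (rate per nt),
#'   `intercept`, `p_value`, `n_points`, `weight_rule`.
#' @export
weighted_linear_trend <- function(profile) {
  ok <- !is.na(profile$rate) & profile$eligible > 0
  if (sum(ok) < 3)
    stop("weighted_linear_trend: fewer than 3 distances with defined rates")
  d <- profile$distance[ok]
  fit <- stats::lm(rate ~ distance, data = profile[ok, , drop = FALSE],
                   weights = profile$eligible[ok])
  sm <- summary(fit)
  cf <- sm$coefficients
  slope <- cf["distance", "Estimate"]
  p <- cf["distance", "Pr(>|t|)"]
  scale <- max(abs(profile$rate[ok]), .Machine$double.eps)
  if (sm$sigma < 1e-10 * scale) {
    # numerically exact fit: constant rates carry no trend evidence,
    # an exact nonzero line is unambiguous
    p <- if (abs(slope) < 1e-10 * scale) 1 else 0
    if (abs(slope) < 1e-10 * scale) slope <- 0
  }
  if (is.nan(p)) p <- 1
  cf["distance", "Estimate"] <- slope
  structure(list(slope = unname(cf["distance", "Estimate"]),
                 intercept = unname(cf["(Intercept)", "Estimate"]),
                 p_value = unname(p),
                 n_points = sum(ok),
                 weight_rule = "eligible sites per distance",
                 category = attr(profile, "category")),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit>%s slope = %.3g per nt (intercept %.3g), p = %.3g, %d distances, weights: %s\n",
              if (is.null(x$category)) "" else paste0(" ", x$category),
              x$slope, x$intercept, x$p_value, x$n_points, x$weight_rule))
  invisible(x)
}

# Cleveland-style locally weighted regression. At each point the
# nearest ceiling(f*n) points enter a tricube-weighted linear fit;
# residual-based bisquare weights (6 * median |res|) robustify over
# `iter` additional passes. Written out here because the smoother's
# neighbourhood rule is pinned to ceiling(f*n), which differs from the
# floor-based count inside stats::lowess.
.lowess_cleveland <- function(x, y, f = 0.6, iter = 3) {
  n <- length(x)
  o <- order(x)
  x <- x[o]; y <- y[o]
  ns <- max(2L, min(n, as.integer(ceiling(f * n))))
  rw <- rep(1, n)
  fit <- numeric(n)
  for (it in 0:iter) {
    for (i in seq_len(n)) {
      d <- abs(x - x[i])
      idx <- order(d, seq_len(n))[seq_len(ns)]
      h <- max(d[idx])
      w <- numeric(n)
      if (h > 0) w[idx] <- (1 - pmin(d[idx] / h, 1)^3)^3 else w[idx] <- 1
      w <- w * rw
      sw <- sum(w)
      if (sw <= 0) { fit[i] <- y[i]; next }
      xm <- sum(w * x) / sw
      ym <- sum(w * y) / sw
      sxx <- sum(w * (x - xm)^2)
      fit[i] <- if (sxx > 0) ym + sum(w * (x - xm) * (y - ym)) / sxx * (x[i] - xm)
                else ym
    }
    if (it < iter) {
      res <- y - fit
      s <- stats::median(abs(res))
      if (s == 0) break
      rw <- (1 - pmin(abs(res) / (6 * s), 1)^2)^2
    }
  }
  list(x = x, y = fit)
}

#' LOWESS smoothing of a profile
#'
#' Locally weighted linear regression: at each distance the nearest
#' `ceiling(f * n)` points enter a tricube-kernel weighted linear fit,
#' robustified by `iter` bisquare reweighting passes (Cleveland's
#' procedure).
#'
#' @param profile A [build_profile()] result.
#' @param f Smoother span in (0, 1]; default 0.6.
#' @param iter Number of robustifying iterations (default 3).
#' @return Data frame of class `lowess_fit` with columns `distance`,
#'   `fitted` at every distance with eligible sites.
#' @export
lowess_profile <- function(profile, f = 0.6, iter = 3) {
  stopifnot(f > 0, f <= 1)
  ok <- !is.na(profile$rate) & profile$eligible > 0
  if (sum(ok) < 3)
    stop("lowess_profile: fewer than 3 usable points")
  lw <- .lowess_cleveland(profile$distance[ok], profile$rate[ok], f = f,
                          iter = iter)
  out <- data.frame(distance = lw$x, fitted = lw$y)
  class(out) <- c("lowess_fit", "data.frame")
  attr(out, "f") <- f
  out
}

#' Classify a focal/sister trend pair
#'
#' @param focal,sister [weighted_linear_trend()] results (or `NULL` for
#'   an unavailable fit, treated as non-significant).
#' @param alpha Significance level (default 0.05).
#' @return One of `"concordant"` (both significant, same slope sign),
#'   `"discordant"` (both significant, opposite signs), `"focal_only"`,
#'   `"none"`.
#' @export
classify_trend_pair <- function(focal, sister, alpha = 0.05) {
  sig <- function(x) !is.null(x) && !is.na(x$p_value) && x$p_value < alpha
  if (sig(focal) && sig(sister)) {
    if (sign(focal$slope) == sign(sister$slope)) "concordant" else "discordant"
  } else if (sig(focal)) "focal_only" else "none"
}

TREND_CLASSES <- c("focal_only", "concordant", "discordant", "none")
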