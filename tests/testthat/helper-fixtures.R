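# Shared fixture builders: everything is generated in code at test time.

# a small scenario spec for fast unit tests
small_spec <- function(label = "null", L = 20000, mu = 0.003, seed = 1,
                       n_reps = 1, ...) {
  scenario_preset(label, n_reps = n_reps, seed = seed, genome_length = L,
                  mu = mu, ...)
}

# sequence with a single GC island of width w centred at `centre` (0-based)
# in an otherwise all-A background
island_genome <- function(L, centre, w) {
  b <- rep("A", L)
  half <- (w - 1) %/% 2
  b[(centre - half):(centre + half) + 1] <- "G"
  genome_seq(paste(b, collapse = ""), id = "island")
}

# apply substitutions (data.frame pos/der) to a genome
mutate_genome <- function(g, pos, der) {
  s <- g$seq
  for (i in seq_along(pos)) substr(s, pos[i] + 1, pos[i] + 1) <- der[i]
  genome_seq(s, id = paste0(g$id, "_mut"))
}

# closed-form weighted least squares with t-test, written from the normal
# equations -- the independent oracle for weighted_linear_trend()
wls_oracle <- function(x, y, w) {
  sw <- sum(w)
  xm <- sum(w * x) / sw
  ym <- sum(w * y) / sw
  sxx <- sum(w * (x - xm)^2)
  slope <- sum(w * (x - xm) * (y - ym)) / sxx
  intercept <- ym - slope * xm
  res <- y - intercept - slope * x
  n <- length(x)
  s2 <- sum(w * res^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  tval <- slope / se
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  list(slope = slope, intercept = intercept, p_value = p, se = se)
}

# naive direct LOWESS recomputation (solves each local weighted linear
# system explicitly) -- the independent oracle for lowess_profile()
lowess_oracle <- function(x, y, f = 0.6, iter = 3) {
  n <- length(x)
  o <- order(x); x <- x[o]; y <- y[o]
  ns <- max(2, min(n, ceiling(f * n)))
  rw <- rep(1, n)
  fit <- numeric(n)
  for (it in 0:iter) {
    for (i in seq_len(n)) {
      d <- abs(x - x[i])
      nb <- order(d, seq_len(n))[seq_len(ns)]
      h <- max(d[nb])
      w <- rep(0, n)
      w[nb] <- if (h > 0) (1 - pmin(d[nb] / h, 1)^3)^3 else 1
      w <- w * rw
      sw <- sum(w)
      if (sw <= 0) { fit[i] <- y[i]; next }
      # explicit weighted normal equations on centred x, solved with
      # solve(); degenerate when the weighted x-spread vanishes
      xc <- x - sum(w * x) / sw
      if (sum(w * xc^2) > 0) {
        X <- cbind(1, xc)
        beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
        fit[i] <- beta[1] + beta[2] * xc[i]
      } else {
        fit[i] <- sum(w * y) / sw
      }
    }
    if (it < iter) {
      res <- y - fit
      s <- stats::median(abs(res))
      if (s == 0) break
      rw <- (1 - pmin(abs(res) / (6 * s), 1)^2)^2
    }
  }
  data.frame(x = x, fitted = fit)
}

# wrap a profile-like data frame for the regression functions
fake_profile <- function(distance, rate, eligible) {
  data.frame(distance = distance, subs = round(rate * eligible),
             eligible = eligible, rate = rate)
}
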