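# Scenario runner: replicate simulation -> parsimony calling -> focal and
# sister profiles against focal dyads -> trend-pair classification.

#' Run a simulation scenario and classify trend pairs
#'
#' For each replicate, simulates a triplet, re-calls substitutions by
#' parsimony, builds per-category substitution-rate profiles for the
#' focal and sister lineages against the focal species' dyads, fits the
#' eligible-site-weighted linear trend for each, and classifies the
#' focal/sister pair as concordant, discordant, focal-only or none.
#'
#' @param spec A [scenario_spec()] (see [scenario_preset()]).
#' @param max_dist Maximum profile distance from the dyad (nt).
#' @param alpha Significance level for the trend classification.
#' @param categories Base-change categories to analyse; defaults to the
#'   six strand-symmetric categories plus the pooled `"W>S"` and
#'   `"S>W"`.
#' @param use_planted If `TRUE`, analyse the planted substitutions
#'   directly instead of re-calling them by parsimony (slightly faster;
#'   identical at singly-hit sites).
#' @return Object of class `scenario_outcome`: list with `class_freq`
#'   (category x trend-class frequency matrix, rows summing to 1),
#'   `per_rep` (per-replicate slopes, p-values and classes) and `spec`.
#' @export
run_scenario <- function(spec, max_dist = 100, alpha = 0.05,
                         categories = c(CATEGORY_LEVELS, "W>S", "S>W"),
                         use_planted = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  rows <- vector("list", spec$n_reps * length(categories))
  ri <- 0L
  for (i in seq_len(spec$n_reps)) {
    ds <- simulate_triplet(spec, seed = rep_seed(spec$seed, i))
    subs <- if (use_planted) ds$subs else call_substitutions(ds)
    n <- genome_length(ds$ancestor)
    dist_all <- distance_to_nearest_dyad(seq.int(0L, n - 1L), ds$focal_dyads,
                                         max_dist = max_dist)
    for (cat in categories) {
      fits <- lapply(c("focal", "sister"), function(lin) {
        pr <- build_profile(subs[subs$lineage == lin, , drop = FALSE],
                            ds$focal_dyads, ds$ancestor, cat,
                            max_dist = max_dist, dist_all = dist_all)
        list(profile = pr,
             fit = tryCatch(weighted_linear_trend(pr), error = function(e) NULL))
      })
      ff <- fits[[1L]]$fit; sf <- fits[[2L]]$fit
      cls <- if (attr(fits[[1L]]$profile, "n_subs") == 0L) "none"
             else classify_trend_pair(ff, sf, alpha = alpha)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        rep = i, category = cat,
        n_focal_subs = attr(fits[[1L]]$profile, "n_subs"),
        n_sister_subs = attr(fits[[2L]]$profile, "n_subs"),
        focal_slope = if (is.null(ff)) NA_real_ else ff$slope,
        focal_p = if (is.null(ff)) NA_real_ else ff$p_value,
        sister_slope = if (is.null(sf)) NA_real_ else sf$slope,
        sister_p = if (is.null(sf)) NA_real_ else sf$p_value,
        class = cls)
    }
  }
  per_rep <- do.call(rbind, rows)
  freq <- prop.table(table(factor(per_rep$category, levels = categories),
                           factor(per_rep$class, levels = TREND_CLASSES)),
                     margin = 1)
  structure(list(class_freq = freq, per_rep = per_rep, spec = spec,
                 alpha = alpha, max_dist = max_dist),
            class = "scenario_outcome")
}

#' @export
print.scenario_outcome <- function(x, ...) {
  cat(sprintf("<scenario_outcome> '%s': %d replicates, alpha = %g\n",
              x$spec$label, x$spec$n_reps, x$alpha))
  print(round(unclass(x$class_freq), 3))
  invisible(x)
}

#' @export
summary.scenario_outcome <- function(object, ...) {
  pr <- object$per_rep
  agg <- do.call(rbind, lapply(split(pr, pr$category), function(d) {
    data.frame(category = d$category[1L],
               mean_focal_slope = mean(d$focal_slope, na.rm = TRUE),
               frac_focal_sig = mean(!is.na(d$focal_p) &
                                       d$focal_p < object$alpha),
               frac_sister_sig = mean(!is.na(d$sister_p) &
                                        d$sister_p < object$alpha),
               modal_class = names(which.max(table(d$class))))
  }))
  rownames(agg) <- NULL
  agg
}

#' Modal trend class of a category in a scenario outcome
#' @param outcome A [run_scenario()] result.
#' @param category Category label.
#' @return The most frequent trend class for that category.
#' @export
modal_class <- function(outcome, category) {
  f <- outcome$class_freq[category, ]
  names(f)[which.max(f)]
}
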