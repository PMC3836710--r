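# Scenario specification and simulation of a focal/sister/outgroup
# triplet from a common ancestor.

#' Scenario specification for the coevolution simulator
#'
#' Bundles the genome, nucleosome geometry and the two branch parameter
#' sets defining one simulation scenario.
#'
#' @param label Scenario name.
#' @param genome_length Ancestral genome length (nt).
#' @param gc Ancestral GC fraction.
#' @param footprint Odd nucleosome footprint (nt); 147 eukaryotic, 85
#'   archaeal.
#' @param min_linker Minimum linker (nt) between footprints.
#' @param focal,sister [branch_params()] for the two descendant
#'   branches.
#' @param outgroup Optional [branch_params()] for a nonzero-length
#'   outgroup branch (default: the outgroup *is* the ancestor, which
#'   makes parsimony exact).
#' @param n_reps Number of replicates for [run_scenario()].
#' @param seed Master seed; per-replicate seeds are derived from it (see
#'   the package vignette for the splitting rule).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(label = "scenario", genome_length = 200000,
                          gc = 0.5, footprint = 147, min_linker = 30,
                          focal = branch_params(mu = 0.003),
                          sister = branch_params(mu = 0.003),
                          outgroup = NULL, n_reps = 1, seed = 1) {
  stopifnot(footprint >= 3, footprint %% 2 == 1, min_linker >= 0,
            n_reps >= 1, genome_length >= 0, gc >= 0, gc <= 1,
            inherits(focal, "branch_params"), inherits(sister, "branch_params"))
  if (!is.null(outgroup)) stopifnot(inherits(outgroup, "branch_params"))
  structure(list(label = label, genome_length = as.integer(genome_length),
                 gc = gc, footprint = as.integer(footprint),
                 min_linker = as.integer(min_linker), focal = focal,
                 sister = sister, outgroup = outgroup,
                 n_reps = as.integer(n_reps), seed = as.integer(seed)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> '%s': L = %d nt (GC %.2f), footprint %d + linker %d, %d rep(s), seed %d\n",
              x$label, x$genome_length, x$gc, x$footprint, x$min_linker,
              x$n_reps, x$seed))
  cat("  focal:  "); print(x$focal)
  cat("  sister: "); print(x$sister)
  invisible(x)
}

# per-replicate seed splitting: replicates take a large stride so that
# the small within-replicate stage offsets can never collide with
# another replicate's stages
rep_seed <- function(seed, rep) {
  as.integer((as.double(seed) + 1000003 * as.double(rep)) %% 2147483647)
}

stage_seed <- function(seed, k) {
  as.integer((as.double(seed) + k) %% 2147483647)
}

#' Built-in scenario presets
#'
#' Ready-made scenarios matching the competing explanations for
#' dyad-anchored substitution trends: `"null"` (no bias of any kind),
#' `"mutation-bias-only"` (weak-to-strong changes twice as likely inside
#' the footprint, no repositioning), `"selection-only"` (position-
#' disrupting changes rejected with probability 0.8), `"repositioning-
#' only"` (dyads re-optimised on the derived sequence, no mutational or
#' selective bias), and `"bias-plus-repositioning"`.
#'
#' @param name Preset name (see above).
#' @param n_reps Number of replicates.
#' @param seed Master seed.
#' @param genome_length,mu,gc Override the default study conditions
#'   (200 kb, 0.003 substitutions/site, GC 0.5).
#' @param footprint,min_linker,search_halfwidth Nucleosome geometry.
#' @return A [scenario_spec()].
#' @export
scenario_preset <- function(name = c("null", "mutation-bias-only",
                                     "selection-only", "repositioning-only",
                                     "bias-plus-repositioning"),
                            n_reps = 50, seed = 1, genome_length = 200000,
                            mu = 0.003, gc = 0.5, footprint = 147,
                            min_linker = 30, search_halfwidth = 73) {
  name <- match.arg(name)
  bp <- function(...) branch_params(mu = mu, search_halfwidth = search_halfwidth, ...)
  pars <- switch(name,
    "null" = bp(),
    "mutation-bias-only" = bp(dyad_bias = c("W>S" = 2)),
    "selection-only" = bp(selection_s = 0.8, sel_threshold = 10),
    "repositioning-only" = bp(reposition = TRUE),
    "bias-plus-repositioning" = bp(dyad_bias = c("W>S" = 2), reposition = TRUE))
  scenario_spec(label = name, genome_length = genome_length, gc = gc,
                footprint = footprint, min_linker = min_linker,
                focal = pars, sister = pars, n_reps = n_reps, seed = seed)
}

#' Simulate one focal/sister/outgroup triplet
#'
#' Generates an ancestor, places nucleosomes on it, evolves the focal and
#' sister branches independently, and uses the ancestor itself as the
#' outgroup (a zero-length outgroup branch, so three-taxon parsimony is
#' exact) unless `spec$outgroup` asks for outgroup-branch evolution. The
#' alignment is gapless by construction.
#'
#' @param spec A [scenario_spec()].
#' @param seed Replicate seed; defaults to `spec$seed`.
#' @return An object of class `sim_triplet`: list with `ancestor`,
#'   `focal`, `sister`, `outgroup` ([genome_seq()]s of equal length),
#'   `ancestral_dyads`, `focal_dyads`, `sister_dyads` ([dyad_calls()]),
#'   `subs` (planted substitutions, both lineages) and `spec`.
#' @export
simulate_triplet <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "scenario_spec"))
  anc <- generate_ancestor(spec$genome_length, gc = spec$gc, seed = seed,
                           id = "ancestor")
  dy <- place_nucleosomes(anc, footprint = spec$footprint,
                          min_linker = spec$min_linker,
                          seed = stage_seed(seed, 1))
  foc <- evolve_branch(anc, dy, spec$focal, footprint = spec$footprint,
                       min_linker = spec$min_linker,
                       seed = stage_seed(seed, 2), lineage = "focal")
  sis <- evolve_branch(anc, dy, spec$sister, footprint = spec$footprint,
                       min_linker = spec$min_linker,
                       seed = stage_seed(seed, 3), lineage = "sister")
  if (is.null(spec$outgroup)) {
    outg <- anc; outg$id <- "outgroup"
  } else {
    outg <- evolve_branch(anc, dy, spec$outgroup, footprint = spec$footprint,
                          min_linker = spec$min_linker,
                          seed = stage_seed(seed, 4), lineage = "outgroup")$genome
  }
  structure(list(ancestor = anc, focal = foc$genome, sister = sis$genome,
                 outgroup = outg, ancestral_dyads = dy,
                 focal_dyads = foc$dyads, sister_dyads = sis$dyads,
                 subs = rbind(foc$subs, sis$subs), spec = spec,
                 seed = seed),
            class = "sim_triplet")
}

#' @export
print.sim_triplet <- function(x, ...) {
  cat(sprintf("<sim_triplet> '%s' (seed %d): %d nt, %d dyads, %d planted substitutions (%d focal / %d sister)\n",
              x$spec$label, x$seed, genome_length(x$ancestor),
              nrow(x$ancestral_dyads), nrow(x$subs),
              sum(x$subs$lineage == "focal"),
              sum(x$subs$lineage == "sister")))
  invisible(x)
}
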