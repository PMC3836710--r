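# Forward simulator: ancestor generation, nucleosome placement, branch
# evolution, repositioning, triplet assembly.

test_that("generate_ancestor respects GC content, length and seed", {
  g <- generate_ancestor(10, gc = 0, seed = 1)
  expect_true(grepl("^[AT]+$", g$seq))
  expect_equal(genome_length(generate_ancestor(0, 0.5)), 0L)
  # observed GC within 3 binomial standard deviations of the target
  g2 <- generate_ancestor(10000, gc = 0.6, seed = 7)
  obs <- mean(strsplit(g2$seq, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(obs - 0.6), 3 * sqrt(0.6 * 0.4 / 10000))
  # reproducibility and error cases
  expect_identical(generate_ancestor(500, 0.4, seed = 3)$seq,
                   generate_ancestor(500, 0.4, seed = 3)$seq)
  expect_error(generate_ancestor(-1, 0.5), "length")
  expect_error(generate_ancestor(10, 1.5), "gc")
})

test_that("affinity_score is mean window GC with bounds checking", {
  g <- genome_seq(strrep("G", 21))
  expect_equal(affinity_score(g, 10, footprint = 21), 1.0)
  a <- genome_seq(strrep("A", 21))
  expect_equal(affinity_score(a, 10, footprint = 21), 0.0)
  m <- genome_seq(strrep("ACGT", 10))  # alternating W/S content
  naive <- mean(strsplit(m$seq, "")[[1]][(20 - 10):(20 + 10) + 1] %in% c("G", "C"))
  expect_equal(affinity_score(m, 20, footprint = 21), naive)
  expect_error(affinity_score(g, 0, footprint = 21), "out of bounds")
  # circular contigs wrap instead of erroring
  gc_circ <- genome_seq(strrep("G", 21), circular = TRUE)
  expect_equal(affinity_score(gc_circ, 0, footprint = 21), 1.0)
})

test_that("place_nucleosomes is greedy, spaced, and finds GC islands", {
  # spacing invariant on a random genome
  g <- generate_ancestor(20000, 0.5, seed = 11)
  dy <- place_nucleosomes(g, footprint = 147, min_linker = 30, seed = 1)
  expect_true(all(diff(dy$pos) >= 147 + 30))
  # a single GC island of exactly footprint width in an AT sea: first
  # (and only competitive) dyad sits at the island centre
  isl <- island_genome(2000, centre = 700, w = 147)
  dy2 <- place_nucleosomes(isl, footprint = 147, min_linker = 30, seed = 1)
  expect_equal(dy2$pos[which.max(dy2$score)], 700L)
  # contig shorter than the footprint
  expect_equal(nrow(place_nucleosomes(genome_seq(strrep("A", 100)),
                                      footprint = 147)), 0L)
  # determinism given seed (ties are everywhere on uniform sequences)
  u <- genome_seq(strrep("A", 3000))
  expect_identical(place_nucleosomes(u, 147, 30, seed = 5),
                   place_nucleosomes(u, 147, 30, seed = 5))
})

test_that("evolve_branch matches its sampling model", {
  anc <- generate_ancestor(100000, 0.5, seed = 2)
  dy <- place_nucleosomes(anc, 147, 30, seed = 3)
  # mu = 0: identity
  r0 <- evolve_branch(anc, dy, branch_params(mu = 0), seed = 4)
  expect_identical(r0$genome$seq, anc$seq)
  expect_equal(nrow(r0$subs), 0L)
  expect_identical(r0$dyads, dy)
  # substitution count within 3 binomial standard deviations of L * mu
  mu <- 0.01
  r1 <- evolve_branch(anc, dy, branch_params(mu = mu), seed = 5)
  expect_lt(abs(nrow(r1$subs) - 100000 * mu),
            3 * sqrt(100000 * mu * (1 - mu)))
  # derived sequence differs from the ancestor exactly at the
  # substituted positions, with the recorded bases
  b_anc <- strsplit(anc$seq, "")[[1]]
  b_der <- strsplit(r1$genome$seq, "")[[1]]
  diffs <- which(b_anc != b_der) - 1L
  expect_identical(diffs, sort(r1$subs$pos))
  expect_identical(b_der[r1$subs$pos + 1L], r1$subs$der)
  expect_identical(b_anc[r1$subs$pos + 1L], r1$subs$anc)
})

test_that("dyad_bias calibration: inside/outside rate ratio matches b", {
  b <- 3
  ratios <- replicate(20, NULL)
  ins_sub <- out_sub <- ins_el <- out_el <- 0
  for (i in 1:20) {
    anc <- generate_ancestor(30000, 0.5, seed = 100 + i)
    dy <- place_nucleosomes(anc, 147, 30, seed = 200 + i)
    r <- evolve_branch(anc, dy, branch_params(mu = 0.005, dyad_bias = b),
                       seed = 300 + i)
    dist <- distance_to_nearest_dyad(0:(genome_length(anc) - 1), dy)
    inside <- !is.na(dist) & dist <= 73
    sd_ <- distance_to_nearest_dyad(r$subs$pos, dy)
    s_in <- !is.na(sd_) & sd_ <= 73
    ins_sub <- ins_sub + sum(s_in); out_sub <- out_sub + sum(!s_in)
    ins_el <- ins_el + sum(inside); out_el <- out_el + sum(!inside)
  }
  ratio <- (ins_sub / ins_el) / (out_sub / out_el)
  # delta-method standard error of the rate ratio on pooled counts
  se <- ratio * sqrt(1 / ins_sub + 1 / out_sub)
  expect_lt(abs(ratio - b), 3 * se)
})

test_that("reposition_dyads is a local argmax re-optimisation", {
  # no sequence change anywhere: an isolated dyad at its local argmax
  # stays put
  isl <- island_genome(2000, centre = 700, w = 147)
  dy <- place_nucleosomes(isl, 147, 30, seed = 1)
  rd <- reposition_dyads(dy, isl, search_halfwidth = 73)
  expect_setequal(rd$pos, dy$pos)
  # a strictly higher-scoring window centred +20 from an isolated dyad
  g <- island_genome(2000, centre = 700, w = 101)
  dy1 <- dyad_calls(700L, contig = g$id)
  g2 <- island_genome(2000, centre = 720, w = 147)   # bigger island at +20
  rd2 <- reposition_dyads(dy1, g2, search_halfwidth = 73, footprint = 147)
  expect_equal(rd2$pos, 720L)
  # zero search radius: unchanged
  expect_identical(reposition_dyads(dy1, g2, search_halfwidth = 0), dy1)
})

test_that("reposition_biased couples dyad movement to substitutions", {
  # no substitutions: unchanged
  g <- generate_ancestor(3000, 0.5, seed = 9)
  dy <- place_nucleosomes(g, 147, 30, seed = 9)
  empty <- data.frame(pos = integer(0), anc = character(0),
                      der = character(0))
  expect_identical(reposition_biased(dy, g, empty), dy)
  # a W>S change at +40 from an isolated dyad attracts it to within the
  # one-turn radius of the changed site
  isl <- island_genome(2000, centre = 700, w = 147)
  dy1 <- dyad_calls(700L, contig = isl$id)
  der <- mutate_genome(isl, pos = 740, der = "G")
  subs <- data.frame(pos = 740L, anc = "A", der = "G")
  rb <- reposition_biased(dy1, der, subs, search_halfwidth = 73,
                          footprint = 147, attract_radius = 10)
  expect_lte(abs(rb$pos - 740L), 10L)
  # an S>W change under the footprint repels the dyad beyond footprint
  # reach of the weakened site
  der2 <- mutate_genome(isl, pos = 690, der = "T")
  subs2 <- data.frame(pos = 690L, anc = "G", der = "T")
  rb2 <- reposition_biased(dy1, der2, subs2, search_halfwidth = 73,
                           footprint = 147)
  expect_gt(abs(rb2$pos - 690L), 73L)
  # GC-conserving changes trigger no movement
  der3 <- mutate_genome(isl, pos = 700, der = "C")
  subs3 <- data.frame(pos = 700L, anc = "G", der = "C")
  expect_equal(reposition_biased(dy1, der3, subs3)$pos, 700L)
})

test_that("simulate_triplet satisfies its structural invariants", {
  # mu = 0 on both branches: everything equals the ancestor
  sp0 <- scenario_spec(genome_length = 5000, focal = branch_params(0),
                       sister = branch_params(0), seed = 1)
  ds0 <- simulate_triplet(sp0)
  expect_identical(ds0$focal$seq, ds0$ancestor$seq)
  expect_identical(ds0$sister$seq, ds0$ancestor$seq)
  expect_equal(nrow(ds0$subs), 0L)
  # planted focal substitutions are exactly the focal-vs-ancestor
  # differences; without repositioning all dyad sets coincide
  ds <- simulate_triplet(small_spec(L = 20000, mu = 0.005), seed = 5)
  ba <- strsplit(ds$ancestor$seq, "")[[1]]
  bf <- strsplit(ds$focal$seq, "")[[1]]
  expect_identical(which(ba != bf) - 1L,
                   sort(ds$subs$pos[ds$subs$lineage == "focal"]))
  expect_identical(ds$focal_dyads$pos, ds$ancestral_dyads$pos)
  expect_identical(ds$sister_dyads$pos, ds$ancestral_dyads$pos)
  # outgroup is the ancestor by default
  expect_identical(ds$outgroup$seq, ds$ancestor$seq)
  # byte-identical determinism
  expect_identical(simulate_triplet(small_spec(L = 10000, seed = 2), seed = 9),
                   simulate_triplet(small_spec(L = 10000, seed = 2), seed = 9))
})

test_that("emitted dyad lists always satisfy the spacing exclusion", {
  for (i in 1:3) {
    ds <- simulate_triplet(small_spec("repositioning-only", L = 30000,
                                      seed = i), seed = 40 + i)
    for (dy in list(ds$ancestral_dyads, ds$focal_dyads, ds$sister_dyads))
      expect_true(all(diff(dy$pos) >= 147 + 30))
  }
})
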