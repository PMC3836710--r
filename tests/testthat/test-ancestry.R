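# Parsimony substitution calling, CpG flags, 4-fold masks, spectra.

test_that("parsimony assigns columns by outgroup agreement", {
  # focal A, sister G, outgroup G -> focal-lineage G>A at position 0
  s <- call_substitutions(triplet_alignment("A", "G", "G"))
  expect_equal(nrow(s), 1L)
  expect_equal(s$lineage, "focal")
  expect_equal(s$anc, "G"); expect_equal(s$der, "A"); expect_equal(s$pos, 0L)
  # focal = sister: the change maps to the internal/outgroup branch
  expect_equal(nrow(call_substitutions(triplet_alignment("A", "A", "G"))), 0L)
  # outgroup matches neither: skipped
  expect_equal(nrow(call_substitutions(triplet_alignment("A", "C", "G"))), 0L)
  # sister-lineage call when outgroup matches focal
  s2 <- call_substitutions(triplet_alignment("ACA", "AGA", "ACA"))
  expect_equal(s2$lineage, "sister")
  expect_equal(s2$anc, "C"); expect_equal(s2$der, "G"); expect_equal(s2$pos, 1L)
  # gaps and ambiguity codes make a column ineligible
  expect_equal(nrow(call_substitutions(triplet_alignment("A-", "G-", "G-"))), 1L)
  expect_equal(nrow(call_substitutions(triplet_alignment("N", "G", "G"))), 0L)
  # focal coordinates skip focal-gap columns
  s3 <- call_substitutions(triplet_alignment("C-A", "C-G", "CCG"))
  expect_equal(s3$pos, 1L)       # second focal base, 0-based
  expect_equal(s3$lineage, "focal")
  expect_error(triplet_alignment("AC", "A", "AC"), "equal")
})

test_that("swapping focal and sister swaps every lineage label only", {
  ds <- simulate_triplet(small_spec(L = 10000, mu = 0.01, seed = 3), seed = 4)
  a <- call_substitutions(triplet_alignment(ds$focal$seq, ds$sister$seq,
                                            ds$outgroup$seq))
  b <- call_substitutions(triplet_alignment(ds$sister$seq, ds$focal$seq,
                                            ds$outgroup$seq))
  swap <- c(focal = "sister", sister = "focal")
  b$lineage <- unname(swap[b$lineage])
  a <- a[order(a$pos, a$lineage), ]; b <- b[order(b$pos, b$lineage), ]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("with outgroup = ancestor, calls recover the planted truth at singly-hit sites", {
  ds <- simulate_triplet(small_spec(L = 30000, mu = 0.008, seed = 6), seed = 7)
  calls <- call_substitutions(ds)
  planted <- ds$subs
  both_hit <- intersect(planted$pos[planted$lineage == "focal"],
                        planted$pos[planted$lineage == "sister"])
  key <- function(d) paste(d$pos, d$anc, d$der, d$lineage)
  expect_setequal(key(calls[!calls$pos %in% both_hit, ]),
                  key(planted[!planted$pos %in% both_hit, ]))
  # every discrepancy is at a position hit on both branches
  expect_true(all(setdiff(key(planted), key(calls)) %in%
                    key(planted[planted$pos %in% both_hit, ])))
})

test_that("CpG context is read from the ancestral strand-symmetric flanks", {
  anc <- genome_seq("AACGT")
  # C>T at the C of an ancestral CpG
  expect_true(flag_cpg(data.frame(pos = 2L, anc = "C"), anc))
  # G>A at the G of the same CpG (strand symmetry)
  expect_true(flag_cpg(data.frame(pos = 3L, anc = "G"), anc))
  # C not followed by G
  expect_false(flag_cpg(data.frame(pos = 1L, anc = "C"), genome_seq("ACATT")))
  # missing flank at the contig edge: non-CpG by decision
  expect_false(flag_cpg(data.frame(pos = 4L, anc = "C"), genome_seq("AAAAC")))
  expect_false(flag_cpg(data.frame(pos = 0L, anc = "G"), genome_seq("GAAAA")))
  # the parsimony caller flags CpG from reconstructed ancestral context
  s <- call_substitutions(triplet_alignment("ATGT", "ACGT", "ACGT"))
  expect_true(s$cpg)   # ancestral ..CG.., C>T on the focal branch
})

test_that("fourfold_mask marks third positions of 4-fold codon families", {
  # Met-Gly-Trp-stop: only the Gly codon third position is 4-fold
  g <- genome_seq("ATGGGATGGTAA")
  m <- fourfold_mask(data.frame(start = 0, end = 12), g)
  expect_equal(which(m$mask) - 1L, 5L)
  expect_equal(m$class, "fourfold")
  # minus strand: reverse complement of ATG GGA TGG TAA on the plus strand
  rc <- genome_seq(revcomp(g$seq))
  m2 <- fourfold_mask(data.frame(start = 0, end = 12, strand = "-"), rc)
  expect_equal(which(m2$mask) - 1L, 12L - 1L - 5L)
  # internal stop codon: transcript skipped with a warning
  stopg <- genome_seq("ATGTAAGGATGA")
  expect_warning(m3 <- fourfold_mask(data.frame(start = 0, end = 12), stopg),
                 "stop")
  expect_false(any(m3$mask))
  # frame violation warns and skips; out-of-bounds errors
  expect_warning(fourfold_mask(data.frame(start = 0, end = 10), g),
                 "multiple of 3")
  expect_error(fourfold_mask(data.frame(start = 0, end = 99), g), "bounds")
  # all eight 4-fold families and no others are recognised
  four <- dyadsub:::.fourfold_prefixes
  expect_setequal(four, c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG"))
})

test_that("global_spectrum counts directed changes and pools categories", {
  subs <- data.frame(anc = c("A", "A", "A", "C"), der = c("G", "G", "G", "T"))
  sp <- global_spectrum(subs)
  expect_equal(sp$directed$count[sp$directed$change == "A>G"], 3L)
  expect_equal(sp$category$count[sp$category$category == "A:T>G:C"], 3L)
  expect_equal(sp$category$count[sp$category$category == "G:C>A:T"], 1L)
  expect_equal(sp$category$fraction[sp$category$category == "A:T>G:C"], 0.75)
  # category counts always equal the sum of their directed constituents
  ds <- simulate_triplet(small_spec(L = 20000, mu = 0.01, seed = 9), seed = 2)
  sp2 <- global_spectrum(ds$subs)
  dir_cat <- as.character(categorize_substitution(
    substr(sp2$directed$change, 1, 1), substr(sp2$directed$change, 3, 3)))
  for (cl in CATEGORY_LEVELS)
    expect_equal(sp2$category$count[sp2$category$category == cl],
                 sum(sp2$directed$count[dir_cat == cl]))
  expect_equal(sum(sp2$directed$fraction), 1)
  # empty input is flagged, fractions undefined
  sp0 <- global_spectrum(subs[0, ])
  expect_true(sp0$empty)
  expect_true(all(is.na(sp0$directed$fraction)))
})

test_that("simulator spectrum is recovered within multinomial error", {
  # a skewed planted spectrum round-trips through evolution + counting
  spec12 <- stats::setNames(rep(1, 12), dyadsub:::DIRECTED_CHANGES)
  spec12["A>G"] <- spec12["T>C"] <- 4
  anc <- generate_ancestor(50000, 0.5, seed = 31)
  dy <- place_nucleosomes(anc, 147, 30, seed = 32)
  r <- evolve_branch(anc, dy, branch_params(mu = 0.01, spectrum = spec12),
                     seed = 33)
  sp <- global_spectrum(r$subs)
  n <- sp$n
  # expected A:T>G:C fraction: rates 4,4 of total 12 entries summing 18
  p_exp <- 8 / 18
  obs <- sp$category$fraction[sp$category$category == "A:T>G:C"]
  expect_lt(abs(obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))
})

test_that("masking restricts substitutions and profiles consistently", {
  ds <- simulate_triplet(small_spec(L = 10000, mu = 0.01, seed = 13), seed = 3)
  calls <- call_substitutions(ds)
  mask <- site_mask(rep(c(TRUE, FALSE), length.out = 10000), class = "all")
  kept <- mask_substitutions(calls, mask)
  expect_lte(nrow(kept), nrow(calls))
  expect_true(all(mask$mask[kept$pos + 1L]))
})
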