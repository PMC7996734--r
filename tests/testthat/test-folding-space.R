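toy <- toy_backend()

test_that("an unpairable alignment yields only the open chain", {
  aln <- rna_alignment("AAAAAAA")
  enum <- enumerate_structures(aln)
  expect_length(enum$structures, 1L)
  expect_equal(nrow(enum$structures[[1]]$pairs), 0L)
  kb <- kbest_hishapes(aln, folding_space_config(k = 5))
  expect_equal(nrow(kb), 1L)
  expect_equal(kb$hishape, "[_]")
  expect_equal(kb$energy, 0.0)
})

test_that("enumeration matches an independent brute-force count and set", {
  aln <- hairpin9()
  cfg <- folding_space_config(k = 50)
  enum <- enumerate_structures(aln, cfg)
  dbs <- sort(vapply(enum$structures, write_dotbracket, character(1)))
  expect_equal(anyDuplicated(dbs), 0L)  # non-ambiguity: each exactly once
  expect_true("(((...)))" %in% dbs)
  kb <- kbest_hishapes(aln, cfg)
  bf <- brute_force_hishapes(aln, cfg)
  expect_equal(kb$hishape, bf$hishape)
  expect_equal(kb$energy, bf$energy)
  expect_equal(kb$hishrep, bf$hishrep)
  expect_equal(kb$hishape[1], "[5]")
  expect_equal(kb$energy[1], -1.0)
})

test_that("base-pairing filter boundary: 0.5 passes at threshold 0.5", {
  # pair (1,9) valid in exactly 1 of 2 rows
  aln <- rna_alignment(c("GGGAAACCC", "AGGAAACCA"))
  expect_equal(pair_fraction(aln, 1, 9), 0.5)
  with_pair <- function(enum, i, j) {
    any(vapply(enum$structures, function(s)
      nrow(s$pairs) && any(s$pairs[, 1] == i & s$pairs[, 2] == j),
      logical(1)))
  }
  e05 <- enumerate_structures(aln, folding_space_config(bp_threshold = 0.5))
  e06 <- enumerate_structures(aln, folding_space_config(bp_threshold = 0.6))
  expect_true(with_pair(e05, 1, 9))
  expect_false(with_pair(e06, 1, 9))
})

test_that("raising the threshold never adds classes (monotonicity)", {
  for (seed in 1:4) {
    gen <- generate_alignment(default_synth(seed = seed, n_rows = 4,
                                            mut_rate = 0.15))
    k1 <- kbest_hishapes(gen$aln, folding_space_config(k = 100,
                                                       bp_threshold = 0.3))
    k2 <- kbest_hishapes(gen$aln, folding_space_config(k = 100,
                                                       bp_threshold = 0.6))
    expect_true(all(k2$hishape %in% k1$hishape))
  }
})

test_that("k-best output is deterministic and well-formed", {
  gen <- generate_alignment(default_synth(seed = 2, n_rows = 4))
  cfg <- folding_space_config(k = 6)
  a <- kbest_hishapes(gen$aln, cfg)
  b <- kbest_hishapes(gen$aln, cfg)
  expect_identical(a, b)
  expect_equal(a$rank, seq_len(nrow(a)))
  expect_true(all(diff(a$energy) >= 0))           # energies non-decreasing
  expect_equal(anyDuplicated(a$hishape), 0L)      # classes pairwise distinct
  # each hishrep maps to its class hishape
  for (r in seq_len(nrow(a))) {
    expect_equal(format(abstract_hishape(parse_dotbracket(a$hishrep[r]), "h")),
                 a$hishape[r])
  }
})

test_that("rank-1 class energy is the constrained minimum pseudo energy", {
  gen <- generate_alignment(default_synth(seed = 6, n_rows = 4))
  enum <- enumerate_structures(gen$aln)
  kb <- kbest_hishapes(gen$aln, folding_space_config(k = 3))
  expect_equal(kb$energy[1], min(enum$energies))
})

test_that("external-loop filter removes costly components, keeps open chain", {
  aln <- hairpin9()
  ctx_structs <- enumerate_structures(aln)$structures
  keep0 <- apply_x_filter(aln, ctx_structs, 0, toy)
  dbs <- vapply(ctx_structs, write_dotbracket, character(1))
  # the positive-energy 2-pair hairpins are removed, the -1.0 hairpin stays
  expect_true(keep0[dbs == "........."])
  expect_true(keep0[dbs == "(((...)))"])
  expect_false(any(keep0[dbs == "((....))."]))
  # boundary: a component at exactly e is retained (only strictly greater cut)
  keep_eq <- apply_x_filter(aln, list(parse_dotbracket("(((...)))")), -1.0, toy)
  expect_true(keep_eq)
  keep_lt <- apply_x_filter(aln, list(parse_dotbracket("(((...)))")), -1.01, toy)
  expect_false(keep_lt)
  # filter applied inside the configuration
  kb <- kbest_hishapes(aln, folding_space_config(k = 10, x_filter = 0))
  expect_true(all(kb$energy <= 0))
})

test_that("k-best equals the brute-force oracle on synthetic alignments", {
  for (seed in 1:6) {
    gen <- generate_alignment(default_synth(seed = seed,
                                            n_rows = c(2, 4, 6)[(seed %% 3) + 1],
                                            mut_rate = 0.1))
    cfg <- folding_space_config(k = 8)
    kb <- kbest_hishapes(gen$aln, cfg)
    bf <- brute_force_hishapes(gen$aln, cfg)
    expect_equal(kb$hishape, bf$hishape)
    expect_equal(kb$energy, bf$energy)
    expect_equal(kb$hishrep, bf$hishrep)
  }
})

test_that("a bistable alignment yields the two hairpins as leading classes", {
  fix <- bistable()
  kb <- kbest_hishapes(fix$aln, folding_space_config(k = 4))
  expect_setequal(kb$hishrep[1:2],
                  c(write_dotbracket(fix$A), write_dotbracket(fix$B)))
  expect_equal(kb$energy[1], kb$energy[2])  # symmetric switch
})
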