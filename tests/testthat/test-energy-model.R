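toy <- toy_backend()

test_that("toy loop energies sum over the loop decomposition", {
  expect_equal(sequence_energy("GGGAAACCC", parse_dotbracket("(((...)))"), toy),
               -1.0)  # 2 stacks + hairpin closure
  expect_equal(sequence_energy("GGAAACC", parse_dotbracket("((...))"), toy),
               1.0)   # 1 stack + hairpin closure
  expect_equal(sequence_energy("ACGUACGUA", rna_structure(9), toy), 0.0)
  # bulge: 2 outer stacks impossible here; one stack, bulge, one stack, hairpin
  expect_equal(sequence_energy("GGAGGAAACCCC",
                               parse_dotbracket("((.((...))))"), toy),
               -2 + 2 - 2 + 3)
  # multiloop: outer 2-pair helix + 2 hairpin helices
  expect_equal(sequence_energy("GGAAGGAAACCAAGGAAACCAACC",
                               parse_dotbracket("((..((...))..((...))..))"), toy),
               -2 + 4 + (-2 + 3) + (-2 + 3))
})

test_that("invalid pairs are errors, not numbers", {
  expect_error(sequence_energy("GGGAAACCA", parse_dotbracket("(((...)))"), toy),
               "invalid")
  expect_error(sequence_energy("GGGAAACCC", parse_dotbracket("((...))"), toy),
               "length")
})

test_that("conservation score V rewards compensatory pairs", {
  # rows form (G,C) and (A,U) at the ends: both valid, distance 2
  aln <- rna_alignment(c("GAAAC", "AAAAU"))
  expect_equal(conservation_score_V(aln, 1, 5), 1.0)
  # identical pairs: distance 0
  expect_equal(conservation_score_V(rna_alignment(c("GAAAC", "GAAAC")), 1, 5), 0)
  # second row cannot pair: whole term drops
  expect_equal(conservation_score_V(rna_alignment(c("GAAAC", "AAAAG")), 1, 5), 0)
  expect_error(conservation_score_V(aln, 0, 5), "range")
  # per_pairs normalization divides by M(M-1)/2 instead of M
  aln4 <- rna_alignment(c("GAAAC", "AAAAU", "GAAAC", "AAAAU"))
  vM <- conservation_score_V(aln4, 1, 5)
  vP <- conservation_score_V(aln4, 1, 5,
                             covariance_params(normalization = "per_pairs"))
  expect_equal(vM * 4, vP * 6)  # same raw sum, different prefactor
})

test_that("gap penalty Q counts rows that cannot pair", {
  expect_equal(gap_penalty_Q(rna_alignment(c("GAAAC", "AAAAC")), 1, 5), 0.5)
  expect_equal(gap_penalty_Q(rna_alignment(c("GAAAC", "AAAAU")), 1, 5), 0)
  expect_equal(gap_penalty_Q(rna_alignment(c("-AAA-", "AAAAC")), 1, 5), 0.5)
  expect_equal(gap_penalty_Q(rna_alignment(c("-AAA-", "-AAA-")), 1, 5), 0)
})

test_that("C = V - phi * Q", {
  aln <- rna_alignment(c("GAAAC", "AAAAU"))
  expect_equal(covariance_C(aln, 1, 5), 1.0)
  alnq <- rna_alignment(c("GAAAC", "AAAAC"))
  expect_equal(covariance_C(alnq, 1, 5), -0.5)
  expect_equal(covariance_C(alnq, 1, 5, covariance_params(phi = 0)), 0)
  expect_equal(covariance_C(alnq, 1, 5, covariance_params(phi = 2)), -1.0)
})

test_that("pair_fraction counts valid rows", {
  aln <- rna_alignment(c("GAAAC", "CAAAG", "AAAAA", "GAAAA"))
  expect_equal(pair_fraction(aln, 1, 5), 0.5)
  expect_equal(pair_fraction(rna_alignment(c("AAAAA")), 1, 5), 0)
  expect_equal(pair_fraction(rna_alignment(c("GAAAC", "CAAAG")), 1, 5), 1.0)
})

test_that("pseudo energy decomposes exactly and follows lambda", {
  aln <- compensatory2()
  s <- parse_dotbracket("((((....))))")
  pe <- consensus_pseudo_energy(aln, s, toy, covariance_params(lam = -1))
  expect_identical(pe$total, pe$mean_energy + pe$covariance_term)
  # hand computation: both rows score -3.0; V = 1,1,0,1 over the 4 pairs
  expect_equal(pe$mean_energy, -3.0)
  expect_equal(pe$covariance_term, -3.0)
  expect_equal(pe$total, -6.0)
  # lambda = 0 leaves the mean energy
  pe0 <- consensus_pseudo_energy(aln, s, toy, covariance_params(lam = 0))
  expect_equal(pe0$total, pe0$mean_energy)
})

test_that("lambda = 0 consensus equals the mean of per-row energies", {
  set.seed(3)
  for (rep in 1:5) {
    gen <- generate_alignment(default_synth(seed = rep, n_rows = 4))
    aln <- gen$aln
    s <- gen$truth$structure
    pe <- consensus_pseudo_energy(aln, s, toy, covariance_params(lam = 0))
    # independent per-row summation
    per_row <- vapply(seq_len(aln$M), function(k) {
      cm <- coordinate_map(aln, k)
      sequence_energy(cm$seq, project_structure(aln, k, s, cm), toy)
    }, numeric(1))
    expect_equal(pe$total, mean(per_row))
  }
})

test_that("M = 1 consensus degenerates to the single-sequence energy", {
  aln <- hairpin9()
  s <- parse_dotbracket("(((...)))")
  pe <- consensus_pseudo_energy(aln, s, toy, covariance_params(lam = 0))
  expect_equal(pe$total, sequence_energy("GGGAAACCC", s, toy))
  # with M = 1 the pair sum in V is empty: C = -phi * Q
  expect_equal(conservation_score_V(aln, 1, 9), 0)
  expect_equal(covariance_C(aln, 1, 9), 0)  # row pairs validly: Q = 0
})

test_that("row projection drops gapped and invalid pairs", {
  aln <- rna_alignment(c("GGGAAACCC", "GG-AAAC-C"))
  s <- parse_dotbracket("(((...)))")
  p2 <- project_structure(aln, 2, s)
  # pairs (1,9) G-C kept, (2,8) gapped out, (3,7) column 3 is a gap in row 2
  expect_equal(p2$length, 7L)
  expect_equal(nrow(p2$pairs), 1L)
  expect_equal(unname(p2$pairs[1, ]), c(1L, 7L))
})

test_that("turner backend evaluates the bundled parameter table", {
  tb <- turner_backend()
  e <- sequence_energy("GGGAAACCC", parse_dotbracket("(((...)))"), tb)
  expect_equal(e, 2 * -3.26 + 5.4, tolerance = 1e-9)  # 2 GC/GC stacks + 3-loop
  expect_identical(e, sequence_energy("GGGAAACCC",
                                      parse_dotbracket("(((...)))"), tb))
  # long loops extrapolate finitely
  e2 <- sequence_energy(paste0("GG", strrep("A", 40), "CC"),
                        parse_dotbracket(paste0("((", strrep(".", 40), "))")),
                        tb)
  expect_true(is.finite(e2))
  expect_error(tb$stack("GAAAAAAGC", 1, 9), "invalid")
})

test_that("covariation signal concentrates on true pair columns", {
  gen <- generate_alignment(default_synth(seed = 101, comp_rate = 0.8))
  aln <- gen$aln
  true_pairs <- gen$truth$pair_cols
  c_true <- mean(apply(true_pairs, 1, function(p)
    covariance_C(aln, p[1], p[2])))
  set.seed(101)
  unpaired <- setdiff(seq_len(aln$L), c(true_pairs))
  rand <- t(replicate(20, sort(sample(unpaired, 2))))
  c_rand <- mean(apply(rand, 1, function(p) covariance_C(aln, p[1], p[2])))
  expect_gt(c_true, c_rand)
})
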