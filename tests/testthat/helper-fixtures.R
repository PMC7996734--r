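# Shared fixtures: all built in code, hand-checkable with the toy backend.

# single hairpin, toy energy -1.0 (2 stacks + hairpin closure)
hairpin9 <- function() rna_alignment("GGGAAACCC")

# 10-nt hairpin used for barrier hand cases (open chain -> (((....))))
hairpin10 <- function() rna_alignment("GGGAAAACCC")

# symmetric bistable switch: two mutually exclusive 4-pair hairpins sharing
# columns 9..12; both hishreps score -3.0 with the toy backend
bistable <- function() {
  list(aln = rna_alignment("GGGGAAAACCCCAAAAGGGG"),
       A = parse_dotbracket("((((....))))........"),
       B = parse_dotbracket("........((((....))))"))
}

# 30-nt switch with room for a third "scaffold" hairpin C between the two
# switch helices; routing through C lowers the refolding saddle
scaffold30 <- function() {
  list(aln = rna_alignment("GGGGAAAAAAAACCCCGGGAAAACCCGGGG"),
       A = parse_dotbracket("((((........)))).............."),
       B = parse_dotbracket("............((((..........))))"),
       M = parse_dotbracket("((((........))))(((....)))....")
  )
}

# 2-row perfectly compensatory alignment over a 12-column hairpin
compensatory2 <- function() {
  rna_alignment(c("GGGGAAAACCCC",
                  "ACGUAAAAACGU"))
}

# random gapped row for coordinate-map property tests
random_gapped_row <- function(n, gap_p = 0.25) {
  chars <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
  gaps <- runif(n) < gap_p
  if (all(gaps)) gaps[1] <- FALSE
  chars[gaps] <- "-"
  paste(chars, collapse = "")
}

# random valid structure on n positions (non-crossing, hairpins >= 3)
random_structure <- function(n, p_pair = 0.6) {
  pairs <- matrix(integer(0), ncol = 2L)
  rec <- function(lo, hi) {
    while (lo <= hi - 4L) {
      if (runif(1) < p_pair) {
        js <- seq(lo + 4L, hi)
        j <- js[sample.int(length(js), 1L)]
        pairs <<- rbind(pairs, c(lo, j))
        rec(lo + 1L, j - 1L)
        lo <- j + 1L
      } else {
        lo <- lo + 1L
      }
    }
  }
  rec(1L, n)
  rna_structure(n, pairs)
}

# test-local base-pair distance (keeps tests independent of internals)
bp_distance_test <- function(a, b) {
  ka <- paste(a$pairs[, 1], a$pairs[, 2])
  kb <- paste(b$pairs[, 1], b$pairs[, 2])
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

# planted structure is a single 6-pair hairpin helix: every planted pair is
# visible to the level-h abstraction the recovery checks run at
default_synth <- function(seed, n_rows = 8L, comp_rate = 0.5,
                          mut_rate = 0.05, ...) {
  synthetic_spec("GGGCGCAAAAGCGCCCAUCAUCAU",
                 parse_dotbracket("((((((....))))))........"),
                 n_rows = n_rows, comp_rate = comp_rate,
                 mut_rate = mut_rate, seed = seed, ...)
}
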