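test_that("scoring scheme enforces sign conventions", {
  s <- scoring_scheme()
  expect_identical(unlist(s[c("match", "mismatch", "gap_open", "gap_extend")]),
                   c(match = 2L, mismatch = -2L, gap_open = -3L,
                     gap_extend = -1L))
  expect_error(scoring_scheme(match = 0), "match")
  expect_error(scoring_scheme(mismatch = 1), "must be < 0")
  expect_error(scoring_scheme(gap_open = 0), "must be < 0")
})

test_that("local alignment reproduces hand-checked cases", {
  a <- smith_waterman("ACGT", "ACGT")
  expect_identical(a$score, 8L)
  expect_equal(a$identity, 1.0)
  expect_identical(a$cigar, "4M")

  # one retained mismatch beats opening a gap
  b <- smith_waterman("ACGTACGT", "ACGAACGT")
  expect_identical(b$score, 12L)
  expect_identical(b$matches, 7L)
  expect_identical(b$columns, 8L)

  # a length-2 gap costs open + extend = 4
  d <- smith_waterman("ACGTAAACGT", "ACGTACGT")
  expect_identical(d$score, 12L)
  expect_identical(d$cigar, "4M2I4M")
  expect_equal(d$identity, 0.8)

  # no positive-scoring pair: empty local alignment
  e <- smith_waterman("AAAA", "CCCC")
  expect_identical(e$score, 0L)
  expect_identical(e$columns, 0L)
  expect_equal(e$identity, 0)
})

test_that("N is a mismatch and bad symbols are rejected by position", {
  # flanked N is retained as a mismatch column, never a match
  a <- smith_waterman("AACCNGGTT", "AACCTGGTT")
  expect_identical(a$matches, 8L)
  expect_identical(a$columns, 9L)
  expect_identical(a$score, 14L)
  n <- smith_waterman("NNNN", "NNNN")
  expect_identical(n$score, 0L)
  expect_error(smith_waterman("ACXT", "ACGT"),
               "invalid symbol 'X' in query at position 3")
  expect_error(smith_waterman("ACGT", "ACGU"),
               "invalid symbol 'U' in reference at position 4")
})

test_that("scores equal the independent affine-gap oracle on random pairs", {
  withr::with_seed(41, {
    for (i in 1:200) {
      q <- random_dna(sample(5:30, 1))
      r <- random_dna(sample(5:30, 1))
      match <- sample(1:4, 1); mismatch <- -sample(1:4, 1)
      go <- -sample(2:6, 1); ge <- -sample(1:3, 1)
      sc <- scoring_scheme(match, mismatch, go, ge)
      expect_identical(smith_waterman(q, r, sc)$score,
                       as.integer(sw_score_oracle(q, r, match, mismatch,
                                                  go, ge)))
    }
  })
})

test_that("scores match Biostrings pairwiseAlignment under the mapped gap convention", {
  skip_if_not_installed("Biostrings")
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                     mismatch = -2,
                                                     baseOnly = TRUE)
  withr::with_seed(43, {
    for (i in 1:25) {
      q <- random_dna(sample(10:60, 1))
      r <- random_dna(sample(10:60, 1))
      ours <- smith_waterman(q, r)$score
      # gap of length L here costs 3 + (L-1) = 2 + L, i.e. opening 2 +
      # extension 1 per symbol in the Biostrings convention
      theirs <- Biostrings::pairwiseAlignment(q, r, type = "local",
                                              substitutionMatrix = submat,
                                              gapOpening = 2,
                                              gapExtension = 1,
                                              scoreOnly = TRUE)
      expect_identical(as.numeric(ours), as.numeric(theirs))
    }
  })
})

test_that("alignment invariants hold: rescoring, symmetry, coordinates", {
  withr::with_seed(47, {
    for (i in 1:40) {
      q <- random_dna(sample(10:50, 1))
      r <- random_dna(sample(10:50, 1))
      a <- smith_waterman(q, r)
      expect_identical(dropseqr:::rescore_alignment(a), a$score)
      expect_identical(smith_waterman(r, q)$score, a$score)
      expect_gte(a$score, 0L)
      # gapped strings reproduce the claimed local segments
      expect_identical(gsub("-", "", a$query_aligned),
                       substr(q, a$query_start + 1, a$query_end))
      expect_identical(gsub("-", "", a$ref_aligned),
                       substr(r, a$ref_start + 1, a$ref_end))
      expect_gte(a$columns,
                 max(a$query_end - a$query_start, a$ref_end - a$ref_start))
    }
  })
})

test_that("mean identity summarizes permutation draws", {
  # no multi-base droplets: degenerate summary
  read <- set_read(list("A", "C", "G", "T"))
  ids <- mean_identity(read, "ACGT", n_draws = 20, seed = 1)
  expect_equal(ids$sd, 0)
  expect_equal(ids$mean, 1.0)

  withr::with_seed(53, {
    ref <- random_dna(60)
    droplets <- c(lapply(1:5, function(i) sample(c("A", "C", "G", "T"), 2)),
                  as.list(strsplit(random_dna(8), "")[[1]]))
    read <- set_read(sample(droplets))
  })
  ids <- mean_identity(read, ref, n_draws = 20, seed = 2)
  expect_gte(ids$mean, min(ids$identities))
  expect_lte(ids$mean, max(ids$identities))
  expect_identical(mean_identity(read, ref, n_draws = 20, seed = 2)$identities,
                   ids$identities)
  expect_error(mean_identity(set_read(list()), ref), "empty set-read")
})

test_that("a zero-error simulated read aligns with identity 1", {
  ref <- paste(rep("ACGT", 30), collapse = "")
  cfg <- sim_config(n_droplets = 400, contamination_rate = 0,
                    misidentify_rate = 0, seed = 5)
  tr <- simulate_release(ref, cfg)
  # error-free limit requires no same-colour double capture
  expect_false(any(grepl("(.)\\1", tr$captured)))
  read <- droplets_to_read(truth_to_calls(tr))
  best <- best_order_search(read, ref, seed = 1)
  expect_equal(best$identity, 1.0)
})

test_that("identity degrades monotonically with contamination", {
  rates <- c(0, 0.05, 0.15)
  mean_ids <- vapply(rates, function(cr) {
    mean(vapply(1:20, function(s) {
      ref <- make_reference(80, 0.5, seed = 1000 + s)
      cfg <- sim_config(n_droplets = 250, contamination_rate = cr,
                        misidentify_rate = 0, seed = s)
      read <- droplets_to_read(truth_to_calls(simulate_release(ref, cfg)))
      mean_identity(read, ref, n_draws = 5, seed = s)$mean
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_ids) <= 0))
})
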