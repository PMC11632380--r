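test_that("the codon rate matrix has the documented structure", {
  # omega = 0 kills every nonsynonymous rate
  spec <- codon_model_spec(kappa = 3)
  Q0 <- build_codon_matrix(spec, 0)
  tab <- codon_tables_for_tests()
  aa <- setNames(tab$aa, tab$codons)
  for (i in seq_len(61)) for (j in seq_len(61)) {
    if (i != j && aa[i] != aa[j]) expect_identical(Q0[i, j], 0)
  }

  # multi-nucleotide changes always have rate zero
  Q <- build_codon_matrix(spec, 0.7)
  nt <- do.call(rbind, strsplit(tab$codons, ""))
  for (i in seq_len(61)) {
    far <- which(colSums(t(nt) != nt[i, ]) > 1)
    expect_true(all(Q[i, far] == 0))
  }

  # zero row sums and unit expected rate for a random spec
  set.seed(4)
  f <- runif(61); f <- f / sum(f)
  spec_r <- codon_model_spec(kappa = runif(1, 0.5, 5), freqs = f)
  Qr <- build_codon_matrix(spec_r, runif(1, 0, 3))
  expect_lt(max(abs(rowSums(Qr))), 1e-12)
  expect_equal(-sum(f * diag(Qr)), 1, tolerance = 1e-12)

  # kappa = 1, omega = 1, uniform frequencies: symmetric rates, uniform
  # stationary distribution (left null vector)
  Qs <- build_codon_matrix(codon_model_spec(kappa = 1, omega = 1, weights = 1), 1)
  expect_lt(max(abs(Qs - t(Qs))), 1e-12)
  expect_lt(max(abs(rep(1 / 61, 61) %*% Qs)), 1e-12)
})

test_that("pruning equals closed-form and exhaustive-enumeration oracles", {
  # 2 taxa, single omega: against the scalar matrix-exponential formula
  spec <- codon_model_spec(kappa = 2.5, omega = 0.5, weights = 1)
  tab <- codon_tables_for_tests()
  two <- parse_newick("(A:0.4,B:0.7);")
  aln2 <- c(A = tab$codons[5], B = tab$codons[17])
  Q <- build_codon_matrix(spec, 0.5)
  P1 <- as.matrix(Matrix::expm(Q * 0.4)); P2 <- as.matrix(Matrix::expm(Q * 0.7))
  oracle <- log(sum(spec$freqs * P1[, 5] * P2[, 17]))
  expect_equal(log_likelihood(aln2, two, spec), oracle, tolerance = 1e-10)

  # 4 taxa x 2 sites: full enumeration over all internal-state assignments
  tr <- oracle_tree_4tax()
  aln <- simulate_codon_alignment(tr, spec, length_codons = 50, seed = 3)
  seqs <- convsel:::decode_codon_alignment(aln)
  seqs <- vapply(seqs, substr, character(1), 1, 6)  # 2 codon sites
  expect_lt(abs(log_likelihood(seqs, tr, spec) - oracle_loglik_4tax(seqs, spec, 0.5)),
            1e-8)

  # mixture likelihood = weighted per-category enumeration
  mix <- codon_model_spec(kappa = 2.5, omega = c(0.1, 1, 2), weights = c(0.5, 0.3, 0.2))
  per_cat <- sapply(mix$omega, function(w) {
    sp1 <- codon_model_spec(kappa = 2.5, freqs = mix$freqs, omega = w, weights = 1)
    # per-site likelihoods recovered from per-site enumeration
    sapply(c(1, 4), function(start) {
      s1 <- vapply(seqs, substr, character(1), start, start + 2)
      exp(oracle_loglik_4tax(s1, sp1, w))
    })
  })
  oracle_mix <- sum(log(per_cat %*% mix$weights))
  expect_lt(abs(log_likelihood(seqs, tr, mix) - oracle_mix), 1e-8)
})

test_that("likelihood obeys site independence, order invariance and missing data", {
  spec <- codon_model_spec()
  tr <- oracle_tree_4tax()
  aln <- simulate_codon_alignment(tr, spec, length_codons = 60, seed = 8)
  seqs <- convsel:::decode_codon_alignment(aln)

  # duplicating every site doubles the log-likelihood
  doubled <- vapply(seqs, function(s) paste0(s, s), character(1))
  expect_equal(log_likelihood(doubled, tr, spec),
               2 * log_likelihood(seqs, tr, spec), tolerance = 1e-8)

  # invariant to sequence order
  expect_equal(log_likelihood(seqs[c(3, 1, 4, 2)], tr, spec),
               log_likelihood(seqs, tr, spec), tolerance = 1e-10)

  # an all-missing codon contributes zero information
  gap <- seqs
  gap[] <- paste0(vapply(gap, substr, character(1), 1, nchar(gap[1]) - 3), "NNN")
  plain <- vapply(seqs, substr, character(1), 1, nchar(seqs[1]) - 3)
  expect_equal(log_likelihood(gap, tr, spec), log_likelihood(plain, tr, spec),
               tolerance = 1e-8)

  # species absent from the tree is a validation error
  bad <- seqs; names(bad)[1] <- "ZZZ"
  expect_error(log_likelihood(bad, tr, spec), "absent from tree")
})
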