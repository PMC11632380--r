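test_that("generate_species_tree gives a seeded unit-depth pure-birth tree", {
  tr <- generate_species_tree(27, seed = 1)
  expect_equal(ape::Ntip(tr), 27)
  expect_equal(tr$Nnode, 26)  # binary rooted
  depths <- ape::node.depth.edgelength(tr)[1:27]
  expect_equal(max(depths), 1, tolerance = 1e-12)
  expect_identical(write_newick(generate_species_tree(10, seed = 7)),
                   write_newick(generate_species_tree(10, seed = 7)))
  expect_error(generate_species_tree(3), ">= 4")
})

test_that("assign_foreground respects mode, count and confound structure", {
  tr <- generate_species_tree(12, seed = 2)
  tt <- assign_foreground(tr, 5, mode = "dispersed", seed = 3)
  expect_equal(sum(tt$foreground), 5)
  expect_setequal(tt$species, tr$tip.label)
  expect_identical(tt, assign_foreground(tr, 5, mode = "dispersed", seed = 3))
  expect_true(all(tt$prepupal_diapause[tt$foreground] == "no"))
  expect_error(assign_foreground(tr, 12, seed = 1), "n_foreground < number")

  # clustered mode fills a whole clade when one of exactly the right size exists
  tr3 <- parse_newick("(((A:1,B:1):1,C:2):1,(D:1,E:1):2);")
  tt3 <- assign_foreground(tr3, 3, mode = "clustered", seed = 1)
  expect_setequal(foreground_species(tt3), c("A", "B", "C"))

  # the sociality confounder associates with foreground status
  big <- generate_species_tree(40, seed = 5)
  tb <- assign_foreground(big, 20, mode = "dispersed", seed = 5,
                          p_social_fg = 1, p_social_bg = 0)
  expect_true(all(tb$sociality[tb$foreground] == "social"))
  expect_true(all(tb$sociality[!tb$foreground] == "solitary"))
})

test_that("simulate_gene_trees plants exactly the requested rate shifts", {
  tr <- generate_species_tree(10, seed = 4)
  tt <- assign_foreground(tr, 4, mode = "dispersed", seed = 4)
  fg <- foreground_species(tt)

  # degenerate parameters: every gene tree proportional to the master
  g0 <- simulate_gene_trees(tr, tt, 5, shift_fraction = 0, multiplier = 1,
                            noise_sd = 0, gene_rate_sd = 0.4, seed = 1)
  for (gt in g0$trees) {
    ratio <- gt$edge.length / tr$edge.length
    expect_lt(diff(range(ratio)), 1e-12)
  }

  # multiplier 3, no noise: foreground terminal branches exactly 3x
  g3 <- simulate_gene_trees(tr, tt, 10, shift_fraction = 1, multiplier = 3,
                            noise_sd = 0, gene_rate_sd = 0, seed = 2)
  bt <- branch_table(tr, foreground = fg)
  for (gt in g3$trees) {
    gbt <- branch_table(gt)
    ratio <- gbt$length / bt$length
    expect_equal(unname(ratio[bt$foreground]), rep(3, sum(bt$foreground)))
    expect_equal(unname(ratio[!bt$foreground]), rep(1, sum(!bt$foreground)))
  }

  # shift bookkeeping
  g <- simulate_gene_trees(tr, tt, 100, shift_fraction = 0.2, seed = 3)
  expect_equal(sum(g$truth$shifted), 20)
})

test_that("codon simulation honours K, omega = 0 and stationarity", {
  spec1 <- codon_model_spec(omega = 1, weights = 1)
  tr <- generate_species_tree(5, seed = 6)
  # K = 1: foreground flag changes nothing (identical seeded draws)
  a1 <- simulate_codon_alignment(tr, spec1, foreground_K = 1, length_codons = 60,
                                 seed = 9, test_branches = c("sp01", "sp02"))
  a2 <- simulate_codon_alignment(tr, spec1, foreground_K = 1, length_codons = 60,
                                 seed = 9)
  expect_identical(a1$states, a2$states)

  # omega = 0 on a long two-taxon branch: only synonymous differences
  two <- parse_newick("(X:2,Y:2);")
  s0 <- codon_model_spec(omega = 0, weights = 1)
  a0 <- simulate_codon_alignment(two, s0, length_codons = 200, seed = 10)
  seqs <- convsel:::decode_codon_alignment(a0)
  expect_identical(oracle_translate(seqs[["X"]]), oracle_translate(seqs[["Y"]]))
  expect_false(identical(seqs[["X"]], seqs[["Y"]]))  # but sequences did diverge

  # empirical codon frequencies approach the stationary distribution
  near0 <- parse_newick("(P:0.000001,Q:0.000001);")
  sp <- codon_model_spec()
  big <- simulate_codon_alignment(near0, sp, length_codons = 10000, seed = 11)
  emp <- tabulate(big$states["P", ], nbins = 61) / 10000
  expect_lt(max(abs(emp - sp$freqs)), 0.008)

  expect_error(simulate_codon_alignment(two, sp, length_codons = 30), ">= 50")
  expect_error(simulate_codon_alignment(two, sp, foreground_K = 0), "> 0")
  expect_error(codon_model_spec(freqs = rep(1 / 61, 61) + 1e-3), "sum to 1")
})

test_that("generate_og_counts plants the documented loss patterns", {
  tr <- generate_species_tree(12, seed = 8)
  tt <- assign_foreground(tr, 6, mode = "dispersed", seed = 8)
  oc <- generate_og_counts(tr$tip.label, tt, n_families = 30, seed = 12)
  cm <- as.matrix(oc$counts)
  fg <- foreground_species(tt)
  bg <- setdiff(tr$tip.label, fg)

  uni <- oc$truth$orthogroup[oc$truth$scenario == "universal_single_copy"]
  expect_true(all(cm[uni, ] == 1))

  ptth <- oc$truth$orthogroup[oc$truth$scenario == "lost_foreground_except_one"]
  exc <- oc$truth$exception[oc$truth$scenario == "lost_foreground_except_one"]
  expect_true(exc %in% fg)
  expect_true(all(cm[ptth, setdiff(fg, exc)] == 0))
  expect_gt(cm[ptth, exc], 0)
  expect_true(all(cm[ptth, bg] >= 1))

  big_fam <- oc$truth$orthogroup[oc$truth$scenario == "large_family"]
  expect_gte(sum(cm[big_fam, ]), 100)
})
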