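test_that("compute_rers is scale-invariant and localizes single-branch shifts", {
  master <- parse_newick("((A:0.4,B:0.3):0.2,(C:0.5,D:0.6):0.1);")

  # gene tree = master x 2: all residuals 0 (scaling absorbed)
  g2 <- master; g2$edge.length <- master$edge.length * 2
  rer <- compute_rers(list(OG1 = g2), master)
  expect_lt(max(abs(rer[!is.na(rer[, 1]), 1])), 1e-10)

  # one branch x 10: that branch carries the unique largest residual
  g10 <- master
  bt <- branch_table(master)
  i <- which(bt$branch_id == "A")
  g10$edge.length[i] <- g10$edge.length[i] * 10
  rer10 <- compute_rers(list(OG1 = g10), master)
  expect_identical(rownames(rer10)[which.max(rer10[, 1])], "A")

  # invariance to positive rescaling of a gene tree (property, several seeds)
  for (seed in 1:10) {
    gt <- with_seed_test(seed, {
      g <- master
      g$edge.length <- g$edge.length * exp(rnorm(length(g$edge.length), 0, 0.4))
      g
    })
    gs <- gt; gs$edge.length <- gs$edge.length * 7.3
    r1 <- compute_rers(list(a = gt), master)
    r2 <- compute_rers(list(a = gs), master)
    expect_equal(r1, r2, tolerance = 1e-9)
  }

  # missing species: its row is NA, others present
  g_miss <- ape::drop.tip(g2, "D")
  rer_m <- compute_rers(list(OG1 = g_miss), master, min_branches = 3)
  expect_true(is.na(rer_m["D", 1]))
  expect_false(anyNA(rer_m[c("A", "B", "C"), 1]))

  # too few branches: orthogroup flagged, all missing
  tiny <- compute_rers(list(OG1 = g2), master, min_branches = 10)
  expect_true(all(is.na(tiny)))
  expect_identical(attr(tiny, "flagged"), "OG1")
})

test_that("correlate_binary matches the exact rank-sum distribution", {
  master <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  traits <- make_traits(master, c("A", "B"))
  rers <- matrix(c(3, 4, 1, 2), 4, 1, dimnames = list(c("A", "B", "C", "D"), "OG1"))

  r <- correlate_binary(rers, traits)
  expect_equal(r$rho, 1)                      # complete separation upward
  expect_equal(r$p_parametric, 2 / 6)         # 2 of C(4,2) splits as extreme

  rers_dn <- rers; rers_dn[, 1] <- c(1, 2, 3, 4)
  expect_equal(correlate_binary(rers_dn, traits)$rho, -1)  # Rho- mirror

  rers_tie <- rers; rers_tie[, 1] <- c(5, 5, 5, 5)
  expect_equal(correlate_binary(rers_tie, traits)$rho, 0)

  # insufficient branches -> untestable
  rers_na <- rers; rers_na["A", 1] <- NA
  expect_false(correlate_binary(rers_na, traits)$testable)
})

test_that("permulated sets respect phylogeny and the empirical-p definition holds", {
  # sister species co-assigned more often than distant pairs on a two-clade tree
  tr <- parse_newick("((A:0.05,B:0.05):0.95,(C:0.05,D:0.05):0.95);")
  perms <- permulate_binary(tr, 2, n_perm = 2000, seed = 5)
  expect_equal(nrow(perms), 2000)
  expect_equal(unname(rowSums(perms)), rep(2, 2000))
  co_sister <- mean(perms[, "A"] & perms[, "B"]) + mean(perms[, "C"] & perms[, "D"])
  co_cross <- mean(perms[, "A"] & perms[, "C"]) + mean(perms[, "B"] & perms[, "D"])
  expect_gt(co_sister, co_cross * 2)
  expect_error(permulate_binary(tr, 4), "< number of tips")

  # hand-checked empirical p-values
  nulls <- matrix(c(0.1, 0.5, 2.5, -3.0), 4, 1, dimnames = list(NULL, "og"))
  expect_equal(empirical_pvalues(c(og = 2.0), nulls)$p_permulation, 0.5)
  expect_equal(empirical_pvalues(c(og = 0), nulls)$p_permulation, 1)
  e0 <- empirical_pvalues(c(og = 99), nulls)
  expect_equal(e0$p_permulation, 0)
  expect_true(e0$at_floor)
  expect_equal(empirical_pvalues(c(og = 99), nulls, pseudo = TRUE)$p_permulation, 1 / 5)
})

test_that("p-value adjustment matches hand-computed step procedures", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  expect_equal(adjust_pvalues(c(0.01, 0.04), "holm"), c(0.02, 0.04))
  expect_equal(adjust_pvalues(0.03, "BH"), 0.03)
  expect_equal(adjust_pvalues(0.03, "holm"), 0.03)
  expect_error(adjust_pvalues(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("rer_scan recovers planted shifts with power increasing in the multiplier", {
  tr <- generate_species_tree(27, seed = 31)
  tt <- assign_foreground(tr, 17, mode = "clustered", seed = 31)
  power_at <- function(mult) {
    g <- simulate_gene_trees(tr, tt, 60, shift_fraction = 0.5, multiplier = mult,
                             noise_sd = 0.25, seed = 32)
    scan <- rer_scan(g$trees, tr, tt, n_perm = 200, seed = 33)
    shifted <- g$truth$orthogroup[g$truth$shifted]
    hits <- scan$orthogroup[!is.na(scan$q_bh) & scan$q_bh < 0.05]
    length(intersect(hits, shifted)) / length(shifted)
  }
  p15 <- power_at(1.5); p2 <- power_at(2); p3 <- power_at(3)
  expect_true(p15 <= p2 && p2 <= p3)
  expect_gt(p3, 0.5)

  # sign property: shifted orthogroups trend Rho+ (acceleration)
  g3 <- simulate_gene_trees(tr, tt, 40, shift_fraction = 1, multiplier = 3,
                            noise_sd = 0.25, seed = 34)
  scan3 <- rer_scan(g3$trees, tr, tt, n_perm = 100, seed = 35)
  expect_gt(median(scan3$rho, na.rm = TRUE), 0)
})
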