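toy_counts <- function(rows) {
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("OG%02d", seq_along(rows))
  colnames(m) <- sprintf("sp%d", seq_len(ncol(m)))
  m
}

test_that("filter_single_copy applies the presence and 70%-ceiling rules", {
  cm <- toy_counts(list(c(1, 1, 1, 1),   # all single-copy -> retained
                        c(1, 1, 2, 1),   # 3 of 4 single, ceil(0.7*4)=3 -> retained
                        c(1, 0, 1, 1),   # absent in one species -> dropped
                        c(2, 2, 1, 1)))  # only 2 single -> dropped
  res <- filter_single_copy(cm, 0.7)
  expect_setequal(res$retained, c("OG01", "OG02"))
  expect_identical(res$excluded[["OG01"]], character(0))
  expect_identical(res$excluded[["OG02"]], "sp3")
  expect_equal(res$n_single_required, 3)

  # idempotence: filtering the retained rows changes nothing
  res2 <- filter_single_copy(cm[res$retained, , drop = FALSE], 0.7)
  expect_identical(res2$retained, res$retained)

  # retained-set size is monotone non-increasing in the threshold
  cm2 <- toy_counts(lapply(1:20, function(i) rpois(6, 1) + 1))
  sizes <- sapply(c(0.3, 0.5, 0.7, 0.9, 1), function(f) {
    length(filter_single_copy(cm2, f)$retained)
  })
  expect_true(all(diff(sizes) <= 0))

  # retained orthogroups are always present in all species
  expect_true(all(rowSums(cm2[filter_single_copy(cm2, 0.5)$retained, ] >= 1) == 6))

  expect_error(filter_single_copy(cm[0, ]), "empty")
})

test_that("filter_alignment_columns removes strictly-over-threshold columns", {
  seqs <- c(a = "A-A-", b = "A-AA", c = "ANA-", d = "AAA-")
  # per column missing fractions: 0, 0.75, 0.25 (one N), 0.75
  out <- filter_alignment_columns(seqs, 0.5)
  expect_identical(as.character(out), c("AA", "AA", "AA", "AA"))
  expect_equal(attr(out, "n_removed"), 2)

  # exactly 50% missing is kept ("over 50%" is strict)
  seqs2 <- c(a = "A-", b = "A-", c = "AA", d = "AA")
  out2 <- filter_alignment_columns(seqs2, 0.5)
  expect_identical(as.character(out2), c("A-", "A-", "AA", "AA"))

  # gapless alignment unchanged
  seqs3 <- c(a = "ACGT", b = "ACGT")
  expect_identical(as.character(filter_alignment_columns(seqs3)), unname(seqs3))

  # everything removed: warning + skip flag
  seqs4 <- c(a = "--", b = "--", c = "AA")
  expect_warning(out4 <- filter_alignment_columns(seqs4, 0.5), "skipped")
  expect_true(attr(out4, "skipped"))
})

test_that("screen_family_loss removes big families then flags trait losses", {
  tr <- generate_species_tree(8, seed = 20)
  tt <- assign_foreground(tr, 4, mode = "dispersed", seed = 20)
  fg <- foreground_species(tt)
  bg <- setdiff(tr$tip.label, fg)

  cm <- matrix(0L, 4, 8, dimnames = list(c("lostfg", "universal", "big", "excfg"),
                                         tr$tip.label))
  cm["lostfg", bg] <- 1L
  cm["universal", ] <- 1L
  cm["big", ] <- 15L                       # 120 genes -> removed by size filter
  cm["excfg", bg] <- 1L
  cm["excfg", fg[1]] <- 2L                 # lost in all foreground except one

  hits <- screen_family_loss(cm, tt, max_family_size = 100)
  expect_setequal(hits$orthogroup, c("lostfg", "excfg"))
  expect_true(all(hits$pattern == "lost_in_foreground"))
  expect_identical(hits$exceptions[hits$orthogroup == "excfg"], fg[1])
  expect_identical(hits$exceptions[hits$orthogroup == "lostfg"], "")

  # strict-majority alternative catches losses all-but-one misses
  tr10 <- generate_species_tree(10, seed = 21)
  tt10 <- assign_foreground(tr10, 5, mode = "dispersed", seed = 21)
  fg10 <- foreground_species(tt10)
  cm2 <- matrix(1L, 1, 10, dimnames = list("halflost", tr10$tip.label))
  cm2[1, fg10[1:3]] <- 0L                  # lost in 3 of 5 foreground
  expect_equal(nrow(screen_family_loss(cm2, tt10, majority_rule = "all_but_m")), 0)
  hits2 <- screen_family_loss(cm2, tt10, majority_rule = "strict_majority")
  expect_identical(hits2$orthogroup, "halflost")

  # losses in the background group are reported symmetrically
  cm3 <- matrix(0L, 1, 8, dimnames = list("lostbg", tr$tip.label))
  cm3[1, fg] <- 1L
  expect_identical(screen_family_loss(cm3, tt)$pattern, "lost_in_background")
})
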