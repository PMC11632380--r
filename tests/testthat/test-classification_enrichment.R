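test_that("classify_selection reproduces the worked set algebra", {
  calls <- selection_calls(rho_pos = c("A", "B"), rho_neg = "C",
                           absrel = c("B", "D"), relaxed = c("A", "E"),
                           intensified = c("C", "F"))
  cat <- classify_selection(calls)
  expect_setequal(cat$possible_positive, c("B", "D"))
  expect_setequal(cat$possible_purifying, "C")
  expect_setequal(cat$possible_relaxed, "E")
  expect_setequal(cat$possible_intensified, "F")
  expect_setequal(cat$best_positive, "B")
  expect_setequal(cat$best_purifying, "C")

  # all-empty input
  empty <- classify_selection(selection_calls())
  expect_true(all(lengths(empty) == 0))

  # an orthogroup both Rho+ and relaxed lands in neither category
  both <- classify_selection(selection_calls(rho_pos = "A", relaxed = "A"))
  expect_false("A" %in% both$possible_positive)
  expect_false("A" %in% both$possible_relaxed)

  expect_error(selection_calls(rho_pos = "A", rho_neg = "A"), "Rho")
  expect_error(selection_calls(relaxed = "A", intensified = "A"), "relaxed")
})

test_that("the four possible categories are pairwise disjoint for random call sets", {
  set.seed(99)
  pool <- sprintf("OG%03d", 1:40)
  for (i in 1:1000) {
    rer_sig <- sample(pool, sample(0:15, 1))
    rho_pos <- sample(rer_sig, rbinom(1, length(rer_sig), 0.5))
    k_sig <- sample(pool, sample(0:15, 1))
    relaxed <- sample(k_sig, rbinom(1, length(k_sig), 0.5))
    calls <- selection_calls(rho_pos = rho_pos,
                             rho_neg = setdiff(rer_sig, rho_pos),
                             absrel = sample(pool, sample(0:10, 1)),
                             relaxed = relaxed,
                             intensified = setdiff(k_sig, relaxed))
    cat <- classify_selection(calls)
    four <- cat[c("possible_positive", "possible_purifying",
                  "possible_relaxed", "possible_intensified")]
    all_m <- unlist(four)
    expect_equal(anyDuplicated(all_m), 0)
    # conservation: Rho+ and Rho- partition the RER-significant set
    expect_equal(length(calls$rho_pos) + length(calls$rho_neg), length(rer_sig))
    # monotonicity: adding an orthogroup to relaxed never adds it to
    # possible_positive
    if (length(cat$possible_positive) > 0) {
      og <- cat$possible_positive[1]
      calls2 <- selection_calls(rho_pos = calls$rho_pos, rho_neg = calls$rho_neg,
                                absrel = calls$absrel,
                                relaxed = union(calls$relaxed, og),
                                intensified = setdiff(calls$intensified, og))
      expect_false(og %in% classify_selection(calls2)$possible_positive)
    }
  }
})

test_that("term enrichment matches hypergeometric enumeration and its filters", {
  # N=20, K=6, n=8, k=5 worked example
  ann <- data.frame(
    orthogroup = c(sprintf("S%02d", 1:20), sprintf("S%02d", 1:6)),
    term = c(rep("base", 20), rep("T1", 6)))
  study <- sprintf("S%02d", c(1:5, 15:17))   # 5 of the 6 T1 members
  res <- fisher_term_enrichment(ann, study, alpha = 0.01, min_annotated = 5)
  expect_equal(res$p[res$term == "T1"], oracle_hyper_upper(5, 6, 8, 20),
               tolerance = 1e-12)
  expect_equal(res$k[res$term == "T1"], 5)

  # terms with K <= min_annotated are not tested
  ann2 <- rbind(ann, data.frame(orthogroup = sprintf("S%02d", 1:5), term = "small"))
  expect_false("small" %in% fisher_term_enrichment(ann2, study)$term)

  # study = universe: every tested term has p = 1
  res_all <- fisher_term_enrichment(ann, sprintf("S%02d", 1:20))
  expect_true(all(abs(res_all$p - 1) < 1e-12))

  expect_error(fisher_term_enrichment(ann, "NOT_THERE"), "outside the universe")
  expect_warning(out <- fisher_term_enrichment(ann, character(0)), "empty study")
  expect_equal(nrow(out), 0)
})

test_that("overlap_test gives exact upper-tail hypergeometric probabilities", {
  u <- sprintf("G%02d", 1:10)
  r <- overlap_test(u[1:5], u[c(1:4)], u)   # N=10, K=4, n=5, k=4
  expect_equal(r$p, 6 / 252, tolerance = 1e-12)
  expect_equal(overlap_test(u[5:9], u[1:4], u)$p, 1)          # k = 0
  expect_equal(overlap_test(u, u[1:4], u)$p, 1)               # n = N forces k = K
  expect_error(overlap_test(u[1], u[2], character(0)), "universe is empty")
})
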