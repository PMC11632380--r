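test_that("PGLS with identity covariance equals OLS exactly", {
  star <- parse_newick("(a:1,b:1,c:1,d:1,e:1,f:1,g:1,h:1);")
  set.seed(7)
  tra <- data.frame(species = star$tip.label,
                    presence = c(0, 1, 0, 1, 1, 0, 1, 1),
                    diapause = c("yes", "no", "yes", "no", "no", "yes", "no", "yes"),
                    x = rnorm(8))
  fit <- pgls_fit(star, tra, "presence", c("diapause", "x"))
  ols <- lm(presence ~ diapause + x, tra)
  expect_equal(unname(fit$coefficients$estimate), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(unname(fit$coefficients$p),
               unname(summary(ols)$coefficients[, 4]), tolerance = 1e-10)
  expect_equal(fit$r_squared, summary(ols)$r.squared, tolerance = 1e-10)
})

test_that("PGLS validates its inputs", {
  tr <- generate_species_tree(8, seed = 50)
  tra <- data.frame(species = tr$tip.label,
                    presence = rep(1, 8),
                    diapause = rep(c("yes", "no"), 4))
  expect_error(pgls_fit(tr, tra, "presence", "diapause"), "constant")
  tra$presence <- c(0, 1, 0, 1, 0, 1, 0, 1)
  tra$dup <- tra$diapause
  expect_error(pgls_fit(tr, tra, "presence", c("diapause", "dup")), "collinear")
  tra$presence[1] <- 2
  expect_error(pgls_fit(tr, tra, "presence", "diapause"), "0/1")
})

test_that("PGLS down-weights phylogenetically clustered coincidences", {
  # two deep clades; response and predictor both perfectly split by clade
  tr <- parse_newick(paste0("((a:0.05,b:0.05,c:0.05,d:0.05):0.95,",
                            "(e:0.05,f:0.05,g:0.05,h:0.05):0.95);"))
  tra <- data.frame(species = letters[1:8],
                    presence = c(1, 1, 1, 0, 0, 0, 0, 1),
                    diapause = rep(c("no", "yes"), each = 4))
  fit <- pgls_fit(tr, tra, "presence", "diapause")
  star <- parse_newick("(a:1,b:1,c:1,d:1,e:1,f:1,g:1,h:1);")
  fit_star <- pgls_fit(star, tra, "presence", "diapause")
  # the Brownian covariance makes the clade-confounded association far less
  # certain than under independence
  expect_gt(fit$coefficients$p[2], fit_star$coefficients$p[2])
})

test_that("Fisher 2x2 matches enumeration over all tables with the margins", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(2, 2, 2, 2), 2)), 1)
  expect_warning(p0 <- fisher_exact_2x2(matrix(c(10, 10, 0, 0), 2)), "zero margin")
  expect_equal(p0, 1)

  set.seed(11)
  for (i in 1:50) {
    tab <- matrix(sample(0:6, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab), oracle_fisher_2x2(tab), tolerance = 1e-9)
  }
})

test_that("reciprocal best hits apply the documented reduction and tie-breaks", {
  hit <- function(q, s, bits, ev = 1e-50) {
    data.frame(qseqid = q, sseqid = s, evalue = ev, bitscore = bits)
  }
  # a1 <-> b1 mutual best: retained; a2 -> b2 best but b2 -> a3: excluded
  ab <- rbind(hit("a1", "b1", 200), hit("a1", "b2", 150),
              hit("a2", "b2", 180))
  ba <- rbind(hit("b1", "a1", 190), hit("b2", "a3", 170),
              hit("b2", "a2", 160))
  rbh <- reciprocal_best_hits(ab, ba)
  expect_identical(rbh$a, "a1")
  expect_identical(rbh$b, "b1")

  # symmetry: swapping the tables mirrors the pair set
  rbh_rev <- reciprocal_best_hits(ba, ab)
  expect_identical(rbh_rev$a, "b1")
  expect_identical(rbh_rev$b, "a1")

  # bit-score tie broken by e-value, then lexicographic subject id
  ab2 <- rbind(hit("a1", "b2", 100, 1e-30), hit("a1", "b1", 100, 1e-40))
  ba2 <- rbind(hit("b1", "a1", 90), hit("b2", "a1", 95))
  expect_identical(reciprocal_best_hits(ab2, ba2)$b, "b1")  # e-value wins
  ab3 <- rbind(hit("a1", "b2", 100), hit("a1", "b1", 100))
  expect_identical(reciprocal_best_hits(ab3, ba2)$b, "b1")  # lexicographic
})

test_that("hit tables respect the e-value cutoff on read", {
  tf <- tempfile(fileext = ".tsv")
  rows <- data.frame(q = c("x1", "x2"), s = c("y1", "y2"), pid = 90, len = 100,
                     mm = 1, go = 0, qs = 1, qe = 100, ss = 1, se = 100,
                     ev = c(1e-50, 1e-5), bs = c(200, 150))
  write.table(rows, tf, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  tab <- read_hit_table(tf)
  expect_identical(tab$qseqid, "x1")
})
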