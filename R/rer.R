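# Relative evolutionary rates (RER), trait correlation on terminal branches,
# and the permulation null (phylogenetically constrained permutations).

#' Compute relative evolutionary rates per orthogroup
#'
#' For each gene tree, branch lengths are matched to the master (species)
#' tree by the clade of tip labels below each branch (missing species are
#' allowed; matching is done on the restriction of master clades to the
#' species present). Gene and master lengths are floored at 1e-9 and
#' log-transformed, and the RERs are the residuals of an ordinary
#' least-squares fit of gene log-lengths on master log-lengths (free slope
#' and intercept, so proportional rescaling of a gene tree leaves the RERs
#' unchanged).
#'
#' @param gene_trees named list of `phylo` gene trees (names = orthogroup ids).
#' @param master_tree the species tree (`phylo`).
#' @param min_branches orthogroups with fewer usable branches are flagged and
#'   left missing (default 5).
#' @return a branch x orthogroup numeric matrix (rownames = master branch
#'   ids, i.e. child-node labels); attribute `flagged` lists skipped
#'   orthogroups.
#' @export
compute_rers <- function(gene_trees, master_tree, min_branches = 5) {
  assert_that(is.list(gene_trees) && length(gene_trees) >= 1L && !is.null(names(gene_trees)),
              "gene_trees must be a non-empty named list")
  master_tree <- ensure_node_labels(validate_tree(master_tree))
  m_clades <- clade_tip_sets(master_tree)
  m_ids <- names(m_clades)
  m_sizes <- vapply(m_clades, length, integer(1))
  m_len <- setNames(master_tree$edge.length, m_ids)
  out <- matrix(NA_real_, length(m_ids), length(gene_trees),
                dimnames = list(m_ids, names(gene_trees)))
  flagged <- character(0)
  for (g in seq_along(gene_trees)) {
    gt <- gene_trees[[g]]
    present <- gt$tip.label
    bad <- setdiff(present, master_tree$tip.label)
    assert_that(length(bad) == 0L,
                paste0("gene tree species absent from master tree: ",
                       paste(bad, collapse = ", ")))
    g_clades <- clade_tip_sets(ensure_node_labels(gt))
    g_len <- setNames(gt$edge.length, names(g_clades))
    g_keys <- vapply(g_clades, paste, character(1), collapse = "\r")
    # restrict master clades to the species present in this gene tree and
    # resolve duplicates child-most (smallest full clade)
    r_keys <- vapply(m_clades, function(s) paste(intersect(s, present), collapse = "\r"),
                     character(1))
    match_for <- rep(NA_character_, length(g_keys))
    for (i in seq_along(g_keys)) {
      cand <- which(r_keys == g_keys[i] & nzchar(r_keys))
      if (length(cand)) match_for[i] <- m_ids[cand[which.min(m_sizes[cand])]]
    }
    ok <- !is.na(match_for)
    if (sum(ok) < min_branches) {
      flagged <- c(flagged, names(gene_trees)[g])
      next
    }
    x <- log(pmax(m_len[match_for[ok]], 1e-9))
    y <- log(pmax(g_len[ok], 1e-9))
    vx <- sum((x - mean(x))^2)
    b <- if (vx > 0) sum((x - mean(x)) * (y - mean(y))) / vx else 0
    a <- mean(y) - b * mean(x)
    out[match_for[ok], g] <- y - (a + b * x)
  }
  attr(out, "flagged") <- flagged
  out
}

#' Correlate RERs with the binary foreground trait on terminal branches
#'
#' Only terminal branches enter the correlation. The statistic rho is a
#' rescaled Mann-Whitney statistic in \[-1, 1\] (Cliff's delta): positive
#' when foreground branches carry higher RERs (accelerated evolution, Rho+),
#' negative when they are slower (increased constraint, Rho-). The
#' parametric p-value comes from the exact rank-sum distribution when
#' `min(n_fg, n_bg) <= 10` (and there are no ties), otherwise from the
#' normal approximation with tie correction.
#'
#' @param rers branch x orthogroup matrix from [compute_rers()].
#' @param traits trait table ([assign_foreground()]); rows of `rers` named by
#'   species give the terminal branches.
#' @return data.frame with columns `orthogroup`, `rho`, `p_parametric`,
#'   `n_fg`, `n_bg`, `testable`.
#' @export
correlate_binary <- function(rers, traits) {
  fg <- foreground_species(traits)
  species <- intersect(rownames(rers), traits$species)
  assert_that(length(species) >= 4L, "need >= 4 terminal branches in the RER matrix")
  res <- lapply(colnames(rers), function(og) {
    v <- rers[species, og]
    keep <- !is.na(v)
    x1 <- v[keep & species %in% fg]
    x0 <- v[keep & !(species %in% fg)]
    if (length(x1) < 2L || length(x0) < 2L) {
      return(data.frame(orthogroup = og, rho = NA_real_, p_parametric = NA_real_,
                        n_fg = length(x1), n_bg = length(x0), testable = FALSE))
    }
    r <- rank(c(x1, x0))
    U <- sum(r[seq_along(x1)]) - length(x1) * (length(x1) + 1) / 2
    rho <- 2 * U / (length(x1) * length(x0)) - 1
    p <- suppressWarnings(
      wilcox.test(x1, x0, exact = min(length(x1), length(x0)) <= 10,
                  correct = TRUE)$p.value
    )
    data.frame(orthogroup = og, rho = rho, p_parametric = p,
               n_fg = length(x1), n_bg = length(x0), testable = TRUE)
  })
  do.call(rbind, res)
}

#' Generate permulated foreground sets
#'
#' The permulation null respects phylogenetic covariance: each replicate
#' simulates Brownian motion on the master tree, ranks the tip values
#' (ties broken by a seeded random tie-break), and assigns the foreground
#' label to the `n_foreground` top-ranked tips.
#'
#' @param master_tree species tree (`phylo`).
#' @param n_foreground number of foreground species per replicate (< tips).
#' @param n_perm number of replicates (default 1000).
#' @param seed optional integer seed.
#' @param sigma2 Brownian rate (only ranks matter; default 1).
#' @return a logical `n_perm x n_species` matrix (colnames = species); each
#'   row is one permulated foreground set.
#' @export
permulate_binary <- function(master_tree, n_foreground, n_perm = 1000,
                             seed = NULL, sigma2 = 1) {
  validate_tree(master_tree)
  n_tip <- ape::Ntip(master_tree)
  assert_that(n_foreground >= 1 && n_foreground < n_tip,
              "need 1 <= n_foreground < number of tips")
  with_seed(seed, {
    out <- matrix(FALSE, n_perm, n_tip, dimnames = list(NULL, master_tree$tip.label))
    for (b in seq_len(n_perm)) {
      v <- simulate_brownian(master_tree, sigma2 = sigma2)
      r <- rank(v, ties.method = "random")
      out[b, r > n_tip - n_foreground] <- TRUE
    }
    out
  })
}

# Null rho statistics: for each orthogroup, recompute rho against every
# permulated foreground set, restricted to the orthogroup's non-missing
# terminal branches. Vectorized over replicates.
null_correlations <- function(rers, perms, species = colnames(perms)) {
  species <- intersect(rownames(rers), species)
  n_perm <- nrow(perms)
  out <- matrix(NA_real_, n_perm, ncol(rers), dimnames = list(NULL, colnames(rers)))
  for (og in colnames(rers)) {
    v <- rers[species, og]
    keep <- which(!is.na(v))
    if (length(keep) < 4L) next
    r <- rank(v[keep])
    Pm <- perms[, species[keep], drop = FALSE]
    n1 <- rowSums(Pm)
    n2 <- length(keep) - n1
    sumr <- as.numeric(Pm %*% r)
    U <- sumr - n1 * (n1 + 1) / 2
    rho <- 2 * U / (n1 * n2) - 1
    rho[n1 < 2 | n2 < 2] <- NA_real_
    out[, og] <- rho
  }
  out
}

#' Empirical p-values from a permulation null
#'
#' `p = #\{|null| >= |observed|\} / #non-missing nulls` per orthogroup
#' (two-sided extremity on the absolute statistic). A p of exactly 0 is
#' reported as 0 and flagged; set `pseudo = TRUE` for the (1+k)/(1+N)
#' alternative.
#'
#' @param observed named numeric vector of observed statistics per orthogroup.
#' @param nulls replicate x orthogroup matrix of null statistics.
#' @param pseudo use the (1+k)/(1+N) estimator instead of the plain proportion.
#' @return data.frame `orthogroup`, `p_permulation`, `n_null`, `at_floor`.
#' @export
empirical_pvalues <- function(observed, nulls, pseudo = FALSE) {
  assert_that(!is.null(names(observed)), "observed must be a named vector")
  assert_that(all(names(observed) %in% colnames(nulls)),
              "every observed statistic needs a null column")
  res <- lapply(names(observed), function(og) {
    nl <- nulls[, og]
    nl <- nl[!is.na(nl)]
    obs <- observed[[og]]
    if (length(nl) == 0L || is.na(obs)) {
      return(data.frame(orthogroup = og, p_permulation = NA_real_,
                        n_null = length(nl), at_floor = FALSE))
    }
    k <- sum(abs(nl) >= abs(obs))
    p <- if (pseudo) (1 + k) / (1 + length(nl)) else k / length(nl)
    data.frame(orthogroup = og, p_permulation = p, n_null = length(nl),
               at_floor = k == 0L)
  })
  do.call(rbind, res)
}

#' Multiple-testing adjustment
#'
#' Standard step-up Benjamini-Hochberg or step-down Holm-Bonferroni
#' adjustment, clipped to 1, with the original order restored.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NAs carried through).
#' @param method `"BH"` or `"holm"`.
#' @return adjusted p-values in the input order.
#' @export
adjust_pvalues <- function(p, method = c("BH", "holm")) {
  method <- match.arg(method)
  check_probs(p)
  p.adjust(p, method = method)
}

#' Full RER-trait scan with permulation calibration
#'
#' Orchestrates [compute_rers()], [correlate_binary()], [permulate_binary()],
#' [empirical_pvalues()] and BH adjustment into the per-orthogroup table the
#' downstream classifier consumes.
#'
#' @param gene_trees named list of gene trees.
#' @param master_tree species tree.
#' @param traits trait table.
#' @param n_perm number of permulation replicates (default 1000).
#' @param seed optional integer seed.
#' @return data.frame with `orthogroup`, `rho`, `p_parametric`,
#'   `p_permulation`, `q_bh`, `n_fg`, `n_bg`.
#' @export
rer_scan <- function(gene_trees, master_tree, traits, n_perm = 1000, seed = NULL) {
  rers <- compute_rers(gene_trees, master_tree)
  cor_tab <- correlate_binary(rers, traits)
  n_fg <- length(foreground_species(traits))
  perms <- permulate_binary(master_tree, n_fg, n_perm = n_perm, seed = seed)
  nulls <- null_correlations(rers, perms)
  obs <- setNames(cor_tab$rho, cor_tab$orthogroup)
  emp <- empirical_pvalues(obs, nulls)
  tab <- merge(cor_tab, emp[, c("orthogroup", "p_permulation")], by = "orthogroup",
               sort = FALSE)
  tab$q_bh <- NA_real_
  ok <- !is.na(tab$p_permulation)
  tab$q_bh[ok] <- adjust_pvalues(tab$p_permulation[ok], "BH")
  tab[, c("orthogroup", "rho", "p_parametric", "p_permulation", "q_bh", "n_fg", "n_bg")]
}
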