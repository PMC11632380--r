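# Likelihood-ratio tests on the codon model: a RELAX-style selection
# intensity (K) test and an aBSREL-style per-branch positive-selection test
# on foreground branches. Branch lengths are taken as given (trees are
# inputs, as when externally estimated trees are supplied to the tests);
# model parameters are estimated by bounded maximum likelihood with
# multi-start optimization.

# Transformed parameterization of the shared 3-class omega model:
#   omega1 = omega2 * exp(t1) <= omega2,   t1 in [-8, 0]
#   omega2 = exp(t2) <= 1,                 t2 in [-8, 0]
#   omega3 = exp(t3) >= 1,                 t3 in [0, 4]
#   weights by stick-breaking on logits b1, b2
#   kappa = exp(lk)
relax_par_bounds <- function(with_k = FALSE) {
  lower <- c(lk = -3, t1 = -8, t2 = -8, t3 = 0, b1 = -8, b2 = -8)
  upper <- c(lk = 3, t1 = 0, t2 = 0, t3 = 4, b1 = 8, b2 = 8)
  if (with_k) {
    lower <- c(lower, logk = log(0.01))
    upper <- c(upper, logk = log(50))
  }
  list(lower = lower, upper = upper)
}

relax_par_to_spec <- function(par, freqs) {
  w1 <- stats::plogis(par[["b1"]])
  w2 <- (1 - w1) * stats::plogis(par[["b2"]])
  om2 <- exp(par[["t2"]])
  codon_model_spec(kappa = exp(par[["lk"]]), freqs = freqs,
                   omega = c(om2 * exp(par[["t1"]]), om2, exp(par[["t3"]])),
                   weights = c(w1, w2, 1 - w1 - w2))
}

relax_default_start <- function() {
  c(lk = log(2), t1 = log(0.1), t2 = 0, t3 = log(1.5),
    b1 = stats::qlogis(0.7), b2 = stats::qlogis(0.25 / 0.3))
}

jitter_start <- function(par, lower, upper, sd = 0.5) {
  pmin(pmax(par + rnorm(length(par), 0, sd), lower + 1e-6), upper - 1e-6)
}

# Bounded quasi-Newton ML step used by all codon fits. factr = 1e8 stops when
# the improvement per step drops below ~1e-8 x |lnL|, well under the ~1e-3
# lnL resolution the likelihood-ratio tests need.
bounded_ml <- function(start, fn, lower, upper, maxit = 200, factr = 1e8) {
  f <- tryCatch(
    optim(start, fn, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(factr = factr, maxit = maxit)),
    error = function(e) list(par = start, value = Inf, convergence = 1L))
  list(par = f$par, objective = f$value, convergence = f$convergence)
}

# Foreground branch ids for the codon tests: terminal branches of foreground
# species, optionally plus internal branches of all-foreground clades.
#' Branch ids leading to foreground species
#'
#' @param tree a `phylo`.
#' @param fg character vector of foreground species.
#' @param include_internal also include internal branches whose entire clade
#'   is foreground (default FALSE: terminal branches only).
#' @return character vector of branch ids (child-node labels).
#' @export
foreground_branch_ids <- function(tree, fg, include_internal = FALSE) {
  tree <- ensure_node_labels(validate_tree(tree))
  fg <- intersect(fg, tree$tip.label)
  if (!include_internal) return(fg)
  clades <- clade_tip_sets(tree)
  names(clades)[vapply(clades, function(s) all(s %in% fg), logical(1))]
}

#' RELAX-style test of selection-intensity shift on foreground branches
#'
#' Fits a shared three-class omega mixture (omega1 <= omega2 <= 1 <= omega3,
#' free weights) plus kappa by maximum likelihood. Under the null the
#' foreground (test) branches use the same omegas as the background (K = 1);
#' under the alternative each omega is exponentiated by a free selection
#' intensity K on the test branches (`omega^K`, K in \[0.01, 50\]). K < 1
#' compresses omegas toward 1 (relaxed selection), K > 1 pushes them away
#' from 1 (intensified selection). The LRT p-value uses chi-square with 1 df
#' (K = 1 is interior).
#'
#' @param aln codon alignment (`codon_align` or named character vector).
#' @param tree rooted `phylo` with branch lengths (taken as fixed).
#' @param test_branches branch ids of the foreground set (e.g. foreground
#'   species names for terminal branches).
#' @param n_starts number of seeded optimizer starts (default 3).
#' @param seed seed for the start jitter.
#' @return object of class `relax_fit`: `lnL_null`, `lnL_alt`, `K`, `lrt`,
#'   `p`, estimated `spec`, `converged`.
#' @export
fit_relax <- function(aln, tree, test_branches, n_starts = 3, seed = 1) {
  assert_that(length(test_branches) >= 1L, "need at least one test branch")
  aln <- as_codon_align(aln)
  assert_that(length(aln$taxa) >= 4L, "need >= 4 taxa")
  ld <- codon_lik_data(aln, tree, test_branches)
  freqs <- estimate_codon_freqs(aln)
  bd0 <- relax_par_bounds(FALSE)
  bd1 <- relax_par_bounds(TRUE)

  cache <- new.env(parent = emptyenv())
  cache$P <- list()
  nll_null <- function(par) {
    names(par) <- names(bd0$lower)
    -loglik_site_mixture(ld, relax_par_to_spec(par, freqs), K = 1, cache = cache)
  }
  nll_alt <- function(par) {
    names(par) <- names(bd1$lower)
    -loglik_site_mixture(ld, relax_par_to_spec(par, freqs), K = exp(par[["logk"]]),
                         cache = cache)
  }

  run <- function(fn, starts, lower, upper) {
    fits <- lapply(seq_along(starts), function(i) {
      bounded_ml(starts[[i]], fn, lower, upper,
                 maxit = if (i == 1) 200 else 40)
    })
    best_i <- which.min(vapply(fits, `[[`, numeric(1), "objective"))
    best <- fits[[best_i]]
    if (best_i != 1) best <- bounded_ml(best$par, fn, lower, upper)
    best$any_converged <- any(vapply(fits, function(f) f$convergence == 0L, logical(1))) ||
      best$convergence == 0L
    best
  }

  with_seed(derive_seed(seed, 101), {
    s0 <- relax_default_start()
    starts0 <- c(list(s0), lapply(seq_len(max(0, n_starts - 1)), function(i) {
      jitter_start(s0, bd0$lower, bd0$upper)
    }))
    fit0 <- run(nll_null, starts0, bd0$lower, bd0$upper)
    lnL_null <- -fit0$objective

    k_starts <- c(1, 0.3, 3)[seq_len(max(1, n_starts))]
    starts1 <- lapply(seq_along(k_starts), function(i) {
      base <- if (i == 1) fit0$par else
        jitter_start(fit0$par, bd0$lower, bd0$upper, sd = 0.25)
      c(base, logk = log(k_starts[i]))
    })
    fit1 <- run(nll_alt, starts1, bd1$lower, bd1$upper)
    lnL_alt <- max(-fit1$objective, lnL_null)  # alt nests null at K = 1

    lrt <- max(2 * (lnL_alt - lnL_null), 0)
    structure(list(
      lnL_null = lnL_null, lnL_alt = lnL_alt,
      K = exp(fit1$par[["logk"]]),
      lrt = lrt,
      p = pchisq(lrt, df = 1, lower.tail = FALSE),
      spec = relax_par_to_spec(fit1$par[seq_len(6)], freqs),
      converged = fit0$any_converged && fit1$any_converged,
      n_test_branches = length(test_branches)
    ), class = "relax_fit")
  })
}

#' @export
print.relax_fit <- function(x, ...) {
  cat(sprintf("Selection-intensity (K) test: K = %.3f, LRT = %.3f, p = %.4g\n",
              x$K, x$lrt, x$p))
  cat(sprintf("  lnL null %.3f | alt %.3f | %d test branch(es)%s\n",
              x$lnL_null, x$lnL_alt, x$n_test_branches,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Per-branch positive-selection test on foreground branches
#'
#' aBSREL-style random-effects test: every branch carries its own omega
#' distribution, drawn independently per site and per branch, so each
#' branch's transition matrix is the weighted mixture of category matrices.
#' A shared background model is fitted first; then, for each test branch,
#' the null gives the branch two classes with omega <= 1 (omega1 free,
#' omega2 = 1) and the alternative adds a third class with omega >= 1 and a
#' free weight. The LRT p-value uses the boundary-aware 50:50 mixture of
#' chi-square df 0 and df 2, followed by Holm correction across the test
#' branches; the orthogroup is called positively selected when any adjusted
#' p falls below `alpha`.
#'
#' @inheritParams fit_relax
#' @param alpha per-orthogroup significance threshold (default 0.05).
#' @return object of class `branch_ps_fit`: `branches` (per-branch
#'   data.frame), `positive` (orthogroup-level call), `lnL_background`.
#' @export
fit_branch_positive <- function(aln, tree, test_branches, n_starts = 3,
                                seed = 1, alpha = 0.05) {
  assert_that(length(test_branches) >= 1L, "need at least one test branch")
  aln <- as_codon_align(aln)
  assert_that(length(aln$taxa) >= 4L, "need >= 4 taxa")
  ld <- codon_lik_data(aln, tree, test_branches)
  freqs <- estimate_codon_freqs(aln)
  bd0 <- relax_par_bounds(FALSE)
  post_ids <- node_ids(ensure_node_labels(validate_tree(tree)))
  edge_ids <- post_ids[ld$edges[, 2]]
  n <- codon_tables()$n

  with_seed(derive_seed(seed, 202), {
    # shared background model, branch-mixture semantics throughout
    cache <- new.env(parent = emptyenv())
    cache$P <- list()
    nll_bg <- function(par) {
      names(par) <- names(bd0$lower)
      -loglik_branch_mixture(ld, relax_par_to_spec(par, freqs), cache = cache)
    }
    s0 <- relax_default_start()
    starts <- c(list(s0), lapply(seq_len(max(0, n_starts - 1)), function(i) {
      jitter_start(s0, bd0$lower, bd0$upper)
    }))
    fits <- lapply(seq_along(starts), function(i) {
      bounded_ml(starts[[i]], nll_bg, bd0$lower, bd0$upper,
                 maxit = if (i == 1) 200 else 40)
    })
    best_i <- which.min(vapply(fits, `[[`, numeric(1), "objective"))
    bg_fit <- fits[[best_i]]
    if (best_i != 1) bg_fit <- bounded_ml(bg_fit$par, nll_bg, bd0$lower, bd0$upper)
    bg_spec <- relax_par_to_spec(bg_fit$par, freqs)
    lnL_bg <- -bg_fit$objective

    # base P cube under the shared model; per-branch tests only replace one slice
    eig_cache <- new.env(parent = emptyenv())
    eig_for <- function(w) {
      key <- sprintf("%.12g", w)
      if (is.null(eig_cache[[key]])) {
        eig_cache[[key]] <- codon_eigen(build_codon_matrix(bg_spec, w), freqs)
      }
      eig_cache[[key]]
    }
    mix_P <- function(omega, weights, len) {
      P <- matrix(0, n, n)
      for (c in seq_along(omega)) P <- P + weights[c] * codon_P(eig_for(omega[c]), len)
      P
    }
    P_base <- array(0, dim = c(n, n, nrow(ld$edges)))
    for (e in seq_len(nrow(ld$edges))) {
      P_base[, , e] <- mix_P(bg_spec$omega, bg_spec$weights, ld$lengths[e])
    }

    branch_ll <- function(e, omega, weights) {
      P <- P_base
      P[, , e] <- mix_P(omega, weights, ld$lengths[e])
      sum(ld$pat_w * prune_patterns(ld, P, freqs))
    }

    rows <- lapply(test_branches, function(b) {
      e <- which(edge_ids == b)
      assert_that(length(e) == 1L, sprintf("test branch '%s' not found", b))
      # null: branch classes {omega1 <= 1 (weight w), omega = 1}
      nll0 <- function(par) {
        w1 <- stats::plogis(par[2])
        -branch_ll(e, c(exp(par[1]), 1), c(w1, 1 - w1))
      }
      f0 <- bounded_ml(c(log(0.2), stats::qlogis(0.7)), nll0,
                       lower = c(-8, -8), upper = c(0, 8))
      # alternative: adds {omega3 >= 1, free weight}
      nll1 <- function(par) {
        w1 <- stats::plogis(par[3])
        w3 <- (1 - w1) * stats::plogis(par[4])
        -branch_ll(e, c(exp(par[1]), 1, exp(par[2])),
                   c(w1, 1 - w1 - w3, w3))
      }
      f1s <- lapply(list(c(f0$par[1], log(2), f0$par[2], stats::qlogis(0.1)),
                         c(f0$par[1], log(8), f0$par[2], stats::qlogis(0.3))),
                    function(s) bounded_ml(s, nll1, lower = c(-8, 0, -8, -8),
                                           upper = c(0, 4, 8, 8)))
      f1 <- f1s[[which.min(vapply(f1s, `[[`, numeric(1), "objective"))]]
      lnl0 <- -f0$objective
      lnl1 <- max(-f1$objective, lnl0)
      lrt <- max(2 * (lnl1 - lnl0), 0)
      p <- if (lrt <= 0) 1 else 0.5 * pchisq(lrt, df = 2, lower.tail = FALSE)
      om3 <- exp(f1$par[2])
      w1 <- stats::plogis(f1$par[3])
      w3 <- (1 - w1) * stats::plogis(f1$par[4])
      data.frame(branch = b, omega1 = exp(f1$par[1]), omega3 = om3,
                 prop_positive = if (om3 > 1) w3 else 0,
                 lnL_null = lnl0, lnL_alt = lnl1, lrt = lrt, p = p,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$p_holm <- adjust_pvalues(tab$p, "holm")
    structure(list(branches = tab,
                   positive = any(tab$p_holm < alpha),
                   lnL_background = lnL_bg,
                   alpha = alpha),
              class = "branch_ps_fit")
  })
}

#' @export
print.branch_ps_fit <- function(x, ...) {
  cat(sprintf("Per-branch positive-selection test (%d branches): %s\n",
              nrow(x$branches),
              if (x$positive) "POSITIVE (some adjusted p < alpha)" else "no call"))
  print(x$branches[, c("branch", "omega3", "prop_positive", "lrt", "p", "p_holm")],
        row.names = FALSE)
  invisible(x)
}
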