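# Independent oracles and small fixtures shared across test files.
# Everything here avoids the code paths it is used to check: transition
# probabilities come from Matrix::expm, likelihoods from explicit
# enumeration of internal states, p-values from direct combinatorial sums.

# Rooted 4-taxon tree with exactly two internal nodes (root trifurcation),
# so the full internal-state space is 61 x 61.
oracle_tree_4tax <- function() {
  parse_newick("((A:0.2,B:0.3):0.25,C:0.4,D:0.5);")
}

# Exhaustive-enumeration log-likelihood for the oracle_tree_4tax() topology
# under a single-omega codon model: explicit double loop over all 61^2
# internal-state assignments, transition matrices via Matrix::expm.
oracle_loglik_4tax <- function(seqs, spec, omega) {
  Q <- build_codon_matrix(spec, omega)
  Pm <- function(t) as.matrix(Matrix::expm(Q * max(t, 1e-8)))
  P_in <- Pm(0.25)  # root -> internal node above A,B
  PA <- Pm(0.2); PB <- Pm(0.3); PC <- Pm(0.4); PD <- Pm(0.5)
  tab <- codon_tables_for_tests()
  st <- sapply(seqs, function(s) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    match(cods, tab$codons)
  })
  if (is.null(dim(st))) st <- matrix(st, 1, dimnames = list(NULL, names(seqs)))
  n_sites <- nrow(st)
  total <- 0
  for (site in seq_len(n_sites)) {
    sA <- st[site, "A"]; sB <- st[site, "B"]; sC <- st[site, "C"]; sD <- st[site, "D"]
    lik <- 0
    for (y in 1:61) {        # root state
      for (x in 1:61) {      # internal node state
        lik <- lik + spec$freqs[y] * P_in[y, x] * PA[x, sA] * PB[x, sB] *
          PC[y, sC] * PD[y, sD]
      }
    }
    total <- total + log(lik)
  }
  total
}

codon_tables_for_tests <- function() {
  # rebuild the sense-codon list from the standard genetic code, written
  # independently of the package internals
  bases <- c("T", "C", "A", "G")
  aa <- strsplit("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", "")[[1]]
  cods <- character(64); k <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1; cods[k] <- paste0(b1, b2, b3)
  }
  list(codons = cods[aa != "*"], aa = aa[aa != "*"])
}

# Translate an in-frame nucleotide string to amino acids (oracle for
# synonymous-only checks).
oracle_translate <- function(s) {
  tab <- codon_tables_for_tests()
  aa_of <- setNames(tab$aa, tab$codons)
  cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  paste(aa_of[cods], collapse = "")
}

# Exact two-sided Fisher p for a 2x2 table by enumerating all tables with
# the observed margins and summing probabilities <= that of the observed
# table (with a small relative tolerance, as in stats::fisher.test).
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_vals <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- sapply(a_vals, function(a) {
    choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1)
  })
  p_obs <- probs[a_vals == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Upper-tail hypergeometric by direct summation.
oracle_hyper_upper <- function(k, K, n, N) {
  vals <- k:min(K, n)
  if (length(vals) == 0 || k > min(K, n)) return(0)
  sum(sapply(vals, function(i) choose(K, i) * choose(N - K, n - i) / choose(N, n)))
}

# Step-up BH and step-down Holm, written directly from their definitions.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- cummax(p[o] * (m - seq_len(m) + 1))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Small deterministic trait table for a given tree and foreground species.
make_traits <- function(tree, fg) {
  data.frame(species = tree$tip.label,
             foreground = tree$tip.label %in% fg,
             prepupal_diapause = ifelse(tree$tip.label %in% fg, "no", "yes"),
             sociality = "solitary",
             stringsAsFactors = FALSE)
}

# Evaluate expr under a local seed without touching the global stream state
# beyond this call.
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
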