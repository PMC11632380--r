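# Codon substitution model: MG94/GY-style rate matrix over the 61 sense
# codons of the universal genetic code, spectral transition probabilities,
# and the pruning likelihood (site-level or branch-level omega mixtures).

.codon_env <- new.env(parent = emptyenv())

# Static codon tables: 61 sense codons, their amino acids, and the list of
# single-nucleotide neighbour pairs annotated with transition/synonymous flags.
codon_tables <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  bases <- c("T", "C", "A", "G")
  aa64 <- strsplit("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", "")[[1]]
  cod64 <- character(64)
  k <- 0L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1L
    cod64[k] <- paste0(b1, b2, b3)
  }
  sense <- aa64 != "*"
  codons <- cod64[sense]
  aa <- aa64[sense]
  n <- length(codons)  # 61
  ntmat <- do.call(rbind, strsplit(codons, ""))
  is_transition <- function(x, y) {
    (x == "A" & y == "G") | (x == "G" & y == "A") | (x == "C" & y == "T") | (x == "T" & y == "C")
  }
  from <- integer(0); to <- integer(0); ts <- logical(0); syn <- logical(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    diff <- ntmat[i, ] != ntmat[j, ]
    if (sum(diff) == 1L) {
      pos <- which(diff)
      from <- c(from, i); to <- c(to, j)
      ts <- c(ts, is_transition(ntmat[i, pos], ntmat[j, pos]))
      syn <- c(syn, aa[i] == aa[j])
    }
  }
  .codon_env$tab <- list(codons = codons, aa = aa, nt = ntmat, n = n,
                         from = from, to = to, is_ts = ts, is_syn = syn)
  .codon_env$tab
}

#' Codon model specification
#'
#' Bundles the parameters shared by the selection tests: the
#' transition/transversion ratio `kappa`, stationary frequencies over the 61
#' sense codons, and a discrete distribution of omega (dN/dS) site categories.
#'
#' @param kappa transition/transversion rate ratio, > 0.
#' @param freqs stationary codon frequencies (length 61, summing to 1 within
#'   1e-6); default uniform.
#' @param omega omega category values, all > 0 (or 0 for a strictly
#'   purifying class).
#' @param weights category weights, summing to 1.
#' @return an object of class `codon_model_spec`.
#' @export
codon_model_spec <- function(kappa = 2, freqs = NULL,
                             omega = c(0.1, 1, 1.5),
                             weights = c(0.7, 0.25, 0.05)) {
  tab <- codon_tables()
  if (is.null(freqs)) freqs <- rep(1 / tab$n, tab$n)
  assert_that(is.numeric(kappa) && length(kappa) == 1L && kappa > 0, "kappa must be > 0")
  assert_that(length(freqs) == tab$n, "freqs must have 61 entries (sense codons)")
  if (abs(sum(freqs) - 1) > 1e-6 || any(freqs < 0)) {
    stop("codon frequencies must be non-negative and sum to 1 within 1e-6", call. = FALSE)
  }
  assert_that(length(omega) == length(weights), "omega and weights lengths differ")
  assert_that(all(omega >= 0), "omega values must be >= 0")
  if (abs(sum(weights) - 1) > 1e-8 || any(weights < 0)) {
    stop("omega weights must be non-negative and sum to 1", call. = FALSE)
  }
  structure(list(kappa = kappa, freqs = as.numeric(freqs),
                 omega = as.numeric(omega), weights = as.numeric(weights)),
            class = "codon_model_spec")
}

#' Build a scaled codon instantaneous rate matrix
#'
#' MG94/GY-style parameterization: for codon pairs differing at exactly one
#' nucleotide the rate is `target frequency x kappa^[transition] x
#' omega^[nonsynonymous]`; multi-nucleotide changes have rate 0. The matrix is
#' scaled so that the expected number of substitutions per unit branch length
#' is 1 at stationarity.
#'
#' @param spec a [codon_model_spec()].
#' @param omega the omega value for this category.
#' @return a 61 x 61 rate matrix with zero row sums.
#' @export
build_codon_matrix <- function(spec, omega) {
  assert_that(inherits(spec, "codon_model_spec"), "spec must be a codon_model_spec")
  assert_that(is.numeric(omega) && length(omega) == 1L && omega >= 0, "omega must be >= 0")
  tab <- codon_tables()
  n <- tab$n
  Q <- matrix(0, n, n, dimnames = list(tab$codons, tab$codons))
  rate <- spec$freqs[tab$to] *
    ifelse(tab$is_ts, spec$kappa, 1) *
    ifelse(tab$is_syn, 1, omega)
  Q[cbind(tab$from, tab$to)] <- rate
  diag(Q) <- -rowSums(Q)
  mu <- -sum(spec$freqs * diag(Q))
  if (mu <= 0) stop("degenerate rate matrix: zero expected substitution rate", call. = FALSE)
  Q / mu
}

# Spectral decomposition of a reversible Q for fast P(t) = A exp(L t) B.
# Returns A (61x61), B (61x61) and eigenvalues lambda.
codon_eigen <- function(Q, freqs) {
  d <- sqrt(pmax(freqs, 1e-12))
  S <- Q * outer(d, 1 / d)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(A = e$vectors * (1 / d), B = t(e$vectors * d), lambda = e$values)
}

# Transition probability matrix from a cached decomposition; branch lengths
# are floored at 1e-8 to keep the matrix nonsingular.
codon_P <- function(eig, t) {
  t <- max(t, 1e-8)
  P <- eig$A %*% (exp(eig$lambda * t) * eig$B)
  P[P < 0] <- 0
  P
}

# ---- alignment representation -------------------------------------------

#' Encode aligned coding sequences as codon states
#'
#' @param seqs named character vector of aligned, in-frame nucleotide
#'   sequences (equal lengths, divisible by 3) over `A,C,G,T,-,N` (case
#'   insensitive). Any codon containing a non-ACGT character, or matching a
#'   stop codon, is treated as missing data.
#' @return an object of class `codon_align`: list with `states` (taxa x sites
#'   integer matrix, NA = missing), `taxa`, `nsites`.
#' @export
encode_codon_alignment <- function(seqs) {
  assert_that(is.character(seqs) && length(seqs) >= 2L && !is.null(names(seqs)),
              "seqs must be a named character vector with >= 2 sequences")
  lens <- nchar(seqs)
  assert_that(length(unique(lens)) == 1L, "sequences must have equal lengths")
  assert_that(lens[1] %% 3 == 0, "alignment length must be divisible by 3")
  tab <- codon_tables()
  nsites <- lens[1] %/% 3
  states <- matrix(NA_integer_, length(seqs), nsites,
                   dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) {
    s <- toupper(seqs[[i]])
    cods <- substring(s, seq(1, lens[1], by = 3), seq(3, lens[1], by = 3))
    states[i, ] <- match(cods, tab$codons)
  }
  structure(list(states = states, taxa = names(seqs), nsites = nsites),
            class = "codon_align")
}

# Back to character sequences (missing codons rendered as NNN).
decode_codon_alignment <- function(aln) {
  tab <- codon_tables()
  apply(aln$states, 1, function(row) {
    cods <- ifelse(is.na(row), "NNN", tab$codons[row])
    paste(cods, collapse = "")
  })
}

as_codon_align <- function(x) {
  if (inherits(x, "codon_align")) return(x)
  encode_codon_alignment(x)
}

# F1x4-style empirical codon frequencies: product of positional-pooled
# nucleotide frequencies, normalized over the 61 sense codons. Nucleotide
# frequencies are floored at 1e-3 so no sense codon gets probability 0.
estimate_codon_freqs <- function(aln) {
  aln <- as_codon_align(aln)
  tab <- codon_tables()
  obs <- table(factor(tab$codons[aln$states[!is.na(aln$states)]], levels = tab$codons))
  ntc <- c(A = 0, C = 0, G = 0, T = 0)
  for (b in names(ntc)) ntc[b] <- sum(obs * rowSums(tab$nt == b))
  ntf <- pmax(ntc / sum(ntc), 1e-3)
  ntf <- ntf / sum(ntf)
  f <- ntf[tab$nt[, 1]] * ntf[tab$nt[, 2]] * ntf[tab$nt[, 3]]
  as.numeric(f / sum(f))
}

# ---- pruning likelihood ---------------------------------------------------

# Precompute everything the optimizer loop needs from (alignment, tree):
# postorder edge list, floored branch lengths, foreground edge flags, tip
# state matrix in tree numbering, and site-pattern compression.
codon_lik_data <- function(aln, tree, test_branches = character()) {
  aln <- as_codon_align(aln)
  tree <- ensure_node_labels(validate_tree(tree))
  extra <- setdiff(aln$taxa, tree$tip.label)
  assert_that(length(extra) == 0L,
              paste0("alignment species absent from tree: ", paste(extra, collapse = ", ")))
  assert_that(ape::Ntip(tree) >= 2L, "tree must have >= 2 tips")
  post <- ape::reorder.phylo(tree, "postorder")
  n_tip <- ape::Ntip(tree)
  bt_ids <- node_ids(tree)
  unknown_fg <- setdiff(test_branches, bt_ids)
  assert_that(length(unknown_fg) == 0L,
              paste0("test branches not in tree: ", paste(unknown_fg, collapse = ", ")))
  fg_edge <- bt_ids[post$edge[, 2]] %in% test_branches
  # tip states in tree tip numbering; tree tips absent from the alignment are
  # treated as missing data
  states <- matrix(0L, n_tip, aln$nsites)
  hit <- match(tree$tip.label, aln$taxa)
  for (i in seq_len(n_tip)) {
    if (!is.na(hit[i])) {
      row <- aln$states[hit[i], ]
      states[i, ] <- ifelse(is.na(row), 0L, row)
    }
  }
  key <- apply(states, 2, paste, collapse = ",")
  first <- !duplicated(key)
  pat_w <- as.numeric(table(key)[key[first]])
  list(states = states[, first, drop = FALSE], pat_w = pat_w,
       edges = post$edge, lengths = pmax(post$edge.length %||% rep(0, nrow(post$edge)), 1e-8),
       fg_edge = fg_edge, n_node = n_tip + tree$Nnode, n_tip = n_tip,
       nsites = aln$nsites)
}

# Per-pattern log-likelihood for one set of per-edge P matrices.
prune_patterns <- function(ld, P_cube, freqs) {
  cpp_prune_loglik(P_cube, ld$edges, ld$states, freqs, ld$n_node)
}

# Memoised transition matrices: within one model fit the branch lengths and
# codon frequencies are fixed, so P matrices are cached by (kappa, omega,
# edge). Finite-difference gradients perturb one parameter at a time, which
# makes most lookups cache hits.
cached_eigen <- function(spec, omega, cache) {
  key <- sprintf("%.14g|%.14g", spec$kappa, omega)
  if (!is.null(cache) && !is.null(cache$eig[[key]])) return(cache$eig[[key]])
  eig <- codon_eigen(build_codon_matrix(spec, omega), spec$freqs)
  if (!is.null(cache)) {
    if (length(cache$eig) > 2000) cache$eig <- list()
    cache$eig[[key]] <- eig
  }
  eig
}

cached_P_set <- function(ld, spec, omega, cache) {
  key <- sprintf("%.14g|%.14g", spec$kappa, omega)
  if (is.null(cache)) {
    eig <- codon_eigen(build_codon_matrix(spec, omega), spec$freqs)
    return(lapply(seq_len(nrow(ld$edges)), function(e) codon_P(eig, ld$lengths[e])))
  }
  hit <- cache$P[[key]]
  if (!is.null(hit)) return(hit)
  eig <- codon_eigen(build_codon_matrix(spec, omega), spec$freqs)
  Ps <- lapply(seq_len(nrow(ld$edges)), function(e) codon_P(eig, ld$lengths[e]))
  if (length(cache$P) > 400) cache$P <- list()  # bound memory
  cache$P[[key]] <- Ps
  Ps
}

# Site-mixture likelihood (RELAX-style): every branch uses category omega_c,
# exponentiated by K on foreground edges; categories are shared across the
# tree and mixed at the site level.
loglik_site_mixture <- function(ld, spec, K = 1, cache = NULL) {
  n <- codon_tables()$n
  ncat <- length(spec$omega)
  om_bg <- spec$omega
  om_fg <- spec$omega^K
  per_cat <- matrix(0, ncat, length(ld$pat_w))
  for (c in seq_len(ncat)) {
    # the per-pattern likelihood of one category depends only on
    # (kappa, background omega, foreground omega); mixing weights do not
    # enter, so whole category rows are reusable across evaluations
    cat_key <- sprintf("%.14g|%.14g|%.14g", spec$kappa, om_bg[c], om_fg[c])
    if (!is.null(cache) && !is.null(cache$cat[[cat_key]])) {
      per_cat[c, ] <- cache$cat[[cat_key]]
      next
    }
    e_bg <- cached_eigen(spec, om_bg[c], cache)
    e_fg <- if (om_fg[c] == om_bg[c]) e_bg else cached_eigen(spec, om_fg[c], cache)
    per_cat[c, ] <- cpp_category_prune(e_bg$A, e_bg$B, e_bg$lambda,
                                       e_fg$A, e_fg$B, e_fg$lambda,
                                       ld$lengths, as.integer(ld$fg_edge),
                                       ld$edges, ld$states, spec$freqs,
                                       ld$n_node)
    if (!is.null(cache)) {
      if (length(cache$cat) > 3000) cache$cat <- list()
      cache$cat[[cat_key]] <- per_cat[c, ]
    }
  }
  m <- Reduce(pmax, lapply(seq_len(ncat), function(c) per_cat[c, ]))
  acc <- 0
  for (c in seq_len(ncat)) acc <- acc + spec$weights[c] * exp(per_cat[c, ] - m)
  sum(ld$pat_w * (log(acc) + m))
}

# Branch-mixture likelihood (aBSREL-style): each edge carries its own omega
# distribution, drawn independently per site and per branch, so each edge's
# transition matrix is the weighted mixture of category matrices.
# edge_mix: list over edges of list(omega=, weights=); edges not listed use
# `spec`'s own categories.
loglik_branch_mixture <- function(ld, spec, edge_mix = NULL, cache = NULL) {
  n <- codon_tables()$n
  P_sets <- new.env(parent = emptyenv())
  set_for <- function(w) {
    key <- sprintf("%.14g", w)
    if (is.null(P_sets[[key]])) P_sets[[key]] <- cached_P_set(ld, spec, w, cache)
    P_sets[[key]]
  }
  P_cube <- array(0, dim = c(n, n, nrow(ld$edges)))
  for (e in seq_len(nrow(ld$edges))) {
    mix <- if (!is.null(edge_mix) && !is.null(edge_mix[[e]])) edge_mix[[e]] else
      list(omega = spec$omega, weights = spec$weights)
    P <- matrix(0, n, n)
    for (c in seq_along(mix$omega)) {
      P <- P + mix$weights[c] * set_for(mix$omega[c])[[e]]
    }
    P_cube[, , e] <- P
  }
  sum(ld$pat_w * prune_patterns(ld, P_cube, spec$freqs))
}

#' Codon alignment log-likelihood by Felsenstein pruning
#'
#' Computes the log-likelihood of a codon alignment on a rooted tree under the
#' package's MG94-style model with a discrete omega mixture shared across the
#' tree. On `test_branches` each category's omega is exponentiated by `K`
#' (`omega^K`), the selection-intensity convention used by the relaxation/
#' intensification test. Ambiguous codons contribute partial likelihood 1 over
#' all states; root states use the stationary frequencies.
#'
#' @param aln a `codon_align` or named character vector of aligned sequences.
#' @param tree a rooted `phylo`; branch lengths in expected substitutions per
#'   codon site (floored at 1e-8).
#' @param spec a [codon_model_spec()].
#' @param test_branches character vector of branch ids (child-node labels)
#'   treated as foreground.
#' @param K selection intensity applied on the test branches.
#' @return the log-likelihood (scalar).
#' @export
log_likelihood <- function(aln, tree, spec, test_branches = character(), K = 1) {
  assert_that(inherits(spec, "codon_model_spec"), "spec must be a codon_model_spec")
  assert_that(is.numeric(K) && length(K) == 1L && K > 0, "K must be > 0")
  ld <- codon_lik_data(aln, tree, test_branches)
  loglik_site_mixture(ld, spec, K)
}
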