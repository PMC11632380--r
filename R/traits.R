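# Trait association: binary-response PGLS under Brownian covariance, Fisher
# exact 2x2 test, and reciprocal-best-hit joining of similarity hit tables.

#' Phylogenetic generalized least squares for a binary response
#'
#' Gaussian GLS with residual covariance proportional to shared root-to-tip
#' path lengths (Brownian motion), the standard treatment of a 0/1 response
#' in comparative tooling. The fit is computed by whitening both sides with
#' the Cholesky factor of the covariance and running ordinary least squares,
#' so with an identity covariance (star tree, unit depths) the estimates
#' equal OLS exactly.
#'
#' @param tree species tree (`phylo`) covering all rows of `traits`.
#' @param traits data.frame with a `species` column, the response and the
#'   predictors.
#' @param response name of the 0/1 response column (0 = absent, 1 = present).
#' @param predictors character vector of predictor columns (categorical
#'   predictors are dummy-coded via factors).
#' @param lambda optional Pagel's lambda multiplier on off-diagonal
#'   covariance (default 1 = pure Brownian; no lambda estimation).
#' @return object of class `pgls_fit`: `coefficients` (estimate, se, t, p),
#'   `r_squared`, `sigma2`, `formula`, `n`.
#' @export
pgls_fit <- function(tree, traits, response, predictors, lambda = 1) {
  validate_tree(tree)
  assert_that("species" %in% names(traits), "traits needs a 'species' column")
  assert_that(response %in% names(traits), sprintf("response '%s' not in traits", response))
  missing_pred <- setdiff(predictors, names(traits))
  assert_that(length(missing_pred) == 0L,
              paste0("predictors not in traits: ", paste(missing_pred, collapse = ", ")))
  off <- setdiff(traits$species, tree$tip.label)
  assert_that(length(off) == 0L,
              paste0("species missing from tree: ", paste(off, collapse = ", ")))
  dat <- traits[match(tree$tip.label, traits$species), , drop = FALSE]
  dat <- dat[!is.na(dat$species), , drop = FALSE]
  y <- as.numeric(dat[[response]])
  assert_that(all(y %in% c(0, 1)), "response must be coded 0/1")
  if (length(unique(y)) < 2L) {
    stop("degenerate fit: the response is constant", call. = FALSE)
  }
  for (p in predictors) if (!is.numeric(dat[[p]])) dat[[p]] <- factor(dat[[p]])
  fml <- stats::as.formula(paste("~", paste(predictors, collapse = " + ")))
  X <- stats::model.matrix(fml, dat)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design: collinear predictor columns among ",
         paste(colnames(X), collapse = ", "), call. = FALSE)
  }
  V <- ape::vcv(tree)[dat$species, dat$species]
  if (lambda != 1) {
    Vd <- diag(V)
    V <- lambda * V
    diag(V) <- Vd
  }
  Ct <- t(chol(V))                 # V = Ct %*% t(Ct)
  yw <- forwardsolve(Ct, y)
  Xw <- forwardsolve(Ct, X)
  colnames(Xw) <- colnames(X)
  fit <- lm(yw ~ Xw - 1)
  cf <- suppressWarnings(summary(fit))$coefficients
  rownames(cf) <- colnames(X)
  # GLS R^2 against the GLS intercept-only model
  ones_w <- forwardsolve(Ct, rep(1, length(y)))
  fit0 <- lm(yw ~ ones_w - 1)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum(stats::residuals(fit0)^2)
  structure(list(
    coefficients = data.frame(term = rownames(cf), estimate = cf[, 1],
                              se = cf[, 2], t = cf[, 3], p = cf[, 4],
                              row.names = NULL, stringsAsFactors = FALSE),
    r_squared = 1 - rss / tss,
    sigma2 = rss / (length(y) - ncol(X)),
    formula = paste(response, "~", paste(predictors, collapse = " + ")),
    n = length(y)
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS (Brownian covariance):", x$formula, "\n")
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat(sprintf("multiple R^2 = %.4f, n = %d\n", x$r_squared, x$n))
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p by summing hypergeometric probabilities no larger than
#' that of the observed table. Any zero margin makes every table with those
#' margins equally likely, so p = 1 (with a warning).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return the two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  assert_that(all(dim(tab) == c(2L, 2L)), "tab must be 2x2")
  assert_that(all(tab >= 0) && all(tab == round(tab)), "counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin: p = 1")
    return(1)
  }
  fisher.test(tab, alternative = "two.sided")$p.value
}

#' Read a tabular similarity hit table (BLAST outfmt 6 dialect)
#'
#' @param path TSV path with the standard 12 columns (qseqid, sseqid, pident,
#'   length, mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore);
#'   extra columns are ignored.
#' @param max_evalue rows with evalue above this are dropped (default 1e-10).
#' @return data.frame with columns `qseqid`, `sseqid`, `evalue`, `bitscore`.
#' @export
read_hit_table <- function(path, max_evalue = 1e-10) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  assert_that(ncol(tab) >= 12L, "expected >= 12 tab-separated columns (outfmt 6)")
  out <- data.frame(qseqid = as.character(tab[[1]]), sseqid = as.character(tab[[2]]),
                    evalue = as.numeric(tab[[11]]), bitscore = as.numeric(tab[[12]]),
                    stringsAsFactors = FALSE)
  out[out$evalue <= max_evalue, , drop = FALSE]
}

# Best hit per query: max bit score, ties by smallest e-value, then
# lexicographically smallest subject id.
best_hits <- function(hits) {
  o <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$qseqid), , drop = FALSE]
}

#' Reciprocal best hits between two similarity searches
#'
#' A pair (a, b) is retained iff b is a's best hit in the forward table and
#' a is b's best hit in the reverse table. Best-hit reduction (max bit
#' score, ties by smallest e-value then lexicographic subject id) is applied
#' inside the operation, so tables with multiple hits per query are handled.
#'
#' @param hits_ab forward hit table (queries from set A against set B), as
#'   from [read_hit_table()].
#' @param hits_ba reverse hit table (B against A).
#' @return data.frame `a`, `b`, sorted and deduplicated.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba) {
  need <- c("qseqid", "sseqid", "bitscore", "evalue")
  assert_that(all(need %in% names(hits_ab)) && all(need %in% names(hits_ba)),
              "hit tables need qseqid, sseqid, bitscore, evalue columns")
  fwd <- best_hits(hits_ab)
  rev <- best_hits(hits_ba)
  back <- setNames(rev$sseqid, rev$qseqid)
  keep <- !is.na(back[fwd$sseqid]) & back[fwd$sseqid] == fwd$qseqid
  keep[is.na(keep)] <- FALSE
  out <- unique(data.frame(a = fwd$qseqid[keep], b = fwd$sseqid[keep],
                           stringsAsFactors = FALSE))
  out[order(out$a, out$b), , drop = FALSE]
}
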