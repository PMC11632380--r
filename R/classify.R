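# Evidence combination: selection categories from the three tests, plus
# term and gene-list enrichment.

#' Combine the three selection tests into a call set
#'
#' @param rho_pos,rho_neg orthogroups RER-significant with positive /
#'   negative rho.
#' @param absrel orthogroups with a per-branch positive-selection call.
#' @param relaxed,intensified orthogroups significant in the K test with
#'   K < 1 / K > 1.
#' @return object of class `selection_calls` (a named list of character sets).
#' @export
selection_calls <- function(rho_pos = character(0), rho_neg = character(0),
                            absrel = character(0), relaxed = character(0),
                            intensified = character(0)) {
  calls <- lapply(list(rho_pos = rho_pos, rho_neg = rho_neg, absrel = absrel,
                       relaxed = relaxed, intensified = intensified),
                  function(x) unique(as.character(x)))
  if (length(intersect(calls$rho_pos, calls$rho_neg)) > 0) {
    stop("an orthogroup cannot be both Rho+ and Rho-", call. = FALSE)
  }
  if (length(intersect(calls$relaxed, calls$intensified)) > 0) {
    stop("an orthogroup cannot be both relaxed (K < 1) and intensified (K > 1)",
         call. = FALSE)
  }
  structure(calls, class = "selection_calls")
}

#' Classify orthogroups into selection categories
#'
#' Combines the calls into four mutually exclusive "possible" categories and
#' two best-evidence flags:
#' * possible positive = (Rho+ or branch-positive) minus relaxed
#' * possible purifying = Rho- minus (branch-positive or relaxed)
#' * possible relaxed = relaxed (K < 1) minus (branch-positive, Rho+, Rho-)
#' * possible intensified = intensified (K > 1) minus (branch-positive, Rho+, Rho-)
#' * best positive = significant in at least 2 of \{branch-positive, Rho+,
#'   intensified\}
#' * best purifying = Rho- and intensified
#'
#' @param calls a [selection_calls()] object.
#' @return object of class `selection_categories`: named list of character
#'   sets `possible_positive`, `possible_purifying`, `possible_relaxed`,
#'   `possible_intensified`, `best_positive`, `best_purifying`.
#' @export
classify_selection <- function(calls) {
  assert_that(inherits(calls, "selection_calls"),
              "calls must be built with selection_calls()")
  sd2 <- function(a, b) setdiff(a, b)
  possible_positive <- sd2(union(calls$rho_pos, calls$absrel), calls$relaxed)
  possible_purifying <- sd2(calls$rho_neg, union(calls$absrel, calls$relaxed))
  noise <- Reduce(union, list(calls$absrel, calls$rho_pos, calls$rho_neg))
  possible_relaxed <- sd2(calls$relaxed, noise)
  possible_intensified <- sd2(calls$intensified, noise)
  all_ids <- Reduce(union, calls)
  votes <- vapply(all_ids, function(og) {
    sum(og %in% calls$absrel, og %in% calls$rho_pos, og %in% calls$intensified)
  }, integer(1))
  structure(list(
    possible_positive = sort(possible_positive),
    possible_purifying = sort(possible_purifying),
    possible_relaxed = sort(possible_relaxed),
    possible_intensified = sort(possible_intensified),
    best_positive = sort(all_ids[votes >= 2]),
    best_purifying = sort(intersect(calls$rho_neg, calls$intensified))
  ), class = "selection_categories")
}

#' @export
print.selection_categories <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("%-22s %d\n", nm, length(x[[nm]])))
  invisible(x)
}

#' Term over-representation by one-sided hypergeometric (Fisher) test
#'
#' Classic per-term Fisher test (no ontology-graph weighting): for each term
#' annotated to more than `min_annotated` orthogroups of the universe, the
#' upper-tail hypergeometric probability of the observed overlap with the
#' study set. The universe defaults to the annotated orthogroups.
#'
#' @param annotation data.frame with columns `orthogroup`, `term` (and
#'   optionally `name`).
#' @param study character vector of study orthogroups (must lie in the
#'   universe).
#' @param universe universe of orthogroups; default: all annotated ones.
#' @param alpha significance threshold on the raw p (default 0.01).
#' @param min_annotated terms need strictly more than this many annotated
#'   universe orthogroups to be tested (default 5).
#' @return data.frame `term`, `name`, `k` (study hits), `K` (universe hits),
#'   `n` (study size), `N` (universe size), `p`, `significant`.
#' @export
fisher_term_enrichment <- function(annotation, study, universe = NULL,
                                   alpha = 0.01, min_annotated = 5) {
  assert_that(all(c("orthogroup", "term") %in% names(annotation)),
              "annotation needs 'orthogroup' and 'term' columns")
  if (is.null(universe)) universe <- unique(annotation$orthogroup)
  assert_that(length(universe) > 0, "universe is empty")
  bad <- setdiff(study, universe)
  assert_that(length(bad) == 0L,
              paste0("study orthogroups outside the universe: ", paste(head(bad, 5), collapse = ", ")))
  if (length(study) == 0L) {
    warning("empty study set: no enrichment computed")
    return(data.frame(term = character(0), name = character(0), k = integer(0),
                      K = integer(0), n = integer(0), N = integer(0),
                      p = numeric(0), significant = logical(0)))
  }
  ann <- annotation[annotation$orthogroup %in% universe, , drop = FALSE]
  ann <- unique(ann[, intersect(c("orthogroup", "term", "name"), names(ann))])
  N <- length(universe)
  n <- length(unique(study))
  terms <- split(ann$orthogroup, ann$term)
  name_of <- if ("name" %in% names(ann)) {
    tapply(ann$name, ann$term, `[`, 1)
  } else NULL
  rows <- lapply(names(terms), function(tm) {
    Kt <- length(unique(terms[[tm]]))
    if (Kt <= min_annotated) return(NULL)
    k <- length(intersect(terms[[tm]], study))
    p <- phyper(k - 1, Kt, N - Kt, n, lower.tail = FALSE)
    data.frame(term = tm, name = if (is.null(name_of)) NA_character_ else name_of[[tm]],
               k = k, K = Kt, n = n, N = N, p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(term = character(0), name = character(0), k = integer(0),
                      K = integer(0), n = integer(0), N = integer(0),
                      p = numeric(0), significant = logical(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$p), , drop = FALSE]
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}

#' Hypergeometric overlap test between a study set and a reference list
#'
#' One-sided (upper tail): probability of at least the observed overlap if
#' the study set were drawn at random from the universe. The reference list
#' is intersected with the universe first.
#'
#' @param study character vector of study orthogroups (within the universe).
#' @param reference character vector (e.g. longevity-gene orthogroups).
#' @param universe character vector of all eligible orthogroups.
#' @return list `k` (overlap), `K`, `n`, `N`, `p`.
#' @export
overlap_test <- function(study, reference, universe) {
  assert_that(length(universe) > 0, "universe is empty")
  study <- intersect(unique(study), universe)
  reference <- intersect(unique(reference), universe)
  k <- length(intersect(study, reference))
  p <- phyper(k - 1, length(reference), length(universe) - length(reference),
              length(study), lower.tail = FALSE)
  list(k = k, K = length(reference), n = length(study), N = length(universe), p = p)
}
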