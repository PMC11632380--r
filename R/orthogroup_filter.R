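# Orthogroup retention, paralog exclusion, alignment-column filtering, and
# the trait-group gene-family loss screen.

#' Read / write an orthogroup gene-count table (OrthoFinder dialect)
#'
#' First column = orthogroup id, one column per species, optional trailing
#' `Total` column (ignored on read, recomputed on write).
#'
#' @param path TSV path.
#' @return data.frame of counts, rownames = orthogroup ids.
#' @export
read_og_counts <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  assert_that(ncol(tab) >= 2L, "count table needs an id column plus species columns")
  rownames(tab) <- tab[[1]]
  tab <- tab[, -1, drop = FALSE]
  if (tolower(names(tab)[ncol(tab)]) == "total") tab <- tab[, -ncol(tab), drop = FALSE]
  as.data.frame(lapply(tab, as.integer), row.names = rownames(tab),
                check.names = FALSE)
}

#' @rdname read_og_counts
#' @param counts count table (data.frame, rownames = orthogroup ids).
#' @param id_col name for the id column on write.
#' @export
write_og_counts <- function(counts, path, id_col = "Orthogroup") {
  out <- data.frame(id = rownames(counts), counts, Total = rowSums(counts),
                    check.names = FALSE)
  names(out)[1] <- id_col
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Retain near-single-copy orthogroups and list paralogous species
#'
#' An orthogroup is retained when it is present (count >= 1) in every
#' species and single-copy (count == 1) in at least
#' `ceil(min_single_fraction x n_species)` species ("at least 70%" rounds
#' up). In retained orthogroups, species with more than one copy are listed
#' as excluded: all their copies are dropped from downstream analyses.
#'
#' @param counts orthogroup x species count table (data.frame or matrix,
#'   rownames = orthogroup ids, non-negative integers).
#' @param min_single_fraction minimum fraction of single-copy species
#'   (default 0.7).
#' @return list with `retained` (character vector of orthogroup ids) and
#'   `excluded` (named list orthogroup -> species with paralogs).
#' @export
filter_single_copy <- function(counts, min_single_fraction = 0.7) {
  counts <- as.matrix(counts)
  assert_that(nrow(counts) >= 1L && ncol(counts) >= 1L, "count table is empty")
  assert_that(all(counts >= 0), "counts must be non-negative")
  assert_that(min_single_fraction > 0 && min_single_fraction <= 1,
              "min_single_fraction must be in (0, 1]")
  need <- ceiling(min_single_fraction * ncol(counts))
  present_all <- rowSums(counts >= 1) == ncol(counts)
  single_n <- rowSums(counts == 1)
  keep <- present_all & single_n >= need
  retained <- rownames(counts)[keep]
  excluded <- lapply(retained, function(og) {
    colnames(counts)[counts[og, ] > 1]
  })
  names(excluded) <- retained
  list(retained = retained, excluded = excluded,
       min_single_fraction = min_single_fraction, n_single_required = need)
}

#' Remove alignment columns with excessive missing data
#'
#' Drops every nucleotide column whose fraction of gap (`-`) or ambiguous
#' (`N`) characters exceeds `max_missing_fraction` ("over 50%" is strict:
#' exactly 50% missing is kept).
#'
#' @param seqs named character vector of aligned sequences of equal length.
#' @param max_missing_fraction maximum tolerated missing fraction per column
#'   (default 0.5).
#' @return the filtered sequences, with attributes `n_removed` and
#'   `skipped` (TRUE when every column was removed, with a warning).
#' @export
filter_alignment_columns <- function(seqs, max_missing_fraction = 0.5) {
  assert_that(is.character(seqs) && length(seqs) >= 1L, "seqs must be character")
  lens <- unique(nchar(seqs))
  assert_that(length(lens) == 1L, "sequences must have equal lengths")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  missing_frac <- colMeans(mat == "-" | mat == "N")
  keep <- missing_frac <= max_missing_fraction
  if (!any(keep)) {
    warning("all alignment columns removed; orthogroup flagged as skipped")
    out <- setNames(rep("", length(seqs)), names(seqs))
    attr(out, "n_removed") <- lens
    attr(out, "skipped") <- TRUE
    return(out)
  }
  out <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
  names(out) <- names(seqs)
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "skipped") <- FALSE
  out
}

#' Screen gene families for trait-associated loss
#'
#' Families with `max_family_size` or more total genes are removed first
#' (large, fast-evolving families are unreliable for presence/absence
#' calls). A remaining family is flagged when it is absent (count 0) in all,
#' or all but `allowed_exceptions`, species of one trait group while present
#' (count >= 1) in all, or most, species of the other group.
#'
#' @param counts orthogroup x species count table.
#' @param traits trait table covering all species in `counts`.
#' @param max_family_size families with at least this many total genes are
#'   removed before screening (default 100).
#' @param majority_rule `"all_but_m"` (default, with `allowed_exceptions = 1`,
#'   the near-universal-loss pattern) or `"strict_majority"`.
#' @param allowed_exceptions number of exception species tolerated in the
#'   lost group under `"all_but_m"`.
#' @param present_fraction minimum fraction of the other group that must
#'   retain the family (default 1 = all).
#' @return data.frame `orthogroup`, `pattern` (`lost_in_foreground` /
#'   `lost_in_background`), `exceptions` (comma-separated species, "" if none).
#' @export
screen_family_loss <- function(counts, traits, max_family_size = 100,
                               majority_rule = c("all_but_m", "strict_majority"),
                               allowed_exceptions = 1, present_fraction = 1) {
  majority_rule <- match.arg(majority_rule)
  counts <- as.matrix(counts)
  species <- colnames(counts)
  assert_that(all(species %in% traits$species), "traits must cover all species in counts")
  fg <- intersect(foreground_species(traits), species)
  bg <- setdiff(species, fg)
  assert_that(length(fg) >= 1L && length(bg) >= 1L, "both trait groups must be non-empty")
  counts <- counts[rowSums(counts) < max_family_size, , drop = FALSE]
  flag_group <- function(lost_grp, kept_grp) {
    absent <- rowSums(counts[, lost_grp, drop = FALSE] == 0)
    present <- rowSums(counts[, kept_grp, drop = FALSE] >= 1)
    thresh <- if (majority_rule == "all_but_m") {
      length(lost_grp) - allowed_exceptions
    } else {
      floor(length(lost_grp) / 2) + 1
    }
    hit <- absent >= thresh & absent < length(lost_grp) + 1 &
      present >= ceiling(present_fraction * length(kept_grp))
    # a family absent everywhere is not a trait-associated loss
    hit <- hit & rowSums(counts[, kept_grp, drop = FALSE]) > 0
    which(hit)
  }
  rows <- list()
  for (side in c("foreground", "background")) {
    lost_grp <- if (side == "foreground") fg else bg
    kept_grp <- if (side == "foreground") bg else fg
    for (i in flag_group(lost_grp, kept_grp)) {
      exc <- lost_grp[counts[i, lost_grp] > 0]
      rows[[length(rows) + 1L]] <- data.frame(
        orthogroup = rownames(counts)[i],
        pattern = paste0("lost_in_", side),
        exceptions = paste(exc, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(orthogroup = character(0), pattern = character(0),
                      exceptions = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
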