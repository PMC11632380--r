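#' Parse a Newick string into a validated rooted tree
#'
#' Thin, validating wrapper around [ape::read.tree()]. Trees are treated as
#' rooted throughout the package; every internal node receives a stable label
#' (existing labels are kept, unlabeled nodes get synthetic `n<k>` ids) so that
#' branches can be addressed by the node they lead to.
#'
#' @param text a Newick string (must end with `;`). Branch lengths are
#'   optional and default to 0.
#' @return an object of class `phylo` with unique tip labels, complete node
#'   labels, and non-negative branch lengths.
#' @examples
#' tr <- parse_newick("((A:1,B:1):0.5,C:2);")
#' branch_table(tr)
#' @export
parse_newick <- function(text) {
  assert_that(is.character(text) && length(text) == 1L, "text must be a single string")
  text <- trimws(text)
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("malformed Newick: unmatched ')' at character %d", i), call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop(sprintf("malformed Newick: %d unclosed '(' at character %d", depth, length(chars)),
         call. = FALSE)
  }
  if (!grepl(";\\s*$", text)) {
    stop(sprintf("malformed Newick: missing terminal ';' at character %d", nchar(text)),
         call. = FALSE)
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("malformed Newick: ", conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("malformed Newick: parser returned no tree", call. = FALSE)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  tree$edge.length[is.na(tree$edge.length)] <- 0
  validate_tree(tree)
  ensure_node_labels(tree)
}

#' Serialize a tree to Newick
#'
#' Round-trips with [parse_newick()]: topology, labels, and branch lengths are
#' preserved (lengths to better than 1e-9 relative precision).
#'
#' @param tree a `phylo` object.
#' @param file optional path; when given the string is also written to disk.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  validate_tree(tree)
  s <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Read one or more Newick trees from a file
#'
#' Accepts one tree per line (or several per file); each tree is validated and
#' given complete node labels.
#'
#' @param path path to a Newick file.
#' @return a single `phylo` if the file holds one tree, otherwise a named list
#'   (`multiPhylo`-like) of `phylo` objects.
#' @export
read_newick <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  trees <- lapply(lines, parse_newick)
  if (length(trees) == 1L) trees[[1]] else trees
}

#' Re-root a tree on an outgroup species
#'
#' Trees are treated as rooted throughout the package; when an input tree's
#' rooting does not reflect the intended outgroup convention, this re-roots
#' it on the branch leading to `outgroup` and resolves the basal
#' trichotomy.
#'
#' @param tree a `phylo`.
#' @param outgroup a tip label to root on.
#' @return the re-rooted tree with complete node labels.
#' @export
root_tree <- function(tree, outgroup) {
  validate_tree(tree)
  assert_that(outgroup %in% tree$tip.label,
              sprintf("outgroup '%s' is not a tip of the tree", outgroup))
  out <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  out$node.label <- NULL  # labels may no longer match the new node numbering
  ensure_node_labels(out)
}

# Validate the core tree invariants: one root, unique tips, lengths >= 0.
validate_tree <- function(tree) {
  assert_that(inherits(tree, "phylo"), "tree must be a 'phylo' object")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch length(s) are not allowed", call. = FALSE)
  }
  n_node <- ape::Ntip(tree) + tree$Nnode
  parents <- unique(tree$edge[, 1])
  roots <- setdiff(parents, tree$edge[, 2])
  assert_that(length(roots) == 1L, "tree must have exactly one root")
  assert_that(n_node == length(unique(c(tree$edge))), "tree edge table is inconsistent")
  invisible(tree)
}

# Give every internal node a label; synthetic ids are n<k> by node number,
# skipping any id already in use.
ensure_node_labels <- function(tree) {
  n_tip <- ape::Ntip(tree)
  labs <- tree$node.label
  if (is.null(labs)) labs <- rep("", tree$Nnode)
  labs[is.na(labs)] <- ""
  used <- c(tree$tip.label, labs[nzchar(labs)])
  for (i in seq_len(tree$Nnode)) {
    if (!nzchar(labs[i])) {
      cand <- paste0("n", n_tip + i)
      while (cand %in% used) cand <- paste0(cand, "x")
      labs[i] <- cand
      used <- c(used, cand)
    }
  }
  if (anyDuplicated(labs)) stop("duplicate internal node labels", call. = FALSE)
  tree$node.label <- labs
  tree
}

# Node label for every node number (tips then internals).
node_ids <- function(tree) {
  tree <- ensure_node_labels(tree)
  c(tree$tip.label, tree$node.label)
}

#' Branch table of a tree
#'
#' One row per non-root branch. A branch is identified by the node it leads to
#' (its child), so the foreground status of a species attaches to its terminal
#' branch.
#'
#' @param tree a `phylo` object.
#' @param foreground optional character vector of foreground species; their
#'   terminal branches get `foreground = TRUE`. Internal branches are never
#'   flagged (only terminal branches carry the trait mapping).
#' @return a data.frame with columns `branch_id`, `parent_id`, `child_id`,
#'   `length`, `is_terminal`, `foreground`.
#' @export
branch_table <- function(tree, foreground = NULL) {
  tree <- ensure_node_labels(validate_tree(tree))
  ids <- node_ids(tree)
  n_tip <- ape::Ntip(tree)
  child <- tree$edge[, 2]
  out <- data.frame(
    branch_id = ids[child],
    parent_id = ids[tree$edge[, 1]],
    child_id = ids[child],
    length = tree$edge.length %||% rep(0, nrow(tree$edge)),
    is_terminal = child <= n_tip,
    foreground = FALSE,
    stringsAsFactors = FALSE
  )
  if (!is.null(foreground)) {
    unknown <- setdiff(foreground, tree$tip.label)
    assert_that(length(unknown) == 0L,
                paste0("foreground species not in tree: ", paste(unknown, collapse = ", ")))
    out$foreground <- out$is_terminal & out$branch_id %in% foreground
  }
  out
}

#' Simulate Brownian motion on a tree
#'
#' Tip values follow a multivariate normal with covariance `sigma2` times the
#' shared root-to-tip path length. Used by the permulation null, which only
#' needs the ranks of the tip values.
#'
#' @param tree a `phylo` object with non-negative branch lengths.
#' @param sigma2 Brownian rate (variance per unit branch length), > 0.
#' @param seed optional integer seed for reproducibility.
#' @return a named numeric vector of tip values (root value 0).
#' @export
simulate_brownian <- function(tree, sigma2 = 1, seed = NULL) {
  validate_tree(tree)
  assert_that(is.numeric(sigma2) && length(sigma2) == 1L && sigma2 > 0,
              "sigma2 must be a single positive number")
  with_seed(seed, {
    tr <- ape::reorder.phylo(tree, "cladewise")
    n_tip <- ape::Ntip(tr)
    n_node <- n_tip + tr$Nnode
    vals <- numeric(n_node)
    root <- setdiff(unique(tr$edge[, 1]), tr$edge[, 2])
    vals[root] <- 0
    len <- tr$edge.length %||% rep(0, nrow(tr$edge))
    inc <- rnorm(nrow(tr$edge), mean = 0, sd = sqrt(sigma2 * len))
    for (e in seq_len(nrow(tr$edge))) {
      vals[tr$edge[e, 2]] <- vals[tr$edge[e, 1]] + inc[e]
    }
    setNames(vals[seq_len(n_tip)], tr$tip.label)
  })
}

# Tip labels descending from each edge's child node, as a list keyed by
# branch id. Used to match gene-tree branches to the species tree.
clade_tip_sets <- function(tree) {
  tree <- ensure_node_labels(tree)
  n_tip <- ape::Ntip(tree)
  ids <- node_ids(tree)
  post <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]; ch <- post$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  out <- lapply(tree$edge[, 2], function(ch) sort(sets[[ch]]))
  names(out) <- ids[tree$edge[, 2]]
  out
}
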