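# Synthetic-data generators emulating the downstream products of a
# comparative-genomics selection study: a species tree, a binary foreground
# trait (with a correlated confounder), trait-correlated gene trees, codon
# alignments with foreground selection-intensity shifts, and orthogroup
# count tables with planted family-loss patterns. All generators are
# bit-reproducible under fixed seeds.

#' Simulation configuration
#'
#' Defaults emulate the structure of the study design the package targets:
#' 27 species of which 17 are foreground (have lost the ancestral trait),
#' pure-birth species tree rescaled to unit depth, per-orthogroup gene trees
#' with lognormal branch noise, and codon alignments under a three-class
#' omega mixture with selection intensity K shifted on foreground branches.
#'
#' @param n_species number of species (>= 4).
#' @param n_foreground number of foreground species (0 < n_foreground < n_species).
#' @param n_orthogroups number of gene trees to simulate.
#' @param shift_fraction fraction of orthogroups with a foreground rate shift.
#' @param multiplier rate multiplier applied to foreground terminal branches
#'   of shifted orthogroups.
#' @param noise_sd sd of the lognormal per-branch noise on gene-tree lengths.
#' @param gene_rate_sd sd of the lognormal per-orthogroup rate factor.
#' @param n_codon_orthogroups number of orthogroups that also get a simulated
#'   codon alignment.
#' @param relax_fraction,intensify_fraction fractions of codon orthogroups
#'   simulated with K = `k_relaxed` / K = `k_intensified` on foreground
#'   branches (the rest use K = 1).
#' @param k_relaxed,k_intensified true selection intensities for the two
#'   shifted scenarios.
#' @param alignment_codons codon alignment length (>= 50).
#' @param kappa,omega,weights codon model parameters (see [codon_model_spec()]).
#' @param foreground_mode `"clustered"` or `"dispersed"` foreground placement.
#' @param p_social_fg,p_social_bg probability that a foreground / background
#'   species is labelled social; the difference generates the trait
#'   confounding probed by the PGLS stage.
#' @param n_families number of orthogroup families in the count table.
#' @param seed base seed; every generator derives its own stream from it.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 27, n_foreground = 17,
                              n_orthogroups = 100, shift_fraction = 0.2,
                              multiplier = 2, noise_sd = 0.2, gene_rate_sd = 0.3,
                              n_codon_orthogroups = 12,
                              relax_fraction = 0.25, intensify_fraction = 0.25,
                              k_relaxed = 0.3, k_intensified = 3,
                              alignment_codons = 300,
                              kappa = 2, omega = c(0.1, 1, 1.5),
                              weights = c(0.7, 0.25, 0.05),
                              foreground_mode = "clustered",
                              p_social_fg = 0.8, p_social_bg = 0.1,
                              n_families = 60, seed = 1) {
  cfg <- list(n_species = n_species, n_foreground = n_foreground,
              n_orthogroups = n_orthogroups, shift_fraction = shift_fraction,
              multiplier = multiplier, noise_sd = noise_sd,
              gene_rate_sd = gene_rate_sd,
              n_codon_orthogroups = n_codon_orthogroups,
              relax_fraction = relax_fraction,
              intensify_fraction = intensify_fraction,
              k_relaxed = k_relaxed, k_intensified = k_intensified,
              alignment_codons = alignment_codons,
              kappa = kappa, omega = omega, weights = weights,
              foreground_mode = foreground_mode,
              p_social_fg = p_social_fg, p_social_bg = p_social_bg,
              n_families = n_families, seed = seed)
  assert_that(cfg$n_species >= 4, "n_species must be >= 4")
  assert_that(cfg$n_foreground > 0 && cfg$n_foreground < cfg$n_species,
              "need 0 < n_foreground < n_species")
  assert_that(cfg$multiplier > 0, "multiplier must be > 0")
  assert_that(cfg$shift_fraction >= 0 && cfg$shift_fraction <= 1,
              "shift_fraction must be in [0, 1]")
  assert_that(all(c(cfg$k_relaxed, cfg$k_intensified) > 0), "true K values must be > 0")
  structure(cfg, class = "simulation_config")
}

#' Generate a pure-birth species tree
#'
#' Yule topology with exponential branching times, rescaled so the maximum
#' root-to-tip depth is exactly 1 (branch lengths are then in relative
#' expected substitutions per site).
#'
#' @param n_species number of tips (>= 4).
#' @param seed optional integer seed.
#' @return a rooted binary `phylo` with tips `sp01`, `sp02`, ...
#' @export
generate_species_tree <- function(n_species, seed = NULL) {
  assert_that(is.numeric(n_species) && n_species >= 4, "n_species must be >= 4")
  with_seed(seed, {
    tr <- ape::rphylo(n_species, birth = 1, death = 0)
    tr$tip.label <- sprintf("sp%02d", seq_len(n_species))
    depth <- max(ape::node.depth.edgelength(tr)[seq_len(n_species)])
    tr$edge.length <- tr$edge.length / depth
    ensure_node_labels(tr)
  })
}

#' Assign the binary foreground trait (and a correlated confounder)
#'
#' Marks `n_foreground` species as having lost the ancestral state (prepupal
#' diapause). `clustered` mode fills whole clades greedily (largest clade
#' that still fits, ties broken at random) to mimic phylogenetically
#' clustered convergent losses; `dispersed` samples tips uniformly. A second
#' binary trait, sociality, is generated to correlate with the foreground
#' flag so the confounding tested by the PGLS stage is present in synthetic
#' data.
#'
#' @param tree species tree (`phylo`).
#' @param n_foreground number of foreground species (< number of tips).
#' @param mode `"clustered"` or `"dispersed"`.
#' @param max_clade optional cap on the size of any single selected clade in
#'   clustered mode; `ceiling(n_foreground / k)` forces at least `k`
#'   independent origins of the derived state (convergence proper). Default
#'   `NULL`: unlimited (pure greedy fill).
#' @param seed optional integer seed.
#' @param p_social_fg,p_social_bg probability of the social label given
#'   foreground / background status.
#' @return a trait table: data.frame with columns `species`, `foreground`,
#'   `prepupal_diapause` (yes/no), `sociality` (solitary/social).
#' @export
assign_foreground <- function(tree, n_foreground, mode = c("clustered", "dispersed"),
                              seed = NULL, p_social_fg = 0.8, p_social_bg = 0.1,
                              max_clade = NULL) {
  mode <- match.arg(mode)
  validate_tree(tree)
  n_tip <- ape::Ntip(tree)
  assert_that(is.numeric(n_foreground) && n_foreground >= 1 && n_foreground < n_tip,
              "need 1 <= n_foreground < number of species")
  with_seed(seed, {
    fg <- character(0)
    if (mode == "dispersed") {
      fg <- sample(tree$tip.label, n_foreground)
    } else {
      clades <- clade_tip_sets(tree)
      remaining <- n_foreground
      repeat {
        if (remaining == 0L) break
        sizes <- vapply(clades, length, integer(1))
        cap <- min(remaining, max_clade %||% remaining)
        ok <- which(sizes <= cap &
                      !vapply(clades, function(s) any(s %in% fg), logical(1)))
        if (length(ok) == 0L) {
          warning("clustered foreground request not satisfiable; falling back to dispersed fill")
          fg <- c(fg, sample(setdiff(tree$tip.label, fg), remaining))
          break
        }
        best <- ok[sizes[ok] == max(sizes[ok])]
        pick <- if (length(best) > 1L) sample(best, 1L) else best
        fg <- c(fg, clades[[pick]])
        remaining <- n_foreground - length(fg)
      }
    }
    is_fg <- tree$tip.label %in% fg
    social <- ifelse(runif(n_tip) < ifelse(is_fg, p_social_fg, p_social_bg),
                     "social", "solitary")
    data.frame(species = tree$tip.label,
               foreground = is_fg,
               prepupal_diapause = ifelse(is_fg, "no", "yes"),
               sociality = social,
               stringsAsFactors = FALSE)
  })
}

#' Species currently flagged as foreground in a trait table
#' @param traits a trait table as returned by [assign_foreground()].
#' @return character vector of species names.
#' @export
foreground_species <- function(traits) {
  assert_that(all(c("species", "foreground") %in% names(traits)),
              "traits must have 'species' and 'foreground' columns")
  traits$species[traits$foreground]
}

#' Simulate per-orthogroup gene trees with trait-correlated rate shifts
#'
#' Every gene tree shares the species topology. Each branch length is the
#' master length times a per-orthogroup lognormal rate, times per-branch
#' lognormal noise, and additionally times `multiplier` on foreground
#' terminal branches of the designated "shifted" orthogroups.
#'
#' @param tree master species tree.
#' @param traits trait table ([assign_foreground()]).
#' @param n_orthogroups number of gene trees.
#' @param shift_fraction fraction of orthogroups that carry the shift.
#' @param multiplier foreground terminal-branch multiplier (> 0).
#' @param noise_sd sd of per-branch lognormal noise (0 = none).
#' @param gene_rate_sd sd of the per-orthogroup lognormal rate factor.
#' @param drop_species optional named list orthogroup -> species to drop from
#'   that gene tree (paralog-excluded species).
#' @param seed optional integer seed.
#' @return list with `trees` (named list of `phylo`) and `truth`
#'   (data.frame `orthogroup`, `shifted`).
#' @export
simulate_gene_trees <- function(tree, traits, n_orthogroups,
                                shift_fraction = 0.2, multiplier = 2,
                                noise_sd = 0.2, gene_rate_sd = 0.3,
                                drop_species = NULL, seed = NULL) {
  validate_tree(tree)
  assert_that(multiplier > 0, "multiplier must be > 0")
  assert_that(shift_fraction >= 0 && shift_fraction <= 1, "shift_fraction must be in [0, 1]")
  fg <- foreground_species(traits)
  with_seed(seed, {
    ids <- sprintf("OG%04d", seq_len(n_orthogroups))
    n_shift <- round(shift_fraction * n_orthogroups)
    shifted <- ids %in% sample(ids, n_shift)
    bt <- branch_table(tree, foreground = fg)
    fg_edge <- bt$foreground  # rows align with tree$edge
    trees <- vector("list", n_orthogroups)
    names(trees) <- ids
    for (g in seq_len(n_orthogroups)) {
      gt <- tree
      rate <- exp(rnorm(1, 0, gene_rate_sd))
      noise <- exp(rnorm(nrow(bt), 0, noise_sd))
      len <- tree$edge.length * rate * noise
      if (shifted[g]) len[fg_edge] <- len[fg_edge] * multiplier
      gt$edge.length <- len
      drop <- drop_species[[ids[g]]]
      if (!is.null(drop) && length(drop) > 0) {
        gt <- ensure_node_labels(ape::drop.tip(gt, drop))
      }
      trees[[g]] <- gt
    }
    list(trees = trees,
         truth = data.frame(orthogroup = ids, shifted = shifted,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a codon alignment with a foreground selection-intensity shift
#'
#' Sites evolve independently along the tree under the MG94-style matrix of
#' [build_codon_matrix()]. Each site draws an omega category from `spec`; on
#' the foreground (test) branches the category's omega is exponentiated by
#' `foreground_K` before the rate matrix is built. Root states are drawn from
#' the stationary codon frequencies, so no stop codons ever appear.
#'
#' @param tree rooted `phylo` with branch lengths in expected substitutions
#'   per codon site.
#' @param spec a [codon_model_spec()].
#' @param foreground_K selection intensity on the test branches (> 0).
#' @param length_codons number of codon sites (>= 50).
#' @param seed optional integer seed.
#' @param test_branches branch ids (child node labels) treated as foreground;
#'   default: none.
#' @param branch_mix optional named list `branch_id -> list(omega=, weights=)`
#'   giving a branch its own omega distribution drawn independently per site
#'   (episodic positive-selection scenarios); overrides `foreground_K` on
#'   those branches.
#' @return a `codon_align`; the per-site true categories are attached as
#'   attribute `site_category`.
#' @export
simulate_codon_alignment <- function(tree, spec, foreground_K = 1, length_codons = 300,
                                     seed = NULL, test_branches = character(),
                                     branch_mix = NULL) {
  assert_that(inherits(spec, "codon_model_spec"), "spec must be a codon_model_spec")
  assert_that(length_codons >= 50, "length_codons must be >= 50")
  assert_that(foreground_K > 0, "foreground_K must be > 0")
  tree <- ensure_node_labels(validate_tree(tree))
  tab <- codon_tables()
  ids <- node_ids(tree)
  with_seed(seed, {
    pre <- ape::reorder.phylo(tree, "cladewise")
    n_tip <- ape::Ntip(tree)
    ncat <- length(spec$omega)
    cats <- sample.int(ncat, length_codons, replace = TRUE, prob = spec$weights)
    node_states <- matrix(NA_integer_, n_tip + tree$Nnode, length_codons)
    root <- setdiff(unique(pre$edge[, 1]), pre$edge[, 2])
    node_states[root, ] <- sample.int(tab$n, length_codons, replace = TRUE,
                                      prob = spec$freqs)
    eig_cache <- new.env(parent = emptyenv())
    eig_for <- function(w) {
      key <- sprintf("%.12g", w)
      if (is.null(eig_cache[[key]])) {
        eig_cache[[key]] <- codon_eigen(build_codon_matrix(spec, w), spec$freqs)
      }
      eig_cache[[key]]
    }
    lens <- pre$edge.length %||% rep(0, nrow(pre$edge))
    for (e in seq_len(nrow(pre$edge))) {
      p <- pre$edge[e, 1]; ch <- pre$edge[e, 2]
      bid <- ids[ch]
      mix <- branch_mix[[bid]]
      if (is.null(mix)) {
        om <- spec$omega
        if (bid %in% test_branches) om <- om^foreground_K
        site_cat <- cats
      } else {
        om <- mix$omega
        site_cat <- sample.int(length(om), length_codons, replace = TRUE,
                               prob = mix$weights)
      }
      P_by_cat <- lapply(om, function(w) {
        P <- codon_P(eig_for(w), lens[e])
        P / rowSums(P)
      })
      out <- integer(length_codons)
      for (cc in seq_along(om)) {
        sel <- which(site_cat == cc)
        if (!length(sel)) next
        by_state <- split(sel, node_states[p, sel])
        for (s in names(by_state)) {
          idx <- by_state[[s]]
          out[idx] <- sample.int(tab$n, length(idx), replace = TRUE,
                                 prob = P_by_cat[[cc]][as.integer(s), ])
        }
      }
      node_states[ch, ] <- out
    }
    seqs <- vapply(seq_len(n_tip), function(i) {
      paste(tab$codons[node_states[i, ]], collapse = "")
    }, character(1))
    names(seqs) <- tree$tip.label
    aln <- encode_codon_alignment(seqs)
    attr(aln, "site_category") <- cats
    aln
  })
}

#' Generate an orthogroup-by-species gene-count table with planted patterns
#'
#' Plants the family-loss patterns the screening stage looks for: a family
#' lost in every foreground species except one designated exception (the
#' "PTTH/torso" pattern), a family lost in all foreground species, a family
#' lost in the background group, universal single-copy families, and one
#' large family (>= 100 genes) that the size filter must remove. The
#' remaining families get random small counts.
#'
#' @param species character vector of species names.
#' @param traits trait table covering all `species`.
#' @param n_families total number of families (>= 6).
#' @param seed optional integer seed.
#' @return list with `counts` (data.frame, rownames = family ids, one column
#'   per species) and `truth` (data.frame `orthogroup`, `scenario`,
#'   `exception`).
#' @export
generate_og_counts <- function(species, traits, n_families = 60, seed = NULL) {
  assert_that(n_families >= 6, "n_families must be >= 6")
  assert_that(all(species %in% traits$species), "traits must cover all species")
  fg <- intersect(foreground_species(traits), species)
  bg <- setdiff(species, fg)
  assert_that(length(fg) >= 2 && length(bg) >= 2,
              "need >= 2 foreground and >= 2 background species")
  with_seed(seed, {
    ids <- sprintf("FAM%04d", seq_len(n_families))
    counts <- matrix(0L, n_families, length(species),
                     dimnames = list(ids, species))
    scen <- rep("random", n_families)
    exception <- rep(NA_character_, n_families)

    counts[1, ] <- 1L
    scen[1] <- "universal_single_copy"

    exc <- sample(fg, 1)
    counts[2, bg] <- 1L
    counts[2, exc] <- 2L
    scen[2] <- "lost_foreground_except_one"
    exception[2] <- exc

    counts[3, bg] <- 1L
    scen[3] <- "lost_foreground"

    counts[4, fg] <- 1L
    scen[4] <- "lost_background"

    big <- pmax(rpois(length(species), 120 / length(species)), 1L)
    counts[5, ] <- big
    if (sum(big) < 100L) counts[5, 1] <- counts[5, 1] + (100L - sum(big))
    scen[5] <- "large_family"

    for (i in 6:n_families) {
      counts[i, ] <- rpois(length(species), 1.1)
    }
    list(counts = as.data.frame(counts),
         truth = data.frame(orthogroup = ids, scenario = scen,
                            exception = exception, stringsAsFactors = FALSE))
  })
}
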