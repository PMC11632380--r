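# End-to-end orchestration: simulate or load inputs, filter, RER +
# permulation, codon selection tests, classification, enrichment, trait
# association; plain TSV/JSON artifacts so any stage can be re-run alone.

#' Read / write aligned FASTA
#'
#' @param path FASTA path.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  x <- ape::read.FASTA(path)
  out <- vapply(as.character(x), function(v) toupper(paste(v, collapse = "")), character(1))
  setNames(out, names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  ape::write.FASTA(ape::as.DNAbin(strsplit(tolower(seqs), "")), path)
  invisible(path)
}

#' Read / write a species trait table
#'
#' TSV with a `species` column; a logical `foreground` column is derived
#' from `prepupal_diapause == "no"` when absent.
#'
#' @param path TSV path.
#' @export
read_trait_table <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  tab <- read.delim(path, stringsAsFactors = FALSE)
  assert_that("species" %in% names(tab), "trait table needs a 'species' column")
  assert_that(!anyDuplicated(tab$species), "duplicate species in trait table")
  if (!"foreground" %in% names(tab)) {
    assert_that("prepupal_diapause" %in% names(tab),
                "need a 'foreground' or 'prepupal_diapause' column")
    tab$foreground <- tab$prepupal_diapause == "no"
  }
  tab$foreground <- as.logical(tab$foreground)
  tab
}

#' @rdname read_trait_table
#' @param traits trait table data.frame.
#' @export
write_trait_table <- function(traits, path) {
  write.table(traits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a complete synthetic study
#'
#' Bundles every generator into one seeded scenario: species tree, traits,
#' trait-correlated gene trees (with paralog-excluded species dropped),
#' codon alignments with foreground selection-intensity shifts, an
#' orthogroup count table (near-single-copy orthogroups plus planted
#' family-loss patterns), and a toy term annotation with one term
#' concentrated in the rate-shifted orthogroups.
#'
#' @param config a [simulation_config()].
#' @return object of class `convsel_study`.
#' @export
simulate_study <- function(config = simulation_config()) {
  assert_that(inherits(config, "simulation_config"),
              "config must be a simulation_config")
  seed <- config$seed
  tree <- generate_species_tree(config$n_species, seed = derive_seed(seed, 1))
  traits <- assign_foreground(tree, config$n_foreground,
                              mode = config$foreground_mode,
                              seed = derive_seed(seed, 2),
                              p_social_fg = config$p_social_fg,
                              p_social_bg = config$p_social_bg)
  og_ids <- sprintf("OG%04d", seq_len(config$n_orthogroups))
  # ~10% of orthogroups carry one paralogous species (count 2, excluded
  # downstream); everything else is single-copy in all species
  paralogs <- with_seed(derive_seed(seed, 3), {
    n_par <- max(1L, round(0.1 * config$n_orthogroups))
    ogs <- sample(og_ids, n_par)
    setNames(as.list(sample(tree$tip.label, n_par, replace = TRUE)), ogs)
  })
  counts_og <- matrix(1L, config$n_orthogroups, config$n_species,
                      dimnames = list(og_ids, tree$tip.label))
  for (og in names(paralogs)) counts_og[og, paralogs[[og]]] <- 2L
  fams <- generate_og_counts(tree$tip.label, traits, n_families = config$n_families,
                             seed = derive_seed(seed, 4))
  counts <- rbind(as.data.frame(counts_og), fams$counts)

  gts <- simulate_gene_trees(tree, traits, config$n_orthogroups,
                             shift_fraction = config$shift_fraction,
                             multiplier = config$multiplier,
                             noise_sd = config$noise_sd,
                             gene_rate_sd = config$gene_rate_sd,
                             drop_species = paralogs,
                             seed = derive_seed(seed, 5))

  spec <- codon_model_spec(kappa = config$kappa, omega = config$omega,
                           weights = config$weights)
  fg <- foreground_species(traits)
  codon_ogs <- with_seed(derive_seed(seed, 6), {
    sample(setdiff(og_ids, names(paralogs)), config$n_codon_orthogroups)
  })
  n_rel <- round(config$relax_fraction * length(codon_ogs))
  n_int <- round(config$intensify_fraction * length(codon_ogs))
  k_true <- c(rep(config$k_relaxed, n_rel), rep(config$k_intensified, n_int),
              rep(1, length(codon_ogs) - n_rel - n_int))
  alignments <- list()
  for (i in seq_along(codon_ogs)) {
    alignments[[codon_ogs[i]]] <- simulate_codon_alignment(
      tree, spec, foreground_K = k_true[i],
      length_codons = config$alignment_codons,
      seed = derive_seed(seed, 100 + i), test_branches = fg)
  }
  codon_truth <- data.frame(orthogroup = codon_ogs, K_true = k_true,
                            scenario = ifelse(k_true < 1, "relaxed",
                                              ifelse(k_true > 1, "intensified", "null")),
                            stringsAsFactors = FALSE)

  annotation <- with_seed(derive_seed(seed, 7), {
    shifted <- gts$truth$orthogroup[gts$truth$shifted]
    rows <- lapply(og_ids, function(og) {
      terms <- sample(sprintf("T%04d", 2:15), sample(1:3, 1))
      if (og %in% shifted && runif(1) < 0.6) terms <- c(terms, "T0001")
      data.frame(orthogroup = og, term = unique(terms), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  structure(list(tree = tree, traits = traits, counts = counts,
                 count_truth = fams$truth, gene_trees = gts$trees,
                 gene_truth = gts$truth, alignments = alignments,
                 codon_truth = codon_truth, annotation = annotation,
                 paralogs = paralogs, spec = spec, config = config),
            class = "convsel_study")
}

#' Write a simulated study to disk as plain-text artifacts
#'
#' Newick species tree, per-orthogroup Newick gene trees and FASTA
#' alignments, TSV trait/count/annotation tables and a JSON ground-truth
#' manifest.
#'
#' @param study a `convsel_study` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(study, dir) {
  assert_that(inherits(study, "convsel_study"), "study must be a convsel_study")
  dir.create(file.path(dir, "gene_trees"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "alignments"), showWarnings = FALSE)
  write_newick(study$tree, file.path(dir, "species_tree.nwk"))
  for (og in names(study$gene_trees)) {
    write_newick(study$gene_trees[[og]], file.path(dir, "gene_trees", paste0(og, ".nwk")))
  }
  for (og in names(study$alignments)) {
    write_fasta(decode_codon_alignment(study$alignments[[og]]),
                file.path(dir, "alignments", paste0(og, ".fasta")))
  }
  write_trait_table(study$traits, file.path(dir, "traits.tsv"))
  write_og_counts(study$counts, file.path(dir, "og_counts.tsv"))
  write.table(study$annotation, file.path(dir, "annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(config = unclass(study$config),
                   gene_truth = study$gene_truth,
                   codon_truth = study$codon_truth,
                   count_truth = study$count_truth,
                   paralogs = study$paralogs)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Default pipeline configuration
#'
#' Thresholds mirror the study conventions: selection-test alpha 0.05,
#' enrichment alpha 0.01 with terms needing more than 5 annotated
#' orthogroups, 70% single-copy retention, 50% column-missingness cutoff,
#' 100-gene family-size filter, and 1,000 permulation replicates.
#'
#' @param ... named overrides of the defaults (nested lists are merged).
#' @return a configuration list.
#' @export
default_pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    out_dir = NULL,
    simulate = NULL,   # list of simulation_config() overrides, or NULL
    paths = list(species_tree = NULL, gene_trees_dir = NULL,
                 alignments_dir = NULL, traits = NULL, og_counts = NULL,
                 annotation = NULL),
    thresholds = list(alpha = 0.05, enrichment_alpha = 0.01,
                      min_single_fraction = 0.7, max_missing_fraction = 0.5,
                      max_family_size = 100, n_perm = 1000, min_annotated = 5),
    flags = list(include_internal = FALSE, pseudo_p = FALSE,
                 n_starts = 3, run_branch_ps = TRUE)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
      cfg[[nm]] <- modifyList(cfg[[nm]], overrides[[nm]])
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  cfg
}

#' Load a pipeline configuration from YAML
#' @param path YAML file with any subset of the [default_pipeline_config()]
#'   fields.
#' @export
read_pipeline_config <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  do.call(default_pipeline_config, yaml::read_yaml(path))
}

pipeline_inputs <- function(config) {
  if (!is.null(config$simulate) && !isFALSE(config$simulate)) {
    sim_over <- if (is.list(config$simulate)) config$simulate else list()
    sim_cfg <- do.call(simulation_config,
                       modifyList(sim_over,
                                  list(seed = sim_over$seed %||% config$seed)))
    study <- simulate_study(sim_cfg)
    return(list(tree = study$tree, traits = study$traits, counts = study$counts,
                gene_trees = study$gene_trees, alignments = study$alignments,
                annotation = study$annotation, study = study))
  }
  p <- config$paths
  for (f in c("species_tree", "traits", "og_counts")) {
    assert_that(!is.null(p[[f]]) && file.exists(p[[f]]),
                sprintf("required input '%s' missing or not found", f))
  }
  for (d in c("gene_trees_dir", "alignments_dir")) {
    if (!is.null(p[[d]])) {
      assert_that(dir.exists(p[[d]]), sprintf("input directory '%s' not found", d))
    }
  }
  tree <- read_newick(p$species_tree)
  traits <- read_trait_table(p$traits)
  counts <- read_og_counts(p$og_counts)
  gene_trees <- list()
  if (!is.null(p$gene_trees_dir)) {
    files <- list.files(p$gene_trees_dir, pattern = "\\.nwk$|\\.tree$|\\.txt$",
                        full.names = TRUE)
    gene_trees <- lapply(files, read_newick)
    names(gene_trees) <- sub("\\.[^.]+$", "", basename(files))
  }
  alignments <- list()
  if (!is.null(p$alignments_dir)) {
    files <- list.files(p$alignments_dir, pattern = "\\.fa$|\\.fasta$", full.names = TRUE)
    alignments <- lapply(files, function(f) encode_codon_alignment(read_fasta(f)))
    names(alignments) <- sub("\\.[^.]+$", "", basename(files))
  }
  annotation <- if (!is.null(p$annotation) && file.exists(p$annotation)) {
    read.delim(p$annotation, stringsAsFactors = FALSE)
  } else NULL
  list(tree = tree, traits = traits, counts = counts, gene_trees = gene_trees,
       alignments = alignments, annotation = annotation, study = NULL)
}

#' Run the full analysis pipeline
#'
#' Executes filter -> RER + permulation -> codon selection tests ->
#' classification -> enrichment -> trait association on either a simulated
#' study (`config$simulate`) or user-supplied files (`config$paths`). All
#' randomness derives from `config$seed`; a rerun with the same
#' configuration reproduces every table.
#'
#' @param config a configuration list ([default_pipeline_config()]), or a
#'   YAML path.
#' @return a report list (tables and summary); when `config$out_dir` is set,
#'   TSV/JSON artifacts and a log are written there.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  th <- config$thresholds
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  say("stage input: %s", if (is.null(config$simulate)) "loading files" else "simulating study")
  inp <- pipeline_inputs(config)
  fg <- foreground_species(inp$traits)
  say("  %d species (%d foreground), %d orthogroups in count table",
      nrow(inp$traits), length(fg), nrow(inp$counts))

  say("stage filter: single-copy >= %.0f%%, family-size < %d",
      100 * th$min_single_fraction, th$max_family_size)
  sc <- filter_single_copy(inp$counts, th$min_single_fraction)
  losses <- screen_family_loss(inp$counts, inp$traits,
                               max_family_size = th$max_family_size)
  say("  retained %d orthogroups; %d trait-associated family losses",
      length(sc$retained), nrow(losses))

  rer_tab <- NULL
  if (length(inp$gene_trees) > 0) {
    use <- intersect(names(inp$gene_trees), sc$retained)
    say("stage rer: %d gene trees, %d permulations", length(use), th$n_perm)
    rer_tab <- rer_scan(inp$gene_trees[use], inp$tree, inp$traits,
                        n_perm = th$n_perm, seed = derive_seed(config$seed, 11))
  }

  relax_tab <- NULL
  ps_tab <- NULL
  if (length(inp$alignments) > 0) {
    test_ids <- foreground_branch_ids(inp$tree, fg,
                                      include_internal = config$flags$include_internal)
    say("stage codon: %d alignments, %d test branches", length(inp$alignments),
        length(test_ids))
    relax_rows <- list(); ps_rows <- list()
    for (og in names(inp$alignments)) {
      aln <- inp$alignments[[og]]
      if (length(aln$taxa) < 4L) {
        say("  %s skipped: fewer than 4 species after exclusion", og)
        next
      }
      flt <- filter_alignment_columns(decode_codon_alignment(aln),
                                      th$max_missing_fraction)
      if (isTRUE(attr(flt, "skipped"))) next
      aln <- encode_codon_alignment(flt)
      fit <- fit_relax(aln, inp$tree, test_ids, n_starts = config$flags$n_starts,
                       seed = derive_seed(config$seed, 21))
      relax_rows[[og]] <- data.frame(orthogroup = og, lnL_null = fit$lnL_null,
                                     lnL_alt = fit$lnL_alt, K = fit$K,
                                     lrt = fit$lrt, p = fit$p,
                                     converged = fit$converged,
                                     stringsAsFactors = FALSE)
      if (isTRUE(config$flags$run_branch_ps)) {
        ps <- fit_branch_positive(aln, inp$tree, test_ids,
                                  n_starts = config$flags$n_starts,
                                  seed = derive_seed(config$seed, 22),
                                  alpha = th$alpha)
        ps_rows[[og]] <- data.frame(orthogroup = og, positive = ps$positive,
                                    min_p_holm = min(ps$branches$p_holm),
                                    stringsAsFactors = FALSE)
      }
    }
    if (length(relax_rows)) {
      relax_tab <- do.call(rbind, relax_rows)
      relax_tab$q <- adjust_pvalues(relax_tab$p, "BH")
    }
    if (length(ps_rows)) ps_tab <- do.call(rbind, ps_rows)
  }

  say("stage classify: combining evidence at alpha = %.2f", th$alpha)
  sig_rer <- if (!is.null(rer_tab)) rer_tab[!is.na(rer_tab$q_bh) & rer_tab$q_bh < th$alpha, ] else NULL
  calls <- selection_calls(
    rho_pos = if (!is.null(sig_rer)) sig_rer$orthogroup[sig_rer$rho > 0] else character(0),
    rho_neg = if (!is.null(sig_rer)) sig_rer$orthogroup[sig_rer$rho < 0] else character(0),
    absrel = if (!is.null(ps_tab)) ps_tab$orthogroup[ps_tab$positive] else character(0),
    relaxed = if (!is.null(relax_tab)) {
      relax_tab$orthogroup[relax_tab$q < th$alpha & relax_tab$K < 1]
    } else character(0),
    intensified = if (!is.null(relax_tab)) {
      relax_tab$orthogroup[relax_tab$q < th$alpha & relax_tab$K > 1]
    } else character(0))
  categories <- classify_selection(calls)

  enrichment <- NULL
  if (!is.null(inp$annotation)) {
    say("stage enrich: classic per-term Fisher, alpha = %.2f", th$enrichment_alpha)
    universe <- unique(inp$annotation$orthogroup)
    enrichment <- lapply(categories[1:4], function(set) {
      study <- intersect(set, universe)
      if (length(study) == 0) return(NULL)
      fisher_term_enrichment(inp$annotation, study, universe = universe,
                             alpha = th$enrichment_alpha,
                             min_annotated = th$min_annotated)
    })
  }

  say("stage traits: PGLS and trait contingency")
  trait_assoc <- NULL
  loss_fam <- losses$orthogroup[losses$pattern == "lost_in_foreground"]
  if (length(loss_fam) > 0) {
    fam <- loss_fam[1]
    tra <- inp$traits
    tra$gene_presence <- as.integer(unlist(inp$counts[fam, tra$species]) >= 1)
    try_pgls <- function(preds) {
      tryCatch(pgls_fit(inp$tree, tra, "gene_presence", preds),
               error = function(e) {
                 say("  pgls (%s) skipped: %s", paste(preds, collapse = "+"),
                     conditionMessage(e))
                 NULL
               })
    }
    fits <- list(
      diapause = try_pgls("prepupal_diapause"),
      sociality = try_pgls("sociality"),
      joint = try_pgls(c("prepupal_diapause", "sociality")))
    ctab <- table(diapause = tra$prepupal_diapause, sociality = tra$sociality)
    trait_assoc <- list(family = fam, pgls = fits,
                        fisher_p = if (all(dim(ctab) == c(2, 2)))
                          fisher_exact_2x2(ctab) else NA_real_)
  }

  report <- list(
    config = config,
    retained = sc$retained, excluded = sc$excluded, family_losses = losses,
    rer = rer_tab, relax = relax_tab, branch_ps = ps_tab,
    calls = calls, categories = categories, enrichment = enrichment,
    trait_association = trait_assoc,
    summary = list(
      n_species = nrow(inp$traits), n_foreground = length(fg),
      n_retained = length(sc$retained),
      n_family_losses = nrow(losses),
      n_rer_significant = if (!is.null(sig_rer)) nrow(sig_rer) else 0L,
      n_rho_pos = length(calls$rho_pos), n_rho_neg = length(calls$rho_neg),
      n_relaxed = length(calls$relaxed), n_intensified = length(calls$intensified),
      n_branch_positive = length(calls$absrel),
      category_sizes = vapply(categories, length, integer(1))),
    log = log_lines
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    outd <- config$out_dir
    if (!is.null(rer_tab)) {
      write.table(rer_tab, file.path(outd, "rer.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    if (!is.null(relax_tab)) {
      write.table(relax_tab, file.path(outd, "relax.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    if (!is.null(ps_tab)) {
      write.table(ps_tab, file.path(outd, "branch_ps.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    write.table(losses, file.path(outd, "family_losses.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cat_tab <- do.call(rbind, lapply(names(categories), function(nm) {
      if (length(categories[[nm]]) == 0) return(NULL)
      data.frame(category = nm, orthogroup = categories[[nm]],
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(cat_tab)) {
      write.table(cat_tab, file.path(outd, "categories.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(report$summary, file.path(outd, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(outd, "pipeline.log"))
  }
  invisible(report)
}
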