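#' Pipeline run configuration
#'
#' Either a simulation config (the default) or paths/objects for real
#' inputs, plus the analysis knobs shared by all stages. A single top-level
#' seed fans out to stage-specific derived seeds so stages stay
#' reproducible when re-run in isolation.
#'
#' @param simulate a [sim_config()] to generate the experiment, or `NULL`
#'   when `inputs` are given.
#' @param inputs optional named list with `counts`, `metadata`, `tree`,
#'   optionally `taxonomy`, `metabolites` — objects or file paths.
#' @param min_count detection threshold for origin classification.
#' @param test_timepoints timepoints for the engraftment test.
#' @param beta_metric `"unweighted"` or `"weighted"` UniFrac.
#' @param anosim_permutations Monte-Carlo permutations for ANOSIM.
#' @param with_metabolomics include the SCFA PCA stage.
#' @param seed top-level integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = sim_config(), inputs = NULL, min_count = 1,
                       test_timepoints = c("T3", "T4", "T5"),
                       beta_metric = c("unweighted", "weighted"),
                       anosim_permutations = 999, with_metabolomics = TRUE,
                       seed = 1L) {
  if (is.null(simulate) && is.null(inputs)) {
    stop("either a simulation config or inputs must be given", call. = FALSE)
  }
  if (!is.null(simulate) && !is.null(inputs)) {
    stop("give either a simulation config or inputs, not both", call. = FALSE)
  }
  structure(list(simulate = simulate, inputs = inputs, min_count = min_count,
                 test_timepoints = test_timepoints,
                 beta_metric = match.arg(beta_metric),
                 anosim_permutations = anosim_permutations,
                 with_metabolomics = with_metabolomics,
                 seed = as.integer(seed)),
            class = "run_config")
}

load_inputs <- function(inputs) {
  get_in <- function(x, reader) {
    if (is.character(x) && length(x) == 1) reader(x) else x
  }
  list(counts = get_in(inputs$counts, read_count_table),
       metadata = validate_metadata(get_in(inputs$metadata, read_metadata)),
       tree = get_in(inputs$tree, read_newick),
       taxonomy = if (!is.null(inputs$taxonomy))
         get_in(inputs$taxonomy, read_taxonomy),
       metabolites = if (!is.null(inputs$metabolites))
         get_in(inputs$metabolites, read_metabolite_table),
       truth = NULL)
}

#' Run the full engraftment analysis pipeline
#'
#' Stages: data (simulate or ingest) -> per-group origin classification ->
#' occupancy series -> paired engraftment tests with BH adjustment ->
#' alpha diversity with per-timepoint Kruskal-Wallis -> UniFrac / PCoA /
#' ANOSIM -> taxonomic rollups (all ASVs and donor-unique ASVs) -> SCFA
#' TIC-normalization, donor averaging and PCA. Deterministic given the
#' config; the manifest records the seed and a config hash. A cross-module
#' identity — filtered phylum rollup row sums must equal the
#' `human_only`-origin occupancy of every sample — is asserted on every
#' run.
#'
#' @param config a [run_config()].
#' @param outdir optional directory; when given, tables/JSON are written
#'   there via [write_bundle()].
#' @return A `report_bundle` list with elements `manifest`, `data`,
#'   `origin`, `occupancy`, `engraftment_tests`, `diversity`,
#'   `diversity_tests`, `beta` (distance matrix, ordination, anosim),
#'   `taxa`, `metabolomics`.
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  dat <- stage("data", {
    if (!is.null(config$simulate)) {
      sim <- simulate_experiment(config$simulate)
      if (config$with_metabolomics) {
        sim$metabolites <- simulate_metabolites(config$simulate)
      }
      sim
    } else {
      load_inputs(config$inputs)
    }
  })
  md <- dat$metadata
  groups <- sort(unique(md$group[md$role == "recipient"]))

  origin_maps <- stage("origin", {
    maps <- lapply(groups, function(g) {
      classify_origin(dat$counts, md, g, min_count = config$min_count)
    })
    names(maps) <- groups
    maps
  })
  occupancy <- stage("occupancy", {
    occ <- lapply(origin_maps, function(mp) occupancy_series(dat$counts, md, mp))
    names(occ) <- groups
    occ
  })
  tests <- stage("engraftment_tests", {
    compare_human_vs_mouse(occupancy, timepoints = config$test_timepoints)
  })
  diversity <- stage("alpha_diversity", alpha_diversity(dat$counts))
  div_tests <- stage("diversity_tests", diversity_group_tests(diversity, md))
  beta <- stage("beta_diversity", {
    rec_ids <- md$sample_id[md$role == "recipient"]
    d <- unifrac(subset_samples(dat$counts, rec_ids), dat$tree,
                 metric = config$beta_metric)
    ord <- pcoa(d, n_axes = 2)
    labels <- md$group[match(rownames(d), md$sample_id)]
    an <- anosim(d, labels, n_permutations = config$anosim_permutations,
                 seed = derive_seed(config$seed, "anosim"))
    list(distances = d, ordination = ord, anosim = an)
  })
  taxa <- stage("taxonomy_rollup", {
    if (is.null(dat$taxonomy)) NULL else {
      unique_sets <- lapply(origin_maps, unique_input_asvs)
      list(
        phylum = top_taxa(rollup(dat$counts, dat$taxonomy, "phylum"), 8),
        family = top_taxa(rollup(dat$counts, dat$taxonomy, "family"), 8),
        phylum_unique_input = lapply(groups, function(g) {
          ids <- group_sample_ids(md, g)
          rollup(subset_samples(dat$counts, ids), dat$taxonomy, "phylum",
                 asv_subset = unique_sets[[g]])
        })
      )
    }
  })
  metabolomics <- stage("metabolomics", {
    if (!config$with_metabolomics || is.null(dat$metabolites)) NULL else {
      norm <- tic_normalize(dat$metabolites)
      donor_ids <- grep("^DONOR", rownames(norm), value = TRUE)
      if (length(donor_ids)) {
        norm <- average_replicates(norm, list(DONOR = donor_ids))
      }
      list(normalized = norm, pca = metabolite_pca(norm))
    }
  })

  stage("identity_checks", {
    if (!is.null(dat$taxonomy)) {
      for (g in groups) {
        ids <- group_sample_ids(md, g)
        rt <- rollup(subset_samples(dat$counts, ids), dat$taxonomy, "phylum",
                     asv_subset = unique_input_asvs(origin_maps[[g]]))
        occ_origin <- occupancy_series(dat$counts, md, origin_maps[[g]],
                                       by = "origin")
        fr <- occ_origin$fractions
        ho <- fr$fraction[fr$class == "human_only"]
        names(ho) <- fr$sample_id[fr$class == "human_only"]
        if (max(abs(rowSums(rt) - ho[rownames(rt)])) > 1e-9) {
          stop("filtered rollup row sums do not match human_only occupancy in ",
               g)
        }
      }
    }
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("engraftkit")),
    seed = config$seed,
    config_hash = config_hash(config),
    simulated = !is.null(config$simulate),
    groups = groups,
    n_samples = nrow(dat$counts),
    n_asvs = ncol(dat$counts),
    warnings = character(0)
  )
  bundle <- structure(list(manifest = manifest, data = dat,
                           origin = origin_maps, occupancy = occupancy,
                           engraftment_tests = tests, diversity = diversity,
                           diversity_tests = div_tests, beta = beta,
                           taxa = taxa, metabolomics = metabolomics),
                      class = "report_bundle")
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

#' Serialize a report bundle to a directory
#'
#' Writes TSV tables (occupancy, tests, diversity, rollups, distances) and
#' JSON (manifest, ordination, ANOSIM, PCA) plus the plain-text report.
#'
#' @param bundle output of [run_pipeline()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wj <- function(x, name) {
    jsonlite::write_json(x, file.path(dir, name), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wj(bundle$manifest, "manifest.json")
  occ <- do.call(rbind, lapply(bundle$occupancy, function(s) {
    cbind(group = s$group, s$summary)
  }))
  wt(occ, "occupancy_summary.tsv")
  frac <- do.call(rbind, lapply(bundle$occupancy, function(s) {
    cbind(group = s$group, s$fractions)
  }))
  wt(frac, "occupancy_fractions.tsv")
  if (!is.null(bundle$engraftment_tests)) {
    wt(bundle$engraftment_tests, "engraftment_tests.tsv")
  }
  wt(bundle$diversity, "alpha_diversity.tsv")
  if (!is.null(bundle$diversity_tests)) {
    wt(bundle$diversity_tests, "diversity_tests.tsv")
  }
  write_dist_matrix(bundle$beta$distances, file.path(dir, "beta_distances.tsv"))
  wj(list(coordinates = as.data.frame(bundle$beta$ordination$coordinates),
          eigenvalues = bundle$beta$ordination$eigenvalues,
          proportion_explained = bundle$beta$ordination$proportion_explained,
          negative_eigenvalue_mass =
            bundle$beta$ordination$negative_eigenvalue_mass),
     "ordination.json")
  wj(unclass(bundle$beta$anosim), "anosim.json")
  if (!is.null(bundle$taxa)) {
    wt(data.frame(sample_id = rownames(bundle$taxa$phylum),
                  unclass(bundle$taxa$phylum), check.names = FALSE),
       "phylum_top.tsv")
    wt(data.frame(sample_id = rownames(bundle$taxa$family),
                  unclass(bundle$taxa$family), check.names = FALSE),
       "family_top.tsv")
  }
  if (!is.null(bundle$metabolomics)) {
    p <- bundle$metabolomics$pca
    wj(list(scores = as.data.frame(p$scores),
            loadings = as.data.frame(p$loadings),
            explained_variance_ratio = p$explained_variance_ratio),
       "metabolite_pca.json")
  }
  writeLines(make_report(bundle), file.path(dir, "report.txt"))
  invisible(dir)
}

#' Human-readable summary of a pipeline run
#'
#' @param bundle output of [run_pipeline()].
#' @return Character vector of report lines.
#' @export
make_report <- function(bundle) {
  fmt <- function(x, d = 3) formatC(x, digits = d, format = "f")
  lines <- c("Engraftment analysis report",
             sprintf("samples: %d  ASVs: %d  config hash: %s",
                     bundle$manifest$n_samples, bundle$manifest$n_asvs,
                     bundle$manifest$config_hash), "")
  for (g in names(bundle$occupancy)) {
    s <- bundle$occupancy[[g]]$summary
    lines <- c(lines, sprintf("Niche occupancy, group %s (mean +/- SD over mice):", g))
    for (tp in unique(s$timepoint)) {
      row <- s[s$timepoint == tp, ]
      lines <- c(lines, sprintf("  %s  %s", tp, paste(
        sprintf("%s %s+/-%s", row$class, fmt(row$mean), fmt(row$sd)),
        collapse = "  ")))
    }
    lines <- c(lines, "")
  }
  if (is.null(bundle$engraftment_tests)) {
    lines <- c(lines, "Engraftment tests: no tests run", "")
  } else {
    t <- bundle$engraftment_tests
    lines <- c(lines, "Human vs mouse occupancy (one-sided paired Wilcoxon, BH-adjusted):",
               sprintf("  %s %s: n=%d W+=%.1f p=%.4g adj=%.4g",
                       t$group, t$timepoint, t$n_pairs, t$statistic, t$p,
                       t$p_adjusted), "")
  }
  if (!is.null(bundle$diversity_tests)) {
    dt <- bundle$diversity_tests
    lines <- c(lines, "Alpha diversity by timepoint (Kruskal-Wallis across groups):",
               sprintf("  %s: H=%.3f df=%d p=%.4g", dt$timepoint,
                       dt$statistic, dt$df, dt$p), "")
  }
  an <- bundle$beta$anosim
  lines <- c(lines, sprintf("ANOSIM over groups: R=%.3f p=%.4g (%d arrangements)",
                            an$R, an$p, an$n_permutations))
  pe <- bundle$beta$ordination$proportion_explained
  lines <- c(lines, sprintf("PCoA axes explain %s of positive-eigenvalue variance",
                            paste(sprintf("%.1f%%", 100 * pe), collapse = ", ")),
             "")
  if (!is.null(bundle$metabolomics)) {
    evr <- bundle$metabolomics$pca$explained_variance_ratio
    lines <- c(lines, sprintf("SCFA PCA: PC1 %.1f%%, PC2 %.1f%% of variance",
                              100 * evr[1], 100 * evr[2]))
  }
  lines
}
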