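# Synthetic FMT experiment generator. Emulates the design of the mouse
# study template: 6 groups x 5 mice, two antibiotic regimens of different
# knockdown strength, 0/1/5 FMT doses, donor material sequenced in
# triplicate, fecal sampling at T0 (baseline), T1 (post-ABX) and T2-T5
# (post-FMT weeks). Latent community dynamics are deterministic given the
# drawn supports and baseline abundances; all stochasticity lives in the
# supports, the log-normal abundances, and Dirichlet-multinomial read
# sampling, so ground-truth niche occupancy is available in closed form.

#' Default per-group design table
#'
#' `G1`-`G3`: 3-day antibiotic regimen (moderate knockdown, fast regrowth)
#' with 0/1/5 FMT doses; `G4`-`G6`: 3-week cycled regimen (deep knockdown,
#' slow regrowth) with 0/1/5 doses.
#'
#' @param abx_knockdown_3d,abx_knockdown_3w log10 reduction of baseline
#'   (mouse) taxa immediately after antibiotics.
#' @param regrowth_3d,regrowth_3w multiplicative per-timepoint recovery of
#'   knocked-down taxa, capped at baseline.
#' @return data.frame: `group`, `regimen`, `abx_knockdown`, `regrowth`,
#'   `n_doses`.
#' @export
default_groups <- function(abx_knockdown_3d = 2, abx_knockdown_3w = 5,
                           regrowth_3d = 10, regrowth_3w = 10^0.3) {
  data.frame(
    group = paste0("G", 1:6),
    regimen = rep(c("3d", "3w"), each = 3),
    abx_knockdown = rep(c(abx_knockdown_3d, abx_knockdown_3w), each = 3),
    regrowth = rep(c(regrowth_3d, regrowth_3w), each = 3),
    n_doses = rep(c(0L, 1L, 5L), 2),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' @param n_asv_pool total size of the ASV pool.
#' @param n_donor number of ASVs in the donor community.
#' @param n_mouse number of ASVs in the recipient baseline community
#'   (shared across groups: all mice come from the same vendor stock).
#' @param shared_fraction fraction of the baseline support that also occurs
#'   in the donor (default 0.08: shared ASVs are a small, <10%, part of the
#'   baseline niche).
#' @param groups design table as from [default_groups()]; one row per
#'   group with `group`, `abx_knockdown` (log10), `regrowth`
#'   (fold/timepoint), `n_doses`.
#' @param engraft_efficiency fraction of a baseline-equivalent biomass
#'   delivered and retained per FMT dose; doses collapse to one additive
#'   pulse `min(1, n_doses * engraft_efficiency)` applied between T1 and
#'   T2.
#' @param read_depth reads per sample.
#' @param overdispersion Dirichlet concentration scale of the
#'   Dirichlet-multinomial read sampler (larger = closer to multinomial).
#' @param abundance_sigma log-normal spread (sdlog) of latent abundances.
#' @param n_mice_per_group,n_donor_reps design sizes.
#' @param index_hop_rate fraction of each sample's expected composition
#'   redistributed uniformly over the whole ASV pool (index-hopping-style
#'   contamination; default 0, the only source of truly unassigned reads).
#' @param seed integer seed governing every random draw.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_asv_pool = 300, n_donor = 120, n_mouse = 100,
                       shared_fraction = 0.08, groups = default_groups(),
                       engraft_efficiency = 0.3, read_depth = 10000,
                       overdispersion = 200, abundance_sigma = 1.5,
                       n_mice_per_group = 5, n_donor_reps = 3,
                       index_hop_rate = 0, seed = 1L) {
  cfg <- list(n_asv_pool = as.integer(n_asv_pool), n_donor = as.integer(n_donor),
              n_mouse = as.integer(n_mouse), shared_fraction = shared_fraction,
              groups = as.data.frame(groups, stringsAsFactors = FALSE),
              engraft_efficiency = engraft_efficiency,
              read_depth = as.integer(read_depth),
              overdispersion = overdispersion,
              abundance_sigma = abundance_sigma,
              n_mice_per_group = as.integer(n_mice_per_group),
              n_donor_reps = as.integer(n_donor_reps),
              index_hop_rate = index_hop_rate, seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_asv_pool >= 2, cfg$n_donor >= 1, cfg$n_mouse >= 1)
  if (cfg$n_donor > cfg$n_asv_pool || cfg$n_mouse > cfg$n_asv_pool) {
    stop("support sizes exceed the ASV pool", call. = FALSE)
  }
  if (cfg$shared_fraction < 0 || cfg$shared_fraction > 1) {
    stop("shared_fraction must lie in [0, 1]", call. = FALSE)
  }
  n_shared <- round(cfg$shared_fraction * cfg$n_mouse)
  if (n_shared > cfg$n_donor) {
    stop("shared_fraction * n_mouse exceeds the donor support", call. = FALSE)
  }
  if (cfg$n_mouse - n_shared > cfg$n_asv_pool - cfg$n_donor) {
    stop("mouse-only support does not fit outside the donor support",
         call. = FALSE)
  }
  need <- c("group", "abx_knockdown", "regrowth", "n_doses")
  missing <- setdiff(need, names(cfg$groups))
  if (length(missing)) {
    stop("groups table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (cfg$engraft_efficiency < 0 || cfg$engraft_efficiency > 1) {
    stop("engraft_efficiency must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$index_hop_rate < 0 || cfg$index_hop_rate > 1) {
    stop("index_hop_rate must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(cfg$read_depth >= 1, cfg$overdispersion > 0,
            cfg$abundance_sigma >= 0, cfg$n_mice_per_group >= 1,
            cfg$n_donor_reps >= 1, all(cfg$groups$regrowth > 0),
            all(cfg$groups$abx_knockdown >= 0), all(cfg$groups$n_doses >= 0))
  cfg
}

#' Simulate a random rooted ASV phylogeny
#'
#' Coalescent-style rooted binary tree with exponentially distributed
#' internode intervals, tips labeled `ASV_1..ASV_n`.
#'
#' @param n_asv_pool number of tips (>= 2).
#' @param seed RNG seed.
#' @return An `ape::phylo` tree with `n_asv_pool` tips and
#'   `n_asv_pool - 1` internal nodes.
#' @export
simulate_tree <- function(n_asv_pool, seed = 1L) {
  if (n_asv_pool < 2) stop("need >= 2 tips", call. = FALSE)
  with_seed(seed, ape::rcoal(n_asv_pool,
                             tip.label = paste0("ASV_", seq_len(n_asv_pool))))
}

#' Simulate a complete FMT engraftment experiment
#'
#' Latent dynamics per mouse: the T0 baseline is a log-normal composition
#' on the recipient support; antibiotics knock the baseline taxa down by
#' `10^-abx_knockdown` at T1; a single FMT pulse of
#' `min(1, n_doses * engraft_efficiency)` baseline-equivalents of the donor
#' profile is added between T1 and T2; between successive timepoints the
#' knocked-down taxa recover by the group's `regrowth` factor, capped at
#' their baseline abundance. Observed counts at every timepoint are
#' Dirichlet-multinomial draws from the latent composition; donor
#' replicates are drawn from the donor profile.
#'
#' @param config a [sim_config()].
#' @return A list: `counts` ([count_table()]), `metadata`, `tree`,
#'   `taxonomy`, and `truth` — a `sim_truth` list holding `true_origin`
#'   (named vector over the pool: `donor_only`/`shared`/`mouse_only`/
#'   `absent`), `latent_abundance` (subject x timepoint list of latent
#'   vectors), and `true_occupancy` (data.frame of expected class
#'   fractions per subject and timepoint).
#' @export
simulate_experiment <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  pool <- paste0("ASV_", seq_len(config$n_asv_pool))
  tree <- simulate_tree(config$n_asv_pool, derive_seed(config$seed, "tree"))

  with_seed(derive_seed(config$seed, "experiment"), {
    donor_support <- sort(sample(config$n_asv_pool, config$n_donor))
    n_shared <- round(config$shared_fraction * config$n_mouse)
    shared <- sort(sample(donor_support, n_shared))
    mouse_only <- sort(sample(setdiff(seq_len(config$n_asv_pool), donor_support),
                              config$n_mouse - n_shared))
    mouse_support <- sort(c(shared, mouse_only))

    true_origin <- rep("absent", config$n_asv_pool)
    true_origin[donor_support] <- "donor_only"
    true_origin[mouse_only] <- "mouse_only"
    true_origin[shared] <- "shared"
    names(true_origin) <- pool

    rlog <- function(idx) {
      v <- numeric(config$n_asv_pool)
      v[idx] <- stats::rlnorm(length(idx), meanlog = 0,
                              sdlog = config$abundance_sigma)
      v
    }
    donor_profile <- rlog(donor_support)

    timepoints <- TIMEPOINT_LEVELS
    meta_rows <- list()
    count_rows <- list()
    latent_store <- list()
    occ_rows <- list()

    sample_counts <- function(latent) {
      pi <- latent / sum(latent)
      if (config$index_hop_rate > 0) {
        pi <- (1 - config$index_hop_rate) * pi +
          config$index_hop_rate / config$n_asv_pool
      }
      rdirichlet_multinomial(config$read_depth,
                             config$overdispersion * pi)
    }

    for (gi in seq_len(nrow(config$groups))) {
      g <- config$groups[gi, ]
      eta_tot <- min(1, g$n_doses * config$engraft_efficiency)
      for (mi in seq_len(config$n_mice_per_group)) {
        subject <- sprintf("%s_M%d", g$group, mi)
        baseline <- rlog(mouse_support)
        pulse <- eta_tot * donor_profile / sum(donor_profile) * sum(baseline)
        mouse_comp <- baseline
        donor_comp <- numeric(config$n_asv_pool)
        for (ti in seq_along(timepoints)) {
          tp <- timepoints[ti]
          if (tp == "T1") mouse_comp <- baseline * 10^(-g$abx_knockdown)
          if (tp == "T2") {
            mouse_comp <- pmin(baseline, mouse_comp * g$regrowth)
            donor_comp <- pulse
          }
          if (tp %in% c("T3", "T4", "T5")) {
            mouse_comp <- pmin(baseline, mouse_comp * g$regrowth)
          }
          latent <- mouse_comp + donor_comp
          sid <- sprintf("%s_%s", subject, tp)
          latent_store[[sid]] <- latent
          count_rows[[sid]] <- sample_counts(latent)
          meta_rows[[sid]] <- data.frame(
            sample_id = sid, subject_id = subject, group = g$group,
            timepoint = tp, role = "recipient", stringsAsFactors = FALSE)
          tot <- sum(latent)
          occ_rows[[sid]] <- data.frame(
            subject_id = subject, group = g$group, timepoint = tp,
            human = sum(latent[donor_support]) / tot,
            mouse = sum(latent[mouse_only]) / tot,
            unassigned = 0, stringsAsFactors = FALSE)
        }
      }
    }
    for (ri in seq_len(config$n_donor_reps)) {
      sid <- sprintf("DONOR_R%d", ri)
      count_rows[[sid]] <- sample_counts(donor_profile)
      meta_rows[[sid]] <- data.frame(
        sample_id = sid, subject_id = "DONOR", group = "DONOR",
        timepoint = NA_character_, role = "donor", stringsAsFactors = FALSE)
    }

    counts <- do.call(rbind, count_rows)
    colnames(counts) <- pool
    metadata <- validate_metadata(do.call(rbind, meta_rows))
    truth <- structure(list(
      true_origin = true_origin,
      latent_abundance = latent_store,
      true_occupancy = {
        df <- do.call(rbind, occ_rows)
        rownames(df) <- NULL
        df
      },
      donor_profile = donor_profile,
      supports = list(donor = pool[donor_support], shared = pool[shared],
                      mouse_only = pool[mouse_only])
    ), class = "sim_truth")

    list(counts = count_table(counts), metadata = metadata, tree = tree,
         taxonomy = simulate_taxonomy(tree), truth = truth, config = config)
  })
}

# Overdispersed read sampler: p ~ Dirichlet(alpha), counts ~ Multinomial(L, p).
rdirichlet_multinomial <- function(depth, alpha) {
  x <- numeric(length(alpha))
  pos <- which(alpha > 0)
  g <- stats::rgamma(length(pos), shape = alpha[pos])
  if (sum(g) <= 0) {
    # extreme overdispersion can underflow every gamma draw; fall back to
    # the expected composition
    g <- alpha[pos]
  }
  x[pos] <- stats::rmultinom(1, depth, g / sum(g))[, 1]
  as.integer(x)
}

# Random but phylogenetically coherent lineages: nested cuts of the ASV
# tree at increasing resolution define phylum .. genus labels, so close
# relatives share higher ranks (as SILVA-style classifications would).
simulate_taxonomy <- function(tree) {
  n <- length(tree$tip.label)
  h <- stats::hclust(stats::as.dist(ape::cophenetic.phylo(tree)),
                     method = "average")
  ks <- c(phylum = 6, class = 12, order = 20, family = 30, genus = 60)
  ks <- pmin(ks, n)
  cuts <- stats::cutree(h, k = ks)
  if (is.null(dim(cuts))) cuts <- matrix(cuts, ncol = length(ks))
  pretty <- c(phylum = "Phylum", class = "Class", order = "Order",
              family = "Family", genus = "Genus")
  tax <- data.frame(asv_id = h$labels, kingdom = "Bacteria",
                    stringsAsFactors = FALSE)
  for (j in seq_along(ks)) {
    rank <- names(ks)[j]
    tax[[rank]] <- sprintf("%s_%02d", pretty[[rank]], cuts[, j])
  }
  tax[match(tree$tip.label, tax$asv_id), , drop = FALSE]
}

#' Simulate a short-chain fatty acid panel with group effects
#'
#' Log-normal intensities with metabolite-specific base levels (acetate
#' dominant, as in fecal SCFA panels) and additive per-group shifts on the
#' log10 scale, for one sample per recipient mouse plus donor replicates.
#' Groups given distinct shifts become separable by PCA after TIC
#' normalization.
#'
#' @param config a [sim_config()] (group structure and seed are reused).
#' @param group_effects named list: metabolite -> named numeric vector of
#'   log10 mean shifts per group. The default mirrors the study contrast:
#'   caproate/valerate elevated in G6, acetate/2-methylbutyrate in G3.
#' @param noise_sd residual log10 spread per measurement (default 0.15).
#' @return Metabolite intensity matrix (samples x metabolites).
#' @export
simulate_metabolites <- function(config = sim_config(),
                                 group_effects = default_scfa_effects(),
                                 noise_sd = 0.15) {
  base_log10 <- c(acetate = 6, propionate = 5.5, butyrate = 5.3,
                  valerate = 4.5, caproate = 4.2, `2-methylbutyrate` = 4.0)
  mets <- union(names(base_log10), names(group_effects))
  if (length(mets) < 2 || nrow(config$groups) < 2) {
    stop("need >= 2 metabolites and >= 2 groups", call. = FALSE)
  }
  groups <- config$groups$group
  samples <- c(as.vector(t(outer(groups, seq_len(config$n_mice_per_group),
                                 function(g, i) sprintf("%s_M%d", g, i)))),
               sprintf("DONOR_R%d", seq_len(config$n_donor_reps)))
  sample_group <- c(rep(groups, each = config$n_mice_per_group),
                    rep("DONOR", config$n_donor_reps))
  with_seed(derive_seed(config$seed, "metabolites"), {
    m <- matrix(0, length(samples), length(mets),
                dimnames = list(samples, mets))
    for (j in seq_along(mets)) {
      met <- mets[j]
      mu <- if (met %in% names(base_log10)) base_log10[[met]] else 4.5
      shift <- numeric(length(samples))
      eff <- group_effects[[met]]
      if (!is.null(eff)) {
        hit <- sample_group %in% names(eff)
        shift[hit] <- eff[sample_group[hit]]
      }
      m[, j] <- 10^(mu + shift + stats::rnorm(length(samples), sd = noise_sd))
    }
    m
  })
}

#' Default SCFA group effects
#'
#' Caproate and valerate elevated in G6, acetate and 2-methylbutyrate in
#' G3 (the contrast driving the biplot separation of the two 5-dose
#' groups).
#'
#' @param size log10 magnitude of the primary shifts (default 1).
#' @return Named list suitable for [simulate_metabolites()].
#' @export
default_scfa_effects <- function(size = 1) {
  list(caproate = c(G6 = size), valerate = c(G6 = 0.8 * size),
       acetate = c(G3 = 0.5 * size), `2-methylbutyrate` = c(G3 = 0.8 * size))
}

#' Write all simulated artifacts to a directory
#'
#' Emits `counts.tsv`, `metadata.tsv`, `tree.nwk`, `taxonomy.tsv`, and
#' (optionally) `metabolites.tsv` in the package's standard formats.
#'
#' @param sim output of [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @param metabolites optional matrix from [simulate_metabolites()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, metabolites = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(sim$counts, file.path(dir, "counts.tsv"))
  write_metadata(sim$metadata, file.path(dir, "metadata.tsv"))
  write_newick(sim$tree, file.path(dir, "tree.nwk"))
  write_taxonomy(sim$taxonomy, file.path(dir, "taxonomy.tsv"))
  if (!is.null(metabolites)) {
    write_metabolite_table(metabolites, file.path(dir, "metabolites.tsv"))
  }
  invisible(dir)
}
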