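test_that("simulated trees are rooted, binary, reproducible", {
  t2 <- simulate_tree(2, seed = 1)
  expect_equal(ape::Ntip(t2), 2)
  t300 <- simulate_tree(300, seed = 3)
  expect_equal(t300$Nnode, 299)                  # binary rooted: n-1 internals
  expect_true(ape::is.rooted(t300))
  expect_true(all(t300$edge.length > 0))
  expect_identical(ape::write.tree(simulate_tree(50, seed = 9)),
                   ape::write.tree(simulate_tree(50, seed = 9)))
  expect_false(identical(ape::write.tree(simulate_tree(50, seed = 9)),
                         ape::write.tree(simulate_tree(50, seed = 10))))
  expect_error(simulate_tree(1), ">= 2")
})

test_that("identical configs produce byte-identical experiments", {
  a <- small_sim(seed = 5)
  b <- small_sim(seed = 5)
  expect_identical(unclass(a$counts), unclass(b$counts))
  expect_identical(a$metadata, b$metadata)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$taxonomy, b$taxonomy)
  expect_identical(a$truth$true_occupancy, b$truth$true_occupancy)
  c <- small_sim(seed = 6)
  expect_false(identical(unclass(a$counts), unclass(c$counts)))
})

test_that("infeasible support configurations are rejected", {
  expect_error(sim_config(n_asv_pool = 50, n_donor = 60), "exceed")
  expect_error(sim_config(n_asv_pool = 100, n_donor = 90, n_mouse = 50,
                          shared_fraction = 0), "does not fit")
  expect_error(sim_config(shared_fraction = 1.2), "shared_fraction")
  expect_error(sim_config(engraft_efficiency = 2), "engraft_efficiency")
})

test_that("without perturbation the mouse class owns the whole niche", {
  groups <- data.frame(group = "G1", regimen = "none", abx_knockdown = 0,
                       regrowth = 1, n_doses = 0L)
  sim <- simulate_experiment(
    sim_config(n_asv_pool = 60, n_donor = 25, n_mouse = 20,
               shared_fraction = 0, groups = groups, read_depth = 2000,
               n_mice_per_group = 3, seed = 2))
  occ <- sim$truth$true_occupancy
  expect_true(all(occ$mouse == 1))
  expect_true(all(occ$human == 0))
})

test_that("total knockdown with a saturating dose hands the niche to the donor", {
  groups <- data.frame(group = "G1", regimen = "max", abx_knockdown = 300,
                       regrowth = 1, n_doses = 1L)
  sim <- simulate_experiment(
    sim_config(n_asv_pool = 60, n_donor = 25, n_mouse = 20,
               shared_fraction = 0, groups = groups,
               engraft_efficiency = 1, read_depth = 2000,
               n_mice_per_group = 3, seed = 2))
  occ <- sim$truth$true_occupancy
  post <- occ[occ$timepoint %in% c("T2", "T3", "T4", "T5"), ]
  expect_true(all(post$human > 1 - 1e-10))
})

test_that("ground-truth occupancy rows sum to one and match supports", {
  sim <- small_sim(seed = 13)
  occ <- sim$truth$true_occupancy
  expect_true(all(abs(occ$human + occ$mouse + occ$unassigned - 1) < 1e-12))
  org <- sim$truth$true_origin
  expect_setequal(names(org)[org %in% c("donor_only", "shared")],
                  sim$truth$supports$donor)
  expect_setequal(names(org)[org == "mouse_only"], sim$truth$supports$mouse_only)
})

test_that("origin classification recovers the simulated ground truth", {
  sim <- small_sim(seed = 21)
  truth <- sim$truth$true_origin
  to_est <- c(donor_only = "human_only", shared = "shared",
              mouse_only = "mouse_only")
  for (g in c("G1", "G6")) {
    om <- classify_origin(sim$counts, sim$metadata, g)
    est <- setNames(om$origin, om$asv_id)
    shared_ids <- intersect(names(est), names(truth)[truth != "absent"])
    agree <- mean(est[shared_ids] == to_est[truth[shared_ids]])
    expect_gte(agree, 0.9)
  }
})

test_that("estimated occupancy tracks latent truth within 0.05", {
  sim <- simulate_experiment(sim_config(seed = 17))
  tr <- sim$truth$true_occupancy
  for (g in c("G3", "G6")) {
    om <- classify_origin(sim$counts, sim$metadata, g)
    est <- occupancy_series(sim$counts, sim$metadata, om)$summary
    for (tp in paste0("T", 0:5)) {
      est_h <- est$mean[est$timepoint == tp & est$class == "human"]
      true_h <- mean(tr$human[tr$group == g & tr$timepoint == tp])
      expect_lt(abs(est_h - true_h), 0.05)
    }
  }
})

test_that("mean engrafted occupancy increases with engraftment efficiency", {
  occ_at <- function(eta) {
    # single-dose 3d group: the pulse is eta itself (no dose saturation)
    # and the recovered baseline keeps occupancy off the ceiling
    groups <- default_groups()[2, ]
    sim <- simulate_experiment(
      sim_config(groups = groups, engraft_efficiency = eta,
                 n_asv_pool = 120, n_donor = 50, n_mouse = 40,
                 read_depth = 3000, seed = 19))
    tr <- sim$truth$true_occupancy
    mean(tr$human[tr$timepoint == "T3"])
  }
  vals <- vapply(c(0.05, 0.3, 0.9), occ_at, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("synthetic taxonomy is nested and phylogenetically coherent", {
  sim <- small_sim(seed = 25)
  tax <- sim$taxonomy
  expect_setequal(tax$asv_id, sim$tree$tip.label)
  # genus determines family: nested cuts never split a genus across families
  split_check <- tapply(tax$family, tax$genus, function(v) length(unique(v)))
  expect_true(all(split_check == 1))
  expect_true(all(nzchar(tax$phylum)))
})

test_that("index hopping is the only source of truly novel reads", {
  sim <- small_sim(seed = 31)
  observed <- colnames(sim$counts)[colSums(unclass(sim$counts)) > 0]
  expect_true(all(sim$truth$true_origin[observed] != "absent"))
  noisy <- simulate_experiment(
    sim_config(n_asv_pool = 80, n_donor = 30, n_mouse = 25, read_depth = 2000,
               index_hop_rate = 0.05, seed = 31))
  observed_noisy <- colnames(noisy$counts)[colSums(unclass(noisy$counts)) > 0]
  expect_true(any(noisy$truth$true_origin[observed_noisy] == "absent"))
})

test_that("simulated metabolite tables are deterministic and group-shifted", {
  cfg <- sim_config(seed = 3)
  m1 <- simulate_metabolites(cfg)
  m2 <- simulate_metabolites(cfg)
  expect_identical(m1, m2)
  expect_setequal(colnames(m1),
                  c("acetate", "propionate", "butyrate", "valerate",
                    "caproate", "2-methylbutyrate"))
  grp <- sub("_M\\d+$", "", rownames(m1))
  cap_g6 <- mean(log10(m1[grp == "G6", "caproate"]))
  cap_g1 <- mean(log10(m1[grp == "G1", "caproate"]))
  expect_gt(cap_g6, cap_g1 + 0.5)
})

test_that("write_simulation emits the five artifacts round-trippably", {
  sim <- small_sim(seed = 1)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir, metabolites = simulate_metabolites(sim$config))
  expect_identical(read_count_table(file.path(dir, "counts.tsv")), sim$counts)
  expect_equal(read_metadata(file.path(dir, "metadata.tsv")), sim$metadata,
               ignore_attr = TRUE)
  tree <- read_newick(file.path(dir, "tree.nwk"))
  expect_setequal(tree$tip.label, sim$tree$tip.label)
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  expect_equal(tax, sim$taxonomy, ignore_attr = TRUE)
  met <- read_metabolite_table(file.path(dir, "metabolites.tsv"))
  expect_equal(met, simulate_metabolites(sim$config), tolerance = 1e-12)
})
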