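scfa_fixture <- function() {
  m <- rbind(S1 = c(2, 3, 5), S2 = c(20, 30, 50), S3 = c(1, 1, 2))
  colnames(m) <- c("acetate", "butyrate", "valerate")
  m
}

test_that("TIC normalization rescales rows to one and is idempotent", {
  m <- scfa_fixture()
  norm <- tic_normalize(m)
  expect_equal(norm["S1", ], c(acetate = 0.2, butyrate = 0.3, valerate = 0.5))
  expect_equal(norm["S1", ], norm["S2", ])       # per-sample scale invariance
  expect_equal(tic_normalize(norm), norm, tolerance = 1e-12)
  bad <- rbind(m, S4 = c(0, 0, 0))
  expect_error(tic_normalize(bad), "S4")
})

test_that("replicate averaging is the per-metabolite arithmetic mean", {
  m <- rbind(D1 = c(1, 10, 5), D2 = c(2, 20, 5), D3 = c(3, 30, 5),
             S1 = c(7, 7, 7))
  colnames(m) <- c("acetate", "butyrate", "valerate")
  out <- average_replicates(m, list(DONOR = c("D1", "D2", "D3")))
  expect_equal(out["DONOR", ], c(acetate = 2, butyrate = 20, valerate = 5))
  expect_equal(out["S1", ], m["S1", ])           # pass-through
  one <- average_replicates(m, list(DONOR = "D2"))
  expect_equal(one["DONOR", ], m["D2", ])        # group of one = identity
  expect_error(average_replicates(m, list(DONOR = character(0))), "empty")
  expect_error(average_replicates(m, list(DONOR = "D9")), "D9")
})

test_that("normalize-then-average differs from average-then-normalize", {
  # unequal replicate totals make the two orders disagree; the pipeline
  # fixes normalize-then-average
  m <- rbind(D1 = c(9, 1), D2 = c(1, 9))
  colnames(m) <- c("acetate", "butyrate")
  norm_avg <- average_replicates(tic_normalize(m), list(D = c("D1", "D2")))
  avg_norm <- tic_normalize(average_replicates(m, list(D = c("D1", "D2"))))
  expect_equal(norm_avg["D", "acetate"], 0.5)
  # here they coincide only by symmetry; break it:
  m2 <- rbind(D1 = c(90, 10), D2 = c(1, 9))
  colnames(m2) <- c("acetate", "butyrate")
  na2 <- average_replicates(tic_normalize(m2), list(D = c("D1", "D2")))
  an2 <- tic_normalize(average_replicates(m2, list(D = c("D1", "D2"))))
  expect_gt(abs(na2["D", "acetate"] - an2["D", "acetate"]), 0.2)
})

test_that("PCA satisfies rank, reconstruction, and orthonormality", {
  set.seed(6)
  t_var <- rnorm(20)
  line <- cbind(a = 2 * t_var, b = -3 * t_var)
  rownames(line) <- paste0("S", 1:20)
  res <- metabolite_pca(abs(line) + 1, center = TRUE, scale = FALSE)
  # collinear data: first component carries essentially all variance
  expect_gt(res$explained_variance_ratio[1], 1 - 1e-9)
  x <- matrix(rexp(60), 10, 6,
              dimnames = list(paste0("S", 1:10), paste0("m", 1:6)))
  res2 <- metabolite_pca(x, scale = FALSE)
  recon <- res2$scores %*% t(res2$loadings)
  expect_lt(max(abs(recon - scale(x, scale = FALSE))), 1e-9)
  gram <- t(res2$loadings) %*% res2$loadings
  expect_lt(max(abs(gram - diag(ncol(gram)))), 1e-9)
  expect_lt(max(abs(colMeans(res2$scores))), 1e-9)
  expect_true(all(diff(res2$explained_variance_ratio) <= 1e-12))
})

test_that("PCA agrees with prcomp up to component signs", {
  set.seed(7)
  x <- matrix(rlnorm(48, sdlog = 1), 8, 6,
              dimnames = list(paste0("S", 1:8), paste0("m", 1:6)))
  mine <- metabolite_pca(x, center = TRUE, scale = TRUE)
  ref <- prcomp(x, center = TRUE, scale. = TRUE)
  k <- ncol(mine$scores)
  expect_equal(abs(unclass(mine$scores)), abs(unclass(ref$x[, 1:k])),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(mine$explained_variance_ratio,
               unname(ref$sdev^2 / sum(ref$sdev^2))[1:k], tolerance = 1e-9)
})

test_that("opposed group shifts produce opposite-sign PC1 loadings", {
  cfg <- sim_config(seed = 10)
  m <- simulate_metabolites(cfg, group_effects = list(
    caproate = c(G6 = 1.5), acetate = c(G3 = 1.5)))
  grp <- sub("_M\\d+$", "", rownames(m))
  res <- metabolite_pca(tic_normalize(m[grp %in% c("G3", "G6"), ]))
  l1 <- res$loadings[, 1]
  expect_lt(l1[["caproate"]] * l1[["acetate"]], 0)
})

test_that("group separation vanishes under the null", {
  # no group effects: PC1 group means stay within noise of each other
  hits <- 0
  for (s in 1:20) {
    m <- simulate_metabolites(sim_config(seed = s), group_effects = list())
    res <- metabolite_pca(tic_normalize(m))
    grp <- sub("_(M|R)\\d+$", "", rownames(m))
    sc <- res$scores[grp %in% c("G3", "G6"), 1]
    gg <- grp[grp %in% c("G3", "G6")]
    sem <- sqrt(stats::var(sc[gg == "G3"]) / sum(gg == "G3") +
                  stats::var(sc[gg == "G6"]) / sum(gg == "G6"))
    if (abs(mean(sc[gg == "G3"]) - mean(sc[gg == "G6"])) < 2 * sem) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 18 * 0.9)
})

test_that("zero-variance metabolites are named in the scaling error", {
  m <- scfa_fixture()
  m[, "valerate"] <- 5
  expect_error(metabolite_pca(m, scale = TRUE), "valerate")
  expect_silent(metabolite_pca(m, scale = FALSE))
})
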