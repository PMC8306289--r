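# Hand-built fixture: 3 donor replicates, one group (G1) with two mice at
# T0 and T3, exercising every origin category.
origin_fixture <- function() {
  asvs <- c("A_donoronly", "B_shared", "C_mouseonly", "D_latecomer",
            "E_absent")
  counts <- rbind(
    DONOR_R1 = c(50L, 50L, 0L, 0L, 0L),
    DONOR_R2 = c(0L, 40L, 0L, 0L, 0L),
    DONOR_R3 = c(10L, 30L, 0L, 0L, 0L),
    G1_M1_T0 = c(0L, 7L, 40L, 0L, 0L),
    G1_M2_T0 = c(0L, 0L, 60L, 0L, 0L),
    G1_M1_T3 = c(10L, 30L, 40L, 20L, 0L),
    G1_M2_T3 = c(25L, 25L, 25L, 25L, 0L))
  colnames(counts) <- asvs
  md <- data.frame(
    sample_id = rownames(counts),
    subject_id = c("DONOR", "DONOR", "DONOR", "G1_M1", "G1_M2", "G1_M1", "G1_M2"),
    group = c(rep("DONOR", 3), rep("G1", 4)),
    timepoint = c(NA, NA, NA, "T0", "T0", "T3", "T3"),
    role = c(rep("donor", 3), rep("recipient", 4)))
  list(counts = count_table(counts), metadata = md)
}

test_that("classify_origin applies the donor/baseline presence rules", {
  fx <- origin_fixture()
  om <- classify_origin(fx$counts, fx$metadata, "G1")
  origin <- setNames(om$origin, om$asv_id)
  expect_equal(origin[["A_donoronly"]], "human_only")   # donor only
  expect_equal(origin[["B_shared"]], "shared")          # donor + one T0 mouse
  expect_equal(origin[["C_mouseonly"]], "mouse_only")
  expect_equal(origin[["D_latecomer"]], "unassigned")   # only at T3
  expect_false("E_absent" %in% om$asv_id)               # never observed
  cls <- setNames(om$class, om$asv_id)
  expect_equal(cls[["B_shared"]], "human")  # shared ASVs count with human
  expect_equal(cls[["A_donoronly"]], "human")
  expect_equal(cls[["C_mouseonly"]], "mouse")
})

test_that("min_count raises the detection bar", {
  fx <- origin_fixture()
  om <- classify_origin(fx$counts, fx$metadata, "G1", min_count = 8)
  origin <- setNames(om$origin, om$asv_id)
  # B's only T0 count is 7 < 8, so it is no longer shared
  expect_equal(origin[["B_shared"]], "human_only")
})

test_that("classify_origin errors without baseline or donor samples", {
  fx <- origin_fixture()
  no_t0 <- fx$metadata[fx$metadata$timepoint %in% "T3" |
                         fx$metadata$role == "donor", ]
  expect_error(classify_origin(fx$counts[rownames(fx$counts) %in%
                                           no_t0$sample_id, ] |> count_table(),
                               no_t0, "G1"), "baseline")
  no_donor <- fx$metadata[fx$metadata$role == "recipient", ]
  expect_error(classify_origin(count_table(unclass(fx$counts)[no_donor$sample_id, ]),
                               no_donor, "G1"), "donor")
})

test_that("classification ignores sample order and non-baseline counts", {
  fx <- origin_fixture()
  om1 <- classify_origin(fx$counts, fx$metadata, "G1")
  shuffle <- rev(seq_len(nrow(fx$counts)))
  om2 <- classify_origin(count_table(unclass(fx$counts)[shuffle, ]),
                         fx$metadata[shuffle, ], "G1")
  expect_equal(om1[order(om1$asv_id), ], om2[order(om2$asv_id), ],
               ignore_attr = TRUE)
  # perturbing T3 counts of already-observed ASVs changes nothing
  m <- unclass(fx$counts)
  m["G1_M1_T3", "A_donoronly"] <- 999L
  om3 <- classify_origin(count_table(m), fx$metadata, "G1")
  expect_equal(om1, om3, ignore_attr = TRUE)
})

test_that("unique_input_asvs returns exactly the human_only set", {
  fx <- origin_fixture()
  om <- classify_origin(fx$counts, fx$metadata, "G1")
  expect_equal(unique_input_asvs(om), "A_donoronly")
  om$origin[om$origin == "human_only"] <- "shared"
  om$class <- c(human_only = "human", shared = "human", mouse_only = "mouse",
                unassigned = "unassigned")[om$origin]
  expect_length(unique_input_asvs(om), 0)
})

test_that("occupancy fractions are per-class relative abundance sums", {
  fx <- origin_fixture()
  om <- classify_origin(fx$counts, fx$metadata, "G1")
  occ <- occupancy_series(fx$counts, fx$metadata, om)
  fr <- occ$fractions
  at <- function(sid, cl) fr$fraction[fr$sample_id == sid & fr$class == cl]
  # G1_M1_T3: human = A(10) + B(30) of 100; mouse = C(40); unassigned = D(20)
  expect_equal(at("G1_M1_T3", "human"), 0.4)
  expect_equal(at("G1_M1_T3", "mouse"), 0.4)
  expect_equal(at("G1_M1_T3", "unassigned"), 0.2)
  # every sample sums to one
  sums <- tapply(fr$fraction, fr$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # summary means/SDs over the two mice at T3
  s <- occ$summary
  expect_equal(s$mean[s$timepoint == "T3" & s$class == "human"],
               mean(c(0.4, 0.5)))
  expect_equal(s$sd[s$timepoint == "T3" & s$class == "human"],
               sd(c(0.4, 0.5)))
  expect_equal(s$n[s$timepoint == "T3" & s$class == "human"], 2)
})

test_that("a sample composed purely of donor ASVs has human fraction one", {
  fx <- origin_fixture()
  m <- unclass(fx$counts)
  m["G1_M2_T3", ] <- c(60L, 40L, 0L, 0L, 0L)
  om <- classify_origin(count_table(m), fx$metadata, "G1")
  occ <- occupancy_series(count_table(m), fx$metadata, om)
  fr <- occ$fractions
  expect_equal(fr$fraction[fr$sample_id == "G1_M2_T3" & fr$class == "human"], 1)
})

test_that("compare_human_vs_mouse pairs mice and applies BH across the family", {
  sim <- small_sim(seed = 7)
  maps <- lapply(c("G3", "G6"), function(g)
    classify_origin(sim$counts, sim$metadata, g))
  occ <- lapply(maps, function(mp) occupancy_series(sim$counts, sim$metadata, mp))
  res <- compare_human_vs_mouse(occ)
  expect_equal(nrow(res), 6)  # 2 groups x T3,T4,T5
  expect_true(all(res$p_adjusted >= res$p - 1e-15))
  expect_equal(res$p_adjusted, bh_adjust(res$p))
  # manual check of one cell: G6 T3 human vs mouse over the 5 mice
  fr <- occ[[2]]$fractions
  sub <- fr[fr$timepoint == "T3", ]
  h <- sub$fraction[sub$class == "human"][order(sub$subject_id[sub$class == "human"])]
  m <- sub$fraction[sub$class == "mouse"][order(sub$subject_id[sub$class == "mouse"])]
  ref <- wilcoxon_signed_rank(h, m, alternative = "greater")
  expect_equal(res$p[res$group == "G6" & res$timepoint == "T3"], ref$p)
})

test_that("missing timepoints are skipped with a warning", {
  fx <- origin_fixture()
  om <- classify_origin(fx$counts, fx$metadata, "G1")
  occ <- occupancy_series(fx$counts, fx$metadata, om)
  expect_warning(res <- compare_human_vs_mouse(occ, timepoints = c("T3", "T4")),
                 "T4 missing")
  expect_equal(nrow(res), 1)
})
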