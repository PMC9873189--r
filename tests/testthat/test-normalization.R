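# Stage-by-stage checks of the four-step normalization, using matrices
# whose factors are known by construction.

pc_fixture <- function(pc_by_sample) {
  # pc_by_sample: 3 x n matrix of positive-control counts
  n <- ncol(pc_by_sample)
  counts <- rbind(matrix(100, 4, n), pc_by_sample)
  toy_matrix(counts = counts, n = n)
}

test_that("positive-control geometric means and factors follow the rule", {
  # top-3 PC counts (100, 400, 1600) have geometric mean 400
  m <- pc_fixture(cbind(c(100, 400, 1600), c(50, 200, 800)))
  res <- positive_control_normalize(m)
  g <- res$matrix$factors$pc_factor_per_sample
  expect_equal(unname(res$factors), c(300 / 400, 300 / 200))

  # after normalization the top-3 geometric mean is equal across samples
  pc <- res$matrix$counts[c("PC1", "PC2", "PC3"), ]
  gm <- apply(pc, 2, function(x) exp(mean(log(x))))
  expect_equal(unname(gm), c(300, 300), tolerance = 1e-9)
})

test_that("equal positive controls leave the matrix unchanged", {
  m <- pc_fixture(cbind(c(100, 400, 1600), c(100, 400, 1600)))
  res <- positive_control_normalize(m)
  expect_equal(unname(res$factors), c(1, 1))
  expect_equal(res$matrix$counts, m$counts, ignore_attr = TRUE)
})

test_that("positive-control normalization preconditions are enforced", {
  m <- toy_matrix()
  m$probes$probe_class[m$probes$probe_id == "PC3"] <- "endogenous"
  expect_error(positive_control_normalize(m), ">= 3 positive-control")

  m <- pc_fixture(cbind(c(100, 400, 1600), c(0, 200, 800)))
  expect_error(positive_control_normalize(m), "S2")
})

two_plate_fixture <- function(refA = 200, refB = 100) {
  probes <- toy_probes()
  samples <- rbind(toy_samples(n = 2, plate = "P1"),
                   toy_samples(n = 2, plate = "P2"))
  samples$sample_id <- c("A1", "AR", "B1", "BR")
  samples$lane <- c("P1_L2", "P1_L1", "P2_L2", "P2_L1")
  samples$is_reference_lane <- c(FALSE, TRUE, FALSE, TRUE)
  counts <- matrix(100, 7, 4,
                   dimnames = list(probes$probe_id, samples$sample_id))
  counts["G1", ] <- c(120, refA, 80, refB)
  m <- count_matrix(counts, probes, samples)
  m$stage <- "pc_normalized"
  m
}

test_that("reference-lane calibration equalizes probes across plates", {
  # G1 reference counts 200 (plate P1) and 100 (plate P2): factors 0.75, 1.5
  m <- two_plate_fixture()
  res <- reference_lane_calibrate(m)
  expect_equal(unname(res$factors["G1", ]), c(0.75, 1.5))
  expect_equal(unname(res$matrix$counts["G1", ]),
               c(120 * 0.75, 150, 80 * 1.5, 150))
  # probes with identical reference counts get factor 1
  expect_equal(unname(res$factors["G2", ]), c(1, 1))
  # positive controls are not touched
  expect_equal(unname(res$matrix$counts["PC1", ]), rep(100, 4))
})

test_that("calibration demands two plates and handles zero references", {
  m <- toy_matrix()
  m$stage <- "pc_normalized"
  expect_error(reference_lane_calibrate(m), ">=2 plates")

  m <- two_plate_fixture()
  m$counts["G2", m$samples$is_reference_lane] <- c(0, 100)
  expect_warning(res <- reference_lane_calibrate(m), "G2")
  expect_equal(unname(res$factors["G2", ]), c(1, 1))
})

test_that("attenuation factors come from titration ratios", {
  tit <- data.frame(probe_id = "G1", count_unattenuated = 1000,
                    count_attenuated = 100)
  expect_equal(unname(estimate_attenuation_factor(tit)), 10)

  tit <- data.frame(probe_id = c("G1", "G1"),
                    count_unattenuated = c(1000, 800),
                    count_attenuated = c(100, 100))
  expect_equal(unname(estimate_attenuation_factor(tit)), 9)

  tit <- data.frame(probe_id = "G1", count_unattenuated = 100,
                    count_attenuated = 100)
  expect_equal(unname(estimate_attenuation_factor(tit)), 1)

  tit$count_attenuated <- 0
  expect_error(estimate_attenuation_factor(tit), "> 0")
})

test_that("attenuation correction multiplies only scoped cells", {
  m <- toy_matrix(counts = matrix(50, 7, 4), treatment = "low")
  m$samples$treatment <- c("low", "low", "high", "high")
  m$stage <- "calibrated"
  res <- attenuation_correct(m, c(G1 = 10),
                             attenuated_sample_ids = c("S1", "S2"))
  expect_equal(unname(res$counts["G1", ]), c(500, 500, 50, 50))
  expect_equal(unname(res$counts["G2", ]), rep(50, 4))
  expect_identical(res$stage, "attenuation_corrected")

  expect_error(attenuation_correct(ferrodecay:::advance_stage(
    toy_matrix(), "calibrated"), c(OTHER = 10), "S1"),
    "without a factor")
})

test_that("the attenuated-sample rule covers low and early recovery", {
  smp <- toy_samples(n = 4)
  smp$treatment <- c("low", "rec", "rec", "high")
  smp$time_min <- c(120, 30, 45, 0)
  expect_identical(attenuated_samples(smp), c("S1", "S2"))
})

hk_fixture <- function(hk, treatment = "low", time_min = 0) {
  n <- length(hk)
  counts <- matrix(200, 7, n)
  counts[4, ] <- hk
  m <- toy_matrix(counts = counts, n = n, treatment = treatment,
                  time_min = time_min)
  m$stage <- "attenuation_corrected"
  m
}

test_that("global housekeeping normalization scales to the mean", {
  # hk counts (50, 100, 150): reference 100, factors (2, 1, 2/3)
  m <- hk_fixture(c(50, 100, 150))
  res <- housekeeping_normalize(m, "HK", mode = "global")
  expect_equal(unname(res$factors), c(2, 1, 2 / 3))
  expect_equal(unname(res$matrix$counts["HK", ]), rep(100, 3))
  expect_identical(res$matrix$stage, "fully_normalized")
})

test_that("per-timepoint normalization is computed within timepoints", {
  # actD samples at t = 30 with hk (80, 120): reference 100
  m <- hk_fixture(c(80, 120, 60, 140), treatment = "actd",
                  time_min = c(30, 30, 60, 60))
  res <- housekeeping_normalize(m, "HK", mode = "per_timepoint")
  expect_equal(unname(res$factors), c(100 / 80, 100 / 120, 100 / 60,
                                      100 / 140))
  expect_equal(unname(res$matrix$counts["HK", ]), c(100, 100, 100, 100))
})

test_that("equal housekeeping counts give unit factors", {
  m <- hk_fixture(c(90, 90, 90))
  res <- housekeeping_normalize(m, "HK", mode = "global")
  expect_equal(unname(res$factors), rep(1, 3))
})

test_that("housekeeping errors and warnings fire as specified", {
  m <- hk_fixture(c(50, 0, 150))
  expect_error(housekeeping_normalize(m, "HK", mode = "global"), "S2")

  m <- hk_fixture(c(80, 120, 60), treatment = "actd",
                  time_min = c(30, 30, 60))
  expect_warning(res <- housekeeping_normalize(m, "HK",
                                               mode = "per_timepoint"),
                 "single sample")
  expect_equal(unname(res$factors[3]), 1)
})

test_that("scalar per-sample stages preserve within-sample gene ratios", {
  sim <- simulate_experiment(seed = 5)
  norm <- suppressWarnings(
    normalize_pipeline(sim$counts, hk_probe = "NUCL_HK",
                       titration = sim$titration))
  raw_ratio <- sim$counts$counts["ISIP1", ] / sim$counts$counts["OST", ]
  norm_ratio <- norm$matrix$counts["ISIP1", ] / norm$matrix$counts["OST", ]
  # reference-lane calibration is per probe, so compare within one plate
  p1 <- sim$counts$samples$plate == "P1"
  expect_equal(norm_ratio[p1] / raw_ratio[p1],
               rep(unname(norm_ratio[p1][1] / raw_ratio[p1][1]), sum(p1)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("normalization recovers simulated expectations up to one scale", {
  des <- design_spec(loading_sigma = 0, lane_efficiency_sigma = 0,
                     noise_sigma = 0)
  sim <- simulate_experiment(des, seed = 3, round_counts = FALSE)
  norm <- suppressWarnings(
    normalize_pipeline(sim$counts, hk_probe = "NUCL_HK",
                       titration = sim$titration))
  m <- norm$matrix
  for (g in c("FLDA1", "MNSOD", "FBA1")) {
    sel <- m$samples$treatment == "rec" & m$samples$experiment == "ST" &
      !m$samples$is_reference_lane
    expected <- trajectory_expectation(sim$truth$genes[[g]], "rec",
                                       m$samples$time_min[sel])
    offset <- log(m$counts[g, sel]) - expected
    expect_lt(diff(range(offset)), 1e-9)
  }
})

test_that("pipeline contract errors surface at the right stage", {
  m <- toy_matrix()
  m$probes$probe_class[5:7] <- "endogenous"
  expect_error(normalize_pipeline(m, hk_probe = "HK"),
               ">= 3 positive-control")

  sim <- simulate_experiment(design_spec(st_treatments = c("high", "low"),
                                         lt_treatments = character(0)),
                             seed = 2)
  sim$counts$samples$plate <- "P1"   # collapse to a single plate
  expect_warning(normalize_pipeline(sim$counts, hk_probe = "NUCL_HK",
                                    titration = sim$titration),
                 "calibration skipped")
})

test_that("normalization shrinks the spread of a constant gene", {
  des <- design_spec(loading_sigma = 0.3, lane_efficiency_sigma = 0.1,
                     noise_sigma = 0.05)
  sim <- simulate_experiment(des, seed = 21)
  norm <- suppressWarnings(
    normalize_pipeline(sim$counts, hk_probe = "NUCL_HK",
                       titration = sim$titration))
  sel <- sim$counts$samples$treatment %in% c("high", "low") &
    !sim$counts$samples$is_reference_lane
  cv <- function(x) sd(x) / mean(x)
  # OST is flat in high/low treatments: loading noise dominates raw counts
  expect_lt(cv(norm$matrix$counts["OST", sel]),
            cv(sim$counts$counts["OST", sel]))
})
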