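test_that("Centiloid maps evaluate the printed linear formulas", {
  expect_equal(suvr_to_centiloid(1.0, "PiB"), 132.53 - 147.64)
  expect_equal(suvr_to_centiloid(114.71 / 107.78, "NAV4694"), 0,
               tolerance = 1e-12)
  expect_equal(suvr_to_centiloid(2.0, "florbetaben"), 147 * 2 - 166.5)
  expect_error(suvr_to_centiloid(1.0, "flutemetamol"), "supported")
  expect_error(suvr_to_centiloid(-1, "PiB"), "suvr")
})

test_that("Centiloid maps are exactly linear and strictly increasing", {
  for (tr in c("PiB", "NAV4694", "florbetaben")) {
    y1 <- suvr_to_centiloid(1.0, tr)
    y2 <- suvr_to_centiloid(2.0, tr)
    slope <- y2 - y1
    intercept <- y1 - slope
    expect_gt(slope, 0)
    # two-point recovery predicts any third evaluation
    expect_equal(suvr_to_centiloid(1.37, tr), slope * 1.37 + intercept,
                 tolerance = 1e-12)
  }
})

test_that("amyloid classification applies the cut-off with ties negative", {
  expect_identical(classify_amyloid(30), "positive")
  expect_identical(classify_amyloid(23.5), "negative")
  expect_identical(classify_amyloid(-10), "negative")
  expect_identical(classify_amyloid(c(10, 50)), c("negative", "positive"))
})

test_that("VOI aggregation is the voxel-weighted mean", {
  reg <- data.frame(region = c("a", "b"), dvr = c(1, 2),
                    voxel_count = c(100, 100))
  expect_equal(aggregate_voi(reg, list(name = "x", members = c("a", "b"))),
               1.5)
  reg2 <- data.frame(region = c("a", "b", "c"), dvr = c(1, 2, 99),
                     voxel_count = c(100, 100, 0))
  expect_equal(aggregate_voi(reg2, list(name = "x",
                                        members = c("a", "b", "c"))), 1.5)
  expect_error(aggregate_voi(reg, list(name = "x", members = c("a", "z"))),
               "z")
  # random profiles match an independent weighted-mean oracle
  set.seed(31)
  for (i in 1:20) {
    reg3 <- data.frame(region = letters[1:7], dvr = runif(7, 0.5, 2.5),
                       voxel_count = sample(50:2000, 7))
    got <- aggregate_voi(reg3, list(name = "v", members = letters[1:7]))
    expect_equal(got, weighted.mean(reg3$dvr, reg3$voxel_count),
                 tolerance = 1e-12)
    expect_gte(got, min(reg3$dvr))
    expect_lte(got, max(reg3$dvr))
  }
})

test_that("early metaVOI membership covers the tau-vulnerable regions", {
  m <- voi_definition("early_metaVOI")$members
  expect_setequal(m, c("entorhinal", "perirhinal", "hippocampus_caudal",
                       "hippocampus_rostral", "parahippocampus_lateral",
                       "parahippocampus_medial", "fusiform"))
  expect_setequal(voi_definition("neocortical_VOI")$members,
                  c("temporal_inferior", "temporal_lateral",
                    "parietal_inferior", "parietal_medial"))
})

test_that("tau threshold is mean + 1 sample SD with metadata", {
  thr <- tau_positivity_threshold(c(1, 1, 1))
  expect_equal(as.numeric(thr), 1)
  expect_identical(attr(thr, "n"), 3L)
  expect_error(tau_positivity_threshold(1), "at least 2")
  # sampling oracle: threshold estimates mu + sigma
  set.seed(32)
  x <- rnorm(1000, 0.9, 0.08)
  thr2 <- as.numeric(tau_positivity_threshold(x))
  se <- 0.08 * sqrt(1 / 1000 + 1 / (2 * 999))   # SE of mean + SE of SD
  expect_lt(abs(thr2 - 0.98), 3 * (se * 2))
})

test_that("threshold is affine-equivariant: thr(a x + b) = a mean + b + a SD", {
  set.seed(33)
  x <- runif(20, 0.7, 1.2)
  a <- 2.5; b <- -0.3
  expect_equal(as.numeric(tau_positivity_threshold(a * x + b)),
               a * mean(x) + b + a * sd(x), tolerance = 1e-12)
})

test_that("tau classification counts match brute-force comparison", {
  set.seed(34)
  dvr <- runif(50, 0.7, 1.6)
  thr <- 1.0
  status <- classify_tau(dvr, thr)
  expect_identical(sum(status == "positive"), sum(dvr > thr))
  expect_identical(classify_tau(1.5, 0.921), "positive")
  expect_identical(classify_tau(0.921, 0.921), "negative")
})

test_that("pet_summary assembles per-subject rows with status calls", {
  amy <- data.frame(subject_id = c("S1", "S2"),
                    tracer = c("PiB", "NAV4694"), suvr = c(1.0, 1.8))
  regions <- names(default_voxel_counts())
  tau <- do.call(rbind, lapply(c("S1", "S2"), function(s) {
    data.frame(subject_id = s, region = regions,
               dvr = if (s == "S1") rep(0.8, 11) else rep(1.4, 11),
               voxel_count = as.integer(default_voxel_counts()))
  }))
  out <- pet_summary(amy, tau,
                     tau_thresholds = list(early_metaVOI = 1.0,
                                           neocortical_VOI = 1.0))
  expect_identical(nrow(out), 2L)
  expect_equal(out$dvr_early_metaVOI, c(0.8, 1.4))
  expect_identical(out$amyloid_status, c("negative", "positive"))
  expect_identical(out$tau_status_early, c("negative", "positive"))
})
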