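test_that("radial density bins by annulus and normalises to 1", {
  pts <- cbind(c(0.1, 0.15, 0.3, 0.4), 0)
  d <- radial_density(pts, 2)
  expect_equal(d$densities, c(0.5, 0.5))    # two per half-range
  expect_equal(d$bin_edges, c(0, 0.2, 0.4))
  # half-open bins: a radius exactly on an interior edge joins the upper bin
  expect_equal(radial_density(cbind(c(0.1, 0.2, 0.3, 0.4), 0), 2)$densities,
               c(0.25, 0.75))
  one_r <- cbind(cos(1:50), sin(1:50)) * 0.7
  d1 <- radial_density(one_r, 5)
  expect_equal(d1$densities, c(0, 0, 0, 0, 1))   # max point in last bin
  expect_error(radial_density(cbind(0, 0), 4), "zero-radius")
  expect_error(radial_density(matrix(numeric(0), 0, 2), 4), "empty")
})

test_that("radial density of a uniform disc follows the area law", {
  set.seed(10)
  n <- 1000
  r <- sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  d <- radial_density(cbind(r * cos(th), r * sin(th)), 10)
  expect_equal(sum(d$densities), 1)
  expected <- (2 * (1:10) - 1) / 100          # annulus area fractions
  expect_lt(max(abs(d$densities - expected)), 0.05)
})

test_that("angular density bins by wedge with origin in wedge 1", {
  axis_pts <- cbind(runif(30, 0.1, 1), 0)
  expect_equal(angular_density(axis_pts, 8)$densities,
               c(1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(angular_density(rbind(c(0, 0)), 6)$densities[1], 1)
  set.seed(11)
  th <- runif(1000, 0, 2 * pi)
  d <- angular_density(cbind(cos(th), sin(th)), 20)
  expect_true(all(abs(d$densities - 1 / 20) < 0.05))
})

test_that("rotating a cloud by one wedge shifts the angular density", {
  set.seed(12)
  pts <- matrix(rnorm(600), ncol = 2)
  bins <- 12
  a <- 2 * pi / bins
  rot <- pts %*% rbind(c(cos(a), sin(a)), c(-sin(a), cos(a)))
  d0 <- angular_density(pts, bins)$densities
  d1 <- angular_density(rot, bins)$densities
  expect_equal(d1, d0[c(bins, seq_len(bins - 1))], tolerance = 1e-12)
})

test_that("density vectors are normalised and refinement-consistent", {
  set.seed(13)
  pts <- matrix(rnorm(800), ncol = 2)
  for (B in c(5, 10, 30)) {
    fine_r <- radial_density(pts, 2 * B)$densities
    coarse_r <- radial_density(pts, B)$densities
    expect_equal(colSums(matrix(fine_r, 2)), coarse_r)
    fine_t <- angular_density(pts, 2 * B)$densities
    coarse_t <- angular_density(pts, B)$densities
    expect_equal(colSums(matrix(fine_t, 2)), coarse_t)
    expect_equal(sum(fine_r), 1)
    expect_true(all(fine_r >= 0 & fine_r <= 1))
  }
})

test_that("densities are invariant to uniform scaling of the cloud", {
  set.seed(14)
  pts <- matrix(rnorm(500), ncol = 2)
  for (s in c(0.01, 3, 1e4)) {
    expect_equal(radial_density(pts * s, 20)$densities,
                 radial_density(pts, 20)$densities)
    expect_equal(angular_density(pts * s, 60)$densities,
                 angular_density(pts, 60)$densities)
  }
})

test_that("feature vectors have the documented length, order and sum", {
  g <- generate_ecg(synthetic_ecg_params(seed = 15))
  rec <- downsample(g$record, 4)
  th <- feature_vector(rec, "II", feature_kind = "theta", theta_bins = 60)
  expect_length(th, 60)
  expect_equal(sum(th), 1)
  expect_match(names(th)[1], "^theta_001$")
  rr <- feature_vector(rec, "II", feature_kind = "r", r_bins = 20)
  expect_length(rr, 20)
  expect_equal(sum(rr), 1)
  both <- feature_vector(rec, "II", feature_kind = "both")
  expect_length(both, 80)
  expect_equal(as.numeric(both[1:60]), as.numeric(th))   # theta block first
  expect_equal(as.numeric(both[61:80]), as.numeric(rr))
  expect_equal(attr(th, "record_id"), rec$record_id)
})

test_that("a supplied reference cycle length overrides per-lead detection", {
  g <- generate_ecg(synthetic_ecg_params(seed = 18))
  rec <- downsample(g$record, 4)
  ch <- select_lead(rec, "II")
  L <- average_cycle_length(detect_r_peaks(ch$samples, ch$fs), ch$fs)
  expect_equal(feature_vector(rec, "V6", L_samples = L$L_samples),
               feature_vector(rec, "V6", L_samples = L$L_samples))
  # a very different L changes tau and therefore the densities
  far <- feature_vector(rec, "V6", L_samples = L$L_samples * 2)
  near <- feature_vector(rec, "V6", L_samples = L$L_samples)
  expect_false(isTRUE(all.equal(as.numeric(far), as.numeric(near))))
})

test_that("feature vectors inherit exact baseline invariance", {
  g <- generate_ecg(synthetic_ecg_params(seed = 16))
  rec <- downsample(g$record, 4)
  shifted <- rec
  shifted$samples <- rec$samples + 0.37
  expect_equal(unname(feature_vector(shifted, "II", feature_kind = "both")),
               unname(feature_vector(rec, "II", feature_kind = "both")))
})

test_that("feature table construction drops failing records with a warning", {
  g1 <- generate_ecg(synthetic_ecg_params(seed = 17), record_id = "ok1",
                     patient_id = "pA")
  flat <- ecg_record("bad1", "pB", 500, "II", matrix(0, 1, 5000))
  expect_warning(
    tab <- build_feature_table(list(g1$record, flat), c("case", "control"),
                               lead = "II"),
    "bad1")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$record_id, "ok1")
  expect_length(attr(tab, "feature_names"), 60)
})
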