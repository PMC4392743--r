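noiseless_config <- function(...) {
  sim_config(n_plants_per_group = 2L, days = 15L, size = 32L, sigma = 0,
             quantize = FALSE, plant_cv = 0, seed = 99L, ...)
}

test_that("at sigma = 0 the engine inverts the generator exactly", {
  cfg <- noiseless_config()
  sim <- simulate_session(cfg, "control", 1, 15)
  on_mask <- sim$truth$leaf > 0
  fv <- compute_parameter(sim$session, "FvFm")
  expect_true(all(abs(fv$values[on_mask] - sim$truth$fvfm) < 1e-9))
  # NPQ(t) = npq_inf (1 - exp(-t/tau)); invert with the known kinetics
  for (t in c(25, 74)) {
    npq <- compute_parameter(sim$session, paste0("NPQ_", t))
    est <- npq$values[on_mask] / (1 - exp(-t / cfg$tau_npq))
    expect_true(all(abs(est - sim$truth$npq_inf) < 1e-9))
  }
  # qP(t) = qp_ss + (1 - qp_ss) exp(-t/tau)
  qp <- compute_parameter(sim$session, "qP_74")
  est <- (qp$values[on_mask] - exp(-74 / cfg$tau_qp)) /
    (1 - exp(-74 / cfg$tau_qp))
  expect_true(all(abs(est - sim$truth$qp_ss) < 1e-9))
})

test_that("noiseless captures respect the physical fluorescence ordering", {
  cfg <- noiseless_config()
  for (grp in c("control", "inoculated")) {
    sim <- simulate_session(cfg, grp, 2, 15)
    im <- sim$session$images
    on <- sim$truth$leaf > 0
    expect_true(all(im$F0[on] >= 0))
    expect_true(all(im$Fm[on] >= im$Fp[on] - 1e-9))
    expect_true(all(im$Fp[on] >= im$Ft_25[on] - 1e-9))
    for (t in c(25, 38, 50, 62, 74)) {
      ft <- im[[paste0("Ft_", t)]]; fmL <- im[[paste0("Fm_L_", t)]]
      f0L <- im[[paste0("F0_L_", t)]]
      expect_true(all(ft[on] >= im$F0[on] - 1e-9), info = t)
      expect_true(all(im$Fm[on] >= fmL[on] - 1e-9), info = t)
      expect_true(all(fmL[on] >= f0L[on] - 1e-9), info = t)
    }
    expect_true(all(im$Fm[on] >= im$Fm_85[on] - 1e-9))
    expect_true(all(im$Ft_85[on] >= im$F0[on] - 1e-9))
  }
})

test_that("stress effects lower the configured parameters on stressed plants only", {
  cfg <- noiseless_config()
  h <- simulate_session(cfg, "control", 1, 15)
  s <- simulate_session(cfg, "inoculated", 1, 15)
  expect_true(s$truth$qp_ss_stressed < s$truth$qp_ss)
  expect_equal(s$truth$qp_ss_stressed / s$truth$qp_ss, 0.5)
  expect_equal(h$truth$qp_ss_stressed, h$truth$qp_ss)  # no effect on controls
  expect_false(h$truth$apparent_healthy == FALSE)
  expect_false(s$truth$apparent_healthy)
  on <- s$truth$leaf > 0
  qp_s <- compute_parameter(s$session, "qP_74")$values
  qp_h <- compute_parameter(h$session, "qP_74")$values
  expect_lt(mean(qp_s[on]), mean(qp_h[h$truth$leaf > 0]))
})

test_that("a fixed seed reproduces sessions; plant latents persist across days", {
  cfg <- sim_config(n_plants_per_group = 2L, days = c(15L, 17L), size = 24L,
                    seed = 123L)
  a <- simulate_session(cfg, "control", 1, 15)
  b <- simulate_session(cfg, "control", 1, 15)
  expect_identical(a$session$images, b$session$images)
  expect_identical(a$truth$fvfm, b$truth$fvfm)
  d2 <- simulate_session(cfg, "control", 1, 17)
  expect_identical(a$truth$fvfm, d2$truth$fvfm)     # same plant, same latents
  expect_false(identical(a$session$images$F0, d2$session$images$F0))  # new noise
  other <- simulate_session(cfg, "control", 2, 15)
  expect_false(identical(a$truth$fvfm, other$truth$fvfm))
})

test_that("inoculation failures are generated healthy and flagged", {
  cfg <- sim_config(n_plants_per_group = 12L, days = 15L, size = 16L,
                    inoculation_failure = 0.5, seed = 5L)
  truths <- lapply(seq_len(12), function(p)
    simulate_session(cfg, "inoculated", p, 15)$truth)
  ok <- vapply(truths, `[[`, logical(1), "infection_success")
  expect_true(any(ok) && any(!ok))  # both outcomes at p = 0.5, n = 12
  for (tr in truths[!ok]) {
    expect_true(tr$apparent_healthy)
    expect_equal(max(tr$stress), 0)
  }
  for (tr in truths[ok]) expect_false(tr$apparent_healthy)
})

test_that("simulate_study emits the complete nomenclature tree plus truth", {
  study <- mini_study()
  # 1 ecotype x 2 treatments x 2 plants x 2 days x 55 measures
  expect_equal(nrow(study$manifest), 440L)
  expect_equal(nrow(study$truth), 8L)
  expect_true(file.exists(file.path(study$root, "truth.csv")))
  # histograms sit beside every image
  hists <- list.files(study$root, pattern = "\\.hist\\.txt$", recursive = TRUE)
  expect_length(hists, 440L)
  h <- read_histogram_file(file.path(study$root, hists[1]))
  expect_gt(sum(h$counts), 0)
  # re-running with the same seed reproduces the truth table
  dir2 <- file.path(tempdir(), "phenocf_ministudy2")
  cfg <- sim_config(n_plants_per_group = 2L, days = c(15L, 17L), size = 24L,
                    seed = 7L)
  study2 <- simulate_study(cfg, dir2)
  expect_identical(study$truth, study2$truth)
  f <- study$manifest$path[1]
  expect_identical(read_cf_image(file.path(study$root, f)),
                   read_cf_image(file.path(dir2, f)))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(fvfm0 = 1), "fvfm0")
  expect_error(sim_config(tau_npq = 0), "positive")
  expect_error(sim_config(sigma = -0.1), "fraction")
  expect_error(sim_config(groups = list(bad = list(delta_qp = 1.5))), "in \\[0, 1\\]")
  cfg <- noiseless_config()
  expect_error(simulate_session(cfg, "nope", 1, 15), "unknown group")
})
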