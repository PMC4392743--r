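test_that("global value is the pixel mean, honouring masks", {
  expect_equal(global_value(matrix(7, 5, 5)), 7)
  expect_equal(global_value(matrix(1:4, 2)), 2.5)
  pimg <- structure(list(values = matrix(c(1, 2, 3, NA), 2),
                         mask = matrix(c(TRUE, TRUE, TRUE, FALSE), 2),
                         label = "x"), class = "cf_parameter_image")
  expect_equal(global_value(pimg), 2)
  allmask <- structure(list(values = matrix(NA_real_, 1, 2),
                            mask = matrix(FALSE, 1, 2), label = "x"),
                       class = "cf_parameter_image")
  expect_error(global_value(allmask), "unmasked")
})

test_that("group summaries use type-7 quartile interpolation", {
  s <- summarize_group(c(1, 2, 3, 4, 5))
  expect_equal(unlist(s[c("min", "q1", "median", "q3", "max")]),
               c(min = 1, q1 = 2, median = 3, q3 = 4, max = 5))
  s1 <- summarize_group(7)
  expect_true(all(unlist(s1[c("min", "q1", "median", "q3", "max", "mean")]) == 7))
  s4 <- summarize_group(c(1, 2, 3, 4))
  expect_equal(s4$q1, 1.75)
  expect_equal(s4$median, 2.5)
  expect_equal(s4$q3, 3.25)
  expect_true(with(s4, min <= q1 && q1 <= median && median <= q3 && q3 <= max))
  expect_error(summarize_group(numeric(0)), "non-empty")
})

test_that("exact Mann-Whitney p-values match full enumeration", {
  r1 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r1$U, 0)
  expect_equal(r1$p_value, 0.1)
  expect_equal(r1$method, "exact")
  expect_equal(r1$p_value, mw_exact_oracle(c(1, 2, 3), c(4, 5, 6)))
  r2 <- mann_whitney_u(c(1, 3), c(2, 4))
  expect_equal(r2$U, 1)
  expect_equal(r2$p_value, 2 / 3, tolerance = 1e-12)
  expect_equal(r2$p_value, mw_exact_oracle(c(1, 3), c(2, 4)))
  set.seed(61)
  for (rep in 1:20) {
    a <- round(rnorm(sample(2:6, 1)), 6)
    b <- round(rnorm(sample(2:6, 1)) + 0.5, 6)
    r <- mann_whitney_u(a, b)
    expect_equal(r$U, u_statistic(a, b))
    if (r$method == "exact") {
      expect_equal(r$p_value, mw_exact_oracle(a, b), tolerance = 1e-10)
    }
  }
  # identical groups: ties force the corrected normal approximation, p = 1
  r3 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r3$p_value, 1)
  expect_equal(r3$method, "normal_approx")
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("U complement identity and exact/approximate agreement hold on random samples", {
  set.seed(71)
  for (rep in 1:50) {
    a <- rnorm(8); b <- rnorm(8)
    expect_equal(u_statistic(a, b) + u_statistic(b, a), 64)
    p_exact <- mw_exact_oracle(a, b)
    p_norm <- mann_whitney_u(a, b)$p_value  # n = 16 -> normal approximation
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("significance codes follow the strict 0.05/0.01 thresholds", {
  expect_equal(significance_code(0.005), "**")
  expect_equal(significance_code(0.03), "*")
  expect_equal(significance_code(0.05), "")
  expect_equal(significance_code(0.0099999), "**")
  expect_equal(significance_code(1), "")
  expect_error(significance_code(1.2), "\\[0, 1\\]")
  expect_error(significance_code(-0.1), "\\[0, 1\\]")
})

test_that("radial panels partition measures by magnitude with half-open bounds", {
  m <- c(a = 0.75, b = 10, c = 100, d = 500)
  p <- radial_panel_partition(m)
  expect_equal(unname(p), 1:4)
  expect_equal(unname(radial_panel_partition(c(x = 1))), 2L)
  expect_equal(unname(radial_panel_partition(c(x = 25))), 3L)
  expect_equal(unname(radial_panel_partition(c(x = 300))), 4L)
  expect_warning(pn <- radial_panel_partition(c(x = -2)), "negative")
  expect_equal(unname(pn), 1L)
  # every measure in exactly one panel
  set.seed(81)
  v <- stats::setNames(runif(30, 0, 600), paste0("m", 1:30))
  pp <- radial_panel_partition(v)
  expect_true(all(pp %in% 1:4))
  expect_length(pp, 30L)
})

test_that("compare_all produces one coded comparison per measure and stratum", {
  set.seed(91)
  sched <- cf_schedule()
  mk <- function(trt, shift) {
    do.call(rbind, lapply(1:4, function(p) data.frame(
      ecotype = "Col0", treatment = trt, plant = sprintf("P%02d", p), day = 15,
      label = sched$label, global_value = rnorm(55) + shift,
      stringsAsFactors = FALSE)))
  }
  tab <- rbind(mk("control", 0), mk("inoculated", 0))
  cmp <- compare_all(tab, c("control", "inoculated"))
  expect_equal(nrow(cmp), 55L)
  expect_equal(cmp$measure, sched$label)  # deterministic schedule order
  # identical groups -> no stars
  tab_same <- tab
  tab_same$global_value <- rep(rep(rnorm(55), 4), 2)
  cmp_same <- compare_all(tab_same, c("control", "inoculated"))
  expect_true(all(cmp_same$code == ""))
  expect_true(all(cmp_same$p_value == 1))
  # strongly separated groups at n = 15/15 earn "**"
  big <- rbind(
    do.call(rbind, lapply(1:15, function(p) data.frame(
      ecotype = "Col0", treatment = "control", plant = sprintf("P%02d", p),
      day = 15, label = "qP_74", global_value = rnorm(1, 10, 0.5)))),
    do.call(rbind, lapply(1:15, function(p) data.frame(
      ecotype = "Col0", treatment = "inoculated", plant = sprintf("P%02d", p),
      day = 15, label = "qP_74", global_value = rnorm(1, 0, 0.5)))))
  cb <- compare_all(big, c("control", "inoculated"))
  expect_equal(cb$code, "**")
  expect_equal(cb$method, "normal_approx")
})
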