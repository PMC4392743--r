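test_that("image tallies use half-open bins with a closed last bin", {
  h <- image_to_histogram(matrix(c(0, 0, 1, 4095), 2), n_bins = 2,
                          range = c(0, 4096))
  expect_equal(h$counts, c(3, 1))
  expect_equal(sum(h$counts), 4)
  hc <- image_to_histogram(matrix(7, 3, 3), n_bins = 16, range = c(0, 16))
  expect_equal(sum(hc$counts > 0), 1L)
  expect_equal(max(hc$counts), 9)
  # the top-of-range value lands in the (closed) last bin
  ht <- image_to_histogram(matrix(c(0, 10), 1), n_bins = 10, range = c(0, 10))
  expect_equal(ht$counts[10], 1)
  # masked pixels excluded; fully masked errors
  pimg <- structure(list(values = matrix(c(1, NA), 1),
                         mask = matrix(c(TRUE, FALSE), 1), label = "x"),
                    class = "cf_parameter_image")
  expect_equal(sum(image_to_histogram(pimg, 4, c(0, 4))$counts), 1)
  allmask <- structure(list(values = matrix(NA_real_, 2, 2),
                            mask = matrix(FALSE, 2, 2), label = "x"),
                       class = "cf_parameter_image")
  expect_error(image_to_histogram(allmask), "masked")
})

test_that("Bhattacharyya coefficient matches hand sums and the scalar oracle", {
  p <- cf_histogram(0:1, c(1, 1))
  q <- cf_histogram(0:1, c(8, 92))
  expect_equal(bhattacharyya_coefficient(p, p), 1)
  expect_equal(bhattacharyya_coefficient(p, q), 0.2 + sqrt(0.46),
               tolerance = 1e-12)
  disj <- bhattacharyya_coefficient(cf_histogram(0:1, c(1, 0)),
                                    cf_histogram(0:1, c(0, 1)))
  expect_equal(disj, 0)
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(2:40, 1)
    a <- cf_histogram(seq_len(n), rpois(n, 5) + 1)
    b <- cf_histogram(seq_len(n), rpois(n, 5) + 1)
    bc <- bhattacharyya_coefficient(a, b)
    expect_equal(bc, bc_scalar_oracle(a$counts, b$counts), tolerance = 1e-12)
    expect_gte(bc, 0); expect_lte(bc, 1 + 1e-12)
  }
  expect_error(bhattacharyya_coefficient(p, cf_histogram(0:2, c(1, 1, 1))),
               "grid")
})

test_that("BC = 1 exactly when the normalized histograms coincide", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:20, 1)
    c1 <- rpois(n, 4) + 1
    same <- cf_histogram(seq_len(n), c1 * sample(1:5, 1))  # scaled copy
    expect_equal(bhattacharyya_coefficient(cf_histogram(seq_len(n), c1), same), 1,
                 tolerance = 1e-12)
    other <- c1; other[1] <- other[1] + 3
    expect_lt(bhattacharyya_coefficient(cf_histogram(seq_len(n), c1),
                                        cf_histogram(seq_len(n), other)),
              1 - 1e-10)
  }
})

test_that("Hellinger distance is bounded, zero iff equal, one iff disjoint", {
  p <- cf_histogram(0:1, c(3, 1))
  expect_equal(histogram_distance(p, p), 0)
  expect_equal(histogram_distance(cf_histogram(0:1, c(1, 0)),
                                  cf_histogram(0:1, c(0, 1))), 1)
  bc <- 0.2 + sqrt(0.46)
  expect_equal(histogram_distance(cf_histogram(0:1, c(50, 50)),
                                  cf_histogram(0:1, c(8, 92))),
               sqrt(1 - bc), tolerance = 1e-12)
  # flagged variant: -log(BC)
  expect_equal(histogram_distance(cf_histogram(0:1, c(50, 50)),
                                  cf_histogram(0:1, c(8, 92)),
                                  kind = "bhattacharyya-log"),
               -log(bc), tolerance = 1e-12)
})

test_that("Hellinger distance satisfies the triangle inequality on random triples", {
  set.seed(41)
  n <- 16L
  for (rep in 1:200) {
    hs <- lapply(1:3, function(i) cf_histogram(seq_len(n), rpois(n, 3)))
    ok <- vapply(hs, function(h) sum(h$counts) > 0, logical(1))
    if (!all(ok)) next
    d12 <- histogram_distance(hs[[1]], hs[[2]])
    d13 <- histogram_distance(hs[[1]], hs[[3]])
    d23 <- histogram_distance(hs[[2]], hs[[3]])
    expect_lte(d12, d13 + d23 + 1e-12)
    expect_lte(d13, d12 + d23 + 1e-12)
    expect_lte(d23, d12 + d13 + 1e-12)
  }
})

test_that("pairwise distance matrices are symmetric, zero-diagonal and match a double loop", {
  set.seed(51)
  hs <- lapply(1:5, function(i) cf_histogram(1:12, rpois(12, 6) + 1))
  names(hs) <- paste0("plant", 1:5)
  d <- pairwise_distances(hs)
  expect_equal(dim(d), c(5L, 5L))
  expect_equal(rownames(d), names(hs))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 5))
  for (i in 1:5) for (j in 1:5) {
    if (i != j) {
      expect_equal(d[i, j], histogram_distance(hs[[i]], hs[[j]]),
                   tolerance = 1e-12)
    }
  }
  same <- pairwise_distances(list(hs[[1]], hs[[1]], hs[[1]]))
  expect_equal(max(same), 0)
  expect_error(pairwise_distances(hs[1]), "at least 2")
})

test_that("rebinning conserves mass and unequal grids are refined before comparison", {
  h <- image_to_histogram(matrix(runif(100, 0, 100), 10), n_bins = 20,
                          range = c(0, 100))
  coarse <- rebin_histogram(h, seq(0, 100, by = 10))
  expect_equal(sum(coarse$counts), sum(h$counts))
  # coarsening a histogram against itself cannot create distance
  expect_equal(histogram_distance(coarse, coarse), 0)
  a <- cf_histogram(c(1, 2, 3), c(5, 5, 5), breaks = c(0, 1.5, 2.5, 3.5))
  b <- cf_histogram(c(1, 3), c(5, 10), breaks = c(0, 2.5, 3.5))
  d <- pairwise_distances(list(a = a, b = b))
  expect_true(is.finite(d[1, 2]))
  expect_error(pairwise_distances(list(a = a, b = b), rebin = FALSE), "grid")
})
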