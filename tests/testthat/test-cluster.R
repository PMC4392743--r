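test_that("three-point linkage matches hand-worked merges for min/max/average rules", {
  d <- matrix(c(0, 2, 6, 2, 0, 8, 6, 8, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  s <- linkage(d, "single")
  expect_equal(s$height, c(2, 6))
  expect_equal(dendrogram_merge_sets(s), list(c("A", "B"), c("A", "B", "C")))
  expect_equal(linkage(d, "complete")$height, c(2, 8))
  expect_equal(linkage(d, "average")$height, c(2, 7))
  # n = 2: single merge at d(1, 2) for every method
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  for (m in c("single", "complete", "average", "mcquitty", "median", "centroid")) {
    l2 <- linkage(d2, m)
    expect_equal(l2$height, 0.4, info = m)
  }
  expect_error(linkage(d, "ward"), "single, complete, average")
  expect_error(linkage(d[1, 1, drop = FALSE], "single"), "at least 2")
})

test_that("all six methods match the naive Lance-Williams agglomerator on random matrices", {
  set.seed(101)
  methods <- c("single", "complete", "average", "mcquitty", "median", "centroid")
  for (rep in 1:30) {
    d <- random_distance_matrix(sample(4:8, 1))
    for (m in methods) {
      got <- linkage(d, m)
      want <- naive_linkage(d, m)
      expect_equal(got$height, want$heights, tolerance = 1e-9,
                   info = sprintf("%s rep %d heights", m, rep))
      expect_equal(dendrogram_merge_sets(got), want$merges,
                   info = sprintf("%s rep %d merges", m, rep))
    }
  }
})

test_that("single-linkage heights are the sorted MST edge weights (Gower-Ross)", {
  skip_if_not_installed("vegan")
  set.seed(111)
  for (rep in 1:20) {
    d <- random_distance_matrix(sample(5:10, 1))
    h <- linkage(d, "single")$height
    mst <- vegan::spantree(stats::as.dist(d))
    expect_equal(h, sort(mst$dist), tolerance = 1e-12)
  }
})

test_that("merge-order cuts return k groups, robust to centroid inversions", {
  d <- matrix(c(0, 2, 6, 2, 0, 8, 6, 8, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dend <- linkage(d, "single")
  expect_equal(unname(cut_k(dend, 1)), c(1, 1, 1))
  expect_equal(length(unique(cut_k(dend, 3))), 3L)
  k2 <- cut_k(dend, 2)
  expect_equal(k2[["A"]], k2[["B"]])
  expect_false(k2[["A"]] == k2[["C"]])
  expect_error(cut_k(dend, 0), "k must be")
  expect_error(cut_k(dend, 4), "k must be")
  set.seed(121)
  for (rep in 1:10) {
    d <- random_distance_matrix(7)
    for (m in c("centroid", "median", "average")) {
      dend <- linkage(d, m)
      for (k in c(2, 3, 7)) {
        cl <- cut_k(dend, k)
        expect_equal(length(unique(cl)), k, info = m)
      }
    }
  }
})

test_that("mis-clustering rate minimizes over label permutations", {
  assign2 <- stats::setNames(c(1, 1, 1, 2, 2, 2), paste0("p", 1:6))
  truth <- stats::setNames(rep(c("ctrl", "inoc"), each = 3), paste0("p", 1:6))
  expect_equal(misclustering_rate(assign2, truth)$rate, 0)
  # swapped ids: still a perfect partition
  expect_equal(misclustering_rate(3 - assign2, truth)$rate, 0)
  one_off <- assign2; one_off["p4"] <- 1
  ev <- misclustering_rate(one_off, truth)
  expect_equal(ev$rate, 1 / 6)
  expect_equal(ev$misclustered, "p4")
  # 1 of 10 leaves wrong -> 0.1
  a10 <- stats::setNames(rep(1:2, each = 5), paste0("q", 1:10))
  t10 <- stats::setNames(rep(c("A", "B"), each = 5), paste0("q", 1:10))
  a10["q1"] <- 2
  expect_equal(misclustering_rate(a10, t10)$rate, 0.1)
  expect_error(misclustering_rate(unname(a10), t10), "named")
  expect_error(misclustering_rate(a10, t10[1:5]), "different leaves")
})

test_that("cut partitions and rates are invariant to leaf relabeling", {
  set.seed(131)
  n <- 10L
  d <- random_distance_matrix(n)
  truth <- stats::setNames(rep(c("a", "b"), each = n / 2), rownames(d))
  base <- misclustering_rate(cut_k(linkage(d, "average"), 2), truth)
  for (rep in 1:5) {
    perm <- sample(n)
    dp <- d[perm, perm]
    got <- misclustering_rate(cut_k(linkage(dp, "average"), 2), truth)
    expect_equal(got$rate, base$rate)
    expect_setequal(got$misclustered, base$misclustered)
  }
})

test_that("cluster_all_measures separates well-separated groups and flags degenerate sets", {
  set.seed(141)
  mk_hist <- function(mu) {
    v <- pmin(pmax(rnorm(400, mu, 30), 0), 4095)
    image_to_histogram(matrix(v, 20), n_bins = 64, range = c(0, 4096))
  }
  plants <- c(sprintf("C%02d", 1:10), sprintf("I%02d", 1:10))
  truth <- stats::setNames(rep(c("ctrl", "inoc"), each = 10), plants)
  hs <- c(lapply(1:10, function(i) mk_hist(800)),
          lapply(1:10, function(i) mk_hist(2500)))
  names(hs) <- plants
  flat <- lapply(plants, function(p) cf_histogram(1:4, c(1, 2, 3, 4)))
  names(flat) <- plants
  res <- cluster_all_measures(list(qP_25 = hs, flatm = flat),
                              method = c("mcquitty", "average"), truth = truth)
  expect_equal(nrow(res), 4L)
  expect_equal(res$rate[res$measure == "qP_25"], c(0, 0))
  expect_true(all(res$degenerate[res$measure == "flatm"]))
  expect_false(any(res$degenerate[res$measure == "qP_25"]))
  # label-shuffled truth: strong clusters cannot beat chance systematically
  shuf <- stats::setNames(sample(truth), plants)
  r2 <- cluster_all_measures(list(qP_25 = hs), method = "mcquitty",
                             truth = shuf)
  expect_gte(r2$rate, 0.2)
  expect_lte(r2$rate, 0.5)
})

test_that("Newick export is well-formed and carries all leaves and heights", {
  d <- matrix(c(0, 2, 6, 2, 0, 8, 6, 8, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nwk <- as_newick(linkage(d, "single"))
  expect_match(nwk, "^\\(.*\\);$")
  for (leaf in c("A", "B", "C")) expect_match(nwk, leaf)
  expect_equal(nwk, "(C:6,(A:2,B:2):4);")
  # parses back with ape
  skip_if_not_installed("ape")
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
})
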