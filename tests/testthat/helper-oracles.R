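# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and hclust/wilcox.test) so they can vouch for
# them.

# --- Mann-Whitney U by full enumeration -------------------------------------
# U = #{(i,j): a_i > b_j} (+ 0.5 per tie); two-sided p by enumerating every
# C(n_a + n_b, n_a) assignment of the pooled values to group a.
u_statistic <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

mw_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  mid <- na * length(b) / 2
  obs <- abs(u_statistic(a, b) - mid)
  sets <- utils::combn(n, na)
  hits <- 0L
  for (j in seq_len(ncol(sets))) {
    ap <- pooled[sets[, j]]; bp <- pooled[-sets[, j]]
    if (abs(u_statistic(ap, bp) - mid) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / ncol(sets)
}

# --- Naive O(n^3) Lance-Williams agglomerator -------------------------------
# single/complete/average recompute inter-cluster distances from the original
# matrix; mcquitty/median apply the recurrence; centroid uses the closed form
# ||c_A - c_B||^2 = meanInter - V_A - V_B on squared distances.
# Returns merge member sets (sorted label vectors) and heights, in
# agglomeration order (min-distance pair first, smallest-index tie-break).
naive_linkage <- function(D, method) {
  n <- nrow(D)
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  squared <- method %in% c("median", "centroid")
  D0 <- if (squared) D^2 else D
  clusters <- as.list(seq_len(n))
  CD <- D0
  merges <- list(); heights <- numeric(0)
  pair_dist <- function(A, B) {
    block <- D0[A, B, drop = FALSE]
    switch(method,
      single = min(block),
      complete = max(block),
      average = mean(block),
      centroid = {
        v <- function(S) sum(D0[S, S, drop = FALSE]) / (2 * length(S)^2)
        mean(block) - v(A) - v(B)
      },
      stop("pair_dist not defined for ", method))
  }
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(Inf, 0L, 0L)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      if (CD[i, j] < best[1] - 1e-15) best <- c(CD[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    merges[[length(merges) + 1L]] <-
      sort(labels[c(clusters[[i]], clusters[[j]])])
    heights <- c(heights, if (squared) sqrt(max(0, best[1])) else best[1])
    newc <- c(clusters[[i]], clusters[[j]])
    # distances from the merged cluster to the others
    others <- setdiff(seq_len(m), c(i, j))
    nd <- vapply(others, function(k) {
      switch(method,
        mcquitty = (CD[i, k] + CD[j, k]) / 2,
        median = CD[i, k] / 2 + CD[j, k] / 2 - CD[i, j] / 4,
        pair_dist(newc, clusters[[k]]))
    }, numeric(1))
    clusters <- c(clusters[others], list(newc))
    m2 <- length(clusters)
    CD2 <- matrix(0, m2, m2)
    CD2[seq_along(others), seq_along(others)] <- CD[others, others]
    CD2[m2, seq_along(others)] <- nd
    CD2[seq_along(others), m2] <- nd
    CD <- CD2
  }
  list(merges = merges, heights = heights)
}

# Member sets of each merge of a cf_dendrogram, in agglomeration order.
dendrogram_merge_sets <- function(dend) {
  n <- length(dend$labels)
  sets <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    grab <- function(x) if (x < 0) dend$labels[-x] else sets[[x]]
    sets[[i]] <- sort(c(grab(dend$merge[i, 1]), grab(dend$merge[i, 2])))
  }
  sets
}

random_distance_matrix <- function(n, labels = sprintf("L%02d", seq_len(n))) {
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2, 0.05, 1)
  d + t(d)
}

# --- scalar Bhattacharyya loop ----------------------------------------------
bc_scalar_oracle <- function(p_counts, q_counts) {
  ph <- p_counts / sum(p_counts); qh <- q_counts / sum(q_counts)
  s <- 0
  for (k in seq_along(ph)) s <- s + sqrt(ph[k] * qh[k])
  s
}

# --- tiny synthetic sessions ------------------------------------------------
# A complete 21-capture session with physically ordered values; matrices are
# `side` x `side` with mild deterministic spatial structure.
complete_test_session <- function(side = 4L, f0 = 1000, fm = 4000) {
  grad <- matrix(seq(0.9, 1.1, length.out = side * side), side, side)
  F0 <- f0 * grad
  Fm <- fm * grad
  imgs <- list(F0 = F0, Fm = Fm, F0_85 = F0, Fm_85 = 0.95 * Fm,
               Fp = F0 + 0.9 * (Fm - F0))
  for (t in c(25L, 38L, 50L, 62L, 74L)) {
    fmL <- Fm * (1 - 0.3 * (1 - exp(-t / 30)))
    qp <- 0.55 + 0.45 * exp(-t / 20)
    imgs[[paste0("Fm_L_", t)]] <- fmL
    imgs[[paste0("Ft_", t)]] <- Fm - qp * (Fm - F0)
    imgs[[paste0("F0_L_", t)]] <- F0 * fmL / Fm
  }
  imgs$Ft_85 <- F0 + 0.2 * (imgs$Ft_74 - F0)
  plant_session(imgs, key = list(ecotype = "Col0", treatment = "control",
                                 plant = "P01", day = 15))
}

# --- shared mini on-disk study (memoized per test run) ----------------------
.fixture_env <- new.env(parent = emptyenv())

mini_study <- function() {
  if (is.null(.fixture_env$study)) {
    dir <- file.path(tempdir(), "phenocf_ministudy")
    cfg <- sim_config(n_plants_per_group = 2L, days = c(15L, 17L), size = 24L,
                      seed = 7L)
    .fixture_env$study <- simulate_study(cfg, dir)
    .fixture_env$config <- cfg
  }
  .fixture_env$study
}
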