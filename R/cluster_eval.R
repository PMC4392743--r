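# Hierarchical agglomerative clustering of histogram distance matrices with
# the six Lance-Williams linkage methods, merge-order k-cuts, Newick export
# and mis-clustering-rate evaluation against known labels.

.linkage_methods <- c("single", "complete", "average", "mcquitty", "median",
                      "centroid")

#' Agglomerative clustering of a distance matrix
#'
#' Repeatedly merges the closest pair under the chosen Lance-Williams
#' update: `single` (min), `complete` (max), `average` (UPGMA),
#' `mcquitty` (WPGMA), `median` (WPGMC) and `centroid` (UPGMC). The two
#' geometric methods (`median`, `centroid`) are applied on squared
#' distances, with square-root heights reported; their heights may invert
#' (decrease), which is recorded on the result.
#'
#' @param d A symmetric distance matrix (e.g. from [pairwise_distances()])
#'   or a `dist` object.
#' @param method One of `"single"`, `"complete"`, `"average"`,
#'   `"mcquitty"`, `"median"`, `"centroid"`.
#' @return An object of class `cf_dendrogram`: list with `merge` (hclust
#'   convention: negative = leaf, positive = earlier merge), `height`,
#'   `labels`, `method` and `inversions` (number of height decreases).
#' @examples
#' d <- matrix(c(0, 2, 6, 2, 0, 8, 6, 8, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' linkage(d, "average")$height  # 2, 7
#' @export
linkage <- function(d, method = "average") {
  if (!method %in% .linkage_methods) {
    stop(sprintf("unknown method '%s'; valid methods: %s", method,
                 paste(.linkage_methods, collapse = ", ")))
  }
  if (inherits(d, "dist")) {
    labels <- attr(d, "Labels")
    if (is.null(labels)) labels <- as.character(seq_len(attr(d, "Size")))
    dd <- d
  } else {
    if (!is.matrix(d) || nrow(d) != ncol(d)) stop("'d' must be a square matrix")
    if (max(abs(d - t(d))) > 1e-12 || any(diag(d) != 0) || any(d < 0)) {
      stop("'d' must be symmetric, non-negative, with zero diagonal")
    }
    labels <- rownames(d)
    if (is.null(labels)) labels <- as.character(seq_len(nrow(d)))
    dd <- stats::as.dist(d)
  }
  n <- attr(dd, "Size")
  if (n < 2L) stop("need at least 2 items")
  squared <- method %in% c("median", "centroid")
  hc <- stats::hclust(if (squared) dd^2 else dd, method = method)
  height <- if (squared) sqrt(pmax(0, hc$height)) else hc$height
  structure(list(merge = hc$merge, height = height, labels = labels,
                 order = hc$order, method = method,
                 inversions = sum(diff(height) < -1e-12)),
            class = "cf_dendrogram")
}

#' @export
print.cf_dendrogram <- function(x, ...) {
  cat(sprintf("CF dendrogram: %d leaves, method '%s', heights [%g, %g]%s\n",
              length(x$labels), x$method, min(x$height), max(x$height),
              if (x$inversions) sprintf(", %d inversion(s)", x$inversions) else ""))
  invisible(x)
}

#' Cut a dendrogram into k clusters by merge order
#'
#' Undoes the last `k - 1` merges in agglomeration order. Unlike a height
#' cut, this is robust to the inversions centroid/median linkage can
#' produce.
#'
#' @param dend A `cf_dendrogram`.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Integer cluster ids (1..k) named by leaf label, in leaf order.
#' @export
cut_k <- function(dend, k) {
  stopifnot(inherits(dend, "cf_dendrogram"))
  n <- length(dend$labels)
  if (k < 1L || k > n) stop(sprintf("k must be in [1, %d]", n))
  comp <- -seq_len(n)                       # component id per leaf
  names(comp) <- dend$labels
  merge_id <- integer(n - 1L)               # component id per merge node
  for (i in seq_len(n - k)) {
    m <- dend$merge[i, ]
    members <- function(x) if (x < 0) which(comp == x) else which(comp == merge_id[x])
    grp <- c(members(m[1]), members(m[2]))
    comp[grp] <- n + i                      # fresh id
    merge_id[i] <- n + i
  }
  ids <- match(comp, unique(comp))
  names(ids) <- dend$labels
  ids
}

#' Mis-clustering rate of an assignment against ground truth
#'
#' Clusters are mapped to truth labels by the best one-to-one assignment
#' (all label permutations, small k), minimizing disagreements.
#'
#' @param assignment Integer/character cluster ids, named by leaf.
#' @param truth Ground-truth labels (treatment or apparent health), named by
#'   leaf; must cover the same leaves.
#' @return A list of class `cf_cluster_eval`: `k`, `rate`, `misclustered`
#'   (leaf names), `mapping` (cluster -> truth label), `assignment`,
#'   `truth`.
#' @export
misclustering_rate <- function(assignment, truth) {
  if (is.null(names(assignment)) || is.null(names(truth))) {
    stop("'assignment' and 'truth' must be named by leaf")
  }
  if (!setequal(names(assignment), names(truth))) {
    stop("'assignment' and 'truth' cover different leaves")
  }
  truth <- truth[names(assignment)]
  cl <- as.integer(factor(assignment))
  tl <- factor(truth)
  k <- nlevels(tl)
  kc <- max(cl)
  if (kc > 8L || k > 8L) stop("permutation search supports at most 8 labels")
  # Contingency of cluster x truth; search truth-label permutations assigned
  # to clusters (clusters beyond k labels, or labels beyond kc clusters, are
  # handled by padding).
  tab <- table(factor(cl, levels = seq_len(kc)), tl)
  kk <- max(k, kc)
  pad <- matrix(0, kk, kk)
  pad[seq_len(kc), seq_len(k)] <- tab
  perms <- .permutations(kk)
  best <- Inf; best_perm <- NULL
  for (p in seq_len(nrow(perms))) {
    hits <- sum(pad[cbind(seq_len(kk), perms[p, ])])
    err <- length(cl) - hits
    if (err < best) { best <- err; best_perm <- perms[p, ] }
  }
  mapped <- levels(tl)[best_perm[cl]]
  mis <- names(assignment)[is.na(mapped) | mapped != as.character(truth)]
  structure(list(k = k, n = length(cl), rate = best / length(cl),
                 misclustered = mis,
                 mapping = stats::setNames(levels(tl)[best_perm[seq_len(kc)]],
                                           sort(unique(assignment))),
                 assignment = assignment, truth = truth),
            class = "cf_cluster_eval")
}

.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1L)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

#' @export
print.cf_cluster_eval <- function(x, ...) {
  cat(sprintf("Cluster evaluation: k = %d, n = %d, mis-clustering rate %.3f (%d leaves)\n",
              x$k, x$n, x$rate, length(x$misclustered)))
  invisible(x)
}

#' Cluster every measure's histogram set and evaluate against truth
#'
#' For each measure: pairwise Hellinger distances, linkage, cut at
#' `k = `number of distinct truth labels, mis-clustering rate. Measures
#' whose histograms are all identical (zero distance matrix) are flagged
#' `degenerate`; their tie-broken tree still yields a deterministic rate.
#'
#' @param histogram_sets Named list (measure -> named list of
#'   [cf_histogram()]s, one per plant).
#' @param method Linkage method, or a vector of methods.
#' @param truth Ground-truth labels named by plant.
#' @param kind Distance kind (see [histogram_distance()]).
#' @return Data frame: `measure`, `method`, `k`, `rate`, `degenerate`.
#' @export
cluster_all_measures <- function(histogram_sets, method = "mcquitty", truth,
                                 kind = "hellinger") {
  rows <- list()
  for (meas in names(histogram_sets)) {
    d <- pairwise_distances(histogram_sets[[meas]], kind = kind)
    degen <- max(d) <= 1e-12
    for (m in method) {
      dend <- linkage(d, m)
      k <- length(unique(truth))
      ev <- misclustering_rate(cut_k(dend, k), truth)
      rows[[length(rows) + 1L]] <- data.frame(
        measure = meas, method = m, k = k, rate = ev$rate,
        degenerate = degen, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are differences of merge heights (leaf branches span from
#' height 0 to their parent merge); inversions may yield negative lengths
#' for centroid/median trees.
#'
#' @param dend A `cf_dendrogram`.
#' @return A single Newick string, terminated by `";"`.
#' @export
as_newick <- function(dend) {
  stopifnot(inherits(dend, "cf_dendrogram"))
  node <- function(i) {
    if (i < 0) list(str = dend$labels[-i], h = 0)
    else {
      a <- node(dend$merge[i, 1]); b <- node(dend$merge[i, 2])
      h <- dend$height[i]
      list(str = sprintf("(%s:%.10g,%s:%.10g)", a$str, h - a$h,
                         b$str, h - b$h),
           h = h)
    }
  }
  paste0(node(nrow(dend$merge))$str, ";")
}

#' Plot a dendrogram with truth labels color-coded
#'
#' @param x A `cf_dendrogram`.
#' @param truth Optional labels named by leaf; leaves are colored by label.
#' @param ... Passed to `plot.hclust`.
#' @export
plot.cf_dendrogram <- function(x, truth = NULL, ...) {
  hc <- list(merge = x$merge, height = cummax(x$height), order = x$order,
             labels = x$labels, method = x$method, call = match.call(),
             dist.method = "hellinger")
  class(hc) <- "hclust"
  graphics::plot(hc, ...)
  if (!is.null(truth)) {
    tl <- factor(truth[x$labels[x$order]])
    graphics::mtext(x$labels[x$order], side = 1, at = seq_along(x$order),
                    col = as.integer(tl), cex = 0.6, las = 2)
  }
  invisible(x)
}
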