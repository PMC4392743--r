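# Histogram construction and Bhattacharyya-based distances.
#
# The Bhattacharyya coefficient between two histograms normalized to unit
# mass is BC = sum_k sqrt(p_k * q_k); the default distance is the Hellinger
# form d = sqrt(1 - BC), a metric bounded in [0, 1]. The unbounded
# Bhattacharyya distance -ln(BC) is available via `kind = "bhattacharyya-log"`.

#' Tally an image into a histogram
#'
#' Bins use half-open intervals `[edge_k, edge_{k+1})`, with the last bin
#' closed on the right. Masked pixels (of a `cf_parameter_image`) and `NA`s
#' are excluded; counts sum to the number of unmasked in-range pixels.
#'
#' @param image A numeric/integer matrix, or a `cf_parameter_image`.
#' @param n_bins Number of uniform bins (default 256).
#' @param range Numeric `(lo, hi)` with `hi > lo`; default `c(0, 4096)`, the
#'   12-bit intensity range. For ratio-valued parameter images pass a shared
#'   observed range (see [shared_range()]).
#' @return A [cf_histogram()] with `breaks` set.
#' @examples
#' image_to_histogram(matrix(c(0, 0, 1, 4095), 2), n_bins = 2)$counts  # 3 1
#' @export
image_to_histogram <- function(image, n_bins = 256L, range = c(0, 4096)) {
  if (inherits(image, "cf_parameter_image")) {
    v <- image$values[image$mask]
  } else {
    v <- as.numeric(image)
  }
  v <- v[is.finite(v)]
  if (!length(v)) stop("image is entirely masked; no pixels to tally")
  if (n_bins < 1L) stop("n_bins must be >= 1")
  lo <- range[1]; hi <- range[2]
  if (!(hi > lo)) stop("range must satisfy hi > lo")
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  idx <- findInterval(v, edges, rightmost.closed = TRUE, left.open = FALSE)
  idx <- idx[idx >= 1L & idx <= n_bins]
  counts <- tabulate(idx, nbins = n_bins)
  cf_histogram(levels = (edges[-1] + edges[-length(edges)]) / 2,
               counts = counts, breaks = edges)
}

#' Shared binning range across a set of images
#'
#' Calculated (ratio-valued) parameter images have no fixed dynamic range;
#' for Bhattacharyya comparison all histograms of one analysis must share a
#' grid. This returns the observed min/max over unmasked pixels of all
#' images in the set (slightly widened at the top so the max falls in the
#' closed last bin).
#'
#' @param images List of matrices or `cf_parameter_image`s.
#' @return Numeric `(lo, hi)`.
#' @export
shared_range <- function(images) {
  vals <- unlist(lapply(images, function(im) {
    v <- if (inherits(im, "cf_parameter_image")) im$values[im$mask] else as.numeric(im)
    v[is.finite(v)]
  }))
  if (!length(vals)) stop("no unmasked pixels in the image set")
  r <- range(vals)
  if (r[2] <= r[1]) r[2] <- r[1] + 1e-6
  r
}

.normalized <- function(h) {
  tot <- sum(h$counts)
  if (tot <= 0) stop("histogram has zero total count")
  h$counts / tot
}

.same_grid <- function(p, q) {
  length(p$levels) == length(q$levels) &&
    isTRUE(all.equal(p$levels, q$levels, tolerance = 1e-9))
}

#' Bhattacharyya coefficient between two histograms
#'
#' @param p,q [cf_histogram()] objects on identical bin grids (use
#'   [rebin_histogram()] first otherwise), each with positive total count.
#' @return `sum(sqrt(p_hat * q_hat))`, in `[0, 1]`; 1 iff the normalized
#'   histograms are equal.
#' @export
bhattacharyya_coefficient <- function(p, q) {
  stopifnot(inherits(p, "cf_histogram"), inherits(q, "cf_histogram"))
  if (!.same_grid(p, q)) {
    stop("histograms are on different bin grids; rebin to a common grid first")
  }
  sum(sqrt(.normalized(p) * .normalized(q)))
}

#' Distance between two histograms
#'
#' @inheritParams bhattacharyya_coefficient
#' @param kind `"hellinger"` (default): `sqrt(1 - BC)`, a metric in
#'   `[0, 1]`; or `"bhattacharyya-log"`: `-log(BC)`, unbounded.
#' @return A non-negative distance; 0 iff the normalized histograms agree.
#' @export
histogram_distance <- function(p, q, kind = c("hellinger", "bhattacharyya-log")) {
  kind <- match.arg(kind)
  bc <- min(1, bhattacharyya_coefficient(p, q))
  if (kind == "hellinger") sqrt(max(0, 1 - bc)) else -log(max(bc, .Machine$double.xmin))
}

#' Rebin a histogram onto a new edge grid
#'
#' Counts are redistributed proportionally to bin-overlap length (mass
#' uniform within each source bin). Histograms without stored breaks are
#' treated as unit-width bins centred on their levels.
#'
#' @param h A [cf_histogram()].
#' @param edges Strictly increasing numeric vector of new bin edges.
#' @return A [cf_histogram()] on the new grid.
#' @export
rebin_histogram <- function(h, edges) {
  stopifnot(inherits(h, "cf_histogram"))
  edges <- as.numeric(edges)
  if (length(edges) < 2L || any(diff(edges) <= 0)) {
    stop("edges must be strictly increasing with at least 2 entries")
  }
  old <- h$breaks
  if (is.null(old)) {
    old <- c(h$levels - 0.5, h$levels[length(h$levels)] + 0.5)
  }
  n_new <- length(edges) - 1L
  counts <- numeric(n_new)
  for (i in seq_along(h$counts)) {
    a <- old[i]; b <- old[i + 1L]
    if (h$counts[i] == 0) next
    for (j in seq_len(n_new)) {
      lo <- max(a, edges[j]); hi <- min(b, edges[j + 1L])
      if (hi > lo) counts[j] <- counts[j] + h$counts[i] * (hi - lo) / (b - a)
    }
  }
  cf_histogram(levels = (edges[-1] + edges[-length(edges)]) / 2,
               counts = counts, breaks = edges, source = h$source)
}

#' Common refinement of several histogram grids
#'
#' Rebins all histograms onto the union of their bin edges, losslessly where
#' edges nest.
#'
#' @param histograms List of [cf_histogram()]s.
#' @return List of histograms on the shared refined grid.
#' @export
common_refinement <- function(histograms) {
  allb <- lapply(histograms, function(h) {
    if (is.null(h$breaks)) c(h$levels - 0.5, h$levels[length(h$levels)] + 0.5)
    else h$breaks
  })
  edges <- sort(unique(round(unlist(allb), 12)))
  lapply(histograms, rebin_histogram, edges = edges)
}

#' Pairwise histogram distance matrix
#'
#' @param histograms List of >= 2 [cf_histogram()]s; names (or sources) label
#'   the matrix.
#' @param kind Distance kind, as in [histogram_distance()].
#' @param rebin If `TRUE` (default), histograms on unequal grids are first
#'   rebinned to their common refinement; if `FALSE`, unequal grids error.
#' @return A symmetric matrix with zero diagonal, labelled in input order.
#' @export
pairwise_distances <- function(histograms, kind = c("hellinger", "bhattacharyya-log"),
                               rebin = TRUE) {
  kind <- match.arg(kind)
  n <- length(histograms)
  if (n < 2L) stop("need at least 2 histograms")
  labels <- names(histograms)
  if (is.null(labels)) {
    labels <- vapply(seq_len(n), function(i) {
      s <- histograms[[i]]$source
      if (is.null(s)) sprintf("h%d", i) else as.character(s)
    }, character(1))
  }
  grids_equal <- all(vapply(histograms[-1], .same_grid, logical(1),
                            q = histograms[[1]]))
  if (!grids_equal) {
    if (!rebin) stop("histograms are on different bin grids (rebin = FALSE)")
    histograms <- common_refinement(histograms)
  }
  P <- vapply(histograms, .normalized, numeric(length(histograms[[1]]$counts)))
  S <- crossprod(sqrt(P))            # S[i, j] = BC(i, j)
  S <- pmin(S, 1)
  d <- if (kind == "hellinger") sqrt(pmax(1 - S, 0)) else -log(pmax(S, .Machine$double.xmin))
  diag(d) <- 0
  dimnames(d) <- list(labels, labels)
  d
}
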