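# Global-value statistics: whole-image means, treatment summaries,
# radial-plot magnitude panels and Mann-Whitney U comparisons.

#' Global value of an image
#'
#' The mean of all pixel values; for a `cf_parameter_image`, masked pixels
#' (zero-denominator pixels) are excluded.
#'
#' @param image Numeric matrix or `cf_parameter_image`.
#' @return The arithmetic mean over (unmasked) pixels.
#' @export
global_value <- function(image) {
  v <- if (inherits(image, "cf_parameter_image")) image$values[image$mask]
       else as.numeric(image)
  v <- v[is.finite(v)]
  if (!length(v)) stop("image has no unmasked pixels; global value undefined")
  mean(v)
}

#' Five-number-plus-mean summary of a group of global values
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7), the convention behind the box plots.
#'
#' @param values Numeric vector, length >= 1.
#' @param group Optional group label stored on the result.
#' @return A one-row data frame: `group`, `n`, `min`, `q1`, `median`, `q3`,
#'   `max`, `mean`.
#' @export
summarize_group <- function(values, group = NA_character_) {
  values <- as.numeric(values)
  if (!length(values) || anyNA(values)) stop("'values' must be non-empty and finite")
  q <- stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  data.frame(group = group, n = length(values), min = q[1], q1 = q[2],
             median = q[3], q3 = q[4], max = q[5], mean = mean(values),
             stringsAsFactors = FALSE)
}

#' Mann-Whitney U test between two groups of global values
#'
#' `U = #\{(i, j): a_i > b_j\} + 0.5 #\{ties\}` with a two-sided p-value:
#' exact (full enumeration over rank assignments) when `n_a + n_b <= 12`
#' and there are no ties, otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param a,b Numeric samples (global values of the two treatments).
#' @param measure Optional measure label stored on the result.
#' @return A one-row data frame: `measure`, `n_a`, `n_b`, `U`, `p_value`,
#'   `code` (significance code) and `method` (`"exact"` or
#'   `"normal_approx"`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1 exactly
#' @export
mann_whitney_u <- function(a, b, measure = NA_character_) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b) <= 12L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  # fully tied samples give a 0/0 normal statistic; no evidence either way
  if (is.nan(wt$p.value)) wt$p.value <- 1
  data.frame(measure = measure, n_a = length(a), n_b = length(b),
             U = unname(wt$statistic), p_value = min(1, wt$p.value),
             code = significance_code(min(1, wt$p.value)),
             method = if (exact) "exact" else "normal_approx",
             stringsAsFactors = FALSE)
}

#' Significance code for a p-value
#'
#' `"**"` for p < 0.01, `"*"` for p < 0.05, `""` otherwise (strict
#' inequalities).
#'
#' @param p A p-value in `[0, 1]`.
#' @return A character code.
#' @export
significance_code <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("'p' must be a single value in [0, 1]")
  }
  if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Partition measures into the four radial-plot magnitude panels
#'
#' Raw fluorescence levels and ratio parameters live on very different
#' scales, so radial plots are split by the group-mean magnitude into four
#' panels: `[0, 1)`, `[1, 25)`, `[25, 300)` and `[300, Inf)` (half-open;
#' boundary values go to the upper panel). Negative means draw a warning and
#' are assigned to the first panel.
#'
#' @param means Named numeric vector: measure label -> mean global value.
#' @return Integer vector (1-4) of panel indices, named like `means`.
#' @export
radial_panel_partition <- function(means) {
  if (!length(means) || anyNA(means)) stop("'means' must be non-empty and finite")
  neg <- means < 0
  if (any(neg)) {
    warning(sprintf("%d negative mean(s) assigned to panel 1", sum(neg)))
  }
  panel <- findInterval(pmax(means, 0), c(0, 1, 25, 300))
  names(panel) <- names(means)
  panel
}

#' Global-value table for a dataset
#'
#' Loads every session of a manifest and reduces all 55 images to their
#' global values. Calculated parameters are always recomputed pixel-wise
#' from the measured captures (any stored calculated TIFFs are
#' integer-scaled browsing copies and are ignored here).
#'
#' @param manifest A `cf_manifest` (from [scan_dataset()]).
#' @param root Dataset root directory the manifest paths are relative to
#'   (defaults to the root recorded by [scan_dataset()]).
#' @param schedule Transient schedule.
#' @param strict,conventional Passed to [compute_parameter()].
#' @return A data frame: `ecotype`, `treatment`, `plant`, `day`, `label`,
#'   `global_value`.
#' @export
global_value_table <- function(manifest, root = attr(manifest, "root"),
                               schedule = cf_schedule(), strict = FALSE,
                               conventional = FALSE) {
  if (is.null(root)) stop("'root' is required to resolve manifest paths")
  keys <- unique(manifest[, c("ecotype", "treatment", "plant", "day")])
  out <- vector("list", nrow(keys))
  measured <- schedule$label[schedule$kind == "measured"]
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sel <- manifest$ecotype == k$ecotype & manifest$treatment == k$treatment &
      manifest$plant == k$plant & manifest$day == k$day
    rec <- manifest[sel, ]
    rec <- rec[rec$label %in% measured, ]
    imgs <- lapply(rec$path, function(p) read_cf_image(file.path(root, p)))
    names(imgs) <- rec$label
    gv_meas <- vapply(imgs, global_value, numeric(1))
    sess <- plant_session(imgs, key = as.list(k))
    calc <- compute_all(sess, schedule, strict = strict,
                        conventional = conventional)
    gv_calc <- vapply(calc, global_value, numeric(1))
    gv <- c(gv_meas, gv_calc)
    out[[i]] <- data.frame(ecotype = k$ecotype, treatment = k$treatment,
                           plant = k$plant, day = k$day, label = names(gv),
                           global_value = unname(gv), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  tab <- tab[order(tab$ecotype, tab$treatment, tab$plant, tab$day,
                   match(tab$label, schedule$label)), ]
  rownames(tab) <- NULL
  tab
}

#' Compare two treatments for every measure
#'
#' One Mann-Whitney U comparison per measure (and per day/ecotype stratum if
#' the table spans several), comparing the global values of the two
#' treatments. No multiple-testing correction is applied by default,
#' matching the per-measure reading of the protocol; `p_adjust` applies
#' `stats::p.adjust` across measures within each stratum.
#'
#' @param table A global-value table ([global_value_table()]).
#' @param treatments Character pair `(a, b)` naming the two groups.
#' @param day Optional day filter.
#' @param ecotype Optional ecotype filter.
#' @param p_adjust `"none"` (default), or any `stats::p.adjust` method.
#' @return A data frame of comparisons in schedule order, one per measure
#'   (x day x ecotype present in the filtered table), with significance
#'   codes.
#' @export
compare_all <- function(table, treatments, day = NULL, ecotype = NULL,
                        p_adjust = "none") {
  stopifnot(length(treatments) == 2L)
  if (!is.null(day)) table <- table[table$day %in% day, ]
  if (!is.null(ecotype)) table <- table[table$ecotype %in% ecotype, ]
  if (!nrow(table)) stop("no rows left after filtering")
  sched <- cf_schedule()
  strata <- unique(table[, c("ecotype", "day")])
  res <- list()
  for (s in seq_len(nrow(strata))) {
    sub <- table[table$ecotype == strata$ecotype[s] & table$day == strata$day[s], ]
    rows <- list()
    for (lab in intersect(sched$label, unique(sub$label))) {
      va <- sub$global_value[sub$label == lab & sub$treatment == treatments[1]]
      vb <- sub$global_value[sub$label == lab & sub$treatment == treatments[2]]
      if (!length(va) || !length(vb)) {
        warning(sprintf("measure '%s': empty group, skipped", lab))
        next
      }
      r <- mann_whitney_u(va, vb, measure = lab)
      r$ecotype <- strata$ecotype[s]; r$day <- strata$day[s]
      rows[[length(rows) + 1L]] <- r
    }
    if (!length(rows)) next
    block <- do.call(rbind, rows)
    if (p_adjust != "none") {
      block$p_value <- stats::p.adjust(block$p_value, method = p_adjust)
      block$code <- vapply(block$p_value, significance_code, character(1))
    }
    res[[length(res) + 1L]] <- block
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[, c("ecotype", "day", "measure", "n_a", "n_b", "U", "p_value", "code",
          "method")]
}

#' Radial plot of treatment means
#'
#' Draws one star/radar panel per magnitude class (see
#' [radial_panel_partition()]); each radius is a measure, one polygon per
#' treatment.
#'
#' @param table Global-value table.
#' @param treatments Treatments to draw.
#' @return Invisibly, the list of per-panel mean matrices.
#' @export
plot_radial_panels <- function(table, treatments = unique(table$treatment)) {
  means <- tapply(table$global_value, list(table$label, table$treatment), mean)
  means <- means[, treatments, drop = FALSE]
  overall <- rowMeans(means)
  panel <- radial_panel_partition(overall)
  op <- graphics::par(mfrow = c(2, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  out <- list()
  for (p in 1:4) {
    m <- means[panel == p, , drop = FALSE]
    out[[p]] <- m
    if (!nrow(m)) { graphics::plot.new(); next }
    graphics::stars(t(m), locations = c(0, 0), key.loc = NULL, scale = FALSE,
                    draw.segments = FALSE, col.lines = seq_len(ncol(m)),
                    main = c("mean < 1", "1-25", "25-300", "> 300")[p])
  }
  invisible(out)
}
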