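# Contact-sheet overviews: per-plant QC (image beside its histogram),
# treatment comparison, and per-plant time kinetics.
#
# A sheet is specified first (a cf_sheet object: grid + panel table), then
# rendered; all panels of one sheet share a common grayscale display range
# (1-99% percentile stretch over the sheet), so panels stay comparable.

.sheet <- function(type, content, measure, grid, panels, meta = list()) {
  stopifnot(all(c("plant", "day", "label", "panel_kind", "path", "missing")
                %in% names(panels)))
  structure(list(type = type, content = content, measure = measure,
                 grid = grid, panels = panels, meta = meta),
            class = "cf_sheet")
}

#' @export
print.cf_sheet <- function(x, ...) {
  cat(sprintf("CF contact sheet [%s/%s] measure %s: %d panel(s), grid %dx%d\n",
              x$type, x$content, x$measure, nrow(x$panels), x$grid[1], x$grid[2]))
  invisible(x)
}

.records_for <- function(manifest, measure, plant = NULL, day = NULL,
                         treatment = NULL) {
  sel <- manifest$label == measure
  if (!is.null(plant)) sel <- sel & manifest$plant %in% plant
  if (!is.null(day)) sel <- sel & manifest$day %in% day
  if (!is.null(treatment)) sel <- sel & manifest$treatment %in% treatment
  manifest[sel, , drop = FALSE]
}

#' Per-plant QC contact sheets
#'
#' One sheet per (plant, measure): each row pairs the image with its
#' histogram, ordered by imaging day. Missing days become placeholder
#' panels.
#'
#' @param manifest A `cf_manifest`.
#' @param measure Measure label to sheet.
#' @param days Days to include (default: all days in the manifest).
#' @return List of `cf_sheet` objects, one per plant.
#' @export
qc_sheets <- function(manifest, measure, days = sort(unique(manifest$day))) {
  plants <- unique(manifest[, c("ecotype", "treatment", "plant")])
  lapply(seq_len(nrow(plants)), function(i) {
    p <- plants[i, ]
    rows <- list()
    for (d in days) {
      rec <- .records_for(manifest, measure, plant = p$plant, day = d)
      rec <- rec[rec$ecotype == p$ecotype & rec$treatment == p$treatment, ]
      miss <- nrow(rec) == 0L
      path <- if (miss) NA_character_ else rec$path[1]
      rows[[length(rows) + 1L]] <- data.frame(
        plant = p$plant, day = d, label = measure,
        panel_kind = "image", path = path, missing = miss,
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        plant = p$plant, day = d, label = measure,
        panel_kind = "histogram", path = path, missing = miss,
        stringsAsFactors = FALSE)
    }
    panels <- do.call(rbind, rows)
    if (any(panels$missing)) {
      message(sprintf("qc sheet %s/%s: %d missing panel(s)", p$plant, measure,
                      sum(panels$missing) / 2L))
    }
    .sheet("qc", "both", measure, grid = c(length(days), 2L), panels,
           meta = list(plant = p$plant, ecotype = p$ecotype,
                       treatment = p$treatment))
  })
}

#' Treatment-comparison contact sheet
#'
#' One sheet per (measure, day, treatment pair): the left block holds one
#' panel per plant of treatment `a`, the right block treatment `b`, plants
#' sorted by id.
#'
#' @inheritParams qc_sheets
#' @param day Imaging day.
#' @param treatments Character pair `(a, b)`.
#' @param content `"images"` or `"histograms"`.
#' @return A `cf_sheet`.
#' @export
treatment_sheets <- function(manifest, measure, day, treatments,
                             content = c("images", "histograms")) {
  content <- match.arg(content)
  stopifnot(length(treatments) == 2L)
  kind <- if (content == "images") "image" else "histogram"
  blocks <- lapply(treatments, function(tr) {
    rec <- .records_for(manifest, measure, day = day, treatment = tr)
    if (!nrow(rec)) stop(sprintf("treatment '%s' has no records for %s on day %s",
                                 tr, measure, day))
    rec <- rec[order(rec$plant), ]
    data.frame(plant = rec$plant, day = day, label = measure,
               panel_kind = kind, path = rec$path, missing = FALSE,
               block = tr, stringsAsFactors = FALSE)
  })
  panels <- do.call(rbind, blocks)
  ncol_grid <- max(vapply(blocks, nrow, integer(1)))
  .sheet("treatment_comparison", content, measure,
         grid = c(2L, ncol_grid), panels,
         meta = list(day = day, treatments = treatments))
}

#' Per-plant kinetics contact sheets
#'
#' One sheet per plant for a measure, panels ordered by imaging day
#' ascending, to visualize the time course.
#'
#' @inheritParams qc_sheets
#' @param content `"images"` or `"histograms"`.
#' @return List of `cf_sheet` objects.
#' @export
kinetics_sheets <- function(manifest, measure,
                            content = c("images", "histograms")) {
  content <- match.arg(content)
  kind <- if (content == "images") "image" else "histogram"
  plants <- unique(manifest[, c("ecotype", "treatment", "plant")])
  lapply(seq_len(nrow(plants)), function(i) {
    p <- plants[i, ]
    rec <- .records_for(manifest, measure, plant = p$plant)
    rec <- rec[rec$ecotype == p$ecotype & rec$treatment == p$treatment, ]
    rec <- rec[order(rec$day), ]
    panels <- data.frame(plant = p$plant, day = rec$day, label = measure,
                         panel_kind = kind, path = rec$path, missing = FALSE,
                         stringsAsFactors = FALSE)
    .sheet("kinetics", content, measure, grid = c(1L, max(1L, nrow(panels))),
           panels, meta = list(plant = p$plant))
  })
}

#' Render a contact sheet to PNG or PDF
#'
#' Deterministic layout: fixed grid, panels placed row-major, pagination
#' when panels exceed the grid capacity. All image panels of the sheet
#' share one grayscale display range, the 1-99% percentile stretch over the
#' whole sheet (recorded in the returned metadata). Histogram panels are
#' filled step plots with axes fixed across the sheet. Each panel is
#' annotated with plant id and day; missing panels render as labelled empty
#' cells.
#'
#' @param sheet A `cf_sheet`.
#' @param out Output path without extension suffix for multi-page PNG (pages
#'   are written as `<out>_pNN.png`); with `format = "pdf"`, a single
#'   multi-page `<out>.pdf`.
#' @param root Dataset root for the panel paths.
#' @param format `"png"` or `"pdf"`.
#' @param bins Bins for histogram panels.
#' @return Metadata list: `files`, `pages`, `panel_count`, `scale` (shared
#'   display range).
#' @export
render_sheet <- function(sheet, out, root = ".", format = c("png", "pdf"),
                         bins = 64L) {
  format <- match.arg(format)
  stopifnot(inherits(sheet, "cf_sheet"))
  panels <- sheet$panels
  imgs <- vector("list", nrow(panels))
  for (i in seq_len(nrow(panels))) {
    if (!panels$missing[i]) {
      imgs[[i]] <- read_cf_image(file.path(root, panels$path[i]))
    }
  }
  pix <- unlist(lapply(imgs[!panels$missing], as.numeric))
  scale <- if (length(pix)) stats::quantile(pix, c(0.01, 0.99), names = FALSE)
           else c(0, 1)
  if (scale[2] <= scale[1]) scale[2] <- scale[1] + 1
  per_page <- prod(sheet$grid)
  pages <- ceiling(nrow(panels) / per_page)
  files <- character(0)
  draw_page <- function(pg) {
    graphics::par(mfrow = sheet$grid, mar = c(1.2, 1.2, 1.2, 0.4))
    idx <- ((pg - 1L) * per_page + 1L):min(pg * per_page, nrow(panels))
    for (i in idx) {
      ann <- sprintf("%s d%s", panels$plant[i], panels$day[i])
      if (panels$missing[i] || is.null(imgs[[i]])) {
        graphics::plot.new(); graphics::box()
        graphics::text(0.5, 0.5, "missing"); graphics::title(ann, cex.main = 0.8)
      } else if (panels$panel_kind[i] == "image") {
        m <- imgs[[i]]
        z <- pmin(pmax((m - scale[1]) / (scale[2] - scale[1]), 0), 1)
        graphics::image(t(z[nrow(z):1, , drop = FALSE]), col = grDevices::gray.colors(256, 0, 1),
                        zlim = c(0, 1), axes = FALSE, useRaster = TRUE)
        graphics::title(ann, cex.main = 0.8)
      } else {
        h <- image_to_histogram(imgs[[i]], n_bins = bins,
                                range = c(scale[1], scale[2] + 1e-9))
        graphics::plot(h$levels, h$counts, type = "s", xlab = "", ylab = "",
                       cex.axis = 0.5, col = "steelblue")
        graphics::polygon(c(h$levels[1], h$levels, h$levels[length(h$levels)]),
                          c(0, h$counts, 0), col = "steelblue", border = NA)
        graphics::title(ann, cex.main = 0.8)
      }
    }
  }
  if (format == "pdf") {
    f <- paste0(out, ".pdf")
    grDevices::pdf(f, width = 11.7, height = 8.3)  # A4 landscape
    on.exit(grDevices::dev.off(), add = TRUE)
    for (pg in seq_len(pages)) draw_page(pg)
    files <- f
  } else {
    for (pg in seq_len(pages)) {
      f <- sprintf("%s_p%02d.png", out, pg)
      grDevices::png(f, width = 1200, height = 850)
      draw_page(pg)
      grDevices::dev.off()
      files <- c(files, f)
    }
  }
  list(files = files, pages = pages, panel_count = nrow(panels),
       scale = scale)
}

#' Panel bookkeeping for a set of sheets
#'
#' CSV sidecar mapping sheet/page/cell to the underlying image record.
#'
#' @param sheets List of `cf_sheet`s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sheet_index <- function(sheets, path) {
  rows <- lapply(seq_along(sheets), function(i) {
    s <- sheets[[i]]
    per_page <- prod(s$grid)
    p <- s$panels
    p$sheet <- i; p$type <- s$type
    p$page <- ((seq_len(nrow(p)) - 1L) %/% per_page) + 1L
    p$cell <- ((seq_len(nrow(p)) - 1L) %% per_page) + 1L
    p[, c("sheet", "type", "page", "cell", "plant", "day", "label",
          "panel_kind", "path", "missing")]
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
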