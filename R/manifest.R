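# Dataset physical layer: 16-bit grayscale TIFFs (12-bit dynamic), histogram
# text files, the directory nomenclature and the experiment manifest.
#
# Nomenclature (this package's dialect):
#   <ecotype>/<treatment>/<day>/<plant>/<measure_label>.tif
# with an optional sibling <measure_label>.hist.txt histogram export.

#' Build the full experiment manifest from a study design
#'
#' Expands the cross product ecotypes x treatments x plants x days x
#' schedule into one record per expected image, in deterministic order
#' (ecotype, treatment, plant, day, schedule order). The reference design
#' (2 ecotypes x 2 treatments x 15 plants x 3 days x 55 measures) yields
#' 9900 records.
#'
#' @param design A list with elements `ecotypes` (character), `treatments`
#'   (character), `plants` (number of plants per ecotype x treatment group,
#'   or a character vector of plant ids) and `days` (integer vector of
#'   imaging days).
#' @param schedule Transient schedule (default [cf_schedule()]).
#' @return A data frame of class `cf_manifest` with columns `ecotype`,
#'   `treatment`, `plant`, `day`, `label` and `path` (relative file path in
#'   the nomenclature).
#' @examples
#' m <- build_manifest(list(ecotypes = c("Col0", "Ler"),
#'                          treatments = c("control", "inoculated"),
#'                          plants = 15, days = c(15, 17, 21)))
#' nrow(m)  # 9900
#' @export
build_manifest <- function(design, schedule = cf_schedule()) {
  for (f in c("ecotypes", "treatments", "plants", "days")) {
    if (is.null(design[[f]]) || length(design[[f]]) == 0L) {
      stop(sprintf("design dimension '%s' is empty", f))
    }
  }
  if (nrow(schedule) == 0L) stop("schedule is empty")
  plants <- design$plants
  if (is.numeric(plants) && length(plants) == 1L) {
    if (plants < 1) stop("design dimension 'plants' is empty")
    plants <- sprintf("P%02d", seq_len(plants))
  }
  rows <- expand.grid(
    label = schedule$label,
    day = design$days,
    plant = plants,
    treatment = design$treatments,
    ecotype = design$ecotypes,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  rows <- rows[, c("ecotype", "treatment", "plant", "day", "label")]
  rows$path <- file.path(rows$ecotype, rows$treatment, rows$day, rows$plant,
                         paste0(rows$label, ".tif"))
  rownames(rows) <- NULL
  class(rows) <- c("cf_manifest", "data.frame")
  rows
}

#' Scan a dataset tree (or zip archive) into a manifest
#'
#' Walks the `<ecotype>/<treatment>/<day>/<plant>/<label>.tif` nomenclature
#' under `root`, validates every measure label against the schedule, and
#' reports cells of the implied design that are missing as well as files
#' whose names do not parse.
#'
#' @param root Dataset directory, or a `.zip` archive of one.
#' @param schedule Transient schedule used for label validation.
#' @return A list with elements `manifest` (found records, `cf_manifest`),
#'   `missing` (data frame of absent cells of the implied full design) and
#'   `unrecognized` (character vector of skipped file paths).
#' @export
scan_dataset <- function(root, schedule = cf_schedule()) {
  if (!file.exists(root)) stop(sprintf("dataset root '%s' does not exist", root))
  if (!dir.exists(root) && grepl("\\.zip$", root, ignore.case = TRUE)) {
    exdir <- tempfile("phenocf_zip_")
    utils::unzip(root, exdir = exdir)
    root <- exdir
  }
  if (!dir.exists(root)) stop(sprintf("dataset root '%s' is not a directory or zip", root))
  files <- list.files(root, pattern = "\\.tif$", recursive = TRUE)
  recs <- list(); unrec <- character(0)
  for (f in files) {
    parts <- strsplit(f, "/", fixed = TRUE)[[1]]
    if (length(parts) < 5L) { unrec <- c(unrec, f); next }
    parts <- utils::tail(parts, 5L)  # tolerate a wrapping directory (zips)
    label <- sub("\\.tif$", "", parts[5])
    ok <- tryCatch({ parse_measure_label(label, schedule); TRUE },
                   error = function(e) FALSE)
    day <- suppressWarnings(as.integer(parts[3]))
    if (!ok || is.na(day)) { unrec <- c(unrec, f); next }
    recs[[length(recs) + 1L]] <- data.frame(
      ecotype = parts[1], treatment = parts[2], plant = parts[4],
      day = day, label = label, path = f, stringsAsFactors = FALSE)
  }
  found <- if (length(recs)) do.call(rbind, recs) else
    data.frame(ecotype = character(0), treatment = character(0),
               plant = character(0), day = integer(0),
               label = character(0), path = character(0))
  if (length(unrec)) {
    warning(sprintf("%d file(s) with unrecognized names skipped (e.g. '%s')",
                    length(unrec), unrec[1]))
  }
  missing <- found[0, c("ecotype", "treatment", "plant", "day", "label")]
  if (nrow(found)) {
    full <- expand.grid(
      label = schedule$label, day = sort(unique(found$day)),
      plant = sort(unique(found$plant)),
      treatment = sort(unique(found$treatment)),
      ecotype = sort(unique(found$ecotype)),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    key <- function(d) paste(d$ecotype, d$treatment, d$plant, d$day, d$label,
                             sep = "\r")
    missing <- full[!(key(full) %in% key(found)),
                    c("ecotype", "treatment", "plant", "day", "label")]
    rownames(missing) <- NULL
  }
  found <- found[order(found$ecotype, found$treatment, found$plant,
                       found$day, match(found$label, schedule$label)), ]
  rownames(found) <- NULL
  class(found) <- c("cf_manifest", "data.frame")
  attr(found, "root") <- root
  list(manifest = found, missing = missing, unrecognized = unrec)
}

#' Read / write a fluorescence image
#'
#' Images are single-channel grayscale TIFFs in a 16-bit unsigned container;
#' the instrument's 12-bit values are stored as-is. The round trip
#' `read_cf_image(write_cf_image(x, p))` is bit-exact.
#'
#' @param path TIFF file path.
#' @return `read_cf_image`: an integer matrix of pixel intensities.
#' @export
read_cf_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("image '%s' does not exist", path))
  a <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(a)) == 3L) {
    stop(sprintf("unsupported format: '%s' is a multi-channel TIFF", path))
  }
  storage.mode(a) <- "integer"
  a
}

#' @rdname read_cf_image
#' @param image Non-negative integer matrix with values < 2^16.
#' @export
write_cf_image <- function(image, path) {
  if (!is.matrix(image)) stop("'image' must be a matrix")
  if (anyNA(image) || any(image < 0) || any(image > 65535)) {
    stop("image values must be integers in [0, 65535]")
  }
  tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Construct a histogram object
#'
#' The clustering currency: a grid of gray levels (or bin midpoints) with
#' non-negative counts. When built from an image, `breaks` carries the bin
#' edges; histograms parsed from instrument text exports carry levels only.
#'
#' @param levels Strictly increasing numeric bin values (gray levels or
#'   midpoints).
#' @param counts Non-negative counts, one per level.
#' @param breaks Optional bin edges (length `length(levels) + 1`).
#' @param source Optional identifier of the image the histogram summarizes.
#' @return An object of class `cf_histogram`.
#' @export
cf_histogram <- function(levels, counts, breaks = NULL, source = NULL) {
  levels <- as.numeric(levels); counts <- as.numeric(counts)
  if (length(levels) != length(counts)) stop("levels and counts differ in length")
  if (length(levels) == 0L) stop("empty histogram")
  if (any(diff(levels) <= 0)) stop("histogram levels must be strictly increasing")
  if (anyNA(counts) || any(counts < 0)) stop("histogram counts must be non-negative")
  if (!is.null(breaks)) {
    breaks <- as.numeric(breaks)
    if (length(breaks) != length(levels) + 1L || any(diff(breaks) <= 0)) {
      stop("breaks must be strictly increasing with length(levels) + 1 entries")
    }
  }
  structure(list(levels = levels, counts = counts, breaks = breaks,
                 source = source),
            class = "cf_histogram")
}

#' @export
print.cf_histogram <- function(x, ...) {
  cat(sprintf("CF histogram: %d bins over [%g, %g], total count %g\n",
              length(x$levels), min(x$levels), max(x$levels), sum(x$counts)))
  invisible(x)
}

#' Read / write a histogram text file
#'
#' The text dialect is one `<bin_value><TAB><count>` pair per line, with
#' optional `#`-prefixed comment lines. Bin values must be strictly
#' increasing and counts non-negative integers.
#'
#' @param path Histogram text file.
#' @return `read_histogram_file`: a [cf_histogram()] object.
#' @export
read_histogram_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("histogram file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) stop(sprintf("'%s': no histogram data lines", path))
  lv <- numeric(length(idx)); ct <- numeric(length(idx))
  for (k in seq_along(idx)) {
    ln <- idx[k]
    parts <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop(sprintf("'%s' line %d: expected '<bin><TAB><count>'", path, ln))
    }
    v <- suppressWarnings(as.numeric(parts))
    if (anyNA(v)) stop(sprintf("'%s' line %d: malformed number", path, ln))
    if (v[2] < 0 || v[2] != round(v[2])) {
      stop(sprintf("'%s' line %d: count must be a non-negative integer", path, ln))
    }
    lv[k] <- v[1]; ct[k] <- v[2]
    if (k > 1L && lv[k] <= lv[k - 1L]) {
      stop(sprintf("'%s' line %d: bin values must be strictly increasing", path, ln))
    }
  }
  cf_histogram(lv, ct, source = path)
}

#' @rdname read_histogram_file
#' @param h A [cf_histogram()] object.
#' @export
write_histogram_file <- function(h, path) {
  stopifnot(inherits(h, "cf_histogram"))
  writeLines(sprintf("%.10g\t%d", h$levels, as.integer(round(h$counts))), path)
  invisible(path)
}

#' Read / write a manifest as CSV
#' @param manifest A `cf_manifest` data frame.
#' @param path CSV file path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(m) <- c("cf_manifest", "data.frame")
  m
}

#' @export
print.cf_manifest <- function(x, ...) {
  cat(sprintf("CF manifest: %d records (%d ecotypes, %d treatments, %d plants, %d days)\n",
              nrow(x), length(unique(x$ecotype)), length(unique(x$treatment)),
              length(unique(paste(x$ecotype, x$treatment, x$plant))),
              length(unique(x$day))))
  invisible(x)
}
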