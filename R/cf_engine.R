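# Pixel-wise computation of the 34 calculated CF-parameter images from a
# plant session's 21 measured captures.
#
# Formulas are implemented exactly as the instrument protocol defines them:
#   Fv/Fm        = (Fm - F0) / Fm                (dark-adapted)
#   F'v/F'm (t)  = (F'm(t) - F'0(t)) / F'm(t)
#   NPQ(t)       = (Fm - F'm(t)) / Fm            (Fm(85) replaces F'm at 85 s)
#   qP(t)        = (Fm - FT(t)) / (Fm - F0)      (dark-adapted Fm, F0)
#   qL(t)        = qP(t) * F'0(t) / FT(t)
#   Qy(t)        = (Fm - FT(t)) / Fm
#   RFD(t)       = (Fp - FT(t)) / FT(t)
# Note NPQ/qP/Qy deliberately use the dark-adapted denominators above, which
# differ from the textbook conventions (NPQ over F'm, qP over F'm - F'0);
# set `conventional = TRUE` for the textbook variants.

#' Bundle one plant's measured captures into a session
#'
#' @param images Named list of integer matrices, one per measured label
#'   (e.g. `"F0"`, `"Fm_L_25"`). All images must share dimensions. A
#'   complete session holds all 21 measured labels of the schedule.
#' @param key Optional identifying list (ecotype, treatment, plant, day).
#' @return An object of class `cf_session`.
#' @export
plant_session <- function(images, key = NULL) {
  if (!length(images) || is.null(names(images)) || any(names(images) == "")) {
    stop("'images' must be a non-empty named list of matrices")
  }
  dims <- lapply(images, dim)
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1L) {
    stop("all session images must share identical dimensions")
  }
  structure(list(images = images, key = key), class = "cf_session")
}

#' @export
print.cf_session <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("CF plant session: %d images of %dx%d", length(x$images),
              d[1], d[2]))
  if (!is.null(x$key)) cat(" [", paste(unlist(x$key), collapse = "/"), "]")
  cat("\n")
  invisible(x)
}

.session_image <- function(session, label, target) {
  img <- session$images[[label]]
  if (is.null(img)) {
    stop(sprintf("session is missing measured image '%s' required by '%s'",
                 label, target))
  }
  img
}

#' Compute one calculated CF-parameter image
#'
#' Evaluates the parameter's formula pixel by pixel on the session's
#' measured captures. Pixels whose denominator is exactly zero are masked;
#' under `strict = TRUE` pixels with a negative numerator or denominator are
#' masked as well. Masked pixels are excluded from downstream global means
#' and histograms.
#'
#' @param session A [plant_session()].
#' @param label Calculated measure label (e.g. `"qP_25"`, `"FvFm"`).
#' @param strict Also mask negative numerators/denominators.
#' @param conventional Use the textbook formula variants (NPQ over F'm, qP
#'   and Qy over light-adapted operands) instead of the protocol forms.
#' @return An object of class `cf_parameter_image`: list with `values`
#'   (numeric matrix, `NA` where masked), `mask` (logical matrix, `TRUE` =
#'   valid) and `label`.
#' @examples
#' s <- plant_session(list(Fm = matrix(4000L, 2, 2), F0 = matrix(1000L, 2, 2)))
#' compute_parameter(s, "FvFm")$values[1, 1]  # 0.75
#' @export
compute_parameter <- function(session, label, strict = FALSE,
                              conventional = FALSE) {
  stopifnot(inherits(session, "cf_session"))
  m <- parse_measure_label(label)
  if (m$kind != "calculated") {
    stop(sprintf("'%s' is a measured capture, not a calculated parameter", label))
  }
  t <- m$timepoint_s
  g <- function(fam) .session_image(session, paste0(fam, "_", t), label)
  ratio <- function(num, den) {
    mask <- if (strict) den > 0 & num >= 0 else den != 0
    v <- ifelse(mask, num / den, NA_real_)
    structure(list(values = v, mask = mask, label = label),
              class = "cf_parameter_image")
  }
  Fm <- function() .session_image(session, "Fm", label)
  F0 <- function() .session_image(session, "F0", label)
  switch(m$family,
    FvFm = ratio(Fm() - F0(), Fm()),
    FvFm_L = ratio(g("Fm_L") - g("F0_L"), g("Fm_L")),
    NPQ = {
      fmp <- if (t == 85L) .session_image(session, "Fm_85", label) else g("Fm_L")
      if (conventional) ratio(Fm() - fmp, fmp) else ratio(Fm() - fmp, Fm())
    },
    qP = {
      ft <- g("Ft")
      if (conventional && t != 85L) {
        ratio(g("Fm_L") - ft, g("Fm_L") - g("F0_L"))
      } else ratio(Fm() - ft, Fm() - F0())
    },
    qL = {
      ft <- g("Ft"); f0p <- g("F0_L")
      den <- (Fm() - F0()) * ft
      num <- (Fm() - ft) * f0p
      ratio(num, den)
    },
    Qy = {
      ft <- g("Ft")
      if (conventional && t != 85L) ratio(g("Fm_L") - ft, g("Fm_L"))
      else ratio(Fm() - ft, Fm())
    },
    RFD = {
      ft <- g("Ft")
      ratio(.session_image(session, "Fp", label) - ft, ft)
    },
    stop(sprintf("no formula for family '%s'", m$family))
  )
}

#' Compute all 34 calculated parameter images of a session
#'
#' @inheritParams compute_parameter
#' @param schedule Transient schedule; its calculated entries are computed.
#' @return Named list of [compute_parameter()] results, in schedule order.
#' @export
compute_all <- function(session, schedule = cf_schedule(), strict = FALSE,
                        conventional = FALSE) {
  labels <- schedule$label[schedule$kind == "calculated"]
  out <- lapply(labels, function(l) {
    compute_parameter(session, l, strict = strict, conventional = conventional)
  })
  names(out) <- labels
  out
}

#' @export
print.cf_parameter_image <- function(x, ...) {
  cat(sprintf("CF parameter image '%s': %dx%d, %d masked pixel(s), range [%g, %g]\n",
              x$label, nrow(x$values), ncol(x$values), sum(!x$mask),
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' Write a calculated parameter image to disk
#'
#' Values are linearly rescaled to the 12-bit range and written as a 16-bit
#' grayscale TIFF; the affine scale is recorded in a `<path>.scale.txt`
#' sidecar and the mask as a 0/1 companion TIFF (`<path>.mask.tif`).
#'
#' @param pimg A `cf_parameter_image`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_parameter_image <- function(pimg, path) {
  stopifnot(inherits(pimg, "cf_parameter_image"))
  v <- pimg$values
  rng <- range(v, na.rm = TRUE)
  span <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
  q <- matrix(0L, nrow(v), ncol(v))
  q[pimg$mask] <- as.integer(round((v[pimg$mask] - rng[1]) / span * 4095))
  write_cf_image(q, path)
  writeLines(c(sprintf("offset\t%.10g", rng[1]),
               sprintf("scale\t%.10g", span / 4095)),
             paste0(path, ".scale.txt"))
  mask <- matrix(as.integer(pimg$mask), nrow(v), ncol(v))
  write_cf_image(mask, paste0(path, ".mask.tif"))
  invisible(path)
}
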