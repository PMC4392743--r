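# Protocol registry: the 13 CF parameter families and the 55-measure
# per-plant induction schedule (dark adaptation, saturating pulse, 60 s
# actinic phase with captures at 25/38/50/62/74 s, dark relaxation at 85 s).

#' The 13 chlorophyll-fluorescence parameter families
#'
#' Returns the registry of CF parameter families handled by the pipeline:
#' six measured fluorescence levels (`F0`, `F0_L`, `Fm`, `Fm_L`, `Fp`, `Ft`)
#' and seven parameters calculated pixel-wise from them (`FvFm`, `FvFm_L`,
#' `NPQ`, `qL`, `qP`, `Qy`, `RFD`). Family codes are filesystem-safe: primed
#' (light-adapted) variants carry an `_L` suffix instead of an apostrophe.
#'
#' @return A data frame with one row per family and columns `family`
#'   (code used in measure labels), `symbol` (conventional notation), `kind`
#'   (`"measured"` or `"calculated"`), `formula` (`NA` for measured
#'   families) and `display_name`.
#' @examples
#' parameter_families()
#' @export
parameter_families <- function() {
  data.frame(
    family = c("F0", "F0_L", "Fm", "Fm_L", "Fp", "Ft",
               "FvFm", "FvFm_L", "NPQ", "qL", "qP", "Qy", "RFD"),
    symbol = c("F_O", "F'_O", "F_m", "F'_m", "F_p", "F_T",
               "Fv/Fm", "F'v/F'm", "NPQ", "qL", "qP", "Q_y", "R_FD"),
    kind = c(rep("measured", 6), rep("calculated", 7)),
    formula = c(rep(NA_character_, 6),
                "(Fm-F0)/Fm",
                "(Fm'-F0')/Fm'",
                "(Fm-Fm')/Fm",
                "qP*(F0'/Ft)",
                "(Fm-Ft)/(Fm-F0)",
                "(Fm-Ft)/Fm",
                "(Fp-Ft)/Ft"),
    display_name = c(
      "Minimal fluorescence (dark-adapted / dark relaxation)",
      "Minimal fluorescence in the light-adapted state",
      "Maximal fluorescence (dark-adapted / dark relaxation)",
      "Maximal fluorescence in the light-adapted state",
      "Peak fluorescence of the initial Kautsky phase",
      "Instantaneous fluorescence",
      "Maximum PSII quantum yield",
      "PSII quantum yield of a light-adapted sample",
      "Non-photochemical quenching",
      "Fraction of open PSII centers (lake model)",
      "Coefficient of photochemical quenching (puddle model)",
      "Instantaneous PSII quantum yield",
      "Fluorescence decline ratio"),
    stringsAsFactors = FALSE
  )
}

# Actinic-phase capture times (s); 74 s is the steady state.
.light_times <- c(25L, 38L, 50L, 62L, 74L)

.timepoint_tag <- function(sec) {
  if (is.na(sec)) return("dark_adapted")
  if (sec == 16L) return("peak")
  if (sec == 74L) return("steady")
  if (sec == 85L) return("dark_relax")
  "light"
}

.make_label <- function(family, sec) {
  if (is.na(sec) || family == "Fp") family else paste0(family, "_", sec)
}

#' The default 55-measure transient schedule
#'
#' Enumerates the per-plant measurement/calculation protocol: 21 measured
#' captures (F_O and F_m dark-adapted and at 85 s, F_p at the 16 s Kautsky
#' peak, F'_O/F'_m/F_T at 25/38/50/62/74 s, F_T additionally at 85 s) and 34
#' calculated parameter images (Fv/Fm dark-adapted; F'v/F'm, qL and RFD at
#' the five light timepoints; NPQ, qP and Qy at the five light timepoints
#' plus the 85 s dark-relaxation point).
#'
#' @return A data frame of class `cf_schedule` with columns `label`
#'   (canonical measure label, e.g. `"qP_25"`, `"Fm_85"`, `"FvFm"`),
#'   `family`, `kind`, `timepoint_s` (`NA` for the dark-adapted state) and
#'   `tag` (one of `dark_adapted`, `peak`, `light`, `steady`, `dark_relax`).
#' @examples
#' sched <- cf_schedule()
#' nrow(sched)                       # 55
#' table(sched$kind)                 # 21 measured, 34 calculated
#' @export
cf_schedule <- function() {
  rows <- list(
    list("F0",     NA_integer_), list("F0", 85L),
    lapply(.light_times, function(t) list("F0_L", t)),
    list("Fm",     NA_integer_), list("Fm", 85L),
    lapply(.light_times, function(t) list("Fm_L", t)),
    list("Fp",     16L),
    lapply(c(.light_times, 85L), function(t) list("Ft", t)),
    list("FvFm",   NA_integer_),
    lapply(.light_times, function(t) list("FvFm_L", t)),
    lapply(c(.light_times, 85L), function(t) list("NPQ", t)),
    lapply(.light_times, function(t) list("qL", t)),
    lapply(c(.light_times, 85L), function(t) list("qP", t)),
    lapply(c(.light_times, 85L), function(t) list("Qy", t)),
    lapply(.light_times, function(t) list("RFD", t))
  )
  flat <- list()
  for (r in rows) {
    if (is.list(r[[1]])) flat <- c(flat, r) else flat <- c(flat, list(r))
  }
  fam <- vapply(flat, function(x) x[[1]], character(1))
  sec <- vapply(flat, function(x) as.integer(x[[2]]), integer(1))
  fams <- parameter_families()
  out <- data.frame(
    label = mapply(.make_label, fam, sec, USE.NAMES = FALSE),
    family = fam,
    kind = fams$kind[match(fam, fams$family)],
    timepoint_s = sec,
    tag = vapply(sec, .timepoint_tag, character(1)),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(out$label))
  class(out) <- c("cf_schedule", "data.frame")
  out
}

#' Parse and validate a canonical measure label
#'
#' Labels follow `<family>[_<seconds>]`; the dark-adapted state carries no
#' suffix and the Kautsky peak capture is plainly `"Fp"`. Only the (family,
#' timepoint) combinations present in [cf_schedule()] are accepted.
#'
#' @param label A single character label, e.g. `"NPQ_85"`, `"FvFm"`, `"Fp"`.
#' @param schedule Schedule to validate against (default [cf_schedule()]).
#' @return A one-row data frame (the matching schedule entry).
#' @examples
#' parse_measure_label("qP_25")
#' @export
parse_measure_label <- function(label, schedule = cf_schedule()) {
  if (!is.character(label) || length(label) != 1L || is.na(label)) {
    stop("'label' must be a single character string")
  }
  i <- match(label, schedule$label)
  if (is.na(i)) {
    # Diagnose: known family at an invalid timepoint vs unknown family.
    fams <- unique(schedule$family)
    fams <- fams[order(nchar(fams), decreasing = TRUE)]
    hit <- fams[vapply(fams, function(f) {
      label == f || startsWith(label, paste0(f, "_"))
    }, logical(1))][1]
    if (!is.na(hit)) {
      valid <- schedule$label[schedule$family == hit]
      stop(sprintf(
        "invalid timepoint for family '%s' in label '%s' (valid: %s)",
        hit, label, paste(valid, collapse = ", ")))
    }
    stop(sprintf("unknown parameter family in label '%s'", label))
  }
  schedule[i, , drop = FALSE]
}

#' @rdname parse_measure_label
#' @export
validate_measure_label <- parse_measure_label

# Measured labels a calculated label depends on (Table-style formulas; at
# 85 s NPQ substitutes Fm(85) for F'm, and qP/Qy use F_T(85) with the
# dark-adapted Fm/F0).
measure_dependencies <- function(label, schedule = cf_schedule()) {
  m <- parse_measure_label(label, schedule)
  if (m$kind != "calculated") return(character(0))
  t <- m$timepoint_s
  tl <- function(fam) paste0(fam, "_", t)
  switch(m$family,
    FvFm   = c("Fm", "F0"),
    FvFm_L = c(tl("Fm_L"), tl("F0_L")),
    NPQ    = if (!is.na(t) && t == 85L) c("Fm", "Fm_85") else c("Fm", tl("Fm_L")),
    qP     = c("Fm", "F0", tl("Ft")),
    qL     = c("Fm", "F0", tl("Ft"), tl("F0_L")),
    Qy     = c("Fm", tl("Ft")),
    RFD    = c("Fp", tl("Ft")),
    stop(sprintf("no dependency rule for family '%s'", m$family))
  )
}

#' Export the schedule as a plain-text table
#'
#' Writes one row per transient measure (label, family, timepoint, kind,
#' formula) as CSV, for documentation and manifest building.
#'
#' @param path Output file path.
#' @param schedule Schedule to export.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(path, schedule = cf_schedule()) {
  fams <- parameter_families()
  out <- schedule
  out$formula <- fams$formula[match(out$family, fams$family)]
  utils::write.csv(as.data.frame(out), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.cf_schedule <- function(x, ...) {
  cat(sprintf("CF transient schedule: %d measures (%d measured, %d calculated)\n",
              nrow(x), sum(x$kind == "measured"), sum(x$kind == "calculated")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}
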