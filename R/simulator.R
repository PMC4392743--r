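# Synthetic FluorCam-like study generator.
#
# Each plant is a rosette of elliptical leaves on a dark background. Pixel
# latents: F0 ~ lognormal (mean f0_mean, coefficient of variation f0_cv);
# Fm = F0 / (1 - Fv/Fm). Induction kinetics generate the 21 measured
# captures:
#   F'm(t) = Fm (1 - npq_inf (1 - exp(-t / tau_npq)))
#   qP(t)  = qp_ss + (1 - qp_ss) exp(-t / tau_qp)
#   FT(t)  = Fm - qP(t) (Fm - F0)
#   F'0(t) = F0 F'm(t) / Fm
#   Fp     = F0 + 0.9 (Fm - F0)
# and for the 20 s dark relaxation (85 s point), a fraction `relax` of the
# quenching recovers:
#   Fm(85) = Fm (1 - (1 - relax) npq_inf (1 - exp(-74 / tau_npq)))
#   FT(85) = F0 + (1 - relax) (FT(74) - F0),  F0(85) = F0.
# Stress (treatment effect) multiplies Fv/Fm, qp_ss and npq_inf by
# (1 - delta * stress(x, y)) over the lesioned leaves. Every capture gets
# multiplicative Gaussian noise (1 + sigma * eps), clamping to the sensor
# range and integer quantization.

#' Simulation configuration
#'
#' Defaults emulate the reference study design: 15 plants per treatment
#' group, a healthy-control group and an inoculated group whose effective
#' stress lowers qP steady-state by 50%, NPQ capacity by 30% and Fv/Fm by
#' 5%, three imaging days, 5% multiplicative capture noise, and 64 x 64
#' frames (the full 512 x 512 sensor is available via `size`).
#'
#' @param n_plants_per_group Plants per ecotype x treatment group.
#' @param ecotypes Ecotype labels.
#' @param days Imaging days (days after inoculation).
#' @param size Image side length in pixels.
#' @param groups Named list of treatment groups; each element is a list of
#'   stress effect sizes `delta_fvfm`, `delta_qp`, `delta_npq` (fractions in
#'   `[0, 1]`, 0 = healthy) and `lesion_fraction` (fraction of leaves
#'   expressing the stress; 1 = whole rosette).
#' @param fvfm0 Healthy maximum PSII quantum yield (default 0.80).
#' @param f0_mean,f0_cv Mean and coefficient of variation of the lognormal
#'   per-pixel F0 field (ADU).
#' @param npq_inf Asymptotic NPQ under the actinic light.
#' @param tau_npq,tau_qp Induction time constants (s).
#' @param qp_ss Steady-state photochemical quenching coefficient.
#' @param relax Fraction of quenching recovered after 20 s darkness.
#' @param plant_cv Plant-to-plant lognormal variability of f0_mean; plant
#'   jitter s.d. on fvfm0 / qp_ss / npq_inf is `plant_cv / 10`.
#' @param sigma Multiplicative capture noise s.d.
#' @param bits Quantization bit depth (12-bit sensor dynamic).
#' @param quantize Quantize captures to integers (disable for analytic
#'   inversion-identity checks).
#' @param n_leaves,rosette_radius Rosette geometry (radius as fraction of
#'   the frame).
#' @param background Background level (ADU), a near-zero dark offset.
#' @param inoculation_failure Probability that an inoculated plant escapes
#'   infection (generated healthy, flagged in the ground truth).
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `cf_sim_config`.
#' @export
sim_config <- function(n_plants_per_group = 15L,
                       ecotypes = "Col0",
                       days = c(15L, 17L, 21L),
                       size = 64L,
                       groups = list(
                         control = list(),
                         inoculated = list(delta_fvfm = 0.05, delta_qp = 0.5,
                                           delta_npq = 0.3,
                                           lesion_fraction = 1)),
                       fvfm0 = 0.80, f0_mean = 400, f0_cv = 0.15,
                       npq_inf = 0.35, tau_npq = 30, tau_qp = 20,
                       qp_ss = 0.55, relax = 0.8,
                       plant_cv = 0.1, sigma = 0.05, bits = 12L,
                       quantize = TRUE,
                       n_leaves = 8L, rosette_radius = 0.42,
                       background = 2, inoculation_failure = 0,
                       seed = 20260921L) {
  cfg <- as.list(environment())
  for (f in c("fvfm0", "qp_ss", "npq_inf", "relax", "sigma",
              "inoculation_failure")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || (f != "sigma" && v > 1)) {
      stop(sprintf("'%s' must be a fraction in [0, 1]", f))
    }
  }
  if (fvfm0 >= 1) stop("fvfm0 must be < 1 (Fm = F0 / (1 - Fv/Fm))")
  if (tau_npq <= 0 || tau_qp <= 0) stop("time constants must be positive")
  for (g in groups) {
    for (f in intersect(names(g), c("delta_fvfm", "delta_qp", "delta_npq",
                                    "lesion_fraction"))) {
      if (g[[f]] < 0 || g[[f]] > 1) stop(sprintf("group effect '%s' must be in [0, 1]", f))
    }
  }
  class(cfg) <- "cf_sim_config"
  cfg
}

#' @export
print.cf_sim_config <- function(x, ...) {
  cat(sprintf(paste0("CF simulation config: %d plants/group x %d group(s) x ",
                     "%d ecotype(s) x %d day(s), %dx%d px, sigma = %g, seed = %d\n"),
              x$n_plants_per_group, length(x$groups), length(x$ecotypes),
              length(x$days), x$size, x$size, x$sigma, x$seed))
  invisible(x)
}

# Rosette mask with per-pixel leaf id (0 = background).
.rosette_mask <- function(size, n_leaves, radius_frac) {
  cx <- (size + 1) / 2
  xy <- expand.grid(r = seq_len(size), c = seq_len(size))
  leaf <- integer(size * size)
  rad <- radius_frac * size
  for (i in seq_len(n_leaves)) {
    th <- 2 * pi * (i - 1) / n_leaves
    lcx <- cx + 0.55 * rad * cos(th); lcy <- cx + 0.55 * rad * sin(th)
    u <- (xy$c - lcx) * cos(th) + (xy$r - lcy) * sin(th)
    v <- -(xy$c - lcx) * sin(th) + (xy$r - lcy) * cos(th)
    inside <- (u / (0.45 * rad))^2 + (v / (0.22 * rad))^2 <= 1
    leaf[inside & leaf == 0L] <- i
  }
  centre <- (xy$c - cx)^2 + (xy$r - cx)^2 <= (0.18 * rad)^2
  leaf[centre & leaf == 0L] <- 1L
  matrix(leaf, size, size)
}

# Deterministic per-plant sub-seed (kept well below 2^31).
.plant_seed <- function(seed, ecotype_i, group_i, plant_i) {
  (seed + 1000003L * ecotype_i + 10007L * group_i + 101L * plant_i) %% 2000000011L
}

#' Simulate one plant session
#'
#' Draws the plant's latent parameter fields (shared across days) and
#' generates the 21 measured captures for one imaging day, plus the ground
#' truth needed to verify recovery.
#'
#' @param config A [sim_config()].
#' @param group Treatment group name (must be in `config$groups`).
#' @param plant Plant index within the group (1-based).
#' @param day Imaging day (one of `config$days`).
#' @param ecotype Ecotype label.
#' @return A list: `session` (a [plant_session()]) and `truth` (list with
#'   `group`, `infection_success`, `apparent_healthy`, plant-level `fvfm`,
#'   `qp_ss`, `npq_inf` (unstressed and stressed), `leaf` id matrix and the
#'   per-pixel stress field).
#' @export
simulate_session <- function(config, group, plant, day,
                             ecotype = config$ecotypes[1]) {
  stopifnot(inherits(config, "cf_sim_config"))
  gi <- match(group, names(config$groups))
  if (is.na(gi)) stop(sprintf("unknown group '%s'", group))
  ei <- match(ecotype, config$ecotypes)
  if (is.na(ei)) stop(sprintf("unknown ecotype '%s'", ecotype))
  eff <- config$groups[[gi]]
  d_fvfm <- eff$delta_fvfm %||% 0
  d_qp <- eff$delta_qp %||% 0
  d_npq <- eff$delta_npq %||% 0
  lesion <- eff$lesion_fraction %||% 1

  # --- plant-level latents (identical across days) ---
  set.seed(.plant_seed(config$seed, ei, gi, plant))
  leaf <- .rosette_mask(config$size, config$n_leaves, config$rosette_radius)
  jit <- config$plant_cv / 10
  fvfm_p <- min(0.99, max(0.01, config$fvfm0 + stats::rnorm(1, 0, jit)))
  qp_p <- min(0.99, max(0.05, config$qp_ss + stats::rnorm(1, 0, jit)))
  npq_p <- min(0.99, max(0.01, config$npq_inf + stats::rnorm(1, 0, jit)))
  f0_p <- config$f0_mean * stats::rlnorm(1, -config$plant_cv^2 / 2, config$plant_cv)
  stressed_group <- (d_fvfm + d_qp + d_npq) > 0
  infection_success <- !stressed_group ||
    stats::runif(1) >= config$inoculation_failure
  expressed <- stressed_group && infection_success
  # stress field over lesioned leaves
  stress <- matrix(0, config$size, config$size)
  if (expressed) {
    n_str <- max(1L, ceiling(lesion * config$n_leaves))
    which_leaves <- sample(seq_len(config$n_leaves), n_str)
    stress[leaf %in% which_leaves] <- 1
  }
  sdlog <- sqrt(log(1 + config$f0_cv^2))
  F0 <- matrix(stats::rlnorm(config$size^2, log(f0_p) - sdlog^2 / 2, sdlog),
               config$size, config$size)

  # --- per-pixel photosynthetic fields ---
  fvfm_px <- fvfm_p * (1 - d_fvfm * stress)
  qp_px <- qp_p * (1 - d_qp * stress)
  npq_px <- npq_p * (1 - d_npq * stress)
  Fm <- F0 / (1 - fvfm_px)

  lt <- c(25L, 38L, 50L, 62L, 74L)
  captures <- list(F0 = F0, Fm = Fm, Fp = F0 + 0.9 * (Fm - F0))
  qp_last <- NULL
  for (t in lt) {
    FmL <- Fm * (1 - npq_px * (1 - exp(-t / config$tau_npq)))
    qpt <- qp_px + (1 - qp_px) * exp(-t / config$tau_qp)
    captures[[paste0("Fm_L_", t)]] <- FmL
    captures[[paste0("Ft_", t)]] <- Fm - qpt * (Fm - F0)
    captures[[paste0("F0_L_", t)]] <- F0 * FmL / Fm
    qp_last <- qpt
  }
  res_npq <- (1 - config$relax) * npq_px * (1 - exp(-74 / config$tau_npq))
  captures$Fm_85 <- Fm * (1 - res_npq)
  captures$Ft_85 <- F0 + (1 - config$relax) * (captures$Ft_74 - F0)
  captures$F0_85 <- F0

  # --- background, noise, quantization (day-specific capture noise) ---
  set.seed((.plant_seed(config$seed, ei, gi, plant) + as.integer(day)) %%
             2000000011L)
  maxval <- 2^config$bits - 1
  bg <- leaf == 0L
  out <- lapply(captures, function(m) {
    m[bg] <- config$background
    if (config$sigma > 0) {
      m <- m * (1 + config$sigma * matrix(stats::rnorm(length(m)), nrow(m)))
    }
    m <- pmin(pmax(m, 0), maxval)
    if (config$quantize) {
      m <- round(m)
      storage.mode(m) <- "integer"
    }
    m
  })
  key <- list(ecotype = ecotype, treatment = group,
              plant = sprintf("P%02d", plant), day = day)
  list(
    session = plant_session(out, key = key),
    truth = list(
      group = group, ecotype = ecotype, plant = sprintf("P%02d", plant),
      day = day, infection_success = infection_success,
      apparent_healthy = !expressed,
      fvfm = fvfm_p, qp_ss = qp_p, npq_inf = npq_p,
      fvfm_stressed = fvfm_p * (1 - d_fvfm),
      qp_ss_stressed = qp_p * (1 - d_qp),
      npq_inf_stressed = npq_p * (1 - d_npq),
      leaf = leaf, stress = stress)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fixed affine scales used to store ratio-valued calculated images in the
# 12-bit integer container (identical for every plant, so stored images stay
# comparable); recorded in parameter_scales.csv at the dataset root.
.calc_scales <- c(FvFm = 2000, FvFm_L = 2000, NPQ = 2000, qL = 2000,
                  qP = 2000, Qy = 2000, RFD = 400)

#' Simulate a complete study onto disk
#'
#' Emits the full nomenclature tree consumable by [scan_dataset()]: one TIFF
#' per transient measure (measured captures as-is; calculated parameter
#' images computed by [compute_all()] and stored under a fixed per-family
#' integer scale, recorded in `parameter_scales.csv`), a histogram text file
#' alongside each image, and a ground-truth CSV.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if absent).
#' @param write_histograms Also write `<label>.hist.txt` files (256 bins
#'   over the sensor range).
#' @param write_calculated Also write the 34 calculated parameter images
#'   (so a full design emits design x 55 TIFFs).
#' @return A list: `manifest` (scan of the emitted tree), `truth`
#'   (data frame, one row per plant x day) and `root` (= `out_dir`).
#' @export
simulate_study <- function(config, out_dir, write_histograms = TRUE,
                           write_calculated = TRUE) {
  stopifnot(inherits(config, "cf_sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sched <- cf_schedule()
  maxval <- 2^config$bits - 1
  truth_rows <- list()
  for (eco in config$ecotypes) {
    for (grp in names(config$groups)) {
      for (pl in seq_len(config$n_plants_per_group)) {
        for (d in config$days) {
          sim <- simulate_session(config, grp, pl, d, ecotype = eco)
          pdir <- file.path(out_dir, eco, grp, d, sprintf("P%02d", pl))
          dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
          disk <- lapply(sim$session$images, function(img) {
            if (!is.integer(img)) {
              img <- round(img); storage.mode(img) <- "integer"
            }
            img
          })
          if (write_calculated) {
            calc <- compute_all(sim$session, sched)
            for (lab in names(calc)) {
              fam <- parse_measure_label(lab, sched)$family
              v <- calc[[lab]]$values
              v[!calc[[lab]]$mask] <- 0
              q <- round(pmin(pmax(v * .calc_scales[[fam]], 0), maxval))
              storage.mode(q) <- "integer"
              disk[[lab]] <- q
            }
          }
          for (lab in names(disk)) {
            img <- disk[[lab]]
            write_cf_image(img, file.path(pdir, paste0(lab, ".tif")))
            if (write_histograms) {
              h <- image_to_histogram(img, n_bins = 256L,
                                      range = c(0, 2^config$bits))
              write_histogram_file(h, file.path(pdir, paste0(lab, ".hist.txt")))
            }
          }
          tr <- sim$truth
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            ecotype = eco, treatment = grp, plant = tr$plant, day = d,
            infection_success = tr$infection_success,
            apparent_healthy = tr$apparent_healthy,
            fvfm = tr$fvfm, qp_ss = tr$qp_ss, npq_inf = tr$npq_inf,
            fvfm_stressed = tr$fvfm_stressed,
            qp_ss_stressed = tr$qp_ss_stressed,
            npq_inf_stressed = tr$npq_inf_stressed,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  truth <- do.call(rbind, truth_rows)
  utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  utils::write.csv(data.frame(family = names(.calc_scales),
                              scale = unname(.calc_scales)),
                   file.path(out_dir, "parameter_scales.csv"),
                   row.names = FALSE)
  scan <- scan_dataset(out_dir, sched)
  list(manifest = scan$manifest, truth = truth, root = out_dir)
}
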