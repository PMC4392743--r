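# Pipeline orchestration: scan -> contact sheets -> global statistics ->
# histogram clustering, with a reproducible run log.

#' Assemble a pipeline run configuration
#'
#' @param input Dataset root directory or zip archive.
#' @param out Output directory for the result bundle.
#' @param stages Character subset of `c("sheets", "globals", "cluster")`.
#' @param measures Measure labels to analyse in the sheet/cluster stages
#'   (default: a representative subset, `FvFm`, `NPQ_74`, `qP_74`); global
#'   statistics always cover the full schedule.
#' @param treatments Treatment pair compared by the global statistics and
#'   used as clustering ground truth (default: the two treatments found).
#' @param linkage_methods Agglomeration methods for the cluster stage.
#' @param distance `"hellinger"` or `"bhattacharyya-log"`.
#' @param bins Histogram bins for clustering.
#' @param conventional Use textbook formula variants in the CF engine.
#' @param render `"png"`, `"pdf"` or `"none"` for contact-sheet output.
#' @param seed Seed recorded in the run log (the analysis itself is
#'   deterministic).
#' @return A list of class `cf_run_config`.
#' @export
run_config <- function(input, out, stages = c("sheets", "globals", "cluster"),
                       measures = c("FvFm", "NPQ_74", "qP_74"),
                       treatments = NULL,
                       linkage_methods = c("single", "complete", "average",
                                           "mcquitty", "median", "centroid"),
                       distance = "hellinger", bins = 256L,
                       conventional = FALSE, render = "png",
                       seed = 1L) {
  stopifnot(all(stages %in% c("sheets", "globals", "cluster")))
  structure(list(input = input, out = out, stages = stages,
                 measures = measures, treatments = treatments,
                 linkage_methods = linkage_methods, distance = distance,
                 bins = as.integer(bins), conventional = conventional,
                 render = render, seed = as.integer(seed)),
            class = "cf_run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the [run_config()] arguments.
#'
#' @param path YAML file.
#' @return A `cf_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

# Histograms (one per plant) for one measure on one day, on a shared grid.
.measure_histograms <- function(sessions, measure, schedule, bins,
                                conventional = FALSE) {
  kind <- parse_measure_label(measure, schedule)$kind
  imgs <- lapply(sessions, function(s) {
    if (kind == "measured") s$images[[measure]]
    else compute_parameter(s, measure, conventional = conventional)
  })
  rng <- if (kind == "measured") c(0, 4096) else {
    r <- shared_range(imgs)
    c(r[1], r[2] + 1e-9)
  }
  lapply(imgs, image_to_histogram, n_bins = bins, range = rng)
}

.load_sessions <- function(manifest, root, schedule, day) {
  measured <- schedule$label[schedule$kind == "measured"]
  sub <- manifest[manifest$day == day & manifest$label %in% measured, ]
  keys <- unique(sub[, c("ecotype", "treatment", "plant")])
  sessions <- list()
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    rec <- sub[sub$ecotype == k$ecotype & sub$treatment == k$treatment &
                 sub$plant == k$plant, ]
    imgs <- lapply(rec$path, function(p) read_cf_image(file.path(root, p)))
    names(imgs) <- rec$label
    id <- paste(k$ecotype, k$treatment, k$plant, sep = "/")
    sessions[[id]] <- plant_session(imgs, key = c(as.list(k), day = day))
  }
  sessions
}

#' Run the analysis pipeline
#'
#' Scans the dataset, then executes the enabled stages: contact sheets
#' (QC, treatment comparison, kinetics), global-value statistics
#' (global-value table, treatment comparisons with Mann-Whitney U tests and
#' significance codes, radial panel assignment), and histogram clustering
#' (per measure and linkage method: Hellinger distance matrix, dendrogram
#' as Newick + merge CSV, mis-clustering rates against the treatment
#' labels). All outputs are CSV/text/PNG/PDF files under `config$out`; a
#' `run.log` records versions, seed and configuration.
#'
#' @param config A [run_config()] (or path to a YAML accepted by
#'   [read_run_config()]).
#' @return Invisibly, a list of the main result tables (`manifest`,
#'   `globals`, `comparisons`, `panels`, `cluster_rates`, `sheet_index`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "cf_run_config"))
  sched <- cf_schedule()
  scan <- scan_dataset(config$input)
  manifest <- scan$manifest
  if (!nrow(manifest)) stop("empty manifest: no images found under input")
  root <- attr(manifest, "root")
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  write_manifest(manifest, file.path(config$out, "manifest.csv"))
  if (nrow(scan$missing)) {
    write_manifest(scan$missing, file.path(config$out, "missing.csv"))
  }
  treatments <- config$treatments
  if (is.null(treatments)) treatments <- sort(unique(manifest$treatment))[1:2]
  days <- sort(unique(manifest$day))
  res <- list(manifest = manifest)
  failures <- character(0)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", name, conditionMessage(e)))
      NULL
    })
  }

  if ("sheets" %in% config$stages) {
    res$sheet_index <- run_stage("sheets", {
      sdir <- file.path(config$out, "sheets")
      dir.create(sdir, showWarnings = FALSE)
      all_sheets <- list()
      for (meas in config$measures) {
        if (parse_measure_label(meas, sched)$kind == "calculated" &&
            !any(manifest$label == meas)) next
        qc <- qc_sheets(manifest, meas)
        kin <- kinetics_sheets(manifest, meas)
        trt <- lapply(days, function(d)
          treatment_sheets(manifest, meas, d, treatments))
        sheets <- c(qc, kin, trt)
        if (config$render != "none") {
          for (j in seq_along(sheets)) {
            nm <- sprintf("%s_%s_%02d", sheets[[j]]$type, meas, j)
            render_sheet(sheets[[j]], file.path(sdir, nm), root = root,
                         format = config$render)
          }
        }
        all_sheets <- c(all_sheets, sheets)
      }
      idx <- file.path(sdir, "sheet_index.csv")
      write_sheet_index(all_sheets, idx)
      idx
    })
  }

  if ("globals" %in% config$stages) {
    run_stage("globals", {
      gv <- global_value_table(manifest, root, sched,
                               conventional = config$conventional)
      utils::write.csv(gv, file.path(config$out, "global_values.csv"),
                       row.names = FALSE)
      cmp <- compare_all(gv, treatments)
      utils::write.csv(cmp, file.path(config$out, "comparisons.csv"),
                       row.names = FALSE)
      means <- tapply(gv$global_value, gv$label, mean)
      panels <- radial_panel_partition(means)
      utils::write.csv(data.frame(label = names(panels),
                                  mean = as.numeric(means[names(panels)]),
                                  panel = as.integer(panels)),
                       file.path(config$out, "radial_panels.csv"),
                       row.names = FALSE)
      grDevices::pdf(file.path(config$out, "radial_plots.pdf"),
                     width = 8, height = 8)
      plot_radial_panels(gv, treatments)
      grDevices::dev.off()
      res$globals <- gv; res$comparisons <- cmp; res$panels <- panels
    })
  }

  if ("cluster" %in% config$stages) {
    run_stage("cluster", {
      cdir <- file.path(config$out, "cluster")
      dir.create(cdir, showWarnings = FALSE)
      rates <- list()
      for (d in days) {
        sessions <- .load_sessions(manifest, root, sched, d)
        grp <- vapply(sessions, function(s) s$key$treatment, character(1))
        keep <- grp %in% treatments
        sessions <- sessions[keep]; grp <- grp[keep]
        for (meas in config$measures) {
          hists <- .measure_histograms(sessions, meas, sched, config$bins,
                                       config$conventional)
          names(hists) <- names(sessions)
          dmat <- pairwise_distances(hists, kind = config$distance)
          utils::write.csv(dmat,
                           file.path(cdir, sprintf("dist_%s_d%s.csv", meas, d)))
          for (m in config$linkage_methods) {
            dend <- linkage(dmat, m)
            writeLines(as_newick(dend),
                       file.path(cdir, sprintf("dend_%s_d%s_%s.nwk", meas, d, m)))
            ev <- misclustering_rate(cut_k(dend, length(unique(grp))),
                                     stats::setNames(grp, names(sessions)))
            rates[[length(rates) + 1L]] <- data.frame(
              day = d, measure = meas, method = m, n = ev$n, rate = ev$rate,
              stringsAsFactors = FALSE)
          }
        }
      }
      rates <- do.call(rbind, rates)
      utils::write.csv(rates, file.path(cdir, "misclustering_rates.csv"),
                       row.names = FALSE)
      res$cluster_rates <- rates
    })
  }

  log <- c(sprintf("phenocf %s | R %s.%s", as.character(utils::packageVersion("phenocf")),
                   R.version$major, R.version$minor),
           sprintf("seed: %d", config$seed),
           sprintf("input: %s", config$input),
           sprintf("stages: %s", paste(config$stages, collapse = ",")),
           sprintf("measures: %s", paste(config$measures, collapse = ",")),
           sprintf("treatments: %s", paste(treatments, collapse = " vs ")),
           sprintf("distance: %s | bins: %d | conventional: %s",
                   config$distance, config$bins, config$conventional),
           sprintf("linkage: %s", paste(config$linkage_methods, collapse = ",")),
           if (length(failures)) paste("FAILED:", failures) else "status: ok")
  writeLines(log, file.path(config$out, "run.log"))
  if (length(failures)) {
    warning(sprintf("%d stage(s) failed: %s", length(failures),
                    paste(failures, collapse = "; ")))
  }
  invisible(res)
}
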