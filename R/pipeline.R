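# End-to-end experiment runner: simulate -> reconstruct (both kernels) ->
# de-bloom -> measure -> evaluate, with deterministic seeding and plain-text
# outputs (CSV measurements, JSON evaluation, optional NIfTI volumes).

#' Configuration of a full phantom experiment
#'
#' @param lumen_diameters vessel inner diameters to simulate, mm.
#' @param stenoses percent stenoses of the series.
#' @param kernels reconstruction kernels to run.
#' @param n_repeats independent HU-draw repeats of the series.
#' @param grid_shape,spacing phantom grid; the default 256 x 256 x 64 grid
#'   is the full-resolution setting, tests use smaller crops.
#' @param plaque_length plaque axial extent, mm.
#' @param rim_strength beam-hardening rim strength passed to the scanner.
#' @param debloom a [debloom_config()].
#' @param debloom_enabled set `FALSE` to skip the correction (DS columns
#'   left empty).
#' @param calcium_threshold HU threshold for calcium volume and lumen
#'   exclusion.
#' @param stenosis_thresholds percent thresholds for diagnostic performance.
#' @param seed global seed; every stochastic draw in the run derives from it.
#' @param outdir output directory, or `NULL` to skip writing.
#' @param write_volumes also write truth/bloomed/debloomed NIfTI volumes.
#' @return An object of class `run_config`.
#' @export
run_config <- function(lumen_diameters = 4.0,
                       stenoses = seq(10, 90, by = 10),
                       kernels = c("STND", "HD_STND"),
                       n_repeats = 1L,
                       grid_shape = c(256L, 256L, 64L),
                       spacing = c(0.234375, 0.234375, 0.625),
                       plaque_length = 4.0,
                       rim_strength = 0.05,
                       debloom = debloom_config(),
                       debloom_enabled = TRUE,
                       calcium_threshold = 600,
                       stenosis_thresholds = c(50, 70),
                       seed = 1L,
                       outdir = NULL,
                       write_volumes = FALSE) {
  kernels <- match.arg(kernels, c("STND", "HD_STND"), several.ok = TRUE)
  structure(list(lumen_diameters = lumen_diameters, stenoses = stenoses,
                 kernels = kernels, n_repeats = as.integer(n_repeats),
                 grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing),
                 plaque_length = plaque_length,
                 rim_strength = rim_strength,
                 debloom = debloom, debloom_enabled = debloom_enabled,
                 calcium_threshold = calcium_threshold,
                 stenosis_thresholds = stenosis_thresholds,
                 seed = as.integer(seed), outdir = outdir,
                 write_volumes = write_volumes),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$debloom <- unclass(x$debloom)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  db <- do.call(debloom_config, x$debloom[!vapply(x$debloom, is.null, logical(1))])
  x$debloom <- db
  x$outdir <- x$outdir %||% NULL
  do.call(run_config, x)
}

#' Slice bookkeeping for a phantom measurement
#'
#' Lesion slices are the plaque's axial extent padded by one slice;
#' reference slices are all slices at least `margin_mm` away from the
#' plaque, so blur cannot leak calcium into the reference lumen.
#'
#' @param truth a `truth_record` from [make_vessel_phantom()].
#' @param margin_mm reference exclusion margin around the plaque, mm.
#' @return List with integer vectors `lesion` and `reference`.
#' @export
phantom_slice_ranges <- function(truth, margin_mm = 2.0) {
  nz <- truth$spec$grid_shape[3]
  sz <- truth$spec$spacing[3]
  ps <- truth$plaque_slices
  if (any(is.na(ps))) { # no plaque: treat the central third as the lesion
    mid <- round(nz / 2)
    ps <- c(mid - 1L, mid + 1L)
  }
  lesion <- max(1L, ps[1] - 1L):min(nz, ps[2] + 1L)
  m <- as.integer(ceiling(margin_mm / sz))
  reference <- setdiff(seq_len(nz),
                       max(1L, ps[1] - m):min(nz, ps[2] + m))
  if (length(reference) < 2L)
    stop("grid too short along z to hold plaque-free reference slices")
  list(lesion = lesion, reference = reference)
}

#' Standard SNR regions of interest for a phantom volume
#'
#' Vessel ROI: the lumen core (quarter of the lumen diameter) on the
#' plaque-free reference slices. Periphery ROI: a background box in the
#' grid corner, mirroring the "periphery outside the vessel" noise
#' measurement.
#'
#' @param volume an [image_volume()].
#' @param truth the matching `truth_record`.
#' @param slices output of [phantom_slice_ranges()].
#' @return List of logical arrays `vessel` and `periphery`.
#' @export
phantom_rois <- function(volume, truth, slices) {
  d <- dim(volume$voxels)
  sp <- volume$spacing
  ctr <- slice_center_index(volume)
  r_core <- truth$spec$lumen_diameter / 4
  xi <- seq_len(d[1]); yi <- seq_len(d[2])
  core2d <- outer(((xi - ctr[1]) * sp[1])^2, ((yi - ctr[2]) * sp[2])^2,
                  `+`) <= r_core^2
  vessel <- array(FALSE, d)
  vessel[, , slices$reference] <- core2d
  cs <- max(4L, min(16L, d[1] %/% 6L))
  periphery <- array(FALSE, d)
  periphery[seq_len(cs), seq_len(cs), ] <- TRUE
  list(vessel = vessel, periphery = periphery)
}

measure_phantom <- function(volume, truth, slices, calcium_threshold) {
  ds <- measure_diameter_stenosis(volume,
                                  reference_slices = slices$reference,
                                  lesion_slices = slices$lesion,
                                  calcium_threshold = calcium_threshold)
  as_ <- measure_area_stenosis(volume,
                               reference_slices = slices$reference,
                               lesion_slices = slices$lesion,
                               calcium_threshold = calcium_threshold)
  cv <- calcium_volume(volume, calcium_threshold)
  list(diameter = ds, area = as_, calcium = cv)
}

#' Run the full phantom experiment
#'
#' For every repeat x lumen diameter, generates the stenosis series with
#' seeded HU draws, then for every kernel simulates the bloomed
#' reconstruction, optionally de-blooms it, and measures original (OS) and
#' de-bloomed (DS) stenosis, calcium volumes and SNR against the ground
#' truth (RS). All randomness derives from `config$seed`; re-running with
#' the same seed reproduces every output byte-for-byte.
#'
#' A failure on one series member is logged (warning) and skipped.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `measurements` (data.frame, one row per
#'   volume x kernel), `evaluation` (nested list of [bland_altman()],
#'   [diagnostic_performance()], plaque-reduction and SNR summaries per
#'   kernel) and `paths` of any files written.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rows <- list()
  paths <- character(0)
  voldir <- NULL
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    if (config$write_volumes) {
      voldir <- file.path(config$outdir, "volumes")
      dir.create(voldir, showWarnings = FALSE)
    }
  }
  task <- 0L
  for (rep_i in seq_len(config$n_repeats)) {
    for (li in seq_along(config$lumen_diameters)) {
      lum <- config$lumen_diameters[li]
      base <- phantom_spec(lumen_diameter = lum,
                           plaque_length = config$plaque_length,
                           grid_shape = config$grid_shape,
                           spacing = config$spacing)
      series <- make_stenosis_series(base, config$stenoses,
                                     seed = derive_seed(config$seed,
                                                        rep_i * 131L + li))
      for (mi in seq_along(series)) {
        member <- series[[mi]]
        vessel_id <- sprintf("rep%d_lum%.1f", rep_i, lum)
        plaque_id <- sprintf("s%02.0f", config$stenoses[mi])
        slices <- phantom_slice_ranges(member$truth)
        if (!is.null(voldir))
          paths <- c(paths, write_volume(member$volume,
            file.path(voldir, sprintf("%s_%s_truth.nii.gz", vessel_id, plaque_id))))
        for (kern in config$kernels) {
          task <- task + 1L
          row <- tryCatch({
            scfg <- scanner_config(kern, rim_strength = config$rim_strength,
                                   seed = derive_seed(config$seed, 7919L + task))
            psf <- build_psf(scfg, member$volume$spacing)
            bloomed <- apply_blooming(member$volume, scfg, psf)
            om <- measure_phantom(bloomed, member$truth, slices,
                                  config$calcium_threshold)
            rois <- phantom_rois(bloomed, member$truth, slices)
            snr_o <- snr(bloomed, rois$vessel, rois$periphery)
            if (!is.null(voldir))
              paths <- c(paths, write_volume(bloomed,
                file.path(voldir, sprintf("%s_%s_%s_bloomed.nii.gz",
                                          vessel_id, plaque_id, kern))))
            if (config$debloom_enabled) {
              db <- debloom(bloomed, psf, config$debloom)
              dm <- measure_phantom(db$volume, member$truth, slices,
                                    config$calcium_threshold)
              snr_d <- snr(db$volume, rois$vessel, rois$periphery)
              if (!is.null(voldir))
                paths <- c(paths, write_volume(db$volume,
                  file.path(voldir, sprintf("%s_%s_%s_debloomed.nii.gz",
                                            vessel_id, plaque_id, kern))))
              db_cols <- list(ds_pct = dm$diameter, ds_area_pct = dm$area,
                              cv_debloomed = dm$calcium,
                              snr_debloomed = snr_d$snr,
                              noise_debloomed = snr_d$noise,
                              iterations = db$report$iterations)
            } else {
              db_cols <- list(ds_pct = NA_real_, ds_area_pct = NA_real_,
                              cv_debloomed = NA_real_,
                              snr_debloomed = NA_real_,
                              noise_debloomed = NA_real_,
                              iterations = NA_integer_)
            }
            c(list(vessel_id = vessel_id, plaque_id = plaque_id,
                   kernel = kern,
                   true_stenosis_pct = member$truth$true_stenosis_pct,
                   true_calcium_volume = member$truth$true_calcium_volume,
                   plaque_hu = member$truth$spec$plaque_hu,
                   contrast_hu = member$truth$spec$contrast_hu,
                   os_pct = om$diameter, os_area_pct = om$area,
                   cv_original = om$calcium,
                   snr_original = snr_o$snr, noise_original = snr_o$noise),
              db_cols)
          }, error = function(e) {
            warning(sprintf("skipping %s %s %s: %s", vessel_id, plaque_id,
                            kern, conditionMessage(e)))
            NULL
          })
          if (!is.null(row)) rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  if (length(rows) == 0L) stop("every series member failed")
  measurements <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  evaluation <- evaluate_measurements(measurements, config$stenosis_thresholds)
  if (!is.null(config$outdir)) {
    mpath <- file.path(config$outdir, "measurements.csv")
    write_measurements_csv(measurements, mpath)
    epath <- file.path(config$outdir, "evaluation.json")
    jsonlite::write_json(evaluation_to_list(evaluation), epath,
                         auto_unbox = TRUE, digits = 6, pretty = TRUE)
    paths <- c(paths, mpath, epath)
  }
  invisible(list(measurements = measurements, evaluation = evaluation,
                 paths = paths))
}

# Fixed-format CSV (percents and HU to one decimal, volumes to three) so
# identical runs are identical files.
write_measurements_csv <- function(m, path) {
  fm <- m
  one <- c("true_stenosis_pct", "plaque_hu", "contrast_hu", "os_pct",
           "os_area_pct", "ds_pct", "ds_area_pct", "snr_original",
           "noise_original", "snr_debloomed", "noise_debloomed")
  three <- c("true_calcium_volume", "cv_original", "cv_debloomed")
  for (cl in intersect(one, names(fm))) fm[[cl]] <- sprintf("%.1f", m[[cl]])
  for (cl in intersect(three, names(fm))) fm[[cl]] <- sprintf("%.3f", m[[cl]])
  fm[fm == "NA"] <- ""
  utils::write.csv(fm, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Evaluate a measurement table
#'
#' Computes, per kernel: Bland-Altman agreement of original (OS) and
#' de-bloomed (DS) stenosis against the reference (RS), diagnostic
#' performance at each threshold before and after correction, mean
#' per-plaque reductions (RCV/RDS/RAS) and the SNR/noise comparison.
#'
#' @param measurements data.frame as produced by [run_experiment()].
#' @param thresholds percent stenosis thresholds.
#' @return Nested list keyed by kernel, class `eval_results`.
#' @export
evaluate_measurements <- function(measurements, thresholds = c(50, 70)) {
  out <- list()
  for (kern in unique(measurements$kernel)) {
    m <- measurements[measurements$kernel == kern, ]
    has_ds <- any(is.finite(m$ds_pct))
    enough <- nrow(m) >= 2L # Bland-Altman needs paired replicates
    ba <- list(os_rs = if (enough) bland_altman(m$os_pct, m$true_stenosis_pct),
               ds_rs = if (has_ds && enough)
                 bland_altman(m$ds_pct, m$true_stenosis_pct))
    dp <- lapply(thresholds, function(th) {
      list(threshold = th,
           original = diagnostic_performance(m$os_pct, m$true_stenosis_pct, th),
           debloomed = if (has_ds)
             diagnostic_performance(m$ds_pct, m$true_stenosis_pct, th))
    })
    names(dp) <- paste0("ge", thresholds)
    change <- NULL
    if (has_ds) {
      pcs <- lapply(seq_len(nrow(m)), function(i)
        plaque_change(plaque_quant(m$cv_original[i], m$os_pct[i],
                                   m$os_area_pct[i]),
                      plaque_quant(m$cv_debloomed[i], m$ds_pct[i],
                                   m$ds_area_pct[i])))
      stat <- function(f) {
        v <- vapply(pcs, function(p) p[[f]], numeric(1))
        v <- v[is.finite(v)]
        if (length(v) == 0) c(mean = NA_real_, sd = NA_real_)
        else c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else NA_real_)
      }
      change <- list(rcv = stat("rcv"), rds = stat("rds"), ras = stat("ras"))
    }
    snr_cmp <- if (has_ds && sum(is.finite(m$snr_original)) > 1 &&
                   sum(is.finite(m$snr_debloomed)) > 1)
      group_compare(m$snr_original[is.finite(m$snr_original)],
                    m$snr_debloomed[is.finite(m$snr_debloomed)])
    out[[kern]] <- list(n = nrow(m), bland_altman = ba,
                        diagnostic = dp, plaque_change = change,
                        snr_comparison = snr_cmp)
  }
  structure(out, class = "eval_results")
}

evaluation_to_list <- function(ev) {
  strip <- function(x) {
    if (is.null(x)) return(NULL)
    if (inherits(x, c("bland_altman", "diagnostic_performance"))) {
      x <- unclass(x)
    }
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  lapply(unclass(ev), strip)
}
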