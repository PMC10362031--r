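# Crop two uniform signals to their common length.
crop_common <- function(a, b) {
  n <- min(length(a$values), length(b$values))
  a$values <- a$values[seq_len(n)]
  b$values <- b$values[seq_len(n)]
  list(a = a, b = b)
}

#' Analyze a synthetic scene end to end
#'
#' Runs the full validation pipeline on a [make_synthetic_scene()] result:
#' template tracking, calibration, second differentiation, resampling of
#' the vision-based SCG to the reference rate, 1-30 Hz bandpass of the
#' reference acceleration, ECG R-peak detection, beat segmentation and
#' ensemble averaging of both signals, then the similarity metrics
#' (Pearson correlation, DTW similarity index, cross-correlation lag,
#' wavelet coherence) and heart rate from both sources.
#'
#' @param scene a [make_synthetic_scene()] result.
#' @param roi tracking region, default the scene's `suggested_roi`.
#' @param tracker a [tracker_config()].
#' @param scg_band reference bandpass edges, Hz.
#' @param hr_band heart-rate bandpass edges, Hz.
#' @param band_fraction DTW corridor half-width fraction.
#' @param coherence_fs rate at which wavelet coherence is computed (the
#'   signal content lives below 30 Hz, so coherence is evaluated on a
#'   decimated grid for speed).
#' @param max_lag cross-correlation search half-range, seconds.
#' @return A `scene_report` list: `trajectory`, per-axis `metrics`
#'   (pearson_r, similarity, lag_s, mean_coherence), `hr_ecg`, `hr_scg`,
#'   `ensembles`, and the programmed ground truth for reference.
#' @export
analyze_scene <- function(scene, roi = scene$suggested_roi,
                          tracker = tracker_config(),
                          scg_band = c(1, 30), hr_band = c(0.7, 1.5),
                          band_fraction = 0.05, coherence_fs = 200,
                          max_lag = 0.3) {
  stopifnot(inherits(scene, "synthetic_scene"))
  common_fs <- scene$truth_acceleration$x$fs

  tpl <- extract_template(scene$frames, roi)
  traj <- track_sequence(scene$frames, tpl, tracker)
  cal <- scaling_factor_from_target(d_mm = scene$scale_mm_per_px * 100,
                                    d_pixel = 100)
  traj_mm <- apply_calibration(traj, cal)

  rpeaks <- detect_r_peaks(scene$truth_ecg)
  hr_ecg <- hr_from_r_peaks(rpeaks)

  per_axis <- list()
  hr_scg <- NULL
  for (axis in c("x", "y")) {
    disp <- uniform_signal(if (axis == "x") traj_mm$ux else traj_mm$uy,
                           fs = traj_mm$frame_rate, units = "mm")
    acc_v60 <- displacement_to_acceleration(disp)
    scg_v <- resample_to(acc_v60, common_fs)
    scg_g <- bandpass(scene$truth_acceleration[[axis]],
                      scg_band[1L], scg_band[2L])
    cc <- crop_common(scg_g, scg_v)
    scg_g <- cc$a; scg_v <- cc$b

    seg_g <- segment_beats(scg_g, rpeaks)
    seg_v <- segment_beats(scg_v, rpeaks)
    ens_g <- ensemble_average(seg_g)
    ens_v <- ensemble_average(seg_v)

    sim <- similarity_index(ens_g, ens_v, band_fraction)
    r <- pearson_r(ens_g$values, ens_v$values)
    lag <- estimate_lag(scg_g, scg_v, max_lag)
    coh <- wavelet_coherence(resample_to(scg_g, coherence_fs),
                             resample_to(scg_v, coherence_fs))

    if (axis == "x") hr_scg <- hr_from_scg(scg_v, band = hr_band)

    per_axis[[axis]] <- list(
      pearson_r = r, similarity = sim, lag_s = lag,
      mean_coherence = mean_coherence_in_coi(coh),
      ensembles = list(gold = ens_g, vision = ens_v),
      coherence = coh
    )
  }

  structure(
    list(trajectory = traj_mm, axes = per_axis,
         hr_ecg = hr_ecg, hr_scg = hr_scg,
         rpeaks = rpeaks, hr_programmed = scene$hr_bpm),
    class = "scene_report"
  )
}

#' @export
print.scene_report <- function(x, ...) {
  cat("<scene_report>\n")
  for (axis in names(x$axes)) {
    m <- x$axes[[axis]]
    cat(sprintf("  %s: r = %.3f, S = %.3f, lag = %.1f ms, coh = %.3f\n",
                axis, m$pearson_r, m$similarity$s, 1000 * m$lag_s,
                m$mean_coherence))
  }
  cat(sprintf("  HR: ecg %.1f bpm, scg %.1f bpm (programmed %s)\n",
              mean_hr(x$hr_ecg), mean_hr(x$hr_scg),
              if (is.null(x$hr_programmed)) "-" else
                sprintf("%.1f", x$hr_programmed)))
  invisible(x)
}

#' Pipeline configuration for file-based runs
#'
#' @param video_dir directory of PNG frames (see
#'   [write_frame_directory()]).
#' @param frame_rate video frame rate, fps.
#' @param rois list of `c(x0, y0, w, h)` tracking regions (one per target).
#' @param rotations per-ROI rotation angles, degrees counterclockwise.
#' @param target_mm,target_px physical and pixel length of the tracked
#'   target, for the scaling factor.
#' @param ecg_csv optional ECG channel (CSV, see [write_signal_csv()]).
#' @param ref_csv_x,ref_csv_y optional per-ROI reference accelerometer
#'   channels (character vectors of CSV paths, one per ROI).
#' @param video_audio_csv,daq_audio_csv optional audio channels carrying
#'   the synchronization taps of the two recording systems.
#' @param scg_band,hr_band band edges, Hz.
#' @param common_fs common analysis rate, Hz.
#' @param band_fraction DTW corridor fraction.
#' @param out_dir output directory for CSVs and the JSON report.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(video_dir, frame_rate, rois,
                            rotations = rep(0, length(rois)),
                            target_mm, target_px,
                            ecg_csv = NULL, ref_csv_x = NULL, ref_csv_y = NULL,
                            video_audio_csv = NULL, daq_audio_csv = NULL,
                            scg_band = c(1, 30), hr_band = c(0.7, 1.5),
                            common_fs = 5000, band_fraction = 0.05,
                            out_dir = tempfile("scgvision_out_")) {
  if (!dir.exists(video_dir)) {
    stop_scg("scg_config_error", "video directory not found: '%s'", video_dir)
  }
  if (length(rois) < 1L) stop_scg("scg_config_error", "need at least one roi")
  for (p in c(ecg_csv, ref_csv_x, ref_csv_y, video_audio_csv, daq_audio_csv)) {
    if (!is.null(p) && !file.exists(p)) {
      stop_scg("scg_config_error", "input file not found: '%s'", p)
    }
  }
  structure(
    list(video_dir = video_dir, frame_rate = frame_rate, rois = rois,
         rotations = rotations, target_mm = target_mm, target_px = target_px,
         ecg_csv = ecg_csv, ref_csv_x = ref_csv_x, ref_csv_y = ref_csv_y,
         video_audio_csv = video_audio_csv, daq_audio_csv = daq_audio_csv,
         scg_band = scg_band, hr_band = hr_band, common_fs = common_fs,
         band_fraction = band_fraction, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the file-based pipeline
#'
#' For every ROI: track, calibrate, differentiate and resample to the
#' common rate, writing per-ROI CSVs. When reference channels are present,
#' the two clocks are synchronized through the audio taps, the reference is
#' bandpassed, both signals are segmented by the ECG R waves and ensemble
#' averaged, and the similarity metrics and heart rates are computed. A
#' failing ROI (e.g. untrackable texture) is recorded in the report and
#' does not stop the remaining ROIs.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the report list (also written as
#'   `report.json` under `config$out_dir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  frames <- read_frame_directory(config$video_dir, config$frame_rate)
  cal <- scaling_factor_from_target(config$target_mm, config$target_px)

  clock <- NULL
  if (!is.null(config$video_audio_csv) && !is.null(config$daq_audio_csv)) {
    taps_vid <- detect_taps(read_signal_csv(config$video_audio_csv))
    taps_daq <- detect_taps(read_signal_csv(config$daq_audio_csv))
    clock <- align_clocks(taps_daq, taps_vid)  # maps DAQ time -> video time
  }
  on_video_clock <- function(sig) {
    if (is.null(clock)) return(sig)
    sig$t0 <- map_time(clock, sig$t0)
    sig
  }

  ecg <- rpeaks <- hr_ecg <- NULL
  if (!is.null(config$ecg_csv)) {
    ecg <- on_video_clock(read_signal_csv(config$ecg_csv))
    rpeaks <- detect_r_peaks(ecg)
    hr_ecg <- hr_from_r_peaks(rpeaks)
  }

  report <- list(rois = list(),
                 clock = if (is.null(clock)) NULL else
                   list(offset = clock$offset, drift = clock$drift),
                 hr_ecg_bpm = if (is.null(hr_ecg)) NULL else mean_hr(hr_ecg))
  for (ri in seq_along(config$rois)) {
    tag <- sprintf("roi%d", ri)
    res <- tryCatch({
      fr <- if (config$rotations[ri] != 0) {
        rotate_frames(frames, config$rotations[ri])
      } else frames
      tpl <- extract_template(fr, config$rois[[ri]])
      traj <- apply_calibration(track_sequence(fr, tpl), cal)
      write_trajectory_csv(traj, file.path(config$out_dir,
                                           paste0(tag, "_trajectory.csv")))
      roi_out <- list(status = "ok")
      for (axis in c("x", "y")) {
        disp <- uniform_signal(if (axis == "x") traj$ux else traj$uy,
                               traj$frame_rate, units = "mm")
        scg_v <- resample_to(displacement_to_acceleration(disp),
                             config$common_fs)
        write_signal_csv(scg_v, file.path(config$out_dir,
                                          sprintf("%s_scg_v_%s.csv", tag, axis)))
        ref_path <- if (axis == "x") config$ref_csv_x[ri] else config$ref_csv_y[ri]
        if (!is.null(ref_path) && !is.na(ref_path) && !is.null(rpeaks)) {
          scg_g <- bandpass(resample_to(on_video_clock(read_signal_csv(ref_path)),
                                        config$common_fs),
                            config$scg_band[1L], config$scg_band[2L])
          cc <- crop_common(scg_g, scg_v)
          ens_g <- ensemble_average(segment_beats(cc$a, rpeaks))
          ens_v <- ensemble_average(segment_beats(cc$b, rpeaks))
          sim <- similarity_index(ens_g, ens_v, config$band_fraction)
          roi_out[[axis]] <- list(
            pearson_r = pearson_r(ens_g$values, ens_v$values),
            similarity_index = sim$s,
            dtw_distance = sim$d,
            lag_s = estimate_lag(cc$a, cc$b, 0.3)
          )
        }
        if (axis == "x") {
          hr <- tryCatch(hr_from_scg(scg_v, config$hr_band),
                         scgvision_error = function(e) NULL)
          roi_out$hr_scg_bpm <- if (is.null(hr)) NA_real_ else mean_hr(hr)
        }
      }
      roi_out
    }, scgvision_error = function(e) {
      list(status = "failed", error = conditionMessage(e))
    })
    report$rois[[tag]] <- res
  }
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}
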