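#' Run the full analysis pipeline from a configuration
#'
#' Executes the requested stages in order — `simulate`, `preprocess`,
#' `decompose`, `ersp`, `connectivity`, `netstats` — writing each stage's
#' outputs as delimited text under `out_dir` together with a `manifest.json`
#' listing every file produced. All randomness derives from the single
#' `seed`, so equal seeds give byte-identical outputs. Each stage checks
#' that its inputs were produced by an earlier stage of the same run (or
#' supplied via `input:`) and stops with the name of the missing stage
#' otherwise.
#'
#' The configuration is a YAML file or an equivalent named list:
#' \preformatted{
#' seed: 1
#' out_dir: results/demo
#' stages: [simulate, preprocess, decompose, ersp, connectivity, netstats]
#' synthetic:             # used by the simulate stage
#'   duration_s: 120
#'   n_channels: 16
#'   sensor_noise_sd: 1
#'   phase_jitter_sd: 0.02
#' input:                 # alternative to simulate
#'   recording: path.tsv
#'   events: events.tsv
#' params:                # pipeline_params() overrides
#'   n_boot_ersp: 100
#' cluster:
#'   k: 7
#'   min_subjects: 1      # single-recording runs: the subject rule is moot
#' }
#'
#' @param config Path to a YAML config or a named list.
#' @param out_dir Optional override of the output directory.
#' @param seed Optional override of the seed.
#' @return Invisibly, the manifest (named list) that was written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg$seed <- as.integer(seed %||% cfg$seed %||% 1L)
  cfg$out_dir <- out_dir %||% cfg$out_dir %||% stop("config must name out_dir")
  stages <- cfg$stages %||% c("simulate", "preprocess", "decompose",
                              "ersp", "connectivity", "netstats")
  known <- c("simulate", "preprocess", "decompose", "ersp", "connectivity",
             "netstats")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  params <- do.call(pipeline_params, as.list(cfg$params %||% list()))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  manifest <- list(seed = cfg$seed, stages = stages, files = list())
  emit <- function(stage, name, writer) {
    path <- file.path(cfg$out_dir, name)
    writer(path)
    manifest$files[[stage]] <<- sort(c(manifest$files[[stage]], name))
    path
  }
  need <- function(what, stage, provider) {
    if (!exists(what, envir = state)) {
      stop(sprintf("stage '%s' requires '%s' (run the '%s' stage or provide input files)",
                   stage, what, provider))
    }
    get(what, envir = state)
  }
  t_all <- proc.time()[3]
  log_stage <- function(stage, t0) {
    message(sprintf("[stepconn] %-12s %6.1f s", stage, proc.time()[3] - t0))
  }

  # external inputs count as preprocessed-ready raw material
  if (!is.null(cfg$input$recording)) {
    assign("recording", read_recording(cfg$input$recording), envir = state)
  }
  if (!is.null(cfg$input$events)) {
    assign("events", read_events(cfg$input$events), envir = state)
  }

  for (stage in stages) {
    t0 <- proc.time()[3]
    switch(stage,
      simulate = {
        sy <- cfg$synthetic %||% list()
        dur <- sy$duration_s %||% 120
        n_ch <- sy$n_channels %||% 16
        spec <- source_network_spec(cadence = params$cadence)
        ev <- generate_events(params$cadence, dur, limb_labels(),
                              phase_jitter_sd = sy$phase_jitter_sd %||% 0.02,
                              seed = cfg$seed)
        ss <- simulate_source_network(spec, ev, fs = params$fs_raw,
                                      duration_s = dur, seed = cfg$seed + 1L)
        mix <- default_mixing(n_ch, spec$n_sources, seed = cfg$seed + 2L)
        rec <- mix_to_scalp(ss, mix, sensor_noise_sd = sy$sensor_noise_sd %||% 1,
                            artifact_spec = NULL, seed = cfg$seed + 3L,
                            condition = sy$condition %||% "active_arms_legs")
        assign("sources", ss, envir = state)
        assign("recording", rec, envir = state)
        assign("events", ev, envir = state)
        emit(stage, "recording.tsv", function(p) write_recording(rec, p))
        emit(stage, "events.tsv", function(p) write_events(ev, p))
        emit(stage, "truth_mixing.tsv", function(p)
          write_matrix_tsv(mix, p, col_names = ss$labels))
        emit(stage, "truth_gains.tsv", function(p)
          write_matrix_tsv(t(ss$gains[, seq(1, ncol(ss$gains),
                                            by = 64), drop = FALSE]), p,
                           col_names = sprintf("%s_to_%s",
                                               ss$labels[spec$edges$from],
                                               ss$labels[spec$edges$to])))
      },
      preprocess = {
        rec <- need("recording", stage, "simulate")
        ev <- need("events", stage, "simulate")
        hp <- highpass_filter(rec, params$highpass_cutoff)
        rj <- reject_artifacts(hp)
        car <- rereference_common_average(rj$recording)
        ev2 <- adjust_events_for_excision(ev, rj$log)
        assign("clean_raw", car, envir = state)
        assign("events", ev2, envir = state)
        assign("rejection_log", rj$log, envir = state)
        emit(stage, "clean_raw.tsv", function(p) write_recording(car, p))
        emit(stage, "events_clean.tsv", function(p) write_events(ev2, p))
        emit(stage, "rejected_channels.tsv", function(p)
          utils::write.table(rj$log$channels, p, sep = "\t",
                             quote = FALSE, row.names = FALSE))
        emit(stage, "rejected_windows.tsv", function(p)
          utils::write.table(rj$log$windows, p, sep = "\t",
                             quote = FALSE, row.names = FALSE))
      },
      decompose = {
        car <- need("clean_raw", stage, "preprocess")
        ica <- infomax_ica(car, seed = cfg$seed + 4L,
                           quality_threshold = params$ica_quality_threshold)
        cl_cfg <- cfg$cluster %||% list()
        k <- min(cl_cfg$k %||% 7, sum(!ica$excluded))
        keep <- which(!ica$excluded)
        # feature blocks: scalp map + log spectrum of each retained component
        maps <- t(ica$mixing[, keep, drop = FALSE])
        specs <- t(vapply(keep, function(i) {
          gs <- grand_mean_spectrum(ica$activations[i, ], car$fs,
                                    resolution = 0.26, seg_s = 2)
          gs$log_power[gs$freq >= 3 & gs$freq <= 40]
        }, numeric(sum({
          gs0 <- grand_mean_spectrum(ica$activations[1, ], car$fs,
                                     resolution = 0.26, seg_s = 2)
          gs0$freq >= 3 & gs0$freq <= 40
        }))))
        subjects <- rep(car$subject_id, length(keep))
        cl <- cluster_components(list(maps, specs), k = k,
                                 subjects = subjects,
                                 min_subjects = cl_cfg$min_subjects %||% 1,
                                 seed = cfg$seed + 5L)
        assign("ica", ica, envir = state)
        assign("clusters", cl, envir = state)
        assign("kept_components", keep, envir = state)
        emit(stage, "ica_unmixing.tsv", function(p) write_matrix_tsv(ica$unmixing, p))
        emit(stage, "ica_activations.tsv", function(p)
          write_matrix_tsv(ica$activations, p))
        emit(stage, "ica_quality.tsv", function(p)
          write_matrix_tsv(cbind(ica$quality, as.numeric(ica$excluded)), p,
                           col_names = c("quality", "excluded")))
        emit(stage, "clusters.tsv", function(p)
          utils::write.table(cl$clusters, p, sep = "\t", quote = FALSE,
                             row.names = FALSE))
      },
      ersp = {
        ica <- need("ica", stage, "decompose")
        cl <- need("clusters", stage, "decompose")
        ev <- need("events", stage, "preprocess")
        car <- need("clean_raw", stage, "preprocess")
        keep <- get("kept_components", envir = state)
        retained <- cl$clusters$cluster[cl$clusters$retained]
        for (rc in retained) {
          comps <- keep[cl$assignment == rc]
          trials <- lapply(comps, function(i)
            make_warped_epochs(ica$activations[i, ], car$fs, ev,
                               params = params)$logpow)
          arr <- array(unlist(trials),
                       dim = c(dim(trials[[1]])[1:2],
                               sum(vapply(trials, function(a) dim(a)[3], 0L))))
          er <- compute_ersp(arr, alpha = params$alpha,
                             n_boot = params$n_boot_ersp,
                             seed = cfg$seed + 6L + rc)
          emit(stage, sprintf("ersp_cluster%02d.tsv", rc), function(p)
            write_matrix_tsv(er$ersp, p))
          emit(stage, sprintf("ersp_cluster%02d_mask.tsv", rc), function(p)
            write_matrix_tsv(er$mask + 0, p))
        }
        assign("ersp_done", TRUE, envir = state)
      },
      connectivity = {
        ica <- need("ica", stage, "decompose")
        cl <- need("clusters", stage, "decompose")
        ev <- need("events", stage, "preprocess")
        car <- need("clean_raw", stage, "preprocess")
        keep <- get("kept_components", envir = state)
        retained <- cl$clusters$cluster[cl$clusters$retained]
        # one representative series per retained cluster: mean activation
        series <- t(vapply(retained, function(rc) {
          comps <- keep[cl$assignment == rc]
          colMeans(ica$activations[comps, , drop = FALSE])
        }, numeric(ncol(ica$activations))))
        rec_s <- recording(series, car$fs,
                           sprintf("cluster%02d", retained))
        conn <- downsample(rec_s, params$fs_mvar)
        conn <- piecewise_detrend(conn, params$detrend_window,
                                  params$detrend_step)
        ep2 <- epoch_recording(conn, ev, cycles = 2)
        sel <- select_model_order(lapply(
          seq(1, dim(ep2)[2] - round(params$mvar_window * params$fs_mvar) + 1,
              by = round(params$mvar_step * params$fs_mvar) * 2),
          function(s) ep2[, s:(s + round(params$mvar_window * params$fs_mvar) - 1), ,
                          drop = FALSE]),
          candidates = params$order_candidates, alpha = params$alpha,
          fs = params$fs_mvar)
        ep1 <- epoch_recording(conn, ev, cycles = 1)
        dtf <- sliding_window_dtf(ep1, params$fs_mvar, sel$order,
                                  params = params,
                                  n_boot = params$n_boot_connectivity,
                                  alpha = params$alpha, seed = cfg$seed + 20L)
        # continuous windows hold one realization, so the order a pooled fit
        # supports may exceed what a single window can estimate; cap it
        wl <- round(params$mvar_window * params$fs_mvar)
        p_cont <- min(sel$order, max(1L, wl %/% (nrow(series) + 1L)))
        dtfc <- sliding_window_dtf(conn$data, params$fs_mvar, p_cont,
                                   params = params, n_boot = 0)
        assign("dtf_epoched", dtf, envir = state)
        assign("dtf_continuous", dtfc, envir = state)
        assign("conn_labels", rec_s$channel_labels, envir = state)
        emit(stage, "order_selection.tsv", function(p)
          utils::write.table(sel$criteria, p, sep = "\t", quote = FALSE,
                             row.names = FALSE))
        emit(stage, "dtf_long.tsv", function(p)
          utils::write.table(dtf_long(dtf, rec_s$channel_labels), p,
                             sep = "\t", quote = FALSE, row.names = FALSE))
      },
      netstats = {
        dtf <- need("dtf_epoched", stage, "connectivity")
        dtfc <- need("dtf_continuous", stage, "connectivity")
        labels <- get("conn_labels", envir = state)
        rec <- need("recording", stage, "simulate")
        maxima <- dtf_pair_maxima(dtf, labels, condition = rec$condition)
        sup <- suprathreshold_pairs(maxima)
        fl <- fluctuation_spectrum(dtfc, nfft = params$fluct_nfft,
                                   fmax = params$fluct_fmax)
        pk <- detect_harmonic_peaks(fl, f0 = params$cadence / 60)
        emit(stage, "suprathreshold.tsv", function(p)
          utils::write.table(sup$table, p, sep = "\t", quote = FALSE,
                             row.names = FALSE))
        emit(stage, "fluctuation_spectrum.tsv", function(p)
          write_matrix_tsv(cbind(fl$freq, fl$power), p,
                           col_names = c("freq_hz", "power")))
        emit(stage, "harmonic_peaks.tsv", function(p)
          utils::write.table(pk$peaks, p, sep = "\t", quote = FALSE,
                             row.names = FALSE))
      })
    log_stage(stage, t0)
  }
  message(sprintf("[stepconn] total        %6.1f s", proc.time()[3] - t_all))
  manifest$files <- manifest$files[order(names(manifest$files))]
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
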