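## End-to-end orchestration: landmarks -> stabilization -> ROI selection ->
## per-episode magnification, trace extraction, cleaning, separation,
## source selection, reconstruction, segment linking and HR estimation.

#' Run the full heart-rate estimation pipeline on a video
#'
#' Executes every stage in order and returns one heart-rate estimate per
#' 15 s segment boundary (the linked tail of each 30 s episode). Episodes
#' whose source selection fails deliberately yield a null (NA) estimate.
#'
#' @param video a [frame_sequence].
#' @param provider landmark provider (see [detect_landmarks]).
#' @param config a `pipeline_config` (default [default_config]).
#' @param selector optional trained `source_selector`; when `NULL` the
#'   power-ratio fallback alone decides (a configuration error if
#'   `select.require_model` is set).
#' @param ablate character vector of stages to skip, any of
#'   `"stab"`, `"cluster"`, `"evm"`, `"window_pca"`, `"post"` (the last
#'   short-circuits everything after trace extraction and reads the
#'   spectral peak of the mean trace).
#' @return A `pipeline_result`: data frame `estimates`
#'   (`segment_start_s`, `hr_bpm`, `mode`, `peak_hz`) plus a `log` list of
#'   per-stage counts and the retained ROI table.
#' @export
run_pipeline <- function(video, provider, config = default_config(),
                         selector = NULL, ablate = character(0)) {
  stopifnot(inherits(video, "frame_sequence"))
  bad <- setdiff(ablate, c("stab", "cluster", "evm", "window_pca", "post"))
  if (length(bad) > 0L)
    stop("unknown ablation switch: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(selector) && isTRUE(config$select$require_model))
    stop("configuration error: select.require_model is set but no model given",
         call. = FALSE)
  fps <- video$fps
  log <- list()

  track <- detect_landmarks(video, provider)
  log$frames_detected <- sum(track$detected)

  if (!"stab" %in% ablate) {
    st <- stabilize_video(video, track,
                          alpha_slow = config$stab$alpha_slow,
                          alpha_fast = config$stab$alpha_fast,
                          theta_threshold = config$stab$theta_threshold,
                          ramp = config$stab$ramp,
                          refine = config$stab$refine,
                          n_reference = config$landmarks$n_reference)
    sv <- st$video
    canonical <- st$canonical
  } else {
    canonical <- build_canonical_reference(track,
                                           n = config$landmarks$n_reference)
    sv <- video
  }

  tris <- tessellate(canonical)
  cand <- filter_anatomical(tris)
  log$triangles_candidate <- nrow(cand)
  if (!"cluster" %in% ablate) {
    cand <- chrominance_filter(cand, sv,
                               reference_uv = c(config$roi$reference_u,
                                                config$roi$reference_v),
                               seed = config$roi$kmeans_seed,
                               nstart = config$roi$kmeans_nstart)
  }
  rois <- order_triangles(cand[cand$retained, , drop = FALSE])
  log$triangles_retained <- nrow(rois)
  if (nrow(rois) == 0L)
    stop("empty ROI: no triangles survived selection", call. = FALSE)
  mask <- roi_mask_from_triangles(rois, sv$height, sv$width)

  len <- config$episode$length_s
  ov <- config$episode$overlap_s
  dur <- sv$frame_count / fps
  starts <- if (dur < len) 0 else seq(0, dur - len, by = len - ov)

  estimates <- data.frame(segment_start_s = numeric(0), hr_bpm = numeric(0),
                          mode = character(0), peak_hz = numeric(0))
  log$episodes <- list()
  prev_rep <- NULL
  for (s in starts) {
    i0 <- round(s * fps) + 1L
    i1 <- min(round((s + len) * fps), sv$frame_count)
    sub <- frame_sequence(sv$frames[i0:i1], fps)
    magv <- if (!"evm" %in% ablate)
      magnify_video(sub, roi_mask_full = mask, alpha = config$evm$alpha,
                    level = config$evm$level, band = config$evm$band)
    else sub
    traces <- extract_traces(magv, rois)
    ep <- segment_episodes(traces, fps, length_s = len, overlap_s = ov,
                           t0 = s, triangle_ids = rois$id)[[1L]]
    res <- .process_episode(ep, config, selector, ablate)
    log$episodes[[length(log$episodes) + 1L]] <-
      c(list(start = s), res$log)
    rep15 <- link_segments(res$representative, prev_rep, fps,
                           link_s = ov)
    est <- estimate_hr(rep15, fps, band = config$evm$band,
                       pad = config$hr$pad)
    estimates <- rbind(estimates, data.frame(
      segment_start_s = s + (len - ov), hr_bpm = est$hr_bpm,
      mode = res$mode, peak_hz = est$peak_hz))
    prev_rep <- res$representative
  }
  structure(list(estimates = estimates, log = log, rois = rois,
                 config = config), class = "pipeline_result")
}

## one episode: gating, per-trace harmonic suppression, separation chain,
## selection, back-projection and alignment
.process_episode <- function(ep, config, selector, ablate) {
  fps <- ep$fps
  null_out <- function(why, mode = "null")
    list(representative = NULL, mode = mode, log = list(reason = why))
  if ("post" %in% ablate) {
    rep <- colMeans(ep$signals)
    return(list(representative = rep - mean(rep), mode = "raw",
                log = list(traces = nrow(ep$signals))))
  }
  gated <- gate_traces(ep, z_thresh = config$clean$z_thresh,
                       ratio_thresh = config$clean$ratio_thresh)
  M <- nrow(gated$signals)
  if (M == 0L) return(null_out("all traces gated out"))
  X <- gated$signals
  for (i in seq_len(M))
    X[i, ] <- as.numeric(harmonic_suppress(X[i, ], fps,
                                           sigma = config$harm$sigma,
                                           alpha = config$harm$alpha,
                                           band = config$evm$band))
  lg <- list(traces_kept = M)

  if (!"window_pca" %in% ablate && M >= 2L) {
    ws <- window_pca(X, plan = plan_windows(M, stride = config$sep$stride),
                     n_pcs = config$sep$n_pcs)
    cs <- correlation_select(ws, threshold = config$sep$corr_thresh)
    lg$window_components <- nrow(ws$components)
    lg$components_selected <- nrow(cs$components)
    gp <- global_pca(cs, max_k = config$sep$max_global)
  } else {
    gp <- global_pca(X, max_k = config$sep$max_global)
  }
  lg$global_components <- nrow(gp$components)

  if (nrow(gp$components) < 2L) {
    rep <- align_and_average(gp$components[1L, ], fps,
                             band = config$evm$band,
                             max_lag_s = config$hr$max_lag_s)
    return(list(representative = rep, mode = "degenerate", log = lg))
  }
  so <- sobi(gp, lags = seq_len(config$sep$sobi_lags))
  so <- cleanup_components(so, fps, tau = config$clean$tau,
                           band = config$evm$band,
                           sigma = config$harm$sigma,
                           alpha = config$harm$alpha)
  sel <- select_components(selector, so, fps,
                           p_threshold = config$select$p_threshold,
                           power_ratio_threshold =
                             config$select$power_ratio_threshold)
  lg$selection_mode <- sel$mode
  lg$n_selected <- length(sel$indices)
  if (sel$mode == "null") return(null_out("no physiological source", "null"))
  to <- if (!is.null(so$parent) && !is.null(so$parent$parent) &&
              identical(so$parent$parent$stage, "window_pca"))
    "traces" else "presobi"
  traces_hat <- back_project(sel, so, to = to)
  rep <- align_and_average(traces_hat, fps, band = config$evm$band,
                           max_lag_s = config$hr$max_lag_s)
  list(representative = rep, mode = sel$mode, log = lg)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d segment(s), %d ROI triangle(s)\n",
              nrow(x$estimates), nrow(x$rois)))
  print(x$estimates)
  invisible(x)
}

#' Write pipeline heart-rate estimates as CSV
#'
#' Columns `segment_start_s, hr_bpm, mode, peak_hz`; null estimates have an
#' empty `hr_bpm` field.
#'
#' @param result a `pipeline_result` (or its `estimates` data frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_hr_csv <- function(result, path) {
  df <- if (inherits(result, "pipeline_result")) result$estimates else result
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Evaluate pipeline estimates against a reference PPG
#'
#' Pairs the per-segment estimates with [process_reference] segments by
#' start time and computes the agreement metrics.
#'
#' @param result a `pipeline_result`.
#' @param ppg reference waveform: list with `x` and `fs` (e.g.
#'   `truth$ppg` or [read_reference_csv]).
#' @return list with `report` ([compute_metrics]) and the paired table.
#' @export
evaluate_against_reference <- function(result, ppg) {
  ref <- process_reference(ppg$x, fs = ppg$fs)
  est <- result$estimates
  m <- match(est$segment_start_s, ref$segment_start_s)
  ok <- !is.na(m)
  pairs <- data.frame(segment_start_s = est$segment_start_s[ok],
                      estimate = est$hr_bpm[ok],
                      reference = ref$hr_bpm[m[ok]])
  list(report = compute_metrics(pairs$estimate, pairs$reference),
       pairs = pairs)
}

#' Build a labelled synthetic source corpus for selector training
#'
#' Generates SOBI sources from random mixtures ([make_mixture]) for several
#' pseudo-subjects (each with its own pulse frequency and SNR range),
#' featurizes them and labels them against the known pulse with
#' [auto_annotate].
#'
#' @param n_subjects number of pseudo-subjects (default 10).
#' @param mixtures_per_subject mixtures per subject (default 7).
#' @param seed base RNG seed.
#' @param snr_range per-channel SNR range (dB) sampled per mixture.
#' @param duration_s,fs mixture length and rate.
#' @return list with `features` (matrix), `labels`, `subjects`.
#' @export
make_source_corpus <- function(n_subjects = 10L, mixtures_per_subject = 7L,
                               seed = 1L, snr_range = c(-5, 15),
                               duration_s = 30, fs = 20) {
  f0s <- seq(0.9, 2.5, length.out = n_subjects)
  feats <- list(); labels <- integer(0); subjects <- integer(0)
  k <- 0L
  for (s in seq_len(n_subjects)) {
    for (m in seq_len(mixtures_per_subject)) {
      k <- k + 1L
      snr <- snr_range[1L] +
        ((s * 131L + m * 17L) %% 100L) / 99 * diff(snr_range)
      mix <- make_mixture(n_channels = 10L, snr_db = snr,
                          seed = seed + 1000L * s + m,
                          duration_s = duration_s, fs = fs,
                          f0_hz = f0s[s])
      gp <- global_pca(mix$X, max_k = 10L)
      so <- sobi(gp, lags = 1:20)
      so <- cleanup_components(so, fs)
      for (i in seq_len(nrow(so$components))) {
        feats[[length(feats) + 1L]] <- featurize(so$components[i, ], fs)
        labels <- c(labels, auto_annotate(so$components[i, ], mix$pulse, fs))
        subjects <- c(subjects, s)
      }
    }
  }
  list(features = do.call(rbind, feats), labels = labels,
       subjects = subjects)
}
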