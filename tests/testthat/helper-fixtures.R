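## Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

## a clean scene: no motion, no noise, no shadow; used for trace checks
clean_scene <- function() fixture("clean_scene", function()
  make_scene(scene_config(duration_s = 30, hr_bpm = 72, drift_amp = 0,
                          jitter_sd = 0, rot_sd = 0, noise_sd = 0,
                          shadow = FALSE, lm_noise_sd = 0, seed = 101)))

## a default-condition scene (motion jitter, shadowed cheek, pixel noise)
study_scene <- function() fixture("study_scene", function()
  make_scene(scene_config(duration_s = 30, hr_bpm = 72, seed = 202)))

## labelled synthetic source corpus + trained selector
source_corpus <- function() fixture("source_corpus", function()
  make_source_corpus(n_subjects = 10, mixtures_per_subject = 7, seed = 11))

trained_selector <- function() fixture("trained_selector", function() {
  corp <- source_corpus()
  train_selector(corp$features, corp$labels, corp$subjects)
})

## tiny flat-colour video helper
flat_video <- function(n_frames, h, w, rgb, fps = 20) {
  fr <- array(rep(rgb, each = h * w), c(h, w, 3))
  frame_sequence(rep(list(fr), n_frames), fps)
}

## canonical_reference wrapper around a plain point matrix
as_canonical <- function(points, n = 15L) {
  structure(list(points = points, n_frames_used = n),
            class = "canonical_reference")
}
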