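# Shared fixture builders. Everything is generated in code; no files ship
# with the tests.

demo_transforms <- function() {
  list(oct_h = similarity_transform(1.02, 2 * pi / 180, c(8, -5),
                                    "oct_h", "faf"),
       oct_v = similarity_transform(0.98, -3 * pi / 180, c(-6, 4),
                                    "oct_v", "faf"),
       maia = similarity_transform(1.10, 5 * pi / 180, c(15, -10),
                                   "maia", "faf"))
}

demo_phantom <- function(seed = 7, render = FALSE, ...) {
  make_phantom(phantom_spec(seed = seed, transforms = demo_transforms(),
                            ...),
               render = render)
}

random_similarity <- function(src = "a", dst = "b") {
  similarity_transform(scale = runif(1, 0.5, 2),
                       rotation = runif(1, -pi + 1e-6, pi),
                       translation = runif(2, -100, 100),
                       src_frame = src, dst_frame = dst)
}

random_phantom_spec <- function(seed) {
  tf <- function(fr) similarity_transform(
    scale = runif(1, 0.9, 1.2), rotation = runif(1, -10, 10) * pi / 180,
    translation = runif(2, -30, 30), src_frame = fr, dst_frame = "faf")
  phantom_spec(seed = seed,
               true_fc = runif(2, 250, 520),
               transforms = list(oct_h = tf("oct_h"), oct_v = tf("oct_v"),
                                 maia = tf("maia")),
               eye = sample(c("OD", "OS"), 1))
}

# Full measurement chain run purely from a phantom's emitted artifacts
# (landmarks, scan lines, fixation stream) -- never from its ground truth.
recover_metrics <- function(ph, cloud_spec, ...) {
  tf_h <- estimate_transform(ph$landmarks$oct_h)
  tf_v <- estimate_transform(ph$landmarks$oct_v)
  tf_m <- estimate_transform(ph$landmarks$maia)
  fc <- intersect_scanlines(ph$scanlines$h, ph$scanlines$v, tf_h, tf_v)
  exam <- make_fixation_exam(cloud_spec, ph$truth$true_fc, ph$ruler,
                             transform = ph$truth$transforms$maia,
                             eye = ph$truth$eye)
  list(metrics = eye_metrics(exam, fc, ph$ruler, transform = tf_m, ...),
       fc = fc, exam = exam)
}
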