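# Shared phantom fixtures, generated in code and cached for the session.
# `small_spec()` is a scaled-down tibia + tray (shorter bone, smaller tray,
# coarser in-plane pixels) for fast unit tests; the full-size default
# phantom (the study-condition geometry) is reserved for the end-to-end and
# acceptance tests and cached so it is built only once.

small_spec <- function(spacing = c(0.7, 0.5, 0.7), ...) {
  phantom_spec(
    bone = list(outer_radius = 16, shell_thickness = 3, length = 45,
                taper_ratio = 0.75, lobe_amplitude = 0.12, lobe_freq = 3,
                lobe_phase = 0.6),
    implant = list(tray_radius_ml = 18, tray_radius_ap = 13,
                   tray_thickness = 3, stem_radius = 4, stem_length = 20,
                   fin_count = 4, fin_length = 12, fin_extent = 5,
                   fin_half_thickness = 1.5),
    spacing = spacing,
    ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, force(expr), envir = .fixture_cache)
  .fixture_cache[[name]]
}

# Full-size default phantom with a known pure translation, its segmentation
# and both structure registrations -- shared across end-to-end tests.
default_translation_analysis <- function() {
  cached("default_translation", {
    spec <- phantom_spec(
      implant_motion = rt_from_params(t = c(0.5, -0.3, 0.2)))
    pair <- generate_pair(spec)
    seg <- segment_pair_masks(pair$baseline)
    reg_impl <- register_rigid(pair$baseline, pair$followup, seg$implant)
    reg_bone <- register_rigid(pair$baseline, pair$followup, seg$bone)
    rel <- relative_motion(reg_bone$transform, reg_impl$transform)
    model <- implant_model(seg$implant)
    list(spec = spec, pair = pair, seg = seg, reg_impl = reg_impl,
         reg_bone = reg_bone, rel = rel, model = model,
         result = decompose_motion(rel, model))
  })
}

small_pair_translation <- function() {
  cached("small_translation", {
    spec <- small_spec(implant_motion = rt_from_params(t = c(0.5, -0.3, 0.2)))
    pair <- generate_pair(spec)
    # the scaled-down bone is intentionally shorter than the 7 cm guideline
    seg <- suppressWarnings(segment_pair_masks(pair$baseline))
    list(spec = spec, pair = pair, seg = seg)
  })
}

# Deterministic random rigid transforms for property tests.
random_rigid <- function(max_t = 2, max_deg = 2) {
  rt_from_params(runif(1, -max_deg, max_deg), runif(1, -max_deg, max_deg),
                 runif(1, -max_deg, max_deg),
                 runif(3, -max_t, max_t),
                 center = runif(3, -20, 20))
}

# Exhaustive per-point displacement maximum: the brute-force oracle for
# MTPM, deliberately written as an explicit loop over points.
mtpm_bruteforce <- function(motion, points) {
  best <- 0
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    q <- as.numeric(rt_apply(motion, p))
    best <- max(best, sqrt(sum((q - p)^2)))
  }
  best
}
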