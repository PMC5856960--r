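#' Flow waveforms
#'
#' A one-cycle flow waveform: data frame with columns `time` (s) and `flow`
#' (mL/s) plus a `period` attribute. [as_flow_waveform()] coerces plain data
#' frames and extracts the coronary branch flow from a simulated
#' `waveform_set`.
#'
#' @param time numeric time grid over one cycle, s, starting at 0.
#' @param flow numeric flow samples, mL/s.
#' @param period cycle duration, s; default `max(time)`.
#' @return object of class `flow_waveform`
#' @export
flow_waveform <- function(time, flow, period = max(time)) {
  stopifnot(length(time) == length(flow), length(time) >= 2L,
            !is.unsorted(time, strictly = TRUE), period > 0)
  structure(data.frame(time = time, flow = flow),
            class = c("flow_waveform", "data.frame"), period = period)
}

#' @param x object to coerce: a `flow_waveform`, a data frame with `time` and
#'   `flow` columns, or a `waveform_set` (its `Q_cor` channel is taken).
#' @rdname flow_waveform
#' @export
as_flow_waveform <- function(x) {
  if (inherits(x, "flow_waveform")) return(x)
  if (inherits(x, "waveform_set"))
    return(flow_waveform(x$time, x$Q_cor, attr(x, "period")))
  if (is.data.frame(x) && all(c("time", "flow") %in% names(x)))
    return(flow_waveform(x$time, x$flow,
                         attr(x, "period") %||% max(x$time)))
  stop("cannot interpret `x` as a one-cycle flow waveform")
}

#' @param run an `lpn_run` or `waveform_set`.
#' @rdname flow_waveform
#' @export
coronary_flow <- function(run) {
  if (inherits(run, "lpn_run")) run <- run$waveforms
  as_flow_waveform(run)
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Raised-cosine bump supported on [t0, t1], peak 1 at the midpoint.
.bump <- function(t, t0, t1) {
  ifelse(t >= t0 & t <= t1, 0.5 * (1 - cos(2 * pi * (t - t0) / (t1 - t0))), 0)
}

#' Fixture flow waveforms
#'
#' Generates simple one-cycle flow waveforms so the shear metrics can be
#' exercised without running the circulation model. Shapes:
#' \describe{
#'   \item{constant}{`q0` everywhere.}
#'   \item{sinusoid}{`q0 + amplitude * sin(2 pi t / period + phase)`.}
#'   \item{biphasic-coronary}{two raised-cosine humps, a small systolic one and
#'     a larger diastolic one (diastolic peak exceeds systolic peak), scaled to
#'     the requested cycle-mean flow -- the canonical left-coronary shape.}
#' }
#'
#' @param shape `"constant"`, `"sinusoid"` or `"biphasic-coronary"`.
#' @param q0 mean flow, mL/s (constant level for `"constant"`).
#' @param amplitude sinusoid amplitude, mL/s.
#' @param phase sinusoid phase, rad.
#' @param period cycle duration, s.
#' @param systolic_fraction fraction of the cycle occupied by systole
#'   (biphasic shape); default `0.3 * sqrt(period) / period`.
#' @param systolic_ratio systolic peak as a fraction of the diastolic peak,
#'   in (0, 1).
#' @param n samples over the cycle.
#' @param noise_sd standard deviation of optional seeded Gaussian jitter,
#'   mL/s.
#' @param seed RNG seed for the jitter.
#' @return a `flow_waveform`
#' @export
fixture_flow_waveform <- function(shape = c("constant", "sinusoid",
                                            "biphasic-coronary"),
                                  q0 = 1, amplitude = 0.5, phase = 0,
                                  period = 0.8,
                                  systolic_fraction = NULL,
                                  systolic_ratio = 0.45,
                                  n = 500L, noise_sd = 0, seed = 1L) {
  shape <- match.arg(shape)
  t <- seq(0, period, length.out = n + 1L)
  q <- switch(shape,
    "constant" = rep_len(q0, length(t)),
    "sinusoid" = q0 + amplitude * sin(2 * pi * t / period + phase),
    "biphasic-coronary" = {
      stopifnot(systolic_ratio > 0, systolic_ratio < 1)
      fs <- systolic_fraction %||% (0.3 * sqrt(period) / period)
      ts <- fs * period
      raw <- systolic_ratio * .bump(t, 0, ts) + .bump(t, ts, period)
      raw_mean <- .trapz(t, raw) / period
      raw * (q0 / raw_mean)
    })
  if (noise_sd > 0)
    q <- q + .with_seed(seed, stats::rnorm(length(t), 0, noise_sd))
  flow_waveform(t, q, period)
}

#' Representative clinical targets for the virtual cohort
#'
#' The fixed patient-level conditions applied to every case of the virtual
#' cohort (the cohort experiment varies geometry only, holding all circulation
#' parameters constant): heart rate 80 beats/min, pressure 110/70 mmHg, stroke
#' volume 60 mL, body surface area 1.5 m^2, coronary branch fraction 0.04 of
#' cardiac output -- a typical school-age/adolescent profile consistent with
#' the patient population carrying large coronary aneurysms.
#'
#' @return a `clinical_targets` object
#' @export
default_clinical_targets <- function() {
  clinical_targets(heart_rate = 80, systolic_pressure = 110,
                   diastolic_pressure = 70, stroke_volume = 60,
                   body_surface_area = 1.5, coronary_flow_fraction = 0.04)
}

#' Generate a synthetic patient
#'
#' Seeded draws of plausible clinical targets (heart rate uniform on 60--100
#' beats/min, systolic pressure 90--130 mmHg, diastolic 50--85 mmHg with
#' systolic > diastolic enforced, stroke volume scaled to body surface area,
#' coronary fraction 0.03--0.05) and a gently curved 3D coronary centerline of
#' stated length. Emulates the role of image-derived patient anatomy; makes no
#' claim to match any real patient. Deterministic per seed; the caller's RNG
#' state is left untouched.
#'
#' @param seed integer seed.
#' @param centerline_length_cm centerline extent, cm.
#' @param n_points centerline samples.
#' @return list with `targets` (a `clinical_targets`) and `centerline`
#'   (a `centerline_path`).
#' @export
generate_patient <- function(seed = 1L, centerline_length_cm = 12,
                             n_points = 121L) {
  .with_seed(as.integer(seed), {
    hr <- stats::runif(1, 60, 100)
    sbp <- stats::runif(1, 90, 130)
    dbp <- stats::runif(1, 50, min(85, sbp - 15))
    bsa <- stats::runif(1, 1.0, 1.9)
    sv <- 40 * bsa * stats::runif(1, 0.92, 1.08)
    f <- stats::runif(1, 0.03, 0.05)
    amp <- stats::runif(2, 0.2, 0.8)     # lateral deflection amplitudes, cm
    ph <- stats::runif(1, 0, pi)
    u <- seq(0, 1, length.out = n_points)
    pts <- cbind(x = u * centerline_length_cm,
                 y = amp[1L] * sin(1.5 * pi * u + ph),
                 z = amp[2L] * (1 - cos(pi * u)))
    list(targets = clinical_targets(hr, sbp, dbp, sv, bsa, f),
         centerline = build_centerline(pts))
  })
}

#' The virtual aneurysm cohort
#'
#' The four fusiform morph specifications of the virtual cohort experiment --
#' (a.1: D_max 8 mm, length 20 mm), (a.2: 8, 40), (b.1: 7, 40),
#' (b.2: 7, 80) -- plus an unmorphed control, sharing one baseline vessel
#' diameter and one set of clinical targets. The maximum diameter is held
#' fixed within each pair while the length (hence aspect ratio) varies, so
#' hemodynamic differences are induced purely by geometry.
#'
#' @param baseline_diameter healthy-segment diameter shared by all cases, mm.
#'   Default 3.5 mm (typical adult LAD caliber; the source anatomy's healthy
#'   caliber is not published).
#' @param s_start proximal neck position, cm from the inlet.
#' @param targets shared `clinical_targets`; default
#'   [default_clinical_targets()].
#' @param seed integer seed controlling the synthetic centerline.
#' @return object of class `cohort_spec`: list with `specs` (four
#'   `aneurysm_spec`s), `control` (degenerate spec), `baseline_diameter`,
#'   `targets`, `seed`.
#' @export
table1_cohort <- function(baseline_diameter = 3.5, s_start = 1,
                          targets = default_clinical_targets(), seed = 1L) {
  stopifnot(inherits(targets, "clinical_targets"))
  mk <- function(id, d, l) aneurysm_spec(d, l, s_start, baseline_diameter, id)
  structure(
    list(specs = list(mk("a.1", 8, 20), mk("a.2", 8, 40),
                      mk("b.1", 7, 40), mk("b.2", 7, 80)),
         control = aneurysm_spec(baseline_diameter, 1e-6, 0,
                                 baseline_diameter, "control"),
         baseline_diameter = baseline_diameter,
         targets = targets, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d morphs + 1 control, baseline %.1f mm, seed %d\n",
              length(x$specs), x$baseline_diameter, x$seed))
  for (s in x$specs) print(s)
  invisible(x)
}

#' Write all synthetic fixtures to a directory
#'
#' Emits the inputs the pipeline consumes, in the standard text formats:
#' `centerline.tsv` (x,y,z in cm), `targets.txt` (flat key = value),
#' `cohort.tsv` (one aneurysm spec per row) and the three fixture flow
#' waveforms as delimited tables.
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer seed.
#' @return invisibly, the vector of files written
#' @export
write_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pat <- generate_patient(seed)
  cohort <- table1_cohort(seed = seed)
  files <- character(0)
  f <- file.path(out_dir, "centerline.tsv")
  write_centerline(pat$centerline, f); files <- c(files, f)
  f <- file.path(out_dir, "targets.txt")
  write_flat(pat$targets, f); files <- c(files, f)
  f <- file.path(out_dir, "cohort.tsv")
  cs <- do.call(rbind, lapply(cohort$specs, function(s)
    data.frame(case_id = s$case_id, d_max_mm = s$d_max, length_mm = s$length,
               s_start_cm = s$s_start, baseline_diameter_mm = s$baseline_diameter)))
  utils::write.table(cs, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  for (shape in c("constant", "sinusoid", "biphasic-coronary")) {
    wf <- fixture_flow_waveform(shape, seed = seed)
    f <- file.path(out_dir, paste0("flow_", sub("-", "_", shape), ".tsv"))
    utils::write.table(format(as.data.frame(wf), digits = 10, trim = TRUE),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
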