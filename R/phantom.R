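# Longitudinal hyperspectral hematoma phantom generator.
#
# Each phantom sample is a radiance cube plus white/dark reference cubes and
# a ground-truth lesion mask.  Lesion pixels follow a Beer-Lambert-style
# mixing model: reflectance = skin baseline * exp(-optical depth), with the
# optical depth driven by the age-dependent chromophore weights of
# time_course_weights() and modulated by (a) a smooth super-Gaussian radial
# falloff whose radius grows then shrinks with age and (b) a smooth random
# heterogeneity field whose relative amplitude increases with age.  The age
# signal therefore lives in BOTH the mean spectrum and the spatial texture;
# spatial averaging (as in the Lasso baseline) destroys the texture channel.

# run expr with a local RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# deterministic per-subject stream seed (splittable-stream contract: adding
# subjects never perturbs existing subjects' draws)
.subject_seed <- function(master_seed, subject_index) {
  as.integer((as.numeric(master_seed) * 1009 + 7919 * subject_index) %% 2147483629)
}

#' Parameters of the hematoma phantom cohort
#'
#' Defaults emulate the study design the package targets: a cohort imaged
#' longitudinally over three weeks (daily early, then at ~48 h intervals),
#' full VIS-NIR spectral sampling, lesions that grow to a mid-course maximum
#' and then fade.  The default test-scale cohort is 8 subjects x 12 ages on
#' 48 x 48 pixel frames; all dimensions are configurable.
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param acquisition_days Ages (days) at which each subject is imaged.
#' @param image_size `(rows, cols)` of each frame in pixels.
#' @param n_bands Number of spectral bands.
#' @param range_min,range_max Spectral range in nm.
#' @param lesion_radius_min,lesion_radius_max Radius (pixels) of the lesion
#'   at age 0 and at its mid-course maximum.
#' @param radius_peak_day Age (days) at which the lesion radius peaks.
#' @param heterogeneity Relative amplitude of the age-dependent spatial
#'   heterogeneity field (0 disables the spatial age channel).
#' @param noise_sd List with `multiplicative` and `additive` Gaussian noise
#'   standard deviations applied to the radiance cube only.
#' @param visibility_threshold Minimum noise-free lesion-vs-skin spectral
#'   angle (radians) for a sample to count as visible; samples below it are
#'   dropped by [generate_cohort()] (0 disables dropout).
#' @param time_course A [time_course_params()] object.
#' @param seed Master integer seed; fully determines the cohort.
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(n_subjects = 8L,
                           acquisition_days = c(0, 1, 2, 3, 5, 6, 7, 9, 11, 13, 16, 19),
                           image_size = c(48L, 48L),
                           n_bands = 204L,
                           range_min = 400, range_max = 1000,
                           lesion_radius_min = 4,
                           lesion_radius_max = 14,
                           radius_peak_day = 6,
                           heterogeneity = 0.6,
                           noise_sd = list(multiplicative = 0.01, additive = 0.002),
                           visibility_threshold = 0,
                           time_course = time_course_params(),
                           seed = 1L) {
  errs <- character()
  if (n_subjects < 1) errs <- c(errs, "n_subjects must be positive")
  if (length(acquisition_days) < 1 || any(acquisition_days < 0)) {
    errs <- c(errs, "acquisition_days must be non-negative and non-empty")
  }
  if (length(image_size) != 2 || any(image_size < 8)) {
    errs <- c(errs, "image_size must be two values >= 8")
  }
  if (n_bands < 2) errs <- c(errs, "n_bands must be >= 2")
  if (lesion_radius_min <= 0 || lesion_radius_max < lesion_radius_min) {
    errs <- c(errs, "lesion radii must satisfy 0 < min <= max")
  }
  if (heterogeneity < 0) errs <- c(errs, "heterogeneity must be >= 0")
  if (length(errs)) stop(paste(errs, collapse = "; "), call. = FALSE)
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      acquisition_days = sort(unique(acquisition_days)),
      image_size = as.integer(image_size),
      n_bands = as.integer(n_bands),
      range_min = range_min, range_max = range_max,
      lesion_radius_min = lesion_radius_min,
      lesion_radius_max = lesion_radius_max,
      radius_peak_day = radius_peak_day,
      heterogeneity = heterogeneity,
      noise_sd = noise_sd,
      visibility_threshold = visibility_threshold,
      time_course = time_course,
      seed = as.integer(seed)
    ),
    class = "phantom_params"
  )
}

# per-subject biological/optical profile, drawn from the subject's own stream
.subject_profile <- function(params, subject_index) {
  .with_seed(.subject_seed(params$seed, subject_index), {
    rows <- params$image_size[1]; cols <- params$image_size[2]
    jit <- floor(min(rows, cols) / 10)
    tc <- params$time_course
    tau_jit <- stats::runif(1, 0.85, 1.15)
    list(
      subject_id = sprintf("S%02d", subject_index),
      melanin = stats::runif(1, 0.10, 0.50),
      depth = stats::runif(1, 0.9, 1.4),
      center = c(
        round(rows / 2) + sample(-jit:jit, 1),
        round(cols / 2) + sample(-jit:jit, 1)
      ),
      radius_scale = stats::runif(1, 0.85, 1.10),
      time_course = time_course_params(
        hb_decay_days = tc$hb_decay_days * tau_jit,
        bili_peak_day = tc$bili_peak_day * tau_jit,
        bili_amp = tc$bili_amp,
        fade_horizon_days = tc$fade_horizon_days,
        oxy_frac_day0 = tc$oxy_frac_day0,
        oxy_frac_late = tc$oxy_frac_late
      ),
      # one noise sub-seed per acquisition, pre-drawn so per-sample rendering
      # is independent of rendering order
      sample_seeds = sample.int(2147483629, length(params$acquisition_days))
    )
  })
}

# skin baseline reflectance spectrum for a subject (NIR-bright, melanin-dimmed)
.skin_baseline <- function(axis, melanin) {
  lam <- axis$centers
  base <- 0.30 + 0.45 / (1 + exp(-(lam - 620) / 60))
  base * exp(-melanin * chromophore_absorption("melanin", axis))
}

# smooth zero-mean unit-sd random field: coarse Gaussian grid, bilinear upsample
.smooth_field <- function(rows, cols, grid = 6L) {
  g <- matrix(stats::rnorm(grid * grid), grid, grid)
  gx <- seq(1, grid, length.out = rows)
  gy <- seq(1, grid, length.out = cols)
  x0 <- pmin(floor(gx), grid - 1L); y0 <- pmin(floor(gy), grid - 1L)
  fx <- gx - x0; fy <- gy - y0
  f <- matrix(0, rows, cols)
  for (j in seq_len(cols)) {
    c0 <- y0[j]; wy <- fy[j]
    col_lo <- g[x0, c0] * (1 - fx) + g[x0 + 1L, c0] * fx
    col_hi <- g[x0, c0 + 1L] * (1 - fx) + g[x0 + 1L, c0 + 1L] * fx
    f[, j] <- col_lo * (1 - wy) + col_hi * wy
  }
  f <- f - mean(f)
  s <- stats::sd(as.vector(f))
  if (s > 0) f / s else f
}

# lesion radius trajectory: grow to the mid-course peak, then shrink
.lesion_radius <- function(age, params) {
  shape <- (age / params$radius_peak_day) * exp(1 - age / params$radius_peak_day)
  params$lesion_radius_min +
    (params$lesion_radius_max - params$lesion_radius_min) * shape
}

# relative amplitude of the spatial heterogeneity channel: 0 at age 0,
# saturating with age (texture becomes mottled as the hematoma organizes)
.heterogeneity_amp <- function(age, params) {
  params$heterogeneity * age / (age + 4)
}

#' Render one phantom acquisition
#'
#' @param profile A subject profile as built internally by
#'   [generate_cohort()]; see Details.  Most users should call
#'   [generate_cohort()] and not this function directly.
#' @param age_days Hematoma age at acquisition (days).
#' @param params A [phantom_params()] object.
#' @param sample_seed Integer seed for this acquisition's noise and
#'   heterogeneity field.
#' @details The subject `profile` carries the per-subject melanin level,
#'   lesion depth factor, lesion center, radius scale and jittered
#'   time-course parameters.  `render_sample()` is deterministic given
#'   (`profile`, `age_days`, `params`, `sample_seed`).
#' @return A list of class `phantom_sample` with elements `radiance`,
#'   `white`, `dark` (arrays `bands x rows x cols`), `mask`
#'   (`rows x cols`, 0/1), `subject_id`, `age_days`, `stage`,
#'   `informative_bands`, `contrast` (noise-free lesion-vs-skin spectral
#'   angle, radians) and `axis`.
#' @export
render_sample <- function(profile, age_days, params, sample_seed = 1L) {
  stopifnot(inherits(params, "phantom_params"))
  if (age_days < 0) stop("`age_days` must be non-negative", call. = FALSE)
  rows <- params$image_size[1]; cols <- params$image_size[2]
  radius <- .lesion_radius(age_days, params) * profile$radius_scale
  if (radius > min(rows, cols) / 2 - 1) {
    stop(sprintf(
      "lesion radius %.1f px exceeds image bounds (%d x %d)",
      radius, rows, cols
    ), call. = FALSE)
  }
  axis <- make_wavelength_axis(params$n_bands, params$range_min, params$range_max)
  lam <- axis$centers
  nb <- params$n_bands

  w <- time_course_weights(age_days, profile$time_course)
  a_spec <- w["oxyhemoglobin"] * chromophore_absorption("oxyhemoglobin", axis) +
    w["deoxyhemoglobin"] * chromophore_absorption("deoxyhemoglobin", axis) +
    w["bilirubin"] * chromophore_absorption("bilirubin", axis)
  skin <- .skin_baseline(axis, profile$melanin)

  # super-Gaussian radial profile: sharp-edged lesion core, smooth shoulder
  rr <- outer(
    (seq_len(rows) - profile$center[1])^2,
    (seq_len(cols) - profile$center[2])^2, `+`
  )
  g <- exp(-(rr / radius^2)^2)
  mask <- (g >= 0.25) * 1L

  .with_seed(sample_seed, {
    amp <- .heterogeneity_amp(age_days, params)
    h <- if (amp > 0) .smooth_field(rows, cols) else matrix(0, rows, cols)
    spatial <- pmax(g * (1 + amp * h), 0) * profile$depth   # rows x cols

    # reflectance cube: bands x rows x cols
    refl <- array(0, dim = c(nb, rows, cols))
    sp_vec <- as.vector(spatial)                 # length rows*cols
    refl[] <- skin * exp(-outer(a_spec, sp_vec)) # band-major broadcast
    refl <- array(refl, dim = c(nb, rows, cols))

    # references: flat high white with a mild spectral tilt and a gentle
    # horizontal illumination gradient; flat low dark
    w_spec <- 0.92 + 0.06 * (lam - params$range_min) /
      (params$range_max - params$range_min)
    gain <- matrix(rep(1 + 0.02 * (seq_len(cols) - 1) / max(cols - 1, 1),
                       each = rows), rows, cols)
    white <- array(0, dim = c(nb, rows, cols))
    white[] <- w_spec * rep(as.vector(gain), each = nb)
    d_spec <- 0.015 + 0.005 * (lam - params$range_min) /
      (params$range_max - params$range_min)
    dark <- array(rep(d_spec, rows * cols), dim = c(nb, rows, cols))

    radiance <- dark + refl * (white - dark)
    ns <- params$noise_sd
    if (ns$multiplicative > 0 || ns$additive > 0) {
      n_tot <- length(radiance)
      radiance <- radiance *
        (1 + stats::rnorm(n_tot, sd = ns$multiplicative)) +
        stats::rnorm(n_tot, sd = ns$additive)
    }

    # noise-free lesion-core vs skin contrast (spectral angle)
    core <- mask == 1L
    contrast <- if (any(core)) {
      core_spec <- skin * exp(-a_spec * profile$depth * mean(g[core]))
      spectral_angle(core_spec, skin)
    } else 0

    informative <- which(
      chromophore_absorption("oxyhemoglobin", axis) > 0.15 |
        chromophore_absorption("deoxyhemoglobin", axis) > 0.15 |
        chromophore_absorption("bilirubin", axis) > 0.15
    )

    structure(
      list(
        radiance = radiance, white = white, dark = dark, mask = mask,
        subject_id = profile$subject_id, age_days = age_days,
        stage = assign_stage(age_days),
        informative_bands = informative,
        contrast = contrast, axis = axis
      ),
      class = "phantom_sample"
    )
  })
}

#' Generate a longitudinal phantom cohort
#'
#' Renders `n_subjects x length(acquisition_days)` samples (minus any
#' samples whose noise-free lesion contrast falls below
#' `visibility_threshold`, emulating the exclusion of acquisitions without a
#' visible hematoma).  Per-subject skin baselines, lesion placement and
#' time-course jitter induce between-subject variation.  The cohort is a
#' pure function of its parameters, including the seed, and each subject is
#' driven by its own random stream, so extending the cohort by a subject
#' never changes existing subjects' data.
#'
#' @param params A [phantom_params()] object.
#' @return A list of class `phantom_cohort`: `samples` (list of
#'   `phantom_sample`), `metadata` (data.frame with `sample_id`,
#'   `subject_id`, `age_days`, `stage`, `contrast`), `excluded` (data.frame
#'   of dropped samples with reasons), `axis`, `informative_bands`, and the
#'   generating `params`.
#' @examples
#' coh <- generate_cohort(phantom_params(
#'   n_subjects = 2, acquisition_days = c(0, 6, 18),
#'   image_size = c(24, 24), n_bands = 30, seed = 7
#' ))
#' coh$metadata
#' @export
generate_cohort <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  samples <- list()
  meta <- list()
  excluded <- list()
  axis <- make_wavelength_axis(params$n_bands, params$range_min, params$range_max)
  for (si in seq_len(params$n_subjects)) {
    prof <- .subject_profile(params, si)
    for (ai in seq_along(params$acquisition_days)) {
      age <- params$acquisition_days[ai]
      smp <- render_sample(prof, age, params, prof$sample_seeds[ai])
      sid <- sprintf("%s_D%02d", prof$subject_id, round(age))
      if (smp$contrast < params$visibility_threshold) {
        excluded[[length(excluded) + 1L]] <- data.frame(
          sample_id = sid, subject_id = prof$subject_id, age_days = age,
          reason = "no visible hematoma (contrast below threshold)",
          stringsAsFactors = FALSE
        )
        next
      }
      samples[[length(samples) + 1L]] <- smp
      meta[[length(meta) + 1L]] <- data.frame(
        sample_id = sid, subject_id = prof$subject_id, age_days = age,
        stage = smp$stage, contrast = smp$contrast, stringsAsFactors = FALSE
      )
    }
  }
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  structure(
    list(
      samples = samples,
      metadata = metadata,
      excluded = if (length(excluded)) do.call(rbind, excluded) else
        data.frame(sample_id = character(), subject_id = character(),
                   age_days = numeric(), reason = character()),
      axis = axis,
      informative_bands = if (length(samples)) samples[[1]]$informative_bands
        else integer(),
      params = params
    ),
    class = "phantom_cohort"
  )
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf(
    "<phantom_cohort> %d samples, %d subjects, %d bands, %dx%d px (%d excluded)\n",
    nrow(x$metadata), length(unique(x$metadata$subject_id)),
    x$params$n_bands, x$params$image_size[1], x$params$image_size[2],
    nrow(x$excluded)
  ))
  invisible(x)
}
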