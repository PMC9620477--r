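#' Specification for the synthetic-EEG generator
#'
#' Defines the layout and signal model of a simulated emotion-EEG cohort:
#' montage preset, sampling rate, epoch length, trials per class, class
#' set, a 1/f background, band-limited oscillators, class-dependent
#' spectral effects, white sensor noise and a master seed. The preset
#' defaults mirror the two study layouts the package emulates:
#' * `"esd"`: 62 channels, 600 Hz, 2 s epochs, five valence classes
#'   (EN, MN, neutral, MP, EP), 30 trials per class.
#' * `"deap"`: 32 channels, 128 Hz, 60 s trials, high/low valence classes
#'   with continuous 1-9 valence/arousal ratings.
#'
#' @param preset `"esd"` or `"deap"`; sets montage, fs, epoch length,
#'   classes and band scheme defaults.
#' @param fs,epoch_length Sampling rate (Hz) and epoch length (s).
#' @param n_subjects Number of subjects in the cohort.
#' @param n_trials_per_class Trials per class per subject.
#' @param classes Character vector of class names.
#' @param background_alpha 1/f^alpha spectral exponent of the background.
#' @param background_amp Background RMS amplitude (microvolts).
#' @param oscillators Data frame `(band, f_low, f_high, amp, channels)`;
#'   `channels` is a list-column of label vectors (or `"all"`).
#' @param effects Data frame `(class, band, channels, factor)` giving a
#'   multiplicative *power* factor applied to the named oscillator on the
#'   named channels for epochs of that class; `channels` a list-column.
#' @param shared_phase_pairs Optional two-column matrix of channel labels
#'   whose oscillator phases are locked within an epoch (ground truth for
#'   phase-locking / coherence features).
#' @param noise_sd White-noise standard deviation (microvolts).
#' @param seed Master seed; with the subject index it fully determines the
#'   output.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(preset = c("esd", "deap"),
                           fs = NULL, epoch_length = NULL,
                           n_subjects = 10,
                           n_trials_per_class = 30,
                           classes = NULL,
                           background_alpha = 1.0,
                           background_amp = 8,
                           oscillators = NULL,
                           effects = NULL,
                           shared_phase_pairs = NULL,
                           noise_sd = 2,
                           seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "esd") {
    montage <- montage_preset("esd")
    bands <- band_scheme_preset("esd6")
    if (is.null(fs)) fs <- 600
    if (is.null(epoch_length)) epoch_length <- 2
    if (is.null(classes)) classes <- c("EN", "MN", "neutral", "MP", "EP")
  } else {
    montage <- montage_preset("deap")
    bands <- band_scheme_preset("deap4")
    if (is.null(fs)) fs <- 128
    if (is.null(epoch_length)) epoch_length <- 60
    if (is.null(classes)) classes <- c("high", "low")
  }
  if (is.null(oscillators)) {
    oscillators <- tibble::tibble(
      band = bands$band,
      f_low = bands$f_low, f_high = bands$f_high,
      amp = c(4, 3.5, 4.5, 2.5, 1.5, 1)[seq_len(nrow(bands))],
      channels = rep(list("all"), nrow(bands))
    )
  }
  if (is.null(effects)) {
    effects <- tibble::tibble(class = character(0), band = character(0),
                              channels = list(), factor = numeric(0))
  } else {
    effects <- tibble::as_tibble(effects)
    if (any(effects$factor <= 0)) stop("generator_spec: effect power factors must be > 0")
  }
  structure(
    list(preset = preset, montage = montage, bands = bands, fs = fs,
         epoch_length = epoch_length, n_subjects = n_subjects,
         n_trials_per_class = n_trials_per_class, classes = classes,
         background_alpha = background_alpha, background_amp = background_amp,
         oscillators = tibble::as_tibble(oscillators), effects = effects,
         shared_phase_pairs = shared_phase_pairs,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "generator_spec"
  )
}

# 1/f^alpha noise of length n with target RMS amp, via spectral shaping of
# white Gaussian noise. Uses the current RNG stream.
pink_noise <- function(n, alpha, amp) {
  pink_noise_multi(n, 1L, alpha, amp)[, 1]
}

# All channels of one epoch in a single mvfft pass: [n x nch].
pink_noise_multi <- function(n, nch, alpha, amp) {
  W <- stats::mvfft(matrix(rnorm(n * nch), n, nch))
  f <- c(1, seq_len(n - 1))                  # avoid DC blow-up
  f <- pmin(f, n - f + 1)                    # symmetric frequency index
  W <- W * f^(-alpha / 2)
  x <- Re(stats::mvfft(W, inverse = TRUE)) / n
  x <- sweep(x, 2, colMeans(x))
  s <- apply(x, 2, sd)
  s[s == 0] <- 1
  sweep(x, 2, amp / s, `*`)
}

#' Generate one subject's synthetic epochs
#'
#' Each epoch is the sum of a 1/f background, band-limited sinusoidal
#' oscillators with per-epoch random phase (and per-epoch frequency drawn
#' uniformly inside the band), and white noise. For epochs of class `c`,
#' the amplitude of an oscillator named in `spec$effects` is multiplied by
#' `sqrt(factor)` on the listed channels, so band *power* scales by
#' `factor`. Output is bit-reproducible given `(spec$seed, subject_index)`.
#'
#' @param spec A [generator_spec].
#' @param subject_index Integer subject number (1-based).
#' @return An [epoch_set] with `n_trials_per_class` epochs per class.
#' @examples
#' sp <- generator_spec("esd", n_trials_per_class = 2, epoch_length = 0.5)
#' es <- generate_subject(sp, 1)
#' table(es$labels)
#' @export
generate_subject <- function(spec, subject_index) {
  stopifnot(inherits(spec, "generator_spec"))
  seed <- (spec$seed + 10007L * as.integer(subject_index)) %% 2147483647L
  withr_seed <- .Random.seed_exists()
  old <- if (withr_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (withr_seed) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  mont <- spec$montage
  labs <- mont$channel_labels
  nch <- length(labs)
  nsamp <- round(spec$fs * spec$epoch_length)
  classes <- rep(spec$classes, each = spec$n_trials_per_class)
  nep <- length(classes)
  tt <- (seq_len(nsamp) - 1) / spec$fs
  arr <- array(0, c(nep, nch, nsamp))

  osc <- spec$oscillators
  eff <- spec$effects
  shared <- spec$shared_phase_pairs
  for (e in seq_len(nep)) {
    cls <- classes[e]
    arr[e, , ] <- t(pink_noise_multi(nsamp, nch, spec$background_alpha,
                                     spec$background_amp))
    for (o in seq_len(nrow(osc))) {
      osc_ch <- osc$channels[[o]]
      if (identical(osc_ch, "all") || identical(osc_ch, list("all"))) osc_ch <- labs
      idx <- match(osc_ch, labs)
      f0 <- runif(1, osc$f_low[o], osc$f_high[o])
      # per-channel random phase, optionally locked within shared pairs
      phases <- runif(nch, 0, 2 * pi)
      if (!is.null(shared)) {
        for (p in seq_len(nrow(shared))) {
          i1 <- match(shared[p, 1], labs); i2 <- match(shared[p, 2], labs)
          phases[i2] <- phases[i1]
        }
      }
      for (ch in idx) {
        a <- osc$amp[o]
        if (nrow(eff)) {
          hit <- eff$class == cls & eff$band == osc$band[o] &
            vapply(eff$channels, function(cc) labs[ch] %in% cc, logical(1))
          if (any(hit)) a <- a * sqrt(prod(eff$factor[hit]))
        }
        arr[e, ch, ] <- arr[e, ch, ] + a * sqrt(2) * sin(2 * pi * f0 * tt + phases[ch])
      }
    }
    m <- arr[e, , ] + matrix(rnorm(nch * nsamp, sd = spec$noise_sd), nch, nsamp)
    arr[e, , ] <- m - rowMeans(m)  # epochs are generated baseline-free
  }
  epoch_set(arr, fs = spec$fs, montage = mont, labels = classes,
            subject_id = sprintf("S%02d", subject_index))
}

.Random.seed_exists <- function() exists(".Random.seed", envir = globalenv())

#' Generate a DEAP-like trial set with valence/arousal ratings
#'
#' Wraps [generate_subject()] for the two-class high/low valence layout
#' and attaches continuous 1-9 ratings: valence is drawn above 5 for
#' `high` trials and below 5 for `low` trials; a configurable fraction of
#' trials receives an arousal rating inside the window `[3.5, 6]` used by
#' the sample-selection protocol, the rest outside it.
#'
#' @param spec A [generator_spec] with `preset = "deap"` (classes
#'   `high`/`low`).
#' @param subject_index Integer subject number.
#' @param arousal_fraction Fraction of trials whose arousal falls inside
#'   `[3.5, 6]`.
#' @return An [epoch_set] with a `ratings` tibble.
#' @export
generate_deap_like <- function(spec, subject_index = 1, arousal_fraction = 1.0) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!setequal(spec$classes, c("high", "low"))) {
    stop("generate_deap_like: spec classes must be {high, low}")
  }
  es <- generate_subject(spec, subject_index)
  seed <- (spec$seed + 10007L * as.integer(subject_index) + 7919L) %% 2147483647L
  old <- if (.Random.seed_exists()) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  nep <- n_epochs(es)
  valence <- ifelse(es$labels == "high", runif(nep, 5.5, 9), runif(nep, 1, 4.5))
  inside <- runif(nep) < arousal_fraction
  arousal <- ifelse(inside, runif(nep, 3.5, 6),
                    ifelse(runif(nep) < 0.5, runif(nep, 1, 3.4), runif(nep, 6.1, 9)))
  es$ratings <- tibble::tibble(valence = valence, arousal = arousal)
  es
}

#' Reference synthetic cohort with a graded high-gamma valence effect
#'
#' The package's canonical ground-truth cohort for electrode-recovery and
#' classification studies: the 62-channel, 600 Hz, 2 s-epoch layout with
#' 30 trials per valence class, and a class-graded high-gamma power
#' effect injected at four frontal/temporal electrodes (F3, F4, T7, T8).
#' The power factors follow a geometric ladder across the five valence
#' classes (EN 3.0, MN 1.75, neutral 1.0, MP 0.57, EP 0.33), i.e. a
#' factor-3 contrast between the extreme-negative class and neutral,
#' emulating the monotone high-frequency valence effect the emotion-EEG
#' literature reports.
#'
#' The effect-carrying oscillator amplitude is raised to 3 microvolts so
#' the injected rhythm is detectable above the 1/f background's in-band
#' power at single-epoch level (a buried oscillator would make every
#' downstream recovery question vacuous).
#'
#' @param n_subjects Cohort size (default 10).
#' @param seed Master seed.
#' @param effect_channels Electrodes carrying the effect.
#' @param effect_band Band carrying the effect (default `"high_gamma"`).
#' @param factors Named per-class power factors.
#' @param effect_amp Base amplitude (microvolts) of the effect-band
#'   oscillator (default 3).
#' @return A [generator_spec].
#' @export
esd_recovery_spec <- function(n_subjects = 10, seed = 1L,
                              effect_channels = c("F3", "F4", "T7", "T8"),
                              effect_band = "high_gamma",
                              factors = c(EN = 3, MN = 1.75, neutral = 1,
                                          MP = 0.57, EP = 0.33),
                              effect_amp = 3) {
  bands <- band_scheme_preset("esd6")
  oscillators <- tibble::tibble(
    band = bands$band,
    f_low = bands$f_low, f_high = bands$f_high,
    amp = c(4, 3.5, 4.5, 2.5, 1.5, 1),
    channels = rep(list("all"), nrow(bands)))
  oscillators$amp[oscillators$band == effect_band] <- effect_amp
  effects <- tibble::tibble(
    class = names(factors),
    band = effect_band,
    channels = rep(list(effect_channels), length(factors)),
    factor = unname(factors))
  generator_spec("esd", n_subjects = n_subjects, seed = seed,
                 oscillators = oscillators, effects = effects)
}

#' Generate a whole synthetic cohort
#'
#' @param spec A [generator_spec].
#' @return A list of [epoch_set]s, one per subject.
#' @export
generate_cohort <- function(spec) {
  lapply(seq_len(spec$n_subjects), function(i) generate_subject(spec, i))
}
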