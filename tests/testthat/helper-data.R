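# Small fixtures built in code.

# Minimal 4-channel montage with two symmetric pairs.
tiny_montage <- function() {
  montage(c("F3", "F4", "T7", "T8"),
          rbind(c("F3", "F4"), c("T7", "T8")),
          c(F3 = "frontal", F4 = "frontal", T7 = "temporal", T8 = "temporal"))
}

# Deterministic random epoch_set on the tiny montage.
tiny_epochs <- function(n_epochs = 4, n_samples = 256, fs = 128, seed = 42,
                        labels = NULL) {
  set.seed(seed)
  if (is.null(labels)) labels <- rep(c("A", "B"), length.out = n_epochs)
  epoch_set(array(rnorm(n_epochs * 4 * n_samples), c(n_epochs, 4, n_samples)),
            fs = fs, montage = tiny_montage(), labels = labels)
}

five_class_labels <- function(n_per = 30) {
  rep(c("EN", "MN", "neutral", "MP", "EP"), each = n_per)
}

# A small ESD-like generator spec (few trials, short epochs) for fast tests.
small_esd_spec <- function(n_trials = 3, epoch_length = 0.5, seed = 7, ...) {
  generator_spec("esd", n_trials_per_class = n_trials,
                 epoch_length = epoch_length, seed = seed, ...)
}
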