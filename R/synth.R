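#' Synthetic FMG generator configuration
#'
#' Describes a virtual gesture-recognition experiment: per-gesture channel
#' amplitude templates (volts, within the 0--3.3 V voltage-divider range),
#' additive between-subject template jitter, within-window AR(1) sensor
#' noise, and a tunable ambiguity that pulls confusable gestures' templates
#' toward their group centroid.
#'
#' Default magnitudes describe a realistic wrist-band recording: usable FSR
#' amplitudes concentrated mid-range (`template_range`), rep-to-rep signal
#' fluctuation of a few tenths of a volt from inconsistent contraction force
#' (`noise_sd`, correlated over ~60 ms at 100 Hz via `ar_coeff`), and
#' anatomical between-subject offsets of similar size (`subject_sd`).
#'
#' @param n_classes Number of gestures, `>= 2`.
#' @param n_channels Number of FSR channels (default 8).
#' @param n_subjects Subjects per class (default 10).
#' @param reps_per_subject Repetitions of each gesture per subject (default 10).
#' @param rate Sampling rate in Hz (default 100).
#' @param window_seconds Window length in seconds (default 1).
#' @param subject_sd SD of the additive per-subject template jitter, volts.
#' @param noise_sd Innovation SD of the AR(1) within-window noise, volts.
#' @param ar_coeff AR(1) coefficient, `0 <= ar_coeff < 1`.
#' @param ambiguity In `[0, 1]`: 0 leaves templates at their drawn spacing,
#'   1 collapses each confusable group onto its centroid.
#' @param confusable List of integer vectors; gestures within a vector are
#'   mutually confusable.
#' @param dynamic Integer ids of dynamic gestures (emulated as
#'   amplitude-boosted static templates).
#' @param noise_channels Channel ids carrying no gesture information (their
#'   template entries are identical across classes).
#' @param template_range Per-channel uniform draw range for templates, volts.
#' @param d_min Minimum pairwise Euclidean template distance before the
#'   ambiguity shrink.
#' @param dynamic_boost Amplitude factor for dynamic gestures.
#' @param class_names Optional gesture names.
#' @param seed Integer seed; generation is byte-deterministic given the
#'   config.
#' @return A list of class `gen_config`.
#' @export
gen_config <- function(n_classes, n_channels = 8, n_subjects = 10,
                       reps_per_subject = 10, rate = 100, window_seconds = 1,
                       subject_sd = 0.25, noise_sd = 0.25, ar_coeff = 0.6,
                       ambiguity = 0.3, confusable = list(), dynamic = integer(0),
                       noise_channels = integer(0),
                       template_range = c(1.2, 2.1), d_min = 0.6,
                       dynamic_boost = 1.2, class_names = NULL, seed = 1) {
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (ar_coeff < 0 || ar_coeff >= 1) stop("ar_coeff must lie in [0, 1)")
  if (ambiguity < 0 || ambiguity > 1) stop("ambiguity must lie in [0, 1]")
  if (any(unlist(confusable) > n_classes)) stop("confusable ids out of range")
  structure(
    list(n_classes = as.integer(n_classes), n_channels = as.integer(n_channels),
         n_subjects = as.integer(n_subjects),
         reps_per_subject = as.integer(reps_per_subject),
         rate = rate, window_seconds = window_seconds,
         subject_sd = subject_sd, noise_sd = noise_sd, ar_coeff = ar_coeff,
         ambiguity = ambiguity, confusable = confusable,
         dynamic = as.integer(dynamic), noise_channels = as.integer(noise_channels),
         template_range = template_range, d_min = d_min,
         dynamic_boost = dynamic_boost, class_names = class_names,
         seed = as.integer(seed)),
    class = "gen_config"
  )
}

#' Ambiguity-tier presets
#'
#' Three gesture sets mirroring increasing confusability: `"low"` -- the
#' nine digit signs with mutual similarity only among 6, 7, 8, 9; `"middle"`
#' -- ten letters A--J with similar hand shapes for A/C/E and G/H and one
#' dynamic sign (J); `"high"` -- twenty signs with five nearly identical
#' pairs (B/4, M/N, U/2, 6/W, S/T) and a dynamic Z.
#'
#' @param name One of `"low"`, `"middle"`, `"high"`.
#' @param ... Overrides passed on to [gen_config()].
#' @return A `gen_config`.
#' @export
fmg_preset <- function(name = c("low", "middle", "high"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    low = list(
      n_classes = 9, class_names = as.character(1:9),
      confusable = list(6:9), dynamic = integer(0), ambiguity = 0.30
    ),
    middle = list(
      n_classes = 10, class_names = LETTERS[1:10],
      confusable = list(c(1L, 3L, 5L), c(7L, 8L)), dynamic = 10L,
      ambiguity = 0.45
    ),
    high = list(
      n_classes = 20,
      class_names = c("B", "4", "M", "N", "U", "2", "6", "W", "S", "T",
                      "A", "C", "E", "G", "H", "I", "K", "L", "O", "Z"),
      confusable = list(c(1L, 2L), c(3L, 4L), c(5L, 6L), c(7L, 8L), c(9L, 10L)),
      dynamic = 20L, ambiguity = 0.60
    )
  )
  do.call(gen_config, utils::modifyList(base, list(...)))
}

#' Draw per-gesture channel-amplitude templates
#'
#' Templates are placed sequentially, uniform per channel over
#' `template_range`, rejecting candidates closer than `d_min` (Euclidean) to
#' any accepted template. Dynamic gestures are amplitude-boosted, then each
#' confusable group is shrunk toward its centroid by the ambiguity factor
#' (`ambiguity = 1` makes group members identical). Noise channels are
#' finally set to a common mid-range constant for every class.
#'
#' @param cfg A [gen_config()].
#' @return Numeric `n_classes x n_channels` matrix of mean activations,
#'   entries within `[0, 3.3]`.
#' @export
make_templates <- function(cfg) {
  stopifnot(inherits(cfg, "gen_config"))
  with_seed(cfg$seed, {
    mu <- matrix(NA_real_, cfg$n_classes, cfg$n_channels)
    for (cl in seq_len(cfg$n_classes)) {
      placed <- FALSE
      for (try in seq_len(5000L)) {
        cand <- stats::runif(cfg$n_channels, cfg$template_range[1], cfg$template_range[2])
        if (cl == 1L ||
            min(sqrt(colSums((t(mu[seq_len(cl - 1L), , drop = FALSE]) - cand)^2))) >= cfg$d_min) {
          mu[cl, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("infeasible template spacing for requested n_classes/n_channels/d_min")
    }
    for (cl in cfg$dynamic) mu[cl, ] <- pmin(mu[cl, ] * cfg$dynamic_boost, 3.3)
    for (grp in cfg$confusable) {
      centroid <- colMeans(mu[grp, , drop = FALSE])
      for (cl in grp) {
        mu[cl, ] <- centroid + (1 - cfg$ambiguity) * (mu[cl, ] - centroid)
      }
    }
    if (length(cfg$noise_channels)) mu[, cfg$noise_channels] <- 1.65
    mu
  })
}

# AR(1) noise of length T with innovation sd `sd`, started from the
# stationary distribution so the window is stationary throughout.
ar1_noise <- function(T, sd, ar) {
  if (sd == 0) return(numeric(T))
  innov <- stats::rnorm(T, 0, sd)
  init <- stats::rnorm(1, 0, sd / sqrt(1 - ar^2))
  as.numeric(stats::filter(innov, ar, method = "recursive", init = init))
}

#' Generate synthetic FMG windows
#'
#' For each class and subject, the class template is jittered once by
#' `N(0, subject_sd)` per channel; each repetition is then an AR(1) process
#' around that subject-level mean with innovation SD `noise_sd`. Classes are
#' exactly balanced (`n_subjects * reps_per_subject` windows per class) and
#' the output is fully deterministic given the config.
#'
#' @param cfg A [gen_config()].
#' @return List with `windows` (list of [signal_window()]) and `manifest`
#'   (data frame with `window_id`, `class`, `class_name`, `subject`, `rep`).
#' @export
generate_fmg <- function(cfg) {
  stopifnot(inherits(cfg, "gen_config"))
  mu <- make_templates(cfg)
  T_len <- max(2L, as.integer(round(cfg$rate * cfg$window_seconds)))
  names <- if (is.null(cfg$class_names)) as.character(seq_len(cfg$n_classes)) else cfg$class_names
  windows <- vector("list", cfg$n_classes * cfg$n_subjects * cfg$reps_per_subject)
  man <- vector("list", length(windows))
  with_seed(cfg$seed + 1L, {
    w <- 0L
    for (cl in seq_len(cfg$n_classes)) {
      for (s in seq_len(cfg$n_subjects)) {
        subj_mu <- mu[cl, ] + stats::rnorm(cfg$n_channels, 0, cfg$subject_sd)
        for (r in seq_len(cfg$reps_per_subject)) {
          w <- w + 1L
          noise <- vapply(seq_len(cfg$n_channels), function(ch)
            ar1_noise(T_len, cfg$noise_sd, cfg$ar_coeff), numeric(T_len))
          samples <- sweep(noise, 2L, subj_mu, "+")
          windows[[w]] <- signal_window(samples, rate = cfg$rate, label = cl)
          man[[w]] <- data.frame(window_id = w, class = cl,
                                 class_name = names[cl], subject = s, rep = r)
        }
      }
    }
  })
  list(windows = windows, manifest = do.call(rbind, man))
}

#' One-call synthetic feature set
#'
#' Runs [generate_fmg()] and [windows_to_features()] back to back.
#'
#' @param cfg A [gen_config()].
#' @return A [labeled_feature_set()].
#' @export
generate_fmg_features <- function(cfg) {
  gen <- generate_fmg(cfg)
  windows_to_features(gen$windows, cfg$class_names)
}
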