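#' Construct a signal window
#'
#' A window of multi-channel FMG samples: `T` time samples by `C` channels
#' (volts), with the sampling rate and the gesture label of the trial.
#'
#' @param samples Numeric `T x C` matrix, `T >= 2`, no missing values.
#' @param rate Sampling rate in Hz (default 100).
#' @param label Integer gesture id.
#' @return A list of class `signal_window`.
#' @export
signal_window <- function(samples, rate = 100, label = NA_integer_) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2) stop("a window needs at least 2 time samples")
  if (ncol(samples) < 1) stop("a window needs at least 1 channel")
  if (anyNA(samples)) stop("window contains missing samples")
  structure(list(samples = samples, rate = rate, label = as.integer(label)),
            class = "signal_window")
}

#' Six basic statistical features per channel
#'
#' For each channel, in fixed order: min, max, RMS, variance, standard
#' deviation, mean. Variance and SD use the sample (`N - 1`) convention;
#' RMS is `sqrt(mean(x^2))`. Channel blocks are concatenated in channel
#' order, so `C` channels give a vector of length `6 C` (8 FMG channels
#' give the canonical 48 features).
#'
#' @param window A [signal_window()].
#' @return Named numeric vector of length `6 * C`, names `ch<i>_<stat>`.
#' @export
extract_features <- function(window) {
  stopifnot(inherits(window, "signal_window"))
  S <- window$samples
  stats_one <- function(x) {
    v <- stats::var(x)
    c(min = min(x), max = max(x), rms = sqrt(mean(x^2)),
      var = v, std = sqrt(v), mean = mean(x))
  }
  blocks <- lapply(seq_len(ncol(S)), function(ch) {
    b <- stats_one(S[, ch])
    names(b) <- paste0("ch", ch, "_", names(b))
    b
  })
  unlist(blocks)
}

#' Feature matrix from a list of windows
#'
#' @param windows List of [signal_window()] objects with labels set.
#' @param class_names Optional class names.
#' @return A [labeled_feature_set()] with one row per window.
#' @export
windows_to_features <- function(windows, class_names = NULL) {
  X <- t(vapply(windows, extract_features,
                numeric(6 * ncol(windows[[1]]$samples))))
  y <- vapply(windows, function(w) w$label, integer(1))
  labeled_feature_set(X, y, class_names)
}

#' Min--max normalization
#'
#' `minmax_fit` learns per-column minima and maxima from the training rows
#' only; `minmax_apply` maps `x' = (x - min) / (max - min)`. Constant
#' columns map to 0. Values outside the training range are not clamped, so
#' test features may fall outside `[0, 1]`.
#'
#' @param train Numeric training feature matrix (non-empty).
#' @return For `minmax_fit`, a list with `mins` and `maxs`.
#' @export
minmax_fit <- function(train) {
  train <- as.matrix(train)
  if (nrow(train) == 0 || ncol(train) == 0) stop("empty training matrix")
  list(mins = apply(train, 2L, min), maxs = apply(train, 2L, max))
}

#' @rdname minmax_fit
#' @param X Matrix to normalize with the fitted parameters.
#' @param params Fit object from `minmax_fit`.
#' @export
minmax_apply <- function(X, params) {
  X <- as.matrix(X)
  span <- params$maxs - params$mins
  out <- sweep(X, 2L, params$mins, "-")
  out <- sweep(out, 2L, ifelse(span > 0, span, 1), "/")
  out[, span == 0] <- 0
  out
}

#' Read raw multi-channel signal CSV plus trial manifest into windows
#'
#' The signal CSV has columns `t, ch1..chC`; the manifest CSV has columns
#' `trial_id, start_row, end_row, label` delimiting one window per gesture
#' repetition (no automatic segmentation is attempted).
#'
#' @param signal_path Path to the raw signal CSV.
#' @param manifest_path Path to the trial manifest CSV.
#' @param rate Sampling rate in Hz.
#' @return List of [signal_window()] objects.
#' @export
read_signal_csv <- function(signal_path, manifest_path, rate = 100) {
  sig <- utils::read.csv(signal_path)
  man <- utils::read.csv(manifest_path)
  ch_cols <- grep("^ch[0-9]+$", names(sig), value = TRUE)
  if (!length(ch_cols)) stop("signal CSV must contain ch1..chC columns")
  lapply(seq_len(nrow(man)), function(i) {
    rows <- man$start_row[i]:man$end_row[i]
    signal_window(as.matrix(sig[rows, ch_cols, drop = FALSE]),
                  rate = rate, label = man$label[i])
  })
}

#' Write windows as a raw signal CSV plus trial manifest
#'
#' Inverse of [read_signal_csv()]; windows are stacked in order with a
#' global time column `t` (seconds).
#'
#' @param windows List of [signal_window()] objects.
#' @param signal_path,manifest_path Output paths.
#' @return Invisibly, a list with both paths.
#' @export
write_signal_csv <- function(windows, signal_path, manifest_path) {
  C <- ncol(windows[[1]]$samples)
  rate <- windows[[1]]$rate
  mats <- lapply(windows, function(w) w$samples)
  all <- do.call(rbind, mats)
  colnames(all) <- paste0("ch", seq_len(C))
  df <- data.frame(t = (seq_len(nrow(all)) - 1) / rate, all)
  ends <- cumsum(vapply(mats, nrow, integer(1)))
  man <- data.frame(
    trial_id = seq_along(windows),
    start_row = c(1L, utils::head(ends, -1) + 1L),
    end_row = ends,
    label = vapply(windows, function(w) w$label, integer(1))
  )
  utils::write.csv(df, signal_path, row.names = FALSE)
  utils::write.csv(man, manifest_path, row.names = FALSE)
  invisible(list(signal = signal_path, manifest = manifest_path))
}
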