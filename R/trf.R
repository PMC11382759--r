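#' Lag axis for temporal response functions
#'
#' The set of latencies at which the forward model relates the speech
#' features to the neural response.  Defaults: -20 ms to 120 ms in 1 ms
#' steps (141 lags), so that pre-stimulus lags provide a built-in sanity
#' band.
#'
#' @param tau_min_ms minimal latency in ms (default -20).
#' @param tau_max_ms maximal latency in ms (default 120).
#' @param step_ms latency increment in ms (default 1).
#' @return an object of class `lag_axis` with fields `lags_ms` and
#'   `n_lags`.
#' @export
lag_axis <- function(tau_min_ms = -20, tau_max_ms = 120, step_ms = 1) {
  if (!(tau_min_ms < tau_max_ms)) stop("tau_min_ms must be below tau_max_ms")
  if (step_ms <= 0) stop("step_ms must be positive")
  lags <- seq(tau_min_ms, tau_max_ms, by = step_ms)
  structure(list(tau_min_ms = tau_min_ms, tau_max_ms = tau_max_ms,
                 step_ms = step_ms, lags_ms = lags, n_lags = length(lags)),
            class = "lag_axis")
}

#' @export
print.lag_axis <- function(x, ...) {
  cat("<lag_axis> ", x$tau_min_ms, "..", x$tau_max_ms, " ms, step ",
      x$step_ms, " ms (", x$n_lags, " lags)\n", sep = "")
  invisible(x)
}

# Lags in samples at a given rate; the step must land on the sample grid.
lags_in_samples <- function(axis, fs) {
  lags <- axis$lags_ms / 1000 * fs
  if (max(abs(lags - round(lags))) > 1e-6)
    stop("lag step is not an integer number of samples at ", fs, " Hz")
  as.integer(round(lags))
}

#' Build the lagged design matrix of the forward model
#'
#' Column block 1 holds the fundamental waveform delayed by each lag,
#' block 2 the envelope modulation likewise: column `k` of a block
#' contains `x[t - tau_k]`, with out-of-range samples zero-filled.  The
#' model `y_t = sum_tau (alpha_tau f_{t-tau} + beta_tau e_{t-tau})` is then
#' a single matrix product of this design with the stacked coefficients
#' `c(alpha, beta)`.
#'
#' @param features a [stimulus_features] object (already aligned with the
#'   response).
#' @param axis a [lag_axis]; its step must be an integer number of samples
#'   at the feature rate.
#' @return numeric matrix, time x (2 * n_lags), with column names
#'   `f@<lag>` and `e@<lag>`.
#' @export
build_design <- function(features, axis = lag_axis()) {
  stopifnot(inherits(features, "stimulus_features"),
            inherits(axis, "lag_axis"))
  lags <- lags_in_samples(axis, features$fs)
  n <- length(features$fundamental)
  lag_block <- function(x) {
    m <- matrix(0, n, length(lags))
    for (k in seq_along(lags)) {
      tau <- lags[k]
      if (tau >= 0) {
        if (tau < n) m[(tau + 1L):n, k] <- x[1L:(n - tau)]
      } else {
        if (-tau < n) m[1L:(n + tau), k] <- x[(1L - tau):n]
      }
    }
    m
  }
  out <- cbind(lag_block(features$fundamental), lag_block(features$envelope))
  colnames(out) <- c(paste0("f@", axis$lags_ms), paste0("e@", axis$lags_ms))
  attr(out, "lag_axis") <- axis
  attr(out, "fs") <- features$fs
  out
}

#' Fit temporal response functions by ridge regression
#'
#' Per channel, minimizes `||y - X w||^2 + lambda ||w||^2` in closed form
#' through a Cholesky factorization of `X'X + lambda I`.  The factorization
#' is shared across channels, so fitting many responses to the same
#' stimulus costs little more than fitting one.
#'
#' @param design design matrix from [build_design()] (time x 2 n_lags).
#' @param response a [neural_recording] or a numeric matrix/vector with
#'   time running along columns (channels x time) or a time-length vector.
#' @param lambda ridge penalty (default 1, applied to the raw,
#'   unstandardized features).
#' @param xtx optionally, a precomputed `crossprod(design)` to reuse across
#'   calls.
#' @return an object of class `trf_model` with fields `alpha` and `beta`
#'   (lags x channels), `lag_axis`, `lambda`, `fs`.
#' @export
fit_ridge <- function(design, response, lambda = 1, xtx = NULL) {
  if (lambda < 0) stop("lambda must be nonnegative")
  axis <- attr(design, "lag_axis")
  fs <- attr(design, "fs")
  if (inherits(response, "neural_recording")) {
    fs <- response$fs
    y <- t(response$samples)
  } else if (is.matrix(response)) {
    y <- if (nrow(response) == nrow(design)) response else t(response)
  } else {
    y <- matrix(response, ncol = 1L)
  }
  if (nrow(y) != nrow(design))
    stop("response length (", nrow(y), ") does not match design rows (",
         nrow(design), ")")
  p <- ncol(design)
  xtx <- xtx %||% crossprod(design)
  if (all(xtx == 0)) stop("degenerate all-zero design")
  R <- chol(xtx + diag(lambda, p))
  w <- backsolve(R, forwardsolve(t(R), crossprod(design, y)))
  n_lags <- p %/% 2L
  structure(list(alpha = w[seq_len(n_lags), , drop = FALSE],
                 beta = w[n_lags + seq_len(n_lags), , drop = FALSE],
                 lag_axis = axis %||% lag_axis(), lambda = lambda, fs = fs),
            class = "trf_model")
}

#' @export
print.trf_model <- function(x, ...) {
  cat("<trf_model> ", nrow(x$alpha), " lags x ", ncol(x$alpha),
      " channel(s), lambda = ", x$lambda, "\n", sep = "")
  invisible(x)
}

#' Channel-averaged TRF magnitudes
#'
#' Takes the absolute value of each coefficient per lag and channel and
#' averages over channels with equal weight.  When channels are the three
#' dipole components of volumetric source points, set
#' `vector_components = 3` to combine each consecutive triplet by its
#' Euclidean norm before averaging.
#'
#' @param model a fitted [trf_model].
#' @param vector_components 1 (plain channels) or 3 (consecutive triplets
#'   form one source point).
#' @return numeric matrix, lags x 2, columns `f` and `e`.
#' @export
trf_magnitude <- function(model, vector_components = 1) {
  stopifnot(inherits(model, "trf_model"))
  collapse <- function(w) {
    if (vector_components == 1) {
      mag <- abs(w)
    } else {
      n_ch <- ncol(w)
      if (n_ch %% vector_components != 0L)
        stop("channel count is not a multiple of vector_components")
      groups <- rep(seq_len(n_ch %/% vector_components),
                    each = vector_components)
      mag <- sapply(unique(groups), function(g)
        sqrt(rowSums(w[, groups == g, drop = FALSE]^2)))
      if (is.null(dim(mag))) mag <- matrix(mag, nrow = nrow(w))
    }
    rowMeans(mag)
  }
  out <- cbind(f = collapse(model$alpha), e = collapse(model$beta))
  rownames(out) <- model$lag_axis$lags_ms
  out
}

#' Smooth envelope of a TRF magnitude curve
#'
#' TRF coefficients oscillate near the stimulus fundamental frequency, and
#' so do their absolute values.  The envelope removes this carrier: the
#' analytic-signal magnitude of the magnitude curve is low-pass filtered
#' (zero-phase Butterworth, cut-off 70 Hz, order 5, with the lag axis
#' treated at the neural sample rate); residual negative values from
#' filtering are clipped to zero.
#'
#' @param magnitude numeric vector of per-lag magnitudes (one feature), or
#'   the lags x 2 matrix from [trf_magnitude()].
#' @param fs sample rate of the lag axis in Hz (default 1000).
#' @param cutoff_hz low-pass cut-off in Hz (default 70).
#' @param order filter order (default 5).
#' @return nonnegative envelope, same shape as `magnitude`.
#' @export
trf_envelope <- function(magnitude, fs = 1000, cutoff_hz = 70, order = 5) {
  if (is.matrix(magnitude)) {
    out <- apply(magnitude, 2L, trf_envelope, fs = fs, cutoff_hz = cutoff_hz,
                 order = order)
    dimnames(out) <- dimnames(magnitude)
    return(out)
  }
  if (length(magnitude) < 3L * (order + 1L))
    stop("magnitude sequence too short for the envelope filter")
  env <- Mod(analytic_signal(magnitude))
  filt <- butter_lowpass(cutoff_hz, fs, order)
  pmax(filtfilt_reflect(filt, env), 0)
}
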