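# Raw fluorescence -> neuropil-corrected dFF0.

#' Baseline fluorescence F0
#'
#' Per trial, the 5th percentile (linear-interpolation convention) of the
#' 1 Hz low-pass smoothed trace; `f0` is the mean of the per-trial
#' percentiles across all trials, dark and stimulation pooled, so that the
#' same baseline serves every context of a neuron.
#'
#' @param trials List of numeric raw traces (one per trial), or a matrix with
#'   one column per trial.
#' @param percentile Percentile in `[0, 100]` (default 5).
#' @param cutoff_hz,order,rate_hz Smoothing parameters, see
#'   [smooth_lowpass()].
#' @param presmoothed If `TRUE`, skip the low-pass step (for traces smoothed
#'   upstream).
#' @return Scalar baseline `f0`.
#' @export
compute_f0 <- function(trials, percentile = 5, cutoff_hz = 1, order = 60L,
                       rate_hz = 40, presmoothed = FALSE) {
  if (is.matrix(trials)) trials <- lapply(seq_len(ncol(trials)),
                                          function(j) trials[, j])
  if (!is.list(trials) || length(trials) == 0) {
    stop("`trials` must be a non-empty list of traces", call. = FALSE)
  }
  per_trial <- vapply(trials, function(f) {
    s <- if (presmoothed) f else smooth_lowpass(f, cutoff_hz, order, rate_hz)
    quantile(s, percentile / 100, names = FALSE, type = 7)
  }, numeric(1))
  mean(per_trial)
}

#' Relative fluorescence change dFF0
#'
#' `dff(t) = (F(t) - f0) / f0`; values may be negative.
#'
#' @param f Raw fluorescence trace.
#' @param f0 Scalar baseline, must be > 0.
#' @return Numeric dFF0 trace.
#' @export
compute_dff <- function(f, f0) {
  stopifnot_scalar(f0, "f0")
  if (f0 <= 0) stop("`f0` must be positive", call. = FALSE)
  (f - f0) / f0
}

#' Nonnegative matrix factorization demixing of soma and neuropil
#'
#' Factorizes a nonnegative trace matrix (rows = signal sources: the ROI
#' trace plus surrounding-neuropil traces; columns = frames) as `V ~ W %*% H`
#' by Lee–Seung multiplicative updates minimizing squared reconstruction
#' error. The component (row of `H`) maximally correlated with the first row
#' of `V` (the ROI trace) is returned as the demixed somatic signal, scaled
#' by its mixing weight into the ROI so it stays in fluorescence units.
#'
#' Traces with negative entries must be shifted by their minimum before
#' calling. The squared error is non-increasing across iterations.
#'
#' @param v Matrix (sources x frames), all entries >= 0; first row is the ROI
#'   trace.
#' @param rank Factorization rank (default 2: soma + neuropil).
#' @param n_iter Maximum multiplicative updates (default 500). `n_iter = 0`
#'   returns the seeded initialization unchanged.
#' @param tol Stop when the relative decrease of the squared error falls
#'   below `tol` (default 1e-8).
#' @param seed Integer seed for the nonnegative random initialization.
#' @return List: `w` (sources x rank), `h` (rank x frames), `err` (squared
#'   error after each iteration, with the initial error first), `somatic`
#'   (demixed ROI trace, length = frames), `component` (index of the somatic
#'   component).
#' @export
nmf_demix <- function(v, rank = 2L, n_iter = 500L, tol = 1e-8, seed = 1L) {
  v <- as.matrix(v)
  if (any(v < 0)) stop("`v` must be nonnegative; shift traces first",
                       call. = FALSE)
  if (rank < 1) stop("`rank` must be >= 1", call. = FALSE)
  if (rank > nrow(v)) stop("`rank` cannot exceed the number of traces",
                           call. = FALSE)
  eps <- .Machine$double.eps
  with_seed(seed, {
    w <- matrix(runif(nrow(v) * rank, 0.1, 1), nrow(v), rank)
    h <- matrix(runif(rank * ncol(v), 0.1, 1), rank, ncol(v))
    err <- numeric(n_iter + 1L)
    err[1L] <- sum((v - w %*% h)^2)
    it <- 0L
    while (it < n_iter) {
      it <- it + 1L
      h <- h * (t(w) %*% v) / (t(w) %*% w %*% h + eps)
      w <- w * (v %*% t(h)) / (w %*% (h %*% t(h)) + eps)
      err[it + 1L] <- sum((v - w %*% h)^2)
      if (err[it] - err[it + 1L] < tol * max(err[it], eps)) break
    }
    err <- err[seq_len(it + 1L)]
    comp <- if (ncol(v) > 1L && stats::sd(v[1L, ]) > 0) {
      cors <- apply(h, 1L, function(r) {
        if (stats::sd(r) == 0) return(-Inf)
        cor(r, v[1L, ])
      })
      which.max(cors)
    } else {
      1L
    }
    list(w = w, h = h, err = err,
         somatic = as.numeric(w[1L, comp] * h[comp, ]), component = comp)
  })
}

#' Full raw-trace to dFF0 conversion for one neuron
#'
#' Optionally demixes the ROI trace from a shared neuropil trace via
#' [nmf_demix()], computes the shared baseline over all trials with
#' [compute_f0()], and returns per-frame dFF0.
#'
#' @param f Raw fluorescence trace (whole session, concatenated trials).
#' @param trial_frames Integer vector assigning each frame to a trial.
#' @param neuropil Optional neuropil trace for demixing.
#' @param demix If `TRUE` and `neuropil` is given, run NMF demixing first.
#' @param rank,n_iter,tol,seed Passed to [nmf_demix()].
#' @param ... Passed to [compute_f0()].
#' @return List: `dff` (numeric trace), `f0` (scalar baseline).
#' @export
process_trace <- function(f, trial_frames, neuropil = NULL, demix = FALSE,
                          rank = 2L, n_iter = 200L, tol = 1e-8, seed = 1L,
                          ...) {
  if (demix && !is.null(neuropil)) {
    v <- rbind(f, neuropil)
    shift <- pmin(apply(v, 1L, min), 0)
    res <- nmf_demix(v - shift, rank = rank, n_iter = n_iter, tol = tol,
                     seed = seed)
    f <- res$somatic + shift[1L]
  }
  trials <- split(f, trial_frames)
  f0 <- compute_f0(trials, ...)
  list(dff = compute_dff(f, f0), f0 = f0)
}
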