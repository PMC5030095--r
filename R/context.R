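# Context-dependence classification: odd/even reliability, variability
# flags, and the CD / CI / OTHER label.

#' Odd/even epoch split of the locomotion modulation index
#'
#' Locomotion epochs within the context are numbered 1..K in temporal order
#' and stationary epochs likewise (independent numbering); an LMI is
#' computed from the odd-numbered locomotion and stationary epochs and
#' another from the even-numbered ones. The variability of a neuron's
#' locomotion response is `|lmi_odd - lmi_even|`. Requires at least two
#' epochs of each state in the context; otherwise the result is invalid
#' (treated as unreliable).
#'
#' @param dff Numeric dFF0 trace.
#' @param labels State factor from [segment_states()].
#' @param context_mask Logical per-frame mask (default: all frames).
#' @param min_state_s Minimum seconds per state passed to [compute_lmi()]
#'   for each half (default 1).
#' @param frame_hz Frame rate, Hz (default 40).
#' @return List: `lmi_odd`, `lmi_even`, `variability`, `valid`.
#' @export
split_odd_even <- function(dff, labels, context_mask = NULL, min_state_s = 1,
                           frame_hz = 40) {
  n <- length(dff)
  if (is.null(context_mask)) context_mask <- rep(TRUE, n)
  idx <- which(context_mask)
  ep <- enumerate_epochs(labels[idx])      # epochs within the context
  res <- list(lmi_odd = NA_real_, lmi_even = NA_real_,
              variability = NA_real_, valid = FALSE)
  parity_mask <- function(state, parity) {
    rows <- which(ep$state == state)
    rows <- rows[seq_along(rows) %% 2L == parity %% 2L]
    m <- logical(n)
    for (r in rows) m[idx[ep$start_frame[r]:ep$end_frame[r]]] <- TRUE
    m
  }
  for (st in c("LOCOMOTION", "STATIONARY")) {
    if (sum(ep$state == st) < 2L) return(res)
  }
  halves <- lapply(1:2, function(parity) {
    m <- parity_mask("LOCOMOTION", parity) | parity_mask("STATIONARY", parity)
    compute_lmi(dff, labels, context_mask = m & context_mask,
                min_state_s = min_state_s, frame_hz = frame_hz)
  })
  if (!halves[[1]]$valid || !halves[[2]]$valid) return(res)
  list(lmi_odd = halves[[1]]$lmi, lmi_even = halves[[2]]$lmi,
       variability = abs(halves[[1]]$lmi - halves[[2]]$lmi), valid = TRUE)
}

#' Flag the most variable neurons of a population
#'
#' Flags neurons whose odd/even variability strictly exceeds the `pct`-th
#' percentile (linear-interpolation convention) of the variability values
#' within their group (cell type x context by default; pass a constant
#' `group` for a global percentile). With all-equal variabilities nothing is
#' flagged.
#'
#' @param variability Numeric vector of `|lmi_odd - lmi_even|` values
#'   (`NA` allowed; flagged `NA`).
#' @param group Optional grouping vector (e.g. cell type); percentile
#'   computed within each group.
#' @param pct Percentile (default 95).
#' @param min_group Minimum valid neurons per group for a meaningful
#'   percentile (default 20); smaller groups get no flags with a warning.
#' @return Logical vector, `TRUE` = high variability.
#' @export
flag_high_variability <- function(variability, group = NULL, pct = 95,
                                  min_group = 20L) {
  if (!length(variability)) stop("empty population", call. = FALSE)
  if (is.null(group)) group <- rep("all", length(variability))
  flags <- rep(NA, length(variability))
  for (g in unique(group)) {
    sel <- group == g
    v <- variability[sel]
    ok <- !is.na(v)
    if (sum(ok) < min_group) {
      warning(sprintf("group '%s' has %d valid neurons (< %d); none flagged",
                      g, sum(ok), min_group), call. = FALSE)
      flags[sel] <- FALSE
      next
    }
    thr <- quantile(v[ok], pct / 100, names = FALSE, type = 7)
    flags[sel] <- !is.na(v) & v > thr
  }
  flags
}

#' Classify a neuron's context dependence
#'
#' A neuron is context-dependent (`CD`) when the bootstrap confidence
#' interval of `LMI_stim - LMI_dark` excludes 0 (significant distance from
#' the identity line) and it is not among the most variable neurons in
#' either context — high variability vetoes the CD label. It is
#' context-independent (`CI`) when not CD, `|LMI_stim - LMI_dark| <
#' delta_band`, and it is locomotion responsive (POSITIVE or NEGATIVE) in at
#' least one context (both contexts if `ci_requires_both`). Everything else
#' is `OTHER`.
#'
#' @param lmi_dark,lmi_stim Point LMIs per context (from [compute_lmi()]).
#' @param boot_dark,boot_stim Bootstrap replicate vectors per context (from
#'   [bootstrap_lmi()]); the difference distribution pairs them per
#'   iteration.
#' @param class_dark,class_stim Responsiveness classes per context.
#' @param high_var_dark,high_var_stim High-variability flags per context.
#' @param ci_level Confidence level for the difference CI (default 0.95).
#' @param delta_band Context-independence band on the LMI difference
#'   (default 0.2).
#' @param ci_requires_both If `TRUE`, CI requires responsiveness in both
#'   contexts (default `FALSE`: either suffices).
#' @return List: `delta_lmi`, `diff_ci_low`, `diff_ci_high`,
#'   `significant_diff`, `high_variability`, `label` (`"CD"`, `"CI"` or
#'   `"OTHER"`), `valid`.
#' @export
classify_context <- function(lmi_dark, lmi_stim, boot_dark, boot_stim,
                             class_dark, class_stim,
                             high_var_dark = FALSE, high_var_stim = FALSE,
                             ci_level = 0.95, delta_band = 0.2,
                             ci_requires_both = FALSE) {
  invalid <- is.na(lmi_dark) || is.na(lmi_stim) ||
    !length(boot_dark) || !length(boot_stim)
  high_var <- isTRUE(high_var_dark) || isTRUE(high_var_stim)
  if (invalid) {
    return(list(delta_lmi = NA_real_, diff_ci_low = NA_real_,
                diff_ci_high = NA_real_, significant_diff = NA,
                high_variability = high_var, label = "OTHER", valid = FALSE))
  }
  nb <- min(length(boot_dark), length(boot_stim))
  diff <- boot_stim[seq_len(nb)] - boot_dark[seq_len(nb)]
  alpha <- (1 - ci_level) / 2
  ci <- quantile(diff, c(alpha, 1 - alpha), names = FALSE, type = 7)
  significant <- ci[1] > 0 || ci[2] < 0
  delta <- lmi_stim - lmi_dark
  responsive <- c(class_dark, class_stim) %in% c("POSITIVE", "NEGATIVE")
  resp_ok <- if (ci_requires_both) all(responsive) else any(responsive)
  label <- if (significant && !high_var) {
    "CD"
  } else if (abs(delta) < delta_band && resp_ok) {
    "CI"
  } else {
    "OTHER"
  }
  list(delta_lmi = delta, diff_ci_low = ci[1], diff_ci_high = ci[2],
       significant_diff = significant, high_variability = high_var,
       label = label, valid = TRUE)
}
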