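# Neuron-level analysis orchestration and per-animal population summaries.

#' Analysis configuration
#'
#' Collects the tunable analysis parameters with their standard defaults.
#'
#' @param n_boot Bootstrap iterations (default 10000).
#' @param R Assumed inter-sample correlation (default 0.35).
#' @param ci_level Confidence level (default 0.95).
#' @param lmi_thresh Responsiveness magnitude threshold (default 0.2).
#' @param delta_band Context-independence band on the LMI difference
#'   (default 0.2).
#' @param min_state_s Minimum seconds per state per context (default 5).
#' @param min_samples Minimum 1 s bins per state for the bootstrap
#'   (default 5).
#' @param var_pct Percentile for the high-variability flag (default 95).
#' @param ci_requires_both CI label needs responsiveness in both contexts
#'   (default `FALSE`).
#' @param demix Run NMF neuropil demixing before dFF0 (default `FALSE`).
#' @param contexts Contexts analyzed per neuron (default `c("DARK",
#'   "STIM")`).
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(n_boot = 10000L, R = 0.35, ci_level = 0.95,
                            lmi_thresh = 0.2, delta_band = 0.2,
                            min_state_s = 5, min_samples = 5L, var_pct = 95,
                            ci_requires_both = FALSE, demix = FALSE,
                            contexts = c("DARK", "STIM")) {
  structure(list(n_boot = n_boot, R = R, ci_level = ci_level,
                 lmi_thresh = lmi_thresh, delta_band = delta_band,
                 min_state_s = min_state_s, min_samples = min_samples,
                 var_pct = var_pct, ci_requires_both = ci_requires_both,
                 demix = demix, contexts = contexts),
            class = "analysis_config")
}

#' Analyze one neuron in one context
#'
#' Point LMI over frames, 1 s-bin samples, bootstrap CI, and responsiveness
#' class, plus the odd/even reliability split.
#'
#' @param dff dFF0 trace.
#' @param labels State factor.
#' @param schedule Stimulus schedule.
#' @param context_mask Logical mask for the context.
#' @param cfg An [analysis_config()].
#' @param frame_hz Frame rate, Hz.
#' @param seed Integer seed for the bootstrap.
#' @return List: `lmi` (from [compute_lmi()]), `boot` (from
#'   [bootstrap_lmi()]), `class`, `split` (from [split_odd_even()]).
#' @export
analyze_neuron_context <- function(dff, labels, schedule, context_mask,
                                   cfg = analysis_config(), frame_hz = 40,
                                   seed = 1L) {
  lmi <- compute_lmi(dff, labels, context_mask,
                     min_state_s = cfg$min_state_s, frame_hz = frame_hz)
  samples <- extract_samples(dff, labels, schedule, context_mask,
                             frame_hz = frame_hz)
  boot <- bootstrap_lmi(samples, n_boot = cfg$n_boot, R = cfg$R,
                        ci_level = cfg$ci_level,
                        min_samples = cfg$min_samples, seed = seed)
  cls <- if (lmi$valid && boot$valid) {
    classify_responsiveness(lmi$lmi, boot$ci_low, boot$ci_high,
                            cfg$lmi_thresh)
  } else {
    "NONE"
  }
  split <- split_odd_even(dff, labels, context_mask, frame_hz = frame_hz)
  list(lmi = lmi, boot = boot, class = cls, split = split)
}

#' Analyze a population of neurons
#'
#' Runs the full neuron-level analysis: dFF0 conversion (optionally NMF
#' neuropil demixing), per-context LMI with bootstrap CI and responsiveness,
#' odd/even variability with population flags, and context-dependence
#' classification.
#'
#' @param traces Frames x neurons matrix of raw fluorescence.
#' @param schedule Stimulus schedule data.frame.
#' @param speed `speed_series` data.frame (or precomputed `labels`).
#' @param meta data.frame with one row per neuron: `neuron_id`, `animal_id`,
#'   `cell_type`, `layer`.
#' @param cfg An [analysis_config()].
#' @param labels Optional precomputed state factor (skips segmentation).
#' @param neuropil Optional shared neuropil trace for demixing.
#' @param seed Integer root seed.
#' @return List: `results` (per neuron x context data.frame), `classes`
#'   (per-neuron context classification data.frame), `labels`, `f0`
#'   (per-neuron baselines).
#' @export
analyze_population <- function(traces, schedule, speed, meta,
                               cfg = analysis_config(), labels = NULL,
                               neuropil = NULL, seed = 1L) {
  frame_hz <- attr(schedule, "frame_hz") %||% 40
  if (is.null(labels)) labels <- segment_states(speed, frame_hz = frame_hz)
  masks <- context_masks(schedule)
  n_neurons <- ncol(traces)
  stopifnot(nrow(meta) == n_neurons)

  rows <- list(); f0s <- numeric(n_neurons)
  per_neuron <- vector("list", n_neurons)
  for (j in seq_len(n_neurons)) {
    pt <- process_trace(traces[, j], schedule$trial, neuropil = neuropil,
                        demix = cfg$demix, seed = derive_seed(seed, 500L + j))
    f0s[j] <- pt$f0
    ctx_res <- list()
    for (ctx in cfg$contexts) {
      a <- analyze_neuron_context(pt$dff, labels, schedule, masks[[ctx]],
                                  cfg, frame_hz,
                                  seed = derive_seed(seed, 1000L * j +
                                                       match(ctx, cfg$contexts)))
      ctx_res[[ctx]] <- a
      rows[[length(rows) + 1L]] <- data.frame(
        neuron_id = meta$neuron_id[j], animal_id = meta$animal_id[j],
        cell_type = meta$cell_type[j], layer = meta$layer[j], context = ctx,
        r_l = a$lmi$r_l, r_s = a$lmi$r_s, lmi = a$lmi$lmi,
        ci_low = a$boot$ci_low, ci_high = a$boot$ci_high,
        n_samples_loco = a$boot$n_loco, n_samples_stat = a$boot$n_stat,
        class = a$class, lmi_odd = a$split$lmi_odd,
        lmi_even = a$split$lmi_even, variability = a$split$variability,
        valid = a$lmi$valid && a$boot$valid, stringsAsFactors = FALSE)
    }
    per_neuron[[j]] <- ctx_res
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL

  # high-variability flags within cell-type x context populations
  results$high_var <- NA
  for (ctx in cfg$contexts) {
    sel <- results$context == ctx
    results$high_var[sel] <- flag_high_variability(
      results$variability[sel], group = results$cell_type[sel],
      pct = cfg$var_pct)
  }

  classes <- NULL
  if (all(c("DARK", "STIM") %in% cfg$contexts)) {
    cls_rows <- lapply(seq_len(n_neurons), function(j) {
      dark <- per_neuron[[j]]$DARK; stim <- per_neuron[[j]]$STIM
      hv <- function(ctx) {
        v <- results$high_var[results$context == ctx &
                                results$neuron_id == meta$neuron_id[j]]
        isTRUE(v[1])
      }
      cc <- classify_context(dark$lmi$lmi, stim$lmi$lmi, dark$boot$boot,
                             stim$boot$boot, dark$class, stim$class,
                             hv("DARK"), hv("STIM"),
                             ci_level = cfg$ci_level,
                             delta_band = cfg$delta_band,
                             ci_requires_both = cfg$ci_requires_both)
      data.frame(neuron_id = meta$neuron_id[j],
                 animal_id = meta$animal_id[j],
                 cell_type = meta$cell_type[j], layer = meta$layer[j],
                 lmi_dark = dark$lmi$lmi, lmi_stim = stim$lmi$lmi,
                 delta_lmi = cc$delta_lmi,
                 significant_diff = cc$significant_diff,
                 high_var_dark = hv("DARK"), high_var_stim = hv("STIM"),
                 label = cc$label, valid = cc$valid,
                 stringsAsFactors = FALSE)
    })
    classes <- do.call(rbind, cls_rows)
    rownames(classes) <- NULL
  }
  list(results = results, classes = classes, labels = labels, f0 = f0s)
}

#' Aggregate neuron-level results per animal
#'
#' Median LMI, mean dFF0 per state, and responsive fractions within
#' animal x cell type x layer x context, over valid neurons only. Animals
#' with zero valid neurons in a cell are omitted with a warning.
#'
#' @param results Per neuron x context data.frame from
#'   [analyze_population()].
#' @return data.frame of per-animal summaries.
#' @export
aggregate_per_animal <- function(results) {
  if (!all(results$valid %in% c(TRUE, FALSE))) {
    stop("`results` must carry a logical `valid` column", call. = FALSE)
  }
  dropped <- unique(results$animal_id[!results$valid])
  valid <- results[results$valid, , drop = FALSE]
  gone <- setdiff(dropped, unique(valid$animal_id))
  if (length(gone)) {
    warning(sprintf("animal(s) with no valid neurons omitted: %s",
                    paste(gone, collapse = ", ")), call. = FALSE)
  }
  key <- interaction(valid$animal_id, valid$cell_type, valid$layer,
                     valid$context, drop = TRUE)
  out <- lapply(split(valid, key), function(d) {
    data.frame(animal_id = d$animal_id[1], cell_type = d$cell_type[1],
               layer = d$layer[1], context = d$context[1],
               median_lmi = median(d$lmi),
               mean_dff_locomotion = mean(d$r_l),
               mean_dff_stationary = mean(d$r_s),
               frac_responsive_positive = mean(d$class == "POSITIVE"),
               frac_responsive_negative = mean(d$class == "NEGATIVE"),
               n_neurons = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$animal_id, out$cell_type, out$layer, out$context), ]
  rownames(out) <- NULL
  out
}

#' Population-level rank tests on per-animal summaries
#'
#' The tests consume per-animal values only (the animal is the experimental
#' unit, preventing pseudo-replication): a two-tailed Wilcoxon signed-rank
#' test on paired per-animal mean dFF0 (locomotion vs stationary, within
#' context) and on paired dark-vs-stim median LMIs; a Kruskal-Wallis test
#' comparing median-LMI distributions across contexts; and, when two layers
#' are present, a Mann-Whitney U test on median LMIs between layers, per
#' context. Cells with fewer than `min_animals` animals are skipped with a
#' warning.
#'
#' @param summaries data.frame from [aggregate_per_animal()].
#' @param min_animals Minimum animals per group (default 3).
#' @return data.frame: `cell_type`, `test`, `context`, `n`, `statistic`,
#'   `p_value`, `direction`.
#' @export
run_population_tests <- function(summaries, min_animals = 3L) {
  # paired signed-rank with the degenerate no-difference case defined:
  # identical vectors carry no evidence, p = 1
  safe_signed_rank <- function(x, y) {
    if (all(x == y)) return(list(statistic = c(V = 0), p.value = 1))
    suppressWarnings(wilcox.test(x, y, paired = TRUE))
  }
  out <- list()
  add <- function(cell_type, test, context, n, statistic, p, direction) {
    out[[length(out) + 1L]] <<- data.frame(
      cell_type = cell_type, test = test, context = context, n = n,
      statistic = unname(statistic), p_value = signif(unname(p), 3),
      direction = direction, stringsAsFactors = FALSE)
  }
  for (ct in unique(summaries$cell_type)) {
    d <- summaries[summaries$cell_type == ct, , drop = FALSE]
    # locomotion vs stationary mean dFF0, per context (signed rank, paired)
    for (ctx in unique(d$context)) {
      dc <- d[d$context == ctx, , drop = FALSE]
      if (nrow(dc) < min_animals) {
        warning(sprintf("%s/%s: %d animals (< %d); test skipped",
                        ct, ctx, nrow(dc), min_animals), call. = FALSE)
        next
      }
      wt <- safe_signed_rank(dc$mean_dff_locomotion, dc$mean_dff_stationary)
      add(ct, "signed_rank_loco_vs_stat", ctx, nrow(dc), wt$statistic,
          wt$p.value,
          if (median(dc$mean_dff_locomotion - dc$mean_dff_stationary) >= 0)
            "locomotion>stationary" else "locomotion<stationary")
    }
    # dark vs stim median LMI: paired signed rank + Kruskal-Wallis
    dd <- d[d$context == "DARK", , drop = FALSE]
    ds <- d[d$context == "STIM", , drop = FALSE]
    common <- intersect(dd$animal_id, ds$animal_id)
    if (length(common) >= min_animals) {
      x <- dd$median_lmi[match(common, dd$animal_id)]
      y <- ds$median_lmi[match(common, ds$animal_id)]
      wt <- safe_signed_rank(y, x)
      add(ct, "signed_rank_dark_vs_stim", "DARK|STIM", length(common),
          wt$statistic, wt$p.value,
          if (median(y - x) >= 0) "stim>dark" else "stim<dark")
      kw <- kruskal.test(list(dark = x, stim = y))
      add(ct, "kruskal_wallis_lmi_context", "DARK|STIM", length(common),
          kw$statistic, kw$p.value,
          if (median(y) >= median(x)) "stim>dark" else "stim<dark")
    }
    # layer comparison (Mann-Whitney U), per context
    layers <- unique(d$layer)
    if (length(layers) == 2L) {
      for (ctx in unique(d$context)) {
        a <- d$median_lmi[d$context == ctx & d$layer == layers[1]]
        b <- d$median_lmi[d$context == ctx & d$layer == layers[2]]
        if (length(a) >= min_animals && length(b) >= min_animals) {
          wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
          add(ct, "mann_whitney_layer", ctx, length(a) + length(b),
              wt$statistic, wt$p.value,
              sprintf("%s%s%s", layers[1],
                      if (median(a) >= median(b)) ">" else "<", layers[2]))
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(cell_type = character(0), test = character(0),
                      context = character(0), n = integer(0),
                      statistic = numeric(0), p_value = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
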