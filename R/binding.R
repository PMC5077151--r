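#' Construct a titration series
#'
#' @param series_id Identifier for the protein/RNA pair.
#' @param rna_conc Constant labelled-RNA concentration (> 0).
#' @param protein_concs Ascending, non-negative protein
#'   concentrations; at least 6 points.
#' @param anisotropy Measured anisotropy, same length.
#' @param replicate_id Replicate identifier.
#' @return An object of class `"titration"`.
#' @export
titration <- function(series_id, rna_conc, protein_concs, anisotropy,
                      replicate_id = 1L) {
  check_number(rna_conc, "rna_conc", min = 0, strict_min = TRUE)
  if (length(protein_concs) != length(anisotropy)) {
    stopf("`protein_concs` and `anisotropy` must have equal length")
  }
  if (length(protein_concs) < 6L) {
    stopf("a titration needs at least 6 points")
  }
  if (any(protein_concs < 0)) stopf("protein concentrations must be >= 0")
  if (is.unsorted(protein_concs)) {
    stopf("`protein_concs` must be sorted ascending")
  }
  structure(list(series_id = series_id, rna_conc = rna_conc,
                 protein_concs = as.numeric(protein_concs),
                 anisotropy = as.numeric(anisotropy),
                 replicate_id = replicate_id),
            class = "titration")
}

#' Fit a two-state binding isotherm to an anisotropy titration
#'
#' Fits `A(P) = a_free + (a_bound - a_free) * FB(P)` with the
#' ligand-depletion (quadratic) bound fraction
#' `FB = ((P + R + KD) - sqrt((P + R + KD)^2 - 4 P R)) / (2 R)`; three
#' free parameters (KD, a_free, a_bound) by least squares. The
#' labelled RNA is at fixed finite concentration, so the depletion
#' form, not a simple hyperbola, is used. Initialisation: endpoints at
#' the observed extremes and KD at the midpoint-crossing
#' concentration, with additional log-spaced KD starts; the best
#' residual is kept. Degenerate (e.g. flat) series never fail
#' silently: the fit is returned with `converged = FALSE` and a
#' diagnostic message.
#'
#' @param t A [titration()].
#' @param n_starts Number of KD starting values (default 5).
#' @return An object of class `"binding_fit"`: list with `kd`, `ka`
#'   (`= 1/kd`), `a_free`, `a_bound`, `residual_norm`, `converged`,
#'   `diagnostics`, `series_id`, `replicate_id`.
#' @export
fit_titration <- function(t, n_starts = 5L) {
  if (!inherits(t, "titration")) stopf("`t` must be a titration")
  P <- t$protein_concs
  y <- t$anisotropy
  R <- t$rna_conc
  unconverged <- function(msg) {
    structure(list(kd = NA_real_, ka = NA_real_, a_free = NA_real_,
                   a_bound = NA_real_, residual_norm = NA_real_,
                   converged = FALSE, diagnostics = msg,
                   series_id = t$series_id, replicate_id = t$replicate_id),
              class = "binding_fit")
  }
  rng <- diff(range(y))
  if (rng < 1e-10) {
    return(unconverged("flat anisotropy series: KD unidentifiable"))
  }
  # midpoint-crossing start for KD
  mid <- min(y) + rng / 2
  above <- which(y >= mid)
  k_mid <- if (length(above)) max(P[above[1]], min(P[P > 0])) else max(P)
  pos <- P[P > 0]
  starts <- unique(c(k_mid, 10^seq(log10(min(pos) / 10),
                                   log10(max(pos) * 10),
                                   length.out = max(1L, n_starts - 1L))))
  df <- data.frame(P = P, y = y)
  best <- NULL
  msgs <- character(0)
  for (k0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a_free + (a_bound - a_free) * bound_fraction(P, R, kd),
        data = df,
        start = list(kd = k0, a_free = min(y), a_bound = max(y)),
        lower = c(kd = .Machine$double.eps, a_free = -Inf, a_bound = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      msgs <- c(msgs, conditionMessage(fit))
      next
    }
    if (is.null(best) || deviance(fit) < deviance(best)) best <- fit
  }
  if (is.null(best)) {
    return(unconverged(paste("no start converged:",
                             paste(unique(msgs), collapse = "; "))))
  }
  cf <- coef(best)
  amp <- cf[["a_bound"]] - cf[["a_free"]]
  converged <- amp > 0 && cf[["kd"]] > 0 && is.finite(cf[["kd"]])
  # amplitude must rise well clear of the residual noise to pin KD down
  resid_sd <- sqrt(deviance(best) / max(1, length(y) - 3))
  if (converged && amp < 3 * resid_sd) {
    converged <- FALSE
  }
  structure(list(kd = cf[["kd"]], ka = 1 / cf[["kd"]],
                 a_free = cf[["a_free"]], a_bound = cf[["a_bound"]],
                 residual_norm = sqrt(deviance(best)),
                 converged = converged,
                 diagnostics = if (converged) NA_character_ else
                   "fitted amplitude not resolved above residual noise",
                 series_id = t$series_id, replicate_id = t$replicate_id),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("binding_fit [%s/%s]: KD = %s (%s)\n", x$series_id,
              x$replicate_id, format(x$kd, digits = 4),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Construct a fold-change result directly
#'
#' Used to encode affinity-change directions from published summaries
#' (fold change vs 1 and significance) without replicate-level data.
#'
#' @param site_id Site identifier.
#' @param fc Association-constant fold change, mutant over wild type
#'   (> 0).
#' @param p_value Two-sided p-value.
#' @param t_statistic Optional t statistic.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `"fold_change_result"`.
#' @export
fold_change_result <- function(site_id, fc, p_value, t_statistic = NA_real_,
                               alpha = 0.05) {
  check_number(fc, "fc", min = 0, strict_min = TRUE)
  check_number(p_value, "p_value", min = 0)
  if (p_value > 1) stopf("`p_value` must be in [0, 1]")
  structure(list(site_id = site_id, fc = fc, t_statistic = t_statistic,
                 p_value = p_value, significant = p_value <= alpha),
            class = "fold_change_result")
}

#' Mutant vs wild-type affinity fold change with Welch's t test
#'
#' `fc = mean(KA_mut) / mean(KA_wt)`; the test is Welch's unequal-
#' variance two-sided t test on log-transformed association constants
#' (affinities are ratio-scale). Requires at least three converged
#' replicate fits per side.
#'
#' @param wt_fits,mut_fits Lists of converged [fit_titration()]
#'   results (>= 3 each).
#' @param site_id Identifier carried into the result.
#' @param alpha Significance level (default 0.05).
#' @return A [fold_change_result()].
#' @export
fold_change <- function(wt_fits, mut_fits, site_id = NA_character_,
                        alpha = 0.05) {
  grab_ka <- function(fits, name) {
    if (length(fits) < 3L) stopf("`%s` needs >= 3 replicate fits", name)
    if (!all(vapply(fits, inherits, logical(1), "binding_fit"))) {
      stopf("`%s` must be binding_fit objects", name)
    }
    if (!all(vapply(fits, `[[`, logical(1), "converged"))) {
      stopf("all `%s` must be converged", name)
    }
    vapply(fits, `[[`, numeric(1), "ka")
  }
  ka_wt <- grab_ka(wt_fits, "wt_fits")
  ka_mut <- grab_ka(mut_fits, "mut_fits")
  fc <- mean(ka_mut) / mean(ka_wt)
  lw <- log(ka_wt); lm_ <- log(ka_mut)
  if (sd(lw) == 0 && sd(lm_) == 0) {
    tt <- list(statistic = c(t = 0),
               p.value = if (isTRUE(all.equal(mean(lw), mean(lm_)))) 1 else 0)
  } else {
    tt <- t.test(lm_, lw, var.equal = FALSE)
  }
  fold_change_result(site_id = site_id, fc = fc,
                     p_value = unname(tt$p.value),
                     t_statistic = unname(tt$statistic), alpha = alpha)
}

#' Predict splicing direction from proximal/distal affinity changes
#'
#' The competition rule: a significant gain of mutant affinity at the
#' proximal site (or loss at the distal site) predicts increased
#' proximal-isoform use; a significant loss at the proximal site (or
#' gain at the distal) predicts decreased use. When both sites change
#' significantly the direction follows the net fold change
#' `fc_prox / fc_dist` relative to 1 (so a distal loss outweighing a
#' proximal loss still predicts a net proximal gain); with no
#' significant change at either site no call is made.
#'
#' @param prox,dist [fold_change_result()]s for the proximal and
#'   distal 3' splice sites of one event.
#' @return `"increased"`, `"decreased"` or `"no_call"`.
#' @export
predict_direction <- function(prox, dist) {
  for (x in list(prox, dist)) {
    if (!inherits(x, "fold_change_result")) {
      stopf("`prox` and `dist` must be fold_change_result objects")
    }
  }
  if (prox$significant && dist$significant) {
    net <- prox$fc / dist$fc
    if (net > 1) "increased" else if (net < 1) "decreased" else "no_call"
  } else if (prox$significant) {
    if (prox$fc > 1) "increased" else if (prox$fc < 1) "decreased" else "no_call"
  } else if (dist$significant) {
    if (dist$fc > 1) "decreased" else if (dist$fc < 1) "increased" else "no_call"
  } else {
    "no_call"
  }
}

#' Competition prediction for one event, scored against observation
#'
#' @param event_id Event identifier.
#' @param prox,dist [fold_change_result()]s for the two sites.
#' @param observed Observed splicing direction, `"increased"` or
#'   `"decreased"` (sign of the proximal-isoform delta-psi), or `NA`.
#' @return An object of class `"competition_prediction"`; `no_call`
#'   predictions score as discordant.
#' @export
competition_prediction <- function(event_id, prox, dist,
                                   observed = NA_character_) {
  if (!is.na(observed) && !observed %in% c("increased", "decreased")) {
    stopf("`observed` must be 'increased', 'decreased' or NA")
  }
  predicted <- predict_direction(prox, dist)
  structure(list(event_id = event_id, prox = prox, dist = dist,
                 predicted = predicted, observed = observed,
                 concordant = !is.na(observed) && predicted == observed),
            class = "competition_prediction")
}

#' Concordance of competition predictions with observed splicing
#'
#' @param predictions List of [competition_prediction()]s; events
#'   without an observed direction are excluded with a warning.
#' @return List with `concordant` (count), `total`, `fraction` (`NaN`
#'   for an empty list) and a per-event `table`.
#' @export
concordance <- function(predictions) {
  if (!all(vapply(predictions, inherits, logical(1),
                  "competition_prediction"))) {
    stopf("`predictions` must be competition_prediction objects")
  }
  has_obs <- vapply(predictions, function(p) !is.na(p$observed), logical(1))
  if (any(!has_obs)) {
    warnf("excluding %d prediction(s) without an observed direction",
          sum(!has_obs))
    predictions <- predictions[has_obs]
  }
  tab <- data.frame(
    event_id = vapply(predictions, `[[`, character(1), "event_id"),
    predicted = vapply(predictions, `[[`, character(1), "predicted"),
    observed = vapply(predictions, `[[`, character(1), "observed"),
    concordant = vapply(predictions, `[[`, logical(1), "concordant"),
    stringsAsFactors = FALSE)
  n <- nrow(tab)
  list(concordant = sum(tab$concordant), total = n,
       fraction = if (n) sum(tab$concordant) / n else NaN, table = tab)
}

#' Published direction-level encoding of the seven tested 3'SS events
#'
#' Loads the bundled table of affinity-change directions (fold change
#' vs 1 plus significance, per proximal and distal 3' splice site) and
#' observed splicing directions for the seven experimentally tested
#' events (CEP164, FMR1, DEK, ZFAND1, FXR1, ATR, MED15). Fold-change
#' magnitudes in the table are direction-level encodings of the
#' published summary: only their side of 1, their ratio for the
#' both-significant case, and the significance flags enter the
#' prediction rule.
#'
#' @param path Optional alternative TSV path.
#' @return Data frame with one row per event.
#' @export
tested_3ss_events <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "s34f_tested_3ss_events.tsv",
                        package = "spliceratio", mustWork = TRUE)
  }
  read_tsv(path, required = c("event_id", "prox_minus3", "dist_minus3",
                              "prox_fc", "prox_p", "dist_fc", "dist_p",
                              "observed"))
}

#' Competition predictions for a fold-change summary table
#'
#' @param events Data frame in the [tested_3ss_events()] layout.
#' @param alpha Significance level (default 0.05).
#' @return List of [competition_prediction()]s.
#' @export
predict_from_table <- function(events, alpha = 0.05) {
  lapply(seq_len(nrow(events)), function(i) {
    row <- events[i, ]
    competition_prediction(
      event_id = row$event_id,
      prox = fold_change_result(paste0(row$event_id, "_prox"),
                                row$prox_fc, row$prox_p, alpha = alpha),
      dist = fold_change_result(paste0(row$event_id, "_dist"),
                                row$dist_fc, row$dist_p, alpha = alpha),
      observed = row$observed)
  })
}
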