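#' Mutant:wild-type ratio from variant-spanning read counts
#'
#' The ratio `rho = alt / ref` and mutant fraction
#' `f = alt / (alt + ref)` are reported per sample. A sample with no
#' reference reads has an infinite ratio (`f = 1`); a sample with no
#' reads at all is an error.
#'
#' @param alt_reads,ref_reads Non-negative counts (vectorised).
#' @param sample_id Optional sample identifiers.
#' @param source Provenance tag, `"rnaseq"` or `"qpcr"`.
#' @return Data frame with columns `sample_id`, `alt_reads`,
#'   `ref_reads`, `rho`, `mutant_fraction`, `source`.
#' @examples
#' ratio_from_reads(50, 50)   # rho 1, f 0.5 (the heterozygous expectation)
#' ratio_from_reads(30, 70)   # rho ~0.43, f 0.30
#' @export
ratio_from_reads <- function(alt_reads, ref_reads, sample_id = NULL,
                             source = "rnaseq") {
  check_counts(alt_reads, "alt_reads")
  check_counts(ref_reads, "ref_reads")
  if (length(alt_reads) != length(ref_reads)) {
    stopf("`alt_reads` and `ref_reads` must have equal length")
  }
  both_zero <- alt_reads == 0 & ref_reads == 0
  if (any(both_zero)) {
    stopf("undefined ratio: sample(s) with zero alt and zero ref reads (index %d)",
          which(both_zero)[1])
  }
  if (is.null(sample_id)) {
    sample_id <- sprintf("sample_%02d", seq_along(alt_reads))
  }
  rho <- ifelse(ref_reads == 0, Inf, alt_reads / ref_reads)
  data.frame(sample_id = sample_id, alt_reads = alt_reads,
             ref_reads = ref_reads, rho = rho,
             mutant_fraction = alt_reads / (alt_reads + ref_reads),
             source = source, stringsAsFactors = FALSE)
}

#' qPCR cycle-difference to fold-change conversion
#'
#' `fold = efficiency^delta_ct`; with perfect doubling a 3.5-cycle
#' difference corresponds to about an 11-fold difference in template.
#'
#' @param delta_ct Cycle-threshold difference(s).
#' @param efficiency Per-cycle amplification factor in (1, 2]
#'   (default 2).
#' @return Fold change(s).
#' @examples
#' fold_from_ct(3.5)  # 11.31, i.e. ~11-fold
#' @export
fold_from_ct <- function(delta_ct, efficiency = 2) {
  check_number(efficiency, "efficiency", min = 1, strict_min = TRUE)
  if (efficiency > 2) stopf("`efficiency` must be in (1, 2]")
  if (!is.numeric(delta_ct) || any(!is.finite(delta_ct))) {
    stopf("`delta_ct` must be finite")
  }
  efficiency^delta_ct
}

#' Mutant:wild-type ratio from allele-sensitive qPCR Ct values
#'
#' The raw ratio is `efficiency^(ct_ref - ct_alt)`. Because the
#' mutant-specific probe also detects the wild-type template at a
#' lower efficiency (quantified as a `cross_reactivity_fold`
#' specificity ratio), the raw signal is linearly unmixed:
#' `corrected = max(0, (raw - 1/cr) * k)` with `k = 1 / (1 - 1/cr)`,
#' so a pure wild-type template measures 0 and a pure mutant template
#' is unchanged. `cross_reactivity_fold = Inf` disables the
#' correction.
#'
#' @param ct_alt,ct_ref Positive finite Ct values from the
#'   mutant-specific and wild-type-specific probes (vectorised).
#' @param efficiency Per-cycle amplification factor in (1, 2].
#' @param cross_reactivity_fold Specificity of the mutant probe (fold
#'   preference for mutant over wild-type template); `Inf` for a
#'   perfectly specific probe.
#' @param sample_id Optional sample identifiers.
#' @return Data frame as in [ratio_from_reads()] with `source`
#'   `"qpcr"` and count columns `NA`.
#' @export
ratio_from_qpcr <- function(ct_alt, ct_ref, efficiency = 2,
                            cross_reactivity_fold = Inf,
                            sample_id = NULL) {
  if (!is.numeric(ct_alt) || !is.numeric(ct_ref) ||
      any(!is.finite(ct_alt)) || any(!is.finite(ct_ref)) ||
      any(ct_alt <= 0) || any(ct_ref <= 0)) {
    stopf("Ct values must be positive and finite")
  }
  if (length(ct_alt) != length(ct_ref)) {
    stopf("`ct_alt` and `ct_ref` must have equal length")
  }
  check_number(efficiency, "efficiency", min = 1, strict_min = TRUE)
  if (efficiency > 2) stopf("`efficiency` must be in (1, 2]")
  check_number(cross_reactivity_fold, "cross_reactivity_fold", min = 1,
               strict_min = TRUE, finite = FALSE)
  raw <- efficiency^(ct_ref - ct_alt)
  if (is.finite(cross_reactivity_fold)) {
    cr <- cross_reactivity_fold
    k <- 1 / (1 - 1 / cr)
    rho <- pmax(0, (raw - 1 / cr) * k)
  } else {
    rho <- raw
  }
  if (is.null(sample_id)) {
    sample_id <- sprintf("sample_%02d", seq_along(ct_alt))
  }
  data.frame(sample_id = sample_id, alt_reads = NA_integer_,
             ref_reads = NA_integer_, rho = rho,
             mutant_fraction = rho / (1 + rho), source = "qpcr",
             stringsAsFactors = FALSE)
}

#' Pearson correlation of mutant:wild-type ratio with event psi
#'
#' Pairs each sample's ratio with its psi for one event and computes
#' Pearson's r. Samples with an infinite ratio are excluded with a
#' warning; optionally one reference point (ratio 0, reference-cohort
#' median psi) is appended before computing r, mirroring plots that
#' anchor the mutation-free cohort at ratio zero.
#'
#' @param ratios Data frame with `sample_id` and `rho` (e.g. from
#'   [ratio_from_reads()]).
#' @param psi_values Named numeric vector of psi keyed by sample id.
#' @param include_reference_point Append the (0, reference median)
#'   anchor? Default `FALSE`.
#' @param reference_psi_median Reference-cohort median psi; required
#'   when the anchor is requested.
#' @return An object of class `"correlation_result"`: list with `r`,
#'   `n`, `included_reference_point`, `reason` (`NA` unless r is
#'   undefined).
#' @export
correlate_ratio_psi <- function(ratios, psi_values,
                                include_reference_point = FALSE,
                                reference_psi_median = NULL) {
  if (!all(c("sample_id", "rho") %in% names(ratios))) {
    stopf("`ratios` must carry sample_id and rho")
  }
  psi <- psi_values[ratios$sample_id]
  rho <- ratios$rho
  inf <- is.infinite(rho)
  if (any(inf)) {
    warnf("excluding %d sample(s) with infinite ratio from correlation",
          sum(inf))
  }
  keep <- !inf & is.finite(psi) & !is.na(rho)
  x <- rho[keep]; y <- unname(psi[keep])
  if (include_reference_point) {
    if (is.null(reference_psi_median)) {
      stopf("`reference_psi_median` is required when including the reference point")
    }
    x <- c(x, 0); y <- c(y, reference_psi_median)
  }
  if (length(x) < 3L) {
    stopf("need at least 3 paired finite observations, have %d", length(x))
  }
  reason <- NA_character_
  if (sd(x) == 0 || sd(y) == 0) {
    r <- NA_real_
    reason <- "zero variance in ratio or psi"
  } else {
    r <- cor(x, y)
  }
  structure(list(r = r, n = length(x),
                 included_reference_point = include_reference_point,
                 reason = reason),
            class = "correlation_result")
}
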