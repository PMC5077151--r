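#' Construct a simulated splice event with site-specific affinities
#'
#' A simulated alternative-splicing event is a pair of competing 3'
#' splice sites (proximal and distal) with apparent association
#' constants for the wild-type and mutant forms of the splicing factor.
#' The occupancy model ([occupancy_psi()]) turns these affinities and a
#' mutant:wild-type ratio into an inclusion fraction for the proximal
#' isoform.
#'
#' @param event_id Character identifier.
#' @param minus3_base Nucleotide at the -3 position of the proximal 3'
#'   splice site; one of `"A"`, `"C"`, `"G"`, `"T"`.
#' @param ka_wt_prox,ka_wt_dist,ka_mut_prox,ka_mut_dist Apparent
#'   association constants (arbitrary reciprocal-concentration units)
#'   of the wild-type and mutant factor for the proximal and distal
#'   sites. All strictly positive.
#' @param sequence_window Optional nucleotide string covering the
#'   proximal acceptor region; the final `n_exonic` characters are
#'   exonic, so the invariant intronic AG occupies the two positions
#'   just before them and the -3 base the position before the AG.
#' @param n_exonic Number of exonic bases at the end of
#'   `sequence_window` (default 3, matching a -20..+3 window).
#' @param responsive Logical; whether mutant and wild-type affinities
#'   differ for this event (bookkeeping used by the cohort simulator).
#' @return An object of class `"sim_event"`.
#' @seealso [simulate_events()], [occupancy_psi()]
#' @export
sim_event <- function(event_id, minus3_base,
                      ka_wt_prox, ka_wt_dist, ka_mut_prox, ka_mut_dist,
                      sequence_window = NULL, n_exonic = 3L,
                      responsive = NA) {
  if (!is.character(event_id) || length(event_id) != 1L) {
    stopf("`event_id` must be a single string")
  }
  if (!minus3_base %in% DNA_BASES) {
    stopf("`minus3_base` must be one of A/C/G/T, got '%s'", minus3_base)
  }
  for (nm in c("ka_wt_prox", "ka_wt_dist", "ka_mut_prox", "ka_mut_dist")) {
    check_number(get(nm), nm, min = 0, strict_min = TRUE)
  }
  if (!is.null(sequence_window)) {
    w <- toupper(sequence_window)
    len <- nchar(w)
    if (len < n_exonic + 3L) stopf("`sequence_window` too short")
    ag <- substr(w, len - n_exonic - 1L, len - n_exonic)
    if (ag != "AG") {
      stopf("`sequence_window` must carry AG at the splice-site boundary, found '%s'", ag)
    }
    m3 <- substr(w, len - n_exonic - 2L, len - n_exonic - 2L)
    if (m3 != minus3_base) {
      stopf("-3 base of `sequence_window` ('%s') disagrees with `minus3_base` ('%s')",
            m3, minus3_base)
    }
    sequence_window <- w
  }
  structure(
    list(event_id = event_id, minus3_base = minus3_base,
         ka_wt_prox = ka_wt_prox, ka_wt_dist = ka_wt_dist,
         ka_mut_prox = ka_mut_prox, ka_mut_dist = ka_mut_dist,
         sequence_window = sequence_window, n_exonic = as.integer(n_exonic),
         responsive = responsive),
    class = "sim_event")
}

#' Inclusion fraction under the proximal/distal occupancy model
#'
#' Competition between a proximal and a distal 3' splice site is
#' resolved by the relative occupancy of total splicing factor at the
#' two sites. With mutant fraction `f = rho / (1 + rho)` the effective
#' association constant at each site is the mixture
#' `f * Ka_mut + (1 - f) * Ka_wt`, and the proximal share of total
#' occupancy is the predicted inclusion fraction:
#'
#' `psi = Kp / (Kp + Kd)` with `Kp`, `Kd` the mixture constants at the
#' proximal and distal sites.
#'
#' The model assumes equal total splicing-factor abundance across
#' samples, so only the mutant:wild-type ratio matters; it is the
#' simplest dose-response form consistent with site competition and is
#' documented as a modelling choice (see the methods vignette).
#'
#' @param event A [sim_event()].
#' @param rho Mutant:wild-type ratio(s), `>= 0` (may be `Inf` for a
#'   pure-mutant limit). Vectorised.
#' @return Numeric vector of inclusion fractions in (0, 1).
#' @examples
#' ev <- sim_event("ev1", "C", ka_wt_prox = 2, ka_wt_dist = 1,
#'                 ka_mut_prox = 1, ka_mut_dist = 1)
#' occupancy_psi(ev, rho = 1)  # (0.5*1 + 0.5*2) / (1.5 + 1) = 0.6
#' @export
occupancy_psi <- function(event, rho) {
  if (!inherits(event, "sim_event")) stopf("`event` must be a sim_event")
  if (!is.numeric(rho) || length(rho) < 1L || any(is.na(rho)) || any(rho < 0)) {
    stopf("`rho` must be non-negative")
  }
  f <- ifelse(is.infinite(rho), 1, rho / (1 + rho))
  kp <- f * event$ka_mut_prox + (1 - f) * event$ka_wt_prox
  kd <- f * event$ka_mut_dist + (1 - f) * event$ka_wt_dist
  kp / (kp + kd)
}

# polypyrimidine-tract-like acceptor window ending ...<m3>AG + exonic bases
sim_window <- function(minus3_base, n_intronic = 20L, n_exonic = 3L) {
  ppt <- sample(DNA_BASES, n_intronic - 3L, replace = TRUE,
                prob = c(0.10, 0.35, 0.10, 0.45))
  exonic <- sample(DNA_BASES, n_exonic, replace = TRUE,
                   prob = c(0.25, 0.20, 0.35, 0.20))
  paste0(paste(ppt, collapse = ""), minus3_base, "AG",
         paste(exonic, collapse = ""))
}

#' Generate a panel of simulated splice events
#'
#' Events receive a -3 base drawn from an acceptor-consensus-like
#' background (C-rich, then T, A rare, G very rare). A fraction of
#' events are "responsive": their mutant affinity for the proximal site
#' differs from wild type in a direction set by the -3 base (-3C and
#' -3A sites gain affinity by `effect_size`, -3T sites lose it, -3G
#' sites are unaffected), mirroring the altered -3 preference of the
#' mutant factor. Non-responsive events have identical mutant and
#' wild-type affinities.
#'
#' @param n_events Number of events.
#' @param seed Integer seed (required; no global random state is used
#'   implicitly).
#' @param prop_responsive Fraction of events with mutant-specific
#'   affinity changes.
#' @param effect_size Fold-change applied to the mutant proximal-site
#'   affinity of responsive events.
#' @param background_minus3 Named probabilities for the -3 base.
#' @param affinity_sdlog Log-scale SD of baseline affinities (centres
#'   baseline inclusion near 0.5 with realistic spread).
#' @return List of [sim_event()] objects.
#' @export
simulate_events <- function(n_events, seed,
                            prop_responsive = 0.25,
                            effect_size = 3,
                            background_minus3 = c(A = 0.10, C = 0.55,
                                                  G = 0.05, T = 0.30),
                            affinity_sdlog = 0.25) {
  check_number(n_events, "n_events", min = 1)
  check_number(seed, "seed")
  check_number(effect_size, "effect_size", min = 0, strict_min = TRUE)
  set.seed(seed)
  m3 <- sample(names(background_minus3), n_events, replace = TRUE,
               prob = background_minus3)
  kwp <- exp(rnorm(n_events, 0, affinity_sdlog))
  kwd <- exp(rnorm(n_events, 0, affinity_sdlog))
  responsive <- runif(n_events) < prop_responsive
  mult <- c(A = effect_size, C = effect_size, G = 1, T = 1 / effect_size)[m3]
  kmp <- ifelse(responsive, kwp * mult, kwp)
  lapply(seq_len(n_events), function(i) {
    sim_event(event_id = sprintf("ev%04d", i), minus3_base = m3[i],
              ka_wt_prox = kwp[i], ka_wt_dist = kwd[i],
              ka_mut_prox = kmp[i], ka_mut_dist = kwd[i],
              sequence_window = sim_window(m3[i]),
              responsive = responsive[i])
  })
}

#' Cohort-simulation configuration
#'
#' Defaults describe a tumour cohort in which 13 of 512 samples carry
#' the splicing-factor point mutation, with mutant:wild-type mRNA
#' ratios spread over the observed 0.26-0.82 range and a mean of 100
#' informative junction reads per event.
#'
#' @param n_wt_samples,n_mut_samples Sample counts.
#' @param ratio_per_mut_sample Mutant:wild-type ratio per mutant sample
#'   (length `n_mut_samples`); defaults to an even spread over
#'   0.26-0.82.
#' @param read_depth_per_event Informative junction reads per event and
#'   sample.
#' @param allele_depth Variant-spanning reads per sample.
#' @param noise_seed Integer seed for all sampling (required).
#' @return An object of class `"sim_cohort_config"`.
#' @export
sim_cohort_config <- function(n_wt_samples = 499L, n_mut_samples = 13L,
                              ratio_per_mut_sample = NULL,
                              read_depth_per_event = 100L,
                              allele_depth = 100L,
                              noise_seed) {
  check_number(n_wt_samples, "n_wt_samples", min = 0)
  check_number(n_mut_samples, "n_mut_samples", min = 0)
  check_number(read_depth_per_event, "read_depth_per_event", min = 0)
  check_number(allele_depth, "allele_depth", min = 0)
  check_number(noise_seed, "noise_seed")
  if (is.null(ratio_per_mut_sample)) {
    ratio_per_mut_sample <- if (n_mut_samples > 1) {
      seq(0.26, 0.82, length.out = n_mut_samples)
    } else if (n_mut_samples == 1) 0.5 else numeric(0)
  }
  if (length(ratio_per_mut_sample) != n_mut_samples) {
    stopf("`ratio_per_mut_sample` must have length n_mut_samples (%d)",
          n_mut_samples)
  }
  if (any(ratio_per_mut_sample < 0)) stopf("ratios must be >= 0")
  structure(
    list(n_wt_samples = as.integer(n_wt_samples),
         n_mut_samples = as.integer(n_mut_samples),
         ratio_per_mut_sample = as.numeric(ratio_per_mut_sample),
         read_depth_per_event = as.integer(read_depth_per_event),
         allele_depth = as.integer(allele_depth),
         noise_seed = as.integer(noise_seed)),
    class = "sim_cohort_config")
}

#' Simulate a cohort of junction and allele read counts
#'
#' For each event and sample, the true inclusion fraction is the
#' occupancy-model prediction at that sample's mutant:wild-type ratio
#' (wild-type samples have ratio 0). Inclusion reads are drawn
#' `Binomial(depth, psi)` with exclusion reads making up the remainder;
#' variant-spanning alternate-allele reads are drawn
#' `Binomial(allele_depth, f)` with `f = rho / (1 + rho)` (0 in
#' wild-type samples). Ground truth (true psi, true rho) is returned
#' alongside for recovery testing.
#'
#' @param events List of [sim_event()] objects (non-empty).
#' @param config A [sim_cohort_config()].
#' @return An object of class `"sim_cohort"`: list with data frames
#'   `junctions` (sample_id, event_id, inclusion_reads,
#'   exclusion_reads), `alleles` (sample_id, alt_reads, ref_reads), the
#'   event definitions `events`, and `truth` (true psi matrix
#'   events x samples, true rho per sample, generating config).
#' @export
simulate_cohort <- function(events, config) {
  if (!length(events)) stopf("`events` must be a non-empty list of sim_event")
  if (!all(vapply(events, inherits, logical(1), "sim_event"))) {
    stopf("`events` must all be sim_event objects")
  }
  if (!inherits(config, "sim_cohort_config")) {
    stopf("`config` must be a sim_cohort_config")
  }
  set.seed(config$noise_seed)
  event_ids <- vapply(events, `[[`, character(1), "event_id")
  sample_ids <- c(sprintf("WT_%03d", seq_len(config$n_wt_samples)),
                  sprintf("MUT_%03d", seq_len(config$n_mut_samples)))
  rho <- setNames(c(rep(0, config$n_wt_samples), config$ratio_per_mut_sample),
                  sample_ids)
  n_e <- length(events); n_s <- length(sample_ids)

  psi_true <- vapply(sample_ids, function(s) {
    vapply(events, occupancy_psi, numeric(1), rho = rho[[s]])
  }, numeric(n_e))
  psi_true <- matrix(psi_true, nrow = n_e, ncol = n_s,
                     dimnames = list(event_ids, sample_ids))

  depth <- config$read_depth_per_event
  inc <- matrix(rbinom(n_e * n_s, depth, as.vector(psi_true)),
                nrow = n_e, dimnames = dimnames(psi_true))
  junctions <- data.frame(
    sample_id = rep(sample_ids, each = n_e),
    event_id = rep(event_ids, times = n_s),
    inclusion_reads = as.vector(inc),
    exclusion_reads = depth - as.vector(inc),
    stringsAsFactors = FALSE)

  f <- rho / (1 + rho)
  f[is.infinite(rho)] <- 1
  alt <- rbinom(n_s, config$allele_depth, f)
  alleles <- data.frame(sample_id = sample_ids, alt_reads = alt,
                        ref_reads = config$allele_depth - alt,
                        stringsAsFactors = FALSE)

  structure(
    list(junctions = junctions, alleles = alleles, events = events,
         truth = list(psi = psi_true, rho = rho, config = config)),
    class = "sim_cohort")
}

#' Event-definition table for a list of simulated events
#'
#' @param events List of [sim_event()] objects.
#' @return Data frame with columns event_id, gene_name, event_type,
#'   coordinates, minus3_base, responsive, sequence_window (gene names
#'   and coordinates are synthetic placeholders).
#' @export
sim_event_table <- function(events) {
  data.frame(
    event_id = vapply(events, `[[`, character(1), "event_id"),
    gene_name = paste0("GENE_", vapply(events, `[[`, character(1), "event_id")),
    event_type = "se",
    coordinates = sprintf("chrS:%d-%d:+",
                          seq_along(events) * 10000L,
                          seq_along(events) * 10000L + 1000L),
    minus3_base = vapply(events, `[[`, character(1), "minus3_base"),
    responsive = vapply(events, `[[`, logical(1), "responsive"),
    sequence_window = vapply(events, function(e) {
      if (is.null(e$sequence_window)) NA_character_ else e$sequence_window
    }, character(1)),
    stringsAsFactors = FALSE)
}

#' Write a simulated cohort to plain-text files
#'
#' Writes `junctions.tsv`, `alleles.tsv`, `events.tsv` and `truth.json`
#' into `dir`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "sim_cohort")) stopf("`cohort` must be a sim_cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(junctions = file.path(dir, "junctions.tsv"),
             alleles = file.path(dir, "alleles.tsv"),
             events = file.path(dir, "events.tsv"),
             truth = file.path(dir, "truth.json"))
  write_tsv(cohort$junctions, paths[["junctions"]])
  write_tsv(cohort$alleles, paths[["alleles"]])
  write_tsv(sim_event_table(cohort$events), paths[["events"]])
  truth <- list(
    rho = as.list(cohort$truth$rho),
    psi = apply(cohort$truth$psi, 2, as.list),
    config = unclass(cohort$truth$config))
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Simulate a fluorescence anisotropy titration
#'
#' Anisotropy follows the two-state ligand-depletion isotherm: the
#' bound fraction of labelled RNA at total protein `P`, total RNA `R`
#' and dissociation constant `kd` is
#' `FB = ((P + R + kd) - sqrt((P + R + kd)^2 - 4 P R)) / (2 R)`,
#' and the signal is `a_free + (a_bound - a_free) * FB` plus
#' homoscedastic Gaussian noise.
#'
#' @param kd True dissociation constant (> 0; concentration units of
#'   `protein_concs`).
#' @param rna_conc Labelled RNA concentration (> 0, constant).
#' @param protein_concs Non-negative, ascending protein concentrations.
#' @param a_free,a_bound Anisotropy endpoints; the signal must increase
#'   on binding, so `a_bound > a_free` is required.
#' @param noise_sd Gaussian noise SD (anisotropy units).
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @param series_id,replicate_id Identifiers carried into the result.
#' @return A [titration()] object.
#' @export
simulate_titration <- function(kd, rna_conc, protein_concs,
                               a_free = 0.05, a_bound = 0.20,
                               noise_sd = 0, seed = NULL,
                               series_id = "sim", replicate_id = 1L) {
  check_number(kd, "kd", min = 0, strict_min = TRUE)
  check_number(rna_conc, "rna_conc", min = 0, strict_min = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  if (any(protein_concs < 0)) stopf("protein concentrations must be >= 0")
  if (is.unsorted(protein_concs)) {
    stopf("`protein_concs` must be sorted ascending")
  }
  if (a_bound <= a_free) {
    stopf("`a_bound` must exceed `a_free`: anisotropy increases on binding")
  }
  if (noise_sd > 0) {
    if (is.null(seed)) stopf("`seed` is required when `noise_sd` > 0")
    set.seed(seed)
  }
  fb <- bound_fraction(protein_concs, rna_conc, kd)
  a <- a_free + (a_bound - a_free) * fb
  if (noise_sd > 0) a <- a + rnorm(length(a), 0, noise_sd)
  titration(series_id = series_id, rna_conc = rna_conc,
            protein_concs = protein_concs, anisotropy = a,
            replicate_id = replicate_id)
}

#' Bound fraction under the ligand-depletion isotherm
#'
#' @param protein Total protein concentration(s).
#' @param rna Total labelled RNA concentration.
#' @param kd Dissociation constant.
#' @return Bound fraction(s) in \\[0, 1\\].
#' @export
bound_fraction <- function(protein, rna, kd) {
  b <- protein + rna + kd
  disc <- pmax(b^2 - 4 * protein * rna, 0)
  (b - sqrt(disc)) / (2 * rna)
}
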