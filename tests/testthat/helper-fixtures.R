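# Brute-force PSI oracle: each read is an isoform assignment; psi is
# the fraction of informative reads assigned to the inclusion isoform.
oracle_psi <- function(read_assignments, min_informative = 1) {
  informative <- read_assignments[read_assignments %in% c("inc", "exc")]
  if (length(informative) < min_informative) {
    return(list(psi = NA_real_, defined = FALSE))
  }
  list(psi = mean(informative == "inc"), defined = TRUE)
}

# neutral event: proximal/distal symmetric unless overridden
make_event <- function(id = "ev", m3 = "C", kwp = 1, kwd = 1,
                       kmp = kwp, kmd = kwd, window = NULL) {
  sim_event(id, m3, ka_wt_prox = kwp, ka_wt_dist = kwd,
            ka_mut_prox = kmp, ka_mut_dist = kmd,
            sequence_window = window)
}

# 60-nt toy contig with one canonical GT..AG intron on the plus strand:
# exon1 [0,25) | intron [25,55) | exon2 [55,60)
toy_genome <- function() {
  set.seed(42)
  left <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
                collapse = "")
  mid <- paste(sample(c("C", "T"), 25, replace = TRUE), collapse = "")
  intron <- paste0("GT", mid, "TAG")  # 30 nt, -3 base T
  right <- "GGACT"
  genome <- Biostrings::DNAStringSet(paste0(left, intron, right))
  names(genome) <- "chrT"
  genome
}

# reverse-complemented genome with mirrored event coordinates
revcomp_genome <- function(genome) {
  Biostrings::reverseComplement(genome)
}

flip_event <- function(event, contig_length) {
  splice_event(event$event_id, event$event_type, event$chrom,
               start = contig_length - event$end,
               end = contig_length - event$start,
               strand = if (event$strand == "+") "-" else "+",
               proximal_3ss = event$proximal_3ss,
               distal_3ss = event$distal_3ss)
}

fake_fit <- function(ka, series_id = "s", replicate_id = 1L) {
  structure(list(kd = 1 / ka, ka = ka, a_free = 0.05, a_bound = 0.2,
                 residual_norm = 0, converged = TRUE,
                 diagnostics = NA_character_, series_id = series_id,
                 replicate_id = replicate_id),
            class = "binding_fit")
}

# cohort whose -3 base sets the direction of the mutant affinity shift;
# used by signature-recovery and end-to-end tests
classification_cohort <- function(n_events, mut_ratios, n_wt, depth,
                                  seed) {
  events <- simulate_events(n_events, seed = seed, prop_responsive = 0.2,
                            effect_size = 3)
  cfg <- sim_cohort_config(n_wt_samples = n_wt,
                           n_mut_samples = length(mut_ratios),
                           ratio_per_mut_sample = mut_ratios,
                           read_depth_per_event = depth,
                           allele_depth = 100, noise_seed = seed + 1)
  simulate_cohort(events, cfg)
}
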