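#' Default pipeline configuration
#'
#' Returns the declarative configuration consumed by
#' [run_pipeline()]. Defaults describe the cohort the simulator
#' emulates (a large tumour cohort with 13 mutant samples over the
#' 0.26-0.82 ratio range) and the analysis thresholds (inclusive 0.10
#' delta-psi, 20 informative reads, alpha 0.05).
#'
#' @param seed Base integer seed; every stage derives its seed from
#'   it.
#' @param out_dir Output directory.
#' @param stages Stages to run, in pipeline order; any subset of
#'   `simulate`, `psi`, `signature`, `ratio`, `correlate`, `binding`,
#'   `predict`.
#' @param n_events,n_wt_samples,n_mut_samples,ratio_per_mut_sample,read_depth_per_event,allele_depth
#'   Simulator settings (see [sim_cohort_config()] and
#'   [simulate_events()]).
#' @param prop_responsive,effect_size Responsive-event fraction and
#'   affinity effect size.
#' @param delta_psi_threshold,min_informative,alpha,min_logo_sequences
#'   Analysis thresholds.
#' @param n_binding_events,n_binding_replicates,binding_noise_frac
#'   Binding-stage settings: number of responsive events whose sites
#'   are titrated, replicates per series, Gaussian noise as a fraction
#'   of the anisotropy dynamic range.
#' @return A list of class `"run_config"`.
#' @export
default_config <- function(seed = 1L, out_dir = "spliceratio_run",
                           stages = c("simulate", "psi", "signature",
                                      "ratio", "correlate", "binding",
                                      "predict"),
                           n_events = 2000L, n_wt_samples = 499L,
                           n_mut_samples = 13L,
                           ratio_per_mut_sample = NULL,
                           read_depth_per_event = 100L,
                           allele_depth = 100L,
                           prop_responsive = 0.25, effect_size = 3,
                           delta_psi_threshold = 0.10,
                           min_informative = 20L, alpha = 0.05,
                           min_logo_sequences = 10L,
                           n_binding_events = 4L,
                           n_binding_replicates = 3L,
                           binding_noise_frac = 0.02) {
  structure(as.list(environment()), class = "run_config")
}

STAGE_ORDER <- c("simulate", "psi", "signature", "ratio", "correlate",
                 "binding", "predict")

read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown)) {
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  }
  cfg[names(raw)] <- raw
  cfg
}

manifest_entry <- function(stage, params, inputs, outputs) {
  list(stage = stage, params = params,
       param_hash = rlang::hash(params),
       inputs = as.character(inputs), outputs = as.character(outputs),
       package = "spliceratio",
       version = as.character(utils::packageVersion("spliceratio")))
}

#' Run the analysis pipeline from a declarative configuration
#'
#' Executes the selected stages in order
#' `simulate -> psi -> signature -> ratio -> correlate -> binding ->
#' predict`, writing plain-text outputs and a JSON run manifest
#' (inputs, parameters and their hash, package version per stage) into
#' the configured output directory. Reruns with an identical
#' configuration are byte-identical. A stage failure halts the run
#' naming the stage and cause.
#'
#' @param config A [default_config()] list, or the path of a YAML file
#'   with fields overriding the defaults.
#' @return Invisibly, a list with `status` (0 on success), the
#'   `manifest` and the per-stage results.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) {
    config <- structure(config, class = "run_config")
  }
  bad <- setdiff(config$stages, STAGE_ORDER)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  stages <- STAGE_ORDER[STAGE_ORDER %in% config$stages]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  state <- list(config = config, manifest = list())
  for (stage in stages) {
    fn <- switch(stage,
                 simulate = stage_simulate, psi = stage_psi,
                 signature = stage_signature, ratio = stage_ratio,
                 correlate = stage_correlate, binding = stage_binding,
                 predict = stage_predict)
    state <- tryCatch(fn(state), error = function(e) {
      stopf("stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(state$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  message(sprintf("pipeline complete: %d stage(s), manifest at %s",
                  length(stages), manifest_path))
  invisible(list(status = 0L, manifest = state$manifest, state = state))
}

path_in <- function(state, file) file.path(state$config$out_dir, file)

# lazily pull a stage input from memory or from an earlier run's files
need <- function(state, name, loader) {
  if (!is.null(state[[name]])) return(state)
  state[[name]] <- loader(state)
  state
}

stage_simulate <- function(state) {
  cfg <- state$config
  events <- simulate_events(cfg$n_events, seed = cfg$seed + 1L,
                            prop_responsive = cfg$prop_responsive,
                            effect_size = cfg$effect_size)
  cohort_cfg <- sim_cohort_config(
    n_wt_samples = cfg$n_wt_samples, n_mut_samples = cfg$n_mut_samples,
    ratio_per_mut_sample = cfg$ratio_per_mut_sample,
    read_depth_per_event = cfg$read_depth_per_event,
    allele_depth = cfg$allele_depth, noise_seed = cfg$seed)
  cohort <- simulate_cohort(events, cohort_cfg)
  paths <- write_cohort(cohort, cfg$out_dir)
  state$cohort <- cohort
  state$events_tab <- sim_event_table(events)
  state$manifest <- c(state$manifest, list(manifest_entry(
    "simulate",
    params = list(seed = cfg$seed, n_events = cfg$n_events,
                  prop_responsive = cfg$prop_responsive,
                  effect_size = cfg$effect_size,
                  cohort = unclass(cohort_cfg)),
    inputs = character(0), outputs = paths)))
  state
}

stage_psi <- function(state) {
  cfg <- state$config
  jpath <- path_in(state, "junctions.tsv")
  epath <- path_in(state, "events.tsv")
  if (is.null(state$cohort)) {
    junctions <- read_junctions(jpath)
    state$events_tab <- read_events(epath)
  } else {
    junctions <- state$cohort$junctions
  }
  pm <- psi_matrix(junctions, state$events_tab,
                   min_informative = cfg$min_informative)
  out <- path_in(state, "psi.tsv")
  write_psi_matrix(pm, out)
  state$psi <- pm
  state$manifest <- c(state$manifest, list(manifest_entry(
    "psi", params = list(min_informative = cfg$min_informative),
    inputs = c(jpath, epath), outputs = out)))
  state
}

mut_wt_samples <- function(pm) {
  samples <- colnames(pm$psi)
  list(mut = grep("^MUT_", samples, value = TRUE),
       wt = grep("^WT_", samples, value = TRUE))
}

stage_signature <- function(state) {
  cfg <- state$config
  state <- need(state, "psi", function(s) {
    read_psi_matrix(path_in(s, "psi.tsv"), cfg$min_informative)
  })
  state <- need(state, "events_tab", function(s) {
    read_events(path_in(s, "events.tsv"))
  })
  if (!"sequence_window" %in% names(state$events_tab)) {
    stopf("event table lacks sequence windows needed for logos")
  }
  windows <- setNames(state$events_tab$sequence_window,
                      state$events_tab$event_id)
  grp <- mut_wt_samples(state$psi)
  if (!length(grp$mut) || !length(grp$wt)) {
    stopf("signature stage needs MUT_* query and WT_* reference samples")
  }
  calls <- list(); deltas <- list()
  logo_dir <- path_in(state, "logos")
  dir.create(logo_dir, showWarnings = FALSE)
  outputs <- character(0)
  for (s in grp$mut) {
    sig <- signature_for_sample(state$psi, grp$wt, s, windows,
                                threshold = cfg$delta_psi_threshold,
                                min_sequences = cfg$min_logo_sequences)
    deltas[[s]] <- sig$delta
    calls[[s]] <- data.frame(
      sample_id = s, class = sig$call$class, score = sig$call$score,
      n_promoted = sum(sig$delta$call == "promoted"),
      n_repressed = sum(sig$delta$call == "repressed"),
      stringsAsFactors = FALSE)
    for (side in c("promoted", "repressed")) {
      logo <- sig[[paste0(side, "_logo")]]
      if (!is.null(logo)) {
        p <- file.path(logo_dir, sprintf("%s_%s_logo.tsv", s, side))
        write_logo(logo, p)
        outputs <- c(outputs, p)
      }
    }
  }
  delta_tab <- do.call(rbind, deltas)
  rownames(delta_tab) <- NULL
  calls_tab <- do.call(rbind, calls)
  rownames(calls_tab) <- NULL
  dpath <- path_in(state, "delta_psi.tsv")
  cpath <- path_in(state, "signature_calls.tsv")
  write_tsv(delta_tab, dpath)
  write_tsv(calls_tab, cpath)
  state$delta <- delta_tab
  state$signature_calls <- calls_tab
  state$manifest <- c(state$manifest, list(manifest_entry(
    "signature",
    params = list(delta_psi_threshold = cfg$delta_psi_threshold,
                  min_logo_sequences = cfg$min_logo_sequences),
    inputs = c(path_in(state, "psi.tsv"), path_in(state, "events.tsv")),
    outputs = c(dpath, cpath, outputs))))
  state
}

stage_ratio <- function(state) {
  apath <- path_in(state, "alleles.tsv")
  alleles <- if (is.null(state$cohort)) read_alleles(apath) else
    state$cohort$alleles
  ratios <- ratio_from_reads(alleles$alt_reads, alleles$ref_reads,
                             sample_id = alleles$sample_id)
  out <- path_in(state, "ratios.tsv")
  write_tsv(ratios, out)
  state$ratios <- ratios
  state$manifest <- c(state$manifest, list(manifest_entry(
    "ratio", params = list(), inputs = apath, outputs = out)))
  state
}

# events ranked by mean |delta psi| across mutant samples
top_shifted_events <- function(delta, n) {
  agg <- tapply(delta$delta_psi, delta$event_id, mean)
  names(sort(abs(agg), decreasing = TRUE))[seq_len(min(n, length(agg)))]
}

stage_correlate <- function(state) {
  cfg <- state$config
  state <- need(state, "psi", function(s) {
    read_psi_matrix(path_in(s, "psi.tsv"), cfg$min_informative)
  })
  state <- need(state, "ratios", function(s) {
    read_tsv(path_in(s, "ratios.tsv"), required = c("sample_id", "rho"))
  })
  state <- need(state, "delta", function(s) {
    read_tsv(path_in(s, "delta_psi.tsv"),
             required = c("event_id", "sample_id", "delta_psi", "call"))
  })
  grp <- mut_wt_samples(state$psi)
  events <- top_shifted_events(state$delta, 5L)
  mut_ratios <- state$ratios[state$ratios$sample_id %in% grp$mut, ]
  rows <- lapply(events, function(ev) {
    psi_col <- state$psi$psi[ev, ]
    ref_med <- median(psi_col[grp$wt], na.rm = TRUE)
    res <- tryCatch(
      correlate_ratio_psi(mut_ratios, psi_col,
                          include_reference_point = TRUE,
                          reference_psi_median = ref_med),
      error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(event_id = ev, r = res$r, n = res$n,
               included_reference_point = res$included_reference_point,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  out <- path_in(state, "correlations.tsv")
  write_tsv(tab, out)
  state$correlations <- tab
  state$manifest <- c(state$manifest, list(manifest_entry(
    "correlate", params = list(n_events = 5L, include_reference_point = TRUE),
    inputs = c(path_in(state, "ratios.tsv"), path_in(state, "psi.tsv")),
    outputs = out)))
  state
}

stage_binding <- function(state) {
  cfg <- state$config
  if (is.null(state$cohort)) {
    stopf("binding stage requires the simulate stage in the same run (site affinities come from the simulated events)")
  }
  events <- state$cohort$events
  responsive <- Filter(function(e) isTRUE(e$responsive) &&
                         e$minus3_base != "G", events)
  if (!length(responsive)) stopf("no responsive events to titrate")
  chosen <- responsive[seq_len(min(cfg$n_binding_events, length(responsive)))]

  a_free <- 0.05; a_bound <- 0.20
  noise_sd <- cfg$binding_noise_frac * (a_bound - a_free)
  fits <- list(); fit_rows <- list(); fc_list <- list()
  seed_i <- 0L
  for (e in chosen) {
    fc_sites <- list()
    for (site in c("prox", "dist")) {
      side_fc <- list()
      for (form in c("wt", "mut")) {
        ka <- e[[paste0("ka_", form, "_", site)]]
        kd <- 1 / ka
        pconc <- kd * c(0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10, 20, 50)
        reps <- lapply(seq_len(cfg$n_binding_replicates), function(r) {
          seed_i <<- seed_i + 1L
          tt <- simulate_titration(
            kd = kd, rna_conc = kd / 10, protein_concs = pconc,
            a_free = a_free, a_bound = a_bound, noise_sd = noise_sd,
            seed = cfg$seed + 5000L + seed_i,
            series_id = sprintf("%s_%s_%s", e$event_id, site, form),
            replicate_id = r)
          fit_titration(tt)
        })
        side_fc[[form]] <- reps
        for (f in reps) {
          fit_rows[[length(fit_rows) + 1L]] <- data.frame(
            series_id = f$series_id, replicate_id = f$replicate_id,
            kd = f$kd, ka = f$ka, a_free = f$a_free, a_bound = f$a_bound,
            residual_norm = f$residual_norm, converged = f$converged,
            stringsAsFactors = FALSE)
        }
      }
      fc_sites[[site]] <- fold_change(
        side_fc$wt, side_fc$mut,
        site_id = sprintf("%s_%s", e$event_id, site), alpha = cfg$alpha)
    }
    fc_list[[e$event_id]] <- fc_sites
  }
  fits_tab <- do.call(rbind, fit_rows)
  fpath <- path_in(state, "binding_fits.tsv")
  write_tsv(fits_tab, fpath)
  state$binding_fc <- fc_list
  state$manifest <- c(state$manifest, list(manifest_entry(
    "binding",
    params = list(n_binding_events = length(chosen),
                  n_binding_replicates = cfg$n_binding_replicates,
                  binding_noise_frac = cfg$binding_noise_frac),
    inputs = character(0), outputs = fpath)))
  state
}

stage_predict <- function(state) {
  cfg <- state$config
  if (is.null(state$binding_fc)) {
    stopf("predict stage requires the binding stage")
  }
  state <- need(state, "delta", function(s) {
    read_tsv(path_in(s, "delta_psi.tsv"),
             required = c("event_id", "sample_id", "delta_psi", "call"))
  })
  obs_mean <- tapply(state$delta$delta_psi, state$delta$event_id, mean)
  preds <- lapply(names(state$binding_fc), function(ev) {
    fc <- state$binding_fc[[ev]]
    obs <- if (ev %in% names(obs_mean)) {
      if (obs_mean[[ev]] >= 0) "increased" else "decreased"
    } else NA_character_
    competition_prediction(ev, fc$prox, fc$dist, observed = obs)
  })
  conc <- suppressWarnings(concordance(preds))
  out <- path_in(state, "predictions.tsv")
  write_tsv(conc$table, out)
  state$concordance <- conc
  state$manifest <- c(state$manifest, list(manifest_entry(
    "predict", params = list(alpha = cfg$alpha),
    inputs = c(path_in(state, "binding_fits.tsv"),
               path_in(state, "delta_psi.tsv")),
    outputs = out)))
  state
}
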