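#' Recognised alternative-splicing event type codes
#'
#' `se` cassette exon, `a5ss`/`a3ss` competing 5'/3' splice sites,
#' `mxe` mutually exclusive exons, `ri`/`ci` retained introns annotated
#' alternative/constitutive, `cj` constitutive junction.
#'
#' @export
EVENT_TYPES <- c("se", "a5ss", "a3ss", "mxe", "ri", "ci", "cj")

#' Percent-spliced-in for one event in one sample
#'
#' The estimator is the junction-read ratio: psi equals the
#' inclusion-supporting reads over all informative reads. For cassette
#' exons (`se`) inclusion is supported by two junctions (upstream and
#' downstream of the exon) that no single read can span both of, so
#' when two inclusion counts are supplied they are averaged before the
#' ratio. Psi is reported as undefined when fewer than
#' `min_informative` reads support the event.
#'
#' @param inclusion_reads Inclusion-junction count; for `se` events a
#'   length-2 vector of the two inclusion junction counts is accepted
#'   and averaged.
#' @param exclusion_reads Exclusion-junction count.
#' @param event_type Event type code (see [EVENT_TYPES]).
#' @param min_informative Minimum informative reads for a defined psi
#'   (default 20).
#' @return An object of class `"psi_value"`: list with `psi`,
#'   `informative_reads`, `defined`.
#' @examples
#' compute_psi(50, 50)                   # psi 0.5, defined
#' compute_psi(12, 5, min_informative = 20)  # undefined: 17 reads
#' @export
compute_psi <- function(inclusion_reads, exclusion_reads,
                        event_type = "se", min_informative = 20) {
  check_counts(inclusion_reads, "inclusion_reads")
  check_counts(exclusion_reads, "exclusion_reads")
  if (!event_type %in% EVENT_TYPES) {
    stopf("unknown event_type '%s'", event_type)
  }
  if (length(inclusion_reads) == 2L) {
    if (event_type != "se") {
      stopf("two inclusion counts are only meaningful for 'se' events")
    }
    inc <- mean(inclusion_reads)
  } else if (length(inclusion_reads) == 1L) {
    inc <- inclusion_reads
  } else {
    stopf("`inclusion_reads` must have length 1 or 2")
  }
  if (length(exclusion_reads) != 1L) {
    stopf("`exclusion_reads` must have length 1")
  }
  informative <- inc + exclusion_reads
  defined <- informative >= min_informative && informative > 0
  psi <- if (informative > 0) inc / informative else NA_real_
  structure(list(psi = psi, informative_reads = informative,
                 defined = defined),
            class = "psi_value")
}

#' Build a psi matrix from a junction-count table
#'
#' One cell per (event, sample); pairs absent from the table are
#' undefined, duplicated pairs are an error, and count rows for events
#' missing from the definitions fail naming the offending id.
#'
#' @param junctions Data frame with columns `sample_id`, `event_id`,
#'   `inclusion_reads`, `exclusion_reads` (see [read_junctions()]).
#' @param events Event definitions: data frame with `event_id` and
#'   `event_type` (see [read_events()]) or a list of [sim_event()]
#'   objects.
#' @param min_informative Minimum informative reads for a defined psi.
#' @return An object of class `"psi_matrix"`: list with numeric
#'   matrices `psi` and `informative` plus logical `defined`, all
#'   events x samples, and the `min_informative` threshold used.
#' @export
psi_matrix <- function(junctions, events, min_informative = 20) {
  if (is.list(events) && !is.data.frame(events) &&
      all(vapply(events, inherits, logical(1), "sim_event"))) {
    events <- sim_event_table(events)
  }
  if (!all(c("event_id", "event_type") %in% names(events))) {
    stopf("`events` must carry event_id and event_type")
  }
  required <- c("sample_id", "event_id", "inclusion_reads", "exclusion_reads")
  missing <- setdiff(required, names(junctions))
  if (length(missing)) {
    stopf("`junctions` missing column(s): %s", paste(missing, collapse = ", "))
  }
  check_counts(junctions$inclusion_reads, "inclusion_reads")
  check_counts(junctions$exclusion_reads, "exclusion_reads")

  unknown <- setdiff(unique(junctions$event_id), events$event_id)
  if (length(unknown)) {
    stopf("junction table contains undefined event(s): %s",
          paste(head(unknown, 5), collapse = ", "))
  }
  key <- paste(junctions$sample_id, junctions$event_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- strsplit(key[duplicated(key)][1], "\r")[[1]]
    stopf("duplicated (sample, event) pair: (%s, %s)", dup[1], dup[2])
  }

  event_ids <- events$event_id
  sample_ids <- unique(junctions$sample_id)
  dims <- list(event_ids, sample_ids)
  psi <- informative <- matrix(NA_real_, length(event_ids),
                               length(sample_ids), dimnames = dims)
  defined <- matrix(FALSE, length(event_ids), length(sample_ids),
                    dimnames = dims)
  if (nrow(junctions)) {
    ei <- match(junctions$event_id, event_ids)
    si <- match(junctions$sample_id, sample_ids)
    idx <- cbind(ei, si)
    inf <- junctions$inclusion_reads + junctions$exclusion_reads
    informative[idx] <- inf
    psi[idx] <- ifelse(inf > 0, junctions$inclusion_reads / inf, NA_real_)
    defined[idx] <- inf >= min_informative & inf > 0
    psi[idx][!defined[idx]] <- NA_real_
  }
  psi[!defined] <- NA_real_
  structure(list(psi = psi, informative = informative, defined = defined,
                 min_informative = min_informative),
            class = "psi_matrix")
}

#' @export
print.psi_matrix <- function(x, ...) {
  cat(sprintf("psi_matrix: %d events x %d samples (%.1f%% defined, min %d reads)\n",
              nrow(x$psi), ncol(x$psi), 100 * mean(x$defined),
              x$min_informative))
  invisible(x)
}

#' Write a psi matrix as TSV (events as rows, samples as columns)
#'
#' Undefined cells are written as `NA`.
#'
#' @param pm A [psi_matrix()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_psi_matrix <- function(pm, path) {
  if (!inherits(pm, "psi_matrix")) stopf("`pm` must be a psi_matrix")
  df <- data.frame(event_id = rownames(pm$psi), pm$psi,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a psi matrix written by [write_psi_matrix()]
#'
#' @param path TSV file path.
#' @param min_informative Threshold recorded on the returned object
#'   (support counts are not stored in the TSV).
#' @return A `"psi_matrix"` object; `informative` is `NA` for cells
#'   read from file.
#' @export
read_psi_matrix <- function(path, min_informative = 20) {
  df <- read_tsv(path, required = "event_id")
  m <- as.matrix(df[, setdiff(names(df), "event_id"), drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$event_id
  structure(list(psi = m,
                 informative = matrix(NA_real_, nrow(m), ncol(m),
                                      dimnames = dimnames(m)),
                 defined = !is.na(m),
                 min_informative = min_informative),
            class = "psi_matrix")
}
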