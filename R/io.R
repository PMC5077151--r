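write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, required = character(0)) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stopf("%s: missing required column(s): %s", path,
          paste(missing, collapse = ", "))
  }
  df
}

#' Read a junction-count table
#'
#' Expects tab-separated columns `sample_id`, `event_id`,
#' `inclusion_reads`, `exclusion_reads`. Count columns are validated
#' cell by cell; a non-integer or negative value fails with the file,
#' line and column named.
#'
#' @param path TSV file path.
#' @return Data frame of junction counts.
#' @export
read_junctions <- function(path) {
  df <- read_tsv(path, required = c("sample_id", "event_id",
                                    "inclusion_reads", "exclusion_reads"))
  for (col in c("inclusion_reads", "exclusion_reads")) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) | val < 0 | val != floor(val))
    if (length(bad)) {
      stopf("%s: line %d, column '%s': invalid count '%s'",
            path, bad[1] + 1L, col, raw[bad[1]])
    }
    df[[col]] <- as.integer(val)
  }
  df
}

#' Read an event-definition table
#'
#' Tab-separated with at least `event_id` and `event_type` columns;
#' genomic `coordinates` and per-event extras (e.g. acceptor sequence
#' windows from the simulator) are carried through when present.
#'
#' @param path TSV file path.
#' @return Data frame of event definitions.
#' @export
read_events <- function(path) {
  df <- read_tsv(path, required = c("event_id", "event_type"))
  bad <- setdiff(unique(df$event_type), EVENT_TYPES)
  if (length(bad)) {
    stopf("%s: unknown event_type value(s): %s", path,
          paste(bad, collapse = ", "))
  }
  if (anyDuplicated(df$event_id)) {
    stopf("%s: duplicated event_id", path)
  }
  df
}

#' Read an allele-count table
#'
#' @param path TSV with columns `sample_id`, `alt_reads`, `ref_reads`.
#' @return Data frame of allele counts.
#' @export
read_alleles <- function(path) {
  df <- read_tsv(path, required = c("sample_id", "alt_reads", "ref_reads"))
  check_counts(df$alt_reads, "alt_reads")
  check_counts(df$ref_reads, "ref_reads")
  df
}

#' Read a titration series table
#'
#' @param path CSV with columns `series_id`, `replicate_id`,
#'   `rna_conc`, `protein_conc`, `anisotropy`.
#' @return List of [titration()] objects, one per
#'   (series_id, replicate_id).
#' @export
read_titrations <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.delim(path, sep = ",", stringsAsFactors = FALSE)
  required <- c("series_id", "replicate_id", "rna_conc", "protein_conc",
                "anisotropy")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stopf("%s: missing required column(s): %s", path,
          paste(missing, collapse = ", "))
  }
  keys <- interaction(df$series_id, df$replicate_id, drop = TRUE)
  lapply(split(df, keys), function(d) {
    d <- d[order(d$protein_conc), ]
    titration(series_id = d$series_id[1], rna_conc = d$rna_conc[1],
              protein_concs = d$protein_conc, anisotropy = d$anisotropy,
              replicate_id = d$replicate_id[1])
  })
}
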