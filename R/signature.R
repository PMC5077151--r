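#' Construct a splice-event record with genomic coordinates
#'
#' Coordinates are 0-based half-open. `start`/`end` delimit the intron
#' whose 3' (acceptor) end is analysed: on the plus strand the intron
#' occupies `[start, end)` and its acceptor AG the final two bases; on
#' the minus strand the intron is the reverse complement of that
#' interval, so the acceptor lies at `start`.
#'
#' @param event_id Identifier.
#' @param event_type One of [EVENT_TYPES].
#' @param chrom Contig name.
#' @param start,end 0-based half-open intron coordinates
#'   (`start < end`).
#' @param strand `"+"` or `"-"`.
#' @param gene_name Optional gene symbol.
#' @param proximal_3ss,distal_3ss Acceptor coordinates of the two
#'   competing sites; required (and required distinct) for `a3ss`
#'   events.
#' @return An object of class `"splice_event"`.
#' @export
splice_event <- function(event_id, event_type, chrom, start, end,
                         strand = "+", gene_name = NA_character_,
                         proximal_3ss = NA_integer_,
                         distal_3ss = NA_integer_) {
  if (!event_type %in% EVENT_TYPES) {
    stopf("unknown event_type '%s'", event_type)
  }
  check_number(start, "start", min = 0)
  check_number(end, "end", min = 0)
  if (start >= end) stopf("`start` must be < `end`")
  if (!strand %in% c("+", "-")) stopf("`strand` must be '+' or '-'")
  if (event_type == "a3ss") {
    if (is.na(proximal_3ss) || is.na(distal_3ss) ||
        proximal_3ss == distal_3ss) {
      stopf("a3ss events need two distinct acceptor coordinates")
    }
  }
  structure(list(event_id = event_id, gene_name = gene_name,
                 event_type = event_type, chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 strand = strand, proximal_3ss = proximal_3ss,
                 distal_3ss = distal_3ss),
            class = "splice_event")
}

#' Delta-psi of one query sample against a reference cohort
#'
#' For every retained event, delta-psi is the query psi minus the
#' median psi across reference samples with a defined value. Events
#' are dropped when the query psi is undefined or fewer than
#' `min_ref_fraction` of reference samples have a defined psi. Events
#' whose inclusion changed by `threshold` or more (inclusive) are
#' called `promoted`; by `-threshold` or less, `repressed`; otherwise
#' `unaffected`.
#'
#' @param psi A [psi_matrix()].
#' @param reference_sample_ids Reference (e.g. mutation-free) sample
#'   ids; must not contain the query.
#' @param query_sample_id Sample to compare.
#' @param threshold Inclusive delta-psi call threshold (default 0.10,
#'   i.e. a change of ten percentage points or more).
#' @param min_ref_fraction Minimum fraction of references with defined
#'   psi (default 0.5).
#' @return Data frame with columns `event_id`, `sample_id`,
#'   `delta_psi`, `call`; the threshold is recorded as an attribute.
#' @export
delta_psi_vs_reference <- function(psi, reference_sample_ids,
                                   query_sample_id, threshold = 0.10,
                                   min_ref_fraction = 0.5) {
  if (!inherits(psi, "psi_matrix")) stopf("`psi` must be a psi_matrix")
  samples <- colnames(psi$psi)
  absent <- setdiff(c(reference_sample_ids, query_sample_id), samples)
  if (length(absent)) {
    stopf("sample(s) not in psi matrix: %s", paste(absent, collapse = ", "))
  }
  if (query_sample_id %in% reference_sample_ids) {
    stopf("query sample '%s' must not be in the reference set",
          query_sample_id)
  }
  check_number(threshold, "threshold", min = 0)

  ref <- psi$psi[, reference_sample_ids, drop = FALSE]
  ref_def <- psi$defined[, reference_sample_ids, drop = FALSE]
  q <- psi$psi[, query_sample_id]
  q_def <- psi$defined[, query_sample_id]
  ref_frac <- rowMeans(ref_def)
  keep <- q_def & ref_frac >= min_ref_fraction & rowSums(ref_def) >= 1
  ref_median <- apply(ref, 1, median, na.rm = TRUE)
  dpsi <- q - ref_median
  # inclusive threshold, robust to binary representation of e.g. 0.5 - 0.4
  eps <- 1e-9
  call <- ifelse(dpsi >= threshold - eps, "promoted",
                 ifelse(dpsi <= -threshold + eps, "repressed", "unaffected"))
  out <- data.frame(event_id = rownames(psi$psi)[keep],
                    sample_id = query_sample_id,
                    delta_psi = unname(dpsi[keep]),
                    call = unname(call[keep]),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  out
}

#' Extract the 3' splice-site window of an event
#'
#' Returns the strand-corrected acceptor window (default positions -20
#' through +3, numbered so that -2/-1 are the invariant intronic AG
#' and +1..+3 the first exonic bases). Events whose intron does not
#' begin GT and end AG in transcript orientation are rejected, as are
#' windows that run past the intron or contig bounds; rejections carry
#' a reason rather than a silent NA.
#'
#' @param event A [splice_event()].
#' @param sequences A named `Biostrings::DNAStringSet` or a FASTA file
#'   path.
#' @param window Integer pair `c(upstream, downstream)` relative to the
#'   acceptor, default `c(-20, 3)`.
#' @return List with `accepted` (logical), `window` (string or `NA`)
#'   and `reason` (string or `NA`).
#' @export
extract_3ss_window <- function(event, sequences, window = c(-20, 3)) {
  if (!inherits(event, "splice_event")) {
    stopf("`event` must be a splice_event")
  }
  if (is.character(sequences) && length(sequences) == 1L) {
    sequences <- Biostrings::readDNAStringSet(sequences)
    names(sequences) <- sub("\\s.*$", "", names(sequences))
  }
  reject <- function(reason) list(accepted = FALSE, window = NA_character_,
                                  reason = reason)
  if (!event$chrom %in% names(sequences)) {
    return(reject(sprintf("contig '%s' not in sequences", event$chrom)))
  }
  contig <- sequences[[event$chrom]]
  len <- length(contig)
  n_up <- -window[1]; n_ex <- window[2]
  if (n_up < 3 || n_ex < 0) stopf("`window` must cover at least -3..0")
  s <- event$start; e <- event$end
  if (e > len) return(reject("intron exceeds contig bounds"))
  if (e - s < n_up) return(reject("intron shorter than requested window"))

  sub <- function(from, to) as.character(Biostrings::subseq(contig, from, to))
  if (event$strand == "+") {
    donor <- sub(s + 1, s + 2)
    acceptor <- sub(e - 1, e)
    if (donor != "GT" || acceptor != "AG") {
      return(reject(sprintf("non-canonical splice sites (%s..%s)",
                            donor, acceptor)))
    }
    if (e + n_ex > len) return(reject("window exceeds contig bounds"))
    win <- sub(e - n_up + 1, e + n_ex)
  } else {
    donor <- chartr("ACGT", "TGCA", paste0(rev(strsplit(sub(e - 1, e), "")[[1]]),
                                           collapse = ""))
    acceptor <- chartr("ACGT", "TGCA", paste0(rev(strsplit(sub(s + 1, s + 2), "")[[1]]),
                                              collapse = ""))
    if (donor != "GT" || acceptor != "AG") {
      return(reject(sprintf("non-canonical splice sites (%s..%s)",
                            donor, acceptor)))
    }
    if (s - n_ex < 0) return(reject("window exceeds contig bounds"))
    plus <- Biostrings::subseq(contig, s - n_ex + 1, s + n_up)
    win <- as.character(Biostrings::reverseComplement(plus))
  }
  list(accepted = TRUE, window = win, reason = NA_character_)
}

#' Build a position-frequency logo with per-position information
#' content
#'
#' Per-position nucleotide frequencies over A/C/G/T plus the
#' information content `IC = 2 + sum(f * log2(f))` bits (with
#' `0 * log2(0)` taken as 0 and no small-sample correction); an
#' invariant position scores 2 bits, a uniform one 0. Ambiguous bases
#' are dropped per column and the remaining frequencies renormalised.
#'
#' @param windows Character vector of equal-length sequences.
#' @param positions Optional position labels (e.g. `-20..-1, +1..+3`);
#'   defaults to acceptor-style labels when the width matches
#'   `n_exonic` exonic positions, else `1..W`.
#' @param n_exonic Number of trailing exonic positions used for
#'   default labels.
#' @return An object of class `"logo_matrix"`: list with `freq` (4 x W
#'   matrix), `ic` (bits per position), `n_sequences`, `positions`.
#' @examples
#' build_logo(c("ACG", "ACT", "ACG"))
#' @export
build_logo <- function(windows, positions = NULL, n_exonic = 3L) {
  if (!length(windows)) stopf("`windows` must contain at least one sequence")
  windows <- toupper(windows)
  w <- unique(nchar(windows))
  if (length(w) != 1L) stopf("`windows` must all have equal length")
  if (is.null(positions)) {
    if (w > n_exonic) {
      positions <- c(seq(-(w - n_exonic), -1), seq_len(n_exonic))
    } else {
      positions <- seq_len(w)
    }
  }
  if (length(positions) != w) stopf("`positions` must have length %d", w)
  chars <- matrix(unlist(strsplit(windows, ""), use.names = FALSE),
                  nrow = length(windows), byrow = TRUE)
  freq <- vapply(seq_len(w), function(j) {
    col <- chars[, j]
    col <- col[col %in% DNA_BASES]
    if (!length(col)) {
      stopf("column %d has no unambiguous bases", j)
    }
    tab <- table(factor(col, levels = DNA_BASES))
    as.numeric(tab) / length(col)
  }, numeric(4))
  dimnames(freq) <- list(DNA_BASES, positions)
  ic <- apply(freq, 2, function(f) {
    2 + sum(ifelse(f > 0, f * log2(f), 0))
  })
  structure(list(freq = freq, ic = ic, n_sequences = length(windows),
                 positions = positions),
            class = "logo_matrix")
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat(sprintf("logo_matrix: %d positions (%s..%s), %d sequences\n",
              length(x$positions), x$positions[1],
              x$positions[length(x$positions)], x$n_sequences))
  invisible(x)
}

#' Nucleotide frequencies at a labelled logo position
#'
#' @param logo A [build_logo()] result.
#' @param position Position label (default `-3`, the base that
#'   discriminates mutant-preferred acceptors).
#' @return Named frequency vector over A/C/G/T.
#' @export
logo_position_freq <- function(logo, position = -3) {
  if (!inherits(logo, "logo_matrix")) stopf("`logo` must be a logo_matrix")
  j <- match(position, logo$positions)
  if (is.na(j)) stopf("position %s not in logo", format(position))
  logo$freq[, j]
}

#' Write a logo matrix as TSV (position, A, C, G, T, IC_bits)
#'
#' @param logo A [build_logo()] result.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_logo <- function(logo, path) {
  df <- data.frame(position = logo$positions, t(logo$freq),
                   IC_bits = logo$ic, check.names = FALSE)
  write_tsv(df, path)
}

#' Classify a sample's splicing signature from its -3 consensus
#'
#' The typical mutant signature requires both discriminating patterns
#' at the -3 position: A more frequent than T among acceptors of
#' promoted events, and T more frequent than C among acceptors of
#' repressed events. Samples with only one or neither pattern
#' (partially or completely absent) collapse to the quasi-wild-type
#' class. The score is
#' `(f_A - f_T)_promoted + (f_T - f_C)_repressed`. Either set smaller
#' than `min_sequences` yields an undetermined call.
#'
#' @param promoted_logo,repressed_logo [build_logo()] results covering
#'   position -3, built from the promoted and repressed acceptor
#'   windows.
#' @param min_sequences Minimum sequences per logo (default 10).
#' @param sample_id Optional identifier carried into the result.
#' @return An object of class `"signature_call"`: list with
#'   `sample_id`, `class` (`"typical_S34F"`, `"quasi_WT"` or
#'   `"undetermined"`), `promoted_minus3`, `repressed_minus3`,
#'   `score`.
#' @export
classify_signature <- function(promoted_logo, repressed_logo,
                               min_sequences = 10L,
                               sample_id = NA_character_) {
  fp <- logo_position_freq(promoted_logo, -3)
  fr <- logo_position_freq(repressed_logo, -3)
  score <- unname((fp["A"] - fp["T"]) + (fr["T"] - fr["C"]))
  if (promoted_logo$n_sequences < min_sequences ||
      repressed_logo$n_sequences < min_sequences) {
    cls <- "undetermined"
  } else if (fp["A"] > fp["T"] && fr["T"] > fr["C"]) {
    cls <- "typical_S34F"
  } else {
    cls <- "quasi_WT"
  }
  structure(list(sample_id = sample_id, class = cls,
                 promoted_minus3 = fp, repressed_minus3 = fr,
                 score = score),
            class = "signature_call")
}

#' @export
print.signature_call <- function(x, ...) {
  cat(sprintf("signature_call: %s -> %s (score %.3f)\n",
              ifelse(is.na(x$sample_id), "<sample>", x$sample_id),
              x$class, x$score))
  invisible(x)
}

#' Delta-psi, logos and signature class for one sample
#'
#' Convenience wrapper: computes delta-psi against the reference set,
#' builds promoted/repressed acceptor logos from per-event sequence
#' windows, and classifies the signature.
#'
#' @param psi A [psi_matrix()].
#' @param reference_sample_ids,query_sample_id As in
#'   [delta_psi_vs_reference()].
#' @param windows Named character vector of acceptor windows (names are
#'   event ids), e.g. the `sequence_window` column of a simulated
#'   event table or [extract_3ss_window()] results.
#' @param threshold Delta-psi call threshold.
#' @param min_sequences Logo floor for a determined class.
#' @return List with `delta` (the delta-psi records), `promoted_logo`,
#'   `repressed_logo` (either may be `NULL` when no events qualify)
#'   and `call` (a `signature_call`).
#' @export
signature_for_sample <- function(psi, reference_sample_ids,
                                 query_sample_id, windows,
                                 threshold = 0.10, min_sequences = 10L) {
  delta <- delta_psi_vs_reference(psi, reference_sample_ids,
                                  query_sample_id, threshold = threshold)
  logo_for <- function(call) {
    ids <- delta$event_id[delta$call == call]
    w <- windows[intersect(ids, names(windows))]
    if (!length(w)) return(NULL)
    build_logo(unname(w))
  }
  promoted <- logo_for("promoted")
  repressed <- logo_for("repressed")
  call <- if (is.null(promoted) || is.null(repressed)) {
    structure(list(sample_id = query_sample_id, class = "undetermined",
                   promoted_minus3 = NULL, repressed_minus3 = NULL,
                   score = NA_real_),
              class = "signature_call")
  } else {
    classify_signature(promoted, repressed, min_sequences = min_sequences,
                       sample_id = query_sample_id)
  }
  list(delta = delta, promoted_logo = promoted,
       repressed_logo = repressed, call = call)
}

#' Compare two differential-splicing signatures over one event universe
#'
#' Counts events called promoted (and repressed) in only the first
#' record set, only the second, or both; for shared events the
#' enhancement is `delta_psi_b - delta_psi_a`, ordered decreasing for
#' waterfall-style display.
#'
#' @param delta_a,delta_b Delta-psi record sets from
#'   [delta_psi_vs_reference()] computed over the same event universe.
#' @return An object of class `"signature_comparison"`: per-direction
#'   counts (`only_a`, `only_b`, `shared`) and shared-event tables
#'   with enhancements.
#' @export
compare_signatures <- function(delta_a, delta_b) {
  for (d in list(delta_a, delta_b)) {
    if (!all(c("event_id", "delta_psi", "call") %in% names(d))) {
      stopf("delta-psi records need event_id, delta_psi and call columns")
    }
  }
  if (!setequal(delta_a$event_id, delta_b$event_id)) {
    stopf("record sets cover different event universes")
  }
  one_direction <- function(call) {
    a <- delta_a$event_id[delta_a$call == call]
    b <- delta_b$event_id[delta_b$call == call]
    shared <- intersect(a, b)
    tab <- data.frame(
      event_id = shared,
      delta_psi_a = delta_a$delta_psi[match(shared, delta_a$event_id)],
      delta_psi_b = delta_b$delta_psi[match(shared, delta_b$event_id)],
      stringsAsFactors = FALSE)
    tab$enhancement <- tab$delta_psi_b - tab$delta_psi_a
    tab <- tab[order(tab$enhancement, decreasing = TRUE), ]
    rownames(tab) <- NULL
    list(only_a = length(setdiff(a, b)), only_b = length(setdiff(b, a)),
         shared = length(shared), shared_events = tab)
  }
  structure(list(promoted = one_direction("promoted"),
                 repressed = one_direction("repressed")),
            class = "signature_comparison")
}

#' Two-group comparison by Mann-Whitney U or Student's t test
#'
#' The Mann-Whitney statistic is the U of the first group; p-values
#' are two-sided, exact when `n_a * n_b <= 400` and tie-free,
#' otherwise a normal approximation with tie correction.
#'
#' @param values_a,values_b Numeric observations.
#' @param method `"mann_whitney"` (default) or `"student_t"` (pooled
#'   variance).
#' @return An object of class `"group_test"`: list with `statistic`,
#'   `p_value`, `method`.
#' @examples
#' group_compare(c(1, 2, 3), c(4, 5, 6))$p_value  # exact 2/20 = 0.1
#' @export
group_compare <- function(values_a, values_b,
                          method = c("mann_whitney", "student_t")) {
  method <- match.arg(method)
  if (!length(values_a) || !length(values_b)) {
    stopf("both groups must be non-empty")
  }
  if (method == "mann_whitney") {
    exact <- length(values_a) * length(values_b) <= 400
    ht <- suppressWarnings(
      wilcox.test(values_a, values_b, exact = exact, correct = TRUE))
  } else {
    if (length(values_a) < 2L || length(values_b) < 2L) {
      stopf("Student's t test needs n >= 2 per group")
    }
    ht <- t.test(values_a, values_b, var.equal = TRUE)
  }
  structure(list(statistic = unname(ht$statistic),
                 p_value = unname(ht$p.value), method = method),
            class = "group_test")
}
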