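make_pm <- function(psi_by_sample, depth = 100) {
  # psi_by_sample: named list sample -> named psi vector over events
  rows <- do.call(rbind, lapply(names(psi_by_sample), function(s) {
    p <- psi_by_sample[[s]]
    data.frame(sample_id = s, event_id = names(p),
               inclusion_reads = round(depth * p),
               exclusion_reads = depth - round(depth * p),
               stringsAsFactors = FALSE)
  }))
  events <- data.frame(event_id = unique(rows$event_id),
                       event_type = "se", stringsAsFactors = FALSE)
  psi_matrix(rows, events, min_informative = 20)
}

test_that("delta psi is taken against the reference median with an inclusive threshold", {
  pm <- make_pm(list(r1 = c(e1 = 0.5, e2 = 0.4, e3 = 0.5),
                     r2 = c(e1 = 0.5, e2 = 0.4, e3 = 0.5),
                     r3 = c(e1 = 0.6, e2 = 0.4, e3 = 0.5),
                     q  = c(e1 = 0.7, e2 = 0.5, e3 = 0.5)))
  d <- delta_psi_vs_reference(pm, c("r1", "r2", "r3"), "q")
  expect_equal(d$delta_psi[d$event_id == "e1"], 0.20)
  expect_equal(d$call[d$event_id == "e1"], "promoted")
  # a shift of exactly ten percentage points is called (inclusive)
  expect_equal(d$delta_psi[d$event_id == "e2"], 0.10)
  expect_equal(d$call[d$event_id == "e2"], "promoted")
  expect_equal(d$call[d$event_id == "e3"], "unaffected")
  expect_error(delta_psi_vs_reference(pm, c("r1", "q"), "q"),
               "must not be in the reference")
})

test_that("events with insufficient reference support are dropped", {
  pm <- make_pm(list(r1 = c(e1 = 0.5), r2 = c(e1 = 0.5),
                     q = c(e1 = 0.6, e2 = 0.9)))
  # e2 undefined in both references -> dropped
  d <- delta_psi_vs_reference(pm, c("r1", "r2"), "q")
  expect_equal(d$event_id, "e1")
})

test_that("acceptor windows are strand-corrected and canonical-site filtered", {
  genome <- toy_genome()
  ev <- splice_event("iv1", "se", "chrT", 25, 55, "+")
  res <- extract_3ss_window(ev, genome)
  expect_true(res$accepted)
  expect_equal(nchar(res$window), 23)
  intron_part <- substr(res$window, 1, 20)
  expect_equal(substr(intron_part, 18, 20), "TAG")
  expect_equal(substr(res$window, 21, 23), "GGA")  # first exonic bases

  # non-canonical acceptor (AC) rejected
  bad <- Biostrings::DNAStringSet(sub("TAGGGACT$", "TACGGACT",
                                      as.character(genome[[1]])))
  names(bad) <- "chrT"
  expect_false(extract_3ss_window(ev, bad)$accepted)

  # window running past the contig end is rejected with a reason
  evr <- splice_event("iv2", "se", "chrT", 28, 58, "+")
  out <- extract_3ss_window(evr, genome)
  if (!out$accepted) expect_match(out$reason, "bounds|canonical")
})

test_that("minus-strand extraction equals the reverse-complement oracle", {
  genome <- toy_genome()
  ev <- splice_event("iv1", "se", "chrT", 25, 55, "+")
  plus <- extract_3ss_window(ev, genome)
  L <- length(genome[[1]])
  flipped <- flip_event(ev, L)
  rc <- revcomp_genome(genome)
  names(rc) <- "chrT"
  minus <- extract_3ss_window(flipped, rc)
  expect_true(minus$accepted)
  expect_identical(minus$window, plus$window)
})

test_that("logo frequencies are normalised and information content bounded", {
  logo <- build_logo(c("ACGT", "ACGA", "ACGC", "ACGG"))
  expect_true(all(abs(colSums(logo$freq) - 1) < 1e-9))
  expect_true(all(logo$ic >= 0 & logo$ic <= 2))
  # invariant column scores the 2-bit ceiling, uniform scores zero
  expect_equal(unname(logo$ic[1]), 2)
  expect_equal(unname(logo$ic[4]), 0)
  # 50/50 two-base column carries exactly one bit
  expect_equal(unname(build_logo(c("A", "A", "C", "C"))$ic), 1)
  # ambiguous bases are dropped per column with renormalisation
  logo_n <- build_logo(c("AN", "AN", "AC", "NC"))
  expect_equal(unname(logo_n$freq["A", 1]), 1)
  expect_equal(unname(logo_n$freq["C", 2]), 1)
  expect_error(build_logo(character(0)), "at least one")
  expect_error(build_logo(c("AC", "ACG")), "equal length")
})

test_that("signature classes follow the -3 composition rule", {
  # windows are -3/-2/-1 + 3 exonic, so position -3 is the first char
  win <- function(base, n) rep(paste0(base, "AGGGA"), n)
  promoted <- build_logo(c(win("C", 10), win("A", 6), win("T", 3),
                           win("G", 1)))
  repressed <- build_logo(c(win("T", 10), win("A", 5), win("C", 4),
                            win("G", 1)))
  call <- classify_signature(promoted, repressed)
  expect_equal(call$class, "typical_S34F")
  expect_gt(call$score, 0)

  # background-like C > T > A composition in both sets is quasi-WT
  bg <- build_logo(c(win("C", 11), win("T", 6), win("A", 2), win("G", 1)))
  expect_equal(classify_signature(bg, bg)$class, "quasi_WT")

  # one pattern alone does not make the typical class
  mixed <- classify_signature(promoted, bg)
  expect_equal(mixed$class, "quasi_WT")

  # sets below the sequence floor are undetermined
  small <- build_logo(win("C", 5))
  expect_equal(classify_signature(small, repressed)$class, "undetermined")
})

test_that("logos are invariant to reverse-complementing the genome", {
  genome <- toy_genome()
  L <- length(genome[[1]])
  ev <- splice_event("iv1", "se", "chrT", 25, 55, "+")
  w_plus <- extract_3ss_window(ev, genome)$window
  rc <- revcomp_genome(genome); names(rc) <- "chrT"
  w_minus <- extract_3ss_window(flip_event(ev, L), rc)$window
  expect_identical(build_logo(rep(w_plus, 3))$freq,
                   build_logo(rep(w_minus, 3))$freq)
})

test_that("signature comparison counts overlap and enhancement", {
  d <- data.frame(event_id = c("e1", "e2", "e3", "e4"),
                  sample_id = "a",
                  delta_psi = c(0.2, 0.15, -0.2, 0.0),
                  call = c("promoted", "promoted", "repressed",
                           "unaffected"),
                  stringsAsFactors = FALSE)
  same <- compare_signatures(d, d)
  expect_equal(same$promoted$shared, 2)
  expect_equal(same$promoted$only_a, 0)
  expect_true(all(same$promoted$shared_events$enhancement == 0))

  d2 <- d
  d2$call <- c("unaffected", "unaffected", "repressed", "promoted")
  d2$delta_psi <- c(0.05, 0.05, -0.3, 0.2)
  cmp <- compare_signatures(d, d2)
  expect_equal(cmp$promoted$shared, 0)
  expect_equal(cmp$promoted$only_a, 2)
  expect_equal(cmp$promoted$only_b, 1)
  expect_equal(cmp$repressed$shared_events$enhancement, -0.1)

  d3 <- d[d$event_id != "e4", ]
  expect_error(compare_signatures(d, d3), "universes")
})

test_that("raising the mutant ratio enhances shared promoted events", {
  co_lo <- classification_cohort(400, rep(0.5, 1), n_wt = 25, depth = 2000,
                                 seed = 51)
  pm <- psi_matrix(co_lo$junctions, co_lo$events)
  wt <- grep("^WT_", colnames(pm$psi), value = TRUE)
  d_lo <- delta_psi_vs_reference(pm, wt, "MUT_001")

  co_hi <- classification_cohort(400, rep(2.0, 1), n_wt = 25, depth = 2000,
                                 seed = 51)
  pm_hi <- psi_matrix(co_hi$junctions, co_hi$events)
  d_hi <- delta_psi_vs_reference(pm_hi, wt, "MUT_001")

  keep <- intersect(d_lo$event_id, d_hi$event_id)
  cmp <- compare_signatures(d_lo[d_lo$event_id %in% keep, ],
                            d_hi[d_hi$event_id %in% keep, ])
  expect_gt(cmp$promoted$shared, 0)
  expect_gt(median(cmp$promoted$shared_events$enhancement), 0)
})

test_that("group comparisons match exact small-sample references", {
  # U of the first group by enumeration of all 4 pairings
  expect_equal(group_compare(c(1, 2), c(3, 4))$statistic, 0)
  # 6!/(3!3!) = 20 arrangements; two-sided p = 2/20
  expect_equal(group_compare(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  # identical groups are maximally non-significant
  expect_equal(group_compare(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(group_compare(numeric(0), 1:3), "non-empty")
  # Student's t variant needs two observations per group
  expect_error(group_compare(1, c(1, 2), method = "student_t"), "n >= 2")
  st <- group_compare(c(1, 2, 3), c(4, 5, 6), method = "student_t")
  expect_lt(st$p_value, 0.05)
})

test_that("end-to-end signature recovery separates high from low ratios", {
  co <- classification_cohort(1200, c(rep(1, 4), rep(0.05, 4)),
                              n_wt = 20, depth = 100, seed = 61)
  pm <- psi_matrix(co$junctions, co$events)
  wt <- grep("^WT_", colnames(pm$psi), value = TRUE)
  windows <- setNames(vapply(co$events, `[[`, character(1),
                             "sequence_window"),
                      vapply(co$events, `[[`, character(1), "event_id"))
  classes <- vapply(sprintf("MUT_%03d", 1:8), function(s) {
    signature_for_sample(pm, wt, s, windows)$call$class
  }, character(1))
  expect_true(all(classes[1:4] == "typical_S34F"))
  expect_true(all(classes[5:8] == "quasi_WT"))
})
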