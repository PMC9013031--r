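specs <- default_panel_specs()

make_report <- function(sample_id, panel, matched_normal, reported, suppressed = NULL) {
  if (is.null(suppressed)) {
    suppressed <- reported[0, , drop = FALSE]
    suppressed$suppression_reason <- character()
  }
  structure(
    list(sample_id = sample_id, panel = panel, matched_normal = matched_normal,
      reported = reported, suppressed = suppressed),
    class = "assay_report"
  )
}

call_row <- function(pos = 100L, af = 0.5, sample_id = "S1", tier = "none",
                     assay_id = "A", ref = "A", alt = "G") {
  data.frame(
    sample_id = sample_id, assay_id = assay_id, gene = "CG001", chrom = "chr1",
    pos = pos, ref = ref, alt = alt,
    variant_class = classify_variant_class(ref, alt),
    allele_frequency = af, read_depth = 1000L, actionability_tier = tier,
    stringsAsFactors = FALSE
  )
}

normal_row <- function(call, depth = 100L, alt_reads = 0L) {
  data.frame(
    sample_id = call$sample_id, chrom = call$chrom, pos = call$pos,
    ref = call$ref, alt = call$alt,
    normal_depth = depth, normal_alt_reads = alt_reads,
    stringsAsFactors = FALSE
  )
}

test_that("is_germline_consistent applies the read and AF thresholds", {
  call <- call_row()
  expect_true(is_germline_consistent(call, normal_row(call, 100L, 45L)))
  expect_false(is_germline_consistent(call, normal_row(call, 100L, 0L)))
  # boundary: depth 10, 2 alt reads (AF 0.2) fails defaults, passes relaxed
  nr <- normal_row(call, 10L, 2L)
  expect_false(is_germline_consistent(call, nr))
  expect_true(is_germline_consistent(call, nr, min_reads = 2L, min_normal_af = 0.15))
  # key mismatch is an error
  other <- call_row(pos = 999L)
  expect_error(is_germline_consistent(call, normal_row(other)), "key mismatch")
})

test_that("germline_af_flag marks the ~50% AF window only", {
  expect_equal(germline_af_flag(c(0.39, 0.40, 0.5, 0.60, 0.61)),
    c(FALSE, TRUE, TRUE, TRUE, FALSE))
})

test_that("classify_discordant follows the fixed decision priority", {
  to_call <- call_row(af = 0.49, assay_id = "TO")
  rep_to <- make_report("S1", "TO", FALSE, to_call)
  empty_tn <- make_report("S1", "TN", TRUE, call_row(pos = 999L))

  # (1) germline: matched-normal absent assay + het normal evidence
  normal <- normal_row(to_call, 100L, 49L)
  rec <- classify_discordant(to_call, rep_to, empty_tn, normal)
  expect_equal(rec$category, "germline")
  expect_true(rec$germline_af_flag)

  # (2) reporting_cap beats caller filtering in priority
  sup <- to_call
  sup$suppression_reason <- "reporting_cap"
  tn_cap <- make_report("S1", "TN", TRUE, call_row(pos = 999L), sup)
  rec <- classify_discordant(to_call, rep_to, tn_cap, normal_row(to_call, 100L, 0L))
  expect_equal(rec$category, "reporting_cap")

  # (3) caller_filtered from a depth/AF suppression record
  low <- call_row(af = 0.03, assay_id = "TO")
  sup <- low
  sup$suppression_reason <- "below_depth_rule"
  tn_filtered <- make_report("S1", "TN", TRUE, call_row(pos = 999L), sup)
  rec <- classify_discordant(low, make_report("S1", "TO", FALSE, low), tn_filtered,
    normal_row(low, 100L, 0L))
  expect_equal(rec$category, "caller_filtered")

  # (4) below_af_threshold: low AF, no suppression record in the other assay
  rec <- classify_discordant(low, make_report("S1", "TO", FALSE, low), empty_tn,
    normal_row(low, 100L, 0L))
  expect_equal(rec$category, "below_af_threshold")

  # (5) unexplained catch-all
  mid <- call_row(af = 0.30)
  rec <- classify_discordant(mid, make_report("S1", "TO", FALSE, mid), empty_tn,
    normal_row(mid, 100L, 0L))
  expect_equal(rec$category, "unexplained")

  # variant present in both reports is not discordant
  both_tn <- make_report("S1", "TN", TRUE, to_call)
  expect_error(classify_discordant(to_call, rep_to, both_tn, normal), "not discordant")
})

test_that("attribution labels are exclusive, exhaustive and recover simulator truth", {
  cohort <- simulate_cohort(simulation_config(seed = 33))
  cs <- compare_cohort(cohort, seed = 34)
  att <- do.call(rbind, lapply(cohort$meta$sample_id, function(id) {
    attribute_discordant(cs$comparisons[[id]], cs$reports_to[[id]],
      cs$reports_tn[[id]], cohort$normal)
  }))
  n_disc <- sum(vapply(cs$comparisons, function(r) r$n_only_a + r$n_only_b, numeric(1)))
  expect_equal(nrow(att), n_disc) # exactly one record per discordant call
  expect_true(all(att$category %in%
    c("germline", "reporting_cap", "caller_filtered", "below_af_threshold", "unexplained")))

  # germline-origin discordant calls are labeled germline
  germ <- att[att$origin == "germline", ]
  expect_gt(nrow(germ), 10)
  expect_gte(mean(germ$category == "germline"), 0.9)
  # artifact-origin TO-only calls are explained by thresholds or filtering
  art <- att[att$origin == "artifact" & att$missing_from == "TN-114", ]
  if (nrow(art) > 0) {
    expect_gte(mean(art$category %in% c("below_af_threshold", "caller_filtered", "reporting_cap")), 0.9)
  }
})

test_that("count_transition_spectrum counts the C>T/G>A channel per stratum", {
  calls <- rbind(
    call_row(pos = 1L, ref = "C", alt = "T"),
    call_row(pos = 2L, ref = "G", alt = "A"),
    call_row(pos = 3L, ref = "A", alt = "G")
  )
  sp <- count_transition_spectrum(calls)
  expect_equal(sp$CT_GA, 2L)
  expect_equal(sp$other, 1L)

  # empty input -> zero counts
  sp0 <- count_transition_spectrum(calls[0, ])
  expect_equal(sum(sp0$n), 0L)

  # indels and multi-base substitutions are 'other'
  indel <- call_row(pos = 4L, ref = "CA", alt = "C")
  mnv <- call_row(pos = 5L, ref = "CC", alt = "TT")
  sp2 <- count_transition_spectrum(rbind(calls, indel, mnv))
  expect_equal(sp2$CT_GA, 2L)
  expect_equal(sp2$other, 3L)

  # order invariance and stratum refinement additivity
  calls5 <- rbind(calls, indel, mnv)
  perm <- calls5[sample(nrow(calls5)), ]
  expect_equal(count_transition_spectrum(perm)$CT_GA, 2L)
  fine <- count_transition_spectrum(calls5, strata = c("x", "x", "y", "y", "x"))
  expect_equal(sum(fine$CT_GA), 2L)
  expect_equal(sum(fine$n), 5L)
  expect_error(count_transition_spectrum(calls5, strata = c("x", "y")), "one label per call")
})
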