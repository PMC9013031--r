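specs <- default_panel_specs()

test_that("depth_threshold_for_cellularity follows the 200/250/500 tiers", {
  tn <- specs$tn
  expect_equal(depth_threshold_for_cellularity(0.60, tn), 200)
  expect_equal(depth_threshold_for_cellularity(0.30, tn), 250)
  expect_equal(depth_threshold_for_cellularity(0.10, tn), 500)
  # both stated endpoints fall in the middle bin
  expect_equal(depth_threshold_for_cellularity(0.20, tn), 250)
  expect_equal(depth_threshold_for_cellularity(0.50, tn), 250)
  expect_error(depth_threshold_for_cellularity(0.5, specs$to), "not tiered")
  expect_error(depth_threshold_for_cellularity(1.2, tn), "\\[0,1\\]")
})

test_that("spec type mismatches are rejected", {
  meta <- make_meta()
  truth <- make_truth(3)
  expect_error(emulate_tumor_only_assay(truth, meta, specs$tn), "matched_normal = FALSE")
  expect_error(
    emulate_tumor_normal_assay(truth, meta, specs$to, make_normal(truth)),
    "matched_normal = TRUE"
  )
})

test_that("the tumor-only reporting cap keeps the top 14 by actionability", {
  meta <- make_meta()
  truth <- make_truth(20, tier = c(rep("1", 5), rep("3", 5), rep("none", 10)))
  rep_ <- emulate_tumor_only_assay(truth, meta, specs$to, seed = 12)
  expect_equal(nrow(rep_$reported), 14L)
  capped <- rep_$suppressed[rep_$suppressed$suppression_reason == "reporting_cap", ]
  expect_equal(nrow(capped), 6L)
  # actionable candidates outrank VUS: every capped-out call is a VUS
  expect_true(all(capped$actionability_tier == "none"))
  # all 10 actionable candidates survive the cap
  expect_equal(sum(rep_$reported$actionability_tier != "none"), 10L)

  # below the cap nothing is dropped
  few <- make_truth(5)
  rep_few <- emulate_tumor_only_assay(few, meta, specs$to, seed = 13)
  expect_equal(nrow(rep_few$reported), 5L)

  # reported and suppressed partition the candidates
  expect_equal(nrow(rep_$reported) + nrow(rep_$suppressed), nrow(truth))
  expect_length(
    intersect(
      paste(rep_$reported$chrom, rep_$reported$pos),
      paste(rep_$suppressed$chrom, rep_$suppressed$pos)
    ),
    0L
  )
})

test_that("a germline heterozygote at depth 3000 is reported by the TO assay", {
  meta <- make_meta()
  truth <- make_truth(1)
  hits <- vapply(1:50, function(i) {
    nrow(emulate_tumor_only_assay(truth, meta, specs$to, seed = 100 + i)$reported)
  }, numeric(1))
  expect_equal(mean(hits), 1) # P(detect 0.5 AF at ~3000x with floor 0.02) ~ 1
})

test_that("the TN assay subtracts germline and keeps somatic calls", {
  meta <- make_meta(cellularity = 0.6)
  truth <- rbind(
    make_truth(3, origin = "germline"),
    transform(make_truth(3, origin = "somatic", true_af = 0.3),
      pos = pos + 500L)
  )
  normal <- make_normal(truth)
  rep_ <- emulate_tumor_normal_assay(truth, meta, specs$tn, normal, seed = 21)
  sub <- rep_$suppressed
  expect_equal(sum(sub$suppression_reason == "germline_subtracted"), 3L)
  expect_true(all(rep_$reported$origin == "somatic"))
  expect_equal(nrow(rep_$reported), 3L)

  # a candidate without a normal row is an error naming the variant key
  expect_error(
    emulate_tumor_normal_assay(truth, meta, specs$tn, normal[-1, ], seed = 21),
    "missing normal evidence.*chr"
  )
})

test_that("panel-private genes never leak into the other assay's report", {
  cohort <- simulate_cohort(tiny_config(seed = 14))
  cs <- compare_cohort(cohort, seed = 15)
  for (id in cohort$meta$sample_id) {
    expect_true(all(cs$reports_to[[id]]$reported$gene %in% specs$to$genes))
    expect_true(all(cs$reports_tn[[id]]$reported$gene %in% specs$tn$genes))
  }
})

test_that("null case: no artifacts, no germline, deep sequencing -> no discordance", {
  cfg <- simulation_config(
    n_per_group = c(FF = 6L, FFPE_H = 0L, FFPE_L = 0L),
    germline_mean = 0, artifact_lambda = c(FF = 0, FFPE_H = 0, FFPE_L = 0),
    seed = 31
  )
  cohort <- simulate_cohort(cfg)
  deep_to <- panel_spec("deepTO", specs$to$genes, FALSE,
    af_floor = 0.01, mean_depth = 1e5)
  deep_tn <- panel_spec("deepTN", specs$tn$genes, TRUE,
    af_floor = 0.01, mean_depth = 1e5)
  discordant <- 0L
  for (id in cohort$meta$sample_id) {
    meta <- cohort$meta[cohort$meta$sample_id == id, , drop = FALSE]
    a <- emulate_tumor_only_assay(cohort$truth[[id]], meta, deep_to, seed = derive2(31, id, 1))
    b <- emulate_tumor_normal_assay(cohort$truth[[id]], meta, deep_tn, cohort$normal,
      seed = derive2(31, id, 2))
    ra <- restrict_to_common_genes(a$reported, deep_to, deep_tn)
    rb <- restrict_to_common_genes(b$reported, deep_to, deep_tn)
    m <- match_calls(ra, rb)
    discordant <- discordant + m$n_only_a + m$n_only_b
  }
  expect_equal(discordant, 0L)
})

test_that("low cellularity with shallow sequencing loses sensitivity (power ordering)", {
  meta <- make_meta(cellularity = 0.10) # demands 500x under the tiered rule
  shallow <- panel_spec("TNshallow", specs$tn$genes, TRUE,
    depth_rule = specs$tn$depth_rule, mean_depth = 250)
  deep <- panel_spec("TNdeep", specs$tn$genes, TRUE,
    depth_rule = specs$tn$depth_rule, mean_depth = 600)
  truth <- make_truth(5, origin = "somatic", true_af = 0.05)
  normal <- make_normal(truth)
  n_rep <- 200L
  n_shallow <- n_deep <- 0L
  for (i in seq_len(n_rep)) {
    n_shallow <- n_shallow + nrow(emulate_tumor_normal_assay(
      truth, meta, shallow, normal, seed = 4000 + i)$reported)
    n_deep <- n_deep + nrow(emulate_tumor_normal_assay(
      truth, meta, deep, normal, seed = 8000 + i)$reported)
  }
  expect_lt(n_shallow, n_deep)
})

test_that("assay reports serialize with suppression reasons", {
  meta <- make_meta()
  truth <- make_truth(20)
  rep_ <- emulate_tumor_only_assay(truth, meta, specs$to, seed = 12)
  path <- withr_tempfile()
  write_assay_report(rep_, path)
  got <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_equal(nrow(got), nrow(rep_$reported) + nrow(rep_$suppressed))
  expect_true("suppression_reason" %in% names(got))
})
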