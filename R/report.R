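# Report assembly and the end-to-end pipeline: simulate a cohort, emulate
# both assays, restrict to the shared genes, match, attribute, count the
# substitution spectrum, run the group/AF/correlation statistics, and
# render summary tables.

af_bin_breaks <- c(0, 0.05, 0.15, 1)
af_bin_labels <- c("<5%", "5-15%", ">15%")

af_bins <- function(af) {
  cut(af, breaks = af_bin_breaks, labels = af_bin_labels,
    include.lowest = TRUE, right = FALSE)
}

#' Worked examples from a published two-panel case study's printed counts
#'
#' Recomputes the headline rates of a published tumor-only vs tumor-normal
#' panel comparison from the partition counts it printed, using
#' [concordance_from_counts()]. These serve as exact, instant acceptance
#' checks of the rate arithmetic. Note the published actionable-stratum
#' figure of 56.7% is inconsistent with its own printed counts
#' (44 / (44 + 17 + 14) = 58.7%); the count-derived value is reported here
#' and the discrepancy is documented rather than reproduced.
#'
#' @return a data.frame with `id`, `description`, `value` (percent, 1
#'   decimal) and the counts used.
#' @examples
#' paper_worked_examples()
#' @export
paper_worked_examples <- function() {
  rows <- list(
    list("overall_discordance",
      "overall discordance, partition (both=51, only TO=99, only TN=31)",
      100 * concordance_from_counts(51, 99, 31)$discordance_rate,
      51, 99, 31),
    list("vus_concordance",
      "VUS-stratum concordance, partition (7, 82, 17) = totals minus actionable",
      100 * concordance_from_counts(7, 82, 17)$concordance_rate,
      7, 82, 17),
    list("actionable_concordance_from_counts",
      "actionable-stratum concordance from printed counts (44, 17, 14); published text prints 56.7",
      100 * concordance_from_counts(44, 17, 14)$concordance_rate,
      44, 17, 14),
    list("replicate_tn_concordance",
      "replicate TN assays, shared 62-24 = 61-23 = 38 with 24 + 23 unique",
      100 * concordance_from_counts(38, 24, 23)$concordance_rate,
      38, 24, 23),
    list("replicate_tn_concordance_ffpe_h",
      "replicate TN, FFPE-H: union 29 with 10 + 6 unique",
      100 * concordance_from_counts(29 - 10 - 6, 10, 6)$concordance_rate,
      29 - 10 - 6, 10, 6),
    list("replicate_tn_concordance_ffpe_l",
      "replicate TN, FFPE-L: union 56 with 14 + 17 unique",
      100 * concordance_from_counts(56 - 14 - 17, 14, 17)$concordance_rate,
      56 - 14 - 17, 14, 17),
    list("germline_share_to_only",
      "share of TO-only calls confirmed germline in the matched normal (32 of 99)",
      100 * 32 / 99, 32, 99, NA),
    list("to_common_gene_total",
      "TO short-variant total on the 92 shared genes (99 TO-only + 51 shared)",
      99 + 51, 51, 99, NA)
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(
      id = r[[1]], description = r[[2]], value = round(r[[3]], 1),
      n_both = r[[4]], n_only_a = r[[5]], n_only_b = r[[6]],
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Compare the two emulated assays for every sample of a cohort
#'
#' Emulates the tumor-only and tumor-normal assay on each sample's truth
#' set, normalizes and restricts both call sets to the panels' shared
#' genes, and matches them.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param specs list with `to` and `tn` [panel_spec]s
#'   (default [default_panel_specs()]).
#' @param seed integer seed for the emulation substreams.
#' @return a list with `reports_to`, `reports_tn` (named lists of
#'   `assay_report`s) and `comparisons` (named list of
#'   `comparison_result`s, A = tumor-only, B = tumor-normal).
#' @export
compare_cohort <- function(cohort, specs = default_panel_specs(), seed = 1L) {
  ids <- cohort$meta$sample_id
  reports_to <- reports_tn <- comparisons <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    meta <- cohort$meta[cohort$meta$sample_id == id, , drop = FALSE]
    truth <- cohort$truth[[id]]
    rep_to <- emulate_tumor_only_assay(
      truth, meta, specs$to,
      seed = derive_seed(seed, paste0("to:", id))
    )
    rep_tn <- emulate_tumor_normal_assay(
      truth, meta, specs$tn, cohort$normal,
      seed = derive_seed(seed, paste0("tn:", id))
    )
    a <- restrict_to_common_genes(normalize_variants(rep_to$reported), specs$to, specs$tn)
    b <- restrict_to_common_genes(normalize_variants(rep_tn$reported), specs$to, specs$tn)
    reports_to[[id]] <- rep_to
    reports_tn[[id]] <- rep_tn
    comparisons[[id]] <- match_calls(a, b)
  }
  list(reports_to = reports_to, reports_tn = reports_tn, comparisons = comparisons)
}

#' Assemble the analysis report bundle
#'
#' Produces (a) an alteration-count table per assay with actionable counts
#' in parentheses, (b) the three-way Venn counts on the shared genes,
#' (c) per-group stacked percentages of both/only-A/only-B calls,
#' (d) an attribution-category histogram binned at 5% and 15% AF, and
#' (e) the printed-count worked examples of [paper_worked_examples()].
#' Deterministic given its inputs.
#'
#' @param cohort the simulated cohort.
#' @param comparison_set result of [compare_cohort()].
#' @param attribution pooled attribution records
#'   (from [attribute_discordant()]).
#' @param spectra a substitution spectrum table
#'   (from [count_transition_spectrum()]).
#' @return an object of class `concordance_report`.
#' @export
build_report <- function(cohort, comparison_set, attribution, spectra) {
  for (part in c("cohort", "comparison_set", "attribution", "spectra")) {
    if (is.null(get(part))) stop("missing upstream input: ", part, call. = FALSE)
  }
  comparisons <- comparison_set$comparisons
  fmt_act <- function(tiers) sprintf("%d (%d)", length(tiers), sum(is_actionable(tiers)))
  pool_tiers <- function(get) unlist(lapply(comparisons, get), use.names = FALSE)
  tiers_both <- pool_tiers(function(r) r$both$actionability_tier)
  tiers_a <- pool_tiers(function(r) r$only_a$actionability_tier)
  tiers_b <- pool_tiers(function(r) r$only_b$actionability_tier)
  alteration_counts <- data.frame(
    call_set = c("assay A (tumor-only)", "assay B (tumor-normal)", "both assays"),
    n_reported = c(
      fmt_act(c(tiers_both, tiers_a)), fmt_act(c(tiers_both, tiers_b)),
      fmt_act(tiers_both)
    ),
    stringsAsFactors = FALSE
  )
  venn <- list(
    both = length(tiers_both), only_a = length(tiers_a), only_b = length(tiers_b)
  )
  by_group <- stratified_summary(comparisons, cohort$meta, "group")
  group_pct <- data.frame(
    stratum = by_group$stratum,
    pct_both = 100 * by_group$n_both / by_group$n_total,
    pct_only_a = 100 * by_group$n_only_a / by_group$n_total,
    pct_only_b = 100 * by_group$n_only_b / by_group$n_total,
    stringsAsFactors = FALSE
  )
  by_actionability <- stratified_summary(comparisons, cohort$meta, "actionability")
  attribution_hist <- if (nrow(attribution)) {
    as.data.frame(table(
      category = attribution$category, af_bin = af_bins(attribution$allele_frequency)
    ), responseName = "count", stringsAsFactors = FALSE)
  } else {
    data.frame(category = character(), af_bin = character(), count = integer(),
      stringsAsFactors = FALSE)
  }
  structure(
    list(
      alteration_counts = alteration_counts,
      venn = venn,
      by_group = by_group,
      group_percentages = group_pct,
      by_actionability = by_actionability,
      attribution_histogram = attribution_hist,
      spectra = spectra,
      worked_examples = paper_worked_examples()
    ),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report>\n")
  cat(sprintf(
    "  shared-gene partition: both=%d only_a=%d only_b=%d\n",
    x$venn$both, x$venn$only_a, x$venn$only_b
  ))
  total <- x$venn$both + x$venn$only_a + x$venn$only_b
  if (total > 0) {
    cat(sprintf("  pooled concordance: %.1f%%\n", 100 * x$venn$both / total))
  }
  cat("  strata:\n")
  print(x$by_group)
  invisible(x)
}

#' Write a report bundle to TSV/JSON files
#'
#' @param report a `concordance_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name),
      sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  }
  wt(report$alteration_counts, "alteration_counts.tsv")
  jsonlite::write_json(report$venn, file.path(dir, "venn_counts.json"), auto_unbox = TRUE)
  wt(report$by_group, "concordance_by_group.tsv")
  wt(report$group_percentages, "group_percentages.tsv")
  wt(report$by_actionability, "concordance_by_actionability.tsv")
  wt(report$attribution_histogram, "attribution_histogram.tsv")
  wt(report$spectra, "transition_spectrum.tsv")
  wt(report$worked_examples, "worked_examples.tsv")
  invisible(dir)
}

#' Run the full concordance pipeline on a simulated cohort
#'
#' simulate -> emulate both assays -> restrict/normalize/match -> attribute
#' discordant calls -> count C>T/G>A spectra -> group Fisher test, AF rank
#' test and quality correlations -> report bundle. Deterministic and
#' byte-reproducible for a fixed `seed`.
#'
#' @param config a [simulation_config()]; its `seed` is overridden by
#'   `seed`.
#' @param seed master integer seed.
#' @param out_dir optional directory; when given, the cohort, per-sample
#'   assay reports, attribution table and report bundle are written there.
#' @return a list with `cohort`, `comparison_set`, `attribution`,
#'   `spectra`, `stats` and `report`.
#' @export
run_pipeline <- function(config = simulation_config(), seed = 1L, out_dir = NULL) {
  config$seed <- as.integer(seed)
  cohort <- simulate_cohort(config)
  comparison_set <- compare_cohort(cohort, seed = derive_seed(seed, "emulate"))
  attribution <- do.call(rbind, c(
    lapply(cohort$meta$sample_id, function(id) {
      attribute_discordant(
        comparison_set$comparisons[[id]],
        comparison_set$reports_to[[id]],
        comparison_set$reports_tn[[id]],
        cohort$normal
      )
    }),
    list(make.row.names = FALSE)
  ))
  # C>T/G>A spectrum of TO-only discordant calls, stratified by group
  to_only <- do.call(rbind, c(
    lapply(comparison_set$comparisons, `[[`, "only_a"),
    list(make.row.names = FALSE)
  ))
  group_of <- cohort$meta$group[match(to_only$sample_id, cohort$meta$sample_id)]
  spectra <- count_transition_spectrum(to_only, strata = group_of)
  by_group <- stratified_summary(comparison_set$comparisons, cohort$meta, "group")
  tests <- list()
  if (all(by_group$n_total > 0) && nrow(by_group) >= 2) {
    tab <- rbind(
      concordant = by_group$n_both,
      discordant = by_group$n_only_a + by_group$n_only_b
    )
    colnames(tab) <- by_group$stratum
    tests$group_fisher <- tryCatch(fisher_exact_rxc(tab), error = function(e) NULL)
  }
  both_af <- unlist(lapply(comparison_set$comparisons, function(r) r$both$mean_af), use.names = FALSE)
  if (nrow(to_only) && length(both_af)) {
    tests$af_to_only_vs_both <- rank_test(to_only$allele_frequency, both_af, paired = FALSE)
  }
  psc <- per_sample_concordance(comparison_set$comparisons)
  ok <- psc$defined
  if (sum(ok) >= 3) {
    meta_idx <- match(psc$sample_id[ok], cohort$meta$sample_id)
    tests$concordance_vs_library_concentration <- tryCatch(
      spearman_correlation(cohort$meta$library_concentration[meta_idx], psc$concordance_rate[ok]),
      error = function(e) NULL
    )
    tests$concordance_vs_q_value <- tryCatch(
      spearman_correlation(cohort$meta$q_value[meta_idx], psc$concordance_rate[ok]),
      error = function(e) NULL
    )
  }
  report <- build_report(cohort, comparison_set, attribution, spectra)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    att <- attribution
    for (col in names(att)) if (is.double(att[[col]])) att[[col]] <- fmt_double(att[[col]])
    utils::write.table(att, file.path(out_dir, "attribution.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    write_report(report, file.path(out_dir, "report"))
    for (id in cohort$meta$sample_id) {
      write_assay_report(
        comparison_set$reports_to[[id]],
        file.path(out_dir, "cohort", paste0(id, "_to_report.tsv"))
      )
      write_assay_report(
        comparison_set$reports_tn[[id]],
        file.path(out_dir, "cohort", paste0(id, "_tn_report.tsv"))
      )
    }
  }
  list(
    cohort = cohort, comparison_set = comparison_set,
    attribution = attribution, spectra = spectra,
    stats = tests, report = report
  )
}
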