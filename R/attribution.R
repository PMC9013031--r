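# Cause attribution for discordant calls: a five-way classification
# (germline leakage, reporting cap, caller filtering, low allele frequency,
# unexplained) plus the C>T/G>A substitution spectrum.

attribution_categories <- c(
  "germline", "reporting_cap", "caller_filtered", "below_af_threshold", "unexplained"
)

# Vectorized core of the germline rule, shared with the tumor-normal
# emulator's subtraction step.
germline_evidence_consistent <- function(normal_alt_reads, normal_depth,
                                         min_reads = 3L, min_normal_af = 0.25) {
  normal_alt_reads >= min_reads & normal_alt_reads / normal_depth >= min_normal_af
}

#' Is a call's matched-normal evidence consistent with a germline variant?
#'
#' True when the matched normal shows at least `min_reads` alternate reads
#' at a normal allele frequency of at least `min_normal_af` — the signature
#' of a heterozygous germline site. Thresholds default to common
#' tumor-normal subtraction practice (3 reads, AF 0.25) and are
#' configurable because vendor rules are undisclosed.
#'
#' @param call a one-row variant call (needs `chrom`, `pos`, `ref`, `alt`).
#' @param normal_row the matching normal-evidence row (`chrom`, `pos`,
#'   `ref`, `alt`, `normal_depth`, `normal_alt_reads`). Keys must match.
#' @param min_reads minimum alternate reads in the normal.
#' @param min_normal_af minimum normal allele frequency.
#' @return logical.
#' @export
is_germline_consistent <- function(call, normal_row, min_reads = 3L, min_normal_af = 0.25) {
  if (!identical(
    paste(call$chrom, call$pos, call$ref, call$alt),
    paste(normal_row$chrom, normal_row$pos, normal_row$ref, normal_row$alt)
  )) {
    stop("normal evidence key mismatch for call ", variant_key(call), call. = FALSE)
  }
  unname(germline_evidence_consistent(
    normal_row$normal_alt_reads, normal_row$normal_depth,
    min_reads = min_reads, min_normal_af = min_normal_af
  ))
}

#' Advisory germline flag from tumor AF alone
#'
#' For data without matched-normal evidence: an observed AF near 50%
#' (default \[0.40, 0.60\]) is suggestive of a heterozygous germline
#' variant. This is only an advisory flag, never the primary germline
#' label.
#'
#' @param allele_frequency observed AF(s).
#' @param range the inclusive AF window.
#' @return logical vector.
#' @export
germline_af_flag <- function(allele_frequency, range = c(0.40, 0.60)) {
  allele_frequency >= range[1] & allele_frequency <= range[2]
}

#' Classify one discordant variant into a cause category
#'
#' Fixed decision priority (each record gets exactly one category):
#' 1. `germline` — the absent assay is matched-normal and the normal
#'    evidence passes [is_germline_consistent()] (the variant was germline
#'    subtracted there);
#' 2. `reporting_cap` — the absent assay detected the variant but dropped
#'    it to its reporting cap;
#' 3. `caller_filtered` — the absent assay suppressed it for a depth or
#'    AF-floor reason;
#' 4. `below_af_threshold` — no suppression record exists in the absent
#'    assay and the reporting assay observed the variant below 5% AF;
#' 5. `unexplained` — the catch-all.
#'
#' @param record a one-row discordant variant call (reported by exactly one
#'   assay).
#' @param reporter_report the `assay_report` that reported it.
#' @param absent_report the `assay_report` that did not.
#' @param normal the cohort normal-evidence table (may be `NULL` for data
#'   without matched-normal evidence; the germline rule then never fires).
#' @param af_threshold AF cut for `below_af_threshold` (default 0.05).
#' @param germline_min_reads,germline_min_af thresholds for the germline
#'   rule.
#' @return a one-row data.frame `AttributionRecord`: variant key fields,
#'   `missing_from`, `category`, `evidence`, `germline_af_flag`.
#' @export
classify_discordant <- function(record, reporter_report, absent_report, normal = NULL,
                                af_threshold = 0.05,
                                germline_min_reads = 3L, germline_min_af = 0.25) {
  key <- variant_key(record)
  if (key %in% variant_key(absent_report$reported)) {
    stop("not discordant: ", key, " is present in both reports", call. = FALSE)
  }
  normal_row <- NULL
  if (!is.null(normal)) {
    nsub <- normal[normal$sample_id == record$sample_id, , drop = FALSE]
    hit <- match(key, variant_key(nsub))
    if (!is.na(hit)) normal_row <- nsub[hit, , drop = FALSE]
  }
  sup <- absent_report$suppressed
  sup_hit <- match(key, variant_key(sup))
  sup_reason <- if (is.na(sup_hit)) NA_character_ else sup$suppression_reason[sup_hit]
  germline_ok <- !is.null(normal_row) && absent_report$matched_normal &&
    is_germline_consistent(record, normal_row,
      min_reads = germline_min_reads, min_normal_af = germline_min_af
    )
  if (germline_ok) {
    category <- "germline"
    evidence <- sprintf(
      "normal AF %.3f (%d/%d reads)",
      normal_row$normal_alt_reads / normal_row$normal_depth,
      normal_row$normal_alt_reads, normal_row$normal_depth
    )
  } else if (!is.na(sup_reason) && sup_reason == "reporting_cap") {
    category <- "reporting_cap"
    evidence <- sprintf("detected by %s but dropped to reporting cap", absent_report$panel)
  } else if (!is.na(sup_reason) && sup_reason %in% c("below_af_floor", "below_depth_rule")) {
    category <- "caller_filtered"
    sup_row <- sup[sup_hit, , drop = FALSE]
    evidence <- sprintf(
      "%s in %s (observed AF %.4f at depth %d)",
      sup_reason, absent_report$panel,
      sup_row$allele_frequency, sup_row$read_depth
    )
  } else if (is.na(sup_reason) && record$allele_frequency < af_threshold) {
    category <- "below_af_threshold"
    evidence <- sprintf("observed AF %.4f < %.2f in %s", record$allele_frequency, af_threshold, reporter_report$panel)
  } else {
    category <- "unexplained"
    evidence <- sprintf(
      "observed AF %.4f in %s; absent-assay record: %s",
      record$allele_frequency, reporter_report$panel,
      if (is.na(sup_reason)) "none" else sup_reason
    )
  }
  data.frame(
    sample_id = record$sample_id, gene = record$gene,
    chrom = record$chrom, pos = record$pos, ref = record$ref, alt = record$alt,
    allele_frequency = record$allele_frequency,
    origin = if ("origin" %in% names(record)) record$origin else NA_character_,
    missing_from = absent_report$panel,
    category = category, evidence = evidence,
    germline_af_flag = germline_af_flag(record$allele_frequency),
    stringsAsFactors = FALSE
  )
}

#' Attribute every discordant call of one sample comparison
#'
#' Runs [classify_discordant()] over `only_a` (absent from assay B) and
#' `only_b` (absent from assay A) of a [match_calls()] result.
#'
#' @param comparison a `comparison_result`.
#' @param report_a,report_b the two `assay_report`s that were compared.
#' @param normal cohort normal-evidence table (or `NULL`).
#' @param ... thresholds passed to [classify_discordant()].
#' @return a data.frame of attribution records (zero rows if concordant).
#' @export
attribute_discordant <- function(comparison, report_a, report_b, normal = NULL, ...) {
  rows <- list()
  for (i in seq_len(nrow(comparison$only_a))) {
    rows[[length(rows) + 1L]] <- classify_discordant(
      comparison$only_a[i, , drop = FALSE], report_a, report_b, normal, ...
    )
  }
  for (i in seq_len(nrow(comparison$only_b))) {
    rows[[length(rows) + 1L]] <- classify_discordant(
      comparison$only_b[i, , drop = FALSE], report_b, report_a, normal, ...
    )
  }
  if (!length(rows)) {
    return(data.frame(
      sample_id = character(), gene = character(), chrom = character(),
      pos = integer(), ref = character(), alt = character(),
      allele_frequency = numeric(), origin = character(),
      missing_from = character(), category = character(),
      evidence = character(), germline_af_flag = logical(),
      stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out
}

#' Count substitution channels (C>T/G>A vs other)
#'
#' A call is on the `CT_GA` channel iff it is a single-base substitution
#' with `(ref, alt)` equal to `(C, T)` or `(G, A)` — the FFPE formalin
#' deamination signature. Multi-base substitutions and indels count as
#' `other`. Counts are returned per stratum; finer strata sum to coarser.
#'
#' @param calls a variant call table.
#' @param strata optional vector (length `nrow(calls)`) of stratum labels;
#'   `NULL` pools everything into one stratum `"all"`.
#' @return a data.frame with `stratum`, `CT_GA`, `other`, `n`.
#' @export
count_transition_spectrum <- function(calls, strata = NULL) {
  n <- nrow(calls)
  if (is.null(strata)) strata <- rep("all", n)
  if (length(strata) != n) stop("strata must have one label per call", call. = FALSE)
  ct <- calls$variant_class == "substitution" &
    nchar(calls$ref) == 1L &
    ((calls$ref == "C" & calls$alt == "T") | (calls$ref == "G" & calls$alt == "A"))
  levels_ <- sort(unique(as.character(strata)))
  out <- do.call(rbind, lapply(levels_, function(s) {
    idx <- strata == s
    data.frame(
      stratum = s, CT_GA = sum(ct[idx]), other = sum(!ct[idx]),
      n = sum(idx), stringsAsFactors = FALSE
    )
  }))
  if (is.null(out)) {
    out <- data.frame(
      stratum = character(), CT_GA = integer(), other = integer(),
      n = integer(), stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  out
}
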