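# Call-set matching and concordance statistics. Variant identity is the
# normalized (chrom, pos, ref, alt) key; gene symbols are annotation only.

#' Concordance and discordance rates from partition counts
#'
#' The concordance rate divides the number of variants found by both assays
#' by that number plus all discordant variants (those found by only one);
#' the discordance rate is its complement. Computed in exact double
#' arithmetic; rounding is left to the caller or to [format]ting helpers.
#'
#' @param n_both,n_only_a,n_only_b non-negative integer counts.
#' @return a list with `concordance_rate` and `discordance_rate`.
#' @examples
#' # a published two-panel case study printed the partition (51, 99, 31):
#' concordance_from_counts(51, 99, 31)$discordance_rate # 0.7182 -> 71.8%
#' @export
concordance_from_counts <- function(n_both, n_only_a, n_only_b) {
  counts <- c(n_both, n_only_a, n_only_b)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  total <- n_both + n_only_a + n_only_b
  if (total == 0) {
    stop("undefined rate: no variants in either call set", call. = FALSE)
  }
  conc <- n_both / total
  list(concordance_rate = conc, discordance_rate = 1 - conc)
}

comparison_result <- function(both, only_a, only_b) {
  n_both <- nrow(both)
  n_a <- nrow(only_a)
  n_b <- nrow(only_b)
  total <- n_both + n_a + n_b
  defined <- total > 0L
  rates <- if (defined) {
    concordance_from_counts(n_both, n_a, n_b)
  } else {
    list(concordance_rate = NA_real_, discordance_rate = NA_real_)
  }
  structure(
    list(
      both = both, only_a = only_a, only_b = only_b,
      n_both = n_both, n_only_a = n_a, n_only_b = n_b,
      defined = defined,
      concordance_rate = rates$concordance_rate,
      discordance_rate = rates$discordance_rate
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  rate <- if (x$defined) sprintf("%.1f%%", 100 * x$concordance_rate) else "undefined"
  cat(sprintf(
    "<comparison_result> both=%d only_a=%d only_b=%d; concordance %s\n",
    x$n_both, x$n_only_a, x$n_only_b, rate
  ))
  invisible(x)
}

#' Match two call sets for one sample on exact normalized variant keys
#'
#' Inputs must already be normalized and restricted to the common genes;
#' each list must contain calls from a single sample (mixed sample IDs
#' raise). Duplicate reports of one key within one assay count once. The
#' partition is symmetric: `match_calls(a, b)$only_a` equals
#' `match_calls(b, a)$only_b`.
#'
#' @param calls_a,calls_b variant call tables for the same sample.
#' @return a `comparison_result` with `both` (matched pairs carrying both
#'   assays' AF/depth and their mean AF), `only_a`, `only_b` and the rates.
#' @export
match_calls <- function(calls_a, calls_b) {
  check_one_sample <- function(calls, label) {
    ids <- unique(calls$sample_id)
    if (length(ids) > 1L) {
      stop("mixed sample_ids in ", label, ": ", paste(ids, collapse = ", "), call. = FALSE)
    }
    ids
  }
  id_a <- check_one_sample(calls_a, "calls_a")
  id_b <- check_one_sample(calls_b, "calls_b")
  if (length(id_a) && length(id_b) && !identical(id_a, id_b)) {
    stop("calls_a and calls_b are from different samples", call. = FALSE)
  }
  a <- calls_a[!duplicated(variant_key(calls_a)), , drop = FALSE]
  b <- calls_b[!duplicated(variant_key(calls_b)), , drop = FALSE]
  ka <- variant_key(a)
  kb <- variant_key(b)
  in_both_a <- ka %in% kb
  shared_a <- a[in_both_a, , drop = FALSE]
  idx_b <- match(variant_key(shared_a), kb)
  both <- shared_a
  both$af_a <- shared_a$allele_frequency
  both$af_b <- b$allele_frequency[idx_b]
  both$mean_af <- (both$af_a + both$af_b) / 2
  both$depth_a <- shared_a$read_depth
  both$depth_b <- b$read_depth[idx_b]
  both$assay_a <- shared_a$assay_id
  both$assay_b <- b$assay_id[idx_b]
  only_a <- a[!in_both_a, , drop = FALSE]
  only_b <- b[!kb %in% ka, , drop = FALSE]
  rownames(both) <- rownames(only_a) <- rownames(only_b) <- NULL
  comparison_result(both, only_a, only_b)
}

# Pooled counts for a set of comparison results.
pool_counts <- function(results) {
  c(
    n_both = sum(vapply(results, `[[`, integer(1), "n_both")),
    n_only_a = sum(vapply(results, `[[`, integer(1), "n_only_a")),
    n_only_b = sum(vapply(results, `[[`, integer(1), "n_only_b"))
  )
}

stratum_row <- function(stratum, n_both, n_only_a, n_only_b) {
  total <- n_both + n_only_a + n_only_b
  conc <- if (total > 0) n_both / total else NA_real_
  data.frame(
    stratum = stratum, n_both = n_both, n_only_a = n_only_a,
    n_only_b = n_only_b, n_total = total,
    concordance_rate = conc,
    discordance_rate = if (total > 0) 1 - conc else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Stratified pooled concordance summary
#'
#' Pools matched/only-A/only-B counts over samples within each stratum and
#' computes the pooled concordance rate (counts are pooled across samples,
#' not averaged per sample, so rates over strata are additive to the
#' overall rate). `strata = "group"` stratifies by sample group (FF /
#' FFPE_H / FFPE_L); `strata = "actionability"` splits every variant into
#' actionable vs VUS before counting (a matched pair's tier is taken from
#' assay A).
#'
#' @param results named list mapping `sample_id` to [match_calls()] results.
#' @param meta sample metadata covering every sample in `results`.
#' @param strata `"group"` or `"actionability"`.
#' @return a data.frame with one row per stratum: counts, total and rates.
#' @export
stratified_summary <- function(results, meta, strata = c("group", "actionability")) {
  strata <- match.arg(strata)
  ids <- names(results)
  if (strata == "group") {
    hit <- match(ids, meta$sample_id)
    if (anyNA(hit)) {
      stop("no metadata for sample(s): ", paste(ids[is.na(hit)], collapse = ", "), call. = FALSE)
    }
    groups <- meta$group[hit]
    out <- do.call(rbind, lapply(sort(unique(groups)), function(g) {
      counts <- pool_counts(results[groups == g])
      stratum_row(g, counts[["n_both"]], counts[["n_only_a"]], counts[["n_only_b"]])
    }))
  } else {
    count_split <- function(get) {
      act <- vus <- 0L
      for (r in results) {
        tiers <- get(r)
        act <- act + sum(is_actionable(tiers))
        vus <- vus + sum(!is_actionable(tiers))
      }
      c(actionable = act, VUS = vus)
    }
    both <- count_split(function(r) r$both$actionability_tier)
    only_a <- count_split(function(r) r$only_a$actionability_tier)
    only_b <- count_split(function(r) r$only_b$actionability_tier)
    out <- rbind(
      stratum_row("actionable", both[["actionable"]], only_a[["actionable"]], only_b[["actionable"]]),
      stratum_row("VUS", both[["VUS"]], only_a[["VUS"]], only_b[["VUS"]])
    )
  }
  rownames(out) <- NULL
  out
}

#' Per-sample concordance rates
#'
#' The pooled formula restricted to one sample. Samples with zero variants
#' in either assay have an undefined rate and are flagged with
#' `defined = FALSE` (callers should exclude them from correlations).
#'
#' @param results named list of [match_calls()] results.
#' @return a data.frame with `sample_id`, counts, `concordance_rate`,
#'   `defined`.
#' @export
per_sample_concordance <- function(results) {
  out <- do.call(rbind, lapply(names(results), function(id) {
    r <- results[[id]]
    data.frame(
      sample_id = id, n_both = r$n_both, n_only_a = r$n_only_a,
      n_only_b = r$n_only_b, concordance_rate = r$concordance_rate,
      defined = r$defined, stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
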