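# Assay emulation: apply a panel's detection and reporting rules to a truth
# set, producing the reported call set plus a suppression ledger explaining
# every candidate the assay did not report.

suppression_reasons <- c(
  "below_af_floor", "below_depth_rule", "germline_subtracted",
  "reporting_cap", "gene_not_on_panel"
)

empty_call_table <- function(extra = c("origin", "true_af", "alt_reads")) {
  cols <- c(variant_table_columns, extra)
  out <- data.frame(
    sample_id = character(), assay_id = character(), gene = character(),
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    variant_class = character(), allele_frequency = numeric(),
    read_depth = integer(), actionability_tier = character(),
    stringsAsFactors = FALSE
  )
  for (e in extra) out[[e]] <- if (e == "true_af") numeric() else if (e == "alt_reads") integer() else character()
  out[, cols, drop = FALSE]
}

# Observe every on-panel truth variant at assay depth and split into
# detected candidates vs detection-level suppressions. Artifact-origin
# variants get a mean-preserving skewed per-assay multiplier on their
# effective AF (library-prep "jackpot" dispersion of deaminated
# molecules), so each assay samples an artifact's signal almost
# independently; germline/somatic AFs are stable and get none.
observe_candidates <- function(truth, spec, config_cv = 0.3, depth_threshold = NULL,
                               artifact_dispersion_shape = 0.3) {
  on_panel <- truth$gene %in% spec$genes
  off <- truth[!on_panel, , drop = FALSE]
  tv <- truth[on_panel, , drop = FALSE]
  n <- nrow(tv)
  depth <- draw_depth(n, spec$mean_depth, config_cv)
  eff_af <- tv$true_af
  if ("origin" %in% names(tv) && !is.null(artifact_dispersion_shape) &&
      is.finite(artifact_dispersion_shape)) {
    art <- which(tv$origin == "artifact")
    if (length(art)) {
      mult <- stats::rgamma(length(art),
        shape = artifact_dispersion_shape, rate = artifact_dispersion_shape)
      eff_af[art] <- pmin(1, eff_af[art] * mult)
    }
  }
  obs <- observe_variant(eff_af, pmax(depth, 1L))
  calls <- data.frame(
    sample_id = tv$sample_id,
    assay_id = rep(spec$name, n),
    gene = tv$gene, chrom = tv$chrom, pos = tv$pos,
    ref = tv$ref, alt = tv$alt, variant_class = tv$variant_class,
    allele_frequency = obs$observed_af,
    read_depth = depth,
    actionability_tier = tv$actionability_tier,
    origin = tv$origin, true_af = tv$true_af,
    alt_reads = obs$alt_reads,
    stringsAsFactors = FALSE
  )
  threshold <- depth_threshold %||%
    (if (identical(spec$depth_rule$type, "fixed")) spec$depth_rule$value else 0)
  below_depth <- calls$read_depth < threshold
  below_af <- calls$allele_frequency < spec$af_floor | calls$alt_reads < spec$min_alt_reads
  reason <- rep(NA_character_, n)
  reason[below_af] <- "below_af_floor"
  reason[below_depth] <- "below_depth_rule" # depth rule takes priority
  detected <- is.na(reason)
  suppressed <- calls[!detected, , drop = FALSE]
  suppressed$suppression_reason <- reason[!detected]
  if (nrow(off)) {
    off_calls <- data.frame(
      sample_id = off$sample_id, assay_id = rep(spec$name, nrow(off)),
      gene = off$gene, chrom = off$chrom, pos = off$pos,
      ref = off$ref, alt = off$alt, variant_class = off$variant_class,
      allele_frequency = rep(NA_real_, nrow(off)),
      read_depth = rep(NA_integer_, nrow(off)),
      actionability_tier = off$actionability_tier,
      origin = off$origin, true_af = off$true_af,
      alt_reads = rep(NA_integer_, nrow(off)),
      stringsAsFactors = FALSE
    )
    off_calls$suppression_reason <- "gene_not_on_panel"
    suppressed <- rbind(suppressed, off_calls)
  }
  list(detected = calls[detected, , drop = FALSE], suppressed = suppressed)
}

# Reporting-cap ranking: actionability tier first (VUS last), then observed
# AF descending, then coordinate for a deterministic tie-break.
cap_order <- function(calls) {
  order(tier_rank(calls$actionability_tier), -calls$allele_frequency, calls$chrom, calls$pos)
}

assay_report <- function(sample_id, spec, reported, suppressed) {
  rownames(reported) <- NULL
  rownames(suppressed) <- NULL
  structure(
    list(
      sample_id = sample_id,
      panel = spec$name,
      matched_normal = spec$matched_normal,
      reported = reported,
      suppressed = suppressed
    ),
    class = "assay_report"
  )
}

#' @export
print.assay_report <- function(x, ...) {
  cat(sprintf(
    "<assay_report> %s / %s: %d reported, %d suppressed (%s)\n",
    x$sample_id, x$panel, nrow(x$reported), nrow(x$suppressed),
    paste(sprintf("%s=%d", names(table(x$suppressed$suppression_reason)),
      table(x$suppressed$suppression_reason)), collapse = ", ")
  ))
  invisible(x)
}

#' Emulate a tumor-only panel assay on one sample's truth set
#'
#' Each on-panel truth variant is observed binomially at a lognormal
#' per-variant depth around the panel mean. Candidates with observed AF
#' below the panel's AF floor or fewer supporting reads than the panel
#' minimum are suppressed (`below_af_floor`). Germline variants are NOT
#' removed: a tumor-only assay cannot distinguish them. If more candidates
#' survive than the panel's reporting cap, candidates are ranked by
#' actionability tier (ascending, VUS last), observed AF (descending) and
#' coordinate, and only the top `reporting_cap` are reported; the rest are
#' suppressed with reason `reporting_cap`.
#'
#' @param truth a per-sample truth set.
#' @param meta the sample's metadata row.
#' @param spec a tumor-only [panel_spec] (`matched_normal = FALSE`).
#' @param seed optional substream seed.
#' @param depth_cv lognormal CV of per-variant depth.
#' @param artifact_dispersion_shape shape of the mean-preserving gamma
#'   multiplier applied to artifact-origin effective AFs per assay (small
#'   values = strong library-prep jackpot dispersion, making artifact calls
#'   nearly independent between assays; `NULL` disables it).
#' @return an `assay_report`.
#' @export
emulate_tumor_only_assay <- function(truth, meta, spec, seed = NULL, depth_cv = 0.3,
                                     artifact_dispersion_shape = 0.3) {
  if (spec$matched_normal) {
    stop("emulate_tumor_only_assay requires a panel with matched_normal = FALSE", call. = FALSE)
  }
  gen <- function() {
    if (nrow(truth) == 0L) {
      et <- empty_call_table()
      es <- et
      es$suppression_reason <- character()
      return(assay_report(meta$sample_id, spec, et, es))
    }
    parts <- observe_candidates(truth, spec,
      config_cv = depth_cv,
      artifact_dispersion_shape = artifact_dispersion_shape
    )
    reported <- parts$detected
    suppressed <- parts$suppressed
    if (is.finite(spec$reporting_cap) && nrow(reported) > spec$reporting_cap) {
      ord <- cap_order(reported)
      keep <- ord[seq_len(spec$reporting_cap)]
      drop <- ord[-seq_len(spec$reporting_cap)]
      capped <- reported[drop, , drop = FALSE]
      capped$suppression_reason <- "reporting_cap"
      suppressed <- rbind(suppressed, capped)
      reported <- reported[sort(keep), , drop = FALSE]
    }
    assay_report(meta$sample_id, spec, reported, suppressed)
  }
  if (is.null(seed)) gen() else local_seed(seed, gen())
}

#' Emulate a matched tumor-normal panel assay on one sample's truth set
#'
#' Detection works as in [emulate_tumor_only_assay()], except the
#' per-variant depth requirement comes from
#' [depth_threshold_for_cellularity()] (low-cellularity samples demand
#' deeper coverage). Any detected candidate whose matched-normal read
#' evidence passes [is_germline_consistent()] is suppressed with reason
#' `germline_subtracted` — this is the germline subtraction a paired panel
#' performs. The packaged tumor-normal panel has no reporting cap.
#'
#' @inheritParams emulate_tumor_only_assay
#' @param spec a matched-normal [panel_spec] (`matched_normal = TRUE`).
#' @param normal the cohort normal-evidence table; must cover every detected
#'   candidate of this sample (a missing row is an error naming the variant).
#' @param germline_min_reads,germline_min_af thresholds passed to
#'   [is_germline_consistent()].
#' @return an `assay_report`.
#' @export
emulate_tumor_normal_assay <- function(truth, meta, spec, normal, seed = NULL,
                                       depth_cv = 0.3,
                                       germline_min_reads = 3L,
                                       germline_min_af = 0.25,
                                       artifact_dispersion_shape = 0.3) {
  if (!spec$matched_normal) {
    stop("emulate_tumor_normal_assay requires a panel with matched_normal = TRUE", call. = FALSE)
  }
  gen <- function() {
    if (nrow(truth) == 0L) {
      et <- empty_call_table()
      es <- et
      es$suppression_reason <- character()
      return(assay_report(meta$sample_id, spec, et, es))
    }
    threshold <- if (identical(spec$depth_rule$type, "cellularity_tiered")) {
      depth_threshold_for_cellularity(meta$tumor_cellularity, spec)
    } else {
      spec$depth_rule$value
    }
    parts <- observe_candidates(truth, spec,
      config_cv = depth_cv, depth_threshold = threshold,
      artifact_dispersion_shape = artifact_dispersion_shape
    )
    reported <- parts$detected
    suppressed <- parts$suppressed
    if (nrow(reported)) {
      nsub <- normal[normal$sample_id == meta$sample_id, , drop = FALSE]
      key <- variant_key(reported)
      nkey <- variant_key(nsub)
      hit <- match(key, nkey)
      if (anyNA(hit)) {
        stop(
          "missing normal evidence for variant(s): ",
          paste(utils::head(key[is.na(hit)], 3L), collapse = ", "),
          call. = FALSE
        )
      }
      germ <- germline_evidence_consistent(
        nsub$normal_alt_reads[hit], nsub$normal_depth[hit],
        min_reads = germline_min_reads, min_normal_af = germline_min_af
      )
      if (any(germ)) {
        sub <- reported[germ, , drop = FALSE]
        sub$suppression_reason <- "germline_subtracted"
        suppressed <- rbind(suppressed, sub)
        reported <- reported[!germ, , drop = FALSE]
      }
    }
    if (is.finite(spec$reporting_cap) && nrow(reported) > spec$reporting_cap) {
      ord <- cap_order(reported)
      drop <- ord[-seq_len(spec$reporting_cap)]
      capped <- reported[drop, , drop = FALSE]
      capped$suppression_reason <- "reporting_cap"
      suppressed <- rbind(suppressed, capped)
      reported <- reported[sort(ord[seq_len(spec$reporting_cap)]), , drop = FALSE]
    }
    assay_report(meta$sample_id, spec, reported, suppressed)
  }
  if (is.null(seed)) gen() else local_seed(seed, gen())
}

#' Serialize an assay report to a variant table TSV
#'
#' Reported calls are written first, then suppressed candidates with their
#' `suppression_reason` (empty for reported rows).
#'
#' @param report an `assay_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assay_report <- function(report, path) {
  rep_ <- report$reported
  rep_$suppression_reason <- rep("", nrow(rep_))
  out <- rbind(rep_, report$suppressed)
  for (col in names(out)) if (is.double(out[[col]])) out[[col]] <- fmt_double(out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
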