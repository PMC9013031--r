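# Synthetic dual-assay cohort simulator. Generates per-sample ground truth
# (germline heterozygotes, cellularity-scaled somatic variants, low-AF FFPE
# deamination artifacts) plus matched-normal read evidence, so every
# downstream stage can be exercised against a known truth.

#' Simulation configuration
#'
#' Defaults emulate the shape of a 30-patient dual-assay study: 10 fresh
#' frozen (FF) samples, 10 high-quality FFPE (`FFPE_H`, library
#' concentration >= 5 nM) and 10 low-quality FFPE (`FFPE_L`, < 5 nM).
#' Germline heterozygotes have true allele frequency exactly 0.5; somatic
#' truth AF is `0.5 * cellularity * clonal_fraction` (diploid heterozygous
#' event, no copy-number modeling); FFPE deamination artifacts are low-AF
#' substitutions, `ct_fraction` of which are C>T or G>A, with per-sample
#' counts Poisson(`artifact_lambda[group]`) ordered FF <= FFPE_H <= FFPE_L.
#'
#' @param n_per_group named integer vector of sample counts per group.
#' @param germline_mean Poisson mean of germline heterozygotes per sample
#'   over the whole mock gene universe. The default 2.5 represents only the
#'   rare germline variants that survive a tumor-only pipeline's upstream
#'   polymorphism filtering, not all heterozygous sites.
#' @param somatic_mean Poisson mean of somatic variants per sample.
#' @param clonal_shape1,clonal_shape2 Beta parameters of the somatic clonal
#'   fraction distribution (default Beta(5,2): mostly clonal).
#' @param artifact_lambda named vector of per-group Poisson artifact means;
#'   must be ordered `FF <= FFPE_H <= FFPE_L`.
#' @param ct_fraction fraction of artifacts on the C>T/G>A channel.
#' @param artifact_af_shape1,artifact_af_shape2 Beta parameters of the
#'   artifact true-AF distribution (default Beta(1,40), ~87% below 5% AF),
#'   truncated below 0.10.
#' @param indel_fraction fraction of germline/somatic variants simulated as
#'   1-3 bp insertions/deletions (artifacts are always substitutions).
#' @param p_actionable named per-origin probability that a variant is
#'   actionable (tier 1..5 rather than VUS).
#' @param cellularity_range uniform range of tumor cellularity (>= 0.20,
#'   matching FFPE inclusion criteria).
#' @param lib_conc_range,q_value_range per-group uniform ranges for DNA
#'   library concentration (nM) and Q-value (PCR-amplifiable fraction).
#' @param normal_mean_depth mean sequencing depth of the matched normal.
#' @param cross_contamination binomial rate of alternate reads in the
#'   normal for non-germline variants.
#' @param depth_cv lognormal coefficient of variation of per-variant depth.
#' @param seed integer master seed; a fixed seed yields a byte-identical
#'   cohort regardless of evaluation order, because each sample uses a
#'   derived substream.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_per_group = c(FF = 10L, FFPE_H = 10L, FFPE_L = 10L),
                              germline_mean = 2.5,
                              somatic_mean = 5,
                              clonal_shape1 = 5, clonal_shape2 = 2,
                              artifact_lambda = c(FF = 0, FFPE_H = 3, FFPE_L = 12),
                              ct_fraction = 0.8,
                              artifact_af_shape1 = 1, artifact_af_shape2 = 40,
                              indel_fraction = 0.15,
                              p_actionable = c(germline = 0.2, somatic = 0.6, artifact = 0.05),
                              cellularity_range = c(0.2, 0.9),
                              lib_conc_range = list(FF = c(5, 31), FFPE_H = c(5, 37), FFPE_L = c(0.2, 4.9)),
                              q_value_range = list(FF = c(0.6, 1.43), FFPE_H = c(0.2, 1.32), FFPE_L = c(0.07, 0.57)),
                              normal_mean_depth = 500,
                              cross_contamination = 0.001,
                              depth_cv = 0.3,
                              seed = 1L) {
  groups <- c("FF", "FFPE_H", "FFPE_L")
  if (!all(groups %in% names(n_per_group))) {
    stop("n_per_group must name FF, FFPE_H and FFPE_L", call. = FALSE)
  }
  if (any(c(germline_mean, somatic_mean, artifact_lambda) < 0)) {
    stop("all rates must be >= 0", call. = FALSE)
  }
  if (ct_fraction < 0 || ct_fraction > 1) stop("ct_fraction must be in [0,1]", call. = FALSE)
  al <- artifact_lambda[groups]
  if (al[["FF"]] > al[["FFPE_H"]] || al[["FFPE_H"]] > al[["FFPE_L"]]) {
    stop("artifact_lambda must satisfy FF <= FFPE_H <= FFPE_L", call. = FALSE)
  }
  if (cellularity_range[1] < 0.20) {
    stop("cellularity_range must start at >= 0.20 (FFPE inclusion criterion)", call. = FALSE)
  }
  structure(
    list(
      n_per_group = n_per_group[groups],
      germline_mean = germline_mean,
      somatic_mean = somatic_mean,
      clonal_shape1 = clonal_shape1, clonal_shape2 = clonal_shape2,
      artifact_lambda = al,
      ct_fraction = ct_fraction,
      artifact_af_shape1 = artifact_af_shape1,
      artifact_af_shape2 = artifact_af_shape2,
      indel_fraction = indel_fraction,
      p_actionable = p_actionable,
      cellularity_range = cellularity_range,
      lib_conc_range = lib_conc_range,
      q_value_range = q_value_range,
      normal_mean_depth = normal_mean_depth,
      cross_contamination = cross_contamination,
      depth_cv = depth_cv,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

bases <- c("A", "C", "G", "T")

# n random variant records over the mock gene model. channel_ct marks which
# rows must be C>T or G>A substitutions; allow_indel enables 1-3 bp indels.
random_variant_sites <- function(n, model, config, channel_ct = rep(FALSE, n),
                                 allow_indel = TRUE) {
  if (n == 0L) {
    return(data.frame(
      gene = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), variant_class = character(),
      substitution_channel = character(), stringsAsFactors = FALSE
    ))
  }
  gi <- sample.int(nrow(model), n, replace = TRUE)
  pos <- as.integer(model$start[gi] + floor(stats::runif(n) * (model$end[gi] - model$start[gi] - 10L)))
  kind <- if (allow_indel) {
    ifelse(stats::runif(n) < config$indel_fraction,
      sample(c("insertion", "deletion"), n, replace = TRUE), "substitution"
    )
  } else {
    rep("substitution", n)
  }
  kind[channel_ct] <- "substitution"
  ref <- alt <- character(n)
  channel <- rep("na", n)
  for (i in seq_len(n)) {
    if (kind[i] == "substitution") {
      if (channel_ct[i]) {
        ref[i] <- sample(c("C", "G"), 1L)
        alt[i] <- if (ref[i] == "C") "T" else "A"
      } else {
        repeat {
          ref[i] <- sample(bases, 1L)
          alt[i] <- sample(setdiff(bases, ref[i]), 1L)
          if (!(ref[i] == "C" && alt[i] == "T") && !(ref[i] == "G" && alt[i] == "A")) break
        }
      }
      channel[i] <- if (channel_ct[i]) "CT_GA" else "other"
    } else {
      anchor <- sample(bases, 1L)
      extra <- paste(sample(bases, sample(1:3, 1L), replace = TRUE), collapse = "")
      if (kind[i] == "insertion") {
        ref[i] <- anchor
        alt[i] <- paste0(anchor, extra)
      } else {
        ref[i] <- paste0(anchor, extra)
        alt[i] <- anchor
      }
    }
  }
  data.frame(
    gene = model$gene[gi], chrom = model$chrom[gi], pos = pos,
    ref = ref, alt = alt, variant_class = classify_variant_class(ref, alt),
    substitution_channel = channel, stringsAsFactors = FALSE
  )
}

draw_tiers <- function(n, origin, config) {
  p <- config$p_actionable[[origin]]
  ifelse(stats::runif(n) < p, as.character(sample.int(5L, n, replace = TRUE)), "none")
}

#' Simulate the germline and somatic ground truth for one sample
#'
#' Germline heterozygotes have `true_af = 0.5` exactly; somatic variants
#' have `true_af = 0.5 * cellularity * clonal_fraction` with the clonal
#' fraction drawn from the configured Beta distribution. Coordinates are
#' drawn uniformly over the mock gene model (shared plus panel-private
#' genes). FFPE artifacts are added separately by [inject_ffpe_artifacts()].
#'
#' @param meta a one-row sample metadata data.frame (see [simulate_cohort()]).
#' @param config a [simulation_config()].
#' @param seed optional integer substream seed; `NULL` uses the current RNG.
#' @return a `data.frame` truth set with variant fields plus `origin`,
#'   `true_af`, `substitution_channel`, `actionability_tier`.
#' @export
simulate_truth_set <- function(meta, config, seed = NULL) {
  gen <- function() {
    model <- mock_gene_model()
    n_g <- stats::rpois(1L, config$germline_mean)
    n_s <- stats::rpois(1L, config$somatic_mean)
    g <- random_variant_sites(n_g, model, config)
    s <- random_variant_sites(n_s, model, config)
    g$origin <- rep("germline", n_g)
    g$true_af <- rep(0.5, n_g)
    s$origin <- rep("somatic", n_s)
    clonal <- stats::rbeta(n_s, config$clonal_shape1, config$clonal_shape2)
    s$true_af <- 0.5 * meta$tumor_cellularity * clonal
    g$actionability_tier <- draw_tiers(n_g, "germline", config)
    s$actionability_tier <- draw_tiers(n_s, "somatic", config)
    truth <- rbind(g, s)
    truth <- cbind(sample_id = rep(meta$sample_id, nrow(truth)), truth,
      stringsAsFactors = FALSE
    )
    truth <- truth[!duplicated(variant_key(truth)), , drop = FALSE]
    rownames(truth) <- NULL
    truth
  }
  if (is.null(seed)) gen() else local_seed(seed, gen())
}

#' Inject FFPE deamination artifacts into a truth set
#'
#' Adds `Poisson(artifact_lambda[group])` artifact variants, a
#' `ct_fraction` of which are C>T or G>A single-base substitutions (the
#' formalin deamination channel). Artifact true AF is drawn from the
#' configured Beta distribution truncated below 0.10, so artifacts are
#' low-frequency by construction. Fresh frozen samples default to rate 0.
#'
#' @inheritParams simulate_truth_set
#' @param truth a truth set from [simulate_truth_set()].
#' @return the truth set with artifact rows appended.
#' @export
inject_ffpe_artifacts <- function(truth, meta, config, seed = NULL) {
  gen <- function() {
    lambda <- config$artifact_lambda[[meta$group]]
    k <- stats::rpois(1L, lambda)
    if (k == 0L) return(truth)
    model <- mock_gene_model()
    ct <- stats::runif(k) < config$ct_fraction
    a <- random_variant_sites(k, model, config, channel_ct = ct, allow_indel = FALSE)
    a$origin <- rep("artifact", k)
    # inverse-CDF truncation keeps true_af strictly below 0.10
    u <- stats::runif(k) * stats::pbeta(0.0999, config$artifact_af_shape1, config$artifact_af_shape2)
    a$true_af <- stats::qbeta(u, config$artifact_af_shape1, config$artifact_af_shape2)
    a$actionability_tier <- draw_tiers(k, "artifact", config)
    a <- cbind(sample_id = rep(meta$sample_id, k), a, stringsAsFactors = FALSE)
    out <- rbind(truth, a)
    out <- out[!duplicated(variant_key(out)), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  if (is.null(seed)) gen() else local_seed(seed, gen())
}

#' Binomial read sampling of a variant at a given depth
#'
#' The sequencing observation model: `alt_reads ~ Binomial(depth, true_af)`
#' and `observed_af = alt_reads / depth`. Vectorized.
#'
#' @param truth_af true allele fraction(s) in \[0,1\].
#' @param depth read depth(s), all >= 1.
#' @param seed optional substream seed.
#' @return a list with `alt_reads` and `observed_af`.
#' @export
observe_variant <- function(truth_af, depth, seed = NULL) {
  if (any(depth < 1)) stop("depth must be >= 1", call. = FALSE)
  gen <- function() {
    n <- max(length(truth_af), length(depth))
    alt <- stats::rbinom(n, size = depth, prob = truth_af)
    list(alt_reads = alt, observed_af = alt / depth)
  }
  if (is.null(seed)) gen() else local_seed(seed, gen())
}

simulate_normal_evidence <- function(truth, config, seed = NULL) {
  gen <- function() {
    n <- nrow(truth)
    if (n == 0L) {
      return(data.frame(
        sample_id = character(), chrom = character(), pos = integer(),
        ref = character(), alt = character(),
        normal_depth = integer(), normal_alt_reads = integer(),
        stringsAsFactors = FALSE
      ))
    }
    depth <- draw_depth(n, config$normal_mean_depth, config$depth_cv)
    p <- ifelse(truth$origin == "germline", 0.5, config$cross_contamination)
    alt <- stats::rbinom(n, depth, p)
    data.frame(
      sample_id = truth$sample_id, chrom = truth$chrom, pos = truth$pos,
      ref = truth$ref, alt = truth$alt,
      normal_depth = depth, normal_alt_reads = alt,
      stringsAsFactors = FALSE
    )
  }
  if (is.null(seed)) gen() else local_seed(seed, gen())
}

#' Simulate a full dual-assay cohort
#'
#' Generates sample metadata (group, cellularity, library concentration,
#' Q-value, cancer type), a per-sample truth set (germline + somatic +
#' group-dependent FFPE artifacts) and a matched-normal read-evidence table
#' covering every truth variant (binomial at AF 0.5 for germline, at the
#' cross-contamination rate otherwise). Each sample is simulated on its own
#' derived RNG substream, so the cohort is byte-identical for a fixed
#' `config$seed` regardless of evaluation order.
#'
#' @param config a [simulation_config()].
#' @return an object of class `cohort`: a list with `meta` (data.frame),
#'   `truth` (named list of per-sample truth sets) and `normal`
#'   (cohort-wide normal evidence data.frame).
#' @examples
#' cohort <- simulate_cohort(simulation_config(seed = 7))
#' table(cohort$meta$group)
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  groups <- rep(names(config$n_per_group), config$n_per_group)
  n <- length(groups)
  sample_id <- sprintf("S%03d", seq_len(n))
  cancer_types <- c(
    "pancreas", "colorectal", "biliary_tract", "CUP", "NSCLC",
    "esophagus", "gastric", "breast", "sarcoma", "bladder"
  )
  meta <- local_seed(derive_seed(config$seed, "meta"), {
    cellularity <- stats::runif(n, config$cellularity_range[1], config$cellularity_range[2])
    lib <- q <- numeric(n)
    for (g in unique(groups)) {
      idx <- groups == g
      lr <- config$lib_conc_range[[g]]
      qr <- config$q_value_range[[g]]
      lib[idx] <- stats::runif(sum(idx), lr[1], lr[2])
      q[idx] <- stats::runif(sum(idx), qr[1], qr[2])
    }
    data.frame(
      sample_id = sample_id, group = groups,
      library_concentration = lib, q_value = q,
      tumor_cellularity = cellularity,
      cancer_type = sample(cancer_types, n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
  truth <- vector("list", n)
  names(truth) <- sample_id
  normal <- vector("list", n)
  for (i in seq_len(n)) {
    m <- meta[i, , drop = FALSE]
    ts <- simulate_truth_set(m, config, seed = derive_seed(config$seed, paste0("truth:", sample_id[i])))
    ts <- inject_ffpe_artifacts(ts, m, config, seed = derive_seed(config$seed, paste0("artifact:", sample_id[i])))
    truth[[i]] <- ts
    normal[[i]] <- simulate_normal_evidence(ts, config, seed = derive_seed(config$seed, paste0("normal:", sample_id[i])))
  }
  structure(
    list(
      meta = meta,
      truth = truth,
      normal = do.call(rbind, c(normal, list(make.row.names = FALSE)))
    ),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d samples (%s); %d truth variants, %d normal-evidence rows\n",
    nrow(x$meta),
    paste(sprintf("%s=%d", names(table(x$meta$group)), table(x$meta$group)), collapse = ", "),
    sum(vapply(x$truth, nrow, integer(1))), nrow(x$normal)
  ))
  invisible(x)
}

#' Serialize a cohort to TSV files
#'
#' Writes `meta.tsv`, `truth.tsv` (variant table dialect plus `origin`,
#' `true_af`, `substitution_channel` columns) and `normal_evidence.tsv`
#' into a directory.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- cohort$meta
  for (col in names(meta)) if (is.double(meta[[col]])) meta[[col]] <- fmt_double(meta[[col]])
  utils::write.table(meta, file.path(dir, "meta.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  truth <- do.call(rbind, c(cohort$truth, list(make.row.names = FALSE)))
  for (col in names(truth)) if (is.double(truth[[col]])) truth[[col]] <- fmt_double(truth[[col]])
  utils::write.table(truth, file.path(dir, "truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(cohort$normal, file.path(dir, "normal_evidence.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}
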