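# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures.

BASES <- c("A", "C", "G", "T")

withr_tempfile <- function(ext = ".tsv") tempfile(fileext = ext)

variant_keys <- function(df) sort(paste(df$chrom, df$pos, df$ref, df$alt))

# small deterministic per-(sample, stage) seed for loops in tests
derive2 <- function(base, id, k) {
  base * 1000L + as.integer(sub("^S0*", "", id)) * 10L + k
}

# A valid random variant call table (unique keys within a sample).
random_calls <- function(n, sample_id = "S1", assay_id = "assayA", seed = 1) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    pos <- sample.int(1e6, n)
    ref <- sample(BASES, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), character(1))
    # a few indels for variety
    idx <- which(stats::runif(n) < 0.2)
    for (i in idx) {
      extra <- paste(sample(BASES, sample(1:3, 1), replace = TRUE), collapse = "")
      if (stats::runif(1) < 0.5) alt[i] <- paste0(ref[i], extra) else {
        ref[i] <- paste0(ref[i], extra)
        alt[i] <- substr(ref[i], 1, 1)
      }
    }
    df <- data.frame(
      sample_id = rep(sample_id, n),
      assay_id = rep(assay_id, n),
      gene = sprintf("CG%03d", sample.int(92, n, replace = TRUE)),
      chrom = paste0("chr", sample.int(22, n, replace = TRUE)),
      pos = pos,
      ref = unname(ref), alt = unname(alt),
      variant_class = classify_variant_class(ref, alt),
      allele_frequency = round(stats::runif(n), 6),
      read_depth = sample.int(5000, n),
      actionability_tier = sample(c(as.character(1:5), "none"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    df[!duplicated(paste(df$chrom, df$pos)), , drop = FALSE]
  })
}

# Sequence-edit oracle for normalization: applying the original and the
# normalized variant to the same context must give the same edited string.
apply_edit <- function(context, ctx_start, pos, ref, alt) {
  off <- pos - ctx_start + 1L
  stopifnot(substr(context, off, off + nchar(ref) - 1L) == ref)
  paste0(
    substr(context, 1L, off - 1L), alt,
    substr(context, off + nchar(ref), nchar(context))
  )
}

random_context_variant <- function() {
  L <- 20L
  context <- paste(sample(BASES, L, replace = TRUE), collapse = "")
  k_ref <- sample(1:5, 1)
  off <- sample(seq_len(L - k_ref - 2L) + 1L, 1)
  ref <- substr(context, off, off + k_ref - 1L)
  repeat {
    alt <- paste(sample(BASES, sample(1:5, 1), replace = TRUE), collapse = "")
    if (alt != ref) break
  }
  list(context = context, ctx_start = 1000L, pos = 1000L + off - 1L, ref = ref, alt = alt)
}

# Brute-force double-loop matcher (independent of match_calls internals).
brute_force_match <- function(calls_a, calls_b) {
  key <- function(df, i) paste(df$chrom[i], df$pos[i], df$ref[i], df$alt[i])
  ka <- vapply(seq_len(nrow(calls_a)), function(i) key(calls_a, i), character(1))
  kb <- vapply(seq_len(nrow(calls_b)), function(i) key(calls_b, i), character(1))
  ka <- unique(ka)
  kb <- unique(kb)
  both <- 0L
  only_a <- 0L
  for (k in ka) {
    hit <- FALSE
    for (k2 in kb) if (k == k2) hit <- TRUE
    if (hit) both <- both + 1L else only_a <- only_a + 1L
  }
  only_b <- 0L
  for (k in kb) {
    hit <- FALSE
    for (k2 in ka) if (k == k2) hit <- TRUE
    if (!hit) only_b <- only_b + 1L
  }
  list(both = both, only_a = only_a, only_b = only_b)
}

# Independent full-enumeration Fisher oracle (recursive over row 1 cells),
# written without reference to fisher_exact_rxc.
fisher_oracle <- function(tab) {
  rs <- rowSums(tab)
  cs <- colSums(tab)
  N <- sum(tab)
  logp <- function(x1) sum(lchoose(cs, x1)) - lchoose(N, rs[1])
  cells <- expand.grid(lapply(cs, function(cj) 0:cj))
  cells <- cells[rowSums(cells) == rs[1], , drop = FALSE]
  lps <- apply(cells, 1, function(x1) logp(as.numeric(x1)))
  obs <- logp(tab[1, ])
  sum(exp(lps[lps <= obs + log(1 + 1e-7)]))
}

# Minimal metadata row for direct truth-set / emulation tests.
make_meta <- function(sample_id = "S1", group = "FF", cellularity = 0.6,
                      lib = 10, q = 0.8) {
  data.frame(
    sample_id = sample_id, group = group,
    library_concentration = lib, q_value = q,
    tumor_cellularity = cellularity, cancer_type = "pancreas",
    stringsAsFactors = FALSE
  )
}

# A truth set of n guaranteed-detectable germline-like variants on shared
# genes (AF 0.5), for cap and subtraction tests.
make_truth <- function(n, sample_id = "S1", origin = "germline",
                       true_af = 0.5, tier = "none", genes = sprintf("CG%03d", 1:92)) {
  model <- mock_gene_model()
  model <- model[model$gene %in% genes, , drop = FALSE]
  gi <- rep_len(seq_len(nrow(model)), n)
  data.frame(
    sample_id = rep(sample_id, n),
    gene = model$gene[gi], chrom = model$chrom[gi],
    pos = model$start[gi] + seq_len(n),
    ref = rep("A", n), alt = rep("G", n),
    variant_class = rep("substitution", n),
    substitution_channel = rep("other", n),
    origin = rep(origin, n), true_af = rep(true_af, n),
    actionability_tier = rep(tier, length.out = n),
    stringsAsFactors = FALSE
  )
}

# Normal evidence consistent with a truth set (germline het ~ AF 0.5,
# otherwise clean normal).
make_normal <- function(truth, depth = 500L) {
  af <- ifelse(truth$origin == "germline", 0.5, 0)
  data.frame(
    sample_id = truth$sample_id, chrom = truth$chrom, pos = truth$pos,
    ref = truth$ref, alt = truth$alt,
    normal_depth = rep(depth, nrow(truth)),
    normal_alt_reads = as.integer(round(depth * af)),
    stringsAsFactors = FALSE
  )
}

# Small, fast simulation config for property tests.
tiny_config <- function(seed = 1, ...) {
  simulation_config(
    n_per_group = c(FF = 4L, FFPE_H = 4L, FFPE_L = 4L),
    seed = seed, ...
  )
}
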