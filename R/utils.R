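# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed`, so simulator substreams do
#' not disturb the global stream. Used to make per-sample simulation
#' order-independent.
#'
#' @param seed integer seed (must be < 2^31).
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic 31-bit sub-seed from a base seed and a text tag; keeps all
# derived seeds inside R's 32-bit integer range.
derive_seed <- function(base, tag) {
  h <- as.double(abs(as.integer(base)) %% 2147483647)
  for (ch in utf8ToInt(as.character(tag))) h <- (h * 31 + ch) %% 2147483647
  as.integer(max(1, h))
}

# Per-variant sequencing depth: lognormal around the assay mean with a fixed
# coefficient of variation, floored at 1 read.
draw_depth <- function(n, mean_depth, cv = 0.3) {
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean_depth) - sdlog^2 / 2
  pmax(1L, as.integer(round(stats::rlnorm(n, meanlog, sdlog))))
}

# Ordinal rank of an actionability tier: 1..5 actionable, "none" (VUS) last.
tier_rank <- function(tier) {
  ifelse(as.character(tier) == "none", 6L, suppressWarnings(as.integer(as.character(tier))))
}

# Is a call actionable (any tier 1..5, i.e. not a VUS)?
is_actionable <- function(tier) as.character(tier) != "none"

variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

# Exact decimal text for doubles so TSV round-trips are lossless.
fmt_double <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}
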