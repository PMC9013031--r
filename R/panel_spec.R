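# Panel specifications: an assay's gene set plus its detection and
# reporting rules (matched normal or not, AF floor, depth rule, cap).

#' Construct a panel specification
#'
#' @param name assay name (used as `assay_id` on emulated calls).
#' @param genes character vector of gene symbols on the panel.
#' @param matched_normal does the assay sequence a matched normal and
#'   subtract germline variants?
#' @param af_floor minimum observed allele frequency for a call to be
#'   reported (fraction).
#' @param min_alt_reads minimum supporting reads for detection.
#' @param depth_rule either `list(type = "fixed", value = <int>)` or
#'   `list(type = "cellularity_tiered", high = 200, mid = 250, low = 500,
#'   lower = 0.2, upper = 0.5)`: the per-variant mean-read-depth requirement.
#'   In the tiered form, cellularity > `upper` demands `high`, cellularity in
#'   \[`lower`, `upper`\] (both endpoints inclusive) demands `mid`, and
#'   cellularity < `lower` demands `low`.
#' @param reporting_cap maximum number of variants reported per sample
#'   (`Inf` = unlimited). Applied after detection, never before.
#' @param mean_depth assay mean sequencing depth used by the emulator.
#' @return an object of class `panel_spec`.
#' @export
panel_spec <- function(name, genes, matched_normal,
                       af_floor = 0.02, min_alt_reads = 4L,
                       depth_rule = list(type = "fixed", value = 0L),
                       reporting_cap = Inf, mean_depth = 1000) {
  if (missing(genes) || is.null(genes) || !length(genes)) {
    stop("panel config error: 'genes' must be a non-empty character vector", call. = FALSE)
  }
  genes <- unique(as.character(genes))
  if (!is.list(depth_rule) || is.null(depth_rule$type) ||
      !depth_rule$type %in% c("fixed", "cellularity_tiered")) {
    stop("panel config error: unknown depth_rule form", call. = FALSE)
  }
  if (depth_rule$type == "fixed") {
    depth_rule$value <- as.numeric(depth_rule$value %||% 0)
  } else {
    depth_rule$high <- as.numeric(depth_rule$high %||% 200)
    depth_rule$mid <- as.numeric(depth_rule$mid %||% 250)
    depth_rule$low <- as.numeric(depth_rule$low %||% 500)
    depth_rule$lower <- as.numeric(depth_rule$lower %||% 0.2)
    depth_rule$upper <- as.numeric(depth_rule$upper %||% 0.5)
  }
  if (is.null(reporting_cap)) reporting_cap <- Inf
  reporting_cap <- as.numeric(reporting_cap)
  if (is.na(reporting_cap) || reporting_cap < 1) {
    stop("panel config error: reporting_cap must be >= 1 or Inf", call. = FALSE)
  }
  structure(
    list(
      name = as.character(name),
      genes = genes,
      matched_normal = isTRUE(matched_normal),
      af_floor = as.numeric(af_floor),
      min_alt_reads = as.integer(min_alt_reads),
      depth_rule = depth_rule,
      reporting_cap = reporting_cap,
      mean_depth = as.numeric(mean_depth)
    ),
    class = "panel_spec"
  )
}

#' @export
print.panel_spec <- function(x, ...) {
  cap <- if (is.finite(x$reporting_cap)) format(x$reporting_cap) else "unlimited"
  cat(
    sprintf(
      "<panel_spec> %s: %d genes, %s, AF floor %.3g, min alt reads %d, depth rule %s, cap %s\n",
      x$name, length(x$genes),
      if (x$matched_normal) "matched tumor-normal" else "tumor-only",
      x$af_floor, x$min_alt_reads, x$depth_rule$type, cap
    )
  )
  invisible(x)
}

#' Load a panel specification from a JSON config
#'
#' The config carries the fields of [panel_spec()]; the gene set is either an
#' inline `"genes"` array or a `"genes_file"` path (one symbol per line)
#' resolved relative to the config file. A `reporting_cap` of `null` means
#' unlimited. Two packaged fixture configs mirror the emulated study design:
#' a 215-gene tumor-only panel (no matched normal, reporting cap 14) and a
#' 114-gene tumor-normal panel (matched normal, cellularity-tiered depth
#' rule 200/250/500, no cap). Fixture AF floors and read minima are declared
#' package defaults, not disclosed vendor values.
#'
#' @param path path to a JSON panel config.
#' @return a `panel_spec`.
#' @examples
#' tn <- load_panel_spec(system.file("extdata/panels/tn_panel.json",
#'   package = "panelconcord"))
#' depth_threshold_for_cellularity(0.6, tn)
#' @export
load_panel_spec <- function(path) {
  if (!file.exists(path)) stop("no such panel config: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  genes <- cfg[["genes"]] # exact match: $genes would partial-match genes_file
  if (is.null(genes)) {
    if (is.null(cfg[["genes_file"]])) {
      stop("panel config error: must provide 'genes' or 'genes_file'", call. = FALSE)
    }
    gf <- cfg[["genes_file"]]
    if (!file.exists(gf)) gf <- file.path(dirname(path), cfg[["genes_file"]])
    if (!file.exists(gf)) stop("panel config error: genes_file not found: ", cfg[["genes_file"]], call. = FALSE)
    genes <- trimws(readLines(gf))
    genes <- genes[nzchar(genes)]
  }
  panel_spec(
    name = cfg$name %||% tools::file_path_sans_ext(basename(path)),
    genes = genes,
    matched_normal = isTRUE(cfg$matched_normal),
    af_floor = cfg$af_floor %||% 0.02,
    min_alt_reads = cfg$min_alt_reads %||% 4L,
    depth_rule = as.list(cfg$depth_rule %||% list(type = "fixed", value = 0L)),
    reporting_cap = cfg$reporting_cap,
    mean_depth = cfg$mean_depth %||% 1000
  )
}

#' Packaged tumor-only and tumor-normal panel fixtures
#'
#' @return a list with elements `to` and `tn`, the two packaged
#'   [panel_spec]s (215-gene tumor-only and 114-gene tumor-normal, sharing
#'   92 genes).
#' @export
default_panel_specs <- function() {
  dir <- system.file("extdata", "panels", package = "panelconcord")
  list(
    to = load_panel_spec(file.path(dir, "to_panel.json")),
    tn = load_panel_spec(file.path(dir, "tn_panel.json"))
  )
}

#' Depth threshold demanded by a tiered panel at a given tumor cellularity
#'
#' The tumor-normal panel's mean-read-depth requirement scales with the
#' pathologist-estimated tumor cellularity of the specimen: 200 reads above
#' 50% cellularity, 250 between 20% and 50% (endpoints inclusive), and 500
#' below 20%, under the packaged defaults.
#'
#' @param cellularity tumor cell fraction in \[0,1\].
#' @param spec a `panel_spec` with a cellularity-tiered depth rule.
#' @return the integer depth threshold.
#' @export
depth_threshold_for_cellularity <- function(cellularity, spec) {
  dr <- spec$depth_rule
  if (!identical(dr$type, "cellularity_tiered")) {
    stop("depth rule is not tiered for panel '", spec$name, "'", call. = FALSE)
  }
  if (any(is.na(cellularity) | cellularity < 0 | cellularity > 1)) {
    stop("cellularity must be in [0,1]", call. = FALSE)
  }
  ifelse(cellularity > dr$upper, dr$high,
    ifelse(cellularity >= dr$lower, dr$mid, dr$low)
  )
}
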