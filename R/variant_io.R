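# Variant table I/O: the package's TSV dialect, validation, normalization,
# and the common-gene restriction used before any cross-panel comparison.

#' Column order of the variant table TSV dialect
#' @export
variant_table_columns <- c(
  "sample_id", "assay_id", "gene", "chrom", "pos", "ref", "alt",
  "variant_class", "allele_frequency", "read_depth", "actionability_tier"
)

variant_classes <- c("substitution", "insertion", "deletion", "delins")
tier_levels <- c(as.character(1:5), "none")

#' Classify a ref/alt pair as substitution, insertion, deletion or delins
#'
#' Vectorized. Equal-length pairs are substitutions; a pair where the shorter
#' allele is a prefix of the longer is an insertion or deletion (VCF anchor
#' convention); anything else is a delins.
#'
#' @param ref,alt character vectors of reference and alternate alleles.
#' @return character vector of variant classes.
#' @export
classify_variant_class <- function(ref, alt) {
  nr <- nchar(ref)
  na_ <- nchar(alt)
  out <- rep("delins", length(ref))
  out[nr == na_] <- "substitution"
  ins <- nr < na_ & substr(alt, 1L, nr) == ref
  out[ins] <- "insertion"
  del <- nr > na_ & substr(ref, 1L, na_) == alt
  out[del] <- "deletion"
  out
}

#' Validate a variant call table
#'
#' Enforces the short-variant contract: all dialect columns present,
#' `allele_frequency` in \[0,1\], `pos >= 1`, `read_depth >= 0`, `ref != alt`,
#' a known `variant_class` and `actionability_tier`, and the short-variant
#' definition that substitutions have equal-length alleles of at most 5
#' bases. Invalid rows raise an error naming the row numbers; they are never
#' silently dropped.
#'
#' @param calls a `data.frame` of variant calls.
#' @return the validated table, invisibly.
#' @export
validate_variant_calls <- function(calls) {
  if (!is.data.frame(calls)) stop("variant calls must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(variant_table_columns, names(calls))
  if (length(missing_cols)) {
    stop(
      "variant table format error: missing required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(calls) == 0L) return(invisible(calls))
  fail <- function(rows, what) {
    stop(
      sprintf(
        "variant validation error: %s at row(s) %s",
        what, paste(utils::head(rows, 5L), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  af <- calls$allele_frequency
  bad <- which(is.na(af) | af < 0 | af > 1)
  if (length(bad)) fail(bad, "allele_frequency outside [0,1]")
  bad <- which(is.na(calls$pos) | calls$pos < 1)
  if (length(bad)) fail(bad, "pos must be >= 1")
  bad <- which(is.na(calls$read_depth) | calls$read_depth < 0)
  if (length(bad)) fail(bad, "read_depth must be >= 0")
  bad <- which(!calls$variant_class %in% variant_classes)
  if (length(bad)) fail(bad, "unknown variant_class")
  bad <- which(!as.character(calls$actionability_tier) %in% tier_levels)
  if (length(bad)) fail(bad, "actionability_tier must be 1..5 or 'none'")
  bad <- which(calls$ref == calls$alt)
  if (length(bad)) fail(bad, "ref == alt is not a variant")
  is_sub <- calls$variant_class == "substitution"
  bad <- which(is_sub & (nchar(calls$ref) != nchar(calls$alt) | nchar(calls$ref) > 5L))
  if (length(bad)) fail(bad, "substitutions must have equal-length alleles of <= 5 bases")
  invisible(calls)
}

#' Read a variant call table
#'
#' Reads the package TSV dialect (see [variant_table_columns]) or, with
#' `dialect = "vcf"`, a single-sample VCF 4.x file whose INFO fields carry
#' `AF`, `DP`, `GENE` and optionally `TIER` (requires the Bioconductor
#' package VariantAnnotation). Every row is validated; invalid rows raise.
#' Extra TSV columns (e.g. `origin`, `true_af`, `suppression_reason`) are
#' preserved.
#'
#' @param path path to the file.
#' @param dialect `"tsv"` (default) or `"vcf"`.
#' @param assay_id for the VCF dialect, assay label to record (default: the
#'   file name without extension).
#' @return a validated `data.frame` of variant calls.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf"), assay_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "vcf") return(read_vcf_calls(path, assay_id = assay_id))
  col_classes <- c(
    sample_id = "character", assay_id = "character", gene = "character",
    chrom = "character", pos = "integer", ref = "character",
    alt = "character", variant_class = "character",
    allele_frequency = "numeric", read_depth = "integer",
    actionability_tier = "character"
  )
  calls <- utils::read.delim(
    path,
    sep = "\t", header = TRUE, stringsAsFactors = FALSE,
    colClasses = col_classes, check.names = FALSE
  )
  validate_variant_calls(calls)
  calls
}

# VCF 4.x dialect: INFO AF (float), DP (integer), GENE (string), TIER
# (string, optional). Leans on VariantAnnotation rather than a hand parser.
read_vcf_calls <- function(path, assay_id = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("the 'vcf' dialect requires the VariantAnnotation package", call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  n <- length(rr)
  need <- setdiff(c("AF", "DP", "GENE"), names(info))
  if (length(need)) {
    stop(
      "variant table format error: missing required column(s): ",
      paste(need, collapse = ", "), " (VCF INFO)",
      call. = FALSE
    )
  }
  sample_ids <- VariantAnnotation::samples(VariantAnnotation::header(vcf))
  sample_id <- if (length(sample_ids)) sample_ids[[1L]] else sub("\\.vcf$", "", basename(path))
  alt <- as.character(unlist(lapply(rr$ALT, function(a) as.character(a)[1L])))
  af <- vapply(info$AF, function(x) as.numeric(x)[1L], numeric(1))
  tier <- if ("TIER" %in% names(info)) as.character(info$TIER) else rep("none", n)
  tier[is.na(tier) | tier == ""] <- "none"
  ref <- as.character(rr$REF)
  calls <- data.frame(
    sample_id = rep(sample_id, n),
    assay_id = rep(assay_id %||% sub("\\.vcf$", "", basename(path)), n),
    gene = as.character(info$GENE),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = as.integer(GenomicRanges::start(rr)),
    ref = ref,
    alt = alt,
    variant_class = classify_variant_class(ref, alt),
    allele_frequency = af,
    read_depth = as.integer(info$DP),
    actionability_tier = tier,
    stringsAsFactors = FALSE
  )
  rownames(calls) <- NULL
  validate_variant_calls(calls)
  calls
}

#' Write a variant call table
#'
#' Writes the TSV dialect with lossless numeric formatting, so
#' `read_variant_table(write_variant_table(x))` reproduces `x` exactly.
#'
#' @param calls a validated variant call table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(calls, path) {
  validate_variant_calls(calls)
  out <- calls
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- fmt_double(out[[col]])
  }
  tryCatch(
    utils::write.table(
      out, path,
      sep = "\t", quote = FALSE, row.names = FALSE, na = "NA"
    ),
    error = function(e) {
      stop("failed to write variant table to '", path, "': ", conditionMessage(e), call. = FALSE)
    }
  )
  invisible(path)
}

# Minimal representation of one allele pair: trim shared trailing then
# shared leading bases, keeping at least one base of each allele (the VCF
# anchor), advancing pos for each leading base removed.
normalize_allele <- function(pos, ref, alt) {
  if (is.na(ref) || is.na(alt) || ref == alt) {
    stop("not a variant: ref == alt", call. = FALSE)
  }
  r <- strsplit(ref, "", fixed = TRUE)[[1L]]
  a <- strsplit(alt, "", fixed = TRUE)[[1L]]
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
    r <- r[-1L]
    a <- a[-1L]
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

#' Normalize variant calls to their canonical minimal representation
#'
#' Trims shared leading/trailing bases (retaining the VCF anchor base for
#' indels) and advances `pos` accordingly, then recomputes `variant_class`.
#' The resulting key `(chrom, pos, ref, alt)` is canonical: normalizing twice
#' is the identity, and two reports of the same allele change from different
#' pipelines acquire the same key.
#'
#' @param calls a variant call table (or any data.frame with `pos`, `ref`,
#'   `alt` columns).
#' @return the table with normalized `pos`, `ref`, `alt`, `variant_class`.
#' @export
normalize_variants <- function(calls) {
  if (nrow(calls) == 0L) return(calls)
  norm <- Map(normalize_allele, calls$pos, calls$ref, calls$alt)
  calls$pos <- vapply(norm, `[[`, integer(1), "pos")
  calls$ref <- vapply(norm, `[[`, character(1), "ref")
  calls$alt <- vapply(norm, `[[`, character(1), "alt")
  if ("variant_class" %in% names(calls)) {
    calls$variant_class <- classify_variant_class(calls$ref, calls$alt)
  }
  calls
}

#' Restrict calls to the genes shared by two panels
#'
#' Cross-panel comparison is only meaningful on the gene intersection (for
#' the emulated study design, 92 of 215/114 genes); calls in panel-private
#' genes are removed. Order is preserved and the operation is symmetric in
#' its two panel arguments.
#'
#' @param calls a variant call table.
#' @param panel_a,panel_b [panel_spec] objects.
#' @return the filtered table.
#' @export
restrict_to_common_genes <- function(calls, panel_a, panel_b) {
  shared <- intersect(panel_a$genes, panel_b$genes)
  out <- calls[calls$gene %in% shared, , drop = FALSE]
  rownames(out) <- NULL
  out
}
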