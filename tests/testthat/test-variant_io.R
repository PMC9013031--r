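test_that("read_variant_table reads well-formed TSVs and rejects bad rows", {
  calls <- random_calls(3)
  path <- withr_tempfile()
  write_variant_table(calls, path)
  got <- read_variant_table(path)
  expect_equal(nrow(got), 3L)

  # header-only file
  empty <- calls[0, , drop = FALSE]
  write_variant_table(empty, path)
  expect_equal(nrow(read_variant_table(path)), 0L)

  # 6-base substitution violates the short-variant definition
  bad <- calls
  bad$ref[2] <- "ACGTTA"
  bad$alt[2] <- "TTTTTT"
  bad$variant_class[2] <- "substitution"
  expect_error(validate_variant_calls(bad), "5 bases")

  # AF outside [0,1] names the row
  bad <- calls
  bad$allele_frequency[3] <- 1.7
  expect_error(validate_variant_calls(bad), "allele_frequency.*row\\(s\\) 3")

  # missing column named in the error
  expect_error(
    validate_variant_calls(calls[, setdiff(names(calls), "gene")]),
    "missing required column.*gene"
  )
  expect_error(read_variant_table("does/not/exist.tsv"), "no such file")
})

test_that("TSV round-trip is the identity on arbitrary valid call sets", {
  for (seed in 1:5) {
    calls <- random_calls(40, seed = seed)
    calls$origin <- sample(c("germline", "somatic", "artifact"), nrow(calls), replace = TRUE)
    calls$true_af <- stats::runif(nrow(calls))
    path <- withr_tempfile()
    write_variant_table(calls, path)
    got <- read_variant_table(path)
    rownames(calls) <- NULL
    expect_equal(got, calls)
  }
})

test_that("normalize_variants trims to the minimal VCF representation", {
  df <- data.frame(
    chrom = "chr1", pos = 100L, ref = "AT", alt = "AG",
    variant_class = "delins", stringsAsFactors = FALSE
  )
  got <- normalize_variants(df)
  expect_equal(got$pos, 101L)
  expect_equal(got$ref, "T")
  expect_equal(got$alt, "G")
  expect_equal(got$variant_class, "substitution")

  # already minimal: unchanged
  df2 <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
    variant_class = "substitution", stringsAsFactors = FALSE)
  expect_equal(normalize_variants(df2), df2)

  expect_error(
    normalize_variants(data.frame(chrom = "chr1", pos = 5L, ref = "A", alt = "A")),
    "not a variant"
  )
})

test_that("normalization is idempotent and preserves the sequence edit", {
  set.seed(42)
  for (i in 1:200) {
    v <- random_context_variant()
    df <- data.frame(chrom = "chr1", pos = v$pos, ref = v$ref, alt = v$alt,
      stringsAsFactors = FALSE)
    n1 <- normalize_variants(df)
    n2 <- normalize_variants(n1)
    expect_identical(n1, n2)
    # the normalized record must encode the same edit of the same context
    edited_orig <- apply_edit(v$context, v$ctx_start, v$pos, v$ref, v$alt)
    edited_norm <- apply_edit(v$context, v$ctx_start, n1$pos, n1$ref, n1$alt)
    expect_identical(edited_norm, edited_orig)
  }
})

test_that("restrict_to_common_genes keeps only the 92-gene intersection, symmetrically", {
  specs <- default_panel_specs()
  expect_length(specs$to$genes, 215L)
  expect_length(specs$tn$genes, 114L)
  expect_length(intersect(specs$to$genes, specs$tn$genes), 92L)

  calls <- random_calls(30, seed = 3)
  calls$gene[1:10] <- "TOG001" # private to the TO panel
  kept <- restrict_to_common_genes(calls, specs$to, specs$tn)
  expect_false("TOG001" %in% kept$gene)
  expect_true(all(kept$gene %in% intersect(specs$to$genes, specs$tn$genes)))
  expect_equal(kept, restrict_to_common_genes(calls, specs$tn, specs$to))

  # all calls in shared genes -> nothing removed
  shared_only <- calls[calls$gene %in% specs$tn$genes, , drop = FALSE]
  expect_equal(
    nrow(restrict_to_common_genes(shared_only, specs$to, specs$tn)),
    nrow(shared_only)
  )
})

test_that("load_panel_spec reads the packaged fixtures and rejects bad configs", {
  specs <- default_panel_specs()
  expect_false(specs$to$matched_normal)
  expect_equal(specs$to$reporting_cap, 14)
  expect_true(specs$tn$matched_normal)
  expect_false(is.finite(specs$tn$reporting_cap))
  expect_equal(depth_threshold_for_cellularity(0.6, specs$tn), 200)

  cfg <- withr_tempfile(ext = ".json")
  writeLines('{"name": "x", "matched_normal": false}', cfg)
  expect_error(load_panel_spec(cfg), "genes")
  writeLines('{"name": "x", "genes": ["G1"], "depth_rule": {"type": "wat"}}', cfg)
  expect_error(load_panel_spec(cfg), "depth_rule")
})

test_that("the VCF dialect maps AF/DP/GENE/TIER into validated calls", {
  vcf <- withr_tempfile(ext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=AF,Number=1,Type=Float,Description="Allele frequency">',
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=TIER,Number=1,Type=String,Description="Actionability tier">',
    "##contig=<ID=chr1>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", sep = "\t"),
    paste("chr1", "100", ".", "A", "G", ".", "PASS", "AF=0.41;DP=500;GENE=CG001;TIER=2", sep = "\t"),
    paste("chr1", "200", ".", "AT", "A", ".", "PASS", "AF=0.05;DP=300;GENE=CG002", sep = "\t")
  ), vcf)
  calls <- read_variant_table(vcf, dialect = "vcf", assay_id = "vcfassay")
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$allele_frequency, c(0.41, 0.05))
  expect_equal(calls$read_depth, c(500L, 300L))
  expect_equal(calls$gene, c("CG001", "CG002"))
  expect_equal(calls$actionability_tier, c("2", "none"))
  expect_equal(calls$variant_class, c("substitution", "deletion"))
  expect_equal(calls$assay_id, rep("vcfassay", 2))
})
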