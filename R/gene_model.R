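#' Mock gene model for the two-panel gene universe
#'
#' A synthetic gene annotation covering the set relations the comparison
#' depends on: 92 genes shared by both panels (`CG001`..`CG092`), 123 genes
#' private to the tumor-only panel (`TOG001`..`TOG123`, shared + private =
#' 215), and 22 genes private to the tumor-normal panel (`TNG001`..`TNG022`,
#' shared + private = 114). Coordinates are synthetic 30 kb intervals laid
#' out round-robin over chr1..chr22; only the set membership and the
#' per-gene intervals matter downstream, not the genome itself.
#'
#' @return a `data.frame` with columns `gene`, `chrom`, `start`, `end`,
#'   `set` (one of `"shared"`, `"to_private"`, `"tn_private"`).
#' @examples
#' m <- mock_gene_model()
#' table(m$set)
#' @export
mock_gene_model <- function() {
  genes <- c(
    sprintf("CG%03d", seq_len(92)),
    sprintf("TOG%03d", seq_len(123)),
    sprintf("TNG%03d", seq_len(22))
  )
  set <- rep(c("shared", "to_private", "tn_private"), c(92L, 123L, 22L))
  n <- length(genes)
  chrom <- paste0("chr", rep_len(1:22, n))
  idx <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  start <- as.integer(1e6 * idx + 1)
  data.frame(
    gene = genes, chrom = chrom, start = start,
    end = start + 30000L - 1L, set = set,
    stringsAsFactors = FALSE
  )
}
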