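#' Generate a synthetic differential-expression table
#'
#' Stand-in for a DESeq2 results table: `n_genes` symbols with log2 fold
#' changes and adjusted p-values, of which exactly `n_dys` pass the
#' `padj < 0.05` significance cut. Dysregulated genes draw `log2fc` around
#' `+/- effect` (random sign) and `padj ~ U(0, 0.05)`; the rest draw small
#' fold changes and `padj ~ U(0.05, 1)`.
#'
#' @param n_genes Total number of genes.
#' @param n_dys Number of genes with `padj < 0.05` (<= `n_genes`).
#' @param effect Absolute log2 fold change of dysregulated genes.
#' @param seed RNG seed.
#' @return A `deg_table` data.frame with columns `gene_symbol`, `log2fc`,
#'   `padj`, `direction`.
#' @export
generate_deg_table <- function(n_genes = 2000L, n_dys = 305L, effect = 1.5,
                               seed = NULL) {
  assert_that(n_dys <= n_genes, "n_dys must be <= n_genes")
  with_seed(seed, {
    symbols <- sprintf("GENE%05d", seq_len(n_genes))
    dys <- sample.int(n_genes, n_dys)
    log2fc <- stats::rnorm(n_genes, 0, 0.1)
    padj <- stats::runif(n_genes, 0.05, 1)
    if (n_dys > 0) {
      sgn <- sample(c(-1, 1), n_dys, replace = TRUE)
      log2fc[dys] <- sgn * (effect + abs(stats::rnorm(n_dys, 0, 0.25)))
      padj[dys] <- stats::runif(n_dys, 0, 0.0499)
    }
    deg_table(data.frame(gene_symbol = symbols, log2fc = log2fc, padj = padj))
  })
}
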