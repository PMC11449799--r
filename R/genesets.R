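# Gene-set stage: DEG table handling, GWAS-catalog intersection weighted by
# study count, and three-way Venn partitions.

#' Differential-expression table
#'
#' @param df A data.frame with columns `gene_symbol`, `log2fc`, `padj`.
#' @return A data.frame of class `deg_table` with a derived `direction`
#'   column (`up`/`down` from the sign of `log2fc`).
#' @export
deg_table <- function(df) {
  assert_that(all(c("gene_symbol", "log2fc", "padj") %in% names(df)),
              "deg table needs gene_symbol, log2fc, padj")
  assert_that(all(df$padj >= 0 & df$padj <= 1), "padj must lie in [0, 1]")
  df$direction <- ifelse(df$log2fc >= 0, "up", "down")
  structure(df, class = c("deg_table", "data.frame"))
}

#' Read a DEG table from TSV
#'
#' @param path TSV with columns `gene_symbol`, `log2fc`, `padj`.
#' @return A [deg_table()].
#' @export
read_deg_table <- function(path) {
  deg_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' GWAS-catalog gene list
#'
#' A local snapshot of catalog genes for a trait, each with the number of
#' studies reporting it at p < 0.01. Consumed as a TSV for reproducibility;
#' no live queries.
#'
#' @param df A data.frame with columns `gene_symbol`, `n_studies`.
#' @return A data.frame of class `gwas_catalog`.
#' @export
gwas_catalog <- function(df) {
  assert_that(all(c("gene_symbol", "n_studies") %in% names(df)),
              "gwas catalog needs gene_symbol, n_studies")
  assert_that(all(df$n_studies >= 1), "n_studies must be >= 1")
  structure(df, class = c("gwas_catalog", "data.frame"))
}

#' @rdname gwas_catalog
#' @param path TSV path.
#' @export
read_gwas_catalog <- function(path) {
  gwas_catalog(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Standardize gene symbols
#'
#' Uppercases, trims and collapses whitespace, and strips trailing version
#' suffixes (`".1"`, `".12"`). Idempotent and deterministic.
#'
#' @param symbols Character vector.
#' @return Standardized character vector, same length.
#' @export
standardize_symbols <- function(symbols) {
  s <- toupper(trimws(as.character(symbols)))
  s <- gsub("\\s+", "", s)
  gsub("\\.[0-9]+$", "", s)
}

#' Intersect significant DEGs with a GWAS catalog
#'
#' Genes present in both the `padj < padj_cutoff` slice of the DEG table and
#' the catalog (after symbol standardization on both sides), annotated with
#' regulation direction, the display color convention (down = blue,
#' up = red) and the catalog study count as weight.
#'
#' @param degs A [deg_table()].
#' @param gwas A [gwas_catalog()].
#' @param padj_cutoff DEG significance cutoff (default 0.05, the
#'   conventional adjusted-p threshold).
#' @return A data.frame with columns `gene_symbol`, `direction`, `color`,
#'   `weight`, `log2fc`, `padj`, sorted by decreasing weight.
#' @export
intersect_degs_gwas <- function(degs, gwas, padj_cutoff = 0.05) {
  assert_that(inherits(degs, "deg_table"), "degs must be a deg_table")
  assert_that(inherits(gwas, "gwas_catalog"), "gwas must be a gwas_catalog")
  sig <- degs[degs$padj < padj_cutoff, , drop = FALSE]
  sig$gene_symbol <- standardize_symbols(sig$gene_symbol)
  cat_sym <- standardize_symbols(gwas$gene_symbol)
  hit <- match(sig$gene_symbol, cat_sym)
  out <- sig[!is.na(hit), c("gene_symbol", "direction", "log2fc", "padj")]
  out$weight <- gwas$n_studies[hit[!is.na(hit)]]
  out$color <- ifelse(out$direction == "down", "blue", "red")
  out <- out[order(-out$weight, out$gene_symbol),
             c("gene_symbol", "direction", "color", "weight", "log2fc", "padj")]
  rownames(out) <- NULL
  out
}

#' Three-way Venn partition counts
#'
#' Counts of the seven regions of a three-set Venn diagram. The region
#' counts sum to `|A union B union C|`.
#'
#' @param a,b,c Character (or atomic) vectors; duplicates are ignored.
#' @return Named integer vector with elements `a_only`, `b_only`, `c_only`,
#'   `ab`, `ac`, `bc`, `abc`.
#' @export
venn3 <- function(a, b, c) {
  a <- unique(a); b <- unique(b); c <- unique(c)
  u <- unique(c(a, b, c))
  ina <- u %in% a; inb <- u %in% b; inc <- u %in% c
  c(a_only = sum(ina & !inb & !inc),
    b_only = sum(!ina & inb & !inc),
    c_only = sum(!ina & !inb & inc),
    ab = sum(ina & inb & !inc),
    ac = sum(ina & !inb & inc),
    bc = sum(!ina & inb & inc),
    abc = sum(ina & inb & inc))
}
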