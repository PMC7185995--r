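# Gene-set logic downstream of RNA-Seq and ChIP-Seq: differential-expression
# gene selection at stated thresholds, top-N peak-gene ranking, and set
# intersection. Alignment, counting, differential testing and peak calling
# happen upstream in dedicated tools; only their set logic lives here.

#' Differential-expression threshold presets
#'
#' Two published threshold conventions coexist for the same analysis: the
#' formal methods definition (adjusted p < 0.05 and |log2FC| > 1.0) and the
#' results-text convention (adjusted p < 0.05 and linear fold change > 1.2,
#' i.e. |log2FC| > log2(1.2)). Both ship as named presets; `methods` is the
#' default because it is the analysis section's formal definition.
#'
#' @param name `"methods"` or `"results"`.
#' @return A list with `padj_max` and `lfc_min`.
#' @export
de_threshold_preset <- function(name = c("methods", "results")) {
  name <- match.arg(name)
  switch(name,
         methods = list(padj_max = 0.05, lfc_min = 1.0),
         results = list(padj_max = 0.05, lfc_min = log2(1.2)))
}

#' Select differentially expressed genes
#'
#' Applies strict thresholds to a gene-level DE table:
#' up = {padj < padj_max and log2FC > lfc_min},
#' down = {padj < padj_max and log2FC < -lfc_min}. Both inequalities are
#' strict, so a gene at exactly padj = 0.05 is excluded.
#'
#' @param de `data.frame` with columns `gene`, `log2fc`, `padj` (one row
#'   per gene).
#' @param padj_max adjusted-p threshold (strict `<`).
#' @param lfc_min absolute log2 fold-change threshold (strict `>`).
#' @return A list: `up` and `down` (character vectors of gene ids),
#'   `n_up`, `n_down`.
#' @export
select_de_genes <- function(de, padj_max = 0.05, lfc_min = 1.0) {
  need <- c("gene", "log2fc", "padj")
  miss <- setdiff(need, names(de))
  if (length(miss))
    stop("DE table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (padj_max <= 0 || lfc_min <= 0)
    stop("thresholds must be > 0", call. = FALSE)
  if (anyDuplicated(de$gene))
    stop("DE table must have one row per gene", call. = FALSE)
  up <- de$gene[de$padj < padj_max & de$log2fc > lfc_min]
  down <- de$gene[de$padj < padj_max & de$log2fc < -lfc_min]
  list(up = up, down = down, n_up = length(up), n_down = length(down))
}

#' Top N genes from a ChIP peak table
#'
#' Reduces each gene to its best peak (smallest p-value; ties within a gene
#' broken by larger signal), then ranks genes by best-peak p-value
#' ascending, ties broken by signal value descending, then by gene id
#' lexicographically so the ordering is total and deterministic. Returns
#' the first `n` unique genes.
#'
#' @param peaks `data.frame` with columns `gene`, `pvalue` (raw peak
#'   p-value; convert if your table stores -log10 p) and `signal`.
#' @param n number of genes to return (default 200).
#' @return Character vector of gene ids, ranked. Warns and returns all
#'   genes if `n` exceeds the number of unique genes.
#' @export
top_chip_genes <- function(peaks, n = 200L) {
  need <- c("gene", "pvalue", "signal")
  miss <- setdiff(need, names(peaks))
  if (length(miss))
    stop("peak table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (any(!is.finite(peaks$pvalue)) || any(!is.finite(peaks$signal)))
    stop("peak scores must be finite", call. = FALSE)
  o <- order(peaks$gene, peaks$pvalue, -peaks$signal)
  best <- peaks[o, , drop = FALSE]
  best <- best[!duplicated(best$gene), , drop = FALSE]
  rank_o <- order(best$pvalue, -best$signal, best$gene)
  ranked <- best$gene[rank_o]
  if (n > length(ranked)) {
    warning(sprintf("n = %d exceeds %d unique genes; returning all", n,
                    length(ranked)))
    n <- length(ranked)
  }
  ranked[seq_len(n)]
}

#' Intersect two gene sets
#'
#' Overlap and exclusive counts for a two-set Venn diagram.
#'
#' @param a,b character vectors of gene ids in a shared namespace.
#' @return A list: `overlap` (sorted character vector), `n_overlap`,
#'   `n_a_only`, `n_b_only`.
#' @export
intersect_gene_sets <- function(a, b) {
  a <- unique(a); b <- unique(b)
  ov <- sort(intersect(a, b))
  list(overlap = ov, n_overlap = length(ov),
       n_a_only = length(setdiff(a, b)), n_b_only = length(setdiff(b, a)))
}
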