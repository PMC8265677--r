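#' 6mA amount in a strand-aware window
#'
#' The 6mA amount of a region is the sum of methylated fractions over its
#' methylated adenines (both strands): site count weighted by methylation
#' level. The window is expressed relative to the gene TSS along the gene
#' orientation; `c(0, 1000)` means the first kilobase downstream of the
#' TSS. Windows running off a chromosome end are truncated, not dropped.
#'
#' @param classified a `ClassifiedSites` data.frame
#' @param gene a single-row gene record (or list) with chrom, strand, tss
#' @param window numeric length-2 `c(from, to)`, TSS-relative, half-open
#' @return numeric amount (>= 0)
#' @export
amount_in_window <- function(classified, gene, window = c(0, 1000)) {
  sel <- classified[classified$chrom == gene$chrom, , drop = FALSE]
  if (nrow(sel) == 0) return(0)
  rel <- if (gene$strand == "+") sel$pos - gene$tss else gene$tss - sel$pos
  sum(sel$frac[rel >= window[1] & rel < window[2]])
}

#' Per-gene 6mA amounts for a window
#'
#' Vectorised convenience over [amount_in_window()].
#'
#' @param classified a `ClassifiedSites` data.frame
#' @param genes gene table from [read_gff3_genes()]
#' @param window TSS-relative window, half-open
#' @return numeric vector named by gene_id
#' @export
gene_amounts <- function(classified, genes, window = c(0, 1000)) {
  bychrom <- split(classified[c("pos", "frac")], classified$chrom)
  out <- vapply(seq_len(nrow(genes)), function(i) {
    d <- bychrom[[genes$chrom[i]]]
    if (is.null(d)) return(0)
    rel <- if (genes$strand[i] == "+") d$pos - genes$tss[i] else genes$tss[i] - d$pos
    sum(d$frac[rel >= window[1] & rel < window[2]])
  }, numeric(1))
  stats::setNames(out, genes$gene_id)
}

new_composite_profile <- function(position, density, type, n_sites, n_genes) {
  structure(list(position = position, density = density, type = type,
                 n_sites = n_sites, n_genes = n_genes),
            class = "CompositeProfile")
}

#' @export
print.CompositeProfile <- function(x, ...) {
  cat("CompositeProfile (", x$type, "): ", length(x$position), " bins, ",
      x$n_sites, " site contributions over ", x$n_genes, " genes\n", sep = "")
  invisible(x)
}

#' Metagene (scaled gene body) 6mA profile
#'
#' Genes longer than `min_len` are scaled to unit length and extended by
#' one unit on each side; every methylated adenine falling in `[-1, 2)`
#' scaled units of a gene contributes its methylated fraction to the bin
#' containing its scaled coordinate (`(pos - start)/length` for `+`
#' genes, mirrored for `-`). Bin values are amounts normalised by the
#' total contributing amount, so the profile is a density summing to 1.
#'
#' @param classified a `ClassifiedSites` data.frame
#' @param genes gene table
#' @param min_len minimum gene length in bp (strictly greater; default
#'   1000)
#' @param bin scaled-coordinate bin width (default 0.05)
#' @return a `CompositeProfile` with `position` = bin left edges on
#'   `[-1, 2)`
#' @export
metagene_profile <- function(classified, genes, min_len = 1000, bin = 0.05) {
  genes <- genes[genes$end - genes$start > min_len, , drop = FALSE]
  if (nrow(genes) == 0) stop("no genes longer than ", min_len, " bp")
  nbin <- round(3 / bin)
  edges <- -1 + bin * (0:nbin)
  acc <- numeric(nbin)
  nsites <- 0L
  bychrom <- split(classified[c("pos", "frac")], classified$chrom)
  for (i in seq_len(nrow(genes))) {
    d <- bychrom[[genes$chrom[i]]]
    if (is.null(d)) next
    len <- genes$end[i] - genes$start[i]
    s <- if (genes$strand[i] == "+") (d$pos - genes$start[i]) / len
         else (genes$end[i] - 1 - d$pos) / len
    keep <- s >= -1 & s < 2
    if (!any(keep)) next
    idx <- pmin(floor((s[keep] + 1) / bin) + 1L, nbin)
    tab <- tapply(d$frac[keep], idx, sum)
    at <- as.integer(names(tab))
    acc[at] <- acc[at] + tab
    nsites <- nsites + sum(keep)
  }
  if (sum(acc) == 0) stop("no sites fall in any gene window")
  new_composite_profile(edges[-length(edges)], acc / sum(acc),
                        "metagene", nsites, nrow(genes))
}

#' TSS-anchored per-base 6mA profile
#'
#' Accumulates methylated fractions per base from 1000 nt upstream to
#' 2000 nt downstream of each TSS, strand-oriented, and normalises to a
#' density summing to 1.
#'
#' @param classified a `ClassifiedSites` data.frame
#' @param genes gene table
#' @param window TSS-relative half-open window (default `c(-1000, 2000)`)
#' @return a `CompositeProfile` with `position` in nt relative to the TSS
#' @export
tss_profile <- function(classified, genes, window = c(-1000, 2000)) {
  if (nrow(classified) == 0) stop("empty call set")
  if (nrow(genes) == 0) stop("no genes")
  npos <- window[2] - window[1]
  acc <- numeric(npos)
  nsites <- 0L
  bychrom <- split(classified[c("pos", "frac")], classified$chrom)
  for (i in seq_len(nrow(genes))) {
    d <- bychrom[[genes$chrom[i]]]
    if (is.null(d)) next
    rel <- if (genes$strand[i] == "+") d$pos - genes$tss[i] else genes$tss[i] - d$pos
    keep <- rel >= window[1] & rel < window[2]
    if (!any(keep)) next
    idx <- rel[keep] - window[1] + 1L
    tab <- tapply(d$frac[keep], idx, sum)
    acc[as.integer(names(tab))] <- acc[as.integer(names(tab))] + tab
    nsites <- nsites + sum(keep)
  }
  if (sum(acc) == 0) stop("no sites fall in any TSS window")
  new_composite_profile(seq(window[1], window[2] - 1L), acc / sum(acc),
                        "tss", nsites, nrow(genes))
}

#' Read the expression table
#'
#' @param path TSV with columns gene_id, counts_veg, counts_s24, log2fc,
#'   padj and optionally fpkm_flag (logical: effectively expressed)
#' @return data.frame
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "counts_veg", "counts_s24", "log2fc", "padj")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing expression columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' Partition genes into expression-response classes
#'
#' * `DEG_up` / `DEG_down`: adjusted p < `padj_cut` and log2 fold change
#'   strictly above `lfc_cut` / below `-lfc_cut`.
#' * `induced` / `repressed`: raw read-count gates — induced means
#'   condition-A counts < `low_count` and condition-B counts >
#'   `high_count`; repressed is the reverse.
#' * `highly_regulated`: the top `top_frac` of genes ranked by |log2fc|,
#'   among effectively expressed genes when an `fpkm_flag` column is
#'   present (all genes otherwise).
#'
#' @param records expression data.frame (see [read_expression_tsv()]);
#'   missing required fields are an error naming the first offending gene
#' @param padj_cut adjusted-p cutoff (default 0.05)
#' @param lfc_cut |log2fc| cutoff, strict (default 2)
#' @param low_count,high_count read-count gates (defaults 300 and 1500)
#' @param top_frac fraction for the highly regulated set (default 0.10)
#' @return named list of gene-id character vectors
#' @export
classify_gene_sets <- function(records, padj_cut = 0.05, lfc_cut = 2,
                               low_count = 300, high_count = 1500,
                               top_frac = 0.10) {
  need <- c("gene_id", "counts_veg", "counts_s24", "log2fc", "padj")
  for (col in need) {
    if (is.null(records[[col]])) stop("missing column: ", col)
    if (anyNA(records[[col]]))
      stop("missing ", col, " for gene ",
           records$gene_id[which(is.na(records[[col]]))[1]])
  }
  deg <- records$padj < padj_cut & abs(records$log2fc) > lfc_cut
  pool <- if (!is.null(records$fpkm_flag)) records[as.logical(records$fpkm_flag), ]
          else records
  ntop <- max(1L, floor(top_frac * nrow(pool)))
  top_ids <- pool$gene_id[order(-abs(pool$log2fc))][seq_len(ntop)]
  list(
    DEG_up = records$gene_id[deg & records$log2fc > 0],
    DEG_down = records$gene_id[deg & records$log2fc < 0],
    induced = records$gene_id[records$counts_veg < low_count &
                                records$counts_s24 > high_count],
    repressed = records$gene_id[records$counts_veg > high_count &
                                  records$counts_s24 < low_count],
    highly_regulated = top_ids
  )
}

#' Correlate 6mA amount change with expression change
#'
#' Pearson correlation (two-sided test) between the raw 6mA amount change
#' (`amount_B - amount_A`, typically over the first kilobase downstream
#' of the TSS) and log2 fold change, over a stated gene set.
#'
#' @param records data.frame with gene_id, amount_A, amount_B, log2fc
#' @param gene_set optional character vector of gene ids to restrict to
#' @return list(r, p, n)
#' @export
amount_expression_correlation <- function(records, gene_set = NULL) {
  for (col in c("gene_id", "amount_A", "amount_B", "log2fc"))
    if (is.null(records[[col]])) stop("missing column: ", col)
  if (!is.null(gene_set))
    records <- records[records$gene_id %in% gene_set, , drop = FALSE]
  n <- nrow(records)
  if (n < 3) stop("need at least 3 genes, got ", n)
  dx <- records$amount_B - records$amount_A
  dy <- records$log2fc
  if (stats::sd(dx) == 0 || stats::sd(dy) == 0)
    stop("zero variance in amount change or expression change")
  ct <- stats::cor.test(dx, dy, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}
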