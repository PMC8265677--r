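# Small in-code fixtures shared across test files.

toy_genome <- function(...) {
  seqs <- c(...)
  if (is.null(names(seqs))) names(seqs) <- paste0("c", seq_along(seqs))
  new_genome(seqs)
}

# build a CallSet from minimal site descriptions; coverage/qv default to
# values that pass the confidence filter
toy_calls <- function(chrom, pos, strand, frac = 0.9, coverage = 100,
                      qv = 40, condition = "Veg") {
  n <- length(pos)
  callset(data.frame(chrom = rep_len(chrom, n), pos = pos,
                     strand = rep_len(strand, n),
                     coverage = rep_len(coverage, n),
                     qv = rep_len(qv, n), frac = rep_len(frac, n),
                     stringsAsFactors = FALSE),
          condition)
}

toy_genes <- function(chrom, start, end, strand,
                      gene_id = sprintf("g%03d", seq_along(start))) {
  data.frame(gene_id = gene_id, chrom = rep_len(chrom, length(start)),
             start = start, end = end, strand = strand,
             tss = ifelse(strand == "+", start, end - 1L),
             stringsAsFactors = FALSE)
}

random_seq <- function(n, at = 0.75) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
        collapse = "")
}
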