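STATE_LEVELS <- c("symmetric", "asymmetric", "nonApT", "unmethylated")

#' Match classified sites across two conditions
#'
#' Keys are strand-resolved adenine positions. Every adenine methylated in
#' either condition appears exactly once; an adenine absent from one
#' condition's (filtered) call set has state `unmethylated` there — which
#' is indistinguishable from sub-threshold methylation, a documented
#' limitation of confidence-filtered calls. Both inputs must have been
#' classified against the same genome.
#'
#' @param classified_A,classified_B `ClassifiedSites` for the two
#'   conditions
#' @param genome the shared `Genome`
#' @return data.frame of class `SiteTransitions` with columns chrom, pos,
#'   strand, state_A, state_B, frac_A, frac_B, level_A, level_B
#' @export
match_conditions <- function(classified_A, classified_B, genome) {
  ck <- genome_checksum(genome)
  for (x in list(classified_A, classified_B))
    if (!identical(attr(x, "genome_checksum"), ck))
      stop("call sets were classified against a different genome")
  key_A <- paste(classified_A$chrom, classified_A$pos, classified_A$strand)
  key_B <- paste(classified_B$chrom, classified_B$pos, classified_B$strand)
  keys <- union(key_A, key_B)
  ia <- match(keys, key_A)
  ib <- match(keys, key_B)
  take <- function(x, i) ifelse(is.na(i), NA, x[i])
  first <- ifelse(is.na(ia), ib, ia)
  src <- ifelse(is.na(ia), "B", "A")
  chrom <- ifelse(src == "A", classified_A$chrom[first], classified_B$chrom[first])
  pos <- ifelse(src == "A", classified_A$pos[first], classified_B$pos[first])
  strand <- ifelse(src == "A", classified_A$strand[first], classified_B$strand[first])
  state_of <- function(cls, i) {
    s <- as.character(cls$class)[i]
    factor(ifelse(is.na(i), "unmethylated", s), levels = STATE_LEVELS)
  }
  out <- data.frame(
    chrom = chrom, pos = as.integer(pos), strand = strand,
    state_A = state_of(classified_A, ia),
    state_B = state_of(classified_B, ib),
    frac_A = take(classified_A$frac, ia),
    frac_B = take(classified_B$frac, ib),
    level_A = take(as.character(classified_A$level_bin), ia),
    level_B = take(as.character(classified_B$level_bin), ib),
    stringsAsFactors = FALSE
  )
  structure(out,
            class = c("SiteTransitions", "data.frame"),
            condition_A = attr(classified_A, "condition"),
            condition_B = attr(classified_B, "condition"),
            genome_checksum = ck)
}

#' Adenine-count transition matrix
#'
#' @param transitions a `SiteTransitions` data.frame
#' @return 4x4 matrix of adenine counts, rows = condition-A state,
#'   columns = condition-B state
#' @export
transition_matrix <- function(transitions) {
  tab <- table(transitions$state_A, transitions$state_B)
  matrix(as.numeric(tab), 4L, 4L,
         dimnames = list(A = STATE_LEVELS, B = STATE_LEVELS))
}

#' Transition fraction with an explicit denominator
#'
#' Percent (1 decimal) of a transition count over a stated denominator —
#' the denominator choice (e.g. condition-A symmetric adenines vs
#' condition-B symmetric adenines) is deliberately explicit because
#' published fractions mix both conventions.
#'
#' @param count transition count(s)
#' @param denominator denominator count(s); must be positive
#' @return percentage(s), rounded to 1 decimal
#' @export
transition_fraction <- function(count, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  round_half_up(100 * count / denominator, 1)
}

#' Genes gaining or losing highly methylated asymmetric 6mA
#'
#' Counts L5 (methylation level >= 80%) asymmetric adenines in the first
#' `window` bp downstream of each gene's TSS (strand-aware) in both
#' conditions; a gene is in the gain set if its condition-B count exceeds
#' its condition-A count, in the loss set if lower. Ties belong to
#' neither.
#'
#' @param classified_A,classified_B `ClassifiedSites` for the two
#'   conditions
#' @param genes gene table from [read_gff3_genes()]
#' @param window downstream window width in bp (default 1000)
#' @return list with `gain` and `loss` gene-id vectors and a per-gene
#'   count data.frame `counts`
#' @export
gene_l5_asym_change <- function(classified_A, classified_B, genes,
                                window = 1000) {
  if (window <= 0) stop("window must be positive")
  count_per_gene <- function(cls) {
    sel <- cls[cls$class == "asymmetric" & cls$level_bin == "L5", , drop = FALSE]
    bychrom <- split(sel$pos, sel$chrom)
    vapply(seq_len(nrow(genes)), function(i) {
      p <- bychrom[[genes$chrom[i]]]
      if (is.null(p)) return(0L)
      rel <- if (genes$strand[i] == "+") p - genes$tss[i] else genes$tss[i] - p
      sum(rel >= 0L & rel < window)
    }, integer(1))
  }
  ca <- count_per_gene(classified_A)
  cb <- count_per_gene(classified_B)
  counts <- data.frame(gene_id = genes$gene_id, count_A = ca, count_B = cb,
                       stringsAsFactors = FALSE)
  list(gain = genes$gene_id[cb > ca],
       loss = genes$gene_id[cb < ca],
       counts = counts)
}

#' Select GATC duplexes for DpnI/DpnII validation
#'
#' Conversion sites are ApT duplexes symmetric in condition A whose both
#' adenines are unmethylated in condition B; retain sites are symmetric in
#' both. Only duplexes whose A/T occupies positions 2-3 of a Watson GATC
#' tetramer qualify (the DpnI/DpnII recognition site).
#'
#' @param transitions a `SiteTransitions` data.frame
#' @param genome the `Genome`
#' @param type "conversion" or "retain"
#' @return data.frame(chrom, watson_pos, tetramer_start) of qualifying
#'   duplexes (0-based)
#' @export
select_conversion_gatc_sites <- function(transitions, genome,
                                         type = c("conversion", "retain")) {
  type <- match.arg(type)
  tr <- transitions
  apt <- is_apt_context(genome, tr$chrom, tr$pos, tr$strand)
  wpos <- ifelse(tr$strand == "+", tr$pos, tr$pos - 1L)
  dup_key <- paste(tr$chrom, wpos)
  # duplex state: both adenines must satisfy the required states; adenines
  # never observed methylated in either condition do not appear in
  # `transitions`, so require both members present for symmetric states
  want_B <- if (type == "conversion") "unmethylated" else "symmetric"
  ok_row <- apt & tr$state_A == "symmetric" & tr$state_B == want_B
  cnt <- table(dup_key[ok_row])
  full <- names(cnt)[cnt == 2L]
  if (!length(full))
    return(data.frame(chrom = character(), watson_pos = integer(),
                      tetramer_start = integer()))
  parts <- strsplit(full, " ", fixed = TRUE)
  chrom <- vapply(parts, `[`, "", 1L)
  wp <- as.integer(vapply(parts, `[`, "", 2L))
  tet_start <- wp - 1L
  len <- unname(genome$lengths[chrom])
  inb <- tet_start >= 0L & tet_start + 4L <= len
  tet <- substr(genome$seqs[chrom], tet_start + 1L, tet_start + 4L)
  keep <- inb & tet == "GATC"
  out <- data.frame(chrom = chrom[keep], watson_pos = wp[keep],
                    tetramer_start = tet_start[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$watson_pos), ]
  rownames(out) <- NULL
  out
}
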