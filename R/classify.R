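CLASS_LEVELS <- c("symmetric", "asymmetric", "nonApT")
LEVEL_BINS <- c("L1", "L2", "L3", "L4", "L5")

#' Bin a methylation fraction into levels L1-L5
#'
#' Bins are left-closed 20% steps: L1 \[0, 0.2), L2 \[0.2, 0.4),
#' L3 \[0.4, 0.6), L4 \[0.6, 0.8), L5 \[0.8, 1\] (closed at 1).
#'
#' @param frac methylated fraction(s) in \[0, 1\]
#' @return factor with levels L1..L5
#' @export
bin_level <- function(frac) {
  if (any(is.na(frac)) || any(frac < 0 | frac > 1))
    stop("frac must lie in [0, 1]")
  idx <- findInterval(frac, c(0, 0.2, 0.4, 0.6, 0.8))
  factor(LEVEL_BINS[idx], levels = LEVEL_BINS)
}

#' Classify filtered calls into symmetric / asymmetric / non-ApT
#'
#' Each strand-resolved adenine call is assigned exactly one class:
#' `nonApT` if its strand-local 3' neighbour is not T; otherwise
#' `symmetric` if the partner adenine of its ApT duplex is also present in
#' the call set, else `asymmetric` (hemimethylated). Symmetric sites are
#' counted as individual adenines, so a fully methylated duplex
#' contributes two symmetric rows sharing one `duplex_id`. Symmetry is
#' evaluated on the call set as given — classify after filtering, so a
#' partner removed by the confidence filter leaves the survivor
#' asymmetric.
#'
#' @param calls a filtered `CallSet`
#' @param genome the `Genome` the calls were made against
#' @return data.frame of class `ClassifiedSites`: call columns plus
#'   `class`, `level_bin`, `duplex_id` (NA for nonApT); carries the
#'   condition label and a genome checksum as attributes
#' @export
classify_sites <- function(calls, genome) {
  df <- as.data.frame(calls)
  refbase <- base_at(genome, df$chrom, df$pos)
  ok <- ifelse(df$strand == "+", refbase == "A", refbase == "T")
  if (any(!ok))
    stop("call at non-adenine reference position, e.g. ",
         df$chrom[!ok][1], ":", df$pos[!ok][1], df$strand[!ok][1])
  apt <- is_apt_context(genome, df$chrom, df$pos, df$strand)
  wpos <- ifelse(df$strand == "+", df$pos, df$pos - 1L)
  partner <- ifelse(df$strand == "+",
                    paste(df$chrom, df$pos + 1L, "-"),
                    paste(df$chrom, df$pos - 1L, "+"))
  keys <- paste(df$chrom, df$pos, df$strand)
  partner_present <- partner %in% keys
  df$class <- factor(ifelse(!apt, "nonApT",
                            ifelse(partner_present, "symmetric", "asymmetric")),
                     levels = CLASS_LEVELS)
  df$level_bin <- bin_level(df$frac)
  df$duplex_id <- ifelse(apt, paste0(df$chrom, ":", wpos), NA_character_)
  structure(df,
            class = c("ClassifiedSites", "data.frame"),
            condition = callset_condition(calls),
            genome_checksum = genome_checksum(genome))
}

#' Composition summary from explicit counts
#'
#' Builds the per-class / per-level composition table directly from
#' adenine counts, e.g. from a published count table. Symmetric sites may
#' be given as duplex pairs (`symmetric_pairs`, counted as 2 adenines
#' each) or directly as adenines.
#'
#' @param symmetric_pairs number of fully methylated ApT duplexes
#' @param asymmetric number of hemimethylated adenines
#' @param non_apt number of methylated non-ApT adenines
#' @param level_counts optional named/ordered vector of 5 adenine counts
#'   (L1..L5)
#' @param symmetric_adenines alternative to `symmetric_pairs`
#' @param density optional genome-wide 6mA/A density (percent) to carry
#' @return object of class `CompositionSummary` with counts, percentages
#'   (1 decimal, half-away-from-zero) and the total
#' @export
composition_from_counts <- function(symmetric_pairs = NULL, asymmetric, non_apt,
                                    level_counts = NULL,
                                    symmetric_adenines = NULL,
                                    density = NA_real_) {
  if (is.null(symmetric_adenines)) {
    stopifnot(!is.null(symmetric_pairs))
    symmetric_adenines <- 2 * symmetric_pairs
  }
  class_counts <- c(symmetric = symmetric_adenines,
                    asymmetric = asymmetric, nonApT = non_apt)
  total <- sum(class_counts)
  out <- list(
    total = total,
    class_counts = class_counts,
    class_pct = round_half_up(100 * class_counts / total, 1),
    density_pct = density
  )
  if (!is.null(level_counts)) {
    stopifnot(length(level_counts) == 5)
    level_counts <- stats::setNames(as.numeric(level_counts), LEVEL_BINS)
    if (sum(level_counts) != total)
      warning("level-bin counts sum to ", sum(level_counts),
              " but class counts sum to ", total)
    out$level_counts <- level_counts
    out$level_pct <- round_half_up(100 * level_counts / total, 1)
  }
  structure(out, class = "CompositionSummary")
}

#' Summarise the composition of a classified call set
#'
#' Counts methylated adenines per class and per level bin and converts
#' them to percentages of the total (1 decimal). If a genome is supplied,
#' the genome-wide 6mA/A density (percent of strand-resolved adenines,
#' i.e. A + T of the Watson sequence, N excluded) is included.
#'
#' @param classified a `ClassifiedSites` data.frame
#' @param genome optional `Genome` for the density denominator
#' @return a `CompositionSummary`
#' @export
summarize_composition <- function(classified, genome = NULL) {
  if (nrow(classified) == 0) stop("no classified sites")
  cls <- table(classified$class)
  lev <- table(classified$level_bin)
  dens <- NA_real_
  if (!is.null(genome)) {
    dens <- 100 * nrow(classified) / count_adenines(genome)
  }
  out <- composition_from_counts(
    symmetric_adenines = as.numeric(cls[["symmetric"]]),
    asymmetric = as.numeric(cls[["asymmetric"]]),
    non_apt = as.numeric(cls[["nonApT"]]),
    level_counts = as.numeric(lev),
    density = dens
  )
  attr(out, "condition") <- attr(classified, "condition")
  out
}

#' @export
print.CompositionSummary <- function(x, ...) {
  cond <- attr(x, "condition")
  cat("Composition", if (!is.null(cond)) paste0("(", cond, ")"), "\n")
  cat("  methylated adenines:", format(x$total, big.mark = ","), "\n")
  for (k in names(x$class_counts))
    cat(sprintf("  %-10s %12s  %5.1f%%\n", k,
                format(x$class_counts[[k]], big.mark = ","), x$class_pct[[k]]))
  if (!is.null(x$level_counts))
    for (k in names(x$level_counts))
      cat(sprintf("  %-10s %12s  %5.1f%%\n", k,
                  format(x$level_counts[[k]], big.mark = ","), x$level_pct[[k]]))
  if (!is.na(x$density_pct))
    cat(sprintf("  6mA/A density: %.2f%%\n", x$density_pct))
  invisible(x)
}

#' Strand-resolved adenine count of a genome
#'
#' Adenines on both strands: Watson A's plus Crick A's (= Watson T's).
#' N bases are ambiguous and excluded. `watson_only` restricts to Watson
#' A's for comparison with single-strand density conventions.
#'
#' @param genome a `Genome`
#' @param watson_only count only Watson-strand A's
#' @return integer count
#' @export
count_adenines <- function(genome, watson_only = FALSE) {
  pats <- if (watson_only) "A" else c("A", "T")
  sum(vapply(genome$seqs, function(s) {
    r <- charToRaw(s)
    sum(r == charToRaw("A")) + if (watson_only) 0L else sum(r == charToRaw("T"))
  }, numeric(1)))
}

#' ApT vs non-ApT percentage split
#'
#' @param summary a `CompositionSummary`
#' @return named numeric `c(apt_pct, non_apt_pct)`, each rounded to 1
#'   decimal so the pair reproduces printed table style
#' @export
apt_fraction <- function(summary) {
  non_apt <- summary$class_counts[["nonApT"]]
  total <- summary$total
  c(apt_pct = round_half_up(100 * (total - non_apt) / total, 1),
    non_apt_pct = round_half_up(100 * non_apt / total, 1))
}

#' Per-bin 6mA density along chromosomes
#'
#' Density is methylated adenines / adenines (6mA/A) per fixed-size bin.
#' The denominator counts strand-resolved adenines by default (Watson A +
#' Watson T), matching strand-resolved calls; `watson_only` switches to
#' Watson A's. Bins without any adenine get NA, not 0.
#'
#' @param classified a `ClassifiedSites` data.frame
#' @param genome the `Genome`
#' @param bin_size bin width in bp (default 1000)
#' @param watson_only denominator convention switch
#' @return data.frame(chrom, bin_start, a_count, meth_count, density) with
#'   a per-chromosome summary in attribute `per_chromosome`
#' @export
chromosome_density <- function(classified, genome, bin_size = 1000,
                               watson_only = FALSE) {
  if (bin_size <= 0) stop("bin_size must be positive")
  per_chrom <- lapply(names(genome$seqs), function(ch) {
    len <- genome$lengths[[ch]]
    nbin <- ceiling(len / bin_size)
    r <- charToRaw(genome$seqs[[ch]])
    is_a <- r == charToRaw("A")
    if (!watson_only) is_a <- is_a | r == charToRaw("T")
    binidx <- (seq_len(len) - 1L) %/% bin_size
    a_count <- as.vector(rowsum(as.numeric(is_a), binidx,
                                reorder = TRUE))
    meth <- classified[classified$chrom == ch, , drop = FALSE]
    meth_count <- tabulate(meth$pos %/% bin_size + 1L, nbins = nbin)
    data.frame(chrom = ch,
               bin_start = (seq_len(nbin) - 1L) * bin_size,
               a_count = a_count,
               meth_count = meth_count,
               density = ifelse(a_count > 0, meth_count / a_count, NA_real_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_chrom)
  rownames(out) <- NULL
  chrom_sum <- do.call(rbind, lapply(split(out, out$chrom), function(d) {
    data.frame(chrom = d$chrom[1], length = genome$lengths[[d$chrom[1]]],
               a_count = sum(d$a_count), meth_count = sum(d$meth_count),
               density = sum(d$meth_count) / sum(d$a_count))
  }))
  chrom_sum <- chrom_sum[order(chrom_sum$length), ]
  rownames(chrom_sum) <- NULL
  attr(out, "per_chromosome") <- chrom_sum
  out
}

#' Position-frequency matrix around methylated adenines
#'
#' Extracts the `[-flank, +flank]` sequence window around each site, read
#' 5'->3' on the methylated strand (Crick-strand sites contribute the
#' reverse complement), and tabulates base counts per position. Windows
#' truncated by a chromosome edge, or containing non-ACGT bases, are
#' excluded with a message.
#'
#' @param classified a `ClassifiedSites` data.frame
#' @param genome the `Genome`
#' @param flank half-window width in nt (default 20)
#' @return 4 x (2*flank+1) matrix, rows A/C/G/T, columns -flank..flank;
#'   every column sums to the number of contributing sites
#' @export
motif_matrix <- function(classified, genome, flank = 20) {
  if (nrow(classified) == 0) stop("no sites")
  len <- unname(genome$lengths[classified$chrom])
  inside <- classified$pos - flank >= 0L & classified$pos + flank <= len - 1L
  df <- classified[inside, , drop = FALSE]
  if (sum(!inside)) message("excluded ", sum(!inside), " edge-truncated window(s)")
  win <- substr(genome$seqs[df$chrom], df$pos + 1L - flank, df$pos + 1L + flank)
  clean <- !grepl("[^ACGT]", win)
  if (any(!clean)) message("excluded ", sum(!clean), " window(s) containing N")
  win <- win[clean]
  if (!length(win)) stop("no usable windows")
  ws <- Biostrings::DNAStringSet(win)
  neg <- df$strand[clean] == "-"
  if (any(neg)) ws[neg] <- Biostrings::reverseComplement(ws[neg])
  cm <- Biostrings::consensusMatrix(ws)[c("A", "C", "G", "T"), , drop = FALSE]
  colnames(cm) <- as.character(seq(-flank, flank))
  cm
}
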