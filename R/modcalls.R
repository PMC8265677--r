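#' Construct a call set
#'
#' A call set is a data.frame of strand-resolved adenine methylation calls
#' (one row per adenine) with attributes recording the condition label and
#' the mean raw coverage used for normalisation. `frac` is stored as a
#' fraction in \[0, 1\]; percent scales appear only at presentation.
#'
#' @param calls data.frame with columns chrom, pos (0-based), strand,
#'   coverage, qv, frac
#' @param condition nonempty condition label (e.g. "Veg", "S24")
#' @return data.frame of class `CallSet`
#' @export
callset <- function(calls, condition) {
  stopifnot(is.character(condition), nzchar(condition))
  need <- c("chrom", "pos", "strand", "coverage", "qv", "frac")
  miss <- setdiff(need, names(calls))
  if (length(miss)) stop("missing call columns: ", paste(miss, collapse = ", "))
  calls <- as.data.frame(calls)[need]
  if (any(!calls$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(calls$frac < 0 | calls$frac > 1))
    stop("frac must lie in [0, 1]")
  if (any(calls$coverage < 0) || any(calls$qv < 0))
    stop("coverage and qv must be non-negative")
  key <- paste(calls$chrom, calls$pos, calls$strand)
  if (anyDuplicated(key))
    stop("duplicate call at: ", key[duplicated(key)][1])
  rownames(calls) <- NULL
  structure(calls,
            class = c("CallSet", "data.frame"),
            condition = condition,
            mean_raw_coverage = if (nrow(calls)) mean(calls$coverage) else NA_real_)
}

#' Condition label of a call set
#' @param calls a `CallSet`
#' @return character scalar
#' @export
callset_condition <- function(calls) attr(calls, "condition")

#' Read SMRT-Link-style modification calls (GFF)
#'
#' Parses a base-modification GFF (1-based coordinates, feature type
#' `m6A`, score column carrying the modification quality value Qv, and
#' `coverage` / `frac` attributes). Records whose reference base is not an
#' adenine on the stated strand are dropped with a message; they indicate
#' a reference mismatch, not valid 6mA.
#'
#' @param path path to the modifications GFF
#' @param genome a `Genome` (reference-base check)
#' @param condition condition label for the resulting call set
#' @param on_missing_frac "error" (default) or "drop"; a call without a
#'   methylated-fraction estimate cannot enter amount statistics
#' @return a [callset()]
#' @export
read_modifications_gff <- function(path, genome, condition,
                                   on_missing_frac = c("error", "drop")) {
  on_missing_frac <- match.arg(on_missing_frac)
  gff <- as.data.frame(rtracklayer::readGFF(path))
  gff <- gff[as.character(gff$type) == "m6A", , drop = FALSE]
  if (nrow(gff) == 0) stop("no m6A records in ", path)
  if (is.null(gff$frac)) gff$frac <- NA_real_
  frac <- suppressWarnings(as.numeric(gff$frac))
  if (anyNA(frac)) {
    if (on_missing_frac == "error")
      stop(sum(is.na(frac)), " record(s) lack a frac attribute")
    keep <- !is.na(frac)
    message("dropped ", sum(!keep), " record(s) lacking frac")
    gff <- gff[keep, , drop = FALSE]; frac <- frac[keep]
  }
  if (is.null(gff$coverage)) stop("records lack a coverage attribute")
  calls <- data.frame(
    chrom = as.character(gff$seqid),
    pos = as.integer(gff$start) - 1L,
    strand = as.character(gff$strand),
    coverage = suppressWarnings(as.numeric(gff$coverage)),
    qv = suppressWarnings(as.numeric(gff$score)),
    frac = frac,
    stringsAsFactors = FALSE
  )
  unknown <- setdiff(unique(calls$chrom), names(genome$seqs))
  if (length(unknown))
    stop("unknown chromosome(s) in calls: ", paste(unknown, collapse = ", "))
  refbase <- base_at(genome, calls$chrom, calls$pos)
  is_a <- ifelse(calls$strand == "+", refbase == "A", refbase == "T")
  if (any(!is_a))
    message("dropped ", sum(!is_a),
            " call(s) whose reference base is not A on the stated strand")
  callset(calls[is_a, , drop = FALSE], condition)
}

#' Write / read the canonical calls TSV
#'
#' Plain-text exchange format: columns chrom, pos0, strand, coverage, qv,
#' frac, with the condition label in a `# condition=` header line.
#'
#' @param calls a `CallSet`
#' @param path file path
#' @return `path` invisibly (writer); a `CallSet` (reader)
#' @export
write_calls_tsv <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# condition=", callset_condition(calls)), con)
  df <- as.data.frame(calls)
  names(df)[names(df) == "pos"] <- "pos0"
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  condition <- sub("^#\\s*condition=", "", first)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  names(df)[names(df) == "pos0"] <- "pos"
  callset(df, condition)
}

#' Normalise call coverage to a common depth
#'
#' Rescales every call's coverage by a single global factor
#' `target / mean(raw coverage)` so call sets sequenced to different depths
#' share the same coverage scale before the confidence filter. `frac` and
#' `qv` are untouched. Applying the operation twice equals once.
#'
#' @param calls a `CallSet`
#' @param target target mean coverage (default 100)
#' @return a `CallSet` with rescaled coverage
#' @export
normalize_coverage <- function(calls, target = 100) {
  if (nrow(calls) == 0) stop("cannot normalise an empty call set")
  m <- mean(calls$coverage)
  if (m <= 0) stop("mean raw coverage must be positive")
  out <- as.data.frame(calls)
  out$coverage <- out$coverage * target / m
  out <- callset(out, callset_condition(calls))
  attr(out, "mean_raw_coverage") <- attr(calls, "mean_raw_coverage")
  attr(out, "normalized_to") <- target
  out
}

#' Confidence filter for modification calls
#'
#' Retains calls with `qv > min_qv` and `coverage > min_cov`, both strict
#' inequalities. Coverage is expected to be normalised first.
#'
#' @param calls a `CallSet`
#' @param min_qv quality-value cutoff (default 30)
#' @param min_cov coverage cutoff (default 25)
#' @return filtered `CallSet`
#' @export
filter_calls <- function(calls, min_qv = 30, min_cov = 25) {
  keep <- calls$qv > min_qv & calls$coverage > min_cov
  out <- callset(as.data.frame(calls)[keep, , drop = FALSE],
                 callset_condition(calls))
  attr(out, "mean_raw_coverage") <- attr(calls, "mean_raw_coverage")
  attr(out, "n_filtered_out") <- sum(!keep)
  out
}
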