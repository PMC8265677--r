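#' Read a minimal BED3 fragment file
#'
#' @param path BED file (0-based half-open intervals, first three columns
#'   used)
#' @return data.frame(chrom, start, end)
#' @export
read_bed_fragments <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 3L)
  if (length(bad)) stop("malformed BED line ", bad[1], ": fewer than 3 fields")
  chrom <- vapply(parts, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad)) stop("malformed BED line ", bad[1], ": bad interval")
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
}

#' Fragment midpoints as nucleosome dyads
#'
#' MNase protects ~147 bp around the dyad, so midpoints of
#' mononucleosome-sized fragments estimate dyad positions. Fragments with
#' lengths outside `[min_len, max_len]` are discarded with a message.
#'
#' @param fragments data.frame(chrom, start, end), 0-based half-open (or
#'   a BED path)
#' @param min_len,max_len inclusive fragment-length gate (defaults
#'   120-180 bp)
#' @return data.frame(chrom, pos) of dyad coordinates
#' @export
fragments_to_dyads <- function(fragments, min_len = 120, max_len = 180) {
  if (is.character(fragments)) fragments <- read_bed_fragments(fragments)
  len <- fragments$end - fragments$start
  keep <- len >= min_len & len <= max_len
  if (any(!keep))
    message("discarded ", sum(!keep), " fragment(s) outside [",
            min_len, ", ", max_len, "] bp")
  data.frame(chrom = fragments$chrom[keep],
             pos = (fragments$start[keep] + fragments$end[keep]) %/% 2L,
             stringsAsFactors = FALSE)
}

#' TSS-anchored composite dyad-density profile
#'
#' Accumulates dyads per base in a strand-oriented window around each
#' gene's TSS, smooths with a centred moving average, and normalises so
#' the densities sum to 1 over the window.
#'
#' @param dyads data.frame(chrom, pos)
#' @param genes gene table
#' @param window TSS-relative half-open window (default `c(-500, 1500)`)
#' @param smooth odd moving-average width in bp (default 31; 1 disables)
#' @return a `DyadProfile` (list: position, density, smooth, n_dyads,
#'   n_genes)
#' @export
composite_dyad_profile <- function(dyads, genes, window = c(-500, 1500),
                                   smooth = 31) {
  if (nrow(genes) == 0) stop("no genes")
  if (smooth < 1 || smooth %% 2 == 0) stop("smooth width must be odd")
  npos <- window[2] - window[1]
  acc <- numeric(npos)
  ndy <- 0L
  bychrom <- split(dyads$pos, dyads$chrom)
  for (i in seq_len(nrow(genes))) {
    p <- bychrom[[genes$chrom[i]]]
    if (is.null(p)) next
    rel <- if (genes$strand[i] == "+") p - genes$tss[i] else genes$tss[i] - p
    keep <- rel >= window[1] & rel < window[2]
    if (!any(keep)) next
    acc <- acc + tabulate(rel[keep] - window[1] + 1L, nbins = npos)
    ndy <- ndy + sum(keep)
  }
  if (sum(acc) == 0) stop("no dyads fall in any TSS window")
  v <- moving_average(acc, smooth)
  structure(list(position = seq(window[1], window[2] - 1L),
                 density = v / sum(v), smooth = smooth,
                 n_dyads = ndy, n_genes = nrow(genes)),
            class = "DyadProfile")
}

#' Build a DyadProfile from an explicit density vector
#'
#' Mostly useful for closed-form checks and idealised profiles.
#'
#' @param position integer positions (TSS-relative)
#' @param density non-negative densities
#' @param normalize rescale to sum 1 (default TRUE)
#' @return a `DyadProfile`
#' @export
dyad_profile <- function(position, density, normalize = TRUE) {
  stopifnot(length(position) == length(density), all(density >= 0))
  if (normalize) density <- density / sum(density)
  structure(list(position = as.integer(position), density = density,
                 smooth = 1L, n_dyads = NA_integer_, n_genes = NA_integer_),
            class = "DyadProfile")
}

#' @export
print.DyadProfile <- function(x, ...) {
  cat("DyadProfile: [", min(x$position), ",", max(x$position) + 1L,
      ") bp,", x$n_dyads, "dyads over", x$n_genes, "genes\n")
  invisible(x)
}

#' Nucleosome positioning degree for the +1..+k nucleosomes
#'
#' A contrast statistic on the composite dyad profile: for nucleosome +k
#' the peak is the profile maximum in the window
#' `[spacing*(k-1), spacing*(k-1) + spacing + 50)` downstream of the TSS;
#' flanking troughs are the minima between adjacent peaks (between the
#' TSS and the +1 peak on the left, and between the last peak and the
#' window end on the right). Peak and trough heights are mean densities
#' within `avg_halfwidth` bp of the located extremum, and
#' `degree = (peak - trough) / (peak + trough)` with the trough height
#' averaged over the two flanks. A flat profile scores 0; an ideal
#' profile with zero-density troughs scores 1. The statistic is invariant
#' under positive rescaling of the profile.
#'
#' @param profile a `DyadProfile`
#' @param k_max number of nucleosomes (default 5)
#' @param spacing expected nucleosome repeat length in bp (default 200)
#' @param avg_halfwidth half-width of the averaging window around each
#'   extremum in bp (default 20)
#' @return data.frame(k, peak_pos, peak_height, trough_height, degree)
#' @export
positioning_degree <- function(profile, k_max = 5, spacing = 200,
                               avg_halfwidth = 20) {
  x <- profile$position
  v <- profile$density
  need <- spacing * (k_max - 1) + spacing + 50
  if (max(x) < need - 1)
    stop("profile window too short for k_max = ", k_max)
  local_mean <- function(center) {
    sel <- x >= center - avg_halfwidth & x <= center + avg_halfwidth
    mean(v[sel])
  }
  # extremum index in [lo, hi); ties resolved to the middle of the tied
  # run so a flat trough is probed at its centre, away from peak tails
  argext <- function(lo, hi, fun) {
    sel <- which(x >= lo & x < hi)
    ext <- fun(v[sel])
    tied <- sel[v[sel] == v[sel][ext]]
    tied[ceiling(length(tied) / 2)]
  }
  peak_idx <- integer(k_max)
  for (k in seq_len(k_max)) {
    lo <- spacing * (k - 1)
    peak_idx[k] <- argext(lo, lo + spacing + 50, which.max)
  }
  peak_pos <- x[peak_idx]
  if (is.unsorted(peak_pos, strictly = TRUE))
    warning("peak positions are not strictly increasing; ",
            "degrees reported anyway")
  # troughs: before +1, between consecutive peaks, after the last peak;
  # the search stays avg_halfwidth away from the flanking peaks so the
  # trough's averaging window cannot swallow a sharp peak
  bounds <- c(0, peak_pos, min(max(x) + 1, peak_pos[k_max] + spacing))
  trough_pos <- numeric(k_max + 1)
  for (j in seq_len(k_max + 1)) {
    lo <- bounds[j]; hi <- max(bounds[j + 1], lo + 1)
    lo2 <- if (j >= 2) lo + avg_halfwidth + 1 else lo       # lo is a peak
    hi2 <- if (j <= k_max) hi - avg_halfwidth else hi       # hi is a peak
    if (hi2 <= lo2) { lo2 <- lo; hi2 <- hi }
    trough_pos[j] <- x[argext(lo2, hi2, which.min)]
  }
  peak_h <- vapply(peak_pos, local_mean, 0)
  trough_h <- vapply(trough_pos, local_mean, 0)
  flank <- (trough_h[seq_len(k_max)] + trough_h[seq_len(k_max) + 1]) / 2
  degree <- ifelse(peak_h + flank > 0, (peak_h - flank) / (peak_h + flank), 0)
  data.frame(k = seq_len(k_max), peak_pos = peak_pos,
             peak_height = peak_h, trough_height = flank, degree = degree)
}

#' Nucleosome repeat length from profile autocorrelation
#'
#' Returns the lag of the first local maximum of the profile's
#' autocorrelation beyond `min_lag`, requiring the autocorrelation there
#' to exceed `min_acf`; profiles with no such maximum (e.g. white noise)
#' raise an "aperiodic" error.
#'
#' @param profile a `DyadProfile` covering at least ~3 periods
#' @param min_lag smallest admissible period in bp (default 50)
#' @param min_acf minimum autocorrelation at the reported lag (default
#'   0.1)
#' @return periodicity in bp
#' @export
estimate_periodicity <- function(profile, min_lag = 50, min_acf = 0.1) {
  v <- profile$density
  n <- length(v)
  a <- stats::acf(v, lag.max = floor(n / 2), plot = FALSE,
                  demean = TRUE)$acf[, 1, 1]
  lags <- seq_along(a) - 1L
  a <- a / (1 - lags / n)  # undo the triangular taper of the n-denominator
  is_max <- c(FALSE, diff(a) > 0) & c(diff(a) <= 0, FALSE)
  cand <- which(is_max & lags > min_lag & a > min_acf)
  if (!length(cand)) stop("aperiodic: no autocorrelation peak beyond lag ",
                          min_lag)
  i <- cand[1]
  # parabolic refinement over the three acf values around the peak
  denom <- a[i - 1] - 2 * a[i] + a[i + 1]
  shift <- if (is.finite(denom) && denom < 0)
    0.5 * (a[i - 1] - a[i + 1]) / denom else 0
  lags[i] + shift
}

#' 6mA position relative to flanking nucleosome dyads
#'
#' For every methylated adenine lying between two consecutive dyads on
#' the same chromosome, reports its relative position
#' `(pos - d_i) / (d_{i+1} - d_i)` in \[0, 1\] together with its
#' methylation-level bin; 0.5 is the linker midpoint for evenly spaced
#' nucleosomes. Sites in inter-dyad gaps wider than `max_gap` (no
#' meaningful neighbouring pair) are excluded; chromosomes with fewer
#' than two dyads are skipped with a message.
#'
#' @param classified a `ClassifiedSites` data.frame
#' @param dyads data.frame(chrom, pos)
#' @param max_gap widest usable inter-dyad distance in bp (default 400)
#' @return data.frame(chrom, pos, rel_pos, level_bin, class)
#' @export
dyad_relative_6ma <- function(classified, dyads, max_gap = 400) {
  out <- lapply(split(classified, classified$chrom), function(sites) {
    ch <- sites$chrom[1]
    d <- sort(unique(dyads$pos[dyads$chrom == ch]))
    if (length(d) < 2) {
      message("skipping chromosome ", ch, ": fewer than 2 dyads")
      return(NULL)
    }
    i <- findInterval(sites$pos, d)
    ok <- i >= 1L & i < length(d)
    gap <- d[pmin(i + 1L, length(d))] - d[pmax(i, 1L)]
    ok <- ok & gap <= max_gap & gap > 0
    if (!any(ok)) return(NULL)
    data.frame(chrom = ch, pos = sites$pos[ok],
               rel_pos = (sites$pos[ok] - d[i[ok]]) / gap[ok],
               level_bin = sites$level_bin[ok],
               class = sites$class[ok], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), pos = integer(),
                      rel_pos = numeric(), level_bin = character(),
                      class = character())
  rownames(out) <- NULL
  out
}

#' Positioning degrees for named gene sets
#'
#' Builds a composite dyad profile per gene set (e.g. the gain / loss
#' sets from [gene_l5_asym_change()]) and reports positioning degrees,
#' plus the gain-minus-loss degree difference for +1 and the mean over
#' +1..+3 when both sets are present.
#'
#' @param gene_sets named list of gene-id character vectors
#' @param dyads data.frame(chrom, pos)
#' @param genes gene table
#' @param k_max number of nucleosomes (default 5)
#' @param min_genes warn when a set is smaller than this (default 50)
#' @param ... passed to [composite_dyad_profile()]
#' @return list with per-set `degrees` data.frames, per-set `profiles`,
#'   and `diff` (gain - loss) when both sets exist
#' @export
compare_positioning <- function(gene_sets, dyads, genes, k_max = 5,
                                min_genes = 50, ...) {
  res <- list(degrees = list(), profiles = list())
  for (nm in names(gene_sets)) {
    ids <- gene_sets[[nm]]
    g <- genes[genes$gene_id %in% ids, , drop = FALSE]
    if (nrow(g) == 0) {
      warning("gene set '", nm, "' is empty; skipped")
      next
    }
    if (nrow(g) < min_genes)
      warning("gene set '", nm, "' has only ", nrow(g), " genes")
    prof <- composite_dyad_profile(dyads, g, ...)
    res$profiles[[nm]] <- prof
    res$degrees[[nm]] <- positioning_degree(prof, k_max = k_max)
  }
  if (all(c("gain", "loss") %in% names(res$degrees))) {
    dg <- res$degrees$gain$degree
    dl <- res$degrees$loss$degree
    res$diff <- c(plus1 = dg[1] - dl[1],
                  plus1_3 = mean(dg[1:3]) - mean(dl[1:3]))
  }
  res
}
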