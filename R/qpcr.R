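#' Read a qPCR Ct table
#'
#' @param path CSV with columns site, condition, ct_dpnI, ct_dpnII,
#'   ct_undigested
#' @return data.frame
#' @export
read_ct_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "condition", "ct_dpnI", "ct_dpnII", "ct_undigested")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing Ct columns: ", paste(miss, collapse = ", "))
  df
}

#' Methylation-sensitive restriction ddCt
#'
#' DpnI cuts methylated GATC and DpnII cuts unmethylated GATC, so the
#' fold difference between the two digests reflects methylation status:
#' `ddCt = dCt_DpnI - dCt_DpnII` with each dCt normalised to the
#' undigested control (`dCt = Ct_digested - Ct_undigested`). The
#' undigested Ct cancels algebraically, so ddCt equals
#' `ct_dpnI - ct_dpnII`; it is still required present as a completeness
#' check of the record.
#'
#' @param record data.frame row(s) with ct_dpnI, ct_dpnII, ct_undigested
#' @return numeric ddCt value(s)
#' @export
ddct <- function(record) {
  vals <- record[c("ct_dpnI", "ct_dpnII", "ct_undigested")]
  if (any(vapply(vals, function(v) any(is.na(v)) || any(!is.finite(v)),
                 logical(1))))
    stop("missing or non-finite Ct value")
  (record$ct_dpnI - record$ct_undigested) -
    (record$ct_dpnII - record$ct_undigested)
}

#' Cross-condition methylation-status change (dddCt)
#'
#' `dddCt = ddCt_veg - ddCt_s24` for the same GATC site. Sites that were
#' methylated (symmetric) in the first condition and unmethylated in the
#' second give dddCt > 0; sites retaining methylation give dddCt close
#' to 0. The statistic is antisymmetric under swapping conditions.
#'
#' @param record_veg,record_s24 single-row data.frames for the same
#'   `site` in the two conditions
#' @return numeric dddCt
#' @export
dddct <- function(record_veg, record_s24) {
  if (!identical(as.character(record_veg$site),
                 as.character(record_s24$site)))
    stop("site id mismatch: ", record_veg$site, " vs ", record_s24$site)
  ddct(record_veg) - ddct(record_s24)
}

#' Per-site DpnI/DpnII validation report
#'
#' Computes ddCt per condition, dddCt (condition A minus condition B) and
#' a qualitative call per site: `retain` when |dddCt| is below
#' `retain_threshold` cycles, `conversion` when dddCt exceeds it, and
#' `reverse` for dddCt below the negative threshold. The raw
#' DpnI-Ct difference between conditions is reported as an auxiliary
#' column.
#'
#' @param ct_table data.frame from [read_ct_csv()] with exactly two
#'   conditions per site
#' @param condition_A,condition_B condition labels (defaults "Veg",
#'   "S24")
#' @param retain_threshold cycles below which a site counts as retained
#'   (default 1)
#' @return data.frame(site, ddct_A, ddct_B, dddct, ct_diff_raw, call)
#' @export
qpcr_report <- function(ct_table, condition_A = "Veg", condition_B = "S24",
                        retain_threshold = 1) {
  sites <- unique(ct_table$site)
  rows <- lapply(sites, function(s) {
    a <- ct_table[ct_table$site == s & ct_table$condition == condition_A, ]
    b <- ct_table[ct_table$site == s & ct_table$condition == condition_B, ]
    if (nrow(a) != 1 || nrow(b) != 1)
      stop("site ", s, " needs exactly one record per condition")
    d <- dddct(a, b)
    data.frame(site = s, ddct_A = ddct(a), ddct_B = ddct(b), dddct = d,
               ct_diff_raw = a$ct_dpnI - b$ct_dpnI,
               call = if (abs(d) < retain_threshold) "retain"
                      else if (d > 0) "conversion" else "reverse",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
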