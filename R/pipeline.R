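#' Pipeline configuration
#'
#' Collects every input path and threshold of the analysis. Inputs may
#' either be files (genome FASTA, gene GFF3, per-condition modification
#' GFFs, MNase fragment BED, expression TSV, Ct CSV) or, when `sim` is
#' given, be generated in memory by the synthetic-data module. Unknown
#' arguments are rejected by the function signature.
#'
#' @param out_dir optional output directory; when set, every stage
#'   writes its machine-readable table there
#' @param sim optional [sim_config()]: simulate all inputs
#' @param genome_fa,genes_gff,calls_A_gff,calls_B_gff,fragments_bed,expression_tsv,ct_csv
#'   input file paths (ignored when `sim` is given)
#' @param condition_A,condition_B condition labels
#' @param exclude_chroms chromosome names to drop before analysis (e.g.
#'   an rDNA chromosome)
#' @param min_qv,min_cov,target_cov confidence-filter and
#'   coverage-normalisation parameters
#' @param amount_window TSS-relative window for gene 6mA amounts
#' @param nucleosome list(window, smooth, k_max, spacing)
#' @param deg list(padj, lfc, low, high, top_frac) expression-class
#'   thresholds
#' @return list of class `PipelineConfig`
#' @export
pipeline_config <- function(out_dir = NULL, sim = NULL,
                            genome_fa = NULL, genes_gff = NULL,
                            calls_A_gff = NULL, calls_B_gff = NULL,
                            fragments_bed = NULL, expression_tsv = NULL,
                            ct_csv = NULL,
                            condition_A = "Veg", condition_B = "S24",
                            exclude_chroms = character(),
                            min_qv = 30, min_cov = 25, target_cov = 100,
                            amount_window = c(0, 1000),
                            nucleosome = list(window = c(-500, 1500),
                                              smooth = 31, k_max = 5,
                                              spacing = 200),
                            deg = list(padj = 0.05, lfc = 2, low = 300,
                                       high = 1500, top_frac = 0.1)) {
  if (is.null(sim)) {
    for (p in c(genome_fa, genes_gff, calls_A_gff, calls_B_gff))
      if (!is.null(p) && !file.exists(p)) stop("input not found: ", p)
    if (is.null(genome_fa) || is.null(calls_A_gff) || is.null(calls_B_gff))
      stop("either give `sim` or genome_fa + calls_A_gff + calls_B_gff")
  }
  structure(as.list(environment()), class = "PipelineConfig")
}

write_tsv <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full 6mA dynamics pipeline
#'
#' Stages run in dependency order: ingest -> normalise/filter ->
#' classify -> dynamics -> gene profiles -> nucleosome -> qPCR ->
#' report. Dropped-record counts are retained at every filter so
#' composition totals stay auditable, and every reported figure has a
#' machine-readable TSV/JSON twin when `out_dir` is set. Reruns with the
#' same configuration and inputs are numerically identical.
#'
#' @param config a [pipeline_config()]
#' @return a report list (summaries, transition matrix and fractions,
#'   profiles, correlations, positioning degrees, qPCR calls)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)

  # ---- ingest -------------------------------------------------------
  if (!is.null(config$sim)) {
    gen <- simulate_genome(config$sim)
    genome <- gen$genome; genes <- gen$genes
    cs <- simulate_callsets(config$sim, genome)
    calls_A <- cs$calls_A; calls_B <- cs$calls_B
    truth <- cs$truth
    frags <- simulate_mnase(config$sim, genome, genes)
    tg <- true_gene_amount_change(truth$adenines, genes,
                                  config$amount_window)
    expr <- simulate_expression(config$sim,
                                data.frame(gene_id = tg$gene_id,
                                           amount_change = tg$amount_change))
    ct_table <- simulate_ct(config$sim,
                            data.frame(site = c("C1", "C2", "C3", "C4", "R1"),
                                       type = c(rep("conversion", 4),
                                                "retain")))
  } else {
    genome <- read_genome_fasta(config$genome_fa)
    genes <- if (!is.null(config$genes_gff))
      read_gff3_genes(config$genes_gff, genome) else NULL
    calls_A <- read_modifications_gff(config$calls_A_gff, genome,
                                      config$condition_A)
    calls_B <- read_modifications_gff(config$calls_B_gff, genome,
                                      config$condition_B)
    frags <- if (!is.null(config$fragments_bed))
      read_bed_fragments(config$fragments_bed) else NULL
    expr <- if (!is.null(config$expression_tsv))
      read_expression_tsv(config$expression_tsv) else NULL
    ct_table <- if (!is.null(config$ct_csv)) read_ct_csv(config$ct_csv)
      else NULL
    truth <- NULL
  }
  if (length(config$exclude_chroms)) {
    keep <- setdiff(names(genome$seqs), config$exclude_chroms)
    genome <- new_genome(genome$seqs[keep])
    drop_cs <- function(x) callset(as.data.frame(x)[x$chrom %in% keep, ],
                                   callset_condition(x))
    calls_A <- drop_cs(calls_A); calls_B <- drop_cs(calls_B)
    if (!is.null(genes)) genes <- genes[genes$chrom %in% keep, ]
    if (!is.null(frags)) frags <- frags[frags$chrom %in% keep, ]
  }

  # ---- normalise, filter, classify ---------------------------------
  prep <- function(calls) {
    filtered <- filter_calls(normalize_coverage(calls, config$target_cov),
                             config$min_qv, config$min_cov)
    classify_sites(filtered, genome)
  }
  cls_A <- prep(calls_A)
  cls_B <- prep(calls_B)
  sum_A <- summarize_composition(cls_A, genome)
  sum_B <- summarize_composition(cls_B, genome)

  report <- list(
    conditions = c(config$condition_A, config$condition_B),
    n_calls_raw = c(nrow(calls_A), nrow(calls_B)),
    n_calls_filtered = c(nrow(cls_A), nrow(cls_B)),
    composition = list(A = sum_A, B = sum_B),
    apt_fraction = list(A = apt_fraction(sum_A), B = apt_fraction(sum_B))
  )
  comp_tab <- data.frame(
    condition = rep(report$conditions, each = 3),
    class = rep(CLASS_LEVELS, 2),
    adenines = c(sum_A$class_counts, sum_B$class_counts),
    pct = c(sum_A$class_pct, sum_B$class_pct))
  write_tsv(comp_tab, out_dir, "composition.tsv")

  # ---- dynamics ----------------------------------------------------
  trans <- match_conditions(cls_A, cls_B, genome)
  tm <- transition_matrix(trans)
  report$transition_matrix <- tm
  sym_A <- tm["symmetric", ]
  report$transition_fractions <- c(
    sym_to_unmethylated = transition_fraction(sym_A[["unmethylated"]],
                                              sum(sym_A)),
    sym_to_asymmetric = transition_fraction(sym_A[["asymmetric"]],
                                            sum(sym_A)))
  write_tsv(as.data.frame.table(tm), out_dir, "transition_matrix.tsv")

  if (!is.null(genes)) {
    gl <- gene_l5_asym_change(cls_A, cls_B, genes,
                              config$amount_window[2])
    report$gain_loss <- list(n_gain = length(gl$gain),
                             n_loss = length(gl$loss))
    if (!is.null(out_dir)) {
      writeLines(gl$gain, file.path(out_dir, "genes_gain_l5_asym.txt"))
      writeLines(gl$loss, file.path(out_dir, "genes_loss_l5_asym.txt"))
    }
  } else gl <- NULL

  # ---- gene profiles ------------------------------------------------
  if (!is.null(genes)) {
    mg_A <- metagene_profile(cls_A, genes)
    mg_B <- metagene_profile(cls_B, genes)
    tp_A <- tss_profile(cls_A, genes)
    tp_B <- tss_profile(cls_B, genes)
    report$profiles <- list(metagene_A = mg_A, metagene_B = mg_B,
                            tss_A = tp_A, tss_B = tp_B)
    write_tsv(data.frame(position = mg_A$position, A = mg_A$density,
                         B = mg_B$density), out_dir, "metagene_profile.tsv")
    write_tsv(data.frame(position = tp_A$position, A = tp_A$density,
                         B = tp_B$density), out_dir, "tss_profile.tsv")
    if (!is.null(expr)) {
      rec <- data.frame(gene_id = genes$gene_id,
                        amount_A = gene_amounts(cls_A, genes,
                                                config$amount_window),
                        amount_B = gene_amounts(cls_B, genes,
                                                config$amount_window))
      rec <- merge(rec, expr, by = "gene_id")
      sets <- classify_gene_sets(rec, config$deg$padj, config$deg$lfc,
                                 config$deg$low, config$deg$high,
                                 config$deg$top_frac)
      responding <- union(sets$induced, sets$repressed)
      corr_sets <- list(all = NULL,
                        highly_regulated = sets$highly_regulated,
                        responding = responding)
      report$correlation <- lapply(corr_sets, function(ids) {
        tryCatch(amount_expression_correlation(rec, ids),
                 error = function(e) list(r = NA_real_, p = NA_real_,
                                          n = if (is.null(ids)) nrow(rec)
                                              else length(ids)))
      })
      report$gene_sets <- lapply(sets, length)
      if (!is.null(out_dir))
        jsonlite::write_json(report$correlation,
                             file.path(out_dir, "correlation.json"),
                             auto_unbox = TRUE, digits = NA)
    }
  }

  # ---- nucleosome ---------------------------------------------------
  if (!is.null(frags) && !is.null(genes)) {
    dyads <- fragments_to_dyads(frags)
    np <- config$nucleosome
    prof <- composite_dyad_profile(dyads, genes, np$window, np$smooth)
    deg <- positioning_degree(prof, np$k_max, np$spacing)
    report$nucleosome <- list(
      degrees = deg,
      periodicity = tryCatch(estimate_periodicity(prof),
                             error = function(e) NA_real_))
    write_tsv(data.frame(position = prof$position, density = prof$density),
              out_dir, "dyad_profile.tsv")
    write_tsv(deg, out_dir, "positioning_degree.tsv")
    rel <- dyad_relative_6ma(cls_A, dyads)
    report$nucleosome$n_interdyad_sites <- nrow(rel)
    if (!is.null(gl) && length(gl$gain) && length(gl$loss)) {
      cmp <- suppressWarnings(
        compare_positioning(gl[c("gain", "loss")], dyads, genes,
                            k_max = np$k_max, window = np$window,
                            smooth = np$smooth))
      report$nucleosome$gain_loss_degree_diff <- cmp$diff
    }
  }

  # ---- qPCR ---------------------------------------------------------
  if (!is.null(ct_table)) {
    report$qpcr <- qpcr_report(ct_table, config$condition_A,
                               config$condition_B)
    write_tsv(report$qpcr, out_dir, "qpcr_report.tsv")
  }

  if (!is.null(out_dir)) {
    digest <- list(
      n_calls_filtered = report$n_calls_filtered,
      apt_fraction = report$apt_fraction,
      transition_fractions = as.list(report$transition_fractions),
      correlation = report$correlation %||% NULL,
      nucleosome_periodicity = report$nucleosome$periodicity %||% NULL)
    jsonlite::write_json(digest, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}
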