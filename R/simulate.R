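#' Simulation configuration
#'
#' One seed fully determines every generator output; each generator draws
#' from its own deterministic substream so stages can be rerun in any
#' order. Defaults emulate an AT-rich polyploid macronuclear genome with
#' duplex 6mA whose composition, level mixtures and two-condition
#' transition behaviour mirror the vegetative-versus-starved contrast:
#' most methylated duplexes fully (symmetrically) methylated with high
#' levels, hemimethylated sites bimodal in level, a large
#' symmetric-to-asymmetric and symmetric-to-unmethylated flux into the
#' second condition, phased nucleosomes at ~200 bp with linker 6mA, and
#' expression fold changes partially coupled to 6mA amount change.
#'
#' @param seed integer master seed
#' @param chrom_lengths named integer vector of chromosome lengths
#' @param at_content genomic A+T fraction (default 0.75)
#' @param n_duplexes number of ApT duplex units carrying methylation
#'   state
#' @param n_nonapt number of non-ApT adenine units
#' @param class_mix condition-A duplex state probabilities
#'   (symmetric/asymmetric/unmethylated)
#' @param p_nonapt_meth condition-A methylation probability of non-ApT
#'   units
#' @param kernel 4x4 row-stochastic transition matrix over
#'   symmetric/asymmetric/nonApT/unmethylated; structurally impossible
#'   targets (a duplex can never become nonApT and vice versa) are
#'   renormalised away per unit kind
#' @param level_models per-class methylation-level distributions (beta or
#'   beta mixtures on \[0, 1\])
#' @param copy_number optional chromosome copy number; when set, levels
#'   are discretised as binomial(copy_number)/copy_number draws
#' @param coverage negative-binomial coverage model (mean, size)
#' @param qv gamma quality-value model (shape, scale, offset)
#' @param genes gene-tiling parameters (min_len, max_len, gap, margin)
#' @param nucleosome phasing parameters (spacing, offset of the +1 dyad,
#'   n_nuc, jitter_sd, frags_per_dyad, frag_len_mean, frag_len_sd)
#' @param expression coupling model (beta, noise_sd, base_mean,
#'   base_size, n_perm)
#' @param ct qPCR model (noise_sd, digest_shift, base_ct)
#' @return list of class `SimConfig`
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chrL = 400000L, chrM = 250000L,
                                         chrS = 120000L),
                       at_content = 0.75,
                       n_duplexes = 20000L,
                       n_nonapt = 4500L,
                       class_mix = c(symmetric = 0.55, asymmetric = 0.40,
                                     unmethylated = 0.05),
                       p_nonapt_meth = 0.9,
                       kernel = default_kernel(),
                       level_models = default_level_models(),
                       copy_number = NULL,
                       coverage = list(mean = 103, size = 10),
                       qv = list(shape = 6, scale = 8, offset = 5),
                       genes = list(min_len = 1500L, max_len = 3000L,
                                    gap = 600L, margin = 3000L),
                       nucleosome = list(spacing = 200L, offset = 100L,
                                         n_nuc = 8L, jitter_sd = 10,
                                         frags_per_dyad = 20,
                                         frag_len_mean = 147,
                                         frag_len_sd = 12),
                       expression = list(beta = 0.5, noise_sd = 1,
                                         base_mean = 800, base_size = 5,
                                         n_perm = 2000L),
                       ct = list(noise_sd = 0.3, digest_shift = 5,
                                 base_ct = 18)) {
  stopifnot(at_content >= 0, at_content <= 1)
  if (abs(sum(class_mix) - 1) > 1e-9) stop("class_mix must sum to 1")
  if (any(class_mix < 0) || any(class_mix > 1))
    stop("class_mix probabilities must lie in [0, 1]")
  if (any(abs(rowSums(kernel) - 1) > 1e-9))
    stop("kernel rows must sum to 1")
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 at_content = at_content, n_duplexes = n_duplexes,
                 n_nonapt = n_nonapt, class_mix = class_mix,
                 p_nonapt_meth = p_nonapt_meth, kernel = kernel,
                 level_models = level_models, copy_number = copy_number,
                 coverage = coverage, qv = qv, genes = genes,
                 nucleosome = nucleosome, expression = expression, ct = ct),
            class = "SimConfig")
}

#' Default two-condition transition kernel
#'
#' Row-stochastic matrix over symmetric / asymmetric / nonApT /
#' unmethylated, shaped like the vegetative-to-starved site behaviour:
#' much of the symmetric methylation becomes hemimethylated or is lost,
#' asymmetric sites mostly persist, non-ApT methylation largely
#' disappears, and unmethylated positions rarely gain.
#'
#' @return 4x4 numeric matrix with dimnames
#' @export
default_kernel <- function() {
  k <- rbind(symmetric    = c(0.22, 0.41, 0.00, 0.37),
             asymmetric   = c(0.06, 0.59, 0.00, 0.35),
             nonApT       = c(0.00, 0.00, 0.33, 0.67),
             unmethylated = c(0.01, 0.05, 0.01, 0.93))
  colnames(k) <- rownames(k)
  k
}

#' Default per-class methylation-level models
#'
#' Symmetric levels concentrate high (most genome copies methylated);
#' asymmetric levels are bimodal; non-ApT levels are broad.
#'
#' @return named list of beta / beta-mixture specs
#' @export
default_level_models <- function() {
  list(symmetric = list(w = 1, shape1 = 8, shape2 = 2),
       asymmetric = list(w = c(0.5, 0.5), shape1 = c(2, 8),
                         shape2 = c(6, 2)),
       nonApT = list(w = 1, shape1 = 2, shape2 = 2))
}

substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * k) %% 2147483629)
}

draw_levels <- function(n, model, copy_number = NULL) {
  if (n == 0) return(numeric(0))
  comp <- sample.int(length(model$w), n, replace = TRUE, prob = model$w)
  x <- stats::rbeta(n, model$shape1[comp], model$shape2[comp])
  if (!is.null(copy_number))
    x <- stats::rbinom(n, copy_number, x) / copy_number
  x
}

#' Simulate an AT-rich genome with tiled gene models
#'
#' Bases are i.i.d. with the configured A+T content (A and T
#' equiprobable, likewise C and G). Genes longer than 1 kb are tiled
#' along each chromosome on alternating strands, leaving a margin at the
#' ends and a fixed gap between neighbours.
#'
#' @param config a [sim_config()]
#' @param with_genes also tile genes (default TRUE)
#' @param dir optional directory: writes `genome.fa` and `genes.gff3`
#' @return list(genome = `Genome`, genes = gene data.frame)
#' @export
simulate_genome <- function(config, with_genes = TRUE, dir = NULL) {
  set.seed(substream_seed(config$seed, 1L))
  p <- c(A = config$at_content / 2, C = (1 - config$at_content) / 2,
         G = (1 - config$at_content) / 2, T = config$at_content / 2)
  seqs <- vapply(config$chrom_lengths, function(L) {
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  genome <- new_genome(seqs)
  genes <- NULL
  if (with_genes) {
    gp <- config$genes
    if (any(config$chrom_lengths < 2000))
      stop("chromosomes shorter than 2 kb cannot carry >1 kb genes")
    rows <- list()
    idx <- 0L
    for (ch in names(genome$seqs)) {
      pos <- gp$margin
      lim <- genome$lengths[[ch]] - gp$margin
      while (TRUE) {
        len <- sample(seq(gp$min_len, gp$max_len), 1L)
        if (pos + len > lim) break
        idx <- idx + 1L
        strand <- if (idx %% 2L == 1L) "+" else "-"
        rows[[idx]] <- data.frame(
          gene_id = sprintf("g%05d", idx), chrom = ch,
          start = pos, end = pos + len, strand = strand,
          tss = if (strand == "+") pos else pos + len - 1L,
          stringsAsFactors = FALSE)
        pos <- pos + len + gp$gap
      }
    }
    genes <- do.call(rbind, rows)
    rownames(genes) <- NULL
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_genome_fasta(genome, file.path(dir, "genome.fa"))
    if (!is.null(genes)) write_gff3_genes(genes, file.path(dir, "genes.gff3"))
  }
  list(genome = genome, genes = genes)
}

restricted_row <- function(kernel, state, allowed) {
  p <- kernel[state, ]
  p[setdiff(colnames(kernel), allowed)] <- 0
  if (sum(p) == 0) stop("kernel row ", state, " has no admissible target")
  p / sum(p)
}

sample_states <- function(states, kernel, allowed) {
  out <- character(length(states))
  for (st in unique(states)) {
    i <- states == st
    p <- restricted_row(kernel, st, allowed)
    out[i] <- sample(colnames(kernel), sum(i), replace = TRUE, prob = p)
  }
  out
}

#' Simulate paired-condition methylation call sets with ground truth
#'
#' Samples ApT duplex units and non-ApT adenine units from the genome,
#' assigns condition-A states from the class mixture, propagates them to
#' condition B through the transition kernel, draws per-adenine
#' methylation levels from the class-conditional models and per-call
#' coverage / quality values, and emits one call set per condition
#' together with a truth table.
#'
#' @param config a [sim_config()]
#' @param genome a `Genome` (typically from [simulate_genome()])
#' @param dir optional directory: writes `calls_A.gff` / `calls_B.gff`
#'   and `truth_adenines.tsv`
#' @return list(calls_A, calls_B, truth) where truth holds `units` (one
#'   row per duplex / non-ApT unit with state_A, state_B) and `adenines`
#'   (one row per strand-resolved adenine with class and level per
#'   condition)
#' @export
simulate_callsets <- function(config, genome, dir = NULL) {
  set.seed(substream_seed(config$seed, 2L))
  dup <- index_apt_duplexes(genome)
  if (nrow(dup) < config$n_duplexes)
    stop("genome has only ", nrow(dup), " ApT duplexes; need ",
         config$n_duplexes)
  dup <- dup[sort(sample.int(nrow(dup), config$n_duplexes)), , drop = FALSE]

  nonapt <- nonapt_adenines(genome)
  if (nrow(nonapt) < config$n_nonapt)
    stop("genome has only ", nrow(nonapt), " non-ApT adenines; need ",
         config$n_nonapt)
  nonapt <- nonapt[sort(sample.int(nrow(nonapt), config$n_nonapt)), ,
                   drop = FALSE]

  dup_states <- c("symmetric", "asymmetric", "unmethylated")
  state_A <- sample(dup_states, nrow(dup), replace = TRUE,
                    prob = config$class_mix[dup_states])
  state_B <- sample_states(state_A, config$kernel, dup_states)
  side_A <- sample(c("W", "C"), nrow(dup), replace = TRUE)
  side_B <- ifelse(state_A == "asymmetric" & state_B == "asymmetric",
                   side_A, sample(c("W", "C"), nrow(dup), replace = TRUE))

  na_state_A <- ifelse(stats::runif(nrow(nonapt)) < config$p_nonapt_meth,
                       "nonApT", "unmethylated")
  na_state_B <- sample_states(na_state_A, config$kernel,
                              c("nonApT", "unmethylated"))

  units <- rbind(
    data.frame(unit_id = paste0("d", seq_len(nrow(dup))), kind = "duplex",
               chrom = dup$chrom, pos = dup$watson_pos, strand = "*",
               state_A = state_A, state_B = state_B,
               stringsAsFactors = FALSE),
    data.frame(unit_id = paste0("n", seq_len(nrow(nonapt))), kind = "nonapt",
               chrom = nonapt$chrom, pos = nonapt$pos, strand = nonapt$strand,
               state_A = na_state_A, state_B = na_state_B,
               stringsAsFactors = FALSE))

  # expand duplexes to their two adenines; class of each adenine per
  # condition follows the unit state and, for hemimethylation, the side
  aden_class <- function(state, side, member) {
    ifelse(state == "symmetric", "symmetric",
           ifelse(state == "asymmetric" & side == member, "asymmetric",
                  "unmethylated"))
  }
  dup_aden <- rbind(
    data.frame(chrom = dup$chrom, pos = dup$watson_pos, strand = "+",
               member = "W", unit = seq_len(nrow(dup)),
               stringsAsFactors = FALSE),
    data.frame(chrom = dup$chrom, pos = dup$crick_pos, strand = "-",
               member = "C", unit = seq_len(nrow(dup)),
               stringsAsFactors = FALSE))
  dup_aden$class_A <- aden_class(state_A[dup_aden$unit],
                                 side_A[dup_aden$unit], dup_aden$member)
  dup_aden$class_B <- aden_class(state_B[dup_aden$unit],
                                 side_B[dup_aden$unit], dup_aden$member)
  na_aden <- data.frame(chrom = nonapt$chrom, pos = nonapt$pos,
                        strand = nonapt$strand, member = "N",
                        unit = seq_len(nrow(nonapt)),
                        class_A = ifelse(na_state_A == "nonApT", "nonApT",
                                         "unmethylated"),
                        class_B = ifelse(na_state_B == "nonApT", "nonApT",
                                         "unmethylated"),
                        stringsAsFactors = FALSE)
  aden <- rbind(dup_aden, na_aden)

  draw_cond <- function(cls) {
    frac <- rep(NA_real_, nrow(aden))
    for (k in c("symmetric", "asymmetric", "nonApT")) {
      i <- cls == k
      frac[i] <- draw_levels(sum(i), config$level_models[[k]],
                             config$copy_number)
    }
    frac
  }
  aden$frac_A <- draw_cond(aden$class_A)
  aden$frac_B <- draw_cond(aden$class_B)

  make_calls <- function(which_cond, label) {
    cls <- aden[[paste0("class_", which_cond)]]
    keep <- cls != "unmethylated"
    n <- sum(keep)
    calls <- data.frame(
      chrom = aden$chrom[keep], pos = aden$pos[keep],
      strand = aden$strand[keep],
      coverage = stats::rnbinom(n, mu = config$coverage$mean,
                                size = config$coverage$size) + 1,
      qv = config$qv$offset + stats::rgamma(n, shape = config$qv$shape,
                                            scale = config$qv$scale),
      frac = aden[[paste0("frac_", which_cond)]][keep],
      stringsAsFactors = FALSE)
    callset(calls[order(calls$chrom, calls$pos, calls$strand), ], label)
  }
  calls_A <- make_calls("A", "Veg")
  calls_B <- make_calls("B", "S24")

  truth <- list(units = units, adenines = aden)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_modifications_gff(calls_A, file.path(dir, "calls_A.gff"))
    write_modifications_gff(calls_B, file.path(dir, "calls_B.gff"))
    utils::write.table(aden, file.path(dir, "truth_adenines.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(calls_A = calls_A, calls_B = calls_B, truth = truth)
}

#' Non-ApT adenine positions of a genome
#'
#' Strand-resolved adenines whose strand-local 3' neighbour is not T:
#' Watson A not followed by T, and Crick A (Watson T) not preceded by A.
#'
#' @param genome a `Genome`
#' @return data.frame(chrom, pos, strand)
#' @keywords internal
nonapt_adenines <- function(genome) {
  res <- lapply(names(genome$seqs), function(ch) {
    r <- charToRaw(genome$seqs[[ch]])
    n <- length(r)
    A <- r == charToRaw("A"); T_ <- r == charToRaw("T")
    watson <- which(A & !c(T_[-1], FALSE))
    crick <- which(T_ & !c(FALSE, A[-n]))
    rbind(data.frame(chrom = ch, pos = watson - 1L, strand = "+",
                     stringsAsFactors = FALSE),
          data.frame(chrom = ch, pos = crick - 1L, strand = "-",
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write a call set as a SMRT-Link-style modifications GFF
#'
#' @param calls a `CallSet`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_modifications_gff <- function(calls, path) {
  df <- as.data.frame(calls)
  lines <- c("##gff-version 3",
             sprintf("%s\tkinModCall\tm6A\t%d\t%d\t%s\t%s\t.\tcoverage=%s;frac=%s",
                     df$chrom, df$pos + 1L, df$pos + 1L,
                     format(df$qv, digits = 15, trim = TRUE, scientific = FALSE),
                     df$strand,
                     format(df$coverage, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     format(df$frac, digits = 15, trim = TRUE,
                            scientific = FALSE)))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate phased MNase fragments
#'
#' Places true dyads at `offset + spacing * k` downstream of each TSS
#' (strand-oriented, k = 0..n_nuc-1), jitters observed dyads with
#' Gaussian noise, and emits mononucleosome-sized fragments centred on
#' them.
#'
#' @param config a [sim_config()]
#' @param genome a `Genome`
#' @param genes gene table
#' @param jitter_sd positional noise sd in bp (defaults to the config
#'   value); larger jitter means fuzzier positioning
#' @param dir optional directory: writes `fragments.bed`
#' @return data.frame(chrom, start, end) of fragments
#' @export
simulate_mnase <- function(config, genome, genes, jitter_sd = NULL,
                           dir = NULL) {
  set.seed(substream_seed(config$seed, 3L))
  np <- config$nucleosome
  jitter_sd <- jitter_sd %||% np$jitter_sd
  k <- rep(seq_len(np$n_nuc) - 1L, times = nrow(genes))
  gi <- rep(seq_len(nrow(genes)), each = np$n_nuc)
  dirn <- ifelse(genes$strand[gi] == "+", 1L, -1L)
  centers <- genes$tss[gi] + dirn * (np$offset + np$spacing * k)
  nfrag <- stats::rpois(length(centers), np$frags_per_dyad)
  center_rep <- rep(centers, nfrag)
  chrom_rep <- rep(genes$chrom[gi], nfrag)
  m <- length(center_rep)
  dyad_obs <- round(center_rep + stats::rnorm(m, 0, jitter_sd))
  len <- pmin(pmax(round(stats::rnorm(m, np$frag_len_mean, np$frag_len_sd)),
                   100L), 200L)
  start <- dyad_obs - len %/% 2L
  end <- start + len
  lim <- unname(genome$lengths[chrom_rep])
  keep <- start >= 0L & end <= lim
  frags <- data.frame(chrom = chrom_rep[keep], start = start[keep],
                      end = end[keep], stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(frags, file.path(dir, "fragments.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  frags
}

#' Expression-model coupling for a target correlation
#'
#' With `log2fc = beta * z + noise` and standardised `z`, the population
#' Pearson correlation between amount change and log2fc is
#' `beta / sqrt(beta^2 + noise_sd^2)`; this inverts that relation.
#'
#' @param rho target correlation in (-1, 1)
#' @param noise_sd noise standard deviation
#' @return coupling coefficient beta
#' @export
beta_for_rho <- function(rho, noise_sd = 1) {
  stopifnot(abs(rho) < 1)
  rho * noise_sd / sqrt(1 - rho^2)
}

#' Simulate an expression table coupled to 6mA amount change
#'
#' `log2fc = beta * standardise(amount_change) + N(0, noise_sd)`. Raw
#' counts are drawn to be consistent with the fold change, and per-gene p
#' values come from a permutation-style null (fold changes under zero
#' coupling), adjusted by Benjamini-Hochberg.
#'
#' @param config a [sim_config()]
#' @param truth_genes data.frame(gene_id, amount_change)
#' @param dir optional directory: writes `expression.tsv`
#' @return expression data.frame (gene_id, counts_veg, counts_s24,
#'   log2fc, padj, fpkm_flag, true_amount_change)
#' @export
simulate_expression <- function(config, truth_genes, dir = NULL) {
  set.seed(substream_seed(config$seed, 4L))
  ep <- config$expression
  n <- nrow(truth_genes)
  z <- truth_genes$amount_change
  z <- if (stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) else rep(0, n)
  log2fc <- ep$beta * z + stats::rnorm(n, 0, ep$noise_sd)
  counts_veg <- stats::rnbinom(n, mu = ep$base_mean, size = ep$base_size) + 1L
  counts_s24 <- as.integer(pmin(pmax(round(counts_veg * 2^log2fc), 0),
                                .Machine$integer.max))
  null_fc <- stats::rnorm(ep$n_perm, 0, ep$noise_sd)
  p <- vapply(log2fc, function(f) (1 + sum(abs(null_fc) >= abs(f))) /
                                  (ep$n_perm + 1), numeric(1))
  out <- data.frame(gene_id = truth_genes$gene_id,
                    counts_veg = counts_veg, counts_s24 = counts_s24,
                    log2fc = log2fc,
                    padj = stats::p.adjust(p, "BH"),
                    fpkm_flag = counts_veg + counts_s24 > 10,
                    true_amount_change = truth_genes$amount_change,
                    stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(out, file.path(dir, "expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}

#' True per-gene 6mA amount change from a truth table
#'
#' @param truth_adenines adenine truth table from [simulate_callsets()]
#' @param genes gene table
#' @param window TSS-relative window (default first kilobase downstream)
#' @return data.frame(gene_id, amount_A, amount_B, amount_change)
#' @export
true_gene_amount_change <- function(truth_adenines, genes,
                                    window = c(0, 1000)) {
  amt <- function(col_cls, col_frac) {
    df <- truth_adenines[truth_adenines[[col_cls]] != "unmethylated",
                         c("chrom", "pos", col_frac)]
    names(df)[3] <- "frac"
    bychrom <- split(df[c("pos", "frac")], df$chrom)
    vapply(seq_len(nrow(genes)), function(i) {
      d <- bychrom[[genes$chrom[i]]]
      if (is.null(d)) return(0)
      rel <- if (genes$strand[i] == "+") d$pos - genes$tss[i]
             else genes$tss[i] - d$pos
      sum(d$frac[rel >= window[1] & rel < window[2]])
    }, numeric(1))
  }
  a <- amt("class_A", "frac_A")
  b <- amt("class_B", "frac_B")
  data.frame(gene_id = genes$gene_id, amount_A = a, amount_B = b,
             amount_change = b - a, stringsAsFactors = FALSE)
}

#' Simulate a DpnI/DpnII qPCR Ct table
#'
#' Conversion-truth sites are methylated (DpnI-sensitive) in the first
#' condition and unmethylated (DpnII-sensitive) in the second; retain
#' sites are methylated in both. Each measured Ct gets independent
#' Gaussian noise.
#'
#' @param config a [sim_config()]
#' @param sites data.frame(site, type) with type in
#'   \{"conversion", "retain"\}
#' @param noise_sd override the configured Ct noise sd
#' @param dir optional directory: writes `ct.csv`
#' @return Ct data.frame (site, condition, ct_dpnI, ct_dpnII,
#'   ct_undigested)
#' @export
simulate_ct <- function(config, sites, noise_sd = NULL, dir = NULL) {
  set.seed(substream_seed(config$seed, 5L))
  cp <- config$ct
  noise_sd <- noise_sd %||% cp$noise_sd
  grid <- expand.grid(site = sites$site, condition = c("Veg", "S24"),
                      stringsAsFactors = FALSE)
  grid$type <- sites$type[match(grid$site, sites$site)]
  meth <- ifelse(grid$type == "retain", TRUE, grid$condition == "Veg")
  n <- nrow(grid)
  noise <- function() stats::rnorm(n, 0, noise_sd)
  out <- data.frame(
    site = grid$site, condition = grid$condition,
    ct_dpnI = cp$base_ct + ifelse(meth, cp$digest_shift, 0) + noise(),
    ct_dpnII = cp$base_ct + ifelse(meth, 0, cp$digest_shift) + noise(),
    ct_undigested = cp$base_ct + noise(),
    stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(dir, "ct.csv"), row.names = FALSE)
  }
  out
}
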