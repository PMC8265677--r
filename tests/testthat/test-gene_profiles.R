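test_that("window amounts sum methylated fractions strand-awarely", {
  g <- toy_genome(c1 = random_seq(10000))
  gene <- toy_genes("c1", 2000L, 4000L, "+")[1, ]
  cls <- structure(data.frame(chrom = "c1", pos = c(2100L, 2500L, 3500L),
                              strand = "+", frac = c(0.5, 0.7, 0.9)),
                   class = c("ClassifiedSites", "data.frame"))
  expect_equal(amount_in_window(cls, gene, c(0, 1000)), 1.2)
  expect_equal(amount_in_window(cls, gene, c(0, 10)), 0)

  # minus-strand gene: downstream runs towards lower coordinates
  gene_m <- toy_genes("c1", 2000L, 4000L, "-")[1, ]
  expect_equal(amount_in_window(cls, gene_m, c(0, 1000)), 0.9)

  # random placement equals a brute-force sum
  set.seed(91)
  pos <- sort(sample(0:9999, 300))
  frac <- runif(300)
  cls2 <- structure(data.frame(chrom = "c1", pos = pos, strand = "+",
                               frac = frac),
                    class = c("ClassifiedSites", "data.frame"))
  rel <- pos - gene$tss
  expect_equal(amount_in_window(cls2, gene, c(0, 1000)),
               sum(frac[rel >= 0 & rel < 1000]))
  expect_equal(unname(gene_amounts(cls2, rbind(gene, gene_m))),
               c(amount_in_window(cls2, gene),
                 amount_in_window(cls2, gene_m)))
})

test_that("metagene profile scales gene bodies and mirrors minus-strand genes", {
  g <- toy_genome(c1 = random_seq(20000))
  gene <- toy_genes("c1", 5000L, 7000L, "+")
  mid <- structure(data.frame(chrom = "c1", pos = 6000L, strand = "+",
                              frac = 1),
                   class = c("ClassifiedSites", "data.frame"))
  prof <- metagene_profile(mid, gene)
  expect_equal(sum(prof$density), 1)
  hot <- prof$position[prof$density > 0]
  expect_equal(hot, 0.5)  # bin [0.5, 0.55)

  # site 500 bp upstream of a 1 kb+ gene scales to -0.5 in the 5' flank
  gene1k <- toy_genes("c1", 5000L, 6001L, "+")
  up <- structure(data.frame(chrom = "c1", pos = 4500L, strand = "+",
                             frac = 1),
                  class = c("ClassifiedSites", "data.frame"))
  pu <- metagene_profile(up, gene1k)
  expect_equal(pu$position[pu$density > 0], -0.5)

  # strand mirror: a minus-strand gene with mirrored sites gives the
  # reversed profile of its plus-strand equivalent
  set.seed(101)
  pos_p <- sample(3000:9000, 50)
  gp <- toy_genes("c1", 5000L, 7000L, "+")
  gm <- toy_genes("c1", 5000L, 7000L, "-")
  mirror <- 5000L + 7000L - 1L - pos_p  # reflect around the gene body
  cp <- structure(data.frame(chrom = "c1", pos = pos_p, strand = "+",
                             frac = runif(50)),
                  class = c("ClassifiedSites", "data.frame"))
  cm <- cp; cm$pos <- mirror
  pp <- metagene_profile(cp, gp)
  pm <- metagene_profile(cm, gm)
  expect_equal(pm$density, pp$density)

  expect_error(metagene_profile(mid, toy_genes("c1", 0L, 500L, "+")),
               "no genes longer")
})

test_that("TSS profile uses strand-oriented per-base coordinates", {
  g <- toy_genome(c1 = random_seq(10000))
  gp <- toy_genes("c1", 4000L, 6000L, "+")
  gm <- toy_genes("c1", 4000L, 6000L, "-")
  at_tss <- structure(data.frame(chrom = "c1", pos = 4000L, strand = "+",
                                 frac = 1),
                      class = c("ClassifiedSites", "data.frame"))
  prof <- tss_profile(at_tss, gp)
  expect_equal(prof$position[prof$density > 0], 0)
  expect_equal(sum(prof$density), 1)

  # 1 bp 5' of a minus-strand TSS: genomic pos = tss + 1, profile pos -1
  up1 <- structure(data.frame(chrom = "c1", pos = 6000L, strand = "+",
                              frac = 1),
                   class = c("ClassifiedSites", "data.frame"))
  pm <- tss_profile(up1, gm)  # tss = 5999
  expect_equal(pm$position[pm$density > 0], -1)

  empty <- structure(data.frame(chrom = character(), pos = integer(),
                                strand = character(), frac = numeric()),
                     class = c("ClassifiedSites", "data.frame"))
  expect_error(tss_profile(empty, gp), "empty")
})

test_that("expression gene classes apply strict documented gates", {
  rec <- data.frame(
    gene_id = paste0("g", 1:6),
    counts_veg = c(200, 1600, 500, 500, 100, 2000),
    counts_s24 = c(1600, 200, 500, 500, 2000, 100),
    log2fc = c(3, -3, 2, 0.5, 4.2, -4.5),
    padj = c(0.01, 0.01, 0.01, 0.9, 0.001, 0.001))
  sets <- classify_gene_sets(rec)
  expect_true("g1" %in% sets$induced)
  expect_true("g5" %in% sets$induced)
  expect_true(all(c("g2", "g6") %in% sets$repressed))
  expect_true(all(c("g1", "g5") %in% sets$DEG_up))
  expect_false("g3" %in% sets$DEG_up)  # log2fc = 2 exactly: strict
  expect_true(all(c("g2", "g6") %in% sets$DEG_down))

  # top 10% by |log2fc| on a 20-gene fixture selects the top 2
  set.seed(111)
  rec20 <- data.frame(gene_id = sprintf("t%02d", 1:20),
                      counts_veg = 500, counts_s24 = 500,
                      log2fc = rnorm(20), padj = runif(20))
  top <- classify_gene_sets(rec20)$highly_regulated
  expect_equal(sort(top),
               sort(rec20$gene_id[order(-abs(rec20$log2fc))][1:2]))

  # fpkm_flag restricts the ranking pool
  rec20$fpkm_flag <- c(rep(TRUE, 10), rep(FALSE, 10))
  top_f <- classify_gene_sets(rec20)$highly_regulated
  expect_true(all(top_f %in% rec20$gene_id[1:10]))

  rec_bad <- rec; rec_bad$padj[2] <- NA
  expect_error(classify_gene_sets(rec_bad), "g2")
})

test_that("amount-expression correlation behaves like Pearson's r", {
  rec <- data.frame(gene_id = paste0("g", 1:10), amount_A = 0,
                    amount_B = seq(0.1, 1, 0.1),
                    log2fc = 3 * seq(0.1, 1, 0.1))
  expect_equal(amount_expression_correlation(rec)$r, 1.0)
  rec$log2fc <- -rec$log2fc
  expect_equal(amount_expression_correlation(rec)$r, -1.0)

  # affine invariance
  set.seed(121)
  rec2 <- data.frame(gene_id = paste0("g", 1:200), amount_A = runif(200),
                     amount_B = runif(200), log2fc = rnorm(200))
  r1 <- amount_expression_correlation(rec2)$r
  rec3 <- rec2
  rec3$log2fc <- 5 * rec3$log2fc + 2
  expect_equal(amount_expression_correlation(rec3)$r, r1)

  expect_error(amount_expression_correlation(rec2[1:2, ]), "at least 3")
  rec4 <- rec2; rec4$log2fc <- 1
  expect_error(amount_expression_correlation(rec4), "zero variance")
})

test_that("simulated coupling is recovered by the correlation estimate", {
  n <- 2000
  rho <- 0.3
  cfg <- sim_config(seed = 77,
                    expression = list(beta = beta_for_rho(rho), noise_sd = 1,
                                      base_mean = 800, base_size = 5,
                                      n_perm = 500))
  set.seed(131)
  truth <- data.frame(gene_id = sprintf("g%04d", 1:n),
                      amount_change = rnorm(n))
  expr <- simulate_expression(cfg, truth)
  rec <- data.frame(gene_id = expr$gene_id, amount_A = 0,
                    amount_B = truth$amount_change, log2fc = expr$log2fc)
  r <- amount_expression_correlation(rec)$r
  expect_lt(abs(r - rho), 3 / sqrt(n))
})
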