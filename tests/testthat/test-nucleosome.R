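test_that("fragment midpoints become dyads and the length gate applies", {
  frags <- data.frame(chrom = "c1", start = c(100L, 0L, 500L),
                      end = c(247L, 80L, 690L))
  expect_message(d <- fragments_to_dyads(frags), "discarded 2")
  expect_equal(d$pos, 173L)

  # all in gate: midpoints exactly
  frags2 <- data.frame(chrom = "c1", start = c(0L, 10L), end = c(150L, 157L))
  d2 <- fragments_to_dyads(frags2)
  expect_equal(d2$pos, c(75L, 83L))

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("c1\t100\t247", "c1\tx\t200"), bed)
  expect_error(read_bed_fragments(bed), "line 2")
  writeLines(c("c1\t100"), bed)
  expect_error(read_bed_fragments(bed), "line 1")
})

test_that("dyad recovery from simulated fragments peaks at the truth", {
  cfg <- sim_config(seed = 5)
  g <- toy_genome(c1 = random_seq(30000))
  genes <- toy_genes("c1", 10000L, 13000L, "+")
  frags <- simulate_mnase(cfg, g, genes, jitter_sd = 5)
  dyads <- fragments_to_dyads(frags)
  # dyads near the first true dyad (tss + 100) centre on it
  near <- dyads$pos[abs(dyads$pos - 10100) <= 50]
  expect_gt(length(near), 5)
  expect_lt(abs(mean(near) - 10100), 5)
})

test_that("composite dyad profile accumulates, smooths and normalises", {
  g <- toy_genome(c1 = random_seq(5000))
  genes <- toy_genes("c1", 2000L, 3500L, "+")
  one <- data.frame(chrom = "c1", pos = 2000L)
  prof <- composite_dyad_profile(one, genes, smooth = 1)
  expect_equal(sum(prof$density), 1)
  expect_equal(prof$position[prof$density > 0], 0)  # delta at the TSS

  # uniform dyads give a flat profile
  unif <- data.frame(chrom = "c1", pos = 0:4999)
  pu <- composite_dyad_profile(unif, genes, smooth = 1)
  expect_true(all(abs(pu$density - 1 / 2000) < 1e-12))

  expect_error(composite_dyad_profile(one, genes, smooth = 4), "odd")

  # phased simulation: peaks near 100, 300, 500 downstream
  cfg <- sim_config(seed = 6)
  genes2 <- toy_genes("c1", c(1000L, 2500L), c(2200L, 3900L), c("+", "-"))
  frags <- simulate_mnase(cfg, g, genes2, jitter_sd = 8)
  prof2 <- composite_dyad_profile(fragments_to_dyads(frags), genes2)
  deg <- positioning_degree(prof2, k_max = 3)
  expect_true(all(abs(deg$peak_pos - c(100, 300, 500)) <= 15))
})

test_that("positioning degree: flat is 0, ideal is 1, cosine matches closed form", {
  x <- -500:1499
  flat <- dyad_profile(x, rep(1, length(x)))
  degf <- positioning_degree(flat)
  expect_equal(degf$degree, rep(0, 5))

  # ideal periodic profile with zero-density troughs
  ideal <- dyad_profile(x, ifelse(((x - 100) %% 200 == 0) & x >= 0, 1, 0))
  expect_equal(positioning_degree(ideal)$degree, rep(1, 5))

  # cosine of amplitude a over mean m: degree = (a c) / m where c is the
  # discrete averaging attenuation over +/-20 bp (Dirichlet kernel)
  m <- 5; a <- 1; L <- 200
  v <- m + a * cos(2 * pi * (x - 100) / L)
  profc <- dyad_profile(x, v, normalize = FALSE)
  w <- 20
  c_att <- mean(cos(2 * pi * (-w:w) / L))
  got <- positioning_degree(profc)$degree
  expect_equal(got, rep(a * c_att / m, 5), tolerance = 1e-6)

  # invariance under positive rescaling
  prof2 <- dyad_profile(x, 7.3 * v, normalize = FALSE)
  expect_equal(positioning_degree(prof2)$degree, got)
})

test_that("positioning degree decreases monotonically with dyad jitter", {
  g <- toy_genome(c1 = random_seq(60000))
  genes <- toy_genes("c1", seq(5000L, 50000L, 5000L),
                     seq(5000L, 50000L, 5000L) + 3000L,
                     rep(c("+", "-"), 5))
  deg1 <- vapply(c(5, 25, 60), function(j) {
    cfg <- sim_config(seed = 42)
    frags <- simulate_mnase(cfg, g, genes, jitter_sd = j)
    prof <- composite_dyad_profile(fragments_to_dyads(frags), genes)
    positioning_degree(prof, k_max = 1)$degree
  }, numeric(1))
  expect_true(all(diff(deg1) < 0))
})

test_that("periodicity is recovered from phased profiles and refused for noise", {
  x <- -500:1499
  cos200 <- dyad_profile(x, 2 + cos(2 * pi * x / 200), normalize = FALSE)
  expect_lt(abs(estimate_periodicity(cos200) - 200), 1)

  set.seed(141)
  noise <- dyad_profile(x, abs(rnorm(length(x))) + 0.5, normalize = FALSE)
  expect_error(estimate_periodicity(noise), "aperiodic")

  # damped oscillation + noise, simulated dyad spacings 150/200/250
  for (s in c(150, 200, 250)) {
    cfg <- sim_config(seed = 8,
                      nucleosome = list(spacing = as.integer(s), offset = 100L,
                                        n_nuc = 8L, jitter_sd = 15,
                                        frags_per_dyad = 30,
                                        frag_len_mean = 147, frag_len_sd = 12))
    g <- toy_genome(c1 = random_seq(60000))
    genes <- toy_genes("c1", seq(5000L, 50000L, 5000L),
                       seq(5000L, 50000L, 5000L) + 3000L,
                       rep(c("+", "-"), 5))
    frags <- simulate_mnase(cfg, g, genes)
    prof <- composite_dyad_profile(fragments_to_dyads(frags), genes,
                                   window = c(-500, 4 * s))
    expect_lt(abs(estimate_periodicity(prof) - s), 0.05 * s + 1e-9)
  }
})

test_that("6mA positions between dyads use interval-relative coordinates", {
  dyads <- data.frame(chrom = "c1", pos = c(1000L, 1200L, 1400L, 2500L))
  cls <- structure(data.frame(chrom = "c1",
                              pos = c(1100L, 1200L, 1300L, 2000L, 100L),
                              strand = "+",
                              frac = c(0.9, 0.9, 0.5, 0.5, 0.5)),
                   class = c("ClassifiedSites", "data.frame"))
  cls$level_bin <- bin_level(cls$frac)
  cls$class <- factor("asymmetric", levels = c("symmetric", "asymmetric",
                                               "nonApT"))
  rel <- dyad_relative_6ma(cls, dyads)
  expect_equal(rel$pos, c(1100L, 1200L, 1300L))
  expect_equal(rel$rel_pos, c(0.5, 0, 0.5))
  # the 1400-2500 gap (1100 bp) exceeds max_gap; site before first dyad
  # has no flanking pair
  expect_false(any(rel$pos %in% c(2000L, 100L)))

  # single-dyad chromosome is skipped with a message
  d1 <- data.frame(chrom = "c1", pos = 1000L)
  expect_message(out <- dyad_relative_6ma(cls, d1), "fewer than 2")
  expect_equal(nrow(out), 0)

  # linker-enriched placement: mode at 0.5
  set.seed(151)
  dy <- data.frame(chrom = "c1", pos = seq(0L, 40000L, 200L))
  linker_pos <- rep(dy$pos[-1], each = 3) - 100L +
    round(rnorm(3 * (nrow(dy) - 1), 0, 15))
  cl2 <- structure(data.frame(chrom = "c1",
                              pos = pmax(1L, linker_pos), strand = "+",
                              frac = 0.9),
                   class = c("ClassifiedSites", "data.frame"))
  cl2$level_bin <- bin_level(cl2$frac)
  cl2$class <- factor("asymmetric", levels = c("symmetric", "asymmetric",
                                               "nonApT"))
  rel2 <- dyad_relative_6ma(cl2, dy)
  h <- hist(rel2$rel_pos, breaks = seq(0, 1, 0.1), plot = FALSE)
  expect_equal(which.max(h$counts), 5)  # densest decile straddles 0.4-0.5
})

test_that("gene-set positioning comparison detects sharper phasing", {
  g <- toy_genome(c1 = random_seq(120000))
  starts <- seq(5000L, 110000L, 5000L)
  genes <- toy_genes("c1", starts, starts + 3000L,
                     rep(c("+", "-"), length(starts) / 2))
  gain <- genes$gene_id[1:11]
  loss <- genes$gene_id[12:22]
  cfg <- sim_config(seed = 43)
  frags <- rbind(
    simulate_mnase(cfg, g, genes[genes$gene_id %in% gain, ], jitter_sd = 5),
    simulate_mnase(sim_config(seed = 44), g,
                   genes[genes$gene_id %in% loss, ], jitter_sd = 35))
  dyads <- fragments_to_dyads(frags)
  cmp <- suppressWarnings(
    compare_positioning(list(gain = gain, loss = loss), dyads, genes))
  expect_gt(cmp$diff[["plus1"]], 0)
  expect_gt(cmp$diff[["plus1_3"]], 0)

  # identical sets: zero difference
  cmp0 <- suppressWarnings(
    compare_positioning(list(gain = gain, loss = gain), dyads, genes))
  expect_equal(unname(cmp0$diff), c(0, 0))

  # empty set warns and is skipped
  w <- capture_warnings(
    cmp1 <- compare_positioning(list(gain = gain, loss = character()),
                                dyads, genes))
  expect_true(any(grepl("empty", w)))
  expect_null(cmp1$diff)
  expect_named(cmp1$degrees, "gain")
})
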