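test_that("duplex classification distinguishes symmetric, asymmetric and non-ApT", {
  g <- toy_genome(c1 = "CATG")
  both <- classify_sites(toy_calls("c1", c(1L, 2L), c("+", "-")), g)
  expect_equal(as.character(both$class), c("symmetric", "symmetric"))
  expect_equal(unique(both$duplex_id), "c1:1")

  one <- classify_sites(toy_calls("c1", 1L, "+"), g)
  expect_equal(as.character(one$class), "asymmetric")

  non <- classify_sites(toy_calls("c1", 1L, "+"), toy_genome(c1 = "CAAG"))
  expect_equal(as.character(non$class), "nonApT")
  expect_true(is.na(non$duplex_id))

  # a call sitting on a non-adenine reference is a hard error
  expect_error(classify_sites(toy_calls("c1", 0L, "+"), g), "non-adenine")
})

test_that("level binning is left-closed with L5 closed at 1", {
  expect_equal(as.character(bin_level(c(0, 0.19999, 0.2, 0.4, 0.6, 0.8, 1))),
               c("L1", "L1", "L2", "L3", "L4", "L5", "L5"))
  expect_error(bin_level(1.2), "\\[0, 1\\]")
  expect_error(bin_level(-0.1), "\\[0, 1\\]")

  set.seed(21)
  x <- runif(5000)
  bins <- bin_level(x)
  brute <- cut(x, c(0, 0.2, 0.4, 0.6, 0.8, 1.0000001), right = FALSE,
               labels = c("L1", "L2", "L3", "L4", "L5"))
  expect_equal(as.character(bins), as.character(brute))
})

test_that("composition arithmetic reproduces percentage conventions", {
  s <- composition_from_counts(symmetric_pairs = 2, asymmetric = 1,
                               non_apt = 1,
                               level_counts = c(0, 0, 0, 1, 5))
  expect_equal(s$total, 6)
  expect_equal(unname(s$class_pct), c(66.7, 16.7, 16.7))
  expect_equal(unname(s$level_pct), c(0, 0, 0, 16.7, 83.3))

  one <- composition_from_counts(symmetric_pairs = 0, asymmetric = 1,
                                 non_apt = 0)
  expect_equal(unname(one$class_pct), c(0, 100, 0))

  # summarising classified sites matches hand counts
  g <- toy_genome(c1 = "CATGCATG")
  cls <- classify_sites(toy_calls("c1", c(1L, 2L, 5L), c("+", "-", "+"),
                                  frac = c(0.9, 0.9, 0.3)), g)
  s2 <- summarize_composition(cls, g)
  expect_equal(unname(s2$class_counts), c(2, 1, 0))
  expect_equal(sum(s2$level_counts), s2$total)
  # density: 3 methylated of 4 strand-resolved adenines (2 A + 2 T)
  expect_equal(s2$density_pct, 100 * 3 / 4)
})

test_that("symmetric adenine counts are even and percentages sum to 100", {
  set.seed(31)
  g <- toy_genome(c1 = random_seq(20000))
  dup <- index_apt_duplexes(g)
  pick <- dup[sample.int(nrow(dup), 300), ]
  # methylate both adenines for half the duplexes, one for the rest
  full <- pick[1:150, ]; hemi <- pick[151:300, ]
  calls <- toy_calls("c1",
                     pos = c(full$watson_pos, full$crick_pos, hemi$watson_pos),
                     strand = c(rep("+", 150), rep("-", 150), rep("+", 150)),
                     frac = runif(450))
  cls <- classify_sites(calls, g)
  expect_equal(sum(cls$class == "symmetric") %% 2, 0)
  s <- summarize_composition(cls)
  expect_lt(abs(sum(s$class_pct) - 100), 0.15)
  expect_lt(abs(sum(s$level_pct) - 100), 0.3)
  # every asymmetric site's partner is absent from the call set
  asym <- cls[cls$class == "asymmetric", ]
  partner <- ifelse(asym$strand == "+",
                    paste(asym$chrom, asym$pos + 1, "-"),
                    paste(asym$chrom, asym$pos - 1, "+"))
  expect_false(any(partner %in% paste(cls$chrom, cls$pos, cls$strand)))
})

test_that("apt_fraction complements the non-ApT percentage", {
  s <- composition_from_counts(symmetric_pairs = 40, asymmetric = 10,
                               non_apt = 10)
  expect_equal(apt_fraction(s),
               c(apt_pct = 90.0, non_apt_pct = 10.0))
  s0 <- composition_from_counts(symmetric_pairs = 5, asymmetric = 2,
                                non_apt = 0)
  expect_equal(apt_fraction(s0), c(apt_pct = 100.0, non_apt_pct = 0.0))
})

test_that("per-bin chromosome density equals a brute-force recount", {
  g <- toy_genome(c1 = "AAAA")
  cls <- classify_sites(toy_calls("c1", 0L, "+", frac = 0.5), g)
  d <- chromosome_density(cls, g, bin_size = 1000)
  expect_equal(d$a_count, 4)              # 4 Watson A, no T
  expect_equal(d$density, 0.25)

  # zero-adenine bin is NA, not 0
  g2 <- toy_genome(c1 = paste0(strrep("G", 1000), "AATT"))
  cls2 <- classify_sites(toy_calls("c1", 1001L, "+"), g2)
  d2 <- chromosome_density(cls2, g2, bin_size = 1000)
  expect_true(is.na(d2$density[1]))
  expect_equal(d2$meth_count, c(0, 1))

  set.seed(41)
  g3 <- toy_genome(c1 = random_seq(5000))
  dup <- index_apt_duplexes(g3)
  pick <- dup[sample.int(nrow(dup), 100), ]
  cls3 <- classify_sites(toy_calls("c1", pick$watson_pos, "+"), g3)
  d3 <- chromosome_density(cls3, g3, bin_size = 500)
  chars <- strsplit(g3$seqs[["c1"]], "")[[1]]
  for (b in seq_len(nrow(d3))) {
    idx <- seq(d3$bin_start[b] + 1, min(d3$bin_start[b] + 500, 5000))
    expect_equal(d3$a_count[b], sum(chars[idx] %in% c("A", "T")))
    expect_equal(d3$meth_count[b],
                 sum(pick$watson_pos >= d3$bin_start[b] &
                       pick$watson_pos < d3$bin_start[b] + 500))
  }
  expect_error(chromosome_density(cls3, g3, bin_size = 0), "positive")
})

test_that("motif matrix is strand-oriented 5'->3' around the methylated A", {
  mid <- strrep("G", 20)
  g <- toy_genome(c1 = paste0(mid, "CCATGG", mid))
  cls <- classify_sites(toy_calls("c1", 22L, "+"), g)
  m <- motif_matrix(cls, g, flank = 2)
  expect_equal(colnames(m), c("-2", "-1", "0", "1", "2"))
  expect_equal(m["A", "0"], 1)
  expect_equal(m["T", "1"], 1)
  expect_equal(unname(colSums(m)), rep(1, 5))

  # all-ApT input: T frequency at +1 is 1
  set.seed(51)
  g2 <- toy_genome(c1 = random_seq(10000))
  dup <- index_apt_duplexes(g2)
  dup <- dup[dup$watson_pos > 20 & dup$watson_pos < 9970, ]
  pick <- dup[sample.int(nrow(dup), 200), ]
  cls2 <- classify_sites(toy_calls("c1", pick$watson_pos, "+"), g2)
  m2 <- motif_matrix(cls2, g2)
  expect_equal(m2["T", "1"] / sum(m2[, "1"]), 1)

  # mixed strands on a palindromic context give the Watson-only matrix
  pal <- paste0(strrep("C", 20), "AT", strrep("G", 20))
  g3 <- toy_genome(c1 = pal, c2 = pal)
  mixed <- classify_sites(toy_calls(c("c1", "c2"), c(20L, 21L), c("+", "-")),
                          g3)
  watson <- classify_sites(toy_calls(c("c1", "c2"), c(20L, 20L), c("+", "+")),
                           g3)
  mm <- motif_matrix(mixed, g3)
  # c2's Crick window is the reverse complement of the Watson context:
  # revcomp(C20 AT G20) centred on the Crick A reads C20 AT G20 again
  expect_equal(mm, motif_matrix(watson, g3))
})

test_that("classification recovers simulated class labels exactly", {
  cfg <- sim_config(seed = 99, chrom_lengths = c(cA = 60000L, cB = 40000L),
                    n_duplexes = 1500, n_nonapt = 400)
  sim <- simulate_genome(cfg, with_genes = FALSE)
  cs <- simulate_callsets(cfg, sim$genome)
  for (cond in c("A", "B")) {
    calls <- if (cond == "A") cs$calls_A else cs$calls_B
    cls <- classify_sites(calls, sim$genome)
    truth <- cs$truth$adenines
    key <- paste(truth$chrom, truth$pos, truth$strand)
    got <- as.character(cls$class[match(key, paste(cls$chrom, cls$pos,
                                                   cls$strand))])
    want <- truth[[paste0("class_", cond)]]
    keep <- want != "unmethylated"
    expect_equal(got[keep], want[keep])
    expect_true(all(is.na(got[!keep])))
  }
})
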