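test_that("dwell model matches closed forms", {
  tx <- toy_txome(strrep("A", 99))   # 100 codons incl stop
  base <- sim_config(stop_pause = 1, te = c())

  base$stall_sites <- data.frame(gene = character(0), codon = integer(0),
                                 ko_factor = numeric(0),
                                 wt_factor = numeric(0))
  expect_equal(simulate_dwell(tx, base, "WT")$G1, rep(1 / 100, 100))

  site <- base
  site$stall_sites <- data.frame(gene = "G1", codon = 50L,
                                 ko_factor = 10, wt_factor = 2)
  ko <- simulate_dwell(tx, site, "KO")$G1
  expect_equal(ko[51], 10 / 109)
  expect_equal(ko[1], 1 / 109)
  wt <- simulate_dwell(tx, site, "WT")$G1
  expect_equal(wt[51], 2 / 101)
  expect_equal(simulate_dwell(tx, site, "RESCUE")$G1, wt)

  bad <- site
  bad$stall_sites$codon <- 500L
  expect_error(simulate_dwell(tx, bad, "KO"), "outside ORF")
})

test_that("noiseless sampling hits expectations exactly", {
  tx <- toy_txome(strrep("A", 99), lead = 30, tail = 30)
  cfg <- sim_config(depth = 10, noise = "none", stop_pause = 1, te = c(),
                    stall_sites = data.frame(gene = character(0),
                                             codon = integer(0),
                                             ko_factor = numeric(0),
                                             wt_factor = numeric(0)))
  fp <- sample_footprints(simulate_dwell(tx, cfg, "WT"), tx, cfg)
  asn <- assign_asites(fp, cfg$true_offsets, tx)
  expect_equal(nrow(asn), 100)
  expect_true(all(asn$count == 10))
  expect_equal(attr(fp, "clipped"), 0)
})

test_that("simulation is deterministic in the seed, truth regardless", {
  tx <- load_human_txome()
  cfg <- sim_config(seed = 21, depth = 20,
                    stall_sites = default_stall_sites(tx))
  d1 <- make_dataset(tx, cfg)
  d2 <- make_dataset(tx, cfg)
  expect_identical(d1$footprints, d2$footprints)

  cfg2 <- cfg
  cfg2$seed <- 22L
  d3 <- make_dataset(tx, cfg2)
  expect_false(identical(d3$footprints$WT, d1$footprints$WT))
  expect_identical(d3$truth$expected, d1$truth$expected)

  out1 <- tempfile(); out2 <- tempfile()
  make_dataset(tx, cfg, out_dir = out1)
  make_dataset(tx, cfg, out_dir = out2)
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), info = f)
  }
})

test_that("Poisson sampling is unbiased within Monte-Carlo bounds", {
  tx <- toy_txome(strrep("LIVA", 25), lead = 30, tail = 30)  # 101 codons
  cfg <- sim_config(depth = 100, stop_pause = 1, te = c(),
                    stall_sites = data.frame(gene = character(0),
                                             codon = integer(0),
                                             ko_factor = numeric(0),
                                             wt_factor = numeric(0)))
  expected <- simulate_dwell(tx, cfg, "WT")
  n_seeds <- 10
  mat <- sapply(seq_len(n_seeds), function(s) {
    fp <- sample_footprints(expected, tx, cfg, seed = 100 + s)
    p <- build_profile(assign_asites(fp, cfg$true_offsets, tx), "G1", tx)
    p$counts
  })
  lambda <- 100 * expected$G1 * length(expected$G1)   # = 100 per codon
  se <- sqrt(lambda / n_seeds)
  within3 <- abs(rowMeans(mat) - lambda) <= 3 * se
  expect_gte(mean(within3), 0.97)
})

test_that("default truth targets the polyproline sites, COX1 3xPro included", {
  tx <- load_human_txome()
  sites <- default_stall_sites(tx)
  expect_equal(nrow(sites), 15)
  cox1_3x <- sites[sites$gene == "COX1" & sites$ko_factor == 16, ]
  expect_equal(cox1_3x$codon, 500)   # last proline of the GCPPP run
  expect_true(all(sites$ko_factor > sites$wt_factor))

  # proline-free transcriptome cannot host auto-discovered stalls
  expect_error(default_stall_sites(toy_txome(strrep("LIVA", 10))),
               "proline-free")
})

test_that("zero depth yields empty footprints but a valid truth table", {
  tx <- load_human_txome()
  cfg <- sim_config(seed = 1, depth = 0)
  ds <- make_dataset(tx, cfg)
  expect_equal(nrow(ds$footprints$KO), 0)
  expect_equal(nrow(ds$truth$stall_sites), 15)
  expect_equal(sum(ds$truth$expected$WT$COX1), 3)   # te weight preserved
})

test_that("reads clipped at transcript bounds are dropped and logged", {
  tx <- toy_txome(strrep("A", 30), lead = 5, tail = 5)  # lead < offsets
  cfg <- sim_config(depth = 10, noise = "none", stop_pause = 1, te = c(),
                    stall_sites = data.frame(gene = character(0),
                                             codon = integer(0),
                                             ko_factor = numeric(0),
                                             wt_factor = numeric(0)))
  fp <- sample_footprints(simulate_dwell(tx, cfg, "WT"), tx, cfg)
  expect_gt(attr(fp, "clipped"), 0)
  expect_true(all(fp$five_prime >= 0))
  expect_true(all(fp$five_prime + fp$length <= nchar(tx$seqs[[1]])))
})

test_that("simulated reads re-align exactly with the naive aligner", {
  tx <- toy_txome("MKLFGASTVWYHQDENRCIPAVILMFWYGHKRDESTNQCA",
                  lead = 30, tail = 30)
  cfg <- sim_config(seed = 3, depth = 5, stop_pause = 1, te = c(),
                    stall_sites = data.frame(gene = character(0),
                                             codon = integer(0),
                                             ko_factor = numeric(0),
                                             wt_factor = numeric(0)))
  fp <- sample_footprints(simulate_dwell(tx, cfg, "WT"), tx, cfg,
                          return_reads = TRUE)
  reads <- attr(fp, "reads")
  expect_equal(length(reads), sum(fp$count))
  aligned <- align_exact(reads, tx)
  expect_equal(as.data.frame(aligned), as.data.frame(fp),
               ignore_attr = TRUE)
})
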