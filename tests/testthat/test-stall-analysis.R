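test_that("genotype ratio profile behaves at identity, spikes and zeros", {
  wt <- profile_from_counts(c(10, 10, 10, 0))
  expect_equal(genotype_ratio_profile(wt, wt), rep(1, 4))

  ko <- profile_from_counts(c(10, 100, 10, 0))
  r <- genotype_ratio_profile(wt, ko, pseudocount = 1e-9)
  expect_equal(r[2], (100 / 120) / (10 / 30), tolerance = 1e-6)
  expect_equal(r[4], 1)    # zero in both genotypes -> p/p

  expect_error(
    genotype_ratio_profile(wt, profile_from_counts(c(1, 1))), "length")
})

test_that("noiseless implanted stalls are called exactly, nulls are clean", {
  tx <- load_human_txome()
  sites <- data.frame(gene = "COX1", codon = c(107L, 174L, 500L),
                      ko_factor = 8, wt_factor = 2)
  cfg <- sim_config(seed = 4, depth = 100, noise = "none",
                    stall_sites = sites)
  ds <- make_dataset(tx, cfg)
  profs <- run_pipeline_profiles(ds, tx)
  ev <- call_stall_events(profs$WT, profs$KO, tx)
  expect_equal(ev$gene, rep("COX1", 3))
  expect_equal(ev$codon, sites$codon)

  # identical genotypes: no events
  expect_equal(nrow(call_stall_events(profs$WT, profs$WT, tx)), 0)
})

test_that("null Poisson simulations produce no stall events", {
  tx <- load_human_txome()
  null_sites <- data.frame(gene = character(0), codon = integer(0),
                           ko_factor = numeric(0), wt_factor = numeric(0))
  for (seed in 1:3) {
    cfg <- sim_config(seed = seed, depth = 100, stall_sites = null_sites)
    ds <- make_dataset(tx, cfg)
    profs <- run_pipeline_profiles(ds, tx)
    ev <- call_stall_events(profs$WT, profs$KO, tx)
    expect_equal(nrow(ev), 0, info = paste("seed", seed))
  }
})

test_that("stall calling is invariant to uniform depth scaling", {
  tx <- load_human_txome()
  cfg <- sim_config(seed = 6, depth = 100,
                    stall_sites = default_stall_sites(tx))
  ds <- make_dataset(tx, cfg)
  profs <- run_pipeline_profiles(ds, tx)
  ev1 <- call_stall_events(profs$WT, profs$KO, tx)

  scale_profiles <- function(pl, f) lapply(pl, function(p)
    profile_from_counts(p$counts * f, gene = p$gene))
  ev2 <- call_stall_events(scale_profiles(profs$WT, 3L),
                           scale_profiles(profs$KO, 3L), tx)
  expect_equal(ev2[, c("gene", "codon")], ev1[, c("gene", "codon")])
  expect_equal(ev2$ratio, ev1$ratio, tolerance = 1e-9)
})

test_that("rescue flags follow the reconstituted profiles", {
  tx <- load_human_txome()
  sites <- data.frame(gene = c("COX1", "COX1", "COX3"),
                      codon = c(107L, 500L, 74L),
                      ko_factor = 8, wt_factor = 2)
  cfg <- sim_config(seed = 8, depth = 100, noise = "none",
                    stall_sites = sites)
  ds <- make_dataset(tx, cfg)
  profs <- run_pipeline_profiles(ds, tx)
  ev <- call_stall_events(profs$WT, profs$KO, tx)
  expect_equal(nrow(ev), 3)

  all_resc <- rescue_check(ev, profs$WT, profs$WT)
  expect_true(all(all_resc$rescued))
  none <- rescue_check(ev, profs$WT, profs$KO)
  expect_false(any(none$rescued))

  # mixed: reconstituted resolves COX1 stalls but not the COX3 one
  mixed <- profs$RESCUE
  mixed[["COX3"]] <- profs$KO[["COX3"]]
  got <- rescue_check(ev, profs$WT, mixed)
  expect_equal(got$rescued, c(TRUE, TRUE, FALSE))

  untested <- rescue_check(ev, profs$WT, profs$RESCUE["COX1"])
  expect_true(is.na(untested$rescued[untested$gene == "COX3"]))
})

test_that("trailing proline-window labels match hand enumeration", {
  expect_equal(proline_window_labels("AAAAPAAAAA"),
               c(0, 0, 0, 0, 1, 1, 1, 1, 1, 0))
  expect_equal(proline_window_labels("PPPPP"), c(1, 2, 3, 3, 3))
  expect_equal(max(proline_window_labels("APAPAPAPA", cap = 3)), 3)
})

test_that("proline-free uniform occupancy sits entirely in group 0", {
  tx <- toy_txome(strrep("LIVA", 10))
  n <- orf_n_codons(tx$orfs[1, ])
  p <- profile_from_counts(rep(5, n))
  sc <- proline_window_scores(list(WT = list(G1 = p), KO = list(G1 = p)),
                              tx)
  expect_equal(sc$wt_sum[sc$group == 0],
               sum(p$rel_within[seq_len(n - 1)]))
  expect_equal(sc$wt_sum[sc$group > 0], rep(0, 3))
  expect_equal(sc$ko_ratio_to_wt[sc$group == 0], 1)
})

test_that("group sums conserve total in-window relative occupancy", {
  tx <- load_human_txome()
  cfg <- sim_config(seed = 9, depth = 50,
                    stall_sites = default_stall_sites(tx))
  ds <- make_dataset(tx, cfg)
  profs <- run_pipeline_profiles(ds, tx)
  sc <- proline_window_scores(profs[c("WT", "KO")], tx)
  for (geno in c("wt", "ko")) {
    col <- paste0(geno, "_sum")
    total <- sum(vapply(profs[[toupper(geno)]], function(p) {
      lab_n <- nchar(translate_orf(tx, p$gene))
      sum(p$rel_within[seq_len(lab_n)])
    }, 0))
    expect_equal(sum(sc[[col]]), total, tolerance = 1e-12)
  }
})
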