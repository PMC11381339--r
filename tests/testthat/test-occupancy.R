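test_that("A-site assignment maps 5' end + offset to the right codon", {
  tx <- toy_txome(strrep("LIVA", 30), lead = 10, tail = 40)  # ORF start 10
  fp <- footprints("tx1", 100L, 32L)
  asn <- assign_asites(fp, c("32" = 15L), tx)
  expect_equal(asn$codon, (100 + 15 - 10) %/% 3)   # codon 35
  expect_equal(asn$count, 1)
})

test_that("footprints in a bicistronic overlap feed both ORF profiles", {
  # ORF "down" starts out of frame inside ORF "up", like ATP8/ATP6
  seqs <- c(bi = paste0(aa2nt("MAAAAAAAAP*"), strrep("A", 40)))
  orfs <- data.frame(transcript_id = "bi", gene = c("up", "down"),
                     start = c(0L, 25L), end = c(33L, 55L),
                     stop_completed_by_polyA = c(FALSE, FALSE))
  tx <- txome_from(seqs, orfs)
  fp <- footprints("bi", 11L, 32L)   # A-site nt 27: in both ORFs
  asn <- assign_asites(fp, c("32" = 16L), tx)
  expect_setequal(asn$gene, c("up", "down"))
  expect_equal(asn$codon[asn$gene == "up"], (27 - 0) %/% 3)
  expect_equal(asn$codon[asn$gene == "down"], (27 - 25) %/% 3)
  rep <- attr(asn, "drop_report")
  expect_equal(unname(rep["assigned"]), 1)  # one footprint, counted once
})

test_that("unknown lengths and out-of-ORF A-sites are dropped and counted", {
  tx <- toy_txome(strrep("LIVA", 10), lead = 30, tail = 30)
  fp <- footprints(rep("tx1", 3), c(30L, 0L, 30L), c(32L, 32L, 29L),
                   c(1L, 2L, 4L))
  asn <- assign_asites(fp, c("32" = 15L), tx)
  rep <- attr(asn, "drop_report")
  expect_equal(unname(rep["input"]), 7)
  expect_equal(unname(rep["unassigned_length"]), 4)   # length 29
  expect_equal(unname(rep["out_of_orf"]), 2)          # A-site at nt 15
  expect_equal(unname(rep["assigned"]), 1)
  expect_equal(sum(rep[c("assigned", "unassigned_length", "out_of_orf")]),
               unname(rep["input"]))
})

test_that("profiles normalise within the ORF and flag empty ORFs", {
  tx <- toy_txome("AA", lead = 0, tail = 10)   # 3 codons incl stop
  asn <- data.frame(gene = c("G1", "G1"), codon = c(0L, 2L),
                    count = c(2L, 2L))
  p <- build_profile(asn, "G1", tx)
  expect_equal(p$counts, c(2, 0, 2))
  expect_equal(p$rel_within, c(0.5, 0, 0.5))
  expect_equal(sum(p$rel_within), 1)

  single <- build_profile(data.frame(gene = "G1", codon = 1L, count = 5L),
                          "G1", tx)
  expect_equal(single$rel_within, c(0, 1, 0))

  empty <- build_profile(asn[0, ], "G1", tx)
  expect_equal(empty$n_total, 0)
  expect_equal(empty$rel_within, rep(0, 3))

  bad <- data.frame(gene = "G1", codon = 7L, count = 1L)
  expect_error(build_profile(bad, "G1", tx), "mismatch")
})

test_that("across-transcriptome distribution sums to one", {
  pa <- profile_from_counts(c(10, 20), gene = "A")
  pb <- profile_from_counts(c(70), gene = "B")
  d <- transcriptome_distribution(list(A = pa, B = pb))
  expect_equal(d$rel_across[d$gene == "A"], 0.3)
  expect_equal(d$rel_across[d$gene == "B"], 0.7)
  expect_equal(sum(d$rel_across), 1)

  expect_equal(transcriptome_distribution(list(A = pa))$rel_across, 1)
  zero <- profile_from_counts(c(0, 0), gene = "Z")
  expect_error(transcriptome_distribution(list(Z = zero)), "no mitochondrial")
})

test_that("counts are conserved and normalisations are scale-invariant", {
  tx <- load_human_txome()
  cfg <- sim_config(seed = 5, depth = 30,
                    stall_sites = default_stall_sites(tx))
  fp <- sample_footprints(simulate_dwell(tx, cfg, "KO"), tx, cfg)
  off <- calibrate_offsets(fp, tx)
  asn <- assign_asites(fp, off, tx)
  rep <- attr(asn, "drop_report")
  expect_equal(sum(rep[c("assigned", "unassigned_length", "out_of_orf")]),
               unname(rep["input"]))
  profs <- build_profiles(asn, tx)
  for (p in profs) {
    if (p$n_total > 0) expect_equal(sum(p$rel_within), 1, tolerance = 1e-12)
  }
  expect_equal(sum(transcriptome_distribution(profs)$rel_across), 1,
               tolerance = 1e-12)

  fp2 <- fp
  fp2$count <- fp2$count * 2L
  profs2 <- build_profiles(assign_asites(fp2, off, tx), tx)
  for (g in names(profs)) {
    expect_equal(profs2[[g]]$rel_within, profs[[g]]$rel_within)
  }
  expect_equal(transcriptome_distribution(profs2)$rel_across,
               transcriptome_distribution(profs)$rel_across)
})
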