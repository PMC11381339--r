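test_that("bed-like dialect parses, aggregates and round-trips", {
  f <- tempfile()
  writeLines(c("# a comment", "COX1tx\t100\t33\t4",
               "COX1tx\t100\t33\t1", "tx2\t5\t31\t2"), f)
  fp <- read_footprints(f, "bed")
  expect_equal(nrow(fp), 2)
  r <- fp[fp$transcript_id == "COX1tx", ]
  expect_equal(c(r$five_prime, r$length, r$count), c(100, 33, 5))

  out <- tempfile()
  write_footprints(fp, out, header = "roundtrip")
  fp2 <- read_footprints(out, "bed")
  expect_equal(as.data.frame(fp2), as.data.frame(fp))
})

test_that("malformed bed records fail with their line number", {
  f <- tempfile()
  writeLines(c("tx1\t0\t32\t1", "tx1\t0\t32"), f)
  expect_error(read_footprints(f, "bed"), "line 2")
  writeLines(c("tx1\t0\t32\t1", "tx1\tzero\t32\t1"), f)
  expect_error(read_footprints(f, "bed"), "line 2")
})

test_that("length filter keeps the inclusive window and conserves counts", {
  fp <- footprints(rep("t", 5), 0:4, c(24, 25, 32, 45, 46))
  kept <- filter_lengths(fp)
  expect_equal(sort(kept$length), c(25, 32, 45))
  expect_equal(sum(kept$count) + attr(kept, "removed_count"), sum(fp$count))

  expect_equal(nrow(filter_lengths(footprints(character(0), integer(0),
                                              integer(0)))), 0)
  one <- filter_lengths(footprints(rep("t", 3), 0:2, 31:33), 32, 32)
  expect_equal(one$length, 32)
  expect_error(filter_lengths(fp, 30, 20), "min_len")
})

test_that("footprints past the transcript end are rejected and logged", {
  tx <- toy_txome(strrep("A", 20), lead = 10, tail = 0)
  len <- nchar(tx$seqs[[1]])
  f <- tempfile()
  writeLines(c(paste("tx1", 0, 32, 1, sep = "\t"),
               paste("tx1", len - 10, 32, 3, sep = "\t")), f)
  fp <- read_footprints(f, "bed", txome = tx)
  expect_equal(nrow(fp), 1)
  expect_equal(attr(fp, "rejected")[["out_of_bounds"]], 3)
})

test_that("SAM subset: primary forward records only, soft clips excluded", {
  tx <- toy_txome(strrep("A", 30), lead = 20, tail = 20)
  seq <- tx$seqs[[1]]
  sam <- tempfile(fileext = ".sam")
  rd <- function(pos1, n) substr(seq, pos1, pos1 + n - 1)
  writeLines(c(
    paste0("@SQ\tSN:tx1\tLN:", nchar(seq)),
    paste("r1", 0, "tx1", 11, 42, "32M", "*", 0, 0, rd(11, 32),
          strrep("I", 32), sep = "\t"),
    paste("r2", 0, "tx1", 11, 42, "32M", "*", 0, 0, rd(11, 32),
          strrep("I", 32), sep = "\t"),                      # duplicate
    paste("r3", 0, "tx1", 21, 42, "3S28M2S", "*", 0, 0, rd(21, 33),
          strrep("I", 33), sep = "\t"),                      # soft-clipped
    paste("r4", 16, "tx1", 31, 42, "32M", "*", 0, 0, rd(31, 32),
          strrep("I", 32), sep = "\t"),                      # reverse
    paste("r5", 4, "*", 0, 0, "*", "*", 0, 0, strrep("A", 32),
          strrep("I", 32), sep = "\t")                       # unmapped
  ), sam)
  fp <- read_footprints(sam, "sam", txome = tx)
  expect_equal(nrow(fp), 2)
  dup <- fp[fp$five_prime == 10, ]
  expect_equal(c(dup$length, dup$count), c(32, 2))
  clip <- fp[fp$five_prime == 20, ]
  expect_equal(clip$length, 28)   # aligned span, clips excluded
  expect_equal(attr(fp, "rejected")[["reverse_strand"]], 1)
})

test_that("exact-match aligner places unique reads and reports the rest", {
  tx <- toy_txome("MKLFGASTVWYHQDENRCIPAVILMFWYGHKRDESTNQCA",
                  lead = 25, tail = 25)
  seq <- tx$seqs[[1]]
  uniq <- substr(seq, 31, 63)              # crosses the ORF, unique
  ambi <- "GTGTGTGTGTGTG"                  # repeats inside the GT lead
  reads <- c(uniq, "TTTTTTTTTTTTTTTTTTTTTTTTTTTTTT", ambi)
  fp <- align_exact(reads, tx)
  rep <- attr(fp, "report")
  expect_equal(unname(rep["aligned"]), 1)
  expect_equal(unname(rep["unaligned"]), 1)
  expect_equal(unname(rep["ambiguous"]), 1)
  expect_equal(fp$five_prime, 30)
  expect_equal(fp$length, 33)
})
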