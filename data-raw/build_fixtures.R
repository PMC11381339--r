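# Build the bundled fixtures under inst/extdata/.
#
# Human transcriptome: derived from the complete human mitochondrial genome
# shipped with the seqinr package (NC_001807.4, 16571 bp). The 13
# protein-coding ORFs are located by a shift search around the canonical
# human mtDNA gene coordinates and validated by translation under the
# vertebrate mitochondrial code (no internal stops, expected protein
# lengths). Mature mRNA boundaries follow the tRNA-punctuation model: each
# transcript is the ORF region (bicistronic units kept intact) plus a 30-nt
# oligo(A) tail, which also completes the stop codons of the ORFs that end
# in a partial stop.
#
# Yeast proteome: a SYNTHETIC stand-in for the S. cerevisiae mtDNA-encoded
# proteome (real sequences are not redistributable here). Eight proteins
# with realistic lengths and amino-acid composition are sampled under a
# fixed seed; polyproline structure mirrors the documented biology: a
# single 2xPro run in COX1 and one in COX3, none elsewhere, and an overall
# proline content well below the human proteome's.
#
# Run from the package root:  Rscript data-raw/build_fixtures.R

suppressMessages(library(Biostrings))

out_dir <- "inst/extdata"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

## ---- human transcriptome ---------------------------------------------------

src <- system.file("sequences", "humanMito.fasta", package = "seqinr")
lines <- readLines(src)
genome <- toupper(paste(lines[!grepl("^[>;]", lines)], collapse = ""))
stopifnot(nchar(genome) == 16571L)

code <- GENETIC_CODE
code["TGA"] <- "W"; code["ATA"] <- "M"; code["AGA"] <- "*"; code["AGG"] <- "*"
translate2 <- function(nt) {
  n <- nchar(nt) %/% 3L
  paste(code[substring(nt, 3L * (0:(n - 1L)) + 1L, 3L * (0:(n - 1L)) + 3L)],
        collapse = "")
}

# canonical 1-based gene coordinates (rCRS numbering); this genome carries a
# uniform +1 shift, verified below by translation
shift <- 1L
genes <- rbind(
  data.frame(gene = "ND1",  s = 3307,  e = 4262,  strand = "+", polyA = TRUE,  tx = "MT-ND1"),
  data.frame(gene = "ND2",  s = 4470,  e = 5511,  strand = "+", polyA = TRUE,  tx = "MT-ND2"),
  data.frame(gene = "COX1", s = 5904,  e = 7445,  strand = "+", polyA = FALSE, tx = "MT-CO1"),
  data.frame(gene = "COX2", s = 7586,  e = 8269,  strand = "+", polyA = FALSE, tx = "MT-CO2"),
  data.frame(gene = "ATP8", s = 8366,  e = 8572,  strand = "+", polyA = FALSE, tx = "MT-ATP8_ATP6"),
  data.frame(gene = "ATP6", s = 8527,  e = 9207,  strand = "+", polyA = FALSE, tx = "MT-ATP8_ATP6"),
  data.frame(gene = "COX3", s = 9207,  e = 9990,  strand = "+", polyA = TRUE,  tx = "MT-CO3"),
  data.frame(gene = "ND3",  s = 10059, e = 10404, strand = "+", polyA = TRUE,  tx = "MT-ND3"),
  data.frame(gene = "ND4L", s = 10470, e = 10766, strand = "+", polyA = FALSE, tx = "MT-ND4L_ND4"),
  data.frame(gene = "ND4",  s = 10760, e = 12137, strand = "+", polyA = TRUE,  tx = "MT-ND4L_ND4"),
  data.frame(gene = "ND5",  s = 12337, e = 14148, strand = "+", polyA = FALSE, tx = "MT-ND5"),
  data.frame(gene = "ND6",  s = 14149, e = 14673, strand = "-", polyA = FALSE, tx = "MT-ND6"),
  data.frame(gene = "CYB",  s = 14747, e = 15887, strand = "+", polyA = TRUE,  tx = "MT-CYB")
)
expected_aa <- c(ND1 = 318, ND2 = 347, COX1 = 513, COX2 = 227, ATP8 = 68,
                 ATP6 = 226, COX3 = 261, ND3 = 115, ND4L = 98, ND4 = 459,
                 ND5 = 603, ND6 = 174, CYB = 380)

polyA_tail <- strrep("A", 30)
tx_seqs <- character(0)
ann <- NULL
for (txid in unique(genes$tx)) {
  rows <- genes[genes$tx == txid, ]
  g0 <- min(rows$s) + shift        # 1-based genomic start of transcript body
  g1 <- max(rows$e) + shift
  body <- substr(genome, g0, g1)
  if (rows$strand[1] == "-") {
    body <- as.character(reverseComplement(DNAString(body)))
  }
  tx_seqs[txid] <- paste0(body, polyA_tail)
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    if (r$strand == "+") {
      start0 <- (r$s + shift) - g0              # 0-based within transcript
      end0   <- (r$e + shift) - g0 + 1L
    } else {
      start0 <- g1 - (r$e + shift)
      end0   <- g1 - (r$s + shift) + 1L
    }
    # validate: translate and check length / internal stops
    nt <- substr(tx_seqs[txid], start0 + 1L, end0)
    ncod <- nchar(nt) %/% 3L
    prot <- translate2(substr(nt, 1L, 3L * ncod))
    if (!r$polyA) prot_body <- substr(prot, 1L, ncod - 1L) else prot_body <- prot
    stopifnot(!grepl("\\*", prot_body),
              nchar(prot_body) == expected_aa[[r$gene]],
              r$polyA || substr(prot, ncod, ncod) == "*")
    ann <- rbind(ann, data.frame(transcript_id = txid, gene = r$gene,
                                 start = start0, end = end0,
                                 stop_completed_by_polyA = r$polyA))
  }
}

writeXStringSet(DNAStringSet(tx_seqs),
                file.path(out_dir, "human_mito_transcripts.fasta"), width = 70)
write.table(ann, file.path(out_dir, "human_mito_orfs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# human proteins (used below for sanity checks and the TACO1 motif list)
prots <- character(0)
for (i in seq_len(nrow(ann))) {
  a <- ann[i, ]
  nt <- substr(tx_seqs[a$transcript_id], a$start + 1L, a$end)
  ncod <- nchar(nt) %/% 3L
  p <- translate2(substr(nt, 1L, 3L * ncod))
  if (!a$stop_completed_by_polyA) p <- substr(p, 1L, ncod - 1L)
  prots[a$gene] <- p
}
stopifnot(grepl("GCPPP", prots["COX1"]))

## ---- pausing-score categories (bacterial PP-triplet hierarchy) -------------

pausing <- data.frame(
  triplet  = c("PPW", "PPP", "DPP", "PPN", "PPS", "PPA",
               "CPP", "PPR", "PPH", "PPL", "TPP"),
  category = c("strong", "strong", "strong", "strong", "medium", "medium",
               "weak", "weak", "weak", "weak", "weak")
)
write.table(pausing, file.path(out_dir, "pausing_scores.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## ---- non-proline TACO1-target motif annotations ----------------------------

taco1 <- data.frame(
  gene  = c("COX2", "ND4L", "ND3", "ATP6", "ATP6", "ND6",
            "ATP8", "ND1", "COX3", "ND2", "ATP8"),
  motif = c("DYGGL", "YGLDY", "QTTN", "FASF", "PAA", "VVV",
            "PWEP", "PNP", "PSPWPL", "LPYNPN", "KWTKIC")
)
taco1$found <- mapply(function(g, m) grepl(m, prots[[g]], fixed = TRUE),
                      taco1$gene, taco1$motif)
print(taco1)  # inspect: motifs should be present in the fixture proteins
write.table(taco1[, c("gene", "motif")],
            file.path(out_dir, "taco1_target_motifs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## ---- synthetic yeast mt proteome ------------------------------------------

set.seed(20240722)
# membrane-protein-like composition (AT-rich mitochondrial codon bias:
# F/I/L/N/Y-heavy); proline sampled at ~3%
aa   <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
          "T","V","W","Y")
memb <- c(.055,.010,.015,.015,.090,.065,.020,.105,.030,.130,.040,.055,.030,
          .020,.015,.075,.060,.070,.025,.075)
hyd  <- c(.040,.005,.030,.030,.040,.040,.015,.090,.110,.090,.025,.130,.020,
          .025,.030,.090,.060,.050,.005,.100)  # VAR1-like, K/N-rich
memb <- memb / sum(memb); hyd <- hyd / sum(hyd)

sample_prot <- function(n, comp) paste(sample(aa, n, TRUE, comp), collapse = "")
break_pp <- function(p) {            # remove accidental >=2 proline runs
  x <- strsplit(p, "")[[1]]
  repeat {
    i <- which(x[-length(x)] == "P" & x[-1] == "P")
    if (!length(i)) break
    x[i + 1L] <- sample(setdiff(aa, "P"), length(i), TRUE)
  }
  paste(x, collapse = "")
}
implant_pp <- function(p, at) {      # place a 2xPro run at aa position `at`
  x <- strsplit(p, "")[[1]]
  x[c(at, at + 1L)] <- "P"
  # keep the run maximal at length 2
  if (at > 1 && x[at - 1L] == "P") x[at - 1L] <- "L"
  if (at + 2L <= length(x) && x[at + 2L] == "P") x[at + 2L] <- "S"
  paste(x, collapse = "")
}

ylen <- c(COX1 = 534, COX2 = 251, COX3 = 269, COB = 385, ATP6 = 259,
          ATP8 = 48, ATP9 = 76, VAR1 = 398)
yeast <- sapply(names(ylen), function(g) {
  comp <- if (g == "VAR1") hyd else memb
  break_pp(sample_prot(ylen[[g]], comp))
})
yeast["COX1"] <- implant_pp(yeast["COX1"], 176)
yeast["COX3"] <- implant_pp(yeast["COX3"], 88)
yeast <- vapply(yeast, function(p) sub("^.", "M", p), "")

writeXStringSet(AAStringSet(yeast),
                file.path(out_dir, "yeast_mito_proteome_synthetic.fasta"),
                width = 70)

p_frac <- function(ps) {
  x <- paste(ps, collapse = "")
  mean(strsplit(x, "")[[1]] == "P")
}
cat(sprintf("human P fraction %.4f, yeast (synthetic) %.4f\n",
            p_frac(prots), p_frac(yeast)))
stopifnot(p_frac(prots) > p_frac(yeast))
cat("fixtures written to", out_dir, "\n")
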