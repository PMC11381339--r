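# Shared fixture builders: everything is generated in code at test time.

# reverse lookup: encode an amino-acid string as codons under the
# mitochondrial code (one fixed codon per amino acid; "*" = AGA stop)
aa2nt <- function(aa) {
  tab <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
           G = "GGT", H = "CAT", I = "ATC", K = "AAA", L = "CTT",
           M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
           S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT",
           "*" = "AGA")
  paste(tab[strsplit(aa, "")[[1]]], collapse = "")
}

# single-ORF toy transcriptome: `protein` (without stop) is encoded with a
# complete AGA stop, padded by `lead`/`tail` nt of non-coding sequence
toy_txome <- function(protein = strrep("A", 40), gene = "G1",
                      tx_id = "tx1", lead = 30L, tail = 30L) {
  orf_nt <- aa2nt(paste0(protein, "*"))
  seq <- paste0(substr(strrep("GT", ceiling(lead / 2)), 1, lead),
                orf_nt,
                substr(strrep("CA", ceiling(tail / 2)), 1, tail))
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(paste0(">", tx_id), seq), fa)
  tsv <- tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(transcript_id = tx_id, gene = gene, start = lead,
               end = lead + nchar(orf_nt), stop_completed_by_polyA = FALSE),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  load_transcriptome(fa, tsv)
}

# write an arbitrary transcriptome definition and load it
txome_from <- function(seqs, orfs) {
  fa <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), fa)
  tsv <- tempfile(fileext = ".tsv")
  utils::write.table(orfs, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  load_transcriptome(fa, tsv)
}

# an occupancy_profile directly from a count vector
profile_from_counts <- function(counts, gene = "G1", sample = "s") {
  n_total <- sum(counts)
  structure(list(gene = gene, sample = sample, counts = as.integer(counts),
                 rel_within = if (n_total > 0) counts / n_total
                              else rep(0, length(counts)),
                 n_total = n_total),
            class = "occupancy_profile")
}

# sensitivity / FDR of called events against a stall-site truth table,
# with truth projected into overlapping ORFs
stall_recovery <- function(events, truth, txome) {
  exp_truth <- expand_stall_sites(txome, truth)
  key <- function(d) paste(d$gene, d$codon)
  called_true <- key(events) %in% key(exp_truth)
  recovered <- vapply(seq_len(nrow(truth)), function(i) {
    proj <- expand_stall_sites(txome, truth[i, , drop = FALSE])
    any(key(events) %in% key(proj))
  }, TRUE)
  list(sensitivity = mean(recovered),
       fdr = if (nrow(events)) mean(!called_true) else 0,
       n_called = nrow(events))
}

run_pipeline_profiles <- function(ds, txome) {
  off <- calibrate_offsets(ds$footprints$WT, txome)
  lapply(ds$footprints, function(f)
    build_profiles(assign_asites(f, off, txome), txome))
}
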