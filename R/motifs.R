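#' Maximal proline runs in a protein
#'
#' @param protein amino-acid string.
#' @param gene gene symbol carried into the records.
#' @return data.frame (\code{gene}, \code{kind}, \code{start},
#'   \code{length}, \code{sequence}, \code{context}): one row per maximal
#'   run of consecutive prolines, classified \code{run1}, \code{run2} or
#'   \code{run3plus}; \code{start} is 0-based; \code{context} is the run
#'   with one flanking residue on each side where available.
#' @export
proline_runs <- function(protein, gene = NA_character_) {
  empty <- data.frame(gene = character(0), kind = character(0),
                      start = integer(0), length = integer(0),
                      sequence = character(0), context = character(0),
                      stringsAsFactors = FALSE)
  if (!nchar(protein)) return(empty)
  m <- gregexpr("P+", protein)[[1]]
  if (m[1] == -1) return(empty)
  lens <- attr(m, "match.length")
  start0 <- as.integer(m) - 1L
  ctx_from <- pmax(as.integer(m) - 1L, 1L)
  ctx_to <- pmin(as.integer(m) + lens, nchar(protein))
  data.frame(gene = gene,
             kind = ifelse(lens >= 3L, "run3plus",
                           ifelse(lens == 2L, "run2", "run1")),
             start = start0,
             length = as.integer(lens),
             sequence = substring(protein, m, m + lens - 1L),
             context = substring(protein, ctx_from, ctx_to),
             stringsAsFactors = FALSE)
}

#' PP-containing triplets of a protein
#'
#' Enumerates the tripeptides implied by each maximal run of >= 2 prolines.
#' Two conventions are supported. \code{"per_run"}: one (X)PP triplet from
#' the run's left flank, one PP(X) from its right flank, plus one internal
#' PPP triplet for runs of >= 3; flanks missing at the protein ends yield no
#' triplet on that side. \code{"per_pair"}: one record per PP *site*, i.e.
#' per occurrence of two consecutive prolines (a 2-run contributes one, a
#' 3-run two); the record's sequence is the XPP tripeptide ending at the
#' site (PPX at the N-terminus). The proteome census total is counted per
#' maximal run, see [proteome_motif_distribution()].
#'
#' @param protein amino-acid string.
#' @param gene gene symbol.
#' @param convention \code{"per_run"} or \code{"per_pair"}.
#' @return data.frame (\code{gene}, \code{kind}, \code{start},
#'   \code{sequence}, \code{context}); \code{start} is the 0-based position
#'   of the triplet (or of the PP site's first proline for per-pair).
#' @export
pp_triplets <- function(protein, gene = NA_character_,
                        convention = c("per_run", "per_pair")) {
  convention <- match.arg(convention)
  runs <- proline_runs(protein, gene)
  runs <- runs[runs$length >= 2L, , drop = FALSE]
  out <- data.frame(gene = character(0), kind = character(0),
                    start = integer(0), sequence = character(0),
                    context = character(0), stringsAsFactors = FALSE)
  add <- function(start0, seq3) {
    ctx_from <- max(start0 - 1L, 0L)
    ctx_to <- min(start0 + 4L, nchar(protein))
    rbind(out, data.frame(gene = gene, kind = "pp_triplet",
                          start = start0, sequence = seq3,
                          context = substr(protein, ctx_from + 1L, ctx_to),
                          stringsAsFactors = FALSE))
  }
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]          # 0-based first P of run
    L <- runs$length[i]
    if (convention == "per_run") {
      if (s > 0) out <- add(s - 1L, substr(protein, s, s + 2L))
      if (s + L < nchar(protein)) {
        out <- add(s + L - 2L, substr(protein, s + L - 1L, s + L + 1L))
      }
      if (L >= 3L) out <- add(s, strrep("P", 3L))
    } else {
      for (p in seq_len(L - 1L)) {       # PP site at positions s+p-1, s+p
        site <- s + p - 1L
        if (site > 0) {
          out <- add(site - 1L, substr(protein, site, site + 2L))
        } else {
          out <- add(site, substr(protein, site + 1L, site + 3L))
        }
      }
    }
  }
  out
}

#' Load the bundled pausing-score category table
#' @param path optional path to a two-column TSV (\code{triplet},
#'   \code{category}); defaults to the bundled table of the bacterial
#'   PP-triplet stalling hierarchy.
#' @return data.frame (\code{triplet}, \code{category}).
#' @export
load_pausing_scores <- function(path = NULL) {
  if (is.null(path)) path <- mito_fixture("pausing_scores")[["tsv"]]
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Annotate motif records with pausing categories
#'
#' @param records data.frame of motif records with a \code{sequence} column.
#' @param table pausing-score table from [load_pausing_scores()].
#' @return \code{records} with a \code{pausing_category} column
#'   (\code{strong}/\code{medium}/\code{weak}/\code{unknown}).
#' @export
annotate_pausing <- function(records, table = load_pausing_scores()) {
  cat_of <- stats::setNames(table$category, table$triplet)
  pc <- unname(cat_of[records$sequence])
  pc[is.na(pc)] <- "unknown"
  records$pausing_category <- pc
  records
}

#' Proline-motif census of a proteome
#'
#' Per-gene counts of 1xPro, 2xPro and >= 3xPro maximal runs and triplet
#' records, with a proteome summary: genes lacking any >= 2-proline run,
#' the total number of >= 3 runs, and the PP-containing triplet total. The
#' total counts one PP-containing motif per maximal >= 2-proline run (each
#' run is one stalling-relevant site whatever its flanking triplets); on
#' the bundled human proteome this yields 15.
#'
#' @param proteome named character vector, gene -> protein.
#' @param convention triplet-enumeration convention passed to
#'   [pp_triplets()] for the per-triplet records.
#' @return list with \code{per_gene} (data.frame ordered by gene),
#'   \code{triplets} (all triplet records), and \code{summary} (list:
#'   \code{genes_lacking_run2}, \code{total_run3plus},
#'   \code{pp_triplet_total}).
#' @export
proteome_motif_distribution <- function(proteome,
                                        convention = c("per_run",
                                                       "per_pair")) {
  convention <- match.arg(convention)
  genes <- sort(names(proteome))
  per_gene <- do.call(rbind, lapply(genes, function(g) {
    runs <- proline_runs(proteome[[g]], g)
    data.frame(gene = g,
               run1 = sum(runs$kind == "run1"),
               run2 = sum(runs$kind == "run2"),
               run3plus = sum(runs$kind == "run3plus"),
               stringsAsFactors = FALSE)
  }))
  per_gene$pp_motifs <- per_gene$run2 + per_gene$run3plus
  triplets <- do.call(rbind, lapply(genes, function(g)
    pp_triplets(proteome[[g]], g, convention)))
  list(per_gene = per_gene,
       triplets = triplets,
       summary = list(
         genes_lacking_run2 = per_gene$gene[per_gene$pp_motifs == 0L],
         total_run3plus = sum(per_gene$run3plus),
         pp_triplet_total = sum(per_gene$pp_motifs)))
}

#' Proline content of a proteome
#'
#' @param proteome named character vector, gene -> protein.
#' @return list with \code{fraction} (prolines / residues over the whole
#'   proteome) and \code{per_gene} data.frame (\code{gene}, \code{length},
#'   \code{prolines}, \code{fraction}).
#' @export
proline_fraction <- function(proteome) {
  if (!length(proteome)) stop("empty proteome")
  per_gene <- do.call(rbind, lapply(sort(names(proteome)), function(g) {
    p <- proteome[[g]]
    np <- sum(strsplit(p, "")[[1]] == "P")
    data.frame(gene = g, length = nchar(p), prolines = np,
               fraction = np / nchar(p), stringsAsFactors = FALSE)
  }))
  list(fraction = sum(per_gene$prolines) / sum(per_gene$length),
       per_gene = per_gene)
}

#' Per-codon proline-window labels
#'
#' Labels each protein position with the number of prolines in a rolling
#' window of \code{window} residues. The default anchor is trailing (the
#' window covering positions \code{i-window+1 .. i}, clamped at the
#' N-terminus), reflecting the nascent-chain context behind the
#' peptidyl-transferase centre; a centered window is selectable. Labels of
#' \code{cap} or more are pooled into group \code{cap}.
#'
#' @param protein amino-acid string.
#' @param window window length in residues.
#' @param anchor \code{"trailing"} or \code{"centered"}.
#' @param cap pooling cap for the group label.
#' @return integer vector of group labels, one per residue.
#' @export
proline_window_labels <- function(protein, window = 5L,
                                  anchor = c("trailing", "centered"),
                                  cap = 3L) {
  anchor <- match.arg(anchor)
  isP <- as.integer(strsplit(protein, "")[[1]] == "P")
  n <- length(isP)
  cs <- cumsum(c(0L, isP))
  idx <- seq_len(n)
  if (anchor == "trailing") {
    from <- pmax(idx - window + 1L, 1L)
    to <- idx
  } else {
    half <- window %/% 2L
    from <- pmax(idx - half, 1L)
    to <- pmin(idx + (window - 1L - half), n)
  }
  pmin(cs[to + 1L] - cs[from], cap)
}
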