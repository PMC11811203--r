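#' Configuration of the promoter-sequence simulator
#'
#' Generates random promoter sequences (i.i.d. background at a stated GC
#' content) with motif instances planted at known offsets relative to the
#' TSS. The default plants mirror the structure observed at a
#' THABS-regulated promoter: two perfect consensus matches within 200 bp
#' upstream of the TSS and one near-perfect (single-mismatch) match about
#' 700 bp upstream, one of them on the minus strand.
#'
#' @param n_promoters Number of promoter sequences.
#' @param length Sequence length in bp.
#' @param gc_content Background GC fraction (default 0.41, human-like).
#' @param tss_offset 0-based position of the TSS within each sequence
#'   (default `length - 200`).
#' @param plants Tibble/data.frame with columns `promoter`, `motif` (the
#'   concrete instance as read on `strand`), `offset` (start relative to the
#'   TSS; negative = upstream) and `strand` (`"+"`/`"-"`; minus-strand
#'   plants are inserted as the reverse complement).
#' @param seed RNG seed.
#' @return Object of class `promoter_sim_config`.
#' @export
promoter_sim_config <- function(
    n_promoters = 20L, length = 1500L, gc_content = 0.41,
    tss_offset = length - 200L,
    plants = tibble::tibble(
      promoter = "P001",
      motif = c("TACGGGCA", "TCCAGGCA", "TACGGGTA"),
      offset = c(-150L, -60L, -700L),
      strand = c("+", "+", "-")),
    seed = NULL) {
  stopifnot(n_promoters >= 1L, length >= 1L,
            gc_content > 0, gc_content < 1,
      tss_offset >= 0L, tss_offset < length)
  plants <- tibble::as_tibble(plants)
  if (nrow(plants)) {
    stopifnot(all(plants$strand %in% c("+", "-")),
              all(grepl("^[ACGT]+$", plants$motif)))
    start <- tss_offset + plants$offset
    end <- start + nchar(plants$motif)
    if (any(start < 0L) || any(end > length))
      stop("planted motifs must lie within the sequence", call. = FALSE)
    for (p in unique(plants$promoter)) {
      i <- which(plants$promoter == p)
      if (length(i) > 1L) {
        o <- i[order(start[i])]
        if (any(start[o][-1L] < end[o][-length(o)]))
          stop("overlapping plants in promoter ", p, call. = FALSE)
      }
    }
  }
  structure(list(n_promoters = as.integer(n_promoters),
                 length = as.integer(length), gc_content = gc_content,
                 tss_offset = as.integer(tss_offset), plants = plants,
                 seed = seed),
            class = "promoter_sim_config")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate promoter sequences with planted motif instances
#'
#' @param cfg A [promoter_sim_config()].
#' @param out_dir Optional directory; when given, writes `promoters.fasta`,
#'   `tss.bed` and `planted_truth.tsv`.
#' @return List with `sequences` (named [Biostrings::DNAStringSet]), `tss`
#'   (tibble: chrom, start, end, name, score, strand — BED-style, 0-based
#'   half-open, one record per promoter), `truth` (tibble of plants with
#'   absolute 0-based `start`/`end`) and `config`.
#' @export
simulate_promoters <- function(cfg = promoter_sim_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "promoter_sim_config"))
  ids <- sprintf("P%03d", seq_len(cfg$n_promoters))
  unknown <- setdiff(cfg$plants$promoter, ids)
  if (length(unknown))
    stop("plants reference unknown promoter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  probs <- c(A = (1 - cfg$gc_content) / 2, C = cfg$gc_content / 2,
             G = cfg$gc_content / 2, T = (1 - cfg$gc_content) / 2)
  seqs <- with_seed_if(cfg$seed, {
    vapply(ids, function(id) {
      paste(sample(DNA_BASES, cfg$length, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
  })
  truth <- tibble::as_tibble(cfg$plants)
  if (nrow(truth)) {
    truth$start <- cfg$tss_offset + truth$offset
    truth$end <- truth$start + nchar(truth$motif)
    truth$planted_seq <- ifelse(truth$strand == "-", revcomp(truth$motif),
                                truth$motif)
    for (i in seq_len(nrow(truth))) {
      p <- truth$promoter[i]
      substr(seqs[p], truth$start[i] + 1L, truth$end[i]) <- truth$planted_seq[i]
    }
  } else {
    truth$start <- integer(0); truth$end <- integer(0)
    truth$planted_seq <- character(0)
  }
  sequences <- Biostrings::DNAStringSet(seqs)
  names(sequences) <- ids
  tss <- tibble::tibble(chrom = ids, start = cfg$tss_offset,
                        end = cfg$tss_offset + 1L, name = ids,
                        score = 0L, strand = "+")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(sequences,
                                file.path(out_dir, "promoters.fasta"))
    utils::write.table(tss, file.path(out_dir, "tss.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(truth, file.path(out_dir, "planted_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(sequences = sequences, tss = tss, truth = truth, config = cfg)
}
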