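#' Scan sequences for a consensus motif with IUPAC-N wildcards
#'
#' Slides the consensus (default the THABS motif `TNNNGGCA`, `N` = any
#' base) over each sequence on both strands and reports windows that agree
#' at all non-N motif positions except at most `max_mismatch`. Minus-strand
#' hits are found by scanning the reverse complement of the motif and are
#' reported in plus-strand coordinates. An `N` in the subject sequence
#' matches nothing and counts as a mismatch at every motif position,
#' including wildcard positions.
#'
#' @param sequences Named character vector, [Biostrings::DNAStringSet], or a
#'   single string. Letters must be A/C/G/T/N.
#' @param motif Consensus over A/C/G/T/N (default `"TNNNGGCA"`).
#' @param max_mismatch Mismatches tolerated at non-N positions (default 0;
#'   1 gives "near-perfect" matches).
#' @param strands Strands to scan (default both).
#' @return Tibble: `seq_id`, `start` (0-based), `end` (half-open), `strand`,
#'   `mismatches`, `match` (plus-strand sequence of the window).
#' @export
scan_thabs <- function(sequences, motif = "TNNNGGCA", max_mismatch = 0L,
                       strands = c("+", "-")) {
  stopifnot(max_mismatch >= 0L, all(strands %in% c("+", "-")))
  motif <- toupper(motif)
  if (!grepl("^[ACGTN]+$", motif))
    stop("`motif` may contain only A, C, G, T, N", call. = FALSE)
  if (inherits(sequences, "DNAStringSet") ||
      inherits(sequences, "DNAString"))
    sequences <- as.character(Biostrings::DNAStringSet(sequences))
  if (is.null(names(sequences)))
    names(sequences) <- if (length(sequences) == 1L) "seq1" else
      paste0("seq", seq_along(sequences))
  sequences <- toupper(sequences)
  for (id in names(sequences)) {
    bad <- regexpr("[^ACGTN]", sequences[[id]])
    if (bad > 0L)
      stop("invalid symbol in sequence '", id, "' at position ", bad,
           call. = FALSE)
  }
  patterns <- list("+" = motif, "-" = revcomp(motif))
  out <- list()
  for (id in names(sequences)) {
    subj <- sequences[[id]]
    L <- nchar(subj)
    m <- nchar(motif)
    if (L < m) next
    sraw <- charToRaw(subj)
    n_windows <- L - m + 1L
    for (strand in strands) {
      pat <- strsplit(patterns[[strand]], "")[[1L]]
      mism <- integer(n_windows)
      for (j in seq_len(m)) {
        window_j <- sraw[j:(j + n_windows - 1L)]
        mism <- mism + if (pat[j] == "N")
          as.integer(window_j == charToRaw("N"))
        else
          as.integer(window_j != charToRaw(pat[j]))
      }
      hit <- which(mism <= max_mismatch)
      if (length(hit))
        out[[length(out) + 1L]] <- tibble::tibble(
          seq_id = id, start = hit - 1L, end = hit - 1L + m,
          strand = strand, mismatches = mism[hit],
          match = substring(subj, hit, hit + m - 1L))
    }
  }
  if (!length(out))
    return(tibble::tibble(seq_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          mismatches = integer(), match = character()))
  res <- dplyr::bind_rows(out)
  res[order(res$seq_id, res$start, res$strand), ]
}

#' Differential-expression calling configuration
#'
#' @param fdr_threshold BH-adjusted significance cut-off (default 0.001).
#' @param fold_change_threshold Minimum fold change; `significant` requires
#'   `|log2FC| >= log2(fold_change_threshold)` (default 2).
#' @param pseudocount Added to counts before log2-CPM transformation
#'   (default 0.5).
#' @return Object of class `de_config`.
#' @export
de_config <- function(fdr_threshold = 0.001, fold_change_threshold = 2,
                      pseudocount = 0.5) {
  stopifnot(fdr_threshold > 0, fdr_threshold <= 1,
            fold_change_threshold >= 1, pseudocount >= 0)
  structure(list(fdr_threshold = fdr_threshold,
                 fold_change_threshold = fold_change_threshold,
                 pseudocount = pseudocount),
            class = "de_config")
}

#' Minimal differential-expression caller
#'
#' Library-size normalisation to log2 counts-per-million (with pseudocount),
#' per-gene log2 fold change between two groups, a two-sided Welch t-test on
#' the log2-CPM values, and Benjamini-Hochberg adjustment. A gene is
#' `significant` when `fdr < fdr_threshold` and
#' `|log2FC| >= log2(fold_change_threshold)`. This deliberately minimal
#' caller is the package's desk-scale stand-in for a full RNA-seq workflow;
#' externally computed DE tables with the same columns can be used
#' downstream instead.
#'
#' @param counts Gene x sample count matrix (rownames = genes).
#' @param group_labels Named character vector: sample -> group.
#' @param contrast Length-2 character: `c(reference, treatment)`; log2FC is
#'   treatment minus reference.
#' @param cfg A [de_config()].
#' @return Tibble: `gene`, `log2FC`, `p`, `fdr`, `significant`, `direction`.
#' @export
call_de <- function(counts, group_labels,
                    contrast = c("sgControl", "sgTHAP1"),
                    cfg = de_config()) {
  stopifnot(is.matrix(counts), length(contrast) == 2L,
            inherits(cfg, "de_config"))
  group_labels <- group_labels[colnames(counts)]
  a <- names(group_labels)[group_labels == contrast[1L]]
  b <- names(group_labels)[group_labels == contrast[2L]]
  if (length(a) < 2L || length(b) < 2L)
    stop("each contrast group needs at least 2 replicates", call. = FALSE)
  lib <- colSums(counts)
  logcpm <- log2(sweep(counts + cfg$pseudocount, 2L, lib, "/") * 1e6)
  xa <- logcpm[, a, drop = FALSE]; xb <- logcpm[, b, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1L, stats::var); vb <- apply(xb, 1L, stats::var)
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  tt <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  zero <- se2 == 0
  p[zero] <- ifelse(mb[zero] == ma[zero], 1, 0)
  fdr <- stats::p.adjust(p, method = "BH")
  lfc <- mb - ma
  tibble::tibble(
    gene = rownames(counts), log2FC = lfc, p = p, fdr = fdr,
    significant = fdr < cfg$fdr_threshold &
      abs(lfc) >= log2(cfg$fold_change_threshold),
    direction = ifelse(lfc < 0, "down", "up"))
}

#' Discount transduction/control artefacts from a DE list
#'
#' Removes from the target DE table every gene that is itself significant in
#' the control contrast (control sgRNA vs untransduced cells at the same
#' thresholds), so that generic responses to transduction are not mistaken
#' for regulator targets.
#'
#' @param de_control DE tibble for the control-vs-untransduced contrast.
#' @param de_target DE tibble for the contrast of interest. Both must cover
#'   the same gene universe.
#' @return `de_target` with control-significant genes removed.
#' @export
discount_control_effects <- function(de_control, de_target) {
  if (!setequal(de_control$gene, de_target$gene) ||
      nrow(de_control) != nrow(de_target))
    stop("DE tables must cover the same gene universe", call. = FALSE)
  drop <- de_control$gene[de_control$significant]
  de_target[!de_target$gene %in% drop, ]
}

# Coerce BED input (path, data.frame or GRanges) to a standard tibble.
as_bed_tbl <- function(x, what = "BED") {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    if (requireNamespace("rtracklayer", quietly = TRUE)) {
      gr <- rtracklayer::import(x, format = "BED")
      return(tibble::tibble(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L,
        end = GenomicRanges::end(gr),
        name = if (!is.null(gr$name)) gr$name else NA_character_,
        strand = as.character(GenomicRanges::strand(gr))))
    }
    d <- utils::read.table(x, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
    names(d)[seq_len(min(6L, ncol(d)))] <-
      c("chrom", "start", "end", "name", "score", "strand")[
        seq_len(min(6L, ncol(d)))]
    x <- d
  }
  if (inherits(x, "GRanges"))
    return(tibble::tibble(
      chrom = as.character(GenomicRanges::seqnames(x)),
      start = GenomicRanges::start(x) - 1L,
      end = GenomicRanges::end(x),
      name = if (!is.null(x$name)) x$name else NA_character_,
      strand = as.character(GenomicRanges::strand(x))))
  x <- tibble::as_tibble(x)
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (!"name" %in% names(x)) x$name <- NA_character_
  if (!"strand" %in% names(x)) x$strand <- "+"
  x
}

#' Intersect DE calls with promoter occupancy to call direct targets
#'
#' A gene's promoter is `occupied` when any peak interval overlaps the
#' window `[TSS - window, TSS + window)` (0-based half-open; the TSS is the
#' interval start for plus-strand genes and the last base for minus-strand
#' genes). A direct target is a gene that is both significant in the DE
#' table and occupied. Genes without a TSS record are reported unannotated
#' and excluded.
#'
#' @param de_list DE tibble ([call_de()] columns), typically
#'   control-discounted.
#' @param peaks Peak intervals: BED path, BED-like data frame
#'   (`chrom`/`start`/`end`, 0-based half-open) or `GRanges`.
#' @param tss TSS records in the same forms; `name` must carry the gene id.
#' @param window Half-width of the promoter window in bp (default 1000).
#' @return List with `calls` (tibble: gene, log2FC, significant, direction,
#'   occupied, direct), `direct_targets` (character), `unannotated`
#'   (genes lacking TSS records).
#' @export
call_direct_targets <- function(de_list, peaks, tss, window = 1000L) {
  stopifnot(window > 0L)
  peaks <- as_bed_tbl(peaks)
  tss <- as_bed_tbl(tss)
  tss$strand[!tss$strand %in% c("+", "-")] <- "+"
  tss_pos <- ifelse(tss$strand == "-", tss$end - 1L, tss$start)

  unannotated <- setdiff(de_list$gene, tss$name)
  keep_tss <- tss$name %in% de_list$gene
  occupied_genes <- character(0)
  if (any(keep_tss) && nrow(peaks)) {
    win <- GenomicRanges::GRanges(
      tss$chrom[keep_tss],
      IRanges::IRanges(start = tss_pos[keep_tss] - window + 1L,
                       end = tss_pos[keep_tss] + window))
    pk <- GenomicRanges::GRanges(
      peaks$chrom, IRanges::IRanges(start = peaks$start + 1L,
                                    end = peaks$end))
    ov <- GenomicRanges::findOverlaps(win, pk)
    occupied_genes <- unique(tss$name[keep_tss][
      unique(S4Vectors::queryHits(ov))])
  }
  calls <- de_list[!de_list$gene %in% unannotated,
                   c("gene", "log2FC", "significant", "direction")]
  calls$occupied <- calls$gene %in% occupied_genes
  calls$direct <- calls$significant & calls$occupied
  list(calls = calls, direct_targets = calls$gene[calls$direct],
       unannotated = unannotated)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample, `dCt = Ct(gene) - Ct(reference gene)`; per gene,
#' `ddCt = dCt(sample) - dCt(control sample)`; the relative quantity is
#' `2^(-ddCt)`. The control sample's relative expression is identically 1.
#'
#' @param ct Sample x gene numeric matrix of Ct values (rownames =
#'   samples).
#' @param reference_gene Column used as the normaliser (e.g. a ribosomal
#'   housekeeping gene).
#' @param control_sample Row used as the calibrator.
#' @return Tibble: `sample`, `gene`, `ct`, `delta_ct`, `delta_delta_ct`,
#'   `rel_expr`.
#' @export
delta_delta_ct <- function(ct, reference_gene, control_sample) {
  stopifnot(is.matrix(ct))
  if (!reference_gene %in% colnames(ct))
    stop("reference gene '", reference_gene, "' absent from Ct table",
         call. = FALSE)
  if (!control_sample %in% rownames(ct))
    stop("control sample '", control_sample, "' absent from Ct table",
         call. = FALSE)
  if (any(!is.finite(ct[, reference_gene])))
    stop("reference-gene Ct values must be finite", call. = FALSE)
  dct <- ct - ct[, reference_gene]
  ddct <- sweep(dct, 2L, dct[control_sample, ], "-")
  tibble::tibble(
    sample = rep(rownames(ct), times = ncol(ct)),
    gene = rep(colnames(ct), each = nrow(ct)),
    ct = as.vector(ct),
    delta_ct = as.vector(dct),
    delta_delta_ct = as.vector(ddct),
    rel_expr = as.vector(2^(-ddct)))
}
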