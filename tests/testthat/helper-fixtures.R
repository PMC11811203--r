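# Shared fixtures and independent oracles for the test suite.

# Small two-segment design: 24 mutagenised positions, 480 variants.
small_design <- function(len = 25L, tile = 12L, seed = 42L,
                         policy = "synonymous_recode") {
  design_library(synthetic_protein(len, seed = seed),
                 mutagenesis_config(tile_length = tile,
                                    wt_control_policy = policy))
}

# Build a count_table object directly from a long counts tibble and key
# metadata, for hand-crafted scoring examples.
manual_count_table <- function(counts, keys) {
  structure(list(counts = counts, accounting = NULL, keys = keys),
            class = "count_table")
}

# Minimal key table: singleton keys, one scope.
manual_keys <- function(ids, wt) {
  tibble::tibble(group_id = ids, segment = 1L,
                 position = seq_along(ids) + 1L,
                 ref_aa = "A", alt_aa = "V",
                 is_wt_group = ids %in% wt,
                 insert_seq = ids, nt_length = nchar(ids))
}

# Independent naive motif oracle: checks every window on both strands by
# character comparison. Subject N matches nothing.
naive_motif_scan <- function(subj, motif, max_mismatch) {
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  m <- nchar(motif)
  out <- list()
  for (strand in c("+", "-")) {
    pat <- strsplit(if (strand == "+") motif else rc(motif), "")[[1]]
    for (i in seq_len(nchar(subj) - m + 1L)) {
      win <- strsplit(substring(subj, i, i + m - 1L), "")[[1]]
      mm <- sum(ifelse(pat == "N", win == "N", win != pat))
      if (mm <= max_mismatch)
        out[[length(out) + 1L]] <- data.frame(
          start = i - 1L, strand = strand, mismatches = mm)
    }
  }
  if (!length(out)) return(data.frame(start = integer(),
                                      strand = character(),
                                      mismatches = integer()))
  do.call(rbind, out)
}

# Independent Hamming search oracle over an arbitrary key set.
naive_nearest_keys <- function(query, keys) {
  d <- vapply(keys, function(k) {
    if (nchar(k) != nchar(query)) return(NA_integer_)
    sum(strsplit(k, "")[[1]] != strsplit(query, "")[[1]])
  }, integer(1))
  d <- unname(d)
  if (all(is.na(d))) return(list(dist = NA_integer_, hits = integer(0)))
  best <- min(d, na.rm = TRUE)
  list(dist = best, hits = unname(which(!is.na(d) & d == best)))
}

# Independent hypergeometric upper tail by direct summation.
naive_hyper_upper <- function(k, K, N, n) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Rank-based AUROC of scores separating labels 1 (positive) vs 0.
rank_auroc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Deep-count RNA-seq configuration used for planted-truth recovery: high
# baseline, low dispersion, six replicates and strong planted effects so
# that every planted gene is comfortably detectable (the weakest planted
# gene sits at |t| ~ 25 on ~10 df, far beyond the BH cut-off near 3e-5).
deep_rnaseq_config <- function(seed = 1L, n_genes = 4000L) {
  rnaseq_sim_config(
    n_genes = n_genes,
    reps = c(untransduced = 6L, sgControl = 6L, sgTHAP1 = 6L),
    baseline_meanlog = log(2000), baseline_sdlog = 1.0,
    dispersion = 0.02,
    n_down = 80L, n_up = 30L, lfc_down = c(-5, -3), lfc_up = c(3, 5),
    n_artifact = 20L, lfc_artifact = c(3, 4),
    n_occupied_de = 30L, n_occupied_bg = 80L, seed = seed)
}

# Lay all genes of an RNA-seq truth table along one chromosome and place a
# peak at every occupied gene's TSS.
truth_to_tss_peaks <- function(truth, spacing = 10000L) {
  tss_pos <- seq_len(nrow(truth)) * spacing
  tss <- tibble::tibble(chrom = "chr1", start = tss_pos,
                        end = tss_pos + 1L, name = truth$gene,
                        score = 0L, strand = "+")
  occ <- which(truth$occupied)
  peaks <- tibble::tibble(chrom = "chr1",
                          start = tss_pos[occ] - 50L,
                          end = tss_pos[occ] + 50L,
                          name = paste0("peak", seq_along(occ)),
                          score = 0L, strand = ".")
  list(tss = tss, peaks = peaks)
}
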