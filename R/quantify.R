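#' Constant-flank configuration for amplicon reads
#'
#' Reads are modelled as `flank5 + insert + flank3`: the 5' flank is matched
#' as a read prefix and the 3' flank as a read suffix, each allowing up to
#' `max_flank_mismatch` substitutions; the insert is everything in between.
#'
#' @param flank5,flank3 Constant DNA flanks (non-empty).
#' @param max_flank_mismatch Substitutions tolerated per flank (default 2).
#' @param require_both When `FALSE` only the 5' flank is required and the
#'   insert is the full remainder of the read.
#' @return Object of class `flank_config`.
#' @export
flank_config <- function(flank5, flank3, max_flank_mismatch = 2L,
                         require_both = TRUE) {
  stopifnot(nzchar(flank5), nzchar(flank3), max_flank_mismatch >= 0L)
  structure(list(flank5 = toupper(flank5), flank3 = toupper(flank3),
                 max_flank_mismatch = as.integer(max_flank_mismatch),
                 require_both = isTRUE(require_both)),
            class = "flank_config")
}

# --- matcher backends ------------------------------------------------------

# Brute-force nearest-key search: for each query, Hamming distance to every
# key of the same length. Returns tibble(query, dist, key_row, n_best).
match_bruteforce <- function(queries, key_seqs, max_mismatch) {
  key_len <- nchar(key_seqs)
  out <- tibble::tibble(query = queries, dist = NA_integer_,
                        key_row = NA_integer_, n_best = 0L)
  for (i in seq_along(queries)) {
    q <- queries[i]
    rows <- which(key_len == nchar(q))
    if (!length(rows)) next
    d <- mismatch_counts(key_seqs[rows], q)
    best <- min(d)
    if (best <= max_mismatch) {
      hits <- rows[d == best]
      out$dist[i] <- best
      out$n_best[i] <- length(hits)
      out$key_row[i] <- hits[1L]
    }
  }
  out
}

# Precompute per-segment structures for the design-aware rescue: key rows by
# codon offset, key codons, wild-type codons, and keys within Hamming 1 of
# the reference codon at their own position (candidates for error-free-
# looking reads).
prep_fast_matcher <- function(index) {
  k <- index$keys
  segs <- index$segments
  lapply(seq_len(nrow(segs)), function(s) {
    rows <- which(k$segment == segs$segment[s] & !is.na(k$codon_offset))
    off <- k$codon_offset[rows]
    codon <- substr(k$insert_seq[rows], 3L * off - 2L, 3L * off)
    wt <- segs$wt_dna[s]
    wt_codon <- substring(wt, 3L * off - 2L, 3L * off)
    d_wt <- as.integer(mapply(hamming, codon, wt_codon))
    list(segment = segs$segment[s], wt = wt, nt_length = segs$nt_length[s],
         rows = rows, off = off, codon = codon,
         near_wt = rows[d_wt == 1L],
         wt_key_row = {
           r <- which(k$segment == segs$segment[s] & is.na(k$codon_offset))
           if (length(r)) r[1L] else NA_integer_
         },
         by_off = split(seq_along(rows), off))
  })
}

# Design-aware unique-1-mismatch rescue for a single query against one
# segment: returns integer rows of keys at Hamming distance exactly 1.
rescue_one_segment <- function(q_raw, prep) {
  wt_raw <- charToRaw(prep$wt)
  diffs <- which(q_raw != wt_raw)
  nd <- length(diffs)
  hits <- integer(0)
  if (!is.na(prep$wt_key_row) && nd == 1L) hits <- prep$wt_key_row
  if (nd == 0L) return(c(hits, prep$near_wt))
  if (nd > 4L) return(hits)
  dcod <- (diffs + 2L) %/% 3L                # codon window of each diff
  tab <- table(dcod)
  for (j in as.integer(names(tab))) {
    inwin <- tab[[as.character(j)]]
    outside <- nd - inwin
    if (outside > 1L) next
    loc <- prep$by_off[[as.character(j)]]
    if (is.null(loc)) next
    qc <- rawToChar(q_raw[(3L * j - 2L):(3L * j)])
    d3 <- vapply(prep$codon[loc], function(c3) hamming(qc, c3), integer(1))
    ok <- which(outside + d3 == 1L)
    hits <- c(hits, prep$rows[loc[ok]])
  }
  unique(hits)
}

# Fast matcher: exact misses resolved via the single-codon-edit structure of
# a design-derived index. Returns same shape as match_bruteforce.
match_design_aware <- function(queries, index, prep) {
  out <- tibble::tibble(query = queries, dist = NA_integer_,
                        key_row = NA_integer_, n_best = 0L)
  seg_len <- vapply(prep, `[[`, integer(1), "nt_length")
  qlen <- nchar(queries)
  for (i in seq_along(queries)) {
    q_raw <- charToRaw(queries[i])
    hits <- integer(0)
    for (s in which(seg_len == qlen[i]))
      hits <- c(hits, rescue_one_segment(q_raw, prep[[s]]))
    hits <- unique(hits)
    if (length(hits)) {
      out$dist[i] <- 1L
      out$n_best[i] <- length(hits)
      out$key_row[i] <- hits[1L]
    }
  }
  out
}

# Assign insert sequences to index keys: exact hash lookup, then (when
# allowed) unique rescue at Hamming distance 1. Returns
# tibble(outcome, key_row, mismatches) aligned with `inserts`.
assign_inserts <- function(inserts, index, max_insert_mismatch = 1L) {
  stopifnot(max_insert_mismatch %in% c(0L, 1L))
  k <- index$keys
  n <- length(inserts)
  key_row <- match(inserts, k$insert_seq)
  outcome <- ifelse(is.na(key_row), "unmatched", "assigned")
  mismatches <- ifelse(is.na(key_row), NA_integer_, 0L)
  todo <- which(is.na(key_row) & nchar(inserts) %in% unique(k$nt_length))
  if (max_insert_mismatch == 1L && length(todo) && nrow(k)) {
    uq <- unique(inserts[todo])
    # exact matches are already resolved, so any hit here is at distance 1;
    # large indices use the single-codon-edit structure, small ones brute force
    res <- if (nrow(k) > 512L)
      match_design_aware(uq, index, prep_fast_matcher(index))
    else
      match_bruteforce(uq, k$insert_seq, 1L)
    m <- match(inserts[todo], res$query)
    hit1 <- res$n_best[m] == 1L
    amb <- res$n_best[m] >= 2L
    key_row[todo[hit1]] <- res$key_row[m[hit1]]
    mismatches[todo[hit1]] <- 1L
    outcome[todo[hit1]] <- "assigned"
    outcome[todo[amb]] <- "ambiguous"
  }
  tibble::tibble(outcome = outcome, key_row = key_row,
                 mismatches = mismatches)
}

# Vectorised read processing: flank location + insert assignment.
process_reads <- function(reads, flank_cfg, index, max_insert_mismatch = 1L) {
  stopifnot(inherits(flank_cfg, "flank_config"))
  f5 <- flank_cfg$flank5; f3 <- flank_cfg$flank3
  n5 <- nchar(f5); n3 <- if (flank_cfg$require_both) nchar(f3) else 0L
  len <- nchar(reads)
  long_enough <- len >= n5 + n3
  ok5 <- logical(length(reads)); ok3 <- logical(length(reads))
  le <- which(long_enough)
  if (length(le)) {
    ok5[le] <- mismatch_counts(substring(reads[le], 1L, n5), f5) <=
      flank_cfg$max_flank_mismatch
    ok3[le] <- if (flank_cfg$require_both)
      mismatch_counts(substring(reads[le], len[le] - n3 + 1L, len[le]), f3) <=
        flank_cfg$max_flank_mismatch
    else TRUE
  }
  has_flanks <- ok5 & ok3
  out <- tibble::tibble(outcome = rep("no_flank", length(reads)),
                        key_row = NA_integer_, mismatches = NA_integer_)
  w <- which(has_flanks)
  if (length(w)) {
    inserts <- substring(reads[w], n5 + 1L, len[w] - n3)
    out[w, ] <- assign_inserts(inserts, index, max_insert_mismatch)
  }
  out
}

#' Assign a single read to a library variant
#'
#' Locates the constant flanks (prefix/suffix, each allowing up to
#' `max_flank_mismatch` substitutions), extracts the insert and matches it
#' against the variant index: exactly, or — when `max_insert_mismatch = 1` —
#' to the unique key at Hamming distance 1. Two or more equally near keys
#' give outcome `ambiguous`; an insert whose length matches no key, or with
#' no key within reach, is `unmatched`; unlocatable flanks give `no_flank`.
#'
#' @param read_seq Read sequence (character).
#' @param flank_cfg A [flank_config()].
#' @param index A [build_reference_index()] result.
#' @param max_insert_mismatch 0 or 1.
#' @return One-row tibble: `outcome` (`assigned`/`ambiguous`/`unmatched`/
#'   `no_flank`), `variant` (collision-group id when assigned),
#'   `mismatches_used`.
#' @export
process_read <- function(read_seq, flank_cfg, index,
                         max_insert_mismatch = 1L) {
  stopifnot(length(read_seq) == 1L)
  r <- process_reads(toupper(read_seq), flank_cfg, index,
                     max_insert_mismatch)
  tibble::tibble(
    outcome = r$outcome,
    variant = ifelse(is.na(r$key_row), NA_character_,
                     index$keys$group_id[r$key_row]),
    mismatches_used = r$mismatches)
}

read_fastq_seqs <- function(path) {
  lines <- readLines(gzfile(path))
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ (line count not a multiple of 4): ", path,
         call. = FALSE)
  lines[seq_along(lines) %% 4L == 2L]
}

parse_fastq_name <- function(path) {
  m <- regmatches(basename(path),
                  regexec("^pool([0-9]+)_rep([0-9]+)_(dim|bright)\\.fastq(\\.gz)?$",
                          basename(path)))[[1L]]
  if (length(m) == 0L)
    stop("cannot resolve pool/replicate/bin from file name: ", path,
         "\n  expected pool<i>_rep<j>_<dim|bright>.fastq[.gz]",
         call. = FALSE)
  list(pool = as.integer(m[2L]), replicate = as.integer(m[3L]), bin = m[4L])
}

#' Tabulate per-bin variant counts from FASTQ files
#'
#' Processes every FASTQ file (named `pool<i>_rep<j>_<bin>.fastq[.gz]`)
#' through the flank/matcher pipeline and tallies assigned reads per index
#' key. Counts are dense: every index key appears for every file, with zero
#' for unobserved variants. Collision groups (keys shared by several
#' variants, e.g. Met/Trp wild-type controls under the default recode
#' policy) are counted once under their group id. The exact accounting
#' identity `assigned + ambiguous + unmatched + no_flank = input` holds per
#' file.
#'
#' @param fastq_files Character vector of FASTQ paths, or a directory.
#' @param index A [build_reference_index()] result.
#' @param flank_cfg A [flank_config()].
#' @param max_insert_mismatch 0 or 1 (default 1).
#' @return Object of class `count_table`: list with `counts` (tibble: pool,
#'   replicate, bin, variant, count), `accounting` (tibble per file: path,
#'   pool, replicate, bin, input, assigned, ambiguous, unmatched, no_flank)
#'   and `keys` (the index key table).
#' @export
tabulate_counts <- function(fastq_files, index,
                            flank_cfg, max_insert_mismatch = 1L) {
  stopifnot(inherits(index, "variant_index"))
  if (length(fastq_files) == 1L && dir.exists(fastq_files))
    fastq_files <- list.files(fastq_files, pattern = "\\.fastq(\\.gz)?$",
                              full.names = TRUE)
  if (!length(fastq_files)) stop("no FASTQ files found", call. = FALSE)
  counts <- list(); accounting <- list()
  for (path in fastq_files) {
    meta <- parse_fastq_name(path)
    reads <- read_fastq_seqs(path)
    r <- process_reads(reads, flank_cfg, index, max_insert_mismatch)
    tal <- tabulate(r$key_row[r$outcome == "assigned"],
                    nbins = nrow(index$keys))
    counts[[length(counts) + 1L]] <- tibble::tibble(
      pool = meta$pool, replicate = meta$replicate, bin = meta$bin,
      variant = index$keys$group_id, count = as.integer(tal))
    accounting[[length(accounting) + 1L]] <- tibble::tibble(
      path = path, pool = meta$pool, replicate = meta$replicate,
      bin = meta$bin, input = length(reads),
      assigned = sum(r$outcome == "assigned"),
      ambiguous = sum(r$outcome == "ambiguous"),
      unmatched = sum(r$outcome == "unmatched"),
      no_flank = sum(r$outcome == "no_flank"))
  }
  structure(list(counts = dplyr::bind_rows(counts),
                 accounting = dplyr::bind_rows(accounting),
                 keys = index$keys),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("<count_table> ", nrow(x$accounting), " FASTQ file(s), ",
      length(unique(x$counts$variant)), " variants; assigned ",
      sum(x$accounting$assigned), "/", sum(x$accounting$input),
      " reads\n", sep = "")
  invisible(x)
}

#' Write a count table (long TSV) and its accounting report (JSON)
#'
#' @param count_table A [tabulate_counts()] result.
#' @param counts_path TSV output (pool, replicate, bin, variant, count).
#' @param accounting_path Optional JSON accounting report.
#' @return `counts_path`, invisibly.
#' @export
write_count_table <- function(count_table, counts_path,
                              accounting_path = NULL) {
  utils::write.table(count_table$counts, counts_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(accounting_path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("writing the accounting report requires the jsonlite package",
           call. = FALSE)
    jsonlite::write_json(count_table$accounting, accounting_path,
                         dataframe = "rows", pretty = TRUE)
  }
  invisible(counts_path)
}
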