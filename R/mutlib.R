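#' Configuration for site-saturation mutagenesis library design
#'
#' @param tile_length Maximum number of residues per mutagenesis segment
#'   (default 36, which tiles a 213-residue protein into six segments).
#' @param alphabet Ordered character vector of the 20 amino-acid symbols.
#' @param skip_initiator Leave the initiator methionine unmutagenised
#'   (default `TRUE`).
#' @param codon_table Named character vector mapping each amino acid to its
#'   single designated codon; see [default_codon_table()].
#' @param wt_control_policy How the per-position wild-type control construct
#'   is encoded: `"synonymous_recode"` (default) gives it a synonymous codon
#'   differing from the designated one so it stays distinguishable by
#'   sequencing; `"reference_codon"` leaves it identical to the reference,
#'   collapsing all controls of a segment onto one sequence. Met and Trp have
#'   no synonymous alternative and always fall back to the reference codon.
#' @return An object of class `mutagenesis_config`.
#' @export
mutagenesis_config <- function(tile_length = 36L,
                               alphabet = AA_ALPHABET,
                               skip_initiator = TRUE,
                               codon_table = default_codon_table(),
                               wt_control_policy = c("synonymous_recode",
                                                     "reference_codon")) {
  wt_control_policy <- match.arg(wt_control_policy)
  tile_length <- as.integer(tile_length)
  if (is.na(tile_length) || tile_length < 1L)
    stop("`tile_length` must be >= 1", call. = FALSE)
  alphabet <- as.character(alphabet)
  if (length(alphabet) != 20L || anyDuplicated(alphabet))
    stop("`alphabet` must contain exactly 20 distinct amino-acid symbols",
         call. = FALSE)
  missing_aa <- setdiff(alphabet, names(codon_table))
  if (length(missing_aa))
    stop("`codon_table` lacks codons for: ", paste(missing_aa, collapse = ", "),
         call. = FALSE)
  codons <- toupper(codon_table[alphabet])
  if (!all(grepl("^[ACGT]{3}$", codons)))
    stop("`codon_table` entries must be valid DNA triplets", call. = FALSE)
  structure(
    list(tile_length = tile_length, alphabet = alphabet,
         skip_initiator = isTRUE(skip_initiator),
         codon_table = stats::setNames(codons, alphabet),
         wt_control_policy = wt_control_policy),
    class = "mutagenesis_config")
}

# Synonymous codons of `aa` under the standard genetic code, lexicographic.
synonymous_codons <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  sort(names(gc)[gc == aa])
}

# Per-position wild-type control codon under the configured policy.
# Returns list(codon, collapsible): collapsible = TRUE when the control is
# sequence-identical to the reference segment.
wt_control_codon <- function(ref_aa, config) {
  designated <- unname(config$codon_table[ref_aa])
  if (config$wt_control_policy == "reference_codon")
    return(list(codon = designated, collapsible = TRUE))
  alt <- setdiff(synonymous_codons(ref_aa), designated)
  if (length(alt) == 0L)                      # Met, Trp
    list(codon = designated, collapsible = TRUE)
  else
    list(codon = alt[[1L]], collapsible = FALSE)
}

#' Design a tiled site-saturation mutagenesis library
#'
#' Partitions the mutagenised positions of a protein into consecutive
#' segments of at most `tile_length` residues (greedy, left to right) and
#' enumerates one variant per (position, amino acid) pair — 20 constructs per
#' position including the wild-type control, whose codon is synonymously
#' recoded so it remains sequence-distinguishable (see
#' [mutagenesis_config()]). Each variant carries the full DNA sequence of its
#' mutagenised segment. A 213-residue protein yields 212 positions, six
#' segments (2-37, 38-73, 74-109, 110-145, 146-181, 182-213) and 4240
#' variants.
#'
#' @param protein_seq Single amino-acid string (one-letter codes), starting
#'   with the initiator methionine when `skip_initiator` is set.
#' @param config A [mutagenesis_config()].
#' @return An object of class `mutagenesis_design`: list with `protein_seq`,
#'   `config`, `tiles` (tibble: `index`, `aa_start`, `aa_end`), `variants`
#'   (tibble: `id`, `position`, `ref_aa`, `alt_aa`, `segment`,
#'   `is_wt_control`, `collapsible`, `insert_seq`) and `pool_layout`
#'   (named list: pool id -> tile indices; consecutive tiles paired).
#' @export
design_library <- function(protein_seq, config = mutagenesis_config()) {
  stopifnot(inherits(config, "mutagenesis_config"))
  protein_seq <- toupper(as.character(protein_seq))
  if (length(protein_seq) != 1L || !nzchar(protein_seq))
    stop("`protein_seq` must be a non-empty string", call. = FALSE)
  aa <- strsplit(protein_seq, "")[[1L]]
  bad <- which(!(aa %in% config$alphabet))
  if (length(bad))
    stop("invalid residue symbol '", aa[bad[1L]], "' at position ", bad[1L],
         call. = FALSE)
  L <- length(aa)
  first <- if (config$skip_initiator) 2L else 1L
  if (config$skip_initiator && aa[1L] != "M")
    stop("`skip_initiator` is set but the sequence does not start with M",
         call. = FALSE)
  if (L < first)
    stop("protein too short: no mutagenisable positions", call. = FALSE)

  starts <- seq.int(first, L, by = config$tile_length)
  tiles <- tibble::tibble(
    index = seq_along(starts),
    aa_start = as.integer(starts),
    aa_end = as.integer(pmin(starts + config$tile_length - 1L, L)))

  ct <- config$codon_table
  # wild-type control codon per distinct reference amino acid (deterministic)
  wtc <- lapply(stats::setNames(nm = unique(aa[first:L])), wt_control_codon,
                config = config)

  variant_rows <- vector("list", nrow(tiles))
  for (t in seq_len(nrow(tiles))) {
    pos <- tiles$aa_start[t]:tiles$aa_end[t]
    seg_aa <- aa[pos]
    seg_codons <- unname(ct[seg_aa])
    n_pos <- length(pos)
    n_alpha <- length(config$alphabet)
    position <- rep(pos, each = n_alpha)
    ref_aa <- rep(seg_aa, each = n_alpha)
    alt_aa <- rep(config$alphabet, times = n_pos)
    is_wt <- alt_aa == ref_aa
    codon <- unname(ct[alt_aa])
    collapsible <- rep(FALSE, length(codon))
    if (any(is_wt)) {
      w <- which(is_wt)
      codon[w] <- vapply(ref_aa[w], function(a) wtc[[a]]$codon, character(1))
      collapsible[w] <- vapply(ref_aa[w], function(a) wtc[[a]]$collapsible,
                               logical(1))
    }
    codon_offset <- rep(seq_len(n_pos), each = n_alpha)
    insert <- vapply(seq_along(position), function(i) {
      s <- seg_codons
      s[codon_offset[i]] <- codon[i]
      paste(s, collapse = "")
    }, character(1))
    variant_rows[[t]] <- tibble::tibble(
      id = paste0(ref_aa, position, alt_aa),
      position = as.integer(position),
      ref_aa = ref_aa, alt_aa = alt_aa,
      segment = t, codon_offset = as.integer(codon_offset),
      is_wt_control = is_wt, collapsible = collapsible,
      insert_seq = insert)
  }
  variants <- dplyr::bind_rows(variant_rows)

  n_tiles <- nrow(tiles)
  pool_ids <- (seq_len(n_tiles) + 1L) %/% 2L
  pool_layout <- lapply(split(tiles$index, pool_ids), as.integer)
  names(pool_layout) <- seq_along(pool_layout)

  structure(
    list(protein_seq = protein_seq, config = config, tiles = tiles,
         variants = variants, pool_layout = pool_layout),
    class = "mutagenesis_design")
}

#' @export
print.mutagenesis_design <- function(x, ...) {
  cat("<mutagenesis_design>\n",
      " protein length: ", nchar(x$protein_seq), " aa\n",
      " segments:       ", nrow(x$tiles), "\n",
      " variants:       ", nrow(x$variants),
      " (", sum(x$variants$is_wt_control), " wild-type controls)\n",
      " pools:          ", length(x$pool_layout), "\n", sep = "")
  invisible(x)
}

#' Build the insert-sequence reference index for a design
#'
#' Maps every distinct segment insert sequence to the (lexicographically
#' sorted) variant ids that share it. Under the default synonymous-recode
#' policy only Met/Trp wild-type controls collapse onto the unmodified
#' reference segment; under `reference_codon` all controls of a segment
#' share one key.
#'
#' @param design A [design_library()] result.
#' @return Object of class `variant_index`: list with `keys` (tibble:
#'   `insert_seq`, `segment`, `codon_offset` — `NA` for keys identical to the
#'   reference segment —, `group_id`, `variant_ids` list-column,
#'   `is_wt_group`, `nt_length`) and `segments` (tibble: `segment`, `wt_dna`,
#'   `nt_length`, `aa_start`, `aa_end`).
#' @export
build_reference_index <- function(design) {
  stopifnot(inherits(design, "mutagenesis_design"))
  v <- design$variants
  if (anyDuplicated(v$id))
    stop("duplicate variant ids in design", call. = FALSE)

  ct <- design$config$codon_table
  aa <- strsplit(design$protein_seq, "")[[1L]]
  segments <- design$tiles
  segments$wt_dna <- vapply(seq_len(nrow(segments)), function(t) {
    paste(unname(ct[aa[segments$aa_start[t]:segments$aa_end[t]]]),
          collapse = "")
  }, character(1))
  segments <- tibble::tibble(
    segment = segments$index, wt_dna = segments$wt_dna,
    nt_length = nchar(segments$wt_dna),
    aa_start = segments$aa_start, aa_end = segments$aa_end)

  if (nrow(v) == 0L) {
    keys <- tibble::tibble(insert_seq = character(), segment = integer(),
                           codon_offset = integer(), group_id = character(),
                           variant_ids = list(), is_wt_group = logical(),
                           nt_length = integer())
    return(structure(list(keys = keys, segments = segments),
                     class = "variant_index"))
  }

  grp <- unname(split(seq_len(nrow(v)), v$insert_seq))
  insert_seq <- sort(unique(v$insert_seq))
  variant_ids <- lapply(grp, function(i) sort(v$id[i]))
  segment <- vapply(grp, function(i) v$segment[i[1L]], integer(1))
  is_wt_ref <- insert_seq == segments$wt_dna[segment]
  codon_offset <- ifelse(is_wt_ref, NA_integer_,
                         vapply(grp, function(i) v$codon_offset[i[1L]],
                                integer(1)))
  singleton <- lengths(grp) == 1L
  first <- vapply(grp, `[[`, integer(1), 1L)
  keys <- tibble::tibble(
    insert_seq = insert_seq, segment = segment,
    codon_offset = as.integer(codon_offset),
    group_id = vapply(variant_ids, paste, character(1), collapse = "|"),
    variant_ids = variant_ids,
    is_wt_group = vapply(grp, function(i) all(v$is_wt_control[i]), logical(1)),
    position = ifelse(singleton, v$position[first], NA_integer_),
    ref_aa = ifelse(singleton, v$ref_aa[first], NA_character_),
    alt_aa = ifelse(singleton, v$alt_aa[first], NA_character_),
    nt_length = nchar(insert_seq))
  keys <- keys[order(keys$segment, keys$group_id), ]
  structure(list(keys = keys, segments = segments), class = "variant_index")
}

#' @export
print.variant_index <- function(x, ...) {
  cat("<variant_index> ", nrow(x$keys), " keys over ",
      nrow(x$segments), " segments (",
      sum(lengths(x$keys$variant_ids) > 1L), " collision groups)\n", sep = "")
  invisible(x)
}

#' Write a design table as TSV
#'
#' Columns: id, position, ref_aa, alt_aa, segment, is_wt_control, insert_seq.
#' @param design A `mutagenesis_design`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_design_tsv <- function(design, path) {
  v <- design$variants[, c("id", "position", "ref_aa", "alt_aa", "segment",
                           "is_wt_control", "insert_seq")]
  utils::write.table(v, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write library insert sequences as FASTA (headers = variant ids)
#' @inheritParams write_design_tsv
#' @return `path`, invisibly.
#' @export
write_insert_fasta <- function(design, path) {
  s <- Biostrings::DNAStringSet(design$variants$insert_seq)
  names(s) <- design$variants$id
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Deterministic synthetic test protein
#'
#' A reproducible random amino-acid sequence starting with methionine, used
#' as a stand-in for a real screen target when only the size of the protein
#' matters (the default mirrors a 213-residue transcription factor). The
#' sequence is synthetic; it is not any natural protein.
#'
#' @param length Protein length in residues (default 213).
#' @param seed RNG seed (fixed default for reproducibility).
#' @return Amino-acid string of `length` residues.
#' @export
synthetic_protein <- function(length = 213L, seed = 101L) {
  stopifnot(length >= 1L)
  with_seed_if(seed, {
    paste(c("M", sample(AA_ALPHABET, length - 1L, replace = TRUE)),
          collapse = "")
  })
}
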