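#' Configuration of the FACS sort-and-sequence screen simulator
#'
#' Generative model of the pooled reporter screen: cells are transduced at
#' low multiplicity of infection (single-copy assumption), each infected
#' cell carries one library variant drawn from a log-normal library
#' composition, its reporter fluorescence is
#' `fluor_base + activity * dynamic_range + Normal(0, noise_sigma)` in log10
#' units, and cells are gated into a dim bin (below `gate`) and a bright bin
#' (at or above it). `reads_per_bin` sequencing reads are drawn multinomially
#' over each bin's cells; each read is `flank5 + insert + flank3` with
#' i.i.d. substitution errors.
#'
#' @param n_cells Cells per pool per replicate; `NULL` (default) auto-sizes
#'   to give 200-fold library representation at the configured MOI.
#' @param moi Expected lentiviral integrations per cell (default 0.3).
#' @param abundance_sigma Log-normal sd of library composition (default 0.5).
#' @param fluor_base log10 fluorescence of an inactive reporter (default 1).
#' @param dynamic_range log10 span between inactive and fully active
#'   (default 2; wild type then sits at 3, one decade above the gate).
#' @param noise_sigma Per-cell log10 fluorescence sd (default 0.3).
#' @param gate log10 threshold splitting dim from bright (default 2,
#'   midway through the dynamic range).
#' @param reads_per_bin Reads sequenced per pool x replicate x bin
#'   (default 200000, about 140 reads per variant per bin — modest relative
#'   to a production short-read run).
#' @param read_error_rate Per-base substitution probability (default 0.001).
#' @param flank5,flank3 Constant DNA flanks around the mutagenised segment.
#' @param n_replicates Independent transduction replicates (default 2).
#' @param seed RNG seed.
#' @return Object of class `sortseq_config`.
#' @export
sortseq_config <- function(n_cells = NULL, moi = 0.3, abundance_sigma = 0.5,
                           fluor_base = 1.0, dynamic_range = 2.0,
                           noise_sigma = 0.3, gate = 2.0,
                           reads_per_bin = 200000L, read_error_rate = 0.001,
                           flank5 = "ACTGGCCGCTTCACT",
                           flank3 = "GTTTAAGAGCTAAGC",
                           n_replicates = 2L, seed = NULL) {
  if (moi <= 0) stop("`moi` must be positive", call. = FALSE)
  if (reads_per_bin <= 0) stop("`reads_per_bin` must be positive", call. = FALSE)
  if (read_error_rate < 0 || read_error_rate >= 1)
    stop("`read_error_rate` must be in [0, 1)", call. = FALSE)
  stopifnot(grepl("^[ACGT]+$", flank5), grepl("^[ACGT]+$", flank3),
            n_replicates >= 1L)
  structure(list(n_cells = n_cells, moi = moi,
                 abundance_sigma = abundance_sigma, fluor_base = fluor_base,
                 dynamic_range = dynamic_range, noise_sigma = noise_sigma,
                 gate = gate, reads_per_bin = as.integer(reads_per_bin),
                 read_error_rate = read_error_rate,
                 flank5 = flank5, flank3 = flank3,
                 n_replicates = as.integer(n_replicates), seed = seed),
            class = "sortseq_config")
}

# Apply i.i.d. per-base substitution errors to a character vector of reads.
inject_read_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  len <- nchar(reads)
  n_err <- stats::rbinom(length(reads), len, rate)
  one <- which(n_err == 1L)
  if (length(one)) {
    pos <- 1L + floor(stats::runif(length(one)) * len[one])
    cur <- substr(reads[one], pos, pos)
    shift <- sample.int(3L, length(one), replace = TRUE)
    new <- DNA_BASES[(match(cur, DNA_BASES) - 1L + shift) %% 4L + 1L]
    substr(reads[one], pos, pos) <- new
  }
  multi <- which(n_err >= 2L)
  for (i in multi) {
    pos <- sample.int(len[i], n_err[i])
    for (p in pos) {
      cur <- substr(reads[i], p, p)
      new <- sample(DNA_BASES[DNA_BASES != cur], 1L)
      substr(reads[i], p, p) <- new
    }
  }
  reads
}

write_fastq <- function(reads, ids, path, qual_char = "I") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(reads)) {
    rec <- matrix(c(paste0("@", ids), reads,
                    rep("+", length(reads)), strrep(qual_char, nchar(reads))),
                  nrow = 4L, byrow = TRUE)
    writeLines(as.vector(rec), con)
  }
  invisible(path)
}

#' Simulate the sorted screen: per-bin FASTQ files plus planted truth
#'
#' Runs the generative model of [sortseq_config()] for every pool and
#' replicate of the design and writes one FASTQ file per pool x replicate x
#' bin, named `pool<p>_rep<r>_<bin>.fastq` (`bin` is `dim` or `bright`).
#' Per-variant cell counts per bin are drawn by exact binomial thinning of
#' the multinomial cell counts with
#' `p(bright) = pnorm((fluor_base + a * dynamic_range - gate) / noise_sigma)`,
#' which is equivalent to simulating each cell's Gaussian fluorescence and
#' gating it. An empty bin produces a warning and an empty FASTQ file.
#'
#' @param design A [design_library()] result.
#' @param activity_map Named activity vector from [simulate_landscape()]
#'   (must cover every design variant).
#' @param cfg A [sortseq_config()].
#' @param out_dir Directory for FASTQ output (created if needed).
#' @return List with `files` (tibble: pool, replicate, bin, path, n_reads),
#'   `truth` (tibble: pool, replicate, bin, variant, cells, reads),
#'   `representation` (tibble: pool, n_variants, n_cells, expected_coverage)
#'   and `config`.
#' @export
simulate_sort_seq <- function(design, activity_map, cfg = sortseq_config(),
                              out_dir) {
  stopifnot(inherits(design, "mutagenesis_design"),
            inherits(cfg, "sortseq_config"))
  v <- design$variants
  missing <- setdiff(v$id, names(activity_map))
  if (length(missing))
    stop("`activity_map` lacks activities for ", length(missing),
         " variants (e.g. ", missing[1L], ")", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  pools <- design$pool_layout
  pool_variants <- lapply(pools, function(tiles) which(v$segment %in% tiles))
  p_infected <- 1 - exp(-cfg$moi)
  n_cells <- cfg$n_cells %||%
    ceiling(200 * max(lengths(pool_variants)) / p_infected)

  representation <- tibble::tibble(
    pool = as.integer(names(pools)),
    n_variants = lengths(pool_variants),
    n_cells = n_cells,
    expected_coverage = n_cells * p_infected / lengths(pool_variants))
  low <- representation$expected_coverage < 200
  if (any(low))
    warning("expected library representation below 200-fold for pool(s) ",
            paste(representation$pool[low], collapse = ", "), call. = FALSE)

  files <- list(); truth <- list()
  with_seed_if(cfg$seed, {
    for (p in seq_along(pools)) {
      idx <- pool_variants[[p]]
      ids <- v$id[idx]
      a <- unname(activity_map[ids])
      mu <- cfg$fluor_base + a * cfg$dynamic_range
      p_bright <- if (cfg$noise_sigma > 0)
        stats::pnorm((mu - cfg$gate) / cfg$noise_sigma)
      else as.numeric(mu >= cfg$gate)
      w <- stats::rlnorm(length(idx), 0, cfg$abundance_sigma)
      templates <- paste0(cfg$flank5, v$insert_seq[idx], cfg$flank3)
      for (r in seq_len(cfg$n_replicates)) {
        n_inf <- stats::rbinom(1L, n_cells, p_infected)
        cells <- as.integer(stats::rmultinom(1L, n_inf, w))
        bright <- stats::rbinom(length(idx), cells, p_bright)
        bins <- list(dim = cells - bright, bright = bright)
        for (bin in names(bins)) {
          bc <- bins[[bin]]
          path <- file.path(out_dir,
                            sprintf("pool%d_rep%d_%s.fastq", p, r, bin))
          if (sum(bc) == 0L) {
            warning(sprintf("pool %d rep %d bin %s: no cells; writing empty FASTQ",
                            p, r, bin), call. = FALSE)
            reads_v <- integer(length(idx))
            write_fastq(character(0), character(0), path)
          } else {
            reads_v <- as.integer(stats::rmultinom(1L, cfg$reads_per_bin, bc))
            reads <- inject_read_errors(rep(templates, reads_v),
                                        cfg$read_error_rate)
            rid <- sprintf("p%dr%d%s:%06d", p, r, substr(bin, 1, 1),
                           seq_along(reads))
            write_fastq(reads, rid, path)
          }
          bin_cells <- bins[[bin]]
          files[[length(files) + 1L]] <- tibble::tibble(
            pool = p, replicate = r, bin = bin, path = path,
            n_reads = sum(reads_v))
          truth[[length(truth) + 1L]] <- tibble::tibble(
            pool = p, replicate = r, bin = bin, variant = ids,
            cells = bin_cells, reads = reads_v)
        }
      }
    }
  })
  list(files = dplyr::bind_rows(files), truth = dplyr::bind_rows(truth),
       representation = representation, config = cfg)
}
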