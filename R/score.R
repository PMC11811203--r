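#' Scoring configuration for sort-seq enrichment
#'
#' @param pseudocount Count pseudocount `c >= 0` added to every variant in
#'   both bins before frequencies are formed (default 0.5).
#' @return Object of class `score_config`.
#' @export
score_config <- function(pseudocount = 0.5) {
  if (pseudocount < 0) stop("`pseudocount` must be >= 0", call. = FALSE)
  structure(list(pseudocount = pseudocount), class = "score_config")
}

#' Replicate-filter configuration
#'
#' @param min_reads_per_replicate Minimum reads (dim + bright) a variant
#'   needs in every replicate to count as recovered (default 20).
#' @param concordance_delta Maximum absolute difference between normalised
#'   replicate scores before a variant is flagged discordant (default 0.5).
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(min_reads_per_replicate = 20L,
                          concordance_delta = 0.5) {
  stopifnot(min_reads_per_replicate >= 0L, concordance_delta >= 0)
  structure(list(min_reads_per_replicate = as.integer(min_reads_per_replicate),
                 concordance_delta = concordance_delta),
            class = "filter_config")
}

#' Wild-type-anchored enrichment scores per variant
#'
#' For each normalisation scope (pool x replicate) the raw enrichment of a
#' variant is the ratio of its pseudocounted frequency in the bright bin to
#' that in the dim bin,
#' `e_v = [(b_v + c) / sum(b + c)] / [(d_v + c) / sum(d + c)]`,
#' and the normalised score is `s_v = e_v / mean(e over wild-type controls
#' of the scope)`, so that the mean wild-type score is exactly 1 in every
#' scope.
#'
#' @param count_table A [tabulate_counts()] result.
#' @param score_cfg A [score_config()].
#' @param design Optional [design_library()] result; when given, each pool's
#'   scope is restricted to the variants of its own segments (per the pool
#'   layout). Otherwise every index key is scored in every pool.
#' @return A `score_table` tibble: one row per variant (collision-group id),
#'   columns `variant`, `pool`, `segment`, `position`, `ref_aa`, `alt_aa`,
#'   `is_wt_control`, then `reads_rep<r>`, `e_rep<r>`, `s_rep<r>` per
#'   replicate and `s_mean`.
#' @export
enrichment_scores <- function(count_table, score_cfg = score_config(),
                              design = NULL) {
  stopifnot(inherits(count_table, "count_table"),
            inherits(score_cfg, "score_config"))
  cc <- count_table$counts
  keys <- count_table$keys
  c0 <- score_cfg$pseudocount
  reps <- sort(unique(cc$replicate))
  pools <- sort(unique(cc$pool))

  pool_rows <- list()
  for (p in pools) {
    scope_keys <- keys
    if (!is.null(design)) {
      tiles <- design$pool_layout[[as.character(p)]]
      if (is.null(tiles))
        stop("pool ", p, " not present in the design pool layout",
             call. = FALSE)
      scope_keys <- keys[keys$segment %in% tiles, ]
    }
    if (!any(scope_keys$is_wt_group))
      stop("no wild-type controls in scope pool ", p, call. = FALSE)
    res <- tibble::tibble(variant = scope_keys$group_id, pool = p,
                          segment = scope_keys$segment,
                          position = scope_keys$position,
                          ref_aa = scope_keys$ref_aa,
                          alt_aa = scope_keys$alt_aa,
                          is_wt_control = scope_keys$is_wt_group)
    for (r in reps) {
      sub <- cc[cc$pool == p & cc$replicate == r, ]
      if (!all(c("dim", "bright") %in% sub$bin))
        stop("pool ", p, " replicate ", r,
             ": both sort bins are required for scoring", call. = FALSE)
      b <- sub$count[sub$bin == "bright"][
        match(res$variant, sub$variant[sub$bin == "bright"])]
      d <- sub$count[sub$bin == "dim"][
        match(res$variant, sub$variant[sub$bin == "dim"])]
      if (anyNA(b) || anyNA(d))
        stop("count table lacks entries for some variants in pool ", p,
             " replicate ", r, call. = FALSE)
      f_b <- (b + c0) / sum(b + c0)
      f_d <- (d + c0) / sum(d + c0)
      e <- f_b / f_d
      s <- e / mean(e[res$is_wt_control])
      res[[paste0("reads_rep", r)]] <- b + d
      res[[paste0("e_rep", r)]] <- e
      res[[paste0("s_rep", r)]] <- s
    }
    pool_rows[[length(pool_rows) + 1L]] <- res
  }
  out <- dplyr::bind_rows(pool_rows)
  out$s_mean <- rowMeans(as.matrix(out[paste0("s_rep", reps)]))
  attr(out, "replicates") <- reps
  class(out) <- c("score_table", class(out))
  out
}

score_replicates <- function(score_table) {
  reps <- attr(score_table, "replicates")
  if (is.null(reps))
    reps <- sort(as.integer(sub("^s_rep", "",
                                grep("^s_rep[0-9]+$", names(score_table),
                                     value = TRUE))))
  if (length(reps) < 2L)
    stop("at least two replicates are required", call. = FALSE)
  reps
}

#' Apply recovery and concordance filters
#'
#' A variant is `recovered` when its total reads (dim + bright) reach
#' `min_reads_per_replicate` in every replicate, `discordant` when it is
#' recovered but its normalised replicate scores differ by more than
#' `concordance_delta` (maximum pairwise absolute difference), and
#' `retained` when recovered and not discordant.
#'
#' @param score_table An [enrichment_scores()] result.
#' @param filter_cfg A [filter_config()].
#' @return The score table with logical columns `recovered`, `discordant`,
#'   `retained` added.
#' @export
apply_filters <- function(score_table, filter_cfg = filter_config()) {
  stopifnot(inherits(filter_cfg, "filter_config"))
  reps <- score_replicates(score_table)
  reads <- as.matrix(score_table[paste0("reads_rep", reps)])
  s <- as.matrix(score_table[paste0("s_rep", reps)])
  recovered <- rowSums(reads >= filter_cfg$min_reads_per_replicate) ==
    length(reps)
  max_delta <- apply(s, 1L, function(x) max(x) - min(x))
  discordant <- recovered & max_delta > filter_cfg$concordance_delta
  score_table$recovered <- recovered
  score_table$discordant <- discordant
  score_table$retained <- recovered & !discordant
  score_table
}

#' Filter bookkeeping summary
#'
#' @param score_table A flagged [apply_filters()] result.
#' @param n_designed Denominator for the retained percentage (defaults to
#'   the number of scored variants).
#' @return One-row tibble: `n_designed`, `n_recovered`, `n_discordant`,
#'   `n_retained`, `pct_retained`.
#' @export
summarize_filters <- function(score_table, n_designed = nrow(score_table)) {
  stopifnot(all(c("recovered", "discordant", "retained") %in%
                  names(score_table)))
  tibble::tibble(
    n_designed = n_designed,
    n_recovered = sum(score_table$recovered),
    n_discordant = sum(score_table$discordant),
    n_retained = sum(score_table$retained),
    pct_retained = 100 * sum(score_table$retained) / n_designed)
}

#' Position-by-amino-acid activity matrix
#'
#' Fills a (mutagenised positions) x 20 grid with the mean normalised score
#' of every retained variant; non-retained or unscored cells are missing.
#' Collision groups spanning several positions (collapsed Met/Trp wild-type
#' controls) cannot be placed in a single cell and stay missing.
#'
#' @param score_table A flagged [apply_filters()] result.
#' @param design The [design_library()] used for scoring.
#' @return Object of class `activity_matrix`: list with `grid` (numeric
#'   matrix, rownames = positions, colnames = alphabet), `position_means`
#'   (named, `NA` where a whole row is missing) and `missing` (tibble:
#'   position, aa).
#' @export
activity_matrix <- function(score_table, design) {
  stopifnot(inherits(design, "mutagenesis_design"),
            "retained" %in% names(score_table))
  alphabet <- design$config$alphabet
  positions <- sort(unique(design$variants$position))
  grid <- matrix(NA_real_, length(positions), length(alphabet),
                 dimnames = list(positions, alphabet))
  st <- score_table[score_table$retained & !is.na(score_table$position), ]
  if (nrow(st)) {
    cell <- paste(st$position, st$alt_aa)
    if (anyDuplicated(cell))
      stop("duplicate (position, amino acid) cells in score table",
           call. = FALSE)
    grid[cbind(match(st$position, positions), match(st$alt_aa, alphabet))] <-
      st$s_mean
  }
  pm <- rowMeans(grid, na.rm = TRUE)
  pm[is.nan(pm)] <- NA_real_
  miss <- which(is.na(grid), arr.ind = TRUE)
  structure(list(grid = grid,
                 position_means = stats::setNames(pm, rownames(grid)),
                 missing = tibble::tibble(
                   position = positions[miss[, 1L]],
                   aa = alphabet[miss[, 2L]])),
            class = "activity_matrix")
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat("<activity_matrix> ", nrow(x$grid), " positions x ", ncol(x$grid),
      " amino acids; ", nrow(x$missing), " missing cells\n", sep = "")
  invisible(x)
}

#' Write the activity matrix as TSV (positions x amino acids, NA = missing)
#' @param am An [activity_matrix()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_activity_matrix <- function(am, path) {
  utils::write.table(data.frame(position = rownames(am$grid), am$grid,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Heatmap of the activity matrix
#'
#' Red-to-blue heatmap of scores (wild type = 1) in protein order, mirroring
#' the standard deep-mutational-scan display; missing cells are grey.
#'
#' @param am An [activity_matrix()] result.
#' @param filename Optional image path (passed to [pheatmap::pheatmap()]).
#' @param ... Further arguments to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
plot_activity_matrix <- function(am, filename = NA, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plotting requires the pheatmap package", call. = FALSE)
  breaks <- seq(0, max(1.5, max(am$grid, na.rm = TRUE)), length.out = 101)
  p <- pheatmap::pheatmap(
    t(am$grid), cluster_rows = FALSE, cluster_cols = FALSE,
    color = grDevices::colorRampPalette(c("#b2182b", "#f7f7f7",
                                          "#2166ac"))(100),
    breaks = breaks, na_col = "grey40", border_color = NA,
    filename = filename, ...)
  invisible(p)
}

# Exact two-sided rank-sum p-value by enumeration (midranks for ties).
exact_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x); n <- length(pooled)
  w_obs <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  combs <- utils::combn(n, nx)
  w_all <- colSums(matrix(r[combs], nrow = nx))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Normal-approximation two-sided rank-sum p-value with tie correction.
approx_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x); ny <- length(y); n <- nx + ny
  w <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  ties <- table(pooled)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  2 * stats::pnorm(-abs(w - mu) / sqrt(sigma2))
}

#' Compare mutational tolerance between structure classes
#'
#' Splits positions into ordered (confidence above `ordered_threshold`,
#' pLDDT-style) and disordered classes and compares their per-position mean
#' activity scores with a two-sided rank-sum test: exact enumeration when
#' both classes have at most 10 positions, tie-corrected normal
#' approximation otherwise.
#'
#' @param am An [activity_matrix()] result.
#' @param annotation Named numeric vector (position -> confidence) or a
#'   data frame with columns `position` and `confidence`; must cover every
#'   matrix position.
#' @param ordered_threshold Confidence cut-off (default 60).
#' @return List with `ordered`/`disordered` (per-position mean scores),
#'   `mean_ordered`, `mean_disordered`, `n_ordered`, `n_disordered`,
#'   `p_value` (`NA` when a class is empty) and `method`.
#' @export
compare_structure_classes <- function(am, annotation,
                                      ordered_threshold = 60) {
  stopifnot(inherits(am, "activity_matrix"))
  if (is.data.frame(annotation))
    annotation <- stats::setNames(annotation$confidence,
                                  annotation$position)
  positions <- rownames(am$grid)
  if (!all(positions %in% names(annotation)))
    stop("`annotation` must cover every matrix position", call. = FALSE)
  conf <- annotation[positions]
  if (any(!is.finite(conf)))
    stop("confidence values must be finite", call. = FALSE)
  pm <- am$position_means
  keep <- !is.na(pm)
  ordered <- pm[keep & conf > ordered_threshold]
  disordered <- pm[keep & conf <= ordered_threshold]
  if (length(ordered) == 0L || length(disordered) == 0L) {
    p <- NA_real_; method <- "undefined (empty class)"
  } else if (length(ordered) <= 10L && length(disordered) <= 10L) {
    p <- exact_ranksum_p(ordered, disordered); method <- "exact"
  } else {
    p <- approx_ranksum_p(ordered, disordered)
    method <- "normal approximation"
  }
  list(ordered = ordered, disordered = disordered,
       mean_ordered = if (length(ordered)) mean(ordered) else NA_real_,
       mean_disordered = if (length(disordered)) mean(disordered)
                         else NA_real_,
       n_ordered = length(ordered), n_disordered = length(disordered),
       p_value = p, method = method)
}

#' Classify listed variants as functionally impaired or active
#'
#' A variant is `impaired` when its mean normalised score falls strictly
#' below `threshold` (default 0.5, i.e. below 50% of wild-type activity);
#' a score of exactly the threshold is `active`. Variants absent from the
#' score table or not retained by the filters are reported unclassifiable
#' and excluded from the impaired fraction.
#'
#' @param score_table A flagged [apply_filters()] result.
#' @param variant_list Character vector of variant ids (e.g. `"C5A"`).
#' @param threshold Activity cut-off (default 0.5).
#' @return List with `calls` (tibble: variant, s_mean, classifiable, call)
#'   and `impaired_fraction` (impaired / classifiable).
#' @export
classify_patient_variants <- function(score_table, variant_list,
                                      threshold = 0.5) {
  stopifnot("retained" %in% names(score_table))
  if (length(variant_list) == 0L)
    stop("`variant_list` must not be empty", call. = FALSE)
  members <- strsplit(score_table$variant, "|", fixed = TRUE)
  row_of <- function(id) {
    hit <- which(vapply(members, function(m) id %in% m, logical(1)))
    if (length(hit)) hit[1L] else NA_integer_
  }
  rows <- unname(vapply(variant_list, row_of, integer(1)))
  s <- ifelse(is.na(rows), NA_real_, score_table$s_mean[rows])
  classifiable <- !is.na(rows) &
    replace(score_table$retained[pmax(rows, 1L)], is.na(rows), FALSE)
  call <- ifelse(!classifiable, "unclassifiable",
                 ifelse(s < threshold, "impaired", "active"))
  calls <- tibble::tibble(variant = variant_list, s_mean = s,
                          classifiable = classifiable, call = call)
  list(calls = calls,
       impaired_fraction = if (any(classifiable))
         sum(call == "impaired") / sum(classifiable) else NA_real_)
}

#' Write a score table as TSV
#' @param score_table A score table (flagged or not).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(score_table, path) {
  utils::write.table(as.data.frame(score_table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
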