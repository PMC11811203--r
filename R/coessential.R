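#' Rank co-essential partners of a query gene
#'
#' Pearson correlation of the query gene's effect-score profile (essentiality
#' across cell lines; more negative = more essential) with every other
#' gene's, using pairwise-complete lines. Partners with fewer than three
#' overlapping lines are skipped with a warning. Hits are ranked by
#' descending correlation, ties broken lexicographically by partner name.
#'
#' @param effects Gene x line numeric matrix (rownames = genes); `NA`
#'   entries allowed.
#' @param query_gene Row name of the query.
#' @param top_k Number of hits to return (default 25; `Inf` for all).
#' @return Tibble: `gene_a` (query), `gene_b`, `pearson_r`, `n_lines`,
#'   `rank`.
#' @export
pairwise_coessentiality <- function(effects, query_gene, top_k = 25L) {
  stopifnot(is.matrix(effects), !is.null(rownames(effects)))
  if (!query_gene %in% rownames(effects))
    stop("query gene '", query_gene, "' not in matrix", call. = FALSE)
  x <- effects[query_gene, ]
  partners <- setdiff(rownames(effects), query_gene)
  n_ok <- rowSums(!is.na(effects[partners, , drop = FALSE]) &
                    matrix(!is.na(x), length(partners), length(x),
                           byrow = TRUE))
  skip <- partners[n_ok < 3L]
  if (length(skip))
    warning(length(skip), " partner(s) skipped (< 3 overlapping lines)",
            call. = FALSE)
  partners <- partners[n_ok >= 3L]
  if (!length(partners))
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          pearson_r = numeric(), n_lines = integer(),
                          rank = integer()))
  r <- suppressWarnings(
    as.numeric(stats::cor(x, t(effects[partners, , drop = FALSE]),
                          use = "pairwise.complete.obs")))
  hits <- tibble::tibble(gene_a = query_gene, gene_b = partners,
                         pearson_r = r,
                         n_lines = as.integer(n_ok[n_ok >= 3L]))
  hits <- hits[order(-hits$pearson_r, hits$gene_b), ]
  hits$rank <- seq_len(nrow(hits))
  utils::head(hits, top_k)
}

#' Count cell lines dependent on a gene at an effect threshold
#'
#' @param effects Gene x line matrix.
#' @param gene Gene name.
#' @param threshold Effect cut-off; lines with effect strictly below it
#'   count as dependent (default -0.25).
#' @return List with `count_below`, `total` (non-missing lines).
#' @export
essential_line_count <- function(effects, gene, threshold = -0.25) {
  stopifnot(is.matrix(effects))
  if (!gene %in% rownames(effects))
    stop("gene '", gene, "' not in matrix", call. = FALSE)
  x <- effects[gene, ]
  x <- x[!is.na(x)]
  if (!length(x))
    stop("gene '", gene, "' has no non-missing effect scores", call. = FALSE)
  list(count_below = sum(x < threshold), total = length(x))
}

#' Relate a gene's essentiality to an expression covariate
#'
#' Pearson correlation between the gene's effect scores and a per-line
#' covariate (e.g. expression of a bypass paralog), plus the covariate's
#' mean among dependent (effect below `threshold`) versus non-dependent
#' lines.
#'
#' @param effects Gene x line matrix.
#' @param gene Gene name.
#' @param covariate Named numeric vector over (a superset of) the lines.
#' @param threshold Dependence cut-off (default -0.25).
#' @return List with `pearson_r` (`NA` for a zero-variance covariate),
#'   `n_lines`, `mean_covariate_dependent`, `mean_covariate_nondependent`.
#' @export
essentiality_expression_relation <- function(effects, gene, covariate,
                                             threshold = -0.25) {
  stopifnot(is.matrix(effects))
  if (!gene %in% rownames(effects))
    stop("gene '", gene, "' not in matrix", call. = FALSE)
  lines <- intersect(colnames(effects), names(covariate))
  x <- effects[gene, lines]
  y <- covariate[lines]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop("covariate defined on fewer than 3 lines with effect scores",
         call. = FALSE)
  r <- if (stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  dep <- x < threshold
  list(pearson_r = r, n_lines = length(x),
       mean_covariate_dependent = if (any(dep)) mean(y[dep]) else NA_real_,
       mean_covariate_nondependent = if (any(!dep)) mean(y[!dep])
                                     else NA_real_)
}

#' Lineage enrichment of a line selection (hypergeometric upper tail)
#'
#' Tests whether a selection of cell lines is enriched for target lineage
#' classes: with `K` target-class lines among `N` total and `k` of them in
#' a selection of size `n`, `p = P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`.
#'
#' @param selection Character vector of selected line names (must be a
#'   subset of `names(lineage_labels)`).
#' @param lineage_labels Named character vector: line -> lineage.
#' @param target_classes Lineage classes counted as hits.
#' @return List with `k`, `n`, `K`, `N`, `p`.
#' @export
lineage_enrichment <- function(selection, lineage_labels, target_classes) {
  if (length(selection) == 0L)
    stop("`selection` must not be empty", call. = FALSE)
  if (!all(selection %in% names(lineage_labels)))
    stop("`selection` contains lines absent from `lineage_labels`",
         call. = FALSE)
  N <- length(lineage_labels)
  K <- sum(lineage_labels %in% target_classes)
  n <- length(selection)
  k <- sum(lineage_labels[selection] %in% target_classes)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  list(k = k, n = n, K = K, N = N, p = p)
}

#' Read / write gene-effect matrices as TSV (genes x lines)
#'
#' @param path TSV path; first column = gene names, header = line ids.
#' @return Numeric matrix with dimnames.
#' @export
read_gene_effects_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         check.names = FALSE, row.names = 1L)
  as.matrix(d)
}

#' @param effects Gene x line matrix.
#' @rdname read_gene_effects_tsv
#' @export
write_gene_effects_tsv <- function(effects, path) {
  utils::write.table(data.frame(gene = rownames(effects), effects,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
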