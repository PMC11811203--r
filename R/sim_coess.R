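#' Configuration of the gene-effect (co-essentiality) simulator
#'
#' Generates a gene x cell-line essentiality matrix (more negative = more
#' essential) with planted structure: gene modules sharing a latent per-line
#' factor (`effect = loading * factor + noise`), and a "rescue" gene whose
#' essentiality is relieved in lines expressing a bypass covariate
#' (`effect = base + beta * standardize(X) + noise`). Lines carry lineage
#' labels; by default the bypass covariate is high in immune lineages,
#' mirroring immunoproteasome-style substitution of an essential subunit.
#'
#' @param n_genes,n_lines Matrix dimensions (`n_lines >= 3`).
#' @param module_specs List of `list(genes = <ids>, loading = <numeric>)`.
#'   Named genes replace the first auto-generated gene names.
#' @param rescue_spec `list(gene, base, beta, high_classes, expr_high,
#'   expr_low, expr_sd)` or `NULL`: the rescue gene's effect is
#'   `base + beta * z(X)` plus noise, where the covariate X is drawn
#'   `Normal(expr_high, expr_sd)` in `high_classes` lineages and
#'   `Normal(expr_low, expr_sd)` elsewhere.
#' @param lineage_levels Lineage label pool.
#' @param immune_fraction Fraction of lines drawn from the first two
#'   (immune) lineage levels (default 0.15).
#' @param noise_sigma Per-entry Gaussian noise sd (default 0.25).
#' @param seed RNG seed.
#' @return Object of class `coess_sim_config`.
#' @export
coess_sim_config <- function(
    n_genes = 1000L, n_lines = 1100L,
    module_specs = list(list(genes = c("REG", "TARGET1", "TARGET2"),
                             loading = 0.2)),
    rescue_spec = list(gene = "REG", base = -0.55, beta = 0.15,
                       high_classes = c("myeloid", "lymphoid"),
                       expr_high = 6, expr_low = 2, expr_sd = 1),
    lineage_levels = c("myeloid", "lymphoid", "lung", "breast", "skin",
                       "colon", "cns", "ovary", "pancreas", "bone"),
    immune_fraction = 0.15,
    noise_sigma = 0.2,
    seed = NULL) {
  if (n_lines < 3L)
    stop("`n_lines` must be >= 3 for correlations to be defined",
         call. = FALSE)
  for (m in module_specs)
    if (!is.finite(m$loading)) stop("module loadings must be finite",
                                    call. = FALSE)
  structure(list(n_genes = as.integer(n_genes), n_lines = as.integer(n_lines),
                 module_specs = module_specs, rescue_spec = rescue_spec,
                 lineage_levels = lineage_levels,
                 immune_fraction = immune_fraction,
                 noise_sigma = noise_sigma, seed = seed),
            class = "coess_sim_config")
}

#' Simulate a gene-effect matrix with planted co-essential modules
#'
#' @param cfg A [coess_sim_config()].
#' @return List with `effects` (gene x line matrix), `lineage` (named
#'   character per line), `expression` (named numeric bypass covariate per
#'   line, `NULL` without a rescue spec), `truth` (module and rescue specs)
#'   and `config`.
#' @export
simulate_gene_effects <- function(cfg = coess_sim_config()) {
  stopifnot(inherits(cfg, "coess_sim_config"))
  special <- unique(c(unlist(lapply(cfg$module_specs, `[[`, "genes")),
                      cfg$rescue_spec$gene))
  if (length(special) > cfg$n_genes)
    stop("`n_genes` smaller than the number of named planted genes",
         call. = FALSE)
  genes <- c(special,
             sprintf("G%05d", seq_len(cfg$n_genes - length(special))))
  lines <- sprintf("L%04d", seq_len(cfg$n_lines))

  with_seed_if(cfg$seed, {
    n_immune <- round(cfg$immune_fraction * cfg$n_lines)
    lineage <- c(sample(cfg$lineage_levels[1:2], n_immune, replace = TRUE),
                 sample(cfg$lineage_levels[-(1:2)], cfg$n_lines - n_immune,
                        replace = TRUE))
    lineage <- stats::setNames(sample(lineage), lines)

    effects <- matrix(stats::rnorm(cfg$n_genes * cfg$n_lines, 0,
                                   cfg$noise_sigma),
                      nrow = cfg$n_genes, dimnames = list(genes, lines))
    for (m in cfg$module_specs) {
      f <- stats::rnorm(cfg$n_lines)
      for (g in m$genes)
        effects[g, ] <- effects[g, ] + m$loading * f
    }
    expression <- NULL
    rs <- cfg$rescue_spec
    if (!is.null(rs)) {
      high <- lineage %in% rs$high_classes
      expression <- stats::setNames(
        stats::rnorm(cfg$n_lines,
                     ifelse(high, rs$expr_high, rs$expr_low), rs$expr_sd),
        lines)
      z <- as.numeric(scale(expression))
      effects[rs$gene, ] <- effects[rs$gene, ] + rs$base + rs$beta * z
    }
    list(effects = effects, lineage = lineage, expression = expression,
         truth = list(module_specs = cfg$module_specs, rescue_spec = rs),
         config = cfg)
  })
}
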