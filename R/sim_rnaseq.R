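#' Configuration of the RNA-seq count simulator
#'
#' Negative-binomial counts for three groups — untransduced cells, cells
#' carrying a control sgRNA and cells with the regulator knocked out
#' (sgTHAP1) — with planted truth: a set of genes shifted in the knockout
#' only (true targets, down- and upregulated), an artifact set shifted in
#' both sgRNA-carrying groups relative to untransduced (transduction
#' response, to be discounted), and per-gene promoter-occupancy flags of
#' which a subset coincides with the planted targets (true direct targets).
#' Default planted sizes (220 down, 57 up, 42 of them occupied) mirror the
#' qualitative structure of a regulator-knockout experiment.
#'
#' @param n_genes Number of genes.
#' @param reps Named integer vector of replicate counts for groups
#'   `untransduced`, `sgControl`, `sgTHAP1` (default 3 each).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of per-gene
#'   baseline expression.
#' @param dispersion NB dispersion (size = 1/dispersion); must be > 0.
#' @param n_down,n_up Numbers of true-target genes down/up in the knockout.
#' @param lfc_down,lfc_up log2 fold-change ranges (uniform) for planted
#'   targets.
#' @param n_artifact Genes DE in both sgRNA groups vs untransduced.
#' @param lfc_artifact Absolute log2 fold-change range for artifact genes
#'   (sign random).
#' @param n_occupied_de Planted targets flagged promoter-occupied
#'   (default 42).
#' @param n_occupied_bg Non-target genes flagged occupied (background
#'   occupancy).
#' @param seed RNG seed.
#' @return Object of class `rnaseq_sim_config`.
#' @export
rnaseq_sim_config <- function(
    n_genes = 10000L,
    reps = c(untransduced = 3L, sgControl = 3L, sgTHAP1 = 3L),
    baseline_meanlog = log(100), baseline_sdlog = 1.3,
    dispersion = 0.08,
    n_down = 220L, n_up = 57L,
    lfc_down = c(-4, -1.5), lfc_up = c(1.5, 3),
    n_artifact = 30L, lfc_artifact = c(1.5, 2.5),
    n_occupied_de = 42L, n_occupied_bg = 200L,
    seed = NULL) {
  if (dispersion <= 0) stop("`dispersion` must be positive", call. = FALSE)
  stopifnot(setequal(names(reps), c("untransduced", "sgControl", "sgTHAP1")),
            all(reps >= 1L),
            n_down + n_up + n_artifact <= n_genes,
            n_occupied_de <= n_down + n_up)
  structure(list(n_genes = as.integer(n_genes), reps = reps,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog, dispersion = dispersion,
                 n_down = as.integer(n_down), n_up = as.integer(n_up),
                 lfc_down = lfc_down, lfc_up = lfc_up,
                 n_artifact = as.integer(n_artifact),
                 lfc_artifact = lfc_artifact,
                 n_occupied_de = as.integer(n_occupied_de),
                 n_occupied_bg = as.integer(n_occupied_bg),
                 seed = seed),
            class = "rnaseq_sim_config")
}

#' Simulate RNA-seq counts with planted differential expression
#'
#' @param cfg An [rnaseq_sim_config()].
#' @param path Optional TSV path for the count matrix (genes x samples).
#' @return List with `counts` (gene x sample integer matrix), `groups`
#'   (named character: sample -> group), `truth` (tibble: gene, de
#'   (`none`/`down`/`up`), lfc, artifact, artifact_lfc, occupied) and
#'   `config`. Planted target and artifact sets are disjoint.
#' @export
simulate_rnaseq_counts <- function(cfg = rnaseq_sim_config(), path = NULL) {
  stopifnot(inherits(cfg, "rnaseq_sim_config"))
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  group_order <- c("untransduced", "sgControl", "sgTHAP1")
  groups <- rep(group_order, times = cfg$reps[group_order])
  samples <- paste0(groups, "_", unlist(lapply(cfg$reps[group_order],
                                               seq_len)))
  groups <- stats::setNames(groups, samples)

  with_seed_if(cfg$seed, {
    pick <- sample(genes, cfg$n_down + cfg$n_up + cfg$n_artifact)
    down <- pick[seq_len(cfg$n_down)]
    up <- pick[cfg$n_down + seq_len(cfg$n_up)]
    artifact <- pick[cfg$n_down + cfg$n_up + seq_len(cfg$n_artifact)]

    truth <- tibble::tibble(gene = genes, de = "none", lfc = 0,
                            artifact = FALSE, artifact_lfc = 0,
                            occupied = FALSE)
    truth$de[match(down, genes)] <- "down"
    truth$de[match(up, genes)] <- "up"
    truth$lfc[match(down, genes)] <-
      stats::runif(cfg$n_down, cfg$lfc_down[1], cfg$lfc_down[2])
    truth$lfc[match(up, genes)] <-
      stats::runif(cfg$n_up, cfg$lfc_up[1], cfg$lfc_up[2])
    truth$artifact[match(artifact, genes)] <- TRUE
    truth$artifact_lfc[match(artifact, genes)] <-
      sample(c(-1, 1), cfg$n_artifact, replace = TRUE) *
      stats::runif(cfg$n_artifact, cfg$lfc_artifact[1], cfg$lfc_artifact[2])
    occ_de <- sample(c(down, up), cfg$n_occupied_de)
    occ_bg <- sample(setdiff(genes, pick),
                     min(cfg$n_occupied_bg, cfg$n_genes - length(pick)))
    truth$occupied[genes %in% c(occ_de, occ_bg)] <- TRUE

    baseline <- stats::rlnorm(cfg$n_genes, cfg$baseline_meanlog,
                              cfg$baseline_sdlog)
    lfc_mat <- matrix(0, cfg$n_genes, length(samples),
                      dimnames = list(genes, samples))
    sg <- groups %in% c("sgControl", "sgTHAP1")
    lfc_mat[, sg] <- lfc_mat[, sg] + truth$artifact_lfc
    ko <- groups == "sgTHAP1"
    lfc_mat[, ko] <- lfc_mat[, ko] + truth$lfc
    mu <- baseline * 2^lfc_mat
    counts <- matrix(stats::rnbinom(length(mu), size = 1 / cfg$dispersion,
                                    mu = mu),
                     nrow = cfg$n_genes, dimnames = dimnames(mu))
    if (!is.null(path))
      utils::write.table(data.frame(gene = genes, counts,
                                    check.names = FALSE),
                         path, sep = "\t", quote = FALSE, row.names = FALSE)
    list(counts = counts, groups = groups, truth = truth, config = cfg)
  })
}
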