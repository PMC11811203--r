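# -- activity landscape -----------------------------------------------------

test_that("landscape fixes wild-type controls at 1 and critical residues at 0", {
  d <- design_library(synthetic_protein(213))
  a <- simulate_landscape(d, landscape_config(seed = 5))
  v <- d$variants
  expect_true(all(a[v$id[v$is_wt_control]] == 1))
  crit <- v$id[v$position %in% c(5, 10, 54, 57) & !v$is_wt_control]
  expect_true(all(a[crit] == 0))
  expect_true(all(a >= 0 & a <= 1.5))
})

test_that("landscape is deterministic and region classes behave as planted", {
  d <- design_library(synthetic_protein(213))
  a1 <- simulate_landscape(d, landscape_config(seed = 9))
  a2 <- simulate_landscape(d, landscape_config(seed = 9))
  expect_identical(a1, a2)
  v <- d$variants[!d$variants$is_wt_control, ]
  zf <- mean(a1[v$id[v$position >= 2 & v$position <= 81]])
  ct <- mean(a1[v$id[v$position >= 192]])
  expect_gt(ct, zf)
  # the narrow cofactor motif overrides the surrounding linker
  motif <- mean(a1[v$id[v$position >= 134 & v$position <= 137]])
  linker <- mean(a1[v$id[v$position >= 82 & v$position <= 133]])
  expect_lt(motif, linker)
})

test_that("positions outside the region map are rejected", {
  d <- design_library("MACDEFGHIK")
  cfg <- landscape_config(region_map = list(zf = c(2, 5)),
                          class_mixtures = list(zf = c(1, 0, 0, 0)),
                          critical_residues = integer(0))
  expect_error(simulate_landscape(d, cfg), "region_map")
})

# -- sort-and-sequence screen ----------------------------------------------

test_that("noise-free sorting sends inactive variants to dim and wild type to bright", {
  d <- small_design()
  v <- d$variants
  a <- stats::setNames(ifelse(v$is_wt_control, 1, 0), v$id)
  cfg <- sortseq_config(n_cells = 20000, noise_sigma = 0, reads_per_bin = 5000,
                        read_error_rate = 0, seed = 1)
  out_dir <- withr::local_tempdir()
  sim <- suppressWarnings(simulate_sort_seq(d, a, cfg, out_dir))
  tr <- sim$truth
  wt_ids <- v$id[v$is_wt_control]
  expect_equal(sum(tr$reads[tr$bin == "dim" & tr$variant %in% wt_ids]), 0L)
  expect_equal(sum(tr$reads[tr$bin == "bright" & !tr$variant %in% wt_ids]), 0L)
  # error-free reads trim to exact index keys
  idx <- build_reference_index(d)
  reads <- readLines(sim$files$path[1])
  reads <- reads[seq_along(reads) %% 4 == 2]
  inserts <- substring(reads, nchar(cfg$flank5) + 1,
                       nchar(reads) - nchar(cfg$flank3))
  expect_true(all(inserts %in% idx$keys$insert_seq))
})

test_that("each non-empty bin FASTQ holds exactly reads_per_bin records", {
  d <- small_design()
  a <- simulate_landscape(d, landscape_config(
    region_map = list(all = c(2, 25)),
    class_mixtures = list(all = c(0.3, 0.3, 0.3, 0.1)),
    critical_residues = integer(0), seed = 2))
  cfg <- sortseq_config(n_cells = 50000, reads_per_bin = 4000, seed = 3)
  sim <- suppressWarnings(simulate_sort_seq(d, a, cfg, withr::local_tempdir()))
  for (i in seq_len(nrow(sim$files))) {
    n_lines <- length(readLines(sim$files$path[i]))
    expect_equal(n_lines, 4L * sim$files$n_reads[i])
    expect_equal(sim$files$n_reads[i], 4000L)
  }
  # cells partition into the two bins
  tr <- sim$truth
  cells <- tapply(tr$cells, list(tr$replicate, tr$bin), sum)
  expect_true(all(rowSums(cells) > 0))
})

test_that("sort simulation is byte-identical under a fixed seed", {
  d <- design_library("MACDEFGH")
  a <- stats::setNames(rep(c(0, 1), length.out = nrow(d$variants)),
                       d$variants$id)
  cfg <- sortseq_config(n_cells = 5000, reads_per_bin = 500, seed = 77)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- suppressWarnings(simulate_sort_seq(d, a, cfg, d1))
  s2 <- suppressWarnings(simulate_sort_seq(d, a, cfg, d2))
  expect_identical(s1$truth, s2$truth)
  for (i in seq_len(nrow(s1$files)))
    expect_identical(readLines(s1$files$path[i]),
                     readLines(s2$files$path[i]))
})

test_that("an empty bin warns and writes an empty FASTQ", {
  d <- design_library("MAC")
  a <- stats::setNames(rep(1, nrow(d$variants)), d$variants$id)
  cfg <- sortseq_config(n_cells = 2000, noise_sigma = 0, reads_per_bin = 100,
                        seed = 4)
  w <- testthat::capture_warnings(
    sim <- simulate_sort_seq(d, a, cfg, withr::local_tempdir()))
  expect_true(any(grepl("no cells", w)))
  dim_files <- sim$files[sim$files$bin == "dim", ]
  expect_true(all(dim_files$n_reads == 0))
  expect_equal(length(readLines(dim_files$path[1])), 0L)
})

test_that("representation below 200-fold triggers a warning", {
  d <- small_design()
  a <- stats::setNames(rep(c(0, 1), length.out = nrow(d$variants)),
                       d$variants$id)
  cfg <- sortseq_config(n_cells = 1000, reads_per_bin = 100, seed = 5)
  expect_warning(simulate_sort_seq(d, a, cfg, withr::local_tempdir()),
                 "below 200-fold")
})

# -- gene-effect simulator --------------------------------------------------

test_that("null gene-effect matrix has near-zero off-diagonal correlations", {
  cfg <- coess_sim_config(n_genes = 60, n_lines = 500, module_specs = list(),
                          rescue_spec = NULL, seed = 11)
  sim <- simulate_gene_effects(cfg)
  cm <- stats::cor(t(sim$effects))
  off <- cm[upper.tri(cm)]
  expect_lt(max(abs(off)), 0.25)
  expect_lt(abs(mean(off)), 0.02)
})

test_that("module correlation matches the closed-form attenuation", {
  # r = loading^2 / (loading^2 + sigma^2) for a two-gene module
  sigma <- 0.5
  cfg <- coess_sim_config(n_genes = 2, n_lines = 10000,
                          module_specs = list(list(genes = c("A", "B"),
                                                   loading = 1.0)),
                          rescue_spec = NULL, noise_sigma = sigma, seed = 21)
  sim <- simulate_gene_effects(cfg)
  r <- stats::cor(sim$effects["A", ], sim$effects["B", ])
  expect_equal(r, 1 / (1 + sigma^2), tolerance = 0.02)
})

test_that("gene-effect simulation is deterministic and validates inputs", {
  cfg <- coess_sim_config(n_genes = 20, n_lines = 30, seed = 8)
  expect_identical(simulate_gene_effects(cfg)$effects,
                   simulate_gene_effects(cfg)$effects)
  expect_error(coess_sim_config(n_lines = 2), ">= 3")
})

# -- promoter simulator -----------------------------------------------------

test_that("planted motifs are recovered verbatim at their offsets", {
  sim <- simulate_promoters(promoter_sim_config(seed = 31))
  hits <- scan_thabs(sim$sequences, max_mismatch = 1)
  for (i in seq_len(nrow(sim$truth))) {
    t <- sim$truth[i, ]
    h <- hits[hits$seq_id == t$promoter & hits$start == t$start &
                hits$strand == t$strand, ]
    expect_equal(nrow(h), 1L)
    expect_equal(h$end, t$end)
  }
  # the two perfect plants are 0-mismatch, the near-perfect one 1-mismatch
  planted <- merge(as.data.frame(sim$truth), as.data.frame(hits),
                   by.x = c("promoter", "start", "strand"),
                   by.y = c("seq_id", "start", "strand"))
  expect_equal(sort(planted$mismatches), c(0L, 0L, 1L))
})

test_that("overlapping plants and out-of-range plants are rejected", {
  expect_error(promoter_sim_config(
    plants = tibble::tibble(promoter = "P001",
                            motif = c("TACGGGCA", "TCCAGGCA"),
                            offset = c(-100L, -95L), strand = "+")),
    "overlapping")
  expect_error(promoter_sim_config(
    length = 300L, tss_offset = 100L,
    plants = tibble::tibble(promoter = "P001", motif = "TACGGGCA",
                            offset = 250L, strand = "+")),
    "within the sequence")
})

test_that("background hit count matches the analytic wildcard probability", {
  gc <- 0.41
  cfg <- promoter_sim_config(n_promoters = 1L, length = 1000000L,
                             gc_content = gc, tss_offset = 0L,
                             plants = tibble::tibble(promoter = character(),
                                                     motif = character(),
                                                     offset = integer(),
                                                     strand = character()),
                             seed = 41)
  sim <- simulate_promoters(cfg)
  hits <- scan_thabs(sim$sequences, "TNNNGGCA", max_mismatch = 0)
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  # fixed positions of TNNNGGCA: T,G,G,C,A — same set on the reverse strand
  p_win <- prod(base_p[c("T", "G", "G", "C", "A")])
  expected <- 2 * (cfg$length - 8 + 1) * p_win
  expect_lt(abs(nrow(hits) - expected), 5 * sqrt(expected))
})

# -- RNA-seq simulator ------------------------------------------------------

test_that("RNA-seq counts are deterministic and respect planted structure", {
  cfg <- rnaseq_sim_config(n_genes = 500, n_down = 10, n_up = 5,
                           n_artifact = 5, n_occupied_de = 5,
                           n_occupied_bg = 10, seed = 51)
  s1 <- simulate_rnaseq_counts(cfg)
  s2 <- simulate_rnaseq_counts(cfg)
  expect_identical(s1$counts, s2$counts)
  tr <- s1$truth
  expect_false(any(tr$artifact & tr$de != "none"))
  expect_equal(sum(tr$de == "down"), 10L)
  expect_equal(sum(tr$de == "up"), 5L)
  # planted shifts move group means in the right direction
  down <- tr$gene[tr$de == "down"]
  ko <- names(s1$groups)[s1$groups == "sgTHAP1"]
  ctl <- names(s1$groups)[s1$groups == "sgControl"]
  expect_lt(mean(s1$counts[down, ko]) / mean(s1$counts[down, ctl]), 0.5)
  expect_error(rnaseq_sim_config(dispersion = 0), "positive")
})
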