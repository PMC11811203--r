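# Hand-crafted one-pool, two-replicate count table.
toy_counts <- function(bright1, dim1, bright2 = bright1, dim2 = dim1,
                       ids = paste0("V", seq_along(bright1)),
                       wt = ids[1]) {
  counts <- dplyr::bind_rows(
    tibble::tibble(pool = 1L, replicate = 1L, bin = "bright",
                   variant = ids, count = as.integer(bright1)),
    tibble::tibble(pool = 1L, replicate = 1L, bin = "dim",
                   variant = ids, count = as.integer(dim1)),
    tibble::tibble(pool = 1L, replicate = 2L, bin = "bright",
                   variant = ids, count = as.integer(bright2)),
    tibble::tibble(pool = 1L, replicate = 2L, bin = "dim",
                   variant = ids, count = as.integer(dim2)))
  manual_count_table(counts, manual_keys(ids, wt))
}

test_that("bin totals cancel in the enrichment ratio (hand example)", {
  # one WT (bright 50, dim 50) and one variant (bright 10, dim 90), c = 0:
  # s_variant = (10/90)/(50/50) = 1/9
  ct <- toy_counts(c(50, 10), c(50, 90))
  st <- enrichment_scores(ct, score_config(pseudocount = 0))
  expect_equal(st$s_rep1[st$variant == "V2"], 1 / 9, tolerance = 1e-12)
  expect_equal(st$s_rep1[st$variant == "V1"], 1, tolerance = 1e-12)
})

test_that("identical counts in both bins give every variant score 1", {
  ct <- toy_counts(c(40, 7, 123), c(40, 7, 123))
  st <- enrichment_scores(ct, score_config())
  expect_true(all(abs(st$s_rep1 - 1) < 1e-12))
  expect_true(all(abs(st$s_rep2 - 1) < 1e-12))
})

test_that("scores are invariant to per-bin rescaling", {
  b <- c(50, 10, 200); d <- c(50, 90, 20)
  s0 <- enrichment_scores(toy_counts(b, d),
                          score_config(pseudocount = 0))$s_rep1
  s10 <- enrichment_scores(toy_counts(b * 10, d),
                           score_config(pseudocount = 0))$s_rep1
  expect_equal(s0, s10, tolerance = 1e-12)
  # with a pseudocount, invariance holds in the large-count limit
  b2 <- c(5e4, 1e4, 2e5); d2 <- c(5e4, 9e4, 2e4)
  sA <- enrichment_scores(toy_counts(b2, d2), score_config(0.5))$s_rep1
  sB <- enrichment_scores(toy_counts(b2 * 10, d2), score_config(0.5))$s_rep1
  expect_true(all(abs(sA / sB - 1) < 0.01))
})

test_that("scores are strictly monotone in bright and dim counts", {
  base <- enrichment_scores(toy_counts(c(50, 20), c(50, 40)),
                            score_config())$s_rep1[2]
  up_b <- enrichment_scores(toy_counts(c(50, 21), c(50, 40)),
                            score_config())$s_rep1[2]
  up_d <- enrichment_scores(toy_counts(c(50, 20), c(50, 41)),
                            score_config())$s_rep1[2]
  expect_gt(up_b, base)
  expect_lt(up_d, base)
})

test_that("wild-type normalisation is exact in every scope", {
  withr::with_seed(33, {
    for (trial in 1:5) {
      n <- 30
      ids <- paste0("V", 1:n)
      wt <- sample(ids, 4)
      ct <- toy_counts(rpois(n, 80), rpois(n, 80), rpois(n, 80),
                       rpois(n, 80), ids = ids, wt = wt)
      ct$keys$is_wt_group <- ids %in% wt
      st <- enrichment_scores(ct, score_config())
      for (r in 1:2)
        expect_lt(abs(mean(st[[paste0("s_rep", r)]][st$is_wt_control]) - 1),
                  1e-9)
    }
  })
  # a scope without wild-type controls is rejected by name
  ct <- toy_counts(c(10, 20), c(10, 20))
  ct$keys$is_wt_group <- FALSE
  expect_error(enrichment_scores(ct), "pool 1")
})

test_that("scoring requires both sort bins in every scope", {
  ct <- toy_counts(c(10, 20), c(10, 20))
  ct$counts <- ct$counts[ct$counts$bin != "dim" | ct$counts$replicate != 2, ]
  expect_error(enrichment_scores(ct), "both sort bins")
})

test_that("replicate filters flag low counts and discordance as specified", {
  ids <- paste0("V", 1:4)
  ct <- toy_counts(c(50, 50, 50, 5), c(50, 48, 200, 5),
                   c(50, 52, 20, 5), c(50, 50, 10, 5), ids = ids)
  st <- apply_filters(enrichment_scores(ct, score_config()),
                      filter_config(min_reads_per_replicate = 20,
                                    concordance_delta = 0.5))
  flags <- st[match(ids, st$variant), c("recovered", "discordant", "retained")]
  expect_equal(flags$recovered, c(TRUE, TRUE, TRUE, FALSE))
  # V3: bright/dim very different between replicates -> discordant
  expect_true(flags$discordant[3])
  expect_false(flags$retained[3])
  expect_true(all(st$retained == (st$recovered & !st$discordant)))
})

test_that("filter bookkeeping reproduces the screen's reported arithmetic", {
  # 4240 designed variants, 238 below the read floor, 179 discordant among
  # the 4002 recovered: 3823 retained = 90.2%
  n <- 4240L
  ids <- sprintf("V%04d", 1:n)
  st <- tibble::tibble(
    variant = ids, pool = 1L, is_wt_control = FALSE,
    reads_rep1 = c(rep(10L, 238L), rep(100L, n - 238L)),
    reads_rep2 = 100L,
    s_rep1 = 1, s_rep2 = c(rep(1, 238L), rep(2, 179L), rep(1.1, n - 417L)))
  attr(st, "replicates") <- 1:2
  st <- apply_filters(st, filter_config())
  sm <- summarize_filters(st, n_designed = n)
  expect_equal(sm$n_recovered, 4002L)
  expect_equal(sm$n_discordant, 179L)
  expect_equal(sm$n_retained, 3823L)
  expect_equal(round(sm$pct_retained, 1), 90.2)
})

test_that("activity matrix places retained scores and reports missing cells", {
  d <- small_design()
  idx <- build_reference_index(d)
  ids <- idx$keys$group_id
  ct <- toy_counts(rep(50L, length(ids)), rep(50L, length(ids)), ids = ids)
  ct$keys <- idx$keys
  st <- apply_filters(enrichment_scores(ct), filter_config())
  am <- activity_matrix(st, d)
  expect_equal(dim(am$grid), c(24L, 20L))
  # collapsed Met/Trp controls cannot be placed; everything else is filled
  n_collapsed <- sum(lengths(idx$keys$variant_ids) > 1L)
  n_members <- sum(lengths(idx$keys$variant_ids)[
    lengths(idx$keys$variant_ids) > 1L])
  expect_equal(nrow(am$missing), n_members)
  # per-position mean equals a brute-force row mean
  for (p in sample(rownames(am$grid), 5))
    expect_equal(unname(am$position_means[p]),
                 mean(am$grid[p, ], na.rm = TRUE))
  # nothing retained -> all-missing matrix with undefined means
  st0 <- st; st0$retained <- FALSE
  am0 <- activity_matrix(st0, d)
  expect_true(all(is.na(am0$grid)))
  expect_true(all(is.na(am0$position_means)))
})

test_that("structure-class comparison matches the exact enumeration example", {
  # ordered scores all 0 (5 positions), disordered all 1 (5 positions):
  # two-sided exact rank-sum p = 2 / choose(10, 5)
  am <- structure(list(
    grid = matrix(c(rep(0, 5), rep(1, 5)), ncol = 1,
                  dimnames = list(1:10, "A")),
    position_means = stats::setNames(c(rep(0, 5), rep(1, 5)), 1:10),
    missing = tibble::tibble(position = integer(), aa = character())),
    class = "activity_matrix")
  ann <- stats::setNames(c(rep(90, 5), rep(30, 5)), 1:10)
  res <- compare_structure_classes(am, ann)
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$mean_ordered, 0)
  expect_equal(res$mean_disordered, 1)
  # empty class -> missing p
  res2 <- compare_structure_classes(am, stats::setNames(rep(90, 10), 1:10))
  expect_true(is.na(res2$p_value))
  # > 10 positions per class switches to the normal approximation
  am$grid <- matrix(rnorm(30), ncol = 1, dimnames = list(1:30, "A"))
  am$position_means <- stats::setNames(as.numeric(am$grid), 1:30)
  res3 <- compare_structure_classes(
    am, stats::setNames(rep(c(90, 30), 15), 1:30))
  expect_equal(res3$method, "normal approximation")
  expect_true(res3$p_value > 0 && res3$p_value <= 1)
})

test_that("patient-variant classification uses a strict threshold", {
  st <- tibble::tibble(variant = c("C5A", "I80V", "L32P", "Q90*x"),
                       s_mean = c(0.1, 1.02, 0.5, 0.4),
                       retained = c(TRUE, TRUE, TRUE, FALSE))
  res <- classify_patient_variants(st, c("C5A", "I80V", "L32P", "Q90*x",
                                         "Z99Z"))
  expect_equal(res$calls$call,
               c("impaired", "active", "active", "unclassifiable",
                 "unclassifiable"))
  expect_equal(res$impaired_fraction, 1 / 3)
  expect_error(classify_patient_variants(st, character(0)), "empty")
})
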