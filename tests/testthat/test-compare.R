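test_that("greedy caliper matching pairs nearest unused partners", {
  a <- c(a = 7.00, b = 6.10)
  b <- c(x = 7.02, y = 6.13, z = 5.00)
  m <- match_by_value(a, b, max_diff = 0.05, scale = "raw")
  expect_equal(m$pairs$id_a, c("a", "b"))
  expect_equal(m$pairs$id_b, c("x", "y"))
  expect_equal(m$unmatched_b, "z")
  expect_true(all(abs(m$pairs$value_a - m$pairs$value_b) <= 0.05))

  # zero caliper keeps only exact-value pairs
  m0 <- match_by_value(c(p = 1, q = 2), c(r = 1, s = 2.001), max_diff = 0)
  expect_equal(nrow(m0$pairs), 1L)
  expect_equal(m0$pairs$id_b, "r")

  # log10 scale
  ml <- match_by_value(c(p = 100), c(r = 101), max_diff = 0.005,
                       scale = "log10")
  expect_equal(nrow(ml$pairs), 1L)
  expect_error(match_by_value(c(p = -1), c(r = 1), 0.1, scale = "log10"),
               "finite")
})

test_that("greedy matching is near-optimal and always respects the caliper", {
  set.seed(31)
  for (i in 1:10) {
    na_ <- sample(4:9, 1); nb <- sample(4:9, 1)
    av <- round(runif(na_, 0, 3), 2); bv <- round(runif(nb, 0, 3), 2)
    names(av) <- paste0("a", seq_len(na_))
    names(bv) <- paste0("b", seq_len(nb))
    caliper <- 0.25
    m <- match_by_value(av, bv, caliper)
    expect_true(all(abs(m$pairs$value_a - m$pairs$value_b) <= caliper))
    expect_equal(anyDuplicated(m$pairs$id_b), 0L)
    opt <- oracle_optimal_match_size(unname(av), unname(bv), caliper)
    expect_gte(nrow(m$pairs), opt - 1L)
    expect_lte(nrow(m$pairs), opt)
  }
})

test_that("paired signed-rank p-values match exact enumeration and wilcox.test", {
  # fixed example against the reference implementation (tied |differences|
  # force the reference onto its continuity-corrected approximation)
  x <- c(1, 2, 3, 4, 5); y <- c(2, 3, 4, 5, 7)
  got <- paired_wilcoxon(x, y, "two.sided")
  ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                             exact = TRUE))
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-6)

  set.seed(13)
  for (i in 1:10) {
    n <- sample(6:11, 1)
    xx <- rnorm(n); yy <- rnorm(n)
    alt <- sample(c("two.sided", "greater", "less"), 1)
    got <- paired_wilcoxon(xx, yy, alt)
    expect_equal(got$p_value, oracle_signed_rank_exact(xx, yy, alt),
                 tolerance = 1e-12, info = i)
  }

  # one-sided power sanity at n = 20 with a uniform shift
  set.seed(14)
  x20 <- rnorm(20) + 1; y20 <- rnorm(20)
  expect_lt(paired_wilcoxon(x20, y20, "greater")$p_value, 0.05)

  # identical vectors: undefined p, flagged
  expect_warning(res0 <- paired_wilcoxon(1:4, 1:4), "zero")
  expect_true(is.na(res0$p_value))
  expect_equal(res0$n, 0L)
})

test_that("unpaired rank-sum p-values match exact enumeration", {
  set.seed(15)
  for (i in 1:8) {
    xx <- rnorm(sample(4:7, 1)); yy <- rnorm(sample(4:7, 1))
    alt <- sample(c("two.sided", "greater", "less"), 1)
    got <- unpaired_wilcoxon(xx, yy, alt)
    expect_equal(got$p_value, oracle_rank_sum_exact(xx, yy, alt),
                 tolerance = 1e-12, info = i)
  }
})

test_that("normal-approximation branch matches the hand-coded Z formula", {
  # independent re-derivation of the continuity-corrected normal
  # approximation, coded from the definition in this test
  set.seed(16)
  n <- 40
  x <- rnorm(n); y <- rnorm(n)
  d <- x - y; r <- rank(abs(d)); v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
  p_want <- 2 * pnorm(-(abs(v - mu) - 0.5) / sig)
  got <- paired_wilcoxon(x, y, "two.sided")
  expect_equal(got$p_value, p_want, tolerance = 1e-6)
})

test_that("effect sizes agree with a direct rank-arithmetic oracle", {
  # identical groups: r ~ 0, superiority 0.5
  es0 <- superiority_effect_size(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(es0$effect_size_r, 0)
  expect_equal(es0$superiority, 0.5)

  # fully separated groups approach the maximum for that n
  set.seed(17)
  hi <- rnorm(15) + 100; lo <- rnorm(15)
  es1 <- superiority_effect_size(hi, lo, paired = FALSE)
  expect_equal(es1$superiority, 1)
  n <- 30; n1 <- 15
  w_max <- n1 * 15
  z_max <- (w_max - n1 * 15 / 2 - 0.5) /
    sqrt(n1 * 15 / 12 * (n + 1))
  expect_equal(es1$effect_size_r, abs(z_max) / sqrt(n), tolerance = 1e-9)

  # paired: r = |Z|/sqrt(pairs) with the signed-rank Z
  x <- c(5, 7, 1, 9, 3, 8, 2, 12, 4, 6)
  y <- c(4, 9, 0, 5, 1, 2, 6, 11, 3, 2)
  es2 <- superiority_effect_size(x, y, paired = TRUE)
  d <- x - y; r <- rank(abs(d)); v <- sum(r[d > 0])
  mu <- 10 * 11 / 4
  ties <- table(r)
  sig <- sqrt(10 * 11 * 21 / 24 - sum(ties^3 - ties) / 48)
  z <- (v - mu - sign(v - mu) * 0.5) / sig
  expect_equal(es2$effect_size_r, abs(z) / sqrt(10), tolerance = 1e-12)
  expect_equal(es2$superiority, mean(x > y) + 0.5 * mean(x == y))
})

test_that("group comparison intersects introns and adjusts across responses", {
  set.seed(18)
  mk_msr <- function(ids, d, a) tibble::tibble(intron_id = ids, msr_d = d,
                                               msr_a = a)
  ids <- 1:200
  base_d <- rbeta(200, 1, 60); base_a <- rbeta(200, 1, 40)
  control <- mk_msr(ids, base_d, base_a)
  case_null <- mk_msr(c(ids, 201L), c(base_d, 0.5), c(base_a, 0.5))

  res <- suppressWarnings(
    compare_msr_groups(case_null, control, alternative = "greater",
                       adjust = "bonferroni"))
  # intron 201 is not shared and must not enter the comparison
  expect_equal(unique(res$n_introns), 200L)
  # identical shared values: no signal
  expect_true(all(is.na(res$p_value) | res$p_value > 0.99))

  case_shift <- mk_msr(ids, base_d * 1.5, base_a * 1.5)
  res2 <- compare_msr_groups(case_shift, control, alternative = "greater",
                             adjust = "bonferroni")
  expect_true(all(res2$p_adj < 0.01))
  expect_true(all(res2$effect_size_r > 0))
  expect_equal(res2$p_adj, pmin(res2$p_value * 2, 1))

  expect_error(compare_msr_groups(mk_msr(1:3, 0, 0), mk_msr(4:6, 0, 0)),
               "common")
})

test_that("age stratification uses closed printed bins and RIN matching", {
  set.seed(19)
  mk <- function(n, tissue, ages, rins) {
    tibble::tibble(sample_id = paste0(tissue, seq_len(n)), tissue = tissue,
                   age = ages, rin = rins)
  }
  # bin edges: 39 -> youngest bin, 40 -> middle bin
  edge <- mk(3, "edge", c(39, 40, 65), c(7, 7, 7))
  res_edge <- age_stratify(edge, min_per_bin = 1L, min_total = 3L)
  got <- res_edge$samples
  expect_equal(got$age_bin[got$age == 39], "20-39")
  expect_equal(got$age_bin[got$age == 40], "40-59")

  # a tissue with bins 30/30/20 fails the 25-per-bin minimum
  small <- mk(80, "small",
              c(rep(25, 30), rep(50, 30), rep(70, 20)),
              rep(7, 80))
  res_small <- age_stratify(small)
  expect_equal(res_small$excluded_tissues, "small")
  expect_equal(nrow(res_small$samples), 0L)

  # matched older samples satisfy the 0.05 RIN caliper
  ok <- mk(90, "ok",
           c(rep(30, 30), rep(50, 30), rep(70, 30)),
           round(runif(90, 6, 9), 2))
  res_ok <- age_stratify(ok)
  expect_equal(res_ok$excluded_tissues, character(0))
  for (m in res_ok$matches) {
    expect_true(all(abs(m$pairs$value_a - m$pairs$value_b) <= 0.05))
  }
  # every retained older sample is a matched one
  older <- res_ok$samples[res_ok$samples$age_bin != "20-39", ]
  matched_ids <- unlist(lapply(res_ok$matches, function(m) m$pairs$id_b))
  expect_true(all(older$sample_id %in% matched_ids))
})

test_that("one-sided comparisons hold their type-I error on null data", {
  set.seed(20)
  reps <- 200
  hits <- 0
  for (r in seq_len(reps)) {
    d_case <- rbeta(120, 1, 80); d_ctrl <- rbeta(120, 1, 80)
    p <- paired_wilcoxon(d_case, d_ctrl, "greater")$p_value
    if (!is.na(p) && p < 0.05) hits <- hits + 1
  }
  rate <- hits / reps
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})
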