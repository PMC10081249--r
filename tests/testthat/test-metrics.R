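make_msr_fixture <- function(d_counts, s_counts, a_counts = NULL) {
  # one + strand intron 101-200 with its annotated junction, one novel donor
  # (96-200) and one novel acceptor (101-204)
  samples <- paste0("s", seq_along(d_counts))
  rows <- list(
    tibble::tibble(chrom = "chr1", start = 101L, end = 200L, strand = "+",
                   sample_id = samples, count = as.integer(s_counts)),
    tibble::tibble(chrom = "chr1", start = 96L, end = 200L, strand = "+",
                   sample_id = samples, count = as.integer(d_counts))
  )
  if (!is.null(a_counts)) {
    rows <- c(rows, list(
      tibble::tibble(chrom = "chr1", start = 101L, end = 204L, strand = "+",
                     sample_id = samples, count = as.integer(a_counts))))
  }
  counts <- dplyr::bind_rows(rows)
  counts <- counts[counts$count > 0, ]
  list(ann = tiny_annotation(), counts = counts)
}

test_that("MSR pools reads across samples before forming the ratio", {
  fx <- make_msr_fixture(d_counts = c(2, 3, 5),
                         s_counts = c(90, 100, 100))
  cls <- classify_and_assign(fx$counts, fx$ann)
  msr <- compute_msr(cls, fx$counts)
  expect_equal(msr$msr_d, 10 / 300)
  expect_equal(msr$msr_a, 0)
  expect_equal(msr$n_samples, 3L)

  # pooling is not the mean of per-sample ratios: build an unbalanced case
  fx2 <- make_msr_fixture(d_counts = c(9, 1), s_counts = c(1, 99))
  cls2 <- classify_and_assign(fx2$counts, fx2$ann)
  msr2 <- compute_msr(cls2, fx2$counts)
  pooled <- 10 / 110
  per_sample_mean <- mean(c(9 / 10, 1 / 100))
  expect_equal(msr2$msr_d, pooled)
  expect_false(isTRUE(all.equal(msr2$msr_d, per_sample_mean)))
})

test_that("no novel reads means MSR of exactly zero", {
  fx <- make_msr_fixture(d_counts = c(0, 0), s_counts = c(50, 60))
  cls <- classify_and_assign(fx$counts, fx$ann)
  msr <- compute_msr(cls, fx$counts)
  expect_equal(msr$msr_d, 0)
  expect_equal(msr$msr_a, 0)
})

test_that("MSR equals the brute-force per-read oracle on random tables", {
  for (seed in c(11, 22)) {
    inst <- random_instance(seed, n_introns = 25, n_junctions = 80)
    cls <- classify_and_assign(inst$junctions, inst$annotation)
    got <- compute_msr(cls, inst$junctions)
    want <- oracle_msr(cls, inst$junctions)
    got <- got[order(got$intron_id), ]
    expect_equal(got$intron_id, want$intron_id)
    expect_equal(got$msr_d, want$msr_d)
    expect_equal(got$msr_a, want$msr_a)
    expect_equal(got$sum_annotated_reads, as.integer(want$S))
  }
})

test_that("MSR is monotone in novel and annotated read counts", {
  base <- make_msr_fixture(d_counts = 5, s_counts = 100)
  cls <- classify_and_assign(base$counts, base$ann)
  msr0 <- compute_msr(cls, base$counts)$msr_d

  more_novel <- make_msr_fixture(d_counts = 8, s_counts = 100)
  cls1 <- classify_and_assign(more_novel$counts, more_novel$ann)
  expect_gte(compute_msr(cls1, more_novel$counts)$msr_d, msr0)

  more_ann <- make_msr_fixture(d_counts = 5, s_counts = 140)
  cls2 <- classify_and_assign(more_ann$counts, more_ann$ann)
  expect_lte(compute_msr(cls2, more_ann$counts)$msr_d, msr0)
})

test_that("unknown sample ids are an error naming the id", {
  fx <- make_msr_fixture(d_counts = 1, s_counts = 10)
  cls <- classify_and_assign(fx$counts, fx$ann)
  expect_error(compute_msr(cls, fx$counts, sample_subset = c("s1", "sX")),
               "sX")
})

test_that("category percentages follow the occurrence and read formulas", {
  # per-sample unique occurrences 10/20/70 across categories
  ann <- tiny_annotation()
  mk <- function(start, end, n, count = 1L) {
    tibble::tibble(chrom = "chr1", start = start, end = end, strand = "+",
                   sample_id = paste0("s", seq_len(n)), count = count)
  }
  counts <- dplyr::bind_rows(
    mk(96L, 200L, 10L),            # novel donor in 10 samples
    mk(101L, 204L, 20L),           # novel acceptor in 20 samples
    mk(101L, 200L, 70L)            # annotated in 70 samples
  )
  cls <- classify_and_assign(counts, ann)
  pct <- category_percentages(cls, counts)
  expect_equal(pct$p_unique[pct$category == "novel_donor"], 10)
  expect_equal(pct$p_unique[pct$category == "novel_acceptor"], 20)
  expect_equal(pct$p_unique[pct$category == "annotated"], 70)
  expect_equal(sum(pct$p_unique), 100)
  expect_equal(sum(pct$p_unique_distinct), 100)

  # reads 1 / 2 / 97
  counts2 <- dplyr::bind_rows(
    mk(96L, 200L, 1L, 1L), mk(101L, 204L, 1L, 2L), mk(101L, 200L, 1L, 97L))
  cls2 <- classify_and_assign(counts2, ann)
  pct2 <- category_percentages(cls2, counts2)
  expect_equal(pct2$p_reads[pct2$category == "annotated"], 97)
  expect_equal(sum(pct2$p_reads), 100)

  # a single category present gets 100%
  counts3 <- mk(101L, 200L, 2L, 5L)
  cls3 <- classify_and_assign(counts3, ann)
  pct3 <- category_percentages(cls3, counts3)
  expect_equal(pct3$p_unique[pct3$category == "annotated"], 100)
})

test_that("TPM follows the RPK / per-million-scaling definition", {
  counts <- tibble::tibble(gene_id = c("g1", "g2"),
                           s1 = c(10, 40))
  lens <- tibble::tibble(gene_id = c("g1", "g2"),
                         gene_length = c(1000, 2000))
  res <- tpm(counts, lens)
  expect_equal(res$s1, c(1e6 / 3, 2e6 / 3), tolerance = 1e-12)

  # single gene gets the whole million
  res1 <- tpm(tibble::tibble(gene_id = "g", s1 = 7),
              tibble::tibble(gene_id = "g", gene_length = 500))
  expect_equal(res1$s1, 1e6)

  # property: columns sum to 1e6 on random matrices
  set.seed(4)
  m <- matrix(rpois(60, 50), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  lens2 <- setNames(sample(200:5000, 10), rownames(m))
  res2 <- tpm(m, lens2)
  sums <- colSums(as.matrix(res2[, -1]))
  expect_equal(unname(sums), rep(1e6, 6), tolerance = 1e-6)

  # zero column flagged as NA
  m0 <- m; m0[, 1] <- 0
  expect_warning(res3 <- tpm(m0, lens2), "zero total RPK")
  expect_true(all(is.na(res3$s1)))
})
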