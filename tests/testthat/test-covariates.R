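test_that("window means are coverage-weighted and orientation-correct", {
  # constant track
  track <- tibble::tibble(chrom = "chr1", start = 1L, end = 2000L,
                          score = 0.5)
  expect_equal(window_mean_score(track, "chr1", 500, "+", "donor"), 0.5)
  expect_equal(window_mean_score(track, "chr1", 500, "-", "acceptor"), 0.5)

  # alternating per-base track over a 4-base window
  track2 <- tibble::tibble(chrom = "chr1", start = 101:104, end = 101:104,
                           score = c(1, 0, 1, 0))
  got <- window_mean_score(track2, "chr1", 103, "+", "donor",
                           exonic = 2L, intronic = 2L, min_coverage = 1)
  expect_equal(got, 0.5)

  # minus-strand donor window at pos p covers [p - intronic + 1, p + exonic];
  # brute-force per-base oracle over an arbitrary track
  set.seed(8)
  base_scores <- runif(200)
  track3 <- tibble::tibble(chrom = "chr1", start = 1:200, end = 1:200,
                           score = base_scores)
  p <- 100L
  want <- mean(base_scores[(p - 35 + 1):(p + 5)])
  expect_equal(window_mean_score(track3, "chr1", p, "-", "donor"), want)
  # and the + strand acceptor window is the same genomic interval
  expect_equal(window_mean_score(track3, "chr1", p, "+", "acceptor"), want)

  # <50% coverage -> undefined
  sparse <- tibble::tibble(chrom = "chr1", start = 100L, end = 110L,
                           score = 1)
  expect_true(is.na(window_mean_score(sparse, "chr1", 100, "+", "donor")))
})

test_that("covariate assembly carries gene and intron features and drops NA rows", {
  cfg <- sim_config(n_genes = 6, n_samples = 4, depth = 200, seed = 5)
  sim <- simulate_dataset(cfg)
  cls <- classify_and_assign(sim$junctions, sim$annotation)
  msr <- compute_msr(cls, sim$junctions)
  gcounts <- gene_read_counts(cls, sim$junctions, sim$annotation)
  gtpm <- tpm(gcounts, gene_lengths(sim$annotation, "merged_exons"))
  track <- tibble::tibble(chrom = rep(names(sim$genome),
                                      Biostrings::width(sim$genome)),
                          start = unlist(lapply(Biostrings::width(sim$genome),
                                                seq_len)),
                          score = 0.25)
  track$end <- track$start
  covs <- build_covariates(sim$annotation, msr, gtpm, sim$genome,
                           toy_splice_model(), track, track)
  expect_true(all(c("gene_length", "median_tpm", "n_transcripts_gene",
                    "protein_coding_fraction", "mes_5ss", "mes_3ss",
                    "conservation_5ss", "constraint_3ss",
                    "intron_length") %in% names(covs)))
  expect_equal(unique(covs$conservation_5ss), 0.25)
  it <- sim$annotation$introns
  gi <- sim$annotation$gene_index
  i1 <- covs$intron_id[1]
  expect_equal(covs$n_transcripts_gene[1],
               gi$n_transcripts[gi$gene_id ==
                                  it$gene_id[it$intron_id == i1]])
  expect_equal(covs$protein_coding_fraction[1],
               it$protein_coding_fraction[it$intron_id == i1])

  # a track with no coverage on one chromosome drops that chromosome's rows
  track_c1 <- track[track$chrom == names(sim$genome)[1], ]
  covs2 <- build_covariates(sim$annotation, msr, gtpm, sim$genome,
                            toy_splice_model(), track_c1, track_c1)
  expect_gt(attr(covs2, "n_dropped"), 0)
  expect_true(all(covs2$intron_id %in%
                    it$intron_id[it$chrom == names(sim$genome)[1]]))

  # TSV round trip
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(covs, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(covs), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("OLS recovers a planted coefficient and flags degenerate designs", {
  set.seed(10)
  n <- 400
  dat <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  dat$y <- 2 * dat$x1 + rnorm(n, sd = 1e-4)
  fit <- fit_linear(dat, "y", c("x1", "x2", "x3"))
  co <- tidy(fit)
  expect_equal(co$estimate[co$term == "x1"], 2, tolerance = 1e-3)
  expect_lt(max(abs(co$estimate[co$term %in% c("x2", "x3")])), 1e-4)
  expect_equal(glance(fit)$n, n)

  # row-order invariance
  fit2 <- fit_linear(dat[sample(n), ], "y", c("x1", "x2", "x3"))
  expect_equal(tidy(fit2)$estimate, co$estimate, tolerance = 1e-9)

  # zero-variance covariate dropped with a warning
  dat$flat <- 1
  expect_warning(fit3 <- fit_linear(dat, "y", c("x1", "flat")),
                 "zero-variance")
  expect_false("flat" %in% tidy(fit3)$term)

  # exact collinearity is an error naming the term
  dat$dup <- dat$x1
  expect_error(fit_linear(dat, "y", c("x1", "dup")), "dup")
})

test_that("BH and Bonferroni adjustments match the step-procedure oracles", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(oracle_bh(p), rep(0.04, 4))
  set.seed(6)
  for (i in 1:10) {
    pr <- runif(sample(3:12, 1))
    expect_equal(p.adjust(pr, "BH"), oracle_bh(pr), tolerance = 1e-12)
    expect_equal(p.adjust(pr, "bonferroni"), oracle_bonferroni(pr),
                 tolerance = 1e-12)
  }
  # and within a fit
  set.seed(11)
  dd <- tibble::tibble(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  dd$y <- dd$a + rnorm(50)
  ft <- fit_linear(dd, "y", c("a", "b", "c"), adjust = "BH")
  co <- tidy(ft)
  nonint <- co$term != "(Intercept)"
  expect_equal(co$q_value[nonint], oracle_bh(co$p_value[nonint]))
  expect_true(all(co$q_value[nonint] >= co$p_value[nonint]))
})

test_that("family adjustment across fits pools both responses", {
  set.seed(12)
  d <- tibble::tibble(x = rnorm(80), z = rnorm(80))
  d$msr_d <- 0.01 * d$x + rnorm(80, sd = 0.01)
  d$msr_a <- rnorm(80, sd = 0.01)
  d$intron_id <- seq_len(80)
  res <- fit_msr_models(dplyr::select(d, intron_id, msr_d, msr_a, x, z))
  expect_setequal(unique(res$coefficients$response), c("msr_d", "msr_a"))
  expect_equal(res$coefficients$q_value,
               oracle_bh(res$coefficients$p_value))
})

test_that("categorical covariates are integer-encoded for reuse of the fit", {
  d <- tibble::tibble(tpm = rnorm(10), center = rep(c("a", "b"), 5),
                      sex = factor(rep(c("m", "f"), each = 5)))
  e <- encode_categorical(d)
  expect_true(is.integer(e$center))
  expect_true(is.integer(e$sex))
  expect_equal(sort(unique(e$center)), 1:2)
})
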