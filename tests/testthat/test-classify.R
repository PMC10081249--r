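test_that("the novel end names the category", {
  ann <- tiny_annotation()
  cls <- classify_junctions(tiny_junctions(), ann)

  exact <- cls[cls$start == 101 & cls$end == 200, ]
  expect_equal(exact$category, "annotated")
  expect_false(is.na(exact$assigned_intron_id))

  # acceptor (200) annotated, donor (96) not -> the donor is novel
  nd <- cls[cls$start == 96, ]
  expect_equal(nd$category, "novel_donor")
  expect_equal(nd$shared_site, "acceptor")

  # donor (101) annotated, acceptor (204) not -> the acceptor is novel
  na_ <- cls[cls$end == 204, ]
  expect_equal(na_$category, "novel_acceptor")
  expect_equal(na_$shared_site, "donor")

  # minus-strand annotated junction
  mb <- cls[cls$chrom == "chr2", ]
  expect_equal(mb$category, "annotated")
})

test_that("novel_combination and unclassified junctions exist and are excluded", {
  ann <- tiny_annotation()
  jx <- tibble::tibble(
    chrom = "chr1",
    start = c(101L, 9000L),   # donor of intron 1 with acceptor of intron 2
    end = c(400L, 9500L),
    strand = "+", sample_id = "s1", count = 1L
  )
  cls <- classify_junctions(jx, ann)
  expect_equal(cls$category[cls$start == 101 & cls$end == 400],
               "novel_combination")
  expect_equal(cls$category[cls$start == 9000], "unclassified")
  expect_true(all(is.na(cls$assigned_intron_id[cls$start %in% c(101, 9000) &
                                                 cls$end %in% c(400, 9500)])))
  msr <- compute_msr(assign_novel(cls, ann), jx)
  expect_equal(nrow(msr), 0L)
})

test_that("strand-unknown junctions adopt a unique matching strand", {
  ann <- tiny_annotation()
  jx <- tibble::tibble(chrom = c("chr1", "chr2"),
                       start = c(101L, 1101L), end = c(200L, 1200L),
                       strand = "?", sample_id = "s1", count = 1L)
  cls <- classify_junctions(jx, ann)
  expect_equal(cls$category, c("annotated", "annotated"))
  expect_equal(cls$strand, c("+", "-"))
  expect_equal(cls$orig_strand, c("?", "?"))
})

test_that("strand-unknown junctions matching both strands are unclassified", {
  # two introns with identical coordinates on opposite strands
  exons <- tibble::tibble(
    transcript_id = c("P", "P", "M", "M"), gene_id = c("gp", "gp", "gm", "gm"),
    chrom = "chr1", strand = c("+", "+", "-", "-"),
    start = c(1L, 201L, 1L, 201L), end = c(100L, 300L, 100L, 300L)
  )
  tx <- tibble::tibble(transcript_id = c("P", "M"), gene_id = c("gp", "gm"),
                       biotype = "protein_coding",
                       is_mane_select = c(TRUE, TRUE))
  ann <- extract_introns(exons, tx)
  jx <- tibble::tibble(chrom = "chr1", start = 101L, end = 200L,
                       strand = "?", sample_id = "s1", count = 1L)
  cls <- classify_junctions(jx, ann)
  expect_equal(cls$category, "unclassified")
})

test_that("novel junctions are assigned by read support, then length, then start", {
  # two introns sharing an acceptor at 400 (+): 101-400 and 301-400
  exons <- tibble::tibble(
    transcript_id = c("A", "A", "B", "B"), gene_id = "g",
    chrom = "chr1", strand = "+",
    start = c(1L, 401L, 201L, 401L), end = c(100L, 500L, 300L, 500L)
  )
  tx <- tibble::tibble(transcript_id = c("A", "B"), gene_id = "g",
                       biotype = "protein_coding",
                       is_mane_select = c(TRUE, FALSE))
  ann <- extract_introns(exons, tx)
  novel <- tibble::tibble(chrom = "chr1", start = 95L, end = 400L,
                          strand = "+", sample_id = "s1", count = 3L)

  # intron A (101-400) has 500 annotated reads, B (301-400) only 20
  counts <- dplyr::bind_rows(
    novel,
    tibble::tibble(chrom = "chr1", start = 101L, end = 400L, strand = "+",
                   sample_id = "s1", count = 500L),
    tibble::tibble(chrom = "chr1", start = 301L, end = 400L, strand = "+",
                   sample_id = "s1", count = 20L)
  )
  cls <- classify_and_assign(counts, ann)
  a_id <- ann$introns$intron_id[ann$introns$start == 101]
  b_id <- ann$introns$intron_id[ann$introns$start == 301]
  expect_equal(cls$assigned_intron_id[cls$start == 95], a_id)

  # equal support -> the shorter intron wins
  counts2 <- dplyr::bind_rows(
    novel,
    tibble::tibble(chrom = "chr1", start = c(101L, 301L), end = 400L,
                   strand = "+", sample_id = "s1", count = 100L)
  )
  cls2 <- classify_and_assign(counts2, ann)
  expect_equal(cls2$assigned_intron_id[cls2$start == 95], b_id)

  # single candidate -> assigned regardless of support
  solo <- tibble::tibble(chrom = "chr1", start = 101L, end = 395L,
                         strand = "+", sample_id = "s1", count = 1L)
  cls3 <- classify_and_assign(dplyr::bind_rows(solo, counts2), ann)
  expect_equal(cls3$assigned_intron_id[cls3$end == 395], a_id)
})

test_that("classification matches the brute-force all-pairs oracle", {
  for (seed in c(101, 202, 303)) {
    inst <- random_instance(seed, n_introns = 30, n_junctions = 120)
    got <- classify_and_assign(inst$junctions, inst$annotation)
    want <- oracle_classify(inst$junctions, inst$annotation)
    key <- function(d) paste(d$chrom, d$start, d$end)
    m <- match(key(got), key(want))
    expect_false(anyNA(m))
    expect_equal(got$category, want$category[m], info = seed)
    expect_equal(got$assigned_intron_id, want$assigned_intron_id[m],
                 info = seed)
    # categories partition the junction set
    expect_equal(nrow(got),
                 nrow(dplyr::distinct(inst$junctions, chrom, start, end,
                                      strand)))
  }
})

test_that("classification is invariant to input order", {
  inst <- random_instance(77)
  got <- classify_and_assign(inst$junctions, inst$annotation)
  set.seed(1)
  shuf <- inst$junctions[sample(nrow(inst$junctions)), ]
  got2 <- classify_and_assign(shuf, inst$annotation)
  expect_equal(got2, got)
})

test_that("contamination rate is 0 for identical annotations and follows the formula", {
  inst <- random_instance(55)
  ct <- contamination_rate(inst$junctions, inst$annotation, inst$annotation)
  expect_equal(ct$j, 0L)
  expect_equal(ct$ct_percent, 0)

  # nested annotations: old has one transcript removed, so its introns'
  # exact matches become novel and are promoted under the new annotation
  ann_new <- tiny_annotation()
  # old annotation lacks gene B entirely
  old_exons <- ann_new$exons[ann_new$exons$gene_id == "GA", ]
  old_tx <- ann_new$transcripts[ann_new$transcripts$gene_id == "GA", ]
  ann_old <- extract_introns(old_exons, old_tx, "old")
  jx <- tibble::tibble(
    chrom = c("chr2", "chr2", "chr1", "chr1"),
    start = c(1101L, 1096L, 96L, 93L),
    end = c(1200L, 1200L, 200L, 200L),
    strand = c("-", "-", "+", "+"),
    sample_id = "s1", count = 1L
  )
  # under old: chr2 junctions unclassified (no gene B), chr1 ones novel_donor
  # under new: 1101-1200 annotated, but it was not novel under old;
  # 96/93 stay novel under both
  ct2 <- contamination_rate(jx, ann_old, ann_new)
  expect_equal(ct2$j, 0L)
  expect_equal(ct2$y, 2L)

  # promote one old-novel junction: new annotation gains transcript with
  # exon ending at 95 so junction 96-200 becomes an annotated intron
  new_exons <- dplyr::bind_rows(
    ann_new$exons,
    tibble::tibble(transcript_id = "T9", gene_id = "GA", chrom = "chr1",
                   strand = "+", start = c(1L, 201L), end = c(95L, 300L)))
  new_tx <- dplyr::bind_rows(
    ann_new$transcripts,
    tibble::tibble(transcript_id = "T9", gene_id = "GA",
                   biotype = "protein_coding", is_mane_select = FALSE))
  ann_new2 <- extract_introns(new_exons, new_tx, "new")
  # old-novel junctions: 96-200 and 93-200 (m = 2); k = 1 promoted
  ct3 <- contamination_rate(jx, ann_old, ann_new2)
  expect_equal(ct3$j, 1L)
  expect_equal(ct3$y, 1L)
  expect_equal(ct3$ct_percent, 100 * 1 / (2 - 1))
})

test_that("y = 0 flags an undefined contamination rate instead of erroring", {
  ann <- tiny_annotation()
  jx <- tibble::tibble(chrom = "chr1", start = 101L, end = 200L,
                       strand = "+", sample_id = "s1", count = 1L)
  expect_warning(ct <- contamination_rate(jx, ann, ann), "undefined")
  expect_true(is.na(ct$ct_percent))
})

test_that("junctions on minor-spliceosome introns are not classified against them", {
  ann <- tiny_annotation()
  minor <- tibble::tibble(chrom = "chr1", start = 101L, end = 200L,
                          strand = "+")
  flagged <- flag_minor_introns(ann, minor)
  jx <- tiny_junctions()
  cls <- classify_junctions(jx, flagged)
  # the exact match to the flagged intron no longer counts as annotated
  expect_false("annotated" %in%
                 cls$category[cls$start == 101 & cls$end == 200])
})
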