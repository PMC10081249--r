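# Small fixtures built in code, shared across test files.

# two genes on opposite strands; gene A has a protein-coding MANE transcript
# and a lncRNA sharing its first intron
tiny_annotation <- function() {
  exons <- tibble::tibble(
    transcript_id = c("T1", "T1", "T1", "T2", "T2", "T3", "T3"),
    gene_id = c("GA", "GA", "GA", "GA", "GA", "GB", "GB"),
    chrom = c(rep("chr1", 5), "chr2", "chr2"),
    strand = c(rep("+", 5), "-", "-"),
    start = c(1L, 201L, 401L, 1L, 201L, 1001L, 1201L),
    end = c(100L, 300L, 500L, 100L, 300L, 1100L, 1300L)
  )
  transcripts <- tibble::tibble(
    transcript_id = c("T1", "T2", "T3"),
    gene_id = c("GA", "GA", "GB"),
    biotype = c("protein_coding", "lncRNA", "protein_coding"),
    is_mane_select = c(TRUE, FALSE, TRUE)
  )
  extract_introns(exons, transcripts, version_label = "tiny")
}

# long junction table for the tiny annotation: annotated plus novel variants
tiny_junctions <- function() {
  tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(101L, 301L, 96L, 101L, 1101L),
    end = c(200L, 400L, 200L, 204L, 1200L),
    strand = c("+", "+", "+", "+", "-"),
    sample_id = "s1",
    count = c(100L, 80L, 5L, 7L, 50L)
  )
}

# random classification instance: introns with some shared boundaries plus a
# junction mix of annotated/novel/junk intervals
random_instance <- function(seed, n_introns = 40, n_junctions = 200,
                            n_samples = 3) {
  set.seed(seed)
  n_tx <- max(2, ceiling(n_introns / 4))
  exon_rows <- list()
  tx_rows <- list()
  for (t in seq_len(n_tx)) {
    chrom <- sample(c("c1", "c2"), 1)
    strand <- sample(c("+", "-"), 1)
    n_ex <- sample(3:6, 1)
    pos <- sample(1:2000, 1)
    starts <- integer(n_ex); ends <- integer(n_ex)
    for (e in seq_len(n_ex)) {
      starts[e] <- pos
      ends[e] <- pos + sample(40:120, 1)
      pos <- ends[e] + sample(60:400, 1)
    }
    tid <- paste0("tx", t)
    exon_rows[[t]] <- tibble::tibble(
      transcript_id = tid, gene_id = paste0("g", (t %% 5) + 1),
      chrom = chrom, strand = strand, start = starts, end = ends)
    tx_rows[[t]] <- tibble::tibble(
      transcript_id = tid, gene_id = paste0("g", (t %% 5) + 1),
      biotype = sample(c("protein_coding", "lncRNA"), 1),
      is_mane_select = t == 1)
  }
  ann <- extract_introns(dplyr::bind_rows(exon_rows),
                         dplyr::bind_rows(tx_rows), "rand")
  it <- ann$introns
  jx <- list()
  for (j in seq_len(n_junctions)) {
    kind <- sample(c("exact", "novel_d", "novel_a", "junk"), 1,
                   prob = c(0.3, 0.25, 0.25, 0.2))
    i <- sample(nrow(it), 1)
    st <- it$start[i]; en <- it$end[i]
    if (kind == "novel_d") {
      # perturb the donor end
      if (it$strand[i] == "+") st <- st + sample(c(-30:-1, 1:30), 1)
      else en <- en + sample(c(-30:-1, 1:30), 1)
    } else if (kind == "novel_a") {
      if (it$strand[i] == "+") en <- en + sample(c(-30:-1, 1:30), 1)
      else st <- st + sample(c(-30:-1, 1:30), 1)
    } else if (kind == "junk") {
      st <- sample(1:8000, 1); en <- st + sample(50:500, 1)
    }
    if (en <= st) next
    jx[[j]] <- tibble::tibble(
      chrom = it$chrom[i], start = st, end = en, strand = it$strand[i],
      sample_id = paste0("s", sample(n_samples, 1)),
      count = sample(1:50, 1))
  }
  junctions <- dplyr::bind_rows(jx) |>
    dplyr::group_by(chrom, start, end, strand, sample_id) |>
    dplyr::summarise(count = sum(count), .groups = "drop")
  list(annotation = ann, junctions = junctions)
}

# genome with one consensus + strand intron: exon1 1..100, intron 101..200
# (GTAAGT ... pyrimidines CAG), exon2 201..300
consensus_genome <- function(seed = 1) {
  set.seed(seed)
  s <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
  s[98:100] <- c("C", "A", "G")
  s[101:106] <- c("G", "T", "A", "A", "G", "T")
  s[181:197] <- sample(c("C", "T"), 17, replace = TRUE)
  s[198:200] <- c("C", "A", "G")
  s[201] <- "G"
  Biostrings::DNAStringSet(c(chrT = paste(s, collapse = "")))
}
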