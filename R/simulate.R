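#' Configuration for the synthetic splicing-noise generator
#'
#' Defines the study conditions emulated by the generator: a small
#' multi-gene annotation with consensus-like splice sites, multi-sample
#' junction tables with known per-intron mis-splicing probabilities, an
#' acceptor offset distribution with an AG-exclusion-zone dead zone, a
#' configurable in-frame offset fraction, and sample metadata (RIN, age).
#' One seed determines all output; per-stage substreams are derived from it
#' so annotation, metadata and reads are independently reproducible.
#'
#' @param n_genes Number of genes.
#' @param n_chroms Chromosomes the genes are distributed over.
#' @param max_transcripts_per_gene Transcript count per gene is drawn
#'   uniformly from 1..this (all transcripts of a gene share its exon
#'   chain; one is always MANE Select).
#' @param noncoding_fraction Expected fraction of non-protein-coding
#'   (lncRNA) transcripts among the extra transcripts of a gene.
#' @param introns_per_transcript Inclusive range the per-gene intron count
#'   is drawn from.
#' @param exon_length_meanlog,exon_length_sdlog,exon_length_min Log-normal
#'   exon length parameters (bp); the default median of ~120 bp mirrors the
#'   typical human exon.
#' @param intron_length_meanlog,intron_length_sdlog,intron_length_min
#'   Log-normal intron length parameters (bp).
#' @param pi_zero_fraction Point mass at zero of the per-intron mis-splicing
#'   probability mixture (fraction of perfectly spliced introns).
#' @param pi_d_values Values the donor-side mis-splicing probability is
#'   drawn from (uniformly) when not zero.
#' @param acceptor_donor_ratio Acceptor-side probability as a multiple of
#'   the donor-side one (acceptor mis-splicing exceeds donor mis-splicing
#'   in real tissues; default 2).
#' @param depth Expected junction reads per intron per sample (Poisson).
#' @param n_samples Number of samples.
#' @param max_offset Maximum |distance| of a novel site from its annotated
#'   site (bp).
#' @param agez_width Width of the acceptor dead zone: no novel acceptor may
#'   fall in the first `agez_width` intronic bases upstream of the 3'ss
#'   (default 18).
#' @param inframe_fraction Target fraction of novel offsets divisible by 3.
#' @param offset_decay Geometric decay rate of offset weights with |d|.
#' @param rin_mean,rin_sd RIN ~ Normal, truncated to [0, 10].
#' @param age_range Ages drawn uniformly (integer years).
#' @param age_effect_factor Multiplier applied to the mis-splicing
#'   probabilities of samples aged 60-79 (1 = no age effect).
#' @param tissue Tissue label written into the metadata.
#' @param seed Integer seed governing all randomness.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 20L, n_chroms = 2L,
                       max_transcripts_per_gene = 3L,
                       noncoding_fraction = 0.3,
                       introns_per_transcript = c(2L, 5L),
                       exon_length_meanlog = log(120),
                       exon_length_sdlog = 0.3, exon_length_min = 50L,
                       intron_length_meanlog = log(400),
                       intron_length_sdlog = 0.4, intron_length_min = 150L,
                       pi_zero_fraction = 0.3,
                       pi_d_values = c(0.01, 0.05, 0.1),
                       acceptor_donor_ratio = 2,
                       depth = 300, n_samples = 10L,
                       max_offset = 30L, agez_width = 18L,
                       inframe_fraction = 0.4, offset_decay = 0.9,
                       rin_mean = 7.5, rin_sd = 1.2,
                       age_range = c(20L, 79L), age_effect_factor = 1,
                       tissue = "synthetic", seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$agez_width >= 0, cfg$inframe_fraction >= 0,
            cfg$inframe_fraction <= 1,
            all(cfg$pi_d_values >= 0),
            all(cfg$pi_d_values * cfg$acceptor_donor_ratio < 1))
  if (cfg$intron_length_min <= 2 * cfg$max_offset + cfg$agez_width + 40) {
    rlang::abort("intron_length_min too small for the offset/AGEZ geometry")
  }
  structure(cfg, class = "sim_config")
}

rand_bases <- function(n) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

# replace each base by a random one with probability `rate`
degenerate <- function(bases, rate = 0.15) {
  hit <- stats::runif(length(bases)) < rate
  bases[hit] <- rand_bases(sum(hit))
  bases
}

#' Simulate a genome and transcript annotation
#'
#' Lays the configured genes out on `n_chroms` chromosomes (both strands),
#' with every intron carrying the consensus donor (`...CAG|GTAAGT...`) and
#' acceptor (`...pyrimidines..CAG|G...`) context in transcript orientation
#' so splice-site scoring is exercisable. Every gene has one MANE Select
#' protein-coding transcript; extra transcripts share the exon chain and are
#' lncRNA with probability `noncoding_fraction`.
#'
#' @param config A [sim_config()].
#' @return A list: `genome` (named [Biostrings::DNAStringSet]) and
#'   `annotation` (a `genome_annotation`).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gap <- 300L
  chrom_seqs <- stats::setNames(vector("list", config$n_chroms),
                                paste0("chrS", seq_len(config$n_chroms)))
  for (nm in names(chrom_seqs)) chrom_seqs[[nm]] <- character(0)
  exon_rows <- list(); tx_rows <- list()

  for (g in seq_len(config$n_genes)) {
    gene_id <- sprintf("GENE%03d", g)
    chrom <- names(chrom_seqs)[((g - 1L) %% config$n_chroms) + 1L]
    strand <- if (stats::runif(1) < 0.5) "+" else "-"
    n_introns <- sample(seq(config$introns_per_transcript[1],
                            config$introns_per_transcript[2]), 1L)
    exon_lens <- pmax(config$exon_length_min,
                      round(stats::rlnorm(n_introns + 1L,
                                          config$exon_length_meanlog,
                                          config$exon_length_sdlog)))
    intron_lens <- pmax(config$intron_length_min,
                        round(stats::rlnorm(n_introns,
                                            config$intron_length_meanlog,
                                            config$intron_length_sdlog)))
    gene_len <- sum(exon_lens) + sum(intron_lens)
    seq_t <- rand_bases(gene_len)

    # transcript-oriented exon intervals within the gene
    t_starts <- integer(n_introns + 1L); t_ends <- integer(n_introns + 1L)
    pos <- 1L
    for (e in seq_len(n_introns + 1L)) {
      t_starts[e] <- pos
      t_ends[e] <- pos + exon_lens[e] - 1L
      pos <- t_ends[e] + 1L
      if (e <= n_introns) pos <- pos + intron_lens[e]
    }
    # plant consensus-like splice-site context around each intron; the
    # invariant GT/AG dinucleotides stay fixed, the remaining consensus
    # bases are lightly degenerate so annotated site strengths vary
    for (i in seq_len(n_introns)) {
      don <- t_ends[i] + 1L              # first intronic base
      acc <- t_starts[i + 1L] - 1L       # last intronic base
      seq_t[(don - 3L):(don - 1L)] <- degenerate(c("C", "A", "G"))
      seq_t[don:(don + 1L)] <- c("G", "T")
      seq_t[(don + 2L):(don + 5L)] <- degenerate(c("A", "A", "G", "T"))
      seq_t[(acc - 19L):(acc - 3L)] <-
        sample(c("C", "T"), 17L, replace = TRUE)
      seq_t[acc - 2L] <- degenerate("C")
      seq_t[(acc - 1L):acc] <- c("A", "G")
      seq_t[acc + 1L] <- degenerate("G")
    }

    offset <- length(chrom_seqs[[chrom]]) + gap
    if (strand == "+") {
      g_seq <- seq_t
      g_starts <- offset + t_starts
      g_ends <- offset + t_ends
    } else {
      g_seq <- rev(c(T = "A", A = "T", C = "G", G = "C")[seq_t])
      g_starts <- offset + (gene_len - t_ends + 1L)
      g_ends <- offset + (gene_len - t_starts + 1L)
      o <- order(g_starts)
      g_starts <- g_starts[o]; g_ends <- g_ends[o]
    }
    chrom_seqs[[chrom]] <- c(chrom_seqs[[chrom]], rand_bases(gap), g_seq)

    n_tx <- sample(seq_len(config$max_transcripts_per_gene), 1L)
    for (t in seq_len(n_tx)) {
      tx_id <- sprintf("%s.T%d", gene_id, t)
      biotype <- if (t == 1L) "protein_coding" else
        if (stats::runif(1) < config$noncoding_fraction) "lncRNA" else
          "protein_coding"
      tx_rows[[tx_id]] <- tibble::tibble(
        transcript_id = tx_id, gene_id = gene_id, biotype = biotype,
        is_mane_select = t == 1L, chrom = chrom, strand = strand
      )
      exon_rows[[tx_id]] <- tibble::tibble(
        transcript_id = tx_id, gene_id = gene_id, chrom = chrom,
        strand = strand, start = g_starts, end = g_ends
      )
    }
  }

  genome <- Biostrings::DNAStringSet(vapply(chrom_seqs, paste,
                                            character(1), collapse = ""))
  annotation <- extract_introns(dplyr::bind_rows(exon_rows),
                                dplyr::bind_rows(tx_rows),
                                version_label = "simulated")
  list(genome = genome, annotation = annotation)
}

#' Simulate sample metadata
#'
#' @param config A [sim_config()].
#' @return A tibble: `sample_id`, `tissue`, `rin`, `age`, `age_bin`,
#'   `msr_factor` (per-sample multiplier on the mis-splicing probabilities;
#'   `age_effect_factor` for samples aged 60-79, 1 otherwise).
#' @export
simulate_metadata <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_samples
  rin <- pmin(10, pmax(0, stats::rnorm(n, config$rin_mean, config$rin_sd)))
  age <- sample(seq(config$age_range[1], config$age_range[2]), n,
                replace = TRUE)
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    tissue = config$tissue,
    rin = round(rin, 2),
    age = age,
    age_bin = dplyr::case_when(age <= 39 ~ "20-39", age <= 59 ~ "40-59",
                               TRUE ~ "60-79"),
    msr_factor = ifelse(age >= 60, config$age_effect_factor, 1)
  )
}

# offset support and weights for novel-site placement; `forbidden` are
# genomic coordinates the novel site may not coincide with
offset_support <- function(kind, config) {
  d <- c(seq(-config$max_offset, -1L), seq(1L, config$max_offset))
  if (kind == "acceptor" && config$agez_width > 0) {
    # transcript-oriented sign: negative = intronic side of the 3'ss
    d <- d[!(d >= -config$agez_width & d <= -1L)]
  }
  w <- config$offset_decay^(abs(d) - 1L)
  list(d = d, w = w)
}

draw_offsets <- function(n, support, config) {
  if (n == 0L) return(integer(0))
  if (length(support$d) == 0L) {
    rlang::abort("no feasible novel-site offsets for an intron; widen max_offset")
  }
  inframe <- support$d %% 3L == 0L
  has_both <- any(inframe) && any(!inframe)
  cls <- if (has_both) {
    stats::runif(n) < config$inframe_fraction
  } else rep(any(inframe), n)
  out <- integer(n)
  for (v in unique(cls)) {
    idx <- which(cls == v)
    pool <- if (v) which(inframe) else which(!inframe)
    out[idx] <- support$d[sample(pool, length(idx), replace = TRUE,
                                 prob = support$w[pool])]
  }
  out
}

#' Draw novel-site offsets from the generator's offset distribution
#'
#' Samples signed novel-to-annotated site distances as placed on individual
#' novel reads: weights decay geometrically with |offset|, offsets divisible
#' by 3 are drawn with probability `inframe_fraction`, and acceptor offsets
#' never fall inside the AG-exclusion-zone dead zone (the first
#' `agez_width` intronic bases). Useful for validating the offset
#' distribution itself, free of the per-intron deduplication that a junction
#' table implies.
#'
#' @param n Number of offsets.
#' @param kind `"donor"` or `"acceptor"`.
#' @param config A [sim_config()]; `config$seed` (+5) seeds the draw.
#' @return Integer vector of signed offsets (never 0).
#' @export
simulate_offsets <- function(n, kind = c("donor", "acceptor"), config) {
  kind <- match.arg(kind)
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 5L)
  draw_offsets(as.integer(n), offset_support(kind, config), config)
}

#' Simulate multi-sample junction reads with known mis-splicing truth
#'
#' Per intron and sample, a total read count is drawn
#' (Poisson with mean `depth`) and partitioned multinomially into novel
#' donor, novel acceptor and annotated reads with probabilities
#' (`pi_d`, `pi_a`, `1 - pi_d - pi_a`). Marginally the novel read counts are
#' Binomial(n, pi) as advertised, and conditional on the donor-side read
#' total the novel donor count is Binomial with success probability
#' `pi_d / (1 - pi_a)` — the value the donor-side mis-splicing ratio
#' estimates, stored as `msr_d_truth` (acceptor analogue `msr_a_truth`).
#' Each novel read is placed at a signed offset from the annotated site
#' drawn from the configured distribution: donor offsets are symmetric
#' around the 5'ss, acceptor offsets avoid the AG-exclusion-zone dead zone
#' on the intronic side, and offsets divisible by 3 are drawn with the
#' configured in-frame fraction. Offsets that would collide with an
#' annotated boundary are excluded from the support.
#'
#' @param sim Output of [simulate_annotation()].
#' @param metadata Output of [simulate_metadata()].
#' @param config A [sim_config()].
#' @param pi_table Optional tibble `intron_id`, `pi_d`, `pi_a` overriding
#'   the configured mixture draw.
#' @return A list: `junctions` (long tibble `chrom`, `start`, `end`,
#'   `strand`, `sample_id`, `count`), `truth` (per-intron tibble with
#'   `pi_d`, `pi_a`, `msr_d_truth`, `msr_a_truth`), `junction_truth`
#'   (per novel junction: coordinates, `kind`, `offset`, `mod3`).
#' @export
simulate_junction_reads <- function(sim, metadata, config, pi_table = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  introns <- sim$annotation$introns
  n_i <- nrow(introns)

  if (is.null(pi_table)) {
    zero <- stats::runif(n_i) < config$pi_zero_fraction
    pi_d <- ifelse(zero, 0,
                   sample(config$pi_d_values, n_i, replace = TRUE))
    pi_a <- pi_d * config$acceptor_donor_ratio
  } else {
    idx <- match(introns$intron_id, pi_table$intron_id)
    pi_d <- pi_table$pi_d[idx]; pi_a <- pi_table$pi_a[idx]
    if (anyNA(pi_d) || anyNA(pi_a)) {
      rlang::abort("pi_table must cover every intron")
    }
  }
  truth <- tibble::tibble(
    intron_id = introns$intron_id,
    chrom = introns$chrom, start = introns$start, end = introns$end,
    strand = introns$strand,
    pi_d = pi_d, pi_a = pi_a,
    msr_d_truth = ifelse(pi_d + pi_a > 0, pi_d / (1 - pi_a), 0),
    msr_a_truth = ifelse(pi_d + pi_a > 0, pi_a / (1 - pi_d), 0)
  )

  donor_set <- split(introns$donor_pos, paste(introns$chrom, introns$strand))
  acceptor_set <- split(introns$acceptor_pos,
                        paste(introns$chrom, introns$strand))
  sup_d <- offset_support("donor", config)
  sup_a <- offset_support("acceptor", config)

  # per-intron supports with boundary collisions removed
  intron_support <- vector("list", n_i)
  for (i in seq_len(n_i)) {
    key <- paste(introns$chrom[i], introns$strand[i])
    sgn <- if (introns$strand[i] == "+") 1L else -1L
    dpos <- introns$donor_pos[i] - sgn * sup_d$d
    apos <- introns$acceptor_pos[i] + sgn * sup_a$d
    keep_d <- !(dpos %in% donor_set[[key]])
    keep_a <- !(apos %in% acceptor_set[[key]])
    intron_support[[i]] <- list(
      donor = list(d = sup_d$d[keep_d], w = sup_d$w[keep_d]),
      acceptor = list(d = sup_a$d[keep_a], w = sup_a$w[keep_a])
    )
  }

  # one cell per intron x sample; multinomial split drawn sequentially
  # (D ~ Bin(n, pd); A | D ~ Bin(n - D, pa / (1 - pd)))
  n_s <- nrow(metadata)
  cell <- tidyr::expand_grid(i = seq_len(n_i), s = seq_len(n_s))
  fac <- if ("msr_factor" %in% names(metadata)) metadata$msr_factor else
    rep(1, n_s)
  pd <- pmin(pi_d[cell$i] * fac[cell$s], 0.45)
  pa <- pmin(pi_a[cell$i] * fac[cell$s], 0.45)
  n_tot <- stats::rpois(nrow(cell), config$depth)
  D <- stats::rbinom(nrow(cell), n_tot, pd)
  A <- stats::rbinom(nrow(cell), n_tot - D, ifelse(pd < 1, pa / (1 - pd), 0))
  S <- n_tot - D - A

  sgn <- ifelse(introns$strand == "+", 1L, -1L)
  ann_rows <- tibble::tibble(
    chrom = introns$chrom[cell$i], start = introns$start[cell$i],
    end = introns$end[cell$i], strand = introns$strand[cell$i],
    sample_id = metadata$sample_id[cell$s], count = S
  )[S > 0L, , drop = FALSE]

  novel_reads <- function(counts, kind) {
    tot <- sum(counts)
    if (tot == 0L) {
      return(tibble::tibble(chrom = character(), start = integer(),
                            end = integer(), strand = character(),
                            sample_id = character(), count = integer(),
                            intron_id = integer(), kind = character(),
                            offset = integer()))
    }
    read_i <- rep(cell$i, counts)
    read_s <- rep(cell$s, counts)
    off <- integer(tot)
    for (i in unique(read_i)) {
      sel <- read_i == i
      off[sel] <- draw_offsets(sum(sel), intron_support[[i]][[kind]], config)
    }
    if (kind == "donor") {
      npos <- introns$donor_pos[read_i] - sgn[read_i] * off
      st <- ifelse(introns$strand[read_i] == "+", npos,
                   introns$start[read_i])
      en <- ifelse(introns$strand[read_i] == "+", introns$end[read_i], npos)
    } else {
      npos <- introns$acceptor_pos[read_i] + sgn[read_i] * off
      st <- ifelse(introns$strand[read_i] == "+", introns$start[read_i],
                   npos)
      en <- ifelse(introns$strand[read_i] == "+", npos, introns$end[read_i])
    }
    tibble::tibble(chrom = introns$chrom[read_i], start = st, end = en,
                   strand = introns$strand[read_i],
                   sample_id = metadata$sample_id[read_s], count = 1L,
                   intron_id = introns$intron_id[read_i], kind = kind,
                   offset = off)
  }
  nd <- novel_reads(D, "donor")
  na_ <- novel_reads(A, "acceptor")

  junctions <- dplyr::bind_rows(
    ann_rows, nd[names(ann_rows)], na_[names(ann_rows)]) |>
    dplyr::group_by(.data$chrom, .data$start, .data$end, .data$strand,
                    .data$sample_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  junction_truth <- dplyr::bind_rows(nd, na_) |>
    dplyr::distinct(.data$chrom, .data$start, .data$end, .data$strand,
                    .data$intron_id, .data$kind, .data$offset) |>
    dplyr::mutate(mod3 = .data$offset %% 3L)
  list(junctions = junctions, truth = truth, junction_truth = junction_truth)
}

#' Write a genome_annotation as GTF
#'
#' Emits transcript and exon features with `gene_id`, `transcript_id`,
#' `transcript_biotype` and, for MANE Select transcripts,
#' `tag "MANE_Select"`, so the file round-trips through
#' [read_gtf_annotation()].
#'
#' @param annotation A `genome_annotation` object (must carry `exons` and
#'   `transcripts`).
#' @param path Output path.
#' @export
write_gtf <- function(annotation, path) {
  ex <- annotation$exons |>
    dplyr::left_join(annotation$transcripts[, c("transcript_id", "biotype",
                                                "is_mane_select")],
                     by = "transcript_id") |>
    dplyr::arrange(.data$chrom, .data$start)
  attrs <- paste0(
    'gene_id "', ex$gene_id, '"; transcript_id "', ex$transcript_id,
    '"; transcript_biotype "', ex$biotype, '";',
    ifelse(ex$is_mane_select, ' tag "MANE_Select";', "")
  )
  lines <- paste(ex$chrom, "simulated", "exon", ex$start, ex$end, ".",
                 ex$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a full synthetic study
#'
#' Runs [simulate_annotation()], [simulate_metadata()] and
#' [simulate_junction_reads()] and optionally writes the dataset to disk
#' (genome FASTA, GTF, one regtools-dialect BED12 junction table per
#' sample, metadata TSV and truth JSON).
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created); `NULL` skips writing.
#' @return A list: `config`, `genome`, `annotation`, `metadata`,
#'   `junctions`, `truth`, `junction_truth`, and `dir` (when written).
#' @export
simulate_dataset <- function(config, dir = NULL) {
  sim <- simulate_annotation(config)
  metadata <- simulate_metadata(config)
  reads <- simulate_junction_reads(sim, metadata, config)
  out <- list(config = config, genome = sim$genome,
              annotation = sim$annotation, metadata = metadata,
              junctions = reads$junctions, truth = reads$truth,
              junction_truth = reads$junction_truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
    write_gtf(sim$annotation, file.path(dir, "annotation.gtf"))
    readr::write_tsv(metadata, file.path(dir, "samples.tsv"))
    for (sid in metadata$sample_id) {
      js <- reads$junctions[reads$junctions$sample_id == sid, , drop = FALSE]
      write_junctions(js, file.path(dir, paste0(sid, ".junctions.bed")),
                      dialect = "regtools_bed12")
    }
    jsonlite::write_json(
      list(truth = reads$truth, junction_truth = reads$junction_truth,
           seed = config$seed),
      file.path(dir, "truth.json"), digits = NA)
    out$dir <- dir
  }
  out
}
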