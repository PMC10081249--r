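#' Extract a splice-site sequence window from a genome
#'
#' Donor (5'ss) windows are 9 bp: 3 exonic bases followed by the first 6
#' intronic bases. Acceptor (3'ss) windows are 23 bp: the last 20 intronic
#' bases followed by 3 exonic bases. Minus-strand windows are
#' reverse-complemented so the returned string always reads 5'->3' in
#' transcript orientation.
#'
#' @param genome A named [Biostrings::DNAStringSet] (names = chromosome
#'   names) or a FASTA file path.
#' @param chrom Chromosome name.
#' @param pos Genomic coordinate of the boundary intronic base (the intron's
#'   first base for a donor, its last base for an acceptor, in genomic
#'   coordinates; on the minus strand these are the intron `end` and `start`
#'   respectively).
#' @param strand `"+"` or `"-"`.
#' @param kind `"donor"` or `"acceptor"`.
#' @return A single uppercase character string (9 or 23 bp), or `NA_character_`
#'   with a warning if the window contains a non-ACGT base.
#' @export
extract_site_sequence <- function(genome, chrom, pos, strand, kind) {
  genome <- as_genome(genome)
  kind <- match.arg(kind, c("donor", "acceptor"))
  stopifnot(strand %in% c("+", "-"))
  if (!chrom %in% names(genome)) {
    rlang::abort(paste0("chromosome not in genome: ", chrom))
  }
  if (kind == "donor") {
    win <- if (strand == "+") c(pos - 3L, pos + 5L) else c(pos - 5L, pos + 3L)
  } else {
    win <- if (strand == "+") c(pos - 19L, pos + 3L) else c(pos - 3L, pos + 19L)
  }
  chrom_len <- Biostrings::width(genome[chrom])
  if (win[1] < 1L || win[2] > chrom_len) {
    rlang::abort(paste0("site window [", win[1], ",", win[2],
                        "] off contig ", chrom))
  }
  s <- Biostrings::subseq(genome[[chrom]], win[1], win[2])
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  s <- toupper(as.character(s))
  if (grepl("[^ACGT]", s)) {
    rlang::warn(paste0("ambiguous base in site window at ", chrom, ":",
                       pos, strand, "; site skipped"))
    return(NA_character_)
  }
  s
}

as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    g <- Biostrings::readDNAStringSet(genome)
    names(g) <- sub("\\s.*$", "", names(g))
    return(g)
  }
  rlang::abort("genome must be a DNAStringSet or a FASTA path")
}

#' Bundled toy splice-site model
#'
#' A position-weight-matrix log-odds model over the same 9 bp donor and
#' 23 bp acceptor windows as the maximum-entropy model, built from a
#' consensus-like base composition (donor consensus CAG|GTAAGT; acceptor
#' polypyrimidine tract ending in AG). It shares the scoring interface of
#' [read_mes_model()] so the whole pipeline can run and be tested without
#' external parameter tables; scores are log2 odds against a uniform
#' background and are comparable within, not across, models.
#'
#' @param consensus_prob Probability mass on the consensus base at strongly
#'   constrained positions.
#' @return An object of class `pwm_splice_model`.
#' @export
toy_splice_model <- function(consensus_prob = 0.7) {
  stopifnot(consensus_prob > 0.25, consensus_prob < 1)
  pwm_from_consensus <- function(consensus, strong) {
    p <- matrix(0.25, nrow = 4, ncol = nchar(consensus),
                dimnames = list(c("A", "C", "G", "T"), NULL))
    bases <- strsplit(consensus, "")[[1]]
    for (i in seq_along(bases)) {
      if (bases[i] == "Y") { # pyrimidine-biased position
        p[, i] <- c(0.08, 0.42, 0.08, 0.42)
      } else if (strong[i]) {
        p[, i] <- (1 - consensus_prob) / 3
        p[bases[i], i] <- consensus_prob
      }
    }
    p
  }
  donor <- pwm_from_consensus("CAGGTAAGT",
                              strong = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                                         TRUE, TRUE, TRUE))
  acceptor <- pwm_from_consensus(
    paste0(strrep("Y", 17), "CAG", "GTC"),
    strong = c(rep(FALSE, 17), TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  )
  structure(list(donor = donor, acceptor = acceptor, background = 0.25),
            class = c("pwm_splice_model", "splice_model"))
}

#' Load published maximum-entropy splice-site parameter tables
#'
#' Reads the parameter-table directory layout of the original
#' maximum-entropy splice-site scorer: a file `me2x5` with one probability
#' per line for each of the 4^7 donor 7-mers (the 9-mer minus the invariant
#' GT dinucleotide) in lexicographic order (A<C<G<T), and files
#' `me2x3acc1` ... `me2x3acc9` with the probabilities of the nine acceptor
#' sub-sequence models (segment lengths 7,7,7,7,7,3,4,3,4) in the same
#' order.
#'
#' @param dir Directory containing the parameter files.
#' @return An object of class `mes_model`.
#' @export
read_mes_model <- function(dir) {
  read_table_file <- function(name, k) {
    path <- file.path(dir, name)
    if (!file.exists(path)) rlang::abort(paste0("missing model table: ", path))
    v <- as.numeric(scan(path, what = character(), quiet = TRUE))
    if (length(v) != 4^k) {
      rlang::abort(paste0(name, " has ", length(v), " values; expected 4^",
                          k, " = ", 4^k))
    }
    v
  }
  acc_lens <- c(7, 7, 7, 7, 7, 3, 4, 3, 4)
  structure(list(
    me2x5 = read_table_file("me2x5", 7),
    acc = lapply(seq_len(9), function(i)
      read_table_file(paste0("me2x3acc", i), acc_lens[i])),
    acc_lens = acc_lens,
    # consensus dinucleotide frequencies and genomic background of the
    # published model (donor positions 4-5 = GT; acceptor positions 19-20 = AG)
    donor_cons1 = c(A = 0.004, C = 0.0032, G = 0.9896, T = 0.0032),
    donor_cons2 = c(A = 0.0034, C = 0.0039, G = 0.0042, T = 0.9884),
    acceptor_cons1 = c(A = 0.9903, C = 0.0032, G = 0.0034, T = 0.003),
    acceptor_cons2 = c(A = 0.0027, C = 0.0037, G = 0.9905, T = 0.003),
    background = c(A = 0.27, C = 0.23, G = 0.23, T = 0.27)
  ), class = c("mes_model", "splice_model"))
}

seq_to_index <- function(seq) {
  # lexicographic rank (1-based) of a k-mer, A<C<G<T
  v <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T")) - 1L
  sum(v * 4^(rev(seq_along(v)) - 1L)) + 1L
}

#' Score a splice-site sequence
#'
#' Scores a 9 bp donor or 23 bp acceptor window with the supplied model.
#' Higher scores indicate sequences closer to the splice-site consensus
#' ("stronger" sites). Scoring is a pure function of (sequence, model).
#'
#' @param seq Uppercase A/C/G/T string of length 9 (donor) or 23 (acceptor);
#'   vectorised.
#' @param model A `pwm_splice_model` or `mes_model`.
#' @param kind `"donor"` or `"acceptor"`.
#' @return Numeric score(s) (log2 odds).
#' @export
score_splice_site <- function(seq, model, kind = c("donor", "acceptor")) {
  kind <- match.arg(kind)
  vapply(seq, function(s) {
    if (is.na(s)) return(NA_real_)
    check_site_seq(s, kind)
    score_one_site(model, s, kind)
  }, numeric(1), USE.NAMES = FALSE)
}

check_site_seq <- function(seq, kind) {
  want <- if (kind == "donor") 9L else 23L
  if (nchar(seq) != want) {
    rlang::abort(paste0(kind, " sequence must be ", want, " bp, got ",
                        nchar(seq), " (", seq, ")"))
  }
  if (grepl("[^ACGT]", seq)) {
    rlang::abort(paste0("sequence contains non-ACGT characters: ", seq))
  }
  invisible(TRUE)
}

score_one_site <- function(model, seq, kind) UseMethod("score_one_site")

#' @export
score_one_site.pwm_splice_model <- function(model, seq, kind) {
  p <- model[[kind]]
  rows <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  sum(log2(p[cbind(rows, seq_along(rows))] / model$background))
}

#' @export
score_one_site.mes_model <- function(model, seq, kind) {
  bg <- model$background
  if (kind == "donor") {
    b4 <- substr(seq, 4, 4); b5 <- substr(seq, 5, 5)
    cons_odds <- (model$donor_cons1[b4] * model$donor_cons2[b5]) /
      (bg[b4] * bg[b5])
    rest <- paste0(substr(seq, 1, 3), substr(seq, 6, 9))
    unname(log2(cons_odds * model$me2x5[seq_to_index(rest)]))
  } else {
    b19 <- substr(seq, 19, 19); b20 <- substr(seq, 20, 20)
    cons_odds <- (model$acceptor_cons1[b19] * model$acceptor_cons2[b20]) /
      (bg[b19] * bg[b20])
    rest <- paste0(substr(seq, 1, 18), substr(seq, 21, 23))
    starts <- c(1, 8, 15, 5, 12, 5, 8, 12, 15)
    segs <- substring(rest, starts, starts + model$acc_lens - 1L)
    sc <- vapply(seq_len(9), function(i)
      model$acc[[i]][seq_to_index(segs[i])], numeric(1))
    maxent <- prod(sc[1:5]) / prod(sc[6:9])
    unname(log2(cons_odds * maxent))
  }
}

#' Delta scores between annotated and paired novel splice sites
#'
#' For every assigned novel junction, scores the annotated splice site of
#' its linked intron and the corresponding novel site, and reports
#' `delta = score_annotated - score_novel`. Novel donor junctions are scored
#' at the 5'ss (9 bp window), novel acceptor junctions at the 3'ss (23 bp
#' window); a positive delta means the novel site is weaker than the
#' annotated one. Sites with ambiguous bases are skipped and tallied in the
#' `n_skipped` attribute.
#'
#' @param classified Classified-and-assigned junction tibble.
#' @param annotation A `genome_annotation` object.
#' @param genome Genome sequence (see [extract_site_sequence()]).
#' @param model A splice-site model ([toy_splice_model()] or
#'   [read_mes_model()]).
#' @return A tibble: junction coordinates, `intron_id`, `kind`, `mes_ann`,
#'   `mes_novel`, `delta`.
#' @export
delta_mes <- function(classified, annotation, genome, model) {
  genome <- as_genome(genome)
  novel <- classified |>
    dplyr::filter(.data$category %in% c("novel_donor", "novel_acceptor"),
                  !is.na(.data$assigned_intron_id))
  introns <- annotation$introns
  if (nrow(novel) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          intron_id = integer(), kind = character(),
                          mes_ann = numeric(), mes_novel = numeric(),
                          delta = numeric()))
  }
  idx <- match(novel$assigned_intron_id, introns$intron_id)
  kind <- ifelse(novel$category == "novel_donor", "donor", "acceptor")
  ann_pos <- ifelse(kind == "donor", introns$donor_pos[idx],
                    introns$acceptor_pos[idx])
  novel_pos <- ifelse(kind == "donor",
                      ifelse(novel$strand == "+", novel$start, novel$end),
                      ifelse(novel$strand == "+", novel$end, novel$start))
  rows <- purrr::pmap(
    list(novel$chrom, novel$strand, kind, ann_pos, novel_pos),
    function(chrom, strand, kind, apos, npos) {
      seq_ann <- tryCatch(
        extract_site_sequence(genome, chrom, apos, strand, kind),
        error = function(e) NA_character_)
      seq_nov <- tryCatch(
        extract_site_sequence(genome, chrom, npos, strand, kind),
        error = function(e) NA_character_)
      if (is.na(seq_ann) || is.na(seq_nov)) {
        return(c(mes_ann = NA_real_, mes_novel = NA_real_))
      }
      c(mes_ann = score_splice_site(seq_ann, model, kind),
        mes_novel = score_splice_site(seq_nov, model, kind))
    })
  scores <- do.call(rbind, rows)
  out <- tibble::tibble(
    chrom = novel$chrom, start = novel$start, end = novel$end,
    strand = novel$strand, intron_id = novel$assigned_intron_id,
    kind = kind,
    mes_ann = scores[, "mes_ann"], mes_novel = scores[, "mes_novel"],
    delta = scores[, "mes_ann"] - scores[, "mes_novel"]
  )
  skipped <- sum(is.na(out$delta))
  out <- out[!is.na(out$delta), , drop = FALSE]
  attr(out, "n_skipped") <- skipped
  out
}
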