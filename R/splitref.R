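# Split-reference assembly generation: cut a finished reference into
# equal-size pieces with a known truth layout — the best-case scaffolding
# input — plus a synthetic genome simulator for fully self-contained tests.

#' Piece-size presets (bp)
#'
#' Named vector of the standard split sizes: 10 kb, 50 kb, 100 kb, 500 kb
#' and 1 Mb.
#' @export
split_presets <- c("10kb" = 1e4, "50kb" = 5e4, "100kb" = 1e5,
                   "500kb" = 5e5, "1mb" = 1e6)

#' Split a reference genome into equal-sized pieces
#'
#' Each chromosome is cut left-to-right into consecutive pieces of exactly
#' `piece_size` bp. A trailing remainder is kept as its own (shorter) piece
#' when at least `min_piece` bp, otherwise merged into the previous piece;
#' a chromosome shorter than `min_piece` becomes a single piece with a
#' warning. Concatenating a chromosome's pieces reproduces its sequence
#' exactly.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param piece_size Target piece size in bp (see [split_presets]).
#' @param min_piece Smallest retained remainder (default `piece_size / 2`).
#' @param name_template Piece naming template with placeholders `{chrom}`
#'   and `{i}` (1-based piece ordinal).
#' @return List with `pieces` (named character vector), `truth`
#'   (`genome_layout`: pieces in genomic order, all forward).
#' @export
split_reference <- function(genome, piece_size,
                            min_piece = ceiling(piece_size / 2),
                            name_template = "{chrom}_p{i}") {
  stopifnot(piece_size >= 1, min_piece <= piece_size, length(genome) >= 1)
  if (is.null(names(genome))) stop("genome sequences must be named")
  pieces <- character(0)
  groups <- list()
  for (chrom in names(genome)) {
    seq <- genome[[chrom]]
    L <- nchar(seq)
    n_full <- L %/% piece_size
    rem <- L - n_full * piece_size
    if (n_full == 0) {
      if (L < min_piece) {
        warning("chromosome ", chrom, " (", L, " bp) shorter than min_piece; ",
                "emitted as a single piece")
      }
      bounds <- c(0, L)
    } else {
      cuts <- piece_size * seq_len(n_full)
      if (rem >= min_piece) {
        bounds <- c(0, cuts, L)
      } else if (rem > 0) {
        bounds <- c(0, cuts[-n_full], L)  # merge remainder into last piece
      } else {
        bounds <- c(0, cuts)
      }
    }
    np <- length(bounds) - 1
    nm <- vapply(seq_len(np), function(i)
      sub("{i}", i, sub("{chrom}", chrom, name_template, fixed = TRUE),
          fixed = TRUE), character(1))
    seg <- substring(seq, bounds[-length(bounds)] + 1, bounds[-1])
    pieces[nm] <- seg
    groups[[chrom]] <- data.frame(contig = nm, orientation = "+",
                                  length = nchar(seg))
  }
  list(pieces = pieces, truth = genome_layout(groups))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

mutate_seq <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic multi-chromosome genome
#'
#' Random-sequence chromosomes at a target GC content, with an optional
#' fraction of each chromosome filled with copies drawn from a small shared
#' repeat library (creating multi-mapping ambiguity) and optional
#' haplotig-like records: lightly mutated (~2% divergence) copies of random
#' chromosome sub-intervals emulating allelic duplicates.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param length_range Length range (bp), one length drawn uniformly per
#'   chromosome; a single value fixes all lengths.
#' @param gc GC content in [0, 1] (default 0.4, a typical eukaryotic value).
#' @param repeat_fraction Fraction of each chromosome covered by repeat
#'   copies (default 0).
#' @param haplotig_fraction Total haplotig length as a fraction of genome
#'   length (default 0).
#' @param haplotig_size Mean haplotig length in bp (default 5000).
#' @param divergence Haplotig point-mutation rate (default 0.02).
#' @param seed Integer seed fixing all randomness.
#' @return List with `genome` (named character vector, `chr1..chrN`) and
#'   `haplotigs` (named character vector, possibly empty).
#' @export
make_synthetic_genome <- function(n_chromosomes, length_range,
                                  gc = 0.4, repeat_fraction = 0,
                                  haplotig_fraction = 0,
                                  haplotig_size = 5000,
                                  divergence = 0.02, seed = 1) {
  stopifnot(n_chromosomes >= 1, all(length_range >= 1),
            gc >= 0, gc <= 1, repeat_fraction >= 0, repeat_fraction < 1,
            haplotig_fraction >= 0, haplotig_fraction < 1)
  set.seed(seed)
  if (length(length_range) == 1) length_range <- rep(length_range, 2)
  lens <- round(stats::runif(n_chromosomes, length_range[1], length_range[2]))
  repeat_unit_len <- 500L
  n_units <- 3L
  repeat_lib <- vapply(seq_len(n_units), function(i)
    random_dna(repeat_unit_len, gc), character(1))
  genome <- character(n_chromosomes)
  names(genome) <- paste0("chr", seq_len(n_chromosomes))
  for (k in seq_len(n_chromosomes)) {
    seq <- random_dna(lens[k], gc)
    if (repeat_fraction > 0) {
      n_copies <- floor(repeat_fraction * lens[k] / repeat_unit_len)
      if (n_copies > 0 && lens[k] > repeat_unit_len) {
        starts <- sample.int(lens[k] - repeat_unit_len, n_copies, replace = TRUE)
        for (s in starts) {
          unit <- repeat_lib[[sample.int(n_units, 1)]]
          substr(seq, s, s + repeat_unit_len - 1) <- unit
        }
      }
    }
    genome[k] <- seq
  }
  haplotigs <- character(0)
  if (haplotig_fraction > 0) {
    target <- haplotig_fraction * sum(nchar(genome))
    got <- 0
    i <- 0
    while (got < target) {
      i <- i + 1
      k <- sample.int(n_chromosomes, 1)
      L <- nchar(genome[[k]])
      hlen <- min(max(200, round(stats::rexp(1, 1 / haplotig_size))), L)
      s <- sample.int(L - hlen + 1, 1)
      frag <- substring(genome[[k]], s, s + hlen - 1)
      haplotigs[paste0("hap", i)] <- mutate_seq(frag, divergence)
      got <- got + hlen
    }
  }
  list(genome = genome, haplotigs = haplotigs)
}
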