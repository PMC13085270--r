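# Readers for contig-to-reference alignments (MUMmer show-coords tabular
# output and PAF) and the placement rule turning alignments into the
# reference-side truth layout. Internal coordinates are 0-based half-open;
# show-coords (1-based inclusive) is converted at this boundary, PAF is
# native.

alignment_record_df <- function(ref_name, ref_start, ref_end, contig_name,
                                contig_start, contig_end, strand,
                                aligned_bases, identity) {
  data.frame(ref_name = ref_name, ref_start = ref_start, ref_end = ref_end,
             contig_name = contig_name, contig_start = contig_start,
             contig_end = contig_end, strand = strand,
             aligned_bases = aligned_bases, identity = identity,
             stringsAsFactors = FALSE)
}

#' Read MUMmer 4 show-coords tabular output
#'
#' Accepts both the default pipe-decorated layout and `show-coords -T` tab
#' output, with or without header lines. Columns expected per data row:
#' reference start/end, query start/end, the two alignment lengths, percent
#' identity, then reference and query names. Reverse-strand rows (query
#' start > query end) are normalised to ascending coordinates with
#' `strand = "-"`. Coordinates are converted from 1-based inclusive to the
#' internal 0-based half-open convention.
#'
#' @param path show-coords output file.
#' @return data.frame of alignment records with columns `ref_name`,
#'   `ref_start`, `ref_end`, `contig_name`, `contig_start`, `contig_end`,
#'   `strand`, `aligned_bases`, `identity`.
#' @export
read_coords <- function(path) {
  lines <- readLines(path)
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    raw <- gsub("|", " ", lines[i], fixed = TRUE)
    tok <- strsplit(trimws(raw), "[ \t]+")[[1]]
    if (length(tok) == 0 || !grepl("^[0-9]", tok[1])) next  # header/blank
    if (length(tok) < 9) stop("malformed show-coords row at line ", i)
    num <- suppressWarnings(as.numeric(tok[1:7]))
    if (anyNA(num)) stop("non-numeric field in show-coords row at line ", i)
    s1 <- num[1]; e1 <- num[2]; s2 <- num[3]; e2 <- num[4]
    idy <- num[7]
    ref <- tok[length(tok) - 1]
    qry <- tok[length(tok)]
    strand <- "+"
    if (s2 > e2) {
      strand <- "-"
      tmp <- s2; s2 <- e2; e2 <- tmp
    }
    recs[[i]] <- alignment_record_df(
      ref, s1 - 1, e1, qry, s2 - 1, e2, strand,
      aligned_bases = e2 - s2 + 1, identity = idy)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0) {
    return(alignment_record_df(character(0), numeric(0), numeric(0),
                               character(0), numeric(0), numeric(0),
                               character(0), numeric(0), numeric(0)))
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Read a PAF alignment file
#'
#' PAF's native 0-based half-open coordinates are kept. `aligned_bases` is
#' the residue-matches field (column 10); identity = matches / alignment
#' block length x 100. The PAF query is the contig, the target the
#' reference.
#'
#' @param path PAF file.
#' @return data.frame of alignment records (same columns as [read_coords()]).
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(alignment_record_df(character(0), numeric(0), numeric(0),
                               character(0), numeric(0), numeric(0),
                               character(0), numeric(0), numeric(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 12)
  if (length(bad)) stop("PAF row with fewer than 12 fields at line ", bad[1])
  f <- function(k) vapply(fields, `[[`, character(1), k)
  num <- function(k) {
    v <- suppressWarnings(as.numeric(f(k)))
    if (anyNA(v)) stop("non-numeric PAF field ", k, " at line ",
                       which(is.na(v))[1])
    v
  }
  strand <- f(5)
  if (!all(strand %in% c("+", "-"))) stop("invalid PAF strand field")
  matches <- num(10)
  block <- num(11)
  alignment_record_df(
    ref_name = f(6), ref_start = num(8), ref_end = num(9),
    contig_name = f(1), contig_start = num(3), contig_end = num(4),
    strand = strand, aligned_bases = matches,
    identity = ifelse(block > 0, matches / block * 100, 0))
}

# Total length of the union of [start, end) intervals.
interval_union_length <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  total <- 0; cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] > cur_e) {
      total <- total + (cur_e - cur_s)
      cur_s <- start[i]; cur_e <- end[i]
    } else {
      cur_e <- max(cur_e, end[i])
    }
  }
  total + (cur_e - cur_s)
}

#' Infer contig placements from alignment records
#'
#' For each contig, candidate chromosomes are scored by aligned bases
#' (overlapping alignments merged by interval union on the contig
#' coordinates, so tandem split hits are not double counted); the best
#' chromosome wins. Position is the aligned-length-weighted midpoint of the
#' winner's reference spans; orientation is the strand carrying the majority
#' of the winner's aligned bases. Contigs whose winning aligned fraction is
#' below `min_aligned_fraction` are unplaced; the chimeric flag is set when
#' the runner-up chromosome holds at least `chimeric_threshold` of the
#' contig's total aligned bases.
#'
#' @param records data.frame from [read_coords()] or [read_paf()].
#' @param contig_lengths Named numeric vector, contig id -> length (bp);
#'   every contig in `records` must be present.
#' @param min_aligned_fraction Placement threshold in [0, 1] (default 0.5).
#' @param chimeric_threshold Runner-up share flagging a chimera (default 0.3).
#' @return data.frame with one row per contig in `contig_lengths`: columns
#'   `contig_id`, `chromosome` (NA when unplaced), `position`,
#'   `orientation`, `aligned_fraction`, `chimeric`.
#' @export
place_contigs <- function(records, contig_lengths,
                          min_aligned_fraction = 0.5,
                          chimeric_threshold = 0.3) {
  stopifnot(is.numeric(contig_lengths), !is.null(names(contig_lengths)))
  unknown <- setdiff(unique(records$contig_name), names(contig_lengths))
  if (length(unknown)) {
    stop("contig(s) in records with unknown length: ",
         paste(unknown, collapse = ", "))
  }
  ids <- sort(names(contig_lengths))
  rows <- lapply(ids, function(cid) {
    len <- contig_lengths[[cid]]
    rec <- records[records$contig_name == cid, , drop = FALSE]
    if (nrow(rec) == 0) {
      return(data.frame(contig_id = cid, chromosome = NA_character_,
                        position = NA_real_, orientation = NA_character_,
                        aligned_fraction = 0, chimeric = FALSE))
    }
    per_chrom <- vapply(split(rec, rec$ref_name), function(d) {
      interval_union_length(d$contig_start, d$contig_end)
    }, numeric(1))
    per_chrom <- per_chrom[order(-per_chrom, names(per_chrom))]
    winner <- names(per_chrom)[1]
    total_aligned <- sum(per_chrom)
    chim <- length(per_chrom) > 1 &&
      per_chrom[2] >= chimeric_threshold * total_aligned
    frac <- min(per_chrom[1] / len, 1)
    wrec <- rec[rec$ref_name == winner, , drop = FALSE]
    mid <- (wrec$ref_start + wrec$ref_end) / 2
    w <- wrec$aligned_bases
    pos <- sum(mid * w) / sum(w)
    plus <- sum(w[wrec$strand == "+"])
    ori <- if (plus * 2 >= sum(w)) "+" else "-"
    if (frac < min_aligned_fraction) {
      return(data.frame(contig_id = cid, chromosome = NA_character_,
                        position = NA_real_, orientation = NA_character_,
                        aligned_fraction = frac, chimeric = chim))
    }
    data.frame(contig_id = cid, chromosome = winner, position = pos,
               orientation = ori, aligned_fraction = frac, chimeric = chim)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the reference truth layout from contig placements
#'
#' One group per chromosome; placed contigs sorted by position (ties broken
#' by contig id), carrying their inferred orientations. Groups are ordered
#' by chromosome name. Unplaced contigs are excluded and listed in the
#' `unplaced` attribute.
#'
#' @param placements data.frame from [place_contigs()].
#' @param contig_lengths Named numeric vector of contig lengths.
#' @return A `genome_layout` with attribute `unplaced`.
#' @export
build_reference_layout <- function(placements, contig_lengths) {
  placed <- placements[!is.na(placements$chromosome), , drop = FALSE]
  if (nrow(placed) == 0) stop("no contigs could be placed")
  groups <- lapply(split(placed, placed$chromosome), function(d) {
    d <- d[order(d$position, d$contig_id), , drop = FALSE]
    data.frame(contig = d$contig_id, orientation = d$orientation,
               length = unname(contig_lengths[d$contig_id]))
  })
  layout <- genome_layout(groups[sort(names(groups))])
  attr(layout, "unplaced") <-
    sort(placements$contig_id[is.na(placements$chromosome)])
  layout
}
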