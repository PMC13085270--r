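# Hi-C read-pair downsampling to a target contact density, in read pairs
# per kilobase of assembly. Pairs (contacts) are the counting unit: read
# bases do not contribute to the contact count. Standard presets: 1, 50,
# 100, 500 and 1000 reads per kilobase.

#' Hi-C density presets (read pairs per kilobase)
#' @export
density_presets <- c(1, 50, 100, 500, 1000)

#' Downsample read pairs to a target density
#'
#' Keeps exactly `floor(target_density * assembly_length / 1000)` pairs,
#' drawn uniformly at random without replacement, output in the original
#' input order. If the target exceeds availability all pairs are returned
#' with a warning. Input pairs are expected to be deduplicated; rows flagged
#' as duplicates are dropped first with a warning.
#'
#' @param pairs data.frame of read pairs (from [read_pairs_tsv()] or
#'   [read_pairs_sam()]): columns `pair_id`, `contig1`, `pos1`, `contig2`,
#'   `pos2` and optionally `duplicate`.
#' @param assembly_length Assembly length in bp (> 0).
#' @param target_density Target density in read pairs per kilobase (> 0).
#' @param seed Integer seed; the same seed reproduces the same subset.
#' @param unit `"pairs"` (default) counts each row once; `"reads"` counts
#'   each row as two reads, i.e. keeps `floor(target * L / 1000 / 2)` rows.
#' @return data.frame of retained pairs, original order preserved.
#' @export
downsample_pairs <- function(pairs, assembly_length, target_density, seed,
                             unit = c("pairs", "reads")) {
  unit <- match.arg(unit)
  if (!is.numeric(assembly_length) || assembly_length <= 0) {
    stop("assembly_length must be positive")
  }
  stopifnot(target_density > 0)
  if ("duplicate" %in% names(pairs) && any(pairs$duplicate)) {
    warning("dropping ", sum(pairs$duplicate), " duplicate-flagged pair(s)")
    pairs <- pairs[!pairs$duplicate, , drop = FALSE]
  }
  keep_count <- floor(target_density * assembly_length / 1000)
  if (unit == "reads") keep_count <- floor(keep_count / 2)
  n <- nrow(pairs)
  if (keep_count >= n) {
    if (keep_count > n) {
      warning("target density needs ", keep_count, " pairs but only ", n,
              " available; returning all")
    }
    return(pairs)
  }
  set.seed(seed)
  idx <- sort(sample.int(n, keep_count))
  out <- pairs[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Contact density of a pair set
#'
#' @param pairs data.frame of read pairs (or anything with `nrow`).
#' @param assembly_length Assembly length in bp (> 0).
#' @return Read pairs per kilobase.
#' @export
pair_density <- function(pairs, assembly_length) {
  if (assembly_length <= 0) stop("assembly_length must be positive")
  nrow(pairs) / (assembly_length / 1000)
}

#' Read/write the tabular read-pair format
#'
#' Five tab-separated columns: `pair_id`, `contig1`, `pos1`, `contig2`,
#' `pos2` (0-based positions), with a header line.
#'
#' @param path File path.
#' @return data.frame of pairs.
#' @export
read_pairs_tsv <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "contig1", "pos1", "contig2", "pos2")
  if (!all(need %in% names(out))) {
    stop("pair TSV must have columns: ", paste(need, collapse = ", "))
  }
  out
}

#' @rdname read_pairs_tsv
#' @param pairs data.frame of pairs.
#' @export
write_pairs_tsv <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read name-paired records from a SAM text file
#'
#' Thin boundary reader: primary alignments are paired by query name;
#' duplicate-flagged (0x400), secondary (0x100), supplementary (0x800) and
#' unmapped (0x4) records are skipped. Positions are converted to 0-based.
#' Reads whose mate never appears are dropped.
#'
#' @param path SAM file (text).
#' @return data.frame of pairs as in [read_pairs_tsv()].
#' @export
read_pairs_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^@", lines)]
  ends <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) stop("malformed SAM record: ", substr(ln, 1, 60))
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 0x4) > 0 || bitwAnd(flag, 0x100) > 0 ||
        bitwAnd(flag, 0x800) > 0 || bitwAnd(flag, 0x400) > 0) next
    qn <- f[1]
    ends[[qn]] <- rbind(ends[[qn]],
                        data.frame(contig = f[3], pos = as.numeric(f[4]) - 1))
  }
  complete <- names(ends)[vapply(ends, nrow, integer(1)) >= 2]
  if (length(complete) == 0) {
    return(data.frame(pair_id = character(), contig1 = character(),
                      pos1 = numeric(), contig2 = character(),
                      pos2 = numeric()))
  }
  out <- do.call(rbind, lapply(complete, function(qn) {
    e <- ends[[qn]]
    data.frame(pair_id = qn, contig1 = e$contig[1], pos1 = e$pos[1],
               contig2 = e$contig[2], pos2 = e$pos[2])
  }))
  out <- out[order(out$pair_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
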