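# FASTA and AGP v2.1 I/O. Sequences are handled as named character vectors;
# Biostrings does the parsing and reverse complementation.

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (case preserved).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(set))  # drop description after first space
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA record name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- as.character(set)
  empty <- nm[nchar(seqs) == 0]
  if (length(empty)) stop("empty sequence for record(s): ",
                          paste(empty, collapse = ", "))
  stats::setNames(seqs, nm)
}

#' Write sequences to FASTA
#'
#' @param records Named character vector of sequences.
#' @param path Output path.
#' @param line_width Sequence line wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 60) {
  stopifnot(line_width >= 1)
  if (is.null(names(records)) || any(names(records) == "")) {
    stop("all records must be named")
  }
  if (anyDuplicated(names(records))) stop("duplicate record names")
  if (any(nchar(records) == 0)) {
    stop("empty sequence for record(s): ",
         paste(names(records)[nchar(records) == 0], collapse = ", "))
  }
  set <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(set, path, width = line_width)
  invisible(path)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Read an AGP v2.1 file as a genome layout
#'
#' One layout group per AGP object; W rows become oriented contigs in part
#' order (length = component_end - component_start + 1); N/U gap rows are
#' recorded in the `"gaps"` attribute but carry no metric weight.
#' Orientations `?`, `0` and `na` are mapped to `+` with a warning.
#'
#' @param path AGP file (tab separated; `#` comment lines ignored).
#' @return A `genome_layout` with attribute `gaps` (data.frame of gap rows).
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) stop("AGP file has no component rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 8)
  if (length(bad)) stop("AGP row with fewer than 8 fields at line ", bad[1])
  groups <- list()
  gaps <- list()
  last_part <- list()
  flagged <- character(0)
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    obj <- f[1]
    obj_start <- as.numeric(f[2]); obj_end <- as.numeric(f[3])
    part <- as.integer(f[4]); type <- f[5]
    if (anyNA(c(obj_start, obj_end, part))) {
      stop("non-numeric AGP coordinates in object ", obj, " row ", k)
    }
    prev <- last_part[[obj]]
    if (is.null(prev)) {
      if (part != 1L) stop("object ", obj, " does not start at part_number 1")
    } else if (part != prev + 1L) {
      stop("non-monotone part_number in object ", obj, ": part ", part,
           " after ", prev)
    }
    last_part[[obj]] <- part
    span <- obj_end - obj_start + 1
    if (type == "W") {
      comp <- f[6]
      comp_start <- as.numeric(f[7]); comp_end <- as.numeric(f[8])
      ori <- if (length(f) >= 9) f[9] else "?"
      comp_len <- comp_end - comp_start + 1
      if (comp_len != span) {
        stop("span mismatch in object ", obj, " part ", part, ": object span ",
             span, " vs component span ", comp_len)
      }
      if (!ori %in% c("+", "-")) {
        flagged <- c(flagged, comp)
        ori <- "+"
      }
      groups[[obj]] <- rbind(groups[[obj]],
                             data.frame(contig = comp, orientation = ori,
                                        length = comp_len))
    } else if (type %in% c("N", "U")) {
      gap_len <- as.numeric(f[6])
      if (is.na(gap_len) || gap_len != span) {
        stop("gap length mismatch in object ", obj, " part ", part)
      }
      gaps[[length(gaps) + 1]] <- data.frame(
        object = obj, part_number = part, gap_length = gap_len,
        gap_type = if (length(f) >= 7) f[7] else NA_character_,
        linkage = if (length(f) >= 8) f[8] else NA_character_
      )
    } else {
      stop("unsupported AGP component_type '", type, "' in object ", obj)
    }
  }
  if (length(flagged)) {
    warning("AGP orientation '?', '0' or 'na' mapped to '+' for: ",
            paste(flagged, collapse = ", "))
  }
  layout <- genome_layout(groups)
  attr(layout, "gaps") <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(object = character(), part_number = integer(),
               gap_length = numeric(), gap_type = character(),
               linkage = character())
  layout
}

#' Write a genome layout as AGP v2.1
#'
#' Emits one object per group: W rows for the contigs, separated by N gap
#' rows of fixed size. Coordinates are recomputed so every row satisfies the
#' AGP span invariant.
#'
#' @param layout A `genome_layout`.
#' @param path Output path.
#' @param gap_length Gap size in bp between consecutive contigs (default 100).
#' @param gap_type AGP gap type (default `"scaffold"`).
#' @param linkage `"yes"` or `"no"` (default `"yes"`).
#' @param evidence Linkage evidence keyword (default `"proximity_ligation"`).
#' @return `path`, invisibly.
#' @export
write_agp <- function(layout, path, gap_length = 100, gap_type = "scaffold",
                      linkage = "yes", evidence = "proximity_ligation") {
  stopifnot(inherits(layout, "genome_layout"), gap_length >= 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  for (obj in names(layout$groups)) {
    g <- layout$groups[[obj]]
    pos <- 1
    part <- 1L
    for (i in seq_len(nrow(g))) {
      if (i > 1) {
        writeLines(paste(obj, pos, pos + gap_length - 1, part, "N",
                         gap_length, gap_type, linkage, evidence,
                         sep = "\t"), con)
        pos <- pos + gap_length
        part <- part + 1L
      }
      len <- g$length[i]
      writeLines(paste(obj, pos, pos + len - 1, part, "W", g$contig[i],
                       1, len, g$orientation[i], sep = "\t"), con)
      pos <- pos + len
      part <- part + 1L
    }
  }
  invisible(path)
}

#' Build scaffold sequences from a layout and contig sequences
#'
#' Concatenates each group's contig sequences in layout order (reverse
#' complementing `-` contigs), separated by runs of `N`.
#'
#' @param layout A `genome_layout`.
#' @param contigs Named character vector of contig sequences covering every
#'   contig in the layout.
#' @param gap_length Number of `N`s between consecutive contigs (default 100).
#' @return Named character vector of scaffold sequences, one per group.
#' @export
scaffold_sequences <- function(layout, contigs, gap_length = 100) {
  stopifnot(inherits(layout, "genome_layout"))
  missing <- setdiff(layout_contigs(layout)$contig, names(contigs))
  if (length(missing)) {
    stop("missing sequence for contig(s): ", paste(missing, collapse = ", "))
  }
  gap <- strrep("N", gap_length)
  out <- vapply(layout$groups, function(g) {
    parts <- vapply(seq_len(nrow(g)), function(i) {
      s <- contigs[[g$contig[i]]]
      if (g$orientation[i] == "-") revcomp(s) else s
    }, character(1))
    paste(parts, collapse = gap)
  }, character(1))
  stats::setNames(out, names(layout$groups))
}

#' Reconstruct a scaffold layout from a scaffold FASTA
#'
#' Locates every contig sequence (forward, else reverse complement) as an
#' exact substring of the scaffold sequences, case-insensitively, and
#' rebuilds the ordered, oriented layout. This is the path for scaffolders
#' that emit FASTA but no AGP; scaffolders that polish or alter sequence
#' need the alignment-based placement path instead.
#'
#' @param scaffolds Named character vector of scaffold sequences.
#' @param contigs Named character vector of contig sequences.
#' @param min_match Minimum contig length (bp) to attempt matching; shorter
#'   contigs are reported unscaffolded. Default 1.
#' @return A `genome_layout`; attribute `unscaffolded` lists contigs found
#'   in no scaffold.
#' @export
layout_from_scaffold_fasta <- function(scaffolds, contigs, min_match = 1) {
  sc <- toupper(scaffolds)
  hits <- list()
  unscaffolded <- character(0)
  for (cid in names(contigs)) {
    cseq <- toupper(contigs[[cid]])
    if (nchar(cseq) < min_match) {
      unscaffolded <- c(unscaffolded, cid)
      next
    }
    rseq <- toupper(revcomp(cseq))
    loci <- list()
    for (sid in names(sc)) {
      fwd <- gregexpr(cseq, sc[[sid]], fixed = TRUE)[[1]]
      fwd <- fwd[fwd > 0]
      for (p in fwd) {
        loci[[length(loci) + 1]] <- data.frame(
          scaffold = sid, start = p, contig = cid, orientation = "+",
          length = nchar(cseq))
      }
      if (rseq != cseq) {
        rev <- gregexpr(rseq, sc[[sid]], fixed = TRUE)[[1]]
        rev <- rev[rev > 0]
        for (p in rev) {
          loci[[length(loci) + 1]] <- data.frame(
            scaffold = sid, start = p, contig = cid, orientation = "-",
            length = nchar(cseq))
        }
      }
    }
    if (length(loci) == 0) {
      unscaffolded <- c(unscaffolded, cid)
    } else if (length(loci) > 1) {
      locs <- vapply(loci, function(l)
        paste0(l$scaffold, ":", l$start, l$orientation), character(1))
      stop("contig ", cid, " found at multiple loci: ",
           paste(locs, collapse = ", "))
    } else {
      hits[[length(hits) + 1]] <- loci[[1]]
    }
  }
  if (length(hits) == 0) stop("no contig could be located in any scaffold")
  tab <- do.call(rbind, hits)
  groups <- lapply(split(tab, tab$scaffold), function(d) {
    d <- d[order(d$start), c("contig", "orientation", "length")]
    rownames(d) <- NULL
    d
  })
  layout <- genome_layout(groups[order(names(groups))])
  attr(layout, "unscaffolded") <- unscaffolded
  layout
}
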