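#' Construct a genome layout
#'
#' A genome layout is the ordered, oriented contig content of a genome:
#' a named list of groups (chromosomes or scaffolds), each group an ordered
#' run of contigs with an orientation and a length in base pairs. It is the
#' signed-permutation representation that all accuracy metrics operate on;
#' nucleotide sequence is deliberately absent.
#'
#' All groups are treated as linear (no circular chromosomes).
#'
#' @param groups Named list. Each element is a data.frame with columns
#'   `contig` (character), `orientation` (`"+"` or `"-"`) and `length`
#'   (positive integer base pairs), rows in layout order.
#' @return An object of class `genome_layout`.
#' @examples
#' gl <- genome_layout(list(chr1 = data.frame(
#'   contig = c("c1", "c2"), orientation = c("+", "-"),
#'   length = c(1000L, 500L))))
#' total_length(gl)
#' @export
genome_layout <- function(groups) {
  if (!is.list(groups)) stop("`groups` must be a list of data.frames")
  if (length(groups) > 0 && (is.null(names(groups)) || anyNA(names(groups)) ||
                             any(names(groups) == ""))) {
    stop("every group must be named")
  }
  if (anyDuplicated(names(groups))) {
    stop("duplicate group names: ",
         paste(unique(names(groups)[duplicated(names(groups))]), collapse = ", "))
  }
  groups <- lapply(groups, function(g) {
    g <- as.data.frame(g)
    need <- c("contig", "orientation", "length")
    if (!all(need %in% names(g))) {
      stop("each group needs columns: ", paste(need, collapse = ", "))
    }
    g <- g[, need]
    g$contig <- as.character(g$contig)
    g$orientation <- as.character(g$orientation)
    g$length <- as.numeric(g$length)
    if (nrow(g) == 0) stop("groups must be non-empty")
    if (!all(g$orientation %in% c("+", "-"))) {
      stop("orientation must be '+' or '-'")
    }
    if (any(!is.finite(g$length)) || any(g$length < 1)) {
      stop("contig lengths must be >= 1")
    }
    rownames(g) <- NULL
    g
  })
  ids <- unlist(lapply(groups, `[[`, "contig"), use.names = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate contig id(s) in layout: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(list(groups = groups), class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  n <- n_contigs(x)
  cat(sprintf("genome_layout: %d group(s), %d contig(s), %s bp\n",
              length(x$groups), n, format(total_length(x), big.mark = ",")))
  for (nm in utils::head(names(x$groups), 8)) {
    g <- x$groups[[nm]]
    shown <- utils::head(paste0(g$contig, g$orientation), 6)
    if (nrow(g) > 6) shown <- c(shown, "...")
    cat(sprintf("  %s [%d]: %s\n", nm, nrow(g), paste(shown, collapse = " ")))
  }
  if (length(x$groups) > 8) cat("  ...\n")
  invisible(x)
}

#' Contig table of a layout
#'
#' @param layout A `genome_layout`.
#' @return data.frame with columns `group`, `contig`, `orientation`, `length`
#'   in layout order.
#' @export
layout_contigs <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  if (length(layout$groups) == 0) {
    return(data.frame(group = character(), contig = character(),
                      orientation = character(), length = numeric()))
  }
  out <- do.call(rbind, lapply(names(layout$groups), function(nm) {
    cbind(group = nm, layout$groups[[nm]])
  }))
  rownames(out) <- NULL
  out
}

#' Named vector of contig lengths in a layout
#' @param layout A `genome_layout`.
#' @return Named numeric vector, contig id -> length (bp).
#' @export
contig_lengths <- function(layout) {
  tab <- layout_contigs(layout)
  stats::setNames(tab$length, tab$contig)
}

#' Number of contigs in a layout
#' @param layout A `genome_layout`.
#' @return Integer count.
#' @export
n_contigs <- function(layout) {
  sum(vapply(layout$groups, nrow, integer(1)))
}

#' Total length of a layout
#'
#' Sum of contig lengths over all groups; invariant under any rearrangement.
#'
#' @param layout A `genome_layout`.
#' @return Total base pairs.
#' @export
total_length <- function(layout) {
  sum(vapply(layout$groups, function(g) sum(g$length), numeric(1)))
}

# Extremity naming: "<contig>:t" (tail, 5' end of the forward strand) and
# "<contig>:h" (head, 3' end of the forward strand). A forward contig is read
# tail..head, a reverse one head..tail.
extremity <- function(contig, end) paste0(contig, ":", end)

# Left/right extremities of an oriented contig in reading direction.
left_extremity <- function(contig, orientation) {
  extremity(contig, ifelse(orientation == "+", "t", "h"))
}
right_extremity <- function(contig, orientation) {
  extremity(contig, ifelse(orientation == "+", "h", "t"))
}

#' Convert a layout to its DCJ adjacency set
#'
#' Decomposes a layout into the extremity pairings of the
#' double-cut-and-join (DCJ) model: every junction between consecutive
#' contigs becomes an unordered adjacency of two extremities; the two ends of
#' each (linear) group become telomeres.
#'
#' @param layout A `genome_layout`.
#' @return Object of class `adjacency_set`: list with `adjacencies` (two
#'   column character matrix, each row an unordered extremity pair stored
#'   sorted) and `telomeres` (character vector of unpaired extremities).
#'   Extremities are named `"<contig>:t"` / `"<contig>:h"`.
#' @examples
#' gl <- genome_layout(list(s = data.frame(contig = c("c1", "c2"),
#'   orientation = c("+", "-"), length = c(10, 10))))
#' layout_to_adjacencies(gl)
#' @export
layout_to_adjacencies <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  adj <- matrix(character(0), ncol = 2)
  tel <- character(0)
  for (g in layout$groups) {
    n <- nrow(g)
    tel <- c(tel, left_extremity(g$contig[1], g$orientation[1]),
             right_extremity(g$contig[n], g$orientation[n]))
    if (n > 1) {
      a <- right_extremity(g$contig[-n], g$orientation[-n])
      b <- left_extremity(g$contig[-1], g$orientation[-1])
      adj <- rbind(adj, cbind(pmin(a, b), pmax(a, b)))
    }
  }
  structure(list(adjacencies = unname(adj), telomeres = unname(tel)),
            class = "adjacency_set")
}

#' @export
print.adjacency_set <- function(x, ...) {
  cat(sprintf("adjacency_set: %d adjacencies, %d telomeres\n",
              nrow(x$adjacencies), length(x$telomeres)))
  invisible(x)
}

# Canonical string key of an adjacency set (order-independent), used for
# identity checks and by the brute-force test oracle.
adjacency_key <- function(aset) {
  pairs <- if (nrow(aset$adjacencies)) {
    sort(paste(aset$adjacencies[, 1], aset$adjacencies[, 2], sep = "|"))
  } else character(0)
  paste(paste(pairs, collapse = ";"),
        paste(sort(aset$telomeres), collapse = ";"), sep = " // ")
}

#' Restrict a layout to a subset of contigs
#'
#' Contigs outside `keep` are deleted and their former neighbours spliced
#' together (groups are never split); groups left empty are dropped. Relative
#' order and orientations of kept contigs are preserved. Used to reduce two
#' layouts to their shared contig set before scoring, and for the
#' exclude-unscaffolded scoring mode.
#'
#' @param layout A `genome_layout`.
#' @param keep Character vector of contig ids to keep (must all exist).
#' @return A `genome_layout` containing exactly the contigs in `keep`.
#' @export
restrict_layout <- function(layout, keep) {
  stopifnot(inherits(layout, "genome_layout"))
  keep <- unique(as.character(keep))
  have <- layout_contigs(layout)$contig
  unknown <- setdiff(keep, have)
  if (length(unknown)) {
    stop("unknown contig id(s) in `keep`: ", paste(unknown, collapse = ", "))
  }
  groups <- lapply(layout$groups, function(g) g[g$contig %in% keep, , drop = FALSE])
  groups <- groups[vapply(groups, nrow, integer(1)) > 0]
  genome_layout(groups)
}

#' Reverse one group of a layout
#'
#' Reverses contig order and flips every orientation in the named group;
#' the adjacency set is invariant under this operation.
#'
#' @param layout A `genome_layout`.
#' @param group Group name.
#' @return Modified `genome_layout`.
#' @export
reverse_group <- function(layout, group) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!group %in% names(layout$groups)) stop("no such group: ", group)
  g <- layout$groups[[group]]
  g <- g[rev(seq_len(nrow(g))), , drop = FALSE]
  g$orientation <- ifelse(g$orientation == "+", "-", "+")
  rownames(g) <- NULL
  layout$groups[[group]] <- g
  layout
}
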