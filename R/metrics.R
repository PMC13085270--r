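# Accuracy metrics between a proposed scaffold layout and a reference
# (truth) layout. Both layouts must cover the same contig set; score()
# handles the restriction and bookkeeping.

check_shared <- function(assembly, reference) {
  a <- layout_contigs(assembly)$contig
  r <- layout_contigs(reference)$contig
  if (length(intersect(a, r)) == 0) stop("layouts share no contigs")
  if (!setequal(a, r)) {
    stop("layouts cover different contig sets; restrict both to the shared ",
         "set with restrict_layout() (or use score(), which does this)")
  }
  invisible(TRUE)
}

# Map extremity -> its pairing in a layout: partner extremity, or "TEL".
extremity_pairing <- function(aset) {
  out <- c(
    stats::setNames(c(aset$adjacencies[, 2], aset$adjacencies[, 1]),
                    c(aset$adjacencies[, 1], aset$adjacencies[, 2])),
    stats::setNames(rep("TEL", length(aset$telomeres)), aset$telomeres)
  )
  out
}

#' DCJ edit distance between two layouts
#'
#' The minimum number of double-cut-and-join operations transforming the
#' assembly layout into the reference layout over their (identical) contig
#' set, computed with the closed form N - (C + I/2): N contigs, C cycles and
#' I odd-length paths in the adjacency graph whose vertices are the
#' adjacencies and telomeres of the two layouts and whose edges connect, for
#' every contig extremity, the two vertices containing it.
#'
#' @param assembly,reference `genome_layout` objects over the same contig
#'   set (use [restrict_layout()] first if they differ).
#' @return Non-negative number of DCJ operations.
#' @export
dcj_distance <- function(assembly, reference) {
  check_shared(assembly, reference)
  a <- layout_to_adjacencies(assembly)
  b <- layout_to_adjacencies(reference)
  n <- n_contigs(assembly)

  # vertex ids: assembly adjacencies, assembly telomeres, then reference's
  vert_of <- function(aset, offset) {
    v <- character(0); id <- integer(0)
    if (nrow(aset$adjacencies)) {
      k <- nrow(aset$adjacencies)
      v <- c(aset$adjacencies[, 1], aset$adjacencies[, 2])
      id <- c(seq_len(k), seq_len(k))
    }
    if (length(aset$telomeres)) {
      v <- c(v, aset$telomeres)
      id <- c(id, nrow(aset$adjacencies) + seq_along(aset$telomeres))
    }
    stats::setNames(id + offset, v)
  }
  na_vert <- nrow(a$adjacencies) + length(a$telomeres)
  nb_vert <- nrow(b$adjacencies) + length(b$telomeres)
  va <- vert_of(a, 0L)
  vb <- vert_of(b, na_vert)
  nv <- na_vert + nb_vert

  # union-find over vertices; one edge per extremity
  parent <- seq_len(nv)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  exts <- names(va)
  for (e in exts) {
    ra <- find(va[[e]]); rb <- find(vb[[e]])
    if (ra != rb) parent[ra] <- rb
  }
  comp_of_edge <- vapply(exts, function(e) find(va[[e]]), integer(1))
  comp_of_vert <- vapply(seq_len(nv), find, integer(1))
  edges_per_comp <- table(comp_of_edge)
  verts_per_comp <- table(comp_of_vert)
  # components with no edges cannot occur (every vertex holds >= 1 extremity)
  comps <- names(edges_per_comp)
  nedge <- as.integer(edges_per_comp[comps])
  nvert <- as.integer(verts_per_comp[comps])
  cycles <- sum(nedge == nvert)
  odd_paths <- sum(nedge == nvert - 1L & nedge %% 2L == 1L)
  n - (cycles + odd_paths / 2)
}

#' Overall accuracy: length fraction of correctly placed contigs
#'
#' A contig is correctly placed when both of its extremities have the same
#' pairing in assembly and reference: adjacent to the same extremity of the
#' same neighbour, or a telomere in both. The score is the summed length of
#' correctly placed contigs divided by the total evaluated length.
#'
#' @inheritParams dcj_distance
#' @return Value in [0, 1].
#' @export
overall_accuracy <- function(assembly, reference) {
  check_shared(assembly, reference)
  pa <- extremity_pairing(layout_to_adjacencies(assembly))
  pr <- extremity_pairing(layout_to_adjacencies(reference))
  tab <- layout_contigs(reference)
  heads <- extremity(tab$contig, "h")
  tails <- extremity(tab$contig, "t")
  ok <- pa[heads] == pr[heads] & pa[tails] == pr[tails]
  sum(tab$length[ok]) / sum(tab$length)
}

#' Grouping accuracy: length-weighted Jaccard with optimal matching
#'
#' Scaffolds are matched one-to-one to reference chromosomes by
#' maximum-weight bipartite matching, where the weight of a
#' (scaffold, chromosome) pair is the length-weighted Jaccard index
#' J = length of shared contigs / length of contigs in either. The score is
#' the chromosome-length-weighted mean of matched J (unmatched chromosomes
#' contribute 0). One-to-one matching ensures a mega-scaffold spanning many
#' chromosomes is credited against at most one of them.
#'
#' @inheritParams dcj_distance
#' @return Value in [0, 1].
#' @export
grouping_accuracy <- function(assembly, reference) {
  check_shared(assembly, reference)
  lens <- contig_lengths(reference)
  scaf <- lapply(assembly$groups, `[[`, "contig")
  chrom <- lapply(reference$groups, `[[`, "contig")
  ns <- length(scaf); nc <- length(chrom)
  w <- matrix(0, ns, nc)
  for (i in seq_len(ns)) {
    for (j in seq_len(nc)) {
      shared <- sum(lens[intersect(scaf[[i]], chrom[[j]])])
      if (shared > 0) {
        either <- sum(lens[union(scaf[[i]], chrom[[j]])])
        w[i, j] <- shared / either
      }
    }
  }
  match_sc <- max_weight_matching(w)  # scaffold index per chromosome, NA if none
  chrom_len <- vapply(chrom, function(cc) sum(lens[cc]), numeric(1))
  j_matched <- ifelse(is.na(match_sc), 0,
                      w[cbind(match_sc, seq_len(nc))])
  sum(chrom_len * j_matched) / sum(lens)
}

# Maximum-weight one-to-one matching on a non-negative ns x nc weight
# matrix. Returns, for each column (chromosome), the matched row (scaffold)
# index or NA. Hungarian algorithm on the square-padded cost matrix.
max_weight_matching <- function(w) {
  ns <- nrow(w); nc <- ncol(w)
  n <- max(ns, nc)
  cost <- matrix(0, n, n)
  if (ns > 0 && nc > 0) cost[seq_len(ns), seq_len(nc)] <- -w
  assign_row <- hungarian_min(cost)  # row -> col
  out <- rep(NA_integer_, nc)
  for (i in seq_len(ns)) {
    j <- assign_row[i]
    if (j <= nc && w[i, j] > 0) out[j] <- i
  }
  out
}

# Hungarian algorithm (shortest augmenting path with potentials) for the
# square assignment problem; minimises total cost. Returns col index per row.
hungarian_min <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost))
  if (n == 0) return(integer(0))
  u <- numeric(n)
  v <- numeric(n + 1)          # index 1 is the virtual column
  p <- integer(n + 1)          # p[j]: row currently assigned to column j-1
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- logical(n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- which(!used)     # all > 1 once j0 visited
      cur <- cost[i0, free - 1L] - u[i0] - v[free]
      upd <- cur < minv[free]
      minv[free[upd]] <- cur[upd]
      way[free[upd]] <- j0
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      u[p[used]] <- u[p[used]] + delta
      v[used] <- v[used] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- integer(n)
  for (j in seq.int(2L, n + 1L)) ans[p[j]] <- j - 1L
  ans
}

# Adjacent pairs of a layout: data.frame of left/right contig, their
# orientations and the signed junction key, one row per junction.
layout_pairs <- function(layout) {
  rows <- lapply(layout$groups, function(g) {
    n <- nrow(g)
    if (n < 2) return(NULL)
    data.frame(
      x = g$contig[-n], y = g$contig[-1],
      ox = g$orientation[-n], oy = g$orientation[-1],
      lx = g$length[-n], ly = g$length[-1]
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(x = character(), y = character(), ox = character(),
                      oy = character(), lx = numeric(), ly = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

pair_keys <- function(pairs) {
  # unsigned: unordered contig pair; signed: unordered extremity pair
  unsigned <- paste(pmin(pairs$x, pairs$y), pmax(pairs$x, pairs$y), sep = "|")
  a <- right_extremity(pairs$x, pairs$ox)
  b <- left_extremity(pairs$y, pairs$oy)
  signed <- paste(pmin(a, b), pmax(a, b), sep = "|")
  list(unsigned = unsigned, signed = signed)
}

ordering_core <- function(assembly, reference, signed) {
  check_shared(assembly, reference)
  ap <- layout_pairs(assembly)
  if (nrow(ap) == 0) {
    warning("assembly has no adjacent contig pairs; ",
            "ordering/orientation accuracy defined as 0")
    return(0)
  }
  rp <- layout_pairs(reference)
  ak <- pair_keys(ap)
  rk <- pair_keys(rp)
  hit <- if (signed) ak$signed %in% rk$signed else ak$unsigned %in% rk$unsigned
  wts <- (ap$lx + ap$ly) / 2
  sum(wts[hit]) / sum(wts)
}

#' Ordering accuracy: length-weighted correct adjacencies
#'
#' For every pair of adjacent contigs in the assembly, the pair is correct
#' when the two contigs are also adjacent (in either order) in the
#' reference. Pairs are weighted by the arithmetic mean of the two contig
#' lengths. Assemblies with no adjacent pair (all singletons) score 0 with a
#' warning.
#'
#' @inheritParams dcj_distance
#' @return Value in [0, 1].
#' @export
ordering_accuracy <- function(assembly, reference) {
  ordering_core(assembly, reference, signed = FALSE)
}

#' Orientation accuracy: ordering plus relative orientation
#'
#' Like [ordering_accuracy()], but a pair only counts when the junction
#' between the two contigs pairs the same extremities as in the reference,
#' i.e. the contigs are adjacent and correctly oriented relative to each
#' other. Always less than or equal to the ordering accuracy.
#'
#' @inheritParams dcj_distance
#' @return Value in [0, 1].
#' @export
orientation_accuracy <- function(assembly, reference) {
  ordering_core(assembly, reference, signed = TRUE)
}

#' N50 of a set of lengths
#'
#' The size at which contigs of equal or greater length cover half the
#' assembly: sort lengths descending and return the first length at which
#' the cumulative sum reaches half the total.
#'
#' @param lengths Numeric vector of positive lengths (bp).
#' @return N50 in bp.
#' @examples
#' n50(c(100, 200, 300, 400))  # 300
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) stop("empty length vector")
  if (any(lengths <= 0)) stop("lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  unname(s[which(cumsum(s) >= sum(s) / 2)[1]])
}

#' Score an assembly layout against a reference layout
#'
#' Restricts both layouts to their shared contig set, computes the five
#' accuracy metrics plus the N50 of the evaluated contigs, and records which
#' contigs were excluded. With `exclude_unscaffolded = TRUE`, assembly
#' contigs sitting in singleton groups (i.e. emitted but never joined) are
#' additionally dropped before scoring when `drop_singletons` is `TRUE`;
#' this is the mode that discounts unscaffolded haplotig-like contigs.
#'
#' @param assembly,reference `genome_layout` objects sharing at least one
#'   contig.
#' @param exclude_unscaffolded Logical; drop reference contigs the assembly
#'   did not scaffold before scoring (absent contigs are always excluded
#'   since the metrics need a common contig set; this flag additionally
#'   controls singleton handling and bookkeeping).
#' @param drop_singletons Logical; with `exclude_unscaffolded`, also treat
#'   assembly singleton groups as unscaffolded. Default `TRUE`.
#' @return A `metrics_report` (list) with fields `edit_distance`,
#'   `overall_accuracy`, `grouping_accuracy`, `ordering_accuracy`,
#'   `orientation_accuracy`, `n50`, `n_contigs_evaluated`,
#'   `n_contigs_excluded`, `excluded_ids`.
#' @export
score <- function(assembly, reference, exclude_unscaffolded = FALSE,
                  drop_singletons = TRUE) {
  stopifnot(inherits(assembly, "genome_layout"),
            inherits(reference, "genome_layout"))
  a_ids <- layout_contigs(assembly)$contig
  r_ids <- layout_contigs(reference)$contig
  shared <- intersect(a_ids, r_ids)
  if (length(shared) == 0) stop("layouts share no contigs")
  evaluated <- shared
  if (exclude_unscaffolded && drop_singletons) {
    singles <- unlist(lapply(assembly$groups, function(g) {
      if (nrow(g) == 1) g$contig else character(0)
    }), use.names = FALSE)
    keep <- setdiff(evaluated, singles)
    if (length(keep) > 0) evaluated <- keep  # never empty the comparison
  }
  excluded <- sort(setdiff(union(a_ids, r_ids), evaluated))
  a <- restrict_layout(assembly, evaluated)
  r <- restrict_layout(reference, evaluated)
  rep <- list(
    edit_distance = dcj_distance(a, r),
    overall_accuracy = overall_accuracy(a, r),
    grouping_accuracy = grouping_accuracy(a, r),
    ordering_accuracy = suppressWarnings(ordering_accuracy(a, r)),
    orientation_accuracy = suppressWarnings(orientation_accuracy(a, r)),
    n50 = n50(layout_contigs(a)$length),
    n_contigs_evaluated = length(evaluated),
    n_contigs_excluded = length(excluded),
    excluded_ids = excluded
  )
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics_report\n")
  cat(sprintf("  edit_distance        %g\n", x$edit_distance))
  for (f in c("overall_accuracy", "grouping_accuracy", "ordering_accuracy",
              "orientation_accuracy")) {
    cat(sprintf("  %-20s %.4f\n", f, x[[f]]))
  }
  cat(sprintf("  n50                  %g\n", x$n50))
  cat(sprintf("  contigs evaluated    %d (excluded %d)\n",
              x$n_contigs_evaluated, x$n_contigs_excluded))
  invisible(x)
}

#' No-scaffolding baseline report
#'
#' Scores the degenerate assembly in which every contig is its own singleton
#' group — the baseline a scaffolder must beat to have added information.
#'
#' @param contigs data.frame with columns `contig` and `length` (or a named
#'   numeric vector of lengths); must be a subset of the reference contigs.
#' @param reference A `genome_layout`.
#' @return A `metrics_report`.
#' @export
baseline_report <- function(contigs, reference) {
  if (is.numeric(contigs) && !is.null(names(contigs))) {
    contigs <- data.frame(contig = names(contigs), length = unname(contigs))
  }
  stopifnot(is.data.frame(contigs), all(c("contig", "length") %in% names(contigs)))
  missing <- setdiff(contigs$contig, layout_contigs(reference)$contig)
  if (length(missing)) {
    stop("contigs not in reference: ", paste(missing, collapse = ", "))
  }
  groups <- lapply(seq_len(nrow(contigs)), function(i) {
    data.frame(contig = contigs$contig[i], orientation = "+",
               length = contigs$length[i])
  })
  names(groups) <- contigs$contig
  score(genome_layout(groups), reference)
}

#' Write metrics reports as TSV
#'
#' One row per report; `excluded_ids` are joined with commas. Extra label
#' columns (e.g. condition, method) can be supplied.
#'
#' @param reports A `metrics_report` or list of them.
#' @param path Output file path.
#' @param labels Optional data.frame of label columns, one row per report.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(reports, path, labels = NULL) {
  if (inherits(reports, "metrics_report")) reports <- list(reports)
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(
      edit_distance = r$edit_distance,
      overall_accuracy = r$overall_accuracy,
      grouping_accuracy = r$grouping_accuracy,
      ordering_accuracy = r$ordering_accuracy,
      orientation_accuracy = r$orientation_accuracy,
      n50 = r$n50,
      n_contigs_evaluated = r$n_contigs_evaluated,
      n_contigs_excluded = r$n_contigs_excluded,
      excluded_ids = paste(r$excluded_ids, collapse = ",")
    )
  }))
  if (!is.null(labels)) tab <- cbind(as.data.frame(labels), tab)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write metrics reports as JSON
#'
#' @inheritParams write_report_tsv
#' @return `path`, invisibly.
#' @export
write_report_json <- function(reports, path, labels = NULL) {
  if (inherits(reports, "metrics_report")) reports <- list(reports)
  objs <- lapply(seq_along(reports), function(i) {
    r <- unclass(reports[[i]])
    if (!is.null(labels)) r <- c(as.list(as.data.frame(labels)[i, , drop = FALSE]), r)
    r
  })
  jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a metrics report TSV back as a data.frame
#' @param path TSV written by [write_report_tsv()].
#' @return data.frame.
#' @export
read_report_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = NA, check.names = FALSE)
}
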