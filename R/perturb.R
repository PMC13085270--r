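# Seeded perturbation of a truth layout by known rearrangement operations.
# Every kind is a single DCJ operation, so k operations from truth give a
# layout at DCJ distance <= k. Kinds map onto the error classes the metrics
# measure: fission/fusion/reciprocal translocation create grouping errors,
# inversions create ordering errors (and, with single-contig flips,
# orientation errors).

op_kinds <- c("inversion", "translocation", "fission", "fusion",
              "orientation_flip")

apply_one <- function(layout, op, idx) {
  groups <- layout$groups
  gname <- function(i) {
    if (i < 1 || i > length(groups)) {
      stop("operation ", idx, " (", op$kind, "): group index ", i,
           " out of range")
    }
    names(groups)[i]
  }
  chk <- function(cond, what) {
    if (!cond) stop("operation ", idx, " (", op$kind, "): ", what)
  }
  flip <- function(d) {
    d <- d[rev(seq_len(nrow(d))), , drop = FALSE]
    d$orientation <- ifelse(d$orientation == "+", "-", "+")
    d
  }
  switch(op$kind,
    inversion = {
      g <- groups[[gname(op$group)]]
      chk(op$start >= 1 && op$end <= nrow(g) && op$start <= op$end,
          "block out of range")
      block <- flip(g[op$start:op$end, , drop = FALSE])
      g <- rbind(
        if (op$start > 1) g[1:(op$start - 1), , drop = FALSE],
        block,
        if (op$end < nrow(g)) g[(op$end + 1):nrow(g), , drop = FALSE])
      groups[[gname(op$group)]] <- g
    },
    orientation_flip = {
      g <- groups[[gname(op$group)]]
      chk(op$pos >= 1 && op$pos <= nrow(g), "position out of range")
      g$orientation[op$pos] <- if (g$orientation[op$pos] == "+") "-" else "+"
      groups[[gname(op$group)]] <- g
    },
    fission = {
      g <- groups[[gname(op$group)]]
      chk(op$after >= 1 && op$after < nrow(g),
          "split point must be strictly inside the group")
      new_name <- paste0(gname(op$group), "_fis", idx)
      chk(!new_name %in% names(groups), "generated group name collides")
      groups[[new_name]] <- g[(op$after + 1):nrow(g), , drop = FALSE]
      groups[[gname(op$group)]] <- g[1:op$after, , drop = FALSE]
    },
    fusion = {
      chk(op$group1 != op$group2, "cannot fuse a group with itself")
      n1 <- gname(op$group1); n2 <- gname(op$group2)
      g2 <- groups[[n2]]
      if (isTRUE(op$invert2)) g2 <- flip(g2)
      groups[[n1]] <- rbind(groups[[n1]], g2)
      groups[[n2]] <- NULL
    },
    translocation = {
      # reciprocal translocation: cut each group once, rejoin crosswise.
      # one DCJ operation; a block move (excision + reinsertion) would be two.
      chk(op$group1 != op$group2, "translocation needs two distinct groups")
      n1g <- gname(op$group1); n2g <- gname(op$group2)
      g1 <- groups[[n1g]]; g2 <- groups[[n2g]]
      chk(op$cut1 >= 0 && op$cut1 <= nrow(g1), "cut1 out of range")
      chk(op$cut2 >= 0 && op$cut2 <= nrow(g2), "cut2 out of range")
      take <- function(g, i, j) {
        if (j < i) g[0, , drop = FALSE] else g[i:j, , drop = FALSE]
      }
      a1 <- take(g1, 1, op$cut1); a2 <- take(g1, op$cut1 + 1, nrow(g1))
      b1 <- take(g2, 1, op$cut2); b2 <- take(g2, op$cut2 + 1, nrow(g2))
      if (identical(op$mode, "crossed")) {
        new1 <- rbind(a1, flip(b1))
        new2 <- rbind(flip(a2), b2)
      } else {
        new1 <- rbind(a1, b2)
        new2 <- rbind(b1, a2)
      }
      groups[[n1g]] <- if (nrow(new1) > 0) new1 else NULL
      groups[[n2g]] <- if (nrow(new2) > 0) new2 else NULL
    },
    stop("operation ", idx, ": unknown kind '", op$kind, "'")
  )
  genome_layout(groups)
}

#' Apply a perturbation trace to a layout
#'
#' Replays the recorded operations in order. The contig set and total length
#' are conserved by every operation.
#'
#' @param layout A `genome_layout`.
#' @param trace A `perturbation_trace` from [random_trace()] or
#'   [read_trace_json()].
#' @return The perturbed `genome_layout`.
#' @export
apply_operations <- function(layout, trace) {
  stopifnot(inherits(layout, "genome_layout"))
  ops <- trace$operations
  for (i in seq_along(ops)) {
    layout <- apply_one(layout, ops[[i]], i)
  }
  layout
}

# Geometric block length with mean 2 contigs, capped to the available run.
draw_block <- function(n) {
  len <- min(1 + stats::rgeom(1, 0.5), n)
  start <- sample.int(n - len + 1, 1)
  c(start, start + len - 1)
}

#' Draw a random perturbation trace
#'
#' Draws `k` operations with the given kind mix, parameters uniform over the
#' valid choices at each step (the layout evolves as operations are drawn).
#' Kinds impossible for the current layout get weight zero for that step,
#' with a warning; deterministic for a fixed seed.
#'
#' @param layout Truth `genome_layout` to perturb.
#' @param k Number of operations (>= 0).
#' @param kind_weights Named non-negative weights over
#'   `inversion`, `translocation`, `fission`, `fusion`, `orientation_flip`
#'   (default uniform).
#' @param seed Integer seed.
#' @return A `perturbation_trace`: list with `seed`, `k` and `operations`.
#' @export
random_trace <- function(layout, k,
                         kind_weights = stats::setNames(rep(1, 5), op_kinds),
                         seed = 1) {
  stopifnot(inherits(layout, "genome_layout"), k >= 0)
  w0 <- rep(0, length(op_kinds))
  names(w0) <- op_kinds
  w0[names(kind_weights)] <- kind_weights
  if (any(w0 < 0) || sum(w0) == 0) stop("weights must be non-negative, not all zero")
  set.seed(seed)
  ops <- list()
  cur <- layout
  warned <- character(0)
  for (i in seq_len(k)) {
    sizes <- vapply(cur$groups, nrow, integer(1))
    w <- w0
    if (length(sizes) < 2) w[c("fusion", "translocation")] <- 0
    if (all(sizes < 2)) w["fission"] <- 0
    if (sum(w) == 0) stop("no operation kind applicable to the layout")
    dropped <- names(w0)[w0 > 0 & w == 0]
    new_drop <- setdiff(dropped, warned)
    if (length(new_drop)) {
      warning("kind(s) not applicable, weight zeroed: ",
              paste(new_drop, collapse = ", "))
      warned <- c(warned, new_drop)
    }
    kind <- sample(op_kinds, 1, prob = w)
    op <- switch(kind,
      inversion = {
        gi <- sample.int(length(sizes), 1)
        b <- draw_block(sizes[gi])
        list(kind = "inversion", group = gi, start = b[1], end = b[2])
      },
      orientation_flip = {
        gi <- sample.int(length(sizes), 1)
        list(kind = "orientation_flip", group = gi,
             pos = sample.int(sizes[gi], 1))
      },
      fission = {
        eligible <- which(sizes >= 2)
        gi <- eligible[sample.int(length(eligible), 1)]
        list(kind = "fission", group = gi,
             after = sample.int(sizes[gi] - 1, 1))
      },
      fusion = {
        gs <- sample.int(length(sizes), 2)
        list(kind = "fusion", group1 = gs[1], group2 = gs[2],
             invert2 = stats::runif(1) < 0.5)
      },
      translocation = {
        gs <- sample.int(length(sizes), 2)
        # interior cuts preferred so the exchange is non-degenerate
        cut_at <- function(n) {
          if (n >= 2) sample.int(n - 1, 1) else sample.int(n + 1, 1) - 1
        }
        list(kind = "translocation", group1 = gs[1], group2 = gs[2],
             cut1 = cut_at(sizes[gs[1]]), cut2 = cut_at(sizes[gs[2]]),
             mode = sample(c("straight", "crossed"), 1))
      })
    ops[[i]] <- op
    cur <- apply_one(cur, op, i)
  }
  structure(list(seed = seed, k = k, operations = ops),
            class = "perturbation_trace")
}

#' @export
print.perturbation_trace <- function(x, ...) {
  kinds <- vapply(x$operations, `[[`, character(1), "kind")
  cat(sprintf("perturbation_trace: k = %d (seed %d)\n", x$k, x$seed))
  if (length(kinds)) print(table(kinds))
  invisible(x)
}

#' Collapse a layout into one mega-scaffold
#'
#' Concatenates all groups, in group order, into a single group — the
#' over-scaffolding failure mode in which a scaffolder outputs one scaffold
#' containing every contig.
#'
#' @param layout A `genome_layout`.
#' @param name Name of the resulting group (default `"megascaffold"`).
#' @return A single-group `genome_layout`.
#' @export
make_megascaffold <- function(layout, name = "megascaffold") {
  stopifnot(inherits(layout, "genome_layout"), length(layout$groups) >= 1)
  if (length(layout$groups) == 1) return(layout)
  g <- do.call(rbind, unname(layout$groups))
  rownames(g) <- NULL
  genome_layout(stats::setNames(list(g), name))
}

#' Serialize / read a perturbation trace as JSON
#' @param trace A `perturbation_trace`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_trace_json` returns the trace.
#' @export
write_trace_json <- function(trace, path) {
  jsonlite::write_json(unclass(trace), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_trace_json
#' @export
read_trace_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  x$seed <- as.integer(x$seed)
  x$k <- as.integer(x$k)
  x$operations <- lapply(x$operations, function(op) {
    for (f in setdiff(names(op), c("kind", "invert2", "mode"))) {
      op[[f]] <- as.integer(op[[f]])
    }
    if (!is.null(op$invert2)) op$invert2 <- isTRUE(op$invert2)
    op
  })
  structure(x, class = "perturbation_trace")
}
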