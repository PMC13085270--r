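# Independent brute-force oracle for the DCJ distance: breadth-first search
# over all DCJ moves on extremity matchings. Deliberately shares no code
# with the package's closed-form implementation.
#
# State: integer vector `part` over extremities 1..2n (contig i has tail
# 2i-1, head 2i); part[e] = partner extremity, or 0 for a telomere.

part_key <- function(p) paste(p, collapse = ",")

# Package-independent conversion of a layout group list to a part vector.
layout_to_part <- function(layout, ids) {
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  p <- integer(2 * n)
  ext <- function(contig, side) {
    i <- idx[[contig]]
    if (side == "t") 2L * i - 1L else 2L * i
  }
  for (g in layout$groups) {
    m <- nrow(g)
    if (m < 2) next
    for (r in seq_len(m - 1)) {
      a <- ext(g$contig[r], if (g$orientation[r] == "+") "h" else "t")
      b <- ext(g$contig[r + 1], if (g$orientation[r + 1] == "+") "t" else "h")
      p[a] <- b
      p[b] <- a
    }
  }
  p
}

dcj_neighbors <- function(p) {
  n2 <- length(p)
  half <- which(p > seq_len(n2))            # one endpoint per adjacency
  tel <- which(p == 0L)
  out <- list()
  add <- function(q) out[[length(out) + 1L]] <<- q
  na <- length(half)
  if (na >= 2) {
    for (i in seq_len(na - 1)) {
      for (j in seq.int(i + 1, na)) {
        e1 <- half[i]; f1 <- p[e1]; e2 <- half[j]; f2 <- p[e2]
        q <- p; q[e1] <- e2; q[e2] <- e1; q[f1] <- f2; q[f2] <- f1; add(q)
        q <- p; q[e1] <- f2; q[f2] <- e1; q[f1] <- e2; q[e2] <- f1; add(q)
      }
    }
  }
  if (na >= 1 && length(tel) >= 1) {
    for (e in half) {
      f <- p[e]
      for (t in tel) {
        q <- p; q[e] <- t; q[t] <- e; q[f] <- 0L; add(q)
        q <- p; q[f] <- t; q[t] <- f; q[e] <- 0L; add(q)
      }
    }
  }
  for (e in half) {                          # cut an adjacency
    q <- p; q[p[e]] <- 0L; q[e] <- 0L; add(q)
  }
  nt <- length(tel)
  if (nt >= 2) {                             # join two telomeres
    for (i in seq_len(nt - 1)) {
      for (j in seq.int(i + 1, nt)) {
        q <- p; q[tel[i]] <- tel[j]; q[tel[j]] <- tel[i]; add(q)
      }
    }
  }
  out
}

# BFS from one state; returns an environment mapping part_key -> distance
# over the whole reachable space (all matchings on 2n extremities).
bfs_dcj_distances <- function(src) {
  dist <- new.env(hash = TRUE, parent = emptyenv())
  assign(part_key(src), 0L, envir = dist)
  frontier <- list(src)
  d <- 0L
  while (length(frontier) > 0) {
    nxt <- list()
    for (p in frontier) {
      for (q in dcj_neighbors(p)) {
        k <- part_key(q)
        if (is.null(get0(k, envir = dist, inherits = FALSE))) {
          assign(k, d + 1L, envir = dist)
          nxt[[length(nxt) + 1L]] <- q
        }
      }
    }
    d <- d + 1L
    frontier <- nxt
  }
  dist
}

oracle_dcj <- function(layout_a, layout_b, ids) {
  dist <- bfs_dcj_distances(layout_to_part(layout_a, ids))
  get0(part_key(layout_to_part(layout_b, ids)), envir = dist, inherits = FALSE)
}
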