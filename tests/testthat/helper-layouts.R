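# Fixture builders shared across tests.

# Canonical keys for comparing adjacency sets (test-side copies).
adjacency_key_of <- function(adj) {
  if (nrow(adj) == 0) return("")
  paste(sort(paste(adj[, 1], adj[, 2], sep = "|")), collapse = ";")
}
adjacency_key <- function(aset) {
  paste(adjacency_key_of(aset$adjacencies),
        paste(sort(aset$telomeres), collapse = ","), sep = " // ")
}

# Quick layout from a list of signed contig vectors, e.g.
# lay(list(c("c1+", "c2-"), "c3+"), len = 100)
lay <- function(groups, len = 100, names = NULL) {
  lens <- len
  gs <- lapply(groups, function(g) {
    contig <- sub("[+-]$", "", g)
    ori <- sub("^.*([+-])$", "\\1", g)
    L <- if (length(lens) == 1) rep(lens, length(contig)) else lens[contig]
    data.frame(contig = contig, orientation = ori, length = unname(L))
  })
  if (is.null(names)) names <- paste0("g", seq_along(gs))
  genome_layout(stats::setNames(gs, names))
}

# Random signed layout over contigs c1..cn split into random groups.
random_layout <- function(n, lengths = NULL, equal_lengths = FALSE) {
  ids <- paste0("c", seq_len(n))
  if (is.null(lengths)) {
    lengths <- if (equal_lengths) rep(100, n) else sample(50:500, n, replace = TRUE)
  }
  if (!is.null(names(lengths))) lengths <- unname(lengths[ids])
  ord <- sample(n)
  signs <- sample(c("+", "-"), n, replace = TRUE)
  nb <- if (n > 1) sample.int(n, 1) - 1 else 0
  breaks <- if (nb > 0) sort(sample.int(n - 1, min(nb, n - 1))) else integer(0)
  bounds <- c(0, breaks, n)
  gs <- lapply(seq_len(length(bounds) - 1), function(k) {
    i <- (bounds[k] + 1):bounds[k + 1]
    data.frame(contig = ids[ord[i]], orientation = signs[ord[i]],
               length = lengths[ord[i]])
  })
  genome_layout(stats::setNames(gs, paste0("g", seq_along(gs))))
}

# All layouts over contigs c1..cn: permutation x signs x group breaks.
enumerate_layouts <- function(n, len = 100) {
  ids <- paste0("c", seq_len(n))
  perms <- if (n == 1) list(1L) else {
    res <- list()
    rec <- function(acc, rest) {
      if (length(rest) == 0) {
        res[[length(res) + 1L]] <<- acc
      } else {
        for (i in seq_along(rest)) rec(c(acc, rest[i]), rest[-i])
      }
    }
    rec(integer(0), seq_len(n))
    res
  }
  signsets <- as.matrix(expand.grid(rep(list(c("+", "-")), n)))
  out <- list()
  for (perm in perms) {
    for (s in seq_len(nrow(signsets))) {
      nbreaks <- if (n > 1) 0:(n - 1) else 0
      for (bpat in if (n > 1) seq_len(2^(n - 1)) else 1) {
        breaks <- which(bitwAnd(bpat - 1, 2^(0:(max(n - 2, 0)))) > 0)
        bounds <- unique(c(0, breaks[breaks < n], n))
        gs <- lapply(seq_len(length(bounds) - 1), function(k) {
          i <- (bounds[k] + 1):bounds[k + 1]
          data.frame(contig = ids[perm[i]],
                     orientation = unname(signsets[s, perm[i]]),
                     length = len)
        })
        out[[length(out) + 1L]] <-
          genome_layout(stats::setNames(gs, paste0("g", seq_along(gs))))
      }
    }
  }
  out
}
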