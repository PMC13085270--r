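write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("read_coords parses rows and converts coordinates", {
  f <- write_lines_tmp(c(
    "/ref.fa /qry.fa",
    "NUCMER",
    "",
    "    [S1]     [E1]  |     [S2]     [E2]  |  [LEN 1]  [LEN 2]  |  [% IDY]  | [TAGS]",
    "=====================================================================================",
    "       1     1000  |        1     1000  |     1000     1000  |   100.00  | chr1\tc1",
    "     501     1500  |     1000        1  |     1000     1000  |    98.50  | chr2\tc2"))
  recs <- read_coords(f)
  expect_equal(nrow(recs), 2)
  # 1-based inclusive -> 0-based half-open
  expect_equal(recs$ref_start[1], 0)
  expect_equal(recs$ref_end[1], 1000)
  expect_equal(recs$contig_start[1], 0)
  expect_equal(recs$strand[1], "+")
  expect_equal(recs$aligned_bases[1], 1000)
  expect_equal(recs$identity[1], 100)
  # descending query coordinates -> minus strand, ascending coordinates
  expect_equal(recs$strand[2], "-")
  expect_equal(recs$contig_start[2], 0)
  expect_equal(recs$contig_end[2], 1000)
  expect_equal(recs$ref_start[2], 500)
})

test_that("read_coords rejects malformed rows and accepts empty files", {
  f <- write_lines_tmp("1 1000 | 1 abc | 1000 1000 | 100.00 | chr1 c1")
  expect_error(read_coords(f), "line 1")
  f2 <- write_lines_tmp("1 1000 chr1")
  expect_error(read_coords(f2), "malformed")
  f3 <- write_lines_tmp(character(0))
  expect_equal(nrow(read_coords(f3)), 0)
})

test_that("read_paf keeps native coordinates and derives identity", {
  f <- write_lines_tmp(c(
    paste("c1", 1000, 0, 1000, "+", "chr1", 5000, 100, 1100, 900, 1000, 60,
          sep = "\t"),
    paste("c2", 800, 0, 800, "-", "chr2", 5000, 0, 800, 800, 800, 60,
          sep = "\t"),
    paste("c2", 800, 0, 400, "+", "chr3", 5000, 0, 400, 400, 400, 60,
          sep = "\t")))
  recs <- read_paf(f)
  expect_equal(recs$identity[1], 90)
  expect_equal(recs$ref_start[1], 100)
  expect_equal(recs$strand[2], "-")
  # multiple chromosomes for one contig: both retained
  expect_equal(sum(recs$contig_name == "c2"), 2)
  bad <- write_lines_tmp("c1\t100\t0\t100")
  expect_error(read_paf(bad), "line 1")
})

paf_line <- function(contig, clen, cs, ce, strand, chrom, rs, re,
                     matches = ce - cs) {
  paste(contig, clen, cs, ce, strand, chrom, 1e6, rs, re, matches, ce - cs,
        60, sep = "\t")
}

test_that("place_contigs applies the scoring, threshold and chimera rules", {
  f <- write_lines_tmp(c(
    paf_line("c1", 1000, 0, 1000, "+", "chr2", 100, 1100),
    # c2: 6 kb on chrA, 4 kb on chrB -> chrA, chimeric
    paf_line("c2", 10000, 0, 6000, "+", "chrA", 0, 6000),
    paf_line("c2", 10000, 6000, 10000, "+", "chrB", 0, 4000),
    # c3: only 30% aligned
    paf_line("c3", 1000, 0, 300, "+", "chr2", 5000, 5300)))
  recs <- read_paf(f)
  pl <- place_contigs(recs, c(c1 = 1000, c2 = 10000, c3 = 1000),
                      min_aligned_fraction = 0.5)
  p1 <- pl[pl$contig_id == "c1", ]
  expect_equal(p1$chromosome, "chr2")
  expect_equal(p1$orientation, "+")
  expect_equal(p1$aligned_fraction, 1)
  expect_false(p1$chimeric)
  p2 <- pl[pl$contig_id == "c2", ]
  expect_equal(p2$chromosome, "chrA")
  expect_true(p2$chimeric)
  p3 <- pl[pl$contig_id == "c3", ]
  expect_true(is.na(p3$chromosome))
  expect_equal(p3$aligned_fraction, 0.3)
  expect_error(place_contigs(recs, c(c1 = 1000)), "c2")
})

test_that("overlapping split hits are union-merged, not double counted", {
  f <- write_lines_tmp(c(
    paf_line("c1", 1000, 0, 600, "+", "chrA", 0, 600),
    paf_line("c1", 1000, 300, 900, "+", "chrA", 300, 900)))
  pl <- place_contigs(read_paf(f), c(c1 = 1000))
  expect_equal(pl$aligned_fraction, 0.9)  # union [0,900), not 1.2 capped
})

test_that("place_contigs is record-order invariant and threshold-monotone", {
  set.seed(31)
  lines <- unlist(lapply(1:12, function(i) {
    n <- sample(1:3, 1)
    vapply(seq_len(n), function(j) {
      s <- sample(0:500, 1)
      e <- s + sample(100:400, 1)
      paf_line(paste0("c", i), 1000, s, min(e, 1000),
               sample(c("+", "-"), 1), sample(c("chrA", "chrB"), 1),
               10000 + s, 10000 + min(e, 1000))
    }, character(1))
  }))
  f <- write_lines_tmp(lines)
  recs <- read_paf(f)
  lens <- stats::setNames(rep(1000, 12), paste0("c", 1:12))
  base <- place_contigs(recs, lens)
  shuf <- place_contigs(recs[sample(nrow(recs)), ], lens)
  expect_equal(shuf, base)
  n_placed <- function(th) {
    sum(!is.na(place_contigs(recs, lens, min_aligned_fraction = th)$chromosome))
  }
  placed <- vapply(c(0.9, 0.5, 0.2, 0), n_placed, numeric(1))
  expect_true(all(diff(placed) >= 0))
})

test_that("build_reference_layout sorts by position with stated tie-breaks", {
  pl <- data.frame(
    contig_id = c("c2", "c1", "cb", "ca", "u1"),
    chromosome = c("chr1", "chr1", "chr2", "chr2", NA),
    position = c(5e5, 1e5, 7, 7, NA),
    orientation = c("+", "-", "+", "+", NA),
    aligned_fraction = c(1, 1, 1, 1, 0.1),
    chimeric = FALSE)
  lens <- c(c1 = 10, c2 = 10, ca = 10, cb = 10, u1 = 10)
  gl <- build_reference_layout(pl, lens)
  expect_equal(names(gl$groups), c("chr1", "chr2"))
  expect_equal(gl$groups$chr1$contig, c("c1", "c2"))
  expect_equal(gl$groups$chr1$orientation, c("-", "+"))
  expect_equal(gl$groups$chr2$contig, c("ca", "cb"))  # position tie -> id order
  expect_equal(attr(gl, "unplaced"), "u1")
  pl0 <- pl[5, , drop = FALSE]
  expect_error(build_reference_layout(pl0, lens), "no contigs could be placed")
})

test_that("split + trivial self-alignment round trip reproduces the truth", {
  # fragment a synthetic genome, construct the exact alignment of each piece
  # to its source interval, and re-derive the layout through placement
  for (seed in c(101, 202)) {
    g <- make_synthetic_genome(3, c(20e3, 40e3), seed = seed)
    sp <- split_reference(g$genome, 5e3)
    truth <- sp$truth
    offsets <- lapply(truth$groups, function(d) cumsum(c(0, d$length))[-(nrow(d) + 1)])
    lines <- unlist(lapply(names(truth$groups), function(chrom) {
      d <- truth$groups[[chrom]]
      vapply(seq_len(nrow(d)), function(i) {
        paf_line(d$contig[i], d$length[i], 0, d$length[i], "+",
                 chrom, offsets[[chrom]][i], offsets[[chrom]][i] + d$length[i])
      }, character(1))
    }))
    recs <- read_paf(write_lines_tmp(lines))
    pl <- place_contigs(recs, contig_lengths(truth))
    rebuilt <- build_reference_layout(pl, contig_lengths(truth))
    expect_equal(lapply(rebuilt$groups, function(g) g[c("contig", "orientation")]),
                 lapply(truth$groups, function(g) g[c("contig", "orientation")]))
  }
})
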