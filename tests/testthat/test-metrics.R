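test_that("dcj_distance handles the canonical small cases", {
  gl <- lay(list(c("c1+", "c2+", "c3+")))
  expect_equal(dcj_distance(gl, gl), 0)
  # one inversion
  expect_equal(dcj_distance(lay(list(c("c1+", "c2-", "c3+"))), gl), 1)
  # one fusion
  expect_equal(dcj_distance(lay(list(c("c1+", "c2+"), "c3+")), gl), 1)
  # distance 0 iff identical adjacency sets: reversed group
  rev3 <- lay(list(c("c3-", "c2-", "c1-")))
  expect_equal(dcj_distance(rev3, gl), 0)
})

test_that("dcj_distance requires a common contig set", {
  a <- lay(list(c("c1+", "c2+")))
  b <- lay(list(c("c1+", "c2+", "c3+")))
  expect_error(dcj_distance(a, b), "restrict_layout")
  expect_error(dcj_distance(a, lay(list("x1+"))), "share no contigs")
})

test_that("dcj_distance is a metric (sampled)", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    a <- random_layout(n, equal_lengths = TRUE)
    b <- random_layout(n, equal_lengths = TRUE)
    cc <- random_layout(n, equal_lengths = TRUE)
    dab <- dcj_distance(a, b)
    expect_equal(dab, dcj_distance(b, a))
    expect_true(dcj_distance(a, cc) <= dab + dcj_distance(b, cc))
    expect_equal(dab == 0,
                 adjacency_key(layout_to_adjacencies(a)) ==
                   adjacency_key(layout_to_adjacencies(b)))
  }
})

test_that("overall_accuracy follows the extremity-pairing rule", {
  ref4 <- lay(list(c("c1+", "c2+", "c3+", "c4+")))
  expect_equal(overall_accuracy(ref4, ref4), 1.0)
  # middle two swapped: every contig has at least one wrong pairing
  expect_equal(overall_accuracy(lay(list(c("c1+", "c3+", "c2+", "c4+"))), ref4), 0.0)
  # chain of 10 with last contig detached: c9 and c10 wrong, 8/10 correct
  ref10 <- lay(list(paste0("c", 1:10, "+")))
  asm10 <- lay(list(paste0("c", 1:9, "+"), "c10+"))
  expect_equal(overall_accuracy(asm10, ref10), 0.8)
})

test_that("grouping_accuracy implements length-weighted Jaccard with 1:1 matching", {
  ref <- lay(list(c("c1+", "c2+", "c3+"), c("c4+", "c5+", "c6+")), len = 100)
  # perfect grouping regardless of internal order
  shuffled <- lay(list(c("c2-", "c1+", "c3+"), c("c6+", "c4-", "c5+")), len = 100)
  expect_equal(grouping_accuracy(shuffled, ref), 1.0)
  # mega-scaffold: J = 300/600 = 0.5 for one chromosome, other unmatched
  expect_equal(grouping_accuracy(make_megascaffold(ref), ref), 0.25)
  # one chromosome split into two equal scaffolds: matched half J = 0.5
  ref1 <- lay(list(c("c1+", "c2+", "c3+", "c4+")), len = 100)
  halves <- lay(list(c("c1+", "c2+"), c("c3+", "c4+")), len = 100)
  expect_equal(grouping_accuracy(halves, ref1), 0.5)
})

test_that("hungarian matching equals brute-force optimum on small matrices", {
  brute <- function(w) {
    n <- nrow(w); m <- ncol(w)
    perms <- function(v) {
      if (length(v) <= 1) return(list(v))
      out <- list()
      for (i in seq_along(v)) {
        for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
      }
      out
    }
    best <- 0
    cols <- seq_len(m)
    for (p in perms(cols)) {
      val <- sum(w[cbind(seq_len(min(n, m)), p[seq_len(min(n, m))])])
      best <- max(best, val)
    }
    best
  }
  set.seed(22)
  for (i in 1:20) {
    n <- sample(2:5, 1)
    w <- matrix(runif(n * n), n, n)
    m <- scaffeval:::max_weight_matching(w)
    got <- sum(w[cbind(m[!is.na(m)], which(!is.na(m)))])
    expect_equal(got, brute(w), tolerance = 1e-12)
  }
})

test_that("ordering and orientation accuracy follow the pair rules", {
  ref <- lay(list(c("c1+", "c2+", "c3+", "c4+")))
  expect_equal(ordering_accuracy(ref, ref), 1.0)
  # full reversal with flips: adjacency is unordered
  rev <- lay(list(c("c4-", "c3-", "c2-", "c1-")))
  expect_equal(ordering_accuracy(rev, ref), 1.0)
  expect_equal(orientation_accuracy(rev, ref), 1.0)
  # [c1,c3,c2,c4]: only the c3-c2 pair is adjacent in the reference
  expect_equal(ordering_accuracy(lay(list(c("c1+", "c3+", "c2+", "c4+"))), ref),
               1 / 3)
  # single internal flip: ordering perfect, orientation zero
  ref3 <- lay(list(c("c1+", "c2+", "c3+")))
  flip <- lay(list(c("c1+", "c2-", "c3+")))
  expect_equal(ordering_accuracy(flip, ref3), 1.0)
  expect_equal(orientation_accuracy(flip, ref3), 0.0)
  # all-singleton assembly: 0 with a warning
  singletons <- lay(list("c1+", "c2+", "c3+"))
  expect_warning(val <- ordering_accuracy(singletons, ref3), "no adjacent")
  expect_equal(val, 0)
})

test_that("pair weights are length-weighted (mean of the two contigs)", {
  lens <- c(c1 = 100, c2 = 100, c3 = 100, c4 = 1000, c5 = 1000)
  ref <- lay(list(c("c1+", "c2+", "c3+", "c4+", "c5+")), len = lens)
  # one wrong pair among light contigs vs one among heavy: different scores
  asm_light_wrong <- lay(list(c("c2+", "c1+", "c3+", "c4+", "c5+")), len = lens)
  # pairs: c2c1 ok (100), c1c3 wrong (100), c3c4 ok (550), c4c5 ok (1000)
  expect_equal(ordering_accuracy(asm_light_wrong, ref),
               (100 + 550 + 1000) / 1750)
  asm_heavy_wrong <- lay(list(c("c1+", "c2+", "c3+", "c5+", "c4+")), len = lens)
  # pairs: c1c2 ok (100), c2c3 ok (100), c3c5 wrong (550), c5c4 ok (1000)
  expect_equal(ordering_accuracy(asm_heavy_wrong, ref),
               (100 + 100 + 1000) / 1750)
})

test_that("n50 matches the cumulative-sum definition", {
  expect_equal(n50(c(100, 200, 300, 400)), 300)
  expect_equal(n50(rep(77, 9)), 77)
  expect_equal(n50(1234), 1234)
  expect_error(n50(numeric(0)), "empty")
})

test_that("score() restricts, reports bookkeeping, honors exclude_unscaffolded", {
  ref <- lay(list(paste0("c", 1:10, "+")))
  expect_identical(unname(unlist(score(ref, ref)[c(
    "edit_distance", "overall_accuracy", "grouping_accuracy",
    "ordering_accuracy", "orientation_accuracy")])), c(0, 1, 1, 1, 1))
  # assembly scaffolds only 8 of 10
  asm <- lay(list(paste0("c", 1:8, "+")))
  rep1 <- score(asm, ref, exclude_unscaffolded = TRUE)
  expect_equal(rep1$n_contigs_excluded, 2)
  expect_equal(rep1$excluded_ids, c("c10", "c9"))
  expect_equal(rep1$n_contigs_evaluated, 8)
  # singleton groups dropped only in exclude mode
  asm2 <- lay(list(paste0("c", 1:8, "+"), "c9+", "c10+"))
  expect_equal(score(asm2, ref, exclude_unscaffolded = TRUE)$n_contigs_excluded, 2)
  expect_equal(score(asm2, ref)$n_contigs_excluded, 0)
})

test_that("excluding haplotig-like misfits never hurts accuracy", {
  set.seed(23)
  for (i in 1:10) {
    ref <- random_layout(12)
    ids <- layout_contigs(ref)$contig
    # assembly scaffolds 9 contigs faithfully, leaves 3 as misfit singletons
    # placed in wrong groups of the reference
    keep <- sample(ids, 9)
    asm <- restrict_layout(ref, keep)
    asm$groups <- c(asm$groups, stats::setNames(
      lapply(setdiff(ids, keep), function(cid) {
        d <- layout_contigs(ref)
        d <- d[d$contig == cid, c("contig", "orientation", "length")]
        rownames(d) <- NULL
        d
      }), paste0("single_", setdiff(ids, keep))))
    asm <- genome_layout(asm$groups)
    with_excl <- score(asm, ref, exclude_unscaffolded = TRUE)
    without <- score(asm, ref, exclude_unscaffolded = FALSE)
    for (f in c("overall_accuracy", "grouping_accuracy")) {
      expect_gte(with_excl[[f]], without[[f]])
    }
  }
})

test_that("baseline_report scores the all-singleton assembly", {
  ref <- lay(list(paste0("c", 1:6, "+")))
  b <- suppressWarnings(baseline_report(contig_lengths(ref), ref))
  expect_equal(b$ordering_accuracy, 0)
  expect_equal(b$overall_accuracy, 0)
  expect_equal(b$edit_distance, 5)  # k - 1 fusions for a chain of k
  # every chromosome a single contig: baseline is perfect
  ref1 <- lay(list("c1+", "c2+", "c3+", "c4+", "c5+"))
  b1 <- suppressWarnings(baseline_report(contig_lengths(ref1), ref1))
  expect_equal(b1$edit_distance, 0)
  expect_equal(b1$overall_accuracy, 1)
  expect_equal(b1$grouping_accuracy, 1)
  expect_error(baseline_report(c(zz = 5), ref1), "zz")
})

test_that("reports serialize to TSV and JSON with identical values", {
  ref <- lay(list(paste0("c", 1:6, "+")))
  asm <- lay(list(paste0("c", 1:3, "+"), paste0("c", 4:6, "+")))
  r <- score(asm, ref)
  tsv <- tempfile(fileext = ".tsv")
  js <- tempfile(fileext = ".json")
  write_report_tsv(r, tsv, labels = data.frame(method = "m1"))
  write_report_json(r, js, labels = data.frame(method = "m1"))
  tab <- read_report_tsv(tsv)
  jsn <- jsonlite::read_json(js, simplifyVector = TRUE)
  for (f in c("edit_distance", "overall_accuracy", "grouping_accuracy",
              "ordering_accuracy", "orientation_accuracy", "n50")) {
    expect_equal(tab[[f]], r[[f]])
    expect_equal(jsn[[f]], r[[f]])
  }
  expect_equal(tab$method, "m1")
})
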