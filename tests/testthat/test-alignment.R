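test_that("read_alignment round-trips FASTA and enforces invariants", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGT", ">s2", "acga"), f)
  aln <- read_alignment(f)
  expect_s3_class(aln, "alignment")
  expect_equal(aln$n_sites, 4L)
  expect_equal(aln$tip_ids, c("s1", "s2"))
  expect_equal(paste(aln$seq["s2", ], collapse = ""), "ACGA")  # upper-cased

  ragged <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGT", ">s2", "ACGTT"), ragged)
  expect_error(read_alignment(ragged), "ragged.*s2")

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGT", ">s1", "ACGA"), dup)
  expect_error(read_alignment(dup), "duplicate.*s1")

  expect_error(read_alignment(file.path(tempdir(), "no-such.fasta")),
               "not found")
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines("this is not fasta", bad)
  expect_error(read_alignment(bad), "FASTA")
})

test_that("alignment maps U to T and writes FASTA back identically", {
  aln <- alignment(c(a = "ACGU", b = "acgu"))
  expect_equal(unname(aln$seq[1, 4]), "T")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, f)
  expect_equal(read_alignment(f)$seq, aln$seq)
})

test_that("p_distance matches hand counts and excludes ambiguous columns", {
  expect_equal(p_distance("ACGT", "ACGT"),
               list(fraction = 0, comparable_sites = 4L))
  expect_equal(p_distance("AAAA", "TTTT"),
               list(fraction = 1, comparable_sites = 4L))
  # gap and N columns dropped pairwise: 1 mismatch among 5 comparable sites
  expect_equal(p_distance("ACGTNA", "ACGA-A"),
               list(fraction = 0.2, comparable_sites = 5L))
  # IUPAC ambiguity codes are treated as missing
  expect_equal(p_distance("ACGR", "ACGT"),
               list(fraction = 0, comparable_sites = 3L))
  expect_error(p_distance("ACGT", "ACG"), "length mismatch")
  # no comparable sites -> flagged missing, never 0
  res <- p_distance("NN--", "AC-T")
  expect_true(is.na(res$fraction))
  expect_equal(res$comparable_sites, 0L)
})

test_that("p_distance is symmetric, bounded, and zero iff identical", {
  set.seed(101)
  for (rep in 1:25) {
    mat <- random_alignment_chars(2, 60, messy_prob = 0.2)
    d1 <- p_distance(mat[1, ], mat[2, ])
    d2 <- p_distance(mat[2, ], mat[1, ])
    expect_identical(d1, d2)
    if (!is.na(d1$fraction)) {
      expect_gte(d1$fraction, 0)
      expect_lte(d1$fraction, 1)
      o <- oracle_p(mat[1, ], mat[2, ])
      expect_identical(d1$fraction == 0,
                       sum(mat[1, ] != mat[2, ] &
                             mat[1, ] %in% BASES & mat[2, ] %in% BASES) == 0)
      expect_equal(d1$fraction, o$p)
    }
  }
})

test_that("distance_matrix matches hand example and naive recount", {
  aln <- alignment(c(a = "AAAA", b = "AATT", c = "TTTT"))
  dm <- distance_matrix(aln, min_comparable = 0)
  expect_equal(unname(dm$p["a", "b"]), 0.5)
  expect_equal(unname(dm$p["a", "c"]), 1.0)
  expect_equal(unname(dm$p["b", "c"]), 0.5)
  expect_equal(unname(diag(dm$p)), rep(0, 3))

  set.seed(202)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    L <- sample(30:200, 1)
    mat <- random_alignment_chars(n, L, messy_prob = 0.15)
    dm <- distance_matrix(alignment(mat), min_comparable = 0)
    expect_equal(dm$p, t(dm$p))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      o <- oracle_p(mat[i, ], mat[j, ])
      expect_equal(unname(dm$p[i, j]), o$p)
      expect_equal(unname(dm$comparable_sites[i, j]), o$n)
    }
  }
})

test_that("pairwise and complete deletion agree when missingness is shared", {
  set.seed(303)
  for (rep in 1:10) {
    n <- sample(3:8, 1); L <- 80
    mat <- matrix(sample(BASES, n * L, replace = TRUE), nrow = n)
    # punch missing columns identically across all rows
    miss <- sample(L, 10)
    mat[, miss] <- "-"
    rownames(mat) <- sprintf("t%d", 1:n)
    dm <- distance_matrix(alignment(mat), min_comparable = 0)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      expect_equal(unname(dm$p[i, j]),
                   oracle_p_complete_deletion(mat, i, j))
    }
  }
})

test_that("distance_matrix warns on missing and low-coverage pairs", {
  aln <- alignment(c(a = "AAAA", b = "----", c = "AATT"))
  expect_warning(distance_matrix(aln, min_comparable = 0), "no comparable")
  aln2 <- alignment(c(a = "AAAA", b = "AATT"))
  expect_warning(distance_matrix(aln2, min_comparable = 50),
                 "fewer than 50")
  expect_error(distance_matrix(alignment(c(a = "ACGT"))), "at least 2")
})

test_that("species_pair_ranges matches exhaustive enumeration", {
  # two individuals of X at 10% and 14% from the single Y individual
  x1 <- paste(rep("A", 50), collapse = "")
  y1 <- paste(c(rep("C", 5), rep("A", 45)), collapse = "")   # 5/50 = 0.10
  x2 <- paste(c(rep("A", 43), rep("G", 7)), collapse = "")   # vs y1: 12/50
  # construct x2 differing from y1 at exactly 7 sites:
  x2 <- paste(c(rep("C", 5), rep("A", 43), rep("G", 2)), collapse = "")
  aln <- alignment(c(x1 = x1, x2 = x2, y1 = y1))
  dm <- distance_matrix(aln, min_comparable = 0)
  expect_equal(unname(dm$p["x1", "y1"]), 0.10)
  expect_equal(unname(dm$p["x2", "y1"]), 0.04)
  sm <- species_map(c("x1", "x2", "y1"), c("X", "X", "Y"))
  ranges <- species_pair_ranges(dm, sm)
  xy <- ranges[ranges$species_a == "X" & ranges$species_b == "Y", ]
  expect_equal(c(xy$min_percent, xy$max_percent), c(4.0, 10.0))

  set.seed(404)
  for (rep in 1:5) {
    n <- 8
    mat <- random_alignment_chars(n, 100, messy_prob = 0.1)
    sp <- sample(c("A", "B", "C"), n, replace = TRUE)
    names(sp) <- rownames(mat)
    sm <- species_map(rownames(mat), sp)
    dm <- distance_matrix(alignment(mat), min_comparable = 0)
    ranges <- species_pair_ranges(dm, sm)
    for (k in seq_len(nrow(ranges))) {
      o <- oracle_ranges(dm$p, sp, ranges$species_a[k], ranges$species_b[k])
      expect_equal(unname(c(ranges$min_percent[k], ranges$max_percent[k])),
                   unname(o))
    }
  }
})

test_that("single individuals give degenerate ranges; unmapped tips error", {
  aln <- alignment(c(a = "AAAA", b = "ATTT", c = "GGGG"))
  dm <- distance_matrix(aln, min_comparable = 0)
  sm <- species_map(c("a", "b", "c"), c("A", "B", "C"))
  ranges <- species_pair_ranges(dm, sm)
  expect_true(all(ranges$min_percent == ranges$max_percent))
  expect_true(all(ranges$type == "between"))
  sm_bad <- species_map(c("a", "b"), c("A", "B"))
  expect_error(species_pair_ranges(dm, sm_bad), "not in species map.*c")
})

test_that("percent rounding is half-away-from-zero to one decimal", {
  # 0.25% would display as 0.2 under round-half-even; Table style gives 0.3
  expect_equal(chronocal:::round_half_up(0.25, 1), 0.3)
  expect_equal(chronocal:::round_half_up(2.249, 1), 2.2)
  expect_equal(chronocal:::round_half_up(-0.25, 1), -0.3)
  # through the range table: 1 mismatch in 400 sites = 0.25% -> 0.3
  a <- paste(rep("A", 400), collapse = "")
  b <- paste(c("T", rep("A", 399)), collapse = "")
  dm <- distance_matrix(alignment(c(a = a, b = b)), min_comparable = 0)
  sm <- species_map(c("a", "b"), c("A", "B"))
  r <- species_pair_ranges(dm, sm)
  expect_equal(r$min_percent, 0.3)
  expect_equal(r$min_percent_raw, 0.25)
})

test_that("within_species_divergence reports range and reference relation", {
  # two conspecifics differing at 2 of 500 sites -> 0.4%, inside 0.2-0.9
  s1 <- paste(rep("A", 500), collapse = "")
  s2 <- paste(c("T", "T", rep("A", 498)), collapse = "")
  dm <- distance_matrix(alignment(c(f1 = s1, f2 = s2, o = s1)),
                        min_comparable = 0)
  sm <- species_map(c("f1", "f2", "o"), c("F", "F", "O"))
  w <- within_species_divergence(dm, sm, "F")
  expect_equal(w$min_percent, 0.4)
  expect_equal(w$max_percent, 0.4)
  expect_true(w$inside_reference)

  # identical conspecifics -> 0-0, below the reference interval
  dm0 <- distance_matrix(alignment(c(f1 = s1, f2 = s1, o = s2)),
                         min_comparable = 0)
  w0 <- within_species_divergence(dm0, sm, "F")
  expect_equal(c(w0$min_percent, w0$max_percent), c(0, 0))
  expect_equal(w0$relation, "below")

  # three conspecifics with pairwise p 0.002, 0.004, 0.006 -> 0.2-0.6
  L <- 1000
  base <- rep("A", L)
  t1 <- base
  t2 <- base; t2[1:2] <- "T"                # 2 diffs vs t1
  t3 <- base; t3[3:6] <- "G"                # 4 vs t1, 6 vs t2
  dm3 <- distance_matrix(
    alignment(rbind(a1 = t1, a2 = t2, a3 = t3)), min_comparable = 0)
  sm3 <- species_map(c("a1", "a2", "a3"), rep("A", 3))
  w3 <- within_species_divergence(dm3, sm3, "A")
  expect_equal(c(w3$min_percent, w3$max_percent), c(0.2, 0.6))
  expect_error(within_species_divergence(dm3, sm3, "Z"), "not found")
  expect_error(
    within_species_divergence(dm, sm, "O"), "fewer than 2")
})

test_that("format_range_matrix collapses degenerate ranges", {
  r <- data.frame(species_a = c("A", "A", "B"), species_b = c("A", "B", "B"),
                  min_percent = c(0.1, 2.2, 0.0), max_percent = c(0.1, 2.9, 0.0),
                  min_percent_raw = c(0.1, 2.2, 0), max_percent_raw = c(0.1, 2.9, 0),
                  n_comparisons = 1L, type = c("within", "between", "within"))
  m <- format_range_matrix(r)
  expect_equal(m["A", "B"], "2.2-2.9")
  expect_equal(m["A", "A"], "0.1")
  expect_equal(m["B", "A"], m["A", "B"])
})
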