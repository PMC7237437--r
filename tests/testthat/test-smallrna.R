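test_that("exact reads map uniquely with zero mismatches", {
  set.seed(1)
  g <- circular_genome("mt", random_seq(2000))
  r <- substr(g$sequence, 100, 121)
  al <- map_reads_mito(data.frame(id = "r1", seq = r), g)
  expect_equal(nrow(al), 1)
  expect_equal(al$start, 100)
  expect_equal(al$end, 121)
  expect_equal(al$n_mismatch, 0)
  expect_false(al$multimap)
})

test_that("reads beyond the mismatch cap stay unmapped", {
  set.seed(2)
  g <- circular_genome("mt", random_seq(2000))
  r <- substr(g$sequence, 100, 121)
  v <- r
  substr(v, 3, 3) <- setdiff(BASES, substr(r, 3, 3))[1]
  substr(v, 9, 9) <- setdiff(BASES, substr(r, 9, 9))[1]
  al <- map_reads_mito(data.frame(id = "v", seq = v), g)
  expect_false(any(al$start == 100 & al$n_mismatch <= 1))
})

test_that("origin-spanning reads map with end < start", {
  set.seed(3)
  g <- circular_genome("mt", random_seq(2000))
  r <- paste0(substr(g$sequence, 1991, 2000), substr(g$sequence, 1, 12))
  al <- map_reads_mito(data.frame(id = "w", seq = r), g)
  expect_true(any(al$start == 1991 & al$end == 12 & al$strand == "+"))
})

test_that("mapping agrees with a brute-force all-positions scan", {
  set.seed(4)
  g <- circular_genome("mt", random_seq(400))
  for (i in 1:15) {
    kind <- sample(c("exact", "mut", "random", "minus", "wrap"), 1)
    s <- sample(400, 1)
    k <- sample(16:30, 1)
    base <- circular_subseq(g, s, (s + k - 2) %% 400 + 1, "+")
    read <- switch(kind,
      exact = base,
      minus = rc_dna(base),
      wrap = circular_subseq(g, 395, 20, "+"),
      mut = { p <- sample(nchar(base), 1)
              substr(base, p, p) <- sample(setdiff(BASES, substr(base, p, p)), 1)
              base },
      random = random_seq(k))
    got <- map_reads_mito(data.frame(id = "x", seq = read), g)
    oracle <- bf_map(read, g$sequence, max_mm = 1)
    if (is.null(oracle)) {
      expect_equal(nrow(got), 0)
    } else {
      best <- min(oracle$n_mismatch)
      oracle <- oracle[oracle$n_mismatch == best, ]
      got_key <- sort(paste(got$start, got$end, got$strand, got$n_mismatch))
      or_key <- sort(paste(oracle$start, oracle$end, oracle$strand,
                           oracle$n_mismatch))
      expect_equal(got_key, or_key)
    }
  }
})

test_that("reads longer than the genome are rejected and empty input is fine", {
  g <- circular_genome("mt", "ACGTACGTAC")
  expect_error(map_reads_mito(data.frame(id = "a", seq = strrep("A", 11)), g),
               "longer than the genome")
  expect_equal(nrow(map_reads_mito(data.frame(id = character(0),
                                              seq = character(0)), g)), 0)
})

test_that("nuclear screen drops exact and 1-mismatch nuclear hits", {
  set.seed(5)
  g <- circular_genome("mt", random_seq(1500))
  r <- substr(g$sequence, 50, 71)
  reads <- data.frame(id = c("a", "b"), seq = c(r, substr(g$sequence, 500, 521)))
  al <- map_reads_mito(reads, g)
  # exact nuclear copy of read a
  nuc <- c(chr1 = paste0(random_seq(40), r, random_seq(40)))
  expect_equal(screen_nuclear(al, reads, nuc), "b")
  # 1-mismatch nuclear copy also discards
  r1 <- r; substr(r1, 5, 5) <- setdiff(BASES, substr(r, 5, 5))[1]
  nuc1 <- c(chr1 = paste0(random_seq(40), r1, random_seq(40)))
  expect_equal(screen_nuclear(al, reads, nuc1), "b")
  # empty screen warns and keeps everything
  expect_warning(kept <- screen_nuclear(al, reads, NULL), "skipped")
  expect_setequal(kept, c("a", "b"))
})

test_that("clustering groups identical reads and separates 1-mismatch reads", {
  set.seed(6)
  g <- circular_genome("mt", random_seq(1500))
  r <- substr(g$sequence, 100, 119)          # 20 nt
  v <- r; substr(v, 10, 10) <- setdiff(BASES, substr(r, 10, 10))[1]
  reads <- data.frame(id = paste0("r", 1:4), seq = c(r, r, r, v))
  al <- map_reads_mito(reads, g)
  al <- al[al$n_mismatch == 0 | al$seq == v, ]
  cl <- cluster_reads(al)
  # 19/20 identity = 0.95 < 0.99: the variant founds its own cluster
  sizes <- sort(cl$size[cl$centroid %in% c(r, v)], decreasing = TRUE)
  expect_equal(cl$size[cl$centroid == r][1], 3)
  expect_true(v %in% cl$centroid)
  # at identity 0.9 the variant joins the abundant centroid
  cl2 <- cluster_reads(al[al$seq %in% c(r, v) & al$start == 100, ],
                       identity = 0.9)
  expect_equal(nrow(cl2), 1)
  expect_equal(cl2$size, 4)
  expect_equal(cl2$centroid, r)
})

test_that("disjoint abundant loci give disjoint clusters of the right size", {
  set.seed(7)
  g <- circular_genome("mt", random_seq(3000))
  a <- substr(g$sequence, 200, 221)
  b <- substr(g$sequence, 900, 921)
  reads <- data.frame(id = paste0("r", 1:260),
                      seq = c(rep(a, 250), rep(b, 10)))
  al <- map_reads_mito(reads, g)
  cl <- cluster_reads(al)
  expect_setequal(cl$size, c(250, 10))
  expect_equal(sum(cl$size), length(unique(al$read_id)))
})

test_that("end profiles count 5'/3' ends with the strand flip", {
  g <- circular_genome("mt", random_seq(500))
  al <- data.frame(read_id = c("p", "m"), seq = "N",
                   start = c(100, 100), end = c(121, 121),
                   strand = c("+", "-"), n_mismatch = 0, multimap = FALSE)
  ep <- end_profile(al, g)
  expect_equal(ep$plus$five[100], 1)
  expect_equal(ep$plus$three[121], 1)
  expect_equal(ep$minus$five[121], 1)
  expect_equal(ep$minus$three[100], 1)
  expect_equal(sum(ep$plus$five), sum(ep$plus$three))
  expect_equal(sum(ep$minus$five), sum(ep$minus$three))
})

test_that("sharpness fractions follow the modal-end tally", {
  # 200 reads all starting at 100; ends split 150/50 between 121 and 122
  members <- data.frame(seq = c("x", "y"), start = c(100, 100),
                        end = c(121, 122), n_mismatch = 0,
                        n_reads = c(150, 50))
  cl <- data.frame(cluster_id = "c1", centroid = "x", size = 200,
                   start = 100, end = 121, strand = "+", multimap = FALSE)
  cl$members <- list(members)
  sf <- sharpness_filter(cl)
  expect_equal(sf$frac5, 1.0)
  expect_equal(sf$frac3, 0.75)
  expect_true(sf$sharp_pass)  # 0.75 meets the inclusive threshold

  # uniform 5' ends over 10 positions fail decisively
  mem2 <- data.frame(seq = letters[1:10], start = 100:109, end = 130,
                     n_mismatch = 0, n_reads = 3)
  cl2 <- data.frame(cluster_id = "c2", centroid = "a", size = 30,
                    start = 100, end = 130, strand = "+", multimap = FALSE)
  cl2$members <- list(mem2)
  sf2 <- sharpness_filter(cl2)
  expect_lte(sf2$frac5, 0.134)
  expect_false(sf2$sharp_pass)
})

test_that("size filter is strictly greater-than", {
  cl <- data.frame(cluster_id = c("a", "b", "c"), centroid = "x",
                   size = c(201, 200, 120), start = 1, end = 22,
                   strand = "+", multimap = FALSE)
  expect_equal(size_filter(cl)$cluster_id, "a")
  expect_setequal(size_filter(cl, 50)$cluster_id, c("a", "b", "c"))
  expect_setequal(size_filter(cl, 119)$cluster_id, c("a", "b", "c"))
})

test_that("FASTQ round trip preserves ids and sequences", {
  reads <- data.frame(id = c("x", "y"), seq = c("ACGTACGTACGTACG",
                                                "TTTTGGGGCCCCAAA"))
  path <- tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  back <- read_smallrna_fastq(path)
  expect_equal(back, reads)
})
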