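test_that("seed scan finds the planted seed complement", {
  # centroid nt 4-10 = GCUACGU; its reverse complement is ACGTAGC
  cen <- "AAAGCUACGUAAAAAAAAAAA"
  utr <- paste0(strrep("C", 30), "ACGTAGC", strrep("C", 30))
  hit <- seed_scan(cen, utr)
  expect_equal(nrow(hit), 1)
  expect_equal(c(hit$site_start, hit$site_end), c(31, 37))
  # the reverse complement of the whole centroid contains exactly one site
  cen2 <- "GCTACGTACGTAGCATGCATGC"
  hit2 <- seed_scan(cen2, rc_dna(cen2))
  expect_equal(nrow(hit2), 1)
  expect_error(seed_scan("ACGTACGT", utr), "shorter")
})

test_that("seed scan equals an exhaustive substring scan on random UTRs", {
  set.seed(11)
  for (i in 1:10) {
    cen <- random_seq(22)
    utr <- random_seq(1000)
    probe <- rc_dna(substr(cen, 4, 10))
    oracle <- integer(0)
    for (p in 1:(nchar(utr) - 6)) {
      if (substr(utr, p, p + 6) == probe) oracle <- c(oracle, p)
    }
    expect_equal(seed_scan(cen, utr)$site_start, oracle)
  }
})

test_that("match counting scores the perfect complement at full length", {
  set.seed(12)
  cen <- random_seq(22)
  utr <- paste0(random_seq(80), rc_dna(cen), random_seq(80))
  s <- seed_scan(cen, utr)
  expect_equal(nrow(s), 1)
  expect_equal(count_matches(cen, utr, s$site_start, s$site_end), 22)
})

test_that("match counting equals exhaustive offset enumeration", {
  set.seed(13)
  bf_count <- function(cen, win_rc) {
    av <- strsplit(cen, "")[[1]]; tv <- strsplit(win_rc, "")[[1]]
    nc <- length(av); nt <- length(tv)
    best <- -Inf; bm <- 0
    for (off in (1 - nc):(nt - 1)) {
      i1 <- max(1, 1 - off); i2 <- min(nc, nt - off)
      if (i1 > i2) next
      # enumerate every sub-interval of this register
      sc <- ifelse(av[i1:i2] == tv[(i1:i2) + off], 1, -3)
      n <- length(sc)
      for (a in 1:n) for (b in a:n) {
        s <- sum(sc[a:b]); m <- sum(sc[a:b] > 0)
        if (s > best || (s == best && m > bm)) { best <- s; bm <- m }
      }
    }
    bm
  }
  for (i in 1:6) {
    cen <- random_seq(20)
    utr <- paste0(random_seq(15), rc_dna(substr(cen, 4, 10)), random_seq(15))
    site <- seed_scan(cen, utr)
    got <- count_matches(cen, utr, site$site_start[1], site$site_end[1],
                         context = 5)
    wstart <- max(1, site$site_start[1] - (20 + 5))
    wend <- min(nchar(utr), site$site_end[1] + (20 + 5))
    expect_equal(got, bf_count(cen, rc_dna(substr(utr, wstart, wend))))
  }
  # seed-only complement stays below the 11-match requirement
  set.seed(14)
  below <- vapply(1:20, function(i) {
    cen <- random_seq(22)
    utr <- paste0(random_seq(60), rc_dna(substr(cen, 4, 10)), random_seq(60))
    s <- seed_scan(cen, utr)
    count_matches(cen, utr, s$site_start[1], s$site_end[1])
  }, numeric(1))
  expect_true(mean(below < 11) >= 0.95)
})

test_that("duplex energy of a perfect duplex is the hand-summed stack total", {
  m <- energy_model()
  set.seed(15)
  for (i in 1:10) {
    cen <- random_seq(22)
    site <- rc_dna(cen)
    av <- strsplit(cen, "")[[1]]
    pairs <- paste0(av, comp_base(av))
    expected <- m$initiation +
      sum(vapply(1:21, function(k) m$stack[pairs[k], pairs[k + 1]],
                 numeric(1)))
    expect_equal(duplex_energy(cen, site, m), expected, tolerance = 1e-12)
  }
})

test_that("duplex energy honours the forced helix and symmetry", {
  # no pairing possible for centroid nt 3-10 -> +Inf
  expect_equal(duplex_energy(strrep("A", 22), strrep("C", 18)), Inf)
  # reverse-complement relabeling of both strands preserves the energy
  set.seed(16)
  for (i in 1:10) {
    cen <- random_seq(22)
    site <- rc_dna(cen)
    e1 <- duplex_energy(cen, site)
    e2 <- duplex_energy(rc_dna(site), rc_dna(cen))
    expect_equal(e1, e2, tolerance = 1e-12)
  }
  expect_error(duplex_energy("ACGTACGT", "ACGTACGTACGT"), "shorter")
})

test_that("any single substitution raises the duplex energy", {
  set.seed(17)
  for (i in 1:5) {
    cen <- random_seq(22)
    site <- rc_dna(cen)
    d0 <- duplex_energy(cen, site)
    for (pos in sample(22, 6)) {
      for (nb in setdiff(BASES, substr(site, pos, pos))) {
        v <- site; substr(v, pos, pos) <- nb
        expect_gt(duplex_energy(cen, v), d0)
      }
    }
  }
})

test_that("accessibility is zero for unstructured sites and positive in stems", {
  a <- accessibility_ddG(strrep("A", 300), 150, 156, -25)
  expect_equal(a$dG_open, 0)
  expect_equal(a$ddG, -25)
  hp <- paste0(strrep("T", 30), strrep("G", 20), strrep("A", 8),
               strrep("C", 20), strrep("T", 30))
  ah <- accessibility_ddG(hp, 31, 37, -25)
  expect_gt(ah$dG_open, 0)
  expect_gt(ah$ddG, -25)
  expect_error(accessibility_ddG("ACGTACGT", 1, 7, Inf), "finite")
})

test_that("constrained folds never beat unconstrained folds", {
  set.seed(18)
  for (i in 1:10) {
    s <- random_seq(80)
    free <- fold_mfe(s)$energy
    open <- fold_mfe(s, blocked = 30:50)$energy
    expect_gte(open, free)
  }
})

test_that("planted perfect complements pass all four requirements", {
  set.seed(19)
  cen <- random_seq(22)
  utr <- paste0(random_seq(150), rc_dna(cen), random_seq(150))
  hits <- evaluate_targets(cen, c(u1 = utr), keep_all = TRUE)
  passing <- hits[hits$pass, ]
  expect_equal(nrow(passing), 1)
  expect_true(passing$n_matches >= 11)
  expect_lt(passing$dG_duplex, -20)
  expect_lt(passing$ddG, -9)
})

test_that("passing hits are a subset of seed hits and thresholds are monotone", {
  set.seed(20)
  cen <- random_seq(22)
  utrs <- c(u1 = paste0(random_seq(100), rc_dna(cen), random_seq(100)),
            u2 = random_seq(400))
  all_hits <- evaluate_targets(cen, utrs, keep_all = TRUE)
  seed_hits <- do.call(rbind, lapply(names(utrs), function(u) {
    s <- seed_scan(cen, utrs[[u]])
    if (nrow(s) == 0) NULL else cbind(utr_id = u, s)
  }))
  expect_true(all(paste(all_hits$utr_id, all_hits$site_start) %in%
                  paste(seed_hits$utr_id, seed_hits$site_start)))
  base <- evaluate_targets(cen, utrs)
  stricter <- evaluate_targets(cen, utrs, min_matches = 15, max_ddG = -15,
                               max_dG = -30)
  expect_true(all(paste(stricter$utr_id, stricter$site_start) %in%
                  paste(base$utr_id, base$site_start)))
  # a hit below the match threshold is excluded regardless of energies
  none <- evaluate_targets(cen, utrs, min_matches = 23)
  expect_equal(nrow(none), 0)
})

test_that("shuffled UTR sets yield no hits at the default thresholds", {
  set.seed(22)
  cen <- random_seq(22)
  hits <- 0
  for (i in 1:40) {
    utr <- random_seq(500)
    hits <- hits + nrow(evaluate_targets(cen, c(u = utr)))
  }
  expect_equal(hits, 0)
})
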