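# Independent oracles used across the suite. These deliberately share no code
# with the package implementations they check.

BASES <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

comp_base <- function(b) chartr("ACGT", "TGCA", b)

# brute-force mapper: rotate the genome and compare every window directly
bf_map <- function(read, genome_seq, max_mm = 1) {
  L <- nchar(genome_seq)
  k <- nchar(read)
  doubled <- paste0(genome_seq, genome_seq)
  rv <- strsplit(read, "")[[1]]
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") rv else rev(strsplit(comp_base(read), "")[[1]])
    for (s in 1:L) {
      wv <- strsplit(substr(doubled, s, s + k - 1), "")[[1]]
      mm <- sum(pat != wv)
      if (mm <= max_mm) {
        e <- s + k - 1
        hits[[length(hits) + 1]] <- data.frame(
          start = s, end = if (e > L) e - L else e, strand = strand,
          n_mismatch = mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) return(NULL)
  do.call(rbind, hits)
}

# brute-force pi: mean over all unordered row pairs of the p-distance,
# divided by (N - 1) ... i.e. sum_{a<b} pi_ab / (N (N - 1)), the unordered
# printed-estimator identity derived from first principles
bf_pi <- function(rows) {
  N <- length(rows)
  s <- 0
  for (a in seq_len(N - 1)) for (b in (a + 1):N) {
    av <- strsplit(rows[a], "")[[1]]
    bv <- strsplit(rows[b], "")[[1]]
    ok <- av %in% BASES & bv %in% BASES
    s <- s + if (sum(ok) == 0) 0 else sum(av[ok] != bv[ok]) / sum(ok)
  }
  s / (N * (N - 1))
}

# independent Dunn oracle: direct substitution into the mean-rank formula
bf_dunn <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  rk <- rank(x)
  tie <- table(x)
  tiesum <- sum(tie^3 - tie)
  sizes <- lengths(groups)
  offsets <- cumsum(c(0, sizes))
  k <- length(groups)
  res <- NULL
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    ri <- mean(rk[(offsets[i] + 1):offsets[i + 1]])
    rj <- mean(rk[(offsets[j] + 1):offsets[j + 1]])
    sigma <- sqrt((N * (N + 1) / 12 - tiesum / (12 * (N - 1))) *
                    (1 / sizes[i] + 1 / sizes[j]))
    z <- (ri - rj) / sigma
    p <- 2 * stats::pnorm(-abs(z))
    res <- rbind(res, data.frame(i = i, j = j, z = z, p = p,
                                 p_adj = min(1, k * (k - 1) / 2 * p)))
  }
  res
}

# tiny annotated genome shared by several tests
make_tiny_genome <- function(seed = 101, L = 3000) {
  set.seed(seed)
  g <- smithscan::circular_genome("tiny", random_seq(L))
  feats <- rbind(
    smithscan::genome_feature("rrnS", "rRNA", 201, 900),
    smithscan::genome_feature("trnA", "tRNA", 1001, 1070),
    smithscan::genome_feature("cox1", "PCG", 1201, 2200),
    smithscan::genome_feature("trnB", "tRNA", 2401, 2470, "-"))
  ann <- smithscan::reannotate_urs(
    smithscan::annotation_set("tiny", feats, length = L), g)
  list(genome = g, annotation = ann)
}
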