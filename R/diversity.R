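# Sliding-window nucleotide diversity on population alignments, with region
# labeling. The estimator is pi_hat = N/(N-1) * sum_{i} sum_{j>i} p_i p_j
# pi_ij over haplotype frequencies, with pi_ij the uncorrected p-distance;
# the doubled (ordered-pair, Nei-style) convention is available by switch.

VALID_BASES <- c("A", "C", "G", "T")

#' Uncorrected pairwise p-distance
#'
#' Mismatches divided by compared sites; sites with a gap or ambiguity in
#' either sequence are excluded from numerator and denominator. 0 when no
#' comparable sites remain.
#'
#' @param a,b equal-length aligned sequences.
#' @return fraction between 0 and 1.
#' @export
pairwise_p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences have different lengths")
  av <- strsplit(toupper(chartr("Uu", "Tt", a)), "")[[1]]
  bv <- strsplit(toupper(chartr("Uu", "Tt", b)), "")[[1]]
  ok <- av %in% VALID_BASES & bv %in% VALID_BASES
  n <- sum(ok)
  if (n == 0) return(0)
  sum(av[ok] != bv[ok]) / n
}

#' Mean nucleotide diversity of an alignment (window)
#'
#' Collapses rows to haplotypes with frequencies p_i and applies
#' pi_hat = N/(N-1) sum_i sum_{j>i} p_i p_j pi_ij (the unordered-pair form).
#' `convention = "ordered"` doubles the sum (the conventional Nei estimator);
#' rank-based test statistics are invariant to this global factor of two.
#'
#' @param rows character vector of aligned sequences (N >= 2).
#' @param convention "printed" (unordered pairs, default) or "ordered".
#' @return pi_hat.
#' @export
nucleotide_diversity <- function(rows, convention = c("printed", "ordered")) {
  convention <- match.arg(convention)
  N <- length(rows)
  if (N < 2) stop("need at least 2 sequences")
  tab <- table(rows)
  if (length(tab) == 1) return(0)
  haps <- names(tab)
  p <- as.numeric(tab) / N
  s <- 0
  for (i in seq_along(haps)[-length(haps)]) {
    for (j in (i + 1):length(haps)) {
      s <- s + p[i] * p[j] * pairwise_p_distance(haps[i], haps[j])
    }
  }
  out <- N / (N - 1) * s
  if (convention == "ordered") out <- 2 * out
  out
}

#' Sliding-window nucleotide diversity
#'
#' Windows start at 1, 1+step, ...; only full-size windows are emitted.
#' Zero-diversity windows are included.
#'
#' @param alignment character vector of aligned sequences.
#' @param size window size in bp (default 10).
#' @param step step in bp (default 5).
#' @param convention passed to [nucleotide_diversity()].
#' @return data.frame(start, end, pi); empty when the alignment is shorter
#'   than `size`.
#' @export
sliding_window_diversity <- function(alignment, size = 10, step = 5,
                                     convention = "printed") {
  stopifnot(size >= 1, step >= 1)
  L <- nchar(alignment[1])
  if (any(nchar(alignment) != L)) stop("alignment rows differ in length")
  if (L < size)
    return(data.frame(start = integer(0), end = integer(0), pi = numeric(0)))
  starts <- as.integer(seq.int(1L, L - size + 1L, by = step))
  N <- length(alignment)
  gapfree <- N >= 2 && !any(grepl("[^ACGT]", alignment))
  if (gapfree) {
    # For gap-free alignments the estimator decomposes per site:
    # sum_{a<b} pi_ab = (1/size) * sum_{s in window} D_s with
    # D_s = C(N,2) - sum_base C(n_base,2) (pairs differing at site s),
    # so pi_hat = sum_s D_s / (size * N * (N-1)). Identical to the
    # haplotype form; verified against it by property test.
    mat <- vapply(alignment, function(r) utf8ToInt(r), integer(L))
    Ds <- rep(choose(N, 2), L)
    for (b in utf8ToInt("ACGT")) {
      nb <- .rowSums(mat == b, L, N)
      Ds <- Ds - nb * (nb - 1) / 2
    }
    cs <- c(0, cumsum(Ds))
    pis <- (cs[starts + size] - cs[starts]) / (size * N * (N - 1))
    if (convention == "ordered") pis <- 2 * pis
  } else {
    pis <- vapply(starts, function(s) {
      nucleotide_diversity(substring(alignment, s, s + size - 1L),
                           convention = convention)
    }, numeric(1))
  }
  data.frame(start = starts, end = starts + size - 1L, pi = pis)
}

REGION_PRECEDENCE <- c("smithRNA", "pre_smithRNA", "tRNA", "rRNA", "PCG", "UR")

#' Label windows with region types
#'
#' Each window is labeled by the region type at its midpoint; when features
#' overlap, precedence is smithRNA > pre_smithRNA > tRNA > rRNA > PCG > UR.
#'
#' @param windows [sliding_window_diversity()] output (alignment coordinates).
#' @param partition an [annotation_set()] or feature data.frame mapped onto
#'   alignment coordinates (no wrap: alignments are linear).
#' @return `windows` with an added `region` column.
#' @export
assign_regions <- function(windows, partition) {
  feats <- if (inherits(partition, "annotation_set")) partition$features
           else partition
  mids <- (windows$start + windows$end) %/% 2
  prec <- rep(Inf, length(mids))
  for (i in seq_len(nrow(feats))) {
    sel <- mids >= feats$start[i] & mids <= feats$end[i]
    if (any(sel)) {
      prec[sel] <- pmin(prec[sel], match(feats$ftype[i], REGION_PRECEDENCE))
    }
  }
  if (any(is.infinite(prec)))
    stop("window midpoint ", mids[which(is.infinite(prec))[1]],
         " not covered by partition")
  windows$region <- REGION_PRECEDENCE[prec]
  windows
}

#' Read an aligned FASTA
#'
#' @param path aligned FASTA (equal-length rows, gaps allowed).
#' @return named character vector of rows.
#' @export
read_alignment_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(ss)), names(ss))
}

#' Read a region table (BED-like TSV on alignment coordinates)
#'
#' Columns: name, ftype, start, end (1-based inclusive), optional strand.
#'
#' @param path TSV with a header.
#' @return feature data.frame usable as an [assign_regions()] partition.
#' @export
read_region_table <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "ftype", "start", "end") %in% names(d)))
  if (!"strand" %in% names(d)) d$strand <- "+"
  d
}
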