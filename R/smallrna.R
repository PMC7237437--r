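# Small RNA pipeline: exhaustive mismatch-tolerant mapping to the circular
# mitogenome, nuclear decoy screening, abundance clustering, 5'/3' end
# profiles, and the cluster-size / end-sharpness requirements.

as_read_df <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot(all(c("id", "seq") %in% names(reads)))
    df <- reads[, c("id", "seq")]
  } else {
    if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
    df <- data.frame(id = names(reads), seq = unname(reads),
                     stringsAsFactors = FALSE)
  }
  df$seq <- toupper(chartr("Uu", "Tt", df$seq))
  df
}

#' Read small RNA reads from FASTQ
#'
#' Qualities are read and ignored; quality trimming is assumed upstream.
#'
#' @param path FASTQ file (gzip allowed).
#' @return data.frame with columns `id`, `seq`.
#' @export
read_smallrna_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1),
             seq = unname(as.character(ss)), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Map small RNA reads to a circular mitochondrial genome
#'
#' Exhaustive full-length, ungapped, end-to-end scan of both strands with at
#' most `max_mismatch` mismatches (N counts as a mismatch), wrap-aware on
#' circular genomes. A read aligning equally well at several loci is reported
#' at all best loci and flagged `multimap`. This exact scan is strictly more
#' sensitive than a heuristic seeded mapper at the same mismatch cap.
#'
#' @param reads data.frame(id, seq) or named character vector.
#' @param genome a [circular_genome()].
#' @param max_mismatch maximum tolerated mismatches (default 1).
#' @return data.frame(read_id, seq, start, end, strand, n_mismatch, multimap);
#'   `start` is the leftmost genomic coordinate, `end < start` marks an
#'   alignment wrapping the origin.
#' @export
map_reads_mito <- function(reads, genome, max_mismatch = 1) {
  stopifnot(inherits(genome, "circular_genome"))
  reads <- as_read_df(reads)
  empty <- data.frame(read_id = character(0), seq = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), n_mismatch = integer(0),
                      multimap = logical(0), stringsAsFactors = FALSE)
  if (nrow(reads) == 0) return(empty)
  L <- genome$length
  lens <- nchar(reads$seq)
  if (any(lens > L)) stop("reads longer than the genome are rejected")
  kmax <- max(lens)
  ext <- if (genome$circular && kmax > 1)
    substr(genome$sequence, 1, kmax - 1) else ""
  subject <- Biostrings::DNAString(paste0(genome$sequence, ext))

  scan_one <- function(s, strand) {
    pat <- if (strand == "+") s else rc_dna(s)
    p <- Biostrings::DNAString(pat)
    m <- Biostrings::matchPattern(p, subject, max.mismatch = max_mismatch,
                                  with.indels = FALSE, fixed = TRUE)
    st <- Biostrings::start(m)
    st <- st[st <= L]
    if (length(st) == 0) return(NULL)
    nmm <- Biostrings::neditStartingAt(p, subject, starting.at = st,
                                       with.indels = FALSE, fixed = TRUE)
    keep <- nmm <= max_mismatch
    st <- st[keep]; nmm <- nmm[keep]
    if (length(st) == 0) return(NULL)
    en <- st + nchar(s) - 1L
    wrap <- en > L
    en[wrap] <- en[wrap] - L
    data.frame(start = st, end = en, strand = strand, n_mismatch = nmm,
               stringsAsFactors = FALSE)
  }

  useqs <- unique(reads$seq)
  per_seq <- lapply(useqs, function(s) {
    hits <- rbind(scan_one(s, "+"), scan_one(s, "-"))
    if (is.null(hits) || nrow(hits) == 0) return(NULL)
    best <- min(hits$n_mismatch)
    hits <- hits[hits$n_mismatch == best, , drop = FALSE]
    hits$multimap <- nrow(hits) > 1
    hits
  })
  names(per_seq) <- useqs
  out <- lapply(seq_len(nrow(reads)), function(i) {
    h <- per_seq[[reads$seq[i]]]
    if (is.null(h)) return(NULL)
    cbind(data.frame(read_id = reads$id[i], seq = reads$seq[i],
                     stringsAsFactors = FALSE), h)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else `rownames<-`(out, NULL)
}

#' Screen mitochondria-mapped reads against a nuclear decoy
#'
#' Discards reads with a full-length alignment at `max_mismatch` or fewer
#' mismatches to any nuclear contig (either strand).
#'
#' @param alignments output of [map_reads_mito()].
#' @param reads the read set (data.frame or named character vector).
#' @param nuclear nuclear contigs as a named character vector, DNAStringSet,
#'   or FASTA path; NULL/empty skips the screen (with a warning).
#' @param max_mismatch mismatch cap for nuclear hits.
#' @return character vector of retained read ids.
#' @export
screen_nuclear <- function(alignments, reads, nuclear, max_mismatch = 1) {
  reads <- as_read_df(reads)
  mapped_ids <- unique(alignments$read_id)
  if (is.null(nuclear) || length(nuclear) == 0) {
    warning("no nuclear contigs supplied; screen skipped, all reads retained")
    return(mapped_ids)
  }
  nuc <- if (inherits(nuclear, "DNAStringSet")) nuclear
         else if (is.character(nuclear) && length(nuclear) == 1 &&
                  file.exists(nuclear)) Biostrings::readDNAStringSet(nuclear)
         else Biostrings::DNAStringSet(norm_dna(nuclear))
  mapped <- reads[reads$id %in% mapped_ids, , drop = FALSE]
  useqs <- unique(mapped$seq)
  hit <- vapply(useqs, function(s) {
    fwd <- sum(Biostrings::vcountPattern(s, nuc, max.mismatch = max_mismatch,
                                         with.indels = FALSE, fixed = TRUE))
    if (fwd > 0) return(TRUE)
    sum(Biostrings::vcountPattern(rc_dna(s), nuc,
                                  max.mismatch = max_mismatch,
                                  with.indels = FALSE, fixed = TRUE)) > 0
  }, logical(1))
  bad_seqs <- useqs[hit]
  mapped$id[!(mapped$seq %in% bad_seqs)]
}

seq_identity <- function(a, b) {
  if (a == b) return(1)
  la <- nchar(a); lb <- nchar(b)
  n <- min(la, lb)
  av <- strsplit(substr(a, 1, n), "")[[1]]
  bv <- strsplit(substr(b, 1, n), "")[[1]]
  sum(av == bv) / max(la, lb)
}

#' Cluster retained reads by abundance
#'
#' Greedy abundance-ordered clustering per strand: unique sequences are sorted
#' by descending read count; each joins the first existing cluster whose
#' centroid identity is at least `identity`, else founds a new cluster. At
#' the default identity 0.99 and typical small RNA lengths this amounts to
#' sequence equality. Identity between unequal-length sequences is matches at
#' aligned 5' ends divided by the longer length.
#'
#' @param alignments alignments of retained reads ([map_reads_mito()] rows).
#' @param identity minimum centroid identity (default 0.99).
#' @return data.frame with one row per cluster-locus: `cluster_id`,
#'   `centroid`, `size` (reads, counted once per locus), `start`, `end`,
#'   `strand`, `multimap`, plus a `members` list-column of member alignment
#'   tables (columns seq, start, end, n_mismatch, n_reads).
#' @export
cluster_reads <- function(alignments, identity = 0.99) {
  empty <- data.frame(cluster_id = character(0), centroid = character(0),
                      size = integer(0), start = integer(0), end = integer(0),
                      strand = character(0), multimap = logical(0),
                      stringsAsFactors = FALSE)
  empty$members <- list()
  if (is.null(alignments) || nrow(alignments) == 0) return(empty)
  out <- list()
  for (str in c("+", "-")) {
    al <- alignments[alignments$strand == str, , drop = FALSE]
    if (nrow(al) == 0) next
    # read counts per unique sequence (each read id once per sequence)
    cnt <- tapply(al$read_id, al$seq, function(x) length(unique(x)))
    useq <- names(sort(cnt, decreasing = TRUE))
    ord <- order(-cnt[useq], useq)   # deterministic tie-break
    useq <- useq[ord]
    centroids <- character(0)
    membership <- integer(0)
    for (s in useq) {
      placed <- FALSE
      for (ci in seq_along(centroids)) {
        if (seq_identity(centroids[ci], s) >= identity) {
          membership <- c(membership, ci); placed <- TRUE; break
        }
      }
      if (!placed) {
        centroids <- c(centroids, s)
        membership <- c(membership, length(centroids))
      }
    }
    names(membership) <- useq
    for (ci in seq_along(centroids)) {
      cen <- centroids[ci]
      member_seqs <- useq[membership == ci]
      cen_al <- al[al$seq == cen, , drop = FALSE]
      cen_loci <- unique(cen_al[, c("start", "end")])
      for (li in seq_len(nrow(cen_loci))) {
        lstart <- cen_loci$start[li]; lend <- cen_loci$end[li]
        mal <- al[al$seq %in% member_seqs, , drop = FALSE]
        # keep member alignments at/overlapping this centroid locus
        ov <- overlaps_locus(mal$start, mal$end, lstart, lend)
        mal <- mal[ov, , drop = FALSE]
        msum <- stats::aggregate(
          list(n_reads = mal$read_id),
          by = list(seq = mal$seq, start = mal$start, end = mal$end,
                    n_mismatch = mal$n_mismatch),
          FUN = function(x) length(unique(x)))
        size <- length(unique(mal$read_id))
        row <- data.frame(
          cluster_id = sprintf("c%s_%d_%d", str, lstart, lend),
          centroid = cen, size = as.integer(size),
          start = lstart, end = lend, strand = str,
          multimap = nrow(cen_loci) > 1 || any(cen_al$multimap),
          stringsAsFactors = FALSE)
        row$members <- list(msum)
        out[[length(out) + 1]] <- row
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$start, res$strand), , drop = FALSE]
}

# interval overlap on possibly-wrapping alignments; member sequences of a
# cluster share near-identical coordinates, so this only needs to be right
# in the neighbourhood of the centroid locus
overlaps_locus <- function(qs, qe, ls, le) {
  qwrap <- qe < qs
  if (le >= ls) {
    (!qwrap & qs <= le & qe >= ls) | (qwrap & (qs <= le | qe >= ls))
  } else {
    qwrap | qs >= ls | qe <= le | qs <= le
  }
}

#' Per-position 5'/3' end profile
#'
#' On the plus strand the 5' end is the alignment start and the 3' end the
#' alignment end; on the minus strand the 5' end is the higher genomic
#' coordinate. Counts accumulate per position per strand, one count per
#' alignment row.
#'
#' @param alignments [map_reads_mito()] output.
#' @param genome a [circular_genome()].
#' @return object of class `end_profile`: list with `plus` and `minus`, each
#'   holding integer vectors `five` and `three` of length `genome$length`.
#' @export
end_profile <- function(alignments, genome) {
  L <- genome$length
  prof <- list(plus = list(five = integer(L), three = integer(L)),
               minus = list(five = integer(L), three = integer(L)),
               length = L)
  for (str in c("+", "-")) {
    al <- alignments[alignments$strand == str, , drop = FALSE]
    if (nrow(al) == 0) next
    five <- if (str == "+") al$start else al$end
    three <- if (str == "+") al$end else al$start
    key <- if (str == "+") "plus" else "minus"
    tf <- table(five); tt <- table(three)
    prof[[key]]$five[as.integer(names(tf))] <- as.integer(tf)
    prof[[key]]$three[as.integer(names(tt))] <- as.integer(tt)
  }
  structure(prof, class = "end_profile")
}

modal_fraction <- function(pos, w) {
  tot <- sum(w)
  agg <- tapply(w, pos, sum)
  i <- which.max(agg)
  list(pos = as.integer(names(agg)[i]), frac = as.numeric(agg[i]) / tot)
}

#' End-sharpness of read clusters
#'
#' For each cluster, computes over its member reads the fraction sharing the
#' modal 5' end and the fraction sharing the modal 3' end; a cluster passes
#' when both fractions reach their thresholds (inclusive). Raw fractions are
#' reported so users can re-threshold.
#'
#' @param clusters [cluster_reads()] output.
#' @param min_frac5,min_frac3 modal-end fraction thresholds (default 0.75).
#' @return `clusters` with added columns mode5, frac5, mode3, frac3,
#'   sharp_pass.
#' @export
sharpness_filter <- function(clusters, min_frac5 = 0.75, min_frac3 = 0.75) {
  n <- nrow(clusters)
  mode5 <- mode3 <- integer(n)
  frac5 <- frac3 <- numeric(n)
  for (i in seq_len(n)) {
    m <- clusters$members[[i]]
    if (is.null(m) || nrow(m) == 0) stop("cluster with no members")
    if (clusters$strand[i] == "+") {
      f <- modal_fraction(m$start, m$n_reads)
      t <- modal_fraction(m$end, m$n_reads)
    } else {
      f <- modal_fraction(m$end, m$n_reads)
      t <- modal_fraction(m$start, m$n_reads)
    }
    mode5[i] <- f$pos; frac5[i] <- f$frac
    mode3[i] <- t$pos; frac3[i] <- t$frac
  }
  clusters$mode5 <- mode5; clusters$frac5 <- frac5
  clusters$mode3 <- mode3; clusters$frac3 <- frac3
  clusters$sharp_pass <- frac5 >= min_frac5 & frac3 >= min_frac3
  clusters
}

#' Cluster size filter
#'
#' Retains clusters with size strictly greater than `min_size` ("a cluster
#' size greater than 200"); size 200 is dropped at the default.
#'
#' @param clusters [cluster_reads()] output.
#' @param min_size threshold (default 200; the relaxed mouse analysis used 50).
#' @return the surviving cluster rows.
#' @export
size_filter <- function(clusters, min_size = 200) {
  clusters[clusters$size > min_size, , drop = FALSE]
}

#' Write per-strand 5'/3'/total end coverage as bedGraph
#'
#' @param profile an [end_profile()].
#' @param dir output directory.
#' @param prefix file name prefix.
#' @param genome_id sequence name for the bedGraph rows.
#' @return paths of the files written.
#' @export
write_end_bedgraph <- function(profile, dir, prefix = "coverage",
                               genome_id = "genome") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (str in c("plus", "minus")) {
    for (kind in c("five", "three")) {
      v <- profile[[str]][[kind]]
      nz <- which(v > 0)
      df <- data.frame(chrom = genome_id, start = nz - 1L, end = nz,
                       value = v[nz])
      p <- file.path(dir, sprintf("%s_%s_%s.bedGraph", prefix, str, kind))
      write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Write the cluster table as TSV
#'
#' @param clusters cluster table (after [sharpness_filter()] for the
#'   sharpness columns).
#' @param path output TSV.
#' @export
write_cluster_tsv <- function(clusters, path) {
  cols <- setdiff(names(clusters), "members")
  write.table(clusters[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
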