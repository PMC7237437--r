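# Synthetic-data generators. Every generator is a deterministic function of
# its seed and parameters and returns its ground truth alongside the data, so
# each pipeline stage can be scored for sensitivity and specificity offline.

OTHER_BASES <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                    G = c("A", "C", "T"), T = c("A", "C", "G"))

random_dna <- function(n) {
  paste(sample(VALID_BASES, n, replace = TRUE), collapse = "")
}

default_gene_plan <- function() {
  pcg <- data.frame(
    name = c("cox1", "cox2", "cox3", "cob", "nad1", "nad2", "nad3", "nad4",
             "nad4l", "nad5", "nad6", "atp6", "atp8"),
    ftype = "PCG",
    length = c(1540L, 690L, 780L, 1140L, 930L, 980L, 350L, 1330L, 290L,
               1700L, 500L, 700L, 160L),
    stringsAsFactors = FALSE)
  rrna <- data.frame(name = c("rrnL", "rrnS"), ftype = "rRNA",
                     length = c(1250L, 950L), stringsAsFactors = FALSE)
  trna <- data.frame(name = paste0("trn", LETTERS[1:22]), ftype = "tRNA",
                     length = rep(66L, 22), stringsAsFactors = FALSE)
  rbind(pcg, rrna, trna)
}

#' Simulate an annotated circular mitochondrial genome
#'
#' Random sequence with non-overlapping protein-coding, rRNA and tRNA genes
#' on both strands separated by unassigned regions (URs are deliberately
#' abundant, bivalve-style), plus optionally planted smithRNA loci (with
#' their 70-bp pre-regions) overlaid on rRNA, tRNA and UR hosts in turn.
#'
#' @param seed RNG seed; same seed, same genome.
#' @param length genome length in bp (default 16500).
#' @param gene_plan data.frame(name, ftype, length); NULL uses a 13-PCG /
#'   2-rRNA / 22-tRNA metazoan-style plan totalling ~14.7 kb.
#' @param n_smith number of smithRNA loci to overlay (default 0).
#' @param smith_length mature smithRNA length (default 22 nt).
#' @param pre_length pre-region length for the overlays (default 70).
#' @return list(genome, annotation (re-annotated, smith features overlaid),
#'   truth = list(plan, smith)).
#' @export
simulate_genome <- function(seed = 1, length = 16500, gene_plan = NULL,
                            n_smith = 0, smith_length = 22, pre_length = 70) {
  set.seed(seed)
  plan <- if (is.null(gene_plan)) default_gene_plan() else gene_plan
  total_genes <- sum(plan$length)
  if (total_genes > length)
    stop("gene plan (", total_genes, " bp) exceeds genome length (", length,
         " bp)")
  n <- nrow(plan)
  plan <- plan[sample.int(n), , drop = FALSE]
  plan$strand <- sample(c("+", "-"), n, replace = TRUE, prob = c(0.8, 0.2))
  slack <- length - total_genes
  # split the UR budget over the n inter-gene gaps
  w <- runif(n)
  gaps <- floor(slack * w / sum(w))
  gaps[1] <- gaps[1] + (slack - sum(gaps))
  pos <- 1L
  feats <- list()
  for (i in seq_len(n)) {
    pos <- pos + gaps[i]
    feats[[i]] <- genome_feature(plan$name[i], plan$ftype[i], pos,
                                 pos + plan$length[i] - 1L, plan$strand[i])
    pos <- pos + plan$length[i]
  }
  feats <- do.call(rbind, feats)
  genome <- circular_genome(sprintf("synthetic_mt_seed%d", seed),
                            random_dna(length))
  ann <- reannotate_urs(annotation_set(genome$id, feats, length = length),
                        genome)
  smith <- NULL
  if (n_smith > 0) {
    host_cycle <- rep(c("rRNA", "tRNA", "UR"), length.out = n_smith)
    f <- ann$features
    used <- character(0)
    rows <- list()
    for (i in seq_len(n_smith)) {
      cand <- f[f$ftype == host_cycle[i] & f$end >= f$start &
                  (f$end - f$start + 1L) >= smith_length + 2L &
                  !(f$name %in% used), , drop = FALSE]
      if (nrow(cand) == 0)
        stop("no ", host_cycle[i], " host long enough for a smithRNA overlay")
      h <- cand[sample.int(nrow(cand), 1), ]
      used <- c(used, h$name)
      maxoff <- (h$end - h$start + 1L) - smith_length
      s <- h$start + sample.int(maxoff + 1L, 1) - 1L
      e <- s + smith_length - 1L
      strand <- h$strand
      category <- c(rRNA = "r", tRNA = "t", UR = "nc")[[host_cycle[i]]]
      rows[[i]] <- data.frame(name = sprintf("smith%d", i), start = s,
                              end = e, strand = strand, host = h$name,
                              category = category, stringsAsFactors = FALSE)
    }
    smith <- do.call(rbind, rows)
    flank <- pre_length - smith_length
    left <- ceiling(flank / 2); right <- floor(flank / 2)
    overlay <- rbind(
      data.frame(name = smith$name, ftype = "smithRNA", start = smith$start,
                 end = smith$end, strand = smith$strand,
                 stringsAsFactors = FALSE),
      data.frame(name = paste0(smith$name, "_pre"), ftype = "pre_smithRNA",
                 start = (smith$start - left - 1L) %% length + 1L,
                 end = (smith$end + right - 1L) %% length + 1L,
                 strand = smith$strand, stringsAsFactors = FALSE))
    ann <- annotation_set(genome$id, rbind(ann$features, overlay),
                          length = length, reannotated = TRUE)
  }
  list(genome = genome, annotation = ann,
       truth = list(plan = plan, smith = smith))
}

# per-site region label over a linear slice, honouring REGION_PRECEDENCE
site_labels <- function(annotation, slice_start, slice_end) {
  L <- annotation$length
  n <- slice_end - slice_start + 1L
  lab <- rep(NA_character_, n)
  feats <- annotation$features
  for (ft in rev(REGION_PRECEDENCE)) {
    sub <- feats[feats$ftype == ft, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      arcs <- feature_arcs(sub$start[i], sub$end[i], L)
      for (a in seq_len(nrow(arcs))) {
        s <- max(arcs[a, 1], slice_start); e <- min(arcs[a, 2], slice_end)
        if (s <= e) lab[(s:e) - slice_start + 1L] <- ft
      }
    }
  }
  if (anyNA(lab)) stop("slice positions not covered; re-annotate URs first")
  lab
}

#' Simulate a population alignment with region-dependent diversity
#'
#' Each sequence independently accumulates single-nucleotide substitutions at
#' per-site rate mu x multiplier(region of the site) (Jukes-Cantor-like
#' uniform choice among the three alternative bases, no indels). Unassigned
#' regions default to a 5-fold elevated rate, emulating relaxed selection.
#'
#' @param genome a [circular_genome()].
#' @param annotation a re-annotated [annotation_set()] (smithRNA and
#'   pre_smithRNA overlays allowed).
#' @param n_seqs number of sequences (default 42, as a gonad amplicon panel).
#' @param mu base per-site substitution rate (default 0.005; must be < 0.05).
#' @param multipliers named multipliers per region type.
#' @param region optional c(start, end) linear slice (defaults to the whole
#'   genome unrolled from position 1).
#' @param seed RNG seed.
#' @return list(alignment = named character vector, labels = per-site region
#'   labels, partition = feature data.frame on alignment coordinates,
#'   truth = list(mu, multipliers, rates)).
#' @export
simulate_population <- function(genome, annotation, n_seqs = 42, mu = 0.005,
                                multipliers = c(PCG = 1, rRNA = 1, tRNA = 1,
                                                smithRNA = 1,
                                                pre_smithRNA = 1, UR = 5),
                                region = NULL, seed = 1) {
  stopifnot(mu < 0.05)
  set.seed(seed)
  if (is.null(region)) region <- c(1L, genome$length)
  slice <- substr(genome$sequence, region[1], region[2])
  labels <- site_labels(annotation, region[1], region[2])
  rates <- mu * unname(multipliers[labels])
  if (anyNA(rates)) stop("multipliers missing for some region type")
  refv <- strsplit(slice, "")[[1]]
  n_sites <- length(refv)
  rows <- character(n_seqs)
  for (s in seq_len(n_seqs)) {
    v <- refv
    hit <- which(runif(n_sites) < rates)
    if (length(hit)) {
      pick <- sample.int(3L, length(hit), replace = TRUE)
      v[hit] <- vapply(seq_along(hit),
                       function(k) OTHER_BASES[[v[hit[k]]]][pick[k]],
                       character(1))
    }
    rows[s] <- paste(v, collapse = "")
  }
  names(rows) <- sprintf("seq%02d", seq_len(n_seqs))
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  partition <- data.frame(
    name = paste0(r$values, "_", seq_along(r$values)), ftype = r$values,
    start = ends - r$lengths + 1L, end = ends, strand = "+",
    stringsAsFactors = FALSE)
  list(alignment = rows, labels = labels, partition = partition,
       truth = list(mu = mu, multipliers = multipliers, rates = rates))
}

#' Simulate a small RNA library with planted sharp loci
#'
#' Each planted locus emits `depth` reads on its strand with 5'/3' ends
#' jittered uniformly within `end_noise` bp; uniform background reads
#' (15-40 nt, both strands) are added on top.
#'
#' @param genome a [circular_genome()].
#' @param annotation re-annotated [annotation_set()]; required when `loci` is
#'   NULL so hosts can be chosen per category.
#' @param loci data.frame(start, end, strand) of planted loci, or NULL to
#'   place `n_loci` of length `locus_length` cycling over rRNA/tRNA/UR hosts.
#' @param n_loci number of loci to place when `loci` is NULL (default 3).
#' @param locus_length mature locus length (default 22 nt).
#' @param depth reads per planted locus (default 250).
#' @param end_noise maximum end jitter in bp (default 0: perfectly sharp).
#' @param n_background uniform background reads (default 300).
#' @param bg_len_range background read length range (default 15-40 nt).
#' @param seed RNG seed.
#' @return list(reads = data.frame(id, seq), truth = loci data.frame with
#'   category and the 5' coordinate used for naming).
#' @export
simulate_reads <- function(genome, annotation = NULL, loci = NULL,
                           n_loci = 3, locus_length = 22, depth = 250,
                           end_noise = 0, n_background = 300,
                           bg_len_range = c(15, 40), seed = 1) {
  set.seed(seed)
  L <- genome$length
  if (is.null(loci)) {
    if (n_loci > 0 && is.null(annotation))
      stop("annotation required to place loci by category")
    rows <- list()
    if (n_loci > 0) {
      host_cycle <- rep(c("rRNA", "tRNA", "UR"), length.out = n_loci)
      f <- annotation$features
      used <- character(0)
      for (i in seq_len(n_loci)) {
        cand <- f[f$ftype == host_cycle[i] & f$end >= f$start &
                    (f$end - f$start + 1L) >= locus_length + 2L &
                    !(f$name %in% used), , drop = FALSE]
        if (nrow(cand) == 0)
          stop("no ", host_cycle[i], " host long enough for a planted locus")
        h <- cand[sample.int(nrow(cand), 1), ]
        used <- c(used, h$name)
        maxoff <- (h$end - h$start + 1L) - locus_length
        s <- h$start + sample.int(maxoff + 1L, 1) - 1L
        rows[[i]] <- data.frame(start = s, end = s + locus_length - 1L,
                                strand = sample(c("+", "-"), 1),
                                stringsAsFactors = FALSE)
      }
    }
    loci <- if (length(rows)) do.call(rbind, rows) else
      data.frame(start = integer(0), end = integer(0), strand = character(0))
  }
  reads <- list()
  for (i in seq_len(nrow(loci))) {
    s0 <- loci$start[i]; e0 <- loci$end[i]; str <- loci$strand[i]
    for (d in seq_len(depth)) {
      j1 <- if (end_noise > 0) sample(-end_noise:end_noise, 1) else 0L
      j2 <- if (end_noise > 0) sample(-end_noise:end_noise, 1) else 0L
      s <- (s0 + j1 - 1L) %% L + 1L
      e <- (e0 + j2 - 1L) %% L + 1L
      reads[[length(reads) + 1]] <- data.frame(
        id = sprintf("locus%d_read%d", i, d),
        seq = circular_subseq(genome, s, e, str), stringsAsFactors = FALSE)
    }
  }
  for (b in seq_len(n_background)) {
    len <- sample(bg_len_range[1]:bg_len_range[2], 1)
    s <- sample.int(L, 1)
    e <- (s + len - 2L) %% L + 1L
    reads[[length(reads) + 1]] <- data.frame(
      id = sprintf("bg_read%d", b),
      seq = circular_subseq(genome, s, e, sample(c("+", "-"), 1)),
      stringsAsFactors = FALSE)
  }
  reads <- if (length(reads)) do.call(rbind, reads) else
    data.frame(id = character(0), seq = character(0))
  truth <- loci
  if (nrow(truth)) {
    truth$five_prime <- ifelse(truth$strand == "+", truth$start, truth$end)
    if (!is.null(annotation)) {
      truth$category <- vapply(seq_len(nrow(truth)), function(i)
        locus_category(annotation, truth$start[i], truth$end[i]),
        character(1))
    }
    truth$sequence <- vapply(seq_len(nrow(truth)), function(i)
      circular_subseq(genome, truth$start[i], truth$end[i], truth$strand[i]),
      character(1))
  }
  list(reads = reads, truth = truth)
}

#' Simulate a 3' UTR collection with planted target sites
#'
#' Random UTRs; for each plant, either the full reverse complement of the
#' candidate (type "perfect") or only the reverse complement of its seed
#' (centroid nt 4-10; type "seed_only") is written into a randomly chosen
#' UTR at a random position (overwriting, so lengths are preserved).
#'
#' @param n_utrs number of UTRs (default 50).
#' @param len_range UTR length range (default 300-800 nt).
#' @param plants data.frame(candidate, type) with type in
#'   "perfect"/"seed_only", or NULL for no plants.
#' @param seed RNG seed.
#' @param seed_start,seed_end seed definition on the candidate (default 4-10).
#' @return list(utrs = named character vector,
#'   truth = data.frame(utr_id, type, insert_start, insert_end)).
#' @export
simulate_utrome <- function(n_utrs = 50, len_range = c(300, 800),
                            plants = NULL, seed = 1,
                            seed_start = 4, seed_end = 10) {
  set.seed(seed)
  lens <- sample(len_range[1]:len_range[2], n_utrs, replace = TRUE)
  utrs <- vapply(lens, random_dna, character(1))
  names(utrs) <- sprintf("utr%03d", seq_len(n_utrs))
  truth <- data.frame(utr_id = character(0), type = character(0),
                      insert_start = integer(0), insert_end = integer(0),
                      stringsAsFactors = FALSE)
  if (!is.null(plants) && nrow(plants) > 0) {
    if (nrow(plants) > n_utrs) stop("more plants than UTRs")
    targets <- sample(names(utrs), nrow(plants))
    for (i in seq_len(nrow(plants))) {
      cand <- norm_dna(plants$candidate[i])
      insert <- switch(plants$type[i],
        perfect = rc_dna(cand),
        seed_only = rc_dna(substr(cand, seed_start, seed_end)),
        none = NULL,
        stop("unknown plant type: ", plants$type[i]))
      if (is.null(insert)) next
      uid <- targets[i]
      ulen <- nchar(utrs[[uid]])
      if (nchar(insert) > ulen) stop("UTR too short for the plant")
      p <- sample.int(ulen - nchar(insert) + 1L, 1)
      substr(utrs[[uid]], p, p + nchar(insert) - 1L) <- insert
      truth <- rbind(truth, data.frame(
        utr_id = uid, type = plants$type[i], insert_start = p,
        insert_end = p + nchar(insert) - 1L, stringsAsFactors = FALSE))
    }
  }
  list(utrs = utrs, truth = truth)
}

#' Simulate a normalized assay measurement table
#'
#' measurement = baseline + group shift + sex effect (females) + Gaussian
#' noise; emulates normalized histone methylation/acetylation readouts.
#'
#' @param n_per_group specimens per group (single integer or named vector).
#' @param group_shifts named numeric shifts per treatment group.
#' @param sex_effect additive effect for female specimens.
#' @param noise_sd Gaussian noise standard deviation.
#' @param baseline grand baseline level.
#' @param timepoint hours post treatment recorded in the table.
#' @param seed RNG seed.
#' @return data.frame(specimen, group, sex, timepoint, measurement).
#' @export
simulate_assay <- function(n_per_group = 30,
                           group_shifts = c(treated = 0, control = 0,
                                            untreated = 0),
                           sex_effect = 0, noise_sd = 1, baseline = 10,
                           timepoint = 24, seed = 1) {
  set.seed(seed)
  groups <- names(group_shifts)
  n <- if (length(n_per_group) == 1)
    setNames(rep(n_per_group, length(groups)), groups)
  else n_per_group[groups]
  rows <- lapply(groups, function(gr) {
    ng <- n[[gr]]
    sex <- rep(c("F", "M"), length.out = ng)
    data.frame(
      specimen = sprintf("%s_%02d", gr, seq_len(ng)), group = gr, sex = sex,
      timepoint = timepoint,
      measurement = baseline + group_shifts[[gr]] +
        sex_effect * (sex == "F") + rnorm(ng, sd = noise_sd),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write reads as FASTQ
#'
#' @param reads data.frame(id, seq).
#' @param path output FASTQ.
#' @param quality_char constant quality character (default "I").
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  ss <- Biostrings::DNAStringSet(setNames(reads$seq, reads$id))
  q <- Biostrings::BStringSet(strrep(quality_char, nchar(reads$seq)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = q)
  invisible(path)
}
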