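# Candidate assembly: naming, pre-region extraction, context folding, and
# standard-format outputs for surviving clusters with surviving targets.

#' Name a smithRNA candidate
#'
#' `<species>_<sex>_smithRNA<number><category>` where number is the 100-based
#' position of the candidate's 5' genomic coordinate (floor(start/100)) and
#' category is r, t, or nc.
#'
#' @param species_tag 4-letter species tag (e.g. "DaRe").
#' @param sex_tag "F" or "M" (the gonad the library came from).
#' @param start 1-based 5' genomic coordinate of the mature candidate.
#' @param category "r", "t" or "nc".
#' @return the candidate name.
#' @examples
#' name_candidate("DrMe", "F", 13450, "r")  # "DrMe_F_smithRNA134r"
#' @export
name_candidate <- function(species_tag, sex_tag, start, category) {
  stopifnot(sex_tag %in% c("F", "M"), category %in% c("r", "t", "nc"))
  sprintf("%s_%s_smithRNA%d%s", species_tag, sex_tag, start %/% 100, category)
}

#' Extract the pre-smithRNA region of a candidate
#'
#' Default: the `pre_length`-bp window centered on the candidate
#' (left flank = ceiling((pre_length - len)/2), right flank = floor),
#' wrap-aware; the window may extend into adjacent features, which keeps the
#' candidate approximately central even at gene boundaries. For candidates in
#' a tRNA gene, the pre-region is instead the whole containing tRNA extended
#' through adjacent unassigned nucleotides up to the next gene features.
#'
#' @param start,end,strand candidate locus (1-based inclusive, wrap-aware).
#' @param annotation a re-annotated [annotation_set()].
#' @param genome the [circular_genome()].
#' @param pre_length default pre-region length (default 70 bp).
#' @param category optional pre-computed category; derived if NULL.
#' @return list(pre_start, pre_end, pre_sequence (strand-aware, DNA),
#'   category).
#' @export
extract_pre_region <- function(start, end, strand, annotation, genome,
                               pre_length = 70, category = NULL) {
  L <- genome$length
  len <- arc_length(start, end, L)
  if (pre_length < len)
    stop("pre_length (", pre_length, ") shorter than the candidate (", len,
         " bp)")
  if (is.null(category)) category <- locus_category(annotation, start, end)
  if (category == "t") {
    mid <- midpoint_position(start, end, L)
    feats <- annotation$features
    trna <- feats[feats$ftype == "tRNA", , drop = FALSE]
    host <- NULL
    for (i in seq_len(nrow(trna))) {
      if (arc_covers(trna$start[i], trna$end[i], L, mid)) {
        host <- trna[i, ]; break
      }
    }
    if (is.null(host)) stop("category t but no containing tRNA found")
    urmask <- coverage_mask(feats[feats$ftype == "UR", , drop = FALSE], L)
    ps <- host$start
    while (urmask[(ps - 2L) %% L + 1L]) ps <- (ps - 2L) %% L + 1L
    pe <- host$end
    while (urmask[pe %% L + 1L]) pe <- pe %% L + 1L
    pre_start <- ps; pre_end <- pe
  } else {
    flank <- pre_length - len
    left <- ceiling(flank / 2); right <- floor(flank / 2)
    pre_start <- (start - left - 1L) %% L + 1L
    e <- if (end >= start) end else end + L
    pre_end <- (e + right - 1L) %% L + 1L
  }
  list(pre_start = as.integer(pre_start), pre_end = as.integer(pre_end),
       pre_sequence = circular_subseq(genome, pre_start, pre_end, strand),
       category = category)
}

#' Assemble named smithRNA candidates
#'
#' Joins surviving clusters with their surviving target hits, categorizes
#' each locus, names it, extracts the pre-region and folds the genomic
#' context. Clusters whose midpoint falls in a protein-coding gene have no
#' r/t/nc category and are skipped (with a message), as are clusters with no
#' passing target.
#'
#' @param clusters cluster table after [size_filter()] and
#'   [sharpness_filter()] (rows failing `sharp_pass` are dropped).
#' @param hits data.frame of passing target hits carrying a `centroid`
#'   column.
#' @param annotation a re-annotated [annotation_set()].
#' @param genome the [circular_genome()].
#' @param species_tag,sex_tag naming tags.
#' @param pre_length pre-region length (default 70).
#' @param fold if TRUE (default), fold the pre-region context.
#' @param model an [energy_model()] for the fold.
#' @return data.frame of candidates with columns name, sequence (RNA),
#'   start, end, strand, category, cluster_size, frac5, frac3, n_targets,
#'   pre_start, pre_end, pre_sequence (RNA), fold; plus a `targets`
#'   list-column.
#' @export
assemble_candidates <- function(clusters, hits, annotation, genome,
                                species_tag = "SySp", sex_tag = "F",
                                pre_length = 70, fold = TRUE,
                                model = energy_model()) {
  if ("sharp_pass" %in% names(clusters))
    clusters <- clusters[clusters$sharp_pass, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(clusters))) {
    cl <- clusters[i, ]
    h <- hits[hits$centroid == cl$centroid & hits$pass, , drop = FALSE]
    if (nrow(h) == 0) next
    category <- locus_category(annotation, cl$start, cl$end)
    if (category == "pcg") {
      message("cluster at ", cl$start, "-", cl$end,
              " maps inside a protein-coding gene; not promoted")
      next
    }
    pre <- extract_pre_region(cl$start, cl$end, cl$strand, annotation,
                              genome, pre_length = pre_length,
                              category = category)
    five_prime <- if (cl$strand == "+") cl$start else cl$end
    row <- data.frame(
      name = name_candidate(species_tag, sex_tag, five_prime, category),
      sequence = dna_to_rna(circular_subseq(genome, cl$start, cl$end,
                                            cl$strand)),
      start = cl$start, end = cl$end, strand = cl$strand,
      category = category, cluster_size = cl$size,
      frac5 = cl$frac5, frac3 = cl$frac3,
      n_targets = nrow(h),
      pre_start = pre$pre_start, pre_end = pre$pre_end,
      pre_sequence = dna_to_rna(pre$pre_sequence),
      fold = if (fold) fold_context(pre$pre_sequence,
                                    model = model)$structure else NA_character_,
      stringsAsFactors = FALSE)
    row$targets <- list(h)
    rows[[length(rows) + 1]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    z <- data.frame(name = character(0), sequence = character(0),
                    start = integer(0), end = integer(0),
                    strand = character(0), category = character(0),
                    cluster_size = integer(0), frac5 = numeric(0),
                    frac3 = numeric(0), n_targets = integer(0),
                    pre_start = integer(0), pre_end = integer(0),
                    pre_sequence = character(0), fold = character(0),
                    stringsAsFactors = FALSE)
    z$targets <- list()
    z
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  # name collisions within the same 100-bp bucket get letter suffixes
  dup <- duplicated(out$name) | duplicated(out$name, fromLast = TRUE)
  if (any(dup)) {
    for (nm in unique(out$name[dup])) {
      idx <- which(out$name == nm)
      if (length(idx) > 1)
        out$name[idx[-1]] <- paste0(nm, letters[seq_along(idx[-1])])
    }
  }
  rownames(out) <- NULL
  out
}

#' Write candidate outputs (GFF3 + FASTA + TSV)
#'
#' @param candidates [assemble_candidates()] output.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @param genome the [circular_genome()] (for the GFF3 wrap convention).
#' @param bed12 also write a BED12 of the mature loci.
#' @return named character vector of the paths written.
#' @export
write_candidate_outputs <- function(candidates, dir, prefix = "smithrna",
                                    genome = NULL, bed12 = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gid <- if (is.null(genome)) "genome" else genome$id
  L <- if (is.null(genome)) NA_integer_ else genome$length
  n <- nrow(candidates)
  feats <- if (n == 0) NULL else rbind(
    data.frame(name = candidates$name, ftype = "smithRNA",
               start = candidates$start, end = candidates$end,
               strand = candidates$strand, stringsAsFactors = FALSE),
    data.frame(name = paste0(candidates$name, "_pre"), ftype = "pre_smithRNA",
               start = candidates$pre_start, end = candidates$pre_end,
               strand = candidates$strand, stringsAsFactors = FALSE))
  ann <- annotation_set(gid, feats, length = L)
  gff <- file.path(dir, paste0(prefix, ".gff3"))
  write_annotation_gff3(ann, gff)
  pre_names <- if (n == 0) character(0) else paste0(candidates$name, "_pre")
  fa_m <- file.path(dir, paste0(prefix, "_mature.fasta"))
  fa_p <- file.path(dir, paste0(prefix, "_pre.fasta"))
  write_fasta(setNames(as.character(candidates$sequence),
                       candidates$name), fa_m)
  write_fasta(setNames(as.character(candidates$pre_sequence), pre_names),
              fa_p)
  tsv <- file.path(dir, paste0(prefix, "_report.tsv"))
  flat <- candidates[, setdiff(names(candidates), "targets"), drop = FALSE]
  flat$target_utrs <- vapply(seq_len(n), function(i)
    paste(candidates$targets[[i]]$utr_id, collapse = ","), character(1))
  if (n == 0) flat$target_utrs <- character(0)
  write.table(flat, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(gff3 = gff, mature = fa_m, pre = fa_p, report = tsv)
  if (bed12 && n > 0) {
    bed <- file.path(dir, paste0(prefix, ".bed12"))
    sz <- mapply(arc_length, candidates$start, candidates$end,
                 MoreArgs = list(L = if (is.na(L)) .Machine$integer.max else L))
    df <- data.frame(chrom = gid, start = candidates$start - 1L,
                     end = candidates$start - 1L + sz,
                     name = candidates$name, score = 0,
                     strand = candidates$strand,
                     thickStart = candidates$start - 1L,
                     thickEnd = candidates$start - 1L + sz,
                     rgb = "0,0,0", blocks = 1L, sizes = paste0(sz, ","),
                     starts = "0,")
    write.table(df, bed, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    paths <- c(paths, bed12 = bed)
  }
  invisible(paths)
}
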