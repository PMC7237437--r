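# Circular mitochondrial genome model: sequence, features, unassigned-region
# re-annotation, and locus categorization. Coordinates are 1-based inclusive;
# a feature with end < start wraps the origin of a circular genome.

REGION_TYPES <- c("PCG", "rRNA", "tRNA", "UR", "smithRNA", "pre_smithRNA")
GENE_TYPES <- c("PCG", "rRNA", "tRNA")

norm_dna <- function(x) {
  x <- chartr("u", "t", tolower(x))
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) stop("sequence contains characters outside {A,C,G,T,U,N}")
  x
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
rc_dna <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert between DNA and RNA alphabets
#'
#' Internally all sequences are stored with T; candidate smithRNA sequences
#' are emitted with U.
#'
#' @param x character vector.
#' @return character vector in the other alphabet.
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

#' Construct a circular genome
#'
#' @param id text label for the molecule.
#' @param sequence nucleotide text; U is normalized to T, N is tolerated.
#' @param circular logical; mitochondrial genomes are normally circular.
#' @return an object of class `circular_genome` with fields `id`, `sequence`,
#'   `length`, `circular`.
#' @export
circular_genome <- function(id, sequence, circular = TRUE) {
  sequence <- norm_dna(sequence)
  structure(
    list(id = id, sequence = sequence, length = nchar(sequence),
         circular = isTRUE(circular)),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %d bp%s\n", x$id, x$length,
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' Construct one genome feature
#'
#' @param name feature name.
#' @param ftype one of PCG, rRNA, tRNA, UR, smithRNA, pre_smithRNA.
#' @param start,end 1-based inclusive coordinates; `end < start` denotes a
#'   feature wrapping the origin.
#' @param strand "+" or "-".
#' @return a one-row data.frame.
#' @export
genome_feature <- function(name, ftype, start, end, strand = "+") {
  ftype <- match.arg(ftype, REGION_TYPES)
  stopifnot(start >= 1, end >= 1, strand %in% c("+", "-"))
  data.frame(name = name, ftype = ftype, start = as.integer(start),
             end = as.integer(end), strand = strand,
             stringsAsFactors = FALSE)
}

#' Construct an annotation set
#'
#' @param genome_id id of the annotated genome.
#' @param features data.frame with columns name, ftype, start, end, strand.
#' @param length genome length in bp (needed for wrap-aware arithmetic).
#' @param reannotated logical; TRUE once URs cover all inter-genic space.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(genome_id, features, length = NA_integer_,
                           reannotated = FALSE) {
  if (is.null(features) || nrow(features) == 0) {
    features <- data.frame(name = character(0), ftype = character(0),
                           start = integer(0), end = integer(0),
                           strand = character(0), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "ftype", "start", "end", "strand") %in%
                  names(features)))
  if (!all(features$ftype %in% REGION_TYPES))
    stop("unknown feature type(s): ",
         paste(setdiff(features$ftype, REGION_TYPES), collapse = ", "))
  if (!is.na(length) && any(features$start > length | features$start < 1))
    stop("feature start outside [1, genome length]")
  structure(
    list(genome_id = genome_id,
         features = features[, c("name", "ftype", "start", "end", "strand")],
         length = as.integer(length)),
    class = "annotation_set", reannotated = isTRUE(reannotated)
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %s: %d features%s\n", x$genome_id,
              nrow(x$features),
              if (isTRUE(attr(x, "reannotated"))) " (URs re-annotated)" else ""))
  print(table(x$features$ftype))
  invisible(x)
}

# A wrap feature (end < start) expands to two linear arcs.
feature_arcs <- function(start, end, L) {
  if (end >= start) {
    matrix(c(start, end), nrow = 1)
  } else {
    rbind(c(start, L), c(1L, end))
  }
}

arc_length <- function(start, end, L) {
  if (end >= start) end - start + 1L else (L - start + 1L) + end
}

arc_covers <- function(start, end, L, pos) {
  arcs <- feature_arcs(start, end, L)
  any(pos >= arcs[, 1] & pos <= arcs[, 2])
}

# Midpoint of a possibly wrapping interval, computed on the unrolled arc.
midpoint_position <- function(start, end, L) {
  e <- if (end >= start) end else end + L
  ((start + e) %/% 2 - 1L) %% L + 1L
}

coverage_mask <- function(features, L) {
  mask <- logical(L)
  for (i in seq_len(nrow(features))) {
    arcs <- feature_arcs(features$start[i], features$end[i], L)
    for (a in seq_len(nrow(arcs))) mask[arcs[a, 1]:arcs[a, 2]] <- TRUE
  }
  mask
}

#' Wrap-aware subsequence of a circular genome
#'
#' @param genome a [circular_genome()].
#' @param start,end 1-based inclusive positions; `end < start` requests a
#'   subsequence wrapping the origin (circular genomes only).
#' @param strand "+" for the forward sequence, "-" for its reverse complement.
#' @return nucleotide text.
#' @examples
#' g <- circular_genome("m", "ACGTACGT")
#' circular_subseq(g, 7, 2, "+")  # "GTAC"
#' @export
circular_subseq <- function(genome, start, end, strand = "+") {
  stopifnot(inherits(genome, "circular_genome"), strand %in% c("+", "-"))
  L <- genome$length
  if (start < 1 || start > L || end < 1 || end > L)
    stop("positions out of range [1, ", L, "]")
  if (end < start && !genome$circular)
    stop("wrap-around subsequence requested on a non-circular genome")
  arcs <- feature_arcs(start, end, L)
  s <- paste0(vapply(seq_len(nrow(arcs)), function(a)
    substr(genome$sequence, arcs[a, 1], arcs[a, 2]), character(1)),
    collapse = "")
  if (strand == "-") rc_dna(s) else s
}

#' Re-annotate unassigned regions (URs)
#'
#' Adds UR features covering exactly the maximal genomic intervals not covered
#' by any PCG/rRNA/tRNA feature. smithRNA and pre_smithRNA features are
#' overlaid and do not mask URs. Existing UR features are replaced, so the
#' operation is idempotent.
#'
#' @param annotation an [annotation_set()] holding the gene features.
#' @param genome the [circular_genome()] being annotated.
#' @return the annotation with URs appended and the re-annotated flag set.
#' @export
reannotate_urs <- function(annotation, genome) {
  stopifnot(inherits(annotation, "annotation_set"),
            inherits(genome, "circular_genome"))
  L <- genome$length
  feats <- annotation$features
  feats <- feats[feats$ftype != "UR", , drop = FALSE]
  genes <- feats[feats$ftype %in% GENE_TYPES, , drop = FALSE]
  if (nrow(genes) > 0) {
    lens <- mapply(arc_length, genes$start, genes$end, MoreArgs = list(L = L))
    if (sum(lens) > L ||
        sum(coverage_mask(genes, L)) < sum(pmin(lens, L))) {
      warning("overlapping gene features; URs computed on the union")
    }
  }
  if (nrow(genes) == 0) {
    urs <- data.frame(name = "UR1", ftype = "UR", start = 1L, end = L,
                      strand = "+", stringsAsFactors = FALSE)
  } else {
    mask <- coverage_mask(genes, L)
    if (all(mask)) {
      urs <- genes[0, , drop = FALSE]
    } else {
      r <- rle(mask)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      gap <- !r$values
      gs <- starts[gap]; ge <- ends[gap]
      # merge the run touching L with the run starting at 1 into one wrap UR
      if (genome$circular && length(gs) > 1 &&
          gs[1] == 1L && ge[length(ge)] == L) {
        gs <- c(gs[-1]); ge[length(ge)] <- ge[1]; ge <- ge[-1]
      } else if (genome$circular && length(gs) == 1 &&
                 gs[1] == 1L && ge[1] == L && nrow(genes) > 0) {
        # genes exist but cover nothing is impossible; keep as-is
      }
      urs <- data.frame(name = paste0("UR", seq_along(gs)), ftype = "UR",
                        start = as.integer(gs), end = as.integer(ge),
                        strand = "+", stringsAsFactors = FALSE)
    }
  }
  out <- rbind(feats, urs)
  annotation_set(annotation$genome_id, out, length = L, reannotated = TRUE)
}

#' Categorize a genomic interval as r / t / nc
#'
#' The interval's midpoint (computed on the unrolled arc for wrapping
#' intervals) decides the category: `r` inside an rRNA gene, `t` inside a
#' tRNA gene, `nc` inside a UR. Intervals whose midpoint falls in a
#' protein-coding gene get the internal label `pcg`; such clusters are
#' reported but not promoted to named candidates.
#'
#' @param annotation a re-annotated [annotation_set()].
#' @param start,end interval coordinates (1-based inclusive, wrap-aware).
#' @param strand unused; categories are positional.
#' @return one of "r", "t", "nc", "pcg".
#' @export
locus_category <- function(annotation, start, end, strand = NULL) {
  stopifnot(inherits(annotation, "annotation_set"))
  if (!isTRUE(attr(annotation, "reannotated")))
    stop("annotation must be re-annotated (run reannotate_urs) first")
  L <- annotation$length
  if (is.na(L)) stop("annotation has no genome length")
  mid <- midpoint_position(start, end, L)
  feats <- annotation$features
  for (ft in c("rRNA", "tRNA", "PCG", "UR")) {
    sub <- feats[feats$ftype == ft, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      if (arc_covers(sub$start[i], sub$end[i], L, mid)) {
        return(switch(ft, rRNA = "r", tRNA = "t", UR = "nc", PCG = "pcg"))
      }
    }
  }
  stop("midpoint ", mid, " covered by no feature; annotation incomplete")
}

#' Read a genome from FASTA
#'
#' @param path FASTA file; the first record is used.
#' @param id optional id override (defaults to the FASTA header word).
#' @param circular logical.
#' @return a [circular_genome()].
#' @export
read_genome_fasta <- function(path, id = NULL, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("no sequences in ", path)
  nm <- if (is.null(id)) strsplit(names(ss)[1], "\\s+")[[1]][1] else id
  circular_genome(nm, as.character(ss[[1]]), circular = circular)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write an annotation to GFF3
#'
#' Wrap-around features are serialized unrolled (end > genome length), the
#' usual circular-genome convention; [read_annotation_gff3()] undoes this when
#' the genome length is known.
#'
#' @param annotation an [annotation_set()].
#' @param path output file.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  f <- annotation$features
  L <- annotation$length
  end_out <- ifelse(!is.na(L) & f$end < f$start, f$end + L, f$end)
  if (nrow(f) == 0) {
    gr <- GenomicRanges::GRanges()
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = annotation$genome_id,
      ranges = IRanges::IRanges(start = f$start, end = end_out),
      strand = f$strand
    )
    gr$source <- "smithscan"
    gr$type <- f$ftype
    gr$ID <- f$name
    gr$Name <- f$name
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read an annotation from GFF3
#'
#' @param path GFF3 file whose `type` column holds the region type.
#' @param genome_length genome length; features with end beyond it are folded
#'   back into wrap-around (end < start) form.
#' @param genome_id optional id override.
#' @return an [annotation_set()]; flagged re-annotated when UR rows exist.
#' @export
read_annotation_gff3 <- function(path, genome_length = NA_integer_,
                                 genome_id = NULL) {
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g, stringsAsFactors = FALSE)
  if (nrow(g) == 0) {
    return(annotation_set(genome_id %||% "genome", NULL,
                          length = genome_length))
  }
  nm <- if ("ID" %in% names(g) && !all(is.na(g$ID))) as.character(g$ID)
        else if ("Name" %in% names(g)) as.character(g$Name)
        else paste0("feature", seq_len(nrow(g)))
  ftype <- as.character(g$type)
  if (!all(ftype %in% REGION_TYPES))
    stop("GFF3 contains unsupported feature types: ",
         paste(setdiff(ftype, REGION_TYPES), collapse = ", "))
  start <- as.integer(g$start); end <- as.integer(g$end)
  if (!is.na(genome_length)) {
    wrap <- end > genome_length
    end[wrap] <- end[wrap] - as.integer(genome_length)
  }
  feats <- data.frame(name = nm, ftype = ftype, start = start, end = end,
                      strand = ifelse(as.character(g$strand) == "-", "-", "+"),
                      stringsAsFactors = FALSE)
  annotation_set(genome_id %||% as.character(g$seqid[1]), feats,
                 length = genome_length,
                 reannotated = any(ftype == "UR"))
}

#' Read an annotation from BED
#'
#' Accepts 3- or 6-column BED (0-based half-open, converted to 1-based
#' inclusive). The region type is taken from an optional 7th column, else
#' inferred from the name prefix (trn -> tRNA, rrn -> rRNA, UR -> UR,
#' otherwise PCG).
#'
#' @param path BED file.
#' @param genome_id id for the annotation set.
#' @param genome_length optional genome length.
#' @return an [annotation_set()].
#' @export
read_annotation_bed <- function(path, genome_id = "genome",
                                genome_length = NA_integer_) {
  b <- read.table(path, sep = "\t", header = FALSE,
                  stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(b) < 3) stop("BED needs at least 3 columns")
  nm <- if (ncol(b) >= 4) as.character(b[[4]])
        else paste0("feature", seq_len(nrow(b)))
  strand <- if (ncol(b) >= 6) ifelse(b[[6]] == "-", "-", "+") else "+"
  ftype <- if (ncol(b) >= 7) as.character(b[[7]]) else {
    ifelse(grepl("^trn", nm, ignore.case = TRUE), "tRNA",
    ifelse(grepl("^rrn", nm, ignore.case = TRUE), "rRNA",
    ifelse(grepl("^UR", nm), "UR", "PCG")))
  }
  feats <- data.frame(name = nm, ftype = ftype,
                      start = as.integer(b[[2]]) + 1L,
                      end = as.integer(b[[3]]), strand = strand,
                      stringsAsFactors = FALSE)
  annotation_set(genome_id, feats, length = genome_length,
                 reannotated = any(ftype == "UR"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
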