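# Pipeline orchestration: a flat configuration object whose defaults are the
# published thresholds, a discovery runner (map -> screen -> cluster -> size
# filter -> sharpness -> target evaluation -> candidate annotation), and a
# conservation runner (windows -> labels -> Kruskal-Wallis + Dunn).

CONFIG_FIELDS <- c(
  "min_cluster_size", "min_frac5", "min_frac3", "identity", "max_mismatch",
  "seed_start", "seed_end", "forced_helix_start", "forced_helix_end",
  "min_matches", "max_ddG", "max_dG", "context", "flank5", "flank3",
  "fold_window", "window_size", "window_step", "pre_length",
  "fold_temperature", "species_tag", "sex_tag", "seed")

#' Pipeline configuration
#'
#' Defaults reproduce the published settings: cluster size > 200, seed =
#' centroid nt 4-10, >= 11 matches, ddG < -9, duplex dG < -20, 10-bp windows
#' with 5-bp steps, clustering identity 0.99, at most 1 mismatch, 70-bp
#' pre-regions, folding temperature 25. Every value can be overridden.
#'
#' @param ... named overrides of the default fields.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_cluster_size = 200, min_frac5 = 0.75, min_frac3 = 0.75,
    identity = 0.99, max_mismatch = 1,
    seed_start = 4, seed_end = 10,
    forced_helix_start = 3, forced_helix_end = 10,
    min_matches = 11, max_ddG = -9, max_dG = -20,
    context = 30, flank5 = 3, flank3 = 15, fold_window = 140,
    window_size = 10, window_step = 5,
    pre_length = 70, fold_temperature = 25,
    species_tag = "SySp", sex_tag = "F", seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Serialize / read a flat key=value configuration file
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `read_config` returns a [pipeline_config()] with file values
#'   layered over the defaults.
#' @export
write_config <- function(config, path) {
  lines <- vapply(CONFIG_FIELDS, function(k)
    sprintf("%s=%s", k, paste(config[[k]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  cfg <- pipeline_config()
  for (p in kv) {
    k <- trimws(p[1]); v <- trimws(p[2])
    if (!k %in% CONFIG_FIELDS) stop("unknown configuration key: ", k)
    num <- suppressWarnings(as.numeric(v))
    cfg[[k]] <- if (is.na(num)) v else num
  }
  cfg
}

load_input <- function(x, loader, what) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop("missing input file for ", what, ": ", x)
    return(loader(x))
  }
  x
}

#' Run the smithRNA discovery scan
#'
#' Executes map -> nuclear screen -> cluster -> size filter -> sharpness ->
#' target evaluation -> candidate annotation, and (optionally) writes the
#' standard outputs plus a manifest of configuration and per-stage counts.
#' The run is deterministic: rerunning with the same inputs and configuration
#' reproduces the output files byte for byte.
#'
#' @param reads data.frame(id, seq) or FASTQ path.
#' @param genome a [circular_genome()] or FASTA path.
#' @param annotation an [annotation_set()] or GFF3 path (re-annotated on the
#'   fly when URs are absent).
#' @param utrs named character vector of 3' UTRs or FASTA path.
#' @param nuclear optional nuclear decoy contigs (vector, DNAStringSet or
#'   FASTA path); NULL skips the screen with a warning.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param fold fold candidate contexts (default TRUE).
#' @return list(candidates, clusters, hits, alignments, profile, manifest).
#' @export
run_scan <- function(reads, genome, annotation, utrs, nuclear = NULL,
                     config = pipeline_config(), out_dir = NULL,
                     fold = TRUE) {
  genome <- load_input(genome, read_genome_fasta, "genome")
  reads <- load_input(reads, read_smallrna_fastq, "reads")
  annotation <- load_input(
    annotation, function(p) read_annotation_gff3(p, genome$length), "annotation")
  utrs <- load_input(utrs, function(p) {
    ss <- Biostrings::readDNAStringSet(p)
    setNames(as.character(ss),
             vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1))
  }, "UTRs")
  if (!isTRUE(attr(annotation, "reannotated")))
    annotation <- reannotate_urs(annotation, genome)
  model <- energy_model(temperature = config$fold_temperature)

  aln <- map_reads_mito(reads, genome, max_mismatch = config$max_mismatch)
  retained <- if (is.null(nuclear) || length(nuclear) == 0) {
    unique(aln$read_id)
  } else {
    screen_nuclear(aln, reads, nuclear, max_mismatch = config$max_mismatch)
  }
  aln2 <- aln[aln$read_id %in% retained, , drop = FALSE]
  profile <- end_profile(aln2, genome)
  clusters <- cluster_reads(aln2, identity = config$identity)
  surv <- size_filter(clusters, min_size = config$min_cluster_size)
  surv <- sharpness_filter(surv, min_frac5 = config$min_frac5,
                           min_frac3 = config$min_frac3)
  sharp <- surv[surv$sharp_pass, , drop = FALSE]
  hits <- lapply(unique(sharp$centroid), function(cen) {
    h <- evaluate_targets(
      cen, utrs, min_matches = config$min_matches, max_ddG = config$max_ddG,
      max_dG = config$max_dG, seed_start = config$seed_start,
      seed_end = config$seed_end,
      forced_helix = c(config$forced_helix_start, config$forced_helix_end),
      context = config$context, flank5 = config$flank5,
      flank3 = config$flank3, fold_window = config$fold_window,
      model = model)
    if (nrow(h)) cbind(data.frame(centroid = cen, stringsAsFactors = FALSE), h)
    else NULL
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits))
    hits <- cbind(data.frame(centroid = character(0)),
                  evaluate_targets("ACGTACGTACGT", character(0)))
  candidates <- assemble_candidates(
    sharp, hits, annotation, genome, species_tag = config$species_tag,
    sex_tag = config$sex_tag, pre_length = config$pre_length, fold = fold,
    model = model)

  manifest <- data.frame(
    key = c("package_version", "seed", "n_reads", "n_mapped_reads",
            "n_retained_reads", "n_clusters", "n_size_pass", "n_sharp_pass",
            "n_target_hits", "n_candidates",
            paste0("config.", CONFIG_FIELDS)),
    value = c(as.character(utils::packageVersion("smithscan")),
              config$seed, nrow(reads), length(unique(aln$read_id)),
              length(unique(aln2$read_id)), nrow(clusters),
              sum(clusters$size > config$min_cluster_size),
              nrow(sharp), nrow(hits), nrow(candidates),
              vapply(CONFIG_FIELDS, function(k)
                paste(config[[k]], collapse = ","), character(1))),
    stringsAsFactors = FALSE)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cluster_tsv(sharpness_filter(clusters,
                                       config$min_frac5, config$min_frac3),
                      file.path(out_dir, "clusters.tsv"))
    write_target_tsv(hits, file.path(out_dir, "target_hits.tsv"))
    write_candidate_outputs(candidates, out_dir, genome = genome)
    write_end_bedgraph(profile, out_dir, genome_id = genome$id)
    write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(candidates = candidates, clusters = clusters, hits = hits,
       alignments = aln2, profile = profile, manifest = manifest)
}

#' Run the locus conservation analysis
#'
#' Sliding-window nucleotide diversity, region labeling, Kruskal-Wallis
#' across the region types and two-tailed Dunn's test with Bonferroni
#' correction; optionally the same tests on an assay measurement table, plus
#' a one-tailed Mann-Whitney contrast between two assay groups.
#'
#' @param alignment named character vector (aligned FASTA path accepted).
#' @param partition feature data.frame / [annotation_set()] on alignment
#'   coordinates (region-table TSV path accepted).
#' @param config a [pipeline_config()] (window size/step, convention).
#' @param convention diversity convention, "printed" or "ordered".
#' @param assay optional assay data.frame (columns group, measurement).
#' @param assay_mw optional c(group_x, group_y) for a Mann-Whitney contrast.
#' @param assay_alternative alternative for the contrast (default "less").
#' @param out_dir optional output directory.
#' @return list(windows, kw, dunn, assay_kw, assay_dunn, assay_mw, manifest).
#' @export
run_diversity <- function(alignment, partition, config = pipeline_config(),
                          convention = "printed", assay = NULL,
                          assay_mw = NULL, assay_alternative = "less",
                          out_dir = NULL) {
  alignment <- load_input(alignment, read_alignment_fasta, "alignment")
  partition <- load_input(partition, read_region_table, "region table")
  windows <- sliding_window_diversity(alignment, size = config$window_size,
                                      step = config$window_step,
                                      convention = convention)
  windows <- assign_regions(windows, partition)
  if (length(unique(windows$region)) < 2)
    stop("only one region type (", unique(windows$region),
         ") present; the Kruskal-Wallis contrast needs at least two")
  groups <- split(windows$pi, windows$region)
  kw <- kruskal_wallis(groups)
  dunn <- dunn_test(groups)
  assay_kw <- assay_dunn <- assay_mw_res <- NULL
  if (!is.null(assay)) {
    ag <- split(assay$measurement, assay$group)
    assay_kw <- kruskal_wallis(ag)
    assay_dunn <- dunn_test(ag)
    if (!is.null(assay_mw)) {
      assay_mw_res <- mann_whitney(ag[[assay_mw[1]]], ag[[assay_mw[2]]],
                                   alternative = assay_alternative)
    }
  }
  manifest <- data.frame(
    key = c("package_version", "seed", "n_sequences", "n_windows",
            "region_types", "convention", "window_size", "window_step",
            "kw_H", "kw_df", "kw_p"),
    value = c(as.character(utils::packageVersion("smithscan")),
              config$seed, length(alignment), nrow(windows),
              paste(sort(unique(windows$region)), collapse = ","),
              convention, config$window_size, config$window_step,
              kw$statistic, kw$df, kw$p.value),
    stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(windows, file.path(out_dir, "windows_pi.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    tests <- rbind(
      data.frame(test = "kruskal_wallis", group1 = "all", group2 = "all",
                 statistic = kw$statistic, p.value = kw$p.value,
                 p.adjusted = NA_real_, stringsAsFactors = FALSE),
      data.frame(test = "dunn", group1 = dunn$group1, group2 = dunn$group2,
                 statistic = dunn$z, p.value = dunn$p.value,
                 p.adjusted = dunn$p.adjusted, stringsAsFactors = FALSE))
    write.table(tests, file.path(out_dir, "tests.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(windows = windows, kw = kw, dunn = dunn, assay_kw = assay_kw,
       assay_dunn = assay_dunn, assay_mw = assay_mw_res, manifest = manifest)
}
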