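# Target prediction: seed scan (centroid nt 4-10, Watson-Crick only),
# blastn-short style match counting, duplex free energy and site
# accessibility, combined into the four mandatory target requirements.

#' Seed-site scan of a 3' UTR
#'
#' Finds every occurrence in the UTR of the reverse complement of centroid
#' positions 4-10 (the shifted seed). Watson-Crick matches only: the seed
#' heptamer is matched literally, so G:U wobble cannot satisfy it.
#' Overlapping occurrences are all reported.
#'
#' @param centroid centroid sequence, 5'->3', length >= 10.
#' @param utr UTR sequence (character) or a single named element.
#' @param seed_start,seed_end centroid positions defining the seed
#'   (default 4 and 10).
#' @return data.frame(site_start, site_end) of 7-nt sites on the UTR.
#' @export
seed_scan <- function(centroid, utr, seed_start = 4, seed_end = 10) {
  centroid <- norm_dna(centroid)
  if (nchar(centroid) < seed_end)
    stop("centroid shorter than the seed region (", seed_end, " nt)")
  utr <- norm_dna(utr)
  seed <- substr(centroid, seed_start, seed_end)
  probe <- rc_dna(seed)
  m <- Biostrings::matchPattern(probe, Biostrings::DNAString(utr),
                                fixed = TRUE)
  data.frame(site_start = Biostrings::start(m), site_end = Biostrings::end(m))
}

#' Best gapless match count near a seed site
#'
#' Computes the best gapless local alignment (match +1, mismatch -3, the
#' blastn-short scoring) between the centroid and the reverse complement of
#' the UTR window centered on the seed site (centroid length + `context` on
#' each side), and returns the number of matched positions in the
#' best-scoring alignment. A match is Watson-Crick complementarity between
#' centroid and UTR.
#'
#' @param centroid centroid sequence.
#' @param utr UTR sequence.
#' @param site_start,site_end seed-site coordinates from [seed_scan()].
#' @param context extra window nucleotides each side (default 30).
#' @return integer: matched positions in the best-scoring gapless alignment.
#' @export
count_matches <- function(centroid, utr, site_start, site_end, context = 30) {
  centroid <- norm_dna(centroid); utr <- norm_dna(utr)
  nc <- nchar(centroid); L <- nchar(utr)
  wstart <- max(1L, site_start - (nc + context))
  wend <- min(L, site_end + (nc + context))
  t <- rc_dna(substr(utr, wstart, wend))
  av <- strsplit(centroid, "")[[1]]
  tv <- strsplit(t, "")[[1]]
  nt <- length(tv)
  best_score <- -Inf; best_matches <- 0L
  for (off in (1 - nc):(nt - 1)) {
    i1 <- max(1, 1 - off); i2 <- min(nc, nt - off)
    if (i1 > i2) next
    sc <- ifelse(av[i1:i2] == tv[(i1:i2) + off], 1, -3)
    # Kadane max-subarray, tracking matches of the best window
    cur <- 0; cur_m <- 0L; run_best <- 0; run_m <- 0L
    for (v in sc) {
      if (cur <= 0) { cur <- 0; cur_m <- 0L }
      cur <- cur + v
      cur_m <- if (v > 0) cur_m + 1L else cur_m
      if (cur > run_best || (cur == run_best && cur_m > run_m)) {
        run_best <- cur; run_m <- cur_m
      }
    }
    if (run_best > best_score ||
        (run_best == best_score && run_m > best_matches)) {
      best_score <- run_best; best_matches <- run_m
    }
  }
  as.integer(best_matches)
}

#' Evaluate centroid-UTR target interactions
#'
#' Applies the four mandatory target requirements to one centroid against a
#' UTR collection: a perfect seed site (centroid nt 4-10, Watson-Crick), at
#' least `min_matches` matched positions in the best gapless alignment,
#' accessibility ddG strictly below `max_ddG`, and duplex free energy
#' strictly below `max_dG`. A centroid may hit several UTRs.
#'
#' @param centroid centroid sequence.
#' @param utrs named character vector of 3' UTR sequences (or data.frame with
#'   columns id, seq).
#' @param min_matches minimum matched positions (default 11, inclusive).
#' @param max_ddG accessibility threshold (default -9, strict).
#' @param max_dG duplex energy threshold (default -20, strict).
#' @param seed_start,seed_end seed definition on the centroid (default 4-10).
#' @param forced_helix centroid positions forced paired in the duplex
#'   (default 3-10).
#' @param context match-count window context (default 30).
#' @param flank5,flank3,fold_window accessibility parameters.
#' @param model an [energy_model()].
#' @param keep_all if TRUE, also return failing evaluated sites with flags.
#' @return data.frame(utr_id, site_start, site_end, n_matches, dG_duplex,
#'   ddG, pass_seed, pass_matches, pass_ddG, pass_dG, pass).
#' @export
evaluate_targets <- function(centroid, utrs,
                             min_matches = 11, max_ddG = -9, max_dG = -20,
                             seed_start = 4, seed_end = 10,
                             forced_helix = c(3, 10), context = 30,
                             flank5 = 3, flank3 = 15, fold_window = 140,
                             model = energy_model(), keep_all = FALSE) {
  if (is.data.frame(utrs)) utrs <- setNames(utrs$seq, utrs$id)
  empty <- data.frame(utr_id = character(0), site_start = integer(0),
                      site_end = integer(0), n_matches = integer(0),
                      dG_duplex = numeric(0), ddG = numeric(0),
                      pass_seed = logical(0), pass_matches = logical(0),
                      pass_ddG = logical(0), pass_dG = logical(0),
                      pass = logical(0), stringsAsFactors = FALSE)
  if (length(utrs) == 0) return(empty)
  centroid <- norm_dna(centroid)
  nc <- nchar(centroid)
  rows <- list()
  for (uid in names(utrs)) {
    utr <- norm_dna(utrs[[uid]])
    sites <- seed_scan(centroid, utr, seed_start, seed_end)
    for (k in seq_len(nrow(sites))) {
      ss <- sites$site_start[k]; se <- sites$site_end[k]
      nm <- count_matches(centroid, utr, ss, se, context = context)
      # target region paired by the full centroid around the seed site:
      # centroid 3' tail extends 5' of the site, centroid nt 1-3 extend 3'
      rs <- max(1L, ss - (nc - seed_end) - 3L)
      re <- min(nchar(utr), se + (seed_start - 1L) + 3L)
      dG <- duplex_energy(centroid, substr(utr, rs, re), model = model,
                          forced_helix = forced_helix)
      ddG <- if (is.finite(dG))
        accessibility_ddG(utr, ss, se, dG, flank5 = flank5, flank3 = flank3,
                          fold_window = fold_window, model = model)$ddG
      else Inf
      flags <- c(seed = TRUE, matches = nm >= min_matches,
                 ddG = is.finite(ddG) && ddG < max_ddG,
                 dG = is.finite(dG) && dG < max_dG)
      rows[[length(rows) + 1]] <- data.frame(
        utr_id = uid, site_start = ss, site_end = se, n_matches = nm,
        dG_duplex = dG, ddG = ddG,
        pass_seed = flags[["seed"]], pass_matches = flags[["matches"]],
        pass_ddG = flags[["ddG"]], pass_dG = flags[["dG"]],
        pass = all(flags), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  if (!keep_all) out <- out[out$pass, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write target hits as TSV
#'
#' @param hits [evaluate_targets()] output, optionally with a `centroid`
#'   column prepended by the pipeline.
#' @param path output TSV.
#' @export
write_target_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
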