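# R-side wrappers around the constrained folding dynamic program.

encode_bases <- function(s) {
  v <- strsplit(norm_dna(s), "")[[1]]
  unname(c(A = 0L, C = 1L, G = 2L, T = 3L, N = -1L)[v])
}

#' Minimum free energy of a simplified nested fold
#'
#' Dynamic program over nested structures scored with the [energy_model()]
#' stack terms only (no loop or multiloop penalties); pairs are Watson-Crick
#' or G:U with hairpin loops of at least `min_hairpin` unpaired bases.
#' Positions listed in `blocked` are forced unpaired, which can only remove
#' structures, so the constrained MFE is >= the unconstrained MFE.
#'
#' @param s nucleotide sequence (T or U).
#' @param blocked integer positions (1-based) forced to stay unpaired.
#' @param model an [energy_model()].
#' @param min_hairpin minimum hairpin loop size (default 3).
#' @param traceback if TRUE also return the dot-bracket structure.
#' @return list(energy, structure); structure is NA unless `traceback`.
#' @export
fold_mfe <- function(s, blocked = integer(0), model = energy_model(),
                     min_hairpin = 3, traceback = FALSE) {
  enc <- encode_bases(s)
  bl <- logical(length(enc))
  bl[blocked[blocked >= 1 & blocked <= length(enc)]] <- TRUE
  res <- .fold_mfe_cpp(enc, bl, stack_as_matrix(model), as.integer(min_hairpin),
                       isTRUE(traceback))
  list(energy = res$energy, structure = res$structure)
}

# 6x6 numeric matrix over pair-type order AT TA CG GC GT TG
stack_as_matrix <- function(model) {
  m <- model$stack[PAIR_CODES, PAIR_CODES]
  storage.mode(m) <- "double"
  m
}

#' Secondary structure of a candidate's genomic context
#'
#' Returns a maximum-stability nested structure of the pre-smithRNA sequence
#' from the simplified stack-scored dynamic program. The structure is
#' illustrative: the score table has no loop penalties, so it overestimates
#' pairing relative to a full thermodynamic folder. The temperature is
#' recorded metadata.
#'
#' @param pre_sequence pre-region sequence (T or U), length >= 10.
#' @param min_hairpin minimum hairpin loop size.
#' @param temperature folding temperature in degrees C (metadata).
#' @param model an [energy_model()].
#' @return list(structure = dot-bracket text, energy, n_pairs, temperature).
#' @export
fold_context <- function(pre_sequence, min_hairpin = 3, temperature = 25,
                         model = energy_model(temperature = temperature)) {
  if (nchar(pre_sequence) < 10) stop("sequence too short to fold (< 10 nt)")
  res <- fold_mfe(pre_sequence, model = model, min_hairpin = min_hairpin,
                  traceback = TRUE)
  n_pairs <- sum(strsplit(res$structure, "")[[1]] == "(")
  list(structure = res$structure, energy = res$energy, n_pairs = n_pairs,
       temperature = temperature)
}

#' Target-site accessibility penalty (ddG)
#'
#' PITA-style accessibility: the opening cost dG_open is the MFE of the
#' `fold_window` subsequence centered on the seed site with the site plus
#' `flank5`/`flank3` nucleotides constrained unpaired, minus the
#' unconstrained MFE (>= 0 by construction). Returns
#' ddG = dG_duplex + dG_open. Single-structure MFE opening cost, not an
#' ensemble free energy.
#'
#' @param utr UTR sequence (5'->3').
#' @param site_start,site_end seed-site coordinates on the UTR (1-based).
#' @param dG_duplex duplex free energy from [duplex_energy()]; must be finite.
#' @param flank5 unpaired flank 5' of the site (default 3 nt).
#' @param flank3 unpaired flank 3' of the site (default 15 nt).
#' @param fold_window length of the folded subsequence (default 140 nt),
#'   truncated at UTR boundaries.
#' @param model an [energy_model()].
#' @return list(ddG, dG_open, dG_duplex).
#' @export
accessibility_ddG <- function(utr, site_start, site_end, dG_duplex,
                              flank5 = 3, flank3 = 15, fold_window = 140,
                              model = energy_model()) {
  if (!is.finite(dG_duplex)) stop("dG_duplex must be finite")
  utr <- norm_dna(utr)
  L <- nchar(utr)
  site_len <- site_end - site_start + 1
  wstart <- max(1L, site_start - as.integer((fold_window - site_len) %/% 2))
  wend <- min(L, wstart + fold_window - 1L)
  wstart <- max(1L, wend - fold_window + 1L)
  sub <- substr(utr, wstart, wend)
  open1 <- max(1L, site_start - flank5) - wstart + 1L
  open2 <- min(L, site_end + flank3) - wstart + 1L
  blocked <- seq.int(max(1L, open1), min(nchar(sub), open2))
  mfe_free <- fold_mfe(sub, model = model)$energy
  mfe_open <- fold_mfe(sub, blocked = blocked, model = model)$energy
  dG_open <- mfe_open - mfe_free
  list(ddG = dG_duplex + dG_open, dG_open = dG_open, dG_duplex = dG_duplex)
}
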