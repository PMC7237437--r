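# Nearest-neighbor RNA duplex thermodynamics. The stack table carries the ten
# canonical Watson-Crick stacking free energies (kcal/mol), completed by the
# rotational symmetry stack(p,q) = stack(rev(q), rev(p)). Steps containing a
# G:U wobble get a weak flat value so that a wobble never stabilizes a helix
# as much as the Watson-Crick pair it replaces.

PAIR_CODES <- c("AT", "TA", "CG", "GC", "GT", "TG")  # T stands in for U
WC_PAIRS <- c("AT", "TA", "CG", "GC")

pair_code <- function(a, b) {
  p <- paste0(a, b)
  ifelse(p %in% PAIR_CODES, p, NA_character_)
}

build_stack_table <- function(gu_one = -0.5, gu_two = -0.3) {
  tab <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_CODES, PAIR_CODES))
  # 5'XY3' / 3'WZ5' entries: p = X:W (outer), q = Y:Z (inner)
  canon <- list(
    c("AT", "AT", -0.93), c("AT", "TA", -1.10), c("TA", "AT", -1.33),
    c("CG", "TA", -2.08), c("CG", "AT", -2.11), c("GC", "TA", -2.24),
    c("GC", "AT", -2.35), c("CG", "GC", -2.36), c("GC", "GC", -3.26),
    c("GC", "CG", -3.42)
  )
  for (e in canon) tab[e[1], e[2]] <- as.numeric(e[3])
  revp <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  for (p in WC_PAIRS) for (q in WC_PAIRS) {
    if (is.na(tab[p, q])) tab[p, q] <- tab[revp(q), revp(p)]
  }
  for (p in PAIR_CODES) for (q in PAIR_CODES) {
    ngu <- (p %in% c("GT", "TG")) + (q %in% c("GT", "TG"))
    if (ngu == 1) tab[p, q] <- gu_one
    if (ngu == 2) tab[p, q] <- gu_two
  }
  tab
}

#' Nearest-neighbor energy model
#'
#' Stacking free energies (kcal/mol, 37 degree Turner-style Watson-Crick
#' values; G:U steps simplified to weak flat values) plus a duplex initiation
#' term. The folding temperature is recorded metadata: the simplified score
#' table is temperature-fixed.
#'
#' @param temperature folding temperature in degrees C, recorded as metadata
#'   (default 25, matching the candidate-context folding convention).
#' @param initiation helix initiation free energy in kcal/mol.
#' @param units unit label carried in outputs (the thresholds -9 and -20 are
#'   applied on the model's native scale).
#' @return object of class `energy_model` with fields `id`, `temperature`,
#'   `initiation`, `stack` (6x6 matrix over pair codes AT/TA/CG/GC/GT/TG),
#'   `units`.
#' @export
energy_model <- function(temperature = 25, initiation = 4.09,
                         units = "kcal/mol") {
  structure(
    list(id = "wc-nn-simplified", temperature = temperature,
         initiation = initiation, stack = build_stack_table(), units = units),
    class = "energy_model"
  )
}

# pair codes along an ungapped duplex of a (5'->3') against b (5'->3',
# reversed so b_rev[i] faces a[i]); NA where the bases cannot pair
duplex_pair_codes <- function(av, bv_rev) {
  vapply(seq_along(av), function(i) pair_code(av[i], bv_rev[i]), character(1))
}

#' Minimum duplex free energy under a forced helix
#'
#' Scores every gapless-and-bulge-free pairing register of the centroid
#' against the target site (antiparallel), summing nearest-neighbor stack
#' terms over consecutive paired positions plus one initiation term, under
#' the constraint that centroid positions `forced_helix[1]..forced_helix[2]`
#' are all paired (Watson-Crick or G:U). Returns +Inf when no register
#' satisfies the constraint.
#'
#' @param centroid cluster centroid sequence, 5'->3' (T or U).
#' @param site target site sequence on the UTR, 5'->3'.
#' @param model an [energy_model()].
#' @param forced_helix centroid positions that must be paired (default 3:10,
#'   the RNAhybrid-style helix constraint; the seed itself is nt 4-10).
#' @return free energy in model units (kcal/mol); +Inf if unsatisfiable.
#' @export
duplex_energy <- function(centroid, site, model = energy_model(),
                          forced_helix = c(3, 10)) {
  centroid <- norm_dna(centroid); site <- norm_dna(site)
  nc <- nchar(centroid); ns <- nchar(site)
  if (nc < max(forced_helix)) stop("centroid shorter than the forced helix")
  if (ns < (forced_helix[2] - forced_helix[1] + 1))
    stop("site shorter than the forced helix")
  av <- strsplit(centroid, "")[[1]]
  bv <- rev(strsplit(site, "")[[1]])   # antiparallel register
  best <- Inf
  # offset: centroid position i faces site-reversed position i + off
  for (off in (1 - nc):(ns - 1)) {
    i1 <- max(1, 1 - off); i2 <- min(nc, ns - off)
    if (i1 > forced_helix[1] || i2 < forced_helix[2]) next
    idx <- i1:i2
    codes <- duplex_pair_codes(av[idx], bv[idx + off])
    pos <- idx
    forced <- pos >= forced_helix[1] & pos <= forced_helix[2]
    if (any(is.na(codes[forced]))) next
    e <- model$initiation
    for (k in seq_len(length(idx) - 1)) {
      if (!is.na(codes[k]) && !is.na(codes[k + 1]))
        e <- e + model$stack[codes[k], codes[k + 1]]
    }
    if (e < best) best <- e
  }
  best
}
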