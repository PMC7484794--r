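STANDARD_AA <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

clean_sequence <- function(sequence, on_nonstandard = c("error", "skip")) {
  on_nonstandard <- match.arg(on_nonstandard)
  stopifnot(is.character(sequence), length(sequence) == 1)
  chars <- strsplit(toupper(gsub("[[:space:]*]", "", sequence)), "")[[1]]
  if (length(chars) == 0)
    stop("invalid-sequence: empty sequence")
  bad <- !(chars %in% STANDARD_AA)
  if (any(bad)) {
    if (on_nonstandard == "error")
      stop("invalid-sequence: non-standard residue(s): ",
           paste(unique(chars[bad]), collapse = ", "))
    warning(sum(bad), " non-standard residue(s) skipped (",
            paste(unique(chars[bad]), collapse = ", "), ")")
    chars <- chars[!bad]
    if (length(chars) == 0)
      stop("invalid-sequence: no standard residues left")
  }
  chars
}

#' Average molecular weight of a protein sequence
#'
#' Sum of average residue masses plus one water (ExPASy ProtParam
#' convention: average, not monoisotopic, masses).
#'
#' @param sequence Amino-acid string over the 20 standard residues.
#' @param on_nonstandard `"error"` (default) or `"skip"` non-standard
#'   residues (B, Z, X, U, ...) with a warning.
#' @return Molecular weight in Da.
#' @examples
#' molecular_weight("G")  # 75.07
#' @export
molecular_weight <- function(sequence, on_nonstandard = c("error", "skip")) {
  chars <- clean_sequence(sequence, on_nonstandard)
  sum(.aa_weights[chars]) - (length(chars) - 1) * .water_mass
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues; positive values are
#' hydrophobic, the scale spans -4.5 (Arg) to 4.5 (Ile).
#'
#' @inheritParams molecular_weight
#' @return GRAVY score (dimensionless).
#' @examples
#' gravy("AG")  # (1.8 - 0.4) / 2 = 0.7
#' @export
gravy <- function(sequence, on_nonstandard = c("error", "skip")) {
  chars <- clean_sequence(sequence, on_nonstandard)
  mean(.kyte_doolittle[chars])
}

#' Guruprasad instability index
#'
#' `(10 / L) * sum` of the dipeptide instability weight values (DIWV) over
#' the L - 1 adjacent residue pairs; values above 40 suggest an in vitro
#' unstable protein.
#'
#' @inheritParams molecular_weight
#' @return Instability index (dimensionless). Individual dipeptide weights
#'   can be negative, so short peptides may score below zero; full-length
#'   proteins land in the usual 10-80 range.
#' @export
instability_index <- function(sequence, on_nonstandard = c("error", "skip")) {
  chars <- clean_sequence(sequence, on_nonstandard)
  L <- length(chars)
  if (L < 2)
    stop("invalid-sequence: instability index needs length >= 2")
  idx <- cbind(match(chars[-L], STANDARD_AA), match(chars[-1], STANDARD_AA))
  (10 / L) * sum(.diwv[idx])
}

protein_charge_at_ph <- function(chars, ph) {
  n <- length(chars)
  counts <- table(factor(chars, levels = STANDARD_AA))
  # positive groups: N-terminus, K, R, H
  nterm_pka <- if (chars[1] %in% names(.pka_nterm_override))
    .pka_nterm_override[[chars[1]]] else .pka_positive[["Nterm"]]
  pos <- 1 / (1 + 10^(ph - nterm_pka))
  for (aa in c("K", "R", "H"))
    pos <- pos + counts[[aa]] / (1 + 10^(ph - .pka_positive[[aa]]))
  # negative groups: C-terminus, D, E, C, Y
  cterm_pka <- if (chars[n] %in% names(.pka_cterm_override))
    .pka_cterm_override[[chars[n]]] else .pka_negative[["Cterm"]]
  neg <- 1 / (1 + 10^(cterm_pka - ph))
  for (aa in c("D", "E", "C", "Y"))
    neg <- neg + counts[[aa]] / (1 + 10^(.pka_negative[[aa]] - ph))
  pos - neg
}

#' Isoelectric point by Henderson-Hasselbalch bisection
#'
#' Solves for the pH at which the net protein charge vanishes, using the
#' Bjellqvist pKa set (with position-specific N- and C-terminal overrides,
#' the ExPASy ProtParam convention) and bisection on \[0, 14\].
#'
#' @inheritParams molecular_weight
#' @param tol pH tolerance of the bisection. Default 0.001 (well inside the
#'   0.01 contract).
#' @return Isoelectric point (pH units).
#' @export
isoelectric_point <- function(sequence, on_nonstandard = c("error", "skip"),
                              tol = 0.001) {
  chars <- clean_sequence(sequence, on_nonstandard)
  lo <- 0; hi <- 14
  # net charge is monotone decreasing in pH
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (protein_charge_at_ph(chars, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Compute all four sequence parameters for a set of proteins
#'
#' @param sequences Named character vector (or `Biostrings::AAStringSet`) of
#'   protein sequences; names are accessions.
#' @param on_nonstandard Passed to the individual calculators.
#' @return Data frame with `accession`, `mw`, `pi`, `gravy`, `instability`.
#' @export
protein_parameters <- function(sequences, on_nonstandard = c("error", "skip")) {
  if (inherits(sequences, "AAStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  on_nonstandard <- match.arg(on_nonstandard)
  data.frame(
    accession = names(sequences),
    mw = vapply(sequences, molecular_weight, 0, on_nonstandard = on_nonstandard),
    pi = vapply(sequences, isoelectric_point, 0, on_nonstandard = on_nonstandard),
    gravy = vapply(sequences, gravy, 0, on_nonstandard = on_nonstandard),
    instability = vapply(sequences, instability_index, 0,
                         on_nonstandard = on_nonstandard),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Number-weighted average of protein parameters over a corona
#'
#' Weights each protein's parameters by its copy number per nanoparticle,
#' characterizing the overall physicochemistry of the adsorbed layer.
#'
#' @param params Data frame from [protein_parameters()] (columns `accession`,
#'   `mw`, `pi`, `gravy`, `instability`).
#' @param copies Named numeric vector of copy numbers (>= 0); names matched
#'   against `params$accession`.
#' @return Named numeric vector with the weighted `mw`, `pi`, `gravy`,
#'   `instability`.
#' @export
number_weighted_average <- function(params, copies) {
  stopifnot(is.data.frame(params), !is.null(names(copies)))
  if (any(copies < 0)) stop("invalid-input: copies must be non-negative")
  common <- intersect(params$accession, names(copies))
  if (length(common) == 0 || sum(copies[common]) <= 0)
    stop("empty-corona: total copy number is zero")
  w <- copies[common] / sum(copies[common])
  p <- params[match(common, params$accession), ]
  c(mw = sum(w * p$mw), pi = sum(w * p$pi),
    gravy = sum(w * p$gravy), instability = sum(w * p$instability))
}
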