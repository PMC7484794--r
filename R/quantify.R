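#' Avogadro constant as printed in the source quantification convention
#'
#' The copy-number conversion deliberately uses 6.023e23 rather than the
#' CODATA value so that outputs match the convention of the original
#' emPAI-based corona quantification; every function taking an `avogadro`
#' argument accepts an override.
#'
#' @export
AVOGADRO_CORONA <- 6.023e23

#' Degree of labeling from UV absorbances
#'
#' Computes the average number of label (cross-linker or dye) molecules per
#' protein from the UV spectrum of the conjugate:
#' \deqn{DOL = \frac{A_{max}\,\epsilon_{280}}{(A_{280} - A_{max} CF)\,\epsilon_{max}}}
#' where the `cf` correction factor removes the label's own contribution at
#' 280 nm.
#'
#' @param a_max Absorbance at the label's lambda_max (dimensionless, >= 0).
#' @param a_280 Absorbance at 280 nm (>= 0).
#' @param eps_280 Protein molar extinction coefficient at 280 nm
#'   (M^-1 cm^-1, > 0).
#' @param eps_max Label molar extinction coefficient at lambda_max
#'   (M^-1 cm^-1, > 0).
#' @param cf Correction factor of the label at 280 nm (>= 0). Default 0.
#' @return Degree of labeling (labels per protein), non-negative.
#' @examples
#' # ~1 label per protein: both molar concentrations equal 1 uM
#' compute_dol(0.271, 0.0664, eps_280 = 66433, eps_max = 271000)
#' @export
compute_dol <- function(a_max, a_280, eps_280, eps_max, cf = 0) {
  stopifnot(is.numeric(a_max), is.numeric(a_280), is.numeric(eps_280),
            is.numeric(eps_max), is.numeric(cf))
  if (any(a_max < 0) || any(a_280 < 0))
    stop("invalid-measurement: absorbances must be non-negative")
  if (any(eps_280 <= 0) || any(eps_max <= 0))
    stop("invalid-measurement: extinction coefficients must be positive")
  if (any(cf < 0))
    stop("invalid-measurement: correction factor must be non-negative")
  corrected <- a_280 - a_max * cf
  if (any(corrected <= 0))
    stop("invalid-measurement: corrected protein absorbance (A280 - Amax*CF) must be positive")
  (a_max * eps_280) / (corrected * eps_max)
}

#' Total corona protein mass per nanoparticle
#'
#' Divides the bulk corona protein mass concentration (BCA assay) by the
#' nanoparticle number concentration to obtain M_total, the overall mass of
#' corona proteins carried by one particle.
#'
#' @param protein_mass_conc Total corona protein mass concentration
#'   (g ml^-1, > 0).
#' @param np_number_conc Nanoparticle number concentration (ml^-1, > 0).
#' @return M_total in grams per nanoparticle.
#' @examples
#' total_mass_per_np(1e-6, 1e12)  # 1 ug/ml over 1e12 NP/ml -> 1e-18 g/NP
#' @export
total_mass_per_np <- function(protein_mass_conc, np_number_conc) {
  if (any(!is.finite(protein_mass_conc)) || any(protein_mass_conc <= 0))
    stop("invalid-measurement: protein_mass_conc must be positive and finite")
  if (any(!is.finite(np_number_conc)) || any(np_number_conc <= 0))
    stop("invalid-measurement: np_number_conc must be positive and finite")
  protein_mass_conc / np_number_conc
}

#' emPAI-weighted mass fractions of corona proteins
#'
#' The weight contribution of each identified protein to the total adsorbed
#' mass in one sample: `empai_i * mw_i / sum_j(empai_j * mw_j)`. Proteins
#' absent from the sample (emPAI 0 or NA) get fraction 0; NA emPAI is treated
#' as not-detected.
#'
#' @param empai Numeric vector of emPAI values for one sample (>= 0; NA means
#'   not detected).
#' @param mw Molecular weights in Da, same length as `empai` (> 0).
#' @return Mass fractions summing to 1.
#' @export
mass_fractions <- function(empai, mw) {
  stopifnot(length(empai) == length(mw))
  if (any(mw <= 0) || any(!is.finite(mw)))
    stop("invalid-measurement: molecular weights must be positive and finite")
  empai[is.na(empai)] <- 0
  if (any(empai < 0) || any(!is.finite(empai)))
    stop("invalid-measurement: emPAI values must be finite and non-negative")
  w <- empai * mw
  total <- sum(w)
  if (total <= 0)
    stop("empty-sample: all emPAI values are zero")
  w / total
}

#' Assemble a per-nanoparticle corona copy-number matrix
#'
#' Applies the emPAI quantification to every sample of an experiment:
#' per-protein mass per nanoparticle is the emPAI mass fraction times that
#' sample's M_total, and the copy number is `mass / mw * N_A`.
#'
#' @param records Data frame with columns `accession`, `mw_da` and one
#'   numeric emPAI column per sample label (the format read by
#'   [read_empai_table()]).
#' @param samples Data frame describing the samples, with columns `label`,
#'   `role` (`"control"` or `"captured"`), and either `m_total` (g per
#'   nanoparticle) or both `protein_mass_conc` (g ml^-1) and
#'   `np_number_conc` (ml^-1). See [sample_measurements()].
#' @param avogadro Avogadro constant; defaults to [AVOGADRO_CORONA].
#' @return A `corona_matrix` object: list with `copies` and `masses`
#'   (proteins x samples matrices), `mw` (named vector, Da), `m_total`
#'   (named vector, g/NP), and `roles` (named character vector).
#' @export
build_corona_matrix <- function(records, samples, avogadro = AVOGADRO_CORONA) {
  stopifnot(is.data.frame(records), is.data.frame(samples))
  if (!all(c("accession", "mw_da") %in% names(records)))
    stop("configuration error: records must have 'accession' and 'mw_da' columns")
  if (!all(c("label", "role") %in% names(samples)))
    stop("configuration error: samples must have 'label' and 'role' columns")
  labels <- as.character(samples$label)
  missing_cols <- setdiff(labels, names(records))
  if (length(missing_cols))
    stop("configuration error: no emPAI column for sample(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(records$accession))
    stop("configuration error: duplicate accessions in records")
  roles <- as.character(samples$role)
  if (!all(roles %in% c("control", "captured")))
    stop("configuration error: sample roles must be 'control' or 'captured'")
  if (sum(roles == "captured") > 1)
    stop("configuration error: at most one captured (HC+SC) sample allowed")

  if ("m_total" %in% names(samples)) {
    m_total <- as.numeric(samples$m_total)
    if (any(!is.finite(m_total)) || any(m_total <= 0))
      stop("invalid-measurement: m_total must be positive and finite")
  } else {
    if (!all(c("protein_mass_conc", "np_number_conc") %in% names(samples)))
      stop("configuration error: samples need m_total or concentration columns")
    m_total <- total_mass_per_np(samples$protein_mass_conc, samples$np_number_conc)
  }
  names(m_total) <- labels
  names(roles) <- labels

  mw <- as.numeric(records$mw_da)
  names(mw) <- records$accession
  n <- nrow(records)
  masses <- matrix(0, n, length(labels),
                   dimnames = list(records$accession, labels))
  for (lab in labels) {
    frac <- mass_fractions(records[[lab]], mw)
    masses[, lab] <- frac * m_total[lab]
  }
  copies <- masses / mw * avogadro

  structure(list(copies = copies, masses = masses, mw = mw,
                 m_total = m_total, roles = roles, avogadro = avogadro),
            class = "corona_matrix")
}

#' Describe sample measurements for corona quantification
#'
#' Convenience constructor for the sample table consumed by
#' [build_corona_matrix()]. Concentrations are given in laboratory units
#' (ug ml^-1 for protein mass) and converted to the internal g ml^-1
#' convention.
#'
#' @param label Character vector of sample labels (e.g. `"HC"`, `"HC-N3"`,
#'   `"D Ctrl"`, `"N3 Ctrl"`, `"HC+SC"`).
#' @param protein_mass_conc_ug_per_ml Total corona protein mass concentration
#'   per sample, ug ml^-1.
#' @param np_number_conc_per_ml Nanoparticle number concentration per sample,
#'   ml^-1.
#' @param captured Label of the single click-captured (HC+SC) sample; all
#'   other samples are controls.
#' @return Data frame with columns `label`, `role`, `protein_mass_conc`,
#'   `np_number_conc` (internal units).
#' @export
sample_measurements <- function(label, protein_mass_conc_ug_per_ml,
                                np_number_conc_per_ml, captured) {
  stopifnot(length(label) == length(protein_mass_conc_ug_per_ml),
            length(label) == length(np_number_conc_per_ml))
  if (!captured %in% label)
    stop("configuration error: captured label '", captured, "' not among samples")
  data.frame(label = as.character(label),
             role = ifelse(label == captured, "captured", "control"),
             protein_mass_conc = protein_mass_conc_ug_per_ml * 1e-6,
             np_number_conc = np_number_conc_per_ml,
             stringsAsFactors = FALSE)
}

#' @export
print.corona_matrix <- function(x, ...) {
  cat("corona_matrix:", nrow(x$copies), "proteins x", ncol(x$copies), "samples\n")
  cat("  controls:", paste(names(x$roles)[x$roles == "control"], collapse = ", "), "\n")
  cat("  captured:", paste(names(x$roles)[x$roles == "captured"], collapse = ", "), "\n")
  cat("  M_total (g/NP):",
      paste(sprintf("%s=%.3g", names(x$m_total), x$m_total), collapse = ", "), "\n")
  invisible(x)
}

control_labels <- function(m) names(m$roles)[m$roles == "control"]
captured_label <- function(m) {
  lab <- names(m$roles)[m$roles == "captured"]
  if (length(lab) != 1)
    stop("configuration error: exactly one captured (HC+SC) sample required")
  lab
}
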