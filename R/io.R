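#' Read an emPAI table
#'
#' Tab- or comma-separated text with a header row: `accession`, `mw_da`,
#' then one numeric emPAI column per sample label. Blank emPAI cells are
#' treated as not-detected (0) and counted in a warning; duplicate
#' accessions are rejected.
#'
#' @param path File path.
#' @param sep Field separator; auto-detected from the header line when NULL.
#' @return Data frame of protein records suitable for
#'   [build_corona_matrix()].
#' @export
read_empai_table <- function(path, sep = NULL) {
  header <- readLines(path, n = 1)
  if (is.null(sep))
    sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  if (!all(c("accession", "mw_da") %in% names(df)))
    stop("parse error: header must contain 'accession' and 'mw_da' (line 1)")
  dup <- df$accession[duplicated(df$accession)]
  if (length(dup))
    stop("parse error: duplicate accession(s): ", paste(unique(dup), collapse = ", "))
  if (any(!is.finite(df$mw_da)) || any(df$mw_da <= 0)) {
    bad <- which(!is.finite(df$mw_da) | df$mw_da <= 0)[1]
    stop("parse error: invalid mw_da at data line ", bad)
  }
  sample_cols <- setdiff(names(df), c("accession", "mw_da"))
  n_blank <- 0
  for (col in sample_cols) {
    if (!is.numeric(df[[col]]))
      stop("parse error: non-numeric emPAI column '", col, "'")
    n_blank <- n_blank + sum(is.na(df[[col]]))
    df[[col]][is.na(df[[col]])] <- 0
    if (any(df[[col]] < 0)) {
      bad <- which(df[[col]] < 0)[1]
      stop("parse error: negative emPAI in column '", col, "' at data line ", bad)
    }
  }
  if (n_blank > 0)
    warning(n_blank, " blank emPAI cell(s) set to 0")
  df
}

#' Read sample measurements from a YAML or JSON config
#'
#' The config is a mapping keyed by sample label; each entry provides
#' `protein_mass_conc_ug_per_ml`, `np_number_conc_per_ml` and a `role`
#' (`"control"` or `"captured"`).
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Data frame for [build_corona_matrix()].
#' @export
read_sample_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  labs <- names(cfg)
  if (is.null(labs) || length(labs) == 0)
    stop("parse error: sample config must be a mapping keyed by sample label")
  get_num <- function(entry, field, lab) {
    v <- entry[[field]]
    if (is.null(v) || !is.numeric(v) || !is.finite(v))
      stop("parse error: sample '", lab, "' needs numeric ", field)
    v
  }
  data.frame(
    label = labs,
    role = vapply(labs, function(l) {
      r <- cfg[[l]][["role"]]
      if (is.null(r)) stop("parse error: sample '", l, "' needs a role")
      r
    }, ""),
    protein_mass_conc = vapply(labs, function(l)
      get_num(cfg[[l]], "protein_mass_conc_ug_per_ml", l), 0) * 1e-6,
    np_number_conc = vapply(labs, function(l)
      get_num(cfg[[l]], "np_number_conc_per_ml", l), 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a corona matrix to CSV with a JSON sidecar
#'
#' Emits `<stem>_copies.csv` and `<stem>_masses.csv` plus
#' `<stem>_meta.json` holding M_total per sample, roles and the Avogadro
#' convention used.
#'
#' @param m A `corona_matrix`.
#' @param stem Output path stem.
#' @return Character vector of written paths, invisibly.
#' @export
write_corona_matrix <- function(m, stem) {
  stopifnot(inherits(m, "corona_matrix"))
  paths <- c(copies = paste0(stem, "_copies.csv"),
             masses = paste0(stem, "_masses.csv"),
             meta = paste0(stem, "_meta.json"))
  for (what in c("copies", "masses")) {
    df <- data.frame(accession = rownames(m[[what]]), m[[what]],
                     check.names = FALSE, row.names = NULL)
    utils::write.csv(df, paths[what], row.names = FALSE)
  }
  jsonlite::write_json(
    list(m_total_g_per_np = as.list(m$m_total),
         roles = as.list(m$roles), avogadro = m$avogadro),
    paths["meta"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write a fitted kinetic grid to CSV
#'
#' Long format: `kd_M`, `koff_per_s`, `weight_ru`.
#'
#' @param fit A `kinetic_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_kinetic_grid <- function(fit, path) {
  stopifnot(inherits(fit, "kinetic_fit"))
  df <- data.frame(kd_M = fit$grid$nodes$kd,
                   koff_per_s = fit$grid$nodes$koff,
                   weight_ru = fit$weights)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the end-to-end corona analysis
#'
#' Chains quantification, SC identification/classification, sequence
#' parameters, and coverage estimation; writes every table plus a run
#' manifest (thresholds, seed, input digests) when `outdir` is given.
#'
#' @param records emPAI data frame (or path to an emPAI table).
#' @param samples Sample measurement data frame (or path to a YAML/JSON
#'   config).
#' @param sequences Optional named character vector of protein sequences
#'   (or FASTA path) for parameter computation.
#' @param enrichment_factor,max_control_cv,similarity_ratio SC-rule
#'   thresholds, see [identify_sc_cluster()] and [classify_sc_types()].
#' @param np_diameter_nm Nanoparticle diameter for coverage. Default 70.
#' @param outdir Optional output directory.
#' @param seed Integer recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return List with `matrix`, `classification`, `composition`,
#'   `clustering`, `params` (NULL without sequences), `coverage`,
#'   `manifest`.
#' @export
run_corona_pipeline <- function(records, samples, sequences = NULL,
                                enrichment_factor = 1.5, max_control_cv = 0.5,
                                similarity_ratio = 1.5, np_diameter_nm = 70,
                                outdir = NULL, seed = 1) {
  inputs <- character(0)
  if (is.character(records) && length(records) == 1) {
    inputs["empai"] <- records
    records <- read_empai_table(records)
  }
  if (is.character(samples) && length(samples) == 1) {
    inputs["samples"] <- samples
    samples <- read_sample_config(samples)
  }
  if (is.character(sequences) && length(sequences) == 1 && file.exists(sequences)) {
    inputs["fasta"] <- sequences
    aa <- Biostrings::readAAStringSet(sequences)
    sequences <- stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  }

  m <- build_corona_matrix(records, samples)
  z <- transform_and_scale(m)
  clustering <- hierarchical_two_way(z)
  sc <- identify_sc_cluster(m, enrichment_factor, max_control_cv)
  classification <- classify_sc_types(m, sc, similarity_ratio)
  composition <- composition_summary(m, classification)

  params <- NULL
  if (!is.null(sequences))
    params <- protein_parameters(sequences, on_nonstandard = "skip")

  footprints <- data.frame(accession = names(m$mw),
                           a_min = sphere_cross_section(m$mw),
                           a_max = sphere_cross_section(m$mw),
                           stringsAsFactors = FALSE)
  coverage <- rbind(
    control_mean = coverage_ratio(m, footprints, np_diameter_nm, "control_mean"),
    captured = coverage_ratio(m, footprints, np_diameter_nm, captured_label(m)))

  manifest <- list(
    package_version = as.character(utils::packageVersion("softcorona")),
    seed = seed,
    thresholds = list(enrichment_factor = enrichment_factor,
                      max_control_cv = max_control_cv,
                      similarity_ratio = similarity_ratio),
    np_diameter_nm = np_diameter_nm,
    n_proteins = nrow(m$copies),
    input_md5 = if (length(inputs)) as.list(tools::md5sum(inputs)) else list())

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_corona_matrix(m, file.path(outdir, "corona"))
    utils::write.csv(classification, file.path(outdir, "classification.csv"),
                     row.names = FALSE)
    utils::write.csv(composition$totals, file.path(outdir, "composition.csv"),
                     row.names = FALSE)
    if (!is.null(params))
      utils::write.csv(params, file.path(outdir, "protein_parameters.csv"),
                       row.names = FALSE)
    utils::write.csv(data.frame(corona = rownames(coverage), coverage,
                                row.names = NULL),
                     file.path(outdir, "coverage.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(matrix = m, classification = classification, composition = composition,
       clustering = clustering, params = params, coverage = coverage,
       manifest = manifest)
}
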