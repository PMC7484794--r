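#' Square-root transform and per-protein z-scaling of a copy matrix
#'
#' Each copy number is square-root transformed, then every protein row is
#' centered and divided by its sample standard deviation (n - 1). Rows with
#' zero variance cannot be scaled and are set to all-zeros; their names are
#' recorded in the `"zero_variance"` attribute. This is the transformation
#' under which the clustered heatmaps are drawn, so z-scores compare one
#' protein across samples.
#'
#' @param m A `corona_matrix` or a non-negative numeric matrix
#'   (proteins x samples).
#' @return Scaled matrix with attribute `zero_variance` (character vector of
#'   flagged row names).
#' @export
transform_and_scale <- function(m) {
  x <- if (inherits(m, "corona_matrix")) m$copies else m
  stopifnot(is.matrix(x), is.numeric(x))
  if (ncol(x) < 2)
    stop("insufficient-data: need at least 2 samples to scale")
  if (any(x < 0)) stop("invalid-input: copy numbers must be non-negative")
  s <- sqrt(x)
  mu <- rowMeans(s)
  sd_r <- apply(s, 1, stats::sd)
  z <- (s - mu) / sd_r
  flat <- sd_r == 0
  z[flat, ] <- 0
  attr(z, "zero_variance") <- rownames(x)[flat]
  z
}

#' Two-way hierarchical clustering of a scaled corona matrix
#'
#' Ward minimum-variance clustering on Euclidean distances, applied to the
#' protein rows and to the sample columns of the z-scaled matrix
#' (`stats::hclust`, method `"ward.D2"`, i.e. Ward on unsquared Euclidean
#' distances). Deterministic for a given input ordering.
#'
#' @param zmatrix Scaled matrix from [transform_and_scale()].
#' @return A `corona_clustering` object: list with `row_hclust`,
#'   `col_hclust`, `row_order`, `col_order`, and `zmatrix`.
#' @export
hierarchical_two_way <- function(zmatrix) {
  stopifnot(is.matrix(zmatrix))
  if (any(!is.finite(zmatrix)))
    stop("invalid-input: zmatrix contains non-finite values")
  row_hc <- stats::hclust(stats::dist(zmatrix, method = "euclidean"),
                          method = "ward.D2")
  col_hc <- stats::hclust(stats::dist(t(zmatrix), method = "euclidean"),
                          method = "ward.D2")
  structure(list(row_hclust = row_hc, col_hclust = col_hc,
                 row_order = row_hc$order, col_order = col_hc$order,
                 zmatrix = zmatrix),
            class = "corona_clustering")
}

control_cv <- function(ctrl) {
  mu <- mean(ctrl)
  if (mu == 0) return(NA_real_)
  stats::sd(ctrl) / mu
}

#' Identify the soft-corona protein set
#'
#' Operationalizes the restriction rule used to call soft-corona (SC)
#' proteins: a protein belongs to the SC set iff its copy number in the
#' captured (HC+SC) sample is at least `enrichment_factor` times the maximum
#' over all control samples AND the controls are mutually consistent
#' (coefficient of variation across controls at most `max_control_cv`, or
#' all controls exactly zero). Proteins detected only after capture
#' (all-zero controls, positive captured copies) qualify and are later
#' classified as "new". A protein merely higher in HC+SC than in the
#' controls is thus not automatically an SC protein.
#'
#' @param m A `corona_matrix` with >= 2 control samples and exactly one
#'   captured sample.
#' @param enrichment_factor Minimum captured/max(control) ratio (>= 1).
#'   Default 1.5.
#' @param max_control_cv Maximum coefficient of variation (sample s.d. over
#'   mean) of the control copies (> 0). Default 0.5.
#' @return Character vector of SC accessions.
#' @export
identify_sc_cluster <- function(m, enrichment_factor = 1.5, max_control_cv = 0.5) {
  stopifnot(inherits(m, "corona_matrix"))
  stopifnot(enrichment_factor >= 1, max_control_cv > 0)
  ctrl_labs <- control_labels(m)
  if (length(ctrl_labs) < 2)
    stop("configuration error: need >= 2 control samples")
  cap_lab <- captured_label(m)
  ctrl <- m$copies[, ctrl_labs, drop = FALSE]
  cap <- m$copies[, cap_lab]
  ctrl_max <- apply(ctrl, 1, max)
  cv <- apply(ctrl, 1, control_cv)
  all_zero <- ctrl_max == 0
  enriched <- cap > 0 & cap >= enrichment_factor * ctrl_max
  consistent <- all_zero | (!is.na(cv) & cv <= max_control_cv)
  rownames(m$copies)[enriched & consistent]
}

#' Classify proteins into hard-corona and soft-corona binding types
#'
#' For every protein, the hard-state copy number is the mean over the
#' control samples and the soft-state copy number is the captured excess
#' `max(0, captured - hard)`. SC proteins are typed by the ratio of the two
#' states: Type 1 has more hard copies (`hard/soft > similarity_ratio`),
#' Type 3 more soft copies (`soft/hard > similarity_ratio`), Type 2 similar
#' copy numbers (neither ratio exceeds the band), and "new" proteins were
#' undetected in every control (`hard = 0`).
#'
#' @param m A `corona_matrix`.
#' @param sc_set Character vector of SC accessions, typically from
#'   [identify_sc_cluster()].
#' @param similarity_ratio Band edge for "similar copy numbers" (> 1).
#'   Default 1.5.
#' @return Data frame with one row per protein: `accession`, `cluster`
#'   (`"HC"`/`"SC"`), `sc_type` (`"type1"`, `"type2"`, `"type3"`, `"new"`,
#'   `"not_applicable"`), `hard_copies`, `soft_copies`, `captured_copies`,
#'   `fold_increase` (NA where undefined), `fold_label` (prints "New" for
#'   capture-only proteins), `control_cv`.
#' @export
classify_sc_types <- function(m, sc_set, similarity_ratio = 1.5) {
  stopifnot(inherits(m, "corona_matrix"), similarity_ratio > 1)
  acc <- rownames(m$copies)
  if (!all(sc_set %in% acc))
    stop("invalid-input: sc_set contains unknown accessions")
  ctrl <- m$copies[, control_labels(m), drop = FALSE]
  cap <- m$copies[, captured_label(m)]
  hard <- rowMeans(ctrl)
  soft <- pmax(0, cap - hard)
  cv <- apply(ctrl, 1, control_cv)

  in_sc <- acc %in% sc_set
  sc_type <- rep("not_applicable", length(acc))
  for (i in which(in_sc)) {
    if (hard[i] == 0) {
      sc_type[i] <- "new"
    } else if (soft[i] == 0 || hard[i] / soft[i] > similarity_ratio) {
      sc_type[i] <- "type1"
    } else if (soft[i] / hard[i] > similarity_ratio) {
      sc_type[i] <- "type3"
    } else {
      sc_type[i] <- "type2"
    }
  }
  fi <- fold_increase(m)
  data.frame(accession = acc,
             cluster = ifelse(in_sc, "SC", "HC"),
             sc_type = sc_type,
             hard_copies = hard,
             soft_copies = soft,
             captured_copies = cap,
             fold_increase = fi$fold,
             fold_label = fi$label,
             control_cv = cv,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Fold increase of protein abundance after soft-corona capture
#'
#' Captured copy number divided by the mean control copy number. Proteins
#' absent from every control but present after capture are flagged `"New"`;
#' proteins absent everywhere are flagged `"undefined"`.
#'
#' @param m A `corona_matrix`.
#' @return Data frame with `accession`, `fold` (numeric, NA where no ratio
#'   exists) and `label` (formatted fold, `"New"`, or `"undefined"`).
#' @export
fold_increase <- function(m) {
  stopifnot(inherits(m, "corona_matrix"))
  ctrl_mean <- rowMeans(m$copies[, control_labels(m), drop = FALSE])
  cap <- m$copies[, captured_label(m)]
  fold <- ifelse(ctrl_mean > 0, cap / ctrl_mean, NA_real_)
  label <- ifelse(ctrl_mean > 0, sprintf("%.2f", fold),
                  ifelse(cap > 0, "New", "undefined"))
  data.frame(accession = rownames(m$copies), fold = fold, label = label,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Copy-number composition of the HC and SC clusters
#'
#' Sums copy numbers over HC-cluster and SC-cluster proteins for the
#' averaged control corona and for the captured (HC+SC) corona, and reports
#' each protein's number percentage within both coronas.
#'
#' @param m A `corona_matrix`.
#' @param classification Data frame from [classify_sc_types()].
#' @return List with `totals` (data frame: cluster x role copy totals and
#'   percentages) and `percentages` (data frame per protein: number percent
#'   in the control-mean and captured coronas).
#' @export
composition_summary <- function(m, classification) {
  stopifnot(inherits(m, "corona_matrix"))
  ctrl_mean <- rowMeans(m$copies[, control_labels(m), drop = FALSE])
  cap <- m$copies[, captured_label(m)]
  cl <- classification$cluster[match(rownames(m$copies), classification$accession)]
  totals <- data.frame(
    cluster = c("HC", "SC"),
    control_total = c(sum(ctrl_mean[cl == "HC"]), sum(ctrl_mean[cl == "SC"])),
    captured_total = c(sum(cap[cl == "HC"]), sum(cap[cl == "SC"])),
    stringsAsFactors = FALSE)
  totals$control_percent <- 100 * totals$control_total / sum(ctrl_mean)
  totals$captured_percent <- 100 * totals$captured_total / sum(cap)
  pct <- data.frame(accession = rownames(m$copies),
                    cluster = cl,
                    control_percent = 100 * ctrl_mean / sum(ctrl_mean),
                    captured_percent = 100 * cap / sum(cap),
                    row.names = NULL, stringsAsFactors = FALSE)
  list(totals = totals, percentages = pct)
}

#' Dendrogram cut best matching a rule-based SC set
#'
#' The SC call is rule-based; the heatmap view identifies the SC cluster
#' visually as a branch of the row dendrogram. This helper scans all
#' clusters obtainable by cutting the row tree at each height (2..k groups)
#' and returns the branch with the highest Jaccard similarity to the
#' rule-based set, for visual parity between the two views.
#'
#' @param clustering A `corona_clustering` from [hierarchical_two_way()].
#' @param sc_set Character vector of rule-based SC accessions.
#' @param max_k Maximum number of groups to consider when cutting. Default 10.
#' @return List with `members` (accessions of the best branch), `k`,
#'   `jaccard`.
#' @export
best_matching_cut <- function(clustering, sc_set, max_k = 10) {
  stopifnot(inherits(clustering, "corona_clustering"))
  labs <- rownames(clustering$zmatrix)
  best <- list(members = character(0), k = NA_integer_, jaccard = 0)
  for (k in 2:min(max_k, length(labs))) {
    cut <- stats::cutree(clustering$row_hclust, k = k)
    for (g in unique(cut)) {
      members <- labs[cut == g]
      jac <- length(intersect(members, sc_set)) /
        length(union(members, sc_set))
      if (!is.nan(jac) && jac > best$jaccard)
        best <- list(members = members, k = k, jaccard = jac)
    }
  }
  best
}
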