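#' Protein volume from mass (partial specific volume model)
#'
#' Volume occupied by a globular protein of mass M (Da), assuming a partial
#' specific volume of 0.73 cm^3 g^-1: `V = 1.212e-3 nm^3/Da * M`.
#'
#' @param mass_da Protein mass in Da (> 0).
#' @return Volume in nm^3.
#' @export
protein_volume <- function(mass_da) {
  if (any(!is.finite(mass_da)) || any(mass_da <= 0))
    stop("invalid-measurement: mass must be positive")
  1.212e-3 * mass_da
}

#' Equivalent-sphere radius of a protein from mass
#'
#' `R = 0.066 * M^(1/3)` (M in Da, R in nm), the sphere consistent with the
#' volume model of [protein_volume()] up to rounding of the constants.
#'
#' @inheritParams protein_volume
#' @return Radius in nm.
#' @export
protein_radius <- function(mass_da) {
  if (any(!is.finite(mass_da)) || any(mass_da <= 0))
    stop("invalid-measurement: mass must be positive")
  0.066 * mass_da^(1 / 3)
}

#' Cross-section area of the equivalent sphere
#'
#' @inheritParams protein_volume
#' @return `pi * R(M)^2` in nm^2.
#' @export
sphere_cross_section <- function(mass_da) {
  pi * protein_radius(mass_da)^2
}

#' Quasi-uniform directions on the unit sphere (Fibonacci lattice)
#'
#' @param n Number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_directions <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# area of the convex hull of `coords` projected on the plane orthogonal to
# the unit vector `dir`
projected_hull_area <- function(coords, dir) {
  dir <- dir / sqrt(sum(dir^2))
  # orthonormal basis of the projection plane
  ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * dir) * dir
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
          dir[3] * e1[1] - dir[1] * e1[3],
          dir[1] * e1[2] - dir[2] * e1[1])
  u <- coords %*% cbind(e1, e2)
  h <- grDevices::chull(u)
  xs <- u[h, 1]; ys <- u[h, 2]
  # shoelace formula
  abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
}

#' Orientation-dependent protein footprint range
#'
#' A protein presents a different cross-section to the particle surface
#' depending on its orientation. With atomic coordinates, the footprint is
#' bracketed by projecting the atoms onto planes orthogonal to
#' `n_directions` quasi-uniform directions and taking the minimum and
#' maximum convex-hull areas. Without coordinates, the equivalent-sphere
#' model is used and both bounds coincide.
#'
#' @param mass_da Protein mass in Da (required when `coords` is NULL).
#' @param coords Optional n x 3 matrix of atom coordinates (nm); at least 4
#'   non-coplanar points.
#' @param n_directions Number of projection directions. Default 1024.
#' @return List with `a_min`, `a_max` (nm^2) and `source`
#'   (`"sphere_model"` or `"coordinates"`).
#' @export
cross_section_range <- function(mass_da = NULL, coords = NULL,
                                n_directions = 1024) {
  if (is.null(coords)) {
    if (is.null(mass_da))
      stop("incomplete-input: need mass_da or coordinates")
    a <- sphere_cross_section(mass_da)
    return(list(a_min = a, a_max = a, source = "sphere_model"))
  }
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3)
  if (nrow(coords) < 4)
    stop("degenerate-geometry: need >= 4 atoms")
  # reject (near-)coplanar clouds: rank of centered coordinates must be 3
  sv <- svd(scale(coords, scale = FALSE))$d
  if (sv[3] < 1e-9 * sv[1])
    stop("degenerate-geometry: coordinates are coplanar or colinear")
  dirs <- fibonacci_directions(n_directions)
  areas <- apply(dirs, 1, function(d) projected_hull_area(coords, d))
  list(a_min = min(areas), a_max = max(areas), source = "coordinates")
}

#' Read atom coordinates from a PDB file
#'
#' ATOM records of the first model via `bio3d::read.pdb`, keeping only
#' blank or 'A' alternate locations; coordinates converted from Angstrom
#' to nm.
#'
#' @param path PDB file path.
#' @return n x 3 coordinate matrix in nm.
#' @export
read_pdb_coords <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("read_pdb_coords needs the 'bio3d' package")
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type == "ATOM" & (is.na(at$alt) | at$alt == "A")
  if (!any(keep)) stop("degenerate-geometry: no ATOM records")
  xyz <- as.matrix(at[keep, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("parse error: malformed ATOM coordinates")
  dimnames(xyz) <- NULL
  xyz / 10
}

#' Nanoparticle coverage ratio by corona proteins
#'
#' Summed protein cross-section area per particle divided by the bare
#' particle surface area `pi * d^2`. The two bounds use each protein's
#' minimum and maximum footprint, spanning the orientation dependence; a
#' ratio above 1 indicates more protein than a flat monolayer could hold.
#'
#' @param m A `corona_matrix`.
#' @param footprints Data frame with columns `accession`, `a_min`, `a_max`
#'   (nm^2) covering every protein with positive copies, e.g. built from
#'   [cross_section_range()].
#' @param diameter_nm Nanoparticle diameter in nm (> 0).
#' @param sample Sample label, or `"control_mean"` for the average of the
#'   control columns.
#' @return Named vector `c(lower =, upper =)`.
#' @export
coverage_ratio <- function(m, footprints, diameter_nm, sample) {
  stopifnot(inherits(m, "corona_matrix"), diameter_nm > 0)
  copies <- if (identical(sample, "control_mean")) {
    rowMeans(m$copies[, control_labels(m), drop = FALSE])
  } else {
    if (!sample %in% colnames(m$copies))
      stop("configuration error: unknown sample '", sample, "'")
    stats::setNames(m$copies[, sample], rownames(m$copies))
  }
  need <- names(copies)[copies > 0]
  idx <- match(need, footprints$accession)
  if (anyNA(idx))
    stop("incomplete-input: missing footprint for ",
         paste(need[is.na(idx)], collapse = ", "))
  area <- pi * diameter_nm^2
  pos <- copies[need]
  c(lower = sum(pos * footprints$a_min[idx]) / area,
    upper = sum(pos * footprints$a_max[idx]) / area)
}
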