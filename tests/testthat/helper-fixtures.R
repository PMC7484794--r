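# Build a corona_matrix with prescribed copy numbers: emPAI values are set
# proportional to copies and M_total to the implied column mass, so
# build_corona_matrix reproduces `copies` exactly.
cm_from_copies <- function(copies, mw = NULL, captured = ncol(copies)) {
  if (is.null(colnames(copies)))
    colnames(copies) <- paste0("S", seq_len(ncol(copies)))
  if (is.null(rownames(copies)))
    rownames(copies) <- paste0("P", seq_len(nrow(copies)))
  if (is.null(mw)) mw <- rep(5e4, nrow(copies))
  records <- data.frame(accession = rownames(copies), mw_da = mw,
                        stringsAsFactors = FALSE)
  for (j in seq_len(ncol(copies))) records[[colnames(copies)[j]]] <- copies[, j]
  m_total <- colSums(copies * mw / AVOGADRO_CORONA)
  samples <- data.frame(
    label = colnames(copies),
    role = ifelse(seq_len(ncol(copies)) == captured, "captured", "control"),
    m_total = m_total, stringsAsFactors = FALSE)
  build_corona_matrix(records, samples)
}

# dense-direction projection oracle, written independently of the package's
# Fibonacci-lattice implementation: random directions + QR-completed basis
brute_force_cross_sections <- function(coords, n_dirs = 10000, seed = 42) {
  set.seed(seed)
  areas <- vapply(seq_len(n_dirs), function(k) {
    d <- stats::rnorm(3)
    d <- d / sqrt(sum(d^2))
    basis <- qr.Q(qr(cbind(d, diag(3)[, 1:2])))[, 2:3]
    u <- coords %*% basis
    h <- grDevices::chull(u)
    x <- u[h, 1]; y <- u[h, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }, 0)
  c(min = min(areas), max = max(areas))
}

# unit regular tetrahedron (edge sqrt(8)) used by the geometry checks
tetrahedron_coords <- function() {
  rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
}
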