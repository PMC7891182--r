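#' Region labels
#'
#' Default region names for an N-node connectome. For 90 nodes the standard
#' AAL-90 cortical/subcortical abbreviations are available via
#' [aal90_labels()]; generic networks use `R001 ... RNNN`.
#'
#' @param n Number of regions.
#' @return Character vector of length `n`.
#' @export
region_labels <- function(n) {
  sprintf("R%03d", seq_len(n))
}

#' AAL-90 region abbreviations
#'
#' Abbreviated names of the 90 cerebral regions (45 per hemisphere) of the
#' Automated Anatomical Labeling parcellation, in standard AAL order with
#' left/right alternating (e.g. `PreCG.L`, `PreCG.R`, ...). Useful for
#' relabelling 90-node matrices so reports read like the neuroimaging
#' literature.
#'
#' @return Character vector of length 90.
#' @export
aal90_labels <- function() {
  base <- c(
    "PreCG", "SFGdor", "ORBsup", "MFG", "ORBmid", "IFGoperc", "IFGtriang",
    "ORBinf", "ROL", "SMA", "OLF", "SFGmed", "ORBsupmed", "REC", "INS",
    "ACG", "DCG", "PCG", "HIP", "PHG", "AMYG", "CAL", "CUN", "LING",
    "SOG", "MOG", "IOG", "FFG", "PoCG", "SPG", "IPL", "SMG", "ANG",
    "PCUN", "PCL", "CAU", "PUT", "PAL", "THA", "HES", "STG", "TPOsup",
    "MTG", "TPOmid", "ITG"
  )
  as.vector(rbind(paste0(base, ".L"), paste0(base, ".R")))
}

#' Validate an FA-weighted connectivity matrix
#'
#' Checks that `w` is a square, symmetric, non-negative numeric matrix with a
#' zero diagonal and weights in `[0, 1]` (mean-FA edge weights). Small
#' numerical asymmetries (up to `tol`) are averaged away; larger ones are an
#' error. Row/column names are attached if missing.
#'
#' @param w Numeric matrix.
#' @param tol Largest tolerated absolute asymmetry.
#' @return The validated (and possibly symmetrized) matrix.
#' @export
as_connectivity_matrix <- function(w, tol = 1e-8) {
  if (!is.matrix(w) || !is.numeric(w)) {
    stop("connectivity matrix must be a numeric matrix", call. = FALSE)
  }
  if (nrow(w) != ncol(w)) stop("non-square matrix", call. = FALSE)
  if (anyNA(w)) stop("matrix contains missing values", call. = FALSE)
  if (any(w < 0)) stop("negative edge weights are not allowed", call. = FALSE)
  asym <- max(abs(w - t(w)))
  if (asym > tol) stop("matrix is not symmetric", call. = FALSE)
  if (asym > 0) w <- (w + t(w)) / 2
  diag(w) <- 0
  if (max(w) > 1 + 1e-12) {
    stop("edge weights must lie in [0, 1] (mean-FA scale)", call. = FALSE)
  }
  if (is.null(rownames(w))) {
    labs <- region_labels(nrow(w))
    dimnames(w) <- list(labs, labs)
  }
  w
}

# Upper-triangle edge index in ascending (i, j) lexicographic order.
# Returns a 2-column integer matrix; the canonical edge enumeration used by
# thresholding, edge statistics and NBS so tie-breaks are deterministic.
edge_index <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  cbind(i = i, j = as.integer(j))
}
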