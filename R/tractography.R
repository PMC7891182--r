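# Deterministic FACT-style streamline tracking on toy voxel grids, and
# streamline-to-matrix network construction (>=3 fibers per edge, mean-FA
# edge weights).

#' Voxel orientation field
#'
#' The tracking substrate: a 3-D grid with per-voxel fractional anisotropy,
#' principal fiber direction (unit vector), and parcel label (0 =
#' background). Direction vectors are normalized; a zero direction where
#' `fa > 0` is an error.
#'
#' @param fa 3-D numeric array of FA values in `[0, 1]` (1- or 2-D input is
#'   promoted by appending unit dimensions).
#' @param direction Numeric array of dimension `c(dim(fa), 3)` holding the
#'   per-voxel principal direction.
#' @param label Integer array of parcel identifiers, same dimension as `fa`.
#' @return An object of class `orientation_field`.
#' @export
orientation_field <- function(fa, direction, label) {
  fa <- promote_3d(fa)
  dm <- dim(fa)
  label <- promote_3d(label)
  if (!identical(dim(label), dm)) {
    stop("label array dimensions must match fa", call. = FALSE)
  }
  if (length(dim(direction)) == length(dm)) {
    # allow direction supplied with trailing component axis collapsed oddly
    stop("direction must have a trailing length-3 component axis", call. = FALSE)
  }
  direction <- array(direction, dim = c(dm, 3))
  if (anyNA(fa) || any(fa < 0) || any(fa > 1)) {
    stop("fa values must lie in [0, 1]", call. = FALSE)
  }
  nvox <- prod(dm)
  dmat <- matrix(direction, nrow = nvox, ncol = 3)
  nrm <- sqrt(rowSums(dmat^2))
  active <- as.vector(fa) > 0
  if (any(active & nrm == 0)) {
    stop("zero direction vector at a voxel with fa > 0", call. = FALSE)
  }
  dmat[nrm > 0, ] <- dmat[nrm > 0, , drop = FALSE] / nrm[nrm > 0]
  structure(
    list(shape = dm, fa = fa, direction = array(dmat, c(dm, 3)),
         label = array(as.integer(label), dm)),
    class = "orientation_field"
  )
}

promote_3d <- function(x) {
  if (is.null(dim(x))) dim(x) <- c(length(x), 1L, 1L)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) stop("expected a 1-, 2- or 3-D array", call. = FALSE)
  x
}

#' Tracking parameters for FACT-style streamline propagation
#'
#' @param fa_seed_min FA threshold used both for seeding and termination
#'   (default 0.2): voxels with `fa >= fa_seed_min` are seeds, and a
#'   streamline stops before entering a voxel below it.
#' @param angle_max_deg Maximum turning angle between consecutive step
#'   directions in degrees (default 45).
#' @param max_steps Safety cap on steps per half-track.
#' @return A `tracking_params` list.
#' @export
tracking_params <- function(fa_seed_min = 0.2, angle_max_deg = 45,
                            max_steps = 1000) {
  if (!is_scalar(fa_seed_min) || fa_seed_min <= 0 || fa_seed_min >= 1) {
    stop("fa_seed_min must lie in (0, 1)", call. = FALSE)
  }
  if (!is_scalar(angle_max_deg) || angle_max_deg <= 0 || angle_max_deg >= 90) {
    stop("angle_max_deg must lie in (0, 90)", call. = FALSE)
  }
  list(fa_seed_min = fa_seed_min, angle_max_deg = angle_max_deg,
       max_steps = max_steps)
}

# Nearest-neighbour voxel offset for a unit direction: component-wise
# rounding; a degenerate all-zero offset falls back to the dominant axis.
step_offset <- function(d) {
  o <- round(d)
  if (all(o == 0)) {
    ax <- which.max(abs(d))
    o[ax] <- sign(d[ax])
  }
  o
}

# One half-track from voxel `v0` with initial travel direction `d0`.
# Voxel-hop propagation: step to the neighbour indicated by the current
# direction; stop when leaving the grid, when the next voxel's FA is below
# threshold, or when its (sign-aligned) direction turns by more than the
# angle limit relative to the current travel direction.
propagate <- function(field, params, v0, d0) {
  dm <- field$shape
  path <- matrix(v0, nrow = 1)
  v <- v0
  d <- d0
  cosmin <- cos(params$angle_max_deg * pi / 180)
  for (s in seq_len(params$max_steps)) {
    nxt <- v + step_offset(d)
    if (any(nxt < 1) || any(nxt > dm)) break
    if (field$fa[nxt[1], nxt[2], nxt[3]] < params$fa_seed_min) break
    dn <- field$direction[nxt[1], nxt[2], nxt[3], ]
    dotp <- sum(d * dn)
    if (dotp < 0) {
      dn <- -dn
      dotp <- -dotp
    }
    if (dotp < cosmin - 1e-12) break
    path <- rbind(path, nxt)
    v <- nxt
    d <- dn
  }
  path
}

#' Deterministic FACT-style whole-field streamline tracking
#'
#' Launches one bidirectional streamline from every voxel with
#' `fa >= fa_seed_min`, propagating voxel-to-voxel along the local principal
#' direction. The two half-tracks (along `+direction` and `-direction` of the
#' seed) are concatenated. A half-track terminates when the next voxel lies
#' outside the grid, has FA below the threshold, or when the local direction
#' turns by more than `angle_max_deg` relative to the current travel
#' direction (directions are sign-aligned first, so the turning angle is at
#' most 90 degrees). Seeds that cannot move in either direction produce no
#' streamline (a streamline has at least two points). Tracking is fully
#' deterministic.
#'
#' @param field An [orientation_field()].
#' @param params A [tracking_params()].
#' @return An object of class `streamline_set`: list with `paths` (list of
#'   k x 3 voxel-coordinate matrices), `fa` (list of per-voxel FA values
#'   along each path), and `endpoints` (2-column matrix of parcel labels at
#'   the two ends).
#' @export
track_fact <- function(field, params = tracking_params()) {
  stopifnot(inherits(field, "orientation_field"))
  seeds <- which(field$fa >= params$fa_seed_min, arr.ind = TRUE)
  paths <- list()
  for (r in seq_len(nrow(seeds))) {
    v0 <- as.integer(seeds[r, ])
    d0 <- field$direction[v0[1], v0[2], v0[3], ]
    fwd <- propagate(field, params, v0, d0)
    bwd <- propagate(field, params, v0, -d0)
    if (nrow(bwd) > 1) {
      path <- rbind(bwd[nrow(bwd):2, , drop = FALSE], fwd)
    } else {
      path <- fwd
    }
    if (nrow(path) >= 2) paths[[length(paths) + 1L]] <- unname(path)
  }
  fa_along <- lapply(paths, function(p) {
    field$fa[p]
  })
  endpoints <- if (length(paths)) {
    t(vapply(paths, function(p) {
      c(field$label[p[1, , drop = FALSE]],
        field$label[p[nrow(p), , drop = FALSE]])
    }, integer(2)))
  } else {
    matrix(integer(0), 0, 2)
  }
  structure(
    list(paths = paths, fa = fa_along, endpoints = endpoints),
    class = "streamline_set"
  )
}

#' Build an FA-weighted connectivity matrix from streamlines
#'
#' Two regions are connected by an edge only when at least `min_fibers`
#' streamlines run between them (default 3, which suppresses spurious
#' connections); the edge weight is the mean FA over all voxels of all
#' connecting streamlines. Streamlines with a background endpoint (label 0)
#' or with both endpoints in the same region are discarded. The result is
#' symmetric with a zero diagonal.
#'
#' @param streams A `streamline_set`.
#' @param n_regions Number of regions (matrix dimension).
#' @param min_fibers Minimum streamline count for an edge.
#' @return A connectivity matrix (`n_regions` x `n_regions`).
#' @export
build_matrix <- function(streams, n_regions, min_fibers = 3) {
  stopifnot(inherits(streams, "streamline_set"))
  if (!is_count(min_fibers)) stop("min_fibers must be >= 1", call. = FALSE)
  if (!is_count(n_regions, min = 2)) {
    stop("n_regions must be an integer >= 2", call. = FALSE)
  }
  ep <- streams$endpoints
  if (nrow(ep) > 0 && any(ep < 0 | ep > n_regions)) {
    stop("endpoint labels outside 0..n_regions", call. = FALSE)
  }
  labs <- region_labels(n_regions)
  counts <- matrix(0L, n_regions, n_regions)
  fa_sum <- matrix(0, n_regions, n_regions)
  vox_n <- matrix(0, n_regions, n_regions)
  for (k in seq_len(nrow(ep))) {
    a <- ep[k, 1]
    b <- ep[k, 2]
    if (a == 0L || b == 0L || a == b) next
    i <- min(a, b)
    j <- max(a, b)
    counts[i, j] <- counts[i, j] + 1L
    fa_sum[i, j] <- fa_sum[i, j] + sum(streams$fa[[k]])
    vox_n[i, j] <- vox_n[i, j] + length(streams$fa[[k]])
  }
  w <- matrix(0, n_regions, n_regions, dimnames = list(labs, labs))
  ok <- which(counts >= min_fibers, arr.ind = TRUE)
  if (nrow(ok)) {
    w[ok] <- fa_sum[ok] / vox_n[ok]
    w[ok[, c(2, 1), drop = FALSE]] <- w[ok]
  }
  as_connectivity_matrix(w)
}

#' Write an orientation field to JSON
#'
#' A single JSON document with the grid shape and the flattened (column-
#' major) fa, direction and label arrays.
#'
#' @param field An `orientation_field`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_orientation_field <- function(field, path) {
  stopifnot(inherits(field, "orientation_field"))
  jsonlite::write_json(
    list(
      shape = field$shape,
      fa = as.vector(field$fa),
      direction = as.vector(field$direction),
      label = as.vector(field$label)
    ),
    path, auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

#' Read an orientation field from JSON
#'
#' @param path File written by [write_orientation_field()].
#' @return An `orientation_field`.
#' @export
read_orientation_field <- function(path) {
  rec <- jsonlite::fromJSON(path)
  dm <- as.integer(rec$shape)
  orientation_field(
    fa = array(as.numeric(rec$fa), dm),
    direction = array(as.numeric(rec$direction), c(dm, 3)),
    label = array(as.integer(rec$label), dm)
  )
}

#' Serialize streamlines as JSON lines
#'
#' One streamline per line: voxel coordinates, per-voxel FA, endpoint labels.
#'
#' @param streams A `streamline_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_streamlines_jsonl <- function(streams, path) {
  stopifnot(inherits(streams, "streamline_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(streams$paths)) {
    writeLines(jsonlite::toJSON(list(
      coords = streams$paths[[k]],
      fa = streams$fa[[k]],
      endpoints = streams$endpoints[k, ]
    ), auto_unbox = FALSE, digits = NA), con)
  }
  invisible(path)
}

#' Read streamlines from JSON lines
#'
#' @param path File written by [write_streamlines_jsonl()].
#' @return A `streamline_set`.
#' @export
read_streamlines_jsonl <- function(path) {
  lines <- readLines(path)
  paths <- vector("list", length(lines))
  fa <- vector("list", length(lines))
  endpoints <- matrix(integer(0), 0, 2)
  if (length(lines)) {
    recs <- lapply(lines, jsonlite::fromJSON)
    paths <- lapply(recs, function(r) matrix(as.integer(r$coords), ncol = 3))
    fa <- lapply(recs, function(r) as.numeric(r$fa))
    endpoints <- t(vapply(recs, function(r) as.integer(r$endpoints),
                          integer(2)))
  }
  structure(list(paths = paths, fa = fa, endpoints = endpoints),
            class = "streamline_set")
}
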