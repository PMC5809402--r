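# Radial B-spline basis over a masked 3D voxel grid: the image-side
# dimension reduction. A lattice of knots with spacing g0 carries one
# compactly supported radial basis function each (support radius 2g,
# g = sqrt(3 g0^2)); stacking phi(distance) into a V x q matrix B turns an
# n x V image panel Y0 into the n x q response matrix Y = Y0 B, and any
# q-vector of weights maps back to a voxel map as B w.

#' Compactly supported radial B-spline
#'
#' Piecewise-cubic radial function of distance \code{d} with scale \code{g}:
#' \deqn{\varphi(d) = \frac{1}{4g^2}\begin{cases}
#'   g^3 + 3g^2(g-d) + 3g(g-d)^2 - 3(g-d)^3 & d \le g \\
#'   (2g-d)^3 & g < d \le 2g \\
#'   0 & d > 2g.\end{cases}}
#' \eqn{\varphi} is continuous, nonincreasing on \eqn{[0, 2g]}, equals
#' \eqn{g} at \eqn{d = 0} and vanishes beyond \eqn{2g} (compact support).
#'
#' @param d Nonnegative distance(s), in voxel units.
#' @param g Positive support scale (support radius is \code{2 * g}).
#' @return Numeric vector of \eqn{\varphi(d)} values in \eqn{[0, g]}.
#' @examples
#' radial_bspline(0, g = 2)   # == g
#' radial_bspline(4, g = 2)   # == 0 at the support boundary
#' @export
radial_bspline <- function(d, g) {
  if (!is.numeric(g) || length(g) != 1L || g <= 0)
    stop_netpls("'g' must be a positive scalar", "netpls_invalid_argument")
  if (any(d < 0)) stop_netpls("'d' must be nonnegative", "netpls_invalid_argument")
  out <- numeric(length(d))
  i1 <- d <= g
  i2 <- d > g & d <= 2 * g
  gd <- g - d[i1]
  out[i1] <- (g^3 + 3 * g^2 * gd + 3 * g * gd^2 - 3 * gd^3) / (4 * g^2)
  out[i2] <- (2 * g - d[i2])^3 / (4 * g^2)
  out
}

#' Support scale from knot spacing
#'
#' The basis scale is tied to the lattice: \code{g = sqrt(3 * g0^2)}, the
#' half-diagonal relation that makes neighbouring basis functions overlap.
#'
#' @param g0 Positive spacing between adjacent knots (voxels).
#' @return The support scale \code{g} (voxels).
#' @examples
#' knot_scale(4) # 6.93 to two decimals
#' @export
knot_scale <- function(g0) {
  if (!is.numeric(g0) || length(g0) != 1L || g0 <= 0)
    stop_netpls("'g0' must be a positive scalar", "netpls_invalid_argument")
  sqrt(3 * g0^2)
}

#' Image panel: vectorized masked 3D images
#'
#' Bundles an n x V intensity matrix with the binary mask and the 0-based
#' grid coordinates of its voxels. Voxel order is the mask scan order with
#' the first (x) index fastest, and is fixed for all downstream artifacts.
#'
#' @param data n x V numeric matrix (rows = subjects, columns = mask voxels),
#'   or an n x dx x dy x dz array to be masked and vectorized.
#' @param mask Binary 3D array; nonzero entries define the V voxels.
#' @return An object of class \code{image_panel} with fields \code{data},
#'   \code{mask}, \code{voxel_coords} (V x 3 integer, 0-based).
#' @export
image_panel <- function(data, mask) {
  mask <- (mask != 0)
  if (length(dim(mask)) != 3L)
    stop_netpls("mask must be a 3D array", "netpls_invalid_argument")
  idx <- which(mask)                       # column-major: x fastest
  if (length(idx) == 0L) stop_netpls("mask is empty", "netpls_empty_input")
  coords <- arrayInd(idx, dim(mask)) - 1L  # 0-based
  if (length(dim(data)) == 4L) {
    if (!all(dim(data)[2:4] == dim(mask)))
      stop_netpls("image grid does not match mask", "netpls_dimension_mismatch")
    data <- matrix(data, nrow = dim(data)[1L])[, idx, drop = FALSE]
  }
  data <- as.matrix(data)
  if (ncol(data) != length(idx))
    stop_netpls("data has wrong number of voxels for this mask",
                "netpls_dimension_mismatch")
  if (anyNA(data))
    stop_netpls("image data contains missing values", "netpls_invalid_argument")
  structure(list(data = data, mask = mask, voxel_coords = coords,
                 linear_index = idx),
            class = "image_panel")
}

#' Place basis knots on a regular lattice over a mask
#'
#' Knots start at the minimum corner of the mask bounding box and step by
#' \code{spacing_g0} along each axis up to the box's far corner. A knot is
#' retained iff at least one mask voxel lies within its support radius
#' \code{2 * g} — this keeps q minimal without losing coverage. Deterministic
#' given mask and spacing.
#'
#' @param mask Binary 3D array with at least one nonzero voxel.
#' @param spacing_g0 Positive knot spacing (voxels), typically 4.
#' @return \code{knot_grid} object: \code{spacing_g0}, \code{support_scale_g},
#'   \code{knots} (q x 3 integer matrix, 0-based grid positions).
#' @export
place_knots <- function(mask, spacing_g0) {
  if (spacing_g0 < 1)
    stop_netpls("'spacing_g0' must be >= 1", "netpls_invalid_argument")
  mask <- (mask != 0)
  idx <- which(mask)
  if (length(idx) == 0L) stop_netpls("mask is empty", "netpls_empty_input")
  coords <- arrayInd(idx, dim(mask)) - 1L
  g <- knot_scale(spacing_g0)
  lo <- apply(coords, 2L, min)
  hi <- apply(coords, 2L, max)
  axes <- lapply(1:3, function(a) lo[a] + spacing_g0 * (0:floor((hi[a] - lo[a]) / spacing_g0)))
  knots <- as.matrix(expand.grid(x = axes[[1L]], y = axes[[2L]], z = axes[[3L]]))
  keep <- .min_dist2_below(knots, coords, (2 * g)^2)
  structure(list(spacing_g0 = spacing_g0, support_scale_g = g,
                 knots = knots[keep, , drop = FALSE]),
            class = "knot_grid")
}

# for each row of `pts`, TRUE iff some row of `ref` is within sqrt(thr2)
.min_dist2_below <- function(pts, ref, thr2) {
  rr <- rowSums(ref^2)
  vapply(seq_len(nrow(pts)), function(i) {
    d2 <- rr - 2 * drop(ref %*% pts[i, ]) + sum(pts[i, ]^2)
    any(d2 <= thr2 + 1e-9)
  }, logical(1L))
}

#' Build the V x q radial basis matrix
#'
#' \code{B[i, j] = phi(||voxel_i - knot_j||_2, g)}; entries vanish beyond the
#' support radius so B is sparse (stored as \code{dgCMatrix}). Knot columns
#' with no support in the mask are dropped (with a message); voxels outside
#' every knot's support give all-zero rows (with a warning) but are kept.
#'
#' @param panel \code{image_panel} (only its geometry is used) or a mask array.
#' @param knot_grid \code{knot_grid} from \code{\link{place_knots}}.
#' @return \code{rbf_basis} object: \code{B} (sparse V x q), \code{knot_grid},
#'   \code{dropped} (indices of dropped knot columns).
#' @export
build_basis <- function(panel, knot_grid) {
  if (!inherits(knot_grid, "knot_grid"))
    stop_netpls("'knot_grid' must come from place_knots()", "netpls_invalid_argument")
  if (!inherits(panel, "image_panel")) panel <- image_panel(
    matrix(0, 1L, sum(panel != 0)), panel)
  coords <- panel$voxel_coords
  knots <- knot_grid$knots
  g <- knot_grid$support_scale_g
  V <- nrow(coords); q0 <- nrow(knots)
  rr <- rowSums(coords^2)
  trip_i <- vector("list", q0); trip_x <- vector("list", q0)
  for (j in seq_len(q0)) {
    d2 <- rr - 2 * drop(coords %*% knots[j, ]) + sum(knots[j, ]^2)
    hit <- which(d2 <= (2 * g)^2 + 1e-9)
    trip_i[[j]] <- hit
    trip_x[[j]] <- radial_bspline(sqrt(pmax(d2[hit], 0)), g)
  }
  lens <- lengths(trip_i)
  B <- Matrix::sparseMatrix(i = unlist(trip_i), j = rep.int(seq_len(q0), lens),
                            x = unlist(trip_x), dims = c(V, q0))
  nz_col <- Matrix::colSums(B != 0) > 0
  dropped <- which(!nz_col)
  if (length(dropped)) {
    message(length(dropped), " knot column(s) with no mask support dropped")
    B <- B[, nz_col, drop = FALSE]
    knot_grid$knots <- knots[nz_col, , drop = FALSE]
  }
  if (any(Matrix::rowSums(B != 0) == 0))
    warning("some mask voxels are outside the support of every knot")
  structure(list(B = B, knot_grid = knot_grid, dropped = dropped,
                 id = rlang::hash(list(knot_grid$knots, knot_grid$spacing_g0))),
            class = "rbf_basis")
}

#' Reduce an image panel through the basis: Y = Y0 B
#'
#' @param panel \code{image_panel} with V voxels matching the basis rows.
#' @param basis \code{rbf_basis}.
#' @return \code{reduced_image_matrix}: dense n x q matrix \code{Y} plus
#'   \code{basis_ref}, the identifier of the producing basis.
#' @export
reduce_images <- function(panel, basis) {
  if (ncol(panel$data) != nrow(basis$B))
    stop_netpls("panel voxel count does not match basis rows",
                "netpls_dimension_mismatch")
  Y <- as.matrix(panel$data %*% basis$B)
  colnames(Y) <- paste0("rbf", seq_len(ncol(Y)))
  structure(list(Y = Y, basis_ref = basis$id), class = "reduced_image_matrix")
}

#' Re-map basis-space weights onto a voxel map
#'
#' Computes \code{values = B \%*\% w}, optionally zeroing entries with
#' \eqn{|value| \le tol}. With the default \code{tol = 0} the nonzero-voxel
#' count is the count of strict nonzeros; a positive \code{tol} (or a
#' relative threshold applied by the caller) gives a tighter support — the
#' mapping from basis-space sparsity to voxel counts is deliberately exposed
#' rather than fixed.
#'
#' @param w Numeric q-vector of basis weights.
#' @param basis \code{rbf_basis}.
#' @param tol Nonnegative absolute threshold; values with \code{abs(v) <= tol}
#'   are set to exactly 0 (default 0).
#' @param source Optional component index recorded on the map.
#' @return \code{brain_map}: \code{values} (length V, aligned with the
#'   panel's voxel order), \code{n_nonzero}, \code{source}.
#' @export
remap_weights <- function(w, basis, tol = 0, source = NA_integer_) {
  if (length(w) != ncol(basis$B))
    stop_netpls("length(w) must equal the number of basis columns",
                "netpls_dimension_mismatch")
  if (tol < 0) stop_netpls("'tol' must be nonnegative", "netpls_invalid_argument")
  v <- as.numeric(basis$B %*% w)
  if (tol > 0) v[abs(v) <= tol] <- 0
  structure(list(values = v, n_nonzero = sum(v != 0), source = source),
            class = "brain_map")
}

#' Half-maximum support of a brain map
#'
#' The basis cannot localize below its own support radius, so the raw
#' nonzero set of \code{B w} is a union of 2g-balls. The conventional way to
#' delimit the extent of a smooth blob is its half-maximum set; this returns
#' the voxel indices with \code{abs(value) >= frac * max(abs(value))}.
#'
#' @param map \code{brain_map}.
#' @param frac Relative threshold in (0, 1]; default 0.5 (half maximum).
#' @return Integer vector of voxel indices (into the panel's voxel order).
#' @export
brain_map_support <- function(map, frac = 0.5) {
  v <- abs(map$values)
  m <- max(v)
  if (m == 0) return(integer(0))
  which(v >= frac * m)
}
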