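#' Rigid transform (rotation + translation)
#'
#' @param rotation dim x dim rotation matrix (orthogonal, det +1)
#' @param translation translation vector in metres
#' @return object of class `rigid_transform`
#' @export
rigid_transform <- function(rotation, translation) {
  rotation <- as.matrix(rotation)
  d <- nrow(rotation)
  stopifnot(ncol(rotation) == d, length(translation) == d)
  if (max(abs(crossprod(rotation) - diag(d))) > 1e-10)
    stop("rotation matrix is not orthogonal")
  if (abs(det(rotation) - 1) > 1e-10)
    stop("rotation matrix must have determinant +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  d <- nrow(x$rotation)
  ang <- if (d == 2) atan2(x$rotation[2, 1], x$rotation[1, 1]) * 180 / pi else
    acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform> %d-D, rotation angle %.3f deg, translation (%s) mm\n",
              d, ang, paste(signif(x$translation * 1e3, 4), collapse = ", ")))
  invisible(x)
}

#' Apply a rigid transform to points
#' @param transform a `rigid_transform`
#' @param points matrix, one point per row (m)
#' @return transformed points
#' @export
apply_rigid <- function(transform, points) {
  points <- rbind(points)
  sweep(points %*% t(transform$rotation), 2, transform$translation, `+`)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`
#' @return the inverse `rigid_transform`
#' @export
invert_rigid <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Rotation matrix about a coordinate axis
#' @param angle_deg rotation angle in degrees
#' @param axis axis index (ignored in 2-D), 1 = x, 2 = y, 3 = z
#' @param dim 2 or 3
#' @return rotation matrix
#' @export
rotation_about_axis <- function(angle_deg, axis = 3, dim = 3) {
  th <- angle_deg * pi / 180
  c2 <- cos(th); s2 <- sin(th)
  if (dim == 2) return(matrix(c(c2, s2, -s2, c2), 2, 2))
  R <- diag(3)
  ij <- setdiff(1:3, axis)
  R[ij[1], ij[1]] <- c2; R[ij[2], ij[2]] <- c2
  # sign convention: right-handed rotation about the named axis
  if (axis == 2) { R[ij[1], ij[2]] <- s2; R[ij[2], ij[1]] <- -s2 }
  else { R[ij[1], ij[2]] <- -s2; R[ij[2], ij[1]] <- s2 }
  R
}

#' Rigid registration of two point sets (Kabsch algorithm)
#'
#' Finds the rotation `R` (det +1) and translation `t` minimising
#' `sum_k ||R src_k + t - dst_k||^2`, via the SVD of the cross-covariance of
#' the centred point sets. Used to register fiducial marker positions seen in
#' the adjunct CT/MR skull image (`src`) to the same markers localised in the
#' photoacoustic frame of reference (`dst`). A reflection solution is
#' corrected by flipping the smallest singular direction.
#'
#' @param src_points K x dim matrix of source points (m)
#' @param dst_points K x dim matrix of destination points (m)
#' @return a `rigid_transform` with an extra field `rmsd`, the root mean
#'   square residual after alignment (m)
#' @examples
#' src <- matrix(rnorm(18), 6, 3)
#' tr0 <- rigid_transform(rotation_about_axis(30, 3), c(0.01, 0, 0))
#' fit <- kabsch_register(src, apply_rigid(tr0, src))
#' fit$rmsd  # ~0
#' @export
kabsch_register <- function(src_points, dst_points) {
  src <- as.matrix(src_points); dst <- as.matrix(dst_points)
  d <- ncol(src)
  stopifnot(ncol(dst) == d, nrow(src) == nrow(dst))
  K <- nrow(src)
  if (K < d) stop(sprintf("need at least %d points in %d-D", d, d))
  cs <- colMeans(src); cd <- colMeans(dst)
  X <- sweep(src, 2, cs); Y <- sweep(dst, 2, cd)
  H <- crossprod(X, Y)   # dim x dim cross-covariance
  sv <- svd(H)
  # degenerate (collinear/coincident) configurations leave the rotation
  # under-determined
  if (sv$d[d - 1] <= max(sv$d[1], 1) * 1e-12 * max(abs(X)) ||
      (d == 2 && sv$d[1] == 0))
    stop("degenerate point configuration: cross-covariance is rank deficient")
  S <- diag(d)
  if (det(sv$v %*% t(sv$u)) < 0) S[d, d] <- -1
  R <- sv$v %*% S %*% t(sv$u)
  tvec <- cd - as.numeric(R %*% cs)
  out <- rigid_transform(R, tvec)
  res <- sweep(src %*% t(R), 2, tvec, `+`) - dst
  out$rmsd <- sqrt(mean(rowSums(res^2)))
  out
}

#' Read fiducial marker points from CSV
#'
#' Plain-text CSV with a header line and one point per row; columns `x`, `y`
#' and (in 3-D) `z`, all in metres.
#'
#' @param path CSV file path
#' @return numeric matrix, one point per row
#' @export
read_fiducials_csv <- function(path) {
  df <- utils::read.csv(path)
  cols <- intersect(c("x", "y", "z"), names(df))
  if (length(cols) < 2) stop("fiducial CSV must have header columns x,y[,z]")
  as.matrix(df[, cols, drop = FALSE])
}

#' Write fiducial marker points to CSV
#' @param points matrix with 2 or 3 columns (m)
#' @param path output path
#' @export
write_fiducials_csv <- function(points, path) {
  points <- as.matrix(points)
  colnames(points) <- c("x", "y", "z")[seq_len(ncol(points))]
  utils::write.csv(as.data.frame(points), path, row.names = FALSE)
  invisible(path)
}
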