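#' Skull mask on a grid
#'
#' @param mask logical array on `grid`
#' @param grid a `pact_grid`
#' @param provenance free text, e.g. "CT", "MR" or "synthetic"
#' @return object of class `skull_mask`
#' @export
skull_mask <- function(mask, grid, provenance = "synthetic") {
  stopifnot(inherits(grid, "pact_grid"))
  mask <- .as_field(mask, grid) > 0
  structure(list(mask = mask, grid = grid, provenance = provenance),
            class = "skull_mask")
}

#' @export
print.skull_mask <- function(x, ...) {
  cat(sprintf("<skull_mask> %s, %d bone voxels (%.1f%%), provenance %s\n",
              paste(x$grid$shape, collapse = "x"), sum(x$mask),
              100 * mean(x$mask), x$provenance))
  invisible(x)
}

# ---- n-D binary morphology -------------------------------------------------
# EBImage's morphology is 2-D only; these shift-based primitives work for both
# 2-D and 3-D arrays and are exact on binary inputs.

.ball_offsets <- function(radius, dim) {
  if (radius <= 0) return(matrix(0L, 1, dim))
  r <- seq(-radius, radius)
  g <- as.matrix(do.call(expand.grid, rep(list(r), dim)))
  g[rowSums(g^2) <= radius^2 + 1e-9, , drop = FALSE]
}

.shift_logical <- function(x, off) {
  d <- dim(x)
  idx <- lapply(seq_along(d), function(a) {
    i <- seq_len(d[a]) - off[a]
    i[i < 1 | i > d[a]] <- NA
    i
  })
  out <- do.call(`[`, c(list(x), idx))
  out[is.na(out)] <- FALSE
  dim(out) <- d
  out
}

.dilate <- function(x, offsets) {
  out <- array(FALSE, dim(x))
  for (k in seq_len(nrow(offsets))) out <- out | .shift_logical(x, offsets[k, ])
  out
}

.erode <- function(x, offsets) !.dilate(!x, -offsets)

#' Connected-component labelling of a binary array (2-D or 3-D)
#'
#' Face-connectivity labelling by iterative frontier expansion; returns an
#' integer array with 0 for background and 1..n for components (component 1
#' is the largest).
#'
#' @param mask logical array
#' @return integer array of labels
#' @export
label_components <- function(mask) {
  mask <- as.array(mask) > 0
  d <- dim(mask)
  nd <- length(d)
  face <- matrix(0L, 2 * nd, nd)
  for (a in seq_len(nd)) { face[2 * a - 1, a] <- 1L; face[2 * a, a] <- -1L }
  labels <- array(0L, d)
  lab <- 0L
  remaining <- mask
  while (any(remaining)) {
    lab <- lab + 1L
    seed <- which(remaining)[1]
    comp <- array(FALSE, d)
    comp[seed] <- TRUE
    repeat {
      grow <- .dilate(comp, face) & mask & !comp
      if (!any(grow)) break
      comp <- comp | grow
    }
    labels[comp] <- lab
    remaining <- remaining & !comp
  }
  # relabel by decreasing size
  if (lab > 1L) {
    sizes <- tabulate(labels[labels > 0L], nbins = lab)
    ord <- order(sizes, decreasing = TRUE)
    remap <- integer(lab); remap[ord] <- seq_len(lab)
    labels[labels > 0L] <- remap[labels[labels > 0L]]
  }
  labels
}

#' Global Otsu threshold of a numeric array
#' @noRd
.otsu_threshold <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) stop("constant volume: threshold is undefined")
  xn <- (x - rng[1]) / (rng[2] - rng[1])
  # EBImage's Otsu operates per 2-D frame; flatten to a single frame so the
  # threshold is computed from the global histogram
  thr <- EBImage::otsu(matrix(xn, nrow = dim(as.array(x))[1]), range = c(0, 1))
  rng[1] + thr * (rng[2] - rng[1])
}

#' Binarize a skull volume and fill enclosed pores
#'
#' Thresholds a CT/MR-derived scalar volume into a bone mask, applies a
#' morphological closing, and fills cavities that are fully enclosed within
#' the bone wall. The cranial cavity -- identified as the largest non-bone
#' component that does not touch the grid boundary -- is preserved as
#' non-bone, so the fluid interior remains a single connected component.
#'
#' @param volume numeric array (2-D or 3-D)
#' @param grid the `pact_grid` the volume lives on
#' @param threshold `"otsu"` (default) or an explicit numeric threshold;
#'   voxels with `volume >= threshold` become bone
#' @param invert set `TRUE` for negative-contrast volumes (e.g. MR of bone in
#'   water) where bone is dark
#' @param closing_radius radius in voxels of the binary closing applied
#'   before hole filling (default 2; 0 disables)
#' @param provenance recorded in the returned mask ("CT", "MR", "synthetic")
#' @return a `skull_mask`
#' @export
binarize_fill_mask <- function(volume, grid, threshold = "otsu", invert = FALSE,
                               closing_radius = 2, provenance = "CT") {
  volume <- .as_field(volume, grid)
  if (any(!is.finite(volume))) stop("volume contains non-finite values")
  if (invert) volume <- max(volume) - volume
  thr <- if (identical(threshold, "otsu")) .otsu_threshold(volume) else as.numeric(threshold)
  mask <- volume >= thr
  if (all(mask) || !any(mask))
    stop(sprintf("pathological threshold %g: mask is uniformly %s", thr, all(mask)))
  if (closing_radius > 0) {
    off <- .ball_offsets(closing_radius, grid$dim)
    mask <- .erode(.dilate(mask, off), off)
  }
  mask <- .fill_enclosed_pores(mask)
  skull_mask(mask, grid, provenance)
}

#' Fill pores enclosed in the bone wall, preserving the cranial cavity
#' @noRd
.fill_enclosed_pores <- function(mask) {
  labels <- label_components(!mask)
  n <- max(labels)
  if (n == 0L) return(mask)
  d <- dim(mask)
  nd <- length(d)
  touches <- logical(n)
  for (a in seq_len(nd)) {
    idx <- lapply(d, seq_len)
    for (side in c(1L, d[a])) {
      idx_a <- idx; idx_a[[a]] <- side
      face <- do.call(`[`, c(list(labels), idx_a))
      touches[unique(face[face > 0L])] <- TRUE
    }
  }
  enclosed <- which(!touches)
  if (length(enclosed) == 0L) return(mask)
  sizes <- tabulate(labels[labels > 0L], nbins = n)
  cavity <- enclosed[which.max(sizes[enclosed])]
  fill <- setdiff(enclosed, cavity)
  if (length(fill)) mask[labels %in% fill] <- TRUE
  mask
}

#' Resample a mask onto a grid under a rigid transform
#'
#' Applies `transform` to the mask (by inverse mapping of target voxel
#' centres) and samples it onto `target` with nearest-neighbour
#' interpolation, preserving binarity.
#'
#' @param mask a `skull_mask`
#' @param transform a `rigid_transform` mapping source coordinates to target
#'   coordinates
#' @param target target `pact_grid`
#' @return a `skull_mask` on `target`
#' @export
rasterize_mask <- function(mask, transform, target) {
  stopifnot(inherits(mask, "skull_mask"), inherits(target, "pact_grid"))
  if (mask$grid$dim != target$dim) stop("dimension mismatch")
  inv <- invert_rigid(transform)
  xyz <- grid_coords(target)
  src <- apply_rigid(inv, xyz)
  idx <- round(coord_to_index(mask$grid, src))
  inb <- rep(TRUE, nrow(idx))
  for (a in seq_len(target$dim))
    inb <- inb & idx[, a] >= 1 & idx[, a] <= mask$grid$shape[a]
  out <- logical(nrow(idx))
  if (any(inb)) {
    lin <- idx[inb, 1]
    mult <- 1
    for (a in seq_len(target$dim - 1)) {
      mult <- mult * mask$grid$shape[a]
      lin <- lin + (idx[inb, a + 1] - 1) * mult
    }
    out[inb] <- mask$mask[lin]
  }
  if (!any(out) && any(mask$mask))
    stop("transformed mask falls entirely outside the target grid")
  skull_mask(array(out, target$shape), target, mask$provenance)
}

#' Jaccard overlap of two masks
#' @param a,b logical arrays or `skull_mask` objects of equal shape
#' @return intersection-over-union in [0, 1]
#' @export
jaccard <- function(a, b) {
  if (inherits(a, "skull_mask")) a <- a$mask
  if (inherits(b, "skull_mask")) b <- b$mask
  sum(a & b) / sum(a | b)
}
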