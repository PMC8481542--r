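#' Convert cubic Angstrom to litres
#'
#' `1 A^3 = 1e-27 L` exactly, so a confined inter-translocase volume of
#' 28,237 A^3 is 2.82e-23 L and 46,659 A^3 is 4.66e-23 L.
#'
#' @param v volume(s) in cubic Angstrom (>= 0).
#' @return volume(s) in litres.
#' @examples
#' angstrom3ToLiters(28237)  # 2.8237e-23
#' @export
angstrom3ToLiters <- function(v) {
  .stopIfNot(all(v >= 0), "'v' must be >= 0")
  v * 1e-27
}

#' Effective molar concentration in a confined volume
#'
#' The local ("affinity trap") concentration of `n` molecules confined
#' to a volume of `v` cubic Angstrom:
#' `1000 * n / (N_A * v * 1e-27)` millimolar, with the Avogadro constant
#' fixed at its exact SI value 6.02214076e23 / mol. A single presequence
#' confined to 28,237-46,659 A^3 corresponds to 58.8-35.6 mM — orders of
#' magnitude above the micromolar-to-submillimolar dissociation
#' constants of the intermembrane-space receptor domains, which is what
#' makes the confined junction an affinity trap.
#'
#' @param n number of molecules (>= 1).
#' @param v confining volume, cubic Angstrom (> 0).
#' @return concentration in mM. Linear in `n`; halving `v` doubles it.
#' @examples
#' molarityFromVolume(1, 28237)  # 58.8 mM
#' molarityFromVolume(1, 46659)  # 35.6 mM
#' @export
molarityFromVolume <- function(n, v) {
  .stopIfNot(all(n >= 1), "'n' must be >= 1")
  .stopIfNot(all(v > 0), "'v' must be > 0")
  avogadro <- 6.02214076e23
  1000 * n / (avogadro * v * 1e-27)
}

#' Axis-aligned bounding cuboid of a point set
#'
#' The minimal axis-aligned box containing the points, inflated by
#' `padding` on every face — the cuboid encapsulating a spatial region
#' such as the volume available between two translocases.
#'
#' @param points N x 3 coordinate matrix (N >= 1), Angstrom.
#' @param padding inflation per face, Angstrom (default 0).
#' @return a [VolumeEstimate-class] (method "cuboid") whose `dims` hold
#'   the edge lengths; the box corners are attached as attributes
#'   `"lower"` and `"upper"`.
#' @export
boundingCuboid <- function(points, padding = 0) {
  points <- as.matrix(points)
  .stopIfNot(nrow(points) >= 1 && ncol(points) == 3,
             "'points' must be a non-empty N x 3 matrix")
  lo <- apply(points, 2, min) - padding
  hi <- apply(points, 2, max) + padding
  dims <- hi - lo
  v <- new("VolumeEstimate", method = "cuboid", dims = as.numeric(dims),
           volumeA3 = prod(dims), volumeL = prod(dims) * 1e-27,
           gridSpacing = NA_real_)
  attr(v, "lower") <- as.numeric(lo)
  attr(v, "upper") <- as.numeric(hi)
  v
}

#' Grid estimate of the solvent-accessible volume of a region
#'
#' Counts regular grid points inside a cuboidal region that lie farther
#' than `exclusionRadius` from every atom of the assembly; the volume is
#' the count times the grid-cell volume. Converges to the true
#' atom-excluded volume as the spacing shrinks, and is monotone
#' non-increasing in the exclusion radius.
#'
#' @param assembly an [XLStructure-class], or `NULL` for an empty region.
#' @param region a cuboid: either a [VolumeEstimate-class] from
#'   [boundingCuboid()] or a list with `lower` and `upper` length-3
#'   corners (Angstrom).
#' @param spacing grid spacing, Angstrom (> 0, smaller than every edge).
#' @param exclusionRadius atom exclusion radius, Angstrom (default 2.0).
#' @return a [VolumeEstimate-class] (method "grid").
#' @export
gridAccessibleVolume <- function(assembly, region, spacing,
                                 exclusionRadius = 2.0) {
  .stopIfNot(spacing > 0, "'spacing' must be > 0")
  if (is(region, "VolumeEstimate")) {
    lo <- attr(region, "lower"); hi <- attr(region, "upper")
    .stopIfNot(!is.null(lo) && !is.null(hi),
               "region VolumeEstimate lacks corner attributes")
  } else {
    lo <- as.numeric(region$lower); hi <- as.numeric(region$upper)
  }
  edges <- hi - lo
  .stopIfNot(all(edges > 0), "region must have positive extent")
  .stopIfNot(spacing <= min(edges), "'spacing' exceeds a region edge")
  ax <- lapply(1:3, function(k) seq(lo[k] + spacing / 2, hi[k] - spacing / 2,
                                    by = spacing))
  grid <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  free <- rep(TRUE, nrow(grid))
  if (!is.null(assembly) && length(assembly) > 0) {
    at <- as.matrix(assembly@atoms[, c("x", "y", "z")])
    r2 <- exclusionRadius^2
    # chunked nearest-atom test to bound memory
    chunk <- max(1L, floor(2e6 / nrow(at)))
    a2 <- rowSums(at^2)
    for (i0 in seq(1L, nrow(grid), by = chunk)) {
      idx <- i0:min(i0 + chunk - 1L, nrow(grid))
      g <- grid[idx, , drop = FALSE]
      d2 <- outer(rowSums(g^2), a2, "+") - 2 * g %*% t(at)
      free[idx] <- apply(d2, 1, min) > r2
    }
  }
  vol <- sum(free) * spacing^3
  new("VolumeEstimate", method = "grid", dims = as.numeric(edges),
      volumeA3 = vol, volumeL = vol * 1e-27, gridSpacing = spacing)
}
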