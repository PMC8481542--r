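#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' two paired point sets, via SVD of the covariance matrix with the
#' standard sign correction that excludes reflections.
#'
#' @param coordsA,coordsB N x 3 coordinate matrices (Angstrom), N >= 3,
#'   rows paired. `coordsB` is superposed onto `coordsA`.
#' @return list with `rotation` (3x3, det +1), `translation` (length 3)
#'   such that `coordsB %*% t(rotation) + translation` best matches
#'   `coordsA`, and `rmsd` (Angstrom), the global minimum over rigid
#'   transforms.
#' @examples
#' a <- matrix(rnorm(30), ncol = 3)
#' kabschSuperpose(a, a)$rmsd  # 0
#' @export
kabschSuperpose <- function(coordsA, coordsB) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  .stopIfNot(nrow(coordsA) == nrow(coordsB),
             "point counts differ (", nrow(coordsA), " vs ", nrow(coordsB), ")")
  .stopIfNot(nrow(coordsA) >= 3L, "at least 3 paired points required")
  ca <- .centroid(coordsA); cb <- .centroid(coordsB)
  A <- sweep(coordsA, 2, ca); B <- sweep(coordsB, 2, cb)
  H <- crossprod(B, A)           # 3x3 covariance
  sv <- svd(H)
  if (min(sv$d) < 1e-12 * max(sv$d, 1e-300) && sum(sv$d > 1e-12) < 2)
    stop("degenerate (collinear or coincident) point set")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - A)^2)))
  list(rotation = R, translation = as.numeric(ca - cb %*% t(R)), rmsd = rmsd)
}

#' RMSD without superposition
#'
#' Root-mean-square coordinate deviation of paired points in a fixed
#' common frame, with no fitting. Used to measure convergence of docked
#' poses relative to a target pose, where superposition would hide the
#' rigid-body displacement of interest.
#'
#' @param coordsA,coordsB N x 3 coordinate matrices, rows paired, N >= 1.
#' @return RMSD in Angstrom. Always >= the Kabsch RMSD of the same pair.
#' @export
rmsdNoSuperposition <- function(coordsA, coordsB) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  .stopIfNot(nrow(coordsA) == nrow(coordsB) && nrow(coordsA) >= 1L,
             "equal, non-zero point counts required")
  sqrt(mean(rowSums((coordsA - coordsB)^2)))
}

#' All-versus-all pairwise RMSD matrix of a decoy ensemble
#'
#' Computes the symmetric matrix of pairwise RMSD values over an
#' ensemble, either with optimal superposition (Kabsch) or in the fixed
#' common frame. The default atom selection is CA only.
#'
#' @param ensemble a [DecoyEnsemble-class]; all decoys must share the
#'   atom selection.
#' @param elety atom-name selection (default "CA").
#' @param superposed use Kabsch superposition per pair (default TRUE).
#' @return symmetric numeric matrix with decoy ids as dimnames, zero
#'   diagonal; attribute `"superposed"` records the variant.
#' @export
pairwiseRmsd <- function(ensemble, elety = "CA", superposed = TRUE) {
  n <- length(ensemble)
  coords <- lapply(ensemble@decoys, atomCoords, elety = elety)
  nref <- nrow(coords[[1]])
  for (i in seq_len(n)) {
    if (nrow(coords[[i]]) != nref)
      stop("decoy '", ensemble@ids[i], "' does not share the atom selection")
  }
  m <- matrix(0, n, n, dimnames = list(ensemble@ids, ensemble@ids))
  if (n >= 2) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        m[i, j] <- m[j, i] <- if (superposed) {
          kabschSuperpose(coords[[i]], coords[[j]])$rmsd
        } else {
          rmsdNoSuperposition(coords[[i]], coords[[j]])
        }
      }
    }
  }
  attr(m, "superposed") <- superposed
  m
}

#' Length of an ideal alpha-helical segment
#'
#' The helical ruler: an alpha helix rises ~1.5 A per residue along its
#' axis, so a 23-residue helix spans ~35 A — enough to cross a lipid
#' bilayer — and a 40-residue helix spans 60 A, the scale of the
#' intermembrane space between the outer- and inner-membrane
#' translocases.
#'
#' @param n number of residues (>= 0).
#' @param rise rise per residue, A/residue (default 1.5).
#' @return helix length in Angstrom, `n * rise`.
#' @examples
#' helixLength(23)  # 34.5 A, approximately a 35 A bilayer span
#' helixLength(40)  # 60 A
#' @export
helixLength <- function(n, rise = 1.5) {
  .stopIfNot(all(n >= 0) && rise > 0, "n >= 0 and rise > 0 required")
  n * rise
}

#' Residues needed to span a distance as an alpha helix
#'
#' Inverse of [helixLength()]: the number of helical residues whose axial
#' extent covers a given distance, rounded to the nearest integer (ties
#' to even).
#'
#' @param length distance to span, Angstrom (>= 0).
#' @param rise rise per residue, A/residue (> 0, default 1.5).
#' @return integer residue count.
#' @examples
#' residuesToSpan(35)  # 23 residues to cross a bilayer
#' @export
residuesToSpan <- function(length, rise = 1.5) {
  .stopIfNot(all(length >= 0), "'length' must be >= 0")
  .stopIfNot(is.numeric(rise) && rise > 0, "'rise' must be > 0")
  as.integer(round(length / rise))
}

#' Build an ideal CA-only alpha helix
#'
#' Places residue i's CA at angle `i * turn` on a cylinder of the given
#' radius, at axial coordinate `i * rise`. With the defaults (rise 1.5 A,
#' radius 2.3 A, turn 100 degrees) this is the standard ideal alpha
#' helix; the axial extent of n residues is `(n - 1) * rise`, one rise
#' less than [helixLength()] which counts n full rises.
#'
#' @param n number of residues (>= 1).
#' @param rise rise per residue, A (default 1.5).
#' @param radius helix radius, A (default 2.3).
#' @param turn twist per residue, degrees (default 100).
#' @param chain chain identifier (default "A").
#' @param id structure id.
#' @return an [XLStructure-class] with one CA per residue (resid "ALA").
#' @export
buildIdealHelix <- function(n, rise = 1.5, radius = 2.3, turn = 100,
                            chain = "A", id = "ideal-helix") {
  .stopIfNot(n >= 1, "'n' must be >= 1")
  i <- seq_len(n) - 1L
  th <- i * turn * pi / 180
  XLStructure(id, data.frame(
    chain = chain, resno = i + 1L, resid = "ALA", elety = "CA",
    x = radius * cos(th), y = radius * sin(th), z = i * rise,
    stringsAsFactors = FALSE))
}
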