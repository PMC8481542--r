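#' Atomic structure container
#'
#' An `XLStructure` holds the ordered atom records of a (possibly
#' multi-chain) atomic model. Coordinates are in Angstrom. The atom table
#' has columns `chain` (single-character chain identifier), `resno`
#' (1-based residue index), `resid` (3-letter residue code), `elety`
#' (PDB atom name, e.g. CA, CB, NZ) and `x`, `y`, `z`.
#'
#' @slot id single character identifier.
#' @slot atoms data.frame of atom records (see Details).
#'
#' @details Residue numbering follows author/PDB numbering (K25 means
#' residue 25). Within a structure the triple (chain, resno, elety) is
#' unique and coordinates are finite.
#'
#' @seealso [parsePdb()], [writePdb()], [atomCoords()]
#' @export
setClass("XLStructure",
  representation(id = "character", atoms = "data.frame"))

setValidity("XLStructure", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atom table must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) < 1L) return("structure must contain at least one atom")
  if (length(object@id) != 1L) return("id must be a single string")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) return("all coordinates must be finite")
  key <- paste(a$chain, a$resno, a$elety)
  if (anyDuplicated(key))
    return("(chain, resno, elety) must be unique within a structure")
  if (any(nchar(a$chain) != 1L)) return("chain identifiers must be 1 character")
  # residue indices non-decreasing per chain in record order
  for (ch in unique(a$chain)) {
    r <- a$resno[a$chain == ch]
    if (is.unsorted(r)) return(sprintf("residue indices in chain %s decrease", ch))
  }
  TRUE
})

#' Construct an XLStructure
#'
#' @param id structure identifier.
#' @param atoms data.frame with columns chain, resno, resid, elety, x, y, z.
#' @return an [XLStructure-class] object.
#' @export
XLStructure <- function(id, atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  new("XLStructure", id = as.character(id), atoms = atoms)
}

#' @describeIn XLStructure-class number of atoms
#' @param x an XLStructure
#' @export
setMethod("length", "XLStructure", function(x) nrow(x@atoms))

setMethod("show", "XLStructure", function(object) {
  a <- object@atoms
  cat(sprintf("XLStructure '%s': %d atoms, %d chain(s) [%s], %d residues\n",
              object@id, nrow(a), length(unique(a$chain)),
              paste(unique(a$chain), collapse = ","),
              length(unique(paste(a$chain, a$resno)))))
})

#' Accessors for XLStructure
#'
#' `atomTable()` returns the atom record data.frame; `structureId()` the
#' identifier; `atomCoords()` an N x 3 coordinate matrix for a selection.
#'
#' @param s an [XLStructure-class].
#' @param elety atom-name selection (default "CA"); `NULL` selects all atoms.
#' @param chain optional chain filter.
#' @return `atomCoords` returns a numeric matrix with rownames
#'   `"chain:resno:elety"`.
#' @export
atomTable <- function(s) s@atoms

#' @rdname atomTable
#' @export
structureId <- function(s) s@id

#' @rdname atomTable
#' @export
atomCoords <- function(s, elety = "CA", chain = NULL) {
  a <- s@atoms
  if (!is.null(elety)) a <- a[a$elety %in% elety, , drop = FALSE]
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- paste(a$chain, a$resno, a$elety, sep = ":")
  m
}

#' Scored decoy ensemble
#'
#' Container for a set of candidate conformations ("decoys") with scalar
#' scores where lower is better (e.g. an ab initio overall score or a
#' docking interface score).
#'
#' @slot decoys list of [XLStructure-class] objects.
#' @slot ids character vector of decoy identifiers.
#' @slot scores numeric scores, lower = better.
#' @export
setClass("DecoyEnsemble",
  representation(decoys = "list", ids = "character", scores = "numeric"))

setValidity("DecoyEnsemble", function(object) {
  n <- length(object@decoys)
  if (length(object@ids) != n || length(object@scores) != n)
    return("decoys, ids and scores must have equal length")
  if (n > 0 && !all(vapply(object@decoys, is, logical(1), "XLStructure")))
    return("all decoys must be XLStructure objects")
  if (anyDuplicated(object@ids)) return("decoy ids must be unique")
  if (n > 0 && !all(is.finite(object@scores))) return("scores must be finite")
  TRUE
})

#' Construct a DecoyEnsemble
#' @param decoys list of XLStructure.
#' @param scores numeric vector, lower = better.
#' @param ids identifiers; defaults to each structure's id.
#' @export
DecoyEnsemble <- function(decoys, scores, ids = NULL) {
  if (is.null(ids)) ids <- vapply(decoys, structureId, character(1))
  new("DecoyEnsemble", decoys = decoys, ids = as.character(ids),
      scores = as.numeric(scores))
}

setMethod("show", "DecoyEnsemble", function(object) {
  cat(sprintf("DecoyEnsemble: %d decoys, score range [%.3g, %.3g]\n",
              length(object@decoys),
              if (length(object@scores)) min(object@scores) else NA,
              if (length(object@scores)) max(object@scores) else NA))
})

#' @describeIn DecoyEnsemble-class number of decoys
#' @param x a DecoyEnsemble
#' @export
setMethod("length", "DecoyEnsemble", function(x) length(x@decoys))

#' Subset a DecoyEnsemble
#' @param x DecoyEnsemble
#' @param i index vector (integer, logical or id character)
#' @param j,drop,... ignored
#' @export
setMethod("[", "DecoyEnsemble", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@ids)
  new("DecoyEnsemble", decoys = x@decoys[i], ids = x@ids[i],
      scores = x@scores[i])
})

#' Ensemble accessors
#' @param e a [DecoyEnsemble-class].
#' @param id a decoy identifier or integer index.
#' @export
decoyIds <- function(e) e@ids

#' @rdname decoyIds
#' @export
decoyScores <- function(e) stats::setNames(e@scores, e@ids)

#' @rdname decoyIds
#' @export
getDecoy <- function(e, id) {
  i <- if (is.character(id)) match(id, e@ids) else as.integer(id)
  if (is.na(i) || i < 1L || i > length(e@decoys))
    stop("no decoy '", id, "' in ensemble")
  e@decoys[[i]]
}

#' Pairwise-nearest-neighbour cluster assignment
#'
#' Result of agglomerative clustering of a decoy ensemble on an
#' all-versus-all RMSD matrix with a distance ceiling.
#'
#' @slot threshold distance ceiling in Angstrom.
#' @slot ids decoy identifiers (matrix order).
#' @slot labels integer cluster label per decoy (1-based, by cluster size).
#' @slot sizes per-cluster member counts.
#' @slot spread per-cluster maximum intra-cluster pairwise RMSD (Angstrom).
#' @export
setClass("ClusterAssignment",
  representation(threshold = "numeric", ids = "character",
                 labels = "integer", sizes = "integer", spread = "numeric"))

setValidity("ClusterAssignment", function(object) {
  if (length(object@labels) != length(object@ids))
    return("one label per id required")
  if (sum(object@sizes) != length(object@labels))
    return("cluster sizes must sum to the number of decoys")
  if (length(object@sizes) != length(object@spread))
    return("one spread per cluster required")
  if (any(object@spread < 0)) return("spreads must be >= 0")
  TRUE
})

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("ClusterAssignment: %d decoys in %d cluster(s) at %.3g A\n",
              length(object@labels), length(object@sizes), object@threshold))
  k <- min(5L, length(object@sizes))
  for (i in seq_len(k))
    cat(sprintf("  cluster %d: size %d, spread %.3g A\n",
                i, object@sizes[i], object@spread[i]))
  if (length(object@sizes) > k) cat("  ...\n")
})

#' @rdname nClusters
#' @export
clusterSizes <- function(cl) stats::setNames(cl@sizes, seq_along(cl@sizes))

#' Cluster accessors
#' @param cl a [ClusterAssignment-class].
#' @export
nClusters <- function(cl) length(cl@sizes)

#' @rdname nClusters
#' @export
clusterLabels <- function(cl) stats::setNames(cl@labels, cl@ids)

#' @rdname nClusters
#' @export
clusterSpread <- function(cl) stats::setNames(cl@spread, seq_along(cl@spread))

#' Final-model selection result
#'
#' @slot finalId identifier of the selected decoy.
#' @slot clusterId integer label of the winning cluster.
#' @slot clusters the [ClusterAssignment-class] of the filtered ensemble.
#' @slot audit data.frame with columns stage, n_in, n_out (pipeline trail).
#' @export
setClass("SelectionResult",
  representation(finalId = "character", clusterId = "integer",
                 clusters = "ClusterAssignment", audit = "data.frame"))

setValidity("SelectionResult", function(object) {
  i <- match(object@finalId, object@clusters@ids)
  if (is.na(i)) return("finalId must belong to the clustered set")
  if (object@clusters@labels[i] != object@clusterId)
    return("finalId must belong to clusterId")
  if (is.unsorted(rev(object@audit$n_out)))
    return("audit decoy counts must be non-increasing")
  TRUE
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: decoy '%s' from cluster %d (size %d)\n",
              object@finalId, object@clusterId,
              object@clusters@sizes[object@clusterId]))
  print(object@audit, row.names = FALSE)
})

#' Selection accessors
#' @param x a [SelectionResult-class].
#' @export
selectedId <- function(x) x@finalId

#' @rdname selectedId
#' @export
selectionAudit <- function(x) x@audit

#' Rigid-body pose of an assembly component
#'
#' @slot rotation 3x3 proper orthogonal matrix.
#' @slot translation length-3 numeric, Angstrom.
#' @export
setClass("PoseTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("PoseTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (length(object@translation) != 3L) return("translation must be length 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    return("rotation must be orthonormal (1e-9)")
  if (abs(det(R) - 1) > 1e-9)
    return("rotation must be proper (det +1 within 1e-9)")
  TRUE
})

#' Construct a PoseTransform
#' @param rotation 3x3 proper orthogonal matrix (default identity).
#' @param translation length-3 vector in Angstrom (default zero).
#' @export
poseTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("PoseTransform", rotation = rotation,
      translation = as.numeric(translation))
}

setMethod("show", "PoseTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("PoseTransform: rotation %.2f deg, translation (%.2f, %.2f, %.2f) A\n",
              ang, object@translation[1], object@translation[2],
              object@translation[3]))
})

#' One candidate placement of a mobile component
#'
#' @slot pose the [PoseTransform-class] applied to the mobile component.
#' @slot energy total flat-harmonic restraint penalty (dimensionless, >= 0).
#' @slot nSatisfied number of satisfied inter-component cross-links.
#' @slot clashCount CA pairs between fixed and posed mobile below the
#'   clash cutoff.
#' @export
setClass("AssemblyState",
  representation(pose = "PoseTransform", energy = "numeric",
                 nSatisfied = "integer", clashCount = "integer"))

setValidity("AssemblyState", function(object) {
  if (object@energy < 0) return("energy must be >= 0")
  if (object@nSatisfied < 0 || object@clashCount < 0)
    return("counts must be >= 0")
  TRUE
})

setMethod("show", "AssemblyState", function(object) {
  cat(sprintf(
    "AssemblyState: energy %.4g, %d link(s) satisfied, %d clash(es)\n",
    object@energy, object@nSatisfied, object@clashCount))
})

#' Confined-volume estimate
#'
#' Volume of a confined region in cubic Angstrom and litres
#' (`volume_l = volume_a3 * 1e-27` exactly).
#'
#' @slot method "cuboid" or "grid".
#' @slot dims cuboid edge lengths in Angstrom (cuboid method only).
#' @slot volumeA3 volume in cubic Angstrom.
#' @slot volumeL volume in litres.
#' @slot gridSpacing grid spacing in Angstrom (grid method only).
#' @export
setClass("VolumeEstimate",
  representation(method = "character", dims = "numeric",
                 volumeA3 = "numeric", volumeL = "numeric",
                 gridSpacing = "numeric"))

setValidity("VolumeEstimate", function(object) {
  if (!object@method %in% c("cuboid", "grid"))
    return("method must be 'cuboid' or 'grid'")
  if (object@volumeA3 < 0) return("volume must be >= 0")
  if (!isTRUE(all.equal(object@volumeL, object@volumeA3 * 1e-27,
                        tolerance = 1e-12)))
    return("volumeL must equal volumeA3 * 1e-27")
  TRUE
})

setMethod("show", "VolumeEstimate", function(object) {
  cat(sprintf("VolumeEstimate (%s): %.6g A^3 = %.3g L\n",
              object@method, object@volumeA3, object@volumeL))
  if (object@method == "cuboid")
    cat(sprintf("  dims: %.2f x %.2f x %.2f A\n",
                object@dims[1], object@dims[2], object@dims[3]))
})

#' Volume accessors
#' @param v a [VolumeEstimate-class].
#' @export
volumeA3 <- function(v) v@volumeA3

#' @rdname volumeA3
#' @export
volumeLiters <- function(v) v@volumeL
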