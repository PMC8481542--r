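#' Default cross-linker dictionary
#'
#' Spacer lengths and distance thresholds for the four linker chemistries
#' commonly used in XL-MS restraint modelling. DSS (11.4 A spacer) and
#' DSSO (10.1 A) link primary amines and are evaluated as CA-CA / CB-CB
#' distance pairs with thresholds of 30 and 22 A. EDC is a zero-length
#' amine-carboxyl linker evaluated on site-specific anchor atoms with a
#' 10 A threshold when a backbone amine (N-terminal residue) is involved
#' and 14 A between side-chain anchors. SDA (3.9 A, amine-photo) has no
#' published thresholds here; its defaults (CA 20 / CB 15 A) scale the
#' DSS thresholds down by roughly the spacer difference and should be
#' treated as package defaults, not literature values.
#'
#' @return data.frame with one row per linker: `name`, `spacer` (A),
#'   `chemistry`, `ca_ca` and `cb_cb` thresholds (A), and `edc_n` /
#'   `edc_side` anchor-atom thresholds (A, EDC only, otherwise NA).
#' @examples
#' defaultLinkers()
#' @export
defaultLinkers <- function() {
  data.frame(
    name = c("DSS", "DSSO", "SDA", "EDC"),
    spacer = c(11.4, 10.1, 3.9, 0),
    chemistry = c("amine-amine", "amine-amine", "amine-photo",
                  "amine-carboxyl"),
    ca_ca = c(30, 30, 20, NA),
    cb_cb = c(22, 22, 15, NA),
    edc_n = c(NA, NA, NA, 10),
    edc_side = c(NA, NA, NA, 14),
    stringsAsFactors = FALSE)
}

#' Restraint evaluation parameters
#'
#' @param sd flat-harmonic width in Angstrom (> 0). Penalties are used
#'   for ranking only, so the scale is immaterial; default 1.0.
#' @param mode `"all"` (every evaluated atom pair must be within its
#'   threshold for the link to count as satisfied — the default, since
#'   CA and CB restraints are imposed simultaneously) or `"any"`.
#' @param caFallback drop the CB-CB pair (keeping CA-CA) when a residue
#'   has no CB (glycine); when `FALSE` such links are unresolvable.
#' @return a list of class `"restraintParams"`.
#' @export
restraintParams <- function(sd = 1.0, mode = c("all", "any"),
                            caFallback = TRUE) {
  mode <- match.arg(mode)
  .stopIfNot(is.numeric(sd) && sd > 0, "'sd' must be > 0")
  structure(list(sd = sd, mode = mode, caFallback = caFallback),
            class = "restraintParams")
}

#' Flat-harmonic restraint penalty
#'
#' Zero while the distance is at or below the threshold; grows
#' quadratically, `((d - x0) / sd)^2`, beyond it. Continuous at `d = x0`.
#' A model is therefore penalised only when the Euclidean distance
#' between the restrained atoms exceeds the linker threshold.
#'
#' @param d distance(s), Angstrom (>= 0).
#' @param x0 threshold, Angstrom (> 0).
#' @param sd harmonic width, Angstrom (> 0).
#' @return penalty value(s), dimensionless, >= 0 (vectorised over `d`).
#' @examples
#' flatHarmonic(25, 30, 1)  # 0: inside the flat region
#' flatHarmonic(34, 30, 1)  # 16
#' @export
flatHarmonic <- function(d, x0, sd = 1.0) {
  .stopIfNot(all(sd > 0), "'sd' must be > 0")
  .stopIfNot(all(x0 > 0), "'x0' must be > 0")
  .stopIfNot(all(d >= 0), "'d' must be >= 0")
  pmax(0, (d - x0) / sd)^2
}

# resolve one cross-link site to (chain, resno); NULL when unresolvable
.resolveSite <- function(atoms, protein, resno) {
  if (!protein %in% atoms$chain) return(NULL)
  if (!any(atoms$chain == protein & atoms$resno == resno)) return(NULL)
  list(chain = protein, resno = as.integer(resno))
}

# pick the EDC anchor atom for a residue: N-terminal residue -> backbone N;
# K -> NZ, D -> CG, E -> CD; fall back to CB then CA
.edcAnchor <- function(atoms, chain, resno) {
  res <- atoms[atoms$chain == chain & atoms$resno == resno, , drop = FALSE]
  firstRes <- min(atoms$resno[atoms$chain == chain])
  if (resno == firstRes && "N" %in% res$elety) return("N")
  want <- switch(res$resid[1], LYS = "NZ", ASP = "CG", GLU = "CD", "CB")
  for (a in unique(c(want, "CB", "CA"))) if (a %in% res$elety) return(a)
  res$elety[1]
}

#' Map a cross-link to the atom pairs it restrains
#'
#' Amine-amine and amine-photo linkers (DSS, DSSO, SDA) restrain the
#' CA-CA and CB-CB pairs of the two linked residues, each against its
#' own threshold; the CB pair is dropped when either residue lacks a CB
#' (glycine) and `caFallback` is set. The zero-length EDC linker
#' restrains one site-specific anchor pair (lysine NZ, aspartate CG,
#' glutamate CD, backbone N for the chain's first residue, CB otherwise)
#' with a 10 A threshold when either anchor is a backbone N and 14 A
#' between side-chain anchors — different anchor atoms carry different
#' applied restraint lengths.
#'
#' @param s an [XLStructure-class].
#' @param link one cross-link: a single-row data.frame or list with
#'   `protein_a`, `res_a`, `protein_b`, `res_b` (proteins name chains).
#' @param linker one row of a linker dictionary (see [defaultLinkers()]).
#' @param params [restraintParams()].
#' @return data.frame with columns `atom_a`, `atom_b`, `threshold` (A).
#' @export
mapLinkAtoms <- function(s, link, linker, params = restraintParams()) {
  atoms <- s@atoms
  sa <- .resolveSite(atoms, link$protein_a, link$res_a)
  sb <- .resolveSite(atoms, link$protein_b, link$res_b)
  if (is.null(sa) || is.null(sb)) {
    bad <- c(if (is.null(sa)) paste0(link$protein_a, ":", link$res_a),
             if (is.null(sb)) paste0(link$protein_b, ":", link$res_b))
    stop("unresolved cross-link site(s): ", paste(bad, collapse = ", "))
  }
  hasAtom <- function(site, a)
    any(atoms$chain == site$chain & atoms$resno == site$resno &
          atoms$elety == a)
  if (identical(linker$name, "EDC")) {
    aa <- .edcAnchor(atoms, sa$chain, sa$resno)
    ab <- .edcAnchor(atoms, sb$chain, sb$resno)
    thr <- if (aa == "N" || ab == "N") linker$edc_n else linker$edc_side
    return(data.frame(atom_a = aa, atom_b = ab, threshold = thr,
                      stringsAsFactors = FALSE))
  }
  pairs <- data.frame(atom_a = "CA", atom_b = "CA",
                      threshold = linker$ca_ca, stringsAsFactors = FALSE)
  if (hasAtom(sa, "CB") && hasAtom(sb, "CB")) {
    pairs <- rbind(pairs, data.frame(atom_a = "CB", atom_b = "CB",
                                     threshold = linker$cb_cb))
  } else if (!params$caFallback) {
    stop("unresolved cross-link site(s): CB missing and caFallback disabled")
  }
  pairs
}

#' Evaluate one cross-link restraint on a structure
#'
#' Computes the Euclidean distance of every restrained atom pair, the
#' total flat-harmonic penalty, and the satisfaction flag (under
#' `mode = "all"` every pair must lie within its threshold; under
#' `"any"` one suffices). Penalty is zero exactly when all pairs are
#' within their thresholds.
#'
#' @inheritParams mapLinkAtoms
#' @return list with `pairs` (data.frame atom_a, atom_b, distance,
#'   threshold), `penalty` and `satisfied`.
#' @export
evaluateLink <- function(s, link, linker, params = restraintParams()) {
  pairs <- mapLinkAtoms(s, link, linker, params)
  atoms <- s@atoms
  coord <- function(protein, resno, a) {
    r <- atoms[atoms$chain == protein & atoms$resno == resno &
                 atoms$elety == a, c("x", "y", "z")]
    if (nrow(r) == 0)
      stop("unresolved cross-link site(s): ", protein, ":", resno, ":", a)
    as.numeric(r[1, ])
  }
  d <- vapply(seq_len(nrow(pairs)), function(i) {
    sqrt(sum((coord(link$protein_a, link$res_a, pairs$atom_a[i]) -
                coord(link$protein_b, link$res_b, pairs$atom_b[i]))^2))
  }, numeric(1))
  pairs$distance <- d
  within <- d <= pairs$threshold
  list(
    pairs = pairs[, c("atom_a", "atom_b", "distance", "threshold")],
    penalty = sum(flatHarmonic(d, pairs$threshold, params$sd)),
    satisfied = if (params$mode == "all") all(within) else any(within))
}

#' Evaluate a set of cross-link restraints on a structure
#'
#' Evaluates every link of a cross-link table against a structure.
#' Links whose sites cannot be resolved to residues present in the
#' structure are reported separately and excluded from the satisfied
#' count and total penalty. The result is independent of link order.
#'
#' @param s an [XLStructure-class].
#' @param links cross-link data.frame (see [parseCrossLinks()]).
#' @param linkers linker dictionary (default [defaultLinkers()]).
#' @param params [restraintParams()].
#' @return list with `table` (one row per resolvable link: the link
#'   fields plus `penalty`, `satisfied`, `min_distance`, `max_distance`),
#'   `nSatisfied`, `totalPenalty`, and `unresolved` (data.frame of
#'   dropped links with a `reason` column).
#' @export
evaluateSet <- function(s, links, linkers = defaultLinkers(),
                        params = restraintParams()) {
  rows <- vector("list", nrow(links))
  unresolved <- list()
  for (i in seq_len(nrow(links))) {
    link <- links[i, , drop = FALSE]
    spec <- linkers[match(link$linker, linkers$name), , drop = FALSE]
    if (is.na(spec$name[1])) {
      unresolved[[length(unresolved) + 1L]] <-
        cbind(link, reason = "unknown linker")
      next
    }
    ev <- tryCatch(evaluateLink(s, link, spec, params), error = identity)
    if (inherits(ev, "error")) {
      unresolved[[length(unresolved) + 1L]] <-
        cbind(link, reason = conditionMessage(ev))
      next
    }
    rows[[i]] <- cbind(link,
                       penalty = ev$penalty, satisfied = ev$satisfied,
                       min_distance = min(ev$pairs$distance),
                       max_distance = max(ev$pairs$distance))
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tab)) {
    tab <- cbind(links[0, , drop = FALSE], penalty = numeric(0),
                 satisfied = logical(0), min_distance = numeric(0),
                 max_distance = numeric(0))
  }
  rownames(tab) <- NULL
  list(table = tab,
       nSatisfied = sum(tab$satisfied),
       totalPenalty = sum(tab$penalty),
       unresolved = if (length(unresolved)) do.call(rbind, unresolved)
                    else cbind(links[0, , drop = FALSE],
                               reason = character(0)))
}
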