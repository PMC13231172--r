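# Geometric observables: ring center-of-geometry (COG) stacking distances
# (with the purine minimum-ring rule) and donor-hydrogen-acceptor H-bonds.

.decodexCache <- new.env(parent = emptyenv())

.readJSONCatalogue <- function(path, what) {
  if (is.null(path)) {
    path <- system.file("extdata", what, package = "decodex")
    key <- what
    if (!is.null(.decodexCache[[key]])) return(.decodexCache[[key]])
    val <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    val[["_comment"]] <- NULL
    .decodexCache[[key]] <- val
    return(val)
  }
  val <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  val[["_comment"]] <- NULL
  val
}

#' Ring-system and H-bond edge catalogues
#'
#' `ringCatalogue()` returns the ring-atom sets used for COG stacking
#' (two rings for purines, one for pyrimidines, the guanidinium group for
#' arginine); `hbondEdges()` returns the per-residue donor/acceptor atoms
#' (donor heavy atoms with their explicit hydrogens).  Both are read from
#' editable JSON shipped in `inst/extdata` and can be replaced by passing a
#' path to a file with the same layout.
#'
#' @param path optional path to an alternative JSON catalogue.
#' @return a named list keyed by residue name.
#' @export
ringCatalogue <- function(path = NULL)
  .readJSONCatalogue(path, "ring_systems.json")

#' @rdname ringCatalogue
#' @export
hbondEdges <- function(path = NULL)
  .readJSONCatalogue(path, "hbond_edges.json")

#' Unweighted center of geometry
#'
#' Arithmetic mean of atom coordinates (no mass weighting).
#'
#' @param coords numeric matrix with one row per atom and 3 columns (x, y, z),
#'   or a length-3 vector for a single atom.
#' @return numeric(3).
#' @examples
#' centerOfGeometry(rbind(c(0, 0, 0), c(2, 0, 0)))
#' @export
centerOfGeometry <- function(coords) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3)
  if (nrow(coords) < 1L) stop("argument error: need at least one atom")
  colMeans(coords)
}

# per-frame COG of an atom index set: returns 3 x nFrames matrix
.cogSeries <- function(traj, idx, frames) {
  out <- matrix(NA_real_, 3L, length(frames))
  for (d in 1:3) {
    m <- traj@coords[idx, d, frames, drop = FALSE]
    dim(m) <- c(length(idx), length(frames))
    out[d, ] <- colMeans(m)
  }
  out
}

# ring definitions (atom index sets) for one residue, from a ring catalogue
.residueRings <- function(traj, chain, resno, ringData = ringCatalogue()) {
  at <- traj@atoms
  row <- which(at$chain == chain & at$resno == resno)
  if (!length(row))
    stop("geometry error: residue (", chain, ", ", resno, ") not in trajectory")
  resname <- at$resname[row[1]]
  defs <- ringData[[resname]]
  if (is.null(defs))
    stop("geometry error: no ring system defined for residue name '",
         resname, "'")
  lapply(defs, function(d)
    .atomIdx(traj, chain, resno, unlist(d$atoms)))
}

#' Minimum ring-pair COG distance between two ring systems
#'
#' Pure-coordinate form of the stacking observable: the minimum over all
#' (ring of A, ring of B) pairs of the Euclidean distance between the ring
#' centers of geometry.  For purines (two rings) against anything this
#' realizes the minimum-ring rule; it is symmetric in its arguments.  Exact
#' COG ties between a purine's two rings resolve toward the later-listed
#' (pyrimidine) ring for determinism.
#'
#' @param ringsA,ringsB lists of numeric atom-coordinate matrices, one matrix
#'   per ring system of the residue.
#' @return numeric(1), Angstrom.
#' @examples
#' hex <- cbind(cos(seq(0, 2 * pi, length.out = 7)[-7]),
#'              sin(seq(0, 2 * pi, length.out = 7)[-7]), 0)
#' cogDistance(list(hex), list(sweep(hex, 2, c(0, 0, 3.4), "+")))
#' @export
cogDistance <- function(ringsA, ringsB) {
  if (!length(ringsA) || !length(ringsB))
    stop("argument error: each residue needs at least one ring system")
  best <- Inf
  for (ra in ringsA) for (rb in ringsB) {
    d <- sqrt(sum((centerOfGeometry(ra) - centerOfGeometry(rb))^2))
    if (d < best) best <- d
  }
  best
}

#' Per-frame stacking distance between two residues
#'
#' Evaluates [cogDistance()] for every frame of a trajectory, resolving each
#' residue's ring system(s) from the ring catalogue by residue name.
#'
#' @param traj a [DecodingTrajectory-class].
#' @param chainA,resnoA,chainB,resnoB residue identifiers.
#' @param frames optional frame subset (default all frames).
#' @param ringData ring catalogue, see [ringCatalogue()].
#' @return numeric vector of COG distances, one per frame.
#' @export
stackingDistance <- function(traj, chainA, resnoA, chainB, resnoB,
                             frames = NULL, ringData = ringCatalogue()) {
  if (is.null(frames)) frames <- seq_len(nFrames(traj))
  ringsA <- .residueRings(traj, chainA, resnoA, ringData)
  ringsB <- .residueRings(traj, chainB, resnoB, ringData)
  best <- rep(Inf, length(frames))
  for (ia in ringsA) {
    ca <- .cogSeries(traj, ia, frames)
    for (ib in ringsB) {
      cb <- .cogSeries(traj, ib, frames)
      d <- sqrt(colSums((ca - cb)^2))
      best <- pmin(best, d)
    }
  }
  best
}

#' Binarize stacking distances
#'
#' Distances at or below the stacking cutoff are classified as stacked (1),
#' larger distances as unstacked (0).
#'
#' @param d numeric vector of COG distances (Angstrom), all `>= 0`.
#' @param params a [GeometryParams-class].
#' @return integer vector of 0/1.
#' @examples
#' classifyStacked(c(4.5, 4.5000001, 3.2))
#' @export
classifyStacked <- function(d, params = geometryParams()) {
  stopifnot(is.numeric(d), all(d >= 0))
  as.integer(d <= params@stackCutoff)
}

#' Construct an H-bond candidate specification
#'
#' A donor-hydrogen-acceptor triple, each given as
#' `c(chain, resno, atom name)`.  Donor and hydrogen must belong to the same
#' residue, the acceptor to a different one.
#'
#' @param donor,hydrogen,acceptor character vectors
#'   `c(chain, resno, atom name)`.
#' @return a list of class `hbondSpec`.
#' @export
hbondSpec <- function(donor, hydrogen, acceptor) {
  stopifnot(length(donor) == 3L, length(hydrogen) == 3L, length(acceptor) == 3L)
  if (!identical(donor[1:2], hydrogen[1:2]))
    stop("donor and hydrogen must belong to the same residue")
  if (identical(donor[1:2], acceptor[1:2]))
    stop("acceptor must belong to a different residue than the donor")
  structure(list(donor = donor, hydrogen = hydrogen, acceptor = acceptor),
            class = "hbondSpec")
}

# vectorized geometric H-bond call on 3 x n coordinate matrices
.callHbond <- function(dxyz, hxyz, axyz, params) {
  da <- sqrt(colSums((dxyz - axyz)^2))
  v1 <- dxyz - hxyz
  v2 <- axyz - hxyz
  cosang <- colSums(v1 * v2) /
    pmax(sqrt(colSums(v1^2)) * sqrt(colSums(v2^2)), .Machine$double.eps)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  as.integer(da <= params@hbondDistCutoff & ang >= params@hbondAngleCutoff)
}

.specCoords <- function(traj, ref, frames) {
  idx <- .atomIdx(traj, ref[1], as.integer(ref[2]), ref[3])
  m <- traj@coords[idx, , frames, drop = FALSE]
  dim(m) <- c(3L, length(frames))
  m
}

#' Detect a geometric hydrogen bond per frame
#'
#' An H-bond is called in a frame iff the heavy-donor to acceptor distance is
#' at or below the distance cutoff and the donor-hydrogen-acceptor angle is
#' at or above the angle cutoff (defaults 3.5 Angstrom, 135 degrees).
#' Detection requires explicit hydrogens in the coordinates.
#'
#' @param traj a [DecodingTrajectory-class].
#' @param spec an [hbondSpec()].
#' @param params a [GeometryParams-class].
#' @param frames optional frame subset.
#' @return integer vector of 0/1, one per frame.
#' @export
detectHbond <- function(traj, spec, params = geometryParams(), frames = NULL) {
  stopifnot(inherits(spec, "hbondSpec"))
  if (is.null(frames)) frames <- seq_len(nFrames(traj))
  hxyz <- tryCatch(.specCoords(traj, spec$hydrogen, frames), error = function(e)
    stop("geometry error: hydrogen atom '", spec$hydrogen[3],
         "' missing in residue (", spec$hydrogen[1], ", ", spec$hydrogen[2],
         "); H-bond analysis needs explicit hydrogens"))
  dxyz <- .specCoords(traj, spec$donor, frames)
  axyz <- .specCoords(traj, spec$acceptor, frames)
  .callHbond(dxyz, hxyz, axyz, params)
}

#' Count satisfied H-bond candidates per frame
#'
#' @param traj a [DecodingTrajectory-class].
#' @param candidates non-empty list of [hbondSpec()] objects.
#' @inheritParams detectHbond
#' @return integer vector, one count per frame, bounded by
#'   `length(candidates)`.
#' @export
hbondCount <- function(traj, candidates, params = geometryParams(),
                       frames = NULL) {
  if (!length(candidates)) stop("argument error: no H-bond candidates given")
  if (is.null(frames)) frames <- seq_len(nFrames(traj))
  counts <- integer(length(frames))
  for (spec in candidates)
    counts <- counts + detectHbond(traj, spec, params, frames)
  counts
}

# Enumerate H-bond candidates between two residues from the edge catalogue:
# donors of X against acceptors of Y and vice versa.  A donor heavy atom that
# is present without any of its listed hydrogens is an error (H-bond analysis
# needs explicit hydrogens); donor/acceptor atoms absent from the trajectory
# are skipped.
.hbondCandidates <- function(traj, refX, refY, edges = hbondEdges()) {
  at <- traj@atoms
  resnameOf <- function(ref) {
    row <- which(at$chain == ref$chain & at$resno == ref$resno)
    if (!length(row))
      stop("geometry error: residue (", ref$chain, ", ", ref$resno,
           ") not in trajectory")
    at$resname[row[1]]
  }
  hasAtom <- function(ref, name)
    any(at$chain == ref$chain & at$resno == ref$resno & at$name == name)
  oneWay <- function(don, acc) {
    ed <- edges[[resnameOf(don)]]
    ea <- edges[[resnameOf(acc)]]
    if (is.null(ed) || is.null(ea)) return(list())
    specs <- list()
    for (d in ed$donors) {
      if (!hasAtom(don, d$heavy)) next
      hyd <- unlist(d$hydrogens)
      hyd <- hyd[vapply(hyd, function(h) hasAtom(don, h), TRUE)]
      if (!length(hyd))
        stop("geometry error: donor ", d$heavy, " of residue (", don$chain,
             ", ", don$resno, ") has no explicit hydrogens in the ",
             "coordinates; H-bond analysis needs explicit hydrogens")
      for (a in unlist(ea$acceptors)) {
        if (!hasAtom(acc, a)) next
        for (h in hyd)
          specs[[length(specs) + 1L]] <- hbondSpec(
            c(don$chain, don$resno, d$heavy),
            c(don$chain, don$resno, h),
            c(acc$chain, acc$resno, a))
      }
    }
    specs
  }
  c(oneWay(refX, refY), oneWay(refY, refX))
}
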