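# Synthetic-data generators: idealized geometries written as multi-model
# PDB, coupled binary event streams with exact pairwise phi ground truth,
# and factorial replicate datasets with injected effects.
#
# The neighborhood generator is geometrically abstract: it reproduces the
# *observables* the pipeline measures (ring COG distances, donor-H-acceptor
# geometry) with controllable per-frame occupancies, not a physically
# realistic fold.  See the methods vignette for the layout.

.complementBase <- function(b)
  c(A = "U", U = "A", G = "C", C = "G")[[b]]

# regular hexagon ring (local x/y, Angstrom), standard pyrimidine naming
.hexRing <- function() {
  ang <- (0:5) * pi / 3
  data.frame(name = c("N1", "C2", "N3", "C4", "C5", "C6"),
             lx = 1.37 * cos(ang), ly = 1.37 * sin(ang))
}

# purine = hexagon + fused imidazole (N9, C8, N7 complete the pentagon on
# the C4-C5 edge); ARG contributes the planar guanidinium group
.baseRingAtoms <- function(resname) {
  hex <- .hexRing()
  if (resname %in% c("C", "U")) return(hex)
  if (resname %in% c("A", "G")) {
    c4 <- unlist(hex[hex$name == "C4", c("lx", "ly")])
    c5 <- unlist(hex[hex$name == "C5", c("lx", "ly")])
    mid <- (c4 + c5) / 2
    out <- mid / sqrt(sum(mid^2))
    edge <- sqrt(sum((c4 - c5)^2))
    R5 <- edge / (2 * sin(pi / 5))
    ctr <- mid + out * R5 * cos(pi / 5)
    a4 <- atan2(c4[2] - ctr[2], c4[1] - ctr[1])
    a5 <- atan2(c5[2] - ctr[2], c5[1] - ctr[1])
    # fill the remaining three pentagon vertices starting beside C5
    step <- 2 * pi / 5
    dirn <- if (sin(a5 - a4) > 0) 1 else -1
    angs <- a5 + dirn * step * 1:3
    pent <- data.frame(name = c("N9", "C8", "N7"),
                       lx = ctr[1] + R5 * cos(angs),
                       ly = ctr[2] + R5 * sin(angs))
    return(rbind(hex, pent))
  }
  if (resname == "ARG") {
    ang <- pi / 2 + c(0, 2, 4) * pi / 3
    return(data.frame(name = c("NE", "NH1", "NH2", "CZ"),
                      lx = c(1.33 * cos(ang), 0),
                      ly = c(1.33 * sin(ang), 0)))
  }
  stop("no ring template for residue name '", resname, "'")
}

.writeSynthetic <- function(atoms, coords, path) {
  traj <- new("DecodingTrajectory", atoms = atoms, coords = coords,
              source = "synthetic")
  if (!is.null(path)) writeMultiModelPDB(traj, path)
  traj
}

#' Generate a stacked base pair as a multi-model PDB
#'
#' Two idealized coplanar-parallel pyrimidine rings with a ring-COG
#' separation of `distance` along the ring normal, plus optional isotropic
#' per-frame Gaussian jitter on every atom.
#'
#' @param distance target COG-COG separation, Angstrom.
#' @param nFrames number of frames (MODEL records).
#' @param jitterSD per-coordinate jitter standard deviation, Angstrom.
#' @param seed integer seed.
#' @param path output PDB path (default a tempfile).
#' @return the PDB file path, invisibly; write-free access via
#'   [readMultiModelPDB()].
#' @export
genStackedPairPDB <- function(distance, nFrames = 1, jitterSD = 0, seed = 1,
                              path = tempfile(fileext = ".pdb")) {
  stopifnot(distance > 0, nFrames >= 1)
  set.seed(seed)
  ring <- .hexRing()
  atoms <- data.frame(
    chain = "M", resno = rep(1:2, each = nrow(ring)),
    resname = "C", name = rep(ring$name, 2),
    element = substr(rep(ring$name, 2), 1, 1), stringsAsFactors = FALSE)
  base <- rbind(cbind(ring$lx, ring$ly, 0),
                cbind(ring$lx, ring$ly, distance))
  coords <- array(rep(base, nFrames), dim = c(nrow(base), 3, nFrames))
  if (jitterSD > 0)
    coords <- coords + array(rnorm(length(coords), 0, jitterSD),
                             dim = dim(coords))
  .writeSynthetic(atoms, coords, path)
  invisible(path)
}

#' Generate a donor-hydrogen-acceptor triad as a multi-model PDB
#'
#' Places a cytosine N4 donor (with hydrogen H41) and a uracil O4 acceptor
#' at exactly the requested heavy-donor to acceptor distance and
#' donor-hydrogen-acceptor angle, identically in every frame.
#'
#' @param dDA donor-acceptor distance, Angstrom.
#' @param angleDHA donor-hydrogen-acceptor angle, degrees in (0, 180].
#' @param nFrames number of frames.
#' @param seed integer seed (kept for interface symmetry; geometry is exact).
#' @param path output PDB path.
#' @return the PDB path, invisibly.  The matching candidate is
#'   `hbondSpec(c("M", 1, "N4"), c("M", 1, "H41"), c("M", 2, "O4"))`.
#' @export
genHbondPDB <- function(dDA, angleDHA, nFrames = 1, seed = 1,
                        path = tempfile(fileext = ".pdb")) {
  stopifnot(dDA > 0, angleDHA > 0, angleDHA <= 180)
  theta <- angleDHA * pi / 180
  # triangle D-H-A with |DH| = 1, |DA| = dDA, angle theta at H
  gam <- asin(pmin(1, sin(theta) / dDA))
  alpha <- pi - theta - gam
  H <- c(cos(alpha), sin(alpha), 0)
  atoms <- data.frame(
    chain = "M", resno = c(1L, 1L, 2L), resname = c("C", "C", "U"),
    name = c("N4", "H41", "O4"), element = c("N", "H", "O"),
    stringsAsFactors = FALSE)
  base <- rbind(c(0, 0, 0), H, c(dDA, 0, 0))
  coords <- array(rep(base, nFrames), dim = c(3, 3, nFrames))
  .writeSynthetic(atoms, coords, path)
  invisible(path)
}

#' Feasible phi interval for a pair of Bernoulli marginals
#'
#' The attainable phi for binary variables with occupancies `p` and `q` is
#' bounded by the Frechet bounds on the joint cell:
#' `max(0, p + q - 1) <= p11 <= min(p, q)`.
#'
#' @param p,q marginal occupancies in (0, 1).
#' @return numeric(2), the attainable `c(min, max)` phi.
#' @export
phiFeasibleInterval <- function(p, q) {
  s <- sqrt(p * (1 - p) * q * (1 - q))
  c(min = (max(0, p + q - 1) - p * q) / s,
    max = (min(p, q) - p * q) / s)
}

#' Generate coupled binary event streams with exact pairwise phi
#'
#' Per-contact Bernoulli streams with specified marginal occupancies.  For
#' every requested pair the 2x2 joint cell probabilities are solved exactly
#' from `(p, q, phi)` and the pair is sampled jointly, independently of
#' other pairs; unpaired contacts are sampled independently.  A contact may
#' appear in at most one coupled pair (the pairwise ground truth would
#' otherwise not be exact).  Infeasible requests error with the attainable
#' Frechet interval.
#'
#' @param nFrames number of frames.
#' @param marginals named numeric vector of occupancies in (0, 1).
#' @param phiPairs optional data.frame with columns `a`, `b`, `phi`.
#' @param seed integer seed.
#' @return integer 0/1 matrix `nFrames x length(marginals)` with the
#'   contacts as named columns.
#' @examples
#' x <- genCoupledBinaries(1000, c(u = 0.5, v = 0.5),
#'                         data.frame(a = "u", b = "v", phi = 0.5), seed = 1)
#' colMeans(x)
#' @export
genCoupledBinaries <- function(nFrames, marginals, phiPairs = NULL, seed = 1) {
  stopifnot(nFrames >= 1, all(marginals > 0), all(marginals < 1),
            !is.null(names(marginals)))
  labs <- names(marginals)
  if (!is.null(phiPairs)) {
    stopifnot(all(c("a", "b", "phi") %in% names(phiPairs)))
    used <- c(phiPairs$a, phiPairs$b)
    if (anyDuplicated(used))
      stop("specification error: a contact may appear in at most one ",
           "coupled pair")
    if (!all(used %in% labs))
      stop("specification error: unknown contact in phiPairs")
    for (i in seq_len(nrow(phiPairs))) {
      p <- marginals[[phiPairs$a[i]]]; q <- marginals[[phiPairs$b[i]]]
      bounds <- phiFeasibleInterval(p, q)
      if (phiPairs$phi[i] < bounds[1] - 1e-12 ||
          phiPairs$phi[i] > bounds[2] + 1e-12)
        stop(sprintf(paste0(
          "specification error: phi = %.4g infeasible for marginals ",
          "(%.3g, %.3g); attainable interval is [%.4g, %.4g]"),
          phiPairs$phi[i], p, q, bounds[1], bounds[2]))
    }
  }
  set.seed(seed)
  X <- matrix(0L, nFrames, length(labs), dimnames = list(NULL, labs))
  paired <- if (is.null(phiPairs)) character() else c(phiPairs$a, phiPairs$b)
  for (lab in setdiff(labs, paired))
    X[, lab] <- rbinom(nFrames, 1L, marginals[[lab]])
  if (!is.null(phiPairs)) for (i in seq_len(nrow(phiPairs))) {
    p <- marginals[[phiPairs$a[i]]]; q <- marginals[[phiPairs$b[i]]]
    phi <- phiPairs$phi[i]
    p11 <- p * q + phi * sqrt(p * (1 - p) * q * (1 - q))
    cells <- c(`11` = p11, `10` = p - p11, `01` = q - p11,
               `00` = 1 - p - q + p11)
    cells <- pmax(cells, 0); cells <- cells / sum(cells)
    draw <- sample(1:4, nFrames, replace = TRUE, prob = cells)
    X[, phiPairs$a[i]] <- as.integer(draw %in% c(1L, 2L))
    X[, phiPairs$b[i]] <- as.integer(draw %in% c(1L, 3L))
  }
  X
}

#' Generate a factorial replicate dataset with injected effects
#'
#' Per-replicate responses over a [studyDesign()] table:
#' `response = baseline + main effects + two-way interaction offsets +
#' noise`.  Noise is lognormal by default (the skewed, non-normal regime
#' that motivates rank-based ANOVA) or Gaussian.  The injected ground truth
#' is attached as `attr(, "groundTruth")` for recovery scoring.
#'
#' @param design data.frame from [studyDesign()] (or any factor table with a
#'   `replicate` column).
#' @param baseline grand-mean baseline.
#' @param mainEffects named list: factor name -> named numeric offsets per
#'   level (unlisted levels are 0).
#' @param interactions named list: `"f1:f2"` -> matrix of per-cell offsets
#'   with dimnames = the two factors' levels.
#' @param noise `"lognormal"` or `"normal"`.
#' @param sigma noise scale: sd for normal noise, sdlog for lognormal
#'   (lognormal noise is mean-centered).
#' @param seed integer seed.
#' @return `design` with a `response` column appended.
#' @export
genFactorialDataset <- function(design, baseline = 0, mainEffects = list(),
                                interactions = list(),
                                noise = c("lognormal", "normal"),
                                sigma = 1, seed = 1) {
  noise <- match.arg(noise)
  stopifnot(sigma > 0)
  set.seed(seed)
  n <- nrow(design)
  mu <- rep(baseline, n)
  for (f in names(mainEffects)) {
    off <- mainEffects[[f]]
    hit <- match(design[[f]], names(off))
    mu <- mu + ifelse(is.na(hit), 0, off[hit])
  }
  for (key in names(interactions)) {
    fs <- strsplit(key, ":", fixed = TRUE)[[1]]
    m <- interactions[[key]]
    i <- match(design[[fs[1]]], rownames(m))
    j <- match(design[[fs[2]]], colnames(m))
    ok <- !is.na(i) & !is.na(j)
    mu[ok] <- mu[ok] + m[cbind(i[ok], j[ok])]
  }
  eps <- if (noise == "normal") rnorm(n, 0, sigma)
         else rlnorm(n, 0, sigma) - exp(sigma^2 / 2)
  out <- design
  out$response <- mu + eps
  attr(out, "groundTruth") <- list(baseline = baseline,
                                   mainEffects = mainEffects,
                                   interactions = interactions,
                                   noise = noise, sigma = sigma)
  out
}

# ---- neighborhood trajectory generator -------------------------------------

# residue layout for a condition; returns a data.frame of the 12 residues
.neighborhoodResidues <- function(condition) {
  n1 <- substr(condition$a_site_n1n2, 1, 1)
  n2 <- substr(condition$a_site_n1n2, 2, 2)
  n3 <- if (condition$wobble == "GU_wobble") "U" else "C"
  plus1 <- strsplit(condition$plus1_codon, "")[[1]]
  data.frame(
    chain = c("T", "T", "T", "C", "C", "P", rep("M", 6)),
    resno = c(36L, 35L, 34L, 1054L, 1196L, 146L, 1:6),
    resname = c(.complementBase(n1), .complementBase(n2), "G",
                "C", "A", "ARG", n1, n2, n3, plus1),
    column = c(rep("car", 6), rep("mrna", 6)),
    colIndex = c(1:6, 1:6),
    stringsAsFactors = FALSE)
}

# stack label -> (column, gap index between colIndex and colIndex + 1)
.stackGapMap <- function() {
  data.frame(label = letters[1:10],
             column = rep(c("car", "mrna"), each = 5),
             gap = rep(1:5, 2), stringsAsFactors = FALSE)
}

# Assign every hbond contact a designated donor(+hydrogen)/acceptor triple.
# Free atoms (outside the ring/guanidinium template) are positionable;
# ring atoms are fixed in the stacked columns and shareable as satellite
# targets.  A free donor heavy is a shared resource holding up to one
# contact per hydrogen, as a mix of "satD" column targets (at most two,
# and only when they are the same atom name in vertically adjacent column
# residues, so the donor can sit on the equidistant circle) and "attach"ed
# free acceptors; a donor with no column target sits at an isolated slot.
# "satA" parks a free acceptor 3 A from a column donor.  Solved by
# most-constrained-first backtracking over the contacts.
.solveHbondPlacement <- function(contacts, residues, edges) {
  ringOf <- function(rid) .baseRingAtoms(residues$resname[rid])$name
  resId <- function(ref) which(residues$chain == ref$chain &
                                 residues$resno == ref$resno)
  optionsFor <- function(ct) {
    X <- resId(ct$partners$a); Y <- resId(ct$partners$b)
    opts <- list()
    for (ori in list(c(X, Y), c(Y, X))) {
      don <- ori[1]; acc <- ori[2]
      ed <- edges[[residues$resname[don]]]
      ea <- edges[[residues$resname[acc]]]
      if (is.null(ed) || is.null(ea)) next
      for (d in ed$donors) for (aa in unlist(ea$acceptors)) {
        dFree <- !(d$heavy %in% ringOf(don))
        aFree <- !(aa %in% ringOf(acc))
        mode <- if (dFree && aFree) "attach"
                else if (dFree) "satD"
                else if (aFree) "satA"
                else next
        opts[[length(opts) + 1L]] <- list(
          mode = mode, don = don, acc = acc, donorHeavy = d$heavy,
          hydrogens = unlist(d$hydrogens), acceptor = aa)
      }
    }
    opts
  }
  allOpts <- lapply(contacts, optionsFor)
  ord <- order(vapply(allOpts, length, 1L))

  placed <- vector("list", length(contacts))
  key <- function(rid, atom) paste0(rid, "|", atom)

  compatibleTargets <- function(cl, acc, atom) {
    if (length(cl$targets) >= 2L) return(FALSE)
    for (t in cl$targets) {
      if (t$atom != atom) return(FALSE)
      if (residues$column[t$acc] != residues$column[acc]) return(FALSE)
      if (abs(residues$colIndex[t$acc] - residues$colIndex[acc]) != 1)
        return(FALSE)
    }
    TRUE
  }

  # state: hUsed (consumed hydrogens), accUsed (consumed free acceptors),
  # clusters: donor key -> list(targets = column targets, nAcc = attached)
  dfs <- function(i, state) {
    if (i > length(ord)) return(state)
    ci <- ord[i]
    for (op in allOpts[[ci]]) {
      dk <- key(op$don, op$donorHeavy)
      freeH <- setdiff(paste0(dk, "#", op$hydrogens), state$hUsed)
      if (!length(freeH)) next
      st <- state
      ok <- switch(op$mode,
        attach = {
          ak <- key(op$acc, op$acceptor)
          if (ak %in% st$accUsed) FALSE
          else {
            cl <- st$clusters[[dk]]
            if (is.null(cl)) cl <- list(targets = list(), nAcc = 0L)
            cl$nAcc <- cl$nAcc + 1L
            st$clusters[[dk]] <- cl
            st$accUsed <- c(st$accUsed, ak)
            TRUE
          }
        },
        satD = {
          cl <- st$clusters[[dk]]
          if (is.null(cl)) cl <- list(targets = list(), nAcc = 0L)
          if (!compatibleTargets(cl, op$acc, op$acceptor)) FALSE
          else {
            cl$targets <- c(cl$targets,
                            list(list(acc = op$acc, atom = op$acceptor)))
            st$clusters[[dk]] <- cl
            TRUE
          }
        },
        satA = {
          ak <- key(op$acc, op$acceptor)
          if (ak %in% st$accUsed) FALSE
          else { st$accUsed <- c(st$accUsed, ak); TRUE }
        })
      if (!ok) next
      st$hUsed <- c(st$hUsed, freeH[1])
      placed[[ci]] <<- c(op, list(hydrogen = sub(".*#", "", freeH[1])))
      res <- dfs(i + 1, st)
      if (!is.null(res)) return(res)
      placed[ci] <<- list(NULL)
    }
    NULL
  }
  final <- dfs(1, list(hUsed = character(), accUsed = character(),
                       clusters = list()))
  if (is.null(final))
    stop("could not assign designated H-bond geometry for this condition")
  placed
}

#' Generate a synthetic decoding-center neighborhood trajectory
#'
#' Builds a toy neighborhood (tRNA anticodon 34-36, A-site codon, the
#' C/A/R CAR mimic, +1 codon) whose per-frame geometry toggles every
#' catalogue contact on or off according to a per-contact occupancy plan.
#' The ten stacks are gaps in two stacked columns (3.4 Angstrom when
#' stacked, 5.5 when unstacked); each H-bond contact is driven by one
#' designated donor-hydrogen-acceptor triple whose hydrogen is oriented
#' toward (on) or away from (off) an acceptor placed 3.0 Angstrom from the
#' donor.  The plan controls the *binarized* per-contact occupancies;
#' contacts not listed in `couple` are drawn independently.
#'
#' @param condition list/row with `a_site_n1n2`, `wobble`, `plus1_codon`.
#' @param occupancy named numeric vector of target occupancies in `[0, 1]`
#'   per contact label; unnamed scalar recycles to all contacts.
#' @param nFrames number of frames.
#' @param seed integer seed.
#' @param catalogue a [ContactCatalogue-class] (default [defaultCatalogue()]).
#' @param couple optional list of label groups; contacts within one group
#'   share a single latent uniform per frame (comonotone coupling).
#' @param jitterSD optional isotropic coordinate jitter, Angstrom.
#' @param path optional PDB output path.
#' @return a [DecodingTrajectory-class].
#' @examples
#' traj <- genNeighborhoodTrajectory(
#'   list(a_site_n1n2 = "UG", wobble = "GU_wobble", plus1_codon = "GCU"),
#'   occupancy = 0.5, nFrames = 50, seed = 1)
#' nFrames(traj)
#' @export
genNeighborhoodTrajectory <- function(condition, occupancy = 0.5,
                                      nFrames = 100, seed = 1,
                                      catalogue = defaultCatalogue(),
                                      couple = NULL, jitterSD = 0,
                                      path = NULL) {
  labs <- contactLabels(catalogue)
  if (is.null(names(occupancy))) {
    stopifnot(length(occupancy) == 1L)
    occupancy <- setNames(rep(occupancy, length(labs)), labs)
  }
  if (!all(labs %in% names(occupancy)))
    stop("occupancy plan must cover every catalogue contact")
  stopifnot(all(occupancy >= 0), all(occupancy <= 1))
  edges <- hbondEdges()
  residues <- .neighborhoodResidues(condition)

  # per-frame event draws (shared latent uniform within couple groups)
  set.seed(seed)
  U <- matrix(runif(nFrames * length(labs)), nFrames, length(labs),
              dimnames = list(NULL, labs))
  if (!is.null(couple)) for (grp in couple) {
    u <- runif(nFrames)
    for (lab in grp) U[, lab] <- u
  }
  E <- sweep(U, 2, occupancy[labs], "<") * 1L

  hbContacts <- Filter(function(ct) ct$kind == "hbond", catalogue@contacts)
  placement <- .solveHbondPlacement(hbContacts, residues, edges)

  # ---- static atom bookkeeping
  nRes <- nrow(residues)
  ringTpl <- lapply(seq_len(nRes), function(i)
    .baseRingAtoms(residues$resname[i]))
  atomRows <- list()
  addAtom <- function(rid, name) {
    atomRows[[length(atomRows) + 1L]] <<- list(rid = rid, name = name)
  }
  for (i in seq_len(nRes)) {
    for (nm in ringTpl[[i]]$name) addAtom(i, nm)
    ed <- edges[[residues$resname[i]]]
    extra <- character()
    if (!is.null(ed)) {
      for (d in ed$donors) extra <- c(extra, d$heavy, unlist(d$hydrogens))
      extra <- c(extra, unlist(ed$acceptors))
    }
    for (nm in setdiff(unique(extra), ringTpl[[i]]$name)) addAtom(i, nm)
  }
  rid <- vapply(atomRows, `[[`, 1L, "rid")
  aname <- vapply(atomRows, `[[`, "", "name")
  atoms <- data.frame(
    chain = residues$chain[rid], resno = residues$resno[rid],
    resname = residues$resname[rid], name = aname,
    element = substr(aname, 1, 1), stringsAsFactors = FALSE)
  natom <- nrow(atoms)
  aidx <- function(r, nm) which(rid == r & aname == nm)

  # ---- per-frame z offsets of the two columns
  gapMap <- .stackGapMap()
  colX <- c(car = 0, mrna = 60)
  zRes <- matrix(0, nRes, nFrames)
  for (cn in c("car", "mrna")) {
    gl <- gapMap[gapMap$column == cn, ]
    gaps <- matrix(5.5, 5, nFrames)
    for (k in seq_len(nrow(gl)))
      gaps[gl$gap[k], ] <- ifelse(E[, gl$label[k]] == 1L, 3.4, 5.5)
    zc <- rbind(0, apply(gaps, 2, cumsum))
    zRes[residues$column == cn, ] <- zc[residues$colIndex[
      residues$column == cn], ]
  }

  coords <- array(NA_real_, dim = c(natom, 3, nFrames))
  setAtom <- function(i, x, y, z) {
    coords[i, 1, ] <<- x; coords[i, 2, ] <<- y; coords[i, 3, ] <<- z
  }

  # column (ring template) atoms; same local orientation for every residue,
  # so same-named atoms of one column are vertically aligned
  for (i in seq_len(nRes)) {
    tpl <- ringTpl[[i]]
    for (k in seq_len(nrow(tpl)))
      setAtom(aidx(i, tpl$name[k]),
              colX[[residues$column[i]]] + tpl$lx[k], tpl$ly[k], zRes[i, ])
  }

  # parking area per residue for unassigned free atoms
  parked <- rep(TRUE, natom)
  ringAtom <- logical(natom)
  for (i in seq_len(nRes))
    ringAtom[rid == i & aname %in% ringTpl[[i]]$name] <- TRUE
  parked[ringAtom] <- FALSE  # already placed

  posOf <- function(i) {
    m <- coords[i, , , drop = FALSE]
    dim(m) <- c(3L, nFrames)
    m
  }

  radialDir <- function(r, atom, rot = 0) {
    tpl <- ringTpl[[r]]
    v <- unlist(tpl[tpl$name == atom, c("lx", "ly")])
    if (sqrt(sum(v^2)) < 1e-6) v <- c(1, 0)
    v <- v / sqrt(sum(v^2))
    th <- rot * pi / 180
    c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2])
  }

  satCount <- new.env(parent = emptyenv())  # azimuth bookkeeping
  nextRot <- function(k) {
    n <- mget(k, envir = satCount, ifnotfound = 0L)[[1]]
    assign(k, n + 1L, envir = satCount)
    c(0, 60, -60, 120, -120, 180)[(n %% 6L) + 1L]
  }

  # toggle rule: ON places the hydrogen 1 A from its donor toward the
  # designated acceptor; OFF points it along a per-cluster horizontal
  # direction chosen >= 60 degrees away from every designated direction and
  # away from the column targets, so no candidate of any contact pair can
  # satisfy the angle criterion
  hbLabels <- vapply(hbContacts, function(ct) ct$label, "")
  rot2 <- function(v, deg) {
    th <- deg * pi / 180
    c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2])
  }
  aimHydrogen <- function(hI, dpos, apos, ev, offDir) {
    u <- apos - dpos
    nrm <- sqrt(colSums(u^2)); u <- sweep(u, 2, nrm, "/")
    setAtom(hI, dpos[1, ] + ev * u[1, ] + (1 - ev) * offDir[1],
            dpos[2, ] + ev * u[2, ] + (1 - ev) * offDir[2],
            dpos[3, ] + ev * u[3, ])
    parked[hI] <<- FALSE
  }

  # satA first: column donor, free acceptor parked 3 A radially outward
  donorGroups <- list()  # free-donor key -> contact indices
  for (ci in seq_along(hbContacts)) {
    pl <- placement[[ci]]
    if (pl$mode %in% c("attach", "satD")) {
      dk <- paste0(pl$don, "|", pl$donorHeavy)
      donorGroups[[dk]] <- c(donorGroups[[dk]], ci)
      next
    }
    ev <- E[, hbLabels[ci]]
    dI <- aidx(pl$don, pl$donorHeavy)
    hI <- aidx(pl$don, pl$hydrogen)
    aI <- aidx(pl$acc, pl$acceptor)
    rot <- nextRot(paste0("A", pl$don, "|", pl$donorHeavy))
    rd <- radialDir(pl$don, pl$donorHeavy, rot)
    dp <- posOf(dI)
    ap <- rbind(dp[1, ] + 3 * rd[1], dp[2, ] + 3 * rd[2], dp[3, ])
    setAtom(aI, ap[1, ], ap[2, ], ap[3, ])
    parked[aI] <- FALSE
    aimHydrogen(hI, dp, ap, ev, -rd)
  }

  # free donor heavies: positioned by their column target(s) when they have
  # any (equidistant circle for two targets), at an isolated slot
  # otherwise; attached free acceptors sit 3 A further out (or at rotated
  # slot directions), one hydrogen per contact
  nSlot <- 0L
  for (dk in names(donorGroups)) {
    cis <- donorGroups[[dk]]
    pls <- placement[cis]
    dI <- aidx(pls[[1]]$don, pls[[1]]$donorHeavy)
    satCis <- cis[vapply(pls, function(p) p$mode == "satD", TRUE)]
    attCis <- cis[vapply(pls, function(p) p$mode == "attach", TRUE)]
    if (length(satCis)) {
      aps <- lapply(satCis, function(ci)
        posOf(aidx(placement[[ci]]$acc, placement[[ci]]$acceptor)))
      pl1 <- placement[[satCis[1]]]
      rot <- nextRot(paste0("T", pl1$acc, "|", pl1$acceptor))
      rd <- radialDir(pl1$acc, pl1$acceptor, rot)
      if (length(satCis) == 1L) {
        ap <- aps[[1]]
        dpos <- rbind(ap[1, ] + 3 * rd[1], ap[2, ] + 3 * rd[2], ap[3, ])
      } else {
        a1 <- aps[[1]]; a2 <- aps[[2]]
        k <- sqrt(pmax(9 - ((a1[3, ] - a2[3, ]) / 2)^2, 0.25))
        dpos <- rbind((a1[1, ] + a2[1, ]) / 2 + k * rd[1],
                      (a1[2, ] + a2[2, ]) / 2 + k * rd[2],
                      (a1[3, ] + a2[3, ]) / 2)
      }
      outDir <- rd          # radially outward, away from the column
      offDir <- rot2(rd, -90)   # perpendicular: away from targets and
      attRot <- 90              # from the +90-degree attach direction
    } else {
      nSlot <- nSlot + 1L
      cx <- -30 - 14 * nSlot
      dpos <- rbind(rep(cx, nFrames), rep(0, nFrames), rep(0, nFrames))
      outDir <- c(1, 0)
      offDir <- c(-1, 0)
      attRot <- 0
    }
    setAtom(dI, dpos[1, ], dpos[2, ], dpos[3, ])
    parked[dI] <- FALSE
    for (j in seq_along(satCis)) {
      ci <- satCis[j]
      aimHydrogen(aidx(placement[[ci]]$don, placement[[ci]]$hydrogen),
                  dpos, aps[[j]], E[, hbLabels[ci]], offDir)
    }
    for (j in seq_along(attCis)) {
      ci <- attCis[j]
      pl <- placement[[ci]]
      dir2 <- rot2(outDir, attRot + (j - 1) * 60)
      ap <- rbind(dpos[1, ] + 3 * dir2[1], dpos[2, ] + 3 * dir2[2],
                  dpos[3, ])
      aI <- aidx(pl$acc, pl$acceptor)
      setAtom(aI, ap[1, ], ap[2, ], ap[3, ])
      parked[aI] <- FALSE
      aimHydrogen(aidx(pl$don, pl$hydrogen), dpos, ap, E[, hbLabels[ci]],
                  offDir)
    }
  }

  # park everything unassigned: one lane per residue, far from the action
  for (i in seq_len(nRes)) {
    ids <- which(parked & rid == i)
    for (k in seq_along(ids))
      setAtom(ids[k], 150 + 8 * i, 3 * k, -30)
  }
  # unused hydrogens of column donor heavies point inward (toward the
  # column axis) so they can never satisfy the angle criterion
  for (i in seq_len(nRes)) {
    ed <- edges[[residues$resname[i]]]
    if (is.null(ed)) next
    for (d in ed$donors) {
      if (!(d$heavy %in% ringTpl[[i]]$name)) next
      for (h in unlist(d$hydrogens)) {
        hI <- aidx(i, h)
        if (!parked[hI]) next
        rd <- radialDir(i, d$heavy)
        dp <- posOf(aidx(i, d$heavy))
        setAtom(hI, dp[1, ] - rd[1], dp[2, ] - rd[2], dp[3, ])
        parked[hI] <- FALSE
      }
    }
  }

  if (jitterSD > 0)
    coords <- coords + array(rnorm(length(coords), 0, jitterSD),
                             dim = dim(coords))
  traj <- .writeSynthetic(atoms, coords, path)
  traj
}
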