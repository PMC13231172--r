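# Shared fixture builders: tiny trajectories constructed directly in code.

# a trajectory from an atom table and a list of per-frame coordinate
# matrices (nAtoms x 3)
makeTraj <- function(atoms, frames, source = "synthetic") {
  coords <- array(NA_real_, dim = c(nrow(atoms), 3, length(frames)))
  for (i in seq_along(frames)) coords[, , i] <- frames[[i]]
  new("DecodingTrajectory", atoms = atoms, coords = coords, source = source)
}

# regular hexagon ring coordinates (circumradius r) in the z = z0 plane,
# offset by (x0, y0)
hexCoords <- function(z0 = 0, x0 = 0, y0 = 0, r = 1.37) {
  ang <- (0:5) * pi / 3
  m <- cbind(x0 + r * cos(ang), y0 + r * sin(ang), rep(z0, 6))
  dimnames(m) <- NULL
  m
}

pyrimidineAtoms <- function(chain, resno, resname = "C") {
  data.frame(chain = chain, resno = resno, resname = resname,
             name = c("N1", "C2", "N3", "C4", "C5", "C6"),
             element = c("N", "C", "N", "C", "C", "C"),
             stringsAsFactors = FALSE)
}

# donor/hydrogen/acceptor triad with exact geometry (one frame)
triadCoords <- function(dDA, angleDHA) {
  theta <- angleDHA * pi / 180
  gam <- asin(min(1, sin(theta) / dDA))
  alpha <- pi - theta - gam
  rbind(c(0, 0, 0), c(cos(alpha), sin(alpha), 0), c(dDA, 0, 0))
}

triadAtoms <- data.frame(
  chain = "M", resno = c(1L, 1L, 2L), resname = c("C", "C", "U"),
  name = c("N4", "H41", "O4"), element = c("N", "H", "O"),
  stringsAsFactors = FALSE)

triadSpec <- hbondSpec(c("M", 1, "N4"), c("M", 1, "H41"), c("M", 2, "O4"))

# angle D-H-A in degrees from coordinates
dhaAngle <- function(d, h, a) {
  v1 <- d - h; v2 <- a - h
  acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
}

# a rigid rotation matrix from three angles
rotMat <- function(a, b, c) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
  Rx %*% Ry %*% Rz
}

defaultCondition <- list(a_site_n1n2 = "UG", wobble = "GU_wobble",
                         plus1_codon = "GCU")
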