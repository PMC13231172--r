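#' @import methods
#' @importFrom stats aov cor cor.test cutree dist hclust kmeans pf p.adjust
#'   rbinom rlnorm rnorm runif sd setNames shapiro.test cmdscale as.dist
#'   complete.cases pt
#' @importFrom utils read.csv write.csv head modifyList
NULL

#' Geometric interaction-calling parameters
#'
#' Holds the three geometric cutoffs used to call interactions from
#' coordinates: the heavy-donor to acceptor distance and the
#' donor-hydrogen-acceptor angle for hydrogen bonds, and the ring
#' center-of-geometry (COG) distance below which two ring systems are
#' classified as stacked.
#'
#' Defaults are the cpptraj-style H-bond criteria (3.5 Angstrom, 135 degrees)
#' and the 4.5 Angstrom stacking threshold commonly used for stable pi-pi and
#' pi-cation stacking of nucleobases.
#'
#' @slot hbondDistCutoff numeric(1), Angstrom; heavy donor-acceptor distance
#'   at or below which (with the angle criterion) an H-bond is called.
#' @slot hbondAngleCutoff numeric(1), degrees in (0, 180]; minimum
#'   donor-hydrogen-acceptor angle.
#' @slot stackCutoff numeric(1), Angstrom; COG-COG distance at or below which
#'   a ring pair is classified as stacked.
#' @export
setClass("GeometryParams",
  representation(
    hbondDistCutoff = "numeric",
    hbondAngleCutoff = "numeric",
    stackCutoff = "numeric"
  ),
  prototype(hbondDistCutoff = 3.5, hbondAngleCutoff = 135, stackCutoff = 4.5)
)

setValidity("GeometryParams", function(object) {
  msg <- character()
  for (s in c("hbondDistCutoff", "hbondAngleCutoff", "stackCutoff")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive finite number", s))
  }
  if (length(object@hbondAngleCutoff) == 1L &&
      is.finite(object@hbondAngleCutoff) &&
      object@hbondAngleCutoff > 180)
    msg <- c(msg, "'hbondAngleCutoff' must lie in (0, 180]")
  if (length(msg)) msg else TRUE
})

#' @param hbondDistCutoff,hbondAngleCutoff,stackCutoff see slots.
#' @return `geometryParams()` returns a validated [GeometryParams-class]
#'   object.
#' @rdname GeometryParams-class
#' @examples
#' geometryParams()
#' geometryParams(stackCutoff = 5)
#' @export
geometryParams <- function(hbondDistCutoff = 3.5, hbondAngleCutoff = 135,
                           stackCutoff = 4.5) {
  new("GeometryParams", hbondDistCutoff = hbondDistCutoff,
      hbondAngleCutoff = hbondAngleCutoff, stackCutoff = stackCutoff)
}

#' Multi-model trajectory of a decoding-center neighborhood
#'
#' Ordered coordinate frames for a fixed set of named atoms grouped by
#' (chain, residue number).  Every frame contains the same atoms in the same
#' order, so coordinates are stored as a dense `nAtoms x 3 x nFrames` array;
#' atom identity (chain, residue number, residue name, atom name, element)
#' lives in a parallel data.frame.
#'
#' @slot atoms data.frame with columns `chain`, `resno`, `resname`, `name`,
#'   `element`; one row per atom, shared by all frames.
#' @slot coords numeric array `nAtoms x 3 x nFrames` (Angstrom).
#' @slot source character(1); originating file path or `"synthetic"`.
#' @export
setClass("DecodingTrajectory",
  representation(atoms = "data.frame", coords = "array", source = "character")
)

setValidity("DecodingTrajectory", function(object) {
  msg <- character()
  at <- object@atoms
  need <- c("chain", "resno", "resname", "name", "element")
  if (!all(need %in% names(at)))
    msg <- c(msg, paste("'atoms' must have columns", paste(need, collapse = ", ")))
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    msg <- c(msg, "'coords' must be an nAtoms x 3 x nFrames array")
  else {
    if (d[1] != nrow(at))
      msg <- c(msg, "nrow(atoms) must match dim(coords)[1]")
    if (d[3] < 1L)
      msg <- c(msg, "a trajectory needs at least one frame")
    if (!all(is.finite(object@coords)))
      msg <- c(msg, "coordinates must be finite")
  }
  if (all(need %in% names(at)) && nrow(at) &&
      anyDuplicated(paste(at$chain, at$resno, at$name)))
    msg <- c(msg, "duplicated (chain, resno, atom name) within a frame")
  if (length(msg)) msg else TRUE
})

#' Labeled contact catalogue
#'
#' An ordered collection of labeled contact definitions.  Each contact is
#' either a `stack` (ring-system COG distance between two residues) or an
#' `hbond` (a family of donor-hydrogen-acceptor candidates between two
#' residues).  The default 26-entry catalogue is built by
#' [defaultCatalogue()].
#'
#' @slot contacts list of contact definitions as returned by [contactDef()].
#' @export
setClass("ContactCatalogue", representation(contacts = "list"))

setValidity("ContactCatalogue", function(object) {
  msg <- character()
  labs <- vapply(object@contacts, function(x) x$label, "")
  if (anyDuplicated(labs))
    msg <- c(msg, "contact labels must be unique within a catalogue")
  ok <- vapply(object@contacts, function(x)
    is.list(x) && all(c("label", "kind", "partners", "site") %in% names(x)) &&
      x$kind %in% c("stack", "hbond"), TRUE)
  if (!all(ok)) msg <- c(msg, "malformed contact definition(s)")
  if (length(msg)) msg else TRUE
})

#' Per-frame interaction series for one contact
#'
#' The per-frame scalar series obtained by evaluating one contact across a
#' trajectory: COG distances in Angstrom for `stack` contacts, non-negative
#' candidate counts for `hbond` contacts, or 0/1 events after
#' [binarizeSeries()].
#'
#' @slot label character(1) contact label.
#' @slot kind `"stack"`, `"hbond"` or `"binary"`.
#' @slot values numeric per-frame values.
#' @slot trimmed logical(1); TRUE once equilibration trimming was applied.
#' @export
setClass("InteractionSeries",
  representation(label = "character", kind = "character",
                 values = "numeric", trimmed = "logical"),
  prototype(trimmed = FALSE)
)

setValidity("InteractionSeries", function(object) {
  msg <- character()
  if (!object@kind %in% c("stack", "hbond", "binary"))
    msg <- c(msg, "kind must be 'stack', 'hbond' or 'binary'")
  if (object@kind == "binary" && length(object@values) &&
      !all(object@values %in% c(0, 1)))
    msg <- c(msg, "binary series values must be 0/1")
  if (object@kind == "hbond" && length(object@values) &&
      (any(object@values < 0) || any(object@values != round(object@values))))
    msg <- c(msg, "hbond series values must be non-negative integers")
  if (length(msg)) msg else TRUE
})
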