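#' Number of frames in a trajectory
#' @param x a [DecodingTrajectory-class].
#' @return integer(1)
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Contact labels of a catalogue
#' @param x a [ContactCatalogue-class].
#' @return character vector of labels, in catalogue order.
#' @export
setGeneric("contactLabels", function(x) standardGeneric("contactLabels"))

#' Per-frame atom coordinates of one residue
#'
#' @param x a [DecodingTrajectory-class].
#' @param chain chain identifier.
#' @param resno residue number (file numbering).
#' @param frames optional integer vector of frame indices (default all).
#' @return a list with `atoms` (the residue's rows of the atom table) and
#'   `coords` (`nAtoms x 3 x nFrames` array restricted to the residue).
#' @export
setGeneric("selectResidue", function(x, chain, resno, frames = NULL)
  standardGeneric("selectResidue"))

#' Arithmetic mean of a (trimmed) interaction series
#' @param series an [InteractionSeries-class].
#' @return numeric(1)
#' @export
setGeneric("meanInteraction", function(series) standardGeneric("meanInteraction"))
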