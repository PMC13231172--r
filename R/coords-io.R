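# Multi-model PDB I/O.
#
# The reader enforces the trajectory invariant that every MODEL contains the
# same (chain, resno, atom name) sequence, reporting the first offending
# frame; the writer emits the identical fixed-column dialect so that
# write -> read round-trips to the printed precision (3 decimals).

.parseAtomLine <- function(line) {
  list(
    name    = trimws(substr(line, 13, 16)),
    altloc  = substr(line, 17, 17),
    resname = trimws(substr(line, 18, 20)),
    chain   = trimws(substr(line, 22, 22)),
    resno   = as.integer(substr(line, 23, 26)),
    icode   = substr(line, 27, 27),
    x = as.numeric(substr(line, 31, 38)),
    y = as.numeric(substr(line, 39, 46)),
    z = as.numeric(substr(line, 47, 54)),
    element = trimws(substr(line, 77, 78))
  )
}

#' Read a multi-model PDB file into a trajectory
#'
#' Parses MODEL/ENDMDL-delimited ATOM/HETATM records into a
#' [DecodingTrajectory-class], one frame per MODEL (a file without MODEL
#' records yields a single frame).  Atom names, residue numbers and chain
#' identifiers are preserved verbatim; frames follow MODEL order.  For
#' alternate locations only the first altloc is kept; insertion codes are
#' rejected.
#'
#' @param path path to an existing PDB file.
#' @return a [DecodingTrajectory-class].
#' @seealso [writeMultiModelPDB()], [selectResidue()]
#' @examples
#' p <- genStackedPairPDB(3.4, nFrames = 2, seed = 1)
#' traj <- readMultiModelPDB(p)
#' nFrames(traj)
#' @export
readMultiModelPDB <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("input error: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  isAtom <- rec %in% c("ATOM  ", "HETATM")
  isModel <- startsWith(lines, "MODEL")
  if (!any(isAtom)) stop("input error: no ATOM/HETATM records in ", path)

  # assign a model index to every line
  model <- cumsum(isModel)
  if (!any(isModel)) model[] <- 1L
  model[model == 0L] <- 1L
  atomLines <- lines[isAtom]
  atomModel <- model[isAtom]
  atomModel <- match(atomModel, sort(unique(atomModel)))

  fields <- lapply(atomLines, .parseAtomLine)
  icode <- vapply(fields, `[[`, "", "icode")
  if (any(icode != " " & icode != ""))
    stop("format error: insertion codes are not supported (line with iCode '",
         icode[which(icode != " " & icode != "")[1]], "')")
  altloc <- vapply(fields, `[[`, "", "altloc")
  keep <- altloc %in% c(" ", "", "A")
  fields <- fields[keep]
  atomModel <- atomModel[keep]

  df <- data.frame(
    chain = vapply(fields, `[[`, "", "chain"),
    resno = vapply(fields, function(f) f$resno, 1L),
    resname = vapply(fields, `[[`, "", "resname"),
    name = vapply(fields, `[[`, "", "name"),
    element = vapply(fields, `[[`, "", "element"),
    x = vapply(fields, function(f) f$x, 1),
    y = vapply(fields, function(f) f$y, 1),
    z = vapply(fields, function(f) f$z, 1),
    stringsAsFactors = FALSE
  )
  df$element[df$element == ""] <- substr(df$name[df$element == ""], 1, 1)

  nf <- max(atomModel)
  key <- paste(df$chain, df$resno, df$name, sep = "|")
  ref <- key[atomModel == 1L]
  for (m in seq_len(nf)[-1]) {
    km <- key[atomModel == m]
    if (length(km) != length(ref) || any(km != ref)) {
      bad <- if (length(km) != length(ref)) {
        "different atom count"
      } else {
        paste0("first mismatch at atom '", km[which(km != ref)[1]], "'")
      }
      stop("format error: frame ", m,
           " does not match the residue/atom set of frame 1 (", bad, ")")
    }
  }

  natom <- length(ref)
  coords <- array(NA_real_, dim = c(natom, 3L, nf))
  ord <- order(atomModel)  # lines are already in order; defensive
  xyz <- as.matrix(df[ord, c("x", "y", "z")])
  for (m in seq_len(nf))
    coords[, , m] <- xyz[((m - 1L) * natom + 1L):(m * natom), , drop = FALSE]

  atoms <- df[atomModel == 1L, c("chain", "resno", "resname", "name", "element")]
  rownames(atoms) <- NULL
  new("DecodingTrajectory", atoms = atoms, coords = coords, source = path)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Emits MODEL/ENDMDL-delimited ATOM records in the same fixed-column dialect
#' that [readMultiModelPDB()] parses, so that a write/read round trip
#' preserves atom names and coordinates to the printed precision.
#'
#' @param traj a [DecodingTrajectory-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMultiModelPDB <- function(traj, path) {
  stopifnot(is(traj, "DecodingTrajectory"))
  at <- traj@atoms
  nf <- nFrames(traj)
  name4 <- ifelse(nchar(at$name) >= 4L, substr(at$name, 1, 4),
                  sprintf("%-4s", paste0(" ", at$name)))
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- traj@coords[, , m, drop = FALSE]
    lines <- sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(at)), name4, at$resname, at$chain, at$resno,
      xyz[, 1, 1], xyz[, 2, 1], xyz[, 3, 1], 1, 0, at$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @rdname nFrames
#' @export
setMethod("nFrames", "DecodingTrajectory", function(x) dim(x@coords)[3])

#' @rdname selectResidue
#' @export
setMethod("selectResidue", "DecodingTrajectory",
  function(x, chain, resno, frames = NULL) {
    idx <- which(x@atoms$chain == chain & x@atoms$resno == resno)
    if (!length(idx))
      stop("lookup error: residue (", chain, ", ", resno,
           ") not present in the trajectory")
    if (is.null(frames)) frames <- seq_len(nFrames(x))
    list(atoms = x@atoms[idx, , drop = FALSE],
         coords = x@coords[idx, , frames, drop = FALSE])
  })

setMethod("show", "DecodingTrajectory", function(object) {
  at <- object@atoms
  res <- unique(paste0(at$chain, ":", at$resno))
  cat("DecodingTrajectory with", nFrames(object), "frame(s),",
      nrow(at), "atoms in", length(res), "residues\n")
  cat("  source:", object@source, "\n")
  cat("  residues:", paste(head(res, 8), collapse = " "),
      if (length(res) > 8) "...", "\n")
})

# internal: atom row indices for (chain, resno, names); errors name the
# residue and atom so contact evaluation can propagate useful messages
.atomIdx <- function(traj, chain, resno, names) {
  at <- traj@atoms
  idx <- integer(length(names))
  for (i in seq_along(names)) {
    j <- which(at$chain == chain & at$resno == resno & at$name == names[i])
    if (length(j) != 1L)
      stop("geometry error: atom '", names[i], "' not resolvable in residue (",
           chain, ", ", resno, ")")
    idx[i] <- j
  }
  idx
}
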