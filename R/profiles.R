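# Per-trajectory contact evaluation and reduction to per-simulation
# fingerprints and site-level H-bond strengths.

#' Construct an interaction series
#' @param label contact label.
#' @param kind `"stack"`, `"hbond"` or `"binary"`.
#' @param values per-frame numeric values.
#' @param trimmed logical(1).
#' @return an [InteractionSeries-class].
#' @export
interactionSeries <- function(label, kind, values, trimmed = FALSE)
  new("InteractionSeries", label = label, kind = kind,
      values = as.numeric(values), trimmed = trimmed)

#' @describeIn InteractionSeries-class number of frames in the series.
#' @param x an `InteractionSeries`.
#' @export
setMethod("length", "InteractionSeries", function(x) length(x@values))

setMethod("show", "InteractionSeries", function(object) {
  cat(sprintf("InteractionSeries '%s' (%s), %d frames%s\n", object@label,
              object@kind, length(object@values),
              if (object@trimmed) ", trimmed" else ""))
})

#' @rdname meanInteraction
#' @export
setMethod("meanInteraction", "InteractionSeries", function(series) {
  if (!length(series@values))
    stop("argument error: cannot average an empty series")
  mean(series@values)
})

#' Remove equilibration frames from a series
#'
#' Two trimming policies coexist, matching the two reductions they feed:
#' `dropFirstN` removes an initial equilibration block (used for
#' frame-resolved covariation; default 2000 frames at production scale) and
#' `keepFinalFraction` retains only the final fraction of frames (used for
#' mean-interaction analyses, e.g. the final 40 of 60 ns, i.e. 2/3).
#' Exactly one policy must be given.
#'
#' @param series an [InteractionSeries-class].
#' @param dropFirstN integer; number of leading frames to drop.
#' @param keepFinalFraction fraction in (0, 1]; tail fraction to keep
#'   (`floor(n * fraction)` frames).
#' @return the trimmed [InteractionSeries-class] (`trimmed` flag set).
#' @examples
#' s <- interactionSeries("g", "stack", rnorm(100, 4))
#' length(trimEquilibration(s, dropFirstN = 20))
#' @export
trimEquilibration <- function(series, dropFirstN = NULL,
                              keepFinalFraction = NULL) {
  stopifnot(is(series, "InteractionSeries"))
  n <- length(series@values)
  if (is.null(dropFirstN) == is.null(keepFinalFraction))
    stop("argument error: give exactly one of dropFirstN / keepFinalFraction")
  if (!is.null(dropFirstN)) {
    if (dropFirstN < 0 || dropFirstN >= n)
      stop("argument error: dropFirstN must leave at least one frame")
    keep <- seq.int(dropFirstN + 1L, n)
  } else {
    if (keepFinalFraction <= 0 || keepFinalFraction > 1)
      stop("argument error: keepFinalFraction must be in (0, 1]")
    k <- floor(n * keepFinalFraction)
    if (k < 1L) stop("argument error: policy would drop every frame")
    keep <- seq.int(n - k + 1L, n)
  }
  interactionSeries(series@label, series@kind, series@values[keep],
                    trimmed = TRUE)
}

.applyTrim <- function(series, trim) {
  if (is.null(trim)) return(series)
  do.call(trimEquilibration, c(list(series), trim))
}

#' Evaluate one contact across a trajectory
#'
#' `stack` contacts yield the per-frame minimum ring-pair COG distance
#' (Angstrom); `hbond` contacts yield the per-frame count of satisfied
#' donor-hydrogen-acceptor candidates (explicit `candidates` if the contact
#' carries them, otherwise enumerated from the edge catalogue).
#'
#' @param traj a [DecodingTrajectory-class].
#' @param contact a [contactDef()] definition.
#' @param params a [GeometryParams-class].
#' @param ringData,edges ring and donor/acceptor catalogues.
#' @return an [InteractionSeries-class] (untrimmed).
#' @export
evaluateContact <- function(traj, contact, params = geometryParams(),
                            ringData = ringCatalogue(), edges = hbondEdges()) {
  a <- contact$partners$a; b <- contact$partners$b
  vals <- tryCatch({
    if (contact$kind == "stack") {
      stackingDistance(traj, a$chain, a$resno, b$chain, b$resno,
                       ringData = ringData)
    } else {
      cands <- contact$candidates
      if (is.null(cands)) cands <- .hbondCandidates(traj, a, b, edges)
      if (!length(cands))
        stop("no H-bond candidates between the partner residues")
      hbondCount(traj, cands, params)
    }
  }, error = function(e)
    stop("contact '", contact$label, "': ", conditionMessage(e),
         call. = FALSE))
  interactionSeries(contact$label, contact$kind, vals)
}

#' Binarize an interaction series
#'
#' Stacking distances become stacked/unstacked events at the stack cutoff
#' (see [classifyStacked()]); H-bond counts become presence events
#' (1 iff at least one candidate satisfied).
#'
#' @param series an [InteractionSeries-class].
#' @param params a [GeometryParams-class].
#' @return a binary [InteractionSeries-class].
#' @examples
#' s <- interactionSeries("g", "stack", c(4.4, 4.6, 3.0), trimmed = TRUE)
#' binarizeSeries(s)@values
#' @export
binarizeSeries <- function(series, params = geometryParams()) {
  v <- switch(series@kind,
    stack = classifyStacked(series@values, params),
    hbond = as.integer(series@values >= 1),
    binary = as.integer(series@values))
  new("InteractionSeries", label = series@label, kind = "binary",
      values = as.numeric(v), trimmed = series@trimmed)
}

#' Site-level H-bond strength of a trajectory
#'
#' For each mRNA nucleotide of the site (A site: codon positions 1-3; CAR
#' site: +1 codon positions 1-3), H-bonding with its nearest
#' complementary-surface residues (the site's grouped `hbond` contacts) is
#' averaged over frames; the site strength is the mean over the site's
#' nucleotides.  With `reduction = "frequency"` (default) each contact
#' contributes its per-frame presence (0/1) and the per-nucleotide value is
#' the mean presence over its contacts; with `reduction = "count"` the
#' per-nucleotide value is the mean total candidate count.
#'
#' @param traj a [DecodingTrajectory-class].
#' @param site `"A_site"` or `"CAR_site"`.
#' @param catalogue a [ContactCatalogue-class] with grouped hbond contacts.
#' @param params a [GeometryParams-class].
#' @param trim optional trim policy list, e.g. `list(keepFinalFraction = 2/3)`.
#' @param reduction `"frequency"` or `"count"`.
#' @return numeric(1).
#' @export
siteHbondStrength <- function(traj, site = c("A_site", "CAR_site"),
                              catalogue = defaultCatalogue(),
                              params = geometryParams(), trim = NULL,
                              reduction = c("frequency", "count")) {
  site <- match.arg(site)
  reduction <- match.arg(reduction)
  groups <- if (site == "A_site") c("M1", "M2", "M3") else c("M4", "M5", "M6")
  cts <- Filter(function(ct) ct$kind == "hbond" && !is.na(ct$group) &&
                  ct$group %in% groups, catalogue@contacts)
  if (!length(cts))
    stop("configuration error: catalogue has no hbond contacts grouped ",
         "under site ", site)
  perNt <- vapply(groups, function(g) {
    gc <- Filter(function(ct) ct$group == g, cts)
    if (!length(gc)) return(NA_real_)
    vals <- vapply(gc, function(ct) {
      s <- .applyTrim(evaluateContact(traj, ct, params), trim)
      if (reduction == "frequency") meanInteraction(binarizeSeries(s, params))
      else meanInteraction(s)
    }, 1)
    if (reduction == "frequency") mean(vals) else sum(vals)
  }, 1)
  mean(perNt, na.rm = TRUE)
}

#' Full-factorial study design of the simulation campaign
#'
#' The factorial condition table indexing every simulation: A-site codon
#' N1N2 dinucleotide (6 levels), wobble-position decoding geometry (G:U
#' wobble vs G:C Watson-Crick) and +1 codon identity (GCU vs CGU), fully
#' crossed (24 conditions) with `replicates` independent replicates each
#' (default 30, i.e. 720 simulations).
#'
#' @param replicates replicates per condition.
#' @return data.frame with columns `a_site_n1n2`, `wobble`, `plus1_codon`,
#'   `replicate`, `simulation_id`.
#' @examples
#' nrow(studyDesign())     # 720
#' @export
studyDesign <- function(replicates = 30) {
  d <- expand.grid(
    replicate = seq_len(replicates),
    plus1_codon = c("GCU", "CGU"),
    wobble = c("GU_wobble", "GC_watson_crick"),
    a_site_n1n2 = c("AG", "AA", "CC", "UG", "UA", "UU"),
    stringsAsFactors = FALSE)[, c("a_site_n1n2", "wobble", "plus1_codon",
                                  "replicate")]
  d$simulation_id <- sprintf("a%s%s_+1%s_r%02d", d$a_site_n1n2,
                             ifelse(d$wobble == "GU_wobble", "U", "C"),
                             d$plus1_codon, d$replicate)
  d
}

#' Build per-simulation interaction fingerprints
#'
#' Evaluates every catalogue contact on every simulation, trims, and reduces
#' to the per-simulation vector of mean interaction strengths (mean COG
#' distance for stacks, mean H-bond count for hbond contacts) — one
#' fingerprint per simulation, assembled as a
#' [SummarizedExperiment::SummarizedExperiment] with contacts as rows and
#' simulations as columns (`colData` holds the condition labels).
#'
#' @param simulations named list; each element is a list with `traj` (a
#'   [DecodingTrajectory-class]) and `condition` (named list/row with the
#'   design factors, e.g. `a_site_n1n2`, `wobble`, `plus1_codon`,
#'   `replicate`).
#' @param catalogue a [ContactCatalogue-class].
#' @param params a [GeometryParams-class].
#' @param trim trim policy list (see [trimEquilibration()]), or NULL.
#' @return a `SummarizedExperiment` with assay `"mean"`.
#' @export
buildFingerprints <- function(simulations, catalogue = defaultCatalogue(),
                              params = geometryParams(), trim = NULL) {
  labs <- contactLabels(catalogue)
  ids <- names(simulations)
  if (is.null(ids)) ids <- sprintf("sim%03d", seq_along(simulations))
  mat <- matrix(NA_real_, nrow = length(labs), ncol = length(simulations),
                dimnames = list(labs, ids))
  for (j in seq_along(simulations)) {
    sim <- simulations[[j]]
    mat[, j] <- tryCatch(
      vapply(catalogue@contacts, function(ct) {
        s <- .applyTrim(evaluateContact(sim$traj, ct, params), trim)
        meanInteraction(s)
      }, 1),
      error = function(e)
        stop("simulation '", ids[j], "' failed evaluation: ",
             conditionMessage(e), call. = FALSE))
  }
  cond <- do.call(rbind, lapply(simulations, function(sim)
    as.data.frame(sim$condition, stringsAsFactors = FALSE)))
  rownames(cond) <- ids
  rd <- catalogueTable(catalogue)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(mean = mat),
    rowData = S4Vectors::DataFrame(rd),
    colData = S4Vectors::DataFrame(cond))
}

#' Scale fingerprints by per-contact standard deviation
#'
#' Divides each contact's row by its standard deviation across all
#' simulations so H-bond and stacking measures are cross-comparable.
#' Zero-variance contacts are left unscaled and flagged in
#' `rowData(se)$scaled`.
#'
#' @param se fingerprint `SummarizedExperiment` from [buildFingerprints()].
#' @return the scaled `SummarizedExperiment` with assay `"scaled"` added.
#' @export
scaleFingerprints <- function(se) {
  m <- SummarizedExperiment::assay(se, "mean")
  sds <- apply(m, 1, sd)
  scaled <- sds > 0
  m2 <- m
  m2[scaled, ] <- m[scaled, , drop = FALSE] / sds[scaled]
  SummarizedExperiment::assays(se)$scaled <- m2
  SummarizedExperiment::rowData(se)$scaled <- scaled
  se
}

#' Long-format fingerprint table
#'
#' @param se fingerprint `SummarizedExperiment`.
#' @param assay assay name (default `"mean"`).
#' @return data.frame keyed by (simulation, condition columns, contact) with
#'   a `mean_value` column, suitable for factorial statistics and CSV export.
#' @export
fingerprintTable <- function(se, assay = "mean") {
  m <- SummarizedExperiment::assay(se, assay)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  out <- data.frame(
    simulation_id = rep(colnames(m), each = nrow(m)),
    contact = rep(rownames(m), times = ncol(m)),
    mean_value = as.vector(m),
    stringsAsFactors = FALSE)
  cbind(out[, "simulation_id", drop = FALSE],
        cd[out$simulation_id, , drop = FALSE],
        out[, c("contact", "mean_value")], row.names = NULL)
}
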