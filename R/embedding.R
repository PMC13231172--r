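# Correlation-distance matrices, 2-D embeddings (UMAP contract, classical
# MDS as the PCA-on-distances route) and hierarchical clustering.

#' Pearson correlation-distance matrix
#'
#' For a set of equally long vectors (columns of `vectors`), computes
#' `D[i, j] = 1 - pearson(v_i, v_j)`: symmetric, zero-diagonal, entries in
#' `[0, 2]`.  Constant vectors have no defined correlation; they are
#' excluded with a warning and listed in `attr(, "excluded")`.
#'
#' @param vectors numeric matrix, one column per labeled item (column names
#'   are the labels); e.g. the 26 contacts as 720-element columns
#'   (interaction-level mode) or the simulations as fingerprint columns
#'   (structure-level mode).
#' @return square labeled distance matrix with attribute `excluded`.
#' @examples
#' v <- cbind(a = 1:10, b = 3 * (1:10) + 7, c = 10:1)
#' correlationDistance(v)
#' @export
correlationDistance <- function(vectors) {
  stopifnot(is.matrix(vectors), ncol(vectors) >= 2)
  if (is.null(colnames(vectors)))
    colnames(vectors) <- sprintf("v%02d", seq_len(ncol(vectors)))
  sds <- apply(vectors, 2, sd)
  excluded <- colnames(vectors)[sds == 0]
  if (length(excluded)) {
    warning("excluding constant vector(s): ", paste(excluded, collapse = ", "))
    vectors <- vectors[, sds > 0, drop = FALSE]
  }
  if (ncol(vectors) < 2)
    stop("fewer than two non-constant vectors remain")
  D <- 1 - cor(vectors)
  D <- (D + t(D)) / 2          # exact symmetry against rounding
  diag(D) <- 0
  D[D < 0] <- 0
  D[D > 2] <- 2
  attr(D, "excluded") <- excluded
  D
}

.checkDistanceMatrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("argument error: need a square distance matrix")
  if (max(abs(D - t(D))) > 1e-8)
    stop("argument error: distance matrix must be symmetric")
  invisible(TRUE)
}

#' Embed a precomputed distance matrix in 2-D
#'
#' `method = "umap"` applies UMAP directly to the distance matrix under the
#' precomputed-metric contract (distances are never recomputed from
#' coordinates), with the pinned hyperparameters `n_neighbors = 15`,
#' `min_dist = 0.1`; the computation is delegated to the installed
#' umap-learn implementation through a subprocess bridge and is reproducible
#' for a fixed seed.  `method = "pca"` performs classical multidimensional
#' scaling (PCA of the double-centered `-D^2/2` matrix) via
#' [stats::cmdscale()], with deterministic axis signs.
#'
#' Several seeds may be passed for `"umap"`; they are embedded in a single
#' subprocess call and returned as a list.
#'
#' @param D square symmetric distance matrix with row/column labels (e.g.
#'   from [correlationDistance()]).
#' @param method `"umap"` or `"pca"`.
#' @param seed integer seed (or vector of seeds for `"umap"`).
#' @param nNeighbors,minDist UMAP hyperparameters; `nNeighbors` is clipped to
#'   `nrow(D) - 1` with a warning when the matrix is smaller.
#' @param python python interpreter used for the UMAP bridge.
#' @return a data.frame with columns `label`, `x`, `y` plus attributes
#'   `method` and `seed`; a named list of such data.frames when several
#'   seeds are given.
#' @export
embedDistance <- function(D, method = c("umap", "pca"), seed = 42L,
                          nNeighbors = 15L, minDist = 0.1,
                          python = Sys.which("python")) {
  method <- match.arg(method)
  .checkDistanceMatrix(D)
  labels <- rownames(D)
  if (is.null(labels)) labels <- sprintf("v%02d", seq_len(nrow(D)))

  if (method == "pca") {
    xy <- cmdscale(as.dist(D), k = 2)
    # deterministic axis orientation: largest-|loading| element positive
    for (j in 1:2) {
      i <- which.max(abs(xy[, j]))
      if (xy[i, j] < 0) xy[, j] <- -xy[, j]
    }
    out <- data.frame(label = labels, x = xy[, 1], y = xy[, 2],
                      row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "method") <- "pca"
    attr(out, "seed") <- seed[1]
    return(out)
  }

  if (nNeighbors >= nrow(D))
    warning("n_neighbors clipped to ", nrow(D) - 1L,
            " (fewer items than requested neighbors)")
  if (!nzchar(python))
    stop("no python interpreter found for the UMAP bridge; ",
         "use method = 'pca' or point 'python' at an interpreter ",
         "with umap-learn installed")
  script <- system.file("python", "umap_embed.py", package = "decodex")
  din <- tempfile(fileext = ".csv"); dout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(din, dout)))
  m <- D; rownames(m) <- labels; colnames(m) <- labels
  write.csv(m, din)
  status <- system2(python,
                    c(script, din, dout, as.integer(nNeighbors),
                      format(minDist), paste(as.integer(seed), collapse = ",")),
                    stdout = FALSE, stderr = "")
  if (status != 0 || !file.exists(dout))
    stop("UMAP bridge failed (exit status ", status, ")")
  res <- read.csv(dout, stringsAsFactors = FALSE, colClasses =
                    c(label = "character"))
  split_res <- lapply(seed, function(s) {
    out <- res[res$seed == s, c("label", "x", "y")]
    rownames(out) <- NULL
    attr(out, "method") <- "umap"
    attr(out, "seed") <- s
    out
  })
  if (length(seed) == 1L) split_res[[1]] else
    setNames(split_res, paste0("seed", seed))
}

#' Agglomerative clustering of a distance matrix
#'
#' Standard hierarchical clustering (via [stats::hclust()]) of a
#' correlation-distance matrix with average or complete linkage.
#'
#' @param D square symmetric distance matrix.
#' @param linkage `"average"` or `"complete"`.
#' @return an [stats::hclust] object (merge list with non-decreasing
#'   heights).
#' @export
hierarchicalCluster <- function(D, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  .checkDistanceMatrix(D)
  if (nrow(D) == 1L)
    return(structure(list(merge = matrix(integer(), 0, 2),
                          height = numeric(0), order = 1L,
                          labels = rownames(D), method = linkage),
                     class = "hclust"))
  hclust(as.dist(D), method = linkage)
}
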