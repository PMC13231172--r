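# Inference layer: aligned rank transform (ART) factorial ANOVA with
# Bonferroni correction, Shapiro-Wilk screening, phi-coefficient covariation
# of binary frame events, and stratified Pearson correlation of site-level
# H-bond strengths.

#' Shapiro-Wilk normality test
#'
#' Thin, argument-checked wrapper used to screen ANOVA residuals for
#' normality (the motivation for the nonparametric ART procedure); it is a
#' gate/report only and never changes pipeline output.
#'
#' @param x numeric vector, `3 <= length(x) <= 5000`, non-constant.
#' @return list with elements `W` and `p`.
#' @export
shapiroWilk <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3 || n > 5000)
    stop("argument error: Shapiro-Wilk needs 3 <= n <= 5000 (got ", n, ")")
  if (sd(x) == 0)
    stop("degenerate input: constant vector")
  sw <- shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Bonferroni correction
#' @param p vector of p values in `[0, 1]`.
#' @param m family size (default `length(p)`).
#' @return adjusted p values, `pmin(1, m * p)`.
#' @examples
#' bonferroni(0.01, m = 5)
#' @export
bonferroni <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1)
  pmin(1, m * p)
}

# ---- aligned rank transform -------------------------------------------------

.checkFactorial <- function(data, response, factors) {
  stopifnot(response %in% names(data), all(factors %in% names(data)))
  if (length(factors) < 1L || length(factors) > 3L)
    stop("designs with 1-3 factors are supported")
  fl <- lapply(data[factors], function(f) factor(f))
  if (any(vapply(fl, nlevels, 1L) < 2L))
    stop("design error: every tested factor needs at least 2 levels")
  cell <- interaction(fl, drop = FALSE)
  if (any(table(droplevels(cell)) < 1L) || nlevels(droplevels(cell)) <
      prod(vapply(fl, nlevels, 1L)))
    stop("design error: empty cells; full-factorial cell means not estimable")
  fl
}

# unweighted marginal means of cell means for a subset of factors
.cellMeanTable <- function(y, fl) {
  cell <- interaction(fl, drop = FALSE)
  tapply(y, cell, mean)
}

#' Align a response for one effect (ART)
#'
#' Aligned-rank-transform alignment: the response is stripped of every
#' estimated effect except the target one, i.e. aligned value =
#' (observation - full-model cell mean) + target-effect estimate, with
#' effect estimates computed from unweighted marginal means of the cell
#' means.  One alignment per tested effect.
#'
#' @param data data.frame with the response and factor columns.
#' @param response response column name.
#' @param factors character vector of factor column names (1-3 factors).
#' @param effect target effect: a factor name (main effect) or
#'   `"A:B"` (two-way interaction).
#' @return numeric vector of aligned responses, same order as `data`.
#' @export
artAlign <- function(data, response, factors, effect) {
  fl <- .checkFactorial(data, response, factors)
  y <- data[[response]]
  terms <- strsplit(effect, ":", fixed = TRUE)[[1]]
  if (!all(terms %in% factors) || length(terms) > 2L)
    stop("design error: effect '", effect,
         "' is not a main effect or two-way interaction of the design")

  cellIdx <- interaction(fl, drop = FALSE)
  cellMeans <- tapply(y, cellIdx, mean)
  resid <- y - cellMeans[cellIdx]

  # effect estimates from unweighted means of cell means
  cm <- cellMeans[!is.na(cellMeans)]
  cellLevels <- do.call(expand.grid, lapply(fl, levels))
  names(cellLevels) <- factors
  allMeans <- tapply(y, cellIdx, mean)  # one per cell, design order
  grand <- mean(allMeans)
  marg <- function(sub) {
    if (!length(sub)) return(grand)
    g <- interaction(cellLevels[sub], drop = FALSE)
    tapply(allMeans, g, mean)
  }
  rowKey <- function(sub) interaction(data.frame(fl)[sub], drop = FALSE)

  if (length(terms) == 1L) {
    est <- marg(terms)[rowKey(terms)] - grand
  } else {
    est <- marg(terms)[rowKey(terms)] -
      marg(terms[1])[rowKey(terms[1])] -
      marg(terms[2])[rowKey(terms[2])] + grand
  }
  as.numeric(resid + est)
}

# full-factorial fixed-effects ANOVA table; closed-form sums of squares for
# balanced designs (the common case here), lm + car::Anova type III with
# sum contrasts otherwise
.factorialAnova <- function(y, fl) {
  k <- length(fl)
  cell <- interaction(fl, drop = FALSE)
  counts <- table(cell)
  balanced <- length(unique(as.integer(counts))) == 1L
  if (!balanced) {
    dat <- data.frame(y = y, fl)
    names(dat)[-1] <- paste0("F", seq_len(k))
    form <- stats::as.formula(paste("y ~", paste(paste0("F", seq_len(k)),
                                                 collapse = "*")))
    fit <- stats::lm(form, data = dat,
                     contrasts = setNames(rep(list("contr.sum"), k),
                                          paste0("F", seq_len(k))))
    a3 <- car::Anova(fit, type = 3)
    tab <- a3[!rownames(a3) %in% c("(Intercept)", "Residuals"), ]
    dfErr <- a3["Residuals", "Df"]
    return(data.frame(term = gsub("F1", names(fl)[1],
                      gsub("F2", names(fl)[min(2, k)],
                      gsub("F3", names(fl)[min(3, k)], rownames(tab)))),
                      df1 = tab$Df, df2 = dfErr,
                      F = tab$`F value`, p = tab$`Pr(>F)`,
                      stringsAsFactors = FALSE))
  }

  nrep <- as.integer(counts[1])
  nlev <- vapply(fl, nlevels, 1L)
  N <- length(y)
  grand <- mean(y)
  cellMeans <- tapply(y, cell, mean)
  SSerr <- sum((y - cellMeans[cell])^2)
  dfErr <- N - prod(nlev)

  subsets <- unlist(lapply(seq_len(k), function(m)
    utils::combn(k, m, simplify = FALSE)), recursive = FALSE)
  margMean <- function(sub) {
    if (!length(sub)) return(grand)
    tapply(y, interaction(fl[sub], drop = FALSE), mean)
  }
  margOf <- list()
  for (s in subsets) margOf[[paste(s, collapse = ",")]] <- margMean(s)

  rows <- lapply(subsets, function(s) {
    key <- interaction(fl[s], drop = FALSE)
    # inclusion-exclusion over sub-subsets
    eff <- margOf[[paste(s, collapse = ",")]][key]
    subsub <- unlist(lapply(seq_len(length(s)), function(m)
      utils::combn(s, m, simplify = FALSE)), recursive = FALSE)
    subsub <- subsub[vapply(subsub, length, 1L) < length(s)]
    for (ss in subsub) {
      sgn <- (-1)^(length(s) - length(ss))
      eff <- eff + sgn * margOf[[paste(ss, collapse = ",")]][
        interaction(fl[ss], drop = FALSE)]
    }
    eff <- eff + (-1)^length(s) * grand
    SS <- sum(eff^2) / 1  # eff is per-observation; each obs counted once
    df1 <- prod(nlev[s] - 1L)
    data.frame(term = paste(names(fl)[s], collapse = ":"),
               df1 = df1, df2 = dfErr,
               F = (SS / df1) / (SSerr / dfErr),
               p = pf((SS / df1) / (SSerr / dfErr), df1, dfErr,
                      lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Aligned rank transform factorial ANOVA
#'
#' For each tested effect: align the response for that effect
#' ([artAlign()]), rank the aligned values (midranks for ties), run a
#' full-factorial fixed-effects ANOVA on the ranks and report only the
#' target effect's F and p.  P values are Bonferroni-corrected across the
#' tested effect family.
#'
#' @inheritParams artAlign
#' @param effects character vector of effects to test; default all main
#'   effects and two-way interactions of the design.
#' @param family Bonferroni family size (default `length(effects)`).
#' @return data.frame with columns `effect`, `F`, `df1`, `df2`, `p`,
#'   `p_bonferroni`.
#' @examples
#' d <- genFactorialDataset(studyDesign(replicates = 5),
#'                          mainEffects = list(wobble = c(GU_wobble = 1)),
#'                          sigma = 0.5, seed = 1)
#' artAnova(d, "response", c("a_site_n1n2", "wobble", "plus1_codon"))
#' @export
artAnova <- function(data, response, factors, effects = NULL,
                     family = NULL) {
  fl <- .checkFactorial(data, response, factors)
  if (is.null(effects)) {
    effects <- factors
    if (length(factors) > 1L)
      effects <- c(effects,
                   utils::combn(factors, 2, paste, collapse = ":"))
  }
  res <- lapply(effects, function(eff) {
    aligned <- artAlign(data, response, factors, eff)
    r <- rank(aligned)  # midranks for ties
    tab <- .factorialAnova(r, fl)
    termName <- paste(strsplit(eff, ":", fixed = TRUE)[[1]], collapse = ":")
    row <- tab[tab$term == termName, , drop = FALSE]
    if (nrow(row) != 1L) {  # term order may differ for interactions
      parts <- strsplit(eff, ":", fixed = TRUE)[[1]]
      hit <- vapply(strsplit(tab$term, ":", fixed = TRUE), function(tt)
        setequal(tt, parts), TRUE)
      row <- tab[hit, , drop = FALSE]
    }
    data.frame(effect = eff, F = row$F, df1 = row$df1, df2 = row$df2,
               p = row$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(family)) family <- length(effects)
  out$p_bonferroni <- bonferroni(out$p, m = family)
  out
}

# ---- phi covariation --------------------------------------------------------

#' Phi coefficient of two binary vectors
#'
#' Association of two binary event streams from the 2x2 contingency table,
#' `phi = (n11 n00 - n10 n01) / sqrt(n1. n0. n.1 n.0)`; identical to the
#' Pearson correlation of the 0/1 vectors.  Constant input has no defined
#' association and is an error (callers report it as missing, never as 0).
#'
#' @param x,y binary (0/1) vectors of equal length `>= 2`.
#' @return numeric(1) in `[-1, 1]`.
#' @examples
#' phiCoefficient(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
phiCoefficient <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2,
            all(x %in% c(0, 1)), all(y %in% c(0, 1)))
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("undefined association: constant binary vector")
  n <- length(x)
  n11 <- sum(x == 1 & y == 1)
  n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1)
  n00 <- n - n11 - n10 - n01
  num <- n11 * n00 - n10 * n01
  den <- sqrt((n11 + n10)) * sqrt((n01 + n00)) *
    sqrt((n11 + n01)) * sqrt((n10 + n00))
  num / den
}

#' Contact-by-contact phi covariation matrix
#'
#' Computes the phi coefficient for every pair of binarized contact series
#' across post-equilibration runs.  With `pooling = "pooled_frames"`
#' (default) the trimmed frames of all runs are concatenated before the 2x2
#' tables are formed; with `"per_run_mean"` phi is computed per run and
#' averaged over the runs where it is defined.  Contacts that are constant
#' (never/always on) have no defined phi: their rows/columns are `NA` and
#' they are listed in `attr(, "undefined")`.
#'
#' @param runs a binary matrix (frames x contacts, column names = labels) or
#'   a list of such matrices, one per run, sharing column names.
#' @param pooling `"pooled_frames"` or `"per_run_mean"`.
#' @return symmetric labeled matrix of phi values with unit diagonal where
#'   defined; attributes `pooling` and `undefined`.
#' @export
covariationMatrix <- function(runs,
                              pooling = c("pooled_frames", "per_run_mean")) {
  pooling <- match.arg(pooling)
  if (is.matrix(runs)) runs <- list(runs)
  labs <- colnames(runs[[1]])
  if (is.null(labs)) labs <- sprintf("c%02d", seq_len(ncol(runs[[1]])))
  for (r in runs)
    if (ncol(r) != length(labs))
      stop("all runs must share the same contact columns")

  phiOf <- function(X) {
    n <- nrow(X)
    cs <- colSums(X)
    ok <- cs > 0 & cs < n
    S <- crossprod(X)               # pairwise n11
    num <- n * S - tcrossprod(cs)
    den <- tcrossprod(sqrt(cs * (n - cs)))
    phi <- pmin(pmax(num / den, -1), 1)  # guard against rounding overshoot
    phi[!ok, ] <- NA_real_
    phi[, !ok] <- NA_real_
    diag(phi)[ok] <- 1
    phi
  }

  if (pooling == "pooled_frames") {
    X <- do.call(rbind, runs)
    phi <- phiOf(X)
  } else {
    mats <- lapply(runs, phiOf)
    phi <- apply(simplify2array(mats), c(1, 2), mean, na.rm = TRUE)
    phi[is.nan(phi)] <- NA_real_
  }
  dimnames(phi) <- list(labs, labs)
  undef <- labs[apply(phi, 1, function(r) all(is.na(r)))]
  attr(phi, "pooling") <- pooling
  attr(phi, "undefined") <- undef
  phi
}

#' Stratified Pearson correlation of A-site vs CAR-site strengths
#'
#' Pearson r with two-sided p (exact t transform, n-2 df) between the
#' per-simulation A-site and CAR-site H-bond strengths, computed separately
#' within every stratum of `strata`, with family-wise Bonferroni correction
#' across strata.  Strata with fewer than `minN` paired observations are
#' skipped with a warning.
#'
#' @param aSite,carSite numeric vectors of per-simulation site strengths.
#' @param strata factor/character vector (or data.frame of condition columns)
#'   defining the strata; use a constant for the unstratified correlation.
#' @param minN minimum paired observations per stratum (default 3).
#' @return data.frame with columns `stratum`, `n`, `r`, `p`, `p_bonferroni`.
#' @export
siteCorrelation <- function(aSite, carSite, strata, minN = 3) {
  if (is.data.frame(strata)) strata <- interaction(strata, sep = "_")
  strata <- as.factor(strata)
  stopifnot(length(aSite) == length(carSite),
            length(strata) == length(aSite))
  rows <- lapply(levels(strata), function(sl) {
    i <- strata == sl & is.finite(aSite) & is.finite(carSite)
    n <- sum(i)
    if (n < minN) {
      warning("stratum '", sl, "' has fewer than ", minN,
              " observations; skipped")
      return(NULL)
    }
    ct <- cor.test(aSite[i], carSite[i], method = "pearson")
    data.frame(stratum = sl, n = n, r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) stop("no stratum met the minimum size")
  out$p_bonferroni <- bonferroni(out$p, m = nrow(out))
  out
}
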