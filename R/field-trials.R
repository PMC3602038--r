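#' Spatial correction of field-trial plot data
#'
#' Fits, for one environment, the model
#' \code{value ~ variety + s(row, column)} where the spatial term is a
#' penalized tensor-product cubic regression spline over the plot grid
#' and the smoothing parameter is chosen by generalized cross-validation.
#' The corrected value is the observation minus the fitted spatial
#' component; the spatial component is centered (mean zero over plots).
#'
#' @param plots data.frame for one environment with columns \code{row},
#'   \code{column}, \code{variety}, \code{value}.
#' @param k basis dimensions for the marginal row/column splines; the
#'   default adapts to the grid, capped at 5 per margin.
#' @return list with \code{spatial} (per-plot spatial component),
#'   \code{corrected} (per-plot corrected value), \code{varietyEffects}
#'   (named coefficients relative to the first variety) and \code{fit}
#'   (the \code{mgcv::gam} object).
#' @export
fitSpatialSurface <- function(plots, k = NULL) {
  stopifnot(all(c("row", "column", "variety", "value") %in% names(plots)))
  if (length(unique(plots$variety)) < 2L) {
    stop("need at least two varieties")
  }
  nr <- length(unique(plots$row))
  nc <- length(unique(plots$column))
  if (is.null(k)) k <- c(min(5L, nr), min(5L, nc))
  if (any(k < 3L)) {
    stop("grid too small for a cubic spline basis; use a larger grid or ",
         "a smaller basis")
  }
  df <- data.frame(value = plots$value, variety = factor(plots$variety),
                   row = plots$row, column = plots$column)
  if (nrow(df) < prod(k) + nlevels(df$variety)) {
    stop("fewer plots than basis dimension; reduce k")
  }
  fit <- mgcv::gam(value ~ variety + te(row, column, bs = "cr", k = k),
                   data = df)
  terms <- predict(fit, type = "terms")
  spatial <- terms[, grep("^te\\(", colnames(terms))]
  spatial <- spatial - mean(spatial)
  veff <- coef(fit)
  veff <- veff[grep("^variety", names(veff))]
  names(veff) <- sub("^variety", "", names(veff))
  list(spatial = spatial, corrected = plots$value - spatial,
       varietyEffects = veff, fit = fit)
}

#' Spatially correct all environments of a trial
#'
#' Applies [fitSpatialSurface()] within each environment and returns the
#' plot table with \code{spatial} and \code{corrected} columns appended.
#'
#' @param plots data.frame with columns \code{env}, \code{row},
#'   \code{column}, \code{variety}, \code{value}.
#' @param ... passed to [fitSpatialSurface()].
#' @return the augmented plot table.
#' @export
correctTrial <- function(plots, ...) {
  stopifnot("env" %in% names(plots))
  pieces <- lapply(split(plots, plots$env), function(p) {
    f <- fitSpatialSurface(p, ...)
    p$spatial <- f$spatial
    p$corrected <- f$corrected
    p
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Aggregate corrected plots into an environment-scaled G x E matrix
#'
#' Per environment, plot values are aggregated to genotype means and the
#' column is divided by the standard deviation of those means, so every
#' environment column has unit standard deviation (environments with very
#' different trait scales then contribute equally to the GGE
#' decomposition).
#'
#' @param plots data.frame with columns \code{env}, \code{variety} and a
#'   value column.
#' @param valueColumn name of the value column (default
#'   \code{"corrected"}, falling back to \code{"value"}).
#' @return genotype x environment matrix of scaled trait means.
#' @export
scaleByEnvironment <- function(plots, valueColumn = NULL) {
  if (is.null(valueColumn)) {
    valueColumn <- if ("corrected" %in% names(plots)) "corrected" else "value"
  }
  agg <- aggregate(plots[[valueColumn]],
                   by = list(variety = plots$variety, env = plots$env),
                   FUN = mean)
  mat <- tapply(agg$x, list(agg$variety, agg$env), mean)
  if (anyNA(mat)) stop("incomplete genotype x environment table")
  sds <- apply(mat, 2, sd)
  if (any(sds == 0)) {
    stop("environment with zero variance of genotype means: ",
         paste(colnames(mat)[sds == 0], collapse = ", "))
  }
  sweep(mat, 2, sds, "/")
}

#' GGE biplot decomposition
#'
#' Environment-centers the genotype x environment matrix (subtracting
#' each environment's mean removes the environment main effect and leaves
#' G + GxE), decomposes it by SVD, and applies symmetric (f = 0.5)
#' scaling: genotype scores and environment loadings are each scaled by
#' the square root of the singular values. The percent of inertia per
#' axis is \code{100 * sigma_i^2 / sum(sigma_j^2)}. Axis signs are fixed
#' so the summed environment loadings on each axis are non-negative.
#'
#' @param gematrix genotype x environment matrix (genotypes in rows).
#' @param nAxes number of axes to use for display and ranking.
#' @return a [GGEResult] carrying the full decomposition.
#' @export
ggeDecompose <- function(gematrix, nAxes = 2L) {
  stopifnot(is.matrix(gematrix), nrow(gematrix) >= 2L,
            ncol(gematrix) >= 1L)
  centered <- sweep(gematrix, 2, colMeans(gematrix))
  sv <- svd(centered)
  d <- sv$d
  rank <- sum(d > max(d) * 1e-12)
  if (nAxes > rank) {
    warning("nAxes exceeds rank ", rank, "; truncated")
    nAxes <- rank
  }
  G <- sv$u %*% diag(sqrt(d), nrow = length(d))
  E <- sv$v %*% diag(sqrt(d), nrow = length(d))
  flip <- colSums(E) < 0
  G[, flip] <- -G[, flip]
  E[, flip] <- -E[, flip]
  rownames(G) <- rownames(gematrix)
  rownames(E) <- colnames(gematrix)
  colnames(G) <- colnames(E) <- paste0("axis", seq_along(d))
  varExp <- if (sum(d^2) > 0) 100 * d^2 / sum(d^2) else rep(0, length(d))
  new("GGEResult", genotypeScores = G, environmentLoadings = E,
      singularValues = d, varianceExplained = varExp,
      nAxes = as.integer(nAxes), centered = centered)
}

#' Rank genotypes toward the ideal cultivar
#'
#' Projects each genotype onto the average-environment axis (the
#' normalized mean of the environment loadings over the first
#' \code{nAxes} axes) to measure its trait level, and onto the
#' orthogonal complement to measure its instability across environments.
#' Genotypes are ranked by level (ascending for \code{direction = "low"},
#' descending for \code{"high"}), ties broken by smaller instability.
#'
#' @param gge a [GGEResult].
#' @param direction \code{"low"} for the lowest stable trait value,
#'   \code{"high"} for the highest.
#' @param nAxes axes used; defaults to the result's \code{nAxes}.
#' @return data.frame \code{genotype}, \code{level}, \code{instability},
#'   ordered from most to least ideal.
#' @export
rankIdealCultivars <- function(gge, direction = c("low", "high"),
                               nAxes = NULL) {
  direction <- match.arg(direction)
  if (is.null(nAxes)) nAxes <- gge@nAxes
  k <- seq_len(min(nAxes, ncol(gge@genotypeScores)))
  E <- gge@environmentLoadings[, k, drop = FALSE]
  G <- gge@genotypeScores[, k, drop = FALSE]
  eBar <- colMeans(E)
  nrm <- sqrt(sum(eBar^2))
  if (nrm < 1e-12) stop("degenerate average-environment vector")
  eHat <- eBar / nrm
  level <- as.numeric(G %*% eHat)
  proj <- outer(level, eHat)
  instability <- sqrt(rowSums((G - proj)^2))
  o <- if (direction == "low") order(level, instability)
       else order(-level, instability)
  data.frame(genotype = rownames(G)[o], level = level[o],
             instability = instability[o], row.names = NULL)
}

#' Relative decrease between two group means
#'
#' \code{100 * (1 - meanA / meanB)}: the percentage by which group A's
#' mean falls below group B's.
#'
#' @param meanA,meanB group means; \code{meanB} must be non-zero.
#' @return the relative decrease in percent.
#' @export
#' @examples
#' relativeDecrease(2.5, 2.9)   # 13.8 to one decimal
relativeDecrease <- function(meanA, meanB) {
  if (meanB == 0) stop("relative decrease undefined: reference mean is 0")
  100 * (1 - meanA / meanB)
}

#' Two-variety contrast
#'
#' Group means with t-based 95\% confidence intervals, a Welch
#' (unequal-variance) two-sided p-value, and the relative decrease of
#' group A versus group B.
#'
#' @param groupA,groupB numeric vectors of at least 2 values each.
#' @param conf confidence level for the per-group CIs.
#' @return list with \code{meanA}, \code{meanB}, \code{ciA}, \code{ciB}
#'   (lower/upper bounds), \code{pValue} and \code{relativeDecrease}
#'   (percent).
#' @export
varietyContrast <- function(groupA, groupB, conf = 0.95) {
  stopifnot(length(groupA) >= 2L, length(groupB) >= 2L)
  groupCi <- function(x) {
    m <- mean(x)
    if (sd(x) == 0) return(c(lower = m, upper = m))
    half <- stats::qt(1 - (1 - conf) / 2, length(x) - 1L) *
      sd(x) / sqrt(length(x))
    c(lower = m - half, upper = m + half)
  }
  if (sd(groupA) == 0 && sd(groupB) == 0) {
    p <- if (mean(groupA) == mean(groupB)) 1 else 0
  } else {
    p <- stats::t.test(groupA, groupB)$p.value
  }
  list(meanA = mean(groupA), meanB = mean(groupB),
       ciA = groupCi(groupA), ciB = groupCi(groupB),
       pValue = p,
       relativeDecrease = relativeDecrease(mean(groupA), mean(groupB)))
}
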