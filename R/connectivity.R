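## Signed and binary connectivity maps and their summaries.

#' Assemble a signed connectivity map from fitted models
#'
#' Entry \code{(i, j)} of the map is the fitted history coefficient of
#' source \code{j} on target \code{i} when target \code{i} has a
#' converged, well-fitted model and the coefficient's confidence interval
#' excludes zero at level \code{alpha}; all other entries are zero. Rows
#' of targets without a usable model are kept (all zero) so the matrix
#' shape is stable across conditions.
#'
#' @param fits named list of type II \linkS4class{NeuronFit} objects.
#' @param roster full unit roster (row/column order of the map).
#' @param wellFitted character vector of target units whose fitted
#'   intensity passed the goodness-of-fit screen; defaults to all
#'   converged targets (i.e. no GOF gating).
#' @param alpha significance level of the coefficient mask.
#' @param condition condition label stored on the map.
#' @param modelSpec \linkS4class{ModelSpec}; defaults to the spec of the
#'   first fit.
#' @return a \linkS4class{ConnectivityMap}.
#' @export
buildConnectivityMap <- function(fits, roster, wellFitted = NULL,
                                 alpha = 0.05, condition = "other",
                                 modelSpec = NULL) {
  if (length(fits) == 0L && is.null(modelSpec))
    modelSpec <- ModelSpec()
  if (length(fits)) {
    if (is.null(names(fits)) ||
        !all(names(fits) == vapply(fits, slot, character(1), "target")))
      stop("fits must be a list named by their target units")
    if (!all(names(fits) %in% roster))
      stop("fitted targets missing from the unit roster")
    if (is.null(modelSpec)) modelSpec <- fits[[1L]]@modelSpec
    badSrc <- !vapply(fits, function(f)
      all(f@sources %in% roster), logical(1))
    if (any(badSrc)) stop("fit sources missing from the unit roster")
  }
  J <- length(roster)
  beta <- matrix(0, J, J, dimnames = list(roster, roster))
  usable <- vapply(fits, function(f)
    f@converged && !f@degenerate, logical(1))
  if (is.null(wellFitted)) wellFitted <- names(fits)[usable]
  fittedMask <- setNames(logical(J), roster)
  for (u in names(fits)[usable]) {
    if (!u %in% wellFitted) next
    fittedMask[u] <- TRUE
    fit <- fits[[u]]
    sig <- waldMask(fit, alpha = alpha)
    src <- names(sig)[sig]
    beta[u, src] <- fit@coef[src]
  }
  new("ConnectivityMap", beta = beta, fittedMask = fittedMask,
      condition = as.character(condition), modelSpec = modelSpec,
      alpha = alpha)
}

#' Binarize a connectivity map
#'
#' @param map a \linkS4class{ConnectivityMap}.
#' @return a \linkS4class{BinaryMap} with 1 wherever the signed map is
#'   nonzero.
#' @export
binarizeMap <- function(map) {
  stopifnot(is(map, "ConnectivityMap"))
  new("BinaryMap", links = (map@beta != 0) + 0,
      condition = map@condition,
      includeSelf = map@modelSpec@includeSelf)
}

#' Connection density
#'
#' Fraction of possible directed links that are significant: the link
#' count over \code{J * (J - 1)} ordered off-diagonal pairs (or
#' \code{J^2} when self-links are allowed). The roster used as the
#' denominator is the modeled roster, i.e. the map's full dimension.
#'
#' @param x a \linkS4class{BinaryMap} or \linkS4class{ConnectivityMap}.
#' @return density in [0, 1].
#' @examples
#' m <- matrix(0, 4, 4); m[1, 2] <- m[2, 3] <- m[4, 1] <- 1
#' b <- new("BinaryMap", links = m, condition = "BL", includeSelf = FALSE)
#' connectionDensity(b)  # 3 / 12 = 0.25
#' @export
connectionDensity <- function(x) {
  if (is(x, "ConnectivityMap")) x <- binarizeMap(x)
  stopifnot(is(x, "BinaryMap"))
  J <- nrow(x@links)
  if (J < 2L && !x@includeSelf) stop("density needs J >= 2")
  possible <- if (x@includeSelf) J^2 else J * (J - 1L)
  sum(x@links) / possible
}

#' Parsimony metric Q
#'
#' \code{Q = n / sqrt(density)}: the fraction \code{n} of non-Poisson
#' units well fitted by the model, divided by the square root of the
#' significant connection density. Both arguments are on the 0-1 fraction
#' scale (using percentages on both just rescales Q by a constant). High
#' Q rewards models that capture the non-Poisson population with few
#' connections; it is the model-selection score used to compare the 1 ms
#' and 10 ms timescales.
#'
#' @param nWellFitFraction fraction of non-Poisson units well fitted.
#' @param density significant connection density, in (0, 1].
#' @return Q, or \code{NA} (with a warning) when the density is zero or
#'   the fraction is undefined.
#' @examples
#' qMetric(0.15, 0.09)  # 0.15 / 0.3 = 0.5
#' @export
qMetric <- function(nWellFitFraction, density) {
  if (is.na(nWellFitFraction) || is.na(density)) return(NA_real_)
  stopifnot(nWellFitFraction >= 0, nWellFitFraction <= 1,
            density >= 0, density <= 1)
  if (density == 0) {
    warning("connection density is zero; Q undefined")
    return(NA_real_)
  }
  nWellFitFraction / sqrt(density)
}

#' Sign and strength summary of a connectivity map
#'
#' Counts and mean strengths of the positive ("excitatory") and negative
#' ("inhibitory") significant coefficients, plus their ratio.
#'
#' @param map a \linkS4class{ConnectivityMap}.
#' @return list with \code{n_pos}, \code{n_neg}, \code{mean_pos},
#'   \code{mean_neg} (NA when a class is empty) and
#'   \code{neg_pos_ratio}.
#' @export
signSummary <- function(map) {
  stopifnot(is(map, "ConnectivityMap"))
  v <- map@beta[map@beta != 0]
  pos <- v[v > 0]
  neg <- v[v < 0]
  list(
    n_pos = length(pos),
    n_neg = length(neg),
    mean_pos = if (length(pos)) mean(pos) else NA_real_,
    mean_neg = if (length(neg)) mean(neg) else NA_real_,
    neg_pos_ratio = if (length(pos)) length(neg) / length(pos) else NA_real_
  )
}

#' Network summary of one condition and timescale
#'
#' Bundles the map-level statistics: density, the parsimony Q, the
#' excitatory/inhibitory split, and the modeling counts from
#' \code{\link{classifyWellFit}}.
#'
#' @param map a \linkS4class{ConnectivityMap}.
#' @param classify output of \code{\link{classifyWellFit}} for the same
#'   condition and binning (optional; Q and the counts are NA without it).
#' @return list with \code{condition}, \code{responseBin}, \code{nUnits},
#'   \code{nLinks}, \code{density}, \code{q}, the sign summary fields,
#'   \code{n_nonpoisson}, \code{n_wellfit_nonpoisson},
#'   \code{wellfit_fraction}.
#' @export
networkSummary <- function(map, classify = NULL) {
  stopifnot(is(map, "ConnectivityMap"))
  dens <- connectionDensity(map)
  ss <- signSummary(map)
  frac <- if (is.null(classify)) NA_real_ else classify$wellFitFraction
  q <- if (!is.na(frac) && dens > 0) qMetric(frac, dens) else NA_real_
  c(list(condition = map@condition,
         responseBin = map@modelSpec@responseBin,
         nUnits = nrow(map@beta),
         nLinks = sum(map@beta != 0),
         density = dens, q = q), ss,
    list(n_nonpoisson = if (is.null(classify)) NA_integer_
           else classify$nNonPoisson,
         n_wellfit_nonpoisson = if (is.null(classify)) NA_integer_
           else classify$nWellFitNonPoisson,
         wellfit_fraction = frac))
}

#' Export a connectivity map as GraphML
#'
#' Writes the significant links as a directed graph (edges weighted by
#' the signed coefficient, source -> target) readable by standard network
#' tools.
#'
#' @param map a \linkS4class{ConnectivityMap}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
exportGraphML <- function(map, path) {
  stopifnot(is(map, "ConnectivityMap"))
  idx <- which(map@beta != 0, arr.ind = TRUE)
  roster <- rownames(map@beta)
  g <- igraph::make_empty_graph(n = length(roster), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = roster)
  if (nrow(idx)) {
    ## igraph edge direction: source -> target
    edges <- rbind(idx[, "col"], idx[, "row"])
    g <- igraph::add_edges(g, as.vector(edges),
                           attr = list(weight = map@beta[idx]))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a connectivity map (or its binary twin) as CSV
#'
#' @param x a \linkS4class{ConnectivityMap} or \linkS4class{BinaryMap}.
#' @param path output file path; rows are targets, columns sources.
#' @return \code{path}, invisibly.
#' @export
writeMapCSV <- function(x, path) {
  m <- if (is(x, "ConnectivityMap")) x@beta
       else if (is(x, "BinaryMap")) x@links
       else stop("x must be a ConnectivityMap or BinaryMap")
  write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
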