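## Cross-condition comparison of binary maps and strengths.

asBinary <- function(x) {
  if (is(x, "ConnectivityMap")) binarizeMap(x)
  else if (is(x, "BinaryMap")) x
  else stop("expected a BinaryMap or ConnectivityMap")
}

#' Shared connections between two binary maps
#'
#' Counts the links significant in both conditions (elementwise AND) and
#' expresses them as a fraction of a chosen denominator:
#' \describe{
#'   \item{symmetric}{\code{n_common / ((n_a + n_b) / 2)}, the mean link
#'     count (default; symmetric in the two maps).}
#'   \item{union}{\code{n_common / |A or B|} (Jaccard).}
#'   \item{of_first}{\code{n_common / n_a} (directional: how much of A
#'     survives in B).}
#' }
#' A "percentage of common connections" has no single canonical
#' denominator, so all three are available and the choice is recorded in
#' the output.
#'
#' @param binA,binB \linkS4class{BinaryMap}s (or signed maps, binarized
#'   on the fly) over the same roster.
#' @param denominator one of \code{"symmetric"}, \code{"union"},
#'   \code{"of_first"}.
#' @return list with \code{pair}, \code{n_a}, \code{n_b},
#'   \code{n_common}, \code{common_fraction} (NA when the denominator is
#'   empty), \code{denominator}.
#' @examples
#' a <- matrix(0, 3, 3); a[1, 2] <- a[2, 3] <- 1
#' b <- matrix(0, 3, 3); b[1, 2] <- b[3, 1] <- 1
#' A <- new("BinaryMap", links = a, condition = "BL", includeSelf = FALSE)
#' B <- new("BinaryMap", links = b, condition = "E", includeSelf = FALSE)
#' sharedConnections(A, B)$common_fraction  # 1 / 2
#' @export
sharedConnections <- function(binA, binB,
                              denominator = c("symmetric", "union",
                                              "of_first")) {
  binA <- asBinary(binA); binB <- asBinary(binB)
  denominator <- match.arg(denominator)
  if (!all(dim(binA@links) == dim(binB@links)))
    stop("maps must share one shape/roster")
  if (!is.null(rownames(binA@links)) && !is.null(rownames(binB@links)) &&
      !identical(rownames(binA@links), rownames(binB@links)))
    stop("maps must share one unit roster")
  nA <- sum(binA@links)
  nB <- sum(binB@links)
  nCommon <- sum(binA@links * binB@links)
  den <- switch(denominator,
                symmetric = (nA + nB) / 2,
                union = nA + nB - nCommon,
                of_first = nA)
  list(pair = c(binA@condition, binB@condition),
       n_a = nA, n_b = nB, n_common = nCommon,
       common_fraction = if (den > 0) nCommon / den else NA_real_,
       denominator = denominator)
}

#' Exact binomial test for connection-pattern change
#'
#' Under the null that each original link is equally likely to be kept or
#' changed (p = 0.5), tests whether the observed number of kept links is
#' surprising. Two-sided by minimum-likelihood summation: the p-value
#' sums all binomial outcomes whose exact mass does not exceed that of
#' the observed count.
#'
#' @param kept number of links retained.
#' @param total number of links at risk (>= 1).
#' @return two-sided exact p-value.
#' @examples
#' binomialChangeTest(5, 20)  # ~ 0.041
#' @export
binomialChangeTest <- function(kept, total) {
  if (length(total) != 1L || total < 1L) stop("total must be >= 1")
  if (kept < 0 || kept > total) stop("kept must lie in [0, total]")
  stats::binom.test(kept, total, p = 0.5)$p.value
}

#' Pairwise persistence matrix over an ordered series of maps
#'
#' Symmetric matrix of pairwise common-connection fractions, diagonal
#' 1.0 (each map shares everything with itself). Used to visualize slow
#' connection drift over repeated recordings.
#'
#' @param maps list of \linkS4class{BinaryMap}s (or signed maps) over one
#'   roster.
#' @param denominator see \code{\link{sharedConnections}}.
#' @return numeric matrix with dimnames from the maps' condition labels.
#' @export
persistenceMatrix <- function(maps, denominator = "symmetric") {
  if (length(maps) < 2L) stop("need at least two maps")
  maps <- lapply(maps, asBinary)
  n <- length(maps)
  labs <- vapply(seq_len(n), function(i) {
    lab <- maps[[i]]@condition
    if (!nzchar(lab) || lab %in% vapply(maps[seq_len(i - 1L)],
                                        slot, character(1), "condition"))
      sprintf("%s#%d", lab, i) else lab
  }, character(1))
  M <- diag(1, n)
  dimnames(M) <- list(labs, labs)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    M[i, j] <- M[j, i] <-
      sharedConnections(maps[[i]], maps[[j]],
                        denominator = denominator)$common_fraction
  }
  M
}

#' Strength correlation over common connections
#'
#' For links significant in both conditions, correlates the two
#' coefficient vectors (Pearson); the full paired table, including links
#' significant in only one condition, is returned for scatter plots.
#'
#' @param mapA,mapB \linkS4class{ConnectivityMap}s on one roster.
#' @return list with \code{strength_r} (NA when fewer than 3 common
#'   links), \code{n_common}, and \code{table} (data.frame: target,
#'   source, beta_a, beta_b, status in both/only_a/only_b).
#' @export
commonStrengthCorrelation <- function(mapA, mapB) {
  stopifnot(is(mapA, "ConnectivityMap"), is(mapB, "ConnectivityMap"))
  if (!identical(dimnames(mapA@beta), dimnames(mapB@beta)))
    stop("maps must share one unit roster")
  inA <- mapA@beta != 0
  inB <- mapB@beta != 0
  any <- which(inA | inB, arr.ind = TRUE)
  status <- ifelse(inA[any] & inB[any], "both",
                   ifelse(inA[any], "only_a", "only_b"))
  tab <- data.frame(
    target = rownames(mapA@beta)[any[, "row"]],
    source = colnames(mapA@beta)[any[, "col"]],
    beta_a = mapA@beta[any],
    beta_b = mapB@beta[any],
    status = status,
    row.names = NULL
  )
  common <- tab[tab$status == "both", , drop = FALSE]
  r <- if (nrow(common) >= 3L) cor(common$beta_a, common$beta_b)
       else NA_real_
  list(strength_r = r, n_common = nrow(common), table = tab)
}

#' Aggregate condition comparisons across sessions
#'
#' Summarizes per-session common-connection fractions by comparison pair
#' (mean, s.e., n) and, with at least \code{minSessions} paired sessions,
#' tests whether the E vs BMI/E overlap exceeds the BL vs E overlap with
#' a paired Wilcoxon signed-rank test.
#'
#' @param comparisons data.frame with columns \code{session},
#'   \code{pair} (e.g. \code{"BL-E"}, \code{"E-BMI/E"}) and
#'   \code{common_fraction}.
#' @param testPairs length-2 character: the two pair labels to contrast
#'   (default \code{c("E-BMI/E", "BL-E")}).
#' @param minSessions minimum paired sessions for a test p-value.
#' @return list with \code{summary} (per-pair data.frame) and
#'   \code{signed_rank_p} (NA, with a \code{note}, when there are too
#'   few sessions).
#' @export
aggregateSessions <- function(comparisons,
                              testPairs = c("E-BMI/E", "BL-E"),
                              minSessions = 5L) {
  need <- c("session", "pair", "common_fraction")
  if (!all(need %in% names(comparisons)))
    stop("comparisons must have columns: ", paste(need, collapse = ", "))
  sm <- do.call(rbind, lapply(split(comparisons, comparisons$pair),
    function(d) data.frame(pair = d$pair[1], n = nrow(d),
                           mean = mean(d$common_fraction),
                           se = if (nrow(d) > 1)
                             sd(d$common_fraction) / sqrt(nrow(d))
                           else NA_real_)))
  rownames(sm) <- NULL
  out <- list(summary = sm, signed_rank_p = NA_real_)
  a <- comparisons[comparisons$pair == testPairs[1], ]
  b <- comparisons[comparisons$pair == testPairs[2], ]
  shared <- intersect(a$session, b$session)
  if (length(shared) < minSessions) {
    out$note <- sprintf(
      "only %d paired sessions (< %d); signed-rank test skipped",
      length(shared), minSessions)
    return(out)
  }
  x <- a$common_fraction[match(shared, a$session)]
  y <- b$common_fraction[match(shared, b$session)]
  if (all(x == y)) {
    out$signed_rank_p <- 1
    out$note <- "no differences between members of any pair"
    return(out)
  }
  out$signed_rank_p <- suppressWarnings(
    wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
  out
}
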