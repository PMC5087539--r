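#' Two-class confusion matrix
#'
#' Counts arranged as predicted (rows) by actual (columns) over
#' \{building, non-building\}.
#'
#' @param bb,bn predicted building with actual building / non-building.
#' @param nb,nn predicted non-building with actual building / non-building.
#' @return An object of class \code{confusion_matrix2}.
#' @export
confusion_matrix2 <- function(bb, bn, nb, nn) {
  m <- matrix(c(bb, bn, nb, nn), 2L, 2L, byrow = TRUE,
              dimnames = list(predicted = c("building", "non_building"),
                              actual = c("building", "non_building")))
  if (any(m < 0)) stop("counts must be non-negative")
  structure(m, class = c("confusion_matrix2", "matrix", "array"))
}

#' Accuracy summary of a two-class confusion matrix
#'
#' Overall accuracy (trace over total), producer's accuracy per class
#' (diagonal over actual-column total), user's accuracy per class (diagonal
#' over predicted-row total), Cohen's kappa with marginal-product expected
#' agreement, and the per-class conditional kappa
#' \code{(p_ii / p_i+ - p_+i) / (1 - p_+i)} on each predicted margin.
#'
#' @param cm a \code{\link{confusion_matrix2}} (or 2x2 count matrix laid out
#'   predicted x actual).
#' @return list with \code{overall}, \code{producer}, \code{user},
#'   \code{kappa} and \code{kappa_class}.
#' @export
accuracy_summary <- function(cm) {
  m <- unclass(cm)
  n <- sum(m)
  if (n <= 0) stop("empty confusion matrix")
  p <- m / n
  po <- sum(diag(p))
  row_m <- rowSums(p)   # predicted margins
  col_m <- colSums(p)   # actual margins
  pe <- sum(row_m * col_m)
  if (pe >= 1) stop("degenerate margins: expected agreement is 1, kappa undefined")
  kappa <- (po - pe) / (1 - pe)
  kc <- (diag(p) / row_m - col_m) / (1 - col_m)
  list(overall = po,
       producer = diag(p) / col_m,
       user = diag(p) / row_m,
       kappa = kappa,
       kappa_class = kc)
}

#' Signed relative error in percent
#'
#' \code{(model - statistic) / statistic * 100}; positive is
#' over-estimation, negative under-estimation.
#'
#' @param P_model modelled population(s).
#' @param P_stat census statistic(s), > 0.
#' @return percent value(s).
#' @export
relative_error <- function(P_model, P_stat) {
  if (any(P_stat <= 0)) stop("relative error undefined for P_stat <= 0")
  (P_model - P_stat) / P_stat * 100
}

#' Total absolute error and its relative form
#'
#' \code{TAE = sum(|P_model - P_stat|)};
#' \code{RTAE = TAE / sum(P_stat)}. For non-negative populations RTAE lies
#' in [0, 2]: 0 is a perfect estimate, 2 a completely wrong one.
#'
#' @param P_model,P_stat per-unit modelled and census populations.
#' @return scalar.
#' @export
rtae <- function(P_model, P_stat) {
  stopifnot(length(P_model) == length(P_stat))
  if (sum(P_stat) <= 0) stop("total census population must be positive")
  sum(abs(P_model - P_stat)) / sum(P_stat)
}

#' @rdname rtae
#' @export
tae <- function(P_model, P_stat) sum(abs(P_model - P_stat))

#' Distribution of per-unit relative errors
#'
#' Counts of units whose |RE| falls below each threshold (cumulative) and
#' the mean |RE|. Units with a zero census population are excluded with a
#' warning.
#'
#' @param P_model,P_stat per-unit modelled and census populations.
#' @param thresholds_pct |RE| thresholds in percent.
#' @return list with \code{counts} (named, cumulative below each threshold),
#'   \code{mean_abs_re} and \code{re} (the signed per-unit values).
#' @export
re_distribution <- function(P_model, P_stat,
                            thresholds_pct = c(10, 20, 30, 40)) {
  keep <- P_stat > 0
  if (!all(keep)) {
    warning(sum(!keep), " unit(s) with zero census population excluded")
    P_model <- P_model[keep]; P_stat <- P_stat[keep]
  }
  re <- relative_error(P_model, P_stat)
  counts <- vapply(thresholds_pct, function(t) sum(abs(re) < t), integer(1))
  names(counts) <- paste0("<", thresholds_pct, "%")
  list(counts = counts, mean_abs_re = mean(abs(re)), re = re)
}
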