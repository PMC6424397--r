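# Confusion matrices, accuracy, Cohen's kappa and the calibration
# regression between estimated and reference defoliation.

#' Round half away from zero
#'
#' Fixed-point rounding matching how percentages are conventionally
#' printed in accuracy tables (0.5 rounds up), unlike base R's
#' round-half-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Build a labeled confusion matrix
#'
#' `counts[i, j]` = units with reference class `i` classified as `j`.
#' Classes absent from the data appear as zero rows/columns.
#'
#' @param reference,predicted class label vectors of equal length.
#' @param class_order character vector fixing the class ordering;
#'   defaults to the sorted union of observed labels.
#' @return a `confusion` object (integer matrix with class dimnames).
#' @export
build_confusion <- function(reference, predicted, class_order = NULL) {
  stopifnot(length(reference) == length(predicted))
  if (is.null(class_order))
    class_order <- sort(unique(c(as.character(reference),
                                 as.character(predicted))))
  ref <- factor(reference, levels = class_order)
  prd <- factor(predicted, levels = class_order)
  m <- table(reference = ref, predicted = prd)
  cm <- matrix(as.integer(m), nrow = length(class_order),
               dimnames = list(reference = class_order,
                               predicted = class_order))
  structure(cm, class = c("confusion", "matrix"))
}

#' Wrap an existing count matrix as a confusion object
#' @param counts square numeric matrix with matching dimnames.
#' @return a `confusion` object.
#' @export
as_confusion <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0))
  if (is.null(rownames(counts)))
    dimnames(counts) <- list(reference = paste0("c", seq_len(nrow(counts))),
                             predicted = paste0("c", seq_len(nrow(counts))))
  storage.mode(counts) <- "integer"
  structure(counts, class = c("confusion", "matrix"))
}

#' @export
print.confusion <- function(x, ...) {
  cat("<confusion matrix> reference (rows) x predicted (columns)\n")
  print(unclass(x))
  cat(sprintf("overall accuracy %.1f%%, kappa %.3f\n",
              overall_accuracy(x), cohens_kappa(x)))
  invisible(x)
}

#' Overall accuracy of a confusion matrix
#'
#' 100 times the trace over the total count.
#'
#' @param cm a `confusion` matrix.
#' @return accuracy in percent.
#' @export
overall_accuracy <- function(cm) {
  tot <- sum(cm)
  if (tot == 0) return(NA_real_)
  100 * sum(diag(cm)) / tot
}

#' Producer's and user's accuracy per class
#'
#' Producer's accuracy = diagonal over row (reference) totals; user's
#' accuracy = diagonal over column (classified) totals.
#'
#' @param cm a `confusion` matrix.
#' @return data.table with `class`, `producer_pct`, `user_pct`.
#' @export
per_class_accuracy <- function(cm) {
  dg <- diag(cm)
  data.table::data.table(
    class = rownames(cm),
    producer_pct = 100 * dg / pmax(rowSums(cm), 1e-12),
    user_pct = 100 * dg / pmax(colSums(cm), 1e-12))
}

#' Cohen's kappa of a confusion matrix
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` the
#' accuracy fraction and expected agreement `p_e` from the row/column
#' marginal products.
#'
#' @param cm a `confusion` matrix.
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(cm) {
  tot <- sum(cm)
  if (tot == 0) return(NA_real_)
  po <- sum(diag(cm)) / tot
  pe <- sum(rowSums(cm) * colSums(cm)) / tot^2
  if (pe >= 1) return(1)
  (po - pe) / (1 - pe)
}

#' Merge (and drop) confusion-matrix classes
#'
#' Rows and columns are summed per group; classes not covered by the
#' grouping are dropped from both axes (their units leave the matrix).
#'
#' @param cm a `confusion` matrix.
#' @param grouping named list: new class name -> character vector of
#'   original classes.
#' @return a `confusion` matrix over the new classes.
#' @export
merge_classes <- function(cm, grouping) {
  stopifnot(all(unlist(grouping) %in% rownames(cm)))
  k <- length(grouping)
  out <- matrix(0L, k, k, dimnames = list(reference = names(grouping),
                                          predicted = names(grouping)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    out[i, j] <- sum(cm[grouping[[i]], grouping[[j]], drop = FALSE])
  }
  structure(out, class = c("confusion", "matrix"))
}

#' Regression of reference on estimated defoliation
#'
#' Ordinary least squares `Y = aX + b` with `R^2 = 1 - SS_res/SS_tot`.
#' A degenerate response (zero variance) yields slope 0 and `R^2 = 0`
#' with a warning instead of failing.
#'
#' @param x estimated defoliation per tree.
#' @param y reference defoliation per tree.
#' @return list with `a` (slope), `b` (intercept), `r_squared`, `n`.
#' @export
fit_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  stopifnot(length(x) >= 2)
  if (stats::var(y) == 0) {
    warning("degenerate regression: response has zero variance")
    return(list(a = 0, b = mean(y), r_squared = 0, n = length(x)))
  }
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(a = unname(co[2]), b = unname(co[1]),
       r_squared = 1 - ss_res / ss_tot, n = length(x))
}
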