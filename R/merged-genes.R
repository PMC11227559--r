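#' @export
print.merged_genes <- function(x, n = 6L, ...) {
  cat(sprintf("Merged gene list (%s method): %d genes\n",
              x$method, nrow(x$table)))
  if (!is.null(x$parameters))
    cat(sprintf("  null: scaled chi-square, c = %.4f, k' = %.4f\n",
                x$parameters$c, x$parameters$k_prime))
  print(utils::head(x$table, n))
  if (nrow(x$table) > n) cat(sprintf("  ... %d more genes\n",
                                     nrow(x$table) - n))
  invisible(x)
}

#' Summarise a merged gene list
#'
#' Reports significance counts of the merged P-values at conventional
#' thresholds and the distribution of the combined scores.
#'
#' @param object A \code{merged_genes} object.
#' @param thresholds P-value thresholds to tabulate.
#' @param ... Unused.
#' @export
summary.merged_genes <- function(object,
                                 thresholds = c(0.2, 0.1, 0.05, 0.01), ...) {
  p <- object$table$merged_p
  counts <- vapply(thresholds, function(a) sum(p < a), numeric(1))
  out <- list(method = object$method,
              n_genes = length(p),
              thresholds = thresholds,
              n_significant = counts,
              fraction_significant = counts / length(p),
              score_summary = summary(object$table$score),
              parameters = object$parameters)
  class(out) <- "summary.merged_genes"
  out
}

#' @export
print.summary.merged_genes <- function(x, ...) {
  cat(sprintf("Merged gene list (%s method), %d genes\n", x$method, x$n_genes))
  if (!is.null(x$parameters))
    cat(sprintf("  null: scaled chi-square, c = %.4f, k' = %.4f\n",
                x$parameters$c, x$parameters$k_prime))
  cat("  significant merged P-values:\n")
  for (i in seq_along(x$thresholds))
    cat(sprintf("    P < %-5g %6d  (%.2f%%)\n", x$thresholds[i],
                x$n_significant[i], 100 * x$fraction_significant[i]))
  cat("  combined score:\n")
  print(x$score_summary)
  invisible(x)
}

#' @export
as.data.frame.merged_genes <- function(x, ...) {
  df <- x$table
  df$method <- x$method
  df
}

#' Extract the merged P-values
#'
#' @param object A \code{merged_genes} object.
#' @param ... Unused.
#' @return Named numeric vector of merged P-values in input gene order.
#' @export
coef.merged_genes <- function(object, ...) {
  stats::setNames(object$table$merged_p, object$table$gene_id)
}

#' Histogram of merged P-values
#'
#' A quick calibration check: under a global null with well-calibrated
#' inputs and full directional agreement the merged P-values should look
#' uniform; directional penalties shift mass towards 1.
#'
#' @param x A \code{merged_genes} object.
#' @param ... Passed to \code{hist}.
#' @export
plot.merged_genes <- function(x, ...) {
  graphics::hist(x$table$merged_p, breaks = 20,
                 main = sprintf("Merged P-values (%s)", x$method),
                 xlab = "merged P-value", ...)
  invisible(x)
}
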