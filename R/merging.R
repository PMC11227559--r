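#' Merge per-gene P-values across omics datasets
#'
#' Front door to the P-value combination methods. Given a genes-by-datasets
#' matrix of P-values, and optionally a matrix of observed direction signs
#' plus a constraints vector (CV) of expected per-dataset directions, returns
#' one combined score and merged P-value per gene.
#'
#' Methods:
#' \describe{
#'   \item{\code{fisher}}{Fisher's method: \eqn{X_F = -2 \sum_i \ln P_i},
#'     referred to a chi-square distribution with \eqn{2k} degrees of freedom.
#'     Assumes independent inputs.}
#'   \item{\code{brown}}{Empirical Brown's method: the same score referred to
#'     a scaled chi-square null whose scale \eqn{c} and degrees of freedom
#'     \eqn{k'} are estimated nonparametrically from the covariation of the
#'     input columns (see \code{\link{estimate_brown_parameters}}). The
#'     appropriate choice when datasets are dependent, as omics datasets
#'     usually are.}
#'   \item{\code{dpm}}{Directional P-value merging: Brown's null applied to a
#'     directionally weighted score in which each log P-value is weighted by
#'     the product of the observed sign \eqn{o_i} and the expected sign
#'     \eqn{e_i} from the CV; agreements accumulate evidence, conflicts cancel
#'     it, and directionless datasets (CV entry 0) contribute unweighted.}
#'   \item{\code{stouffer_directional}}{Signed Z-score combination in the
#'     style of GWAS meta-analysis: per-dataset quantiles
#'     \eqn{\Phi^{-1}(P_i/2)} weighted by the direction signs, summed and
#'     scaled by \eqn{\sqrt k}; two-sided normal merged P-value.}
#'   \item{\code{strube_directional}}{As above but with separate directional
#'     and directionless blocks and, by default, covariance-adjusted
#'     denominators for dependent inputs (see
#'     \code{\link{strube_directional_merge}}).}
#' }
#'
#' @param scores Numeric matrix of P-values (genes in rows, datasets in
#'   columns) with dimnames; entries in (0, 1], zeros clamped to 1e-300.
#' @param directions Optional same-shaped matrix of observed direction signs
#'   (reduced to -1/0/+1). Required information for the directional methods;
#'   ignored by \code{fisher} and \code{brown}.
#' @param cv Optional constraints vector of expected per-dataset directions
#'   in \{-1, 0, +1\}; 0 marks a directionless dataset. Defaults to all
#'   zeros (fully non-directional analysis).
#' @param method Combination method, see Details.
#' @param ... Passed on to the method-specific function, e.g.
#'   \code{covariance_adjusted} for \code{strube_directional} or
#'   \code{parameters} for \code{brown}/\code{dpm}.
#'
#' @return An object of class \code{merged_genes}: a list with a
#'   \code{table} data frame (\code{gene_id}, \code{score},
#'   \code{merged_p}), the \code{method} tag, and for the Brown-family
#'   methods the estimated null \code{parameters}. Gene order follows the
#'   input rows.
#' @seealso \code{\link{dpm_merge}}, \code{\link{brown_merge}},
#'   \code{\link{run_enrichment}}
#' @examples
#' p <- matrix(c(0.01, 0.3, 0.02, 0.8), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("rna", "protein")))
#' d <- matrix(c(1, 1, 1, -1), nrow = 2, dimnames = dimnames(p))
#' fit <- merge_pvalues(p, d, cv = c(1, 1), method = "dpm")
#' fit
#' @export
merge_pvalues <- function(scores, directions = NULL, cv = NULL,
                          method = c("dpm", "brown", "fisher",
                                     "stouffer_directional",
                                     "strube_directional"),
                          ...) {
  method <- match.arg(method)
  switch(method,
    fisher = fisher_merge(scores),
    brown = brown_merge(scores, ...),
    dpm = dpm_merge(scores, directions, cv, ...),
    stouffer_directional = stouffer_directional_merge(scores, directions, cv),
    strube_directional = strube_directional_merge(scores, directions, cv, ...)
  )
}

new_merged_genes <- function(gene_ids, score, merged_p, method,
                             parameters = NULL) {
  structure(
    list(table = data.frame(gene_id = gene_ids, score = score,
                            merged_p = merged_p,
                            row.names = NULL,
                            stringsAsFactors = FALSE),
         method = method,
         parameters = parameters),
    class = "merged_genes")
}

#' Fisher's method for combining P-values
#'
#' Per gene, \eqn{X_F = -2 \sum_i \ln P_i} and the merged P-value is the
#' upper chi-square tail with \eqn{2k} degrees of freedom. With a single
#' dataset this is the identity map on P-values.
#'
#' @inheritParams merge_pvalues
#' @return A \code{merged_genes} object.
#' @export
fisher_merge <- function(scores) {
  scores <- as_score_matrix(scores)
  k <- ncol(scores)
  x <- -2 * rowSums(log(scores))
  p <- stats::pchisq(x, df = 2 * k, lower.tail = FALSE)
  new_merged_genes(rownames(scores), x, p, "fisher")
}

#' Estimate the empirical Brown null parameters
#'
#' Estimates the scale \eqn{c} and degrees of freedom \eqn{k'} of the scaled
#' chi-square distribution approximating the null of \eqn{-2 \sum_i \ln P_i}
#' when the input columns covary. Following the empirical Brown's method,
#' each column is standardised, mapped through its own right-continuous
#' empirical CDF \eqn{\hat e}, and transformed to \eqn{w = -2 \ln \hat e};
#' the null variance is \eqn{Var[X] = \sum_i var(w_i) + 2 \sum_{i<j}
#' cov(w_i, w_j)} with sample (co)variances taken across genes, while the
#' expectation is fixed at the theoretical \eqn{E[X] = 2k}. Then
#' \eqn{c = Var[X] / (2 E[X])} and \eqn{k' = 2 E[X]^2 / Var[X]}.
#'
#' If the estimated variance is non-positive (possible for degenerate, very
#' small inputs) the independence parameters \eqn{c = 1}, \eqn{k' = 2k} are
#' returned with a warning.
#'
#' @inheritParams merge_pvalues
#' @return An object of class \code{brown_parameters}: list with \code{c},
#'   \code{k_prime}, \code{expected_X}, \code{var_X}.
#' @export
estimate_brown_parameters <- function(scores) {
  scores <- as_score_matrix(scores)
  k <- ncol(scores)
  n <- nrow(scores)
  if (n < 2L)
    stop("at least 2 genes are required to estimate covariances",
         call. = FALSE)
  expected_x <- 2 * k
  w <- apply(scores, 2L, function(col) {
    z <- (col - mean(col)) / max(stats::sd(col), .Machine$double.eps)
    -2 * log(stats::ecdf(z)(z))
  })
  cov_w <- stats::cov(w)
  var_x <- sum(cov_w)  # sum of variances + twice the pairwise covariances
  if (!is.finite(var_x) || var_x <= 0) {
    warning("non-positive estimated variance; falling back to independence",
            call. = FALSE)
    return(new_brown_parameters(1, 2 * k, expected_x, 2 * expected_x))
  }
  new_brown_parameters(var_x / (2 * expected_x),
                       2 * expected_x^2 / var_x,
                       expected_x, var_x)
}

new_brown_parameters <- function(c, k_prime, expected_x, var_x) {
  stopifnot(c > 0, k_prime > 0)
  structure(list(c = c, k_prime = k_prime,
                 expected_X = expected_x, var_X = var_x),
            class = "brown_parameters")
}

#' @export
print.brown_parameters <- function(x, ...) {
  cat(sprintf("Empirical Brown null: c = %.4f, k' = %.4f (E[X] = %g, Var[X] = %.4f)\n",
              x$c, x$k_prime, x$expected_X, x$var_X))
  invisible(x)
}

#' Empirical Brown's method for dependent P-values
#'
#' Per gene, \eqn{X_B = -2 \sum_i \ln P_i}; the merged P-value is the upper
#' chi-square tail with \eqn{k'} degrees of freedom evaluated at
#' \eqn{X_B / c}, with \eqn{c} and \eqn{k'} from
#' \code{\link{estimate_brown_parameters}}.
#'
#' @inheritParams merge_pvalues
#' @param parameters Optional precomputed \code{brown_parameters}; by
#'   default estimated from \code{scores}.
#' @return A \code{merged_genes} object carrying the null parameters.
#' @export
brown_merge <- function(scores, parameters = NULL) {
  scores <- as_score_matrix(scores)
  if (is.null(parameters)) parameters <- estimate_brown_parameters(scores)
  x <- -2 * rowSums(log(scores))
  p <- stats::pchisq(x / parameters$c, df = parameters$k_prime,
                     lower.tail = FALSE)
  new_merged_genes(rownames(scores), x, p, "brown", parameters)
}

#' Directionally weighted combined score for one gene
#'
#' Computes the DPM score for a single gene:
#' \deqn{X = -2( -| \sum_{dir} \ln(P_i)\, o_i e_i | + \sum_{dirless} \ln P_i )}
#' where the first sum runs over datasets with a nonzero constraints-vector
#' entry \eqn{e_i} and the second over directionless datasets
#' (\eqn{e_i = 0}). Either block may be empty. When every directional
#' dataset agrees with the constraints (\eqn{o_i e_i = +1}) the score equals
#' Fisher's \eqn{X_F}; conflicting directions cancel inside the absolute
#' value and reduce the score. The absolute value makes the CV globally sign
#' invariant: negating every entry of \code{cv} leaves the score unchanged.
#'
#' An observed direction of 0 in a directional dataset drops that dataset's
#' term entirely; a warning is emitted when this discards actual evidence
#' (P < 1).
#'
#' @param p_row Numeric vector of P-values in (0, 1].
#' @param o_row Numeric vector of observed direction signs, same length.
#' @param cv Constraints vector, same length.
#' @return The combined score, a single non-negative number.
#' @examples
#' dpm_score(c(0.01, 0.5), c(1, 1), c(1, -1))  # ~7.824
#' dpm_score(c(0.05, 0.05), c(1, -1), c(1, -1))  # agreement: Fisher's score
#' @export
dpm_score <- function(p_row, o_row, cv) {
  if (length(p_row) != length(o_row) || length(p_row) != length(cv))
    stop("'p_row', 'o_row' and 'cv' must have equal lengths", call. = FALSE)
  p_row <- pmax(pmin(p_row, 1), 1e-300)
  o_row <- sign(o_row)
  cv <- sign(cv)
  directional <- cv != 0
  dropped <- directional & o_row == 0 & p_row < 1
  if (any(dropped))
    warning(sprintf(
      "%d directional dataset(s) with direction 0 drop evidence (P < 1)",
      sum(dropped)), call. = FALSE)
  lp <- log(p_row)
  dir_sum <- sum(lp[directional] * o_row[directional] * cv[directional])
  dirless_sum <- sum(lp[!directional])
  -2 * (-abs(dir_sum) + dirless_sum)
}

# Vectorised DPM scores over all genes of a validated triple.
dpm_scores <- function(scores, directions, cv) {
  lp <- log(scores)
  directional <- cv != 0
  dir_sum <- if (any(directional)) {
    as.vector((lp[, directional, drop = FALSE] *
               directions[, directional, drop = FALSE]) %*%
              cv[directional])
  } else 0
  dirless_sum <- if (any(!directional)) {
    rowSums(lp[, !directional, drop = FALSE])
  } else 0
  dropped <- directions == 0 & rep(directional, each = nrow(scores)) &
    scores < 1
  if (any(dropped))
    warning(sprintf(
      "%d directional entries with direction 0 drop evidence (P < 1)",
      sum(dropped)), call. = FALSE)
  -2 * (-abs(dir_sum) + dirless_sum)
}

#' Directional P-value merging (DPM)
#'
#' Combines per-gene P-values with observed direction signs under a
#' constraints vector: the directionally weighted score of
#' \code{\link{dpm_score}} is referred to the empirical Brown scaled
#' chi-square null estimated from the undirected P-value matrix. Genes whose
#' directions comply with the constraints retain full Fisher/Brown evidence;
#' genes with conflicting directions are penalised, and the merged P-value
#' can never be smaller than Brown's for the same gene.
#'
#' With an all-zero constraints vector every dataset is directionless and
#' the result is identical to \code{\link{brown_merge}}.
#'
#' @inheritParams merge_pvalues
#' @inheritParams brown_merge
#' @return A \code{merged_genes} object carrying the null parameters.
#' @examples
#' set.seed(1)
#' p <- matrix(runif(200), ncol = 2,
#'             dimnames = list(sprintf("g%03d", 1:100), c("kd", "oe")))
#' d <- matrix(sample(c(-1, 1), 200, TRUE), ncol = 2, dimnames = dimnames(p))
#' fit <- dpm_merge(p, d, cv = c(-1, 1))
#' summary(fit)
#' @export
dpm_merge <- function(scores, directions = NULL, cv = NULL,
                      parameters = NULL) {
  v <- validate_inputs(scores, directions, cv)
  if (is.null(parameters)) parameters <- estimate_brown_parameters(v$scores)
  x <- dpm_scores(v$scores, v$directions, v$cv)
  p <- stats::pchisq(x / parameters$c, df = parameters$k_prime,
                     lower.tail = FALSE)
  new_merged_genes(rownames(v$scores), x, p, "dpm", parameters)
}

#' Directional Stouffer (signed Z-score) merging
#'
#' Converts each P-value to the quantile \eqn{\Phi^{-1}(P_i/2)} and combines
#' the quantiles with the direction weights \eqn{o_i e_i} for directional
#' datasets (unweighted for directionless ones), scaled by \eqn{\sqrt k}:
#' the signed Z-score combination used in GWAS meta-analysis. The merged
#' P-value is the two-sided normal tail \eqn{2\Phi(-|Z|)}. Assumes
#' independent inputs; with a single dataset this is the identity map.
#'
#' @inheritParams merge_pvalues
#' @return A \code{merged_genes} object with \code{score} holding Z.
#' @export
stouffer_directional_merge <- function(scores, directions = NULL, cv = NULL) {
  v <- validate_inputs(scores, directions, cv)
  k <- ncol(v$scores)
  q <- stats::qnorm(v$scores / 2)
  weights <- sweep(v$directions, 2L, v$cv, `*`)
  weights[, v$cv == 0] <- 1
  z <- rowSums(q * weights) / sqrt(k)
  p <- 2 * stats::pnorm(-abs(z))
  new_merged_genes(rownames(v$scores), z, pmin(p, 1), "stouffer_directional")
}

#' Directional Strube merging for dependent P-values
#'
#' Combines the quantiles \eqn{\Phi^{-1}(P_i/2)} in two blocks: the
#' directional datasets weighted by \eqn{o_i e_i} and taken in absolute
#' value, plus the directionless datasets unweighted:
#' \deqn{Z_S = \left|\frac{\sum_{dir} \Phi^{-1}(P_i/2)\, o_i e_i}{d_1}\right|
#'   + \frac{\sum_{dirless} \Phi^{-1}(P_i/2)}{d_0}.}
#' By default the denominators \eqn{d_1, d_0} account for the covariation of
#' the input columns: each is \eqn{\sqrt{\sum \rho}} over the block's
#' pairwise correlation matrix of the quantile-transformed columns (which
#' reduces to \eqn{\sqrt j} and \eqn{\sqrt{k-j}} for uncorrelated inputs);
#' \code{covariance_adjusted = FALSE} uses the plain \eqn{\sqrt j} and
#' \eqn{\sqrt{k-j}}. The merged P-value is \eqn{2\Phi(-|Z_S|)}.
#'
#' @inheritParams merge_pvalues
#' @param covariance_adjusted Use covariance-adjusted denominators
#'   (default) or the literal square-root block sizes.
#' @return A \code{merged_genes} object with \code{score} holding
#'   \eqn{Z_S}.
#' @export
strube_directional_merge <- function(scores, directions = NULL, cv = NULL,
                                     covariance_adjusted = TRUE) {
  v <- validate_inputs(scores, directions, cv)
  k <- ncol(v$scores)
  directional <- v$cv != 0
  j <- sum(directional)
  if (j == 0 && k == 0)
    stop("no datasets to merge", call. = FALSE)
  q <- stats::qnorm(v$scores / 2)

  block_denominator <- function(cols) {
    if (!covariance_adjusted || length(cols) == 1L || nrow(q) < 2L)
      return(sqrt(length(cols)))
    rho <- stats::cor(q[, cols, drop = FALSE])
    s <- sum(rho)
    if (!is.finite(s) || s <= 0) sqrt(length(cols)) else sqrt(s)
  }

  z_dir <- 0
  if (j > 0) {
    w <- sweep(v$directions[, directional, drop = FALSE], 2L,
               v$cv[directional], `*`)
    z_dir <- abs(rowSums(q[, directional, drop = FALSE] * w) /
                 block_denominator(which(directional)))
  }
  z_dirless <- 0
  if (j < k) {
    z_dirless <- rowSums(q[, !directional, drop = FALSE]) /
      block_denominator(which(!directional))
  }
  z <- z_dir + z_dirless
  p <- pmin(2 * stats::pnorm(-abs(z)), 1)
  new_merged_genes(rownames(v$scores), z, p, "strube_directional")
}
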