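#' Rank genes by merged P-value
#'
#' Orders the genes of a merged list by ascending merged P-value, breaking
#' ties lexicographically by gene identifier so the ranking is deterministic.
#'
#' @param merged A \code{merged_genes} object.
#' @return Character vector of gene identifiers, most significant first,
#'   with attribute \code{tie_break = "lexicographic"}.
#' @export
rank_genes <- function(merged) {
  tab <- if (inherits(merged, "merged_genes")) merged$table else merged
  if (nrow(tab) == 0) stop("empty merged gene list", call. = FALSE)
  ord <- order(tab$merged_p, tab$gene_id, method = "radix")
  structure(tab$gene_id[ord], tie_break = "lexicographic")
}

#' Ranked hypergeometric enrichment test for one gene set
#'
#' Walks down a ranked gene list and evaluates the one-sided
#' over-representation (upper-tail hypergeometric) P-value of the gene set
#' in each top fraction, returning the minimum over cutoffs together with
#' the optimal cutoff and the overlapping genes. Candidate cutoffs are the
#' ranks at which a set member enters the list: between member entries the
#' upper-tail P-value only grows, so the minimum is attained at a member
#' rank. No correction is applied across cutoffs; the minimum is the set's
#' statistic and multiple-testing correction happens across gene sets.
#'
#' @param ranked Character vector of gene identifiers ordered most
#'   significant first (the statistical background).
#' @param members Character vector of gene-set members; genes outside the
#'   background are ignored.
#' @return List with \code{raw_p}, \code{optimal_cutoff} (number of top
#'   genes) and \code{overlap_genes} (members within the cutoff, in rank
#'   order). An empty intersection gives \code{raw_p = 1} with the cutoff at
#'   the full background.
#' @examples
#' ranked <- paste0("g", 1:10)
#' ranked_hypergeometric_test(ranked, c("g1", "g2", "g3"))  # p = 1/120
#' @export
ranked_hypergeometric_test <- function(ranked, members) {
  n_bg <- length(ranked)
  hit_ranks <- which(ranked %in% members)
  if (length(hit_ranks) == 0L)
    return(list(raw_p = 1, optimal_cutoff = n_bg,
                overlap_genes = character(0)))
  n_set <- length(hit_ranks)
  # at cutoff hit_ranks[i] the top contains exactly i members
  p_at <- stats::phyper(seq_along(hit_ranks) - 1L,
                        m = n_set, n = n_bg - n_set,
                        k = hit_ranks, lower.tail = FALSE)
  best <- which.min(p_at)
  list(raw_p = p_at[best],
       optimal_cutoff = hit_ranks[best],
       overlap_genes = ranked[hit_ranks[seq_len(best)]])
}

#' Multiple-testing adjustment of P-values
#'
#' Holm step-down family-wise error rate control (default in the pathway
#' analysis) or Benjamini-Hochberg false discovery rate, both capped at 1.
#'
#' @param p_values Numeric vector of P-values in [0, 1].
#' @param method \code{"holm"} or \code{"bh"}.
#' @return Adjusted P-values in the input order.
#' @export
adjust_pvalues <- function(p_values, method = c("holm", "bh")) {
  method <- match.arg(method)
  if (!is.numeric(p_values) || any(is.na(p_values)) ||
      any(p_values < 0 | p_values > 1))
    stop("P-values must be numeric and within [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = if (method == "bh") "BH" else "holm")
}

# Intersect a gene-set library with the background and apply size bounds.
filter_gene_sets <- function(library, background, min_size, max_size) {
  sets <- lapply(library$sets, function(s) {
    s$members <- intersect(s$members, background)
    s
  })
  keep <- vapply(sets, function(s) {
    length(s$members) >= min_size && length(s$members) <= max_size
  }, logical(1))
  sets[keep]
}

#' Pathway enrichment analysis of a merged gene list
#'
#' Ranks the merged genes by P-value, intersects each gene set with the
#' statistical background, filters sets by size, tests each retained set
#' with the ranked hypergeometric test, and corrects across sets. For every
#' significant set the analysis is repeated on each input dataset column
#' alone (when \code{scores} is supplied) to attribute the enrichment to the
#' datasets that independently support it; sets supported by no single
#' dataset are labelled \code{"combined-only"}.
#'
#' @param merged A \code{merged_genes} object.
#' @param library A \code{gene_set_library} from \code{\link{read_gmt}} or
#'   \code{\link{gene_set_library}}.
#' @param background Character vector of background gene identifiers
#'   (default: all merged genes). Must be a subset of the merged genes.
#' @param correction \code{"holm"} (family-wise error rate, default) or
#'   \code{"bh"} (false discovery rate).
#' @param alpha Significance threshold on adjusted P-values (default 0.05).
#' @param min_size,max_size Gene-set size bounds applied after background
#'   intersection (defaults 10 and 1000).
#' @param scores Optional P-value matrix used for per-dataset evidence
#'   attribution of the significant sets.
#' @return An object of class \code{enrichment_result}: a data frame with
#'   one row per tested set (\code{set_id}, \code{name}, \code{set_size},
#'   \code{optimal_cutoff}, \code{overlap_size}, \code{overlap_genes},
#'   \code{raw_p}, \code{adjusted_p}, \code{significant}, \code{evidence}),
#'   sorted by adjusted then raw P-value.
#' @export
run_enrichment <- function(merged, library, background = NULL,
                           correction = c("holm", "bh"), alpha = 0.05,
                           min_size = 10, max_size = 1000, scores = NULL) {
  correction <- match.arg(correction)
  tab <- merged$table
  if (is.null(background)) background <- tab$gene_id
  if (!all(background %in% tab$gene_id))
    stop("background contains genes absent from the merged list",
         call. = FALSE)
  ranked <- rank_genes(merged)
  ranked <- ranked[ranked %in% background]

  sets <- filter_gene_sets(library, background, min_size, max_size)
  if (length(sets) == 0L) {
    warning("no gene sets left after background intersection and size filtering",
            call. = FALSE)
    return(empty_enrichment_result())
  }

  tests <- lapply(sets, function(s) ranked_hypergeometric_test(ranked, s$members))
  res <- data.frame(
    set_id = vapply(sets, `[[`, "", "set_id"),
    name = vapply(sets, `[[`, "", "name"),
    set_size = vapply(sets, function(s) length(s$members), integer(1)),
    optimal_cutoff = vapply(tests, function(t) as.integer(t$optimal_cutoff),
                            integer(1)),
    overlap_size = vapply(tests, function(t) length(t$overlap_genes),
                          integer(1)),
    overlap_genes = vapply(tests, function(t)
      paste(t$overlap_genes, collapse = ";"), ""),
    raw_p = vapply(tests, `[[`, numeric(1), "raw_p"),
    row.names = NULL, stringsAsFactors = FALSE)
  res$adjusted_p <- adjust_pvalues(res$raw_p, correction)
  res$significant <- res$adjusted_p < alpha
  res$evidence <- NA_character_

  if (!is.null(scores) && any(res$significant)) {
    sig_ids <- res$set_id[res$significant]
    ev <- column_contributions(scores, library, background, sig_ids,
                               correction = correction, alpha = alpha,
                               min_size = min_size, max_size = max_size)
    res$evidence[res$significant] <- ev[sig_ids]
  }

  res <- res[order(res$adjusted_p, res$raw_p, res$set_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "correction") <- correction
  attr(res, "alpha") <- alpha
  class(res) <- c("enrichment_result", "data.frame")
  res
}

empty_enrichment_result <- function() {
  res <- data.frame(set_id = character(0), name = character(0),
                    set_size = integer(0), optimal_cutoff = integer(0),
                    overlap_size = integer(0), overlap_genes = character(0),
                    raw_p = numeric(0), adjusted_p = numeric(0),
                    significant = logical(0), evidence = character(0),
                    stringsAsFactors = FALSE)
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' @export
print.enrichment_result <- function(x, n = 10L, ...) {
  cat(sprintf("Pathway enrichment: %d gene sets tested, %d significant\n",
              nrow(x), sum(x$significant)))
  cols <- c("set_id", "set_size", "optimal_cutoff", "overlap_size",
            "raw_p", "adjusted_p", "evidence")
  print(utils::head(as.data.frame(x)[, cols, drop = FALSE], n))
  if (nrow(x) > n) cat(sprintf("  ... %d more sets\n", nrow(x) - n))
  invisible(x)
}

#' Attribute significant pathways to the input datasets
#'
#' For each input dataset the enrichment analysis is repeated on that single
#' column's P-values alone (genes ranked by the column, same background,
#' size bounds and correction). A dataset counts as evidence for a gene set
#' when the set's single-column adjusted P-value falls below \code{alpha};
#' sets supported by no single dataset are labelled \code{"combined-only"}.
#'
#' @param scores P-value matrix (genes x datasets) with dimnames.
#' @param library A \code{gene_set_library}.
#' @param background Background gene identifiers.
#' @param significant_sets Identifiers of the sets to label (typically the
#'   significant sets of \code{\link{run_enrichment}}).
#' @param correction,alpha,min_size,max_size As in
#'   \code{\link{run_enrichment}}.
#' @return Named character vector over \code{significant_sets}: dataset
#'   identifiers joined by \code{";"}, or \code{"combined-only"}.
#' @export
column_contributions <- function(scores, library, background,
                                 significant_sets,
                                 correction = c("holm", "bh"), alpha = 0.05,
                                 min_size = 10, max_size = 1000) {
  correction <- match.arg(correction)
  scores <- as_score_matrix(scores)
  support <- matrix(FALSE, nrow = length(significant_sets),
                    ncol = ncol(scores),
                    dimnames = list(significant_sets, colnames(scores)))
  sets <- filter_gene_sets(library, background, min_size, max_size)
  sets <- sets[vapply(sets, function(s) s$set_id %in% significant_sets,
                      logical(1))]
  for (d in colnames(scores)) {
    col <- scores[background, d]
    ranked <- background[order(col, background, method = "radix")]
    raw <- vapply(sets, function(s)
      ranked_hypergeometric_test(ranked, s$members)$raw_p, numeric(1))
    adj <- adjust_pvalues(raw, correction)
    hit <- vapply(sets, `[[`, "", "set_id")[adj < alpha]
    support[rownames(support) %in% hit, d] <- TRUE
  }
  out <- apply(support, 1L, function(row) {
    if (any(row)) paste(colnames(support)[row], collapse = ";")
    else "combined-only"
  })
  stats::setNames(as.character(out), rownames(support))
}

#' Build enrichment-map node and edge tables
#'
#' Converts significant enrichment results into tables importable into
#' Cytoscape-style network tools: one node per significant gene set, and an
#' edge between two sets whenever their overlap coefficient
#' \eqn{|A \cap B| / \min(|A|, |B|)} (computed on the
#' background-intersected members) reaches the similarity threshold.
#'
#' @param results An \code{enrichment_result}.
#' @param library The \code{gene_set_library} the results came from.
#' @param similarity_threshold Minimum overlap coefficient for an edge
#'   (default 0.375).
#' @param background Optional background used to intersect members before
#'   computing overlaps (defaults to all members).
#' @return List with data frames \code{nodes} (\code{set_id}, \code{name},
#'   \code{adjusted_p}, \code{evidence}) and \code{edges} (\code{set_id_a},
#'   \code{set_id_b}, \code{similarity}).
#' @export
build_enrichment_map <- function(results, library,
                                 similarity_threshold = 0.375,
                                 background = NULL) {
  keep <- results[results$significant, , drop = FALSE]
  nodes <- data.frame(set_id = keep$set_id, name = keep$name,
                      adjusted_p = keep$adjusted_p,
                      evidence = keep$evidence,
                      row.names = NULL, stringsAsFactors = FALSE)
  members <- lapply(library$sets, `[[`, "members")
  names(members) <- vapply(library$sets, `[[`, "", "set_id")
  members <- members[nodes$set_id]
  if (!is.null(background))
    members <- lapply(members, intersect, background)
  edges <- data.frame(set_id_a = character(0), set_id_b = character(0),
                      similarity = numeric(0), stringsAsFactors = FALSE)
  if (nrow(nodes) >= 2L) {
    pairs <- utils::combn(nodes$set_id, 2L)
    sim <- apply(pairs, 2L, function(ab) {
      a <- members[[ab[1]]]; b <- members[[ab[2]]]
      denom <- min(length(a), length(b))
      if (denom == 0) 0 else length(intersect(a, b)) / denom
    })
    hit <- sim >= similarity_threshold
    edges <- data.frame(set_id_a = pairs[1, hit], set_id_b = pairs[2, hit],
                        similarity = sim[hit], stringsAsFactors = FALSE)
  }
  list(nodes = nodes, edges = edges)
}
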