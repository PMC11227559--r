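# Independent oracles and fixture builders used across the test files.

# Literal term-by-term evaluation of the directional score: loop over
# datasets, accumulate the weighted directional and unweighted directionless
# log sums separately, apply the absolute value at the end.
oracle_dpm_score <- function(p, o, e) {
  dir_sum <- 0
  dirless_sum <- 0
  for (i in seq_along(p)) {
    if (e[i] != 0) {
      dir_sum <- dir_sum + log(p[i]) * o[i] * e[i]
    } else {
      dirless_sum <- dirless_sum + log(p[i])
    }
  }
  -2 * (-abs(dir_sum) + dirless_sum)
}

# Exact upper-tail hypergeometric probability P(X >= x) from binomial
# coefficients only (no calls into the distribution functions under test).
oracle_hyper_tail <- function(x, n_set, n_bg, n_top) {
  hi <- min(n_set, n_top)
  if (x > hi) return(0)
  sum(vapply(x:hi, function(i)
    choose(n_set, i) * choose(n_bg - n_set, n_top - i), numeric(1))) /
    choose(n_bg, n_top)
}

# Brute-force ranked hypergeometric test: scan every cutoff 1..N.
oracle_ranked_hypergeom <- function(ranked, members) {
  n_bg <- length(ranked)
  is_member <- ranked %in% members
  n_set <- sum(is_member)
  if (n_set == 0) return(list(raw_p = 1, optimal_cutoff = n_bg))
  best_p <- Inf
  best_cut <- n_bg
  for (cut in seq_len(n_bg)) {
    x <- sum(is_member[seq_len(cut)])
    p <- oracle_hyper_tail(x, n_set, n_bg, cut)
    if (p < best_p) {
      best_p <- p
      best_cut <- cut
    }
  }
  list(raw_p = best_p, optimal_cutoff = best_cut)
}

# A small P-value matrix with gene/dataset names.
make_scores <- function(values, n_datasets = 2,
                        genes = NULL, datasets = NULL) {
  m <- matrix(values, ncol = n_datasets)
  rownames(m) <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- datasets %||% paste0("d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A merged_genes-shaped object from explicit per-gene P-values, for driving
# the enrichment layer with hand-chosen rankings.
merged_from_p <- function(p) {
  structure(list(table = data.frame(gene_id = names(p), score = -log(p),
                                    merged_p = unname(p),
                                    stringsAsFactors = FALSE),
                 method = "fisher", parameters = NULL),
            class = "merged_genes")
}

# Library of named gene sets from a named list of member vectors.
library_from_list <- function(sets, min_size = 1, max_size = 1000) {
  gene_set_library(
    lapply(names(sets), function(id)
      list(set_id = id, name = id, members = sets[[id]])),
    min_size = min_size, max_size = max_size)
}
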