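#' Construct a gene-set library
#'
#' @param sets List of gene sets, each a list with \code{set_id},
#'   \code{name} and a character vector \code{members} (deduplicated,
#'   non-empty).
#' @param min_size,max_size Default size bounds recorded with the library.
#' @return An object of class \code{gene_set_library}.
#' @export
gene_set_library <- function(sets, min_size = 10, max_size = 1000) {
  sets <- lapply(sets, function(s) {
    stopifnot(!is.null(s$set_id), !is.null(s$members))
    if (is.null(s$name)) s$name <- s$set_id
    s$members <- unique(as.character(s$members))
    if (length(s$members) == 0)
      stop(sprintf("gene set '%s' has no members", s$set_id), call. = FALSE)
    s[c("set_id", "name", "members")]
  })
  ids <- vapply(sets, `[[`, "", "set_id")
  if (anyDuplicated(ids)) {
    warning("duplicate gene-set identifiers; keeping the last of each",
            call. = FALSE)
    sets <- sets[!duplicated(ids, fromLast = TRUE)]
  }
  structure(list(sets = sets, min_size = min_size, max_size = max_size),
            class = "gene_set_library")
}

#' @export
print.gene_set_library <- function(x, ...) {
  sizes <- vapply(x$sets, function(s) length(s$members), integer(1))
  cat(sprintf("Gene-set library: %d sets (member counts %s-%s), size bounds [%g, %g]\n",
              length(x$sets),
              if (length(sizes)) min(sizes) else "-",
              if (length(sizes)) max(sizes) else "-",
              x$min_size, x$max_size))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Each line holds a set identifier, a description and at least one member,
#' tab-separated. Empty member tokens are skipped and duplicate members
#' collapsed; when the same set identifier appears on several lines the last
#' one wins, with a warning.
#'
#' @param path Path to a GMT file.
#' @param min_size,max_size Default size bounds recorded with the library.
#' @return A \code{gene_set_library}.
#' @export
read_gmt <- function(path, min_size = 10, max_size = 1000) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop(sprintf("GMT parse error at line %d: fewer than 3 tab-separated fields",
                   i), call. = FALSE)
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      stop(sprintf("GMT parse error at line %d: no gene members", i),
           call. = FALSE)
    list(set_id = fields[1], name = fields[2], members = members)
  })
  gene_set_library(sets, min_size = min_size, max_size = max_size)
}

#' Write a gene-set library in GMT format
#'
#' @param library A \code{gene_set_library}.
#' @param path Output path.
#' @export
write_gmt <- function(library, path) {
  lines <- vapply(library$sets, function(s)
    paste(c(s$set_id, s$name, s$members), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read P-value and direction matrices from TSV files
#'
#' Both files are tab-separated with a header row of dataset identifiers and
#' a first column of gene identifiers. Missing or blank cells take the
#' no-evidence convention P = 1 and direction = 0; numeric direction values
#' (log fold-changes, log hazard ratios) are reduced to unit signs. When no
#' direction file is given the direction matrix is all zeros. The direction
#' file must cover exactly the same genes and datasets as the P-value file
#' (row order may differ; directions are aligned to the score rows).
#'
#' @param p_path Path to the P-value TSV.
#' @param d_path Optional path to the direction TSV.
#' @return List with \code{scores} and \code{directions} matrices.
#' @export
read_score_tables <- function(p_path, d_path = NULL) {
  scores <- read_matrix_tsv(p_path, fill_value = 1)
  if (any(scores < 0) || any(scores > 1))
    stop(sprintf("'%s' contains values outside [0, 1]", p_path),
         call. = FALSE)
  if (is.null(d_path)) {
    directions <- array(0, dim(scores), dimnames = dimnames(scores))
  } else {
    directions <- read_matrix_tsv(d_path, fill_value = 0)
    if (!setequal(rownames(directions), rownames(scores)) ||
        !setequal(colnames(directions), colnames(scores)))
      stop("direction file genes/datasets do not match the P-value file",
           call. = FALSE)
    directions <- sign(directions[rownames(scores), colnames(scores),
                                  drop = FALSE])
  }
  list(scores = scores, directions = directions)
}

read_matrix_tsv <- function(path, fill_value) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  if (ncol(df) < 2L)
    stop(sprintf("'%s' needs a gene column plus at least one dataset", path),
         call. = FALSE)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    stop(sprintf("duplicate gene identifiers in '%s'", path), call. = FALSE)
  raw <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(raw) <- "character"
  raw[!is.na(raw) & trimws(raw) == ""] <- NA
  m <- suppressWarnings(array(as.numeric(raw), dim(raw), dimnames(raw)))
  if (any(is.na(m) & !is.na(raw)))
    stop(sprintf("non-numeric value in '%s'", path), call. = FALSE)
  n_filled <- sum(is.na(m))
  if (n_filled > 0)
    message(sprintf("'%s': %d missing cell(s) filled with %g",
                    basename(path), n_filled, fill_value))
  m[is.na(m)] <- fill_value
  rownames(m) <- genes
  m
}

#' Write the analysis outputs of a run
#'
#' Emits a deterministic set of tab-separated files into \code{out_dir}:
#' \code{genes.tsv} (merged gene list, input order preserved),
#' \code{pathways.tsv} (enrichment results), \code{nodes.tsv} and
#' \code{edges.tsv} (enrichment-map tables), \code{run_config.txt} (echo of
#' the run configuration) and \code{log.txt}. P-values are written in
#' full-precision scientific notation.
#'
#' @param merged A \code{merged_genes} object.
#' @param enrichment Optional \code{enrichment_result}.
#' @param map_tables Optional list with \code{nodes}/\code{edges} from
#'   \code{\link{build_enrichment_map}}.
#' @param run_config Optional named list echoed to \code{run_config.txt}.
#' @param out_dir Output directory, created if needed.
#' @param log_lines Optional character vector appended to \code{log.txt}.
#' @return Character vector of the files written (the manifest).
#' @export
write_outputs <- function(merged, enrichment = NULL, map_tables = NULL,
                          run_config = NULL, out_dir, log_lines = character(0)) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory '%s'", out_dir),
         call. = FALSE)
  manifest <- character(0)
  fmt_p <- function(p) formatC(p, format = "e", digits = 15)

  genes <- merged$table
  genes$merged_p <- fmt_p(genes$merged_p)
  genes$method <- merged$method
  f <- file.path(out_dir, "genes.tsv")
  utils::write.table(genes, f, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- c(manifest, f)

  if (!is.null(enrichment)) {
    path_df <- as.data.frame(enrichment)
    path_df$raw_p <- fmt_p(path_df$raw_p)
    path_df$adjusted_p <- fmt_p(path_df$adjusted_p)
    f <- file.path(out_dir, "pathways.tsv")
    utils::write.table(path_df, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest <- c(manifest, f)
  }
  if (!is.null(map_tables)) {
    nodes <- map_tables$nodes
    nodes$adjusted_p <- fmt_p(nodes$adjusted_p)
    f <- file.path(out_dir, "nodes.tsv")
    utils::write.table(nodes, f, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- c(manifest, f)
    f <- file.path(out_dir, "edges.tsv")
    utils::write.table(map_tables$edges, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest <- c(manifest, f)
  }
  if (!is.null(run_config)) {
    f <- file.path(out_dir, "run_config.txt")
    writeLines(paste(names(run_config),
                     vapply(run_config, function(v)
                       paste(format(v), collapse = ","), ""),
                     sep = "\t"), f)
    manifest <- c(manifest, f)
  }
  f <- file.path(out_dir, "log.txt")
  writeLines(c(sprintf("method\t%s", merged$method),
               sprintf("n_genes\t%d", nrow(merged$table)),
               log_lines), f)
  manifest <- c(manifest, f)
  manifest
}
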