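#' Construct an expression cohort matrix
#'
#' A genes x samples numeric matrix for one cancer-type cohort, with unique
#' gene symbols as rownames, unique sample IDs as colnames, finite or
#' missing values, and the cohort label carried in the \code{cancer_type}
#' attribute. Gene symbols are case-sensitive and matched exactly throughout
#' the package.
#'
#' @param values numeric matrix with dimnames.
#' @param cancer_type cohort label.
#' @return matrix of class \code{"expression_cohort"}.
#' @export
expression_cohort <- function(values, cancer_type) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) stop("duplicate gene symbol: ", dup[1L])
  if (anyDuplicated(colnames(values))) stop("duplicate sample IDs")
  if (any(is.infinite(values))) stop("values must be finite or missing")
  structure(values, cancer_type = as.character(cancer_type),
            class = c("expression_cohort", class(values)))
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf("expression cohort '%s': %d genes x %d samples (%d missing cells)\n",
              attr(x, "cancer_type"), nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

# accepted missing tokens on read; always written as "NA"
.na_tokens <- c("NA", "NaN", "")

.parse_num <- function(cells, line_no, path) {
  out <- suppressWarnings(as.numeric(cells))
  bad <- is.na(out) & !(cells %in% .na_tokens)
  if (any(bad))
    stop(sprintf("non-numeric cell '%s' at line %d of %s",
                 cells[which(bad)[1L]], line_no, path))
  out[cells %in% .na_tokens] <- NA_real_
  out
}

#' Read an expression matrix from tab-separated text
#'
#' Dialect: header row of sample IDs with a leading gene-symbol column, one
#' row per gene, tab separators; missing cells written as \code{NA}
#' (\code{NaN} and empty cells also accepted on read). Malformed input is
#' rejected, never coerced.
#'
#' @param path file path.
#' @param cancer_type cohort label; defaults to the file name without
#'   extension.
#' @return an [expression_cohort()].
#' @export
read_expression_tsv <- function(path, cancer_type = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("expression file needs a header and >=1 gene row: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  n_col <- length(header)
  if (n_col < 2L) stop("header must contain >=1 sample column: ", path)
  samples <- header[-1L]
  genes <- character(length(lines) - 1L)
  vals <- matrix(NA_real_, nrow = length(lines) - 1L, ncol = n_col - 1L)
  for (i in seq_along(genes)) {
    cells <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1L]]
    # a trailing missing cell yields one fewer field after strsplit
    if (length(cells) == n_col - 1L && endsWith(lines[i + 1L], "\t"))
      cells <- c(cells, "")
    if (length(cells) != n_col)
      stop(sprintf("ragged row at line %d of %s (%d fields, expected %d)",
                   i + 1L, path, length(cells), n_col))
    genes[i] <- cells[1L]
    vals[i, ] <- .parse_num(cells[-1L], i + 1L, path)
  }
  dup <- genes[duplicated(genes)]
  if (length(dup)) stop("duplicate gene symbol: ", dup[1L], " in ", path)
  dimnames(vals) <- list(genes, samples)
  if (is.null(cancer_type))
    cancer_type <- sub("\\.[^.]*$", "", basename(path))
  expression_cohort(vals, cancer_type)
}

#' Write an expression matrix as tab-separated text
#'
#' Inverse of [read_expression_tsv()]; byte-deterministic, missing cells
#' written as \code{NA}, values at full precision so write-then-read
#' round-trips.
#'
#' @param mat an expression cohort matrix.
#' @param path output file path.
#' @export
write_expression_tsv <- function(mat, path) {
  stopifnot(is.matrix(mat))
  cells <- matrix(sprintf("%.17g", mat), nrow = nrow(mat))
  cells[is.na(mat)] <- "NA"
  lines <- c(paste(c("gene", colnames(mat)), collapse = "\t"),
             paste(rownames(mat), apply(cells, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then member gene symbols, all
#' tab-separated. Member order is preserved; duplicate members within a set
#' are stored once. Lines with fewer than three fields are rejected with
#' their line number.
#'
#' @param path GMT file path.
#' @return list of class \code{"gene_set_collection"}: per set a list with
#'   \code{name}, \code{description}, \code{genes}.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    cells <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(cells) < 3L)
      stop(sprintf("GMT line %d has %d fields; need name, description, >=1 member",
                   i, length(cells)))
    genes <- unique(cells[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop(sprintf("GMT line %d has no members", i))
    sets[[i]] <- list(name = cells[1L], description = cells[2L], genes = genes)
  }
  nm <- vapply(sets, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate set name: ", nm[duplicated(nm)][1L])
  names(sets) <- nm
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection in GMT format
#' @param sets a \code{gene_set_collection} (or compatible list).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$description, s$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a ranked gene table as a RNK file
#'
#' Two tab-separated columns (gene symbol, median correlation), sorted
#' descending by value, full float precision — the preranked input format of
#' gene-set enrichment tools.
#'
#' @param table a ranked gene table from [rank_genes()] (needs columns
#'   \code{gene} and \code{median_r}).
#' @param path output path.
#' @export
write_rnk <- function(table, path) {
  stopifnot(all(c("gene", "median_r") %in% names(table)))
  keep <- !is.na(table$median_r)
  tab <- table[keep, , drop = FALSE]
  ord <- order(-tab$median_r, tab$gene)
  writeLines(paste(tab$gene[ord], sprintf("%.17g", tab$median_r[ord]),
                   sep = "\t"), path)
  invisible(path)
}

#' Read a RNK file into a ranked list
#' @param path RNK path (gene, score per line, tab-separated).
#' @return data.frame with columns \code{gene}, \code{score}, sorted
#'   descending by score.
#' @export
read_rnk <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) stop(sprintf("RNK line %d does not have 2 fields", bad[1L]))
  genes <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(genes)) stop("duplicate gene in RNK: ",
                                 genes[duplicated(genes)][1L])
  score <- .parse_num(vapply(parts, `[[`, "", 2L), 1L, path)
  ord <- order(-score, genes)
  data.frame(gene = genes[ord], score = score[ord], stringsAsFactors = FALSE)
}

#' Read a gene list (one symbol per line)
#'
#' \code{#} starts a comment; blank lines ignored; order preserved;
#' duplicates are an error. Used for curated panels such as the 40-gene
#' immune-checkpoint candidate panel shipped in \code{inst/extdata}.
#'
#' @param path file path.
#' @return character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  dup <- lines[duplicated(lines)]
  if (length(dup)) stop("duplicate gene symbol in list: ", dup[1L])
  lines
}

#' Read/write a responder cohort table
#'
#' Tab-separated with header \code{sample_id}, \code{response}
#' (\code{responder}|\code{nonresponder}), \code{CD3E_TPM}, \code{PDCD1_TPM}.
#'
#' @param path file path.
#' @return data.frame of class \code{"responder_cohort"}.
#' @export
read_responder_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "response", "CD3E_TPM", "PDCD1_TPM")
  if (!all(need %in% names(df)))
    stop("responder table needs columns: ", paste(need, collapse = ", "))
  if (!all(df$response %in% c("responder", "nonresponder")))
    stop("response labels must be 'responder' or 'nonresponder'")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id")
  if (any(df$CD3E_TPM < 0, na.rm = TRUE) || any(df$PDCD1_TPM < 0, na.rm = TRUE))
    stop("TPM values must be >= 0")
  class(df) <- c("responder_cohort", "data.frame")
  df
}

#' @rdname read_responder_tsv
#' @param cohort a responder cohort data.frame.
#' @export
write_responder_tsv <- function(cohort, path) {
  lines <- c("sample_id\tresponse\tCD3E_TPM\tPDCD1_TPM",
             sprintf("%s\t%s\t%.17g\t%.17g", cohort$sample_id,
                     cohort$response, cohort$CD3E_TPM, cohort$PDCD1_TPM))
  writeLines(lines, path)
  invisible(path)
}

# shared table writer: header + rows, 6 significant digits for numerics
.write_table_tsv <- function(df, path) {
  fmt_col <- function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "NA", sprintf("%.6g", x))
    else as.character(x)
  }
  cells <- vapply(df, fmt_col, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  lines <- c(paste(names(df), collapse = "\t"),
             apply(cells, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}
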