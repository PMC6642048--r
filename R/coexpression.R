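#' Pairwise-complete Pearson correlation
#'
#' Product-moment correlation restricted to indices where both vectors are
#' non-missing, the convention used throughout the package for expression
#' matrices with unassayed cells. Returns \code{NA} when fewer than two
#' complete pairs remain or either restricted vector has zero variance.
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation in [-1, 1], or \code{NA}.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  xs <- x[ok]; ys <- y[ok]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
  stats::cor(xs, ys)
}

#' Correlate every gene with a marker gene across cancer-type cohorts
#'
#' For each non-excluded cohort, computes the pairwise-complete Pearson
#' correlation of every gene in the universe with the marker gene (the pan
#' T-cell marker CD3E in the reference analysis; PDCD1 or CTLA4 when
#' building checkpoint profiles). Cells supported by fewer than
#' \code{min_samples} complete pairs are set missing rather than reported as
#' unstable estimates; genes absent from a cohort are missing there
#' ("not assayed") and computed everywhere else. Signed correlations are
#' stored — absolute values enter only the complementarity scores.
#'
#' @param cohorts named list of [expression_cohort()] matrices.
#' @param marker marker gene symbol; must be present in every non-excluded
#'   cohort.
#' @param gene_universe genes to profile; default: union of all cohort genes.
#' @param min_samples minimum complete pairs per cell (default 10).
#' @param excluded_types cohort labels dropped before any computation (the
#'   reference analysis drops thymoma, whose tumors alter T-cell composition).
#' @return object of class \code{"correlation_profile"}: list with
#'   \code{marker}, \code{r} (gene x type matrix), \code{n_used}
#'   (complete-pair counts).
#' @export
marker_correlation_profile <- function(cohorts, marker,
                                       gene_universe = NULL,
                                       min_samples = 10L,
                                       excluded_types = character(0)) {
  stopifnot(is.list(cohorts), length(cohorts) > 0L)
  if (is.null(names(cohorts)) || anyDuplicated(names(cohorts)))
    stop("cohorts must be uniquely named by cancer type")
  keep <- setdiff(names(cohorts), excluded_types)
  if (!length(keep)) stop("all cohorts excluded")
  cohorts <- cohorts[keep]
  if (is.null(gene_universe))
    gene_universe <- unique(unlist(lapply(cohorts, rownames)))
  if (!length(gene_universe)) stop("empty gene universe")
  r <- matrix(NA_real_, nrow = length(gene_universe), ncol = length(cohorts),
              dimnames = list(gene_universe, names(cohorts)))
  n_used <- matrix(0L, nrow = nrow(r), ncol = ncol(r), dimnames = dimnames(r))
  for (ty in names(cohorts)) {
    mat <- cohorts[[ty]]
    if (!marker %in% rownames(mat))
      stop("marker '", marker, "' absent from cohort '", ty, "'")
    m <- mat[marker, ]
    genes <- intersect(gene_universe, rownames(mat))
    sub <- mat[genes, , drop = FALSE]
    cnt <- as.integer(rowSums(!is.na(sub) & rep(!is.na(m), each = nrow(sub))))
    rr <- suppressWarnings(
      stats::cor(t(sub), m, use = "pairwise.complete.obs")[, 1L])
    rr[cnt < max(2L, min_samples)] <- NA_real_
    r[genes, ty] <- rr
    n_used[genes, ty] <- cnt
  }
  structure(list(marker = marker, r = r, n_used = n_used),
            class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat(sprintf("correlation profile vs %s: %d genes x %d cancer types (%d missing cells)\n",
              x$marker, nrow(x$r), ncol(x$r), sum(is.na(x$r))))
  med <- median_across_types(x)
  top <- utils::head(sort(med, decreasing = TRUE), 5L)
  cat("top genes by median correlation:\n")
  for (g in names(top)) cat(sprintf("  %-10s %.3f\n", g, top[g]))
  invisible(x)
}

#' Median correlation across cancer types
#'
#' Per-gene median over the non-missing per-type correlations; an even count
#' of types takes the mean of the two central values; a gene with no
#' non-missing cell is \code{NA}.
#'
#' @param profile a \code{correlation_profile} (or a gene x type matrix).
#' @return named numeric vector of medians.
#' @export
median_across_types <- function(profile) {
  r <- if (inherits(profile, "correlation_profile")) profile$r else profile
  stopifnot(is.matrix(r))
  apply(r, 1L, function(v) if (all(is.na(v))) NA_real_ else
    stats::median(v, na.rm = TRUE))
}

#' Rank genes by median marker correlation
#'
#' Descending order, rank 1 = largest median; ties broken by ascending gene
#' symbol; genes with missing medians are placed last with missing rank.
#'
#' @param medians named numeric vector (gene -> median correlation), or a
#'   \code{correlation_profile}.
#' @return data.frame of class \code{"ranked_gene_table"} with columns
#'   \code{gene}, \code{median_r}, \code{rank}.
#' @export
rank_genes <- function(medians) {
  if (inherits(medians, "correlation_profile"))
    medians <- median_across_types(medians)
  stopifnot(is.numeric(medians), !is.null(names(medians)))
  if (all(is.na(medians))) stop("no non-missing medians to rank")
  ord <- order(is.na(medians), -ifelse(is.na(medians), -Inf, medians),
               names(medians))
  out <- data.frame(gene = names(medians)[ord], median_r = medians[ord],
                    rank = NA_integer_, stringsAsFactors = FALSE,
                    row.names = NULL)
  n_ok <- sum(!is.na(medians))
  out$rank[seq_len(n_ok)] <- seq_len(n_ok)
  class(out) <- c("ranked_gene_table", "data.frame")
  out
}

#' @export
print.ranked_gene_table <- function(x, n = 10L, ...) {
  cat(sprintf("ranked gene table: %d genes (marker correlation medians)\n",
              nrow(x)))
  print.data.frame(utils::head(x, n), digits = 3)
  if (nrow(x) > n) cat("...", nrow(x) - n, "more rows\n")
  invisible(x)
}
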