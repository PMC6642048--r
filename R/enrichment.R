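#' Weighted running-sum enrichment score
#'
#' Walks the ranked gene list from top to bottom. At a gene inside the set
#' ("hit") the running sum rises by \eqn{|s_i|^p / \sum_{hits} |s_j|^p}; at a
#' miss it falls by \eqn{1/(N - N_{hits})}. The enrichment score (ES) is the
#' signed deviation of maximal absolute value, so a set concentrated at the
#' top of the ranking approaches +1 and one concentrated at the bottom
#' approaches -1. \code{weight_exponent = 1} is the classic "weighted"
#' scheme; 0 recovers the unweighted Kolmogorov-Smirnov statistic. Hit
#' increments use \eqn{|s|^p} regardless of the score's sign. A tie between
#' the extreme positive and negative deviations resolves toward the positive
#' side for determinism. If all hit weights are zero the hits fall back to
#' equal weights.
#'
#' @param ranked data.frame with columns \code{gene}, \code{score}, sorted
#'   descending by score (e.g. from [read_rnk()]).
#' @param gene_set character vector of member symbols.
#' @param weight_exponent p >= 0, default 1.
#' @return list with \code{es}, \code{peak} (1-based position of the
#'   extreme), \code{n_hits}, and the \code{running} sum vector.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  stopifnot(is.data.frame(ranked), all(c("gene", "score") %in% names(ranked)),
            weight_exponent >= 0)
  hit <- ranked$gene %in% gene_set
  if (!any(hit))
    stop("gene set has empty intersection with the ranked universe")
  .es_core(ranked$score, hit, weight_exponent, keep_running = TRUE)
}

# running-sum core on a logical hit mask; O(N)
.es_core <- function(scores, hit, p, keep_running = FALSE) {
  n <- length(scores)
  n_hit <- sum(hit)
  if (n_hit == n) stop("gene set covers the entire ranked universe")
  w <- abs(scores[hit])^p
  tot <- sum(w)
  if (tot == 0) { w <- rep(1, n_hit); tot <- n_hit }
  steps <- rep(-1 / (n - n_hit), n)
  steps[hit] <- w / tot
  running <- cumsum(steps)
  i_max <- which.max(running)
  i_min <- which.min(running)
  # ties toward the positive side
  es <- if (running[i_max] >= -running[i_min]) running[i_max] else running[i_min]
  peak <- if (running[i_max] >= -running[i_min]) i_max else i_min
  out <- list(es = es, peak = peak, n_hits = n_hit)
  if (keep_running) out$running <- running
  out
}

#' Gene-permutation null distribution of the enrichment score
#'
#' ES values for uniformly random gene subsets of a given size drawn from
#' the ranked universe — the null of preranked enrichment, which has no
#' phenotype labels to permute.
#'
#' @param ranked ranked list (as in [enrichment_score()]).
#' @param set_size subset size, <= number of ranked genes.
#' @param n_perm number of permutations (>= 1).
#' @param weight_exponent p >= 0.
#' @param seed integer seed; identical seeds give identical samples.
#' @return numeric vector of \code{n_perm} ES values in [-1, 1].
#' @export
permutation_null <- function(ranked, set_size, n_perm = 1000L,
                             weight_exponent = 1, seed = 1L) {
  n <- nrow(ranked)
  stopifnot(n_perm >= 1L, set_size >= 1L, set_size < n)
  set.seed(as.integer(seed))
  vapply(seq_len(n_perm), function(i) {
    hit <- logical(n)
    hit[sample.int(n, set_size)] <- TRUE
    .es_core(ranked$score, hit, weight_exponent)$es
  }, 0)
}

#' Normalize enrichment scores and attach p and FDR q values
#'
#' NES = ES divided by the mean |null ES| of the same sign as the observed
#' ES (ES = 0 gives NES = 0 by convention). The nominal p-value is the
#' fraction of same-sign null ES at least as extreme as the observed ES,
#' floored at 1/(n_perm + 1); a degenerate null with no same-sign values
#' reports that floor and is flagged in the \code{degenerate} column. The
#' FDR q for a set is the ratio of the fraction of pooled null NES at least
#' as extreme to the fraction of observed NES at least as extreme, computed
#' per sign, clamped to [0, 1], and made monotone from the most extreme NES
#' inward.
#'
#' @param observed named numeric vector of observed ES per set.
#' @param nulls named list of null ES vectors, one per set.
#' @param sizes optional named integer vector of set sizes (reported only).
#' @return data.frame of class \code{"gsea_result"} sorted by NES
#'   descending: columns \code{name}, \code{size}, \code{es}, \code{nes},
#'   \code{p}, \code{q}, \code{degenerate}.
#' @export
normalize_and_fdr <- function(observed, nulls, sizes = NULL) {
  stopifnot(length(observed) == length(nulls),
            !is.null(names(observed)), all(names(observed) %in% names(nulls)))
  nm <- names(observed)
  norm_one <- function(es, null) {
    if (es == 0) return(0)
    same <- null[sign(null) == sign(es)]
    if (!length(same)) return(NA_real_)
    es / mean(abs(same))
  }
  nes <- vapply(nm, function(s) norm_one(observed[[s]], nulls[[s]]), 0)
  null_nes <- lapply(nm, function(s) {
    null <- nulls[[s]]
    pos <- null[null >= 0]; neg <- null[null < 0]
    c(if (length(pos) && any(pos > 0)) pos / mean(pos[pos > 0]) else NULL,
      if (length(neg)) neg / mean(-neg) else NULL)
  })
  p <- degenerate <- numeric(length(nm))
  for (i in seq_along(nm)) {
    es <- observed[[i]]; null <- nulls[[nm[i]]]
    n_perm <- length(null)
    same <- null[sign(null) == sign(es) | es == 0]
    if (!length(same)) {
      p[i] <- 1 / (n_perm + 1); degenerate[i] <- 1
    } else {
      p[i] <- max(mean(abs(same) >= abs(es)), 1 / (n_perm + 1))
      degenerate[i] <- 0
    }
  }
  pool <- unlist(null_nes)
  q <- rep(NA_real_, length(nm))
  for (sgn in c(1, -1)) {
    idx <- which(!is.na(nes) & sign(nes) == sgn)
    if (!length(idx)) next
    for (i in idx) {
      frac_null <- if (sgn > 0) mean(pool >= nes[i]) else mean(pool <= nes[i])
      frac_obs <- if (sgn > 0) mean(nes[idx] >= nes[i]) else
        mean(nes[idx] <= nes[i])
      q[i] <- min(1, max(0, frac_null / frac_obs))
    }
    # step-up monotonization: each q is the minimum of its own ratio and the
    # ratios at all less extreme thresholds
    ord <- idx[order(abs(nes[idx]))]
    q[ord] <- cummin(q[ord])
  }
  q[!is.na(nes) & nes == 0] <- 1
  out <- data.frame(name = nm,
                    size = if (is.null(sizes)) NA_integer_ else
                      as.integer(sizes[nm]),
                    es = as.numeric(observed), nes = nes, p = p,
                    q = q, degenerate = as.logical(degenerate),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$nes, out$name), ]
  rownames(out) <- NULL
  class(out) <- c("gsea_result", "data.frame")
  out
}

#' Preranked gene-set enrichment analysis
#'
#' End-to-end preranked enrichment: restrict each set to the ranked
#' universe, drop sets outside [\code{min_size}, \code{max_size}], compute
#' the weighted running-sum ES, build a gene-permutation null per set size
#' (shared across sets of equal size), and report NES, nominal p, and FDR q,
#' sorted by NES descending. Deterministic under a fixed seed and invariant
#' to the order of sets in the GMT file.
#'
#' @param rnk a RNK path or a ranked data.frame (\code{gene}, \code{score}).
#' @param gmt a GMT path or a \code{gene_set_collection}.
#' @param n_perm permutations per set size (default 1000).
#' @param weight_exponent p, default 1 (the "weighted" scheme).
#' @param seed integer seed.
#' @param min_size,max_size set-size bounds after universe restriction.
#' @return a \code{"gsea_result"} data.frame (see [normalize_and_fdr()]).
#' @export
preranked_gsea <- function(rnk, gmt, n_perm = 1000L, weight_exponent = 1,
                           seed = 1L, min_size = 2L, max_size = 500L) {
  ranked <- if (is.character(rnk)) read_rnk(rnk) else rnk
  sets <- if (is.character(gmt)) read_gmt(gmt) else gmt
  stopifnot(is.data.frame(ranked), nrow(ranked) >= 2L)
  members <- lapply(sets, function(s) intersect(s$genes, ranked$gene))
  sz <- lengths(members)
  keep <- sz >= min_size & sz <= max_size & sz < nrow(ranked)
  if (sum(!keep))
    message(sum(!keep), " gene set(s) outside size bounds dropped")
  if (!any(keep)) stop("no gene sets survive size restriction")
  members <- members[keep]; sz <- sz[keep]
  # process sets in name order so GMT line order cannot matter
  ord <- order(names(members))
  members <- members[ord]; sz <- sz[ord]
  observed <- vapply(members, function(g)
    enrichment_score(ranked, g, weight_exponent)$es, 0)
  nulls_by_size <- lapply(sort(unique(sz)), function(k)
    permutation_null(ranked, k, n_perm, weight_exponent,
                     seed = as.integer(seed) + k))
  names(nulls_by_size) <- as.character(sort(unique(sz)))
  nulls <- lapply(as.character(sz), function(k) nulls_by_size[[k]])
  names(nulls) <- names(members)
  normalize_and_fdr(observed, nulls, sizes = stats::setNames(sz, names(members)))
}

#' @export
print.gsea_result <- function(x, n = 10L, ...) {
  cat(sprintf("preranked enrichment: %d gene sets (NES descending)\n", nrow(x)))
  print.data.frame(utils::head(x, n), digits = 3)
  if (nrow(x) > n) cat("...", nrow(x) - n, "more rows\n")
  invisible(x)
}
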