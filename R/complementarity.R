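#' PDCD1 complementarity score
#'
#' Scores a candidate target for complementarity to PD-1 blockade:
#' \deqn{|\rho_{TC}| (|\rho_{TC}| - |\rho_{TP}|)}
#' where \eqn{\rho_{TC}} is the target's correlation with the T-cell marker
#' and \eqn{\rho_{TP}} its correlation with PDCD1. High when the gene tracks
#' T-cell abundance but not PD-1 expression. Vectorized; missing inputs give
#' missing scores.
#'
#' @param rho_tc,rho_tp correlations in [-1, 1].
#' @return score in [-1, 1].
#' @export
pdcd1_complementarity <- function(rho_tc, rho_tp) {
  .check_rho(rho_tc, "rho_tc"); .check_rho(rho_tp, "rho_tp")
  abs(rho_tc) * (abs(rho_tc) - abs(rho_tp))
}

#' Joint PDCD1/CTLA4 complementarity score
#'
#' Extends the complementarity score to both targeted checkpoints:
#' \deqn{|\rho_{TC}| \min(|\rho_{TC}| - |\rho_{TP}|,\;
#'                        |\rho_{TC}| - |\rho_{TA}|)}
#' with \eqn{\rho_{TA}} the correlation with CTLA4. Reduces to
#' [pdcd1_complementarity()] when \eqn{\rho_{TA} = \rho_{TP}}.
#'
#' @param rho_tc,rho_tp,rho_ta correlations in [-1, 1].
#' @return score in [-1, 1].
#' @export
joint_complementarity <- function(rho_tc, rho_tp, rho_ta) {
  .check_rho(rho_tc, "rho_tc"); .check_rho(rho_tp, "rho_tp")
  .check_rho(rho_ta, "rho_ta")
  abs(rho_tc) * pmin(abs(rho_tc) - abs(rho_tp), abs(rho_tc) - abs(rho_ta))
}

.check_rho <- function(x, what) {
  if (any(abs(x) > 1, na.rm = TRUE))
    stop(what, " outside [-1, 1]")
  invisible(x)
}

#' Complementarity table across cancer types
#'
#' Computes the complementarity score per (gene, cancer type) from the
#' marker and checkpoint correlation profiles, then summarizes each gene by
#' the median of its per-type scores and ranks descending (ties by gene
#' symbol). The median is of per-type scores, not the score of median
#' correlations — the two orders differ. A (gene, type) cell missing in any
#' required profile is excluded from that gene's median rather than
#' zero-filled. The marker's own median correlation rank is reported
#' alongside for dual CS / CD3E-rank reporting.
#'
#' @param profile_tc \code{correlation_profile} vs the T-cell marker.
#' @param profile_tp \code{correlation_profile} vs PDCD1.
#' @param profile_ta \code{correlation_profile} vs CTLA4; required iff
#'   \code{score_kind = "joint"}.
#' @param score_kind \code{"pdcd1"} or \code{"joint"}.
#' @return data.frame of class \code{"complementarity_table"}: columns
#'   \code{gene}, \code{median_score}, \code{score_rank}, \code{median_rho_tc},
#'   \code{rho_tc_rank}, then one \code{score.<type>} column per cancer type.
#' @export
complementarity_table <- function(profile_tc, profile_tp, profile_ta = NULL,
                                  score_kind = c("pdcd1", "joint")) {
  score_kind <- match.arg(score_kind)
  stopifnot(inherits(profile_tc, "correlation_profile"),
            inherits(profile_tp, "correlation_profile"))
  if (score_kind == "joint" && is.null(profile_ta))
    stop("joint score requires a CTLA4 profile")
  profs <- list(profile_tc, profile_tp)
  if (score_kind == "joint") profs <- c(profs, list(profile_ta))
  types <- colnames(profile_tc$r)
  genes <- rownames(profile_tc$r)
  for (p in profs[-1L]) {
    if (!setequal(colnames(p$r), types))
      stop("cancer-type sets differ: ",
           paste(union(setdiff(colnames(p$r), types),
                       setdiff(types, colnames(p$r))), collapse = ", "))
    if (!setequal(rownames(p$r), genes))
      stop("profiles must share a gene universe")
  }
  tc <- profile_tc$r[genes, types, drop = FALSE]
  tp <- profile_tp$r[genes, types, drop = FALSE]
  sc <- if (score_kind == "pdcd1") {
    pdcd1_complementarity(tc, tp)
  } else {
    ta <- profile_ta$r[genes, types, drop = FALSE]
    joint_complementarity(tc, tp, ta)
  }
  med_sc <- apply(sc, 1L, function(v) if (all(is.na(v))) NA_real_ else
    stats::median(v, na.rm = TRUE))
  med_tc <- median_across_types(profile_tc)[genes]
  rk_tc <- rank_genes(med_tc)
  rk_sc <- rank_genes(med_sc)
  out <- data.frame(gene = rk_sc$gene,
                    median_score = rk_sc$median_r,
                    score_rank = rk_sc$rank,
                    median_rho_tc = med_tc[rk_sc$gene],
                    rho_tc_rank = rk_tc$rank[match(rk_sc$gene, rk_tc$gene)],
                    stringsAsFactors = FALSE, row.names = NULL)
  per_type <- as.data.frame(sc[match(out$gene, genes), , drop = FALSE])
  names(per_type) <- paste0("score.", types)
  out <- cbind(out, per_type)
  rownames(out) <- NULL
  attr(out, "score_kind") <- score_kind
  class(out) <- c("complementarity_table", "data.frame")
  out
}

#' @export
print.complementarity_table <- function(x, n = 10L, ...) {
  cat(sprintf("%s complementarity: %d genes, %d cancer types\n",
              attr(x, "score_kind"), nrow(x),
              sum(startsWith(names(x), "score."))))
  print.data.frame(utils::head(x[, 1:5], n), digits = 3)
  if (nrow(x) > n) cat("...", nrow(x) - n, "more rows\n")
  invisible(x)
}

#' Reporting view: records with positive median score
#'
#' Retains genes with median complementarity score strictly above zero,
#' order preserved; the full table remains the table of record.
#'
#' @param records a \code{complementarity_table}.
#' @return subset with the same class and column layout.
#' @export
filter_positive_scores <- function(records) {
  stopifnot(is.data.frame(records), "median_score" %in% names(records))
  out <- records[!is.na(records$median_score) & records$median_score > 0, ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}
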