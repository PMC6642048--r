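#' Simulation configuration for multi-cancer-type expression cohorts
#'
#' Defines a linear-Gaussian latent-factor model of bulk tumor expression.
#' Each sample i in a cohort carries two independent standard-normal latent
#' variables: a T-cell infiltration level f_i and a PD-1-axis level g_i.
#' Gene g's expression is
#' \deqn{x_{gi} = \lambda_g f_i + \kappa_g g_i + \epsilon_{gi}, \quad
#'       \epsilon_{gi} \sim N(0, \sigma_g^2).}
#' The designated marker gene (the CD3E stand-in) is the noiseless
#' infiltration factor itself (\eqn{\lambda = 1, \kappa = 0, \sigma = 0}), so
#' the population correlation of any gene with the marker has the closed form
#' \eqn{\lambda_g / \sqrt{\lambda_g^2 + \kappa_g^2 + \sigma_g^2}} — the
#' recovery target for every downstream correlation estimate.
#'
#' @param gene_specs data.frame with columns \code{gene} (unique symbols),
#'   \code{lambda} (T-cell axis loading), \code{kappa} (PD-1 axis loading),
#'   \code{sigma} (noise sd, must be >= 0).
#' @param marker gene symbol designated as the infiltration marker; its row
#'   must have \code{lambda = 1, kappa = 0, sigma = 0}.
#' @param n_cancer_types number of cohorts to simulate.
#' @param n_samples_per_type samples per cohort.
#' @param missing_rate proportion of cells set missing completely at random
#'   (exercises the pairwise-complete correlation path). Default 0.
#' @param seed master integer seed; per-type seeds are derived from it.
#' @return object of class \code{"sim_config"}.
#' @seealso [simulate_pan_cancer()], [default_gene_specs()]
#' @export
simulation_config <- function(gene_specs, marker,
                              n_cancer_types = 31L,
                              n_samples_per_type = 310L,
                              missing_rate = 0,
                              seed = 1L) {
  stopifnot(is.data.frame(gene_specs),
            all(c("gene", "lambda", "kappa", "sigma") %in% names(gene_specs)))
  if (anyDuplicated(gene_specs$gene))
    stop("duplicate gene symbols in gene_specs")
  if (any(gene_specs$sigma < 0)) stop("all sigma must be >= 0")
  if (!is.character(marker) || length(marker) != 1L || !marker %in% gene_specs$gene)
    stop("marker must name exactly one gene in gene_specs")
  m <- gene_specs[gene_specs$gene == marker, ]
  if (m$lambda != 1 || m$kappa != 0 || m$sigma != 0)
    stop("marker gene must have lambda = 1, kappa = 0, sigma = 0")
  if (n_cancer_types < 1L) stop("n_cancer_types must be positive")
  if (n_samples_per_type < 1L) stop("n_samples_per_type must be positive")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  structure(list(gene_specs = gene_specs, marker = marker,
                 n_cancer_types = as.integer(n_cancer_types),
                 n_samples_per_type = as.integer(n_samples_per_type),
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default gene specifications emulating a pan-cancer immune panel
#'
#' Builds a deterministic spec table: the CD3E marker; PDCD1 and CTLA4
#' stand-ins loaded on both latent axes with loadings solved from the
#' closed-form factor-model correlation so their population marker
#' correlations sit near 0.81 and 0.73 respectively; a ladder of T-cell
#' genes (CD2 at the top) with marker correlations spread over roughly
#' 0.3-0.95; and unrelated null genes.
#'
#' @param n_tcell number of T-cell-axis genes besides the marker and the two
#'   checkpoint stand-ins.
#' @param n_null number of genes with no loading on either axis.
#' @return data.frame usable as \code{gene_specs} in [simulation_config()].
#' @export
default_gene_specs <- function(n_tcell = 40L, n_null = 60L) {
  stopifnot(n_tcell >= 1L, n_null >= 0L)
  # evenly spaced target marker correlations, highest first (CD2-like at .955)
  rho <- seq(0.955, 0.30, length.out = n_tcell)
  # marker corr rho = lambda/sqrt(lambda^2+sigma^2) with kappa = 0:
  # fix lambda = 0.9 and solve sigma
  lam <- rep(0.9, n_tcell)
  sig <- lam * sqrt(1 / rho^2 - 1)
  tcell <- data.frame(
    gene   = c("CD2", sprintf("TC%03d", seq_len(n_tcell - 1L))),
    lambda = lam, kappa = 0, sigma = sig,
    stringsAsFactors = FALSE)
  nulls <- if (n_null > 0L)
    data.frame(gene = sprintf("NULL%03d", seq_len(n_null)),
               lambda = 0, kappa = 0, sigma = 1, stringsAsFactors = FALSE)
  else NULL
  rbind(
    data.frame(gene = "CD3E", lambda = 1, kappa = 0, sigma = 0,
               stringsAsFactors = FALSE),
    # corr(PDCD1, CD3E) = .80/sqrt(.80^2+.45^2+.35^2) ~ 0.814
    data.frame(gene = "PDCD1", lambda = 0.80, kappa = 0.45, sigma = 0.35,
               stringsAsFactors = FALSE),
    # corr(CTLA4, CD3E) = .71/sqrt(.71^2+.42^2+.52^2) ~ 0.728
    data.frame(gene = "CTLA4", lambda = 0.71, kappa = 0.42, sigma = 0.52,
               stringsAsFactors = FALSE),
    tcell, nulls)
}

#' Simulate one cancer-type cohort
#'
#' Draws the latent factors and per-gene noise for a single cohort under the
#' factor model described in [simulation_config()].
#'
#' @param config a \code{sim_config}.
#' @param type_label cohort label (e.g. a TCGA-style cancer-type code).
#' @param seed integer seed for this cohort.
#' @return numeric genes x samples matrix of class \code{"expression_cohort"}
#'   with a \code{cancer_type} attribute; missing cells are \code{NA}.
#' @export
simulate_cancer_cohort <- function(config, type_label, seed) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples_per_type
  if (n < 1L) stop("non-positive sample count")
  gs <- config$gene_specs
  set.seed(as.integer(seed))
  f <- stats::rnorm(n)
  g <- stats::rnorm(n)
  eps <- matrix(stats::rnorm(nrow(gs) * n), nrow = nrow(gs)) * gs$sigma
  x <- outer(gs$lambda, f) + outer(gs$kappa, g) + eps
  if (config$missing_rate > 0) {
    drop <- stats::runif(length(x)) < config$missing_rate
    x[drop] <- NA_real_
  }
  dimnames(x) <- list(gs$gene, sprintf("%s_S%04d", type_label, seq_len(n)))
  expression_cohort(x, cancer_type = type_label)
}

#' Simulate a pan-cancer collection of cohorts
#'
#' One cohort per cancer type. Per-type seeds are derived deterministically
#' from the master seed as \code{seed + rank of the label among sorted
#' labels}, so results do not depend on the order in which labels are given.
#'
#' @param config a \code{sim_config}.
#' @param type_labels optional character vector of distinct cohort labels;
#'   defaults to \code{C01, C02, ...}.
#' @return named list of \code{expression_cohort} matrices.
#' @export
simulate_pan_cancer <- function(config, type_labels = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(type_labels))
    type_labels <- sprintf("C%02d", seq_len(config$n_cancer_types))
  if (anyDuplicated(type_labels)) stop("duplicate cancer-type labels")
  if (length(type_labels) != config$n_cancer_types)
    stop("type_labels length must equal n_cancer_types")
  idx <- match(type_labels, sort(type_labels))
  out <- lapply(seq_along(type_labels), function(i)
    simulate_cancer_cohort(config, type_labels[i], config$seed + idx[i]))
  names(out) <- type_labels
  out
}

#' Responder-cohort simulation configuration
#'
#' Emulates a checkpoint-therapy cohort in which PDCD1 expression is linearly
#' coupled to CD3E expression, with tighter coupling (smaller residual sd) in
#' responders than non-responders, plus an optional very-high-expression
#' outlier responder. CD3E values are drawn log-normal so TPM-like positivity
#' holds; PDCD1 is clamped at zero.
#'
#' @param n_responders,n_nonresponders group sizes (defaults 14 and 12).
#' @param slope,intercept coefficients of the PDCD1-on-CD3E coupling.
#' @param responder_sd,nonresponder_sd residual standard deviations; the
#'   default preset keeps \code{responder_sd <= nonresponder_sd}.
#' @param include_outlier add one responder with CD3E and PDCD1 at 5x the
#'   cohort maximum (replacing an ordinary responder, keeping group sizes).
#' @param cd3e_meanlog,cd3e_sdlog log-normal parameters of the CD3E draws.
#' @param seed integer seed.
#' @return object of class \code{"responder_sim_config"}.
#' @export
responder_sim_config <- function(n_responders = 14L, n_nonresponders = 12L,
                                 slope = 0.5, intercept = 1,
                                 responder_sd = 1.5, nonresponder_sd = 20,
                                 include_outlier = TRUE,
                                 cd3e_meanlog = 3, cd3e_sdlog = 1,
                                 seed = 1L) {
  if (n_responders < 1L || n_nonresponders < 1L)
    stop("cohort sizes must be positive")
  if (responder_sd < 0 || nonresponder_sd < 0) stop("sds must be >= 0")
  structure(list(n_responders = as.integer(n_responders),
                 n_nonresponders = as.integer(n_nonresponders),
                 slope = slope, intercept = intercept,
                 responder_sd = responder_sd,
                 nonresponder_sd = nonresponder_sd,
                 include_outlier = isTRUE(include_outlier),
                 cd3e_meanlog = cd3e_meanlog, cd3e_sdlog = cd3e_sdlog,
                 seed = as.integer(seed)),
            class = "responder_sim_config")
}

#' Simulate a responder/non-responder expression cohort
#'
#' @param config a \code{responder_sim_config}.
#' @return data.frame of class \code{"responder_cohort"} with columns
#'   \code{sample_id}, \code{response} (\code{responder}|\code{nonresponder}),
#'   \code{CD3E_TPM}, \code{PDCD1_TPM}. When an outlier is planted its sample
#'   id is recorded in the \code{outlier_id} attribute.
#' @export
simulate_responder_cohort <- function(config) {
  stopifnot(inherits(config, "responder_sim_config"))
  set.seed(config$seed)
  n_r <- config$n_responders
  n_n <- config$n_nonresponders
  n <- n_r + n_n
  cd3e <- stats::rlnorm(n, config$cd3e_meanlog, config$cd3e_sdlog)
  sds <- c(rep(config$responder_sd, n_r), rep(config$nonresponder_sd, n_n))
  pdcd1 <- pmax(0, config$intercept + config$slope * cd3e + stats::rnorm(n, 0, sds))
  out <- data.frame(
    sample_id = sprintf("P%02d", seq_len(n)),
    response = rep(c("responder", "nonresponder"), c(n_r, n_n)),
    CD3E_TPM = cd3e, PDCD1_TPM = pdcd1,
    stringsAsFactors = FALSE)
  if (config$include_outlier) {
    out$CD3E_TPM[n_r] <- 5 * max(out$CD3E_TPM)
    out$PDCD1_TPM[n_r] <- 5 * max(out$PDCD1_TPM)
    attr(out, "outlier_id") <- out$sample_id[n_r]
  }
  class(out) <- c("responder_cohort", "data.frame")
  out
}

#' Z-score normalize an expression cohort gene-wise
#'
#' Standardizes each gene to mean 0 and sample sd 1 over its non-missing
#' entries, mirroring the per-gene z-score form in which public pan-cancer
#' expression matrices are distributed. Genes with fewer than two non-missing
#' finite values or zero variance cannot be standardized; they are emitted as
#' all-missing with a warning. Pearson correlations are invariant to this
#' per-gene affine rescaling.
#'
#' @param mat an \code{expression_cohort} (or plain genes x samples matrix).
#' @return matrix of the same shape and class.
#' @export
zscore_normalize <- function(mat) {
  stopifnot(is.matrix(mat))
  out <- mat
  bad <- character(0)
  for (i in seq_len(nrow(mat))) {
    v <- mat[i, ]
    ok <- is.finite(v)
    if (sum(ok) < 2L || stats::sd(v[ok]) == 0) {
      out[i, ] <- NA_real_
      bad <- c(bad, rownames(mat)[i])
    } else {
      out[i, ok] <- (v[ok] - mean(v[ok])) / stats::sd(v[ok])
    }
  }
  if (length(bad))
    warning("genes with <2 values or zero variance set to missing: ",
            paste(bad, collapse = ", "))
  out
}
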