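#' Build the TE assembly-success design
#'
#' One row per assessed TE copy: binary perfect-assembly outcome, copy
#' length, GC content of the copy plus 1 kbp of flanking sequence on each
#' side (truncated at scaffold ends), divergence from the family canonical
#' sequence, the number of high-identity copies in the family (divergence
#' strictly below `high_identity_div`), and the family label. All predictors
#' are standardized to zero mean and unit variance; the
#' divergence-by-high-copies interaction is the product of the two
#' standardized columns (not itself re-standardized).
#'
#' @param assessments Per-feature assessment table (see [assess_all()]);
#'   only TE rows are used.
#' @param genome A `genome_bundle` providing TE metadata and sequences.
#' @param flank Flanking context for the GC predictor (default 1000).
#' @param high_identity_div Divergence threshold below which a copy counts
#'   as high-identity (default 0.01, strict inequality).
#' @return A `te_glmm_data` data frame with raw predictors, standardized
#'   `z_*` columns and the `z_interaction` column; copies lacking divergence
#'   are dropped and counted in the `dropped` attribute.
#' @export
build_design <- function(assessments, genome, flank = 1000L,
                         high_identity_div = 0.01) {
  tes <- genome$tes
  a <- assessments[assessments$feature_type == "TE", , drop = FALSE]
  m <- merge(a, tes, by = "feature_id")
  dropped <- sum(is.na(m$divergence))
  m <- m[!is.na(m$divergence), , drop = FALSE]
  high <- tapply(m$divergence < high_identity_div, m$family, sum)
  slens <- stats::setNames(Biostrings::width(genome$seqs), names(genome$seqs))
  gc_flank <- vapply(seq_len(nrow(m)), function(i) {
    s <- max(0L, m$start[i] - flank)
    e <- min(slens[[m$ref_id[i]]], m$end[i] + flank)
    v <- Biostrings::Views(genome$seqs[[m$ref_id[i]]], s + 1L, e)
    Biostrings::letterFrequency(v, "GC", as.prob = TRUE)[1, 1]
  }, 0)
  out <- data.frame(
    feature_id = m$feature_id,
    y = as.integer(m$perfect),
    length = m$end - m$start,
    gc_flank = gc_flank,
    divergence = m$divergence,
    high_copies = as.integer(high[m$family]),
    family = m$family,
    stringsAsFactors = FALSE
  )
  std <- function(x, name) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop(sprintf("cannot standardize zero-variance predictor '%s'", name))
    }
    (x - mean(x)) / s
  }
  out$z_length <- std(out$length, "length")
  out$z_gc_flank <- std(out$gc_flank, "gc_flank")
  out$z_divergence <- std(out$divergence, "divergence")
  out$z_high_copies <- std(out$high_copies, "high_copies")
  out$z_interaction <- out$z_divergence * out$z_high_copies
  attr(out, "dropped") <- dropped
  class(out) <- c("te_glmm_data", "data.frame")
  out
}

# log(1 + exp(x)) without overflow for large x
log1pexp <- function(x) {
  out <- x
  small <- x <= 30
  out[small] <- log1p(exp(x[small]))
  out[!small] <- x[!small] + exp(-x[!small])
  out
}

# Laplace-approximate marginal log-likelihood of the random-intercept
# logistic model. theta = c(beta, log_sigma); X includes the intercept.
glmm_loglik <- function(theta, X, y, fam_idx, n_fam) {
  k <- ncol(X)
  beta <- theta[seq_len(k)]
  sigma <- exp(theta[k + 1L])
  eta0 <- drop(X %*% beta)
  u <- numeric(n_fam)
  inv_s2 <- 1 / sigma^2
  for (iter in seq_len(100L)) {
    eta <- eta0 + u[fam_idx]
    p <- stats::plogis(eta)
    grad <- rowsum(y - p, fam_idx, reorder = TRUE)[, 1] - u * inv_s2
    W <- rowsum(p * (1 - p), fam_idx, reorder = TRUE)[, 1]
    step <- grad / (W + inv_s2)
    u <- u + step
    if (max(abs(grad)) < 1e-10) break
  }
  eta <- eta0 + u[fam_idx]
  p <- stats::plogis(eta)
  W <- rowsum(p * (1 - p), fam_idx, reorder = TRUE)[, 1]
  ll_cond <- sum(y * eta - log1pexp(eta))
  sum_pen <- sum(u^2) * inv_s2 / 2
  ll_cond - sum_pen - 0.5 * sum(log1p(sigma^2 * W))
}

#' Fit the random-intercept logistic model of TE assembly success
#'
#' Maximizes the Laplace-approximate marginal likelihood of a logistic
#' regression with a per-family random intercept: fixed effects are the
#' standardized copy length, flank GC, divergence, number of high-identity
#' family copies, and the divergence-by-high-copies interaction. Family
#' intercepts are integrated out by a Laplace approximation (exact inner
#' Newton optimization per family); fixed starting values (beta = 0,
#' sigma = 1) and a gradient tolerance of 1e-8 make the fit deterministic.
#' Wald standard errors come from the observed information of the marginal
#' log-likelihood.
#'
#' @param data A `te_glmm_data` from [build_design()], or any data frame
#'   with `y`, `family` and the `z_*` predictor columns.
#' @param predictors Character vector of predictor column names.
#' @return A `te_glmm_fit` list: `beta`, `se`, `z`, `p`, `sigma_family`,
#'   `loglik`, `converged`, `n`, `n_families`.
#' @export
fit_glmm <- function(data,
                     predictors = c("z_length", "z_gc_flank", "z_divergence",
                                    "z_high_copies", "z_interaction")) {
  stopifnot(all(c("y", "family", predictors) %in% names(data)))
  fam <- factor(data$family)
  if (nlevels(fam) < 2L) stop("need at least 2 families")
  y <- as.numeric(data$y)
  if (length(unique(y)) < 2L) stop("outcome is constant")
  X <- cbind(`(Intercept)` = 1, as.matrix(data[predictors]))
  fam_idx <- as.integer(fam)
  n_fam <- nlevels(fam)
  k <- ncol(X)

  nll <- function(theta) -glmm_loglik(theta, X, y, fam_idx, n_fam)
  start <- c(rep(0, k), 0)  # beta = 0, log(sigma) = 0 i.e. sigma = 1
  fit <- stats::nlminb(start, nll,
                       lower = c(rep(-Inf, k), -10), upper = c(rep(Inf, k), 5),
                       control = list(iter.max = 1000, eval.max = 2000,
                                      rel.tol = 1e-12, x.tol = 1e-12))
  if (!fit$convergence %in% c(0, 1)) {
    stop("GLMM did not converge: ", fit$message)
  }
  theta <- fit$par
  beta <- theta[seq_len(k)]
  names(beta) <- colnames(X)
  if (any(abs(beta) > 15)) {
    stop("complete separation suspected: a coefficient diverged")
  }

  H <- stats::optimHess(theta, nll)
  se_full <- tryCatch({
    V <- solve(H)
    sqrt(pmax(diag(V)[seq_len(k)], 0))
  }, error = function(e) {
    V <- solve(H[seq_len(k), seq_len(k)])
    sqrt(pmax(diag(V), 0))
  })
  se <- stats::setNames(se_full, colnames(X))
  z <- beta / se
  out <- list(
    beta = beta, se = se, z = z,
    p = 2 * stats::pnorm(-abs(z)),
    sigma_family = exp(theta[k + 1L]),
    loglik = -fit$objective,
    converged = TRUE,
    n = length(y),
    n_families = n_fam,
    predictors = predictors
  )
  class(out) <- "te_glmm_fit"
  out
}

#' @export
print.te_glmm_fit <- function(x, ...) {
  cat(sprintf("Random-intercept logistic fit: %d copies, %d families\n",
              x$n, x$n_families))
  tab <- data.frame(estimate = x$beta, se = x$se, z = x$z, p = x$p)
  print(round(tab, 4))
  cat(sprintf("family random-intercept SD: %.4f; log-likelihood: %.3f\n",
              x$sigma_family, x$loglik))
  invisible(x)
}

#' Predicted probability curves from a fitted TE model
#'
#' Predicted perfect-assembly probability along a grid of one standardized
#' covariate, with the other covariates at 0 (their mean) and the random
#' intercept at 0. When the gridded covariate enters the
#' divergence-by-high-copies interaction, one curve is produced per
#' reference value of the partner covariate (`conditions`), visualizing how
#' many high-identity family copies modulate the divergence effect.
#'
#' @param fit A `te_glmm_fit`.
#' @param covariate Name of the gridded predictor (a `z_*` column).
#' @param grid Standardized grid values (default -2.5 to 2.5).
#' @param conditions Standardized reference values of the interaction
#'   partner (default low = -1, high = +1); ignored for covariates outside
#'   the interaction.
#' @return Data frame with `covariate`, `value`, `condition`, `prob`.
#' @export
predict_curves <- function(fit, covariate,
                           grid = seq(-2.5, 2.5, length.out = 51),
                           conditions = c(low = -1, high = 1)) {
  all_cov <- names(fit$beta)[-1]
  if (!covariate %in% all_cov) {
    stop("unknown covariate: ", covariate)
  }
  b <- fit$beta
  partner <- switch(covariate,
                    z_divergence = "z_high_copies",
                    z_high_copies = "z_divergence",
                    NULL)
  if (is.null(partner) || !"z_interaction" %in% names(b)) {
    eta <- b["(Intercept)"] + b[covariate] * grid
    return(data.frame(covariate = covariate, value = grid,
                      condition = "all", prob = stats::plogis(unname(eta)),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(names(conditions), function(cn) {
    cv <- conditions[[cn]]
    eta <- b["(Intercept)"] + b[covariate] * grid + b[partner] * cv +
      b["z_interaction"] * grid * cv
    data.frame(covariate = covariate, value = grid, condition = cn,
               prob = stats::plogis(unname(eta)), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
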