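# Shared builders for small deterministic fixtures.

tiny_families <- function() {
  list(
    te_family("famA", canonical_length = 2000, copy_number = 6,
              mean_divergence = 0.02, tandem_fraction = 0.4),
    te_family("famB", canonical_length = 1200, copy_number = 8,
              mean_divergence = 0.10)
  )
}

tiny_genome <- function(seed = 1L, scaffold_length = 2e5, n_scaffolds = 2L,
                        gene_density = 25) {
  generate_genome(n_scaffolds = n_scaffolds,
                  scaffold_length = scaffold_length,
                  families = tiny_families(),
                  gene_density = gene_density,
                  seed = seed)
}

ref_lengths_of <- function(genome) {
  stats::setNames(Biostrings::width(genome$seqs), names(genome$seqs))
}

# random alignment-block sets for property tests
random_blocks <- function(n, contig_len = 1000L, ref_len = 10000L) {
  s <- sample.int(contig_len - 1L, n, replace = TRUE) - 1L
  e <- pmin(contig_len, s + sample.int(200L, n, replace = TRUE))
  rs <- sample.int(ref_len - 300L, n, replace = TRUE) - 1L
  alignment_blocks(
    contig_id = "c1", contig_start = s, contig_end = e,
    ref_id = sample(c("r1", "r2"), n, replace = TRUE),
    ref_start = rs, ref_end = rs + (e - s),
    strand = sample(c("+", "-"), n, replace = TRUE),
    identity = round(stats::runif(n, 0.8, 1), 4)
  )
}

# exhaustive best-subset search over all 2^n block subsets (oracle)
exhaustive_best_score <- function(blocks, tol = 50L) {
  n <- nrow(blocks)
  s <- blocks$contig_start; e <- blocks$contig_end
  w <- blocks$identity * blocks$aligned_length
  compat <- outer(seq_len(n), seq_len(n), function(i, j) {
    pmin(e[i], e[j]) - pmax(s[i], s[j]) <= tol
  })
  diag(compat) <- TRUE  # overlap constraint is pairwise between distinct blocks
  bit <- 2^(seq_len(n) - 1L)
  best <- 0
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, bit) > 0)
    if (all(compat[idx, idx])) best <- max(best, sum(w[idx]))
  }
  best
}

# O(n^2) pairwise transitive-merge oracle for pseudo_assemble
pseudo_assemble_oracle <- function(placements, min_overlap = 800L,
                                   min_len = 1000L) {
  out <- list()
  for (ref in unique(placements$ref_id)) {
    p <- placements[placements$ref_id == ref, , drop = FALSE]
    n <- nrow(p)
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (comp[i] == comp[j]) next
          ov <- min(p$ref_end[i], p$ref_end[j]) -
            max(p$ref_start[i], p$ref_start[j])
          if (ov >= min_overlap) {
            comp[comp == comp[j]] <- comp[i]
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    for (k in unique(comp)) {
      s <- min(p$ref_start[comp == k]); e <- max(p$ref_end[comp == k])
      if (e - s >= min_len) {
        out[[length(out) + 1L]] <- data.frame(
          ref_id = ref, start = s, end = e, length = e - s,
          n_reads = sum(comp == k), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(ref_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      n_reads = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$ref_id, res$start), ]
}

# cumulative-scan N(x) oracle
nx_oracle <- function(lengths, x = 50, genome_size = NULL) {
  lengths <- sort(lengths, decreasing = TRUE)
  target <- (x / 100) * if (is.null(genome_size)) sum(lengths) else genome_size
  acc <- 0
  for (i in seq_along(lengths)) {
    acc <- acc + lengths[i]
    if (acc >= target) return(list(N = lengths[i], L = i, reached = TRUE))
  }
  list(N = 0, L = length(lengths), reached = FALSE)
}

# 51-point adaptive Gauss-Hermite marginal log-likelihood oracle for the
# random-intercept logistic model. Nodes are recentered at each family's
# conditional mode (found with stats::optimize, independent of the package's
# Newton solver) and rescaled by the curvature there; without this adaptation
# the fixed Hermite grid undersamples the sharply peaked integrand once the
# number of observations per family is large.
gh_loglik <- function(beta, sigma, X, y, fam_idx, n_points = 51L) {
  gh <- local({
    # Golub-Welsch via eigen decomposition of the Jacobi matrix
    i <- seq_len(n_points - 1L)
    b <- sqrt(i / 2)
    A <- matrix(0, n_points, n_points)
    A[cbind(i, i + 1L)] <- b
    A[cbind(i + 1L, i)] <- b
    ev <- eigen(A, symmetric = TRUE)
    list(nodes = ev$values, weights = sqrt(pi) * ev$vectors[1, ]^2)
  })
  eta0 <- drop(X %*% beta)
  ll <- 0
  for (g in sort(unique(fam_idx))) {
    rows <- fam_idx == g
    # log integrand: conditional Bernoulli log-likelihood + N(0, sigma^2) prior
    lg <- function(u) {
      eta <- eta0[rows] + u
      sum(y[rows] * eta - ifelse(eta > 30, eta, log1p(exp(eta)))) +
        stats::dnorm(u, 0, sigma, log = TRUE)
    }
    u_hat <- stats::optimize(lg, c(-10 * sigma - 10, 10 * sigma + 10),
                             maximum = TRUE, tol = 1e-12)$maximum
    p_hat <- stats::plogis(eta0[rows] + u_hat)
    scale <- 1 / sqrt(sum(p_hat * (1 - p_hat)) + 1 / sigma^2)
    # integral exp(lg(u)) du via substitution u = u_hat + sqrt(2)*scale*x
    terms <- vapply(seq_along(gh$nodes), function(q) {
      x <- gh$nodes[q]
      log(gh$weights[q]) + x^2 + lg(u_hat + sqrt(2) * scale * x)
    }, 0)
    m <- max(terms)
    ll <- ll + m + log(sum(exp(terms - m))) + log(sqrt(2) * scale)
  }
  ll
}
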