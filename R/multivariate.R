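#' @keywords internal
permutation_result <- function(name, statistic, p, n_perm, seed,
                               R2 = NA_real_) {
  structure(list(statistic_name = name, statistic = statistic, R2 = R2,
                 p_value = p, n_permutations = n_perm, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("%s = %.4f", x$statistic_name, x$statistic))
  if (!is.na(x$R2)) cat(sprintf(", R2 = %.4f", x$R2))
  cat(sprintf(", p = %.4g (%d permutations)\n", x$p_value, x$n_permutations))
  invisible(x)
}

#' All permutations of 1..n
#' @keywords internal
all_permutations <- function(n) {
  if (n > 8) stopf("exhaustive enumeration limited to n <= 8")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Align a predictor vector to distance-matrix ids
#' @keywords internal
align_predictor <- function(predictor, ids) {
  if (!is.null(names(predictor))) {
    miss <- setdiff(ids, names(predictor))
    if (length(miss)) stopf("predictor lacks sample '%s'", miss[1])
    predictor <- predictor[ids]
  } else if (length(predictor) != length(ids)) {
    stopf("predictor length %d does not match %d samples",
          length(predictor), length(ids))
  }
  predictor
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance in the
#' McArdle-Anderson formulation: the squared distance matrix is
#' Gower-centred (`G = -1/2 C D^2 C`) and projected onto the hat matrix of
#' the predictor's design matrix. For a categorical predictor the design is
#' the usual one-way dummy coding; a numeric predictor is fit as the
#' single-term marginal model (intercept + variable). The p-value permutes
#' sample identities (rows/columns of the distance matrix) freely and uses
#' the `(exceedances + 1) / (n_perm + 1)` estimator; with
#' `permutations = "exhaustive"` all `n!` relabellings are enumerated and
#' the p-value is the exact proportion with `F >= F_obs`.
#'
#' @param dm Distance matrix (`dist` or symmetric matrix with ids).
#' @param predictor Categorical labels (character/factor) or a numeric
#'   vector, optionally named by sample id.
#' @param n_perm Number of random permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @param permutations `"random"` or `"exhaustive"` (n <= 8).
#' @return A `"permutation_result"` with the pseudo-F statistic and `R2`.
#' @export
permanova <- function(dm, predictor, n_perm = 999, seed = 1,
                      permutations = c("random", "exhaustive")) {
  permutations <- match.arg(permutations)
  dm <- as_distance_matrix(dm)
  n <- nrow(dm)
  ids <- rownames(dm)
  predictor <- align_predictor(predictor, ids)
  if (anyNA(predictor)) stopf("predictor contains missing values")

  if (is.numeric(predictor)) {
    if (length(unique(predictor)) < 2) stopf("constant predictor")
    X <- cbind(1, predictor)
  } else {
    f <- factor(predictor)
    if (nlevels(f) < 2) stopf("constant predictor")
    X <- stats::model.matrix(~f)
  }
  qrX <- qr(X)
  H <- tcrossprod(qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE])
  df_model <- qrX$rank - 1
  df_resid <- n - qrX$rank
  if (df_resid < 1) stopf("no residual degrees of freedom")

  C <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * C %*% (dm^2) %*% C
  ss_total <- sum(diag(G))
  f_stat <- function(Gp) {
    ssm <- sum(H * Gp)
    ((ssm / df_model) / ((ss_total - ssm) / df_resid))
  }
  ss_model <- sum(H * G)
  R2 <- if (ss_total > 0) ss_model / ss_total else NA_real_
  F_obs <- f_stat(G)

  if (permutations == "exhaustive") {
    perms <- all_permutations(n)
    F_perm <- apply(perms, 1, function(p) f_stat(G[p, p]))
    p_val <- mean(F_perm >= F_obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    F_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      f_stat(G[p, p])
    }, numeric(1)))
    p_val <- (sum(F_perm >= F_obs - 1e-12) + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  out <- permutation_result("pseudo-F", F_obs, p_val, n_used, seed, R2 = R2)
  out$df <- c(model = df_model, residual = df_resid)
  out
}

#' Analysis of similarities (ANOSIM)
#'
#' `R = (mean between-group rank - mean within-group rank) / (n_pairs / 2)`
#' on the ranked dissimilarities (average ranks for ties), with a free
#' permutation test of group labels. Computation is delegated to
#' [vegan::anosim].
#'
#' @param dm Distance matrix.
#' @param groups Group labels (>= 2 groups, each with >= 2 members),
#'   optionally named by sample id.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A `"permutation_result"` with the ANOSIM R statistic.
#' @export
anosim <- function(dm, groups, n_perm = 999, seed = 1) {
  dm <- as_distance_matrix(dm)
  groups <- factor(align_predictor(groups, rownames(dm)))
  if (nlevels(groups) < 2) stopf("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2))
    stopf("singleton group '%s'", names(sizes)[sizes < 2][1])
  fit <- with_seed(seed, vegan::anosim(stats::as.dist(dm), groups,
                                       permutations = n_perm))
  permutation_result("ANOSIM R", unname(fit$statistic), fit$signif,
                     n_perm, seed)
}

#' Mantel test between two distance matrices
#'
#' Correlates the off-diagonal entries of two distance matrices over the
#' same samples (Spearman by default) and assesses significance by
#' permuting one matrix's sample ids. Delegates to [vegan::mantel].
#'
#' @param dm1,dm2 Distance matrices over identical id sets.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A `"permutation_result"` with the Mantel r statistic.
#' @export
mantel <- function(dm1, dm2, method = c("spearman", "pearson"),
                   n_perm = 999, seed = 1) {
  method <- match.arg(method)
  dm1 <- as_distance_matrix(dm1)
  dm2 <- as_distance_matrix(dm2)
  if (!setequal(rownames(dm1), rownames(dm2)))
    stopf("the two matrices cover different samples")
  dm2 <- dm2[rownames(dm1), rownames(dm1)]
  fit <- with_seed(seed, vegan::mantel(stats::as.dist(dm1),
                                       stats::as.dist(dm2),
                                       method = method,
                                       permutations = n_perm))
  permutation_result("Mantel r", unname(fit$statistic), fit$signif,
                     n_perm, seed)
}
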