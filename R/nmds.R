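# Nonmetric multidimensional scaling by iterative majorization.
#
# Minimizes Kruskal stress-1: sqrt(sum (d - dhat)^2 / sum d^2), where d are
# configuration distances and dhat the isotonic (monotone in the
# dissimilarity order) fitted distances. Each iteration alternates a
# monotone regression of d on the dissimilarity ranks (secondary treatment
# of ties: tied dissimilarities share one fitted value) with a Guttman
# transform of the configuration. Iterations stop when the stress decrease
# falls below tol; a step that would increase stress is discarded, so the
# reported stress trace is non-increasing.

# weighted pool-adjacent-violators for isotonic regression
pava <- function(y, w) {
  n <- length(y)
  vals <- numeric(0); wts <- numeric(0); sizes <- integer(0)
  for (i in seq_len(n)) {
    vals <- c(vals, y[i]); wts <- c(wts, w[i]); sizes <- c(sizes, 1L)
    k <- length(vals)
    while (k > 1 && vals[k - 1] > vals[k]) {
      merged_w <- wts[k - 1] + wts[k]
      vals[k - 1] <- (vals[k - 1] * wts[k - 1] + vals[k] * wts[k]) / merged_w
      wts[k - 1] <- merged_w
      sizes[k - 1] <- sizes[k - 1] + sizes[k]
      vals <- vals[-k]; wts <- wts[-k]; sizes <- sizes[-k]
      k <- k - 1
    }
  }
  rep(vals, sizes)
}

# monotone fit of distances d on dissimilarities diss (secondary ties)
monotone_fit <- function(diss, d) {
  groups <- match(diss, sort(unique(diss)))
  means <- tapply(d, groups, mean)
  wts <- tabulate(groups)
  fitted_groups <- pava(as.numeric(means), as.numeric(wts))
  fitted_groups[groups]
}

kruskal_stress <- function(d, dhat) {
  denom <- sum(d^2)
  if (denom == 0) return(0)
  sqrt(sum((d - dhat)^2) / denom)
}

nmds_single <- function(diss_vec, x0, n, k, max_iter, tol) {
  X <- x0
  d <- as.numeric(dist(X))
  dhat <- monotone_fit(diss_vec, d)
  stress <- kruskal_stress(d, dhat)
  trace <- stress
  for (it in seq_len(max_iter)) {
    # Guttman transform with current dhat
    Dm <- matrix(0, n, n); Dm[lower.tri(Dm)] <- d; Dm <- Dm + t(Dm)
    Hm <- matrix(0, n, n); Hm[lower.tri(Hm)] <- dhat; Hm <- Hm + t(Hm)
    B <- matrix(0, n, n)
    nz <- Dm > 0
    B[nz] <- -Hm[nz] / Dm[nz]
    diag(B) <- -rowSums(B)
    Xn <- B %*% X / n
    dn <- as.numeric(dist(Xn))
    dhn <- monotone_fit(diss_vec, dn)
    sn <- kruskal_stress(dn, dhn)
    if (sn > stress + 1e-15) break  # discard the worsening step
    improved <- stress - sn
    X <- Xn; d <- dn; dhat <- dhn; stress <- sn
    trace <- c(trace, stress)
    if (improved < tol) break
  }
  list(points = X, stress = stress, stress_trace = trace)
}

#' Nonmetric multidimensional scaling (Kruskal stress-1)
#'
#' Embeds a dissimilarity matrix in k dimensions by iterative majorization
#' (Guttman transform) alternating with a monotone regression of distances
#' on dissimilarity ranks. The first start is the classical (Torgerson)
#' scaling solution; the remaining restarts are random under the seed. The
#' best configuration (lowest stress) is returned, centred, with its stress
#' trace.
#'
#' @param beta symmetric dissimilarity matrix with zero diagonal, at least
#'   k + 1 samples.
#' @param k embedding dimension (default 2).
#' @param seed integer seed governing restarts and tie breaking.
#' @param n_restarts number of starts (default 10; the first is metric).
#' @param max_iter iteration cap per start (default 500).
#' @param tol convergence threshold on the stress decrease (default 1e-6).
#' @return list of class \code{"nmds_fit"}: \code{points} (n x k matrix),
#'   \code{stress} (Kruskal stress-1 in [0, 1]), \code{stress_trace} of the
#'   winning start.
#' @export
nmds <- function(beta, k = 2, seed = 1L, n_restarts = 10, max_iter = 500,
                 tol = 1e-6) {
  beta <- as.matrix(beta)
  n <- nrow(beta)
  stopifnot(n >= k + 1, isTRUE(all.equal(beta, t(beta))),
            all(diag(beta) == 0))
  diss_vec <- beta[lower.tri(beta)]
  if (all(diss_vec == 0)) {
    pts <- matrix(0, n, k, dimnames = list(rownames(beta), NULL))
    return(structure(list(points = pts, stress = 0, stress_trace = 0),
                     class = "nmds_fit"))
  }
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      x0 <- if (r == 1) {
        cm <- cmdscale(beta, k = k)
        if (ncol(cm) < k) cbind(cm, matrix(rnorm(n * (k - ncol(cm)), 0, 1e-4), n))
        else cm
      } else {
        matrix(rnorm(n * k), n, k)
      }
      fit <- nmds_single(diss_vec, x0, n, k, max_iter, tol)
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
    pts <- scale(best$points, center = TRUE, scale = FALSE)
    attr(pts, "scaled:center") <- NULL
    rownames(pts) <- rownames(beta)
    structure(list(points = pts, stress = best$stress,
                   stress_trace = best$stress_trace),
              class = "nmds_fit")
  })
}
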