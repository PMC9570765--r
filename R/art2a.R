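# column-standardize (dropping zero-variance columns) then L2-normalize rows;
# ART-2a compares patterns by dot product, so rows must be unit vectors
art2a_preprocess <- function(X) {
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  keep <- sdev > 0
  if (!any(keep)) {
    # fully constant design (e.g. identical patterns): fall back to the raw
    # rows so that identical vectors land in one cluster
    Xs <- X
  } else {
    Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sdev[keep], "/")
  }
  norms <- sqrt(rowSums(Xs^2))
  bad <- which(norms == 0)
  if (length(bad)) {
    abort(sprintf("row %d has zero norm after standardization", bad[1]),
          class = "sibcut_error_input")
  }
  Xs / norms
}

#' ART-2a adaptive-resonance clustering
#'
#' Sequential clustering of unit-normalized descriptor rows. Each pattern is
#' compared with every existing cluster centroid by dot product; if the best
#' similarity reaches the vigilance threshold the pattern joins that cluster
#' and the centroid moves toward it (renormalized convex combination),
#' otherwise the pattern founds a new cluster. Presentation order is a
#' seeded random permutation and epochs repeat until assignments stabilize.
#'
#' @param data An encoded dataset tibble from [encode_dataset()], or a
#'   numeric matrix of descriptors.
#' @param vigilance Similarity threshold in (0, 1).
#' @param learning_rate Centroid update weight in (0, 1]; default 0.1.
#' @param max_epochs Maximum presentation sweeps; default 20.
#' @param seed Integer seed for the presentation order.
#' @return An object of class `sibcut_art2a`: `assignment` (integer label
#'   per row, input order), `centroids` (unit-norm rows), `n_clusters`,
#'   `n_multimember`, `vigilance`, `epochs_run`, `converged`.
#' @export
art2a_cluster <- function(data, vigilance, learning_rate = 0.1,
                          max_epochs = 20L, seed = 1L) {
  stopifnot(vigilance > 0, vigilance < 1,
            learning_rate > 0, learning_rate <= 1, max_epochs >= 1)
  X <- if (is.matrix(data)) data else encoded_parts(data)$X
  n <- nrow(X)
  if (n < 1L) abort("empty dataset", class = "sibcut_error_input")
  Xn <- art2a_preprocess(X)
  order_idx <- withr_seed(seed, sample.int(n))
  centroids <- matrix(numeric(0), nrow = 0, ncol = ncol(Xn))
  assignment <- rep(NA_integer_, n)
  epochs <- 0L
  converged <- FALSE
  for (ep in seq_len(max_epochs)) {
    epochs <- ep
    prev <- assignment
    for (i in order_idx) {
      x <- Xn[i, ]
      if (nrow(centroids) > 0) {
        sims <- drop(centroids %*% x)
        best <- which.max(sims)
        if (sims[best] >= vigilance) {
          assignment[i] <- best
          cnew <- (1 - learning_rate) * centroids[best, ] + learning_rate * x
          centroids[best, ] <- cnew / sqrt(sum(cnew^2))
          next
        }
      }
      centroids <- rbind(centroids, x)
      assignment[i] <- nrow(centroids)
    }
    if (identical(prev, assignment)) { converged <- TRUE; break }
  }
  sizes <- tabulate(assignment, nbins = nrow(centroids))
  structure(list(
    assignment = assignment,
    centroids = centroids,
    n_clusters = nrow(centroids),
    n_multimember = sum(sizes >= 2L),
    cluster_sizes = sizes,
    vigilance = vigilance,
    learning_rate = learning_rate,
    epochs_run = epochs,
    converged = converged,
    seed = seed
  ), class = "sibcut_art2a")
}

#' @export
print.sibcut_art2a <- function(x, ...) {
  cat(sprintf(
    "<sibcut_art2a> %d clusters (%d multimember) at vigilance %.4f; %d epochs%s\n",
    x$n_clusters, x$n_multimember, x$vigilance, x$epochs_run,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

# evaluate an expression under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Tune the vigilance parameter to a target multimember-cluster count
#'
#' Bisection on the vigilance in (0, 1): the multimember-cluster count grows
#' with vigilance over the useful range, so the bracket is narrowed until the
#' requested count is hit or the bracket width falls below 1e-4. Returns the
#' closest achieved count (ties resolved toward the smaller vigilance).
#'
#' @param data Encoded dataset tibble or numeric matrix.
#' @param target_multimember Desired number of clusters with >= 2 members.
#' @param learning_rate,max_epochs,seed Passed to [art2a_cluster()].
#' @param lower,upper Initial vigilance bracket.
#' @return A list: `vigilance`, `achieved` (multimember count there),
#'   `clustering` (the `sibcut_art2a` object at the returned vigilance).
#' @export
tune_vigilance <- function(data, target_multimember, learning_rate = 0.1,
                           max_epochs = 20L, seed = 1L,
                           lower = 0.01, upper = 0.999) {
  X <- if (is.matrix(data)) data else encoded_parts(data)$X
  n <- nrow(X)
  stopifnot(target_multimember >= 1, target_multimember <= n %/% 2)
  best <- NULL
  probe <- function(v) {
    cl <- art2a_cluster(X, vigilance = v, learning_rate = learning_rate,
                        max_epochs = max_epochs, seed = seed)
    better <- is.null(best) ||
      abs(cl$n_multimember - target_multimember) <
        abs(best$clustering$n_multimember - target_multimember) ||
      (abs(cl$n_multimember - target_multimember) ==
         abs(best$clustering$n_multimember - target_multimember) &&
         v < best$vigilance)
    if (better) best <<- list(vigilance = v, clustering = cl)
    cl$n_multimember
  }
  lo <- lower; hi <- upper
  c_lo <- probe(lo)
  if (c_lo == target_multimember) {
    return(list(vigilance = best$vigilance, achieved = c_lo,
                clustering = best$clustering))
  }
  c_hi <- probe(hi)
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    c_mid <- probe(mid)
    if (c_mid == target_multimember) break
    if (c_mid < target_multimember) lo <- mid else hi <- mid
  }
  achieved <- best$clustering$n_multimember
  if (achieved != target_multimember) {
    warn(sprintf(
      "target of %d multimember clusters not reachable; best achieved %d at vigilance %.5f",
      target_multimember, achieved, best$vigilance))
  }
  list(vigilance = best$vigilance, achieved = achieved,
       clustering = best$clustering)
}
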