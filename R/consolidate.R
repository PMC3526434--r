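#' Consolidate distance matrices across iterations
#'
#' Distances from the N randomized ensemble iterations (or the solo
#' per-chromosome runs) are combined by an unweighted elementwise mean;
#' per-pair standard deviation is reported as a convergence diagnostic.
#'
#' @param ds list of symmetric distance matrices sharing one sample
#'   index.
#' @return an object of class `consolidation`: list with `mean`
#'   (consolidated matrix), `sd` (per-pair standard deviation, 0 for a
#'   single input) and `n_iterations`.
#' @export
average_distances <- function(ds) {
  if (length(ds) < 1L) stop("need >= 1 distance matrix", call. = FALSE)
  ids <- rownames(ds[[1L]])
  for (d in ds) {
    if (!identical(rownames(d), ids) || !identical(colnames(d), ids))
      stop("distance matrices have mismatching sample indices", call. = FALSE)
  }
  N <- length(ds)
  m <- Reduce(`+`, ds) / N
  if (N > 1L) {
    ss <- Reduce(`+`, lapply(ds, function(d) (d - m)^2))
    sdm <- sqrt(ss / (N - 1L))
  } else {
    sdm <- m * 0
  }
  structure(list(mean = m, sd = sdm, n_iterations = N),
            class = "consolidation")
}

#' @export
print.consolidation <- function(x, ...) {
  cat(sprintf("consolidated distances: %d samples, N = %d iterations\n",
              nrow(x$mean), x$n_iterations))
  cat(sprintf("mean per-pair sd: %.4g\n",
              mean(x$sd[upper.tri(x$sd)])))
  invisible(x)
}

#' Convergence curve of the running consolidated mean
#'
#' For N = 2..length(ds), the Frobenius norm of the change in the
#' running mean when the N-th matrix is added. For i.i.d. noisy inputs
#' the curve decays as O(1/N).
#'
#' @param ds list of >= 2 distance matrices sharing one sample index.
#' @return data.frame with columns `n` and `change`.
#' @export
convergence_curve <- function(ds) {
  if (length(ds) < 2L) stop("need >= 2 matrices", call. = FALSE)
  acc <- ds[[1L]]
  out <- data.frame(n = integer(0L), change = numeric(0L))
  for (N in 2:length(ds)) {
    prev_mean <- acc / (N - 1L)
    acc <- acc + ds[[N]]
    new_mean <- acc / N
    out <- rbind(out, data.frame(
      n = N, change = sqrt(sum((new_mean - prev_mean)^2))))
  }
  out
}
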