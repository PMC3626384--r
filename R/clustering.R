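#' Fuzzy C-means clustering of pixel intensities
#'
#' Partitions a vector of pixel intensities into `C` fuzzy clusters on the
#' 1-D intensity axis with distances `D_ik = |x_k - c_i|`. Memberships and
#' centres are updated alternately,
#' \deqn{u_{ik} = \Big[\sum_{j=1}^{C} (D_{ik}/D_{jk})^{2/(m-1)}\Big]^{-1},
#'   \qquad c_i = \frac{\sum_k u_{ik}^m x_k}{\sum_k u_{ik}^m},}
#' until the largest membership change drops below `epsilon` or `max_iter` is
#' reached. These updates alternately minimize the fuzzy within-cluster
#' sum of squares \eqn{J_m = \sum_i \sum_k u_{ik}^m D_{ik}^2}, which is
#' recorded per iteration in `objective_trace` (non-increasing). A pixel
#' coinciding with a centre receives a singleton membership (1 for that
#' cluster, 0 elsewhere), where the membership formula is undefined.
#'
#' Initial centres are drawn uniformly from the observed intensity range
#' using `seed` (the run is deterministic given the seed; the session RNG
#' state is left untouched). If the update collapses two centres onto the
#' same value, the duplicates are re-drawn (with a warning), at most 5 times.
#'
#' With `C = 4` (the default used for ventilation images) the ascending
#' centres are labelled `negligible < low < intermediate < high` ventilation.
#'
#' A `backend = "kmeans"` alternative runs hard K-means ([stats::kmeans()])
#' from the same initial centres — both algorithms share the same cost
#' function, and on well-separated data the argmax FCM labels coincide with
#' the K-means partition.
#'
#' @param values numeric vector of pixel intensities (length `N >= C`).
#' @param C number of clusters (default 4).
#' @param m fuzziness exponent, > 1 (default 2).
#' @param epsilon membership-change stopping criterion in (0, 1).
#' @param max_iter maximum number of update sweeps.
#' @param seed integer seed for the random centre initialization.
#' @param init_centers optional numeric vector of `C` starting centres
#'   (overrides the random initialization).
#' @param backend `"fcm"` (default) or `"kmeans"`.
#' @return an object of class `cluster_model`: list with `centers` (ascending),
#'   `memberships` (`C x N`, columns sum to 1), `labels` (integer `1..C`,
#'   argmax class after sorting centres), `class_names`, `objective_trace`,
#'   `n_iter`, `C`, `m`, `backend`.
#' @export
fcm_cluster <- function(values, C = 4, m = 2, epsilon = 1e-5, max_iter = 100,
                        seed = 1L, init_centers = NULL,
                        backend = c("fcm", "kmeans")) {
  backend <- match.arg(backend)
  x <- as.numeric(values)
  N <- length(x)
  if (N < C) stop(sprintf("need at least C = %d points, got %d", C, N), call. = FALSE)
  stopifnot(m > 1, epsilon > 0, epsilon < 1, max_iter >= 1)

  if (is.null(init_centers)) {
    centers <- with_local_seed(seed, runif(C, min(x), max(x)))
  } else {
    stopifnot(length(init_centers) == C)
    centers <- as.numeric(init_centers)
  }

  if (backend == "kmeans") {
    return(kmeans_backend(x, centers, C, m, max_iter))
  }

  u_prev <- NULL
  trace <- numeric(0)
  reinits <- 0L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    D <- abs(outer(centers, x, "-"))  # C x N
    u <- fcm_memberships(D, m)
    trace <- c(trace, sum((u^m) * D^2))
    if (!is.null(u_prev) && max(abs(u - u_prev)) < epsilon) break
    if (iter >= max_iter) break
    u_prev <- u
    w <- u^m
    centers_new <- as.numeric((w %*% x) / rowSums(w))
    dup <- duplicated(round(centers_new, 12L))
    if (any(dup)) {
      reinits <- reinits + 1L
      if (reinits > 5L) {
        stop("cluster centres collapsed repeatedly (5 reinitializations)", call. = FALSE)
      }
      warning(sprintf("%d collapsed centre(s) reinitialized", sum(dup)), call. = FALSE)
      centers_new[dup] <- with_local_seed(seed + reinits,
                                          runif(sum(dup), min(x), max(x)))
    }
    centers <- centers_new
  }

  finalize_cluster_model(x, centers, u, trace, iter, C, m, "fcm")
}

fcm_memberships <- function(D, m) {
  C <- nrow(D)
  expo <- 2 / (m - 1)
  zero <- D == 0
  Dm <- D^(-expo)                       # (1/D)^{2/(m-1)}
  u <- sweep(Dm, 2L, colSums(Dm), "/")  # u_ik = D_ik^-e / sum_j D_jk^-e
  # singleton rule where a point coincides with >=1 centre
  hit <- which(colSums(zero) > 0L)
  if (length(hit)) {
    u[, hit] <- 0
    first0 <- apply(zero[, hit, drop = FALSE], 2L, which.max)
    u[cbind(first0, hit)] <- 1
  }
  u
}

kmeans_backend <- function(x, centers, C, m, max_iter) {
  centers <- sort(centers)
  km <- kmeans(x, centers = matrix(centers, ncol = 1L), iter.max = max_iter,
               algorithm = "Lloyd")
  ord <- order(km$centers[, 1L])
  relab <- match(seq_len(C), ord)
  labels <- relab[km$cluster]
  u <- matrix(0, C, length(x))
  u[cbind(labels, seq_along(x))] <- 1
  structure(
    list(centers = as.numeric(km$centers[ord, 1L]),
         memberships = u, labels = labels,
         class_names = ventilation_class_names(C),
         objective_trace = km$tot.withinss, n_iter = km$iter,
         C = C, m = m, backend = "kmeans"),
    class = "cluster_model"
  )
}

finalize_cluster_model <- function(x, centers, u, trace, iter, C, m, backend) {
  ord <- order(centers)
  centers <- centers[ord]
  u <- u[ord, , drop = FALSE]
  labels <- max.col(t(u), ties.method = "first")
  structure(
    list(centers = centers, memberships = u, labels = labels,
         class_names = ventilation_class_names(C),
         objective_trace = trace, n_iter = iter, C = C, m = m,
         backend = backend),
    class = "cluster_model"
  )
}

ventilation_class_names <- function(C) {
  if (C == 4L) c("negligible", "low", "intermediate", "high")
  else paste0("class", seq_len(C))
}

#' Closed-form fuzzy membership of a single intensity
#'
#' Evaluates the fuzzy C-means membership formula for one intensity against a
#' fixed set of cluster centres, with the singleton rule when the intensity
#' coincides with a centre.
#'
#' @param x a single intensity.
#' @param centers distinct cluster centres.
#' @param m fuzziness exponent, > 1.
#' @return membership vector over the centres (sums to 1).
#' @examples
#' exact_membership(5, c(0, 10))    # c(0.5, 0.5)
#' exact_membership(2, c(0, 10))    # c(16/17, 1/17)
#' @export
exact_membership <- function(x, centers, m = 2) {
  stopifnot(length(x) == 1L, !anyDuplicated(centers), m > 1)
  D <- matrix(abs(centers - x), ncol = 1L)
  as.numeric(fcm_memberships(D, m))
}

#' Evaluate the fuzzy clustering objective
#'
#' The fuzzy within-cluster sum of squares
#' \eqn{J_m = \sum_i \sum_k u_{ik}^m |x_k - c_i|^2} at given memberships and
#' centres. Used to verify a fitted model against an independent evaluation.
#'
#' @param values data vector.
#' @param model a `cluster_model`, or a list with `memberships` and `centers`.
#' @return the objective value.
#' @export
fcm_objective <- function(values, model) {
  m <- model$m %||% 2
  D <- abs(outer(model$centers, as.numeric(values), "-"))
  sum((model$memberships^m) * D^2)
}

#' Refine the initial mask with the fitted ventilation classes
#'
#' Drops from the initial mask every pixel whose argmax class is the lowest
#' (`negligible` ventilation) cluster, and returns the surviving pixels
#' labelled by class. The model must have been fitted on exactly the pixels
#' where the initial mask is 1, taken slice by slice in column-major order
#' (the order produced by [masked_values()]).
#'
#' @param stack the source `image_stack`.
#' @param initial the initial `mask_stack` (from [apply_threshold()]).
#' @param model a `cluster_model` fitted on `masked_values(stack, initial)`.
#' @return a list with `mask` (refined `mask_stack`, a subset of `initial`)
#'   and `labels` (an integer label stack: 0 = background, `1..C` = class
#'   index in ascending-centre order; negligible pixels are set to 0).
#' @export
refine_mask <- function(stack, initial, model) {
  stopifnot(inherits(stack, "image_stack"), inherits(initial, "mask_stack"),
            inherits(model, "cluster_model"))
  if (!same_geometry(stack, initial)) {
    stop("stack and initial mask geometry differ", call. = FALSE)
  }
  n_on <- sum(vapply(initial$slices, sum, numeric(1L)))
  if (length(model$labels) != n_on) {
    stop(sprintf("model was fitted on %d pixels but the mask has %d",
                 length(model$labels), n_on), call. = FALSE)
  }
  refined <- initial$slices
  labels <- lapply(initial$slices, function(s) matrix(0L, nrow(s), ncol(s)))
  offset <- 0L
  for (k in seq_len(n_slices(initial))) {
    idx <- which(initial$slices[[k]] == 1L)
    if (length(idx)) {
      lab_k <- model$labels[offset + seq_along(idx)]
      offset <- offset + length(idx)
      keep <- lab_k > 1L
      refined[[k]][idx[!keep]] <- 0L
      labels[[k]][idx[keep]] <- lab_k[keep]
    }
  }
  list(mask = mask_stack(refined, like = initial), labels = labels)
}

#' Extract masked pixel intensities in canonical order
#'
#' Returns the intensities of `stack` at the pixels where `mask` is 1, slice
#' by slice, column-major within each slice. This is the pixel order assumed
#' by [refine_mask()].
#'
#' @param stack an `image_stack`.
#' @param mask a `mask_stack` with the same geometry.
#' @return numeric vector.
#' @export
masked_values <- function(stack, mask) {
  stopifnot(same_geometry(stack, mask))
  unlist(lapply(seq_len(n_slices(stack)), function(k) {
    stack$slices[[k]][mask$slices[[k]] == 1L]
  }), use.names = FALSE)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> %s, C=%d, m=%g, %d iteration(s)\n",
              x$backend, x$C, x$m, x$n_iter))
  cat("  centers:", paste(sprintf("%.4g", x$centers), collapse = ", "), "\n")
  cat("  classes:", paste(x$class_names, collapse = " < "), "\n")
  invisible(x)
}

# run expr under a temporary RNG state; restores the session RNG afterwards
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
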