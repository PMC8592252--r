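#' Row-standardise temporal profiles
#'
#' Centres and scales each profile to mean 0, standard deviation 1
#' (population sd, the Mfuzz convention). Zero-variance rows cannot be
#' scaled and are excluded; their ids are returned in the `excluded`
#' attribute.
#'
#' @param profiles numeric matrix, rows = siRNAs, columns = timepoints
#'   (T >= 2); rownames are ids.
#' @return standardised matrix with attribute `excluded`.
#' @export
standardize_profiles <- function(profiles) {
  m <- as.matrix(profiles)
  stopifnot(ncol(m) >= 2L)
  mu <- rowMeans(m)
  sdp <- sqrt(rowMeans((m - mu)^2))
  zero <- sdp < 1e-12
  if (all(zero)) stop("all profiles have zero variance", call. = FALSE)
  excluded <- rownames(m)[zero] %||% which(zero)
  z <- (m[!zero, , drop = FALSE] - mu[!zero]) / sdp[!zero]
  attr(z, "excluded") <- excluded
  z
}

fcm_memberships <- function(d2, m) {
  # u_ik = 1 / sum_j (d2_ik / d2_jk)^(1/(m-1)); exact-zero distances get
  # full membership (split equally if several).
  expo <- 1 / (m - 1)
  inv <- d2^(-expo)
  u <- inv / rowSums(inv)
  zero <- d2 < 1e-14
  any_zero <- rowSums(zero) > 0L
  if (any(any_zero)) {
    u[any_zero, ] <- zero[any_zero, , drop = FALSE] /
      rowSums(zero[any_zero, , drop = FALSE])
  }
  u
}

fcm_run <- function(X, c, m, max_iter, tol, init_rows) {
  centers <- X[init_rows, , drop = FALSE]
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- vapply(seq_len(c), function(k) {
      rowSums(sweep(X, 2L, centers[k, ], "-")^2)
    }, numeric(nrow(X)))
    d2 <- matrix(d2, nrow = nrow(X))
    u <- fcm_memberships(d2, m)
    trace <- c(trace, sum(u^m * d2))
    um <- u^m
    new_centers <- (t(um) %*% X) / colSums(um)
    move <- max(abs(new_centers - centers))
    centers <- new_centers
    if (move < tol) break
  }
  list(centers = centers, membership = u, objective = trace[length(trace)],
       objective_trace = trace, iterations = length(trace))
}

#' Fuzzy c-means clustering of temporal profiles
#'
#' Standard fuzzy c-means (the algorithm behind Mfuzz's soft partitioning)
#' with Euclidean distance: memberships and centres alternate until the
#' maximum centre movement falls below `tol` or `max_iter` is reached.
#' Centres are initialised as `c` distinct data rows chosen by seeded
#' sampling; `restarts` independent starts are run and the fit with the
#' lowest objective is kept.
#'
#' @param X numeric matrix (n x T), typically standardised profiles.
#' @param c number of clusters (>= 2; default 4).
#' @param m fuzzifier (> 1; default 2).
#' @param max_iter,tol stopping rule.
#' @param seed RNG seed for initialisation.
#' @param restarts independent restarts; best objective kept.
#' @return an object of class `fcm_model`: centers (c x T), membership
#'   (n x c, rows sum to 1), hard `labels` (argmax, ties to the lowest
#'   cluster index), `objective`, per-iteration `objective_trace`, and the
#'   call parameters.
#' @export
fuzzy_cmeans <- function(X, c = 4L, m = 2, max_iter = 200L, tol = 1e-6,
                         seed = 1L, restarts = 5L) {
  X <- as.matrix(X)
  if (c < 2L) stop("c must be >= 2", call. = FALSE)
  if (!all(is.finite(X))) stop("non-finite values in input", call. = FALSE)
  if (m <= 1) stop("fuzzifier m must be > 1", call. = FALSE)
  n <- nrow(X)
  if (n < c) stop("need at least c rows", call. = FALSE)
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(seed + r - 1L)
    init_rows <- sample.int(n, c)
    fit <- fcm_run(X, c, m, max_iter, tol, init_rows)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  labels <- max.col(best$membership, ties.method = "first")
  structure(list(centers = best$centers, membership = best$membership,
                 labels = labels, objective = best$objective,
                 objective_trace = best$objective_trace,
                 iterations = best$iterations,
                 c = c, m = m, seed = seed, data = X),
            class = "fcm_model")
}

#' Per-cluster summary of a fuzzy c-means fit
#'
#' @param model an `fcm_model` from [fuzzy_cmeans()].
#' @param profiles optional matrix of profiles to average (defaults to the
#'   matrix the model was fitted on).
#' @return data.frame: cluster, size (hard labels), mean trajectory columns
#'   `mean_1 ..`, and a `pattern` descriptor with one of up/down/flat per
#'   consecutive interval (e.g. `"up,up"`). Empty clusters get size 0 and
#'   `NA` trajectories.
#' @export
cluster_summary <- function(model, profiles = NULL) {
  stopifnot(inherits(model, "fcm_model"))
  X <- if (is.null(profiles)) model$data else as.matrix(profiles)
  Tn <- ncol(X)
  rows <- lapply(seq_len(model$c), function(k) {
    members <- model$labels == k
    size <- sum(members)
    traj <- if (size > 0L) colMeans(X[members, , drop = FALSE]) else
      rep(NA_real_, Tn)
    dirs <- if (size > 0L) {
      d <- diff(traj)
      paste(ifelse(d > 1e-9, "up", ifelse(d < -1e-9, "down", "flat")),
            collapse = ",")
    } else NA_character_
    df <- data.frame(cluster = k, size = size, pattern = dirs)
    traj_df <- as.data.frame(t(traj))
    names(traj_df) <- paste0("mean_", seq_len(Tn))
    cbind(df, traj_df)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
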