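#' Design matrix for the voxel-wise age regression
#'
#' Columns: intercept, age (the effect of interest), sex (0/1 indicator for
#' male) and the global mean uptake — the two nuisance covariates.
#'
#' @param cohort Cohort tibble (`subject_id`, `age`, `sex`).
#' @param global_means Numeric vector of per-subject global mean uptake, in
#'   cohort order.
#' @return Numeric matrix with column names
#'   `c("intercept", "age", "sex", "global_mean")`.
#' @export
make_design <- function(cohort, global_means) {
  if (length(global_means) != nrow(cohort)) {
    abort("`global_means` must have one value per cohort row")
  }
  X <- cbind(
    intercept = 1,
    age = cohort$age,
    sex = as.numeric(cohort$sex == "male"),
    global_mean = global_means
  )
  if (qr(X)$rank < ncol(X)) abort("design matrix is rank deficient")
  X
}

# stack a list of pet_volumes into an n x V matrix over the mask
.stack_volumes <- function(volumes, mask) {
  V <- sum(mask)
  Y <- matrix(NA_real_, nrow = length(volumes), ncol = V)
  for (i in seq_along(volumes)) {
    d <- if (inherits(volumes[[i]], "pet_volume")) volumes[[i]]$data
         else volumes[[i]]
    if (!identical(dim(d), dim(mask))) {
      abort("all volumes must share the mask's grid shape")
    }
    Y[i, ] <- d[mask]
  }
  Y
}

# t-statistics for one column of X, vectorized over response columns of Y
.tmap_core <- function(X, Y, col) {
  n <- nrow(X); p <- ncol(X)
  XtXi <- chol2inv(chol(crossprod(X)))
  B <- XtXi %*% crossprod(X, Y)           # p x V coefficients
  res <- Y - X %*% B
  sigma2 <- colSums(res^2) / (n - p)
  se <- sqrt(sigma2 * XtXi[col, col])
  list(t = drop(B[col, ]) / se, df = n - p, beta = drop(B[col, ]))
}

#' Mass-univariate GLM t-map for the age effect
#'
#' Ordinary least squares at every voxel of the mask, returning the
#' t-statistic of the age coefficient with `n - p` degrees of freedom.
#' Voxels with zero residual variance get infinite (nonzero effect) or NaN
#' (no effect) statistics rather than silent zeros.
#'
#' @param volumes List of `pet_volume` objects (or 3-D arrays), one per
#'   subject, all on the mask's grid.
#' @param design Design matrix from [make_design()]; must contain an
#'   `"age"` column and be full column rank.
#' @param mask Logical 3-D array selecting the voxels to fit.
#' @return An object of class `stat_map`: list with the 3-D `t` array (NA
#'   outside the mask), `df`, `mask` and the effect column name.
#' @export
fit_glm <- function(volumes, design, mask) {
  if (is.null(colnames(design)) || !("age" %in% colnames(design))) {
    abort("`design` must have a column named 'age'")
  }
  if (length(volumes) != nrow(design)) {
    abort("number of volumes must match the design rows")
  }
  if (length(volumes) <= ncol(design)) {
    abort("fewer subjects than design columns plus one")
  }
  if (qr(design)$rank < ncol(design)) abort("design matrix is rank deficient")
  if (!any(mask)) abort("`mask` is empty")
  Y <- .stack_volumes(volumes, mask)
  core <- .tmap_core(design, Y, which(colnames(design) == "age"))
  tarr <- array(NA_real_, dim = dim(mask))
  tarr[mask] <- core$t
  barr <- array(NA_real_, dim = dim(mask))
  barr[mask] <- core$beta
  structure(list(t = tarr, beta = barr, df = core$df, mask = mask,
                 effect = "age"),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  tv <- x$t[x$mask]
  cat(sprintf("<stat_map> %s voxels, df = %d, t range %.3f..%.3f\n",
              sum(x$mask), x$df, min(tv, na.rm = TRUE),
              max(tv, na.rm = TRUE)))
  invisible(x)
}

#' Permutation family-wise-error threshold for the age effect
#'
#' Controls the FWE rate of the voxel-wise age t-map by the permutation
#' distribution of the maximum |t| over the mask. Nuisance covariates are
#' handled by the Freedman-Lane scheme: the responses are residualized on
#' the nuisance columns, the residuals permuted, the nuisance fit added
#' back, and the full model refitted. The threshold is the empirical
#' (1 - alpha) quantile of the max-|t| null (two-tailed by construction).
#'
#' @inheritParams fit_glm
#' @param n_perm Number of permutations (>= 100).
#' @param alpha FWE level in (0, 1]; `alpha = 1` degenerately returns the
#'   minimum of the null maxima.
#' @param seed Integer seed for the permutations.
#' @param permutations Optional `n_perm` x n matrix of explicit subject
#'   permutations (rows index permutations), e.g. for exhaustive
#'   enumeration; overrides random generation.
#' @return The numeric threshold, with the vector of null maxima attached
#'   as attribute `"max_stats"`.
#' @export
permutation_fwe <- function(volumes, design, mask, n_perm = 1000,
                            alpha = 0.05, seed = 1L, permutations = NULL) {
  if (alpha <= 0 || alpha > 1) abort("`alpha` must lie in (0, 1]")
  if (is.null(permutations) && n_perm < 100) {
    abort("`n_perm` must be at least 100")
  }
  if (!("age" %in% colnames(design))) {
    abort("`design` must have a column named 'age'")
  }
  Y <- .stack_volumes(volumes, mask)
  n <- nrow(Y)
  col <- which(colnames(design) == "age")
  Z <- design[, -col, drop = FALSE]
  Hz <- Z %*% chol2inv(chol(crossprod(Z))) %*% t(Z)
  Fit <- Hz %*% Y
  Res <- Y - Fit
  if (is.null(permutations)) {
    permutations <- withr::with_seed(seed, {
      t(replicate(n_perm, sample.int(n)))
    })
  }
  n_perm <- nrow(permutations)
  maxs <- vapply(seq_len(n_perm), function(j) {
    Ystar <- Fit + Res[permutations[j, ], , drop = FALSE]
    max(abs(.tmap_core(design, Ystar, col)$t))
  }, numeric(1))
  k <- max(1L, ceiling((1 - alpha) * n_perm))
  thr <- sort(maxs)[k]
  attr(thr, "max_stats") <- maxs
  thr
}

# 26-connected neighbor offsets in 3-D
.neighbor_offsets <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
}

# label connected components among the given voxel coordinates (m x 3)
.connected_components <- function(coords, dims) {
  m <- nrow(coords)
  if (m == 0L) return(integer(0))
  lin <- (coords[, 3] - 1L) * dims[1] * dims[2] +
    (coords[, 2] - 1L) * dims[1] + coords[, 1]
  id_of <- new.env(hash = TRUE, size = m)
  for (i in seq_len(m)) assign(as.character(lin[i]), i, envir = id_of)
  offs <- .neighbor_offsets()
  comp <- integer(m)
  cur <- 0L
  for (i in seq_len(m)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- sweep(offs, 2, as.numeric(coords[v, ]), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      nlin <- (nb[, 3] - 1) * dims[1] * dims[2] + (nb[, 2] - 1) * dims[1] +
        nb[, 1]
      for (l in nlin) {
        key <- as.character(l)
        j <- if (exists(key, envir = id_of, inherits = FALSE)) {
          get(key, envir = id_of, inherits = FALSE)
        } else NA_integer_
        if (!is.na(j) && comp[j] == 0L) {
          comp[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

#' Cluster-extent table of a thresholded statistic map
#'
#' Suprathreshold voxels (`|t| >= threshold`) are separated by sign and
#' labeled by 26-connectivity; clusters smaller than the extent threshold
#' are dropped. Records report the 0-based peak voxel index and its mm
#' coordinate through the affine.
#'
#' @param stat_map A `stat_map` from [fit_glm()].
#' @param threshold Positive height threshold on |t|.
#' @param extent Minimum cluster size in voxels (default 50).
#' @param affine Optional 4x4 voxel-to-mm affine for peak coordinates.
#' @param connectivity Neighborhood definition; only 26 is implemented.
#' @return Tibble sorted by size (descending): `cluster_id`, `sign`,
#'   `size`, `peak_t`, `peak_i`, `peak_j`, `peak_k` (0-based),
#'   `peak_x/y/z` (mm, if an affine is given).
#' @export
cluster_table <- function(stat_map, threshold, extent = 50L, affine = NULL,
                          connectivity = 26L) {
  stopifnot(inherits(stat_map, "stat_map"))
  if (!is.finite(threshold) || threshold <= 0) {
    abort("`threshold` must be positive")
  }
  if (connectivity != 26L) abort("only 26-connectivity is implemented")
  dims <- dim(stat_map$t)
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- which(!is.na(stat_map$t) & sgn * stat_map$t >= threshold,
                   arr.ind = TRUE)
    comp <- .connected_components(supra, dims)
    for (cid in seq_len(max(comp, 0L))) {
      vox <- supra[comp == cid, , drop = FALSE]
      if (nrow(vox) < extent) next
      tv <- stat_map$t[vox]
      pk <- which.max(abs(tv))
      rec <- tibble::tibble(
        sign = if (sgn > 0) "positive" else "negative",
        size = nrow(vox),
        peak_t = tv[pk],
        peak_i = as.integer(vox[pk, 1]) - 1L,
        peak_j = as.integer(vox[pk, 2]) - 1L,
        peak_k = as.integer(vox[pk, 3]) - 1L
      )
      if (!is.null(affine)) {
        mm <- affine %*% c(vox[pk, ] - 1L, 1)
        rec$peak_x <- mm[1]; rec$peak_y <- mm[2]; rec$peak_z <- mm[3]
      }
      out[[length(out) + 1L]] <- rec
    }
  }
  if (!length(out)) {
    res <- tibble::tibble(
      cluster_id = integer(0), sign = character(0), size = integer(0),
      peak_t = numeric(0), peak_i = integer(0), peak_j = integer(0),
      peak_k = integer(0)
    )
    return(res)
  }
  res <- dplyr::arrange(dplyr::bind_rows(out), dplyr::desc(.data$size))
  res$cluster_id <- seq_len(nrow(res))
  dplyr::relocate(res, "cluster_id")
}
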