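# Independent oracles used across the suite.

# Cox-de Boor recursion for one B-spline basis function B_{i,d}(x)
cox_de_boor <- function(x, i, d, knots) {
  if (d == 0) {
    # half-open support, closed at the final interval so the right
    # boundary is covered
    last <- max(which(knots < max(knots)))
    if ((knots[i] <= x && x < knots[i + 1]) ||
        (x == max(knots) && knots[i] < knots[i + 1] && i == last)) {
      return(1)
    }
    return(0)
  }
  w1 <- 0
  if (knots[i + d] > knots[i]) {
    w1 <- (x - knots[i]) / (knots[i + d] - knots[i]) *
      cox_de_boor(x, i, d - 1, knots)
  }
  w2 <- 0
  if (knots[i + d + 1] > knots[i + 1]) {
    w2 <- (knots[i + d + 1] - x) / (knots[i + d + 1] - knots[i + 1]) *
      cox_de_boor(x, i + 1, d - 1, knots)
  }
  w1 + w2
}

cox_de_boor_row <- function(x, knots, degree) {
  nb <- length(knots) - degree - 1L
  vapply(seq_len(nb), function(i) cox_de_boor(x, i, degree, knots),
         numeric(1))
}

# per-voxel lm() oracle for the age t-map
tmap_lm_oracle <- function(Y, design) {
  apply(Y, 2, function(y) {
    fit <- lm(y ~ design - 1)
    summary(fit)$coefficients["designage", "t value"]
  })
}

# brute-force ROI means by an explicit voxel loop
roi_means_loop_oracle <- function(vol, atlas) {
  out <- c()
  for (lab in as.integer(names(atlas$name_map))) {
    tot <- 0; cnt <- 0
    d <- dim(atlas$labels)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (atlas$labels[i, j, k] == lab) {
        tot <- tot + vol$data[i, j, k]
        cnt <- cnt + 1
      }
    }
    out[atlas$name_map[[as.character(lab)]]] <- tot / cnt
  }
  out
}

# tiny deterministic pet_volume from a vector
vec_volume <- function(x) {
  pet_volume(array(x, dim = c(length(x), 1, 1)))
}

# small random cohort + full-rank design for voxel-wise fixtures
tiny_design <- function(n, seed = 1) {
  withr::with_seed(seed, {
    co <- tibble::tibble(
      subject_id = sprintf("S%03d", 1:n),
      age = runif(n, 20, 80),
      sex = rep(c("male", "female"), length.out = n)
    )
    gm <- runif(n, 0.9, 1.1)
  })
  list(cohort = co, design = make_design(co, gm))
}

vols_from_matrix <- function(Y, dims) {
  lapply(seq_len(nrow(Y)), function(i) {
    pet_volume(array(Y[i, ], dim = dims))
  })
}

# all permutations of 1..n (n small)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
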