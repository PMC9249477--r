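# Independent oracle implementations used to cross-check the package.
# Everything here is written directly from the defining formulas with plain
# loops, deliberately sharing no code with the package internals.

# -- class statistics: direct summation over gray levels -----------------

oracle_class_stats <- function(p, t) {
  L <- length(p)                      # p[i + 1] is the mass of level i
  w0 <- 0; w1 <- 0
  for (i in 0:(L - 1)) {
    if (i <= t) w0 <- w0 + p[i + 1] else w1 <- w1 + p[i + 1]
  }
  stats_of <- function(lo, hi, w) {
    if (w <= 0) return(list(m = NA_real_, ssq = NA_real_, H = NA_real_))
    m <- 0
    for (i in lo:hi) m <- m + i * p[i + 1] / w
    ssq <- 0
    for (i in lo:hi) ssq <- ssq + p[i + 1] * (i - m)^2 / w
    H <- 0
    for (i in lo:hi) {
      q <- p[i + 1] / w
      if (q > 0) H <- H - q * log(q)
    }
    list(m = m, ssq = ssq, H = H)
  }
  c0 <- stats_of(0, t, w0)
  c1 <- stats_of(t + 1, L - 1, w1)
  list(w0 = w0, w1 = w1, m0 = c0$m, m1 = c1$m,
       s0sq = c0$ssq, s1sq = c1$ssq, H0 = c0$H, H1 = c1$H)
}

oracle_entropy_sum <- function(p, t) {
  s <- oracle_class_stats(p, t)
  if (is.na(s$H0) || is.na(s$H1)) return(NA_real_)
  s$H0 + s$H1
}

oracle_min_error_objective <- function(p, t) {
  s <- oracle_class_stats(p, t)
  if (is.na(s$s0sq) || is.na(s$s1sq) || s$s0sq <= 0 || s$s1sq <= 0)
    return(NA_real_)
  1 + s$w0 * log(s$s0sq / s$w0^2) + s$w1 * log(s$s1sq / s$w1^2)
}

# Exhaustive scan over every candidate threshold; smallest t wins ties.
oracle_best_threshold <- function(p, objective, maximize) {
  nz <- which(p > 0) - 1L
  cand <- seq.int(min(nz), max(nz) - 1L)
  best_t <- NA_integer_; best_v <- NA_real_
  for (t in cand) {
    v <- objective(p, t)
    if (is.na(v)) next
    if (is.na(best_v) || (maximize && v > best_v) || (!maximize && v < best_v)) {
      best_v <- v; best_t <- t
    }
  }
  list(t_star = best_t, value = best_v)
}

# -- graph-cut energy: direct evaluation of the labeling energy ----------

oracle_seed_likelihood <- function(values, L, pc) {
  counts <- integer(L)
  for (v in values) counts[v + 1L] <- counts[v + 1L] + 1L
  (counts + pc) / (length(values) + pc * L)
}

oracle_energy <- function(I, labels, seeds, lambda, sigma, connectivity, pc, L) {
  pf <- oracle_seed_likelihood(I[seeds == 1L], L, pc)
  pb <- oracle_seed_likelihood(I[seeds == -1L], L, pc)
  nr <- nrow(I); nc <- ncol(I)
  E <- 0
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    v <- I[r, c] + 1L
    E <- E + lambda * (if (labels[r, c]) -log(pf[v]) else -log(pb[v]))
  }
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    for (o in offs) {
      r2 <- r + o[1L]; c2 <- c + o[2L]
      if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
      if (labels[r, c] != labels[r2, c2])
        E <- E + exp(-(I[r, c] - I[r2, c2])^2 / (2 * sigma^2)) / sqrt(sum(o^2))
    }
  }
  E
}

# Minimum energy over all labelings consistent with the seeds.
oracle_min_energy <- function(I, seeds, lambda, sigma, connectivity, pc, L) {
  free <- which(seeds == 0L)
  base <- seeds == 1L
  best <- Inf
  for (code in 0:(2^length(free) - 1L)) {
    lab <- base
    if (length(free))
      lab[free] <- bitwAnd(bitwShiftR(code, seq_along(free) - 1L), 1L) == 1L
    e <- oracle_energy(I, lab, seeds, lambda, sigma, connectivity, pc, L)
    if (e < best) best <- e
  }
  best
}

# -- connected components: stack-based flood fill ------------------------

oracle_components <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  comps <- list()
  neigh <- if (connectivity == 4L) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
         c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  }
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    px <- list()
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      px[[length(px) + 1L]] <- cur
      for (o in neigh) {
        r <- cur[1L] + o[1L]; c <- cur[2L] + o[2L]
        if (r >= 1L && r <= nr && c >= 1L && c <= nc &&
            mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
    comps[[length(comps) + 1L]] <- do.call(rbind, px)
  }
  comps
}

oracle_artifacts <- function(mask, min_size = 5L) {
  nr <- nrow(mask); nc <- ncol(mask)
  bg <- oracle_components(!mask, 4L)
  holes <- 0L
  for (comp in bg) {
    touches <- any(comp[, 1L] == 1L | comp[, 1L] == nr |
                   comp[, 2L] == 1L | comp[, 2L] == nc)
    if (!touches) holes <- holes + 1L
  }
  fg <- oracle_components(mask, 8L)
  isolated <- sum(vapply(fg, nrow, integer(1)) < min_size)
  list(holes = holes, isolated_points = as.integer(isolated))
}

# -- literal transcription of the printed scoring tables -----------------
# Band closures: boundary measurements join the lower-scoring band;
# "none" means exactly zero.

oracle_table_points <- function(category, x) {
  switch(category,
    collapse = if (x == 0) 6L else if (x <= 5) 4L else if (x <= 10) 2L else 0L,
    broadening = if (x == 0) 6L else if (x < 5) 4L else if (x <= 10) 2L else 0L,
    angulation = if (x == 0) 6L else if (x < 10) 4L else if (x <= 20) 2L else 0L,
    stop("unknown category"))
}

oracle_damage_points <- function(n_articular) {
  c(`0` = 6L, `1` = 4L, `2` = 4L, `3` = 2L, `4` = 0L)[[as.character(n_articular)]]
}

oracle_comminution_points <- function(fragments) {
  if (fragments == 0) 6L else if (fragments == 1) 4L
  else if (fragments == 2) 2L else 0L
}

oracle_displacement_grade <- function(total) {
  if (total == 18) "excellent" else if (total >= 12) "good"
  else if (total >= 6) "common" else "bad"
}

oracle_total_grade <- function(total) {
  if (total >= 28) "excellent" else if (total >= 20) "good"
  else if (total >= 10) "common" else "bad"
}

# -- small random fixtures ----------------------------------------------

random_histogram <- function(levels, seed) {
  set.seed(seed)
  counts <- rpois(levels, lambda = 3)
  if (sum(counts > 0) < 2L) counts[c(1L, levels)] <- counts[c(1L, levels)] + 1L
  histogram_from_weights(counts)
}

random_gray_image <- function(nr, nc, levels, seed) {
  set.seed(seed)
  gray_image(matrix(sample.int(levels, nr * nc, replace = TRUE) - 1L, nr, nc),
             levels = levels)
}
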