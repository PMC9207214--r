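# Independent brute-force oracles. These deliberately re-derive each
# quantity with the most literal possible algorithm (plain loops, textbook
# formulas) and share no code with the package implementations they check.

oracle_path_length <- function(x, y) {
  total <- 0
  for (i in seq_along(x)[-1]) {
    total <- total + sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2)
  }
  total
}

# Same jitter-merging semantics as the package (sub-min_step steps merged
# forward, trailing remainder dropped), but angles via atan2 of the cross
# and dot products instead of acos, and everything in explicit loops.
oracle_direction_changes <- function(x, y, angle_threshold = 90, min_step = 2) {
  vecs <- list()
  ax <- ay <- 0
  for (i in seq_along(x)[-1]) {
    ax <- ax + (x[i] - x[i - 1])
    ay <- ay + (y[i] - y[i - 1])
    if (sqrt(ax^2 + ay^2) >= min_step && sqrt(ax^2 + ay^2) > 0) {
      vecs[[length(vecs) + 1]] <- c(ax, ay)
      ax <- ay <- 0
    }
  }
  if (length(vecs) < 2) return(0L)
  count <- 0L
  for (i in 2:length(vecs)) {
    a <- vecs[[i - 1]]
    b <- vecs[[i]]
    ang <- abs(atan2(a[1] * b[2] - a[2] * b[1], a[1] * b[1] + a[2] * b[2]))
    if (ang * 180 / pi >= angle_threshold - 1e-9) count <- count + 1L
  }
  count
}

# Literal run scanner over a z series: walk the samples, open an event at
# the first supra-threshold sample, close at the first sub-threshold one.
oracle_call_runs <- function(z, threshold = 2) {
  events <- list()
  open <- FALSE
  start <- NA_integer_
  for (i in seq_along(z)) {
    if (z[i] >= threshold && !open) {
      open <- TRUE
      start <- i
    }
    if (z[i] < threshold && open) {
      events[[length(events) + 1]] <- c(start, i - 1L)
      open <- FALSE
    }
  }
  if (open) events[[length(events) + 1]] <- c(start, length(z))
  events
}

# Even-odd point-in-polygon by counting crossings of a horizontal ray,
# evaluated pixel by pixel.
oracle_polygon_mask <- function(vertices, rows, cols) {
  inside_one <- function(py, px) {
    nv <- nrow(vertices)
    crossings <- 0L
    for (i in seq_len(nv)) {
      j <- if (i == 1) nv else i - 1L
      y1 <- vertices[i, 1]; x1 <- vertices[i, 2]
      y2 <- vertices[j, 1]; x2 <- vertices[j, 2]
      if ((y1 > py) != (y2 > py)) {
        x_at <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
        if (px < x_at) crossings <- crossings + 1L
      }
    }
    crossings %% 2L == 1L
  }
  mask <- matrix(FALSE, rows, cols)
  for (r in 0:(rows - 1)) {
    for (c in 0:(cols - 1)) mask[r + 1, c + 1] <- inside_one(r, c)
  }
  mask
}

# Adjusted Rand index straight from the contingency-table formula.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  choose2 <- function(m) m * (m - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Random simple (convex) polygon whose vertices avoid pixel-center ties.
random_convex_polygon <- function(rows, cols, n_pts = 6) {
  y <- runif(n_pts, -0.3, rows - 0.7) + 0.13
  x <- runif(n_pts, -0.3, cols - 0.7) + 0.13
  hull <- chull(x, y)
  cbind(y[hull], x[hull])
}

random_track <- function(n_points, scale = 10) {
  track(paste0("rt", sample.int(1e6, 1)),
        t_min = seq(0, by = 5, length.out = n_points),
        x_um = cumsum(runif(n_points, -scale, scale)),
        y_um = cumsum(runif(n_points, -scale, scale)))
}
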