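# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: exhaustive enumeration, double loops, counting.

# exhaustive constrained target selection: best sum over all subsets of at
# most `max_targets` lesions with at most `max_per_organ` per organ
brute_best_target_sum <- function(values, organs, max_targets = 5,
                                  max_per_organ = 2) {
  n <- length(values)
  best <- 0
  for (size in seq_len(min(n, max_targets))) {
    for (combo in utils::combn(n, size, simplify = FALSE)) {
      if (any(table(organs[combo]) > max_per_organ)) next
      s <- sum(values[combo])
      if (s > best) best <- s
    }
  }
  best
}

# double-loop weighted kappa, written without matrix algebra
loop_kappa <- function(m, q = 2) {
  k <- nrow(m)
  n <- sum(m)
  po <- 0; pe <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    w <- if (q == 0) as.numeric(i == j) else 1 - (abs(i - j) / (k - 1))^q
    po <- po + m[i, j] * w / n
    pe <- pe + sum(m[i, ]) * sum(m[, j]) * w / n^2
  }
  (po - pe) / (1 - pe)
}

# brute-force sphere-member scan for suv_max / sphere means on small grids
brute_voi_values <- function(grid, center, radius) {
  d <- dim(grid$values)
  out <- numeric(0)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    pos <- grid$origin_mm + (c(i, j, k) - 1) * grid$voxel_size_mm
    if (sum((pos - center)^2) <= radius^2)
      out <- c(out, grid$values[i, j, k])
  }
  out
}

# empirical survivor function at time t with no censoring
empirical_survivor <- function(times, t) mean(times > t)

# a small deterministic scan pair with configurable percent change
toy_pair <- function(baseline_suv = c(10, 8), factor = 1, organs = c("a", "b"),
                     new_sul = numeric(0), liver_mean = 2, liver_sd = 0.1) {
  n <- length(baseline_suv)
  base <- data.frame(
    lesion_id = sprintf("b%d", seq_len(n)), organ = organs[seq_len(n)],
    suv_max = baseline_suv, suv_mean = 0.6 * baseline_suv,
    suv_peak = 0.85 * baseline_suv, sul_peak = 0.7 * baseline_suv,
    mtv_ml = rep(5, n), tlg = 3 * baseline_suv,
    stringsAsFactors = FALSE
  )
  fu <- base
  fu$lesion_id <- sprintf("f%d", seq_len(n))
  fu$mapped_baseline_id <- base$lesion_id
  for (col in c("suv_max", "suv_mean", "suv_peak", "sul_peak", "tlg"))
    fu[[col]] <- factor * fu[[col]]
  if (length(new_sul)) {
    fu <- rbind(fu, data.frame(
      lesion_id = sprintf("n%d", seq_along(new_sul)),
      organ = sprintf("new%d", seq_along(new_sul)),
      suv_max = new_sul / 0.7, suv_mean = 0.6 * new_sul / 0.7,
      suv_peak = 0.85 * new_sul / 0.7, sul_peak = new_sul,
      mtv_ml = 5, tlg = 3 * new_sul / 0.7,
      mapped_baseline_id = NA_character_, stringsAsFactors = FALSE
    ))
  }
  scan_pair("toy", base, fu,
            liver_followup = liver_reference_values(liver_mean, liver_sd),
            background_mean = 1, background_sd = 0.1)
}
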