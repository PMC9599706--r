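# Independent oracles and small fixtures used across the suite.

# Short evenly spaced test grid (decreasing, like the acquisition grid).
toy_grid <- function(lo = 1000, hi = 2000, n = 501) seq(hi, lo, length.out = n)

# Trapezoidal quadrature over increasing x: the independent area oracle.
trapz_oracle <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Noise-free preset (all per-spectrum variability and noise zeroed).
quiet_preset <- function(condition = "untreated") {
  condition_preset(condition, height_cv = 0, center_jitter_sd = 0, noise_sd = 0)
}

# Brute-force Ward agglomeration: at each step merge the pair of clusters
# whose union minimally increases total within-cluster sum of squares.
# Heights follow the ward.D2 convention: height = sqrt(2 * increase in ESS).
brute_force_ward_heights <- function(X) {
  ess <- function(rows) {
    sub <- X[rows, , drop = FALSE]
    sum(sweep(sub, 2L, colMeans(sub))^2)
  }
  clusters <- as.list(seq_len(nrow(X)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- NULL
    best_inc <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        inc <- ess(c(clusters[[i]], clusters[[j]])) - ess(clusters[[i]]) - ess(clusters[[j]])
        if (inc < best_inc) {
          best_inc <- inc
          best <- c(j, i)
        }
      }
    }
    heights <- c(heights, sqrt(2 * best_inc))
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
    clusters[[best[1]]] <- merged
  }
  heights
}

# Hand-computed one-way ANOVA F from explicit sums of squares.
anova_f_oracle <- function(groups_list) {
  all_vals <- unlist(groups_list)
  grand <- mean(all_vals)
  ssb <- sum(vapply(groups_list, function(g) length(g) * (mean(g) - grand)^2, numeric(1)))
  ssw <- sum(vapply(groups_list, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups_list) - 1L
  df2 <- length(all_vals) - length(groups_list)
  (ssb / df1) / (ssw / df2)
}

# Preprocess one spectrum and fit one analysis window, as the pipeline does.
fit_window_of <- function(spectrum, window_name, ...) {
  model <- band_model(window_name)
  fit_bands(prepare_window(area_normalize(spectrum), model), model, ...)
}
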