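# small grid that still satisfies the atlas layout constraints: keeps the
# heavier simulation tests fast
tiny_phantom <- function(...) {
  phantom_config(grid = c(40, 40, 36), ...)
}

tiny_config <- function(phantom = list(), ...) {
  validate_config(config = c(
    list(phantom = utils::modifyList(list(grid = c(40, 40, 36)), phantom)),
    list(...)
  ))
}

# average ranks computed from first principles (independent of base rank())
avg_ranks <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1))
}

# Spearman rs and t-approximation p from the rank formula
spearman_oracle <- function(x, y) {
  rx <- avg_ranks(x); ry <- avg_ranks(y)
  n <- length(x)
  rs <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  tstat <- rs * sqrt((n - 2) / (1 - rs^2))
  list(rs = rs, p = 2 * pt(-abs(tstat), n - 2))
}

# direct-formula paired t
paired_t_oracle <- function(x, y) {
  d <- x - y; n <- length(d)
  tstat <- mean(d) / (sd(d) / sqrt(n))
  list(t = tstat, df = n - 1, p = 2 * pt(-abs(tstat), n - 1))
}

# direct-formula Welch t with Welch-Satterthwaite df
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

# chi-square by explicit O/E summation
chi2_oracle <- function(a, b, c, d) {
  o <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  sum((o - e)^2 / e)
}

# BH step-up adjusted p by the explicit min-over-steps formula
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  sorted <- p[o] * n / seq_len(n)
  adj[o] <- rev(cummin(rev(sorted)))
  pmin(1, adj)
}

# build a region_status_matrix from explicit positivity patterns
fake_matrix <- function(ab_mat, css_mat, lobes = NULL) {
  np <- nrow(ab_mat); nr <- ncol(ab_mat)
  pid <- rep(sprintf("P%02d", seq_len(np)), each = nr)
  rid <- rep(seq_len(nr), np)
  ab <- tibble::tibble(patient_id = pid, region_id = rid,
                       ab_pos = as.logical(t(ab_mat)))
  if (!is.null(lobes)) ab$lobe <- rep(lobes, np)
  css <- tibble::tibble(patient_id = pid, region_id = rid,
                        css_pos = as.logical(t(css_mat)))
  assemble_matrix(ab, css)
}
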