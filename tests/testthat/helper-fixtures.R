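# Small in-code fixtures shared across test files.

# 3 host + 1 target proteins over 2 runs, one missing cell
tiny_table <- function() {
  tibble::tibble(
    accession = c("P77398", "P76344", "P17169", "P69905"),
    run1 = c(10, 20, NA, 30),
    run2 = c(5, 15, 25, 100)
  )
}

tiny_groups <- function(tbl = tiny_table()) {
  assign_groups(tbl, target_ids = "P69905", host_ids = c("P77398", "P76344", "P17169"))
}

# exact points on R = a + b * w
line_points <- function(w, a = 0, b = 0.001) {
  tibble::tibble(w_known = w, R = a + b * w)
}

# independent normal-equations oracle for the straight-line fit
ols_oracle <- function(w, R) {
  X <- cbind(1, w)
  beta <- solve(t(X) %*% X, t(X) %*% R)
  res <- R - X %*% beta
  n <- length(R)
  list(
    a = beta[1], b = beta[2],
    s_yx = sqrt(sum(res^2) / (n - 2)),
    S_xx = sum((w - mean(w))^2)
  )
}

# inverse prediction from an oracle fit
oracle_predict <- function(w, R, y0) {
  o <- ols_oracle(w, R)
  (y0 - o$a) / o$b
}
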