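# Independent oracles: explicit normal-equations OLS, numeric F-tail
# integration, and brute-force leave-one-out DFFITS. These never touch the
# package's fitting path.

# treatment-coded design matrices built by hand
oracle_design <- function(x, cohorts, reference, interaction = TRUE) {
  labels <- c(reference, setdiff(sort(unique(cohorts)), reference))
  X <- matrix(1, nrow = length(x), ncol = 1)
  colnames(X) <- "(Intercept)"
  for (lab in labels[-1]) {
    X <- cbind(X, as.numeric(cohorts == lab))
    colnames(X)[ncol(X)] <- paste0("cohort", lab)
  }
  if (interaction) {
    X <- cbind(X, x)
    colnames(X)[ncol(X)] <- "x"
    for (lab in labels[-1]) {
      X <- cbind(X, x * as.numeric(cohorts == lab))
      colnames(X)[ncol(X)] <- paste0("cohort", lab, ":x")
    }
  }
  X
}

# OLS by explicit inversion of the normal equations
oracle_ols <- function(y, X) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  resid <- as.vector(y - X %*% beta)
  list(beta = setNames(as.vector(beta), colnames(X)),
       rss = sum(resid^2), resid = resid, xtx_inv = xtx_inv)
}

# upper tail of the F distribution by numeric integration of its density
oracle_f_tail <- function(f, df1, df2) {
  stats::integrate(function(t) stats::df(t, df1, df2), lower = f,
                   upper = Inf, rel.tol = 1e-12)$value
}

# two-sided coefficient p-values from the unscaled covariance diagonal
oracle_coef_p <- function(y, X) {
  fit <- oracle_ols(y, X)
  df_resid <- length(y) - ncol(X)
  sigma2 <- fit$rss / df_resid
  se <- sqrt(diag(fit$xtx_inv) * sigma2)
  t_stat <- fit$beta / se
  setNames(2 * stats::pt(abs(t_stat), df_resid, lower.tail = FALSE),
           colnames(X))
}

# DFFITS by n leave-one-out refits (each via the normal equations)
oracle_dffits <- function(y, X) {
  n <- length(y)
  p <- ncol(X)
  full <- oracle_ols(y, X)
  h <- diag(X %*% full$xtx_inv %*% t(X))
  yhat <- as.vector(X %*% full$beta)
  vapply(seq_len(n), function(i) {
    loo <- oracle_ols(y[-i], X[-i, , drop = FALSE])
    yhat_del <- sum(X[i, ] * loo$beta)
    s_del <- sqrt(loo$rss / (n - 1 - p))
    (yhat[i] - yhat_del) / (s_del * sqrt(h[i]))
  }, numeric(1))
}

# fixed, printed 10-sample 2-cohort dataset used across regression tests
fixture_pair10 <- function() {
  list(
    y = c(0.10, 0.18, 0.24, 0.41, 0.48, 0.35, 0.30, 0.26, 0.22, 0.11),
    x = c(1.2, 2.3, 3.1, 4.8, 5.5, 1.9, 2.8, 3.6, 4.1, 5.9),
    cohorts = rep(c("A", "B"), each = 5)
  )
}

# fixed, printed 12-sample 2-cohort dataset for influence diagnostics
fixture_pair12 <- function() {
  list(
    y = c(0.05, 0.12, 0.21, 0.33, 0.38, 0.47, 0.44, 0.35, 0.28, 0.25,
          0.16, 0.09),
    x = c(0.5, 1.1, 2.0, 3.2, 3.9, 4.6, 0.8, 1.6, 2.4, 3.0, 4.2, 5.1),
    cohorts = rep(c("A", "B"), each = 6)
  )
}

# small merged table built in code
make_merged <- function(values, omes, cohorts = rep(c("A", "B"), length.out = nrow(values))) {
  data <- dplyr::bind_cols(
    tibble::tibble(
      sample_id = sprintf("s%02d", seq_len(nrow(values))),
      cohort = cohorts
    ),
    tibble::as_tibble(values)
  )
  merged_table(data, tibble::tibble(feature = colnames(values), ome = omes))
}

# pair_screen stand-in with prescribed p-values, for top-table threshold and
# sorting logic
fake_screen <- function(p, microbe = sprintf("m%02d", seq_along(p)),
                        immune = rep("i1", length(p))) {
  out <- tibble::tibble(
    microbe = microbe, immune = immune, n = 20L,
    F = rev(seq_along(p)), p = p, max_influence = 1,
    interaction_p = replicate(length(p), c(B = 0.5), simplify = FALSE),
    fit = replicate(length(p), NULL, simplify = FALSE),
    degenerate = FALSE, reason = NA_character_
  )
  class(out) <- c("pair_screen", class(out))
  attr(out, "reference") <- "A"
  out
}

write_temp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_csv(df, path, progress = FALSE)
  path
}
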