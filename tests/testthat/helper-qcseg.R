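# shared fixtures, all generated in code

# positive random series (safe for dp3, which divides by the block mean)
rand_pos_series <- function(n, seed) {
  withr::with_seed(seed, stats::runif(n, 1, 10))
}

# noiseless piecewise-constant series from segment lengths and level means
step_series <- function(lengths, means) {
  rep(means, lengths)
}

# direct two-pass reference scores, independent of the package's prefix
# machinery (oracle for the scoring module)
direct_score <- function(x, start, end, method) {
  xb <- x[start:end]
  n <- length(xb)
  m <- mean(xb)
  sse <- sum((xb - m)^2)
  switch(method,
    dp1 = sum(abs(xb - m)),
    dp2 = sse,
    dp3 = sse / m,
    dp4 = if (sse == 0) 0 else sse / stats::sd(xb),
    dp5 = if (max(xb) == min(xb)) 0 else stats::sd(xb) / (max(xb) - min(xb)),
    dp6 = mean(abs(xb - m)),
    dp7 = sse / n
  )
}

# every change-point vector for n points, K blocks, min segment length L
all_partitions <- function(n, K, L = 1L) {
  if (K == 1L) return(list(integer(0)))
  combos <- utils::combn(n - 1L, K - 1L)
  out <- list()
  for (j in seq_len(ncol(combos))) {
    cp <- combos[, j]
    if (all(diff(c(0L, cp, n)) >= L)) out[[length(out) + 1L]] <- cp
  }
  out
}

# CSV fixture writer for io tests
write_series_csv <- function(df, path = withr::local_tempfile(fileext = ".csv",
                                                              .local_envir = parent.frame())) {
  readr::write_csv(df, path)
  path
}

# run the bundled CLI script in a child R process against the installed package
run_cli <- function(args) {
  script <- system.file("cli", "qcseg.R", package = "qcseg")
  res <- suppressWarnings(system2(
    "Rscript", c(script, args),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  ))
  list(status = attr(res, "status") %||% 0L, output = res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
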