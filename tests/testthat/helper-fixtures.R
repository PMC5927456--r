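# Fixture builders and independent oracles shared across test files.

make_profile <- function(depths, temps, oxy, date = as.Date("2008-01-15")) {
  tibble::tibble(date = date, depth_m = depths,
                 temp_c = temps, do_mgl = oxy)
}

make_records <- function(months, lengths_by_month, clutch = NULL,
                         egg = NULL, hatched = NULL) {
  purrr::imap_dfr(lengths_by_month, function(lens, i) {
    n <- length(lens)
    tibble::tibble(
      date = as.Date(sprintf("2008-%02d-15", months[as.integer(i)])),
      female_id = seq_len(n),
      length_um = lens,
      egg_major_um = if (is.null(egg)) NA_real_ else egg[[as.integer(i)]],
      egg_minor_um = NA_real_,
      clutch_size = if (is.null(clutch)) NA_real_
                    else clutch[[as.integer(i)]],
      hatched = if (is.null(hatched)) NA_real_
                else hatched[[as.integer(i)]])
  })
}

# Sigma-formula Pearson correlation, written independently of the package.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Exhaustive Mann-Whitney null: statistic distribution over every subset
# of size n_a (bitmask enumeration, independent of the package's combn
# route). Returns the two-sided exact p for the min-U statistic.
oracle_mwu_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); n_a <- length(a)
  stat <- function(ia) {
    r <- rank(pooled)
    ua <- sum(r[ia]) - n_a * (n_a + 1) / 2
    min(ua, n_a * (n - n_a) - ua)
  }
  obs <- stat(seq_len(n_a))
  us <- c()
  for (mask in 0:(2^n - 1)) {
    bits <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(bits) == n_a) us <- c(us, stat(bits))
  }
  mean(us <= obs + 1e-9)
}
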