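# Shared fixtures built in code.

all_fdi_positions <- function() as.integer(outer(c(10L, 20L, 30L, 40L), 1:7, `+`))

# Random but valid chart: a subset of teeth, real-valued depths, some
# unmeasured sites (with their BOP flags also missing, as the contract
# requires).
random_chart <- function(n_teeth = 12, subject_id = "S1", missing_rate = 0.1) {
  teeth <- sort(sample(all_fdi_positions(), n_teeth))
  ch <- tibble::tibble(subject_id = subject_id, tooth = teeth)
  ppd <- matrix(round(stats::runif(n_teeth * 6, 0.5, 9.5), 2), ncol = 6)
  drop <- matrix(stats::runif(n_teeth * 6) < missing_rate, ncol = 6)
  # keep at least one measured site per tooth
  drop[cbind(seq_len(n_teeth), sample.int(6, n_teeth, replace = TRUE))] <- FALSE
  ppd[drop] <- NA
  bop <- matrix(stats::rbinom(n_teeth * 6, 1, 0.3), ncol = 6)
  bop[drop] <- NA
  sites <- c("mb", "b", "db", "dl", "l", "ml")
  for (j in 1:6) ch[[paste0("ppd_", sites[j])]] <- ppd[, j]
  for (j in 1:6) ch[[paste0("bop_", sites[j])]] <- bop[, j]
  ch
}

# Minimal hand-built cohort (no generator involved) for summary edge cases.
manual_cohort <- function(charts, covariates) {
  out <- tibble::as_tibble(covariates)
  attr(out, "charts") <- charts
  class(out) <- c("pisa_cohort", class(out))
  out
}

# Independent naive evaluation of the original polynomial (term-by-term, no
# Horner), used as the oracle against the package's evaluator.
naive_poly_pesa <- function(coef_row, x) {
  a <- as.numeric(coef_row[paste0("a", 1:6)])
  sum(a * x^(1:6))
}

# Brute-force exact two-sided signed-rank p-value by enumerating all 2^n
# sign assignments of the |differences| ranks.
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}
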