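# Fixture builders shared across the suite.

# Minimal well-formed participant table (3 rows, one missing post score).
tiny_cohort_df <- function() {
  data.frame(
    id = c("a", "b", "c"),
    sex = c("male", "female", "male"),
    age_years = c(40, 55, 70),
    laterality = c("unilateral", "bilateral", "bilateral"),
    hearing_loss_db = c(30.5, 60, 95),
    thi_baseline = c(20, 50, 80),
    thi_post = c(10, 45, NA),
    decision_sedep = c("negative", "positive", "positive"),
    decision_pcu = c("negative", "positive", NA),
    stringsAsFactors = FALSE)
}

# Single-group generator truth with negligible axis truncation (tail mass
# ~1e-3), used wherever parameter recovery is asserted at tight tolerance.
recovery_config <- function(n, seed, noise = 0) {
  synthetic_config(
    n = n, prior_pos = 0.5,
    sedep = list(mu_pos = 75, s_pos = 8, mu_neg = 55, s_neg = 8,
                 criterion = 65),
    decision_noise = noise, seed = seed)
}

# Exhaustive log-likelihood grid search: the independent oracle for the
# logistic MLE. Returns the (mu, s) grid argmax.
grid_search_logistic <- function(values, mu_range, s_range, step = 0.01) {
  mu_grid <- seq(mu_range[1], mu_range[2], by = step)
  s_grid <- seq(s_range[1], s_range[2], by = step)
  best <- c(-Inf, NA, NA)
  for (s in s_grid) {
    ll <- vapply(mu_grid,
                 function(m) sum(stats::dlogis(values, m, s, log = TRUE)),
                 numeric(1))
    i <- which.max(ll)
    if (ll[i] > best[1]) best <- c(ll[i], mu_grid[i], s)
  }
  list(mu = best[2], s = best[3], loglik = best[1],
       step = step,
       interior = best[2] > mu_range[1] & best[2] < mu_range[2] &
         best[3] > s_range[1] & best[3] < s_range[2])
}

# Random valid truth-state model for property-style loops.
random_model <- function() {
  mu_neg <- stats::runif(1, 20, 60)
  uvsdt_model(
    logis_dist(mu_neg + stats::runif(1, 2, 40), stats::runif(1, 4, 20)),
    logis_dist(mu_neg, stats::runif(1, 4, 20)),
    prior_pos = stats::runif(1, 0.2, 0.8))
}
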