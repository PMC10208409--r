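# Small cohorts built in code for fast tests.

# a tiny strongly-separated two-bag cohort: features determine the label
tiny_cohort <- function(n_per_bag = 20, d = 3, seed = 11) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_bag * d, mean = -2), ncol = d),
             matrix(rnorm(n_per_bag * d, mean = 2), ncol = d))
  bags <- factor(rep(c("lo", "hi"), each = n_per_bag), levels = c("lo", "hi"))
  list(x = x, bags = bags,
       labels_cat = c(lo = 0, hi = 1),
       labels_vec = rbind(lo = c(0.2, 0.3), hi = c(0.8, 0.7)))
}

# random variant-call table covering all filter clause combinations
random_calls <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(alt_reads = sample(0:12, n, replace = TRUE),
             vaf = round(runif(n, 0, 0.1), 3),
             pop_freq = ifelse(runif(n) < 0.3, NA,
                               round(runif(n, 0, 0.05), 4)))
}

small_sim <- function(seed = 5, scale = 0.2) {
  simulate_cohort(sim_config(scale = scale, seed = seed))
}
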