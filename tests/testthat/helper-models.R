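# shared fixtures: cost models, string enumeration, random maps

# three-symbol model of the worked duplication-history example:
# d(a,b) = d(b,c) = 1, d(a,c) = 2, c_dup = 0.5
worked_cost_model <- function() {
  ab <- c("a", "b", "c")
  d <- matrix(c(0, 1, 2,
                1, 0, 1,
                2, 1, 0), 3, byrow = TRUE, dimnames = list(ab, ab))
  cost_model(d, c_dup = 0.5, c_ins = 1.5, c_del = 1.5)
}

# random (possibly non-metric) cost model over an alphabet
random_cost_model <- function(alphabet, equal_indel = TRUE) {
  k <- length(alphabet)
  d <- matrix(0, k, k, dimnames = list(alphabet, alphabet))
  vals <- round(stats::runif(k * (k - 1) / 2, 0.2, 3), 2)
  d[upper.tri(d)] <- vals
  d <- d + t(d)
  c_dup <- round(stats::runif(1, 0.2, 1), 2)
  c_ins <- round(stats::runif(1, 1, 2.5), 2)
  c_del <- if (equal_indel) c_ins else round(stats::runif(1, 1, 2.5), 2)
  cost_model(d, c_dup = c_dup, c_ins = c_ins, c_del = c_del)
}

# all non-empty strings over `alphabet` up to length maxlen (list of vectors)
all_strings <- function(alphabet, maxlen) {
  out <- list()
  grow <- list(character(0))
  for (len in seq_len(maxlen)) {
    grow <- unlist(lapply(grow, function(p)
      lapply(alphabet, function(s) c(p, s))), recursive = FALSE)
    out <- c(out, grow)
  }
  out
}

random_map <- function(id, alphabet, len) {
  mini_map(id, sample(alphabet, len, replace = TRUE))
}

# study conditions of the direction-recovery experiment: duplication-driven
# burst evolution over an ordered 8-symbol alphabet, graded costs
bias_sim_alphabet <- letters[1:8]
bias_sim_root <- rep(c("b", "g", "d", "h", "a", "f"), each = 4)
bias_sim_costs <- function()
  gradient_cost_model(bias_sim_alphabet, c_ins = 2.5, c_del = 2.5)
bias_sim_params <- function(beta, seed)
  sim_params(bias_sim_alphabet, bias_sim_root, n_events = 30,
             p_dup = 1, p_mut = 0, p_indel = 0,
             beta = beta, burst = 0.85, dup_mut = 0.1, seed = seed)

# study conditions of the polar-variability experiment: mutation-driven
pivot_sim_params <- function(mut_end_bias, seed)
  sim_params(bias_sim_alphabet, bias_sim_root, n_events = 20,
             p_dup = 0.2, p_mut = 0.7, p_indel = 0.1,
             mut_end_bias = mut_end_bias, seed = seed)
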