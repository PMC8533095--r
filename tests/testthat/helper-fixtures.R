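# Fixtures are built in code; nothing is read from disk.

# tiny binary case with a perfectly separating first gene
separable_case <- function(n_per_class = 6, n_noise = 8, seed = 11) {
  set.seed(seed)
  n <- 2 * n_per_class
  ids <- sprintf("P%02d", seq_len(n))
  sens <- rep(c(TRUE, FALSE), each = n_per_class)
  x <- cbind(marker = as.numeric(sens),
             matrix(rbinom(n * n_noise, 1, 0.3), n, n_noise,
                    dimnames = list(NULL, sprintf("noise%02d", seq_len(n_noise)))))
  rownames(x) <- ids
  fm <- feature_matrix(x, "SNV")
  resp <- response_records(ids, "trt", ifelse(sens, "PR", "PD"))
  build_case_dataset(fm, resp, "trt", "synthetic", min_n = 5)
}

# balanced case with pure-noise features
noise_case <- function(n = 20, p = 15, seed = 5, profile = "SNV") {
  set.seed(seed)
  ids <- sprintf("P%02d", seq_len(n))
  sens <- rep(c(TRUE, FALSE), length.out = n)
  x <- if (profile %in% c("SNV", "CNA")) {
    matrix(rbinom(n * p, 1, 0.3), n, p)
  } else {
    matrix(abs(rnorm(n * p, 5)), n, p)
  }
  dimnames(x) <- list(ids, sprintf("g%03d", seq_len(p)))
  fm <- feature_matrix(x, profile)
  resp <- response_records(ids, "trt", ifelse(sens, "SD", "PD"))
  build_case_dataset(fm, resp, "trt", "synthetic", min_n = 5)
}

# enumeration oracle for the two-sided Fisher p-value: probabilities of all
# tables with the observed margins via binomial coefficients only
fisher_oracle <- function(a, b, c, d) {
  ns <- a + c; nr <- b + d; m <- a + b; n <- ns + nr
  support <- max(0, m - nr):min(m, ns)
  prob <- vapply(support, function(k)
    choose(ns, k) * choose(nr, m - k) / choose(n, m), numeric(1))
  obs <- prob[support == a]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

fast_cfg <- function(...) rf_config(n_trees = 20, ...)
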