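# random 0/1/2 marker matrix with per-locus allele frequencies
rand_markers <- function(J, p, seed = 1L, freq = c(0.2, 0.8)) {
  set.seed(seed)
  fq <- runif(p, freq[1], freq[2])
  M <- vapply(fq, function(pk) rbinom(J, 2L, pk), integer(J))
  dimnames(M) <- list(sprintf("L%03d", seq_len(J)),
                      sprintf("M%04d", seq_len(p)))
  M
}

# split a simulated trial into train/test around one held-out environment
split_env <- function(sim, env) {
  idx <- sim$index
  test <- idx$env == env
  list(train = which(!test), test = which(test),
       idx_train = obs_index(as.character(idx$env[!test]),
                             as.character(idx$line[!test]),
                             env_levels = levels(idx$env),
                             line_levels = levels(idx$line)),
       idx_test = obs_index(as.character(idx$env[test]),
                            as.character(idx$line[test]),
                            env_levels = levels(idx$env),
                            line_levels = levels(idx$line)))
}

# train-mean baseline NRMSE pooled over all held-out folds of a report
pooled_train_mean_nrmse <- function(rep) {
  obs <- unlist(lapply(rep$predictions, `[[`, "y_obs"), use.names = FALSE)
  pred <- unlist(lapply(seq_along(rep$predictions), function(i)
    rep_len(rep$folds$train_mean[i], rep$folds$n_test[i])), use.names = FALSE)
  nrmse(obs, pred)
}
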