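#' Normalized root mean squared error
#'
#' \deqn{\mathrm{NRMSE} = \sqrt{\tfrac{1}{T}\sum_i (y_i - \hat y_i)^2} \; / \; \bar y}
#' i.e. the RMSE of the predictions divided by the mean of the observed
#' values. Undefined (an error) when the observed mean is numerically
#' zero.
#'
#' @param y_obs,y_pred numeric vectors of equal, positive length.
#' @return nonnegative scalar.
#' @export
nrmse <- function(y_obs, y_pred) {
  if (length(y_obs) != length(y_pred) || length(y_obs) == 0L)
    stop("y_obs and y_pred must have equal, nonzero length")
  m <- mean(y_obs)
  if (abs(m) <= 1e-12)
    stop("NRMSE undefined for mean-zero response")
  sqrt(mean((y_obs - y_pred)^2)) / m
}

#' Relative efficiency of PLS against GBLUP in NRMSE terms
#'
#' The ratio \eqn{RE = \mathrm{NRMSE}_{GBLUP} / \mathrm{NRMSE}_{PLS}}.
#' Values above 1 mean the PLS predictions had the lower error (PLS
#' superior); below 1, GBLUP was superior; exactly 1, the two methods
#' were equally efficient.
#'
#' @param nrmse_gblup,nrmse_pls positive scalars.
#' @return the ratio.
#' @export
relative_efficiency <- function(nrmse_gblup, nrmse_pls) {
  if (any(c(nrmse_gblup, nrmse_pls) <= 0))
    stop("relative efficiency requires positive NRMSE values")
  nrmse_gblup / nrmse_pls
}

# deterministic per-fold seed from the master seed, an ID string and a
# purpose tag, kept inside the 32-bit integer range
derive_seed <- function(seed, id, purpose) {
  h <- sum(utf8ToInt(paste0(id, ":", purpose)) *
             seq_along(utf8ToInt(paste0(id, ":", purpose)))) %% 99991L
  as.integer((as.numeric(seed) * 1009 + h * 131 + 17) %% 2147483647)
}

#' Leave-one-environment-out evaluation of PLS and GBLUP
#'
#' Runs the full benchmarking protocol: each environment in turn is held
#' out as the test set and the models are trained on all remaining
#' environments. For PLS, the number of latent variables is chosen by an
#' inner k-fold cross-validation on the training rows only (the held-out
#' environment is never touched during tuning), the model is refit on the
#' whole training set with the selected count, and the complete held-out
#' environment is predicted. GBLUP requires no tuning. Accuracy is
#' summarized per environment and globally (pooled over all held-out
#' predictions) as NRMSE, with the relative efficiency
#' GBLUP-NRMSE / PLS-NRMSE when both methods are run.
#'
#' The predictor matrix for PLS is the relationship-augmented design
#' \eqn{[X_L L_E | X_g L_g | X_{gL}(L_E \otimes L_g)]} (the GE block
#' present only for `predictor = "E+G+GE"`); GBLUP is the matching
#' Bayesian reaction-norm model. When `use_env_covariates` is `FALSE`
#' (or no covariates exist) the environmental relationship matrix is the
#' identity.
#'
#' @param data a `met_data` (from [read_met_dataset()]) or `met_sim`
#'   (from [simulate_met()]) object; markers must be QC-complete (no
#'   missing calls).
#' @param trait trait column name in `data$pheno` (default: first trait).
#' @param methods any of `"PLS"`, `"GBLUP"`.
#' @param predictor `"E+G+GE"` or `"E+G"`.
#' @param use_env_covariates build `H` from the covariate table when one
#'   exists (default), otherwise use the identity.
#' @param inner_folds folds of the nested tuning CV (default 5).
#' @param ncomp_max cap on latent variables evaluated (default
#'   `min(n_train - 1, ncol(X), 30)`).
#' @param chain named vector of GBLUP chain settings
#'   (`iterations`, `burn_in`, `thin`).
#' @param seed master seed; all fold-level seeds derive from it
#'   deterministically, so a rerun reproduces the report exactly.
#' @param scale passed to [pls_fit()].
#' @return an object of class `loeo_report`: per-fold results (`folds`),
#'   global summaries (`global`), relative efficiencies (`re`), and the
#'   aligned held-out observations/predictions (`predictions`).
#' @export
loeo <- function(data, trait = NULL,
                 methods = c("PLS", "GBLUP"),
                 predictor = c("E+G+GE", "E+G"),
                 use_env_covariates = TRUE,
                 inner_folds = 5L, ncomp_max = NULL,
                 chain = c(iterations = 12000L, burn_in = 2000L, thin = 5L),
                 seed = 1L, scale = FALSE) {
  predictor <- match.arg(predictor)
  methods <- match.arg(methods, c("PLS", "GBLUP"), several.ok = TRUE)
  pheno <- data$pheno
  if (is.null(trait)) {
    trait <- setdiff(names(pheno), c("env", "line"))[1L]
    if (is.na(trait)) stop("no trait column found")
  }
  if (!trait %in% names(pheno)) stop("trait '", trait, "' not in phenotype")
  y <- as.numeric(pheno[[trait]])
  ok <- !is.na(y)
  pheno <- pheno[ok, , drop = FALSE]; y <- y[ok]
  if (anyNA(data$markers))
    stop("markers contain missing calls; run qc_markers() first")

  index <- obs_index(pheno$env, pheno$line)
  I <- n_env(index); J <- n_line(index)
  if (I < 2L) stop("leave-one-environment-out needs at least 2 environments")
  miss_mk <- setdiff(levels(index$line), rownames(data$markers))
  if (length(miss_mk))
    stop("lines without marker data: ", paste(miss_mk, collapse = ", "))

  G <- genomic_kinship(data$markers[levels(index$line), , drop = FALSE])
  if (use_env_covariates && !is.null(data$covariates)) {
    H <- env_kinship(data$covariates[levels(index$env), , drop = FALSE])
  } else {
    H <- identity_kinship(levels(index$env))
  }
  L_g <- kinship_sqrt(G)
  L_E <- kinship_sqrt(H)
  bundle <- build_augmented(build_incidence(index), L_E, L_g,
                            predictor = predictor)
  X <- bundle$X_aug

  envs <- levels(index$env)
  folds <- list(); preds <- list()
  for (e in envs) {
    test <- index$env == e
    train <- !test
    if (!any(test)) stop("environment ", e, " has no observations")
    train_lines <- unique(index$line[train])
    new_lines <- setdiff(unique(as.character(index$line[test])),
                         as.character(train_lines))
    row <- list(env = e, n_test = sum(test), n_train = sum(train),
                n_new_lines = length(new_lines),
                train_mean = mean(y[train]))
    pr <- list(y_obs = y[test])

    if ("PLS" %in% methods) {
      sel <- select_ncomp(X[train, , drop = FALSE], y[train],
                          k_folds = inner_folds, ncomp_max = ncomp_max,
                          seed = derive_seed(seed, e, "inner_cv"),
                          scale = scale)
      fit <- pls_fit(X[train, , drop = FALSE], y[train],
                     ncomp = sel$ncomp, scale = scale)
      pr$PLS <- predict(fit, X[test, , drop = FALSE])
      row$ncomp <- sel$ncomp
      row$nrmse_PLS <- nrmse(y[test], pr$PLS)
    }
    if ("GBLUP" %in% methods) {
      idx_train <- obs_index(as.character(index$env[train]),
                             as.character(index$line[train]),
                             env_levels = envs,
                             line_levels = levels(index$line))
      idx_test <- obs_index(as.character(index$env[test]),
                            as.character(index$line[test]),
                            env_levels = envs,
                            line_levels = levels(index$line))
      gf <- gblup_fit(y[train], idx_train, idx_test, G = G, H = H,
                      include_GE = (predictor == "E+G+GE"),
                      iterations = chain[["iterations"]],
                      burn_in = chain[["burn_in"]],
                      thin = chain[["thin"]],
                      seed = derive_seed(seed, e, "gblup"))
      pr$GBLUP <- gf$yhat_test
      row$nrmse_GBLUP <- nrmse(y[test], pr$GBLUP)
    }
    folds[[e]] <- row
    preds[[e]] <- pr
  }

  fold_df <- do.call(rbind, lapply(folds, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(fold_df) <- NULL

  pooled_obs <- unlist(lapply(preds, `[[`, "y_obs"), use.names = FALSE)
  global <- list()
  for (m in methods) {
    pooled_pred <- unlist(lapply(preds, `[[`, m), use.names = FALSE)
    global[[m]] <- c(nrmse_global = nrmse(pooled_obs, pooled_pred),
                     nrmse_env_mean = mean(fold_df[[paste0("nrmse_", m)]]))
  }
  global_df <- data.frame(method = names(global),
                          do.call(rbind, global), row.names = NULL)

  re <- NULL
  if (all(c("PLS", "GBLUP") %in% methods)) {
    re <- data.frame(
      environment = c(envs, "Global"),
      re_nrmse = c(mapply(relative_efficiency, fold_df$nrmse_GBLUP,
                          fold_df$nrmse_PLS),
                   relative_efficiency(
                     global_df$nrmse_global[global_df$method == "GBLUP"],
                     global_df$nrmse_global[global_df$method == "PLS"])),
      row.names = NULL)
  } else {
    warning("relative efficiency requires both PLS and GBLUP; skipped")
  }

  structure(list(folds = fold_df, global = global_df, re = re,
                 predictions = preds, trait = trait, predictor = predictor,
                 methods = methods, use_env_covariates = use_env_covariates,
                 inner_folds = inner_folds, seed = as.integer(seed),
                 chain = chain),
            class = "loeo_report")
}

#' @export
print.loeo_report <- function(x, ...) {
  cat(sprintf("Leave-one-environment-out report: trait '%s', predictor %s\n",
              x$trait, x$predictor))
  print(x$folds, digits = 4)
  cat("\nGlobal (pooled held-out predictions):\n")
  print(x$global, digits = 4)
  if (!is.null(x$re)) {
    cat("\nRelative efficiency (NRMSE_GBLUP / NRMSE_PLS; >1 favours PLS):\n")
    print(x$re, digits = 4)
  }
  invisible(x)
}

#' @export
summary.loeo_report <- function(object, ...) as.data.frame(object)

#' Tidy per-row view of a LOEO report
#'
#' One row per (environment or Global, method) with the NRMSE and, when
#' both methods were run, the relative efficiency.
#'
#' @param x a `loeo_report`.
#' @param ... unused.
#' @export
as.data.frame.loeo_report <- function(x, ...) {
  rows <- list()
  for (m in x$methods) {
    col <- paste0("nrmse_", m)
    rows[[m]] <- data.frame(
      trait = x$trait, predictor = x$predictor,
      environment = c(x$folds$env, "Global"),
      method = m,
      nrmse = c(x$folds[[col]],
                x$global$nrmse_global[x$global$method == m]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(x$re))
    out$re_nrmse <- x$re$re_nrmse[match(out$environment,
                                        x$re$environment)]
  out
}

#' Bar plot of per-environment relative efficiency
#'
#' @param x a `loeo_report` run with both methods.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.loeo_report <- function(x, ...) {
  if (is.null(x$re))
    stop("plot requires a report with both PLS and GBLUP")
  bp <- graphics::barplot(x$re$re_nrmse, names.arg = x$re$environment,
                          ylab = "RE (NRMSE GBLUP / NRMSE PLS)",
                          main = sprintf("Relative efficiency, %s (%s)",
                                         x$trait, x$predictor), ...)
  graphics::abline(h = 1, lty = 2)
  invisible(bp)
}
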