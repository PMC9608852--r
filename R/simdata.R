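#' Simulate a multi-environment trial from the reaction-norm model
#'
#' Draws a complete synthetic dataset — marker matrix, optional
#' environmental covariates, and phenotypes — from the variance-component
#' model used throughout the package:
#' \deqn{y_{ij} = \mu + L_i + g_j + gL_{ij} + \epsilon_{ij}}
#' with \eqn{L \sim N(0, \sigma^2_E H)}, \eqn{g \sim N(0, \sigma^2_g G)},
#' \eqn{gL \sim N(0, \sigma^2_{gL}(H \otimes G))} and i.i.d. residuals.
#' Markers are drawn per locus as Binomial(2, p_k) with allele
#' frequencies uniform on `freq_range`; covariates are standard normal.
#' The relationship matrices used to draw the effects are the REALIZED
#' `G` and `H` computed from the drawn markers/covariates, so
#' parameter-recovery experiments are internally consistent. With `r = 0`
#' no covariate table is produced and `H` is the identity (environment
#' effects i.i.d.).
#'
#' Unbalancedness removes `round(missing_frac * I * J)` (environment,
#' line) combinations uniformly at random, redrawing the removal set if
#' it would orphan a line or an environment entirely.
#'
#' @param J,I,p,r numbers of lines, environments, markers and
#'   environmental covariates (`r = 0` for none).
#' @param varcomp named numeric vector of the true variance components
#'   `env`, `line`, `ge`, `resid` (all nonnegative).
#' @param mu intercept (grand mean of the trait).
#' @param missing_frac fraction of (environment, line) combinations left
#'   unobserved, in `[0, 1)`.
#' @param freq_range range of marker allele frequencies, within
#'   (0.05, 0.95).
#' @param seed integer seed; the dataset is reproducible from it.
#' @return an object of class `met_sim`: a list with `markers`,
#'   `covariates` (or `NULL`), `pheno` (data frame `env`, `line`, `y`),
#'   `index` (the [obs_index()]), `G`, `H` (realized kinships) and
#'   `truth` (drawn effects, residuals and the configuration).
#' @examples
#' sim <- simulate_met(J = 30, I = 4, p = 200, seed = 7)
#' head(sim$pheno)
#' @export
simulate_met <- function(J = 100L, I = 5L, p = 1000L, r = 0L,
                         varcomp = c(env = 1, line = 1, ge = 0.5, resid = 1),
                         mu = 10, missing_frac = 0,
                         freq_range = c(0.1, 0.9), seed = 1L) {
  if (J < 2L) stop("J must be >= 2")
  if (I < 2L) stop("I must be >= 2")
  if (p < 1L) stop("p must be >= 1")
  need <- c("env", "line", "ge", "resid")
  if (!all(need %in% names(varcomp))) stop("varcomp must name ",
                                           paste(need, collapse = ", "))
  if (any(varcomp < 0)) stop("variance components must be nonnegative")
  if (missing_frac < 0 || missing_frac >= 1)
    stop("missing_frac must be in [0, 1)")
  if (freq_range[1] < 0.05 || freq_range[2] > 0.95 ||
      freq_range[1] >= freq_range[2])
    stop("freq_range must be increasing and within (0.05, 0.95)")

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed))
  set.seed(as.integer(seed))

  line_ids <- sprintf("L%03d", seq_len(J))
  env_ids <- sprintf("E%02d", seq_len(I))
  freq <- stats::runif(p, freq_range[1], freq_range[2])
  markers <- vapply(freq, function(pk) stats::rbinom(J, 2L, pk),
                    integer(J))
  dimnames(markers) <- list(line_ids, sprintf("M%05d", seq_len(p)))

  covariates <- NULL
  if (r > 0L) {
    covariates <- matrix(stats::rnorm(I * r), I, r,
                         dimnames = list(env_ids,
                                         sprintf("EC%02d", seq_len(r))))
    H <- env_kinship(covariates)
  } else {
    H <- identity_kinship(env_ids)
  }
  G <- genomic_kinship(markers)
  L_H <- kinship_sqrt(H)
  L_G <- kinship_sqrt(G)

  L <- sqrt(varcomp["env"]) * drop(L_H %*% stats::rnorm(I))
  g <- sqrt(varcomp["line"]) * drop(L_G %*% stats::rnorm(J))
  gl <- sqrt(varcomp["ge"]) * drop(kron(L_H, L_G) %*% stats::rnorm(I * J))
  names(L) <- env_ids; names(g) <- line_ids

  # full environment-major grid, then uniform removal of combinations
  grid_env <- rep(seq_len(I), each = J)
  grid_line <- rep(seq_len(J), times = I)
  n_remove <- round(missing_frac * I * J)
  keep <- seq_len(I * J)
  if (n_remove > 0L) {
    for (attempt in seq_len(1000L)) {
      drop_idx <- sample(I * J, n_remove)
      keep_try <- setdiff(seq_len(I * J), drop_idx)
      if (length(unique(grid_env[keep_try])) == I &&
          length(unique(grid_line[keep_try])) == J) {
        keep <- keep_try
        break
      }
      if (attempt == 1000L)
        stop("could not draw an unbalanced design without orphaning a ",
             "line or environment; lower missing_frac")
    }
  }
  ei <- grid_env[keep]; li <- grid_line[keep]
  eps <- stats::rnorm(length(keep), 0, sqrt(varcomp["resid"]))
  signal <- mu + L[ei] + g[li] + gl[keep]
  y <- signal + eps

  pheno <- data.frame(env = env_ids[ei], line = line_ids[li], y = y,
                      stringsAsFactors = FALSE)
  index <- obs_index(pheno$env, pheno$line,
                     env_levels = env_ids, line_levels = line_ids)
  structure(list(markers = markers, covariates = covariates,
                 pheno = pheno, index = index, G = G, H = H,
                 truth = list(mu = mu, L = L, g = g, gl = gl, eps = eps,
                              signal = unname(signal), varcomp = varcomp,
                              freq = freq, seed = as.integer(seed),
                              missing_frac = missing_frac)),
            class = "met_sim")
}

#' @export
print.met_sim <- function(x, ...) {
  cat(sprintf("<met_sim> %d lines x %d environments, %d markers%s, %d phenotype rows\n",
              n_line(x$index), n_env(x$index), ncol(x$markers),
              if (is.null(x$covariates)) ""
              else sprintf(", %d env covariates", ncol(x$covariates)),
              nrow(x$pheno)))
  invisible(x)
}

#' Best-achievable NRMSE of a simulated dataset
#'
#' The normalized RMSE between the simulated phenotypes and the true
#' signal (intercept plus all drawn effects) — i.e. the residual noise
#' floor. No predictor can beat this on the same rows except by chance,
#' so it bounds the NRMSE of any fitted method from below.
#'
#' @param sim a [simulate_met()] result.
#' @return the floor NRMSE (zero when the residual variance is zero).
#' @export
truth_nrmse_floor <- function(sim) {
  stopifnot(inherits(sim, "met_sim"))
  if (all(sim$truth$eps == 0)) return(0)
  nrmse(sim$pheno$y, sim$truth$signal)
}
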