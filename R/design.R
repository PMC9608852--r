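#' Observation index of a multi-environment trial
#'
#' Records which (environment, line) combinations were actually observed,
#' together with the full sets of environment and line levels. It defines
#' the row space of the phenotype vector and of every design matrix.
#' Unbalanced trials simply list fewer than `I * J` pairs.
#'
#' @param env,line vectors of equal length giving the environment and line
#'   of each observation, in phenotype row order.
#' @param env_levels,line_levels optional full level sets (character).
#'   Defaults to the sorted unique values observed. Supplying them allows
#'   levels present in the kinship matrices but unobserved here.
#' @return an `obs_index` object: a data frame with factor columns `env`
#'   and `line`.
#' @export
obs_index <- function(env, line, env_levels = NULL, line_levels = NULL) {
  if (length(env) != length(line)) stop("env and line must have equal length")
  env <- as.character(env); line <- as.character(line)
  if (is.null(env_levels)) env_levels <- sort(unique(env))
  if (is.null(line_levels)) line_levels <- sort(unique(line))
  if (!all(env %in% env_levels)) stop("env values outside env_levels")
  if (!all(line %in% line_levels)) stop("line values outside line_levels")
  key <- paste(env, line, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (environment, line) pair: ",
         gsub("\r", " / ", d, fixed = TRUE))
  }
  out <- data.frame(env = factor(env, levels = env_levels),
                    line = factor(line, levels = line_levels),
                    stringsAsFactors = FALSE)
  class(out) <- c("obs_index", "data.frame")
  out
}

n_env <- function(index) nlevels(index$env)
n_line <- function(index) nlevels(index$line)

#' @export
print.obs_index <- function(x, ...) {
  cat(sprintf("<obs_index> %d observations, %d environments x %d lines (%s)\n",
              nrow(x), n_env(x), n_line(x),
              if (nrow(x) == n_env(x) * n_line(x)) "balanced" else "unbalanced"))
  invisible(x)
}

#' Incidence (dummy) design matrices for a trial
#'
#' Builds the 0/1 incidence matrices for environments (`X_L`, n x I),
#' lines (`X_g`, n x J), and their interaction (`X_gL`, n x IJ). Every row
#' of each matrix sums to exactly one. Interaction columns follow the
#' environment-major Kronecker convention: column `(i - 1) * J + j`
#' corresponds to (environment i, line j), matching the block structure of
#' `kron(L_E, L_g)`. All `I * J` interaction columns are kept even when the
#' trial is unbalanced; only rows are dropped.
#'
#' @param index an [obs_index()].
#' @return list with components `X_L`, `X_g`, `X_gL`.
#' @export
build_incidence <- function(index) {
  stopifnot(inherits(index, "obs_index"))
  n <- nrow(index)
  I <- n_env(index); J <- n_line(index)
  ei <- as.integer(index$env); li <- as.integer(index$line)
  X_L <- matrix(0, n, I, dimnames = list(NULL, levels(index$env)))
  X_L[cbind(seq_len(n), ei)] <- 1
  X_g <- matrix(0, n, J, dimnames = list(NULL, levels(index$line)))
  X_g[cbind(seq_len(n), li)] <- 1
  inter_names <- as.vector(t(outer(levels(index$env), levels(index$line),
                                   paste, sep = ":")))
  X_gL <- matrix(0, n, I * J, dimnames = list(NULL, inter_names))
  X_gL[cbind(seq_len(n), (ei - 1L) * J + li)] <- 1
  list(X_L = X_L, X_g = X_g, X_gL = X_gL)
}

#' Relationship-augmented design matrix for PLS
#'
#' Post-multiplies the incidence blocks by the symmetric square roots of
#' the environmental and genomic relationship matrices and binds them into
#' the single predictor matrix used by the PLS model:
#' \deqn{X = [X_L L_E \;|\; X_g L_g \;|\; X_{gL}(L_E \otimes L_g)]}
#' with the third block present only when the predictor includes the
#' genotype-by-environment (GE) term. Because the multipliers are square,
#' each augmented block has the same dimension as its incidence block, so
#' `X` is `n x (I + J + IJ)` with GE and `n x (I + J)` without.
#'
#' @param incidence list as returned by [build_incidence()].
#' @param L_E symmetric square root of the environmental relationship
#'   matrix (I x I), from [kinship_sqrt()].
#' @param L_g symmetric square root of the genomic relationship matrix
#'   (J x J).
#' @param predictor `"E+G+GE"` (default) or `"E+G"`.
#' @return a `design_bundle`: list with the augmented matrix `X_aug`, the
#'   incidence blocks, the roots and the predictor tag.
#' @export
build_augmented <- function(incidence, L_E, L_g,
                            predictor = c("E+G+GE", "E+G")) {
  predictor <- match.arg(predictor)
  L_E <- as.matrix(L_E); L_g <- as.matrix(L_g)
  I <- ncol(incidence$X_L); J <- ncol(incidence$X_g)
  if (!all(dim(L_E) == c(I, I)))
    stop("L_E must be ", I, " x ", I, " to match the environment incidence")
  if (!all(dim(L_g) == c(J, J)))
    stop("L_g must be ", J, " x ", J, " to match the line incidence")
  blocks <- list(incidence$X_L %*% L_E, incidence$X_g %*% L_g)
  colnames(blocks[[1L]]) <- colnames(incidence$X_L)
  colnames(blocks[[2L]]) <- colnames(incidence$X_g)
  if (predictor == "E+G+GE") {
    blocks[[3L]] <- incidence$X_gL %*% kron(L_E, L_g)
    colnames(blocks[[3L]]) <- colnames(incidence$X_gL)
  }
  structure(list(X_aug = do.call(cbind, blocks),
                 X_L = incidence$X_L, X_g = incidence$X_g,
                 X_gL = incidence$X_gL,
                 L_E = L_E, L_g = L_g, predictor = predictor),
            class = "design_bundle")
}

#' @export
print.design_bundle <- function(x, ...) {
  cat(sprintf("<design_bundle> predictor=%s, X_aug %d x %d\n",
              x$predictor, nrow(x$X_aug), ncol(x$X_aug)))
  invisible(x)
}
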