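#' Relationship (kinship) matrices from markers or environmental covariates
#'
#' `genomic_kinship()` builds the genomic relationship matrix G of a set of
#' lines from a matrix of SNP dosage codes (0/1/2), and `env_kinship()`
#' builds the environmental relationship matrix H of a set of environments
#' from a table of environmental covariates. Both use the same recipe:
#' columns are centered and scaled to unit sample variance
#' (`n - 1` denominator), constant (monomorphic) columns are dropped, and
#' the kinship is the cross-product of the standardized matrix divided by
#' the number of retained columns,
#' \deqn{K = W W^\top / p'}
#' With all columns retained this gives the exact identity
#' \eqn{\mathrm{tr}(K) = n - 1} where `n` is the number of rows.
#'
#' @param markers numeric matrix of SNP codes in \{0, 1, 2\}, lines in rows,
#'   markers in columns. Row names (line IDs) are carried through. Missing
#'   values are not allowed: run [qc_markers()] first.
#' @param method scaling of the marker matrix. `"standardized"` (default)
#'   centers and scales each marker column to unit sample variance;
#'   `"vanraden1"` centers by twice the allele frequency and divides the
#'   cross-product by \eqn{2\sum_k p_k(1-p_k)}.
#' @return an object of class `kinship`: the symmetric relationship matrix
#'   with attributes `ids` (row/column identifiers), `kind` (`"genomic"`,
#'   `"environmental"` or `"identity"`) and `n_dropped` (constant columns
#'   removed before the cross-product).
#' @seealso [kinship_sqrt()] for the symmetric square root used to augment
#'   design matrices, [identity_kinship()] for the no-covariate case.
#' @examples
#' M <- matrix(c(0, 2, 1, 0, 2, 1), nrow = 3,
#'             dimnames = list(c("L1", "L2", "L3"), NULL))
#' G <- genomic_kinship(M)
#' sum(diag(G))  # J - 1 = 2
#' @export
genomic_kinship <- function(markers, method = c("standardized", "vanraden1")) {
  method <- match.arg(method)
  markers <- as.matrix(markers)
  if (nrow(markers) < 2L)
    stop("need at least 2 lines to compute a genomic relationship matrix")
  if (anyNA(markers))
    stop("marker matrix contains missing values; apply qc_markers() first")
  if (!all(markers %in% c(0, 1, 2)))
    stop("marker codes must be 0, 1 or 2")
  ids <- rownames(markers)
  if (is.null(ids)) ids <- paste0("L", seq_len(nrow(markers)))
  if (method == "vanraden1") {
    p_hat <- colMeans(markers) / 2
    keep <- p_hat > 0 & p_hat < 1
    if (!any(keep)) stop("no informative markers (all monomorphic)")
    Wc <- sweep(markers[, keep, drop = FALSE], 2L, 2 * p_hat[keep])
    denom <- 2 * sum(p_hat[keep] * (1 - p_hat[keep]))
    K <- tcrossprod(Wc) / denom
    n_drop <- sum(!keep)
  } else {
    std <- standardize_columns(markers)
    if (std$n_kept == 0L) stop("no informative markers (all monomorphic)")
    K <- tcrossprod(std$W) / std$n_kept
    n_drop <- std$n_dropped
  }
  new_kinship(K, ids = ids, kind = "genomic", n_dropped = n_drop)
}

#' @rdname genomic_kinship
#' @param covariates numeric matrix or data frame of environmental
#'   covariates, environments in rows, covariates in columns. Row names
#'   (environment IDs) are carried through.
#' @export
env_kinship <- function(covariates) {
  covariates <- as.matrix(covariates)
  if (!is.numeric(covariates)) stop("covariates must be numeric")
  if (nrow(covariates) < 2L)
    stop("need at least 2 environments to compute an environmental relationship matrix")
  if (ncol(covariates) < 1L) stop("need at least 1 covariate")
  if (anyNA(covariates)) stop("covariate table contains missing values")
  ids <- rownames(covariates)
  if (is.null(ids)) ids <- paste0("E", seq_len(nrow(covariates)))
  std <- standardize_columns(covariates)
  if (std$n_kept == 0L) stop("all covariates are constant across environments")
  K <- tcrossprod(std$W) / std$n_kept
  new_kinship(K, ids = ids, kind = "environmental", n_dropped = std$n_dropped)
}

#' Identity environmental relationship matrix
#'
#' Used when no environmental covariates are available, in which case the
#' environmental relationship matrix reduces to the identity and environment
#' effects are exchangeable a priori.
#'
#' @param ids environment identifiers (character vector), or a single
#'   integer count `I` (IDs are then `E1 ... EI`).
#' @return a `kinship` object of kind `"identity"`.
#' @export
identity_kinship <- function(ids) {
  if (is.numeric(ids) && length(ids) == 1L) {
    if (ids < 1) stop("environment count must be at least 1")
    ids <- paste0("E", seq_len(ids))
  }
  ids <- as.character(ids)
  if (length(ids) < 1L) stop("environment count must be at least 1")
  new_kinship(diag(length(ids)), ids = ids, kind = "identity", n_dropped = 0L)
}

# center/scale columns to unit sample variance, dropping constant columns
standardize_columns <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  keep <- sdv > 0
  W <- sweep(X[, keep, drop = FALSE], 2L, mu[keep])
  W <- sweep(W, 2L, sdv[keep], "/")
  list(W = W, n_kept = sum(keep), n_dropped = sum(!keep))
}

new_kinship <- function(K, ids, kind, n_dropped = 0L) {
  K <- (K + t(K)) / 2          # enforce exact symmetry
  dimnames(K) <- list(ids, ids)
  structure(K, ids = ids, kind = kind, n_dropped = as.integer(n_dropped),
            class = c("kinship", "matrix", "array"))
}

#' @export
print.kinship <- function(x, ...) {
  cat(sprintf("<kinship> kind=%s, %d x %d", attr(x, "kind"),
              nrow(x), ncol(x)))
  nd <- attr(x, "n_dropped")
  if (!is.null(nd) && nd > 0L) cat(sprintf(" (%d constant columns dropped)", nd))
  cat(sprintf(", trace = %.6g\n", sum(diag(x))))
  invisible(x)
}

#' Symmetric matrix square root of a kinship matrix
#'
#' Computes the unique symmetric positive semi-definite square root
#' \eqn{L = U \mathrm{diag}(\sqrt{\lambda}) U^\top} from the symmetric
#' eigendecomposition, so that \eqn{L L = K}. Small negative eigenvalues
#' (floating-point noise) are clipped to zero; eigenvalues below
#' `-1e-8 * max(|lambda|)` raise an error because the matrix is then not
#' positive semi-definite in any meaningful sense.
#'
#' The symmetric (rather than Cholesky) root is used throughout the package
#' so that `X %*% L` is well defined independent of any transposition
#' convention.
#'
#' @param K a symmetric matrix, typically a `kinship` object.
#' @return a symmetric matrix of class `kinship_root` with the same
#'   dimnames as `K`.
#' @export
kinship_sqrt <- function(K) {
  K <- unclass(as.matrix(K))
  if (nrow(K) != ncol(K)) stop("kinship matrix must be square")
  if (max(abs(K - t(K))) > 1e-10 * max(abs(K), 1))
    stop("kinship matrix is not symmetric")
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  lam <- eg$values
  lam_max <- max(abs(lam), .Machine$double.eps)
  if (any(lam < -1e-8 * lam_max))
    stop("matrix not PSD: eigenvalue ", format(min(lam)), " below tolerance")
  lam[lam < 0] <- 0
  L <- eg$vectors %*% (sqrt(lam) * t(eg$vectors))
  L <- (L + t(L)) / 2
  dimnames(L) <- dimnames(K)
  structure(L, class = c("kinship_root", "matrix", "array"))
}

#' Kronecker product
#'
#' Thin wrapper over base [kronecker()] that preserves the block
#' convention used package-wide for genotype-by-environment covariance
#' structures: `kron(A, B)` has block `(i, j)` equal to `A[i, j] * B`, so
#' with environments in `A` and lines in `B` the combined index is
#' environment-major (environment outer, line inner).
#'
#' @param A,B numeric matrices.
#' @return the Kronecker product, a
#'   `(nrow(A)*nrow(B)) x (ncol(A)*ncol(B))` matrix.
#' @export
kron <- function(A, B) kronecker(as.matrix(A), as.matrix(B))
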