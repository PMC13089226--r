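#' Brownian-motion covariance matrix from a dated tree
#'
#' Under Brownian trait evolution the expected covariance between two tips
#' is proportional to the shared path length from the root to their most
#' recent common ancestor; the diagonal holds root-to-tip distances.
#' Computed directly from the edge matrix by path-length bookkeeping.
#'
#' @param tree An `ape` phylo with branch lengths (Myr).
#' @param taxa Tip labels to include (default all), in the requested order.
#' @return A symmetric positive semi-definite matrix (Myr) with dimnames.
#' @export
brownian_covariance <- function(tree, taxa = tree$tip.label) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing)) {
    stop("taxa absent from the tree: ", paste(missing, collapse = ", "))
  }
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  # root-to-node depths by preorder accumulation over the edge matrix
  depth <- numeric(nnode)
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    depth[ord$edge[i, 2L]] <- depth[ord$edge[i, 1L]] + ord$edge.length[i]
  }
  idx <- match(taxa, tree$tip.label)
  mrca <- ape::mrca(tree, full = FALSE)
  C <- matrix(depth[mrca[idx, idx, drop = FALSE]], length(idx), length(idx))
  diag(C) <- depth[idx]
  dimnames(C) <- list(taxa, taxa)
  C
}

#' Phylogenetic generalized least squares under Brownian motion
#'
#' Fits `y = intercept + slope * x` by generalized least squares with error
#' covariance proportional to the Brownian matrix C of the tree:
#' `beta = (X' C^-1 X)^-1 X' C^-1 y`. Both the ML and REML log-likelihoods
#' are computed; ML feeds the AICc (k = 3) so that PGLS and OLS models are
#' compared on the same likelihood flavor.
#'
#' @param x,y Numeric vectors (log10 scale), aligned with `tree` tips or
#'   with the rows of `C`.
#' @param tree An `ape` phylo with branch lengths; ignored when `C` is given.
#' @param C Optional precomputed covariance matrix.
#' @param taxa Optional tip labels aligning x/y with the tree.
#' @return A list of class `log_linear_fit` with `method = "PGLS"`, fields
#'   `slope`, `intercept`, `n`, `sigma2` (ML), `loglik` (ML), `loglik_reml`,
#'   `aicc`, and `predict`.
#' @export
fit_pgls <- function(x, y, tree = NULL, C = NULL, taxa = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  n <- length(x)
  if (is.null(C)) {
    if (is.null(tree)) stop("either a tree or a covariance matrix is required")
    taxa <- taxa %||% tree$tip.label
    if (length(taxa) != n) stop("taxa must align with x and y")
    C <- brownian_covariance(tree, taxa)
  }
  stopifnot(nrow(C) == n, ncol(C) == n)
  R <- tryCatch(chol(C), error = function(e) {
    stop("Brownian covariance matrix is singular or not positive definite")
  })
  X <- cbind(intercept = 1, slope = x)
  # whiten by the Cholesky factor: solve R' z = v
  wX <- backsolve(R, X, transpose = TRUE)
  wy <- backsolve(R, y, transpose = TRUE)
  beta <- qr.coef(qr(wX), wy)
  r <- wy - wX %*% beta
  rss <- sum(r * r)
  logdetC <- 2 * sum(log(diag(R)))
  sigma2 <- rss / n
  loglik <- -0.5 * (n * log(2 * pi * sigma2) + logdetC + n)
  p <- ncol(X)
  sigma2_reml <- rss / (n - p)
  loglik_reml <- -0.5 * ((n - p) * log(2 * pi * sigma2_reml) + logdetC +
                           determinant(crossprod(wX), logarithm = TRUE)$modulus[1L] +
                           (n - p))
  structure(list(slope = unname(beta[2L]), intercept = unname(beta[1L]),
                 n = n, r_squared = NULL, sigma2 = sigma2,
                 loglik = loglik, loglik_reml = loglik_reml,
                 aicc = aicc(loglik, 3L, n), method = "PGLS",
                 predict = function(xnew) unname(beta[1L] + beta[2L] * xnew)),
            class = "log_linear_fit")
}

#' Time-calibrate a cladogram by the minimum-branch-length method
#'
#' Dates a (possibly polytomous) topology from tip first-appearance ages:
#' polytomies are resolved randomly under the seed, node ages are
#' initialized to the age of their oldest descendant, and parent ages are
#' pushed older until every branch is at least `mbl` long (default 1 Myr).
#' Deterministic for a given seed.
#'
#' @param topology An `ape` phylo; edge lengths, if any, are ignored.
#' @param tip_ages Named numeric vector of first-appearance dates (Ma),
#'   one per tip.
#' @param mbl Minimum branch length (Myr).
#' @param seed Integer seed for random polytomy resolution.
#' @return A dated `phylo` with branch lengths in Myr and attributes
#'   `root.time` (Ma) and `tip.ages`.
#' @export
time_calibrate_mbl <- function(topology, tip_ages, mbl = 1, seed = 1L) {
  stopifnot(inherits(topology, "phylo"), mbl > 0)
  missing <- setdiff(topology$tip.label, names(tip_ages))
  if (length(missing)) {
    stop("missing tip age(s) for: ", paste(missing, collapse = ", "))
  }
  set.seed(seed)
  tree <- ape::multi2di(topology, random = TRUE)
  tree$edge.length <- NULL
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  age <- numeric(nnode)
  age[seq_len(ntip)] <- tip_ages[tree$tip.label]
  ord <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[i, 1L]; child <- ord$edge[i, 2L]
    age[parent] <- max(age[parent], age[child] + mbl)
  }
  tree$edge.length <- age[tree$edge[, 1L]] - age[tree$edge[, 2L]]
  attr(tree, "root.time") <- age[ntip + 1L]
  attr(tree, "tip.ages") <- age[seq_len(ntip)]
  tree
}
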