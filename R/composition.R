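#' @title Community composition statistics
#' @description First-principles implementations of the composition analyses:
#'   read-count filtering and rarefaction, Bray-Curtis dissimilarity,
#'   principal coordinates analysis, and permutational multivariate ANOVA
#'   (PERMANOVA) with sequential sums of squares.
#' @name composition
NULL

#' Filter shallow samples and rarefy to even depth
#'
#' Samples with fewer than `min_reads` total reads are removed; each retained
#' sample is subsampled without replacement to exactly `depth` reads (default:
#' the minimum retained row sum), standardising sequencing effort.
#'
#' @param counts Samples x taxa non-negative integer matrix with row names.
#' @param min_reads Minimum library size to retain a sample (default 1000;
#'   a sample with exactly `min_reads` reads is retained).
#' @param depth Rarefaction depth; must not exceed any retained row sum.
#' @param seed RNG seed for the subsampling.
#' @return The filtered, rarefied count matrix (all row sums equal `depth`).
#' @export
filter_and_rarefy <- function(counts, min_reads = 1000, depth = NULL,
                              seed = 1L) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  keep <- rowSums(counts) >= min_reads
  if (!any(keep)) stop("all samples fall below min_reads = ", min_reads)
  counts <- counts[keep, , drop = FALSE]
  if (is.null(depth)) depth <- min(rowSums(counts))
  if (depth > min(rowSums(counts)))
    stop("depth exceeds the smallest retained library")
  set.seed(seed)
  out <- counts
  for (i in seq_len(nrow(counts))) {
    row <- counts[i, ]
    if (sum(row) == depth) next  # already at depth: unchanged by construction
    pool <- rep.int(seq_along(row), row)
    drawn <- sample(pool, depth, replace = FALSE)
    out[i, ] <- tabulate(drawn, nbins = length(row))
  }
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(u, v) = sum|u - v| / sum(u + v)`, in [0, 1]: 0 for identical samples,
#' 1 for samples sharing no taxa.
#'
#' @param counts Samples x taxa abundance matrix (rarefied).
#' @return A symmetric `n x n` matrix with zero diagonal.
#' @export
bray_curtis <- function(counts) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (any(rowSums(counts) == 0))
    stop("Bray-Curtis undefined for empty samples")
  d <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- sum(abs(counts[i, ] - counts[j, ]))
    den <- sum(counts[i, ] + counts[j, ])
    d[i, j] <- d[j, i] <- num / den
  }
  d
}

# Gower double-centred matrix from a distance matrix: G = -0.5 * C A C with
# A = d^2 elementwise and C the centring matrix.
.gower_centre <- function(d) {
  a <- -0.5 * d^2
  n <- nrow(d)
  sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: eigendecomposition of the Gower double-centred
#' squared-distance matrix; coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues. Negative eigenvalues, which arise
#' for semi-metric dissimilarities such as Bray-Curtis, are reported rather
#' than silently dropped; percent variance is computed over positive
#' eigenvalues.
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @param tol Eigenvalues within `tol * max(|eigenvalue|)` of zero are
#'   treated as null axes.
#' @return List with `coordinates` (n x n_positive_axes), `eigenvalues`
#'   (all of them, descending), `percent_variance` (per positive axis).
#' @export
pcoa <- function(d, tol = 1e-8) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  e <- eigen(.gower_centre(d), symmetric = TRUE)
  thresh <- tol * max(abs(e$values))
  pos <- e$values > thresh
  coords <- sweep(e$vectors[, pos, drop = FALSE], 2,
                  sqrt(e$values[pos]), `*`)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords,
       eigenvalues = e$values,
       percent_variance = 100 * e$values[pos] / sum(e$values[pos]))
}

#' Permutational multivariate ANOVA on a distance matrix
#'
#' Partitions the total sum of squared distances among factors with
#' sequential (Type I) sums of squares computed from projection (hat)
#' matrices applied to the Gower-centred matrix, and assesses significance by
#' permuting sample labels. The p-value uses the add-one correction
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)` and can never be exactly
#' zero.
#'
#' @param d Symmetric distance matrix.
#' @param factors Data frame of factors (one row per sample); terms enter the
#'   model in column order (sequential SS).
#' @param n_perm Number of permutations (default 9999).
#' @param seed RNG seed.
#' @return Data frame with one row per term plus a residual row: `df`,
#'   `sum_sq`, `pseudo_F`, `partial_R2`, `p_value`.
#' @export
permanova <- function(d, factors, n_perm = 9999, seed = 1L) {
  d <- as.matrix(d)
  factors <- as.data.frame(factors)
  n <- nrow(d)
  stopifnot(nrow(factors) == n, n_perm >= 1)
  for (nm in names(factors)) {
    factors[[nm]] <- factor(factors[[nm]])
    if (nlevels(factors[[nm]]) < 2)
      stop("factor '", nm, "' has fewer than 2 levels")
  }
  G <- .gower_centre(d)
  terms <- names(factors)

  # sequential hat matrices: H_k projects onto the span of terms 1..k
  design <- function(upto) {
    X <- matrix(1, n, 1)
    for (t in terms[seq_len(upto)])
      X <- cbind(X, stats::model.matrix(~f, data.frame(f = factors[[t]]))[, -1,
                                                                          drop = FALSE])
    X
  }
  hats <- lapply(0:length(terms), function(k) {
    X <- design(k)
    if (qr(X)$rank < ncol(X) && k > 0)
      stop("confounded factors: '", terms[k],
           "' is aliased with earlier terms")
    X %*% solve(crossprod(X), t(X))
  })
  df_term <- vapply(factors, function(f) nlevels(f) - 1L, integer(1))
  df_res <- n - 1L - sum(df_term)

  # tr(H G) = sum(H * G) for symmetric H, G: avoids the full matrix product
  ss_parts <- function(Gm) {
    ss <- vapply(seq_along(terms), function(k)
      sum(hats[[k + 1]] * Gm) - sum(hats[[k]] * Gm), numeric(1))
    ss_tot <- sum(diag(Gm))
    c(ss, ss_tot - sum(ss))
  }
  obs <- ss_parts(G)
  ss_res <- obs[length(obs)]
  F_obs <- (obs[seq_along(terms)] / df_term) / (ss_res / df_res)

  set.seed(seed)
  exceed <- rep(0L, length(terms))
  for (p in seq_len(n_perm)) {
    idx <- sample.int(n)
    ssp <- ss_parts(G[idx, idx])
    Fp <- (ssp[seq_along(terms)] / df_term) / (ssp[length(ssp)] / df_res)
    exceed <- exceed + (Fp >= F_obs - 1e-12)
  }
  ss_tot <- sum(obs)
  data.frame(term = c(terms, "residual"),
             df = c(df_term, df_res),
             sum_sq = obs,
             pseudo_F = c(F_obs, NA_real_),
             partial_R2 = obs / ss_tot,
             p_value = c((1 + exceed) / (1 + n_perm), NA_real_),
             row.names = NULL)
}
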