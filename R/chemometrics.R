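## Chemometrics: column standardization, single-linkage agglomeration on
## Euclidean distances with deterministic tie-breaking, Newick export, and
## PCA via eigendecomposition of the covariance/correlation matrix.
##
## The agglomeration and the eigendecomposition are implemented here rather
## than delegated because the package guarantees bit-reproducible trees and
## loadings: ties merge the lexicographically smallest label pair, and each
## principal component is oriented so its largest-magnitude loading is
## positive. stats::hclust and stats::prcomp make neither guarantee.

#' Standardize descriptor columns
#'
#' Centers each column to mean 0 and scales to sample standard deviation 1
#' (n-1 denominator), the conventional pre-treatment before distance-based
#' and principal component analyses of descriptors on incommensurate
#' scales.
#'
#' @param table a descriptor table (see [as_descriptor_table()]).
#' @return the standardized table (numeric matrix, same dimnames).
#' @export
standardize <- function(table) {
  table <- as_descriptor_table(table)
  sds <- apply(table, 2L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("cannot standardize constant column(s): %s",
                 paste(colnames(table)[sds == 0], collapse = ", ")),
         call. = FALSE)
  }
  scale(table, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Single-linkage hierarchical clustering on Euclidean distances
#'
#' Agglomerative clustering where the distance between two clusters is the
#' minimum pairwise Euclidean distance between their members. When several
#' candidate merges tie at the minimum distance, the pair whose member
#' labels sort lexicographically smallest is merged, so the tree is fully
#' deterministic.
#'
#' @param table a descriptor table.
#' @param axis cluster `"rows"` (compounds; default) or `"columns"`
#'   (descriptors).
#' @param standardize standardize columns first (default `FALSE`; raw
#'   values keep the magnitude structure of the descriptors, which is
#'   itself informative when comparing logP scales).
#' @return an object of class `"linkage_tree"`: list with `labels` (leaf
#'   labels), `merge` (n-1 x 2 matrix, `stats::hclust()` convention:
#'   negative entries are leaves, positive entries earlier merges),
#'   `height` (merge heights, non-decreasing) and `members` (list of
#'   `list(a =, b =)` character vectors giving the two member sets joined
#'   at each merge).
#' @examples
#' tab <- load_fixture("table4_theoretical_logp")
#' single_linkage(tab)
#' @export
single_linkage <- function(table, axis = c("rows", "columns"),
                           standardize = FALSE) {
  axis <- match.arg(axis)
  table <- as_descriptor_table(table)
  if (standardize) table <- standardize(table)
  if (axis == "columns") table <- t(table)
  n <- nrow(table)
  if (n < 2L) stop("need >= 2 items on the clustering axis", call. = FALSE)
  labels <- rownames(table)
  d <- as.matrix(stats::dist(table))

  ## active clusters: id -> leaf indices; id negative for leaves,
  ## positive = merge number (hclust convention)
  clusters <- lapply(seq_len(n), function(i) i)
  ids <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- vector("list", n - 1L)

  ## single-linkage distance between clusters = min pairwise
  clu_dist <- function(i, j) min(d[clusters[[i]], clusters[[j]]])
  ## tie-break key: sorted member labels, collapsed
  clu_key <- function(i) paste(sort(labels[clusters[[i]]]), collapse = "\1")

  for (step in seq_len(n - 1L)) {
    k <- length(clusters)
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in seq((i + 1L), k)) {
        dij <- clu_dist(i, j)
        if (is.null(best) || dij < best$d - 1e-12 ||
            (abs(dij - best$d) <= 1e-12 && {
              key <- sort(c(clu_key(i), clu_key(j)))
              bkey <- sort(c(clu_key(best$i), clu_key(best$j)))
              key[1] < bkey[1] || (key[1] == bkey[1] && key[2] < bkey[2])
            })) {
          best <- list(i = i, j = j, d = dij)
        }
      }
    }
    i <- best$i; j <- best$j
    ## present the smaller-keyed member set first
    if (clu_key(j) < clu_key(i)) { tmp <- i; i <- j; j <- tmp }
    merge[step, ] <- c(ids[i], ids[j])
    height[step] <- best$d
    members[[step]] <- list(a = sort(labels[clusters[[i]]]),
                            b = sort(labels[clusters[[j]]]))
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    ids[i] <- step
    clusters[[j]] <- NULL
    ids <- ids[-j]
  }
  structure(list(labels = labels, merge = merge, height = height,
                 members = members),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("Single-linkage tree over %d leaves\n", n))
  for (k in seq_along(x$height)) {
    cat(sprintf("  %2d: {%s} + {%s} at %.4f\n", k,
                paste(x$members[[k]]$a, collapse = ", "),
                paste(x$members[[k]]$b, collapse = ", "),
                x$height[k]))
  }
  invisible(x)
}

## characters that break Newick syntax are replaced by '_'
sanitize_newick_label <- function(x) gsub("[ ,():;'\"\\[\\]]", "_", x)

#' Export a linkage tree as a Newick string
#'
#' Branch lengths follow the ultrametric convention: a leaf (or subtree of
#' height h_c) joined at merge height h receives branch length
#' (h - h_c) / 2, so all leaves lie at equal depth and the two-leaf tree at
#' height h renders as `(A:h/2,B:h/2);`.
#'
#' @param tree a `"linkage_tree"` from [single_linkage()].
#' @return a single Newick string, terminated with `;`.
#' @export
to_newick <- function(tree) {
  if (!inherits(tree, "linkage_tree")) {
    stop("'tree' must be a linkage_tree", call. = FALSE)
  }
  labels <- sanitize_newick_label(tree$labels)
  build <- function(id) {
    if (id < 0L) {
      list(str = labels[-id], h = 0)
    } else {
      a <- build(tree$merge[id, 1L])
      b <- build(tree$merge[id, 2L])
      h <- tree$height[id]
      list(str = sprintf("(%s:%.10g,%s:%.10g)",
                         a$str, (h - a$h) / 2, b$str, (h - b$h) / 2),
           h = h)
    }
  }
  n <- length(tree$labels)
  if (n == 1L) return(paste0(labels, ";"))
  paste0(build(nrow(tree$merge))$str, ";")
}

#' Principal component analysis of a descriptor table
#'
#' Eigendecomposition of the covariance matrix of the (optionally
#' standardized) descriptors. With `standardize = TRUE` (the default, and
#' the conventional choice for descriptors on different scales) this is PCA
#' on the correlation matrix, and the eigenvalues sum to the number of
#' variables. Eigenvalues below `tol` are reported as exact zeros; with n
#' observations at most n-1 eigenvalues can be nonzero.
#'
#' Each component's sign is fixed so that its largest-magnitude loading is
#' positive, making loadings and scores reproducible across runs and
#' platforms.
#'
#' @param table a descriptor table (>= 2 rows, >= 2 columns).
#' @param standardize standardize columns first (default `TRUE`).
#' @param tol eigenvalues below this are treated as zero (default 1e-10).
#' @return an object of class `"descriptor_pca"`: list with `eigenvalues`
#'   (descending), `explained` (percent of total variance per component),
#'   `cumulative` (cumulative percent), `loadings` (variables x
#'   components), `scores` (observations x components), `standardized`,
#'   `center`, `scale`.
#' @examples
#' pca <- descriptor_pca(load_fixture("table4_theoretical_logp"))
#' scree(pca)
#' @export
descriptor_pca <- function(table, standardize = TRUE, tol = 1e-10) {
  table <- as_descriptor_table(table)
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("PCA needs >= 2 observations and >= 2 variables", call. = FALSE)
  }
  if (standardize) {
    x <- standardize(table)
    ctr <- attr(x, "scaled:center")
    scl <- attr(x, "scaled:scale")
  } else {
    x <- scale(table, center = TRUE, scale = FALSE)
    ctr <- attr(x, "scaled:center")
    scl <- rep(1, ncol(table))
  }
  covm <- crossprod(x) / (nrow(x) - 1L)
  eig <- eigen(covm, symmetric = TRUE)
  ev <- eig$values
  ev[ev < tol] <- 0
  load <- eig$vectors
  ## orient: largest |loading| positive; ties resolved by first occurrence
  for (k in seq_len(ncol(load))) {
    imax <- which.max(abs(load[, k]))
    if (load[imax, k] < 0) load[, k] <- -load[, k]
  }
  comp <- paste0("PC", seq_along(ev))
  dimnames(load) <- list(colnames(table), comp)
  scores <- x %*% load
  dimnames(scores) <- list(rownames(table), comp)
  total <- sum(ev)
  structure(list(eigenvalues = ev,
                 explained = 100 * ev / total,
                 cumulative = cumsum(100 * ev / total),
                 loadings = load,
                 scores = scores,
                 standardized = standardize,
                 center = ctr, scale = scl),
            class = "descriptor_pca")
}

#' @export
print.descriptor_pca <- function(x, ...) {
  nz <- sum(x$eigenvalues > 0)
  cat(sprintf("PCA (%s data): %d nonzero component(s)\n",
              if (x$standardized) "standardized" else "centered", nz))
  print(utils::head(scree(x), nz), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Scree summary of a PCA result
#'
#' @param result a `"descriptor_pca"` object.
#' @return data frame with columns `component`, `eigenvalue`,
#'   `explained_pct` and `cumulative_pct`, components in descending
#'   eigenvalue order.
#' @export
scree <- function(result) {
  if (!inherits(result, "descriptor_pca")) {
    stop("'result' must be a descriptor_pca", call. = FALSE)
  }
  data.frame(component = seq_along(result$eigenvalues),
             eigenvalue = result$eigenvalues,
             explained_pct = result$explained,
             cumulative_pct = result$cumulative)
}
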