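#' Assemble per-target phenotype profiles into a complete matrix
#'
#' Accepts either a matrix (validated and returned with dimnames), or a
#' long data.frame `target,assay,value`. Every target must have every
#' assay; any gap is an error naming the missing target/assay pairs.
#'
#' @param x matrix or long data.frame of normalized assay means.
#' @return numeric matrix, rows = targets, columns = assays (column order
#'   = first appearance).
#' @export
build_profile_matrix <- function(x) {
  if (is.matrix(x)) {
    if (anyNA(x)) {
      bad <- which(is.na(x), arr.ind = TRUE)
      stop("missing profile value(s): ",
           paste(rownames(x)[bad[, 1]], colnames(x)[bad[, 2]],
                 sep = "/", collapse = ", "), call. = FALSE)
    }
    return(x)
  }
  req <- c("target", "assay", "value")
  if (!is.data.frame(x) || !all(req %in% names(x)))
    stop("need a matrix or a data.frame with columns target, assay, value",
         call. = FALSE)
  targets <- unique(x$target)
  assays <- unique(x$assay)
  m <- matrix(NA_real_, length(targets), length(assays),
              dimnames = list(targets, assays))
  m[cbind(match(x$target, targets), match(x$assay, assays))] <- x$value
  build_profile_matrix(m)
}

#' Unsupervised hierarchical clustering of phenotype profiles
#'
#' Rows are standardized (mean 0, SD 1 per target), then clustered by
#' agglomerative hierarchical clustering on Euclidean distance with
#' complete linkage — the defaults of the standard R heatmap routine — and
#' the dendrogram is cut into `k` groups. Deterministic given the matrix;
#' invariant to row order and to affine rescaling of any single row.
#'
#' @param m profile matrix (targets x assays), >= 2 rows and columns.
#' @param k number of groups to cut.
#' @param dist_method distance passed to [stats::dist()].
#' @param linkage agglomeration method for [stats::hclust()].
#' @param scale_rows standardize rows first (required for the default
#'   shape-based grouping; a constant row is an error).
#' @return list of class `g1_clustering`: `hclust`, `groups` (named
#'   integer vector), `k`, `params`.
#' @export
cluster_targets <- function(m, k = 2, dist_method = "euclidean",
                            linkage = "complete", scale_rows = TRUE) {
  m <- build_profile_matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("need at least 2 targets and 2 assay columns", call. = FALSE)
  if (k < 1 || k > nrow(m)) stop("k out of range", call. = FALSE)
  if (scale_rows) {
    sds <- apply(m, 1, sd)
    if (any(sds == 0))
      stop("constant profile row(s): ",
           paste(rownames(m)[sds == 0], collapse = ", "),
           "; cannot standardize", call. = FALSE)
    m <- t(scale(t(m)))
  }
  hc <- hclust(dist(m, method = dist_method), method = linkage)
  structure(list(hclust = hc, groups = cutree(hc, k = k), k = k,
                 params = list(dist = dist_method, linkage = linkage,
                               scale_rows = scale_rows,
                               assays = colnames(m))),
            class = "g1_clustering")
}

#' @export
print.g1_clustering <- function(x, ...) {
  cat("Hierarchical phenotype clustering (", x$params$dist, "/",
      x$params$linkage, if (x$params$scale_rows) ", row-standardized" else "",
      "), k = ", x$k, "\n", sep = "")
  for (g in sort(unique(x$groups)))
    cat("  group ", g, ": ",
        paste(names(x$groups)[x$groups == g], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Test whether a clustering reproduces a planted bipartition
#'
#' @param clustering a `g1_clustering` (k = 2).
#' @param group_a,group_b character vectors of target names.
#' @return `TRUE` when the two cut groups equal the two sets (in either
#'   order).
#' @export
matches_bipartition <- function(clustering, group_a, group_b) {
  g <- clustering$groups
  ga <- names(g)[g == 1]; gb <- names(g)[g == 2]
  (setequal(ga, group_a) && setequal(gb, group_b)) ||
    (setequal(ga, group_b) && setequal(gb, group_a))
}

#' Write a clustering dendrogram as a newick tree
#'
#' @param clustering a `g1_clustering`.
#' @param path output file.
#' @export
write_dendrogram <- function(clustering, path) {
  ape::write.tree(ape::as.phylo(clustering$hclust), file = path)
  invisible(path)
}
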