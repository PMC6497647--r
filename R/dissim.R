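#' Dissimilarity matrices over stimulus items
#'
#' A `dissim_matrix` stores the pairwise dissimilarity structure of `n_items`
#' stimuli in condensed form: the row-major upper triangle of the symmetric
#' square matrix, a vector of length `n_items * (n_items - 1) / 2`. For 24
#' items this is the familiar 276-pair vector. All consumers in the package
#' (searchlight stacks, network averages, the expert model) share this
#' ordering, which also matches the ordering of [stats::dist()] objects.
#'
#' @param values numeric condensed vector, length `n_items * (n_items - 1) / 2`,
#'   finite and non-negative (correlation-distance units lie in `[0, 2]`).
#' @param item_ids character vector of item identifiers, length `n_items`.
#' @return An object of class `dissim_matrix` with fields `n_items`, `values`
#'   and `item_ids`.
#' @examples
#' dm <- dissim_matrix(c(0.1, 0.2, 0.3), c("a", "b", "c"))
#' as.matrix(dm)
#' @export
dissim_matrix <- function(values, item_ids) {
  n <- length(item_ids)
  if (n < 2L) stop("a dissimilarity matrix needs at least 2 items")
  if (anyDuplicated(item_ids)) stop("item_ids must be unique")
  values <- as.numeric(values)
  if (length(values) != n * (n - 1L) / 2L) {
    stop(sprintf("condensed length %d does not match %d items (expected %d)",
                 length(values), n, n * (n - 1L) / 2L))
  }
  if (any(!is.finite(values))) stop("dissimilarities must be finite")
  if (any(values < 0)) stop("dissimilarities must be non-negative")
  structure(list(n_items = n, values = values,
                 item_ids = as.character(item_ids)),
            class = "dissim_matrix")
}

#' @export
as.matrix.dissim_matrix <- function(x, ...) {
  n <- x$n_items
  m <- matrix(0, n, n, dimnames = list(x$item_ids, x$item_ids))
  # column-major lower-triangle fill order is (2,1),(3,1),...,(n,1),(3,2),...
  # i.e. pairs (1,2),(1,3),...,(1,n),(2,3),... — the condensed order itself
  m[lower.tri(m)] <- x$values
  m + t(m)
}

#' @export
print.dissim_matrix <- function(x, ...) {
  cat(sprintf("<dissim_matrix: %d items, %d condensed entries>\n",
              x$n_items, length(x$values)))
  invisible(x)
}

# Condensed position of pair (i, j), i < j, in row-major upper-triangle order.
condensed_index <- function(i, j, n) {
  stopifnot(all(i < j), all(j <= n))
  (i - 1L) * n - i * (i - 1L) / 2L + (j - i)
}

#' Condensed correlation-distance matrix of item patterns
#'
#' Computes, for every item pair, one minus the Pearson correlation of the
#' two pattern rows. This is the "correlation distance" used at every
#' searchlight location; distances lie in `[0, 2]` and are invariant to
#' shifting or positively rescaling any item's pattern.
#'
#' @param patterns numeric matrix, items in rows, features (voxels) in
#'   columns; at least 3 rows and 2 columns; every row must have nonzero
#'   variance. Row names, if present, become item ids.
#' @return A [dissim_matrix] over the rows of `patterns`.
#' @export
condensed_correlation_dm <- function(patterns) {
  patterns <- as.matrix(patterns)
  if (nrow(patterns) < 3L) stop("need at least 3 item patterns")
  if (ncol(patterns) < 2L) stop("need at least 2 features per pattern")
  ids <- rownames(patterns)
  if (is.null(ids)) ids <- paste0("item", seq_len(nrow(patterns)))
  sds <- apply(patterns, 1L, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- ids[which(sds == 0 | !is.finite(sds))]
    stop(sprintf("degenerate (zero-variance) pattern for item(s): %s",
                 paste(bad, collapse = ", ")))
  }
  d <- 1 - stats::cor(t(patterns))
  # clamp tiny negative rounding on perfectly correlated rows
  vals <- pmin(pmax(t(d)[lower.tri(d)], 0), 2)
  dissim_matrix(vals, ids)
}

#' Spearman similarity between two dissimilarity matrices
#'
#' Rank correlation of the condensed entries, the standard second-order
#' comparison of a neural and a model dissimilarity structure in
#' representational similarity analysis. Ties receive average ranks.
#'
#' @param dm_a,dm_b [dissim_matrix] objects over the same items in the same
#'   order.
#' @return Spearman's rho in `[-1, 1]`.
#' @export
spearman_dm_similarity <- function(dm_a, dm_b) {
  stopifnot(inherits(dm_a, "dissim_matrix"), inherits(dm_b, "dissim_matrix"))
  if (dm_a$n_items != dm_b$n_items || !identical(dm_a$item_ids, dm_b$item_ids))
    stop("dissimilarity matrices are not aligned: item sets/order differ")
  stats::cor(dm_a$values, dm_b$values, method = "spearman")
}

#' Fisher z-transformation
#'
#' Variance-stabilizing transform `z = atanh(r) = 0.5 * log((1 + r)/(1 - r))`
#' of a correlation coefficient.
#'
#' @param r numeric vector with `|r| < 1`.
#' @return `atanh(r)`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("fisher_z requires |r| < 1")
  atanh(r)
}

# Capped variant used by the searchlight RSA score: rho = +/-1 maps to
# +/- atanh(1 - 1e-16) ~ +/-18.71 and sets the "capped" attribute.
fisher_z_capped <- function(r) {
  cap <- atanh(1 - 1e-16)
  capped <- abs(r) >= 1
  z <- r
  z[!capped] <- atanh(r[!capped])
  z[capped] <- sign(r[capped]) * cap
  attr(z, "capped") <- capped
  z
}

#' Entrywise average of dissimilarity matrices
#'
#' @param dms nonempty list of [dissim_matrix] objects with identical item
#'   ordering.
#' @return A [dissim_matrix]: the entrywise arithmetic mean.
#' @export
average_dm <- function(dms) {
  if (length(dms) == 0L) stop("cannot average an empty list of DMs")
  ref <- dms[[1L]]
  stopifnot(inherits(ref, "dissim_matrix"))
  for (dm in dms[-1L]) {
    if (!identical(dm$item_ids, ref$item_ids))
      stop("dissimilarity matrices are not aligned: item sets/order differ")
  }
  vals <- rowMeans(vapply(dms, function(d) d$values,
                          numeric(length(ref$values))))
  dissim_matrix(vals, ref$item_ids)
}

#' Expert similarity model with category labels
#'
#' Bundles an item-level dissimilarity matrix (the "high-dimensional" expert
#' model used by the searchlight RSA score) with a 3-way category labelling
#' of the items (the "dimensionality-reduced" model consumed by the SVM step
#' of the informational-network score).
#'
#' @param dm a [dissim_matrix] over the stimulus items.
#' @param categories factor or character vector of category labels, one per
#'   item, named by or aligned to `dm$item_ids`; exactly the items of `dm`,
#'   at least 2 items per category.
#' @return An object of class `expert_model` with fields `dm` and
#'   `categories` (a named factor).
#' @export
expert_model <- function(dm, categories) {
  stopifnot(inherits(dm, "dissim_matrix"))
  if (!is.null(names(categories))) {
    if (!setequal(names(categories), dm$item_ids))
      stop("category names and dm item_ids do not coincide")
    categories <- categories[dm$item_ids]
  } else if (length(categories) != dm$n_items) {
    stop("need one category label per item")
  }
  categories <- factor(as.character(categories))
  names(categories) <- dm$item_ids
  if (any(table(categories) < 2L))
    stop("every category needs at least 2 items")
  structure(list(dm = dm, categories = categories), class = "expert_model")
}

#' Build a synthetic expert model with block category structure
#'
#' Stand-in for an expert rater's pairwise dissimilarity ratings: same-category
#' pairs get distance `within_d`, cross-category pairs `between_d`, plus
#' symmetric Gaussian jitter truncated so that every within-category distance
#' stays below every between-category distance. Deterministic for a fixed
#' seed.
#'
#' @param n_items number of stimuli (default 24).
#' @param category_sizes integer vector summing to `n_items` (default three
#'   categories of 8, named cantilever/truss/vertical_load).
#' @param within_d,between_d base distances, `0 <= within_d < between_d`.
#' @param jitter_sd standard deviation of the pairwise jitter; must be small
#'   enough not to invert the within/between ordering.
#' @param seed integer seed.
#' @param category_names optional labels, one per category.
#' @return An [expert_model].
#' @export
build_expert_model <- function(n_items = 24L,
                               category_sizes = c(8L, 8L, 8L),
                               within_d = 0.4, between_d = 1.2,
                               jitter_sd = 0.08, seed = 1L,
                               category_names = NULL) {
  if (sum(category_sizes) != n_items)
    stop("category_sizes must sum to n_items")
  if (!(within_d >= 0 && within_d < between_d))
    stop("need 0 <= within_d < between_d")
  if (is.null(category_names)) {
    defaults <- c("cantilever", "truss", "vertical_load")
    category_names <- if (length(category_sizes) <= 3L)
      defaults[seq_along(category_sizes)]
    else paste0("cat", seq_along(category_sizes))
  }
  labels <- rep(category_names, times = category_sizes)
  ids <- sprintf("item%02d", seq_len(n_items))
  same <- outer(labels, labels, "==")
  base <- ifelse(t(same)[lower.tri(same)], within_d, between_d)
  # jitter is truncated at +/- the half-gap, so ordering cannot invert; a
  # jitter_sd at or beyond the half-gap would mostly saturate the truncation
  gap <- (between_d - within_d) / 2
  if (jitter_sd >= gap)
    stop("jitter_sd large enough to invert within/between ordering")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  jit <- if (jitter_sd > 0)
    pmin(pmax(stats::rnorm(length(base), 0, jitter_sd), -gap + 1e-9),
         gap - 1e-9)
  else rep(0, length(base))
  em <- expert_model(dissim_matrix(base + jit, ids),
                     stats::setNames(labels, ids))
  em
}

# save/restore .Random.seed so seeded helpers don't perturb the caller's RNG
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Read or write a dissimilarity matrix as square TSV
#'
#' The on-disk form is the full symmetric matrix with item ids as header row
#' and first column.
#'
#' @param dm a [dissim_matrix].
#' @param path file path.
#' @return `write_dm_tsv` returns `path` invisibly; `read_dm_tsv` returns a
#'   [dissim_matrix].
#' @export
write_dm_tsv <- function(dm, path) {
  m <- as.matrix(dm)
  utils::write.table(data.frame(item_id = rownames(m), m,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dm_tsv
#' @export
read_dm_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!identical(colnames(m), ids))
    stop("TSV header items do not match row items")
  if (max(abs(m - t(m))) > 1e-12) stop("matrix in TSV is not symmetric")
  dissim_matrix(t(m)[lower.tri(m)], ids)
}

#' Read or write item category labels as two-column TSV
#'
#' @param categories named factor/character of item categories.
#' @param path file path.
#' @return `read_categories_tsv` returns a named factor.
#' @export
write_categories_tsv <- function(categories, path) {
  utils::write.table(data.frame(item_id = names(categories),
                                category = as.character(categories)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_categories_tsv
#' @export
read_categories_tsv <- function(path) {
  tab <- utils::read.delim(path)
  stats::setNames(factor(tab$category), tab$item_id)
}
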