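#' Hierarchical clustering of searchlight dissimilarity matrices
#'
#' Agglomerates the rows of a condensed-DM stack (one searchlight DM per
#' row) with average linkage, using one minus the Pearson correlation
#' between condensed vectors as the observation distance. Searchlights whose
#' DMs correlate strongly — i.e. encode the same representational structure —
#' merge early, forming candidate informational networks.
#'
#' @param dm_stack numeric m x p matrix: m condensed DMs of length p. A
#'   `searchlight_result` is also accepted.
#' @return An object of class `infonet_dendrogram`: the underlying
#'   [stats::hclust] tree plus per-internal-node member sets and heights.
#' @export
hierarchical_cluster <- function(dm_stack) {
  if (inherits(dm_stack, "searchlight_result")) dm_stack <- dm_stack(dm_stack)
  dm_stack <- as.matrix(dm_stack)
  m <- nrow(dm_stack)
  if (m < 2L) stop("need at least 2 DMs to cluster")
  sds <- apply(dm_stack, 1L, stats::sd)
  if (any(sds == 0 | !is.finite(sds)))
    stop(sprintf("constant DM row(s): %s",
                 paste(which(sds == 0 | !is.finite(sds)), collapse = ", ")))
  d <- stats::as.dist(1 - stats::cor(t(dm_stack)))
  hc <- stats::hclust(d, method = "average")
  structure(list(hclust = hc,
                 members = node_members(hc),
                 heights = hc$height,
                 n_obs = m),
            class = "infonet_dendrogram")
}

#' @export
print.infonet_dendrogram <- function(x, ...) {
  cat(sprintf("<infonet_dendrogram: %d observations, %d internal nodes>\n",
              x$n_obs, length(x$members)))
  invisible(x)
}

# member sets (sorted leaf indices) for each internal node of an hclust tree
node_members <- function(hc) {
  n <- nrow(hc$merge)
  members <- vector("list", n)
  for (k in seq_len(n)) {
    pick <- function(v) if (v < 0L) -v else members[[v]]
    members[[k]] <- sort(c(pick(hc$merge[k, 1L]), pick(hc$merge[k, 2L])))
  }
  members
}

node_signatures <- function(members) {
  vapply(members, paste, character(1L), collapse = ",")
}

#' Multiscale-bootstrap AU p-values for dendrogram nodes
#'
#' For each scale factor `r`, resamples `ceiling(r * p)` of the `p` condensed
#' coordinates with replacement, reclusters, and records for every internal
#' node of the reference tree the fraction of replicate trees containing a
#' node with an identical member set (the bootstrap proportion `BP_r`). The
#' approximately unbiased p-value comes from the least-squares fit of
#' `qnorm(1 - BP_r) = v * sqrt(r) + c / sqrt(r)` over the scales with
#' `0 < BP_r < 1`, as `au = 1 - pnorm(v - c)`. The ordinary bootstrap
#' proportion `bp` is `BP` at (the scale closest to) `r = 1`.
#'
#' The root is flagged `"root"`: every replicate tree trivially contains the
#' full member set, so its support carries no information and
#' [cut_networks()] ignores it except as fallback.
#'
#' @param dm_stack m x p condensed-DM matrix (or `searchlight_result`).
#' @param dendrogram matching [hierarchical_cluster()] result.
#' @param scales numeric vector of at least 3 scale factors (default
#'   `seq(0.5, 1.4, by = 0.1)`). A single scale of 1 reduces to the ordinary
#'   bootstrap (`au` not fitted, set to `bp`).
#' @param n_boot_per_scale bootstrap replicates per scale (`>= 20`;
#'   default 100).
#' @param seed integer seed; the whole procedure is bit-reproducible.
#' @return data.frame of class `node_support` with one row per internal
#'   node: `node`, `size`, `height`, `bp`, `au`, `v`, `c`, `fit_rss`,
#'   `flag` (`""`, `"root"`, `"always_recovered"`, `"never_recovered"`,
#'   `"degenerate_fit"`). The per-scale BP matrix is attached as attribute
#'   `bp_matrix`, the member sets as `members`.
#' @export
multiscale_bootstrap_au <- function(dm_stack, dendrogram,
                                    scales = seq(0.5, 1.4, by = 0.1),
                                    n_boot_per_scale = 100L, seed = 1L) {
  if (inherits(dm_stack, "searchlight_result")) dm_stack <- dm_stack(dm_stack)
  dm_stack <- as.matrix(dm_stack)
  stopifnot(inherits(dendrogram, "infonet_dendrogram"),
            nrow(dm_stack) == dendrogram$n_obs)
  single_scale <- length(scales) == 1L && isTRUE(all.equal(scales, 1))
  if (!single_scale && length(scales) < 3L)
    stop("need at least 3 scales (or the single scale 1)")
  if (n_boot_per_scale < 20L) stop("need n_boot_per_scale >= 20")
  p <- ncol(dm_stack)
  m <- nrow(dm_stack)
  members <- dendrogram$members
  n_nodes <- length(members)
  tstack <- t(dm_stack)  # p x m: columns are observations

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)

  # order-independent member-set fingerprints: each leaf gets a fixed random
  # integer weight; a node's fingerprint is the exact sum over its members
  # (all sums < 2^53, so doubles are exact; collisions have probability
  # ~ m^2 / 2^40). This replaces per-replicate member-list construction.
  leaf_w <- floor(stats::runif(m) * 2^40)
  node_hashes <- function(merge) {
    h <- numeric(nrow(merge))
    for (k in seq_len(nrow(merge))) {
      l <- merge[k, 1L]; r <- merge[k, 2L]
      h[k] <- (if (l < 0L) leaf_w[-l] else h[l]) +
              (if (r < 0L) leaf_w[-r] else h[r])
    }
    h
  }
  orig_h <- vapply(members, function(s) sum(leaf_w[s]), numeric(1L))

  bp_mat <- matrix(0, n_nodes, length(scales),
                   dimnames = list(NULL, sprintf("r=%.2f", scales)))
  for (si in seq_along(scales)) {
    p_star <- max(2L, ceiling(scales[si] * p))
    hits <- integer(n_nodes)
    for (b in seq_len(n_boot_per_scale)) {
      idx <- sample.int(p, p_star, replace = TRUE)
      cc <- suppressWarnings(stats::cor(tstack[idx, , drop = FALSE]))
      cc[!is.finite(cc)] <- 0  # zero-variance rows under resampling
      hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
      hits <- hits + (orig_h %in% node_hashes(hc$merge))
    }
    bp_mat[, si] <- hits / n_boot_per_scale
  }

  bp_at_1 <- bp_mat[, which.min(abs(scales - 1)), drop = TRUE]
  is_root <- lengths(members) == m
  au <- numeric(n_nodes); v <- rep(NA_real_, n_nodes)
  cc_ <- rep(NA_real_, n_nodes); rss <- rep(NA_real_, n_nodes)
  flag <- character(n_nodes)
  for (k in seq_len(n_nodes)) {
    bpk <- bp_mat[k, ]
    if (is_root[k]) {
      au[k] <- 1; flag[k] <- "root"
    } else if (single_scale) {
      au[k] <- bp_at_1[k]; flag[k] <- "degenerate_fit"
    } else if (all(bpk >= 1)) {
      au[k] <- 1; flag[k] <- "always_recovered"
    } else if (all(bpk <= 0)) {
      au[k] <- 0; flag[k] <- "never_recovered"
    } else {
      use <- bpk > 0 & bpk < 1
      if (sum(use) < 2L) {
        au[k] <- bp_at_1[k]; flag[k] <- "degenerate_fit"
      } else {
        r <- scales[use]
        y <- stats::qnorm(1 - bpk[use])
        X <- cbind(sqrt(r), 1 / sqrt(r))
        fit <- stats::lm.fit(X, y)
        v[k] <- fit$coefficients[1L]
        cc_[k] <- fit$coefficients[2L]
        rss[k] <- sum(fit$residuals^2)
        au[k] <- 1 - stats::pnorm(v[k] - cc_[k])
      }
    }
  }
  out <- data.frame(node = seq_len(n_nodes), size = lengths(members),
                    height = dendrogram$heights, bp = bp_at_1, au = au,
                    v = v, c = cc_, fit_rss = rss, flag = flag,
                    stringsAsFactors = FALSE)
  attr(out, "bp_matrix") <- bp_mat
  attr(out, "members") <- members
  attr(out, "scales") <- scales
  class(out) <- c("node_support", "data.frame")
  out
}

#' Cut statistically reliable informational networks from the tree
#'
#' Returns the maximal (highest) non-root nodes with `au >= au_threshold`
#' and at least `min_size` members; no returned set is nested in another.
#' The root itself is never a candidate — its member set is recovered by
#' every replicate tree, so its AU value is uninformative. If no node
#' qualifies, the single root set (all observations) is returned with a
#' warning, so that downstream scoring always has at least one network.
#'
#' @param dendrogram an `infonet_dendrogram`.
#' @param support matching [multiscale_bootstrap_au()] result.
#' @param au_threshold AU significance threshold in `(0, 1]` (default 0.95).
#' @param min_size minimum members per network (default 2).
#' @return list of integer member vectors (observation indices), with
#'   attributes `nodes` (internal node ids, `NA` for the root fallback),
#'   `heights`, and `fallback` (logical).
#' @export
cut_networks <- function(dendrogram, support, au_threshold = 0.95,
                         min_size = 2L) {
  stopifnot(inherits(dendrogram, "infonet_dendrogram"))
  if (!(au_threshold > 0 && au_threshold <= 1))
    stop("au_threshold must lie in (0, 1]")
  if (min_size < 1L) stop("min_size must be >= 1")
  members <- dendrogram$members
  n_nodes <- length(members)
  root <- n_nodes
  merge <- dendrogram$hclust$merge
  picked <- integer(0)
  walk <- function(node) {
    if (node < 0L) return(invisible())  # leaf
    if (node != root && support$au[node] >= au_threshold &&
        support$size[node] >= min_size) {
      picked <<- c(picked, node)
      return(invisible())
    }
    walk(merge[node, 1L])
    walk(merge[node, 2L])
  }
  walk(root)
  if (length(picked) == 0L) {
    warning("no node reached the AU threshold; falling back to the root set")
    out <- list(sort(unique(unlist(members[root]))))
    attr(out, "nodes") <- NA_integer_
    attr(out, "heights") <- dendrogram$heights[root]
    attr(out, "fallback") <- TRUE
    return(out)
  }
  picked <- sort(picked)
  out <- members[picked]
  attr(out, "nodes") <- picked
  attr(out, "heights") <- dendrogram$heights[picked]
  attr(out, "fallback") <- FALSE
  out
}

#' Export a dendrogram with node support as JSON or Newick
#'
#' @param dendrogram an `infonet_dendrogram`.
#' @param support optional `node_support`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_dendrogram_json <- function(dendrogram, support = NULL, path) {
  nodes <- lapply(seq_along(dendrogram$members), function(k) {
    nd <- list(node = k, members = dendrogram$members[[k]],
               height = dendrogram$heights[k])
    if (!is.null(support)) {
      nd$bp <- support$bp[k]; nd$au <- support$au[k]
      nd$flag <- support$flag[k]
    }
    nd
  })
  jsonlite::write_json(nodes, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dendrogram_json
#' @export
write_dendrogram_newick <- function(dendrogram, path) {
  hc <- dendrogram$hclust
  labels <- if (is.null(hc$labels)) paste0("dm", seq_len(dendrogram$n_obs))
            else hc$labels
  build <- function(node, parent_h) {
    if (node < 0L)
      return(sprintf("%s:%g", labels[-node], parent_h))
    h <- hc$height[node]
    sprintf("(%s,%s):%g",
            build(hc$merge[node, 1L], h), build(hc$merge[node, 2L], h),
            parent_h - h)
  }
  root <- nrow(hc$merge)
  h <- hc$height[root]
  nwk <- sprintf("(%s,%s);", build(hc$merge[root, 1L], h),
                 build(hc$merge[root, 2L], h))
  writeLines(nwk, path)
  invisible(path)
}
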