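# Independent oracles used to freeze expected values. These deliberately use
# naive loops / direct enumeration, not the package's own code paths.

# per-pair 1 - Pearson correlation, looped
oracle_cor_dm <- function(patterns) {
  n <- nrow(patterns)
  out <- numeric(n * (n - 1) / 2)
  k <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      k <- k + 1
      out[k] <- 1 - cor(patterns[i, ], patterns[j, ])
    }
  }
  out
}

# entrywise mean of condensed vectors, looped
oracle_mean_dm <- function(value_list) {
  out <- numeric(length(value_list[[1]]))
  for (k in seq_along(out)) {
    s <- 0
    for (v in value_list) s <- s + v[k]
    out[k] <- s / length(value_list)
  }
  out
}

# integer offsets within Euclidean radius, by direct enumeration
oracle_sphere_size <- function(radius) {
  r <- ceiling(radius)
  count <- 0
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    if (sqrt(dx^2 + dy^2 + dz^2) <= radius) count <- count + 1
  }
  count
}

# vertex count of an icosahedron subdivided n times per edge, by explicit
# construction: barycentric lattice points on every face, deduplicated by an
# exact key over the (vertex, coefficient) pairs shared across faces
oracle_icosa_vertices <- function(n) {
  # icosahedron from golden-ratio coordinates; faces = vertex triples whose
  # pairwise distances all equal the edge length 2
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    cbind(0, c(1, 1, -1, -1), c(phi, -phi, phi, -phi)),
    cbind(c(1, 1, -1, -1), c(phi, -phi, phi, -phi), 0),
    cbind(c(phi, -phi, phi, -phi), 0, c(1, 1, -1, -1)))
  d <- as.matrix(dist(v))
  faces <- Filter(function(f) all(abs(d[f, f][upper.tri(diag(3))] - 2) < 1e-9),
                  combn(12, 3, simplify = FALSE))
  stopifnot(length(faces) == 20)
  keys <- character(0)
  for (f in faces) {
    for (i in 0:n) for (j in 0:(n - i)) {
      k <- n - i - j
      coef <- c(i, j, k)
      keep <- coef > 0
      ord <- order(f[keep])
      keys <- c(keys, paste(f[keep][ord], coef[keep][ord], collapse = "|"))
    }
  }
  length(unique(keys))
}

# Welch statistic by the textbook formula
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# m DMs per group around k uncorrelated prototypes, plus i.i.d. noise
make_planted_stack <- function(m_per_group, k_groups, p = 276,
                               noise_sd = 0.6, seed = 1) {
  set.seed(seed)
  proto <- matrix(rnorm(k_groups * p), k_groups, p)
  proto[rep(seq_len(k_groups), each = m_per_group), ] +
    matrix(rnorm(m_per_group * k_groups * p, 0, noise_sd),
           m_per_group * k_groups, p)
}

# small cohort used by several test files (cheap but full-featured)
tiny_cohort <- function(seed = 11, expertise = c(0.05, 0.4, 0.6, 0.95),
                        ...) {
  generate_cohort(cohort_spec(n_subjects_per_group = length(expertise) / 2,
                              expertise = expertise, n_runs = 1L,
                              seed = seed, ...))
}

fast_infonet_config <- function(seed = 5) {
  list(scales = seq(0.6, 1.4, by = 0.2), n_boot_per_scale = 40L, seed = seed)
}
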