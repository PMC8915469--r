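# In-code fixtures and independent oracles shared across test files.

# Tiny two-family dataset whose heterogeneity values can be checked by
# hand: each sample's pattern is explicit.
toy_dataset <- function() {
  samples <- data.frame(
    sample_id = c("d1_T0", "p1_T0", "p2_T0", "d1_T60", "p1_T60", "p2_T60",
                  "e1_T0", "e2_T0"),
    family_id = c(rep("FA", 6), rep("FB", 2)),
    subject_id = c("FA-D", "FA-P1", "FA-P2", "FA-D", "FA-P1", "FA-P2",
                   "FB-P1", "FB-P2"),
    subject_role = c("dam", "puppy", "puppy", "dam", "puppy", "puppy",
                     "puppy", "puppy"),
    matrix = c("rectal", "meconium", "meconium", "rectal", "rectal",
               "rectal", "meconium", "meconium"),
    time_point = c("T0", "T0", "T0", "T60", "T60", "T60", "T0", "T0"),
    stringsAsFactors = FALSE
  )
  patterns <- rbind(
    d1_T0  = c(1, 1, 0, 0),
    p1_T0  = c(1, 0, 1, 0),
    p2_T0  = c(0, 1, 1, 0),
    d1_T60 = c(1, 1, 0, 0),
    p1_T60 = c(1, 1, 0, 0),
    p2_T60 = c(1, 1, 0, 1),
    e1_T0  = c(0, 0, 1, 1),
    e2_T0  = c(1, 0, 0, 1)
  )
  colnames(patterns) <- c("Escherichia", "Enterococcus", "Proteus",
                          "Clostridium")
  records <- do.call(rbind, lapply(rownames(patterns), function(sid) {
    g <- colnames(patterns)[patterns[sid, ] == 1]
    if (!length(g)) return(NULL)
    data.frame(sample_id = sid, genus = g, species = "", growth = "low",
               stringsAsFactors = FALSE)
  }))
  list(samples = samples, records = records, patterns = patterns)
}

rand_binary_matrix <- function(n, g, p = 0.5) {
  matrix(rbinom(n * g, 1L, p), n, g,
         dimnames = list(sprintf("s%02d", seq_len(n)),
                         sprintf("g%02d", seq_len(g))))
}

rand_dist_matrix <- function(n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2)
  d <- d + t(d)
  dimnames(d) <- list(sprintf("s%02d", seq_len(n)),
                      sprintf("s%02d", seq_len(n)))
  d
}

# Independent exact rank-sum oracle: enumerates group assignments and
# works on the Mann-Whitney U statistic computed by direct pairwise
# comparison (not on rank sums), then doubles the smaller tail.
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  u_stat <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_stat(a, b)
  idx <- utils::combn(n, na)
  u_null <- apply(idx, 2, function(i) u_stat(pooled[i], pooled[-i]))
  min(1, 2 * min(mean(u_null <= u_obs + 1e-9),
                 mean(u_null >= u_obs - 1e-9)))
}

# Euclidean distance matrix of random planar points (2D-embeddable by
# construction), for ordination recovery checks.
planar_dist <- function(n) {
  pts <- cbind(runif(n), runif(n))
  d <- as.matrix(stats::dist(pts))
  dimnames(d) <- list(sprintf("s%02d", seq_len(n)),
                      sprintf("s%02d", seq_len(n)))
  list(points = pts, d = d)
}
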