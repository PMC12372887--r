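# Independent oracles used to check package results. These deliberately use
# naive direct computation (or a different library) and never call the code
# path they verify.

# brute-force three-way threshold partition
oracle_partition <- function(ids, activities, lo, hi) {
  list(inhibited = ids[activities <= lo],
       noninhibited = ids[activities >= hi],
       unclassified = ids[activities > lo & activities < hi])
}

# direct-summation Jensen-Shannon divergence, log base 2
oracle_jsd <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    s <- 0
    for (i in seq_along(a)) if (a[i] > 0) s <- s + a[i] * log2(a[i] / b[i])
    s
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

# literal Henikoff position-based weights on a character matrix
oracle_henikoff <- function(m) {
  aa20 <- c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V")
  w <- numeric(nrow(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    obs <- col[col %in% aa20]
    if (length(obs) == 0) next
    r <- length(unique(obs))
    for (i in seq_len(nrow(m))) {
      if (col[i] %in% aa20) w[i] <- w[i] + 1 / (r * sum(obs == col[i]))
    }
  }
  w / sum(w)
}

# position-by-position identity count over mutually non-gap columns
oracle_identity <- function(a, b) {
  aa20 <- c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V")
  both <- a %in% aa20 & b %in% aa20
  100 * sum(a[both] == b[both]) / sum(both)
}

# linear scan mapping alignment columns to author numbers
oracle_map <- function(ref_chars, first) {
  out <- rep(NA_integer_, length(ref_chars))
  k <- 0
  for (i in seq_along(ref_chars)) {
    if (ref_chars[i] != "-") {
      out[i] <- first + k
      k <- k + 1
    }
  }
  out
}

# membership scan over region intervals
oracle_region <- function(residue, spans) {
  for (nm in names(spans)) {
    s <- spans[[nm]]
    for (k in seq_len(nrow(s))) {
      if (residue >= s$start[k] && residue <= s$end[k]) return(nm)
    }
  }
  "unassigned"
}

# exhaustive nearest-centroid assignment with circular distance
oracle_nearest_cluster <- function(angles, library) {
  circ <- function(a, b) {
    d <- abs(a - b) %% 360
    ifelse(d > 180, 360 - d, d)
  }
  dists <- sapply(library$clusters, function(cen) {
    mean(circ(angles, c(cen[, "phi"], cen[, "psi"])))
  })
  best <- which.min(dists)
  if (dists[best] > library$assignment_cutoff) "unassigned"
  else names(dists)[best]
}

# exhaustive double-loop minimum inter-atom distance
oracle_min_distance <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
  }
  best
}

# random proper rotation + translation
random_rigid_motion <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(rotation = q, translation = stats::rnorm(3, sd = 10))
}
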