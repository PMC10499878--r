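# shared fixtures and independent oracles (built in code, never stored)

# small acquisition geometry that still fits one algal cell comfortably
small_config <- function(seed = 1L, cycles = 6L, pixels = 96L, ...) {
  generator_config(pixels = pixels, cycles = cycles, seed = seed, ...)
}

# deterministic textured image for registration fixtures
textured_image <- function(side = 64, seed = 42) {
  set.seed(seed)
  base <- matrix(rpois(side * side, 5), side)
  r <- (side %/% 3):(side %/% 3 + side %/% 6)
  c_ <- (side %/% 2):(side %/% 2 + side %/% 6)
  base[r, c_] <- base[r, c_] + 40  # bright blob
  base
}

# independent exhaustive-search registration oracle: minimize the sum of
# squared differences over the overlapping region, scanning every shift
ssd_oracle_shift <- function(ref, img, max_shift) {
  best <- Inf; best_sh <- c(0L, 0L)
  for (dr in -max_shift:max_shift) for (dc in -max_shift:max_shift) {
    nr <- nrow(ref); nc <- ncol(ref)
    r1 <- max(1, 1 + dr); r2 <- min(nr, nr + dr)
    c1 <- max(1, 1 + dc); c2 <- min(nc, nc + dc)
    a <- ref[r1:r2, c1:c2]
    b <- img[(r1:r2) - dr, (c1:c2) - dc]
    ssd <- mean((a - b)^2)
    if (ssd < best - 1e-12) { best <- ssd; best_sh <- c(dr, dc) }
  }
  best_sh
}

# independent connected-components oracle via igraph on the pixel graph
igraph_component_count <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  n <- nrow(px)
  if (n == 0) return(0L)
  key <- px[, 1] * (ncol(mask) + 2) + px[, 2]
  idx <- seq_len(n)
  names(idx) <- key
  edges <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb_key <- (px[, 1] + dr) * (ncol(mask) + 2) + (px[, 2] + dc)
    hit <- !is.na(idx[as.character(nb_key)])
    edges <- c(edges, rbind(idx[hit], idx[as.character(nb_key[hit])]))
  }
  g <- igraph::make_graph(edges = as.numeric(edges), n = n,
                          directed = FALSE)
  igraph::count_components(g)
}

# exhaustive permutation oracle for rank statistics on tiny samples:
# returns p = Pr(stat(perm) >= stat(obs)) over all assignments
perm_oracle_p <- function(values, groups, stat_fn) {
  obs <- stat_fn(values, groups)
  perms <- combinat_perms(length(values))
  hits <- 0
  for (i in seq_len(nrow(perms))) {
    s <- stat_fn(values[perms[i, ]], groups)
    if (s >= obs - 1e-12) hits <- hits + 1
  }
  hits / nrow(perms)
}

# all permutations of 1..n as rows (n <= 8)
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- combinat_perms(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0
  for (pos in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      out[r + i, ] <- append(sub[i, ], n, after = pos - 1)
    }
    r <- r + nrow(sub)
  }
  out
}

# brute-force all-pairs Chebyshev distance between two pixel sets
min_chebyshev <- function(px_a, px_b) {
  best <- Inf
  for (i in seq_len(nrow(px_a))) {
    d <- pmax(abs(px_b[, 1] - px_a[i, 1]), abs(px_b[, 2] - px_a[i, 2]))
    best <- min(best, min(d))
  }
  best
}

# place a disk mask into a matrix (constructed fixtures for segmentation)
add_disk <- function(img, row, col, radius, value) {
  rr <- row(img); cc <- col(img)
  img[(rr - row)^2 + (cc - col)^2 <= radius^2] <- value
  img
}
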