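#' Build the strain-level guild feature table
#'
#' Four features per strain: bacterial median daily C_net and N_net
#' (incorporation) and algal median daily C_net and N_net in the same
#' co-culture (remineralization). Strains with any missing feature are
#' dropped (with a message) before z-standardization — mirroring the
#' removal of a strain with missing data from the clustering.
#'
#' @param strain_summary Data frame with columns `strain`, `bact_C_daily`,
#'   `bact_N_daily`, `algal_C_daily`, `algal_N_daily` (medians; `NA` =
#'   missing).
#' @param drop_incomplete Drop strains with missing features (default
#'   `TRUE`; `FALSE` errors on any `NA`).
#' @return An object of class `guild_features`: list with `X`
#'   (standardized matrix, strains as rownames), `center`, `scale`,
#'   `dropped` (strain names).
#' @export
build_feature_table <- function(strain_summary, drop_incomplete = TRUE) {
  cols <- c("bact_C_daily", "bact_N_daily", "algal_C_daily", "algal_N_daily")
  stopifnot(all(c("strain", cols) %in% names(strain_summary)))
  raw <- as.matrix(strain_summary[, cols])
  rownames(raw) <- strain_summary$strain
  incomplete <- apply(raw, 1, function(r) any(is.na(r)))
  if (any(incomplete) && !drop_incomplete) {
    stop("missing features present and drop_incomplete = FALSE",
         call. = FALSE)
  }
  dropped <- rownames(raw)[incomplete]
  if (length(dropped)) {
    message("dropping strains with missing features: ",
            paste(dropped, collapse = ", "))
  }
  raw <- raw[!incomplete, , drop = FALSE]
  if (nrow(raw) < 4) stop("need >= 4 complete strains", call. = FALSE)
  ctr <- colMeans(raw)
  scl <- apply(raw, 2, stats::sd)
  if (any(scl == 0)) scl[scl == 0] <- 1  # constant column: center only
  X <- sweep(sweep(raw, 2, ctr), 2, scl, "/")
  structure(list(X = X, center = ctr, scale = scl, dropped = dropped),
            class = "guild_features")
}

# squared Euclidean distances from rows of X to rows of C
sq_dist_to_centers <- function(X, C) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * X %*% t(C)
  pmax(d2, 0)
}

#' K-means clustering (k-means++ seeding, Lloyd iterations)
#'
#' Best of `n_init` restarts by within-cluster sum of squares (inertia).
#' Each restart seeds centers k-means++ style (first center uniform,
#' subsequent centers drawn with probability proportional to squared
#' distance from the nearest chosen center) and runs Lloyd's algorithm to
#' convergence; empty clusters are reseeded at the point farthest from its
#' center. Deterministic for a given `seed`.
#'
#' @param X Numeric matrix, rows = observations.
#' @param k Number of clusters, `1 <= k <= nrow(X)`.
#' @param seed Integer seed.
#' @param n_init Number of restarts (`>= 1`).
#' @param max_iter Lloyd iteration cap per restart.
#' @return List with `labels` (integers `1..k`), `centers`, `inertia`.
#' @export
kmeans_fit <- function(X, k, seed = 1L, n_init = 10L, max_iter = 100L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) stop("k must not exceed the number of rows", call. = FALSE)
  if (n_init < 1) stop("n_init must be >= 1", call. = FALSE)
  with_seed(seed, {
    best <- NULL
    for (init in seq_len(n_init)) {
      # k-means++ seeding
      centers <- X[sample.int(n, 1L), , drop = FALSE]
      while (nrow(centers) < k) {
        d2 <- apply(sq_dist_to_centers(X, centers), 1, min)
        if (sum(d2) == 0) {
          pick <- sample.int(n, 1L)
        } else {
          pick <- sample.int(n, 1L, prob = d2)
        }
        centers <- rbind(centers, X[pick, , drop = FALSE])
      }
      labels <- rep(1L, n)
      for (it in seq_len(max_iter)) {
        d2 <- sq_dist_to_centers(X, centers)
        new_labels <- max.col(-d2, ties.method = "first")
        for (j in seq_len(k)) {
          if (!any(new_labels == j)) {  # reseed empty cluster
            far <- which.max(d2[cbind(seq_len(n), new_labels)])
            new_labels[far] <- j
          }
        }
        if (it > 1 && all(new_labels == labels)) break
        labels <- new_labels
        for (j in seq_len(k)) {
          centers[j, ] <- colMeans(X[labels == j, , drop = FALSE])
        }
      }
      inertia <- sum((X - centers[labels, , drop = FALSE])^2)
      if (is.null(best) || inertia < best$inertia - 1e-12) {
        best <- list(labels = labels, centers = centers, inertia = inertia)
      }
    }
    best
  })
}

#' Elbow selection of the cluster count
#'
#' Runs over a consecutive k range, the elbow is operationalized as the k
#' maximizing the second forward difference of the inertia curve
#' \eqn{(I_{k-1} - I_k) - (I_k - I_{k+1})} (maximum curvature), ties broken
#' toward the smaller k. Only interior k values are eligible. A
#' non-monotone inertia sequence draws a warning but still selects.
#'
#' @param inertias Named numeric vector, names = consecutive integer k
#'   values (`>= 4` of them).
#' @return The chosen k (integer).
#' @examples
#' elbow_select(c("1" = 100, "2" = 50, "3" = 10, "4" = 9, "5" = 8.5))  # 3
#' @export
elbow_select <- function(inertias) {
  ks <- as.integer(names(inertias))
  if (length(ks) < 4 || any(diff(ks) != 1L)) {
    stop("need >= 4 consecutive k values", call. = FALSE)
  }
  if (any(diff(inertias) > 1e-9)) {
    warning("inertia sequence is not non-increasing")
  }
  interior <- 2:(length(ks) - 1)
  d2 <- (inertias[interior - 1] - inertias[interior]) -
        (inertias[interior] - inertias[interior + 1])
  ks[interior][which.max(d2)]  # which.max takes the first (smaller k) tie
}

#' Cluster strains into functional guilds
#'
#' Fits k-means for every k in `k_range`, selects k by the elbow method,
#' and returns guild labels with the inertia curve.
#'
#' @param features A `guild_features` from [build_feature_table()].
#' @param k_range Consecutive candidate k values (default `1:6`).
#' @param seed,n_init Passed to [kmeans_fit()].
#' @return List with `chosen_k`, `labels` (named by strain), `inertia`
#'   (named by k), `seed`, `n_init`.
#' @export
assign_guilds <- function(features, k_range = 1:6, seed = 1L, n_init = 10L) {
  stopifnot(inherits(features, "guild_features"))
  X <- features$X
  k_range <- k_range[k_range <= nrow(X)]
  fits <- lapply(k_range, function(k) kmeans_fit(X, k, seed = seed,
                                                 n_init = n_init))
  inertia <- stats::setNames(vapply(fits, `[[`, numeric(1), "inertia"),
                             k_range)
  chosen <- elbow_select(inertia)
  labels <- fits[[match(chosen, k_range)]]$labels
  names(labels) <- rownames(X)
  list(chosen_k = chosen, labels = labels, inertia = inertia,
       seed = seed, n_init = n_init)
}

#' Adjusted Rand index between two partitions
#'
#' Permutation-invariant agreement between clusterings; 1 for identical
#' partitions, ~0 for independent ones. Used instead of raw label equality
#' wherever cluster recovery is asserted.
#'
#' @param a,b Label vectors of equal length.
#' @return The ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
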