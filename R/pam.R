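#' k-medoids clustering by PAM (partitioning around medoids)
#'
#' A greedy BUILD phase seeds the k medoids, then a SWAP phase repeatedly
#' exchanges a medoid for a non-medoid whenever the exchange lowers the
#' total within-cluster dissimilarity, until a local optimum is reached.
#' Because single-swap descent can stall in a local optimum even on small
#' instances, the SWAP phase is run from several deterministic seedings —
#' the classical BUILD seed (rooted at the most central point) plus greedy
#' BUILD completions rooted at the most peripheral points — and the best
#' local optimum is kept. Medoids are actual observations; the
#' dissimilarity is the Euclidean distance between feature rows. All ties
#' (BUILD candidate, SWAP pair, point assignment) are broken by the lowest
#' row index, and no randomness is involved, so the result is fully
#' reproducible.
#'
#' @param x Numeric matrix or data frame of features, one row per
#'   observation. For TSH-by-FT4 clustering the rows are typically
#'   z-standardized first (see [cluster_thyroid()]).
#' @param k Number of medoids, `2 <= k <= n`.
#' @param seed Recorded in the result for provenance symmetry with the
#'   stochastic stages; the algorithm itself is deterministic.
#' @param nstart Number of SWAP starts (default 10): the classical BUILD
#'   seeding plus up to `nstart - 1` rooted alternatives. `nstart = 1` is
#'   the classical single-start algorithm.
#' @return An object of class `thyro_pam`: a list with `k`, `medoid_idx`
#'   (row indices), `medoids` (feature rows), `assignment` (cluster index
#'   per observation, clusters numbered by medoid order), `cost` (total
#'   distance to assigned medoid) and `iterations` (SWAP passes).
#' @export
#' @examples
#' x <- rbind(c(0, 0), c(0, 1), c(10, 10), c(10, 11))
#' pam_fit(x, 2)$cost  # 2
pam_fit <- function(x, k, seed = NULL, nstart = 10) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (anyNA(x)) stop("features must be complete (no missing coordinates)",
                     call. = FALSE)
  if (k < 1 || k > n) stop("k must be between 1 and n = ", n, call. = FALSE)
  d <- as.matrix(stats::dist(x))

  # BUILD: the root medoid (classically the point minimizing total
  # distance), then greedily the point whose addition most reduces the
  # cost. which.min takes the lowest index on ties.
  build_seed <- function(root) {
    medoids <- root
    dnear <- d[, medoids]
    while (length(medoids) < k) {
      cand <- setdiff(seq_len(n), medoids)
      new_costs <- colSums(pmin(d[, cand, drop = FALSE], dnear))
      best <- cand[which.min(new_costs)]
      medoids <- c(medoids, best)
      dnear <- pmin(dnear, d[, best])
    }
    medoids
  }

  # SWAP: steepest descent over all (medoid, non-medoid) exchanges;
  # candidates scanned in increasing index order so ties keep the first.
  swap_descend <- function(medoids) {
    cost <- sum(apply(d[, medoids, drop = FALSE], 1, min))
    iterations <- 0L
    eps <- 1e-12
    repeat {
      nm <- nearest_two(d, medoids)
      best_cost <- cost
      best_swap <- NULL
      non_medoids <- setdiff(seq_len(n), medoids)
      if (length(non_medoids) == 0) break
      for (m in sort(medoids)) {
        base <- ifelse(nm$nearest == m, nm$d2, nm$d1)
        new_costs <- colSums(pmin(d[, non_medoids, drop = FALSE], base))
        j <- which.min(new_costs)
        if (new_costs[j] < best_cost - eps) {
          best_cost <- new_costs[j]
          best_swap <- c(m, non_medoids[j])
        }
      }
      if (is.null(best_swap)) break
      medoids <- c(setdiff(medoids, best_swap[1]), best_swap[2])
      cost <- best_cost
      iterations <- iterations + 1L
      if (iterations > 1000L) break  # safety; never reached on clinical n
    }
    list(medoids = medoids, cost = cost, iterations = iterations)
  }

  # multi-start: the classical BUILD seed (rooted at the most central
  # point) plus BUILD completions rooted at the most peripheral points,
  # each refined by SWAP; the best local optimum is kept (ties keep the
  # earlier start). Entirely deterministic.
  total_dist <- colSums(d)
  roots <- unname(which.min(total_dist))
  if (nstart > 1 && k < n) {
    peripheral <- order(total_dist, decreasing = TRUE)
    roots <- c(roots, setdiff(peripheral, roots))[seq_len(min(nstart, n))]
  }
  runs <- lapply(roots, function(r) swap_descend(build_seed(r)))
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "cost"))]]

  medoids <- sort(best$medoids)
  assignment <- apply(d[, medoids, drop = FALSE], 1, which.min)
  cost <- sum(d[cbind(seq_len(n), medoids[assignment])])
  structure(
    list(k = k, medoid_idx = medoids, medoids = x[medoids, , drop = FALSE],
         assignment = as.integer(assignment), cost = cost,
         iterations = best$iterations, seed = seed),
    class = "thyro_pam"
  )
}

# nearest and second-nearest medoid distance per point
nearest_two <- function(d, medoids) {
  dm <- d[, medoids, drop = FALSE]
  ord1 <- apply(dm, 1, which.min)
  d1 <- dm[cbind(seq_len(nrow(dm)), ord1)]
  dm[cbind(seq_len(nrow(dm)), ord1)] <- Inf
  d2 <- apply(dm, 1, min)
  list(nearest = medoids[ord1], d1 = d1, d2 = d2)
}

#' Per-observation silhouette widths
#'
#' \eqn{s(i) = (b(i) - a(i)) / \max(a(i), b(i))} with \eqn{a(i)} the mean
#' distance of observation i to the other members of its own cluster and
#' \eqn{b(i)} the smallest mean distance to any other cluster. Observations
#' in singleton clusters get \eqn{s(i) = 0} by convention. Values lie in
#' \[-1, 1\].
#'
#' @param x Feature matrix (one row per observation).
#' @param assignment Integer cluster index per observation.
#' @return Numeric vector of silhouette widths.
#' @export
silhouette_widths <- function(x, assignment) {
  d <- as.matrix(stats::dist(as.matrix(x)))
  n <- nrow(d)
  stopifnot(length(assignment) == n)
  clusters <- sort(unique(assignment))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- assignment[i]
    own_members <- which(assignment == own)
    if (length(own_members) == 1) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own_members, i)])
    b <- min(vapply(setdiff(clusters, own), function(cl) {
      mean(d[i, assignment == cl])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

#' Select the number of medoids by average silhouette width
#'
#' Runs [pam_fit()] for every candidate k and keeps the model with the
#' highest average silhouette width (ties go to the smaller k). The full
#' profile of average widths is retained so the selection is auditable.
#'
#' @param x Feature matrix.
#' @param k_range Candidate values of k (default 2:8), all within
#'   `[2, n - 1]`.
#' @param seed,nstart Passed to [pam_fit()].
#' @return The selected `thyro_pam` model, augmented with `silhouette`
#'   (per-observation widths), `avg_silhouette` and `profile` (tibble of
#'   `k`, `avg_silhouette`).
#' @export
select_k <- function(x, k_range = 2:8, seed = NULL, nstart = 10) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (nrow(unique(x)) == 1) stop("no cluster structure: all points identical",
                                 call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > n - 1)) {
    stop("k_range must lie within [2, n - 1]", call. = FALSE)
  }
  fits <- lapply(k_range, function(k) pam_fit(x, k, seed = seed, nstart = nstart))
  sils <- lapply(fits, function(f) silhouette_widths(x, f$assignment))
  avg <- vapply(sils, mean, numeric(1))
  best <- which.max(avg)  # ties -> smaller k
  model <- fits[[best]]
  model$silhouette <- sils[[best]]
  model$avg_silhouette <- avg[best]
  model$profile <- tibble::tibble(k = k_range, avg_silhouette = avg)
  model
}

#' @export
print.thyro_pam <- function(x, ...) {
  cat("k-medoids (PAM) fit: k =", x$k, " cost =", signif(x$cost, 5), "\n")
  cat("medoid rows:", paste(x$medoid_idx, collapse = ", "), "\n")
  if (!is.null(x$avg_silhouette)) {
    cat("average silhouette width:", round(x$avg_silhouette, 3), "\n")
  }
  invisible(x)
}
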