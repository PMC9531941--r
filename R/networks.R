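# Consensus network partitioning of boundary-overlap matrices. Overlap
# matrices carry positive and (occasionally) negative weights; community
# quality is the asymmetric signed modularity Q* that down-weights the
# negative-weight term by the share of negative strength.

renumber_labels <- function(labels) {
  match(labels, unique(labels))
}

split_signed <- function(w) {
  list(Wp = pmax(w, 0), Wn = -pmin(w, 0))
}

# Q* for a (possibly self-looped) signed matrix; internal workhorse.
qstar <- function(w, labels, gamma) {
  s <- split_signed(w)
  sp <- rowSums(s$Wp); sn <- rowSums(s$Wn)
  vp <- sum(sp); vn <- sum(sn)
  same <- outer(labels, labels, `==`)
  qpart <- function(Wx, sx, vx) {
    if (vx <= 0) return(0)
    Sx <- rowsum(sx, labels)
    (sum(Wx[same]) - gamma * sum(Sx^2) / vx) / vx
  }
  qp <- qpart(s$Wp, sp, vp)
  qn <- qpart(s$Wn, sn, vn)
  coef <- if (vp + vn > 0) vn / (vp + vn) else 0
  qp - coef * qn
}

check_sym <- function(w) {
  w <- as.matrix(w)
  if (nrow(w) != ncol(w) || max(abs(w - t(w)), na.rm = TRUE) > 1e-10 ||
      !identical(which(is.na(w)), which(is.na(t(w)))))
    stop("matrix must be symmetric")
  w
}

#' Asymmetric signed modularity
#'
#' Modularity of a labelling of a signed weighted graph, computed
#' separately on the positive and negative parts and combined as
#' `Q* = Q+ - Q- * v- / (v+ + v-)`, so that negative weights get less
#' importance than positive ones. Missing entries are treated as zero
#' weight (with a message).
#'
#' @param w symmetric weighted matrix with zero diagonal.
#' @param labels integer community label per node.
#' @param gamma resolution parameter (default 1); larger values favour
#'   smaller communities.
#' @return A single number.
#' @export
modularity_signed <- function(w, labels, gamma = 1) {
  w <- check_sym(w)
  if (anyNA(w)) {
    message(sprintf("modularity_signed: %d missing entries treated as zero", sum(is.na(w))))
    w[is.na(w)] <- 0
  }
  if (any(abs(diag(w)) > 1e-12)) stop("matrix must have a zero diagonal")
  if (all(w == 0)) stop("all-zero matrix")
  if (length(labels) != nrow(w)) stop("one label per node required")
  qstar(w, as.integer(renumber_labels(labels)), gamma)
}

# Node-level local moving until no single reassignment improves Q*.
# Works on a (possibly self-looped) matrix; used both as the Louvain
# level-1 pass and as the final fine-tuning pass.
local_moving <- function(w, gamma, labels, max_pass = 200L) {
  n <- nrow(w)
  s <- split_signed(w)
  sp <- rowSums(s$Wp); sn <- rowSums(s$Wn)
  vp <- sum(sp); vn <- sum(sn)
  coef <- if (vp + vn > 0) vn / (vp + vn) else 0
  labels <- renumber_labels(labels)
  C <- max(labels)
  M <- matrix(0, n, C); M[cbind(seq_len(n), labels)] <- 1
  Kp <- s$Wp %*% M; Kn <- s$Wn %*% M
  Sp <- as.vector(crossprod(M, sp)); Sn <- as.vector(crossprod(M, sn))
  for (pass in seq_len(max_pass)) {
    moved <- FALSE
    for (i in sample.int(n)) {
      a <- labels[i]
      kpa <- Kp[i, a] - s$Wp[i, i]; kna <- Kn[i, a] - s$Wn[i, i]
      spa <- Sp[a] - sp[i]; sna <- Sn[a] - sn[i]
      gp <- if (vp > 0) 2 * Kp[i, ] / vp - 2 * gamma * sp[i] * Sp / vp^2 else numeric(C)
      gn <- if (vn > 0) 2 * Kn[i, ] / vn - 2 * gamma * sn[i] * Sn / vn^2 else numeric(C)
      base_p <- if (vp > 0) 2 * kpa / vp - 2 * gamma * sp[i] * spa / vp^2 else 0
      base_n <- if (vn > 0) 2 * kna / vn - 2 * gamma * sn[i] * sna / vn^2 else 0
      delta <- (gp - base_p) - coef * (gn - base_n)
      delta[a] <- 0
      b <- which.max(delta)
      if (delta[b] > 1e-12 && b != a) {
        labels[i] <- b
        Kp[, a] <- Kp[, a] - s$Wp[, i]; Kp[, b] <- Kp[, b] + s$Wp[, i]
        Kn[, a] <- Kn[, a] - s$Wn[, i]; Kn[, b] <- Kn[, b] + s$Wn[, i]
        Sp[a] <- Sp[a] - sp[i]; Sp[b] <- Sp[b] + sp[i]
        Sn[a] <- Sn[a] - sn[i]; Sn[b] <- Sn[b] + sn[i]
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  renumber_labels(labels)
}

aggregate_graph <- function(w, labels) {
  C <- max(labels)
  M <- matrix(0, nrow(w), C); M[cbind(seq_len(nrow(w)), labels)] <- 1
  crossprod(M, w %*% M)
}

#' One Louvain run with signed modularity and fine-tuning
#'
#' Greedy Louvain optimization of the asymmetric signed modularity
#' (local moving + graph aggregation until no merge remains), followed by a
#' node-level fine-tuning pass that reassigns single nodes while Q*
#' improves. Deterministic given the seed.
#'
#' @param w symmetric signed matrix, zero diagonal; NA entries are treated
#'   as zero weight.
#' @param gamma resolution parameter.
#' @param seed integer seed controlling the node visiting order.
#' @return Object of class `partition` with `labels` (contiguous ids),
#'   `gamma`, `quality` (Q*), `reps = 1`, `seed`.
#' @export
louvain_once <- function(w, gamma = 1, seed = 1) {
  w <- check_sym(w)
  if (anyNA(w)) w[is.na(w)] <- 0
  diag(w) <- 0
  if (all(w == 0)) stop("all-zero matrix")
  n <- nrow(w)
  with_seed(seed, {
    node_comm <- seq_len(n)
    cur <- w
    repeat {
      lab <- local_moving(cur, gamma, seq_len(nrow(cur)))
      if (max(lab) == nrow(cur)) break       # no merge: level converged
      node_comm <- lab[node_comm]
      cur <- aggregate_graph(cur, lab)
      if (nrow(cur) == 1L) break
    }
    labels <- local_moving(w, gamma, renumber_labels(node_comm))  # fine-tuning
    structure(list(labels = labels, gamma = gamma,
                   quality = qstar(w, labels, gamma), reps = 1L, seed = seed),
              class = "partition")
  })
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d nodes in %d network(s), gamma = %g, Q* = %.4f\n",
              length(x$labels), max(x$labels), x$gamma, x$quality))
  invisible(x)
}

coassignment <- function(labmat) {
  # proportion of columns (repetitions) assigning each node pair together
  A <- matrix(0, nrow(labmat), nrow(labmat))
  for (r in seq_len(ncol(labmat)))
    A <- A + outer(labmat[, r], labmat[, r], `==`)
  A <- A / ncol(labmat)
  diag(A) <- 0
  A
}

#' Consensus partition of a signed overlap matrix
#'
#' Repeats [louvain_once()] `reps` times, summarizes co-assignment
#' frequencies in a consensus matrix, zeroes entries below the level
#' expected when module labels are assigned to nodes at random (estimated
#' from `n_null` random assignments using the module-size distributions of
#' the repetitions), and re-partitions the thresholded consensus matrix —
#' iterating until the consensus matrix contains only zeros and ones.
#'
#' @inheritParams louvain_once
#' @param reps number of repetitions per round (default 100).
#' @param max_iter maximum consensus rounds before failing (default 20).
#' @param n_null random label assignments for the chance threshold
#'   (default 1000).
#' @return Object of class `partition` (quality evaluated on the original
#'   matrix `w`).
#' @export
consensus_partition <- function(w, gamma = 1, reps = 100, seed = 1,
                                max_iter = 20, n_null = 1000) {
  w <- check_sym(w)
  if (anyNA(w)) {
    message(sprintf("consensus_partition: %d missing entries treated as zero", sum(is.na(w))))
    w[is.na(w)] <- 0
  }
  if (reps < 2) stop("reps must be at least 2")
  n <- nrow(w)
  rep_seeds <- matrix(derive_seeds(seed, max_iter * reps), max_iter, reps)
  null_seed <- derive_seeds(seed + 1L, 1L)
  cur <- w
  for (iter in seq_len(max_iter)) {
    labmat <- vapply(seq_len(reps), function(r)
      louvain_once(cur, gamma, rep_seeds[iter, r])$labels, integer(n))
    A <- coassignment(labmat)
    if (all(A == 0 | A == 1)) {
      labels <- renumber_labels(labmat[, 1L])
      return(structure(list(labels = labels, gamma = gamma,
                            quality = qstar(zero_diag(w), labels, gamma),
                            reps = reps, seed = seed, consensus = A,
                            iterations = iter),
                       class = "partition"))
    }
    tau <- with_seed(null_seed, {
      picks <- sample.int(reps, n_null, replace = TRUE)
      mean(vapply(picks, function(r) {
        sizes <- tabulate(labmat[, r])
        sum(sizes * (sizes - 1)) / (n * (n - 1))
      }, numeric(1)))
    })
    A[A < tau] <- 0
    if (all(A == 0))
      stop("consensus did not converge: thresholded consensus matrix is empty")
    cur <- A
  }
  stop(sprintf("consensus did not converge within %d rounds (last matrix had %d fractional entries)",
               max_iter, sum(!(cur == 0 | cur == 1))))
}

zero_diag <- function(w) { diag(w) <- 0; w }

#' Adjusted mutual information between two labelings
#'
#' Mutual information corrected for chance agreement under the permutation
#' model and normalized by the larger of the two entropies, so 1 means
#' identical partitions and values near 0 mean chance-level agreement.
#' When both labelings are degenerate (the normalizer equals the expected
#' MI), returns 1 if the partitions are identical and 0 otherwise.
#'
#' @param labels_a,labels_b label vectors of equal length.
#' @return A single number, at most 1.
#' @export
adjusted_mutual_information <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("labelings must have equal length")
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  ai <- rowSums(tab); bj <- colSums(tab)
  nz <- tab > 0
  MI <- sum((tab[nz] / n) * log(tab[nz] * n / (ai[row(tab)[nz]] * bj[col(tab)[nz]])))
  Ha <- -sum((ai / n) * log(ai / n))
  Hb <- -sum((bj / n) * log(bj / n))
  EMI <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    a <- ai[i]; b <- bj[j]
    lo <- max(1, a + b - n); hi <- min(a, b)
    if (lo > hi) next
    nij <- lo:hi
    logp <- lgamma(a + 1) + lgamma(b + 1) + lgamma(n - a + 1) + lgamma(n - b + 1) -
      lgamma(n + 1) - lgamma(nij + 1) - lgamma(a - nij + 1) - lgamma(b - nij + 1) -
      lgamma(n - a - b + nij + 1)
    EMI <- EMI + sum(exp(logp) * (nij / n) * log(nij * n / (a * b)))
  }
  den <- max(Ha, Hb) - EMI
  if (abs(den) < 1e-12) {
    same <- identical(outer(labels_a, labels_a, `==`), outer(labels_b, labels_b, `==`))
    return(if (same) 1 else 0)
  }
  (MI - EMI) / den
}

#' Sweep the resolution parameter and pick the best-matching partition
#'
#' Runs [consensus_partition()] at each resolution and returns the one
#' whose labels are most similar (by [adjusted_mutual_information()]) to a
#' reference labelling; ties go to the smaller gamma. Resolutions whose
#' consensus fails to converge are skipped with a warning.
#'
#' @inheritParams consensus_partition
#' @param reference_labels reference network label per node (e.g. an atlas
#'   label assigned by majority vote over searchlight voxels).
#' @param gammas resolutions to try (default `seq(1, 3, by = 0.1)`).
#' @return The winning `partition`, with elements `ami` and `sweep` (a data
#'   frame of gamma and aMI) attached.
#' @export
gamma_sweep <- function(w, reference_labels, gammas = seq(1, 3, by = 0.1),
                        reps = 100, seed = 1, max_iter = 20, n_null = 1000) {
  if (length(reference_labels) != nrow(w)) stop("one reference label per node required")
  best <- NULL; best_ami <- -Inf
  rows <- list()
  for (g in gammas) {
    p <- tryCatch(consensus_partition(w, gamma = g, reps = reps, seed = seed,
                                      max_iter = max_iter, n_null = n_null),
                  error = function(e) {
                    warning(sprintf("gamma = %g skipped: %s", g, conditionMessage(e)))
                    NULL
                  })
    if (is.null(p)) next
    a <- adjusted_mutual_information(p$labels, reference_labels)
    rows[[length(rows) + 1L]] <- data.frame(gamma = g, ami = a)
    if (a > best_ami + 1e-12) { best <- p; best_ami <- a }
  }
  if (is.null(best)) stop("no resolution converged")
  best$ami <- best_ami
  best$sweep <- do.call(rbind, rows)
  best
}

#' Majority-vote reference labels for searchlights
#'
#' Assigns each searchlight the reference network label that occurs most
#' frequently among its member voxels (ties to the smallest label).
#'
#' @param label_vol 3-D integer array of voxelwise reference network
#'   labels (0 or NA = unlabeled).
#' @param searchlights output of [build_searchlights()].
#' @return Integer vector of labels (NA when no member voxel is labeled).
#' @export
searchlight_reference_labels <- function(label_vol, searchlights) {
  vapply(searchlights, function(sl) {
    labs <- label_vol[sl$members]
    labs <- labs[!is.na(labs) & labs != 0]
    if (!length(labs)) return(NA_integer_)
    tt <- table(labs)
    as.integer(names(tt)[which.max(tt)])
  }, integer(1))
}
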