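#' Stack of candidate segmentations on a common grid
#'
#' @param labels list of R binary [labelmap()]s on identical grids (one per
#'   atlas/rater).
#' @param atlas_ids optional character ids (defaults to `rater1..raterR`).
#' @return An object of class `decision_stack`.
#' @export
decision_stack <- function(labels, atlas_ids = NULL) {
  if (!length(labels)) stop("decision stack needs >= 1 label map",
                            call. = FALSE)
  ok <- vapply(labels, inherits, logical(1), "labelmap")
  if (!all(ok)) stop("all stack members must be labelmaps", call. = FALSE)
  ref <- labels[[1]]
  for (l in labels[-1])
    if (!same_geometry(ref, l))
      stop("decision stack grids must be identical", call. = FALSE)
  if (is.null(atlas_ids)) atlas_ids <- paste0("rater", seq_along(labels))
  stopifnot(length(atlas_ids) == length(labels))
  structure(list(decisions = labels, atlas_ids = as.character(atlas_ids)),
            class = "decision_stack")
}

stack_matrix <- function(stack) {
  # n_vox x R 0/1 matrix
  vapply(stack$decisions, function(l) as.vector(l$voxels),
         integer(length(stack$decisions[[1]]$voxels)))
}

fusion_result <- function(fused, method, posterior = NULL, performance = NULL,
                          iterations = 0L, converged = TRUE, audit = NULL) {
  structure(list(fused = fused, method = method, posterior = posterior,
                 performance = performance, iterations = iterations,
                 converged = converged, audit = audit),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("<fusion_result: %s> %d foreground voxels, %d iteration(s)%s\n",
              x$method, sum(x$fused$voxels), x$iterations,
              if (isTRUE(x$converged)) "" else " (not converged)"))
  invisible(x)
}

#' Majority-vote label fusion
#'
#' A voxel is foreground iff strictly more than half of the raters mark it
#' (minority obeys the majority); with an even number of raters a tie goes to
#' background — deterministic and conservative for a puncture-target
#' structure.
#'
#' @param stack a [decision_stack()].
#' @return A `fusion_result` with the fused [labelmap()].
#' @export
majority_vote <- function(stack) {
  stopifnot(inherits(stack, "decision_stack"))
  R <- length(stack$decisions)
  votes <- Reduce(`+`, lapply(stack$decisions, function(l) l$voxels))
  fused <- labelmap((votes > R / 2) * 1L, like = stack$decisions[[1]])
  fusion_result(fused, "mv")
}

#' STAPLE label fusion (binary EM)
#'
#' Simultaneous Truth and Performance Level Estimation: treats each atlas as
#' a rater with unknown sensitivity \eqn{p_j} and specificity \eqn{q_j} and
#' alternates an E-step (per-voxel posterior foreground probability
#' \eqn{W_i} under the current parameters and a fixed foreground prior) with
#' an M-step (\eqn{p_j = \sum_i W_i d_{ij} / \sum_i W_i},
#' \eqn{q_j = \sum_i (1-W_i)(1-d_{ij}) / \sum_i (1-W_i)}) until the mean
#' absolute posterior change falls below `tol`. The fused map is
#' \eqn{W \ge 0.5}.
#'
#' EM statistics are restricted to a region of interest (the union of all
#' atlas foregrounds dilated by `roi_dilate` voxels) so that the vast empty
#' background of a small structure does not swamp the specificity estimates;
#' set `roi_dilate = Inf` to use the whole volume. The default radius of 2
#' voxels is the scale of residual registration error: much larger radii
#' drive the specificity estimates so close to 1 that a couple of positive
#' votes outweigh the prior and the consensus degenerates toward the union
#' of the candidate masks.
#'
#' @param stack a [decision_stack()] with R >= 2.
#' @param tol convergence threshold on mean |delta W| (default 1e-6).
#' @param max_iter maximum EM iterations.
#' @param prior foreground prior probability, or `"auto"` = mean foreground
#'   fraction of the stack over the ROI (held fixed during EM).
#' @param roi_dilate ROI dilation radius in voxels (default 2).
#' @return A `fusion_result` with posterior map, per-atlas `p`/`q`, iteration
#'   count, convergence flag, and the EM log-likelihood trajectory in
#'   `$audit$loglik`.
#' @export
staple <- function(stack, tol = 1e-6, max_iter = 100L, prior = "auto",
                   roi_dilate = 2L) {
  stopifnot(inherits(stack, "decision_stack"))
  R <- length(stack$decisions)
  if (R < 2) stop("STAPLE needs at least 2 raters", call. = FALSE)
  D <- stack_matrix(stack)
  if (!any(D == 1) || !any(D == 0))
    stop("STAPLE needs at least one foreground and one background voxel ",
         "across the stack", call. = FALSE)
  ref <- stack$decisions[[1]]
  dims <- dim(ref$voxels)
  union_fg <- array(rowSums(D) > 0, dim = dims)
  roi <- if (is.finite(roi_dilate)) as.vector(dilate6(union_fg, roi_dilate))
         else rep(TRUE, nrow(D))
  Droi <- D[roi, , drop = FALSE]
  n <- nrow(Droi)
  pi0 <- if (identical(prior, "auto")) mean(Droi) else as.numeric(prior)
  pi0 <- min(max(pi0, 1e-6), 1 - 1e-6)
  clamp <- function(x) pmin(pmax(x, 1e-5), 1 - 1e-5)
  p <- rep(0.9999, R)
  q <- rep(0.9999, R)
  W <- rep(pi0, n)
  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E-step in log space: a_i = log P(D_i | T=1) pi, b_i = log P(D_i | T=0)(1-pi)
    a <- log(pi0) + Droi %*% log(p) + (1 - Droi) %*% log(1 - p)
    b <- log(1 - pi0) + (1 - Droi) %*% log(q) + Droi %*% log(1 - q)
    mx <- pmax(a, b)
    lse <- mx + log(exp(a - mx) + exp(b - mx))
    loglik <- c(loglik, sum(lse))
    Wnew <- as.vector(exp(a - lse))
    dW <- mean(abs(Wnew - W))
    W <- Wnew
    # M-step
    sw <- sum(W)
    sn <- sum(1 - W)
    p <- clamp(as.vector(crossprod(Droi, W)) / sw)
    q <- clamp(as.vector(crossprod(1 - Droi, 1 - W)) / sn)
    if (iter > 1 && dW < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged)
    warning("STAPLE did not converge within ", max_iter, " iterations",
            call. = FALSE)
  Wfull <- numeric(nrow(D))
  Wfull[roi] <- W
  posterior <- array(Wfull, dim = dims)
  fused <- labelmap((posterior >= 0.5) * 1L, like = ref)
  fusion_result(fused, "staple", posterior = posterior,
                performance = data.frame(atlas_id = stack$atlas_ids,
                                         p = p, q = q),
                iterations = iter, converged = converged,
                audit = list(loglik = loglik, prior = pi0,
                             roi_voxels = n))
}

# 6-connectivity binary dilation by `r` voxels (r passes of face-neighbor max)
dilate6 <- function(mask, r) {
  m <- mask
  d <- dim(m)
  for (k in seq_len(r)) {
    out <- m
    out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
    out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
    out[, , -1] <- out[, , -1] | m[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
    m <- out
  }
  m
}

#' SIMPLE label fusion (selective iterative discarding)
#'
#' Starts from the majority-vote estimate, scores every retained atlas by its
#' Dice agreement with the current estimate, discards atlases scoring below
#' `mean - alpha * sd` (never dropping below `min_keep`; when the rule would,
#' only the worst-ranked are discarded), re-fuses the remainder by majority
#' vote, and repeats until no atlas is discarded or `max_rounds` is reached.
#'
#' @param stack a [decision_stack()].
#' @param alpha discard strictness (larger keeps more; `Inf` reduces to
#'   plain majority voting).
#' @param max_rounds maximum discard rounds.
#' @param min_keep minimum number of retained atlases (>= 2).
#' @return A `fusion_result`; `$audit$trail` records per-round Dice scores
#'   and kept/discarded flags.
#' @export
simple_fuse <- function(stack, alpha = 1.0, max_rounds = 5L, min_keep = 3L) {
  stopifnot(inherits(stack, "decision_stack"))
  R <- length(stack$decisions)
  if (min_keep < 2) stop("'min_keep' must be >= 2", call. = FALSE)
  if (R < min_keep)
    stop("stack has fewer than 'min_keep' atlases", call. = FALSE)
  if (all(vapply(stack$decisions, function(l) sum(l$voxels), numeric(1)) == 0))
    stop("all atlases are empty", call. = FALSE)
  keep <- rep(TRUE, R)
  estimate <- majority_vote(stack)$fused
  trail <- list()
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    idx <- which(keep)
    scores <- vapply(idx, function(j)
      dice(stack$decisions[[j]], estimate, warn = FALSE), numeric(1))
    thr <- mean(scores) - alpha * stats::sd(scores)
    cand <- if (is.finite(thr)) which(scores < thr) else integer(0)
    n_allowed <- sum(keep) - min_keep
    if (length(cand) > n_allowed)  # ranked discard, never below min_keep
      cand <- cand[order(scores[cand])][seq_len(max(0L, n_allowed))]
    drop_local <- logical(length(idx))
    drop_local[cand] <- TRUE
    trail[[rounds]] <- data.frame(round = rounds,
                                  atlas_id = stack$atlas_ids[idx],
                                  dice_vs_estimate = scores,
                                  discarded = drop_local)
    if (!any(drop_local) || rounds >= max_rounds) {
      if (any(drop_local) && rounds >= max_rounds) {
        keep[idx[drop_local]] <- FALSE
        estimate <- majority_vote(
          decision_stack(stack$decisions[keep],
                         stack$atlas_ids[keep]))$fused
      }
      break
    }
    keep[idx[drop_local]] <- FALSE
    estimate <- majority_vote(
      decision_stack(stack$decisions[keep], stack$atlas_ids[keep]))$fused
  }
  fusion_result(estimate, "simple", iterations = rounds,
                audit = list(trail = do.call(rbind, trail),
                             kept = stack$atlas_ids[keep]))
}
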