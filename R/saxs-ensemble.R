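## Flexible-tail conformer generation and multi-state ensemble fitting.
##
## The disordered toxin N-terminus is emulated as a self-avoiding bead
## chain grafted onto a rigid body; pools of such conformers are fitted to
## an experimental curve as sparse weighted mixtures (MultiFoXS-style
## multi-state models).

#' Bead ensemble container
#'
#' A pool of coarse-grained conformers sharing bead count and form-factor
#' weights, with simplex weights and anchor metadata recording which bead
#' indices are the rigid part and which the flexible tail.
#'
#' @param members list of N x 3 coordinate matrices (equal N).
#' @param weights simplex weights (>= 0, sum 1); default uniform.
#' @param rigid_range,tail_range integer index ranges into the bead list.
#' @return Object of class `bead_ensemble`.
#' @export
bead_ensemble <- function(members, weights = NULL, rigid_range = NULL,
                          tail_range = NULL) {
  if (!is.list(members) || length(members) < 1L)
    stop_domain("`members` must be a non-empty list of coordinate matrices")
  members <- lapply(members, as_bead_matrix)
  n <- nrow(members[[1L]])
  if (any(vapply(members, nrow, integer(1)) != n))
    stop_domain("all ensemble members must share the same bead count")
  if (is.null(weights)) weights <- rep(1 / length(members), length(members))
  if (length(weights) != length(members) || any(weights < 0))
    stop_domain("`weights` must be non-negative, one per member")
  s <- sum(weights)
  if (abs(s - 1) > 1e-9) stop_domain("`weights` must sum to 1 (got ", s, ")")
  structure(list(members = members, weights = weights,
                 rigid_range = rigid_range, tail_range = tail_range,
                 n_beads = n),
            class = "bead_ensemble")
}

#' @export
print.bead_ensemble <- function(x, ...) {
  cat(sprintf("Bead ensemble: %d members x %d beads\n",
              length(x$members), x$n_beads))
  invisible(x)
}

#' Generate self-avoiding flexible-tail conformers
#'
#' Appends a self-avoiding random chain of `n_tail` beads to an anchor bead
#' of a rigid body: uniform random directions on the sphere, fixed bond
#' length, and rejection of any bead closer than `clash_radius` to the
#' rigid body or to prior tail beads. Each bead gets a bounded number of
#' retries before the whole chain restarts; persistent failure raises an
#' error naming the colliding region. Deterministic given `seed`.
#'
#' @param rigid N x 3 coordinate matrix of the rigid body, A.
#' @param anchor_index row index of the anchor bead in `rigid`.
#' @param n_tail number of tail beads (>= 0).
#' @param n_conformers number of conformers (>= 1).
#' @param seed integer seed.
#' @param bond tail bond length, A (Ca virtual bond, default 3.8).
#' @param clash_radius minimum allowed bead-bead distance, A (default 2;
#'   0 disables self-avoidance, giving an ideal chain).
#' @param max_bead_retries,max_chain_restarts rejection-sampling bounds.
#' @return A [bead_ensemble()] with uniform weights; beads
#'   `1..nrow(rigid)` are the rigid part, the rest the tail.
#' @export
generate_tail_conformers <- function(rigid, anchor_index = 1L, n_tail = 22L,
                                     n_conformers = 1L, seed = 1L,
                                     bond = 3.8, clash_radius = 2.0,
                                     max_bead_retries = 60L,
                                     max_chain_restarts = 200L) {
  rigid <- as_bead_matrix(rigid)
  if (anchor_index < 1L || anchor_index > nrow(rigid))
    stop_domain("`anchor_index` out of range")
  if (n_tail < 0L) stop_domain("`n_tail` must be >= 0")
  if (n_conformers < 1L) stop_domain("`n_conformers` must be >= 1")
  nr <- nrow(rigid)
  anchor <- rigid[anchor_index, ]

  grow_chain <- function() {
    tail <- matrix(NA_real_, n_tail, 3L)
    prev <- anchor
    for (b in seq_len(n_tail)) {
      placed <- FALSE
      for (try in seq_len(max_bead_retries)) {
        u <- stats::rnorm(3L)
        u <- u / sqrt(sum(u^2))
        cand <- prev + bond * u
        if (clash_radius > 0) {
          d2r <- rowSums(sweep(rigid, 2L, cand)^2)
          ok <- all(d2r >= clash_radius^2)
          if (ok && b > 1L) {
            dprev <- tail[seq_len(b - 1L), , drop = FALSE]
            d2t <- rowSums(sweep(dprev, 2L, cand)^2)
            ok <- all(d2t >= clash_radius^2)
          }
          if (!ok) next
        }
        tail[b, ] <- cand
        prev <- cand
        placed <- TRUE
        break
      }
      if (!placed) return(NULL)
    }
    tail
  }

  members <- with_seed(seed, {
    lapply(seq_len(n_conformers), function(k) {
      if (n_tail == 0L) return(rigid)
      for (r in seq_len(max_chain_restarts)) {
        tail <- grow_chain()
        if (!is.null(tail)) return(rbind(rigid, tail))
      }
      stop_domain("tail growth failed after ", max_chain_restarts,
                  " restarts: persistent clash against the rigid body near the anchor")
    })
  })
  bead_ensemble(members,
                rigid_range = c(1L, nr),
                tail_range = if (n_tail > 0L) c(nr + 1L, nr + n_tail) else NULL)
}

#' Chi-squared of a model profile against an experimental one
#'
#' Fits the analytic least-squares scale factor
#' `c = sum(I_exp I_mod / s^2) / sum(I_mod^2 / s^2)` and returns the
#' reduced discrepancy `chi2 = mean(((I_exp - c I_mod)/s)^2)`. A model on a
#' different q grid is resampled onto the experimental grid by linear
#' interpolation (no extrapolation).
#'
#' @param exp experimental [scattering_profile()] (sigma > 0).
#' @param model model [scattering_profile()].
#' @return List with `c` (scale) and `chi2`.
#' @export
chi2_with_scale <- function(exp, model) {
  if (!inherits(exp, "scattering_profile") ||
      !inherits(model, "scattering_profile"))
    stop_domain("`exp` and `model` must be scattering_profile objects")
  Imod <- resample_onto(model, exp$q)
  s <- exp$sigma
  if (any(s <= 0)) stop_domain("experimental sigma must be > 0")
  c_opt <- sum(exp$I * Imod / s^2) / sum(Imod^2 / s^2)
  chi2 <- mean(((exp$I - c_opt * Imod) / s)^2)
  list(c = c_opt, chi2 = chi2)
}

resample_onto <- function(model, q) {
  if (length(model$q) == length(q) && all(model$q == q)) return(model$I)
  if (min(q) < min(model$q) - 1e-12 || max(q) > max(model$q) + 1e-12)
    stop_domain("model q range does not cover the experimental grid; refusing to extrapolate")
  stats::approx(model$q, model$I, xout = q)$y
}

## Lawson-Hanson non-negative least squares, min ||A x - b||, x >= 0.
## A has very few columns here (k <= 4 mixture members).
nnls_fit <- function(A, b, tol = 1e-12) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- crossprod(A, b - A %*% x)
  it <- 0L
  while (any(!passive & w > tol * max(abs(w), 1)) && it < 30L * n) {
    it <- it + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      P <- which(passive)
      z[P] <- tryCatch(
        as.numeric(solve(crossprod(A[, P, drop = FALSE]),
                         crossprod(A[, P, drop = FALSE], b))),
        error = function(e) rep(0, length(P)))
      if (all(z[P] > tol)) { x <- z; break }
      neg <- P[z[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg] + 1e-300))
      x <- x + alpha * (z - x)
      passive[x <= tol & passive] <- FALSE
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  x
}

#' Multi-state ensemble fit
#'
#' For each number of states `k = 1..max_states`, selects the subset of
#' pool profiles and simplex weights minimizing the scaled chi-squared of
#' the weighted profile sum against the experimental curve. Subsets are
#' enumerated exactly while `choose(pool, k)` stays below
#' `enumeration_bound`; beyond that a beam search seeded by the best
#' `(k-1)`-state models is used. Per-subset coefficients come from
#' non-negative least squares on sigma-weighted intensities; weights are
#' the normalized coefficients and the overall scale is refit analytically.
#' `chi2` is non-increasing in `k` by construction.
#'
#' @param pool list of [scattering_profile()] model profiles.
#' @param exp experimental [scattering_profile()].
#' @param max_states maximum number of states (<= 4 is typical).
#' @param enumeration_bound exact-search limit on `choose(pool, k)`
#'   (default 25000).
#' @param beam_width beam width for large pools (default 100).
#' @return Object of class `multistate_fit`: per-k list with `members`
#'   (pool indices), `weights`, `scale`, `chi2`, plus `best_k` (smallest k
#'   within 1% of the best chi2).
#' @export
multistate_enumerate <- function(pool, exp, max_states = 4L,
                                 enumeration_bound = 25000,
                                 beam_width = 100L) {
  if (!is.list(pool) || length(pool) < 1L) stop_domain("`pool` must be non-empty")
  if (max_states < 1L) stop_domain("`max_states` must be >= 1")
  P <- length(pool)
  max_states <- min(max_states, P)
  ## sigma-weighted design matrix: columns are pool profiles on exp grid
  s <- exp$sigma
  M <- vapply(pool, function(p) resample_onto(p, exp$q) / s,
              numeric(length(exp$q)))
  b <- exp$I / s
  npt <- length(b)

  score_subset <- function(idx) {
    A <- M[, idx, drop = FALSE]
    x <- nnls_fit(A, b)
    r <- b - A %*% x
    list(members = idx, coef = x, chi2 = sum(r^2) / npt)
  }

  results <- vector("list", max_states)
  prev_subsets <- list(integer(0))
  for (k in seq_len(max_states)) {
    if (choose(P, k) <= enumeration_bound) {
      subsets <- utils::combn(P, k, simplify = FALSE)
    } else {
      ## beam: extend the best (k-1)-subsets by every non-member
      cand <- unique(unlist(lapply(prev_subsets, function(sset) {
        lapply(setdiff(seq_len(P), sset),
               function(j) sort(c(sset, j)))
      }), recursive = FALSE))
      subsets <- unique(cand)
    }
    scored <- lapply(subsets, score_subset)
    chis <- vapply(scored, `[[`, numeric(1), "chi2")
    ord <- order(chis)
    best <- scored[[ord[1L]]]
    keepn <- min(beam_width, length(ord))
    prev_subsets <- lapply(scored[ord[seq_len(keepn)]], `[[`, "members")

    coef <- best$coef
    tot <- sum(coef)
    weights <- if (tot > 0) coef / tot else rep(1 / length(coef), length(coef))
    results[[k]] <- list(k = k, members = best$members, weights = weights,
                         scale = tot, chi2 = best$chi2)
  }
  chis <- vapply(results, `[[`, numeric(1), "chi2")
  best_k <- which(chis <= min(chis) * 1.01)[1L]
  structure(list(per_k = results, best_k = best_k), class = "multistate_fit")
}

#' @export
print.multistate_fit <- function(x, ...) {
  for (r in x$per_k)
    cat(sprintf("  k = %d: chi2 = %.4g, members = {%s}, weights = {%s}\n",
                r$k, r$chi2, paste(r$members, collapse = ","),
                paste(sprintf("%.3f", r$weights), collapse = ",")))
  cat(sprintf("  best k = %d\n", x$best_k))
  invisible(x)
}

#' Weighted Rg distribution of a multi-state fit
#'
#' Histograms the radii of gyration of the selected ensemble members,
#' weighted by the fitted state weights (summing to 1).
#'
#' @param fit a `multistate_fit`.
#' @param ensemble the [bead_ensemble()] the pool profiles came from.
#' @param bin_width histogram bin width, A (default 0.5).
#' @param k which k-state model to use (default the fit's `best_k`).
#' @return data.frame with `rg_lo`, `rg_hi`, `weight`; attribute
#'   `member_rg` carries the per-member Rg values.
#' @export
rg_distribution <- function(fit, ensemble, bin_width = 0.5, k = NULL) {
  if (!inherits(fit, "multistate_fit")) stop_domain("`fit` must be a multistate_fit")
  if (!inherits(ensemble, "bead_ensemble"))
    stop_domain("`ensemble` must be a bead_ensemble")
  k <- k %||% fit$best_k
  sel <- fit$per_k[[k]]
  if (max(sel$members) > length(ensemble$members))
    stop_domain("fit refers to members missing from the ensemble")
  rg <- vapply(ensemble$members[sel$members], rg_from_coords, numeric(1))
  lo <- floor(min(rg) / bin_width) * bin_width
  breaks <- seq(lo, max(rg) + bin_width, by = bin_width)
  bin <- findInterval(rg, breaks, rightmost.closed = TRUE)
  w <- vapply(seq_len(length(breaks) - 1L),
              function(i) sum(sel$weights[bin == i]), numeric(1))
  out <- data.frame(rg_lo = breaks[-length(breaks)], rg_hi = breaks[-1L],
                    weight = w)
  attr(out, "member_rg") <- rg
  out
}
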