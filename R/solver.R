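#' Penalty-solver configuration
#'
#' Collects the tunable parameters of the first-order penalty method.
#'
#' @param beta_pen Positive penalty parameter, or \code{"auto"} for
#'   0.01 * |f(X0)| (the recommended scaling to the initial objective).
#' @param radius_factor Ball safeguard radius is
#'   \code{radius_factor * sqrt(K)} per block; must be >= 1.
#' @param stepsize_rule One of \code{"ABB"} (alternating Barzilai-Borwein,
#'   the default), \code{"BB1"}, \code{"BB2"}, \code{"fixed"}.
#' @param mu_init Initial stepsize (also the fixed stepsize under
#'   \code{"fixed"}).
#' @param mu_min,mu_max Clamping bounds for the BB stepsizes.
#' @param tol Relative gradient-norm convergence tolerance.
#' @param max_iter Iteration cap.
#' @param seed Seed for the random orthonormal initialisation.
#' @param init \code{"random_orthonormal"} (QR of a Gaussian matrix, per
#'   view) or \code{"spectral"} (bottom-K eigenvectors of each L_m).
#' @param literal_sign If TRUE, use the plus sign on the multiplier term of
#'   the augmented-Lagrangian gradient (audit switch; see
#'   \code{\link{aug_lagrangian_gradient}}). Default FALSE.
#' @return Object of class \code{solver_config}.
#' @export
solver_config <- function(beta_pen = "auto", radius_factor = 1.04,
                          stepsize_rule = c("ABB", "BB1", "BB2", "fixed"),
                          mu_init = 1e-3, mu_min = 1e-10, mu_max = 1e2,
                          tol = 1e-6, max_iter = 1000L, seed = 1L,
                          init = c("random_orthonormal", "spectral"),
                          literal_sign = FALSE) {
  stepsize_rule <- match.arg(stepsize_rule)
  init <- match.arg(init)
  if (!identical(beta_pen, "auto") && (!is.numeric(beta_pen) || beta_pen <= 0))
    stop("beta_pen must be a positive number or \"auto\"")
  stopifnot(radius_factor >= 1, mu_init > 0, mu_min > 0, mu_min < mu_max,
            tol > 0, max_iter >= 1)
  structure(list(beta_pen = beta_pen, radius_factor = radius_factor,
                 stepsize_rule = stepsize_rule, mu_init = mu_init,
                 mu_min = mu_min, mu_max = mu_max, tol = tol,
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 init = init, literal_sign = literal_sign),
            class = "solver_config")
}

#' Gradient of the augmented Lagrangian, block-wise
#'
#' For each view, D_m = G_m - X_m delta(X_m) + beta_pen X_m (X_m' X_m - I)
#' with G_m the m-th block of L X and delta the closed-form multiplier
#' psi(G_m' X_m). The minus sign on the multiplier term is the
#' Riemannian-correction convention of the penalty framework: at a feasible
#' point it reduces D_m to the projected gradient
#' G_m - X_m psi(G_m' X_m), which vanishes on invariant subspaces.
#' \code{literal_sign = TRUE} flips it to a plus for auditing.
#'
#' @param op A \code{\link{block_operator}}.
#' @param x An \code{\link{embedding_blocks}} object.
#' @param beta_pen Positive penalty parameter.
#' @param literal_sign Use the plus-sign variant (default FALSE).
#' @return List of M gradient blocks D_m.
#' @export
aug_lagrangian_gradient <- function(op, x, beta_pen, literal_sign = FALSE) {
  g <- mv_gradient(op, x)
  sgn <- if (literal_sign) 1 else -1
  lapply(seq_len(x$n_views), function(m) {
    xm <- x$blocks[[m]]
    gm <- g$blocks[[m]]
    viol <- crossprod(xm) - diag(x$n_dim)
    gm + sgn * xm %*% mv_multiplier(gm, xm) + beta_pen * xm %*% viol
  })
}

#' Gradient step with ball safeguard
#'
#' Computes X_m - mu * D_m per block and rescales any block whose Frobenius
#' norm exceeds the radius r back onto the sphere of radius r.
#'
#' @param x An \code{\link{embedding_blocks}} object.
#' @param d List of gradient blocks (same shapes).
#' @param mu Nonnegative stepsize.
#' @param r Positive safeguard radius.
#' @return Updated \code{embedding_blocks}.
#' @export
step_and_safeguard <- function(x, d, mu, r) {
  stopifnot(mu >= 0, r > 0)
  out <- lapply(seq_len(x$n_views), function(m) {
    xt <- x$blocks[[m]] - mu * d[[m]]
    if (!all(is.finite(xt)))
      stop("divergence: non-finite iterate produced in the gradient step")
    nrm <- norm(xt, "F")
    if (nrm > r) xt * (r / nrm) else xt
  })
  embedding_blocks(out)
}

#' Barzilai-Borwein stepsize from consecutive differences
#'
#' With S the iterate difference and Y the gradient difference (both
#' vectorised across all blocks): BB1 = <S,S>/<S,Y>, BB2 = <S,Y>/<Y,Y>.
#' Under the alternating rule, odd iterations use BB1 and even ones BB2.
#' The result is clamped to [mu_min, mu_max]; a non-positive or non-finite
#' raw value falls back to mu_max.
#'
#' @param s_prev,y_prev Lists of difference blocks, or NULL on the first
#'   iteration (then \code{mu_init} is returned).
#' @param iter Current iteration number (controls ABB parity).
#' @param rule \code{"ABB"}, \code{"BB1"} or \code{"BB2"}.
#' @param mu_init First-iteration stepsize.
#' @param mu_min,mu_max Clamping bounds.
#' @return Scalar stepsize.
#' @export
bb_stepsize <- function(s_prev, y_prev, iter, rule = "ABB",
                        mu_init = 1e-3, mu_min = 1e-10, mu_max = 1e2) {
  if (is.null(s_prev) || is.null(y_prev)) return(mu_init)
  s <- unlist(s_prev, use.names = FALSE)
  y <- unlist(y_prev, use.names = FALSE)
  ss <- sum(s * s)
  sy <- sum(s * y)
  yy <- sum(y * y)
  use_bb1 <- switch(rule,
                    ABB = (iter %% 2L) == 1L,
                    BB1 = TRUE,
                    BB2 = FALSE,
                    stop("unknown stepsize rule: ", rule))
  mu <- if (use_bb1) ss / sy else sy / yy
  if (!is.finite(mu) || mu <= 0) return(mu_max)
  min(max(mu, mu_min), mu_max)
}

init_blocks <- function(op, k, config) {
  n <- op$n_nodes
  if (config$init == "spectral") {
    blocks <- lapply(op$laplacians, function(l) {
      e <- eigen(as.matrix(l), symmetric = TRUE)
      e$vectors[, seq(n, n - k + 1L), drop = FALSE]
    })
  } else {
    set.seed(config$seed)
    blocks <- lapply(seq_len(op$n_views), function(m) {
      qr.Q(qr(matrix(stats::rnorm(n * k), n, k)))
    })
  }
  embedding_blocks(blocks)
}

polar_orthonormalize <- function(x) {
  embedding_blocks(lapply(x$blocks, function(b) {
    sv <- svd(b)
    sv$u %*% t(sv$v)
  }))
}

#' Solve the coupled multiview spectral clustering problem
#'
#' Minimises Tr(X' L X) subject to one orthogonality constraint per view
#' (X_m' X_m = I_K) with a first-order penalty method: plain gradient steps
#' on the augmented Lagrangian, a per-block ball safeguard of radius
#' \code{radius_factor * sqrt(K)}, and alternating Barzilai-Borwein
#' stepsizes. Iteration stops when the relative gradient norm
#' max_m ||D_m||_F / max(1, ||X||_F) drops below \code{tol} or at
#' \code{max_iter}. The returned blocks are polished to exact feasibility
#' by per-block polar orthonormalisation (the penalty iterate itself is
#' only approximately orthonormal); the pre-polish iterate and residual are
#' kept in the state for inspection.
#'
#' @param op A \code{\link{block_operator}}.
#' @param k Embedding dimension K (number of clusters).
#' @param config A \code{\link{solver_config}}.
#' @return List with \code{x} (feasible \code{embedding_blocks}),
#'   \code{state}: \code{converged}, \code{iterations}, \code{beta_pen},
#'   \code{radius}, \code{history} (data frame iter / f / h / feasibility /
#'   mu), \code{pre_polar_feasibility}, \code{post_polar_feasibility},
#'   \code{x_pre_polar}.
#' @export
solve_mvcpm <- function(op, k, config = solver_config()) {
  stopifnot(inherits(op, "block_operator"), inherits(config, "solver_config"))
  if (k < 1L || k > op$n_nodes) stop("k must lie in [1, N]")
  x <- init_blocks(op, k, config)
  beta_pen <- config$beta_pen
  if (identical(beta_pen, "auto")) {
    f0 <- abs(mv_objective(op, x))
    beta_pen <- if (f0 > 0) 0.01 * f0 else 0.01
  }
  r <- config$radius_factor * sqrt(k)

  hist_iter <- integer(0); hist_f <- hist_h <- hist_feas <- hist_mu <- numeric(0)
  x_prev <- NULL; d_prev <- NULL
  converged <- FALSE
  iter_done <- 0L
  for (iter in seq_len(config$max_iter)) {
    d <- aug_lagrangian_gradient(op, x, beta_pen, config$literal_sign)
    gnorm <- max(vapply(d, norm, numeric(1), type = "F"))
    xnorm <- sqrt(sum(unlist(lapply(x$blocks, function(b) sum(b^2)))))
    f_val <- mv_objective(op, x)
    h_val <- mv_merit(op, x, beta_pen)
    feas <- feasibility_residual(x)

    if (gnorm / max(1, xnorm) <= config$tol) {
      hist_iter <- c(hist_iter, iter)
      hist_f <- c(hist_f, f_val); hist_h <- c(hist_h, h_val)
      hist_feas <- c(hist_feas, feas); hist_mu <- c(hist_mu, NA_real_)
      converged <- TRUE
      iter_done <- iter
      break
    }

    mu <- if (config$stepsize_rule == "fixed") {
      config$mu_init
    } else if (is.null(x_prev)) {
      config$mu_init
    } else {
      s_prev <- mapply(`-`, x$blocks, x_prev$blocks, SIMPLIFY = FALSE)
      y_prev <- mapply(`-`, d, d_prev, SIMPLIFY = FALSE)
      bb_stepsize(s_prev, y_prev, iter, config$stepsize_rule,
                  config$mu_init, config$mu_min, config$mu_max)
    }

    hist_iter <- c(hist_iter, iter)
    hist_f <- c(hist_f, f_val); hist_h <- c(hist_h, h_val)
    hist_feas <- c(hist_feas, feas); hist_mu <- c(hist_mu, mu)

    x_prev <- x; d_prev <- d
    x <- tryCatch(step_and_safeguard(x, d, mu, r),
                  error = function(e)
                    stop("iteration ", iter, ": ", conditionMessage(e),
                         call. = FALSE))
    iter_done <- iter
  }

  pre_feas <- feasibility_residual(x)
  x_out <- polar_orthonormalize(x)
  state <- list(converged = converged,
                iterations = iter_done,
                beta_pen = beta_pen,
                radius = r,
                history = data.frame(iter = hist_iter, f = hist_f,
                                     h = hist_h, feasibility = hist_feas,
                                     mu = hist_mu),
                pre_polar_feasibility = pre_feas,
                post_polar_feasibility = feasibility_residual(x_out),
                x_pre_polar = x)
  list(x = x_out, state = state)
}
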