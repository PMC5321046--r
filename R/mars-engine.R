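#' Hinge function
#'
#' The elementary truncated-linear spline piece: `max(0, x - t)` for the
#' positive direction and `max(0, t - x)` for the negative one, with the knot
#' at value `t`.
#'
#' @param x Numeric vector.
#' @param knot Knot value `t`.
#' @param direction `+1` for `(x - t)+`, `-1` for `(t - x)+`.
#' @return Numeric vector of hinge evaluations.
#' @export
hinge <- function(x, knot, direction = 1) {
  stopifnot(is.finite(knot), direction %in% c(-1, 1))
  pmax(0, direction * (x - knot))
}

# ---- internal term / basis helpers -----------------------------------------

# A term is list(var, knot, dir, linear); a basis function is
# list(terms = list(term, ...)) and evaluates to the product of its terms.

new_term <- function(var, knot, dir, linear = FALSE) {
  list(var = as.integer(var), knot = as.numeric(knot),
       dir = as.integer(dir), linear = isTRUE(linear))
}

term_signature <- function(tm) {
  sprintf("%d:%.17g:%d:%d", tm$var, tm$knot, tm$dir, as.integer(tm$linear))
}

basis_signature <- function(bf) {
  paste(sort(vapply(bf$terms, term_signature, character(1))), collapse = "|")
}

basis_order <- function(bf) length(bf$terms)

basis_vars <- function(bf) vapply(bf$terms, function(t) t$var, integer(1))

n_knots_of_basis <- function(bf) sum(!vapply(bf$terms, function(t) t$linear, logical(1)))

# C1 piecewise-cubic replacement for a hinge (Friedman-style truncated
# cubic): zero below tlo, linear (x - t) above thi, cubic blend in between,
# continuous with continuous first derivative at both side knots.
cubic_hinge <- function(x, knot, tlo, thi, dir = 1) {
  if (dir < 0) return(cubic_hinge(-x, -knot, -thi, -tlo, 1))
  d <- thi - tlo
  s <- thi - knot
  p <- (3 * s - d) / d^2
  r <- (d - 2 * s) / d^3
  u <- x - tlo
  out <- ifelse(x <= tlo, 0, ifelse(x >= thi, x - knot, p * u^2 + r * u^3))
  out
}

eval_term <- function(tm, x, side = NULL) {
  if (tm$linear) return(x - tm$knot)
  if (is.null(side)) return(hinge(x, tm$knot, tm$dir))
  cubic_hinge(x, tm$knot, side[1], side[2], tm$dir)
}

# Basis-function evaluation matrix (n x M), without intercept column.
basis_matrix <- function(basis, X, cubic = FALSE, side_knots = NULL) {
  n <- nrow(X)
  M <- length(basis)
  if (M == 0L) return(matrix(numeric(0), n, 0))
  out <- matrix(1, n, M)
  for (m in seq_len(M)) {
    terms <- basis[[m]]$terms
    sides <- if (cubic && !is.null(side_knots)) side_knots[[m]] else NULL
    for (k in seq_along(terms)) {
      sd <- if (!is.null(sides)) sides[[k]] else NULL
      out[, m] <- out[, m] * eval_term(terms[[k]], X[, terms[[k]]$var], sd)
    }
  }
  out
}

model_matrix_mars <- function(model, X) {
  cbind(1, basis_matrix(model$basis, X, model$cubic, model$side_knots))
}

# Minimum-norm least squares via SVD (rank-deficient safe). y may be a matrix.
ls_minnorm <- function(A, y) {
  sv <- svd(A)
  tol <- max(dim(A)) * max(sv$d, 0) * .Machine$double.eps
  pos <- sv$d > tol
  if (!any(pos)) {
    if (is.matrix(y)) return(matrix(0, ncol(A), ncol(y)))
    return(rep(0, ncol(A)))
  }
  U <- sv$u[, pos, drop = FALSE]
  V <- sv$v[, pos, drop = FALSE]
  coef <- V %*% (crossprod(U, y) / sv$d[pos])
  if (is.matrix(y)) coef else drop(coef)
}

new_mars_model <- function(intercept, coef, basis, cubic = FALSE,
                           side_knots = NULL, var_ranges, var_binary,
                           var_names = NULL, training_sse = NA_real_,
                           training_r2 = NA_real_, penalty = NA_real_) {
  structure(list(intercept = as.numeric(intercept),
                 coef = as.numeric(coef),
                 basis = basis,
                 cubic = isTRUE(cubic),
                 side_knots = side_knots,
                 var_ranges = var_ranges,
                 var_binary = var_binary,
                 var_names = var_names,
                 training_sse = training_sse,
                 training_r2 = training_r2,
                 penalty = penalty),
            class = "mars_model")
}

#' @export
print.mars_model <- function(x, ...) {
  cat(sprintf("MARS model: intercept + %d basis function(s), %s hinges\n",
              length(x$basis), if (x$cubic) "cubic" else "linear"))
  if (length(x$basis)) {
    for (m in seq_along(x$basis)) {
      lab <- vapply(x$basis[[m]]$terms, function(t) {
        v <- if (!is.null(x$var_names)) x$var_names[t$var] else paste0("x", t$var)
        if (t$linear) sprintf("(%s - %.4g)", v, t$knot)
        else if (t$dir > 0) sprintf("(%s - %.4g)+", v, t$knot)
        else sprintf("(%.4g - %s)+", t$knot, v)
      }, character(1))
      cat(sprintf("  %+.5g * %s\n", x$coef[m], paste(lab, collapse = " * ")))
    }
  }
  if (is.finite(x$training_r2)) cat(sprintf("  training r2 = %.4f\n", x$training_r2))
  invisible(x)
}

check_newdata <- function(model, X) {
  X <- as.matrix(X)
  p <- ncol(model$var_ranges)
  if (!is.null(model$var_names) && !is.null(colnames(X)) &&
      all(model$var_names %in% colnames(X))) {
    X <- X[, model$var_names, drop = FALSE]
  } else if (ncol(X) != p) {
    stop(sprintf("newdata has %d columns; model expects %d", ncol(X), p))
  }
  storage.mode(X) <- "double"
  X
}

#' Predict from a fitted MARS model
#'
#' @param object A `mars_model`.
#' @param newdata Matrix or data frame with the model's predictor columns
#'   (matched by name when available, otherwise by position).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.mars_model <- function(object, newdata, ...) {
  X <- check_newdata(object, newdata)
  B <- basis_matrix(object$basis, X, object$cubic, object$side_knots)
  out <- rep(object$intercept, nrow(X))
  if (ncol(B)) out <- out + drop(B %*% object$coef)
  out
}

#' Coefficient of determination of a fitted model
#'
#' `1 - SSE/SST` against the given responses; constant responses yield 0
#' with a warning.
#'
#' @param model A `mars_model`.
#' @param X Predictor matrix.
#' @param y Response vector.
#' @return Scalar r-squared.
#' @export
r_squared <- function(model, X, y) {
  pred <- predict(model, X)
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) {
    warning("response has zero variance; r_squared defined as 0")
    return(0)
  }
  1 - sum((y - pred)^2) / sst
}

#' Generalized cross-validation score
#'
#' `(sse/n) / (1 - C/n)^2` with effective parameter count
#' `C = n_basis + 1 + penalty * n_knots`. Inadmissible models (`C >= n`)
#' score `Inf`.
#'
#' @param sse Residual sum of squares.
#' @param n Number of observations.
#' @param n_basis Number of basis functions (intercept excluded).
#' @param n_knots Total number of hinge knots in the model.
#' @param penalty Non-negative curvature penalty.
#' @return GCV score (scalar).
#' @export
gcv_score <- function(sse, n, n_basis, n_knots, penalty) {
  C <- n_basis + 1 + penalty * n_knots
  if (C >= n) return(Inf)
  (sse / n) / (1 - C / n)^2
}

# ---- forward pass ----------------------------------------------------------

# Candidate knots for one variable at the current step: observed values whose
# sorted position leaves >= edge observations on either side, that keep
# >= between observations strictly between themselves and every knot already
# placed on this variable, thinned to at most `cap` evenly index-spaced values.
admissible_knots <- function(xs_sorted, edge, existing, between, cap) {
  n <- length(xs_sorted)
  if (n < 2L * edge + 1L) return(numeric(0))
  vals <- unique(xs_sorted[seq.int(edge + 1L, n - edge)])
  if (length(existing)) {
    n_lt <- function(v) findInterval(v, xs_sorted, left.open = TRUE)
    n_le <- function(v) findInterval(v, xs_sorted)
    ok <- rep(TRUE, length(vals))
    for (k in existing) {
      lo <- pmin(vals, k); hi <- pmax(vals, k)
      cnt <- n_lt(hi) - n_le(lo)
      ok <- ok & vals != k & cnt >= between
    }
    vals <- vals[ok]
  }
  if (length(vals) > cap) {
    idx <- unique(round(seq(1, length(vals), length.out = cap)))
    vals <- vals[idx]
  }
  vals
}

#' Forward pass of the spline engine
#'
#' Greedily grows a set of reflected hinge-pair basis functions (and their
#' products with existing functions, up to the interaction cap) that
#' maximally reduce the residual sum of squares, subject to the sample-count
#' knot constraints. Binary predictors enter as single linear terms. Stops at
#' `max_initial_funcs` basis functions or when no admissible candidate
#' reduces the error.
#'
#' @param X Predictor matrix (n x p).
#' @param y Response vector.
#' @param constraints A [fit_constraints()] object.
#' @return An unpruned, linear-mode `mars_model`.
#' @export
mars_forward <- function(X, y, constraints) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  cc <- constraints
  if (n < 2L * cc$min_obs_to_edge + 1L)
    stop(sprintf("forward pass needs at least %d rows for min_obs_to_edge = %d (got %d)",
                 2L * cc$min_obs_to_edge + 1L, cc$min_obs_to_edge, n))
  binary <- apply(X, 2, function(v) length(unique(v)) == 2L)
  sorted <- lapply(seq_len(p), function(j) sort(X[, j]))
  var_ranges <- apply(X, 2, range)

  basis <- list()
  # construction route of each basis function, for cheap duplicate checks
  route <- data.frame(parent = integer(0), var = integer(0),
                      knot = numeric(0), linear = logical(0))
  knots_by_var <- rep(list(numeric(0)), p)
  Bfull <- matrix(1, n, 1)
  qrB <- qr(Bfull)
  res_y <- qr.resid(qrB, y)
  sse <- sum(res_y^2)
  sst <- sum((y - mean(y))^2)
  gain_tol <- max(sst, 1e-300) * 1e-12

  repeat {
    M <- length(basis)
    if (M + 1L > cc$max_initial_funcs) break
    if (sse <= 1e-13 * max(sst, 1)) break
    can_pair <- M + 2L <= cc$max_initial_funcs

    order_of <- vapply(basis, basis_order, integer(1))
    parents <- c(0L, which(order_of < cc$max_interaction))

    ak_var <- lapply(seq_len(p), function(j) {
      if (binary[j]) return(numeric(0))
      admissible_knots(sorted[[j]], cc$min_obs_to_edge, knots_by_var[[j]],
                       cc$min_obs_between_knots, cc$knot_thinning)
    })
    cand_parent <- integer(0); cand_var <- integer(0)
    cand_knot <- numeric(0); cand_pair <- logical(0)
    for (pa in parents) {
      pvars <- if (pa == 0L) integer(0) else basis_vars(basis[[pa]])
      used <- route$parent == pa
      for (j in seq_len(p)) {
        if (j %in% pvars) next
        used_knots <- route$knot[used & route$var == j]
        if (binary[j]) {
          if (any(used & route$var == j & route$linear)) next
          cand_parent <- c(cand_parent, pa); cand_var <- c(cand_var, j)
          cand_knot <- c(cand_knot, min(X[, j])); cand_pair <- c(cand_pair, FALSE)
        } else {
          if (!can_pair) next
          ak <- ak_var[[j]]
          if (length(used_knots)) ak <- setdiff(ak, used_knots)
          if (!length(ak)) next
          cand_parent <- c(cand_parent, rep(pa, length(ak)))
          cand_var <- c(cand_var, rep(j, length(ak)))
          cand_knot <- c(cand_knot, ak)
          cand_pair <- c(cand_pair, rep(TRUE, length(ak)))
        }
      }
    }
    nc <- length(cand_parent)
    if (nc == 0L) break

    # Candidate columns: two per reflected pair, one per linear term.
    pc_mat <- Bfull[, cand_parent + 1L, drop = FALSE]
    xj_mat <- X[, cand_var, drop = FALSE]
    dev <- sweep(xj_mat, 2, cand_knot)
    U1 <- pc_mat * ifelse(cand_pair[col(dev)], pmax(dev, 0), dev)
    U2 <- pc_mat * pmax(-dev, 0)
    raw1 <- colSums(U1^2); raw2 <- colSums(U2^2)
    raw_scale <- max(raw1, raw2, 1)
    Q <- qr.Q(qrB)
    R1 <- U1 - Q %*% crossprod(Q, U1)
    R2 <- U2 - Q %*% crossprod(Q, U2)
    a11 <- colSums(R1^2); a22 <- colSums(R2^2)
    a12 <- colSums(R1 * R2)
    b1 <- as.numeric(crossprod(R1, res_y))
    b2 <- as.numeric(crossprod(R2, res_y))
    col_tol <- 1e-10 * raw_scale

    ok1 <- a11 > col_tol
    ok2 <- cand_pair & a22 > col_tol
    g1 <- ifelse(ok1, b1^2 / pmax(a11, 1e-300), 0)
    g2 <- ifelse(ok2, b2^2 / pmax(a22, 1e-300), 0)
    den <- a11 * a22 - a12^2
    both <- ok1 & ok2 & den > 1e-12 * a11 * a22
    gains <- pmax(g1, g2)
    gains[both] <- (b1[both]^2 * a22[both] - 2 * b1[both] * b2[both] * a12[both] +
                      b2[both]^2 * a11[both]) / den[both]

    gmax <- max(gains)
    if (!is.finite(gmax) || gmax <= gain_tol) break
    # Tie-break: best gain, then lowest variable index, then smallest knot,
    # then earliest parent.
    near <- which(gains >= gmax - 1e-9 * gmax)
    sel <- near[order(cand_var[near], cand_knot[near], cand_parent[near])][1]

    pa <- cand_parent[sel]; j <- cand_var[sel]; t <- cand_knot[sel]
    pterms <- if (pa > 0L) basis[[pa]]$terms else list()
    newcols <- NULL
    if (cand_pair[sel]) {
      for (dir in c(1L, -1L)) {
        raw <- if (dir > 0L) raw1[sel] else raw2[sel]
        if (raw <= 1e-24 * raw_scale) next
        bf <- list(terms = c(pterms, list(new_term(j, t, dir))))
        basis[[length(basis) + 1L]] <- bf
        route <- rbind(route, data.frame(parent = pa, var = j, knot = t,
                                         linear = FALSE))
        newcols <- cbind(newcols, if (dir > 0L) U1[, sel] else U2[, sel])
      }
      knots_by_var[[j]] <- sort(unique(c(knots_by_var[[j]], t)))
    } else {
      bf <- list(terms = c(pterms, list(new_term(j, t, 1L, linear = TRUE))))
      basis[[length(basis) + 1L]] <- bf
      route <- rbind(route, data.frame(parent = pa, var = j, knot = t,
                                       linear = TRUE))
      newcols <- U1[, sel, drop = FALSE]
    }
    if (is.null(newcols)) break
    Bfull <- cbind(Bfull, newcols)
    qrB <- qr(Bfull)
    res_y <- qr.resid(qrB, y)
    new_sse <- sum(res_y^2)
    if (new_sse > sse - gain_tol && length(basis) > 2L) {
      # numerically no progress: drop what we just added and stop
      keep <- seq_len(length(basis) - ncol(newcols))
      basis <- basis[keep]
      route <- route[keep, , drop = FALSE]
      Bfull <- Bfull[, seq_len(length(keep) + 1L), drop = FALSE]
      qrB <- qr(Bfull); res_y <- qr.resid(qrB, y)
      break
    }
    sse <- new_sse
  }

  cf <- ls_minnorm(Bfull, y)
  fitted_sse <- sum((y - Bfull %*% cf)^2)
  r2 <- if (sst > 0) 1 - fitted_sse / sst else 0
  new_mars_model(intercept = cf[1],
                 coef = if (length(cf) > 1) cf[-1] else numeric(0),
                 basis = basis,
                 cubic = FALSE,
                 var_ranges = var_ranges,
                 var_binary = binary,
                 var_names = colnames(X),
                 training_sse = fitted_sse,
                 training_r2 = r2)
}

# ---- backward pruning ------------------------------------------------------

# Greedy backward deletion from precomputed Gram quantities, via inverse
# downdating: deleting column j raises SSE by beta_j^2 / [G^-1]_jj, and
# G^-1, beta update by the partitioned-inverse identity. Records the best
# model of every size; `protected` columns (always including the intercept,
# column 1) are never deleted. Returns the GCV-optimal column subset among
# sizes with n_basis <= max_final.
prune_gram <- function(G, b, yty, n, knot_counts, penalty, max_final,
                       protected = integer(0)) {
  m0 <- ncol(G)
  protected <- sort(unique(c(1L, protected)))
  Ginv <- tryCatch(chol2inv(chol(G)), error = function(e) NULL)
  if (is.null(Ginv)) {
    Ginv <- chol2inv(chol(G + diag(1e-9 * mean(diag(G)), m0)))
  }
  beta <- drop(Ginv %*% b)
  sse <- max(yty - sum(b * beta), 0)

  S <- seq_len(m0)
  states <- vector("list", m0)
  record <- function(S, sse) {
    nb <- length(S) - 1L
    nk <- sum(knot_counts[setdiff(S, 1L)])
    list(S = S, sse = sse, n_basis = nb,
         gcv = gcv_score(sse, n, nb, nk, penalty))
  }
  states[[length(S)]] <- record(S, sse)

  while (length(S) > length(protected)) {
    rem <- which(!(S %in% protected))
    dsse <- beta[rem]^2 / pmax(diag(Ginv)[rem], 1e-300)
    gcvs <- vapply(seq_along(rem), function(k) {
      Snew <- S[-rem[k]]
      nb <- length(Snew) - 1L
      nk <- sum(knot_counts[setdiff(Snew, 1L)])
      gcv_score(sse + dsse[k], n, nb, nk, penalty)
    }, numeric(1))
    k <- which.min(gcvs)
    j <- rem[k]
    h <- Ginv[, j]
    beta <- beta[-j] - h[-j] * (beta[j] / h[j])
    Ginv <- Ginv[-j, -j, drop = FALSE] - tcrossprod(h[-j]) / h[j]
    sse <- sse + dsse[k]
    S <- S[-j]
    states[[length(S)]] <- record(S, sse)
  }

  sizes <- which(!vapply(states, is.null, logical(1)))
  elig <- sizes[vapply(states[sizes], function(st) st$n_basis <= max_final,
                       logical(1))]
  if (!length(elig)) elig <- min(sizes)
  gv <- vapply(states[elig], function(st) st$gcv, numeric(1))
  best <- elig[order(gv, elig)][1]
  states[[best]]
}

prune_path <- function(B, y, knot_counts, penalty, max_final,
                       protected = integer(0)) {
  n <- nrow(B)
  sst <- sum((y - mean(y))^2)
  st <- prune_gram(crossprod(B), as.numeric(crossprod(B, y)), sum(y^2), n,
                   knot_counts, penalty, max_final, protected)
  cf <- ls_minnorm(B[, st$S, drop = FALSE], y)
  sse_exact <- sum((y - B[, st$S, drop = FALSE] %*% cf)^2)
  list(kept = setdiff(st$S, 1L) - 1L,  # basis indices of the input model
       coef = cf, sse = sse_exact,
       gcv = gcv_score(sse_exact, n, st$n_basis,
                       sum(knot_counts[setdiff(st$S, 1L)]), penalty),
       r2 = if (sst > 0) 1 - sse_exact / sst else 0)
}

#' Backward pruning pass
#'
#' Iteratively deletes the basis function whose removal minimizes the GCV
#' score, records the best model of each size, and returns the GCV-optimal
#' model with at most `max_final_funcs` basis functions (coefficients refit
#' by least squares).
#'
#' @param model A `mars_model` (typically from [mars_forward()]).
#' @param X,y Training data.
#' @param constraints A [fit_constraints()] object; its `penalty` must be
#'   numeric (resolve `"cv"` with [select_penalty_cv()] first).
#' @param protected Integer indices of basis functions that may never be
#'   deleted.
#' @return A pruned `mars_model` with attribute `kept_idx` giving the
#'   retained basis indices of the input model.
#' @export
backward_prune <- function(model, X, y, constraints, protected = integer(0)) {
  X <- check_newdata(model, X)
  penalty <- constraints$penalty
  if (is.character(penalty))
    stop("penalty is \"cv\"; resolve it with select_penalty_cv() before pruning")
  if (length(model$basis) == 0L) {
    out <- model
    attr(out, "kept_idx") <- integer(0)
    return(out)
  }
  B <- model_matrix_mars(model, X)
  kc <- vapply(model$basis, n_knots_of_basis, integer(1))
  pr <- prune_path(B, y, c(0L, kc), penalty, constraints$max_final_funcs,
                   protected = protected + 1L)
  kept <- pr$kept
  out <- new_mars_model(intercept = pr$coef[1],
                        coef = if (length(pr$coef) > 1) pr$coef[-1] else numeric(0),
                        basis = model$basis[kept],
                        cubic = model$cubic,
                        side_knots = if (!is.null(model$side_knots)) model$side_knots[kept],
                        var_ranges = model$var_ranges,
                        var_binary = model$var_binary,
                        var_names = model$var_names,
                        training_sse = pr$sse,
                        training_r2 = pr$r2,
                        penalty = penalty)
  attr(out, "kept_idx") <- kept
  attr(out, "gcv") <- pr$gcv
  out
}

# ---- cubic conversion ------------------------------------------------------

#' Convert a linear-hinge model to C1 piecewise-cubic form
#'
#' Each hinge is replaced by a cubic piece with side knots at the midpoints
#' to the adjacent knots on the same variable (data extremes serve as outer
#' boundaries); linear (binary-predictor) terms are left untouched.
#' Coefficients are refit by least squares on the cubic basis. Outside every
#' side-knot interval the cubic and linear bases agree exactly.
#'
#' @param model A linear-mode `mars_model`.
#' @param X Training predictor matrix (for the refit and the data extremes).
#' @param y Training response (for the refit).
#' @return A cubic-mode `mars_model`.
#' @export
to_cubic <- function(model, X, y) {
  if (model$cubic) return(model)
  X <- check_newdata(model, X)
  p <- ncol(model$var_ranges)
  knots_by_var <- rep(list(numeric(0)), p)
  for (bf in model$basis) for (tm in bf$terms) {
    if (!tm$linear)
      knots_by_var[[tm$var]] <- sort(unique(c(knots_by_var[[tm$var]], tm$knot)))
  }
  rng <- apply(X, 2, range)
  side_knots <- lapply(model$basis, function(bf) {
    lapply(bf$terms, function(tm) {
      if (tm$linear) return(NULL)
      ks <- knots_by_var[[tm$var]]
      lo <- rng[1, tm$var]; hi <- rng[2, tm$var]
      below <- ks[ks < tm$knot]; above <- ks[ks > tm$knot]
      prev <- if (length(below)) max(below) else lo
      nxt <- if (length(above)) min(above) else hi
      tlo <- (prev + tm$knot) / 2
      thi <- (tm$knot + nxt) / 2
      if (thi - tlo < 1e-12 * max(hi - lo, 1)) return(NULL)
      c(tlo, thi)
    })
  })
  out <- model
  out$cubic <- TRUE
  out$side_knots <- side_knots
  if (length(model$basis)) {
    B <- model_matrix_mars(out, X)
    cf <- ls_minnorm(B, y)
    out$intercept <- cf[1]
    out$coef <- cf[-1]
    out$training_sse <- sum((y - B %*% cf)^2)
    sst <- sum((y - mean(y))^2)
    out$training_r2 <- if (sst > 0) 1 - out$training_sse / sst else 0
  }
  out
}

# ---- penalty selection and the full fit ------------------------------------

#' Select the curvature penalty by k-fold cross-validation
#'
#' For each grid value the full forward + backward fit is cross-validated;
#' the value minimizing the mean squared prediction error is returned, ties
#' broken toward the smallest penalty. Fold assignment is deterministic given
#' `constraints$rng_seed`.
#'
#' @param X,y Training data.
#' @param constraints A [fit_constraints()] object.
#' @param grid Candidate penalties (defaults to `constraints$penalty_grid`).
#' @return The selected penalty, with the per-penalty CV error in attribute
#'   `"cv_mse"`.
#' @export
select_penalty_cv <- function(X, y, constraints, grid = constraints$penalty_grid) {
  if (!length(grid)) stop("empty penalty grid")
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  k <- constraints$cv_folds
  if (n < k) stop("need at least as many rows as cv_folds")
  folds <- with_seed(constraints$rng_seed, sample(rep_len(seq_len(k), n)))
  grid <- sort(as.numeric(grid))
  mse <- vapply(grid, function(pen) {
    cc <- constraints; cc$penalty <- pen
    err <- 0
    for (f in seq_len(k)) {
      tr <- folds != f
      fit <- mars_forward(X[tr, , drop = FALSE], y[tr], cc)
      fit <- backward_prune(fit, X[tr, , drop = FALSE], y[tr], cc)
      if (cc$cubic) fit <- to_cubic(fit, X[tr, , drop = FALSE], y[tr])
      err <- err + sum((y[!tr] - predict(fit, X[!tr, , drop = FALSE]))^2)
    }
    err / n
  }, numeric(1))
  best <- grid[which(mse <= min(mse) + 1e-12 * (1 + min(mse)))[1]]
  attr(best, "cv_mse") <- stats::setNames(mse, grid)
  best
}

#' Fit a MARS model (forward pass, pruning, optional cubic smoothing)
#'
#' @param X Predictor matrix.
#' @param y Response vector.
#' @param constraints A [fit_constraints()] object; `penalty = "cv"` is
#'   resolved by [select_penalty_cv()] first.
#' @return A pruned `mars_model`.
#' @export
mars_fit <- function(X, y, constraints = fit_constraints()) {
  cc <- constraints
  if (is.character(cc$penalty)) cc$penalty <- as.numeric(select_penalty_cv(X, y, cc))
  fwd <- mars_forward(X, y, cc)
  fit <- backward_prune(fwd, X, y, cc)
  if (cc$cubic) fit <- to_cubic(fit, X, y)
  fit$penalty <- cc$penalty
  fit
}

# ---- serialization ---------------------------------------------------------

#' Serialize a MARS model to JSON
#'
#' Self-describing single-model container: intercept, coefficients, basis
#' term lists, cubic side knots, variable metadata and engine version.
#'
#' @param model A `mars_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mars_model <- function(model, path) {
  obj <- list(engine = "tpmars",
              version = as.character(utils::packageVersion("tpmars")),
              intercept = model$intercept,
              coef = model$coef,
              cubic = model$cubic,
              penalty = model$penalty,
              var_names = model$var_names,
              var_ranges = model$var_ranges,
              var_binary = model$var_binary,
              basis = lapply(model$basis, function(bf) {
                lapply(bf$terms, function(tm) tm)
              }),
              side_knots = model$side_knots,
              training_sse = model$training_sse,
              training_r2 = model$training_r2)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a MARS model serialized with [write_mars_model()]
#'
#' @param path JSON file path.
#' @return A `mars_model`.
#' @export
read_mars_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  basis <- lapply(obj$basis, function(bf) {
    list(terms = lapply(bf, function(tm) {
      new_term(tm$var, tm$knot, tm$dir, isTRUE(tm$linear))
    }))
  })
  side <- NULL
  if (!is.null(obj$side_knots)) {
    side <- lapply(obj$side_knots, function(bf) {
      lapply(bf, function(s) if (is.null(s)) NULL else as.numeric(unlist(s)))
    })
  }
  vr <- matrix(unlist(obj$var_ranges), nrow = 2)
  new_mars_model(intercept = as.numeric(obj$intercept),
                 coef = as.numeric(unlist(obj$coef)),
                 basis = basis,
                 cubic = isTRUE(obj$cubic),
                 side_knots = side,
                 var_ranges = vr,
                 var_binary = as.logical(unlist(obj$var_binary)),
                 var_names = if (is.null(obj$var_names)) NULL else as.character(unlist(obj$var_names)),
                 training_sse = as.numeric(obj$training_sse),
                 training_r2 = as.numeric(obj$training_r2),
                 penalty = if (is.null(obj$penalty)) NA_real_ else as.numeric(obj$penalty))
}
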