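# Multivariate REML for the animal model with maternal- and paternal-
# identity random effects and a log centroid-size covariate.
#
# The model for the t-variate phenotype row y_i of individual i is
#   y = X beta + a + m_dam + p_sire + e,
# a ~ N(0, G (x) A), m ~ N(0, Mat (x) I_dams), p ~ N(0, Pat (x) I_sires),
# e ~ N(0, R (x) I). Estimation works on the marginal covariance of the
# phenotyped individuals (the A submatrix of observed ids), so
#   V = G (x) A_oo + Mat (x) DD' + Pat (x) SS' + R (x) I,
# with DD'/SS' the shared-dam / shared-sire indicators. Updates are exact
# EM steps (monotone in the restricted likelihood, PSD by construction)
# with average-information (AI) acceleration guarded by step halving and
# fall-back to EM; components that collapse to the boundary are pinned at
# zero. Starting values come from method-of-moments covariances of
# parent-offspring and half-sib pairs when the design provides them.

#' Assemble data for the animal model
#'
#' @param traits n x t numeric matrix of shape variables (e.g., retained
#'   principal-component scores), one row per phenotyped individual.
#' @param log_cs Numeric n-vector: log centroid size (fixed covariate,
#'   centred internally before fitting).
#' @param ids Character n-vector of individual ids.
#' @param ped A [pedigree()]; every id must be present. Dam and sire of
#'   each row are looked up here.
#' @return Object of class `animal_model_data`.
#' @export
animal_model_data <- function(traits, log_cs, ids, ped) {
  Y <- as.matrix(traits)
  ids <- as.character(ids)
  n <- nrow(Y)
  if (length(log_cs) != n || length(ids) != n)
    stop("traits, log_cs and ids must agree in length", call. = FALSE)
  if (anyNA(Y)) stop("missing trait values are not supported", call. = FALSE)
  if (anyDuplicated(ids))
    stop("one phenotype row per individual is required", call. = FALSE)
  miss <- setdiff(ids, ped$id)
  if (length(miss) > 0L)
    stop("phenotyped ids missing from the pedigree: ",
         paste(utils::head(miss, 5L), collapse = ", "),
         if (length(miss) > 5L) ", ...", call. = FALSE)
  pos <- match(ids, ped$id)
  structure(list(Y = Y, log_cs = as.numeric(log_cs), ids = ids,
                 dam = ped$dam[pos], sire = ped$sire[pos]),
            class = "animal_model_data")
}

#' @export
print.animal_model_data <- function(x, ...) {
  cat(sprintf("Animal-model data: %d individuals, %d traits, %d dams, %d sires\n",
              nrow(x$Y), ncol(x$Y), length(unique(stats::na.omit(x$dam))),
              length(unique(stats::na.omit(x$sire)))))
  invisible(x)
}

# Assemble V = sum_k Theta_k (x) B_k by trait blocks.
reml_V_ <- function(theta, env) {
  n <- env$n; t <- env$t
  V <- matrix(0, n * t, n * t)
  for (r in seq_len(t)) for (s in seq_len(t)) {
    blk <- matrix(0, n, n)
    for (k in seq_along(env$B))
      if (theta[[k]][r, s] != 0) blk <- blk + theta[[k]][r, s] * env$B[[k]]
    V[(r - 1L) * n + seq_len(n), (s - 1L) * n + seq_len(n)] <- blk
  }
  V
}

chol_safe_ <- function(V) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch))
    ch <- chol(V + diag(1e-10 * max(mean(diag(V)), 1e-300), nrow(V)))
  ch
}

# Restricted log-likelihood (up to the additive -(nt-p)/2 log(2pi)
# constant). Cheap path (want_P = FALSE) uses triangular backsolves only;
# full path also returns Py and the projection matrix P needed by EM/AI.
reml_eval_ <- function(theta, env, want_P = TRUE) {
  V <- reml_V_(theta, env)
  ch <- chol_safe_(V)
  if (!want_P) {
    W1 <- backsolve(ch, cbind(env$Xs, env$y), transpose = TRUE)
    nx <- ncol(env$Xs)
    XtVX <- crossprod(W1[, seq_len(nx), drop = FALSE])
    chX <- chol(XtVX)
    Xty <- crossprod(W1[, seq_len(nx), drop = FALSE], W1[, nx + 1L])
    bhat <- backsolve(chX, backsolve(chX, Xty, transpose = TRUE))
    yPy <- sum(W1[, nx + 1L]^2) - sum(Xty * bhat)
    logl <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) + yPy)
    return(list(logl = logl, beta = matrix(bhat, ncol = env$t)))
  }
  Vi <- chol2inv(ch)
  VX <- Vi %*% env$Xs
  XtVX <- crossprod(env$Xs, VX)
  chX <- chol(XtVX)
  Wsolve <- chol2inv(chX)
  bhat <- Wsolve %*% crossprod(VX, env$y)
  Py <- Vi %*% env$y - VX %*% (Wsolve %*% crossprod(VX, env$y))
  logl <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) +
                    sum(env$y * Py))
  M <- VX %*% Wsolve
  list(logl = logl, Py = Py, beta = matrix(bhat, ncol = env$t),
       P = Vi - tcrossprod(M, VX))
}

# Per component: W[r,s] = w_r' B w_s (w = trait blocks of Py),
# T[r,s] = tr(P_rs B), plus B %*% w reused by the AI step.
reml_wt_ <- function(ev, env) {
  n <- env$n; t <- env$t
  w <- matrix(ev$Py, n, t)
  lapply(seq_along(env$B), function(k) {
    Bw <- env$B[[k]] %*% w
    W <- crossprod(w, Bw)
    Tm <- matrix(0, t, t)
    for (r in seq_len(t)) for (s in seq_len(r)) {
      Tm[r, s] <- Tm[s, r] <-
        sum(ev$P[(r - 1L) * n + seq_len(n), (s - 1L) * n + seq_len(n)] *
              env$B[[k]])
    }
    list(W = W, T = Tm, Bw = Bw)
  })
}

psd_project_ <- function(m, floor = 0) {
  ee <- eigen((m + t(m)) / 2, symmetric = TRUE)
  lam <- pmax(ee$values, floor)
  ee$vectors %*% (t(ee$vectors) * lam)
}

# Method-of-moments starting values from OLS residual cross-covariances of
# parent-offspring, maternal half-sib and paternal half-sib pairs. Falls
# back to S/4 per component when a pair class is absent.
moment_start_ <- function(data, X0, active) {
  Y <- data$Y
  t <- ncol(Y)
  E <- stats::resid(stats::lm.fit(X0, Y))
  E <- as.matrix(E)
  S <- stats::cov(Y)
  pair_cov_ <- function(i, j) {
    if (length(i) < 5L) return(NULL)
    M <- crossprod(E[i, , drop = FALSE], E[j, , drop = FALSE]) / length(i)
    (M + t(M)) / 2
  }
  # parent-offspring pairs (parent has a phenotype row)
  po_i <- integer(0); po_j <- integer(0)
  for (par in c("dam", "sire")) {
    pj <- match(data[[par]], data$ids)
    ok <- which(!is.na(pj))
    po_i <- c(po_i, ok); po_j <- c(po_j, pj[ok])
  }
  # half-sib pairs by shared parent, split by the other parent
  key <- function(a, b) paste(a, b, sep = "\r")
  hs_pairs_ <- function(shared, other) {
    i <- integer(0); j <- integer(0)
    grp <- split(seq_along(shared), shared)
    for (g in grp) {
      if (length(g) < 2L) next
      cmb <- utils::combn(g, 2L)
      keep <- other[cmb[1L, ]] != other[cmb[2L, ]]
      i <- c(i, cmb[1L, keep]); j <- c(j, cmb[2L, keep])
    }
    list(i = i, j = j)
  }
  known <- !is.na(data$dam) & !is.na(data$sire)
  dm <- ifelse(known, data$dam, NA)
  sr <- ifelse(known, data$sire, NA)
  mh <- hs_pairs_(ifelse(is.na(dm), paste0("?", seq_along(dm)), dm), sr)
  ph <- hs_pairs_(ifelse(is.na(sr), paste0("?", seq_along(sr)), sr), dm)
  C_po <- pair_cov_(po_i, po_j)
  C_mh <- pair_cov_(mh$i, mh$j)
  C_ph <- pair_cov_(ph$i, ph$j)

  G0 <- if (!is.null(C_po) && "G" %in% active) psd_project_(2 * C_po)
        else if ("G" %in% active) S / 4 else matrix(0, t, t)
  Mat0 <- if (!is.null(C_mh) && "Mat" %in% active)
    psd_project_(C_mh - G0 / 4) else if ("Mat" %in% active) S / 4
    else matrix(0, t, t)
  Pat0 <- if (!is.null(C_ph) && "Pat" %in% active)
    psd_project_(C_ph - G0 / 4) else if ("Pat" %in% active) S / 4
    else matrix(0, t, t)
  # keep the explained part strictly inside the phenotypic covariance
  tot <- sum(diag(G0 + Mat0 + Pat0))
  if (tot > 0.9 * sum(diag(S))) {
    f <- 0.9 * sum(diag(S)) / tot
    G0 <- f * G0; Mat0 <- f * Mat0; Pat0 <- f * Pat0
  }
  R0 <- psd_project_(S - G0 - Mat0 - Pat0, 0.02 * mean(diag(S)))
  list(G = G0, Mat = Mat0, Pat = Pat0, R = R0)
}

#' REML estimation of shape variance components (animal model)
#'
#' Maximizes the multivariate restricted log-likelihood of the animal model
#' with additive-genetic, maternal-identity and paternal-identity random
#' effects and fixed intercept + log centroid size per trait. Updates are
#' exact EM steps (monotone restricted likelihood, positive-semidefinite
#' components by construction), accelerated by default with average-
#' information steps; an AI step is accepted only if it keeps the
#' components in the parameter space and does not decrease the likelihood,
#' otherwise it is halved and ultimately replaced by the EM step.
#' Components whose trace collapses to the boundary are pinned at zero for
#' the remaining iterations.
#'
#' @param data An [animal_model_data()].
#' @param ped A [pedigree()]; required when `"animal"` is among
#'   `components`.
#' @param components Character subset of
#'   `c("animal", "maternal", "paternal")` naming the random effects to
#'   fit besides the residual. Excluded components are fixed at zero.
#' @param start Optional list with starting matrices `G`, `Mat`, `Pat`,
#'   `R`; default is a method-of-moments estimate from parent-offspring
#'   and half-sib covariances (sample covariance / 4 where the design has
#'   no such pairs).
#' @param max_iter Maximum iterations (default 2000).
#' @param tol_logl Convergence: absolute restricted-log-likelihood change.
#' @param tol_par Convergence: maximum relative parameter change.
#' @param accelerate Use AI acceleration after `ai_start` EM iterations.
#' @param ai_start Number of initial pure-EM iterations.
#' @param verbose Print the likelihood trajectory.
#' @return Object of class `variance_components`: matrices `G`, `Mat`,
#'   `Pat`, `R`, their sum `P`, fixed effects `beta` (rows: intercept,
#'   log CS; columns: traits), `logL` (up to an additive constant),
#'   `logL_path`, `n_iter`, `converged`, and the step type per iteration
#'   (`steps`).
#' @export
reml_fit <- function(data, ped = NULL,
                     components = c("animal", "maternal", "paternal"),
                     start = NULL, max_iter = 2000L, tol_logl = 1e-8,
                     tol_par = 1e-6, accelerate = TRUE, ai_start = 1L,
                     verbose = FALSE) {
  stopifnot(inherits(data, "animal_model_data"))
  components <- match.arg(components, several.ok = TRUE)
  Y <- data$Y
  n <- nrow(Y); t <- ncol(Y)
  X0 <- cbind(intercept = 1, log_cs = data$log_cs - mean(data$log_cs))
  if (qr(X0)$rank < ncol(X0)) X0 <- X0[, 1L, drop = FALSE]
  p <- ncol(X0)
  if (n < p + 1L) stop("need more observations than fixed effects",
                       call. = FALSE)

  B <- list(); q <- c()
  if ("animal" %in% components) {
    if (is.null(ped)) stop("components include \"animal\" but ped is NULL",
                           call. = FALSE)
    A <- relationship_matrix(ped)
    B$G <- A[data$ids, data$ids]
    q["G"] <- n
  }
  if ("maternal" %in% components) {
    dams <- factor(data$dam)
    if (nlevels(dams) < 2L)
      stop("need at least 2 distinct dams for a maternal component",
           call. = FALSE)
    Zf <- matrix(0, n, nlevels(dams))
    Zf[cbind(which(!is.na(data$dam)), as.integer(dams)[!is.na(data$dam)])] <- 1
    B$Mat <- tcrossprod(Zf)
    q["Mat"] <- nlevels(dams)
  }
  if ("paternal" %in% components) {
    sires <- factor(data$sire)
    if (nlevels(sires) < 2L)
      stop("need at least 2 distinct sires for a paternal component",
           call. = FALSE)
    Zf <- matrix(0, n, nlevels(sires))
    Zf[cbind(which(!is.na(data$sire)),
             as.integer(sires)[!is.na(data$sire)])] <- 1
    B$Pat <- tcrossprod(Zf)
    q["Pat"] <- nlevels(sires)
  }
  B$R <- diag(n)
  q["R"] <- n

  n_par <- length(B) * t * (t + 1L) / 2L
  if (n_par > n)
    warning(sprintf("%d covariance parameters for %d observations; estimates may be poorly determined",
                    n_par, n))

  S <- stats::cov(Y)
  scale0 <- max(mean(diag(S)), 0)
  active_names <- intersect(c("G", "Mat", "Pat"), names(B))
  if (scale0 < 1e-20 * max(1, max(abs(Y)))^2) {
    zero <- matrix(0, t, t)
    return(new_vc_(zero, zero, zero, zero,
                   beta = matrix(0, p, t), logL = NA_real_,
                   logL_path = numeric(0), n_iter = 0L, converged = TRUE,
                   steps = character(0), trait_names = colnames(Y)))
  }

  theta <- moment_start_(data, X0, active_names)[names(B)]
  names(theta) <- names(B)
  if (!is.null(start))
    for (k in names(B)) if (!is.null(start[[k]])) theta[[k]] <- start[[k]]
  floorR <- 1e-12 * scale0
  pin_tol <- 1e-7 * scale0
  pinned <- stats::setNames(rep(FALSE, length(B)), names(B))

  env <- list(n = n, t = t, y = as.vector(Y),
              Xs = kronecker(diag(t), X0), B = B)
  lower_idx <- which(lower.tri(matrix(0, t, t), diag = TRUE))
  pack_ <- function(th)
    unlist(lapply(th, function(m) m[lower_idx]), use.names = FALSE)
  unpack_one_ <- function(v) {
    m <- matrix(0, t, t)
    m[lower_idx] <- v
    m + t(m) - diag(diag(m), t)
  }

  logl_path <- numeric(0)
  steps <- character(0)
  ev <- reml_eval_(theta, env)
  converged <- FALSE
  iter <- 0L
  ai_skip <- 0L
  prev_d <- NULL
  prev_step <- ""
  repeat {
    iter <- iter + 1L
    logl_path[iter] <- ev$logl
    if (verbose)
      message(sprintf("iter %3d  logL %.8f", iter, ev$logl))
    old_pack <- pack_(theta)
    wt <- reml_wt_(ev, env)

    # exact EM proposal (pinned components stay at zero)
    th_em <- theta
    for (k in seq_along(B)) {
      if (pinned[k]) next
      Th <- theta[[k]]
      upd <- Th + (Th %*% (wt[[k]]$W - wt[[k]]$T) %*% Th) / q[k]
      th_em[[k]] <- (upd + t(upd)) / 2
    }
    th_em$R <- psd_project_(th_em$R, floorR)

    step <- "em"
    th_new <- th_em

    if (accelerate && iter > ai_start && ai_skip == 0L) {
      # AI (average-information) Newton step taken on the lower Cholesky
      # factors of the free components, so any step stays inside the PSD
      # cone and near-boundary components naturally freeze.
      free <- names(B)[!pinned]
      npar1 <- length(lower_idx)
      gvec <- numeric(0)
      dmat <- NULL
      for (k in match(free, names(B))) {
        Wk <- wt[[k]]$W; Tk <- wt[[k]]$T; Bw <- wt[[k]]$Bw
        for (idx in lower_idx) {
          i <- (idx - 1L) %% t + 1L
          j <- (idx - 1L) %/% t + 1L
          mult <- if (i == j) 1 else 2
          gvec <- c(gvec, 0.5 * mult * (Wk[i, j] - Tk[i, j]))
          d <- numeric(n * t)
          d[(i - 1L) * n + seq_len(n)] <- Bw[, j]
          if (i != j)
            d[(j - 1L) * n + seq_len(n)] <- d[(j - 1L) * n + seq_len(n)] +
              Bw[, i]
          dmat <- cbind(dmat, d)
        }
      }
      Pd <- ev$P %*% dmat
      AI <- 0.5 * crossprod(dmat, Pd)

      # chain rule to Cholesky parameters: theta_ij = sum_b L[i,b] L[j,b]
      Ls <- list()
      J <- matrix(0, length(gvec), length(gvec))
      ok_chol <- TRUE
      for (ki in seq_along(free)) {
        k <- free[ki]
        jit <- 1e-10 * max(scale0, sum(diag(theta[[k]])))
        Lk <- tryCatch(t(chol(theta[[k]] + diag(jit, t))),
                       error = function(e) NULL)
        if (is.null(Lk)) { ok_chol <- FALSE; break }
        Ls[[k]] <- Lk
        Jk <- matrix(0, npar1, npar1)
        for (col in seq_len(npar1)) {
          a <- (lower_idx[col] - 1L) %% t + 1L
          b <- (lower_idx[col] - 1L) %/% t + 1L
          dTh <- matrix(0, t, t)
          dTh[a, ] <- dTh[a, ] + Lk[, b]
          dTh[, a] <- dTh[, a] + Lk[, b]
          Jk[, col] <- dTh[lower_idx]
        }
        J[(ki - 1L) * npar1 + seq_len(npar1),
          (ki - 1L) * npar1 + seq_len(npar1)] <- Jk
      }
      if (ok_chol) {
        gl <- crossprod(J, gvec)
        AIl <- crossprod(J, AI %*% J)
        AIl <- AIl + diag(1e-8 * max(diag(AIl), 1e-300), nrow(AIl))
        delta <- tryCatch(solve(AIl, gl), error = function(e) NULL)
        if (!is.null(delta)) {
          for (half in 0:6) {
            cand <- theta
            for (ki in seq_along(free)) {
              k <- free[ki]
              Lk <- Ls[[k]]
              Lk[lower_idx] <- Lk[lower_idx] +
                delta[(ki - 1L) * npar1 + seq_len(npar1)] / 2^half
              cand[[k]] <- tcrossprod(Lk)
            }
            ev_try <- tryCatch(reml_eval_(cand, env, want_P = FALSE),
                               error = function(e) NULL)
            if (!is.null(ev_try) && is.finite(ev_try$logl) &&
                ev_try$logl >= ev$logl - 1e-10) {
              th_new <- cand
              step <- "ai"
              break
            }
          }
        }
      }
    }

    if (accelerate && iter > ai_start && ai_skip == 0L && step == "em")
      ai_skip <- 3L                      # AI rejected; rest it a few rounds
    else if (ai_skip > 0L) ai_skip <- ai_skip - 1L

    # pin collapsed components at the zero boundary
    for (k in active_names) {
      if (!pinned[k] && sum(diag(th_new[[k]])) < pin_tol) {
        th_new[[k]] <- matrix(0, t, t)
        pinned[k] <- TRUE
        prev_d <- NULL
      }
    }

    d1 <- pack_(th_new) - pack_(theta)
    theta <- th_new
    ev_new <- reml_eval_(theta, env)

    # Aitken extrapolation of the linear EM tail: when two successive EM
    # directions are nearly proportional (rate rho), jump to the
    # geometric-series limit, keeping the step only if it improves.
    if (step == "em" && prev_step == "em" && !is.null(prev_d) &&
        sum(prev_d^2) > 0) {
      rho <- sum(d1 * prev_d) / sum(prev_d^2)
      alang <- sum(d1 * prev_d) /
        sqrt(sum(d1^2) * sum(prev_d^2) + 1e-300)
      if (rho > 0.3 && rho < 0.995 && alang > 0.95) {
        gain <- min(rho / (1 - rho), 50)
        cand_v <- pack_(theta) + gain * d1
        cand <- theta
        ofs <- 0L
        npar1 <- length(lower_idx)
        for (k in names(B)) {
          cand[[k]] <- psd_project_(unpack_one_(cand_v[ofs + seq_len(npar1)]))
          ofs <- ofs + npar1
        }
        cand$R <- psd_project_(cand$R, floorR)
        ev_try <- tryCatch(reml_eval_(cand, env, want_P = FALSE),
                           error = function(e) NULL)
        if (!is.null(ev_try) && is.finite(ev_try$logl) &&
            ev_try$logl > ev_new$logl) {
          theta <- cand
          ev_new <- reml_eval_(theta, env)
          step <- "aitken"
          d1 <- NULL
        }
      }
    }
    prev_d <- d1
    prev_step <- steps[iter] <- step
    par_rel <- max(abs(pack_(theta) - old_pack) /
                     pmax(abs(pack_(theta)), 1e-3 * scale0))
    dl <- ev_new$logl - logl_path[iter]
    ev <- ev_new
    if (abs(dl) < tol_logl && par_rel < tol_par) {
      iter <- iter + 1L
      logl_path[iter] <- ev$logl
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }

  zero <- matrix(0, t, t)
  new_vc_(theta$G %||% zero, theta$Mat %||% zero, theta$Pat %||% zero,
          theta$R,
          beta = ev$beta, logL = ev$logl, logL_path = logl_path,
          n_iter = iter, converged = converged, steps = steps,
          trait_names = colnames(Y))
}

new_vc_ <- function(G, Mat, Pat, R, beta, logL, logL_path, n_iter,
                    converged, steps, trait_names = NULL) {
  nm <- trait_names %||% paste0("PC", seq_len(nrow(R)))
  lab <- function(m) {
    dimnames(m) <- list(nm, nm)
    m
  }
  structure(list(G = lab(G), Mat = lab(Mat), Pat = lab(Pat), R = lab(R),
                 P = lab(G + Mat + Pat + R), beta = beta, logL = logL,
                 logL_path = logL_path, n_iter = n_iter,
                 converged = converged, steps = steps),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("Animal-model variance components (%d traits): logL = %.6g, %d iterations, %s\n",
              nrow(x$R), x$logL, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  pr <- variance_proportions(x)
  cat("Trace proportions of P: ",
      paste(sprintf("%s = %.4f", names(pr), pr), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
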