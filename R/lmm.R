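#' Residual covariance structures for repeated measures
#'
#' Parametric families for the within-subject residual covariance across
#' the `T` repeated levels, each with a smooth unconstrained
#' parameterization for the optimizer:
#' \describe{
#'   \item{iid}{independent, 1 parameter (log variance).}
#'   \item{cs}{compound symmetry, 2 (log variance, Fisher-z correlation;
#'     proposals below the `-1/(T-1)` positive-definite bound are
#'     rejected).}
#'   \item{ar1}{first-order autoregressive, 2.}
#'   \item{arh1}{heterogeneous AR(1): per-level variances plus one
#'     correlation, `T + 1`.}
#'   \item{toep}{Toeplitz: one variance plus a free correlation per lag,
#'     `T` (tanh-transformed lags with positive-definiteness rejection).}
#'   \item{un}{unstructured, `T(T+1)/2` via the log-Cholesky factor.}
#'   \item{sppow}{spatial power: correlation `rho^|t_i - t_j|` over
#'     possibly unequally spaced times, 2 (`rho` in (0,1)); equals ar1 on
#'     equally spaced integer times.}
#' }
#'
#' @param T_ number of repeated levels.
#' @return data frame of structure names and parameter counts.
#' @export
cov_structures <- function(T_ = 7) {
  data.frame(
    structure = c("iid", "cs", "ar1", "arh1", "toep", "un", "sppow"),
    n_params = c(1, 2, 2, T_ + 1, T_, T_ * (T_ + 1) / 2, 2))
}

## ---- structure definitions ------------------------------------------------

## Each structure: list(npar, names, make(theta) -> T x T matrix or NULL
## (rejected proposal), start(S) -> theta from an empirical covariance,
## fix_map(name, value) -> c(index, theta-scale value))
make_structure <- function(kind, T_, times = NULL) {
  kind <- match.arg(tolower(kind),
                    c("iid", "cs", "ar1", "arh1", "toep", "un", "sppow"))
  if (is.null(times)) times <- seq_len(T_)
  clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  lag1 <- function(S) {
    R <- suppressWarnings(stats::cov2cor(S))
    r <- R[cbind(seq_len(T_ - 1), seq_len(T_ - 1) + 1)]
    mean(r[is.finite(r)], na.rm = TRUE)
  }
  switch(kind,
    iid = list(kind = kind, npar = 1L, names = "log_sigma2",
      make = function(th) exp(th[1]) * diag(T_),
      start = function(S) log(mean(diag(S))),
      fix_map = function(nm, v) switch(nm, sigma2 = c(1, log(v)), NULL)),
    cs = list(kind = kind, npar = 2L, names = c("log_sigma2", "z_rho"),
      make = function(th) {
        rho <- tanh(th[2])
        if (rho <= -1 / (T_ - 1) + 1e-12) return(NULL)
        exp(th[1]) * ((1 - rho) * diag(T_) + rho)
      },
      start = function(S) c(log(mean(diag(S))),
                            atanh(clamp(mean(stats::cov2cor(S)[lower.tri(S)],
                                             na.rm = TRUE),
                                        -0.9 / (T_ - 1), 0.95))),
      fix_map = function(nm, v) switch(nm, sigma2 = c(1, log(v)),
                                       rho = c(2, atanh(v)), NULL)),
    ar1 = list(kind = kind, npar = 2L, names = c("log_sigma2", "z_rho"),
      make = function(th) {
        rho <- tanh(th[2])
        exp(th[1]) * rho^abs(outer(seq_len(T_), seq_len(T_), "-"))
      },
      start = function(S) c(log(mean(diag(S))),
                            atanh(clamp(lag1(S), -0.95, 0.95))),
      fix_map = function(nm, v) switch(nm, sigma2 = c(1, log(v)),
                                       rho = c(2, atanh(v)), NULL)),
    arh1 = list(kind = kind, npar = T_ + 1L,
      names = c(paste0("log_sigma2_", seq_len(T_)), "z_rho"),
      make = function(th) {
        s <- exp(th[seq_len(T_)] / 2)
        rho <- tanh(th[T_ + 1])
        outer(s, s) * rho^abs(outer(seq_len(T_), seq_len(T_), "-"))
      },
      start = function(S) c(log(pmax(diag(S), 1e-8)),
                            atanh(clamp(lag1(S), -0.95, 0.95))),
      fix_map = function(nm, v) switch(nm, rho = c(T_ + 1L, atanh(v)), NULL)),
    toep = list(kind = kind, npar = T_,
      names = c("log_sigma2", paste0("z_rho_lag", seq_len(T_ - 1))),
      make = function(th) {
        r <- c(1, tanh(th[-1]))
        M <- exp(th[1]) *
          matrix(r[abs(outer(seq_len(T_), seq_len(T_), "-")) + 1], T_, T_)
        ev <- tryCatch(chol(M), error = function(e) NULL)
        if (is.null(ev)) NULL else M
      },
      start = function(S) {
        R <- stats::cov2cor(S)
        rl <- vapply(seq_len(T_ - 1), function(k) {
          v <- R[cbind(seq_len(T_ - k), seq_len(T_ - k) + k)]
          mean(v[is.finite(v)], na.rm = TRUE)
        }, numeric(1))
        ## shrink towards zero so the start is safely positive definite
        c(log(mean(diag(S))), atanh(clamp(0.7 * rl, -0.9, 0.9)))
      },
      fix_map = function(nm, v) switch(nm, sigma2 = c(1, log(v)), NULL)),
    un = list(kind = kind, npar = as.integer(T_ * (T_ + 1) / 2),
      names = paste0("lchol_", seq_len(T_ * (T_ + 1) / 2)),
      make = function(th) {
        L <- matrix(0, T_, T_)
        L[lower.tri(L, diag = TRUE)] <- th
        diag(L) <- exp(diag(L))
        tcrossprod(L)
      },
      start = function(S) {
        M <- S
        k <- 0
        repeat {
          L <- tryCatch(t(chol(M)), error = function(e) NULL)
          if (!is.null(L)) break
          k <- k + 1
          M <- M + 10^(k - 8) * mean(diag(S)) * diag(T_)
          if (k > 20) { L <- diag(sqrt(pmax(diag(S), 1e-8))); break }
        }
        diag(L) <- log(diag(L))
        L[lower.tri(L, diag = TRUE)]
      },
      fix_map = function(nm, v) NULL),
    sppow = list(kind = kind, npar = 2L, names = c("log_sigma2", "q_rho"),
      make = function(th) {
        rho <- stats::plogis(th[2])
        exp(th[1]) * rho^abs(outer(times, times, "-"))
      },
      start = function(S) c(log(mean(diag(S))),
                            stats::qlogis(clamp(lag1(S), 0.02, 0.95))),
      fix_map = function(nm, v) switch(nm, sigma2 = c(1, log(v)),
                                       rho = c(2, stats::qlogis(v)), NULL))
  )
}

#' Optimizer control for [hslmm()]
#'
#' @param n_starts number of optimizer starts (1 data-driven start plus
#'   `n_starts - 1` jittered restarts).
#' @param jitter SD of the restart jitter on the transformed parameters.
#' @param reltol relative convergence tolerance of the quasi-Newton search.
#' @param maxit maximum iterations per start.
#' @param seed seed for the restart jitter (restarts are deterministic).
#' @export
hslmm_control <- function(n_starts = 3, jitter = 0.3, reltol = 1e-10,
                          maxit = 500, seed = 1L) {
  list(n_starts = n_starts, jitter = jitter, reltol = reltol,
       maxit = maxit, seed = as.integer(seed))
}

#' Repeated-measures linear mixed model by REML
#'
#' Fits `fixed` with optional random intercepts and a structured residual
#' covariance over the repeated levels of each subject. Fixed effects are
#' profiled out by generalized least squares inside the restricted
#' likelihood, which is maximized by a quasi-Newton search over smooth
#' unconstrained transforms of the covariance parameters (log variances,
#' Fisher-z correlations, log-Cholesky for the unstructured family);
#' proposals outside the positive-definite region are rejected. Subjects
#' may have missing repeated levels (the structure is subset to the
#' observed levels); subjects with a single observation are allowed.
#'
#' Fixed-effect tests are marginal Wald F tests with residual degrees of
#' freedom `n_obs - rank(X)`.
#'
#' @param fixed model formula for the fixed effects.
#' @param data data frame.
#' @param subject name of the subject (repeated blocks) column.
#' @param order name of the column giving the repeated level (factor or
#'   integer); its sorted unique values define the `T` levels.
#' @param structure residual covariance structure, see [cov_structures()].
#' @param random character vector of grouping-factor column names that get
#'   independent random intercepts (e.g. litter; use the subject column
#'   itself for a random animal effect).
#' @param times numeric times attached to the `T` ordered levels (used by
#'   `sppow`; defaults to `1:T`).
#' @param fix named list pinning covariance parameters (e.g.
#'   `list(rho = 0)`).
#' @param control a [hslmm_control()] list.
#' @return object of class `hslmm`; see [summary.hslmm()]. Key fields:
#'   `beta`, `vcov`, `Sigma` (fitted T x T residual covariance),
#'   `random_var`, `reml_loglik`, `aic`, `aicc`, `bic`, `anova`,
#'   `converged`.
#' @export
hslmm <- function(fixed, data, subject, order, structure = "un",
                  random = NULL, times = NULL, fix = NULL,
                  control = hslmm_control()) {
  cl <- match.call()
  vars <- unique(c(all.vars(fixed), subject, order, random))
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("columns not in data: ", paste(miss, collapse = ", "))
  dat <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  for (v in names(dat)) if (is.character(dat[[v]])) dat[[v]] <- factor(dat[[v]])

  mf <- stats::model.frame(fixed, dat)
  trms <- attr(mf, "terms")
  y <- stats::model.response(mf)
  X <- drop_aliased(stats::model.matrix(trms, mf))
  N <- nrow(X); rank_X <- ncol(X)

  subj <- factor(dat[[subject]])
  olev <- sort(unique(dat[[order]]))
  o <- match(dat[[order]], olev)
  T_ <- length(olev)
  if (anyDuplicated(paste(subj, o)))
    stop("duplicate subject x order rows")
  st <- make_structure(structure, T_, times)

  rnd <- lapply(random, function(r) factor(dat[[r]]))
  names(rnd) <- random
  n_rand <- length(rnd)

  ## partition into independent blocks: connected components of subjects
  ## linked through shared random-factor levels
  comp <- as.integer(subj)
  if (n_rand) {
    repeat {
      changed <- FALSE
      for (f in rnd) {
        mn <- stats::ave(comp, f, FUN = min)
        if (any(mn != comp)) { comp <- stats::ave(mn, subj, FUN = min); changed <- TRUE }
      }
      if (!changed) break
    }
  }
  ## precompute, per block, vectorized assembly maps: positions of the
  ## within-subject Sigma entries in V, and of each random factor's
  ## variance additions, so likelihood evaluations do no inner loops
  groups <- split(seq_len(N), comp)
  g_info <- lapply(groups, function(ix) {
    ng <- length(ix)
    oix <- o[ix]
    posS <- integer(0); sigI <- integer(0)
    for (r in split(seq_along(ix), droplevels(subj[ix]))) {
      posS <- c(posS, as.vector(outer(r, (r - 1L) * ng, "+")))
      oo <- oix[r]
      sigI <- c(sigI, as.vector(outer(oo, (oo - 1L) * T_, "+")))
    }
    posR <- lapply(rnd, function(f) {
      out <- integer(0)
      for (r in split(seq_along(ix), droplevels(f[ix])))
        out <- c(out, as.vector(outer(r, (r - 1L) * ng, "+")))
      out
    })
    list(ng = ng, X = X[ix, , drop = FALSE], y = y[ix],
         posS = posS, sigI = sigI, posR = posR)
  })
  build_V <- function(g, Sg, s2r, v_floor) {
    Vv <- numeric(g$ng * g$ng)
    Vv[g$posS] <- Sg[g$sigI]
    if (n_rand) for (k in seq_len(n_rand))
      Vv[g$posR[[k]]] <- Vv[g$posR[[k]]] + s2r[k]
    V <- matrix(Vv, g$ng, g$ng)
    diag(V) <- diag(V) + v_floor
    V
  }

  ## fixed (pinned) covariance parameters
  fix_idx <- integer(0); fix_val <- numeric(0)
  for (nm in names(fix)) {
    mp <- st$fix_map(nm, fix[[nm]])
    if (is.null(mp)) stop("cannot fix parameter '", nm, "' for structure ",
                          st$kind)
    fix_idx <- c(fix_idx, mp[1]); fix_val <- c(fix_val, mp[2])
  }
  free_struct <- setdiff(seq_len(st$npar), fix_idx)
  n_free <- length(free_struct) + n_rand

  full_theta <- function(par) {
    th <- numeric(st$npar)
    th[free_struct] <- par[seq_along(free_struct)]
    th[fix_idx] <- fix_val
    th
  }

  ## balanced fast path: with no random terms and every subject complete,
  ## X'V^-1 X collapses to sums of per-level cross-products weighted by
  ## the inverse structure matrix, with no per-subject loop
  balanced <- n_rand == 0 &&
    all(tabulate(as.integer(subj), nlevels(subj)) == T_)
  if (balanced) {
    sidx <- lapply(seq_len(T_), function(t) {
      i <- which(o == t)
      i[order(as.integer(subj[i]))]
    })
    Xt <- lapply(sidx, function(i) X[i, , drop = FALSE])
    yt <- lapply(sidx, function(i) y[i])
    n_subj_b <- nlevels(subj)
    Cxx <- array(0, c(rank_X, rank_X, T_, T_))
    Cxy <- array(0, c(rank_X, T_, T_))
    Cyy <- matrix(0, T_, T_)
    for (t in seq_len(T_)) for (s in seq_len(T_)) {
      Cxx[, , t, s] <- crossprod(Xt[[t]], Xt[[s]])
      Cxy[, t, s] <- crossprod(Xt[[t]], yt[[s]])[, 1]
      Cyy[t, s] <- sum(yt[[t]] * yt[[s]])
    }
  }

  ## variance floor: keeps REML bounded and vcov computable when a
  ## variance estimate hits the boundary (reported as 0 downstream)
  neg2reml_balanced <- function(par) {
    Sg <- st$make(full_theta(par))
    if (is.null(Sg) || !all(is.finite(Sg))) return(1e10)
    diag(Sg) <- diag(Sg) + v_floor
    U <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(U)) return(1e10)
    Si <- chol2inv(U)
    XtViX <- matrix(0, rank_X, rank_X)
    XtViy <- numeric(rank_X); ytViy <- 0
    for (t in seq_len(T_)) for (s in seq_len(T_)) {
      XtViX <- XtViX + Si[t, s] * Cxx[, , t, s]
      XtViy <- XtViy + Si[t, s] * Cxy[, t, s]
      ytViy <- ytViy + Si[t, s] * Cyy[t, s]
    }
    Uc <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(Uc)) return(1e10)
    beta <- backsolve(Uc, backsolve(Uc, XtViy, transpose = TRUE))
    val <- n_subj_b * 2 * sum(log(diag(U))) + 2 * sum(log(diag(Uc))) +
      (ytViy - sum(beta * XtViy)) + (N - rank_X) * log(2 * pi)
    if (!is.finite(val)) 1e10 else val
  }

  neg2reml <- function(par) {
    if (balanced) return(neg2reml_balanced(par))
    Sg <- st$make(full_theta(par))
    if (is.null(Sg) || !all(is.finite(Sg))) return(1e10)
    s2r <- exp(par[length(free_struct) + seq_len(n_rand)])
    logdet <- 0; XtViX <- matrix(0, rank_X, rank_X)
    XtViy <- numeric(rank_X); ytViy <- 0
    for (g in g_info) {
      U <- tryCatch(chol(build_V(g, Sg, s2r, v_floor)),
                    error = function(e) NULL)
      if (is.null(U)) return(1e10)
      A <- backsolve(U, g$X, transpose = TRUE)
      b <- backsolve(U, g$y, transpose = TRUE)
      logdet <- logdet + 2 * sum(log(diag(U)))
      XtViX <- XtViX + crossprod(A)
      XtViy <- XtViy + crossprod(A, b)[, 1]
      ytViy <- ytViy + sum(b^2)
    }
    Uc <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(Uc)) return(1e10)
    beta <- backsolve(Uc, backsolve(Uc, XtViy, transpose = TRUE))
    ld2 <- 2 * sum(log(diag(Uc)))
    val <- logdet + ld2 + (ytViy - sum(beta * XtViy)) +
      (N - rank_X) * log(2 * pi)
    if (!is.finite(val)) 1e10 else val
  }

  ## starting values from the OLS residual empirical covariance
  r_ols <- stats::lm.fit(X, y)$residuals
  S_emp <- matrix(NA_real_, T_, T_)
  for (a in seq_len(T_)) for (b in a:T_) {
    sa <- subj[o == a]; sb <- subj[o == b]
    common <- intersect(sa, sb)
    if (length(common) >= 2) {
      ra <- r_ols[o == a][match(common, sa)]
      rb <- r_ols[o == b][match(common, sb)]
      S_emp[a, b] <- S_emp[b, a] <- mean(ra * rb)
    }
  }
  vbar <- mean(diag(S_emp), na.rm = TRUE)
  if (!is.finite(vbar) || vbar <= 0) vbar <- stats::var(y) %||% 1
  if (!is.finite(vbar) || vbar <= 0) vbar <- 1
  scale0 <- max(vbar, stats::var(y), 1e-12)
  ## floor on the data scale: a perfectly fitting model lands here
  v_floor <- 1e-10 * scale0
  vbar <- max(vbar, 10 * v_floor)
  S_emp[is.na(S_emp)] <- 0
  diag(S_emp)[diag(S_emp) < 10 * v_floor] <- vbar
  shrink <- if (n_rand) 0.8 else 1
  start_full <- st$start(S_emp * shrink)
  start0 <- c(start_full[free_struct],
              rep(log(0.15 * vbar), n_rand))

  ## a correlation-free fallback start, always positive definite
  safe0 <- c(st$start(diag(diag(S_emp), T_) * shrink)[free_struct],
             rep(log(0.15 * vbar + 1e-8), n_rand))

  rs <- local_seed(control$seed)
  on.exit(rs())
  best <- NULL
  last_err <- NULL
  for (s in seq_len(max(1, control$n_starts))) {
    par0 <- if (s == 1) start0 else
      start0 + stats::rnorm(length(start0), 0, control$jitter)
    k <- 0
    while (neg2reml(par0) >= 1e9 && k < 8) {
      par0 <- 0.5 * par0 + 0.5 * safe0
      k <- k + 1
    }
    op <- tryCatch(
      stats::optim(par0, neg2reml, method = "BFGS",
                   control = list(maxit = control$maxit,
                                  reltol = control$reltol)),
      error = function(e) { last_err <<- conditionMessage(e); NULL })
    if (is.null(op) || !is.finite(op$value) || op$value >= 1e9) next
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best))
    stop("hslmm: REML optimization failed for structure ", st$kind,
         if (!is.null(last_err)) paste0(" (", last_err, ")"))
  ## polish with Nelder-Mead from the best point (helps flat ridges)
  if (length(best$par) >= 2) {
    pol <- tryCatch(stats::optim(best$par, neg2reml, method = "Nelder-Mead",
                                 control = list(maxit = 2000,
                                                reltol = control$reltol)),
                    error = function(e) NULL)
    if (!is.null(pol) && is.finite(pol$value) && pol$value < best$value)
      best <- pol
  }

  ## assemble the fit at the optimum
  par <- best$par
  Sg <- st$make(full_theta(par))
  s2r <- exp(par[length(free_struct) + seq_len(n_rand)])
  logdet <- 0; XtViX <- matrix(0, rank_X, rank_X)
  XtViy <- numeric(rank_X); ytViy <- 0
  for (g in g_info) {
    U <- chol(build_V(g, Sg, s2r, v_floor))
    A <- backsolve(U, g$X, transpose = TRUE)
    b <- backsolve(U, g$y, transpose = TRUE)
    logdet <- logdet + 2 * sum(log(diag(U)))
    XtViX <- XtViX + crossprod(A)
    XtViy <- XtViy + crossprod(A, b)[, 1]
    ytViy <- ytViy + sum(b^2)
  }
  vcov_beta <- chol2inv(chol(XtViX))
  beta <- (vcov_beta %*% XtViy)[, 1]
  names(beta) <- colnames(X)
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  m2ll <- best$value
  q <- n_free
  aic <- m2ll + 2 * q
  nstar <- N - rank_X
  aicc <- if (nstar - q - 1 > 0) aic + 2 * q * (q + 1) / (nstar - q - 1)
          else Inf
  bic <- m2ll + q * log(nlevels(subj))

  ## marginal Wald F per fixed term
  asg <- attr(X, "assign")
  labels <- attr(trms, "term.labels")
  anova_tab <- do.call(rbind, lapply(seq_along(labels), function(t_i) {
    cols <- which(asg == t_i)
    if (!length(cols)) return(NULL)
    b <- beta[cols]
    W <- tryCatch(
      drop(crossprod(b, solve(vcov_beta[cols, cols, drop = FALSE], b))),
      error = function(e) NA_real_)
    Fv <- W / length(cols)
    data.frame(term = labels[t_i], df1 = length(cols), df2 = N - rank_X,
               F = Fv,
               p = stats::pf(Fv, length(cols), N - rank_X,
                             lower.tail = FALSE))
  }))
  rownames(anova_tab) <- NULL

  rv <- stats::setNames(as.numeric(s2r), random)
  small <- rv < 1e-6 * scale0
  if (any(small))
    warning("random-effect variance(s) on the boundary, reported as 0: ",
            paste(random[small], collapse = ", "))
  rv_rep <- ifelse(small, 0, rv)

  structure(list(
    call = cl, formula = fixed, terms = trms, structure = st$kind,
    theta = stats::setNames(full_theta(par), st$names),
    Sigma = `dimnames<-`(Sg, list(olev, olev)),
    random_var = rv_rep, beta = beta, vcov = vcov_beta,
    reml_loglik = -m2ll / 2, m2ll = m2ll, q = q,
    aic = aic, aicc = aicc, bic = bic,
    n_obs = N, n_subjects = nlevels(subj), rank_X = rank_X,
    anova = anova_tab, converged = best$convergence == 0,
    subject = subject, order = order, order_levels = olev, times = times,
    random = random, fix = fix, xlevels = stats::.getXlevels(trms, mf),
    contrasts = attr(X, "contrasts"), x_cols = colnames(X),
    model_data = dat, fitted = drop(X %*% beta),
    residuals = y - drop(X %*% beta), control = control
  ), class = "hslmm")
}

#' @export
print.hslmm <- function(x, ...) {
  cat("Repeated-measures LMM (REML), residual structure:",
      toupper(x$structure), "\n")
  cat(" ", deparse(x$formula), "\n")
  cat("  subjects:", x$n_subjects, " obs:", x$n_obs,
      " covariance params:", x$q, "\n")
  if (length(x$random_var))
    cat("  random intercepts:",
        paste(sprintf("%s (var %.4g)", names(x$random_var), x$random_var),
              collapse = ", "), "\n")
  cat(sprintf("  REML logLik %.3f | AIC %.2f AICc %.2f BIC %.2f | %s\n",
              x$reml_loglik, x$aic, x$aicc, x$bic,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.hslmm <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tab <- data.frame(estimate = object$beta, se = se,
                    t = object$beta / se,
                    p = 2 * stats::pt(abs(object$beta / se),
                                      object$n_obs - object$rank_X,
                                      lower.tail = FALSE))
  out <- list(fit = object, coefficients = tab, anova = object$anova)
  class(out) <- "summary.hslmm"
  out
}

#' @export
print.summary.hslmm <- function(x, ...) {
  print(x$fit)
  cat("\nFixed effects:\n")
  print(round(x$coefficients, 4))
  cat("\nMarginal Wald F tests:\n")
  print(x$anova, row.names = FALSE)
  cat("\nFitted residual covariance:\n")
  print(round(x$fit$Sigma, 4))
  invisible(x)
}

#' @export
coef.hslmm <- function(object, ...) object$beta

#' @export
vcov.hslmm <- function(object, ...) object$vcov

#' @export
logLik.hslmm <- function(object, ...) {
  structure(object$reml_loglik, df = object$q + object$rank_X,
            nobs = object$n_obs, class = "logLik")
}

#' @export
residuals.hslmm <- function(object, ...) object$residuals

#' @export
fitted.hslmm <- function(object, ...) object$fitted

#' @export
anova.hslmm <- function(object, ...) object$anova
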