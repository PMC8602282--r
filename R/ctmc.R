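# Continuous-time Markov multi-state modelling of enterotype series.
#
# Intensities q_rs(z) = q_rs0 exp(beta_rs . z); observations are snapshots
# of the state at the collection times, so each interval contributes
# P(t2 - t1; z) = expm(Q(z) (t2 - t1)) evaluated at the covariates in force
# at the interval start. The likelihood kernel lives in C++ (matrix
# exponential per unique (dt, z) configuration).

# Assemble interval data from per-sample series.
.ctmcIntervals <- function(state, participant, day, covariates) {
  o <- order(participant, day)
  state <- state[o]; participant <- participant[o]; day <- day[o]
  if (!is.null(covariates))
    covariates <- covariates[o, , drop = FALSE]
  from <- integer(0); to <- integer(0); dt <- numeric(0)
  Z <- NULL
  for (p in unique(participant)) {
    i <- which(participant == p)
    if (length(i) < 2) next
    from <- c(from, state[i[-length(i)]])
    to <- c(to, state[i[-1]])
    dt <- c(dt, diff(day[i]))
    if (!is.null(covariates))
      Z <- rbind(Z, covariates[i[-length(i)], , drop = FALSE])
  }
  if (is.null(covariates)) Z <- matrix(0, length(from), 0)
  ok <- stats::complete.cases(Z) & !is.na(from) & !is.na(to) & dt > 0
  list(from = from[ok], to = to[ok], dt = dt[ok],
       Z = Z[ok, , drop = FALSE])
}

# Group intervals by identical (dt, covariates) so the C++ kernel computes
# each matrix exponential once; done once per fit, not per likelihood call.
.ctmcGroups <- function(iv) {
  key <- cbind(iv$dt, iv$Z)
  kk <- apply(key, 1, paste, collapse = "\r")
  uq <- key[!duplicated(kk), , drop = FALSE]
  grp <- match(kk, kk[!duplicated(kk)]) - 1L
  list(uq_dt = uq[, 1], uq_z = uq[, -1, drop = FALSE],
       group = as.integer(grp),
       from = as.integer(iv$from - 1L), to = as.integer(iv$to - 1L))
}

.ctmcNll <- function(par, gr, n_states, trans_idx) {
  cpp_ctmc_nll(par, n_states,
               as.integer(trans_idx[, 1] - 1L),
               as.integer(trans_idx[, 2] - 1L),
               gr$uq_dt, gr$uq_z, gr$group, gr$from, gr$to)
}

#' Fit a continuous-time Markov model with covariates on transition
#' intensities
#'
#' Maximum likelihood over products of matrix-exponential transition
#' probabilities between successive observations of each participant
#' (snapshot observation scheme; gaps between samples enter as elapsed
#' days). Each allowed transition r -> s has intensity
#' \code{q_rs0 exp(beta_rs . z)}; all off-diagonal transitions are allowed
#' by default. Optimisation is BFGS on the unconstrained (log q, beta)
#' parameterisation with numeric gradients; standard errors come from the
#' inverted numeric Hessian at the optimum, and a covariate's risk ratio
#' per unit increase is exp(beta) with a Wald 95\% CI (an effect is
#' conventionally called significant when that CI excludes 1).
#'
#' @param state integer state per sample (1..n_states) or factor.
#' @param participant participant id per sample.
#' @param day observation day per sample.
#' @param covariates optional numeric matrix/data.frame of per-sample
#'   covariate values (value in force from that sample until the next); no
#'   scaling is applied, so risk ratios are per unit of the supplied
#'   covariate.
#' @param states optional state labels.
#' @param allowed optional 2-column matrix of allowed (from, to) state
#'   indices.
#' @param max_iter BFGS iteration cap.
#' @return A \linkS4class{CTMCModel}; non-convergence warns and returns the
#'   best point found.
#' @export
ctmcFit <- function(state, participant, day, covariates = NULL,
                    states = NULL, allowed = NULL, max_iter = 400L) {
  if (is.factor(state) || is.character(state)) {
    if (is.null(states)) states <- sort(unique(as.character(state)))
    state <- match(as.character(state), states)
  } else if (is.null(states)) {
    states <- as.character(seq_len(max(state)))
  }
  K <- length(states)
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  cov_names <- colnames(covariates)
  if (!is.null(covariates) && is.null(cov_names))
    cov_names <- paste0("z", seq_len(ncol(covariates)))
  iv <- .ctmcIntervals(state, participant, day, covariates)
  if (!length(iv$from)) stop("no usable observation intervals")
  if (length(unique(c(iv$from, iv$to))) < 2)
    stop("degenerate state series: a single state is ever observed")
  if (is.null(allowed)) {
    allowed <- cbind(rep(seq_len(K), each = K), rep(seq_len(K), times = K))
    allowed <- allowed[allowed[, 1] != allowed[, 2], , drop = FALSE]
  }
  ntr <- nrow(allowed)
  ncov <- ncol(iv$Z)

  # crude-rate initialisation: observed r->s counts over time at risk in r
  time_at <- tapply(iv$dt, iv$from, sum)
  q0 <- vapply(seq_len(ntr), function(t) {
    cnt <- sum(iv$from == allowed[t, 1] & iv$to == allowed[t, 2])
    tt <- time_at[as.character(allowed[t, 1])]
    if (is.na(tt) || tt <= 0) tt <- sum(iv$dt)
    max(cnt, 0.5) / tt
  }, numeric(1))
  par0 <- c(log(q0), rep(0, ntr * ncov))

  gr <- .ctmcGroups(iv)
  fn <- function(p) .ctmcNll(p, gr, K, allowed)
  opt <- stats::optim(par0, fn, method = "BFGS", hessian = TRUE,
                      control = list(maxit = max_iter, reltol = 1e-10))
  if (opt$convergence != 0)
    warning("CTMC optimisation did not fully converge (code ",
            opt$convergence, ")")
  se <- rep(NA_real_, length(opt$par))
  h <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  if (!is.null(h)) {
    dg <- diag(h)
    se[dg > 0] <- sqrt(dg[dg > 0])
  }

  Q <- matrix(0, K, K, dimnames = list(states, states))
  for (t in seq_len(ntr))
    Q[allowed[t, 1], allowed[t, 2]] <- exp(opt$par[t])
  diag(Q) <- -rowSums(Q)
  beta <- matrix(opt$par[-seq_len(ntr)], ntr, ncov,
                 dimnames = list(paste(states[allowed[, 1]],
                                       states[allowed[, 2]], sep = "->"),
                                 cov_names))
  new("CTMCModel", states = states, Q = Q, beta = beta,
      par = opt$par, se = se, logLik = -opt$value,
      covariates = if (ncov) cov_names else character(),
      trans_idx = allowed, convergence = as.integer(opt$convergence),
      n_obs = length(iv$from))
}

#' Risk ratios of a fitted CTMC
#'
#' exp(beta) per unit covariate increase with Wald 95\% confidence
#' intervals; \code{significant} marks intervals excluding 1.
#'
#' @param model a \linkS4class{CTMCModel}.
#' @param level confidence level (default 0.95).
#' @return data.frame: from, to, covariate, rr, lo, hi, significant.
#' @export
riskRatios <- function(model, level = 0.95) {
  ntr <- nrow(model@trans_idx)
  ncov <- length(model@covariates)
  if (!ncov) return(data.frame())
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- list(); k <- 0L
  for (c in seq_len(ncov)) for (t in seq_len(ntr)) {
    b <- model@par[ntr + (c - 1) * ntr + t]
    s <- model@se[ntr + (c - 1) * ntr + t]
    k <- k + 1L
    out[[k]] <- data.frame(
      from = model@states[model@trans_idx[t, 1]],
      to = model@states[model@trans_idx[t, 2]],
      covariate = model@covariates[c],
      rr = exp(b), lo = exp(b - zq * s), hi = exp(b + zq * s),
      significant = is.finite(s) && (exp(b - zq * s) > 1 ||
                                       exp(b + zq * s) < 1))
  }
  do.call(rbind, out)
}

#' Transition probability matrix of a fitted CTMC
#'
#' P(t; z) = expm(Q(z) t); rows sum to one.
#'
#' @param model a \linkS4class{CTMCModel}.
#' @param t elapsed time (days).
#' @param z covariate vector (default all zero, i.e. baseline intensities).
#' @return K x K matrix of transition probabilities.
#' @export
ctmcTransitionProbs <- function(model, t, z = NULL) {
  K <- length(model@states)
  ntr <- nrow(model@trans_idx)
  ncov <- length(model@covariates)
  if (is.null(z)) z <- rep(0, ncov)
  Q <- matrix(0, K, K, dimnames = list(model@states, model@states))
  for (tr in seq_len(ntr)) {
    lq <- model@par[tr]
    if (ncov)
      for (c in seq_len(ncov)) lq <- lq + model@par[ntr + (c - 1) * ntr + tr] * z[c]
    Q[model@trans_idx[tr, 1], model@trans_idx[tr, 2]] <- exp(lq)
  }
  diag(Q) <- -rowSums(Q)
  cpp_expm(Q * t)
}

#' Likelihood-ratio test between nested CTMC models
#'
#' 2 * (logL_full - logL_null) against chi-square with df equal to the
#' parameter-count difference. The models must be fitted on the same
#' intervals (checked via observation counts) and properly nested.
#'
#' @param full,null fitted \linkS4class{CTMCModel}s.
#' @return data.frame with \code{statistic}, \code{df}, \code{p}.
#' @export
ctmcLRTest <- function(full, null) {
  if (full@n_obs != null@n_obs)
    stop("models were fitted on different data")
  df <- length(full@par) - length(null@par)
  if (df < 0) stop("models are not nested (full has fewer parameters)")
  stat <- max(0, 2 * (full@logLik - null@logLik))
  data.frame(statistic = stat, df = df,
             p = if (df == 0) 1 else
               stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Simulate snapshot observations of a CTMC with covariates
#'
#' Gillespie simulation of the continuous-time chain per series, observed
#' at integer days; one constant covariate vector per series (drawn
#' standard normal when \code{beta} is supplied and \code{z} is not).
#'
#' @param n_series number of independent series.
#' @param n_obs observations per series (days 0..n_obs-1).
#' @param Q baseline intensity matrix (rows sum to zero).
#' @param beta optional n_trans x n_cov matrix of log risk ratios, rows
#'   ordered as all off-diagonal (from, to) pairs by row.
#' @param z optional n_series x n_cov covariate matrix.
#' @param seed integer seed.
#' @return data.frame with \code{id}, \code{day}, \code{state} and
#'   covariate columns.
#' @export
simulateCTMC <- function(n_series, n_obs, Q, beta = NULL, z = NULL,
                         seed = NULL) {
  K <- nrow(Q)
  allowed <- cbind(rep(seq_len(K), each = K), rep(seq_len(K), times = K))
  allowed <- allowed[allowed[, 1] != allowed[, 2], , drop = FALSE]
  ncov <- if (is.null(beta)) 0L else ncol(beta)
  .withSeed(seed, {
    if (ncov && is.null(z))
      z <- matrix(stats::rnorm(n_series * ncov), n_series)
    out <- vector("list", n_series)
    for (s in seq_len(n_series)) {
      Qs <- Q
      if (ncov) {
        for (t in seq_len(nrow(allowed))) {
          mult <- exp(sum(beta[t, ] * z[s, ]))
          Qs[allowed[t, 1], allowed[t, 2]] <-
            Q[allowed[t, 1], allowed[t, 2]] * mult
        }
        diag(Qs) <- 0
        diag(Qs) <- -rowSums(Qs)
      }
      tmax <- n_obs - 1
      st <- sample.int(K, 1)
      times <- 0; states <- st; tt <- 0
      while (tt < tmax) {
        rate <- -Qs[st, st]
        if (rate <= 0) break
        tt <- tt + stats::rexp(1, rate)
        if (tt >= tmax) break
        st <- sample.int(K, 1, prob = pmax(Qs[st, ], 0) /
                           sum(pmax(Qs[st, ], 0)))
        times <- c(times, tt); states <- c(states, st)
      }
      obs_state <- states[findInterval(0:tmax, times)]
      df <- data.frame(id = sprintf("s%04d", s), day = 0:tmax,
                       state = obs_state)
      if (ncov) for (c in seq_len(ncov)) df[[paste0("z", c)]] <- z[s, c]
      out[[s]] <- df
    }
    do.call(rbind, out)
  })
}
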