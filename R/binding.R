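# Saturation-binding analysis: specific-binding arithmetic, one-site
# Michaelis-Menten least-squares fits, a hierarchical Bayesian model with
# group-level Kd/Bmax and day-level Bmax effects, and credible-interval-based
# classification of competitive versus mixed inhibition.

#' Specific binding from paired total and nonspecific counts
#'
#' `specific = total - nsb` at matching ligand concentrations, floored at
#' zero; rows where nonspecific exceeded total are flagged rather than
#' silently truncated.
#'
#' @param total data.frame with `ligand_conc_nM`, `counts` (condition
#'   "total"), plus any grouping columns.
#' @param nsb data.frame with the matching nonspecific counts.
#' @param by columns identifying a matched pair (default concentration plus
#'   group/day when present).
#' @return `total` with `counts` replaced by `specific` and a logical
#'   `floored` column.
#' @export
specific_binding <- function(total, nsb,
                             by = intersect(c("group", "day", "ligand_conc_nM"),
                                            names(total))) {
  if (!all(by %in% names(nsb))) stop("`by` columns missing in nsb", call. = FALSE)
  key <- function(d) do.call(paste, c(d[by], sep = "\r"))
  kt <- key(total)
  kn <- key(nsb)
  if (anyDuplicated(kn)) stop("nonspecific rows are not uniquely keyed", call. = FALSE)
  m <- match(kt, kn)
  if (anyNA(m)) stop("unpaired concentrations between total and nsb", call. = FALSE)
  raw <- total$counts - nsb$counts[m]
  out <- total
  out$specific <- pmax(0, raw)
  out$floored <- raw < 0
  out$counts <- NULL
  out
}

#' One-site saturation binding least-squares fit
#'
#' Minimizes the squared error of `B = Bmax * L / (L + Kd)` over `(Kd, Bmax)`
#' on the log-parameter scale (Nelder-Mead followed by a BFGS polish).
#' Deterministic; used both standalone and as the initialization of the
#' hierarchical sampler.
#'
#' @param conc ligand concentrations (nM), >= 4 values spanning Kd.
#' @param specific specific binding (counts).
#' @return list of class `saturation_fit` with `kd`, `bmax`, `rss`,
#'   `converged`.
#' @export
fit_saturation_mle <- function(conc, specific) {
  if (length(conc) != length(specific)) stop("length mismatch", call. = FALSE)
  if (length(unique(conc)) < 4L) stop("need >= 4 concentrations", call. = FALSE)
  if (any(conc <= 0)) stop("concentrations must be > 0", call. = FALSE)
  bmax0 <- max(specific) * 1.2 + 1e-9
  kd0 <- conc[which.min(abs(specific - max(specific) / 2))]
  rss_fn <- function(p) {
    mu <- exp(p[2]) * conc / (conc + exp(p[1]))
    sum((specific - mu)^2)
  }
  fit <- optim(c(log(kd0), log(bmax0)), rss_fn, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-15))
  polish <- optim(fit$par, rss_fn, method = "BFGS",
                  control = list(maxit = 1000, reltol = 1e-15))
  p <- if (polish$value <= fit$value) polish$par else fit$par
  structure(list(kd = exp(p[1]), bmax = exp(p[2]), rss = rss_fn(p),
                 converged = fit$convergence == 0L || polish$convergence == 0L),
            class = "saturation_fit")
}

# Log posterior machinery -----------------------------------------------------

# layout of the parameter vector: lkd[1..G], lbm[1..G], u[1..n_gd],
# ltau, lsigma
binding_logpost <- function(theta, dat) {
  G <- dat$G
  lkd <- theta[seq_len(G)]
  lbm <- theta[G + seq_len(G)]
  u <- theta[2 * G + seq_len(dat$n_gd)]
  tau <- exp(theta[2 * G + dat$n_gd + 1L])
  sigma <- exp(theta[2 * G + dat$n_gd + 2L])
  lmu <- lbm[dat$g_idx] + u[dat$gd_idx] + dat$logL -
    log(dat$L + exp(lkd)[dat$g_idx])
  resid <- dat$logy - lmu
  ll <- -length(resid) * log(sigma) - 0.5 * sum(resid^2) / sigma^2
  lp <- sum(dnorm(lkd, dat$lkd0, 1.5, log = TRUE)) +
    sum(dnorm(lbm, dat$lbm0, 1.5, log = TRUE)) +
    sum(dnorm(u, 0, tau, log = TRUE)) +
    dnorm(tau, 0, 0.5, log = TRUE) + log(tau) +       # half-normal + Jacobian
    dnorm(sigma, 0, 0.5, log = TRUE) + log(sigma)
  ll + lp
}

#' Hierarchical Bayesian saturation-binding fit
#'
#' Estimates the one-site (Michaelis-Menten) binding parameters by group and
#' day: group-level `Kd` and `Bmax` with lognormal day-level random effects on
#' `Bmax`, a half-normal prior on the day-effect scale, and proportional
#' (lognormal) observation error. Priors on `log Kd` / `log Bmax` are weakly
#' informative normals centred on the per-group least-squares estimates
#' (sd 1.5 on the log scale). Sampling is component-wise adaptive random-walk
#' Metropolis (adaptation during burn-in only); convergence is assessed by
#' the split-chain scale-reduction statistic and flagged - never silently -
#' when above `rhat_tol`.
#'
#' @param dataset data.frame with columns `group`, `day`, `ligand_conc_nM`,
#'   `specific` (positive specific counts; nonpositive rows are dropped with
#'   a message).
#' @param n_chains number of chains.
#' @param n_iter total MCMC iterations across chains.
#' @param burn_in total burn-in iterations across chains.
#' @param seed RNG seed (chain `c` uses `seed + c - 1`).
#' @param rhat_tol convergence tolerance on the split-chain statistic.
#' @param warn emit an R warning on non-convergence (the result carries the
#'   status regardless).
#' @return list of class `binding_posterior`: `groups` (data.frame of
#'   posterior mean and 95% credible interval for Kd and Bmax per group),
#'   `days` (day-level Bmax summaries), `tau` and `sigma` summaries,
#'   `diagnostics` (n_chains, n_iter, burn_in, max_rhat, converged), and the
#'   pooled post-burn-in `draws` for the group-level parameters.
#' @export
fit_binding_hier <- function(dataset, n_chains = 3L, n_iter = 50000L,
                             burn_in = 25000L, seed = 1L, rhat_tol = 1.01,
                             warn = TRUE) {
  need <- c("group", "day", "ligand_conc_nM", "specific")
  stopifnot(all(need %in% names(dataset)))
  if (burn_in >= n_iter) stop("`burn_in` must be smaller than `n_iter`", call. = FALSE)
  drop <- dataset$specific <= 0
  if (any(drop)) {
    message(sum(drop), " nonpositive specific counts dropped from the fit")
    dataset <- dataset[!drop, , drop = FALSE]
  }
  groups <- sort(unique(dataset$group))
  G <- length(groups)
  gd_key <- paste(dataset$group, dataset$day, sep = "\r")
  gd_levels <- unique(gd_key[order(match(dataset$group, groups), dataset$day)])
  per_group_days <- table(sub("\r.*", "", gd_levels))
  if (any(per_group_days < 2L)) {
    stop("each group needs >= 2 days for the hierarchical day effects", call. = FALSE)
  }
  tab <- table(gd_key, dataset$ligand_conc_nM)
  if (any(rowSums(tab > 0) < 4L)) {
    stop("each group x day needs >= 4 concentrations", call. = FALSE)
  }
  dat <- list(
    G = G,
    g_idx = match(dataset$group, groups),
    gd_idx = match(gd_key, gd_levels),
    n_gd = length(gd_levels),
    L = dataset$ligand_conc_nM,
    logL = log(dataset$ligand_conc_nM),
    logy = log(dataset$specific)
  )
  mle <- lapply(groups, function(g) {
    sub <- dataset[dataset$group == g, ]
    fit_saturation_mle(sub$ligand_conc_nM, sub$specific)
  })
  dat$lkd0 <- log(vapply(mle, `[[`, numeric(1), "kd"))
  dat$lbm0 <- log(vapply(mle, `[[`, numeric(1), "bmax"))
  n_par <- 2L * G + dat$n_gd + 2L
  iter_chain <- ceiling(n_iter / n_chains)
  burn_chain <- ceiling(burn_in / n_chains)
  keep_chain <- iter_chain - burn_chain

  run_chain <- function(chain_seed) {
    with_seed(chain_seed, {
      theta <- c(dat$lkd0 + rnorm(G, 0, 0.1), dat$lbm0 + rnorm(G, 0, 0.1),
                 rnorm(dat$n_gd, 0, 0.05), log(0.1), log(0.1))
      scales <- rep(0.2, n_par)
      lp <- binding_logpost(theta, dat)
      draws <- matrix(NA_real_, keep_chain, n_par)
      for (it in seq_len(iter_chain)) {
        for (j in seq_len(n_par)) {
          prop <- theta
          prop[j] <- prop[j] + rnorm(1, 0, scales[j])
          lp_prop <- binding_logpost(prop, dat)
          accept <- log(runif(1)) < lp_prop - lp
          if (accept) {
            theta <- prop
            lp <- lp_prop
          }
          if (it <= burn_chain) {
            gamma <- min(0.05, 1 / sqrt(it))
            scales[j] <- scales[j] * exp(gamma * ((if (accept) 1 else 0) - 0.44))
          }
        }
        if (it > burn_chain) draws[it - burn_chain, ] <- theta
      }
      draws
    })
  }
  chains <- lapply(seq_len(n_chains), function(cc) run_chain(seed + cc - 1L))

  # split-chain scale reduction on the group-level and variance parameters
  track <- c(seq_len(2L * G), 2L * G + dat$n_gd + 1L, 2L * G + dat$n_gd + 2L)
  rhats <- vapply(track, function(j) {
    halves <- unlist(lapply(chains, function(d) {
      n <- nrow(d)
      h <- floor(n / 2)
      list(d[seq_len(h), j], d[(n - h + 1L):n, j])
    }), recursive = FALSE)
    split_rhat(halves)
  }, numeric(1))
  max_rhat <- max(rhats)
  converged <- is.finite(max_rhat) && max_rhat <= rhat_tol
  if (!converged && warn) {
    warning(sprintf("chains may not have converged (max split R-hat = %.3f)",
                    max_rhat), call. = FALSE)
  }
  pooled <- do.call(rbind, chains)
  summarize <- function(x) {
    q <- quantile(x, c(0.025, 0.975), names = FALSE)
    c(mean = mean(x), lower = q[1], upper = q[2])
  }
  kd_draws <- exp(pooled[, seq_len(G), drop = FALSE])
  bm_draws <- exp(pooled[, G + seq_len(G), drop = FALSE])
  gsum <- do.call(rbind, lapply(seq_len(G), function(i) {
    ks <- summarize(kd_draws[, i])
    bs <- summarize(bm_draws[, i])
    data.frame(group = groups[i], kd_mean = ks[1], kd_lower = ks[2],
               kd_upper = ks[3], bmax_mean = bs[1], bmax_lower = bs[2],
               bmax_upper = bs[3], kd_mle = exp(dat$lkd0[i]),
               bmax_mle = exp(dat$lbm0[i]))
  }))
  rownames(gsum) <- NULL
  day_sum <- do.call(rbind, lapply(seq_len(dat$n_gd), function(i) {
    g_of_gd <- dat$g_idx[match(i, dat$gd_idx)]
    d <- exp(pooled[, G + g_of_gd] + pooled[, 2L * G + i])
    s <- summarize(d)
    parts <- strsplit(gd_levels[i], "\r", fixed = TRUE)[[1]]
    data.frame(group = parts[1], day = parts[2], bmax_mean = s[1],
               bmax_lower = s[2], bmax_upper = s[3])
  }))
  rownames(day_sum) <- NULL
  tau_draws <- exp(pooled[, 2L * G + dat$n_gd + 1L])
  sigma_draws <- exp(pooled[, 2L * G + dat$n_gd + 2L])
  structure(list(
    groups = gsum, days = day_sum,
    tau = summarize(tau_draws), sigma = summarize(sigma_draws),
    diagnostics = list(n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
                       max_rhat = max_rhat, converged = converged,
                       rhat_tol = rhat_tol),
    draws = list(kd = kd_draws, bmax = bm_draws, tau = tau_draws,
                 sigma = sigma_draws, groups = groups)
  ), class = "binding_posterior")
}

# Classical split R-hat over a list of sequences of (possibly) equal length.
split_rhat <- function(seqs) {
  n <- min(vapply(seqs, length, 1L))
  if (n < 2L) return(NA_real_)
  m <- vapply(seqs, function(s) mean(s[seq_len(n)]), numeric(1))
  v <- vapply(seqs, function(s) var(s[seq_len(n)]), numeric(1))
  W <- mean(v)
  B <- n * var(m)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Classify inhibitor interaction from posterior summaries
#'
#' Operationalizes the asymptote comparison between an inhibitor group and
#' the inhibitor-free reference: the interaction is called `competitive` when
#' the group's Bmax 95% credible interval overlaps the reference interval
#' (the asymptote difference is within experimental noise) while its Kd
#' interval is shifted wholly above the reference; `mixed` when the Bmax
#' interval lies entirely below the reference interval; `indeterminate`
#' otherwise.
#'
#' @param posterior a `binding_posterior` from [fit_binding_hier()].
#' @param reference_group name of the inhibitor-free group.
#' @return data.frame with `group` and `classification` for every
#'   non-reference group.
#' @export
classify_inhibition <- function(posterior, reference_group = "total") {
  stopifnot(inherits(posterior, "binding_posterior"))
  g <- posterior$groups
  if (!reference_group %in% g$group) {
    stop("reference group not present in the posterior", call. = FALSE)
  }
  ref <- g[g$group == reference_group, ]
  others <- g[g$group != reference_group, , drop = FALSE]
  cls <- vapply(seq_len(nrow(others)), function(i) {
    o <- others[i, ]
    bmax_overlap <- o$bmax_lower <= ref$bmax_upper && o$bmax_upper >= ref$bmax_lower
    bmax_below <- o$bmax_upper < ref$bmax_lower
    kd_shifted_up <- o$kd_lower > ref$kd_upper
    if (bmax_below) "mixed"
    else if (bmax_overlap && kd_shifted_up) "competitive"
    else "indeterminate"
  }, character(1))
  data.frame(group = others$group, classification = cls, row.names = NULL)
}
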