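CONC_FAMILIES <- c("normal", "lognormal", "gamma", "weibull",
                   "uniform", "triangular")
POSITIVE_FAMILIES <- c("lognormal", "gamma", "weibull")

# triangular distribution on [a, b] with mode m
dtri <- function(x, a, b, m) {
  d <- numeric(length(x))
  up <- x >= a & x <= m
  dn <- x > m & x <= b
  d[up] <- 2 * (x[up] - a) / ((b - a) * (m - a))
  d[dn] <- 2 * (b - x[dn]) / ((b - a) * (b - m))
  d
}

ptri <- function(q, a, b, m) {
  p <- numeric(length(q))
  p[q >= b] <- 1
  up <- q > a & q <= m
  dn <- q > m & q < b
  p[up] <- (q[up] - a)^2 / ((b - a) * (m - a))
  p[dn] <- 1 - (b - q[dn])^2 / ((b - a) * (b - m))
  p
}

qtri <- function(p, a, b, m) {
  pc <- (m - a) / (b - a)
  ifelse(p <= pc,
         a + sqrt(p * (b - a) * (m - a)),
         b - sqrt((1 - p) * (b - a) * (b - m)))
}

rtri <- function(n, a, b, m) qtri(stats::runif(n), a, b, m)

#' Anderson-Darling statistic against a fitted CDF
#'
#' `A^2 = -n - (1/n) * sum((2i - 1) * (log F(x_(i)) + log(1 - F(x_(n+1-i)))))`
#' over the order statistics `x_(1) <= ... <= x_(n)`. Smaller values indicate
#' a better fit; the statistic weights the distribution tails more heavily
#' than Kolmogorov-Smirnov, which suits right-skewed concentration data.
#'
#' @param x Numeric sample.
#' @param cdf A vectorized CDF function.
#' @return The A-squared statistic.
#' @export
#' @examples
#' ad_statistic(rnorm(50), pnorm)
ad_statistic <- function(x, cdf) {
  n <- length(x)
  u <- cdf(sort(x))
  eps <- 1e-12
  u <- pmin(pmax(u, eps), 1 - eps)
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
}

# chi-square GOF on equiprobable bins of the fitted distribution
chisq_gof <- function(x, quantile_fun, n_par) {
  n <- length(x)
  k <- max(3L, min(10L, floor(n / 5)))
  edges <- quantile_fun(seq(0, 1, length.out = k + 1))
  edges[1] <- -Inf
  edges[k + 1] <- Inf
  obs <- table(cut(x, edges, include.lowest = TRUE))
  expd <- n / k
  stat <- sum((as.numeric(obs) - expd)^2 / expd)
  df <- k - 1L - n_par
  p <- if (df >= 1L) stats::pchisq(stat, df, lower.tail = FALSE) else NA_real_
  list(stat = stat, df = df, p = p)
}

fit_one_family <- function(pos, allv, family) {
  # returns list(params, cdf, qf, n_par, data_used) or NULL on failure
  widen <- function(v) {
    r <- max(v) - min(v)
    pad <- if (r > 0) r / length(v) else abs(v[1]) * 1e-3 + 1e-12
    c(min(v) - pad, max(v) + pad)
  }
  tryCatch(switch(family,
    normal = {
      p <- list(mean = mean(allv), sd = stats::sd(allv))
      if (p$sd <= 0) return(NULL)
      list(params = p, cdf = function(q) stats::pnorm(q, p$mean, p$sd),
           qf = function(pr) stats::qnorm(pr, p$mean, p$sd),
           n_par = 2L, data_used = allv)
    },
    lognormal = {
      lx <- log(pos)
      p <- list(meanlog = mean(lx), sdlog = stats::sd(lx))
      if (p$sdlog <= 0) return(NULL)
      list(params = p, cdf = function(q) stats::plnorm(q, p$meanlog, p$sdlog),
           qf = function(pr) stats::qlnorm(pr, p$meanlog, p$sdlog),
           n_par = 2L, data_used = pos)
    },
    gamma = {
      sc <- mean(pos)
      f <- suppressWarnings(fitdistrplus::fitdist(pos / sc, "gamma"))
      p <- list(shape = unname(f$estimate["shape"]),
                rate = unname(f$estimate["rate"]) / sc)
      list(params = p, cdf = function(q) stats::pgamma(q, p$shape, p$rate),
           qf = function(pr) stats::qgamma(pr, p$shape, p$rate),
           n_par = 2L, data_used = pos)
    },
    weibull = {
      sc <- mean(pos)
      f <- suppressWarnings(fitdistrplus::fitdist(pos / sc, "weibull"))
      p <- list(shape = unname(f$estimate["shape"]),
                scale = unname(f$estimate["scale"]) * sc)
      list(params = p, cdf = function(q) stats::pweibull(q, p$shape, p$scale),
           qf = function(pr) stats::qweibull(pr, p$shape, p$scale),
           n_par = 2L, data_used = pos)
    },
    uniform = {
      # endpoints widened by range/n so no observation sits at F = 0 or 1
      ab <- widen(allv)
      p <- list(min = ab[1], max = ab[2])
      list(params = p, cdf = function(q) stats::punif(q, p$min, p$max),
           qf = function(pr) stats::qunif(pr, p$min, p$max),
           n_par = 2L, data_used = allv)
    },
    triangular = {
      ab <- widen(allv)
      ll <- function(m) sum(log(pmax(dtri(allv, ab[1], ab[2], m), 1e-300)))
      opt <- stats::optimize(ll, interval = ab, maximum = TRUE)
      p <- list(min = ab[1], max = ab[2], mode = opt$maximum)
      list(params = p, cdf = function(q) ptri(q, p$min, p$max, p$mode),
           qf = function(pr) qtri(pr, p$min, p$max, p$mode),
           n_par = 3L, data_used = allv)
    }
  ), error = function(e) NULL)
}

#' Fit a concentration distribution with Anderson-Darling selection
#'
#' Fits each candidate family by maximum likelihood and selects the family
#' with the smallest Anderson-Darling statistic; a chi-square statistic on
#' equiprobable bins is recorded as a secondary diagnostic but does not drive
#' selection. Non-detect zeros are handled as a point mass at zero: the
#' strictly positive families (lognormal, gamma, Weibull) are fitted to the
#' positive part and carry the observed zero fraction as mixture weight,
#' while the real-line families (normal, uniform, triangular) are fitted to
#' all values. Fewer than 8 samples (or fewer than 2 distinct values among
#' them) fall back to the empirical distribution; an all-identical sample
#' degenerates to a point mass with a warning.
#'
#' @param x Numeric vector of concentration samples (canonical units),
#'   `>= 0`, at least 2 values.
#' @param families Candidate families, a subset of
#'   `c("normal", "lognormal", "gamma", "weibull", "uniform", "triangular")`.
#' @param variable Label for the fitted variable (e.g.
#'   `"acrolein|aerosol"`).
#' @return An object of class `conc_fit`: `family`, `params`, `zero_w` (the
#'   zero mixture weight for positive families), `gof` (per-family AD and
#'   chi-square table), `n`, and for the fallback families the retained
#'   `values`.
#' @seealso [rconc_fit()] to draw from a fit, [simulate.risk_assessment()].
#' @export
#' @examples
#' set.seed(1)
#' fit_concentration(rlnorm(200, -1, 1))
fit_concentration <- function(x, families = CONC_FAMILIES, variable = "x") {
  if (length(x) < 2L) stop("need at least 2 samples to fit", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("samples must be finite and non-negative", call. = FALSE)
  }
  families <- match.arg(families, CONC_FAMILIES, several.ok = TRUE)
  new_fit <- function(family, params, zero_w = 0, gof = NULL, values = NULL) {
    structure(list(variable = variable, family = family, params = params,
                   zero_w = zero_w, gof = gof, n = length(x),
                   values = values),
              class = "conc_fit")
  }
  if (length(unique(x)) == 1L) {
    warning("all samples identical; returning a point mass at ", x[1],
            call. = FALSE)
    return(new_fit("point_mass", list(value = x[1])))
  }
  w <- mean(x == 0)
  pos <- x[x > 0]
  if (length(x) < 8L || length(unique(pos)) < 2L) {
    return(new_fit("empirical", list(), zero_w = 0, values = x))
  }
  rows <- list()
  fits <- list()
  for (fam in families) {
    f <- fit_one_family(pos, x, fam)
    if (is.null(f)) next
    ad <- ad_statistic(f$data_used, f$cdf)
    if (!is.finite(ad)) next
    cs <- chisq_gof(f$data_used, f$qf, f$n_par)
    fits[[fam]] <- f
    rows[[fam]] <- data.frame(family = fam, ad = ad, chisq = cs$stat,
                              chisq_df = cs$df, chisq_p = cs$p,
                              stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    warning("no parametric family could be fitted; using empirical",
            call. = FALSE)
    return(new_fit("empirical", list(), zero_w = 0, values = x))
  }
  gof <- do.call(rbind, rows)
  rownames(gof) <- NULL
  best <- gof$family[which.min(gof$ad)]
  zw <- if (best %in% POSITIVE_FAMILIES) w else 0
  new_fit(best, fits[[best]]$params, zero_w = zw, gof = gof)
}

#' @export
print.conc_fit <- function(x, ...) {
  cat(sprintf("<conc_fit> %s: %s (n = %d", x$variable, x$family, x$n))
  if (x$zero_w > 0) cat(sprintf(", zero mass %.3f", x$zero_w))
  cat(")\n")
  if (length(x$params)) {
    cat("  params:", paste(sprintf("%s = %.4g", names(x$params),
                                   unlist(x$params)), collapse = ", "), "\n")
  }
  if (!is.null(x$gof)) {
    cat("  goodness of fit (selection by smallest AD):\n")
    print(x$gof, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Draw random concentrations from a fitted distribution
#'
#' For the strictly positive families the zero mixture weight is honoured:
#' each draw is 0 with probability `zero_w` and a draw from the fitted
#' positive part otherwise. Real-line families may produce negative values;
#' the Monte Carlo engine truncates those at 0.
#'
#' @param fit A [fit_concentration()] result.
#' @param n Number of draws.
#' @return Numeric vector of `n` draws.
#' @export
rconc_fit <- function(fit, n) {
  p <- fit$params
  draws <- switch(fit$family,
    point_mass = rep(p$value, n),
    empirical = sample(fit$values, n, replace = TRUE),
    normal = stats::rnorm(n, p$mean, p$sd),
    lognormal = stats::rlnorm(n, p$meanlog, p$sdlog),
    gamma = stats::rgamma(n, p$shape, p$rate),
    weibull = stats::rweibull(n, p$shape, p$scale),
    uniform = stats::runif(n, p$min, p$max),
    triangular = rtri(n, p$min, p$max, p$mode),
    stop("unknown family ", fit$family, call. = FALSE)
  )
  if (fit$zero_w > 0) {
    draws[stats::runif(n) < fit$zero_w] <- 0
  }
  draws
}

#' Build moment-matched lognormal fits from concentration summaries
#'
#' Convenience used when only summary statistics are available (as for the
#' packaged compilation): each chemical/matrix gets a lognormal moment-matched
#' to the summary mean and SD ([moment_lognormal()]). A summary with zero SD
#' becomes a point mass.
#'
#' @param summaries A summary table as from [packaged_summaries()].
#' @return Named list of `conc_fit` objects keyed `"chemical|matrix"`.
#' @export
summary_fits <- function(summaries) {
  fits <- list()
  for (i in seq_len(nrow(summaries))) {
    row <- summaries[i, , drop = FALSE]
    key <- paste(row$chemical, row$matrix, sep = "|")
    fits[[key]] <- if (row$sd > 0 && row$mean > 0) {
      par <- moment_lognormal(row$mean, row$sd)
      structure(list(variable = key, family = "lognormal",
                     params = par, zero_w = 0, gof = NULL, n = row$n_refs,
                     values = NULL),
                class = "conc_fit")
    } else {
      structure(list(variable = key, family = "point_mass",
                     params = list(value = row$mean), zero_w = 0, gof = NULL,
                     n = row$n_refs, values = NULL),
                class = "conc_fit")
    }
  }
  fits
}

#' Monte Carlo propagation of concentration uncertainty through the pipeline
#'
#' Draws `nsim` concentration vectors from the fitted distributions
#' (truncating negative draws at 0), evaluates the full deterministic
#' exposure-to-risk pipeline for every draw, and summarizes each output as
#' percentiles, mean and exceedance probability against its acceptability
#' threshold (hazard quotient and acute risk 1, cancer risk 1e-6). Only
#' concentrations are stochastic; scenario constants stay at their scenario
#' values. Results are bit-for-bit reproducible for a given `seed`.
#'
#' @param object A [risk_assessment()] (supplies references, scenario, and
#'   the chemical/matrix layout).
#' @param nsim Number of iterations (default 10000; below 1000 a warning is
#'   issued because tail percentiles are unstable).
#' @param seed Integer seed; recorded in the result.
#' @param fits Named list of [fit_concentration()] objects keyed
#'   `"chemical|matrix"`. Every chemical/matrix present in the assessment
#'   must have a fit (missing ones are a hard error). Defaults to
#'   moment-matched lognormal fits from the assessment's summaries
#'   ([summary_fits()]).
#' @param ... Unused.
#' @return An object of class `risk_simulation`: `table` (one row per output:
#'   target, mean, percentiles 1/5/25/50/75/95/99, threshold, exceedance and
#'   certainty in percent), `outputs` (per-draw values), `inputs` (per-draw
#'   concentrations), `nsim`, `seed`.
#' @export
#' @examples
#' fit <- risk_assessment()
#' sim <- simulate(fit, nsim = 2000, seed = 7)
#' head(sim$table)
simulate.risk_assessment <- function(object, nsim = 10000, seed = NULL,
                                     fits = NULL, ...) {
  if (nsim < 1) stop("nsim must be >= 1", call. = FALSE)
  if (nsim < 1000) {
    warning("nsim < 1000: percentile and exceedance estimates are unstable",
            call. = FALSE)
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  if (is.null(fits)) fits <- summary_fits(object$summaries)
  set.seed(seed)
  summ <- object$summaries
  keys <- paste(summ$chemical, summ$matrix, sep = "|")
  missing_fit <- setdiff(keys, names(fits))
  if (length(missing_fit)) {
    stop("no fitted distribution for: ", paste(missing_fit, collapse = ", "),
         call. = FALSE)
  }
  inputs <- vapply(keys, function(k) pmax(rconc_fit(fits[[k]], nsim), 0),
                   numeric(nsim))
  colnames(inputs) <- keys
  scen <- object$scenario
  refs <- object$refs
  outputs <- list()
  for (i in seq_along(keys)) {
    chem <- summ$chemical[i]
    mat <- summ$matrix[i]
    p <- inputs[, i]
    tox <- refs[refs$chemical == chem, , drop = FALSE]
    if (mat == "aerosol") {
      d <- dose_inhalation(p, scen)
      ref <- noncancer_reference_dose(chem, "inhalation", refs, scen)
      if (!is.na(ref$value)) {
        outputs[[paste("HQ", "inhalation", chem, sep = "|")]] <-
          hazard_quotient(d, ref$value)
      }
      if (!is.na(tox$cpv_inh)) {
        outputs[[paste("CR", "inhalation", chem, sep = "|")]] <-
          cancer_risk(d, tox$cpv_inh)
      }
    } else {
      d_o <- dose_oral(p, scen)
      d_d <- dose_dermal(p, chem, scen, object$dermal_mode)
      i_a <- acute_intake(p, scen)
      ref_o <- noncancer_reference_dose(chem, "oral", refs, scen)
      ref_d <- noncancer_reference_dose(chem, "dermal", refs, scen)
      if (!is.na(ref_o$value)) {
        outputs[[paste("HQ", "oral", chem, sep = "|")]] <-
          hazard_quotient(d_o, ref_o$value)
      }
      if (!is.na(ref_d$value)) {
        outputs[[paste("HQ", "dermal", chem, sep = "|")]] <-
          hazard_quotient(d_d, ref_d$value)
      }
      if (!is.na(tox$cpv_oral)) {
        outputs[[paste("CR", "oral", chem, sep = "|")]] <-
          cancer_risk(d_o, tox$cpv_oral)
      }
      if (!is.na(tox$sf_derm)) {
        outputs[[paste("CR", "dermal", chem, sep = "|")]] <-
          cancer_risk(d_d, tox$sf_derm)
      }
      if (!is.na(tox$ld50_oral)) {
        outputs[[paste("AR", "oral", chem, sep = "|")]] <-
          acute_risk(i_a, tox$ld50_oral)
      }
      if (!is.na(tox$ld50_derm)) {
        outputs[[paste("AR", "dermal", chem, sep = "|")]] <-
          acute_risk(i_a, tox$ld50_derm)
      }
    }
  }
  # route totals across chemicals, per draw
  for (route in c("inhalation", "oral", "dermal")) {
    for (kind in c("HQ", "CR", "AR")) {
      nm <- grep(paste0("^", kind, "\\|", route, "\\|"), names(outputs),
                 value = TRUE)
      if (!length(nm)) next
      tot <- Reduce(`+`, outputs[nm])
      label <- c(HQ = "HI", CR = "CR_total", AR = "AR_total")[[kind]]
      outputs[[paste(label, route, sep = "|")]] <- tot
    }
  }
  probs <- c(1, 5, 25, 50, 75, 95, 99) / 100
  tab <- do.call(rbind, lapply(names(outputs), function(nm) {
    v <- outputs[[nm]]
    kind <- sub("\\|.*$", "", nm)
    thr <- switch(kind, CR = 1e-6, CR_total = 1e-6, 1)
    q <- stats::quantile(v, probs, names = FALSE)
    data.frame(target = nm, mean = mean(v),
               p1 = q[1], p5 = q[2], p25 = q[3], p50 = q[4], p75 = q[5],
               p95 = q[6], p99 = q[7], threshold = thr,
               exceedance_pct = 100 * mean(v > thr),
               certainty_pct = 100 * (1 - mean(v > thr)),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(table = tab, outputs = outputs, inputs = inputs,
                 nsim = nsim, seed = seed),
            class = "risk_simulation")
}

#' @export
print.risk_simulation <- function(x, ...) {
  cat(sprintf("Monte Carlo risk simulation: %d iterations, seed %d\n",
              x$nsim, x$seed))
  tot <- x$table[grepl("^(HI|CR_total|AR_total)\\|", x$table$target), ,
                 drop = FALSE]
  disp <- tot[c("target", "mean", "p5", "p50", "p95", "exceedance_pct")]
  disp$mean <- fmt3(disp$mean)
  disp$p5 <- fmt3(disp$p5)
  disp$p50 <- fmt3(disp$p50)
  disp$p95 <- fmt3(disp$p95)
  print(disp, row.names = FALSE)
  invisible(x)
}

#' Exceedance probability of simulated risks
#'
#' The fraction of draws strictly above a threshold, and its complement
#' ("certainty"): the Monte Carlo estimate of the probability that an
#' individual's risk crosses the acceptability limit.
#'
#' @param draws Numeric vector of simulated risk values.
#' @param threshold Acceptability threshold.
#' @return A list with `exceedance` and `certainty`, both in `[0, 1]`.
#' @export
#' @examples
#' exceedance_probability(runif(1e4, 0, 2), 1)
exceedance_probability <- function(draws, threshold) {
  e <- mean(draws > threshold)
  list(exceedance = e, certainty = 1 - e)
}

#' Rank-correlation sensitivity analysis of a simulation output
#'
#' Computes the Spearman rank correlation of each stochastic input
#' (concentration) with the chosen output across the Monte Carlo draws and
#' expresses each input's contribution as its squared rank correlation
#' normalized to 100%: `contribution_i = r_i^2 / sum_j r_j^2 * 100` (the
#' conventional "contribution to variance" of spreadsheet risk tools).
#'
#' @param sim A [simulate.risk_assessment()] result.
#' @param target Name of an output in `sim$table$target`
#'   (e.g. `"HI|inhalation"`).
#' @return A data frame of class `sensitivity_report` with columns
#'   `variable`, `spearman_r`, `contribution_pct`, sorted by decreasing
#'   contribution; attribute `method` is `"spearman_r2_normalized"`.
#' @export
#' @examples
#' fit <- risk_assessment()
#' sim <- simulate(fit, nsim = 2000, seed = 7)
#' head(sensitivity(sim, "HI|inhalation"))
sensitivity <- function(sim, target) {
  stopifnot(inherits(sim, "risk_simulation"))
  if (!target %in% names(sim$outputs)) {
    stop("unknown simulation target '", target, "'", call. = FALSE)
  }
  y <- sim$outputs[[target]]
  vary <- apply(sim$inputs, 2L, function(v) stats::sd(v) > 0)
  r <- rep(0, ncol(sim$inputs))
  names(r) <- colnames(sim$inputs)
  if (stats::sd(y) == 0) {
    warning("output is constant across draws; all contributions are zero",
            call. = FALSE)
  } else if (any(vary)) {
    r[vary] <- apply(sim$inputs[, vary, drop = FALSE], 2L,
                     function(v) stats::cor(v, y, method = "spearman"))
  }
  denom <- sum(r^2)
  contrib <- if (denom > 0) r^2 / denom * 100 else r * 0
  out <- data.frame(variable = names(r), spearman_r = unname(r),
                    contribution_pct = unname(contrib),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$contribution_pct), ]
  rownames(out) <- NULL
  attr(out, "method") <- "spearman_r2_normalized"
  attr(out, "target") <- target
  class(out) <- c("sensitivity_report", class(out))
  out
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Sensitivity of %s (%s)\n", attr(x, "target"),
              attr(x, "method")))
  disp <- as.data.frame(x)
  disp$spearman_r <- sprintf("%.3f", disp$spearman_r)
  disp$contribution_pct <- sprintf("%.2f", disp$contribution_pct)
  print(utils::head(disp, 10), row.names = FALSE)
  invisible(x)
}
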