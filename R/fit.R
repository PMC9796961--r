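#' Settings for composite-likelihood fitting
#'
#' The likelihood surface is Monte-Carlo estimated, so the optimizer is a
#' derivative-free multi-start search: each replicate draws a random start
#' within the search bounds (log-uniform for sizes, times and migration
#' rates; uniform for proportions), pre-scans a handful of additional random
#' candidates, and then runs Nelder-Mead cycles in transformed space until
#' the relative likelihood improvement between cycles drops below
#' `stop_tol`. Common random numbers (the same simulation seed for every
#' evaluation within a replicate) keep the surface deterministic during a
#' replicate's search; the final likelihood of each replicate is re-evaluated
#' with `n_sims_final` simulations under one seed shared by all replicates
#' so that replicates are compared on equal footing.
#'
#' @param n_sims coalescent simulations per likelihood evaluation during the
#'   search (default 1e5).
#' @param n_sims_final simulations for the final per-replicate evaluation
#'   (default 2.5e5).
#' @param cycles maximum optimization cycles per replicate (default 40).
#' @param iters_per_cycle Nelder-Mead iterations per cycle (default 20).
#' @param stop_tol relative lnL improvement below which a replicate stops
#'   (default 0.001).
#' @param n_replicates independent starts (default 100).
#' @param prescan random candidate points screened before the first cycle
#'   (default 12).
#' @param triage_cycles cycles run for every replicate before triage
#'   (default `NULL`: all replicates run the full `cycles` budget).
#' @param deepen_top when triage is active, the number of best-so-far
#'   replicates that continue from `triage_cycles` up to `cycles`, as one
#'   uninterrupted Nelder-Mead run (default 3). Also the number of top
#'   replicates polished when `polish_iters > 0`.
#' @param polish_iters extra Nelder-Mead iterations applied to the top
#'   replicates at `n_sims_final` simulations per evaluation (default 0).
#'   Searching at moderate `n_sims` and polishing at high `n_sims` keeps the
#'   search fast while preventing the selected optimum from exploiting the
#'   Monte-Carlo noise of a single simulation stream.
#' @param common_random_numbers reuse one simulation seed across evaluations
#'   within a replicate (default `TRUE`).
#' @param bounds named list of search bounds on the natural scale:
#'   `N` (diploid sizes), `T` (generations), `m` (per-generation rates),
#'   `gamma` (proportions). The migration bound tops out at `1e-6` per
#'   generation: beyond that, with divergence times of order 1e6
#'   generations, the demes are effectively panmictic (many migrants per
#'   lineage per epoch), which is outside the distinct-taxa hypothesis space
#'   and makes exact coalescent simulation needlessly expensive.
#' @return an object of class `fit_settings`.
#' @export
fit_settings <- function(n_sims = 1e5, n_sims_final = 2.5e5, cycles = 40,
                         iters_per_cycle = 20, stop_tol = 0.001,
                         n_replicates = 100, prescan = 12,
                         triage_cycles = NULL, deepen_top = 3,
                         polish_iters = 0,
                         common_random_numbers = TRUE,
                         bounds = list(N = c(1e3, 1e7), T = c(1e3, 1e7),
                                       m = c(1e-10, 1e-6),
                                       gamma = c(0.001, 0.999))) {
  s <- list(n_sims = as.integer(n_sims),
            n_sims_final = as.integer(n_sims_final),
            cycles = as.integer(cycles),
            iters_per_cycle = as.integer(iters_per_cycle),
            stop_tol = stop_tol, n_replicates = as.integer(n_replicates),
            prescan = as.integer(prescan),
            triage_cycles = if (is.null(triage_cycles)) NULL
                            else as.integer(triage_cycles),
            deepen_top = as.integer(deepen_top),
            polish_iters = as.integer(polish_iters),
            common_random_numbers = isTRUE(common_random_numbers),
            bounds = bounds)
  if (s$n_sims < 1000 || s$n_sims_final < 1000) stop("n_sims must be >= 1000")
  if (s$cycles < 1 || s$iters_per_cycle < 1) stop("cycles must be positive")
  if (s$stop_tol <= 0) stop("stop_tol must be > 0")
  if (s$n_replicates < 1) stop("n_replicates must be >= 1")
  if (s$prescan < 0) stop("prescan must be >= 0")
  if (!is.null(s$triage_cycles) &&
      (s$triage_cycles < 1 || s$triage_cycles > s$cycles)) {
    stop("triage_cycles must lie in [1, cycles]")
  }
  if (s$deepen_top < 0) stop("deepen_top must be >= 0")
  if (s$polish_iters < 0) stop("polish_iters must be >= 0")
  structure(s, class = "fit_settings")
}

#' Composite log-likelihood of an observed joint SFS
#'
#' Treating unlinked SNPs as independent multinomial draws over folded
#' polymorphic SFS entries, the composite log-likelihood is
#' `sum_i m_i * log(p_i)` over entries with observed mass `m_i > 0`, in
#' natural log. Monomorphic cells never contribute (the analysis is
#' conditioned on polymorphism), so padding the observed spectrum with
#' monomorphic mass leaves the value unchanged. Entries with observed mass
#' but zero probability give `-Inf`; the expected-SFS generator floors such
#' probabilities, so finite values are guaranteed along the fitting path.
#'
#' @param observed a `joint_sfs` of observed masses (counts; may be
#'   fractional after projection).
#' @param probs a `joint_sfs` on the probability scale with matching
#'   dimensions (e.g. from [expected_sfs()]).
#' @return the composite log-likelihood (natural log).
#' @export
composite_loglik <- function(observed, probs) {
  stopifnot(inherits(observed, "joint_sfs"), inherits(probs, "joint_sfs"))
  if (!identical(dim(observed$mass), dim(probs$mass))) {
    stop("observed and expected SFS dimensions do not match")
  }
  sup <- .folded_support(dim(observed$mass))
  m <- observed$mass[sup]
  p <- probs$mass[sup]
  use <- m > 0
  if (!any(use)) return(0)
  sum(m[use] * log(p[use]))
}

#' Anchor effective size from nucleotide diversity
#'
#' Under neutrality the expected nucleotide diversity is `pi = 4 N_e mu`,
#' so `N_e = pi / (4 mu)`. One deme's contemporary size is fixed this way so
#' the remaining parameters are identifiable from a polymorphism-conditioned
#' SFS.
#'
#' @param pi nucleotide diversity (>= 0).
#' @param mu mutation rate per site per generation (> 0).
#' @return diploid effective population size.
#' @export
#' @examples
#' ne_from_pi(0.0112, 2.8e-9)  # 1e6
ne_from_pi <- function(pi, mu) {
  if (mu <= 0) stop("mu must be > 0")
  if (pi < 0) stop("pi must be >= 0")
  pi / (4 * mu)
}

# --- optimizer parameterization -------------------------------------------
# Sizes, T_div1 and migration rates are searched in log space; proportions
# (gamma) in logit space. Event ordering is built into the parameterization:
# T_hyb = r * T_div1 (fusion), T_div2 = r2 * T_div1 and T_int = r1 * T_div2
# (bifurcating/introgression), each ratio in logit space, so every internal
# point satisfies the ordering constraints by construction.

.logit <- function(p) log(p / (1 - p))
.inv_logit <- function(x) 1 / (1 + exp(-x))

.internal_names <- function(spec) {
  nm <- free_param_names(spec)
  nm[nm == "T_hyb"] <- "r_hyb"
  nm[nm == "T_div2"] <- "r_div2"
  nm[nm == "T_int"] <- "r_int"
  nm
}

.to_internal <- function(spec, params) {
  x <- numeric(0)
  for (nm in free_param_names(spec)) {
    v <- params[[nm]]
    xi <- switch(nm,
      T_hyb = .logit(v / params[["T_div1"]]),
      T_div2 = .logit(v / params[["T_div1"]]),
      T_int = .logit(v / params[["T_div2"]]),
      if (startsWith(nm, "gamma")) .logit(v) else log(v)
    )
    names(xi) <- .internal_names(spec)[match(nm, free_param_names(spec))]
    x <- c(x, xi)
  }
  x
}

.from_internal <- function(spec, x) {
  nm_int <- .internal_names(spec)
  nm_nat <- free_param_names(spec)
  vals <- setNames(numeric(length(x)), nm_nat)
  # magnitude params first so ratios can resolve
  for (i in seq_along(nm_nat)) {
    nm <- nm_nat[i]
    if (nm %in% c("T_hyb", "T_div2", "T_int")) next
    vals[nm] <- if (startsWith(nm, "gamma")) .inv_logit(x[i]) else exp(x[i])
  }
  if ("T_div2" %in% nm_nat) {
    vals["T_div2"] <- .inv_logit(x[match("r_div2", nm_int)]) * vals["T_div1"]
  }
  if ("T_int" %in% nm_nat) {
    vals["T_int"] <- .inv_logit(x[match("r_int", nm_int)]) * vals["T_div2"]
  }
  if ("T_hyb" %in% nm_nat) {
    vals["T_hyb"] <- .inv_logit(x[match("r_hyb", nm_int)]) * vals["T_div1"]
  }
  vals
}

.bounds_of <- function(nm, bounds) {
  if (startsWith(nm, "N_")) bounds$N
  else if (startsWith(nm, "T_")) bounds$T
  else if (startsWith(nm, "m_")) bounds$m
  else bounds$gamma
}

# soft quadratic penalty (on the log scale) for natural-scale bound
# violations; keeps Nelder-Mead informed outside the box
.bound_penalty <- function(spec, params, bounds) {
  pen <- 0
  for (nm in free_param_names(spec)) {
    b <- .bounds_of(nm, bounds)
    v <- params[[nm]]
    if (v < b[1]) pen <- pen + (log(b[1]) - log(max(v, 1e-300)))^2
    if (v > b[2]) pen <- pen + (log(v) - log(b[2]))^2
  }
  1e4 * pen
}

.draw_start <- function(spec, bounds) {
  nm_nat <- free_param_names(spec)
  vals <- setNames(numeric(length(nm_nat)), nm_nat)
  for (nm in nm_nat) {
    b <- .bounds_of(nm, bounds)
    if (startsWith(nm, "gamma")) {
      vals[nm] <- runif(1, max(b[1], 0.05), min(b[2], 0.95))
    } else if (nm %in% c("T_hyb", "T_div2", "T_int")) {
      vals[nm] <- NA  # resolved from ratios below
    } else {
      vals[nm] <- exp(runif(1, log(b[1]), log(b[2])))
    }
  }
  if ("T_div2" %in% nm_nat) vals["T_div2"] <- runif(1, 0.1, 0.9) * vals["T_div1"]
  if ("T_int" %in% nm_nat) vals["T_int"] <- runif(1, 0.1, 0.9) * vals["T_div2"]
  if ("T_hyb" %in% nm_nat) vals["T_hyb"] <- runif(1, 0.1, 0.9) * vals["T_div1"]
  vals
}

#' Build a demographic model from a free-parameter vector
#'
#' @param spec a `model_spec`.
#' @param params named numeric vector covering `free_param_names(spec)`.
#' @param anchor fixed diploid size of the `bin` deme.
#' @param mu mutation rate per site per generation.
#' @param generation_time_years generation time.
#' @return a `demographic_model`.
#' @export
model_from_params <- function(spec, params, anchor, mu = 2.8e-9,
                              generation_time_years = 1) {
  args <- c(list(spec = spec, N_bin = anchor), as.list(params),
            list(mu = mu, generation_time_years = generation_time_years))
  do.call(demographic_model, args)
}

#' Fit a demographic model to an observed folded joint SFS
#'
#' Maximizes the multinomial composite likelihood over the scenario's free
#' parameters by multi-start derivative-free search (see [fit_settings()]),
#' with the `bin` deme's contemporary size fixed at `anchor`. Deterministic
#' given `seed`.
#'
#' @param observed a folded, polymorphic-only `joint_sfs` of counts.
#' @param spec the `model_spec` to fit.
#' @param anchor fixed diploid size of the `bin` deme (see [ne_from_pi()]).
#' @param settings a `fit_settings` object.
#' @param seed integer seed controlling starts and simulation streams.
#' @param mu mutation rate per site per generation.
#' @return an object of class `fit_result`: point estimates for the free
#'   parameters, the maximum composite log-likelihood `lnL`, a per-replicate
#'   trace (`replicate`, `seed`, `lnL` and parameter columns), the
#'   per-replicate accepted-lnL sequences (`cycle_trace`), and the index of
#'   the selected replicate.
#' @export
fit_model <- function(observed, spec, anchor, settings = fit_settings(),
                      seed = 1, mu = 2.8e-9) {
  stopifnot(inherits(observed, "joint_sfs"), inherits(spec, "model_spec"),
            inherits(settings, "fit_settings"))
  if (!observed$folded || !observed$polymorphic_only) {
    stop("observed SFS must be folded and polymorphic-only")
  }
  if (anchor <= 0) stop("anchor must be > 0")
  if (settings$n_replicates < 1) stop("need at least one replicate")
  n <- observed$n
  samples <- sample_config(n[1], n[2], n[3])
  nm_nat <- free_param_names(spec)
  final_seed <- .derive_seed(seed, 999983)

  eval_ll <- function(params, n_sims, sim_seed) {
    pen <- .bound_penalty(spec, params, settings$bounds)
    model <- model_from_params(spec, params, anchor, mu)
    probs <- expected_sfs(model, samples, n_sims, sim_seed)
    composite_loglik(observed, probs) - pen
  }

  make_fn <- function(rep_seed, n_sims, stream = 1) {
    eval_count <- 0L
    function(x) {
      sim_seed <- if (settings$common_random_numbers) {
        .derive_seed(rep_seed, stream)
      } else {
        eval_count <<- eval_count + 1L
        .derive_seed(rep_seed, stream + 7 * eval_count)
      }
      params <- .from_internal(spec, x)
      ll <- tryCatch(eval_ll(params, n_sims, sim_seed),
                     error = function(e) -Inf)
      if (!is.finite(ll)) -1e12 else ll
    }
  }
  nm <- function(x, fn, maxit) {
    optim(x, fn, method = "Nelder-Mead",
          control = list(fnscale = -1, maxit = maxit,
                         warn.1d.NelderMead = FALSE))
  }
  # short cycles with the stop rule, all under the replicate's search stream
  run_cycles <- function(state, fn, n_cycles) {
    for (cyc in seq_len(n_cycles)) {
      opt <- nm(state$x, fn, settings$iters_per_cycle)
      rel <- (opt$value - state$ll) / max(abs(state$ll), 1)
      if (opt$value > state$ll) {
        state$x <- opt$par
        state$ll <- opt$value
      }
      state$accepted <- c(state$accepted, state$ll)
      if (rel < settings$stop_tol) {
        state$converged <- TRUE
        break
      }
    }
    state
  }

  triage <- if (is.null(settings$triage_cycles)) settings$cycles
            else settings$triage_cycles
  reps <- vector("list", settings$n_replicates)
  for (rep in seq_len(settings$n_replicates)) {
    rep_seed <- .derive_seed(seed, rep)
    fn <- make_fn(rep_seed, settings$n_sims)
    starts <- .with_seed(rep_seed, {
      lapply(seq_len(1 + settings$prescan), function(i) {
        .draw_start(spec, settings$bounds)
      })
    })
    xs <- lapply(starts, function(s) .to_internal(spec, s))
    lls <- vapply(xs, fn, numeric(1))
    state <- list(x = xs[[which.max(lls)]], ll = max(lls),
                  accepted = max(lls), converged = FALSE)
    state <- run_cycles(state, fn, triage)
    reps[[rep]] <- c(state, list(seed = rep_seed))
  }
  top_reps <- function() {
    lls <- vapply(reps, `[[`, numeric(1), "ll")
    k <- min(settings$deepen_top, length(reps))
    order(lls, decreasing = TRUE)[seq_len(k)]
  }
  # the most promising replicates spend the remaining cycle budget as one
  # uninterrupted Nelder-Mead run (simplex adaptation is lost on restarts)
  if (triage < settings$cycles && settings$deepen_top > 0) {
    for (rep in top_reps()) {
      fn <- make_fn(reps[[rep]]$seed, settings$n_sims)
      budget <- (settings$cycles - triage) * settings$iters_per_cycle
      opt <- nm(reps[[rep]]$x, fn, budget)
      if (opt$value > reps[[rep]]$ll) {
        reps[[rep]]$x <- opt$par
        reps[[rep]]$ll <- opt$value
      }
      reps[[rep]]$accepted <- c(reps[[rep]]$accepted, reps[[rep]]$ll)
    }
  }
  # polish the leaders against a fresh, larger simulation stream so the
  # final optimum cannot ride one stream's Monte-Carlo fluctuations
  if (settings$polish_iters > 0 && settings$deepen_top > 0) {
    for (rep in top_reps()) {
      fnp <- make_fn(reps[[rep]]$seed, settings$n_sims_final, stream = 2)
      opt <- nm(reps[[rep]]$x, fnp, settings$polish_iters)
      reps[[rep]]$x <- opt$par
    }
  }
  for (rep in seq_along(reps)) {
    params_hat <- .from_internal(spec, reps[[rep]]$x)
    ll_final <- eval_ll(params_hat, settings$n_sims_final, final_seed)
    reps[[rep]] <- list(seed = reps[[rep]]$seed, lnL = ll_final,
                        params = params_hat,
                        accepted = reps[[rep]]$accepted)
  }

  lnls <- vapply(reps, `[[`, numeric(1), "lnL")
  best <- which.max(lnls)
  trace <- data.frame(
    replicate = seq_along(reps),
    seed = vapply(reps, `[[`, numeric(1), "seed"),
    lnL = lnls
  )
  pmat <- do.call(rbind, lapply(reps, `[[`, "params"))
  colnames(pmat) <- nm_nat
  trace <- cbind(trace, as.data.frame(pmat))
  structure(list(
    spec = spec,
    estimates = reps[[best]]$params,
    lnL = lnls[best],
    k = param_count(spec),
    anchor = anchor,
    mu = mu,
    trace = trace,
    cycle_trace = lapply(reps, `[[`, "accepted"),
    best_replicate = best,
    settings = settings,
    n_snps = observed$n_snps,
    sample_sizes = n
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: lnL = %.2f (k = %d, %d replicates)\n",
              format(x$spec), x$lnL, x$k, nrow(x$trace)))
  print(signif(x$estimates, 4))
  invisible(x)
}

#' Write a fit result to JSON (with a TSV replicate trace alongside)
#'
#' @param fit a `fit_result`.
#' @param path output JSON path; the replicate trace is written to the same
#'   path with extension `.trace.tsv`.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  doc <- list(topology = fit$spec$topology, gene_flow = fit$spec$gene_flow,
              lnL = fit$lnL, k = fit$k, anchor = fit$anchor, mu = fit$mu,
              n_snps = fit$n_snps, best_replicate = fit$best_replicate,
              estimates = as.list(fit$estimates))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  trace_path <- sub("\\.json$", "", path)
  write.table(fit$trace, paste0(trace_path, ".trace.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
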