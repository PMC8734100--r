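#' Simulated-annealing configuration
#'
#' Defaults are the schedule that works across short- and long-read
#' datasets without per-dataset tuning: step `delta = 1`, initial
#' temperature `T0 = 2.8`, cooling factor `alpha = 0.7`, 8 cycles of 3
#' trials each.  `parity = "odd"` doubles the effective step so proposals
#' stay on odd k (most k-spectrum EC tools require odd k).
#'
#' @param k_min,k_max inclusive bounds of the k range.
#' @param delta base step size (default 1).
#' @param T0 initial temperature (default 2.8).
#' @param alpha temperature scale factor per cycle, in (0, 1) (default 0.7).
#' @param cycles number of cycles (default 8).
#' @param trials_per_cycle proposal-evaluate-accept steps at constant
#'   temperature per cycle (default 3).
#' @param parity `"any"` or `"odd"`.
#' @param k_init optional starting k; default is the range midpoint
#'   adjusted to the requested parity.
#' @param seed optional integer seed for the proposal/acceptance draws.
#' @return an object of class `anneal_config`.
#' @export
anneal_config <- function(k_min, k_max, delta = 1L, T0 = 2.8, alpha = 0.7,
                          cycles = 8L, trials_per_cycle = 3L,
                          parity = c("any", "odd"), k_init = NULL,
                          seed = NULL) {
  parity <- match.arg(parity)
  if (k_min > k_max) stop("k_min must be <= k_max")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (T0 <= 0) stop("T0 must be positive")
  if (delta < 1) stop("delta must be >= 1")
  structure(list(k_min = as.integer(k_min), k_max = as.integer(k_max),
                 delta = as.integer(delta), T0 = T0, alpha = alpha,
                 cycles = as.integer(cycles),
                 trials_per_cycle = as.integer(trials_per_cycle),
                 parity = parity,
                 k_init = if (is.null(k_init)) NULL else as.integer(k_init),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "anneal_config")
}

#' Acceptance probability for a worsening move
#'
#' `p = exp(-dE / (T * dE_avg))`, where `dE_avg` is the running mean of
#' `|dE|` over proposals so far; dividing by it makes the probability
#' scale-free in perplexity units.  A flat landscape (`dE_avg = 0`) accepts
#' only moves with `dE = 0`.
#'
#' @param dE energy (perplexity) increase, `>= 0`.
#' @param T current temperature, `> 0`.
#' @param dE_avg running mean absolute energy change, `>= 0`.
#' @return probability in `(0, 1]` (monotone decreasing in `dE`,
#'   increasing in `T`).
#' @export
acceptance_probability <- function(dE, T, dE_avg) {
  if (T <= 0) stop("temperature must be positive")
  if (dE_avg < 0 || dE < 0) stop("dE and dE_avg must be non-negative")
  if (dE_avg == 0) return(as.numeric(dE == 0))
  min(1, exp(-dE / (T * dE_avg)))
}

#' Simulated-annealing search over k
#'
#' Walks over the k grid minimizing the energy returned by `evaluate`
#' (corpus perplexity in the full pipeline).  Each cycle runs
#' `trials_per_cycle` proposals at constant temperature: the current k is
#' perturbed by one (parity-scaled) step in a random direction, reflected
#' back inward at the range bounds; improvements are always accepted,
#' worsenings with [acceptance_probability]; after each cycle the
#' temperature is multiplied by `alpha` and the walk restarts from the
#' best state seen so far (an elitist restart: with a budget of only
#' `cycles * trials_per_cycle` proposals, cooling anneals around the
#' incumbent optimum instead of wherever an accepted uphill excursion
#' happens to have drifted).  Evaluations are cached so each
#' distinct k is evaluated at most once, and the returned best is the
#' minimum over every k evaluated (not just accepted ones), with ties
#' going to the smaller k.  An `evaluate` error marks that k infeasible
#' and the proposal is retried (bounded).
#'
#' @param evaluate function `k -> energy` (deterministic per k).
#' @param cfg an [anneal_config].
#' @return list with `best_k`, `best_energy`, `history` (data frame:
#'   cycle, trial, k, energy, T, p, accepted), `evaluations` (data frame
#'   k, energy for every distinct k tried), `n_evaluations`.
#' @export
sa_search <- function(evaluate, cfg) {
  stopifnot(inherits(cfg, "anneal_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  step <- cfg$delta * if (cfg$parity == "odd") 2L else 1L
  snap_parity <- function(k) {
    if (cfg$parity == "odd" && k %% 2L == 0L) {
      k <- if (k + 1L <= cfg$k_max) k + 1L else k - 1L
    }
    max(cfg$k_min, min(cfg$k_max, k))
  }
  cache <- new.env(parent = emptyenv())
  infeasible <- new.env(parent = emptyenv())
  feval <- function(k) {
    key <- as.character(k)
    if (!is.null(cache[[key]])) return(cache[[key]])
    if (!is.null(infeasible[[key]])) return(NA_real_)
    val <- tryCatch(evaluate(k), error = function(e) {
      message("k = ", k, " infeasible: ", conditionMessage(e))
      NA_real_
    })
    if (is.na(val)) infeasible[[key]] <- TRUE else cache[[key]] <- val
    val
  }

  k_cur <- if (!is.null(cfg$k_init)) snap_parity(cfg$k_init)
           else snap_parity((cfg$k_min + cfg$k_max) %/% 2L)
  E_cur <- feval(k_cur)
  if (is.na(E_cur)) {
    for (k in seq(cfg$k_min, cfg$k_max)) {
      k <- snap_parity(k)
      E_cur <- feval(k)
      if (!is.na(E_cur)) { k_cur <- k; break }
    }
    if (is.na(E_cur)) stop("no feasible k in [", cfg$k_min, ", ",
                           cfg$k_max, "]")
  }

  T <- cfg$T0
  dE_sum <- 0; dE_n <- 0L
  hist <- vector("list", cfg$cycles * cfg$trials_per_cycle)
  hi <- 0L
  for (cycle in seq_len(cfg$cycles)) {
    for (trial in seq_len(cfg$trials_per_cycle)) {
      E_new <- NA_real_; cand <- k_cur
      for (attempt in seq_len(10L)) {
        dir <- sample(c(-1L, 1L), 1L)
        cand <- k_cur + dir * step
        if (cand < cfg$k_min || cand > cfg$k_max)
          cand <- k_cur - dir * step  # reflect at the boundary
        cand <- snap_parity(cand)
        E_new <- feval(cand)
        if (!is.na(E_new)) break
      }
      if (is.na(E_new)) next  # neighbourhood infeasible; try next trial
      dE <- E_new - E_cur
      dE_sum <- dE_sum + abs(dE); dE_n <- dE_n + 1L
      dE_avg <- dE_sum / dE_n
      if (dE <= 0) {
        p <- 1; accepted <- TRUE
      } else {
        p <- acceptance_probability(dE, T, dE_avg)
        accepted <- runif(1) < p
      }
      hi <- hi + 1L
      hist[[hi]] <- data.frame(cycle = cycle, trial = trial, k = cand,
                               energy = E_new, T = T, p = p,
                               accepted = accepted)
      if (accepted) { k_cur <- cand; E_cur <- E_new }
    }
    T <- T * cfg$alpha
    # elitist restart: begin the next (cooler) cycle at the best k so far
    ev <- ls(cache)
    energies <- vapply(ev, function(n) cache[[n]], numeric(1))
    best_now <- as.integer(ev[which.min(energies)])
    if (cache[[as.character(best_now)]] < E_cur) {
      k_cur <- best_now
      E_cur <- cache[[as.character(best_now)]]
    }
  }
  evals <- data.frame(
    k = as.integer(ls(cache)),
    energy = vapply(ls(cache), function(n) cache[[n]], numeric(1)))
  evals <- evals[order(evals$k), , drop = FALSE]
  rownames(evals) <- NULL
  best_i <- which(evals$energy == min(evals$energy))[1L]  # ties: lower k
  list(best_k = evals$k[best_i], best_energy = evals$energy[best_i],
       history = do.call(rbind, hist[seq_len(hi)]),
       evaluations = evals, n_evaluations = nrow(evals))
}

#' Exhaustive search over an explicit k list
#'
#' Evaluates every k and returns the argmin (first occurrence on ties).
#' The resulting table is the input for [normalized_correlation] and the
#' oracle against which [sa_search] is validated.
#'
#' @param evaluate function `k -> energy`; errors mark a k infeasible.
#' @param k_values non-empty vector of k values.
#' @return list with `best_k`, `best_energy`, `table` (data frame `k`,
#'   `energy`, rows in input order).
#' @export
exhaustive_search <- function(evaluate, k_values) {
  if (!length(k_values)) stop("k_values must be non-empty")
  energy <- vapply(k_values, function(k)
    tryCatch(evaluate(k), error = function(e) NA_real_), numeric(1))
  tab <- data.frame(k = as.integer(k_values), energy = energy)
  if (all(is.na(energy))) stop("every k was infeasible")
  best_i <- which.min(energy)  # first occurrence on ties, NAs skipped
  list(best_k = tab$k[best_i], best_energy = tab$energy[best_i], table = tab)
}
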