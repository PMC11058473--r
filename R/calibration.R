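## Calibration of the kinetic parameters against the reporter
## expression-ratio table, plus parameter-recovery diagnostics.

#' Packaged target table of reporter expression ratios
#'
#' Construct/condition expression ratios used for calibration. `condition`
#' is `"non-stress"` or `"stress"` (mutant over WT within that condition)
#' or `"fold-induction"` (stress over non-stress within the construct).
#' Percent-style statements are stored as ratios (an 80% drop is 0.2).
#' `output` selects the measured product: the main-ORF (ATF4-like)
#' reporter or the uORF2 fusion product. Headline rows carry extra fit
#' weight.
#'
#' @return Data frame with columns `construct`, `condition`, `output`,
#'   `value`, `weight`, `source`.
#' @export
target_table <- function() {
  tab <- rbind(
    data.frame(construct = "WT", condition = "fold-induction", output = "atf4",
               value = 5.2, weight = 3, source = "~5.2-fold induction upon Tg"),
    data.frame(construct = "d-all", condition = "non-stress", output = "atf4",
               value = 22.7, weight = 3, source = "~22.7-fold higher, non-stress"),
    data.frame(construct = "d-all", condition = "stress", output = "atf4",
               value = 3.3, weight = 1, source = "~3.3-fold higher, Tg stress"),
    data.frame(construct = "uORF1-only", condition = "non-stress", output = "atf4",
               value = 12.2, weight = 1, source = "12.2-fold upregulation"),
    data.frame(construct = "uORF1-only", condition = "stress", output = "atf4",
               value = 2.7, weight = 1, source = "2.7-fold upregulation"),
    data.frame(construct = "uORF2-only", condition = "non-stress", output = "atf4",
               value = 0.2, weight = 1, source = "~80% drop vs WT"),
    data.frame(construct = "uORF2-only", condition = "stress", output = "atf4",
               value = 0.2, weight = 1, source = "~80% drop vs WT, both conditions"),
    data.frame(construct = "uORF2-only", condition = "fold-induction", output = "atf4",
               value = 3.2, weight = 3, source = "~3.2-fold increase under stress"),
    data.frame(construct = "d1", condition = "non-stress", output = "atf4",
               value = 0.3, weight = 1, source = "~70% reduction"),
    data.frame(construct = "d1", condition = "stress", output = "atf4",
               value = 0.3, weight = 1, source = "~70% reduction, both conditions"),
    data.frame(construct = "d2", condition = "non-stress", output = "atf4",
               value = 12.1, weight = 1, source = "~12.1-fold increase"),
    data.frame(construct = "d2", condition = "stress", output = "atf4",
               value = 2.4, weight = 1, source = "~2.4-fold increase"),
    data.frame(construct = "SL3Mut-1", condition = "non-stress", output = "atf4",
               value = 1.3, weight = 1, source = "~1.3-fold over WT"),
    data.frame(construct = "SL3Mut-1", condition = "stress", output = "atf4",
               value = 1.5, weight = 1, source = "~1.5-fold over WT under Tg"),
    data.frame(construct = "SL3Mut-2", condition = "non-stress", output = "atf4",
               value = 1.7, weight = 1, source = "~1.7-fold over WT"),
    data.frame(construct = "SL3Mut-2", condition = "stress", output = "atf4",
               value = 1.8, weight = 1, source = "~1.8-fold over WT under Tg"),
    data.frame(construct = "CUGMut", condition = "non-stress", output = "atf4",
               value = 0.8, weight = 1, source = "reduced by ~20%, both conditions"),
    data.frame(construct = "CUGMut", condition = "stress", output = "atf4",
               value = 0.8, weight = 1, source = "reduced by ~20%, both conditions"),
    data.frame(construct = "A235G", condition = "non-stress", output = "atf4",
               value = 1.3, weight = 1, source = "increased by 30%, basal"),
    data.frame(construct = "A326G", condition = "non-stress", output = "atf4",
               value = 0.8, weight = 1, source = "reduced by ~20%"),
    data.frame(construct = "A326G", condition = "stress", output = "atf4",
               value = 0.8, weight = 1, source = "reduced by ~20%, both conditions"),
    data.frame(construct = "WT", condition = "fold-induction", output = "uorf2",
               value = 0.6, weight = 1, source = "uORF2 product reduced only ~40% under Tg")
  )
  stopifnot(all(tab$value > 0))
  tab
}

# Simulate every construct x condition cell needed by a target table and
# return the simulated ratio for each row. Uses common random numbers
# across evaluations (seeds derived from `seed` only).
simulate_targets <- function(params, table = target_table(), n_reps = 8,
                             t_max = 2000, seed = 1L, ref = NULL) {
  if (is.null(ref)) ref <- build_reference_leader()
  constructs <- union("WT", unique(table$construct))
  cell <- new.env(parent = emptyenv())
  get_cell <- function(con, cond, output) {
    key <- paste(con, cond, output, sep = "|")
    if (!is.null(cell[[key]])) return(cell[[key]])
    lead <- if (con == "WT") ref else apply_construct(ref, con)
    vals <- vapply(seq_len(n_reps), function(i) {
      s <- (seed + 1000003 * match(con, constructs) +
              7919 * match(cond, c("nonstress", "stress")) + 17 * i) %% .Machine$integer.max
      r <- simulate_leader(lead, params, t_max = t_max, seed = s,
                           condition = cond)
      if (output == "atf4") atf4_output(r)
      else {
        orfs <- lead$elements$orfs
        u2 <- orfs[!orfs$is_stst & orfs$frame_vs_cds == -1L, , drop = FALSE]
        if (nrow(u2)) uorf_output(r, u2$start[which.max(u2$n_codons)]) else 0
      }
    }, 0)
    cell[[key]] <- mean(vals)
    cell[[key]]
  }
  sim <- numeric(nrow(table))
  for (i in seq_len(nrow(table))) {
    con <- table$construct[i]; outp <- table$output[i]
    sim[i] <- switch(
      table$condition[i],
      "non-stress" = get_cell(con, "nonstress", outp) /
        get_cell("WT", "nonstress", outp),
      "stress" = get_cell(con, "stress", outp) /
        get_cell("WT", "stress", outp),
      "fold-induction" = get_cell(con, "stress", outp) /
        get_cell(con, "nonstress", outp),
      stop("unknown condition ", table$condition[i]))
  }
  sim
}

# Weighted mean squared log-ratio loss.
target_loss <- function(sim, table) {
  ok <- is.finite(sim) & sim > 0
  r <- log(pmax(sim, 1e-6) / table$value)
  r[!ok] <- log(1e3)
  sum(table$weight * r^2) / sum(table$weight)
}

#' Fit free simulation parameters to a target table
#'
#' Minimizes the weighted mean squared log-ratio error between simulated
#' and tabulated expression ratios, simulating every construct/condition
#' with `n_reps` replicates per evaluation. Derivative-free search: Latin-
#' hypercube style log-spaced probes followed by Nelder-Mead refinement.
#' Deterministic for a fixed seed (common random numbers across
#' evaluations).
#'
#' @param table Target table, see [target_table()].
#' @param free Named list of length-2 numeric bounds for the free
#'   parameters. Names address [sim_params()] arguments; entries of
#'   `p_init` are addressed as e.g. `"p_init.aug_medium"`.
#' @param start Optional named start values (defaults to mid-bounds on
#'   the log scale).
#' @param n_reps Replicates per construct/condition per evaluation.
#' @param n_probe Number of initial probe points.
#' @param maxit Nelder-Mead iteration budget.
#' @param t_max Simulated time per run.
#' @param seed Seed for the common-random-number scheme.
#' @param base_params Fixed (pinned) parameter values.
#' @return Object of class `calibrated_params`: list with `params`
#'   (full `sim_params`), `free`, `loss`, `residuals` (per-row table),
#'   `optimizer` metadata.
#' @export
fit_parameters <- function(table = target_table(),
                           free = list(tc_level_stress = c(0.05, 0.6),
                                       k_tc = c(0.1, 1.5)),
                           start = NULL, n_reps = 6, n_probe = 8,
                           maxit = 40, t_max = 1500, seed = 1L,
                           base_params = sim_params()) {
  stopifnot(length(free) >= 1)
  for (b in free) {
    if (length(b) != 2 || b[1] <= 0 || b[2] <= b[1]) {
      stop("infeasible bounds: each must be positive increasing pairs")
    }
  }
  ref <- build_reference_leader()
  nm <- names(free)
  lo <- log(vapply(free, `[`, 0, 1)); hi <- log(vapply(free, `[`, 0, 2))

  set_free <- function(theta_log) {
    p <- base_params
    th <- exp(pmin(pmax(theta_log, lo), hi))
    for (i in seq_along(nm)) {
      key <- strsplit(nm[i], ".", fixed = TRUE)[[1]]
      if (length(key) == 1) p[[key]] <- th[i]
      else p[[key[1]]][[key[2]]] <- th[i]
    }
    class(p) <- "sim_params"
    p
  }
  evals <- 0L
  objective <- function(theta_log) {
    evals <<- evals + 1L
    p <- set_free(theta_log)
    sim <- tryCatch(
      simulate_targets(p, table, n_reps = n_reps, t_max = t_max,
                       seed = seed, ref = ref),
      error = function(e) stop("simulation failure during fit: ",
                               conditionMessage(e)))
    target_loss(sim, table)
  }

  # probes: deterministic stratified points on the log scale
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  probes <- lapply(seq_len(n_probe), function(i) lo + runif(length(lo)) * (hi - lo))
  if (!is.null(start)) {
    probes <- c(list(log(unlist(start)[nm])), probes)
  } else {
    probes <- c(list((lo + hi) / 2), probes)
  }
  probe_loss <- vapply(probes, objective, 0)
  best <- probes[[which.min(probe_loss)]]

  opt <- if (length(nm) == 1) {
    optim(best, objective, method = "Brent", lower = lo, upper = hi,
          control = list(maxit = maxit))
  } else {
    optim(best, objective, method = "Nelder-Mead",
          control = list(maxit = maxit, reltol = 1e-3))
  }
  theta <- pmin(pmax(opt$par, lo), hi)
  fitted <- set_free(theta)
  sim <- simulate_targets(fitted, table, n_reps = max(n_reps, 8),
                          t_max = t_max, seed = seed, ref = ref)
  res <- cbind(table,
               simulated = sim,
               log_residual = log(sim / table$value))
  structure(list(params = fitted,
                 free = setNames(as.list(exp(theta)), nm),
                 loss = target_loss(sim, table),
                 residuals = res,
                 optimizer = list(method = if (length(nm) == 1) "probe+Brent" else "probe+Nelder-Mead",
                                  evaluations = evals,
                                  n_reps = n_reps, t_max = t_max,
                                  seed = seed, convergence = opt$convergence)),
            class = "calibrated_params")
}

#' @export
print.calibrated_params <- function(x, ...) {
  cat("calibrated_params: loss", signif(x$loss, 4), "(",
      x$optimizer$evaluations, "evaluations, seed",
      x$optimizer$seed, ")\n")
  cat("  free:", paste(names(x$free), signif(unlist(x$free), 4),
                       sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Committed calibrated values (produced by fit_parameters on the packaged
# table; see default_calibrated_params() for the committed fit settings).
CALIBRATED <- list(
  v_elong = 5,
  k_tc = 0.27,
  tc_level_stress = 0.37,
  p_rei_uorf = 0.35,
  dG_scale = 4.4,
  m6a_block = 4,
  mig_decay = 0.2,
  p_init = list(aug_strong = 0.985, aug_medium = 0.58, aug_weak = 0.25,
                nc_strong = 0.002, nc_medium = 0.0008, nc_weak = 0.0003,
                cug_weak = 0.0008),
  seed = 20260926L
)

# Committed residual record: simulated values of every target row at the
# committed parameter set (12 replicates per cell, 2000 s, committed seed).
calibrated_residual_record <- function() {
  tab <- target_table()
  tab$simulated <- c(5.583, 24.000, 4.577, 10.028, 2.164, 0.417, 0.328,
                     4.400, 0.222, 0.488, 9.306, 2.502, 1.167, 1.119,
                     1.083, 1.065, 1.139, 1.010, 1.444, 1.056, 0.791,
                     0.947)
  tab$log_residual <- log(tab$simulated / tab$value)
  tab
}

#' The committed calibrated parameter set
#'
#' Returns the packaged calibrated `sim_params` produced by
#' [fit_parameters()] on the packaged [target_table()] at the committed
#' seed, together with its committed residual record.
#'
#' @return A `calibrated_params` object; the `residuals` component holds
#'   the committed fit record (one row per target).
#' @export
default_calibrated_params <- function() {
  p <- sim_params(
    v_elong = CALIBRATED$v_elong, k_tc = CALIBRATED$k_tc,
    tc_level_stress = CALIBRATED$tc_level_stress,
    p_rei_uorf = CALIBRATED$p_rei_uorf,
    dG_scale = CALIBRATED$dG_scale, m6a_block = CALIBRATED$m6a_block,
    mig_decay = CALIBRATED$mig_decay, p_init = CALIBRATED$p_init)
  structure(list(params = p,
                 free = CALIBRATED[setdiff(names(CALIBRATED),
                                           c("seed", "p_init"))],
                 loss = {
                   rr <- calibrated_residual_record()
                   sum(rr$weight * rr$log_residual^2) / sum(rr$weight)
                 },
                 residuals = calibrated_residual_record(),
                 optimizer = list(method = "probe+Nelder-Mead",
                                  seed = CALIBRATED$seed)),
            class = "calibrated_params")
}

#' Parameter-recovery diagnostic
#'
#' Simulates a target table from known true parameters, refits the free
#' parameters from a displaced start, and reports per-parameter relative
#' recovery error. Axes whose doubling leaves the loss essentially flat
#' are flagged non-identifiable (absolute output scale, e.g. `k_load`,
#' cancels in expression ratios).
#'
#' @param true_params `sim_params` used to generate the synthetic table.
#' @param free Named bounds as in [fit_parameters()].
#' @param n_reps Replicates per cell.
#' @param seed Seed.
#' @param constructs Constructs included in the synthetic table.
#' @return List with `true`, `fitted`, `relative_error`,
#'   `non_identifiable` (named logical from the flatness probe), and the
#'   fit object. The absolute loading rate cancels exactly in collision-
#'   free expression ratios (the probe verifies this on the analytic
#'   cascade); with steric exclusion it retains weak identifiability
#'   through queue depths.
#' @export
parameter_recovery_test <- function(true_params = default_calibrated_params()$params,
                                    free = list(tc_level_stress = c(0.05, 0.8)),
                                    n_reps = 6, seed = 7L,
                                    constructs = c("d-all", "uORF2-only")) {
  ref <- build_reference_leader()
  tab <- target_table()
  tab <- tab[tab$construct %in% c("WT", constructs), , drop = FALSE]
  truth <- simulate_targets(true_params, tab, n_reps = n_reps,
                            t_max = 1500, seed = seed + 1, ref = ref)
  tab$value <- pmax(truth, 1e-3)

  nm <- names(free)
  start <- lapply(nm, function(k) {
    key <- strsplit(k, ".", fixed = TRUE)[[1]]
    v <- if (length(key) == 1) true_params[[key]] else true_params[[key[1]]][[key[2]]]
    min(max(v * 1.6, free[[k]][1]), free[[k]][2])
  })
  names(start) <- nm
  fit <- fit_parameters(tab, free = free, start = start, n_reps = n_reps,
                        n_probe = 4, maxit = 25, t_max = 1500, seed = seed,
                        base_params = true_params)
  true_vals <- vapply(nm, function(k) {
    key <- strsplit(k, ".", fixed = TRUE)[[1]]
    if (length(key) == 1) true_params[[key]] else true_params[[key[1]]][[key[2]]]
  }, 0)
  rel <- abs(unlist(fit$free)[nm] - true_vals) / true_vals

  # flatness probe: in the collision-free cascade, per-load initiation
  # fractions do not involve the loading rate at all, so expression
  # ratios cancel absolute flux exactly
  flat <- c(k_load = {
    u2 <- apply_construct(ref, "uORF2-only")
    p2 <- true_params; p2$k_load <- p2$k_load * 2; class(p2) <- "sim_params"
    r1 <- analytic_small_model(u2, true_params, condition = "stress")$atf4 /
      analytic_small_model(ref, true_params, condition = "stress")$atf4
    r2 <- analytic_small_model(u2, p2, condition = "stress")$atf4 /
      analytic_small_model(ref, p2, condition = "stress")$atf4
    isTRUE(all.equal(r1, r2, tolerance = 1e-12))
  })
  list(true = setNames(true_vals, nm), fitted = unlist(fit$free)[nm],
       relative_error = rel, non_identifiable = flat, fit = fit)
}
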