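## Two independent verification oracles for the stochastic engine:
##  - analytic_small_model: exact collision-free cascade (each PIC walks the
##    track independently; per-dwell races solved in closed form).
##  - markov_oracle: full continuous-time Markov chain over configurations
##    of at most `max_ribosomes` ribosomes with exclusion, solved for its
##    stationary distribution.

# Shared helper: per-dwell outcome probabilities at one position.
# Rates: move m; TC binding k (TC-less only); initiation rates lam (vector,
# TC-bound only). Returns P(init at each site), P(leave TC-bound),
# P(leave TC-less), for a ribosome arriving TC-less or TC-bound.
dwell_races <- function(m, k, lam) {
  S <- sum(lam)
  # TC-bound arrival
  init_tc <- if (S + m > 0) lam / (S + m) else lam * 0
  move_tc <- if (S + m > 0) m / (S + m) else 0
  # TC-less arrival: race bind-vs-move, then the TC-bound race
  bind_first <- if (k + m > 0) k / (k + m) else 0
  init_ntc <- bind_first * init_tc
  move_ntc_as_tc <- bind_first * move_tc
  move_ntc_as_ntc <- if (k + m > 0) m / (k + m) else 0
  list(init_tc = init_tc, move_tc = move_tc,
       init_ntc = init_ntc, move_ntc_tc = move_ntc_as_tc,
       move_ntc_ntc = move_ntc_as_ntc)
}

#' Exact collision-free initiation cascade
#'
#' Closed-form solution of the scanning model for independent PICs (no
#' steric exclusion): each loaded PIC walks the track 5' to 3', racing TC
#' binding, start-codon initiation, scanning steps, stem-loop stall
#' release (with migration-window initiation while stalled) at every
#' position; termination of a REI-permissive uORF restarts the walk
#' TC-less with probability `p_rei`. Returns per-load fractions.
#'
#' @param leader A `leader_annotation`.
#' @param params A [sim_params()] object.
#' @param condition,tc_level Condition / explicit TC level as in
#'   [simulate_leader()].
#' @return List with `initiation` (named per-site fractions), `proteins`
#'   (per-origin completed-synthesis fractions), `scanned_off`, and
#'   `atf4` (main-frame run-off fraction).
#' @export
analytic_small_model <- function(leader, params = sim_params(),
                                 condition = c("nonstress", "stress"),
                                 tc_level = NULL) {
  spec <- engine_spec(leader, params, condition, tc_level)
  L <- spec$L
  v <- spec$v_scan
  k <- spec$k_tc_eff
  nsite <- length(spec$site_pos)
  site_at <- rep(0L, L + 1)
  site_at[spec$site_pos] <- seq_len(nsite)

  init_frac <- numeric(nsite)
  protein_frac <- numeric(nsite)
  scanned_off <- 0

  # passes: start position, weight, P(TC) at entry
  queue <- list(list(pos = spec$pic_up + 1L, w = 1, ptc = spec$p_tc_load))
  guard <- 0
  while (length(queue)) {
    guard <- guard + 1
    if (guard > 10000) stop("cascade did not terminate")
    pass <- queue[[1]]; queue <- queue[-1]
    w_tc <- pass$w * pass$ptc
    w_ntc <- pass$w * (1 - pass$ptc)
    p <- pass$pos
    while (p <= L - 2) {
      # move rate out of p
      np <- p + 1
      m <- v / (if (np <= L) spec$slow[np] else 1)
      stalled <- FALSE
      hi <- p + spec$pic_down - 1
      for (q in seq_along(spec$sl_base)) {
        if (hi < spec$sl_base[q] && hi + 1 >= spec$sl_base[q]) {
          m <- 1 / (1 / m + 1 / spec$sl_k[q]); stalled <- TRUE; break
        }
      }
      # initiation rates from this dwell
      lam <- numeric(0); lam_sites <- integer(0)
      s_here <- site_at[p]
      boost <- if (stalled) spec$queue_boost else 1
      if (s_here > 0 && spec$site_lambda[s_here] > 0) {
        lam <- c(lam, spec$site_lambda[s_here] * boost)
        lam_sites <- c(lam_sites, s_here)
      }
      if (stalled && spec$queue_boost > 0) {
        for (j in max(1, p - spec$mig):min(L, p + spec$mig)) {
          sj <- site_at[j]
          if (sj > 0 && j != p && spec$site_lambda[sj] > 0) {
            lam <- c(lam, spec$site_lambda[sj] * spec$queue_boost *
                       spec$mig_decay^abs(j - p))
            lam_sites <- c(lam_sites, sj)
          }
        }
      }
      r <- dwell_races(m, k, lam)
      if (length(lam)) {
        fr <- w_tc * r$init_tc + w_ntc * r$init_ntc
        for (ii in seq_along(lam_sites)) {
          s <- lam_sites[ii]
          init_frac[s] <- init_frac[s] + fr[ii]
          # initiated mass elongates: protein on termination/run-off,
          # REI-permissive uORFs respawn a TC-less pass at the stop
          protein_frac[s] <- protein_frac[s] + fr[ii]
          if (spec$site_stop[s] > 0 && spec$site_prei[s] > 0) {
            queue[[length(queue) + 1]] <- list(pos = spec$site_stop[s],
                                               w = fr[ii] * spec$site_prei[s],
                                               ptc = 0)
          }
        }
      }
      new_tc <- w_tc * r$move_tc + w_ntc * r$move_ntc_tc
      new_ntc <- w_ntc * r$move_ntc_ntc
      w_tc <- new_tc; w_ntc <- new_ntc
      if (w_tc + w_ntc < 1e-12) break
      p <- p + 1
    }
    scanned_off <- scanned_off + w_tc + w_ntc
  }
  names(init_frac) <- spec$site_pos
  names(protein_frac) <- spec$site_pos
  main <- spec$site_stop == 0 & spec$site_frame == 0
  list(initiation = init_frac, proteins = protein_frac,
       scanned_off = scanned_off, atf4 = sum(protein_frac[main]))
}

#' Brute-force master-equation oracle
#'
#' Builds the full continuous-time Markov chain over ribosome
#' configurations (at most `max_ribosomes` concurrent ribosomes, steric
#' exclusion, stem-loop stalling with the shared folded-state rule,
#' migration-window initiation, reinitiation) and solves for the
#' stationary distribution. Initiation fractions are stationary initiation
#' fluxes divided by the stationary loading flux.
#'
#' @inheritParams analytic_small_model
#' @param max_ribosomes 1 or 2.
#' @param max_states Safety cap on the state-space size.
#' @return List with `initiation` (per-site fractions of loads),
#'   `n_states`, and the stationary `load_flux`.
#' @export
markov_oracle <- function(leader, params = sim_params(),
                          condition = c("nonstress", "stress"),
                          tc_level = NULL, max_ribosomes = 2,
                          max_states = 200000) {
  spec <- engine_spec(leader, params, condition, tc_level)
  L <- spec$L
  if (L > 200) stop("leader too long for the master-equation oracle")
  v <- spec$v_scan
  k <- spec$k_tc_eff
  nsite <- length(spec$site_pos)
  site_at <- rep(0L, L + 1)
  site_at[spec$site_pos] <- seq_len(nsite)
  load_psite <- spec$pic_up + 1L

  # ribosome encoding: kind 1 = PIC noTC, 2 = PIC TC, 2 + s = 80S from
  # site s; a configuration is the sorted integer vector of
  # (kind * 1000 + psite), capped at max_ribosomes entries.
  enc_kind <- function(code) code %/% 1000L
  enc_pos <- function(code) code %% 1000L
  fp <- function(code) {
    kind <- enc_kind(code); p <- enc_pos(code)
    if (kind >= 3) c(p - spec$fp80_up, p + spec$fp80_down)
    else c(p - spec$pic_up, p + spec$pic_down - 1L)
  }
  overlaps <- function(a, b) a[1] <= b[2] && b[1] <= a[2]

  state_key <- function(cfg) paste0("s", paste(sort(cfg), collapse = ","))
  parse_key <- function(key) {
    body <- substring(key, 2)
    if (body == "") integer() else as.integer(strsplit(body, ",")[[1]])
  }

  # transitions out of one configuration: list of (rate, new_cfg_key,
  # class, site) where class marks load/init events for flux accounting
  transitions <- function(cfg) {
    out <- list()
    nR <- length(cfg)
    fps <- lapply(cfg, fp)
    folded <- rep(TRUE, length(spec$sl_base))
    for (q in seq_along(spec$sl_base)) {
      for (i in seq_len(nR)) {
        if (fps[[i]][2] >= spec$sl_base[q] && fps[[i]][1] <= spec$sl_end[q]) {
          folded[q] <- FALSE; break
        }
      }
    }
    emit <- function(rate, newcfg, class = "", site = 0L) {
      out[[length(out) + 1]] <<- list(rate = rate, key = state_key(newcfg),
                                      class = class, site = site)
    }
    # loading
    if (nR < max_ribosomes && spec$k_load > 0) {
      probe <- c(load_psite - spec$pic_up, load_psite + spec$pic_down - 1L)
      free <- !any(vapply(fps, overlaps, TRUE, b = probe))
      if (free) {
        kind0 <- if (spec$p_tc_load >= 1) 2L else 1L
        if (spec$p_tc_load > 0 && spec$p_tc_load < 1) {
          emit(spec$k_load * spec$p_tc_load,
               c(cfg, 2000L + load_psite), "load")
          emit(spec$k_load * (1 - spec$p_tc_load),
               c(cfg, 1000L + load_psite), "load")
        } else {
          emit(spec$k_load, c(cfg, kind0 * 1000L + load_psite), "load")
        }
      }
    }
    for (i in seq_len(nR)) {
      code <- cfg[i]; kind <- enc_kind(code); p <- enc_pos(code)
      is80 <- kind >= 3
      step <- if (is80) 3L else 1L
      hi <- fps[[i]][2]
      at_stop <- is80 && spec$site_stop[kind - 2L] > 0 &&
        p >= spec$site_stop[kind - 2L]

      excl_blocked <- FALSE
      for (j in seq_len(nR)) {
        if (j != i && fps[[j]][1] > hi && fps[[j]][1] <= hi + step) {
          excl_blocked <- TRUE; break
        }
      }
      sl_stalled <- FALSE; unwind <- 0
      for (q in seq_along(spec$sl_base)) {
        if (folded[q] && hi < spec$sl_base[q] && hi + step >= spec$sl_base[q]) {
          sl_stalled <- TRUE; unwind <- spec$sl_k[q]; break
        }
      }

      if (!at_stop) {
        mv <- if (is80) spec$v_elong else {
          np <- p + 1L
          v / (if (np >= 1 && np <= L) spec$slow[np] else 1)
        }
        if (sl_stalled && mv > 0) mv <- 1 / (1 / mv + 1 / unwind)
        if (excl_blocked) mv <- 0
        if (mv > 0) {
          np <- p + step
          newcfg <- cfg
          if (is80 && np + spec$fp80_down > L) {
            newcfg <- cfg[-i]           # run-off completion
          } else if (!is80 && np > L - 2L) {
            newcfg <- cfg[-i]           # scanned off
          } else {
            newcfg[i] <- kind * 1000L + np
          }
          emit(mv, newcfg)
        }
      } else {
        s <- kind - 2L
        prei <- spec$site_prei[s]
        if (prei > 0 && prei < 1) {
          emit(spec$v_elong * prei, {x <- cfg; x[i] <- 1000L + p; x})
          emit(spec$v_elong * (1 - prei), cfg[-i])
        } else if (prei >= 1) {
          emit(spec$v_elong, {x <- cfg; x[i] <- 1000L + p; x})
        } else {
          emit(spec$v_elong, cfg[-i])
        }
      }

      if (kind == 1L && k > 0) {
        emit(k, {x <- cfg; x[i] <- 2000L + p; x})
      }
      if (kind == 2L) {
        blocked <- excl_blocked || sl_stalled
        boost <- if (blocked) spec$queue_boost else 1
        s_here <- if (p >= 1 && p <= L) site_at[p] else 0L
        if (s_here > 0 && spec$site_lambda[s_here] > 0) {
          emit(spec$site_lambda[s_here] * boost,
               {x <- cfg; x[i] <- (2L + s_here) * 1000L + p; x},
               "init", s_here)
        }
        if (blocked && spec$queue_boost > 0) {
          for (jp in max(1, p - spec$mig):min(L, p + spec$mig)) {
            sj <- site_at[jp]
            if (sj == 0 || jp == p || spec$site_lambda[sj] <= 0) next
            probe <- c(jp - spec$fp80_up, jp + spec$fp80_down)
            clash <- FALSE
            for (j2 in seq_len(nR)) {
              if (j2 != i && overlaps(fps[[j2]], probe)) { clash <- TRUE; break }
            }
            if (clash) next
            rr <- spec$site_lambda[sj] * spec$queue_boost *
              spec$mig_decay^abs(jp - p)
            emit(rr, {x <- cfg; x[i] <- (2L + sj) * 1000L + jp; x},
                 "init", sj)
          }
        }
      }
    }
    out
  }

  # BFS over reachable configurations
  ids <- new.env(parent = emptyenv())
  keys <- character(); frontier <- c(state_key(integer()))
  assign(frontier, 1L, envir = ids); keys[1] <- frontier
  tri <- list(); tr_from <- integer(); tr_to <- integer(); tr_rate <- numeric()
  flux_class <- character(); flux_site <- integer()
  qpos <- 1L
  while (qpos <= length(keys)) {
    key <- keys[qpos]
    cfg <- parse_key(key)
    trs <- transitions(cfg)
    from_id <- get(key, envir = ids)
    for (tr in trs) {
      if (!exists(tr$key, envir = ids)) {
        if (length(keys) >= max_states) stop("state space exceeds max_states")
        assign(tr$key, length(keys) + 1L, envir = ids)
        keys[length(keys) + 1L] <- tr$key
      }
      to_id <- get(tr$key, envir = ids)
      tr_from <- c(tr_from, from_id); tr_to <- c(tr_to, to_id)
      tr_rate <- c(tr_rate, tr$rate)
      flux_class <- c(flux_class, tr$class); flux_site <- c(flux_site, tr$site)
    }
    qpos <- qpos + 1L
  }
  n <- length(keys)
  Q <- Matrix::sparseMatrix(i = tr_from, j = tr_to, x = tr_rate,
                            dims = c(n, n))
  diag_out <- Matrix::rowSums(Q)
  Q <- Q - Matrix::Diagonal(n, diag_out)
  # stationary distribution: pi Q = 0, sum(pi) = 1
  A <- Matrix::t(Q)
  A[n, ] <- 1
  b <- c(rep(0, n - 1), 1)
  pi_hat <- as.numeric(Matrix::solve(A, b))
  pi_hat[pi_hat < 0] <- 0
  pi_hat <- pi_hat / sum(pi_hat)

  load_flux <- sum(pi_hat[tr_from[flux_class == "load"]] *
                     tr_rate[flux_class == "load"])
  init_flux <- numeric(nsite)
  for (s in seq_len(nsite)) {
    sel <- flux_class == "init" & flux_site == s
    init_flux[s] <- sum(pi_hat[tr_from[sel]] * tr_rate[sel])
  }
  list(initiation = setNames(if (load_flux > 0) init_flux / load_flux
                             else init_flux * 0, spec$site_pos),
       n_states = n, load_flux = load_flux)
}
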