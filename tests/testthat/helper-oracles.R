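# Independent reference implementations used as oracles.  These are written
# in plain R directly from the model definitions and share no code with the
# package's compiled engines.

# ---- brute-force cellular automaton on a 2D lattice ------------------------
# states: 0 resting, 1 excited, 2 refractory; synchronous update;
# params: per-node theta, gain, E, R (matrices); active: logical matrix.
# stimuli: list of list(step, cells = 2-col matrix) firing resting cells.
# Returns per-step state history and fire log.
ca_oracle <- function(active, theta, gain, E, R, n_steps, stimuli = list(),
                      neighborhood = 4) {
  nr <- nrow(active); nc <- ncol(active)
  st <- matrix(0L, nr, nc); ph <- matrix(0L, nr, nc); e <- matrix(0, nr, nc)
  offs <- if (neighborhood == 4) {
    list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  } else {
    o <- list()
    for (a in -1:1) for (b in -1:1) if (a != 0 || b != 0) o <- c(o, list(c(a, b)))
    o
  }
  history <- vector("list", n_steps)
  fires <- list()
  for (step in 0:(n_steps - 1)) {
    for (sv in stimuli) {
      if (sv$step == step) {
        for (r in seq_len(nrow(sv$cells))) {
          i <- sv$cells[r, 1]; j <- sv$cells[r, 2]
          if (active[i, j] && st[i, j] == 0L) {
            st[i, j] <- 1L; ph[i, j] <- 0L; e[i, j] <- 0
            fires[[length(fires) + 1]] <- c(step, i, j)
          }
        }
      }
    }
    st_new <- st; ph_new <- ph
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (!active[i, j]) next
      if (st[i, j] == 0L) {
        n_exc <- 0L
        for (o in offs) {
          ii <- i + o[1]; jj <- j + o[2]
          if (ii >= 1 && jj >= 1 && ii <= nr && jj <= nc &&
              active[ii, jj] && st[ii, jj] == 1L) n_exc <- n_exc + 1L
        }
        if (n_exc > 0) e[i, j] <- e[i, j] + gain[i, j] * n_exc
        if (e[i, j] >= theta[i, j]) {
          st_new[i, j] <- 1L; ph_new[i, j] <- 0L; e[i, j] <- 0
          fires[[length(fires) + 1]] <- c(step + 1, i, j)
        }
      } else if (st[i, j] == 1L) {
        if (ph[i, j] + 1L >= E[i, j]) { st_new[i, j] <- 2L; ph_new[i, j] <- 0L }
        else ph_new[i, j] <- ph[i, j] + 1L
      } else {
        if (ph[i, j] + 1L >= R[i, j]) {
          st_new[i, j] <- 0L; ph_new[i, j] <- 0L; e[i, j] <- 0
        } else ph_new[i, j] <- ph[i, j] + 1L
      }
    }
    st <- st_new; ph <- ph_new
    history[[step + 1]] <- list(state = st, phase = ph, e = e)
  }
  list(history = history, fires = fires)
}

# ---- plain-R single-cell integrator for the point kinetics -----------------
# Forward Euler on the reaction equations only, via the exported reaction
# functions; independent of the compiled stepper.
cell_oracle <- function(params, u0, v0, dt, t_max, kick = NULL,
                        rate_fn = reaction_rogers) {
  n <- ceiling(t_max / dt)
  u <- numeric(n + 1); v <- numeric(n + 1); tt <- (0:n) * dt
  u[1] <- u0; v[1] <- v0
  for (i in seq_len(n)) {
    r <- rate_fn(u[i], v[i], params)
    u[i + 1] <- u[i] + dt * r$du_dt
    v[i + 1] <- v[i] + dt * r$dv_dt
    if (!is.null(kick) && tt[i + 1] >= kick$at &&
        tt[i + 1] <= kick$at + kick$duration)
      u[i + 1] <- kick$amplitude
  }
  tibble::tibble(time = tt, u = u, v = v)
}

# upward threshold crossings of a sampled trace
crossings <- function(time, u, thresh = 0.5) {
  idx <- which(u[-1] >= thresh & u[-length(u)] < thresh)
  time[idx + 1]
}

# flood fill connectivity (6-neighbour) for geometry tests
n_components <- function(labels) {
  d <- dim(labels)
  seen <- array(FALSE, d)
  comp <- 0L
  idx_all <- which(labels != 0L)
  for (start in idx_all) {
    if (seen[start]) next
    comp <- comp + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      k <- (cur - 1) %/% (d[1] * d[2])
      rem <- (cur - 1) %% (d[1] * d[2])
      j <- rem %/% d[1]; i <- rem %% d[1]
      for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
        ii <- i + o[1]; jj <- j + o[2]; kk <- k + o[3]
        if (ii < 0 || jj < 0 || kk < 0 || ii >= d[1] || jj >= d[2] || kk >= d[3]) next
        nb <- 1 + ii + d[1] * jj + d[1] * d[2] * kk
        if (!seen[nb] && labels[nb] != 0L) { seen[nb] <- TRUE; queue <- c(queue, nb) }
      }
    }
  }
  comp
}
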