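# Beads-on-a-string chromosome reconstruction: self-avoiding random walk
# initialisation, volume-exclusion / chromatin-tension / Hi-C restraint
# forces, damped Newtonian dynamics under Verlet integration, convergence
# diagnostics and model validation.

#' Simulation parameters for chromosome reconstruction
#'
#' Houses every physical constant and integration setting of the dynamics
#' `m a_i = -gamma v_i + F_rep + F_ten + F_hic`. The repulsion rest length
#' is tied to the bead radius (`d_rep0 = 2 r_bead`: springs engage when
#' beads overlap). The tension and Hi-C rest lengths default to the same
#' bead-contact distance but are free parameters.
#'
#' Force constants are a stability parametrisation, not measurements: the
#' defaults give an overdamped, convergent system at `dt = 0.01` for
#' chromatin-scale models (bead radius 25 nm for a 150 kb bin, so model
#' distances land in the 100-300 nm regime).
#'
#' @param m bead mass (arbitrary mass unit).
#' @param gamma nucleoplasm drag coefficient (force per velocity).
#' @param k_rep volume-exclusion spring constant.
#' @param k_ten chromatin (backbone) spring constant.
#' @param k_hic Hi-C restraint spring constant.
#' @param r_bead bead radius, nm.
#' @param c2 backbone rest length, nm.
#' @param d_hic0 Hi-C restraint rest length, nm.
#' @param dt integration time step.
#' @param n_steps number of Verlet steps per replicate.
#' @param n_replicates number of independently initialised replicates.
#' @param seed run seed; per-replicate seeds are derived from it unless
#'   `seeds` is given explicitly.
#' @param seeds optional integer vector of length `n_replicates`.
#' @param record_every record energy/RMSD diagnostics every this many steps.
#' @return a `sim_params` list; `d_rep0` is always `2 * r_bead`.
#' @export
sim_params <- function(m = 1, gamma = 0.5, k_rep = 1, k_ten = 1, k_hic = 0.3,
                       r_bead = 25, c2 = 2 * r_bead, d_hic0 = 2 * r_bead,
                       dt = 0.01, n_steps = 10000L, n_replicates = 3L,
                       seed = 1L, seeds = NULL, record_every = 100L) {
  p <- list(m = m, gamma = gamma, k_rep = k_rep, k_ten = k_ten, k_hic = k_hic,
            r_bead = r_bead, d_rep0 = 2 * r_bead, c2 = c2, d_hic0 = d_hic0,
            dt = dt, n_steps = as.integer(n_steps),
            n_replicates = as.integer(n_replicates),
            seed = as.integer(seed),
            record_every = as.integer(record_every))
  stopifnot(all(vapply(p[c("m", "gamma", "k_rep", "k_ten", "k_hic", "r_bead",
                           "d_rep0", "c2", "d_hic0", "dt")],
                       function(v) is.numeric(v) && v > 0, logical(1))),
            p$n_steps >= 1L, p$n_replicates >= 1L, p$record_every >= 1L)
  p$seeds <- if (is.null(seeds)) derive_seeds(p$seed, p$n_replicates)
             else as.integer(seeds)
  if (length(p$seeds) != p$n_replicates)
    stop_sc("need %d replicate seeds, got %d", p$n_replicates, length(p$seeds))
  class(p) <- "sim_params"
  p
}

#' Initialise a conformation as a self-avoiding random walk
#'
#' Beads are placed sequentially at fixed step length in uniformly random
#' directions; a placement is accepted only if it keeps all non-consecutive
#' bead pairs at least `exclusion` apart. A blocked walk is restarted from
#' scratch, up to `max_restarts` times.
#'
#' @param n_beads number of beads.
#' @param step_length consecutive bead spacing, nm.
#' @param exclusion minimum non-consecutive pair distance, nm; must not
#'   exceed `step_length`.
#' @param seed RNG seed (the walk is deterministic given it).
#' @param max_restarts restart budget before giving up.
#' @param max_tries direction draws per bead before declaring the walk blocked.
#' @return an `n_beads` x 3 coordinate matrix.
#' @export
init_sarw <- function(n_beads, step_length, exclusion, seed,
                      max_restarts = 100L, max_tries = 200L) {
  stopifnot(n_beads >= 1, step_length > 0)
  if (exclusion > step_length)
    stop_sc("exclusion (%g) must be <= step_length (%g)", exclusion, step_length)
  with_seed(seed, {
    for (attempt in seq_len(max_restarts)) {
      x <- matrix(0, n_beads, 3)
      ok <- TRUE
      for (i in seq_len(n_beads)[-1]) {
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          u <- stats::rnorm(3)
          u <- u / sqrt(sum(u^2))
          cand <- x[i - 1L, ] + step_length * u
          if (i > 2L) {
            d2 <- colSums((t(x[seq_len(i - 2L), , drop = FALSE]) - cand)^2)
            if (min(d2) < exclusion^2) next
          }
          x[i, ] <- cand
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) return(x)
    }
    stop_sc("self-avoiding walk failed after %d restarts; try a smaller exclusion",
            max_restarts)
  })
}

# Deterministically separate exactly coincident beads so unit vectors are
# defined; magnitude is infinitesimal on the model scale.
resolve_coincident <- function(x, eps, seed = 1L) {
  d2 <- as.matrix(stats::dist(x))^2
  diag(d2) <- Inf
  if (min(d2) > 0) return(x)
  hits <- which(d2 == 0, arr.ind = TRUE)
  hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
  message(sprintf("separating %d coincident bead pair(s) by %.3g nm",
                  nrow(hits), eps))
  with_seed(seed, {
    for (k in seq_len(nrow(hits))) {
      u <- stats::rnorm(3)
      x[hits[k, 2], ] <- x[hits[k, 2], ] + eps * u / sqrt(sum(u^2))
    }
  })
  x
}

#' Volume-exclusion force field
#'
#' Linear-elastic repulsion between any two overlapping beads: each pair
#' closer than `d_rep0` contributes `k_rep * (d - d_rep0)` along the unit
#' vector between them (negative coefficient, so the beads are pushed
#' apart). Pairs at or beyond `d_rep0` contribute nothing.
#'
#' @param conf n x 3 coordinate matrix.
#' @param p a [sim_params()].
#' @return n x 3 force matrix; rows sum to the zero vector.
#' @export
force_repulsion <- function(conf, p) {
  n <- nrow(conf)
  if (n < 2L) return(matrix(0, n, 3))
  conf <- resolve_coincident(conf, 1e-6 * p$r_bead)
  d <- as.matrix(stats::dist(conf))
  active <- d < p$d_rep0
  diag(active) <- FALSE
  if (!any(active)) return(matrix(0, n, 3))
  # F_i = sum_j c_ij (x_j - x_i) with c_ij = k (d - d0) / d on active pairs
  cmat <- matrix(0, n, n)
  cmat[active] <- p$k_rep * (d[active] - p$d_rep0) / d[active]
  cmat %*% conf - rowSums(cmat) * conf
}

#' Chromatin tension force field
#'
#' Linear-elastic springs between genomically consecutive beads with rest
#' length `c2`; end beads carry one term, interior beads two.
#'
#' @inheritParams force_repulsion
#' @return n x 3 force matrix.
#' @export
force_tension <- function(conf, p) {
  n <- nrow(conf)
  stopifnot(n >= 2L)
  conf <- resolve_coincident(conf, 1e-6 * p$r_bead)
  b <- conf[-1L, , drop = FALSE] - conf[-n, , drop = FALSE]
  len <- sqrt(rowSums(b^2))
  fb <- (p$k_ten * (len - p$c2) / len) * b      # on bead i, toward i+1
  f <- matrix(0, n, 3)
  f[-n, ] <- f[-n, ] + fb
  f[-1L, ] <- f[-1L, ] - fb
  f
}

#' Hi-C restraint force field
#'
#' One spring of rest length `d_hic0` per constraint pair (the cis pairs
#' whose interaction frequency exceeded the chosen cutoff).
#'
#' @inheritParams force_repulsion
#' @param constraints a `constraint_set` or a data.frame with 0-based
#'   columns `i`, `j`.
#' @return n x 3 force matrix.
#' @export
force_hic <- function(conf, constraints, p) {
  n <- nrow(conf)
  cons <- constraint_pairs(constraints)
  f <- matrix(0, n, 3)
  if (nrow(cons) == 0L) return(f)
  if (any(cons$i < 0 | cons$j >= n))
    stop_sc("constraint index out of range for a %d-bead model", n)
  conf <- resolve_coincident(conf, 1e-6 * p$r_bead)
  ii <- cons$i + 1L; jj <- cons$j + 1L
  b <- conf[jj, , drop = FALSE] - conf[ii, , drop = FALSE]
  len <- sqrt(rowSums(b^2))
  fb <- (p$k_hic * (len - p$d_hic0) / len) * b  # on bead i, toward j
  add <- rowsum(rbind(fb, -fb), group = c(ii, jj))
  idx <- as.integer(rownames(add))
  f[idx, ] <- f[idx, ] + add
  f
}

constraint_pairs <- function(constraints) {
  if (is.null(constraints))
    return(data.frame(i = integer(), j = integer()))
  if (inherits(constraints, "constraint_set")) constraints$constraints
  else as.data.frame(constraints)
}

total_force <- function(conf, constraints, p, f_ext = NULL) {
  f <- force_repulsion(conf, p) + force_hic(conf, constraints, p)
  if (nrow(conf) >= 2L) f <- f + force_tension(conf, p)
  if (!is.null(f_ext)) f <- f + f_ext
  f
}

#' Create a simulation state
#'
#' @param conf starting n x 3 coordinates.
#' @return a `sim_state` list: positions `x`, previous positions `x_prev`
#'   (equal to `x`, i.e. zero initial velocity), velocities `v`, `step`.
#' @export
sim_state <- function(conf) {
  stopifnot(is.matrix(conf), ncol(conf) == 3L, all(is.finite(conf)))
  structure(list(x = conf, x_prev = conf, v = conf * 0, step = 0L),
            class = "sim_state")
}

#' One Verlet step of the damped Newtonian dynamics
#'
#' Position-Verlet update of `m a = -gamma v + F_rep + F_ten + F_hic`, with
#' the velocity in the drag term estimated from successive positions,
#' `v = (x_t - x_{t-dt}) / dt`. The stored velocity after the step is the
#' same backward estimate at the new position, so the steady state of a
#' constant applied force is exactly the terminal velocity `F / gamma`.
#'
#' @param state a [sim_state()].
#' @param constraints `constraint_set`, pair data.frame, or NULL.
#' @param p a [sim_params()].
#' @param f_ext optional n x 3 external force (testing hook).
#' @return the advanced `sim_state`.
#' @export
step_verlet <- function(state, constraints, p, f_ext = NULL) {
  x <- state$x
  v <- (x - state$x_prev) / p$dt
  f <- total_force(x, constraints, p, f_ext)
  a <- (f - p$gamma * v) / p$m
  x_new <- 2 * x - state$x_prev + a * p$dt^2
  if (!all(is.finite(x_new)))
    stop_sc("non-finite coordinates at step %d; reduce dt or force constants",
            state$step + 1L)
  state$x_prev <- x
  state$x <- x_new
  state$v <- (x_new - x) / p$dt
  state$step <- state$step + 1L
  state
}

#' Pseudo-energy of a simulation state
#'
#' Sum of kinetic energy and the potential energy stored in all engaged
#' springs: repulsion pairs closer than `d_rep0`, every backbone bond, and
#' every Hi-C restraint. Monitored as the convergence indicator of a run.
#'
#' @inheritParams step_verlet
#' @return scalar energy, non-negative.
#' @export
pseudo_energy <- function(state, constraints, p) {
  x <- state$x
  n <- nrow(x)
  e <- 0.5 * p$m * sum(state$v^2)
  if (n >= 2L) {
    d <- as.matrix(stats::dist(x))
    up <- upper.tri(d)
    act <- up & d < p$d_rep0
    e <- e + 0.5 * p$k_rep * sum((d[act] - p$d_rep0)^2)
    bond <- d[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)]
    e <- e + 0.5 * p$k_ten * sum((bond - p$c2)^2)
    cons <- constraint_pairs(constraints)
    if (nrow(cons)) {
      dc <- d[cbind(cons$i + 1L, cons$j + 1L)]
      e <- e + 0.5 * p$k_hic * sum((dc - p$d_hic0)^2)
    }
  }
  e
}

#' Optimal-superposition RMSD between two conformations
#'
#' Root-mean-square deviation after removing translation and rotation by
#' the Kabsch procedure (SVD of the covariance matrix, with the proper
#' rotation branch).
#'
#' @param a,b n x 3 coordinate matrices with equal bead counts.
#' @return RMSD in nm; symmetric in its arguments.
#' @export
rmsd <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop_sc("conformations differ in shape")
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  h <- crossprod(ac, bc)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((bc - ac %*% t(rot))^2)))
}

#' Reconstruct a chromosome model from Hi-C constraints
#'
#' Runs `n_replicates` independent simulations, each initialised from a
#' distinct self-avoiding random walk, for a fixed number of Verlet steps
#' (convergence is monitored, not used as a stopping rule). Pseudo-energy
#' and RMSD-to-final-structure are recorded at the record interval.
#'
#' @param x a `cis_matrix` (constraints are then selected with `mode`), a
#'   `constraint_set`, or NULL for a free chain.
#' @param params a [sim_params()].
#' @param mode cutoff mode passed to [select_constraints()] when `x` is a
#'   `cis_matrix`.
#' @param n_beads bead count; required when it cannot be inferred from `x`.
#' @param q percentile for `mode = "percentile"`.
#' @return a `hichrom_fit`: list with `replicates` (each holding
#'   `conformation`, `metrics`, `seed`), `constraints`, `params`, `chrom`.
#' @export
reconstruct <- function(x, params = sim_params(), mode = "mean",
                        n_beads = NULL, q = 35) {
  if (inherits(x, "cis_matrix")) {
    constraints <- select_constraints(x, mode = mode, q = q)
    n_beads <- x$n_bins
    chrom <- x$chrom
  } else if (inherits(x, "constraint_set")) {
    constraints <- x
    chrom <- x$chrom
    if (is.null(n_beads)) n_beads <- max(x$constraints$i, x$constraints$j) + 1L
  } else if (is.null(x)) {
    constraints <- NULL
    chrom <- NA_character_
    if (is.null(n_beads)) stop_sc("n_beads required for a free chain")
  } else stop_sc("x must be a cis_matrix, constraint_set, or NULL")
  if (n_beads < 2L) stop_sc("need at least 2 beads")
  cons <- constraint_pairs(constraints)
  if (nrow(cons) && max(cons$i, cons$j) >= n_beads)
    stop_sc("constraints reference beads beyond n_beads = %d", n_beads)

  p <- params
  reps <- vector("list", p$n_replicates)
  for (r in seq_len(p$n_replicates)) {
    res <- try({
      conf <- init_sarw(n_beads, step_length = p$c2,
                        exclusion = min(p$d_rep0, p$c2), seed = p$seeds[r])
      st <- sim_state(conf)
      rec_steps <- seq(p$record_every, p$n_steps, by = p$record_every)
      snaps <- vector("list", length(rec_steps))
      energy <- numeric(length(rec_steps))
      k <- 0L
      for (s in seq_len(p$n_steps)) {
        st <- step_verlet(st, constraints, p)
        if (s %% p$record_every == 0L) {
          k <- k + 1L
          snaps[[k]] <- st$x
          energy[k] <- pseudo_energy(st, constraints, p)
        }
      }
      final <- st$x
      metrics <- data.frame(
        step = rec_steps,
        energy = energy,
        rmsd_to_final = vapply(snaps, rmsd, numeric(1), b = final))
      list(conformation = final, metrics = metrics, seed = p$seeds[r])
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      warn_sc("replicate %d failed: %s", r, attr(res, "condition")$message)
      res <- NULL
    }
    reps[[r]] <- res
  }
  reps <- Filter(Negate(is.null), reps)
  if (!length(reps)) stop_sc("all replicates failed")
  structure(list(replicates = reps, constraints = constraints, params = p,
                 chrom = chrom, n_beads = n_beads),
            class = "hichrom_fit")
}

#' @export
print.hichrom_fit <- function(x, ...) {
  cat(sprintf("chromosome model fit: %s, %d beads, %d replicate(s), %d constraints\n",
              x$chrom, x$n_beads, length(x$replicates),
              nrow(constraint_pairs(x$constraints))))
  for (r in seq_along(x$replicates)) {
    m <- x$replicates[[r]]$metrics
    cat(sprintf("  replicate %d (seed %d): final energy %.4g\n", r,
                x$replicates[[r]]$seed, m$energy[nrow(m)]))
  }
  invisible(x)
}

#' Validate a model against its Hi-C constraints
#'
#' Spearman rank correlation between constraint interaction frequencies
#' and model Euclidean distances (expected negative: frequent contacts sit
#' close), plus the cosine similarity between the max-normalised IF vector
#' and the max-normalised inverse-distance vector over the same pairs.
#'
#' @param conf n x 3 coordinate matrix.
#' @param constraints a `constraint_set` (with IF values) or data.frame
#'   `i`, `j`, `IF`.
#' @return list with `spearman` and `cosine`.
#' @export
validate_model <- function(conf, constraints) {
  cons <- constraint_pairs(constraints)
  if (nrow(cons) < 3L) stop_sc("need at least 3 constraints to validate")
  if (!"IF" %in% names(cons)) stop_sc("constraints carry no IF values")
  d <- sqrt(rowSums((conf[cons$j + 1L, , drop = FALSE] -
                       conf[cons$i + 1L, , drop = FALSE])^2))
  sp <- stats::cor(cons$IF, d, method = "spearman")
  a <- cons$IF / max(cons$IF)
  b <- (1 / d) / max(1 / d)
  list(spearman = sp, cosine = sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
}
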