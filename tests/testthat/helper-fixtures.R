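# Shared fixtures, generated in code at test time.

# small laminar array for unit tests
small_array <- function(n = 8, pitch = 100, top = 200) {
  laminar_array(n_contacts = n, pitch = pitch, top = top)
}

# a compact two-population scenario with well-separated rank-1 dipoles;
# recovery is near-perfect by construction, which makes it a good oracle
# for end-to-end plumbing
two_pop_scenario <- function(seed = 1, duration = 60) {
  specs <- list(
    population_spec("upper", c(150, 750), n_sources = 60, rank = 1,
                    amplitude = 1, temporal = "pulse", frequency = 60,
                    delay_ms = 2, dipole_extent = 400),
    population_spec("lower", c(850, 1450), n_sources = 60, rank = 1,
                    amplitude = 1, temporal = "burst", frequency = 30,
                    delay_ms = 8, dipole_extent = 400)
  )
  structure(list(specs = specs, geometry = column_geometry(),
                 array = laminar_array(), sigma = 0.3, dt = 0.1,
                 duration = duration, coupling = 0.3, seed = seed),
            class = "lampop_scenario")
}

# random spatiotemporal matrix of known rank
random_lowrank <- function(n, m, rank, seed = 1, noise = 0) {
  set.seed(seed)
  x <- matrix(0, n, m)
  for (k in seq_len(rank)) x <- x + outer(rnorm(n), rnorm(m))
  if (noise > 0) x <- x + noise * matrix(rnorm(n * m), n, m)
  x
}

# greedy permutation/sign matching score between recovered and true signal
# sets (rows): returns the matched |correlation| per true signal
match_abs_cor <- function(recovered, truth) {
  cc <- abs(stats::cor(t(recovered), t(truth)))
  out <- numeric(ncol(cc))
  for (s in seq_len(ncol(cc))) {
    ij <- arrayInd(which.max(cc), dim(cc))
    out[ij[2]] <- cc[ij[1], ij[2]]
    cc[ij[1], ] <- -1
    cc[, ij[2]] <- -1
  }
  out
}

# Independent brute-force enumerator for component-to-population assignment:
# recursively tries every per-component choice of (unused | population x
# sign), scores each complete assignment by per-population Pearson
# correlation of the summed maps with the references, and keeps the
# lexicographic best following population order by descending reference
# power. Deliberately written without reusing any package internals.
brute_force_assignment <- function(maps, refs) {
  k <- length(maps)
  p <- length(refs)
  ref_pow <- vapply(refs, function(r) sum((r - mean(r))^2), numeric(1))
  pop_order <- order(ref_pow, decreasing = TRUE)
  choices <- c(list(c(0, 0)),
               unlist(lapply(seq_len(p), function(i) {
                 list(c(i, 1), c(i, -1))
               }), recursive = FALSE))
  best <- NULL
  score_of <- function(asgn) {
    sapply(seq_len(p), function(i) {
      total <- 0 * maps[[1]]
      used <- FALSE
      for (c_i in seq_len(k)) {
        if (asgn[[c_i]][1] == i) {
          total <- total + asgn[[c_i]][2] * maps[[c_i]]
          used <- TRUE
        }
      }
      if (!used || stats::sd(as.vector(total)) == 0) return(0)
      stats::cor(as.vector(total), as.vector(refs[[i]]))
    })
  }
  recurse <- function(asgn, c_i) {
    if (c_i > k) {
      sc <- score_of(asgn)
      key <- sc[pop_order]
      if (is.null(best)) {
        best <<- list(score = sc, key = key)
      } else {
        cmp <- key - best$key
        nz <- which(abs(cmp) > 1e-12)
        if (length(nz) > 0 && cmp[nz[1]] > 0) {
          best <<- list(score = sc, key = key)
        }
      }
      return(invisible())
    }
    for (ch in choices) {
      asgn[[c_i]] <- ch
      recurse(asgn, c_i + 1)
    }
  }
  recurse(vector("list", k), 1)
  best$score
}
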